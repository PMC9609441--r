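#' Logistic (sigmoid) activation
#'
#' f(x) = 1 / (1 + exp(-x)), the bounded hidden-layer activation of the
#' D50(t) surrogate network.
#'
#' @param x Numeric vector or matrix.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Rectified linear unit
#'
#' g(x) = max(0, x), the output activation: a milled median size is
#' non-negative, so the surrogate is a regression with a rectified output.
#'
#' @param x Numeric vector or matrix.
#' @return Non-negative values.
#' @export
relu <- function(x) pmax(x, 0)

#' He weight initialization
#'
#' Zero-mean normal weights with variance 2 / n_in, the fan-in scaled
#' initialization suited to rectified activations.
#'
#' @param n_in,n_out Layer sizes (> 0).
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return An `n_in x n_out` weight matrix.
#' @export
he_init <- function(n_in, n_out, seed = NULL) {
  stopifnot(n_in > 0, n_out > 0)
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(n_in * n_out, mean = 0, sd = sqrt(2 / n_in)), n_in, n_out)
}

# forward pass; returns activations and pre-activations of every layer
.ann_forward <- function(W, b, X) {
  L <- length(W)
  A <- vector("list", L + 1); Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
    A[[l + 1]] <- if (l < L) sigmoid(Z[[l]]) else relu(Z[[l]])
  }
  list(A = A, Z = Z)
}

# backprop gradients of the mean squared error 1/n sum (yhat - y)^2
.ann_gradients <- function(W, b, X, Y) {
  L <- length(W)
  fw <- .ann_forward(W, b, X)
  n <- nrow(X)
  delta <- 2 * (fw$A[[L + 1]] - Y) / n * (fw$Z[[L]] > 0)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- t(fw$A[[l]]) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(W[[l]])) * fw$A[[l]] * (1 - fw$A[[l]])
  }
  list(gW = gW, gb = gb, loss = mean((fw$A[[L + 1]] - Y)^2))
}

#' Train the feed-forward D50(t) surrogate network
#'
#' A small fully connected network (sigmoid hidden layers, ReLU output)
#' trained by full-batch gradient descent with error backpropagation on the
#' squared prediction error. Times are min-max scaled to `[0, 1]` and sizes
#' scaled by the maximum observed D50. Weights follow the He initialization;
#' the output bias starts at the mean scaled target and, if the output unit
#' is inactive for most samples at initialization, the sign of the output
#' weight vector is flipped (a distribution-preserving revival under the
#' symmetric He law) so training never starts from a dead rectifier.
#'
#' @param data Data frame with columns `time_s` and `d50_um` (>= 2 rows).
#' @param layer_sizes Integer vector of layer widths including input and
#'   output, default `c(1, 8, 8, 1)`.
#' @param seed Integer seed for the weight initialization.
#' @param epochs Number of full-batch gradient steps.
#' @param learning_rate Step size of the descent.
#' @param restarts Train this many independently initialized networks
#'   (seeds `seed`, `seed + 1000`, ...) and keep the best.
#' @return An object of class `ann_surrogate` with fields `weights`,
#'   `biases`, `layer_sizes`, `scaling`, `mse_percent`, `loss_trace`, `seed`.
#' @export
train_ann <- function(data, layer_sizes = c(1, 8, 8, 1), seed = 42,
                      epochs = 20000, learning_rate = 0.05, restarts = 1) {
  stopifnot(is.data.frame(data), all(c("time_s", "d50_um") %in% names(data)))
  if (nrow(data) < 2) stop("need at least 2 training points")
  if (any(data$d50_um <= 0)) stop("d50 values must be positive")
  fits <- lapply(seq_len(restarts) - 1L, function(r)
    .train_ann_once(data, layer_sizes, seed + 1000L * r, epochs, learning_rate))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "mse_percent"))]]
  best$seed <- seed
  best
}

.train_ann_once <- function(data, layer_sizes, seed, epochs, learning_rate) {
  t_rng <- range(data$time_s)
  y_max <- max(data$d50_um)
  X <- matrix((data$time_s - t_rng[1]) / diff(t_rng), ncol = 1)
  Y <- matrix(data$d50_um / y_max, ncol = 1)
  L <- length(layer_sizes) - 1L
  set.seed(seed)
  W <- lapply(seq_len(L), function(l) he_init(layer_sizes[l], layer_sizes[l + 1]))
  b <- lapply(seq_len(L), function(l) rep(0, layer_sizes[l + 1]))
  b[[L]] <- rep(mean(Y), layer_sizes[L + 1])
  if (mean(.ann_forward(W, b, X)$Z[[L]] > 0) < 0.5) W[[L]] <- -W[[L]]
  trace_at <- unique(c(1, seq(0, epochs, by = max(1, epochs %/% 100))[-1]))
  loss_trace <- numeric(0)
  for (ep in seq_len(epochs)) {
    g <- .ann_gradients(W, b, X, Y)
    if (!is.finite(g$loss))
      stop("training diverged (loss is not finite); reduce learning_rate")
    for (l in seq_len(L)) {
      W[[l]] <- W[[l]] - learning_rate * g$gW[[l]]
      b[[l]] <- b[[l]] - learning_rate * g$gb[[l]]
    }
    if (ep %in% trace_at) loss_trace <- c(loss_trace, g$loss)
  }
  pred <- .ann_forward(W, b, X)$A[[L + 1]] * y_max
  structure(list(weights = W, biases = b, layer_sizes = layer_sizes,
                 scaling = list(t_min = t_rng[1], t_max = t_rng[2], y_max = y_max),
                 mse_percent = relative_mse(as.numeric(pred), data$d50_um),
                 loss_trace = loss_trace, epochs = epochs,
                 learning_rate = learning_rate, seed = seed, data = data),
            class = "ann_surrogate")
}

#' @export
print.ann_surrogate <- function(x, ...) {
  cat("ann_surrogate:", paste(x$layer_sizes, collapse = "-"),
      "network, sigmoid hidden / ReLU output\n")
  cat(sprintf("  trained %d epochs (lr %.3g, seed %d); training MSE %.3g %%\n",
              x$epochs, x$learning_rate, x$seed, x$mse_percent))
  invisible(x)
}

#' @export
predict.ann_surrogate <- function(object, times, extrapolate = FALSE, ...) {
  s <- object$scaling
  if (!extrapolate && (any(times < s$t_min) || any(times > s$t_max)))
    stop("requested times outside the training span; set extrapolate = TRUE ",
         "to override")
  X <- matrix((times - s$t_min) / (s$t_max - s$t_min), ncol = 1)
  L <- length(object$weights)
  as.numeric(.ann_forward(object$weights, object$biases, X)$A[[L + 1]]) * s$y_max
}

#' @export
plot.ann_surrogate <- function(x, ...) {
  tt <- seq(x$scaling$t_min, x$scaling$t_max, length.out = 200)
  graphics::plot(x$data$time_s, x$data$d50_um, xlab = "time (s)",
                 ylab = "D50 (um)", ...)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Polynomial regression surrogate of the D50(t) profile
#'
#' Ordinary least-squares fit of D50 against time with a raw polynomial
#' basis.
#'
#' @param data Data frame with columns `time_s` and `d50_um`.
#' @param order Polynomial order (>= 1, < number of distinct times).
#' @return An object of class `poly_surrogate` with the `lm` fit,
#'   `coefficients` and training `mse_percent`.
#' @export
polyfit_profile <- function(data, order = 2) {
  stopifnot(is.data.frame(data), all(c("time_s", "d50_um") %in% names(data)))
  n_distinct <- length(unique(data$time_s))
  if (order < 1) stop("order must be >= 1")
  if (order >= n_distinct)
    stop("order too high: need more distinct times than the order")
  fit <- stats::lm(d50_um ~ poly(time_s, degree = order, raw = TRUE), data = data)
  structure(list(fit = fit, order = order,
                 coefficients = unname(stats::coef(fit)),
                 mse_percent = relative_mse(stats::fitted(fit), data$d50_um),
                 t_range = range(data$time_s), data = data),
            class = "poly_surrogate")
}

#' @export
print.poly_surrogate <- function(x, ...) {
  cat(sprintf("poly_surrogate: order-%d fit, training MSE %.3g %%\n",
              x$order, x$mse_percent))
  invisible(x)
}

#' @export
predict.poly_surrogate <- function(object, times, extrapolate = FALSE, ...) {
  if (!extrapolate && (any(times < object$t_range[1]) || any(times > object$t_range[2])))
    stop("requested times outside the training span; set extrapolate = TRUE ",
         "to override")
  as.numeric(stats::predict(object$fit, newdata = data.frame(time_s = times)))
}

#' Augment a sparse D50(t) data set into a dense reference profile
#'
#' Evaluates a trained surrogate (network or polynomial) on a dense time
#' grid; negative predictions are floored at zero since a size cannot be
#' negative.
#'
#' @param model An `ann_surrogate` or `poly_surrogate`.
#' @param t_grid Evaluation times, s.
#' @param extrapolate Allow evaluation outside the training span.
#' @return A data frame of class `surrogate_profile` with columns `time_s`
#'   and `d50_um`; the surrogate's training MSE and method are attached as
#'   attributes `mse_percent` and `method`.
#' @export
augment_profile <- function(model, t_grid, extrapolate = FALSE) {
  pred <- pmax(predict(model, t_grid, extrapolate = extrapolate), 0)
  out <- data.frame(time_s = t_grid, d50_um = pred)
  class(out) <- c("surrogate_profile", "data.frame")
  attr(out, "mse_percent") <- model$mse_percent
  attr(out, "method") <- if (inherits(model, "ann_surrogate")) "ann"
    else paste0("polynomial(", model$order, ")")
  out
}
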