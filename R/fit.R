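#' Relative mean squared error in percent
#'
#' The repo-wide goodness-of-fit metric for D50 profiles:
#' 100 * mean((pred - obs)^2) / ref^2 with `ref = 1` um by default, i.e. the
#' plain mean squared error on the micrometre scale expressed in percent.
#' This normalization reproduces the percent-MSE scale on which milling
#' surrogate and breakage fits are conventionally reported. A scale-invariant
#' variant normalizing by the mean square of the observations is available
#' via `normalize = "mean_square"`.
#'
#' @param pred Predicted values.
#' @param obs Observed values (same length).
#' @param normalize `"unit"` (default) or `"mean_square"`.
#' @param ref Reference scale for `normalize = "unit"` (default 1).
#' @return Relative MSE in percent.
#' @examples
#' relative_mse(c(1, 2), c(1, 2))        # 0
#' relative_mse(1.1 * c(1, 2), c(1, 2), normalize = "mean_square")  # 1
#' @export
relative_mse <- function(pred, obs, normalize = c("unit", "mean_square"), ref = 1) {
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  normalize <- match.arg(normalize)
  denom <- if (normalize == "unit") ref^2 else {
    ms <- mean(obs^2)
    if (ms == 0) stop("obs must not be all zero for mean-square normalization")
    ms
  }
  100 * mean((pred - obs)^2) / denom
}

# parameter-space description per family: transformed coordinates used by the
# optimizer (rate constants on log10 scale)
.fit_space <- function(family) {
  switch(family,
    de_vegt = list(names = "log10_c", lower = NA, upper = NA),
    austin = list(names = c("phi", "gamma_b", "beta", "log10_a", "d"),
                  lower = c(0, 0.1, 0.1, -8, 0),
                  upper = c(1, 8, 8, -1, 3)),
    kapur = list(names = c("e", "k", "log10_A"),
                 lower = c(0.1, 0, -8),
                 upper = c(8, 3, -1)),
    stop("unknown breakage family: ", family))
}

.par_to_model <- function(family, par, x_crit = NULL, b_exponent = 1.25) {
  switch(family,
    de_vegt = devegt_model(10^par[["log10_c"]], b_exponent = b_exponent),
    austin = austin_model(par[["phi"]], par[["gamma_b"]], par[["beta"]],
                          10^par[["log10_a"]], par[["d"]], x_crit = x_crit),
    kapur = kapur_model(par[["e"]], par[["k"]], 10^par[["log10_A"]]))
}

#' Fit a breakage model to a reference D50(t) profile
#'
#' Estimates the tuning parameters of a breakage family by minimizing the
#' relative MSE between the simulated and the reference median-size profile
#' (maximum likelihood under i.i.d. Gaussian residuals reduces to this least
#' squares problem). The scalar de Vegt constant is found by golden-section
#' search on its logarithm over an automatically scaled bracket; the Austin
#' and Kapur families use bounded quasi-Newton descent from a fixed
#' Latin-hypercube multistart, so the fit is deterministic given `seed`.
#'
#' @param family `"de_vegt"`, `"austin"` or `"kapur"`.
#' @param reference Data frame with columns `time_s` and `d50_um`
#'   (>= 3 points).
#' @param psd0 Initial [psd].
#' @param mech A [material_mechanics] record.
#' @param bounds Optional list with `lower`/`upper` replacing the default
#'   transformed-parameter bounds.
#' @param n_starts Number of Latin-hypercube starts (Austin/Kapur).
#' @param seed Integer seed fixing the multistart design.
#' @param fix Named list of tuning parameters to hold fixed (natural names,
#'   e.g. `list(phi = 0.3)`; rate constants on their natural scale).
#' @param extra_starts Optional matrix of additional start points in the
#'   transformed parameter space (one row per start).
#' @param b_exponent de Vegt cumulative-distribution exponent.
#' @param rtol,atol Solver tolerances passed to [simulate_milling()].
#' @return An object of class `breakage_fit`.
#' @export
fit_breakage <- function(family = c("de_vegt", "austin", "kapur"), reference,
                         psd0, mech = material_mechanics(), bounds = NULL,
                         n_starts = 8, seed = 1, fix = list(),
                         extra_starts = NULL, b_exponent = 1.25,
                         rtol = 1e-8, atol = 1e-12) {
  family <- match.arg(family)
  stopifnot(is.data.frame(reference), all(c("time_s", "d50_um") %in% names(reference)))
  if (nrow(reference) < 3) stop("reference profile needs at least 3 points")
  reference <- reference[order(reference$time_s), ]
  t_ref <- reference$time_s
  sim_times <- sort(unique(c(0, t_ref)))
  idx <- match(t_ref, sim_times)
  x_crit <- psd0$grid$edges[psd0$grid$n + 1]
  n_eval <- 0L

  sim_d50 <- function(model) {
    res <- simulate_milling(psd0, model, mech, times = sim_times,
                            rtol = rtol, atol = atol)
    res$d50_um[idx]
  }
  objective <- function(par_named) {
    n_eval <<- n_eval + 1L
    model <- .par_to_model(family, par_named, x_crit, b_exponent)
    tryCatch(relative_mse(sim_d50(model), reference$d50_um),
             error = function(e) 1e6)
  }

  space <- .fit_space(family)
  if (family == "de_vegt") {
    # auto-scaled bracket: the constant that makes the fastest bin turn over
    # once per reference horizon sits mid-bracket
    s1 <- max(devegt_rate(psd0$grid, 1, mech))
    mid <- log10(1 / (s1 * max(t_ref)))
    lo <- if (is.null(bounds)) mid - 4 else bounds$lower
    hi <- if (is.null(bounds)) mid + 4 else bounds$upper
    op <- stats::optimize(function(l) objective(c(log10_c = l)), c(lo, hi),
                          tol = 1e-5)
    best_par <- c(log10_c = op$minimum)
    best_val <- op$objective
    starts <- data.frame(log10_c = op$minimum, mse_percent = op$objective)
    converged <- TRUE
  } else {
    lower <- if (is.null(bounds)) space$lower else bounds$lower
    upper <- if (is.null(bounds)) space$upper else bounds$upper
    names(lower) <- names(upper) <- space$names
    fixed_tr <- .fix_to_transformed(family, fix)
    free <- setdiff(space$names, names(fixed_tr))
    if (length(free) == 0) stop("no free parameters left to fit")
    assemble <- function(p_free) {
      p <- c(p_free, fixed_tr)
      p[space$names]
    }
    set.seed(seed)
    X <- lhs::randomLHS(n_starts, length(free))
    starts_mat <- sweep(sweep(X, 2, upper[free] - lower[free], "*"),
                        2, lower[free], "+")
    colnames(starts_mat) <- free
    if (!is.null(extra_starts)) {
      es <- as.matrix(extra_starts)[, free, drop = FALSE]
      es <- pmin(pmax(es, matrix(lower[free], nrow(es), length(free), byrow = TRUE)),
                 matrix(upper[free], nrow(es), length(free), byrow = TRUE))
      starts_mat <- rbind(starts_mat, es)
    }
    best_val <- Inf; best_par <- NULL; converged <- FALSE
    rows <- vector("list", nrow(starts_mat))
    for (r in seq_len(nrow(starts_mat))) {
      p0 <- starts_mat[r, ]
      v0 <- objective(assemble(p0))
      o <- tryCatch(
        stats::optim(p0, function(p) objective(assemble(stats::setNames(p, free))),
                     method = "L-BFGS-B", lower = lower[free], upper = upper[free],
                     control = list(maxit = 300, factr = 1e9)),
        error = function(e) NULL)
      # keep the better of the start itself and the descent end point, so a
      # warm start can never be degraded by the optimizer
      cand_val <- if (is.null(o)) v0 else min(o$value, v0)
      cand_par <- if (is.null(o) || v0 <= o$value) p0 else stats::setNames(o$par, free)
      rows[[r]] <- data.frame(t(p0), mse_percent = cand_val)
      if (cand_val < best_val) {
        best_val <- cand_val
        best_par <- assemble(cand_par)
        converged <- converged || (!is.null(o) && o$convergence == 0)
      }
    }
    if (!is.finite(best_val)) stop("all optimization starts failed")
    starts <- do.call(rbind, rows)
  }

  model <- .par_to_model(family, best_par, x_crit, b_exponent)
  fitted_profile <- data.frame(time_s = t_ref, d50_um = sim_d50(model))
  structure(list(model = model, family = family, mse_percent = best_val,
                 converged = converged, n_evaluations = n_eval,
                 par = best_par, reference = reference, fitted = fitted_profile,
                 starts = starts, seed = seed, psd0 = psd0, mech = mech,
                 b_exponent = b_exponent),
            class = "breakage_fit")
}

# map natural-scale fixed parameters onto the transformed optimizer space
.fix_to_transformed <- function(family, fix) {
  if (length(fix) == 0) return(numeric(0))
  out <- numeric(0)
  for (nm in names(fix)) {
    val <- fix[[nm]]
    tr <- switch(paste(family, nm),
      "austin a" = c(log10_a = log10(val)),
      "kapur A" = c(log10_A = log10(val)),
      stats::setNames(val, nm))
    out <- c(out, tr)
  }
  out
}

#' @export
print.breakage_fit <- function(x, ...) {
  cat("breakage_fit:", x$family, "family\n")
  cat(sprintf("  relative MSE = %.4g %% over %d reference points (%d evaluations)\n",
              x$mse_percent, nrow(x$reference), x$n_evaluations))
  print(x$model)
  invisible(x)
}

#' @export
summary.breakage_fit <- function(object, ...) {
  cat("Breakage model fit (", object$family, ")\n", sep = "")
  cat(sprintf("  reference points : %d\n", nrow(object$reference)))
  cat(sprintf("  relative MSE     : %.4g %%\n", object$mse_percent))
  cat(sprintf("  converged        : %s\n", object$converged))
  cat(sprintf("  objective calls  : %d\n", object$n_evaluations))
  cat("  tuning parameters:\n")
  print(coef(object))
  invisible(object)
}

#' @export
coef.breakage_fit <- function(object, ...) {
  p <- object$model$params
  unlist(p[!vapply(p, is.null, TRUE)])
}

#' @export
fitted.breakage_fit <- function(object, ...) object$fitted$d50_um

#' @export
residuals.breakage_fit <- function(object, ...)
  object$fitted$d50_um - object$reference$d50_um

#' Predict the D50 profile of a fitted breakage model
#'
#' @param object A `breakage_fit`.
#' @param times Output times, s (0 is prepended internally).
#' @param ... Unused.
#' @return Data frame with `time_s` and `d50_um`.
#' @export
predict.breakage_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$reference$time_s
  sim_times <- sort(unique(c(0, times)))
  res <- simulate_milling(object$psd0, object$model, object$mech, times = sim_times)
  data.frame(time_s = times, d50_um = res$d50_um[match(times, sim_times)])
}

#' @export
plot.breakage_fit <- function(x, ...) {
  dense <- predict(x, seq(0, max(x$reference$time_s), length.out = 100))
  graphics::plot(x$reference$time_s, x$reference$d50_um, xlab = "time (s)",
                 ylab = "D50 (um)", ...)
  graphics::lines(dense$time_s, dense$d50_um)
  invisible(x)
}

#' Fit and compare the three breakage families
#'
#' Fits the de Vegt, Kapur and Austin families against the same reference
#' profile. The families are nested (the de Vegt kernel is the Kapur kernel
#' with e = 1.25 and k = 3/4; the Kapur kernel is the Austin kernel with
#' phi = 1), so each richer family is additionally warm-started from the
#' simpler family's optimum: the fitted MSEs are then guaranteed to be
#' ordered Austin <= Kapur <= de Vegt.
#'
#' @inheritParams fit_breakage
#' @return An object of class `breakage_comparison`: `fits` (named list of
#'   [fit_breakage] results) and `table` (data.frame with family,
#'   n_tuning_parameters, mse_percent, ordered by fit quality).
#' @export
compare_breakage <- function(reference, psd0, mech = material_mechanics(),
                             n_starts = 8, seed = 1, b_exponent = 1.25) {
  fit_dv <- fit_breakage("de_vegt", reference, psd0, mech, seed = seed,
                         b_exponent = b_exponent)
  # de Vegt equivalent in Kapur coordinates: same cumulative distribution
  # exponent, rate S = c_eff * x_um^(3/4)
  s_dv <- devegt_rate(psd0$grid, fit_dv$model$params$c_rate, mech)
  c_eff <- s_dv[1] / (psd0$grid$x[1] * 1e6)^0.75
  ws_kapur <- matrix(c(b_exponent, 0.75, log10(c_eff)), nrow = 1,
                     dimnames = list(NULL, c("e", "k", "log10_A")))
  fit_kp <- fit_breakage("kapur", reference, psd0, mech, n_starts = n_starts,
                         seed = seed, extra_starts = ws_kapur)
  # Kapur equivalent in Austin coordinates: phi = 1, gamma = e, d = k,
  # a = A * x_crit_um^k (Austin normalizes the size by x_crit)
  pk <- fit_kp$model$params
  xc_um <- psd0$grid$edges[psd0$grid$n + 1] * 1e6
  ws_austin <- matrix(c(1, pk$e, pk$e, log10(pk$A * xc_um^pk$k), pk$k), nrow = 1,
                      dimnames = list(NULL, c("phi", "gamma_b", "beta", "log10_a", "d")))
  fit_au <- fit_breakage("austin", reference, psd0, mech, n_starts = n_starts,
                         seed = seed, extra_starts = ws_austin)
  fits <- list(de_vegt = fit_dv, kapur = fit_kp, austin = fit_au)
  tab <- data.frame(
    family = c("austin", "kapur", "de_vegt"),
    n_tuning_parameters = c(5L, 3L, 1L),
    mse_percent = c(fit_au$mse_percent, fit_kp$mse_percent, fit_dv$mse_percent))
  tab <- tab[order(tab$mse_percent), ]
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab), class = "breakage_comparison")
}

#' @export
print.breakage_comparison <- function(x, ...) {
  cat("Breakage family comparison (relative MSE, %):\n")
  print(x$table)
  invisible(x)
}
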