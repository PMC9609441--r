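#' Material mechanics of the milled particles
#'
#' Mechanical and energetic parameters entering the de Vegt breakage rate.
#' The default record holds literature-typical placeholder values for a
#' small-molecule crystalline drug such as itraconazole; because the de Vegt
#' rate is linear in its tuning constant, only the product of the constant
#' with these parameters is identifiable from milling data, and fits report
#' the effective rate constant.
#'
#' @param rho Particle density, kg m^-3.
#' @param hardness Particle hardness H, Pa.
#' @param yield_pressure Yield pressure P_y, Pa.
#' @param k1c Stress intensity factor, Pa m^(1/2).
#' @param delta_solubility Solubility parameter delta, Pa^(1/2).
#' @param poisson Poisson's ratio (0 < v < 0.5).
#' @param young Young's modulus, Pa.
#' @param v0 Unit crystal volume, m^3.
#' @param wm_kin Mass-specific impact energy, J kg^-1.
#' @param mill_volume Mill chamber volume, m^3 (default 48 mL).
#' @return An object of class `material_mechanics`.
#' @export
material_mechanics <- function(rho = 1270, hardness = 5e8, yield_pressure = 1e8,
                               k1c = 1e5, delta_solubility = 2e4, poisson = 0.3,
                               young = 5e9, v0 = 1e-27, wm_kin = 100,
                               mill_volume = 48e-6) {
  vals <- c(rho, hardness, yield_pressure, k1c, delta_solubility,
            poisson, young, v0, wm_kin, mill_volume)
  if (any(vals <= 0)) stop("all mechanics parameters must be strictly positive")
  if (poisson >= 0.5) stop("poisson must lie in (0, 0.5)")
  structure(list(rho = rho, hardness = hardness, yield_pressure = yield_pressure,
                 k1c = k1c, delta_solubility = delta_solubility, poisson = poisson,
                 young = young, v0 = v0, wm_kin = wm_kin, mill_volume = mill_volume),
            class = "material_mechanics")
}

#' Kinetic energy of the particles in a size interval
#'
#' E_kin = W_m,kin * rho * V_i: mass-specific impact energy times particle
#' mass.
#'
#' @param wm_kin Mass-specific impact energy, J kg^-1 (>= 0).
#' @param rho Particle density, kg m^-3 (>= 0).
#' @param vi Particle volume, m^3 (>= 0).
#' @return Kinetic energy, J.
#' @export
kinetic_energy <- function(wm_kin, rho, vi) {
  if (any(c(wm_kin, rho, vi) < 0)) stop("inputs must be non-negative")
  wm_kin * rho * vi
}

#' Fracture energy density of a size interval
#'
#' E_fract = 0.896 (pi (1 - v^2) / Y)^(2/3) (0.0183 delta^2 (V0/Vi)^(1/4))^(5/3).
#' Scales with particle volume as Vi^(-5/12): finer particles are harder to
#' fracture.
#'
#' @param poisson Poisson's ratio.
#' @param young Young's modulus, Pa (> 0).
#' @param delta Solubility parameter, Pa^(1/2).
#' @param v0 Unit crystal volume, m^3.
#' @param vi Particle volume, m^3 (> 0).
#' @return Fracture energy density, J m^-3.
#' @export
fracture_energy <- function(poisson, young, delta, v0, vi) {
  if (any(vi <= 0)) stop("vi must be > 0")
  if (young <= 0) stop("young must be > 0")
  0.896 * (pi * (1 - poisson^2) / young)^(2 / 3) *
    (0.0183 * delta^2 * (v0 / vi)^(1 / 4))^(5 / 3)
}

#' de Vegt breakage rate over a size grid
#'
#' S(i) = c E_kin,i E_fract,i P_y / (rho V H x_i K_1C), evaluated at the
#' representative size of each interval with spherical particle volumes.
#' The rate is linear in the tuning constant `c`; the mechanics record fixes
#' the remaining factors, so `c` acts as the single effective rate constant.
#' The net size dependence is x^(3 - 5/4 - 1) = x^(3/4).
#'
#' @param grid A [size_grid].
#' @param c_rate Tuning constant (>= 0, dimensionless).
#' @param mech A [material_mechanics] record.
#' @return Breakage rate vector, s^-1, one entry per bin.
#' @export
devegt_rate <- function(grid, c_rate, mech = material_mechanics()) {
  if (c_rate < 0) stop("c_rate must be >= 0")
  vi <- pi / 6 * grid$x^3
  ekin <- kinetic_energy(mech$wm_kin, mech$rho, vi)
  efract <- fracture_energy(mech$poisson, mech$young, mech$delta_solubility,
                            mech$v0, vi)
  c_rate * ekin * efract * mech$yield_pressure /
    (mech$rho * mech$mill_volume * mech$hardness * grid$x * mech$k1c)
}

#' Cumulative de Vegt breakage distribution
#'
#' B(xi; xj) = (xi/xj)^p: the mass fraction of fragments from a particle of
#' size xj that are finer than xi. The exponent defaults to 1.25, the value
#' obtained by combining the de Vegt distribution and rate laws, but is
#' exposed because dimensional analysis of the underlying rate yields 0.75
#' (see the methods vignette).
#'
#' @param xi Fragment size, m (0 < xi <= xj).
#' @param xj Parent size, m.
#' @param exponent Power-law exponent (default 1.25).
#' @return Cumulative fragment mass fraction in `[0, 1]`.
#' @export
devegt_cumulative_b <- function(xi, xj, exponent = 1.25) {
  if (any(xi <= 0) || any(xj <= 0)) stop("sizes must be positive")
  if (any(xi > xj)) stop("xi must not exceed xj")
  (xi / xj)^exponent
}

#' Cumulative Austin breakage distribution
#'
#' B(xi; xj) = phi (xi/xj)^gamma + (1 - phi) (xi/xj)^beta, a two-population
#' power law mixing a fine-fragment mode (gamma) and a coarse-fragment mode
#' (beta).
#'
#' @param xi Fragment size, m (0 < xi <= xj).
#' @param xj Parent size, m.
#' @param phi Mixing fraction in `[0, 1]`.
#' @param gamma_b,beta Power-law exponents (> 0).
#' @return Cumulative fragment mass fraction.
#' @export
austin_cumulative_b <- function(xi, xj, phi, gamma_b, beta) {
  if (any(xi <= 0) || any(xj <= 0)) stop("sizes must be positive")
  if (any(xi > xj)) stop("xi must not exceed xj")
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  r <- xi / xj
  phi * r^gamma_b + (1 - phi) * r^beta
}

#' Austin breakage rate
#'
#' S(x) = a (x / x_crit)^d for x >= x_crit and exactly 0 below the critical
#' size, the size under which no further breakage occurs.
#'
#' @param xi Particle size, m.
#' @param a Rate constant, s^-1 (>= 0).
#' @param d Size exponent.
#' @param x_crit Critical size, m (> 0).
#' @return Breakage rate, s^-1.
#' @export
austin_rate <- function(xi, a, d, x_crit) {
  if (a < 0) stop("a must be >= 0")
  if (x_crit <= 0) stop("x_crit must be > 0")
  ifelse(xi >= x_crit, a * (xi / x_crit)^d, 0)
}

#' Cumulative Kapur breakage distribution
#'
#' B(xi; xj) = (xi/xj)^e; with e = 1.25 this coincides with the de Vegt
#' distribution.
#'
#' @param xi Fragment size, m (0 < xi <= xj).
#' @param xj Parent size, m.
#' @param e Power-law exponent.
#' @return Cumulative fragment mass fraction.
#' @export
kapur_cumulative_b <- function(xi, xj, e) {
  if (any(xi <= 0) || any(xj <= 0)) stop("sizes must be positive")
  if (any(xi > xj)) stop("xi must not exceed xj")
  (xi / xj)^e
}

#' Kapur breakage rate
#'
#' S(x) = A x^k with the size expressed in micrometres, the scale on which
#' the rate constant A (s^-1) is conventionally reported.
#'
#' @param xi Particle size, m.
#' @param A Rate constant, s^-1 (>= 0).
#' @param k Size exponent.
#' @return Breakage rate, s^-1.
#' @export
kapur_rate <- function(xi, A, k) {
  if (any(xi <= 0)) stop("sizes must be positive")
  if (A < 0) stop("A must be >= 0")
  A * (xi * 1e6)^k
}

#' Breakage model specification
#'
#' Constructors for the three breakage kernel families used by the
#' population balance: the single-constant de Vegt model, the five-parameter
#' Austin model and the three-parameter Kapur model.
#'
#' @param c_rate de Vegt tuning constant (>= 0).
#' @param b_exponent Cumulative-distribution exponent of the de Vegt model.
#' @param phi,gamma_b,beta Austin distribution parameters.
#' @param a,d Austin rate parameters (a in s^-1).
#' @param x_crit Austin critical size, m; `NULL` defaults to the finest grid
#'   edge when the operator is assembled.
#' @param e Kapur distribution exponent.
#' @param k Kapur rate exponent.
#' @param A Kapur rate constant, s^-1.
#' @return An object of class `breakage_model` with a `family` field.
#' @name breakage_model
NULL

#' @rdname breakage_model
#' @export
devegt_model <- function(c_rate, b_exponent = 1.25) {
  if (c_rate < 0) stop("c_rate must be >= 0")
  structure(list(family = "de_vegt",
                 params = list(c_rate = c_rate, b_exponent = b_exponent)),
            class = "breakage_model")
}

#' @rdname breakage_model
#' @export
austin_model <- function(phi, gamma_b, beta, a, d, x_crit = NULL) {
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  if (a < 0) stop("a must be >= 0")
  structure(list(family = "austin",
                 params = list(phi = phi, gamma_b = gamma_b, beta = beta,
                               a = a, d = d, x_crit = x_crit)),
            class = "breakage_model")
}

#' @rdname breakage_model
#' @export
kapur_model <- function(e, k, A) {
  if (A < 0) stop("A must be >= 0")
  structure(list(family = "kapur", params = list(e = e, k = k, A = A)),
            class = "breakage_model")
}

#' @export
print.breakage_model <- function(x, ...) {
  cat("breakage_model:", x$family, "\n")
  p <- x$params[!vapply(x$params, is.null, TRUE)]
  cat(paste0("  ", names(p), " = ", vapply(p, format, "")), sep = "\n")
  invisible(x)
}

#' Discretize a cumulative breakage distribution onto a grid
#'
#' Builds the lower-triangular breakage-fraction matrix b(i, j): the
#' cumulative distribution B(x; x_j) is differenced across the edges of each
#' receiving bin i > j. Fragments coarser than the first receiving bin's
#' upper edge (but finer than the parent) are assigned to bin j + 1, and the
#' finest bin absorbs the sub-grid tail, so every source column sums to
#' exactly 1 and mass is conserved by construction.
#'
#' @param B Cumulative distribution `function(xi, xj)`, monotone
#'   non-decreasing in `xi` with B(xj; xj) = 1.
#' @param grid A [size_grid].
#' @return An `n x n` lower-triangular matrix with unit column sums for
#'   columns 1..n-1.
#' @export
discretize_breakage <- function(B, grid) {
  n <- grid$n
  edges <- grid$edges
  b <- matrix(0, n, n)
  for (j in seq_len(n - 1)) {
    xj <- grid$x[j]
    # inner edges separating the receiving bins j+1 .. n
    vals <- if (j + 2 <= n) B(edges[(j + 2):n], xj) else numeric(0)
    if (any(diff(vals) > 1e-12))
      stop("cumulative breakage distribution is not monotone in xi")
    hi <- c(1, vals)   # top tail (between the parent and its bin floor) -> bin j+1
    lo <- c(vals, 0)   # sub-grid tail -> finest bin
    b[(j + 1):n, j] <- hi - lo
  }
  b
}

#' Assemble the breakage operator of a model on a grid
#'
#' Evaluates the family's breakage rate at every representative size and
#' discretizes its cumulative fragment distribution. The finest bin acts as
#' a sink (its rate is forced to zero) so no mass ever leaves the grid.
#'
#' @param model A [breakage_model].
#' @param grid A [size_grid].
#' @param mech A [material_mechanics] record (used by the de Vegt family).
#' @return An object of class `breakage_operator` with fields `S` (s^-1) and
#'   `b` (lower-triangular fraction matrix).
#' @export
breakage_operator <- function(model, grid, mech = material_mechanics()) {
  stopifnot(inherits(model, "breakage_model"), inherits(grid, "size_grid"))
  p <- model$params
  op <- switch(model$family,
    de_vegt = list(
      S = devegt_rate(grid, p$c_rate, mech),
      b = discretize_breakage(function(xi, xj)
        devegt_cumulative_b(xi, xj, p$b_exponent), grid)),
    austin = {
      xc <- if (is.null(p$x_crit)) grid$edges[grid$n + 1] else p$x_crit
      list(S = austin_rate(grid$x, p$a, p$d, xc),
           b = discretize_breakage(function(xi, xj)
             austin_cumulative_b(xi, xj, p$phi, p$gamma_b, p$beta), grid))
    },
    kapur = list(
      S = kapur_rate(grid$x, p$A, p$k),
      b = discretize_breakage(function(xi, xj)
        kapur_cumulative_b(xi, xj, p$e), grid)),
    stop("unknown breakage family: ", model$family)
  )
  op$S[grid$n] <- 0   # finest bin is a sink
  structure(list(S = op$S, b = op$b, grid = grid, model = model),
            class = "breakage_operator")
}
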