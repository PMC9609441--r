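#' Spray dryer configuration
#'
#' Operating inputs of the drying chamber and the feed. Equipment defaults
#' follow the bench-scale run the package models: 110 degC drying air at
#' 800 L h^-1, 5 bar atomization pressure, a 5 L chamber and a 1 h run. The
#' feed defaults describe the milled suspension: 1.75 g solids (API +
#' stabilizer + mannitol) in 9 mL water, i.e. an initial dry-basis moisture
#' of 9/1.75 kg kg^-1. The droplet residence time defaults to the chamber
#' volume over the air flow. Gas-phase properties are evaluated at ambient
#' pressure (the 5 bar figure is the atomizing-air pressure, not the chamber
#' pressure).
#'
#' @param air_temperature_C Inlet drying air temperature, degC.
#' @param air_flow_Lh Air volumetric flow, L h^-1.
#' @param air_pressure_bar Atomizing air pressure, bar (recorded, not used
#'   in the gas-phase balances).
#' @param chamber_volume_L Drying chamber volume, L.
#' @param drying_time_h Run duration, h.
#' @param feed_solids_kg Total solids fed over the run, kg.
#' @param initial_moisture Initial dry-basis moisture, kg water per kg
#'   solids.
#' @param feed_temperature_K Feed (droplet) temperature, K.
#' @param residence_time_s Droplet residence time, s; default
#'   `chamber_volume_L / air_flow_Lh * 3600`.
#' @param inlet_humidity Inlet air humidity ratio, kg water per kg dry air.
#' @param h_coeff Droplet heat-transfer coefficient, J m^-2 s^-1 K^-1.
#' @param x_crit Critical dry-basis moisture of the falling-rate law.
#' @param droplet_median_m,droplet_gsd,n_droplet_bins Lognormal droplet
#'   size law (median in m, geometric SD) and its discretization.
#' @param n_solids_bins Number of solids classes the feed PSD is collapsed
#'   to.
#' @param rho_solid Solids density, kg m^-3.
#' @param cp_solid,cp_water,cp_vapor,cp_air Specific heats, J kg^-1 K^-1.
#' @param lambda0 Latent heat of vaporization of water at the reference
#'   temperature, J kg^-1.
#' @param ambient_pressure_Pa Chamber gas pressure, Pa.
#' @return An object of class `dryer_config`.
#' @export
dryer_config <- function(air_temperature_C = 110, air_flow_Lh = 800,
                         air_pressure_bar = 5, chamber_volume_L = 5,
                         drying_time_h = 1, feed_solids_kg = 1.75e-3,
                         initial_moisture = 9 / 1.75,
                         feed_temperature_K = 298.15,
                         residence_time_s = chamber_volume_L / air_flow_Lh * 3600,
                         inlet_humidity = 0.005, h_coeff = 50, x_crit = 1,
                         droplet_median_m = 20e-6, droplet_gsd = 1.8,
                         n_droplet_bins = 5, n_solids_bins = 5,
                         rho_solid = 1400, cp_solid = 1200, cp_water = 4187,
                         cp_vapor = 1880, cp_air = 1006, lambda0 = 2.501e6,
                         ambient_pressure_Pa = 101325) {
  cfg <- as.list(environment())
  pos <- c("air_flow_Lh", "chamber_volume_L", "drying_time_h", "feed_solids_kg",
           "initial_moisture", "feed_temperature_K", "inlet_humidity", "h_coeff",
           "x_crit", "droplet_median_m", "n_droplet_bins", "n_solids_bins",
           "rho_solid", "cp_solid", "cp_water", "cp_vapor", "cp_air", "lambda0",
           "ambient_pressure_Pa")
  bad <- pos[vapply(cfg[pos], function(v) !is.numeric(v) || v <= 0, TRUE)]
  if (length(bad)) stop("dryer_config fields must be positive: ",
                        paste(bad, collapse = ", "))
  if (residence_time_s < 0) stop("residence_time_s must be >= 0")
  if (droplet_gsd < 1) stop("droplet_gsd must be >= 1")
  structure(cfg, class = "dryer_config")
}

#' @export
print.dryer_config <- function(x, ...) {
  cat("dryer_config:", x$air_temperature_C, "degC,", x$air_flow_Lh, "L/h,",
      x$chamber_volume_L, "L chamber; residence", signif(x$residence_time_s, 4),
      "s\n")
  invisible(x)
}

#' Lognormal droplet size discretization
#'
#' Splits a lognormal droplet-diameter law into `n_bins` equal-probability
#' intervals represented by their median diameters, so the mass weights are
#' uniform and sum to one. A geometric SD of 1 degenerates to a single
#' diameter at the median.
#'
#' @param median Median droplet diameter, m.
#' @param gsd Geometric standard deviation (>= 1).
#' @param n_bins Number of droplet classes (>= 1).
#' @return A data frame with columns `size` (m) and `weight`.
#' @export
lognormal_droplets <- function(median, gsd, n_bins) {
  if (gsd < 1) stop("gsd must be >= 1")
  stopifnot(median > 0, n_bins >= 1)
  p_mid <- (seq_len(n_bins) - 0.5) / n_bins
  data.frame(size = stats::qlnorm(p_mid, meanlog = log(median), sdlog = log(gsd)),
             weight = rep(1 / n_bins, n_bins))
}

#' Saturation vapor pressure of water
#'
#' Magnus-type correlation P_sat = 610.94 exp(17.625 Tc / (Tc + 243.04)) Pa
#' with Tc in degC, applied over -40..150 degC.
#'
#' @param temperature Temperature, K.
#' @return Saturation pressure, Pa.
#' @export
saturation_pressure <- function(temperature) {
  tc <- temperature - 273.15
  if (any(tc < -40 | tc > 150))
    stop("temperature outside the validity range of the saturation correlation ",
         "(-40..150 degC)")
  610.94 * exp(17.625 * tc / (tc + 243.04))
}

#' Relative humidity of moist air
#'
#' Converts a humidity ratio to a water partial pressure,
#' p_w = Y P / (0.622 + Y), and divides by the saturation pressure.
#'
#' @param temperature Air temperature, K.
#' @param humidity_ratio Humidity ratio Y, kg water per kg dry air.
#' @param pressure Total pressure, Pa.
#' @return Relative humidity (1 at saturation).
#' @export
relative_humidity <- function(temperature, humidity_ratio, pressure = 101325) {
  pw <- humidity_ratio * pressure / (0.622 + humidity_ratio)
  pw / saturation_pressure(temperature)
}

# humidity ratio of saturated air at T, P
.saturation_humidity <- function(temperature, pressure) {
  ps <- saturation_pressure(temperature)
  if (ps >= pressure) return(Inf)
  0.622 * ps / (pressure - ps)
}

#' Wet-bulb temperature of moist air
#'
#' Solves the adiabatic-saturation balance
#' (cp_air + Y cp_vapor)(T - T_wb) = lambda (Y_sat(T_wb) - Y) by bisection
#' (Brent root finding) for T_wb. Saturated air returns T_wb = T.
#'
#' @param temperature Dry-bulb temperature, K.
#' @param humidity_ratio Humidity ratio, kg kg^-1.
#' @param pressure Total pressure, Pa.
#' @param cp_air,cp_vapor Specific heats, J kg^-1 K^-1.
#' @param lambda Latent heat of vaporization, J kg^-1.
#' @return Wet-bulb temperature, K (<= dry-bulb; equal at saturation).
#' @export
wet_bulb <- function(temperature, humidity_ratio, pressure = 101325,
                     cp_air = 1006, cp_vapor = 1880, lambda = 2.4e6) {
  ysat_t <- .saturation_humidity(temperature, pressure)
  if (humidity_ratio >= ysat_t) return(temperature)
  g <- function(twb)
    (cp_air + humidity_ratio * cp_vapor) * (temperature - twb) -
      lambda * (.saturation_humidity(twb, pressure) - humidity_ratio)
  lo <- 233.16
  if (g(lo) <= 0) return(lo)
  sol <- tryCatch(stats::uniroot(g, c(lo, temperature), tol = 1e-8),
                  error = function(e)
                    stop("wet-bulb iteration failed to converge: ",
                         conditionMessage(e)))
  sol$root
}

#' Unhindered droplet drying rate
#'
#' N_u = (h / lambda) A (T_v - T_wb): the evaporation rate of a pure-liquid
#' droplet of surface area A in gas at T_v.
#'
#' @param h Heat-transfer coefficient, J m^-2 s^-1 K^-1.
#' @param lambda Latent heat, J kg^-1 (> 0).
#' @param area Droplet surface area, m^2.
#' @param t_gas Gas temperature, K.
#' @param t_wb Wet-bulb temperature, K.
#' @return Drying rate, kg s^-1.
#' @export
unhindered_rate <- function(h, lambda, area, t_gas, t_wb) {
  if (lambda <= 0) stop("lambda must be > 0")
  (h / lambda) * area * (t_gas - t_wb)
}

#' Relative drying rate of a solids-laden droplet
#'
#' Falling-rate hindrance factor f in N = f N_u: unity above the critical
#' moisture and linear in the moisture content below it (the default
#' falling-rate law; the critical moisture is configurable).
#'
#' @param x Dry-basis moisture, kg kg^-1 (>= 0).
#' @param x_crit Critical moisture (> 0).
#' @return f in `[0, 1]`.
#' @export
relative_drying_rate <- function(x, x_crit) {
  if (x_crit <= 0) stop("x_crit must be > 0")
  if (any(x < 0)) stop("moisture must be >= 0")
  pmin(1, x / x_crit)
}

# latent heat at temperature T consistent with the vapor/liquid heat
# capacities and the reference latent heat at T0 = 273.15 K
.lambda_at <- function(T, cfg) cfg$lambda0 + (cfg$cp_vapor - cfg$cp_water) * (T - 273.15)

# enthalpy of moist air per kg dry air (reference: liquid water / dry air
# at T0 = 273.15 K)
.moist_air_enthalpy <- function(T, Y, cfg)
  cfg$cp_air * (T - 273.15) + Y * (cfg$lambda0 + cfg$cp_vapor * (T - 273.15))

# geometry and per-class constants of a drying run
.drying_setup <- function(config, psd = NULL) {
  cfg <- config
  n_i <- if (is.null(psd)) 1L else cfg$n_solids_bins
  w_i <- if (is.null(psd)) 1 else {
    # collapse the PSD into n_i classes of (nearly) equal mass
    grp <- cut(cumsum(psd$w) - psd$w / 2, breaks = seq(0, 1, length.out = n_i + 1),
               include.lowest = TRUE, labels = FALSE)
    as.numeric(tapply(psd$w, factor(grp, levels = seq_len(n_i)), sum,
                      default = 0))
  }
  w_i <- w_i / sum(w_i)
  drops <- lognormal_droplets(cfg$droplet_median_m, cfg$droplet_gsd,
                              cfg$n_droplet_bins)
  n_z <- nrow(drops)
  # resident solids mass split over (i, z) classes
  m_dot_solids <- cfg$feed_solids_kg / (cfg$drying_time_h * 3600)
  M_resident <- m_dot_solids * cfg$residence_time_s
  M_s <- outer(w_i, drops$weight) * M_resident          # n_i x n_z
  x0 <- cfg$initial_moisture
  rho_susp <- (1 + x0) / (1 / cfg$rho_solid + x0 / 1000)
  m_drop0 <- rho_susp * pi / 6 * drops$size^3            # initial mass of one droplet
  n_drops <- sweep(M_s * (1 + x0), 2, m_drop0, "/")      # droplet counts
  # gas inventory and flow
  T_in <- cfg$air_temperature_C + 273.15
  P <- cfg$ambient_pressure_Pa
  m_air <- P * (cfg$chamber_volume_L / 1000) / (287.05 * T_in)
  m_dot_air <- P / (287.05 * T_in) * (cfg$air_flow_Lh / 1000 / 3600)
  list(cfg = cfg, n_i = n_i, n_z = n_z, nc = n_i * n_z, M_s = as.vector(M_s),
       n_drops = as.vector(n_drops), m_s_per_drop = as.vector(M_s / n_drops),
       T_in = T_in, P = P, m_air = m_air, m_dot_air = m_dot_air,
       class_i = rep(seq_len(n_i), n_z), class_z = rep(seq_len(n_z), each = n_i))
}

# total droplet surface area of each class at moisture x
.droplet_area <- function(x, setup) {
  cfg <- setup$cfg
  v_drop <- setup$m_s_per_drop * (1 / cfg$rho_solid + pmax(x, 0) / 1000)
  d <- (6 * v_drop / pi)^(1 / 3)
  setup$n_drops * pi * d^2
}

# time derivatives of the drying state; state layout:
# [x (nc), Tp (nc), m_v, H_g, W_in, W_out, H_in, H_out, E_drop]
drying_rhs <- function(t, state, setup) {
  cfg <- setup$cfg
  nc <- setup$nc
  if (length(state) != 2 * nc + 7) stop("drying state has wrong dimension")
  x <- state[seq_len(nc)]
  Tp <- state[nc + seq_len(nc)]
  m_v <- state[2 * nc + 1]
  H_g <- state[2 * nc + 2]
  Y_out <- m_v / setup$m_air
  T_v <- 273.15 + (H_g - m_v * cfg$lambda0) /
    (setup$m_air * cfg$cp_air + m_v * cfg$cp_vapor)
  T_wb <- wet_bulb(T_v, Y_out, setup$P, cfg$cp_air, cfg$cp_vapor,
                   .lambda_at(T_v, cfg))
  A <- .droplet_area(x, setup)
  lam_p <- .lambda_at(Tp, cfg)
  f <- pmin(1, pmax(x, 0) / cfg$x_crit)
  Ndot <- pmax(f * (cfg$h_coeff / lam_p) * A * (T_v - T_wb), 0)
  conv <- cfg$h_coeff * A * (T_v - Tp)
  dx <- -Ndot / setup$M_s
  dTp <- (conv - Ndot * lam_p) / (setup$M_s * (cfg$cp_solid + pmax(x, 0) * cfg$cp_water))
  # vapor leaves the droplets at Tp and joins the gas inventory
  h_transfer <- sum(Ndot * (cfg$lambda0 + cfg$cp_vapor * (Tp - 273.15)))
  dm_v <- setup$m_dot_air * (cfg$inlet_humidity - Y_out) + sum(Ndot)
  dH_in <- setup$m_dot_air * .moist_air_enthalpy(setup$T_in, cfg$inlet_humidity, cfg)
  dH_out <- setup$m_dot_air * .moist_air_enthalpy(T_v, Y_out, cfg)
  dH_g <- dH_in - dH_out - sum(conv) + h_transfer
  dE_drop <- sum(conv) - h_transfer
  c(dx, dTp, dm_v, dH_g,
    setup$m_dot_air * cfg$inlet_humidity, setup$m_dot_air * Y_out,
    dH_in, dH_out, dE_drop)
}

#' Simulate spray drying of a milled suspension
#'
#' Integrates the coupled droplet (moisture and temperature per solids x
#' droplet class) and gas-phase (vapor mass and enthalpy) balances over the
#' droplet residence time, by default with the package's fixed-step BDF
#' integrator. The droplet population is the resident feed of one residence
#' time, split over the solids classes of the milled PSD and the lognormal
#' droplet classes; the gas phase is a single well-mixed zone. Cumulative
#' inflow/outflow states are co-integrated so that water and enthalpy
#' closures are exact linear combinations of the integrated states.
#'
#' @param config A [dryer_config].
#' @param psd Optional milled [psd]; when omitted a single solids class is
#'   used.
#' @param solver `"bdf"` (fixed-step, see [bdf_integrate()]) or `"lsoda"`
#'   (adaptive, via deSolve).
#' @param n_steps Number of BDF steps over the residence time.
#' @param bdf_order BDF order (1..5).
#' @return An object of class `spraydry_result`: trajectories of class
#'   moistures, particle and gas temperatures and outlet humidity, the
#'   solids-mass-weighted mean final moisture, and closure diagnostics.
#' @export
simulate_spraydry <- function(config = dryer_config(), psd = NULL,
                              solver = c("bdf", "lsoda"), n_steps = 200,
                              bdf_order = 2) {
  stopifnot(inherits(config, "dryer_config"))
  solver <- match.arg(solver)
  setup <- .drying_setup(config, psd)
  nc <- setup$nc
  T_in <- setup$T_in
  m_v0 <- setup$m_air * config$inlet_humidity
  H_g0 <- setup$m_air * .moist_air_enthalpy(T_in, config$inlet_humidity, config)
  E_d0 <- sum(setup$M_s * (config$cp_solid + config$initial_moisture * config$cp_water) *
                (config$feed_temperature_K - 273.15))
  state0 <- c(rep(config$initial_moisture, nc),
              rep(config$feed_temperature_K, nc),
              m_v0, H_g0, 0, 0, 0, 0, E_d0)
  t_end <- config$residence_time_s
  if (t_end == 0) {
    traj <- matrix(state0, nrow = 1)
    times <- 0
  } else if (solver == "bdf") {
    resid <- function(t, x, xdot) xdot - drying_rhs(t, x, setup)
    sol <- bdf_integrate(resid, state0, t_end, h = t_end / n_steps,
                         k = bdf_order)
    traj <- sol$x
    times <- sol$times
  } else {
    sol <- deSolve::ode(state0, seq(0, t_end, length.out = n_steps + 1),
                        function(t, y, p) list(drying_rhs(t, y, setup)),
                        parms = NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-12)
    if (attr(sol, "istate")[1] < 0) stop("spray-drying integration failed")
    traj <- unname(sol[, -1, drop = FALSE])
    times <- sol[, 1]
  }
  x_cols <- seq_len(nc)
  moisture <- pmax(traj[, x_cols, drop = FALSE], 0)
  m_v <- traj[, 2 * nc + 1]
  H_g <- traj[, 2 * nc + 2]
  T_v <- 273.15 + (H_g - m_v * config$lambda0) /
    (setup$m_air * config$cp_air + m_v * config$cp_vapor)
  final <- traj[nrow(traj), ]
  w_solids <- if (sum(setup$M_s) > 0) setup$M_s / sum(setup$M_s) else rep(1 / nc, nc)
  liquid0 <- sum(setup$M_s) * config$initial_moisture
  liquid_end <- sum(setup$M_s * pmax(final[x_cols], 0))
  water_in <- final[2 * nc + 3]; water_out <- final[2 * nc + 4]
  water_closure <- ((liquid_end + final[2 * nc + 1]) - (liquid0 + m_v0) -
                      (water_in - water_out)) /
    max(liquid0 + m_v0 + water_in, .Machine$double.eps)
  h_in <- final[2 * nc + 5]; h_out <- final[2 * nc + 6]
  enth_closure <- ((final[2 * nc + 2] + final[2 * nc + 7]) -
                     (H_g0 + E_d0) - (h_in - h_out)) /
    max(abs(H_g0) + h_in, .Machine$double.eps)
  structure(list(
    times = times, moisture = moisture,
    particle_temperature = traj[, nc + seq_len(nc), drop = FALSE],
    gas_temperature = T_v, outlet_humidity = m_v / setup$m_air,
    final_moisture = pmax(final[x_cols], 0),
    mean_final_moisture = sum(w_solids * pmax(final[x_cols], 0)),
    closure = list(water = water_closure, enthalpy = enth_closure),
    setup = setup, config = config, solver = solver),
    class = "spraydry_result")
}

#' @export
print.spraydry_result <- function(x, ...) {
  cat("spraydry_result:", x$setup$n_i, "solids x", x$setup$n_z,
      "droplet classes,", x$solver, "solver\n")
  cat(sprintf("  mean final moisture %.4g kg/kg; outlet gas %.1f K\n",
              x$mean_final_moisture,
              x$gas_temperature[length(x$gas_temperature)]))
  cat(sprintf("  closure: water %.2g, enthalpy %.2g (relative)\n",
              x$closure$water, x$closure$enthalpy))
  invisible(x)
}

#' @export
plot.spraydry_result <- function(x, ...) {
  graphics::matplot(x$times, x$moisture, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "dry-basis moisture (kg/kg)", ...)
  invisible(x)
}

#' Two-factor design space of the spray dryer
#'
#' Full-factorial sweep of the inlet air temperature and air flow; the
#' response is the solids-mass-weighted mean final moisture. Failed cells
#' are flagged and left `NA` while the rest of the grid completes. The
#' droplet residence time is held at the base configuration's value so the
#' two factors act through the gas-phase balances only.
#'
#' @param config Base [dryer_config].
#' @param t_range Air temperatures, degC.
#' @param flow_range Air flows, L h^-1.
#' @param psd Optional milled [psd].
#' @param ... Passed to [simulate_spraydry()].
#' @return A data frame of class `design_space` with columns `T_C`,
#'   `flow_Lh`, `final_moisture`, `failed`.
#' @export
design_space <- function(config = dryer_config(), t_range, flow_range,
                         psd = NULL, ...) {
  if (length(t_range) == 0 || length(flow_range) == 0)
    stop("factor ranges must be non-empty")
  grid <- expand.grid(T_C = t_range, flow_Lh = flow_range,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    cfg <- config
    cfg$air_temperature_C <- grid$T_C[r]
    cfg$air_flow_Lh <- grid$flow_Lh[r]
    tryCatch(simulate_spraydry(cfg, psd = psd, ...)$mean_final_moisture,
             error = function(e) NA_real_)
  })
  grid$final_moisture <- unlist(res)
  grid$failed <- is.na(grid$final_moisture)
  class(grid) <- c("design_space", "data.frame")
  grid
}

#' @export
plot.design_space <- function(x, ...) {
  tt <- sort(unique(x$T_C)); ff <- sort(unique(x$flow_Lh))
  z <- matrix(x$final_moisture[order(x$flow_Lh, x$T_C)], length(tt), length(ff))
  graphics::filled.contour(tt, ff, z, xlab = "air temperature (degC)",
                           ylab = "air flow (L/h)", ...)
  invisible(x)
}
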