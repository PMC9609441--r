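#' PC-SAFT segment parameters of a chain molecule
#'
#' Bundles the three segment-level PC-SAFT parameters of a molecule: the
#' number of segments per chain, the segment diameter and the depth of the
#' segment pair potential. The pair-potential depth is stored as `u/k` in
#' Kelvin (the usual tabulated form) and converted to Joules with the
#' Boltzmann constant at the point of use.
#'
#' @param m_seg Number of segments per chain (dimensionless, > 0).
#' @param sigma Segment diameter in Angstrom (> 0).
#' @param u_over_k Pair-potential depth over the Boltzmann constant, in K (> 0).
#' @return An object of class `segment_params`.
#' @examples
#' segment_params(m_seg = 418, sigma = 2.89, u_over_k = 206.74)
#' @export
segment_params <- function(m_seg, sigma, u_over_k) {
  stopifnot(is.numeric(m_seg), is.numeric(sigma), is.numeric(u_over_k))
  if (m_seg <= 0 || sigma <= 0 || u_over_k <= 0)
    stop("all segment parameters must be strictly positive")
  structure(list(m_seg = m_seg, sigma = sigma, u_over_k = u_over_k),
            class = "segment_params")
}

#' Stabilizer material record
#'
#' @param name Stabilizer name.
#' @param mw Molar mass, g mol^-1 (> 0).
#' @param segments A [segment_params] object.
#' @param density Mass density, kg m^-3 (> 0).
#' @param zeta_potential Zeta potential, mV.
#' @param gmi_reference Optional reference interfacial Gibbs energy, stored
#'   with units as printed in its source table (see [stabilizer_table()]).
#' @return An object of class `stabilizer_record`.
#' @export
stabilizer_record <- function(name, mw, segments, density, zeta_potential = NA_real_,
                              gmi_reference = NULL) {
  stopifnot(inherits(segments, "segment_params"))
  if (mw <= 0) stop("mw must be > 0")
  if (density <= 0) stop("density must be > 0")
  structure(list(name = name, mw = mw, segments = segments, density = density,
                 zeta_potential = zeta_potential, gmi_reference = gmi_reference),
            class = "stabilizer_record")
}

#' Active pharmaceutical ingredient record
#'
#' @param name API name.
#' @param mr Molar mass, g mol^-1.
#' @param vm Molar volume, m^3 mol^-1 (> 0).
#' @param s0 Aqueous solubility of the pure API, mol L^-1 (> 0).
#' @param segments A [segment_params] object.
#' @param delta_interlayer Distance between molecular layers, m.
#' @return An object of class `api_record`.
#' @export
api_record <- function(name, mr, vm, s0, segments, delta_interlayer) {
  stopifnot(inherits(segments, "segment_params"))
  if (vm <= 0) stop("vm must be > 0")
  if (s0 <= 0) stop("s0 must be > 0")
  structure(list(name = name, mr = mr, vm = vm, s0 = s0, segments = segments,
                 delta_interlayer = delta_interlayer),
            class = "api_record")
}

#' Berthelot-Lorentz combining rules
#'
#' Cross segment diameter as the arithmetic mean and cross pair-potential
#' depth as the geometric mean of the pure-component values.
#'
#' @param sigma_a,sigma_b Segment diameters (same unit, > 0).
#' @param eps_a,eps_b Pair-potential depths (same unit, > 0).
#' @return A list with components `sigma_ab` and `eps_ab`.
#' @examples
#' lorentz_berthelot(2.89, 3.34, 206.74, 192.72)
#' @export
lorentz_berthelot <- function(sigma_a, sigma_b, eps_a, eps_b) {
  if (any(c(sigma_a, sigma_b, eps_a, eps_b) <= 0))
    stop("all inputs to the combining rules must be strictly positive")
  list(sigma_ab = (sigma_a + sigma_b) / 2, eps_ab = sqrt(eps_a * eps_b))
}

#' Group-contribution segment number of an EO/PO (co)polymer
#'
#' Segments per chain of ethylene-oxide and propylene-oxide based polymers
#' scale linearly with molar mass: 0.052 per g mol^-1 for EO and 0.037 for
#' PO. For a copolymer the per-group contributions combine weighted by the
#' mass fraction of each group, see [poloxamer_segments()].
#'
#' @param mw_total Total molar mass attributed to the group, g mol^-1 (>= 0).
#' @param group Either `"EO"` or `"PO"`.
#' @return Segment-number contribution (dimensionless).
#' @examples
#' copolymer_segments(1000, "EO")  # 52
#' copolymer_segments(1000, "PO")  # 37
#' @export
copolymer_segments <- function(mw_total, group = c("EO", "PO")) {
  if (mw_total < 0) stop("mw_total must be >= 0")
  group <- match.arg(group)
  coefs <- c(EO = 0.052, PO = 0.037)
  unname(coefs[group]) * mw_total
}

#' PC-SAFT parameters of an EO/PO copolymer (poloxamer)
#'
#' Combines the EO and PO group parameters into copolymer segment
#' parameters: segments per chain add up group-wise from the mass assigned
#' to each group, while the cross diameter and energy follow the
#' Berthelot-Lorentz rules weighted implicitly through the EO mass fraction.
#'
#' @param mw_total Copolymer molar mass, g mol^-1.
#' @param eo_mass_fraction Mass fraction of EO in the copolymer, in `[0, 1]`.
#' @param groups Group parameter table, by default [eo_po_groups()].
#' @return A [segment_params] object for the copolymer.
#' @export
poloxamer_segments <- function(mw_total, eo_mass_fraction, groups = eo_po_groups()) {
  if (eo_mass_fraction < 0 || eo_mass_fraction > 1)
    stop("eo_mass_fraction must lie in [0, 1]")
  f <- c(EO = eo_mass_fraction, PO = 1 - eo_mass_fraction)
  m_seg <- copolymer_segments(mw_total * f["EO"], "EO") +
    copolymer_segments(mw_total * f["PO"], "PO")
  eo <- groups[groups$group == "EO", ]
  po <- groups[groups$group == "PO", ]
  cross <- lorentz_berthelot(eo$sigma_A, po$sigma_A, eo$u_over_k_K, po$u_over_k_K)
  # mass-fraction weighted blend of pure-group and cross parameters
  sigma <- f["EO"]^2 * eo$sigma_A + f["PO"]^2 * po$sigma_A +
    2 * f["EO"] * f["PO"] * cross$sigma_ab
  u_over_k <- f["EO"]^2 * eo$u_over_k_K + f["PO"]^2 * po$u_over_k_K +
    2 * f["EO"] * f["PO"] * cross$eps_ab
  segment_params(unname(m_seg), unname(sigma), unname(u_over_k))
}

#' Surface tension of a particulate solid from bulk properties
#'
#' gamma = -0.33 kB T (NA rho / Mr)^(2/3) * (ln(S0 / 55.6) + 5), with the
#' solubility `s0` in mol L^-1 compared against the molarity of pure water
#' (55.6 mol L^-1). For sparingly soluble drugs the bracket is negative and
#' gamma is positive.
#'
#' @param temperature Temperature, K (> 0).
#' @param density Particle density, g m^-3 (> 0).
#' @param mr Molar mass, g mol^-1 (> 0).
#' @param s0 Aqueous solubility of the pure API, mol L^-1 (> 0).
#' @return Surface tension, N m^-1.
#' @export
surface_tension <- function(temperature, density, mr, s0) {
  if (any(c(temperature, density, mr) <= 0)) stop("inputs must be strictly positive")
  if (s0 <= 0) stop("s0 must be > 0 (log undefined otherwise)")
  -0.33 * .const$kB * temperature * (.const$Na * density / mr)^(2 / 3) *
    (log(s0 / .const$water_molarity) + 5)
}

#' Surface Gibbs energy term of a nanoparticle
#'
#' Gms = (2 gamma Vm / r) (1 - C / r) with C = 1.5 (Vm / NA)^(1/3), the
#' curvature correction length.
#'
#' @param gamma Surface tension, N m^-1.
#' @param vm Molar volume, m^3 mol^-1 (> 0).
#' @param radius Particle characteristic size, m (> 0).
#' @return Surface Gibbs energy, J mol^-1.
#' @export
gibbs_surface <- function(gamma, vm, radius) {
  if (radius <= 0) stop("radius must be > 0")
  if (vm <= 0) stop("vm must be > 0")
  C <- 1.5 * (vm / .const$Na)^(1 / 3)
  (2 * gamma * vm / radius) * (1 - C / radius)
}

#' Interfacial Gibbs energy term contributed by the stabilizer
#'
#' Gmi = 1.7 eps_API sigma_API rho_stab Delta (sigma_x eps_x / m_stab)
#'       (gamma Vm / r), where `sigma_x` and `eps_x` are the API-stabilizer
#' cross parameters from the Berthelot-Lorentz rules. Pair-potential depths
#' are stored as u/k in Kelvin and converted to Joules here; segment
#' diameters are converted from Angstrom to metres.
#'
#' @param api An [api_record].
#' @param stab A [stabilizer_record].
#' @param gamma Surface tension, N m^-1.
#' @param vm API molar volume, m^3 mol^-1.
#' @param radius Particle characteristic size, m (> 0).
#' @return Interfacial Gibbs energy, J mol^-1.
#' @export
gibbs_interface <- function(api, stab, gamma, vm, radius) {
  stopifnot(inherits(api, "api_record"), inherits(stab, "stabilizer_record"))
  if (stab$segments$m_seg == 0) stop("m_stab must be non-zero")
  if (radius <= 0) stop("radius must be > 0")
  ang <- 1e-10
  eps_api <- api$segments$u_over_k * .const$kB
  eps_stab <- stab$segments$u_over_k * .const$kB
  cross <- lorentz_berthelot(api$segments$sigma * ang, stab$segments$sigma * ang,
                             eps_api, eps_stab)
  1.7 * eps_api * (api$segments$sigma * ang) * stab$density *
    api$delta_interlayer * cross$sigma_ab * cross$eps_ab /
    stab$segments$m_seg * (gamma * vm / radius)
}

#' Solubility enhancement ratio from the Gibbs energy gain
#'
#' K2/K1 = exp(GEE / (R T)): the ratio of the dissolution equilibrium
#' coefficient after and before the size reduction.
#'
#' @param gee Total Gibbs energy gain (surface + interface), J mol^-1.
#' @param temperature Dissolution temperature, K (> 0).
#' @return The dimensionless ratio K2/K1.
#' @examples
#' solubility_enhancement(0, 298.15)  # 1
#' @export
solubility_enhancement <- function(gee, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  exp(gee / (.const$R * temperature))
}

#' Full Gibbs energy assessment of an API/stabilizer pair
#'
#' Computes surface tension, the curvature parameter C, the surface and
#' interfacial Gibbs terms, their total and the implied solubility
#' enhancement ratio for a particle of characteristic size `radius`.
#'
#' @inheritParams gibbs_interface
#' @param temperature Temperature, K.
#' @return A list of class `gibbs_result` with components `gamma`, `c_param`,
#'   `gms`, `gmi`, `gee`, `k_ratio`, `temperature`, `radius`.
#' @export
gibbs_energy <- function(api, stab, temperature, radius) {
  density_g_m3 <- api$mr / api$vm   # g mol^-1 / (m^3 mol^-1) = g m^-3
  gamma <- surface_tension(temperature, density_g_m3, api$mr, api$s0)
  gms <- gibbs_surface(gamma, api$vm, radius)
  gmi <- gibbs_interface(api, stab, gamma, api$vm, radius)
  gee <- gms + gmi
  structure(list(gamma = gamma,
                 c_param = 1.5 * (api$vm / .const$Na)^(1 / 3),
                 gms = gms, gmi = gmi, gee = gee,
                 k_ratio = solubility_enhancement(gee, temperature),
                 temperature = temperature, radius = radius),
            class = "gibbs_result")
}

#' @export
print.gibbs_result <- function(x, ...) {
  cat("Gibbs energy assessment at", x$temperature, "K, r =", x$radius, "m\n")
  cat(sprintf("  gamma  = %.4g N/m\n  Gms    = %.4g J/mol\n", x$gamma, x$gms))
  cat(sprintf("  Gmi    = %.4g J/mol\n  GEE    = %.4g J/mol\n", x$gmi, x$gee))
  cat(sprintf("  K2/K1  = %.4g\n", x$k_ratio))
  invisible(x)
}

#' Rank stabilizer candidates by interfacial Gibbs energy
#'
#' Sorts candidates in decreasing order of their interfacial Gibbs energy
#' contribution Gmi; the stabilizer contributing dominantly to the Gibbs
#' energy decrease is selected. Ties are broken lexicographically by name.
#'
#' @param candidates A data.frame with columns `name` and `gmi`, or a named
#'   numeric vector of Gmi values.
#' @return A data.frame sorted by decreasing `gmi` with a logical `selected`
#'   column; the selected name is attached as attribute `"selected"`.
#' @examples
#' rank_stabilizers(c(`HPC-SL` = 0.0019, `Poloxamer-407` = 0.0039,
#'                    `Poloxamer-188` = 0.0056))
#' @export
rank_stabilizers <- function(candidates) {
  if (is.numeric(candidates))
    candidates <- data.frame(name = names(candidates), gmi = unname(candidates),
                             stringsAsFactors = FALSE)
  if (!is.data.frame(candidates) || !all(c("name", "gmi") %in% names(candidates)))
    stop("candidates must have 'name' and 'gmi'")
  if (nrow(candidates) == 0) stop("empty candidate list")
  ord <- order(-candidates$gmi, candidates$name)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$selected <- seq_len(nrow(out)) == 1L
  attr(out, "selected") <- out$name[1L]
  out
}

#' Linear-in-temperature property interpolation
#'
#' Contract for tabulated temperature-dependent properties (density, heat
#' capacity) supplied by the user in place of an equation-of-state solve.
#'
#' @param temperature Tabulated temperatures, K (strictly increasing).
#' @param value Property values at those temperatures.
#' @return A function of temperature performing linear interpolation;
#'   evaluation outside the tabulated range is an error.
#' @export
property_table <- function(temperature, value) {
  stopifnot(length(temperature) == length(value), length(temperature) >= 2)
  if (any(diff(temperature) <= 0)) stop("temperatures must be strictly increasing")
  force(value)
  function(t) {
    if (any(t < temperature[1] | t > temperature[length(temperature)]))
      stop("temperature outside tabulated range")
    stats::approx(temperature, value, xout = t)$y
  }
}

#' Read a materials file (YAML or JSON)
#'
#' The file holds one `api` block and a list of `stabilizers`, each with the
#' fields of [api_record()] / [stabilizer_record()] (segment parameters
#' nested under `segments`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `api` ([api_record]) and `stabilizers`
#'   (list of [stabilizer_record]).
#' @export
read_materials <- function(path) {
  if (!file.exists(path)) stop("materials file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  seg <- function(s) segment_params(s$m_seg, s$sigma, s$u_over_k)
  api <- if (!is.null(raw$api)) {
    a <- raw$api
    api_record(a$name, a$mr, a$vm, a$s0, seg(a$segments), a$delta_interlayer)
  }
  stabs <- lapply(raw$stabilizers, function(s) {
    stabilizer_record(s$name, s$mw, seg(s$segments), s$density,
                      if (is.null(s$zeta_potential)) NA_real_ else s$zeta_potential,
                      s$gmi_reference)
  })
  list(api = api, stabilizers = stabs)
}

#' Write a stabilizer ranking report as CSV
#'
#' @param ranking Output of [rank_stabilizers()].
#' @param records Optional list of [stabilizer_record] objects supplying
#'   density and zeta potential columns.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_ranking_csv <- function(ranking, path, records = NULL) {
  out <- ranking
  if (!is.null(records)) {
    byname <- stats::setNames(records, vapply(records, `[[`, "", "name"))
    out$density <- vapply(out$name, function(n)
      if (n %in% names(byname)) byname[[n]]$density else NA_real_, 0)
    out$zeta_potential <- vapply(out$name, function(n)
      if (n %in% names(byname)) byname[[n]]$zeta_potential else NA_real_, 0)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
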