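#' EO/PO group parameters for poloxamer copolymers
#'
#' Segment-number coefficients (per unit molar mass), segment diameters and
#' pair-potential depths of the ethylene-oxide and propylene-oxide groups
#' used to assemble poloxamer PC-SAFT parameters.
#'
#' @return Data frame with columns `group`, `m_seg_per_mw`, `sigma_A`
#'   (Angstrom) and `u_over_k_K` (K).
#' @export
eo_po_groups <- function() {
  data.frame(group = c("EO", "PO"),
             m_seg_per_mw = c(0.052, 0.037),
             sigma_A = c(2.89, 3.34),
             u_over_k_K = c(206.74, 192.72),
             stringsAsFactors = FALSE)
}

#' Reference wet-milling experiments
#'
#' Three replicate comminution runs of an itraconazole suspension
#' stabilized with Poloxamer-188: median size D50 sampled at six grinding
#' times. These discrete points are the training data for the D50(t)
#' surrogates.
#'
#' @param long If `TRUE` (default) one row per observation with an
#'   `experiment` column; otherwise one column per experiment.
#' @return A data frame with columns `time_s`, `d50_um` and (long form)
#'   `experiment`.
#' @export
milling_experiments <- function(long = TRUE) {
  wide <- data.frame(
    time_s = c(360, 720, 1440, 2160, 2880, 3600),
    experiment_1 = c(1.39, 0.874, 0.784, 0.522, 0.467, 0.305),
    experiment_2 = c(1.31, 0.792, 0.742, 0.501, 0.434, 0.297),
    experiment_3 = c(1.37, 0.846, 0.783, 0.520, 0.436, 0.301))
  if (!long) return(wide)
  long_df <- data.frame(
    time_s = rep(wide$time_s, 3),
    experiment = rep(1:3, each = nrow(wide)),
    d50_um = c(wide$experiment_1, wide$experiment_2, wide$experiment_3))
  long_df[order(long_df$time_s, long_df$experiment), c("time_s", "d50_um", "experiment")]
}

#' Mill and spray-dryer operating inputs
#'
#' The operating record of the modelled bench process: formulation
#' quantities, mill settings and spray-dryer settings, with the declared
#' input/output role and units.
#'
#' @return Data frame with columns `model`, `parameter`, `type`, `value`,
#'   `unit`.
#' @export
process_defaults <- function() {
  data.frame(
    model = c(rep("wet_mill", 10), rep("spray_dryer", 6)),
    parameter = c("water_quantity", "api_content", "stabilizer_content",
                  "mannitol_content", "initial_d50", "grinding_time",
                  "rotor_speed", "rotor_diameter", "equipment_volume", "d50_t",
                  "air_temperature", "air_flow", "air_pressure",
                  "chamber_volume", "drying_time", "final_d50"),
    type = c(rep("input", 9), "output", rep("input", 5), "output"),
    value = c(9, 0.5, 0.25, 1, 1.5, 1, 600, 40, 48,
              NA, 110, 800, 5, 5, 1, 10),
    unit = c("mL", "g", "g", "g", "um", "h", "rpm", "mm", "mL", "um",
             "degC", "L/h", "bar", "L", "h", "um"),
    stringsAsFactors = FALSE)
}

#' Stabilizer candidate records
#'
#' Interfacial Gibbs energy contributions, densities and zeta potentials of
#' the three screened stabilizers. The Gmi column is stored with
#' units-as-printed in its source record (no unit is declared there); it is
#' used for ranking, not recomputation.
#'
#' @return Data frame with columns `name`, `gmi`, `density_kgm3`,
#'   `zeta_potential_mV` and attribute `gmi_units = "as-printed"`.
#' @export
stabilizer_table <- function() {
  out <- data.frame(
    name = c("HPC-SL", "Poloxamer-407", "Poloxamer-188"),
    gmi = c(0.0019, 0.0039, 0.0056),
    density_kgm3 = c(1320, 954, 951),
    zeta_potential_mV = c(-11.7, -13.7, -17.0),
    stringsAsFactors = FALSE)
  attr(out, "gmi_units") <- "as-printed"
  out
}

#' Export the bundled reference tables as CSV files
#'
#' Writes one CSV per bundled table (group parameters, milling experiments,
#' process defaults, stabilizer records) into `outdir`. Re-export is
#' idempotent.
#'
#' @param outdir Writable output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  tables <- list(eo_po_groups = eo_po_groups(),
                 milling_experiments = milling_experiments(long = FALSE),
                 process_defaults = process_defaults(),
                 stabilizer_table = stabilizer_table())
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}
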