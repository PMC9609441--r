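# default run configuration; mill and dryer blocks mirror the bench
# operating record in process_defaults()
.default_config <- function() {
  list(
    seed = 42L,
    outdir = NULL,
    materials = NULL,
    mill = list(water_mL = 9, api_g = 0.5, stabilizer_g = 0.25, mannitol_g = 1,
                initial_d50_um = 1.5, grinding_time_h = 1, rotor_rpm = 600,
                rotor_diameter_mm = 40, volume_mL = 48,
                grid_x_min_um = 0.05, grid_x_max_um = 5, grid_n_bins = 20,
                psd_gsd = 1.5),
    surrogate = list(layer_sizes = c(1, 8, 8, 1), epochs = 20000,
                     learning_rate = 0.05, restarts = 1, poly_order = 2,
                     n_dense = 61),
    fit = list(n_starts = 8),
    dryer = list(air_temperature_C = 110, air_flow_Lh = 800,
                 air_pressure_bar = 5, chamber_volume_L = 5, drying_time_h = 1),
    design_space = list(enabled = FALSE,
                        t_range = c(90, 110, 130),
                        flow_range = c(600, 800, 1000)),
    stages = list(milling = TRUE, spraydry = TRUE))
}

# recursive merge of user values into defaults; unknown keys are an error
.merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(paste(c(path, ""), collapse = "/"), unknown, sep = "", collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      # single-bracket assignment keeps NULL-valued keys instead of
      # deleting them from the list
      defaults[nm] <- list(user[[nm]])
    }
  }
  defaults
}

#' Load a digital-twin run configuration
#'
#' Reads a YAML (or JSON) run configuration and fills every missing field
#' with the bench-process defaults (see [process_defaults()]). Unknown keys
#' raise an error naming the offending entries, so typos never pass
#' silently.
#'
#' @param path Optional path to a YAML/JSON file; `NULL` yields the pure
#'   defaults.
#' @param overrides Optional named list merged on top of the file values.
#' @return A validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path, simplifyVector = TRUE) else yaml::read_yaml(path)
    if (length(user)) cfg <- .merge_config(cfg, user)
  }
  if (length(overrides)) cfg <- .merge_config(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the digital-twin thread end to end
#'
#' Executes the manufacturing thread in order: (a) stabilizer selection by
#' interfacial Gibbs energy ranking, (b) augmentation of the discrete
#' milling experiments into a dense D50(t) reference (polynomial reference
#' for fitting; the network surrogate is trained alongside), (c) breakage
#' family fitting and comparison, (d) milling simulation with the best
#' family, and (e) spray drying of the milled suspension, optionally
#' followed by a design-space sweep. A stage failure marks the stage and
#' skips everything downstream. The run is deterministic given the
#' configuration seed, which fans out to the surrogate training and the
#' multistart grids.
#'
#' @param config A `run_config` from [load_run_config()].
#' @return A list of class `twin_thread` with one entry per stage (each
#'   carrying `status` plus stage outputs) and a `report` summary; if
#'   `config$outdir` is set, a JSON report and CSV outputs are written
#'   there.
#' @export
run_thread <- function(config = load_run_config()) {
  stopifnot(inherits(config, "run_config"))
  stages <- list()
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (failed) return(list(status = "skipped"))
    out <- tryCatch(c(list(status = "ok"), fun()),
                    error = function(e) list(status = "failed",
                                             error = conditionMessage(e)))
    if (!identical(out$status, "ok")) failed <<- TRUE
    out
  }

  stages$stabilizer <- run_stage("stabilizer", function() {
    cand <- if (!is.null(config$materials)) {
      mats <- read_materials(config$materials)
      data.frame(name = vapply(mats$stabilizers, `[[`, "", "name"),
                 gmi = vapply(mats$stabilizers, function(s)
                   s$gmi_reference %||% NA_real_, 0))
    } else {
      tab <- stabilizer_table()
      data.frame(name = tab$name, gmi = tab$gmi)
    }
    ranking <- rank_stabilizers(cand)
    list(ranking = ranking, selected = attr(ranking, "selected"))
  })

  data <- milling_experiments()
  t_end <- config$mill$grinding_time_h * 3600
  stages$surrogate <- run_stage("surrogate", function() {
    sg <- config$surrogate
    poly <- polyfit_profile(data, order = sg$poly_order)
    ann <- train_ann(data, layer_sizes = sg$layer_sizes, seed = config$seed,
                     epochs = sg$epochs, learning_rate = sg$learning_rate,
                     restarts = sg$restarts)
    t_grid <- seq(0, t_end, length.out = sg$n_dense)
    list(poly = poly, ann = ann,
         reference = augment_profile(poly, t_grid, extrapolate = TRUE),
         ann_profile = augment_profile(ann, t_grid, extrapolate = TRUE))
  })

  grid <- size_grid(config$mill$grid_x_min_um * 1e-6,
                    config$mill$grid_x_max_um * 1e-6, config$mill$grid_n_bins)
  psd0 <- psd_lognormal(grid, config$mill$initial_d50_um * 1e-6,
                        config$mill$psd_gsd)
  mech <- material_mechanics(mill_volume = config$mill$volume_mL * 1e-6)

  if (isTRUE(config$stages$milling)) {
    stages$milling_fit <- run_stage("milling_fit", function() {
      cmp <- compare_breakage(stages$surrogate$reference, psd0, mech,
                              n_starts = config$fit$n_starts,
                              seed = config$seed)
      list(comparison = cmp, best_family = cmp$table$family[1])
    })
    stages$milling_sim <- run_stage("milling_sim", function() {
      best <- stages$milling_fit$comparison$fits[[stages$milling_fit$best_family]]
      sim <- simulate_milling(psd0, best$model, mech, t_end = t_end)
      list(result = sim, final_d50_um = sim$d50_um[length(sim$d50_um)])
    })
  } else {
    stages$milling_fit <- list(status = "disabled")
    stages$milling_sim <- list(status = "disabled")
  }

  if (isTRUE(config$stages$spraydry)) {
    stages$spraydry <- run_stage("spraydry", function() {
      dcfg <- do.call(dryer_config, config$dryer)
      milled <- if (identical(stages$milling_sim$status, "ok")) {
        w_end <- stages$milling_sim$result$w[nrow(stages$milling_sim$result$w), ]
        psd(grid, w_end / sum(w_end))
      } else NULL
      res <- simulate_spraydry(dcfg, psd = milled)
      out <- list(result = res, mean_final_moisture = res$mean_final_moisture)
      if (isTRUE(config$design_space$enabled)) {
        out$design_space <- design_space(dcfg, config$design_space$t_range,
                                         config$design_space$flow_range,
                                         psd = milled)
      }
      out
    })
  } else {
    stages$spraydry <- list(status = "disabled")
  }

  report <- list(
    seed = config$seed,
    stages = lapply(stages, `[[`, "status"),
    selected_stabilizer = stages$stabilizer$selected,
    surrogate_mse_percent = if (identical(stages$surrogate$status, "ok"))
      list(polynomial = stages$surrogate$poly$mse_percent,
           ann = stages$surrogate$ann$mse_percent),
    breakage_mse_percent = if (identical(stages$milling_fit$status, "ok"))
      stats::setNames(as.list(stages$milling_fit$comparison$table$mse_percent),
                      stages$milling_fit$comparison$table$family),
    final_d50_um = stages$milling_sim$final_d50_um,
    mean_final_moisture = stages$spraydry$mean_final_moisture)

  out <- structure(c(stages, list(report = report, config = config)),
                   class = "twin_thread")
  if (!is.null(config$outdir)) write_thread_outputs(out, config$outdir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist the outputs of a thread run
#'
#' Writes the JSON summary report and the stage CSVs (stabilizer ranking,
#' dense reference profile, breakage comparison, milling trajectory) into a
#' directory.
#'
#' @param thread A `twin_thread`.
#' @param outdir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_thread_outputs <- function(thread, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(thread$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (identical(thread$stabilizer$status, "ok"))
    utils::write.csv(thread$stabilizer$ranking,
                     file.path(outdir, "stabilizer_ranking.csv"),
                     row.names = FALSE)
  if (identical(thread$surrogate$status, "ok"))
    utils::write.csv(thread$surrogate$reference,
                     file.path(outdir, "reference_profile.csv"),
                     row.names = FALSE)
  if (identical(thread$milling_fit$status, "ok"))
    utils::write.csv(thread$milling_fit$comparison$table,
                     file.path(outdir, "breakage_comparison.csv"),
                     row.names = FALSE)
  if (identical(thread$milling_sim$status, "ok"))
    utils::write.csv(as.data.frame(thread$milling_sim$result),
                     file.path(outdir, "milling_trajectory.csv"),
                     row.names = FALSE)
  invisible(outdir)
}

#' @export
print.twin_thread <- function(x, ...) {
  cat("twin_thread (seed", x$report$seed, ")\n")
  for (nm in names(x$report$stages))
    cat(sprintf("  %-12s %s\n", nm, x$report$stages[[nm]]))
  if (!is.null(x$report$selected_stabilizer))
    cat("  selected stabilizer:", x$report$selected_stabilizer, "\n")
  if (!is.null(x$report$breakage_mse_percent)) {
    m <- unlist(x$report$breakage_mse_percent)
    cat("  breakage MSE (%):",
        paste(names(m), signif(m, 3), sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$report$mean_final_moisture))
    cat("  mean final moisture:", signif(x$report$mean_final_moisture, 4),
        "kg/kg\n")
  invisible(x)
}
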