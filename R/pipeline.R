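# File-level pipeline wrappers tying the modules together: each stage reads
# and writes the plain-text formats defined by the other modules and emits
# traceable JSON reports (package version, config hash, seed).  The
# command-line script at inst/cli/hspfit.R is a thin dispatcher over these.

report_stamp <- function(config, seed = NA_integer_) {
  list(package = "hspfit",
       version = as.character(utils::packageVersion("hspfit")),
       config_hash = config_hash(config),
       seed = seed)
}

#' Classify solvents from a solubility CSV
#'
#' @param input Solubility CSV ([read_solubility()] format).
#' @param output Optional output CSV for the labels
#'   (`solvent,label,rationale`).
#' @param threshold Classification threshold in g/L (default 20).
#' @param overrides Optional named character vector of manual label
#'   overrides.
#' @param quiet Suppress the progress message (default `FALSE`).
#' @return The `"solvent_labels"` data frame, invisibly.
#' @export
run_classify <- function(input, output = NULL, threshold = 20,
                         overrides = NULL, quiet = FALSE) {
  measurements <- read_solubility(input)
  labels <- classify_solvents(measurements, threshold = threshold,
                              overrides = overrides)
  s <- classification_summary(labels)
  if (!quiet) {
    message(sprintf(
      "classified %d solvents at %.1f g/L (%d overrides): %d good, %d bad",
      s$n_total, threshold, length(overrides), s$n_good, s$n_bad))
  }
  if (!is.null(output)) write_labels(labels, output)
  invisible(labels)
}

#' Classify and fit a Hansen sphere from a solubility CSV
#'
#' Runs [classify_solvents()] then [fit_sphere()] and (optionally) writes
#' the JSON fit report.
#'
#' @inheritParams run_classify
#' @param solvents Solvent library CSV path, or `NULL` for the bundled
#'   library.
#' @param config A [fit_config()].
#' @param solute Solute name; defaults to the one in the solubility table.
#' @param output Optional JSON report path ([write_fit_report()]).
#' @return The `"hsp_fit"` result, invisibly.
#' @export
run_fit <- function(input, solvents = NULL, output = NULL, threshold = 20,
                    overrides = NULL, config = fit_config(), solute = NULL,
                    quiet = FALSE) {
  measurements <- read_solubility(input)
  lib <- load_solvent_library(solvents)
  labels <- classify_solvents(measurements, threshold = threshold,
                              overrides = overrides)
  solute <- solute %||% unique(measurements$solute)[1]
  fit <- fit_sphere(labels, lib, config = config, solute = solute)
  if (!quiet) {
    message(sprintf(
      "fitted sphere for %s: centre (%.1f, %.1f, %.1f), R0 %.1f, data fit %.1f%%",
      solute, fit$sphere$center[1], fit$sphere$center[2],
      fit$sphere$center[3], fit$sphere$r0, fit$data_fit_percent))
  }
  if (!is.null(output)) write_fit_report(fit, output)
  invisible(fit)
}

#' RED profiles and synergy summary for binary solvent systems
#'
#' For each `solvent1 + solvent2` system, computes the RED profile of the
#' solute across the composition grid, writes one profile CSV per system
#' (when `output_dir` is given) and a single synergy summary JSON.
#'
#' @param sphere A [hansen_sphere()], an `"hsp_fit"`, or a path to a sphere
#'   JSON ([read_hansen_sphere()]).
#' @param systems List of length-2 character vectors
#'   `c(solvent1, solvent2)`; solvent names resolve through the library.
#' @param solvents Solvent library CSV path, or `NULL` for the bundled
#'   library.
#' @param grid_step Composition step for the profile grid (default 0.1).
#' @param output_dir Optional directory for per-system CSVs and
#'   `synergy_summary.json`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `profiles` (one [red_profile()] per
#'   system) and `summary` (the serialisable synergy summary).
#' @export
run_profile <- function(sphere, systems, solvents = NULL, grid_step = 0.1,
                        output_dir = NULL, quiet = FALSE) {
  if (is.character(sphere)) sphere <- read_hansen_sphere(sphere)
  if (inherits(sphere, "hsp_fit")) sphere <- sphere$sphere
  if (!inherits(sphere, "hansen_sphere")) {
    stop_input("`sphere` must be a hansen_sphere, hsp_fit or JSON path")
  }
  if (!is.list(systems) || !length(systems) ||
      !all(vapply(systems, function(s) is.character(s) && length(s) == 2L,
                  logical(1)))) {
    stop_input("`systems` must be a list of c(solvent1, solvent2) pairs")
  }
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 0.5) {
    stop_input("grid_step must be in (0, 0.5]")
  }
  lib <- load_solvent_library(solvents)
  grid <- unique(c(seq(0, 1, by = grid_step), 1))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  profiles <- list()
  rows <- list()
  for (sys in systems) {
    r1 <- lookup_solvent(lib, sys[1])
    r2 <- lookup_solvent(lib, sys[2])
    prof <- red_profile(sphere, r1, r2, grid = grid)
    tag <- paste0(gsub("[^a-z0-9]+", "_", r1$name), "__",
                  gsub("[^a-z0-9]+", "_", r2$name))
    profiles[[tag]] <- prof
    rows[[tag]] <- list(system = paste(r1$name, "+", r2$name),
                        synergy = prof$shape == "interior_minimum",
                        x_min_grid = prof$x_min_grid,
                        x_min_closed_form = prof$x_min_closed_form,
                        red_min = prof$red_min_closed_form,
                        curvature = prof$curvature)
    if (!is.null(output_dir)) {
      write_red_profile(prof, file.path(output_dir,
                                        paste0("profile_", tag, ".csv")))
    }
    if (!quiet) {
      message(sprintf("%s + %s: %s (grid minimum at x2 = %.1f)",
                      r1$name, r2$name,
                      if (prof$shape == "interior_minimum") "synergy"
                      else "no synergy",
                      prof$x_min_grid))
    }
  }
  summary <- c(report_stamp(list(systems = systems, grid_step = grid_step)),
               list(solute = sphere$solute,
                    sphere = list(delta_d = sphere$center[[1]],
                                  delta_p = sphere$center[[2]],
                                  delta_h = sphere$center[[3]],
                                  r0 = sphere$r0),
                    systems = unname(rows)))
  if (!is.null(output_dir)) {
    jsonlite::write_json(summary,
                         file.path(output_dir, "synergy_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(profiles = profiles, summary = summary))
}

#' Generate and write a synthetic dataset
#'
#' Writes `solvents.csv` (library format), `solubility.csv`
#' ([read_solubility()] format), `labels.csv` and `metadata.json` (the full
#' generator configuration plus provenance stamp) into `output_dir`.
#'
#' @param config A [synthetic_config()].
#' @param output_dir Output directory (created if needed).
#' @param quiet Suppress the progress message.
#' @return The `"hsp_synthetic"` dataset, invisibly.
#' @export
run_simulate <- function(config = synthetic_config(), output_dir,
                         quiet = FALSE) {
  d <- generate_dataset(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_solvent_library(d$library, file.path(output_dir, "solvents.csv"))
  utils::write.csv(d$measurements, file.path(output_dir, "solubility.csv"),
                   row.names = FALSE)
  utils::write.csv(d$labels, file.path(output_dir, "labels.csv"),
                   row.names = FALSE)
  meta <- c(report_stamp(unclass(config), seed = config$seed),
            list(truth = list(delta_d = config$truth$center[[1]],
                              delta_p = config$truth$center[[2]],
                              delta_h = config$truth$center[[3]],
                              r0 = config$truth$r0),
                 n_solvents = config$n_solvents,
                 box = config$box,
                 boundary_margin = config$boundary_margin,
                 label_noise = config$label_noise,
                 solubility_map = config$solubility_map,
                 threshold = d$threshold))
  jsonlite::write_json(meta, file.path(output_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!quiet) {
    message(sprintf("wrote synthetic dataset (%d solvents, seed %d) to %s",
                    config$n_solvents, config$seed, output_dir))
  }
  invisible(d)
}

# Known keys of the plain-text run configuration.
run_config_keys <- c("solubility_csv", "solvent_csv", "output_dir",
                     "threshold", "overrides", "solute", "fit", "systems",
                     "grid_step", "seed", "log_level")

#' Read a pipeline run configuration
#'
#' YAML file with keys `solubility_csv`, `solvent_csv` (optional),
#' `output_dir`, `threshold`, `overrides` (map solvent -> label), `solute`,
#' `fit` (passed to [fit_config()]), `systems` (list of two-element solvent
#' name lists), `grid_step`, `seed` and `log_level`.  Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A validated list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_input(sprintf("run config not found: '%s'", path))
  }
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_input(paste0("malformed config: ",
                                                        conditionMessage(e))))
  if (!is.list(cfg)) stop_input("run config must be a YAML mapping")
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    stop_input(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(cfg$overrides)) cfg$overrides <- unlist(cfg$overrides)
  if (!is.null(cfg$fit)) cfg$fit <- do.call(fit_config, cfg$fit)
  if (!is.null(cfg$systems)) {
    cfg$systems <- lapply(cfg$systems, as.character)
  }
  class(cfg) <- "run_config"
  cfg
}
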