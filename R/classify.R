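# Solvent classification: turn equilibrium solubility measurements into the
# good/bad labels that drive sphere fitting.

#' Read a solubility table
#'
#' CSV with header
#' `solute,solvent,solubility_g_per_l,quantifiable[,temperature_k,pressure_mpa,...]`.
#' `quantifiable = false` marks solvents in which the solute was too
#' insoluble to calibrate (no numeric value required).  Extra columns (e.g.
#' a `source` or `lower_bound` annotation) are preserved.
#'
#' @param path CSV file path.
#' @return A data frame of measurements; temperature and pressure default to
#'   298.15 K and 0.1 MPa when absent.
#' @export
read_solubility <- function(path) {
  if (!file.exists(path)) {
    stop_input(sprintf("solubility file not found: '%s'", path))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) stop_input(paste0("malformed solubility CSV: ",
                                          conditionMessage(e))))
  required <- c("solute", "solvent", "solubility_g_per_l", "quantifiable")
  if (!all(required %in% names(df)) || nrow(df) == 0L) {
    stop_input(paste0("solubility CSV must be non-empty with columns ",
                      paste(required, collapse = ", ")))
  }
  df$quantifiable <- tolower(as.character(df$quantifiable)) %in%
    c("true", "t", "1", "yes")
  df$solubility_g_per_l <- suppressWarnings(as.numeric(df$solubility_g_per_l))
  if (any(df$quantifiable & (is.na(df$solubility_g_per_l) |
                             df$solubility_g_per_l < 0))) {
    stop_input("quantifiable rows must carry a non-negative solubility in g/L")
  }
  if (!"temperature_k" %in% names(df)) df$temperature_k <- 298.15
  if (!"pressure_mpa" %in% names(df)) df$pressure_mpa <- 0.1
  df
}

#' Classify solvents as good or bad from solubility measurements
#'
#' A solvent is "good" when the measured solubility reaches the threshold
#' (inclusive), "bad" otherwise; solvents in which the solute could not be
#' quantified are bad by construction.  Manual overrides, for deliberate
#' judgment calls on borderline solvents, are applied last and flagged as
#' such.
#'
#' @param measurements Data frame as returned by [read_solubility()] (one
#'   row per solvent for a single solute).
#' @param threshold Classification threshold in g/L; default 20.
#' @param overrides Optional named character vector, e.g.
#'   `c("n-propyl acetate" = "good")`.
#' @return A data frame of class `"solvent_labels"` with columns `solvent`,
#'   `label` (`good`/`bad`), `rationale` (`above_threshold`,
#'   `below_threshold`, `insoluble_unquantifiable`, `manual_override`) and
#'   `solubility_g_per_l`.
#' @examples
#' m <- data.frame(solute = "x", solvent = c("a", "b"),
#'                 solubility_g_per_l = c(25, 3), quantifiable = TRUE)
#' classify_solvents(m, threshold = 20)
#' @export
classify_solvents <- function(measurements, threshold = 20, overrides = NULL) {
  if (!is.data.frame(measurements) || nrow(measurements) == 0L) {
    stop_input("`measurements` must be a non-empty data frame")
  }
  if (!all(c("solvent", "solubility_g_per_l", "quantifiable") %in%
           names(measurements))) {
    stop_input("measurements need columns solvent, solubility_g_per_l, quantifiable")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0) {
    stop_input("threshold must be a single positive number (g/L)")
  }
  solv <- canonical_name(measurements$solvent)
  if (anyDuplicated(solv)) {
    stop_input(paste0("duplicate measurements for solvent(s): ",
                      paste(unique(solv[duplicated(solv)]), collapse = ", ")))
  }
  q <- measurements$quantifiable
  val <- measurements$solubility_g_per_l
  label <- ifelse(!q, "bad", ifelse(val >= threshold, "good", "bad"))
  rationale <- ifelse(!q, "insoluble_unquantifiable",
                      ifelse(val >= threshold, "above_threshold",
                             "below_threshold"))
  if (!is.null(overrides) && length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop_input("overrides must be a named character vector solvent -> label")
    }
    if (!all(overrides %in% c("good", "bad"))) {
      stop_input("override labels must be 'good' or 'bad'")
    }
    onames <- canonical_name(names(overrides))
    missing <- setdiff(onames, solv)
    if (length(missing)) {
      stop_input(paste0("override for unmeasured solvent(s): ",
                        paste(missing, collapse = ", ")))
    }
    idx <- match(onames, solv)
    label[idx] <- unname(overrides)
    rationale[idx] <- "manual_override"
  }
  out <- data.frame(solvent = solv, label = label, rationale = rationale,
                    solubility_g_per_l = val, quantifiable = q,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("solvent_labels", "data.frame")
  out
}

#' Summarise a set of solvent labels
#'
#' @param labels A [classify_solvents()] result (or any data frame with
#'   `solvent` and `label` columns).
#' @return A list of class `"classification_summary"`: counts and
#'   alphabetically sorted good/bad solvent lists.
#' @export
classification_summary <- function(labels) {
  if (!is.data.frame(labels) || nrow(labels) == 0L) {
    stop_input("`labels` must be a non-empty data frame")
  }
  good <- sort(labels$solvent[labels$label == "good"])
  bad <- sort(labels$solvent[labels$label == "bad"])
  structure(list(n_total = nrow(labels), n_good = length(good),
                 n_bad = length(bad), good = good, bad = bad),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("%d solvents: %d good, %d bad\n", x$n_total, x$n_good, x$n_bad))
  cat("good:", if (length(x$good)) paste(x$good, collapse = ", ") else "(none)", "\n")
  cat("bad: ", if (length(x$bad)) paste(x$bad, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Write / read a label table
#'
#' Plain CSV with columns `solvent,label,rationale`.
#'
#' @param labels A `"solvent_labels"` data frame.
#' @param path CSV path.
#' @return `path` (write) or the labels data frame (read).
#' @export
write_labels <- function(labels, path) {
  stopifnot(is.data.frame(labels))
  utils::write.csv(labels[, c("solvent", "label", "rationale")], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("label file not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("solvent", "label") %in% names(df)) || nrow(df) == 0L) {
    stop_input("label CSV must be non-empty with columns solvent, label")
  }
  if (!all(df$label %in% c("good", "bad"))) {
    stop_input("labels must be 'good' or 'bad'")
  }
  df$solvent <- canonical_name(df$solvent)
  class(df) <- c("solvent_labels", "data.frame")
  df
}

#' Threshold-robustness harness: re-label and refit at several thresholds
#'
#' Re-runs classification and sphere fitting at alternative solubility
#' limits (by default 15, 20 and 30 g/L) in a single call, so the
#' sensitivity of the fitted sphere to the classification threshold can be
#' inspected directly.
#'
#' @param measurements Solubility measurements ([read_solubility()] format).
#' @param lib Solvent library ([load_solvent_library()]).
#' @param thresholds Numeric vector of thresholds in g/L.
#' @param overrides Optional overrides passed to [classify_solvents()].
#' @param config Fit settings ([fit_config()]).
#' @param solute Solute name recorded in the fitted spheres.
#' @return Named list (one element per threshold) of [fit_sphere()] results.
#' @export
fit_threshold_sweep <- function(measurements, lib, thresholds = c(15, 20, 30),
                                overrides = NULL, config = fit_config(),
                                solute = "") {
  res <- lapply(thresholds, function(th) {
    labels <- classify_solvents(measurements, threshold = th,
                                overrides = overrides)
    fit_sphere(labels, lib, config = config, solute = solute)
  })
  names(res) <- paste0("threshold_", thresholds)
  res
}
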