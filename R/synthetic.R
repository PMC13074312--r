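# Seeded synthetic datasets with the statistical structure the sphere
# analysis assumes: a ground-truth sphere, a solvent cloud kept away from
# the RED = 1 boundary, labels from the truth sphere (optionally flipped),
# and solubility magnitudes decaying with RED.

#' Configuration for synthetic classification datasets
#'
#' Solvents are drawn uniformly in a box of Hansen space and
#' rejection-sampled so that no solvent has true RED within
#' `boundary_margin` of 1.  The solubility map is
#' `s = s_max * exp(-decay_k * RED^2) * exp(eps)`, `eps ~ N(0, sigma^2)`:
#' a declared generative link whose only role is to make the full
#' solubility -> threshold -> labels -> sphere pipeline exercisable.  With
#' the defaults (`s_max` 100 g/L, `decay_k = log(5)`), the RED = 1 boundary
#' maps exactly onto the 20 g/L classification threshold, so thresholding
#' noise-free solubilities recovers the true labels.  `label_noise` flips
#' each label independently; flips are realised by mirroring RED about 1 in
#' the solubility map so that emitted measurements stay consistent with the
#' flipped labels.
#'
#' @param n_solvents Number of synthetic solvents.
#' @param box Per-axis sampling ranges (MPa^(1/2)); defaults dD \[13, 20\],
#'   dP \[0, 20\], dH \[0, 25\] span the common organic-solvent region.
#' @param truth Ground-truth [hansen_sphere()].
#' @param boundary_margin Half-width of the excluded RED band around 1.
#' @param label_noise Probability of flipping each label; in \[0, 0.5).
#' @param s_max,decay_k,sigma Solubility-map parameters (g/L, -, lognormal
#'   sd).
#' @param seed Integer seed governing all draws.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_solvents = 20L,
                             box = list(delta_d = c(13, 20),
                                        delta_p = c(0, 20),
                                        delta_h = c(0, 25)),
                             truth = hansen_sphere(12, 10, 12, 8,
                                                   solute = "synthetic solute"),
                             boundary_margin = 0.15, label_noise = 0,
                             s_max = 100, decay_k = log(5), sigma = 0,
                             seed = 1L) {
  if (!inherits(truth, "hansen_sphere")) {
    stop_input("`truth` must be a hansen_sphere")
  }
  if (!is.numeric(label_noise) || label_noise < 0 || label_noise >= 0.5) {
    stop_input("label_noise must lie in [0, 0.5)")
  }
  if (!is.numeric(boundary_margin) || boundary_margin < 0) {
    stop_input("boundary_margin must be >= 0")
  }
  stopifnot(n_solvents >= 4, s_max > 0, decay_k > 0, sigma >= 0)
  structure(list(n_solvents = as.integer(n_solvents), box = box,
                 truth = truth, boundary_margin = boundary_margin,
                 label_noise = label_noise,
                 solubility_map = list(s_max = s_max, decay_k = decay_k,
                                       sigma = sigma),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic solvent set, labels and solubility table
#'
#' Fully reproducible from `config$seed` (per-stage sub-seeds are derived
#' from it).  The threshold that recovers the true labels from noise-free
#' solubilities is `s_max * exp(-decay_k)` (20 g/L under the defaults).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `"hsp_synthetic"`: `library` (a
#'   `"solvent_library"` of the synthetic solvents), `measurements`
#'   (solubility table in [read_solubility()] format), `labels` (observed
#'   label, true label and true RED per solvent), `threshold` (the
#'   label-recovering threshold) and the `config`.
#' @examples
#' d <- generate_dataset(synthetic_config(seed = 7))
#' classification_summary(classify_solvents(d$measurements, d$threshold))
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_solvents
  box <- config$box
  truth <- config$truth
  m <- config$boundary_margin

  pts <- with_seed(sub_seed(config$seed, 1L), {
    acc <- matrix(numeric(0), 0, 3)
    attempts <- 0
    max_attempts <- max(2000, 100 * n)
    while (nrow(acc) < n && attempts < max_attempts) {
      k <- max(4 * n, 64)
      cand <- cbind(stats::runif(k, box$delta_d[1], box$delta_d[2]),
                    stats::runif(k, box$delta_p[1], box$delta_p[2]),
                    stats::runif(k, box$delta_h[1], box$delta_h[2]))
      attempts <- attempts + k
      red_c <- ra_to_points(truth$center, cand) / truth$r0
      keep <- abs(red_c - 1) > m
      acc <- rbind(acc, cand[keep, , drop = FALSE])
    }
    if (nrow(acc) < n) {
      stop_constraint(sprintf(
        paste0("boundary margin %.2f is infeasible in this box ",
               "(rejection rate %.1f%%); use a smaller margin"),
        m, 100 * (1 - nrow(acc) / attempts)))
    }
    acc[seq_len(n), , drop = FALSE]
  })

  names_v <- sprintf("solvent_%02d", seq_len(n))
  red_true <- ra_to_points(truth$center, pts) / truth$r0
  true_label <- ifelse(red_true <= 1, "good", "bad")

  flip <- if (config$label_noise > 0) {
    with_seed(sub_seed(config$seed, 2L),
              stats::runif(n) < config$label_noise)
  } else {
    rep(FALSE, n)
  }
  # mirror RED about 1 for flipped solvents so the emitted solubility lands
  # on the other side of the recovery threshold
  red_eff <- ifelse(flip, pmax(2 - red_true, 0), red_true)
  label <- ifelse(red_eff <= 1, "good", "bad")

  map <- config$solubility_map
  eps <- if (map$sigma > 0) {
    with_seed(sub_seed(config$seed, 3L), stats::rnorm(n, 0, map$sigma))
  } else {
    rep(0, n)
  }
  sol <- map$s_max * exp(-map$decay_k * red_eff^2) * exp(eps)

  lib <- data.frame(name = names_v, delta_d = pts[, 1], delta_p = pts[, 2],
                    delta_h = pts[, 3], synonyms = "", source = "synthetic",
                    stringsAsFactors = FALSE)
  attr(lib, "version") <- sprintf("synthetic-seed-%d", config$seed)
  class(lib) <- c("solvent_library", "data.frame")

  measurements <- data.frame(
    solute = truth$solute, solvent = names_v, solubility_g_per_l = sol,
    quantifiable = TRUE, temperature_k = 298.15, pressure_mpa = 0.1,
    stringsAsFactors = FALSE)
  labels <- data.frame(solvent = names_v, label = label,
                       true_label = true_label, red_true = red_true,
                       flipped = flip, stringsAsFactors = FALSE)
  structure(list(library = lib, measurements = measurements, labels = labels,
                 threshold = map$s_max * exp(-map$decay_k), config = config),
            class = "hsp_synthetic")
}

#' @export
print.hsp_synthetic <- function(x, ...) {
  cat(sprintf(
    "Synthetic HSP dataset: %d solvents (seed %d), %d good / %d bad, margin %.2f\n",
    nrow(x$labels), x$config$seed, sum(x$labels$label == "good"),
    sum(x$labels$label == "bad"), x$config$boundary_margin))
  cat(sprintf("  truth: centre (%.1f, %.1f, %.1f), R0 %.1f; label-recovering threshold %.1f g/L\n",
              x$config$truth$center[1], x$config$truth$center[2],
              x$config$truth$center[3], x$config$truth$r0, x$threshold))
  invisible(x)
}
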