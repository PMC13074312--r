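# Hansen sphere fitting: constrained global maximisation of a
# geometric-mean desirability ("size factor") over centre coordinates and
# interaction radius.
#
# The radius is handled by substitution rather than penalty: candidates are
# (dD, dP, dH, s) with R0 = max(1, max Ra over good solvents + s), s >= 0.
# Every candidate therefore satisfies the hard containment constraint
# R0 >= Ra,good,MAX by construction, and all good solvents end up at
# RED <= 1 in every returned sphere.

#' Sphere-fit configuration
#'
#' Default parameter bounds encode the physically motivated constraint set
#' for polyphenol-like solutes: 10 <= dD <= 25, 5 <= dP, dH <= 25 (all in
#' MPa^(1/2)), R0 between 1 and max(Ra over good solvents) + 2, never below
#' the largest good-solvent distance.  `r0_soft_max` is the nominal upper
#' bound on R0 (10 MPa^(1/2)); when the good-solvent set itself forces a
#' larger radius the containment constraint takes precedence and a warning
#' names the binding solvent.
#'
#' @param seed Integer seed; the fit is fully deterministic given it.
#' @param n_restarts Independent optimizer restarts (best result kept).
#' @param pop_size,max_gen Differential-evolution population size and
#'   generation count.
#' @param f,cr DE mutation weight and crossover rate.
#' @param bounds List of per-parameter `c(lower, upper)` bounds for
#'   `delta_d`, `delta_p`, `delta_h` and the radius slack `r0_slack`
#'   (R0 = max Ra,good + slack).
#' @param r0_min,r0_soft_max Lower bound and nominal upper bound on R0.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(seed = 42L, n_restarts = 10L, pop_size = 40L,
                       max_gen = 150L, f = 0.8, cr = 0.9,
                       bounds = list(delta_d = c(10, 25),
                                     delta_p = c(5, 25),
                                     delta_h = c(5, 25),
                                     r0_slack = c(0, 2)),
                       r0_min = 1, r0_soft_max = 10) {
  cfg <- list(seed = as.integer(seed), n_restarts = as.integer(n_restarts),
              pop_size = as.integer(pop_size), max_gen = as.integer(max_gen),
              f = f, cr = cr, bounds = bounds, r0_min = r0_min,
              r0_soft_max = r0_soft_max, objective = "penalized_datafit")
  stopifnot(cfg$n_restarts >= 1, cfg$pop_size >= 8, cfg$max_gen >= 1,
            all(vapply(bounds, function(b) b[1] <= b[2], logical(1))))
  class(cfg) <- "fit_config"
  cfg
}

# Desirability objective for a population of candidates.
#   theta: P x 4 matrix (dD, dP, dH, s);  S: n x 3 solvent coordinates;
#   good: logical length n.  Returns the geometric-mean desirability `obj`
#   (1 at perfect separation), the realised radius `r0`, and the search
#   score = obj - 1e-6 * R0 implementing the smaller-radius tie-break.
de_objective <- function(theta, S, good, r0_min = 1) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  n <- nrow(S)
  ra2 <- 4 * outer(theta[, 1], S[, 1], "-")^2 +
             outer(theta[, 2], S[, 2], "-")^2 +
             outer(theta[, 3], S[, 3], "-")^2
  ra <- sqrt(ra2)                                   # P x n
  ra_good <- ra[, good, drop = FALSE]
  max_ra_good <- do.call(pmax, c(asplit(ra_good, 2), list(numeric(nrow(ra)))))
  r0 <- pmax(r0_min, max_ra_good + theta[, 4])
  # good solvents are inside by construction; penalty accrues only for bad
  # solvents captured inside the sphere: d_i = exp(-|Ra_i - R0|)
  pen <- 0
  if (any(!good)) {
    ra_bad <- ra[, !good, drop = FALSE]
    excess <- pmax(r0 - ra_bad, 0)                  # recycled by column
    pen <- rowSums(excess)
  }
  obj <- exp(-pen / n)
  list(score = obj - 1e-6 * r0, obj = obj, r0 = r0, max_ra_good = max_ra_good)
}

# Plain DE (rand/1/bin) maximising de_objective over the bounded box.
run_de <- function(S, good, cfg, seed, init) {
  lo <- vapply(cfg$bounds, `[`, numeric(1), 1)
  hi <- vapply(cfg$bounds, `[`, numeric(1), 2)
  P <- cfg$pop_size
  with_seed(seed, {
    pop <- sapply(1:4, function(j) stats::runif(P, lo[j], hi[j]))
    pop[1, ] <- pmin(pmax(init, lo), hi)
    ev <- de_objective(pop, S, good, cfg$r0_min)
    score <- ev$score
    n_eval <- P
    for (g in seq_len(cfg$max_gen)) {
      r1 <- sample.int(P, P, replace = TRUE)
      r2 <- sample.int(P, P, replace = TRUE)
      r3 <- sample.int(P, P, replace = TRUE)
      mutant <- pop[r1, ] + cfg$f * (pop[r2, ] - pop[r3, ])
      mutant <- pmin(pmax(mutant, rep(lo, each = P)), rep(hi, each = P))
      mask <- matrix(stats::runif(P * 4) < cfg$cr, P, 4)
      mask[cbind(seq_len(P), sample.int(4, P, replace = TRUE))] <- TRUE
      trial <- ifelse(mask, mutant, pop)
      ev_t <- de_objective(trial, S, good, cfg$r0_min)
      n_eval <- n_eval + P
      accept <- ev_t$score >= score        # accept ties: drift on plateaus
      pop[accept, ] <- trial[accept, ]
      score[accept] <- ev_t$score[accept]
    }
    best <- which.max(score)
    ev_b <- de_objective(pop[best, , drop = FALSE], S, good, cfg$r0_min)
    list(theta = pop[best, ], score = score[best], obj = ev_b$obj,
         r0 = ev_b$r0, max_ra_good = ev_b$max_ra_good, n_eval = n_eval)
  })
}

#' Fit a Hansen sphere to good/bad solvent labels
#'
#' Maximises a geometric-mean desirability in which every correctly
#' classified solvent contributes 1 and every misclassified solvent
#' contributes `exp(-|Ra - R0|)`, over the bounded box of [fit_config()],
#' using a seeded differential-evolution search with restarts.  The initial
#' estimate is the component-wise mean of the good-solvent HSPs.  Ties at
#' equal desirability are resolved toward the smaller radius.  The
#' containment constraint `R0 >= max(Ra, good)` is enforced by construction,
#' so every good solvent has RED <= 1 in the returned sphere.
#'
#' @param labels Solvent labels ([classify_solvents()] or [read_labels()]).
#' @param lib Solvent library ([load_solvent_library()]) resolving every
#'   labelled solvent.
#' @param config A [fit_config()].
#' @param solute Solute name recorded in the fitted sphere.
#' @return An object of class `"hsp_fit"`: the fitted [hansen_sphere()],
#'   `data_fit_percent`, a `per_solvent` table of distances and RED values,
#'   `objective_value`, `n_evaluations` and `seed_used`.
#' @examples
#' path <- system.file("extdata", "solubility_resveratrol_synthetic.csv",
#'                     package = "hspfit")
#' labels <- classify_solvents(read_solubility(path))
#' fit <- fit_sphere(labels, load_solvent_library(),
#'                   config = fit_config(n_restarts = 2))
#' @export
fit_sphere <- function(labels, lib, config = fit_config(), solute = "") {
  if (!is.data.frame(labels) || !all(c("solvent", "label") %in% names(labels))) {
    stop_input("`labels` must be a data frame with columns solvent, label")
  }
  if (!all(labels$label %in% c("good", "bad"))) {
    stop_input("labels must be 'good' or 'bad'")
  }
  S <- resolve_hsp_matrix(lib, labels$solvent)
  good <- labels$label == "good"
  if (!any(good)) {
    stop_constraint("no good solvents: a Hansen sphere cannot be fitted")
  }
  if (nrow(S) < 4) {
    warning("fewer than 4 labelled solvents; the fit is underdetermined")
  }
  if (all(good)) {
    warning("all solvents labelled good; returning the minimal enclosing sphere")
  }
  lo <- vapply(config$bounds, `[`, numeric(1), 1)
  hi <- vapply(config$bounds, `[`, numeric(1), 2)
  init <- c(pmin(pmax(colMeans(S[good, , drop = FALSE]), lo[1:3]), hi[1:3]), 0)

  best <- NULL
  n_eval <- 0
  for (r in seq_len(config$n_restarts)) {
    res <- run_de(S, good, config, sub_seed(config$seed, r), init)
    n_eval <- n_eval + res$n_eval
    if (is.null(best) || res$score > best$score) best <- res
  }

  if (best$max_ra_good > config$r0_soft_max) {
    ra_good <- ra_to_points(hsp(best$theta[1], best$theta[2], best$theta[3]),
                            S[good, , drop = FALSE])
    binding <- labels$solvent[good][which.max(ra_good)]
    warning(sprintf(
      paste0("constraint conflict: good solvent '%s' (Ra = %.2f) forces ",
             "R0 = %.2f above the nominal upper bound %.1f; the containment ",
             "constraint takes precedence"),
      binding, max(ra_good), best$r0, config$r0_soft_max))
  }

  sphere <- hansen_sphere(best$theta[1], best$theta[2], best$theta[3],
                          best$r0, solute = solute, provenance = "fitted")
  ev <- evaluate_sphere(sphere, labels, lib)
  structure(list(sphere = sphere,
                 data_fit_percent = ev$data_fit_percent,
                 per_solvent = ev$per_solvent,
                 objective_value = best$obj,
                 n_evaluations = n_eval,
                 seed_used = config$seed,
                 config = config),
            class = "hsp_fit")
}

#' Evaluate any Hansen sphere against a labelled solvent set
#'
#' Computes per-solvent Hansen distances, RED values and classification
#' agreement for a given sphere, with no optimisation — e.g. to audit a
#' literature sphere against one's own labels.  A solvent is correctly
#' classified when it is good with RED <= 1 or bad with RED > 1.
#'
#' @inheritParams fit_sphere
#' @param sphere A [hansen_sphere()].
#' @return An object of class `"sphere_evaluation"`: `per_solvent` data
#'   frame (`solvent`, `label`, `ra`, `red`, `correctly_classified`),
#'   `data_fit_percent` and the desirability `objective_value`.
#' @export
evaluate_sphere <- function(sphere, labels, lib) {
  if (!inherits(sphere, "hansen_sphere")) {
    stop_input("`sphere` must be a hansen_sphere object")
  }
  if (!is.data.frame(labels) || !all(c("solvent", "label") %in% names(labels))) {
    stop_input("`labels` must be a data frame with columns solvent, label")
  }
  S <- resolve_hsp_matrix(lib, labels$solvent)
  ra <- ra_to_points(sphere$center, S)
  red_v <- ra / sphere$r0
  good <- labels$label == "good"
  correct <- (good & red_v <= 1) | (!good & red_v > 1)
  desir <- ifelse(correct, 1, exp(-abs(ra - sphere$r0)))
  per <- data.frame(solvent = labels$solvent, label = labels$label,
                    ra = ra, red = red_v, correctly_classified = correct,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(sphere = sphere, per_solvent = per,
                 data_fit_percent = 100 * mean(correct),
                 objective_value = exp(mean(log(desir)))),
            class = "sphere_evaluation")
}

#' @export
print.hsp_fit <- function(x, ...) {
  cat("Hansen sphere fit\n")
  print(x$sphere)
  cat(sprintf("  data fit: %.1f%%  (objective %.4f, %d evaluations, seed %d)\n",
              x$data_fit_percent, x$objective_value, x$n_evaluations,
              x$seed_used))
  mis <- x$per_solvent[!x$per_solvent$correctly_classified, , drop = FALSE]
  if (nrow(mis)) {
    cat("  misclassified:",
        paste(sprintf("%s (%s, RED %.2f)", mis$solvent, mis$label, mis$red),
              collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
print.sphere_evaluation <- function(x, ...) {
  cat(sprintf("Sphere evaluation: data fit %.1f%% over %d solvents\n",
              x$data_fit_percent, nrow(x$per_solvent)))
  df <- x$per_solvent
  df$ra <- round(df$ra, 2)
  df$red <- round(df$red, 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Serialise a fit result or sphere to JSON
#'
#' The report embeds the package version, a configuration hash and the seed
#' so that any emitted sphere can be traced to the run that produced it.
#'
#' @param fit An `"hsp_fit"` (or a bare [hansen_sphere()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  if (inherits(fit, "hansen_sphere")) {
    fit <- list(sphere = fit, data_fit_percent = NA_real_,
                per_solvent = NULL, objective_value = NA_real_,
                seed_used = NA_integer_, config = NULL)
  }
  sph <- fit$sphere
  report <- list(
    package = "hspfit",
    version = as.character(utils::packageVersion("hspfit")),
    solute = sph$solute,
    center = list(delta_d = sph$center[[1]], delta_p = sph$center[[2]],
                  delta_h = sph$center[[3]]),
    delta_t = hsp_total(sph$center),
    r0 = sph$r0,
    provenance = sph$provenance,
    data_fit_percent = fit$data_fit_percent,
    objective_value = fit$objective_value,
    seed = fit$seed_used,
    config = if (!is.null(fit$config)) unclass(fit$config),
    config_hash = config_hash(unclass(fit$config)),
    per_solvent = fit$per_solvent)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a Hansen sphere from a JSON report
#'
#' Accepts files written by [write_fit_report()] as well as minimal
#' `{solute, center: {delta_d, delta_p, delta_h}, r0}` JSON.
#'
#' @param path JSON file path.
#' @return A [hansen_sphere()].
#' @export
read_hansen_sphere <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("sphere file not found: '%s'", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$center) || is.null(x$r0)) {
    stop_input("sphere JSON must contain 'center' and 'r0'")
  }
  hansen_sphere(x$center$delta_d, x$center$delta_p, x$center$delta_h, x$r0,
                solute = x$solute %||% "",
                provenance = x$provenance %||% "literature")
}

#' Export sphere and solvent coordinates for external plotting
#'
#' Writes a flat CSV of solvent points (with labels and RED values) plus the
#' sphere centre and radius — a static alternative to interactive 3-D
#' renderings of Hansen space.
#'
#' @inheritParams evaluate_sphere
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_hansen_space <- function(sphere, labels, lib, path) {
  ev <- evaluate_sphere(sphere, labels, lib)
  S <- resolve_hsp_matrix(lib, labels$solvent)
  pts <- data.frame(kind = "solvent", name = labels$solvent,
                    delta_d = S[, 1], delta_p = S[, 2], delta_h = S[, 3],
                    label = labels$label, red = ev$per_solvent$red,
                    r0 = NA_real_, stringsAsFactors = FALSE)
  ctr <- data.frame(kind = "sphere_center", name = sphere$solute,
                    delta_d = sphere$center[[1]], delta_p = sphere$center[[2]],
                    delta_h = sphere$center[[3]], label = NA_character_,
                    red = 0, r0 = sphere$r0, stringsAsFactors = FALSE)
  utils::write.csv(rbind(pts, ctr), path, row.names = FALSE)
  invisible(path)
}
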