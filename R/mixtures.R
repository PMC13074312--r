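# Binary solvent mixtures: linear HSP mixing on mole fraction, RED profiles
# across composition, the closed-form minimum-RED composition, and synergy
# classification.
#
# Because the mixture HSP is linear in composition, the squared Hansen
# distance along the mixing path is a convex quadratic
# Ra^2(x) = a x^2 + b x + c with a >= 0, so a RED profile has at most one
# interior minimum and the minimising composition is available in closed
# form.

#' Hansen parameters of a binary solvent mixture
#'
#' Component-wise linear blend on mole fraction:
#' \eqn{\delta_i = \delta_1 x_1 + \delta_2 (1 - x_1)} for i = D, P, H.
#' Mole-fraction weighting is the convention used throughout the package; a
#' volume-fraction blend is available behind `molar_volumes` for users who
#' supply the required molar volumes.
#'
#' @param s1,s2 HSP triples of the two pure solvents (anything [as_hsp()]
#'   accepts, including [lookup_solvent()] records).
#' @param x1 Mole fraction of solvent 1, in \[0, 1\].
#' @param molar_volumes Optional numeric length-2 vector (cm^3/mol) of the
#'   two solvents; when supplied, weighting is by volume fraction instead of
#'   mole fraction.
#' @return The mixture HSP triple.
#' @examples
#' mix_hsp(hsp(15.1, 12.3, 22.3), hsp(16.0, 9.0, 5.1), x1 = 0.5)
#' @export
mix_hsp <- function(s1, s2, x1, molar_volumes = NULL) {
  s1 <- as_hsp(s1)
  s2 <- as_hsp(s2)
  if (!is.numeric(x1) || length(x1) != 1L || !is.finite(x1) ||
      x1 < 0 || x1 > 1) {
    stop_input("x1 must be a single mole fraction in [0, 1]")
  }
  w1 <- x1
  if (!is.null(molar_volumes)) {
    if (!is.numeric(molar_volumes) || length(molar_volumes) != 2L ||
        any(molar_volumes <= 0)) {
      stop_input("molar_volumes must be two positive numbers (cm^3/mol)")
    }
    w1 <- x1 * molar_volumes[1] /
      (x1 * molar_volumes[1] + (1 - x1) * molar_volumes[2])
  }
  v <- w1 * unclass(s1) + (1 - w1) * unclass(s2)
  hsp(v[1], v[2], v[3])
}

# Quadratic coefficients of Ra^2 along the mixing path, indexed by x2 (mole
# fraction of solvent 2): Ra^2(x2) = a x2^2 + b x2 + c.
mixing_quadratic <- function(sphere, s1, s2) {
  c0 <- unclass(as_hsp(s1)) - unclass(sphere$center)
  dv <- unclass(as_hsp(s2)) - unclass(as_hsp(s1))
  w <- c(4, 1, 1)
  list(a = sum(w * dv^2), b = 2 * sum(w * c0 * dv), c = sum(w * c0^2))
}

#' RED profile of a solute across a binary solvent mixture
#'
#' Computes the mixture HSP ([mix_hsp()]), Hansen distance and RED at every
#' grid composition, classifies the profile shape, and reports both the grid
#' argmin and the closed-form minimising composition.  Compositions are
#' indexed by the mole fraction of solvent 2 (`x2`), so `x2 = 0` is pure
#' solvent 1.  The profile has shape `"interior_minimum"` when the grid
#' minimum lies strictly below both endpoint RED values, and `"monotonic"`
#' otherwise; grid ties resolve to the smaller `x2`.
#'
#' @param sphere The solute's [hansen_sphere()].
#' @param s1,s2 Pure-solvent HSPs (anything [as_hsp()] accepts).
#' @param grid Strictly increasing compositions in \[0, 1\]; default 0 to 1
#'   in steps of 0.1.
#' @param names Optional `c(solvent1, solvent2)` names for reporting.
#' @return An object of class `"red_profile"`: `points` data frame
#'   (`x2, delta_d, delta_p, delta_h, ra, red`), `shape`, `x_min_grid`,
#'   `x_min_closed_form`, `red_min_closed_form` and the quadratic curvature
#'   `a` (a flatness diagnostic).
#' @examples
#' resv <- hansen_sphere(12.2, 9.9, 12.7, 10.1)
#' lib <- load_solvent_library()
#' red_profile(resv, lookup_solvent(lib, "methanol"),
#'             lookup_solvent(lib, "MiBK"))
#' @export
red_profile <- function(sphere, s1, s2, grid = seq(0, 1, by = 0.1),
                        names = c("solvent1", "solvent2")) {
  if (!inherits(sphere, "hansen_sphere")) {
    stop_input("`sphere` must be a hansen_sphere object")
  }
  nm1 <- if (is.list(s1) && !is.null(s1$name)) s1$name else names[1]
  nm2 <- if (is.list(s2) && !is.null(s2$name)) s2$name else names[2]
  s1 <- as_hsp(s1)
  s2 <- as_hsp(s2)
  if (!is.numeric(grid) || length(grid) < 2L || any(grid < 0) ||
      any(grid > 1) || any(diff(grid) <= 0)) {
    stop_input("grid must be strictly increasing mole fractions in [0, 1]")
  }
  q <- mixing_quadratic(sphere, s1, s2)
  ra <- sqrt(pmax(q$a * grid^2 + q$b * grid + q$c, 0))
  mix <- outer(grid, unclass(s2)) + outer(1 - grid, unclass(s1))
  red_v <- ra / sphere$r0
  i_min <- which.min(red_v)                # first index: ties -> smaller x2
  interior <- red_v[i_min] < red_v[1] && red_v[i_min] < red_v[length(red_v)]
  cf <- min_red_composition(sphere, s1, s2)
  structure(list(
    solute = sphere,
    solvents = c(nm1, nm2),
    points = data.frame(x2 = grid, delta_d = mix[, 1], delta_p = mix[, 2],
                        delta_h = mix[, 3], ra = ra, red = red_v),
    shape = if (interior) "interior_minimum" else "monotonic",
    x_min_grid = grid[i_min],
    red_min_grid = red_v[i_min],
    x_min_closed_form = cf$x_min,
    red_min_closed_form = cf$red_min,
    curvature = q$a),
    class = "red_profile")
}

#' Closed-form composition of minimum RED
#'
#' Exact minimiser of RED over the mixing path: with
#' \eqn{R_a^2(x_2) = a x_2^2 + b x_2 + c} (a >= 0), the minimum lies at
#' \eqn{x^* = \mathrm{clamp}(-b / 2a, 0, 1)}; for a degenerate path
#' (identical solvents, a = 0) the profile is constant or linear in
#' \eqn{R_a^2} and the endpoint with the smaller RED is returned (ties to
#' `x2 = 0`).
#'
#' @inheritParams red_profile
#' @return List with `x_min` (mole fraction of solvent 2), `red_min`, and
#'   the quadratic coefficients `a`, `b`, `c`.
#' @export
min_red_composition <- function(sphere, s1, s2) {
  if (!inherits(sphere, "hansen_sphere")) {
    stop_input("`sphere` must be a hansen_sphere object")
  }
  q <- mixing_quadratic(sphere, as_hsp(s1), as_hsp(s2))
  red_at <- function(x) sqrt(max(q$a * x^2 + q$b * x + q$c, 0)) / sphere$r0
  if (q$a > 0) {
    x_min <- min(max(-q$b / (2 * q$a), 0), 1)
  } else {
    x_min <- if (red_at(1) < red_at(0)) 1 else 0
  }
  list(x_min = x_min, red_min = red_at(x_min), a = q$a, b = q$b, c = q$c)
}

#' Predict synergistic solubility enhancement in a binary mixture
#'
#' A mixture is predicted synergistic when its RED profile has an interior
#' minimum — i.e. some blend of the two solvents sits closer to the solute
#' in Hansen space than either pure solvent, matching the interior
#' solubility maximum observed in synergistic systems.
#'
#' @inheritParams red_profile
#' @return An object of class `"synergy_report"`: `synergy` (logical),
#'   `x_at_min` (grid composition of minimum RED), `red_at_min`,
#'   `endpoint_reds` (pure-solvent REDs), `x_min_closed_form` and
#'   `curvature`.
#' @examples
#' resv <- hansen_sphere(12.2, 9.9, 12.7, 10.1)
#' lib <- load_solvent_library()
#' predict_synergy(resv, lookup_solvent(lib, "methanol"),
#'                 lookup_solvent(lib, "MEK"))
#' @export
predict_synergy <- function(sphere, s1, s2, grid = seq(0, 1, by = 0.1),
                            names = c("solvent1", "solvent2")) {
  prof <- red_profile(sphere, s1, s2, grid = grid, names = names)
  structure(list(
    solute = sphere$solute,
    solvents = prof$solvents,
    synergy = prof$shape == "interior_minimum",
    x_at_min = prof$x_min_grid,
    red_at_min = prof$red_min_grid,
    endpoint_reds = c(prof$points$red[1],
                      prof$points$red[nrow(prof$points)]),
    x_min_closed_form = prof$x_min_closed_form,
    curvature = prof$curvature),
    class = "synergy_report")
}

#' @export
print.red_profile <- function(x, ...) {
  cat(sprintf("RED profile%s: %s + %s (x2 = mole fraction of %s)\n",
              if (nzchar(x$solute$solute)) paste0(" of ", x$solute$solute) else "",
              x$solvents[1], x$solvents[2], x$solvents[2]))
  cat(sprintf("  shape: %s; grid minimum RED %.2f at x2 = %.2f (closed form x* = %.3f)\n",
              x$shape, x$red_min_grid, x$x_min_grid, x$x_min_closed_form))
  pts <- x$points
  pts[, -1] <- round(pts[, -1], 2)
  print.data.frame(pts, row.names = FALSE)
  invisible(x)
}

#' @export
print.synergy_report <- function(x, ...) {
  cat(sprintf("%s + %s: %s\n", x$solvents[1], x$solvents[2],
              if (x$synergy) "synergy predicted (interior RED minimum)"
              else "no synergy predicted (monotonic RED profile)"))
  cat(sprintf("  minimum RED %.2f at x2 = %.2f; endpoint REDs %.2f / %.2f\n",
              x$red_at_min, x$x_at_min, x$endpoint_reds[1], x$endpoint_reds[2]))
  invisible(x)
}

#' Write a RED profile to CSV
#'
#' One row per grid composition: `x2,delta_d,delta_p,delta_h,ra,red`.
#'
#' @param profile A [red_profile()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_red_profile <- function(profile, path) {
  stopifnot(inherits(profile, "red_profile"))
  utils::write.csv(profile$points, path, row.names = FALSE)
  invisible(path)
}
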