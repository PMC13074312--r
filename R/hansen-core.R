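# Hansen-space geometry: the three-component decomposition of cohesive
# energy density, the factor-4 scaled metric, and RED.

#' Hansen solubility parameter triple
#'
#' Constructs a point in Hansen space from its dispersion, polar and
#' hydrogen-bonding components, all in MPa^(1/2).  The total parameter
#' \eqn{\delta_T = \sqrt{\delta_D^2 + \delta_P^2 + \delta_H^2}} is available
#' through [hsp_total()].
#'
#' @param delta_d Dispersion component (MPa^(1/2)), non-negative.
#' @param delta_p Polar component (MPa^(1/2)), non-negative.
#' @param delta_h Hydrogen-bonding component (MPa^(1/2)), non-negative.
#' @return An object of class `"hsp"`: a named numeric vector of length 3.
#' @examples
#' hsp(12.2, 9.9, 12.7)
#' @export
hsp <- function(delta_d, delta_p, delta_h) {
  v <- c(delta_d, delta_p, delta_h)
  if (!is.numeric(v) || length(v) != 3L || anyNA(v) || any(!is.finite(v))) {
    stop_input("Hansen parameters must be three finite numbers (MPa^(1/2))")
  }
  if (any(v < 0)) {
    stop_input("Hansen parameters must be non-negative")
  }
  structure(stats::setNames(as.numeric(v), c("delta_d", "delta_p", "delta_h")),
            class = "hsp")
}

#' Coerce to an HSP triple
#'
#' Accepts an `"hsp"` object, a numeric vector of length 3 (taken as
#' \eqn{\delta_D, \delta_P, \delta_H}), or a list/data.frame row with
#' `delta_d`, `delta_p`, `delta_h` fields (e.g. a solvent record).
#'
#' @param x Object to coerce.
#' @return An `"hsp"` object.
#' @export
as_hsp <- function(x) {
  if (inherits(x, "hsp")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(hsp(x[1], x[2], x[3]))
  if ((is.list(x) || is.data.frame(x)) &&
      all(c("delta_d", "delta_p", "delta_h") %in% names(x))) {
    return(hsp(x$delta_d[1], x$delta_p[1], x$delta_h[1]))
  }
  if (is.list(x) && !is.null(x$hsp)) return(as_hsp(x$hsp))
  stop_input("cannot interpret object as an HSP triple")
}

#' @export
print.hsp <- function(x, ...) {
  cat(sprintf(
    "HSP triple (MPa^1/2): dD = %.1f, dP = %.1f, dH = %.1f  [dT = %.1f]\n",
    x[1], x[2], x[3], hsp_total(x)))
  invisible(x)
}

#' Total solubility parameter
#'
#' Euclidean norm of the three partial Hansen parameters,
#' \eqn{\delta_T = \sqrt{\delta_D^2 + \delta_P^2 + \delta_H^2}} (MPa^(1/2)).
#'
#' @param x An HSP triple (or anything [as_hsp()] accepts).
#' @return The total parameter \eqn{\delta_T} in MPa^(1/2).
#' @examples
#' hsp_total(hsp(12.2, 9.9, 12.7))  # 20.2
#' @export
hsp_total <- function(x) {
  x <- as_hsp(x)
  sqrt(sum(unclass(x)^2))
}

#' Hansen distance between two points in Hansen space
#'
#' The solute-solvent affinity metric
#' \eqn{R_a = \sqrt{4(\delta_{Da}-\delta_{Db})^2 + (\delta_{Pa}-\delta_{Pb})^2
#' + (\delta_{Ha}-\delta_{Hb})^2}}.  The factor 4 on the dispersion term is
#' part of the standard definition and is what sphere fitting and RED use
#' throughout.  The unweighted Euclidean distance, as seen in 3-D renderings
#' of Hansen space, is available behind the explicit `visual` flag; it must
#' not be used for solvent selection.
#'
#' @param a,b HSP triples (or anything [as_hsp()] accepts).
#' @param visual If `TRUE`, drop the factor 4 (plain Euclidean distance,
#'   for plotting only).  Default `FALSE`.
#' @return Distance in MPa^(1/2).
#' @examples
#' hansen_distance(hsp(12.2, 9.9, 12.7), hsp(16.0, 5.7, 15.8))  # 9.22
#' @export
hansen_distance <- function(a, b, visual = FALSE) {
  a <- as_hsp(a)
  b <- as_hsp(b)
  w <- c(if (isTRUE(visual)) 1 else 4, 1, 1)
  sqrt(sum(w * (unclass(a) - unclass(b))^2))
}

# Vectorised factor-4 distance from one centre to the rows of an n x 3
# matrix of solvent coordinates.
ra_to_points <- function(center, m) {
  center <- unclass(as_hsp(center))
  sqrt(4 * (m[, 1] - center[1])^2 +
           (m[, 2] - center[2])^2 +
           (m[, 3] - center[3])^2)
}

#' Hansen solubility sphere of a solute
#'
#' A solute's position in Hansen space together with its interaction radius
#' \eqn{R_0}.  Solvents with Hansen distance \eqn{R_a \le R_0} (RED
#' \eqn{\le 1}) are predicted to be good solvents.
#'
#' @param delta_d,delta_p,delta_h Sphere centre components (MPa^(1/2)).
#' @param r0 Interaction radius \eqn{R_0} (MPa^(1/2)), strictly positive.
#' @param solute Solute name (text).
#' @param provenance Either `"fitted"` (from solubility data) or
#'   `"literature"`.
#' @return An object of class `"hansen_sphere"`.
#' @examples
#' hansen_sphere(12.2, 9.9, 12.7, 10.1, solute = "trans-resveratrol",
#'               provenance = "literature")
#' @export
hansen_sphere <- function(delta_d, delta_p, delta_h, r0, solute = "",
                          provenance = c("fitted", "literature")) {
  provenance <- match.arg(provenance)
  center <- hsp(delta_d, delta_p, delta_h)
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 <= 0) {
    stop_input("sphere radius r0 must be a single positive number")
  }
  structure(list(center = center, r0 = as.numeric(r0),
                 solute = as.character(solute), provenance = provenance),
            class = "hansen_sphere")
}

#' @export
print.hansen_sphere <- function(x, ...) {
  cat(sprintf("Hansen sphere%s (%s)\n",
              if (nzchar(x$solute)) paste0(" of ", x$solute) else "",
              x$provenance))
  cat(sprintf("  centre (MPa^1/2): dD = %.1f, dP = %.1f, dH = %.1f  [dT = %.1f]\n",
              x$center[1], x$center[2], x$center[3], hsp_total(x$center)))
  cat(sprintf("  radius R0 = %.1f MPa^1/2\n", x$r0))
  invisible(x)
}

#' Relative energy difference (RED)
#'
#' \eqn{RED = R_a / R_0}, the Hansen distance between solute and solvent
#' normalised by the solute's interaction radius.  RED < 1 predicts a good
#' solvent; values near 1 are boundary cases.
#'
#' @param sphere A [hansen_sphere()].
#' @param solvent HSP triple of the solvent (or anything [as_hsp()] accepts).
#' @return Dimensionless RED value.
#' @examples
#' sph <- hansen_sphere(12.2, 9.9, 12.7, 10.1)
#' red(sph, hsp(16.0, 5.7, 15.8))  # 0.91
#' @export
red <- function(sphere, solvent) {
  if (!inherits(sphere, "hansen_sphere")) {
    stop_input("`sphere` must be a hansen_sphere object")
  }
  if (!is.finite(sphere$r0) || sphere$r0 <= 0) {
    stop_input("invalid sphere: radius r0 must be positive")
  }
  hansen_distance(sphere$center, solvent) / sphere$r0
}

#' Relative deviation between an HSP value and a literature value
#'
#' \eqn{RD = |\delta_i - \delta_{i,lit}| / \delta_{denom} \times 100\%}.
#' The default denominator is the literature value; the alternative
#' `"this_work"` convention is exposed because published comparisons are not
#' always consistent about which value normalises the difference.
#'
#' @param this_work HSP value from the present analysis (MPa^(1/2)).
#' @param literature Literature HSP value (MPa^(1/2)).
#' @param convention Denominator convention, `"literature"` (default) or
#'   `"this_work"`.
#' @return An object of class `"rd_comparison"` with fields `this_work`,
#'   `literature`, `rd_percent` and `denominator_convention`.
#' @examples
#' relative_deviation(12.7, 13.1)$rd_percent  # 3.1
#' @export
relative_deviation <- function(this_work, literature,
                               convention = c("literature", "this_work")) {
  convention <- match.arg(convention)
  for (v in list(this_work, literature)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_input("HSP values for relative deviation must be single finite numbers")
    }
  }
  denom <- if (convention == "literature") literature else this_work
  if (denom == 0) {
    stop_input(sprintf("zero denominator: %s value is 0", convention))
  }
  structure(list(this_work = this_work, literature = literature,
                 rd_percent = abs(this_work - literature) / abs(denom) * 100,
                 denominator_convention = convention),
            class = "rd_comparison")
}

#' @export
print.rd_comparison <- function(x, ...) {
  cat(sprintf("RD = %.1f%%  (this work %.2f vs literature %.2f, denominator: %s)\n",
              x$rd_percent, x$this_work, x$literature, x$denominator_convention))
  invisible(x)
}
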