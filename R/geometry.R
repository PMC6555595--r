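#' Area of a traced ROI polygon
#'
#' Shoelace (surveyor's) area of a simple polygon traced along the perimeter
#' of a Par aggregate, in square micrometres. Orientation does not matter;
#' self-intersecting polygons are rejected.
#'
#' @param vertices n x 2 matrix of vertex coordinates (micrometres), n >= 3.
#' @return Area in um^2.
#' @examples
#' roi_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
roi_area <- function(vertices) {
  xy <- .as_xy(vertices)
  # drop an explicit closing vertex
  if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ]))
    xy <- xy[-nrow(xy), , drop = FALSE]
  n <- nrow(xy)
  if (n < 3L) stop("a polygon needs at least 3 vertices")
  if (any(!is.finite(xy))) stop("non-finite vertex coordinates")
  if (.self_intersects(xy)) stop("self-intersecting polygon")
  j <- c(2:n, 1L)
  a <- abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
  if (a <= 0) stop("degenerate polygon with zero area")
  a
}

# Test whether any two non-adjacent edges of a closed polygon cross.
.self_intersects <- function(xy) {
  n <- nrow(xy)
  seg <- cbind(xy, xy[c(2:n, 1L), , drop = FALSE])
  crosses <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
      (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent around the wrap
      if (crosses(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

#' Summarize aggregate sizes per group with pairwise KS tests
#'
#' @param groups Named list of numeric area vectors (um^2), one per
#'   condition.
#' @param pairs Optional list of length-2 character vectors of group names
#'   to compare; defaults to all pairs.
#' @return List with `summary` (per-group mean, sd, n) and `tests`
#'   (two-sample Kolmogorov-Smirnov statistic and p per pair).
#' @export
aggregate_size_summary <- function(groups, pairs = NULL) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("'groups' must be a named list of area vectors")
  if (any(lengths(groups) == 0)) stop("empty group")
  summ <- data.frame(group = names(groups),
                     mean = vapply(groups, mean, 1),
                     sd = vapply(groups, function(g)
                       if (length(g) > 1L) stats::sd(g) else NA_real_, 1),
                     n = vapply(groups, length, 1L), row.names = NULL)
  if (is.null(pairs))
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    kt <- suppressWarnings(stats::ks.test(groups[[p[1]]], groups[[p[2]]]))
    data.frame(group_a = p[1], group_b = p[2],
               ks_statistic = unname(kt$statistic), p_value = kt$p.value)
  }))
  list(summary = summ, tests = tests)
}

#' Centrosome-crescent fan geometry
#'
#' From the cell centre, the two edges of the cortical crescent span an
#' angular sector (the "fan") of extent theta1, measured clockwise from
#' `edge_a` to `edge_b` in image coordinates (y down, clockwise positive on
#' screen). theta2 is the clockwise angle from `edge_a` to the centrosome
#' direction. The centrosome lies within the fan when
#' `0 <= theta2 <= theta1` (edges inclusive, so boundary cases are not
#' excluded by measurement noise).
#'
#' @param center,edge_a,edge_b,centrosome Length-2 coordinates
#'   (micrometres). `edge_a` is the crescent edge from which both angles are
#'   measured.
#' @return List of class `fan_geometry`: `theta1_deg`, `theta2_deg`
#'   (both in `[0, 360)`), `within_fan`.
#' @export
crescent_fan <- function(center, edge_a, edge_b, centrosome) {
  va <- as.numeric(edge_a) - as.numeric(center)
  vb <- as.numeric(edge_b) - as.numeric(center)
  vc <- as.numeric(centrosome) - as.numeric(center)
  for (v in list(va, vb, vc))
    if (sqrt(sum(v^2)) <= 0 || any(!is.finite(v)))
      stop("zero-length or non-finite direction vector from the cell center")
  th1 <- .cw_angle_deg(va, vb)
  if (th1 == 0) stop("crescent edges are coincident: fan extent undefined")
  th2 <- .cw_angle_deg(va, vc)
  structure(list(theta1_deg = th1, theta2_deg = th2,
                 within_fan = th2 <= th1),
            class = "fan_geometry")
}

#' Fraction of cells whose centrosome lies within the crescent fan
#'
#' @param cohort List of `fan_geometry` objects (from [crescent_fan()]) or a
#'   logical vector of within-fan flags.
#' @return List: `count_inside`, `n`, `fraction`.
#' @export
fraction_within_fan <- function(cohort) {
  flags <- if (is.logical(cohort)) cohort
           else vapply(cohort, function(f) {
             stopifnot(inherits(f, "fan_geometry"))
             f$within_fan
           }, logical(1))
  if (length(flags) < 1L) stop("empty cohort")
  list(count_inside = sum(flags), n = length(flags),
       fraction = mean(flags))
}

#' Per-cell expression ratio between two transfection conditions
#'
#' Western-blot staining intensities report expression over the whole
#' culture; dividing by the transfection efficiency (fraction of cells
#' actually expressing) converts each to a per-cell level, and the ratio of
#' the two per-cell levels is the fold difference in expression.
#'
#' @param intensity_a,intensity_b Measured blot intensities (>= 0).
#' @param transfection_eff_a,transfection_eff_b Transfection efficiencies in
#'   (0, 1].
#' @return Fold ratio `(intensity_a / eff_a) / (intensity_b / eff_b)`.
#' @examples
#' expression_ratio(5.5e4, 1, 3.4e3, 1)  # ~16.2-fold
#' @export
expression_ratio <- function(intensity_a, transfection_eff_a,
                             intensity_b, transfection_eff_b) {
  .check_scalar(intensity_a, "intensity_a", 0)
  .check_scalar(intensity_b, "intensity_b", 0)
  .check_scalar(transfection_eff_a, "transfection_eff_a", 0, 1,
                strict_lower = TRUE)
  .check_scalar(transfection_eff_b, "transfection_eff_b", 0, 1,
                strict_lower = TRUE)
  if (intensity_b == 0) stop("zero denominator: intensity_b must be > 0")
  (intensity_a / transfection_eff_a) / (intensity_b / transfection_eff_b)
}

#' Fisher's exact tests of polarized-cell fractions with Bonferroni
#' correction
#'
#' Each condition's (polarized, non-polarized) counts are compared against
#' the reference condition in a 2x2 table by Fisher's exact test
#' (two-sided); raw p-values are Bonferroni-adjusted by the number of
#' comparisons (capped at 1).
#'
#' @param counts Data frame with columns `condition`, `polarized`,
#'   `non_polarized` (non-negative integer counts), reference in the first
#'   row unless named by `reference`.
#' @param reference Name of the reference condition (default: first row).
#' @return Data frame: `condition`, `odds_ratio`, `p_raw`, `p_bonferroni`.
#' @export
polarized_fraction_test <- function(counts, reference = NULL) {
  req <- c("condition", "polarized", "non_polarized")
  if (!all(req %in% names(counts)))
    stop("'counts' needs columns condition, polarized, non_polarized")
  if (any(counts$polarized < 0) || any(counts$non_polarized < 0))
    stop("negative counts")
  if (is.null(reference)) reference <- counts$condition[1]
  if (!reference %in% counts$condition) stop("unknown reference condition")
  ref <- counts[counts$condition == reference, ]
  others <- counts[counts$condition != reference, , drop = FALSE]
  if (nrow(others) == 0) stop("no conditions to compare against the reference")
  m <- nrow(others)
  out <- do.call(rbind, lapply(seq_len(m), function(i) {
    tab <- matrix(c(others$polarized[i], others$non_polarized[i],
                    ref$polarized, ref$non_polarized), nrow = 2,
                  byrow = TRUE)
    ft <- stats::fisher.test(tab)
    data.frame(condition = others$condition[i],
               odds_ratio = unname(ft$estimate), p_raw = ft$p.value)
  }))
  out$p_bonferroni <- pmin(out$p_raw * m, 1)
  out
}
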