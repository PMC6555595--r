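#' Radius of the circle through three points
#'
#' The local curvature radius of a membrane region is estimated as the radius
#' of the unique circle through three points on it: R = abc / (4K), where a,
#' b, c are the side lengths of the triangle they span and K its area. A
#' triangle whose area falls below `tol` (in square micrometres) is treated
#' as degenerate: the membrane is locally straight and the radius infinite.
#'
#' @param p1,p2,p3 Numeric length-2 coordinates (micrometres).
#' @param tol Collinearity tolerance on the doubled triangle area
#'   (default 1e-9 um^2, beyond tracing precision).
#' @return Radius in micrometres.
#' @examples
#' circumradius(c(1, 0), c(0, 1), c(-1, 0))  # 1
#' @export
circumradius <- function(p1, p2, p3, tol = 1e-9) {
  pts <- rbind(p1, p2, p3)
  if (!is.numeric(pts) || ncol(pts) != 2 || any(!is.finite(pts)))
    stop("points must be finite numeric length-2 coordinates")
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  ce <- sqrt(sum((p1 - p2)^2))
  if (min(a, b, ce) == 0) stop("duplicate points: circumradius undefined")
  cross2 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
    (p2[2] - p1[2]) * (p3[1] - p1[1])
  area2 <- abs(cross2)   # twice the triangle area
  if (area2 / 2 < tol)
    stop("collinear points: infinite radius / straight membrane")
  a * b * ce / (2 * area2)
}

#' Construct a membrane trace
#'
#' An ordered closed polyline of equatorial membrane coordinates together
#' with the arc spans (in micrometres along the contour) where Par signal
#' co-localizes with the membrane (the Par-islands).
#'
#' @param coords n x 2 matrix of membrane coordinates in micrometres, ordered
#'   along the contour; the contour is closed from the last vertex back to
#'   the first.
#' @param island_spans Two-column matrix or data frame of
#'   `(start_um, end_um)` arc spans, `0 <= start < end <= contour length`,
#'   non-overlapping. May be `NULL` for cells without islands.
#' @param cell_id Optional identifier.
#' @return A list of class `membrane_trace` with the coordinates, arc
#'   positions of the vertices, total contour length, island spans and a
#'   `has_islands` flag.
#' @export
membrane_trace <- function(coords, island_spans = NULL, cell_id = NA) {
  xy <- .as_xy(coords)
  if (nrow(xy) < 3L) stop("a membrane trace needs at least 3 points")
  cum <- .arc_lengths(xy, closed = TRUE)
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate trace: zero contour length")
  spans <- NULL
  if (!is.null(island_spans) && NROW(island_spans) > 0) {
    spans <- as.matrix(island_spans)[, 1:2, drop = FALSE]
    colnames(spans) <- c("start_um", "end_um")
    if (any(spans[, 1] >= spans[, 2]))
      stop("island spans must have start_um < end_um")
    if (any(spans < 0) || any(spans > total))
      stop("island span exceeds the contour length")
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (nrow(spans) > 1 &&
        any(spans[-1, 1] < spans[-nrow(spans), 2]))
      stop("island spans overlap")
  }
  structure(list(coords = xy, arc_um = cum[-length(cum)],
                 contour_length_um = total, island_spans = spans,
                 has_islands = !is.null(spans), cell_id = cell_id),
            class = "membrane_trace")
}

#' Partition a membrane contour into curvature regions
#'
#' Classifies the closed equatorial contour into Par-island regions (island
#' spans longer than `min_island_um`), neighboring regions (within
#' `exclusion_um` of an island edge, measured geodesically along the
#' contour), and non-neighboring regions: the remaining stretches, split into
#' consecutive compartments of at most `max_region_um` starting at the edge
#' of the exclusion zone. For traces without islands the whole contour is
#' split into `non_island_cell` compartments of at most `max_region_um`.
#' Neighboring regions are classified but carry no curvature measurement;
#' only islands, non-neighboring and non-island-cell compartments do.
#'
#' @param trace A [membrane_trace()].
#' @param min_island_um Minimum island arc length to count as an island
#'   region (default 1).
#' @param exclusion_um Arc distance from an island edge within which the
#'   membrane is "neighboring" (default 5).
#' @param max_region_um Maximum compartment length for non-neighboring and
#'   non-island-cell regions (default 5).
#' @return Data frame with columns `region_class`, `start_um`, `end_um`
#'   (arc positions; `end_um` may exceed the contour length for regions that
#'   wrap past the origin) and `length_um`.
#' @export
partition_regions <- function(trace, min_island_um = 1, exclusion_um = 5,
                              max_region_um = 5) {
  stopifnot(inherits(trace, "membrane_trace"))
  .check_scalar(min_island_um, "min_island_um", 0)
  .check_scalar(exclusion_um, "exclusion_um", 0)
  .check_scalar(max_region_um, "max_region_um", 0, strict_lower = TRUE)
  total <- trace$contour_length_um

  chop <- function(start, len, cls) {
    # split [start, start + len] into consecutive chunks <= max_region_um
    n <- ceiling(len / max_region_um)
    if (n == 0L) return(NULL)
    # consecutive compartments of at most max_region_um from the region edge
    edges <- start + c(seq(0, by = max_region_um, length.out = n), len)
    data.frame(region_class = cls, start_um = edges[-length(edges)],
               end_um = edges[-1])
  }

  if (!trace$has_islands) {
    out <- chop(0, total, "non_island_cell")
  } else {
    spans <- trace$island_spans
    keep <- (spans[, 2] - spans[, 1]) > min_island_um
    islands <- spans[keep, , drop = FALSE]
    out <- NULL
    if (nrow(islands) > 0)
      out <- data.frame(region_class = "island",
                        start_um = islands[, 1], end_um = islands[, 2])
    if (nrow(islands) == 0) {
      # spans too short to be islands: treat remaining contour as one piece
      out <- chop(0, total, "non_neighboring")
    } else {
      # neighboring zone: within exclusion_um of any island edge (and not
      # inside an island). Build the complement of islands as gaps, then
      # trim exclusion_um off both ends of each gap.
      n_is <- nrow(islands)
      gaps <- cbind(islands[, 2],
                    c(islands[-1, 1], islands[1, 1] + total))
      for (g in seq_len(n_is)) {
        g0 <- gaps[g, 1]; g1 <- gaps[g, 2]
        glen <- g1 - g0
        if (glen <= 2 * exclusion_um) {
          # entire gap is neighboring
          out <- rbind(out, data.frame(region_class = "neighboring",
                                       start_um = g0, end_um = g1))
        } else {
          out <- rbind(out,
                       data.frame(region_class = "neighboring",
                                  start_um = g0, end_um = g0 + exclusion_um),
                       chop(g0 + exclusion_um, glen - 2 * exclusion_um,
                            "non_neighboring"),
                       data.frame(region_class = "neighboring",
                                  start_um = g1 - exclusion_um, end_um = g1))
        }
      }
    }
  }
  out$length_um <- out$end_um - out$start_um
  rownames(out) <- NULL
  out
}

#' Curvature radius of one contour region
#'
#' Takes the first and last trace vertices inside the region and the vertex
#' nearest the region's arc-length midpoint, and returns the radius of the
#' circle through the three. Regions whose three points are collinear are
#' returned with radius `NA` and a note, matching the convention that a
#' straight membrane has infinite curvature radius and is excluded from
#' summaries.
#'
#' @param trace A [membrane_trace()].
#' @param start_um,end_um Arc span of the region (from
#'   [partition_regions()]; `end_um` may exceed the contour length for
#'   wrapping regions).
#' @param region_class Label copied into the result.
#' @return One-row data frame: `region_class`, `start_um`, `end_um`,
#'   `radius_um` (`NA` if degenerate), `note`.
#' @export
region_radius <- function(trace, start_um, end_um,
                          region_class = "region") {
  stopifnot(inherits(trace, "membrane_trace"))
  total <- trace$contour_length_um
  arc <- trace$arc_um
  len <- end_um - start_um
  if (len <= 0) stop("region must have positive arc length")
  # vertices whose (unwrapped) arc position falls inside the region
  rel <- (arc - start_um) %% total
  inside <- which(rel <= len + 1e-9)
  if (length(inside) < 3L)
    stop("region has fewer than 3 trace points; cannot fit a circle")
  ord <- inside[order(rel[inside])]
  p1 <- trace$coords[ord[1L], ]
  p3 <- trace$coords[ord[length(ord)], ]
  mid <- ord[which.min(abs(rel[ord] - len / 2))]
  p2 <- trace$coords[mid, ]
  r <- tryCatch(circumradius(p1, p2, p3), error = function(e) NA_real_)
  data.frame(region_class = region_class, start_um = start_um,
             end_um = end_um, radius_um = r,
             note = if (is.na(r)) "infinite radius (straight region)" else "")
}

#' Measure curvature radii for all measurable regions of a trace
#'
#' Runs [partition_regions()] and [region_radius()] and returns radii for
#' island, non-neighboring and non-island-cell compartments (neighboring
#' regions are classified but not measured).
#'
#' @inheritParams partition_regions
#' @return Data frame as from [region_radius()], one row per measured
#'   region, with the trace's `cell_id` prepended.
#' @export
measure_trace_curvature <- function(trace, min_island_um = 1,
                                    exclusion_um = 5, max_region_um = 5) {
  parts <- partition_regions(trace, min_island_um, exclusion_um,
                             max_region_um)
  parts <- parts[parts$region_class %in%
                   c("island", "non_neighboring", "non_island_cell"), ,
                 drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(parts)), function(i)
    region_radius(trace, parts$start_um[i], parts$end_um[i],
                  parts$region_class[i])))
  cbind(cell_id = trace$cell_id, out)
}

#' Compare curvature-radius distributions between region groups
#'
#' @param measurements Data frame with columns `region_class` and
#'   `radius_um` (rows with `NA` radius are dropped), or a named list of
#'   numeric radius vectors.
#' @param pairs Optional list of length-2 character vectors naming the group
#'   pairs to test; defaults to all pairs.
#' @return A list with `summary` (per-group `median`, `n`) and `tests`
#'   (per pair: two-sample Kolmogorov-Smirnov statistic and p-value).
#' @export
curvature_compare <- function(measurements, pairs = NULL) {
  if (is.data.frame(measurements)) {
    measurements <- measurements[!is.na(measurements$radius_um), ]
    groups <- split(measurements$radius_um, measurements$region_class)
  } else groups <- measurements
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 values")
  summ <- data.frame(group = names(groups),
                     median = vapply(groups, stats::median, 1),
                     n = vapply(groups, length, 1L),
                     row.names = NULL)
  if (is.null(pairs))
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    if (!all(p %in% names(groups))) stop("unknown group in 'pairs'")
    kt <- suppressWarnings(stats::ks.test(groups[[p[1]]], groups[[p[2]]]))
    data.frame(group_a = p[1], group_b = p[2],
               ks_statistic = unname(kt$statistic), p_value = kt$p.value)
  }))
  list(summary = summ, tests = tests)
}
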