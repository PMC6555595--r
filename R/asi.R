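#' Asymmetric index of a closed equatorial intensity profile
#'
#' The asymmetric index (ASI) measures how one-sided a fluorescence signal is
#' along the equatorial perimeter of a cell. The intensities are summed over
#' every contiguous window covering exactly half of the perimeter samples; for
#' each window the absolute difference between the window sum and the sum over
#' the complementary half is normalized by the total intensity, and the ASI is
#' the maximum of these normalized differences. A perfectly uniform profile has
#' ASI 0; a profile whose entire signal sits inside one contiguous half has
#' ASI 1.
#'
#' The maximum over all n half-windows is computed in O(n) from cumulative
#' sums; ties in the maximizing start position are resolved toward the
#' smallest start index.
#'
#' @param profile A `perimeter_profile` object from
#'   [perimeter_profile()], or a numeric vector of non-negative
#'   intensities at equally spaced positions around the closed contour
#'   (even length, at least 8).
#' @param threshold Polarization cutoff applied to the ASI (strict
#'   inequality). Default 0.35.
#'
#' @return A list of class `asi_result` with elements `asi` (in `[0, 1]`),
#'   `argmax_start_index` (1-based start of the maximizing half-window),
#'   `polarized` (logical, `asi > threshold`), and `threshold`.
#'
#' @examples
#' asi(c(rep(1, 50), rep(0, 50)))$asi   # 1: all signal in one half
#' asi(rep(2, 100))$asi                 # 0: uniform
#' @export
asi <- function(profile, threshold = 0.35) {
  x <- if (inherits(profile, "perimeter_profile")) profile$intensities
       else profile
  if (!is.numeric(x)) stop("profile intensities must be numeric")
  n <- length(x)
  if (n < 8L || n %% 2L != 0L)
    stop("profile length must be even and >= 8 (closed contour halves)")
  if (any(!is.finite(x))) stop("profile contains non-finite intensities")
  if (any(x < 0)) stop("negative intensity: profiles are fluorescence and must be >= 0")
  total <- sum(x)
  if (total <= 0) stop("total intensity is zero; ASI is undefined")
  h <- n %/% 2L
  # window sums for all n cyclic half-windows via one cumulative sum
  cs <- c(0, cumsum(c(x, x[seq_len(h - 1L)])))
  win <- cs[(h + 1L):(h + n)] - cs[seq_len(n)]
  vals <- abs(2 * win - total) / total
  idx <- which.max(vals)  # which.max returns the first (smallest) index on ties
  asi_val <- min(vals[idx], 1)  # guard against rounding just above 1
  res <- list(asi = asi_val, argmax_start_index = idx,
              polarized = classify_polarized(asi_val, threshold),
              threshold = threshold)
  class(res) <- "asi_result"
  res
}

#' @export
print.asi_result <- function(x, ...) {
  cat(sprintf("ASI = %.4f (%s at threshold %.2f), half-window start index %d\n",
              x$asi, if (x$polarized) "polarized" else "non-polarized",
              x$threshold, x$argmax_start_index))
  invisible(x)
}

#' Classify a cell as polarized from its ASI
#'
#' A cell is polarized when its asymmetric index strictly exceeds the cutoff;
#' a cell exactly at the cutoff is non-polarized. The default cutoff of 0.35
#' is the upper end of the ASI range observed for membrane-bound GFP, which
#' cannot polarize, so values above it cannot be explained by fluctuation of
#' a uniform cortical signal.
#'
#' @param asi_value ASI value(s) in `[0, 1]`.
#' @param threshold Cutoff (default 0.35).
#' @return Logical vector: `TRUE` for polarized.
#' @export
classify_polarized <- function(asi_value, threshold = 0.35) {
  if (!is.numeric(asi_value) || any(!is.finite(asi_value)))
    stop("'asi_value' must be finite numeric")
  if (any(asi_value < 0 | asi_value > 1))
    stop("ASI values must lie in [0, 1]")
  .check_scalar(threshold, "threshold", 0, 1)
  asi_value > threshold
}

#' Construct a perimeter intensity profile
#'
#' Ordered intensity samples at equally spaced arc positions along a closed
#' equatorial contour. Sample index n wraps to 1. Odd-length input is
#' resampled to the next even count by linear interpolation along arc length,
#' since the half-perimeter windows of the ASI require an even sample count.
#'
#' @param intensities Non-negative numeric vector.
#' @param spacing_um Arc distance between consecutive samples in micrometres
#'   (default 0.108, one confocal pixel).
#' @param cell_id Optional identifier.
#' @return A list of class `perimeter_profile`.
#' @export
perimeter_profile <- function(intensities, spacing_um = 0.108, cell_id = NA) {
  if (!is.numeric(intensities) || length(intensities) < 8L)
    stop("at least 8 intensity samples are required")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and >= 0")
  .check_scalar(spacing_um, "spacing_um", 0, strict_lower = TRUE)
  n <- length(intensities)
  if (n %% 2L != 0L) {
    # resample the closed profile onto n+1 equally spaced positions
    m <- n + 1L
    pos <- (seq_len(m) - 1L) * n / m
    i0 <- floor(pos); w <- pos - i0
    nxt <- c(intensities[-1], intensities[1])
    intensities <- (1 - w) * intensities[i0 + 1L] + w * nxt[i0 + 1L]
    spacing_um <- spacing_um * n / m
  }
  structure(list(intensities = intensities, spacing_um = spacing_um,
                 cell_id = cell_id),
            class = "perimeter_profile")
}

#' Extract a perimeter profile from an image along a traced contour
#'
#' Resamples a closed contour polyline to uniform arc spacing (even sample
#' count) and measures, at each resampled position, the mean image intensity
#' over a band of the given width centred on the contour and perpendicular to
#' it. This reproduces tracing the cell perimeter with a wide line and
#' reading the intensity along it.
#'
#' @param image Numeric matrix (grayscale), rows = y, columns = x.
#' @param contour_polyline n x 2 matrix of contour vertices in micrometres
#'   (columns x, y; 0-based pixel-centre origin).
#' @param pixel_um Image pixel size in micrometres (default 0.108).
#' @param band_width_um Width of the perpendicular measurement band
#'   (default 0.5).
#' @param spacing_um Target arc spacing between profile samples; defaults to
#'   `pixel_um`.
#' @param closed Set `TRUE` to treat a polyline whose last vertex differs
#'   from its first as closed by an implicit final segment. When `FALSE`,
#'   first and last vertices must coincide.
#' @param band_samples Number of interpolation points across the band.
#' @param cell_id Optional identifier.
#' @return A [perimeter_profile()].
#' @export
extract_perimeter_profile <- function(image, contour_polyline,
                                      pixel_um = 0.108,
                                      band_width_um = 0.5,
                                      spacing_um = pixel_um,
                                      closed = FALSE,
                                      band_samples = 11L,
                                      cell_id = NA) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix")
  xy <- .as_xy(contour_polyline)
  first_last_same <- isTRUE(all.equal(xy[1, ], xy[nrow(xy), ],
                                      tolerance = 1e-9))
  if (!closed && !first_last_same)
    stop("open polyline: first and last vertices differ and 'closed' is not set")
  if (first_last_same) xy <- xy[-nrow(xy), , drop = FALSE]
  .check_scalar(band_width_um, "band_width_um", 0, strict_lower = TRUE)
  .check_scalar(spacing_um, "spacing_um", 0, strict_lower = TRUE)

  cum <- .arc_lengths(xy, closed = TRUE)
  total <- cum[length(cum)]
  n <- max(8L, round(total / spacing_um))
  if (n %% 2L == 1L) n <- n + 1L
  s <- (seq_len(n) - 1L) * total / n
  pts <- .point_at_arc(xy, s, closed = TRUE)
  # tangent by central difference of neighbouring resampled points
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  prv <- rbind(pts[n, , drop = FALSE], pts[-n, , drop = FALSE])
  tg <- nxt - prv
  tl <- sqrt(rowSums(tg^2))
  nrm <- cbind(-tg[, 2], tg[, 1]) / tl   # unit normal
  off <- seq(-band_width_um / 2, band_width_um / 2, length.out = band_samples)

  vals <- numeric(n)
  for (i in seq_len(n)) {
    px <- (pts[i, 1] + off * nrm[i, 1]) / pixel_um
    py <- (pts[i, 2] + off * nrm[i, 2]) / pixel_um
    v <- .bilinear(image, px, py)
    if (anyNA(v))
      stop(sprintf(paste0("measurement band extends outside the image at arc ",
                          "position %.3f um"), s[i]))
    vals[i] <- mean(v)
  }
  perimeter_profile(pmax(vals, 0), spacing_um = total / n, cell_id = cell_id)
}

#' Summarize ASI values over a cohort of cells
#'
#' @param asi_values Numeric vector of per-cell ASI values in `[0, 1]`.
#' @param bin_width Histogram bin width on `[0, 1]` (default 0.05).
#' @param threshold Polarization cutoff (default 0.35, strict).
#' @return A list with `n`, `mean`, `sd` (n-1 denominator), `n_polarized`,
#'   `fraction_polarized`, and `histogram` (data frame of bin edges and
#'   counts).
#' @export
asi_cohort_summary <- function(asi_values, bin_width = 0.05,
                               threshold = 0.35) {
  if (length(asi_values) < 1L) stop("empty cohort")
  if (any(!is.finite(asi_values)) || any(asi_values < 0 | asi_values > 1))
    stop("ASI values must be finite and in [0, 1]")
  .check_scalar(bin_width, "bin_width", 0, 1, strict_lower = TRUE)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  counts <- as.vector(table(cut(asi_values, breaks,
                                include.lowest = TRUE, right = TRUE)))
  pol <- classify_polarized(asi_values, threshold)
  list(n = length(asi_values),
       mean = mean(asi_values),
       sd = if (length(asi_values) > 1L) stats::sd(asi_values) else NA_real_,
       n_polarized = sum(pol),
       fraction_polarized = mean(pol),
       histogram = data.frame(bin_low = breaks[-length(breaks)],
                              bin_high = breaks[-1],
                              count = counts))
}
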