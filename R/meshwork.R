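#' Sobel edge enhancement
#'
#' Gradient-magnitude image from the 3x3 Sobel kernels (horizontal and
#' vertical first differences), used to highlight meshwork contour shapes
#' before tracing. Borders are handled by replicate padding; the output is
#' rescaled so its maximum equals the input's intensity range (a constant
#' image maps to all zeros).
#'
#' @param image Numeric matrix (2-D grayscale).
#' @return Matrix of the same size.
#' @export
edge_enhance <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("edge enhancement requires a 2-D numeric matrix")
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3L || nc < 3L) stop("image must be at least 3 x 3")
  pad <- rbind(image[1, , drop = FALSE], image, image[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(dr, dc) pad[(2L + dr):(nr + 1L + dr),
                             (2L + dc):(nc + 1L + dc)]
  # Sobel x (columns) and y (rows) responses
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  rng <- diff(range(image))
  if (max(mag) > 0 && rng > 0) mag <- mag * (rng / max(mag))
  mag
}

#' Arc lengths of traced contours
#'
#' Polyline length (sum of consecutive Euclidean distances) of each traced
#' contour between its terminal ends and/or branching points.
#'
#' @param traces A single n x 2 coordinate matrix or a list of them
#'   (micrometres).
#' @return Numeric vector of lengths in micrometres.
#' @export
contour_lengths <- function(traces) {
  if (!is.list(traces) || is.data.frame(traces)) traces <- list(traces)
  vapply(traces, function(tr) {
    xy <- .as_xy(tr)
    if (nrow(xy) < 2L) stop("a contour trace needs at least 2 points")
    sum(sqrt(rowSums((xy[-1, , drop = FALSE] -
                        xy[-nrow(xy), , drop = FALSE])^2)))
  }, numeric(1))
}

#' Kernel density of contour lengths
#'
#' Gaussian kernel density estimate of a sample of contour lengths on a
#' uniform grid spanning `[0, max(lengths) + 3 * bandwidth]`. This is the
#' "density plot" to which the multi-Gaussian comb is fitted.
#'
#' @param lengths Numeric vector of lengths (micrometres), at least 10.
#' @param bandwidth `"sj"` (Sheather-Jones, the default: Silverman's
#'   rule-of-thumb badly oversmooths strongly multimodal length samples),
#'   `"silverman"` (`stats::bw.nrd0`), or a positive number (micrometres).
#' @param grid_points Number of grid points (default 512).
#' @return A list of class `density_curve`: `grid` (um), `density`,
#'   `bandwidth_um`, `n`.
#' @export
length_density <- function(lengths, bandwidth = "sj",
                           grid_points = 512L) {
  if (length(lengths) < 10L)
    stop("at least 10 lengths are required for a stable density estimate")
  if (any(!is.finite(lengths)) || any(lengths < 0))
    stop("lengths must be finite and non-negative")
  bw <- if (identical(bandwidth, "sj")) stats::bw.SJ(lengths)
        else if (identical(bandwidth, "silverman")) stats::bw.nrd0(lengths)
        else .check_scalar(bandwidth, "bandwidth", 0, strict_lower = TRUE)
  d <- stats::density(lengths, bw = bw, kernel = "gaussian",
                      from = 0, to = max(lengths) + 3 * bw,
                      n = grid_points)
  curve <- structure(list(grid = d$x, density = d$y, bandwidth_um = bw,
                          n = length(lengths)),
                     class = "density_curve")
  integ <- .trapz(curve$grid, curve$density)
  if (abs(integ - 1) > 1e-3)
    warning(sprintf("density integrates to %.4f (mass near/below zero?)",
                    integ))
  curve
}

.gauss_comb <- function(par, x, k) {
  A <- par[seq_len(k)]
  mu <- par[k + seq_len(k)]
  sg <- par[2 * k + seq_len(k)]
  y <- numeric(length(x))
  for (j in seq_len(k)) y <- y + A[j] * exp(-(x - mu[j])^2 / (2 * sg[j]^2))
  y
}

#' Fit a sum of k Gaussian components to a density curve
#'
#' Least-squares fit of `y(x) = sum_j A_j exp(-(x - mu_j)^2 / (2 sigma_j^2))`
#' to a length-density curve, with `A_j >= 0`, `sigma_j > 0` and means
#' constrained to the grid range. A comb of regularly spaced components
#' fitted this way exposes the recurring unit-segment length of the
#' meshwork as the mean consecutive spacing of the fitted means.
#'
#' Initialization places the means at the k tallest local maxima of the
#' density when that many exist (padded with evenly spaced positions
#' otherwise), with `sigma_j` set to the KDE bandwidth and `A_j` to the
#' density at `mu_j`; up to `restarts` seeded random perturbations of the
#' initial means are tried if the optimizer fails to converge or a strictly
#' better residual is found.
#'
#' @param density A `density_curve` from [length_density()].
#' @param k Number of components (default 7).
#' @param init Optional numeric vector of initial means (length k).
#' @param restarts Maximum number of perturbed restarts (default 10).
#' @param seed Integer seed for the restart perturbations (default 1).
#' @return A list of class `mixture_fit`: `components` (data frame
#'   `amplitude`, `mean_um`, `sd_um`, sorted by mean), `rss`, `converged`,
#'   `k`, and the peak-interval summary `peak_interval_mean_um`,
#'   `peak_interval_sd_um`.
#' @export
fit_k_gaussians <- function(density, k = 7L, init = NULL, restarts = 10L,
                            seed = 1L) {
  stopifnot(inherits(density, "density_curve"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  x <- density$grid; y <- density$density
  bw <- density$bandwidth_um
  rng <- range(x)

  peak_means <- function() {
    n <- length(y)
    i <- which(y >= c(Inf, y[-n]) & y >= c(y[-1], Inf) &
                 (y > c(Inf, y[-n]) | y > c(y[-1], Inf)))
    # merge plateau duplicates (consecutive indices within 2 grid steps)
    if (length(i) > 1L) i <- i[c(TRUE, diff(i) > 2L)]
    i <- i[order(y[i], decreasing = TRUE)]
    mu <- sort(x[i[seq_len(min(k, length(i)))]])
    if (length(mu) < k) {
      extra <- seq(rng[1] + bw, rng[2] - bw, length.out = k)
      extra <- extra[!vapply(extra, function(e)
        any(abs(e - mu) < bw), logical(1))]
      mu <- sort(c(mu, extra[seq_len(k - length(mu))]))
    }
    mu
  }
  init_full <- NULL
  mu0 <- if (is.null(init)) {
    peak_means()
  } else if (is.list(init)) {
    # full nested initialization: amplitudes, means and sds supplied
    if (!all(c("amplitude", "mean_um", "sd_um") %in% names(init)) ||
        length(init$mean_um) != k)
      stop("'init' list must supply amplitude, mean_um, sd_um of length k")
    ord0 <- order(init$mean_um)
    init_full <- c(pmax(init$amplitude[ord0], 0), init$mean_um[ord0],
                   pmax(init$sd_um[ord0], 1e-4))
    sort(init$mean_um)
  } else {
    if (length(init) != k) stop("'init' must supply k initial means")
    sort(init)
  }

  lower <- c(rep(0, k), rep(rng[1], k), rep(max(bw / 20, 1e-4), k))
  upper <- c(rep(2 * max(y), k), rep(rng[2], k), rep(diff(rng), k))
  resid_fn <- function(par) .gauss_comb(par, x, k) - y

  run_fit <- function(mu, par_full = NULL) {
    A0 <- pmax(stats::approx(x, y, xout = mu, rule = 2)$y, 1e-6)
    par0 <- if (is.null(par_full)) c(A0, mu, rep(bw, k)) else par_full
    par0 <- pmin(pmax(par0, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, maxfev = 20000)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = fit$par, rss = sum(fit$fvec^2),
         converged = fit$info %in% 1:3)
  }

  best <- run_fit(mu0, init_full)
  if (is.null(best) || !best$converged) {
    for (r in seq_len(restarts)) {
      jit <- .with_seed(seed + r, stats::rnorm(k))
      mu_r <- sort(pmin(pmax(mu0 + jit * bw, rng[1]), rng[2]))
      cand <- run_fit(mu_r)
      if (!is.null(cand) &&
          (is.null(best) || cand$rss < best$rss ||
             (cand$converged && !best$converged))) best <- cand
      if (!is.null(best) && best$converged) break
    }
  }
  if (is.null(best))
    stop("Gaussian comb fit failed: optimizer returned no solution")
  if (!best$converged)
    stop(sprintf(paste0("Gaussian comb fit did not converge after %d ",
                        "restarts (best residual sum of squares %.4g); ",
                        "k may exceed the resolvable modes"),
                 restarts, best$rss))
  ord <- order(best$par[k + seq_len(k)])
  comp <- data.frame(amplitude = best$par[seq_len(k)][ord],
                     mean_um = best$par[k + seq_len(k)][ord],
                     sd_um = best$par[2 * k + seq_len(k)][ord])
  pi_ <- if (k >= 2L) peak_interval_from_means(comp$mean_um)
         else c(mean_um = NA_real_, sd_um = NA_real_)
  structure(list(components = comp, rss = best$rss, converged = TRUE,
                 k = k, peak_interval_mean_um = pi_[["mean_um"]],
                 peak_interval_sd_um = pi_[["sd_um"]]),
            class = "mixture_fit")
}

peak_interval_from_means <- function(means) {
  d <- diff(means)
  c(mean_um = mean(d), sd_um = if (length(d) > 1L) stats::sd(d) else 0)
}

#' Peak interval of a fitted Gaussian comb
#'
#' The mean and standard deviation of the k - 1 consecutive differences
#' between the sorted component means: the recurring spacing of the comb,
#' interpreted as the unit-segment length of the meshwork.
#'
#' @param fit A `mixture_fit` from [fit_k_gaussians()], or a numeric vector
#'   of sorted component means.
#' @return Named numeric vector `c(mean_um, sd_um)`.
#' @export
peak_interval <- function(fit) {
  means <- if (inherits(fit, "mixture_fit")) fit$components$mean_um else fit
  if (length(means) < 2L) stop("peak interval needs at least 2 means")
  if (any(diff(means) <= 0))
    stop("component means must be strictly increasing (sorted, no duplicates)")
  peak_interval_from_means(means)
}

#' Spectral periodicity of a density curve
#'
#' Detects periodic structure in a length-density curve: the second
#' derivative (central differences) of the density is zero-padded to the
#' next power of two, Fourier-transformed, and the squared magnitude taken
#' as power. The major frequency is the argmax of power over strictly
#' positive frequencies up to Nyquist (zero bin excluded; ties broken toward
#' the lowest frequency) and its reciprocal is the implied repeat interval.
#' A curve with no isolated dominant peak above broadband power (maximum
#' power below twice the median) is flagged aperiodic.
#'
#' @param density A `density_curve` on a uniform grid with at least 64
#'   points.
#' @return A list of class `spectral_result`: `frequencies` (per um),
#'   `power`, `major_frequency_um_inv`, `implied_interval_um`, `periodic`
#'   (logical flag).
#' @export
spectral_periodicity <- function(density) {
  stopifnot(inherits(density, "density_curve"))
  x <- density$grid; y <- density$density
  if (length(x) < 64L) stop("need at least 64 grid points")
  dx <- diff(x)
  if (max(abs(dx - dx[1])) > 1e-8 * dx[1])
    stop("spectral analysis requires a uniform grid")
  dx <- dx[1]
  n <- length(y)
  d2 <- (y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]) / dx^2
  npad <- .next_pow2(length(d2))
  ft <- stats::fft(c(d2, rep(0, npad - length(d2))))
  half <- npad %/% 2L
  freqs <- (1:half) / (npad * dx)
  power <- Mod(ft[2:(half + 1L)])^2
  imax <- which.max(power)  # first index on ties: lowest frequency wins
  fmax <- freqs[imax]
  # Periodicity flag: the major peak must be an isolated spectral line, not
  # the broad lump a smooth aperiodic density produces. Two conditions:
  # the peak stands above broadband power (>= 2x the median), and its
  # quality factor f / (half-power width) is >= 2 -- i.e. the implied
  # repeat fits at least about twice into the density's support.
  half_p <- power[imax] / 2
  il <- imax; while (il > 1L && power[il - 1L] >= half_p) il <- il - 1L
  ir <- imax; while (ir < length(power) && power[ir + 1L] >= half_p)
    ir <- ir + 1L
  width <- freqs[min(ir + 1L, length(freqs))] -
    freqs[max(il - 1L, 1L)]
  periodic <- power[imax] >= 2 * stats::median(power) &&
    fmax / width >= 2
  structure(list(frequencies = freqs, power = power,
                 major_frequency_um_inv = fmax,
                 implied_interval_um = 1 / fmax,
                 periodic = periodic),
            class = "spectral_result")
}

#' Straight segment lengths with a single-Gaussian summary
#'
#' Straight-line distances between segment endpoint pairs (the shortest
#' length between terminal ends, corners and/or branching points of traced
#' contours), summarized by sample mean and standard deviation and by a
#' single-Gaussian least-squares fit to the length histogram.
#'
#' @param segments Data frame or matrix with columns
#'   `x1_um, y1_um, x2_um, y2_um`, or a numeric vector of pre-computed
#'   lengths (micrometres).
#' @param bins Number of histogram bins for the Gaussian fit (default:
#'   Sturges).
#' @return List: `lengths_um`, `n`, `mean_um`, `sd_um`, and
#'   `gaussian_fit` (amplitude, mean, sd from the histogram fit, or `NULL`
#'   if the histogram is too coarse to fit).
#' @export
segment_length_stats <- function(segments, bins = NULL) {
  if (is.numeric(segments) && is.null(dim(segments))) {
    len <- segments
  } else {
    m <- as.matrix(as.data.frame(segments)[, c("x1_um", "y1_um",
                                               "x2_um", "y2_um")])
    len <- sqrt((m[, 3] - m[, 1])^2 + (m[, 4] - m[, 2])^2)
  }
  if (any(!is.finite(len)) || any(len <= 0))
    stop("zero-length or non-finite segment")
  if (length(len) < 2L) stop("need at least 2 segments")
  h <- if (is.null(bins)) graphics::hist(len, plot = FALSE)
       else graphics::hist(len, breaks = bins, plot = FALSE)
  gfit <- NULL
  if (sum(h$counts > 0) >= 4L) {
    par0 <- c(max(h$counts), mean(len), stats::sd(len))
    fit <- tryCatch(minpack.lm::nls.lm(
      par = par0, lower = c(0, 0, 1e-6), upper = c(Inf, Inf, Inf),
      fn = function(p) p[1] * exp(-(h$mids - p[2])^2 / (2 * p[3]^2)) -
        h$counts), error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:3)
      gfit <- list(amplitude = fit$par[1], mean_um = fit$par[2],
                   sd_um = fit$par[3])
  }
  list(lengths_um = len, n = length(len), mean_um = mean(len),
       sd_um = stats::sd(len), gaussian_fit = gfit)
}

#' Segment width as the FWHM of a fitted cross-section Gaussian
#'
#' Fits `baseline + A exp(-(x - mu)^2 / (2 sigma^2))` to an intensity
#' profile taken orthogonally across a segment and returns the full width at
#' half maximum, `2 sqrt(2 ln 2) sigma`.
#'
#' @param positions_um Sample positions across the segment (micrometres),
#'   at least 7, straddling the peak.
#' @param intensities Intensities at those positions.
#' @return List: `fwhm_um`, `sigma_um`, `mean_um`, `amplitude`, `baseline`.
#' @export
segment_width_fwhm <- function(positions_um, intensities) {
  x <- as.numeric(positions_um); y <- as.numeric(intensities)
  if (length(x) != length(y)) stop("positions and intensities differ in length")
  if (length(x) < 7L) stop("need at least 7 samples across the segment")
  ord <- order(x); x <- x[ord]; y <- y[ord]
  imax <- which.max(y)
  if (imax == 1L || imax == length(y) || diff(range(y)) == 0)
    stop("no interior peak in the cross-section profile (monotone or flat)")
  base0 <- min(y); amp0 <- max(y) - base0
  # initial sigma from the half-maximum crossing width
  above <- which(y >= base0 + amp0 / 2)
  w0 <- max(x[max(above)] - x[min(above)], 2 * (x[2] - x[1]))
  sig0 <- w0 / (2 * sqrt(2 * log(2)))
  fit <- minpack.lm::nls.lm(
    par = c(amp0, x[imax], sig0, base0),
    lower = c(0, min(x), 1e-6, -Inf), upper = c(Inf, max(x), Inf, Inf),
    fn = function(p) p[4] + p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) - y,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:3) stop("cross-section Gaussian fit did not converge")
  sg <- fit$par[3]
  list(fwhm_um = 2 * sqrt(2 * log(2)) * sg, sigma_um = sg,
       mean_um = fit$par[2], amplitude = fit$par[1], baseline = fit$par[4])
}
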