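# Seeded generators producing every input the pipeline consumes, each with a
# ground-truth record so analysis results can be checked against construction.

#' Simulate a perimeter intensity profile with a contiguous crescent
#'
#' Builds a closed equatorial profile of `n_samples` equally spaced samples
#' in which a contiguous arc of `round(n_samples * crescent_fraction)`
#' samples sits at `crescent_level` and the rest at `background_level`,
#' with additive Gaussian noise truncated at zero (fluorescence is
#' non-negative). The crescent start position is drawn uniformly; the ASI is
#' rotation invariant, so placement does not affect the statistic.
#'
#' @param n_samples Even sample count, >= 8.
#' @param crescent_fraction Fraction of the perimeter covered by the
#'   crescent, in (0, 1].
#' @param crescent_level,background_level Signal levels (>= 0).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param spacing_um Arc spacing (default 0.108 um).
#' @return List: `profile` (a [perimeter_profile()]) and `truth` with the
#'   crescent span, levels and the exact noise-free ASI
#'   `min(m, n - m) * (c - b) / (m c + (n - m) b)` where `m` is the crescent
#'   sample count.
#' @export
make_perimeter_profile <- function(n_samples, crescent_fraction,
                                   crescent_level, background_level,
                                   noise_sd, seed,
                                   spacing_um = 0.108) {
  n <- as.integer(n_samples)
  if (n %% 2L != 0L)
    stop("n_samples must be even: ASI half-windows need an even sample count")
  if (n < 8L) stop("n_samples must be >= 8")
  .check_scalar(crescent_fraction, "crescent_fraction", 0, 1,
                strict_lower = TRUE)
  .check_scalar(crescent_level, "crescent_level", 0)
  .check_scalar(background_level, "background_level", 0)
  .check_scalar(noise_sd, "noise_sd", 0)
  set.seed(seed)
  m <- round(n * crescent_fraction)
  start <- sample.int(n, 1L)
  x <- rep(background_level, n)
  if (m > 0) x[((start - 1L + seq_len(m) - 1L) %% n) + 1L] <- crescent_level
  if (noise_sd > 0) x <- pmax(x + stats::rnorm(n, 0, noise_sd), 0)
  total <- m * crescent_level + (n - m) * background_level
  true_asi <- if (total > 0)
    min(m, n - m) * (crescent_level - background_level) / total else NA_real_
  list(profile = perimeter_profile(x, spacing_um = spacing_um),
       truth = list(n = n, crescent_samples = m, crescent_start = start,
                    crescent_level = crescent_level,
                    background_level = background_level,
                    noise_sd = noise_sd, true_asi = true_asi))
}

#' Simulate three points on (or jittered off) a circular arc
#'
#' @param radius_um Circle radius (> 0).
#' @param center Length-2 centre coordinates (default origin).
#' @param theta_start,theta_mid,theta_end Distinct angles in degrees.
#' @param jitter_sd Isotropic Gaussian jitter sd applied to each coordinate
#'   (um).
#' @param seed Integer seed.
#' @return List: `points` (3 x 2 matrix) and `truth` (radius, center,
#'   angles).
#' @export
make_arc_points <- function(radius_um, center = c(0, 0),
                            theta_start = 0, theta_mid = 45,
                            theta_end = 90, jitter_sd = 0, seed = 1L) {
  .check_scalar(radius_um, "radius_um", 0, strict_lower = TRUE)
  .check_scalar(jitter_sd, "jitter_sd", 0)
  th <- c(theta_start, theta_mid, theta_end)
  if (anyDuplicated(th %% 360))
    stop("angles must be distinct: coincident points define no circle")
  set.seed(seed)
  r <- th * pi / 180
  pts <- cbind(center[1] + radius_um * cos(r),
               center[2] + radius_um * sin(r))
  if (jitter_sd > 0)
    pts <- pts + matrix(stats::rnorm(6, 0, jitter_sd), ncol = 2)
  list(points = pts,
       truth = list(radius_um = radius_um, center = center,
                    theta_deg = th, jitter_sd = jitter_sd))
}

#' Simulate contour lengths from a Gaussian comb mixture
#'
#' Draws `n` lengths from a k-component Gaussian mixture whose means sit at
#' `j * spacing_um` for j = 1..k. Draws below zero are redrawn rather than
#' clipped, so each component keeps its Gaussian shape.
#'
#' @param n Sample size.
#' @param spacing_um Comb spacing (> 0).
#' @param component_sds Either one sd for all components or a length-k
#'   vector (>= 0).
#' @param weights Component weights, summing to 1 (default uniform).
#' @param k Number of components (>= 2).
#' @param seed Integer seed.
#' @return List: `lengths_um` and `truth` (means, sds, weights, spacing).
#' @export
make_comb_lengths <- function(n, spacing_um, component_sds,
                              weights = rep(1 / k, k), k = 7L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  .check_scalar(spacing_um, "spacing_um", 0, strict_lower = TRUE)
  if (any(component_sds < 0)) stop("negative sd")
  sds <- rep_len(component_sds, k)
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (length(weights) != k) stop("need one weight per component")
  set.seed(seed)
  means <- spacing_um * seq_len(k)
  comp <- sample.int(k, n, replace = TRUE, prob = weights)
  x <- stats::rnorm(n, means[comp], sds[comp])
  bad <- which(x < 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), means[comp[bad]], sds[comp[bad]])
    bad <- bad[x[bad] < 0]
  }
  list(lengths_um = x,
       truth = list(spacing_um = spacing_um, means_um = means,
                    sds_um = sds, weights = weights, component = comp))
}

#' Simulate a raster image of a square meshwork lattice
#'
#' Rasterizes a square lattice of lines whose edge lengths all equal the
#' grid pitch, emitting the image together with the ground-truth edge
#' polylines (in micrometres) and a line mask. A fixture for edge
#' enhancement and contour tracing.
#'
#' @param grid_pitch_um Lattice pitch (> 2 * line width).
#' @param pixel_um Pixel size (<= line width, so lines are resolved).
#' @param line_width_um Drawn line width.
#' @param noise_sd Additive Gaussian noise sd (truncated at 0).
#' @param seed Integer seed.
#' @param n_cells Lattice cells per side (>= 1).
#' @param margin_um Blank margin around the lattice.
#' @return List: `image` (matrix in `[0, 1]` plus noise), `mask` (logical
#'   line mask), `polylines` (list of 2 x 2 edge matrices, um),
#'   `pixel_um`, and `truth` (pitch, edge count).
#' @export
make_meshwork_image <- function(grid_pitch_um, pixel_um, line_width_um,
                                noise_sd, seed = 1L, n_cells = 4L,
                                margin_um = grid_pitch_um / 2) {
  .check_scalar(grid_pitch_um, "grid_pitch_um", 0, strict_lower = TRUE)
  .check_scalar(pixel_um, "pixel_um", 0, strict_lower = TRUE)
  .check_scalar(line_width_um, "line_width_um", 0, strict_lower = TRUE)
  if (pixel_um > line_width_um)
    stop("pixel_um must not exceed line_width_um (lines must be resolved)")
  if (grid_pitch_um <= 2 * line_width_um)
    stop("grid_pitch_um must exceed twice the line width")
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("image must contain at least one lattice cell")
  set.seed(seed)
  extent <- n_cells * grid_pitch_um
  side_um <- extent + 2 * margin_um
  npix <- ceiling(side_um / pixel_um)
  # pixel-centre coordinates in um
  cx <- (seq_len(npix) - 1L) * pixel_um
  lines_at <- margin_um + (0:n_cells) * grid_pitch_um
  near_line <- function(v) {
    d <- vapply(v, function(p) min(abs(p - lines_at)), 1)
    d <= line_width_um / 2 & v >= margin_um - line_width_um / 2 &
      v <= margin_um + extent + line_width_um / 2
  }
  on_x <- near_line(cx)
  within <- cx >= margin_um - 1e-9 & cx <= margin_um + extent + 1e-9
  mask <- outer(on_x & within, within, "&") |
    outer(within, on_x & within, "&")   # rows = y, cols = x
  img <- mask * 1
  if (noise_sd > 0)
    img <- pmax(img + matrix(stats::rnorm(length(img), 0, noise_sd),
                             nrow = nrow(img)), 0)
  # ground-truth unit edges between adjacent lattice nodes
  polylines <- list()
  for (i in 0:n_cells) for (j in 0:n_cells) {
    p <- c(margin_um + i * grid_pitch_um, margin_um + j * grid_pitch_um)
    if (i < n_cells)
      polylines[[length(polylines) + 1L]] <-
        rbind(p, p + c(grid_pitch_um, 0))
    if (j < n_cells)
      polylines[[length(polylines) + 1L]] <-
        rbind(p, p + c(0, grid_pitch_um))
  }
  list(image = img, mask = mask, polylines = polylines, pixel_um = pixel_um,
       truth = list(grid_pitch_um = grid_pitch_um, n_edges = length(polylines)))
}

#' Simulate an intensity cross-section of known FWHM
#'
#' Sampled Gaussian of width parameter `sigma = fwhm / (2 sqrt(2 ln 2))`
#' on a uniform position grid, plus baseline and optional noise.
#'
#' @param fwhm_um Full width at half maximum (> 2 * pixel_um).
#' @param amplitude Peak height above baseline.
#' @param baseline Constant offset.
#' @param pixel_um Sample spacing.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer seed.
#' @param half_extent_um Half-width of the sampled window (default
#'   `2 * fwhm_um`).
#' @return List: `positions_um`, `intensities`, `truth` (fwhm, sigma,
#'   amplitude, baseline).
#' @export
make_cross_profile <- function(fwhm_um, amplitude, baseline, pixel_um,
                               noise_sd, seed = 1L,
                               half_extent_um = 2 * fwhm_um) {
  .check_scalar(fwhm_um, "fwhm_um", 0, strict_lower = TRUE)
  if (fwhm_um <= 2 * pixel_um)
    stop("fwhm_um must exceed twice the pixel size to be resolvable")
  .check_scalar(noise_sd, "noise_sd", 0)
  set.seed(seed)
  sigma <- fwhm_um / (2 * sqrt(2 * log(2)))
  x <- seq(-half_extent_um, half_extent_um, by = pixel_um)
  y <- baseline + amplitude * exp(-x^2 / (2 * sigma^2))
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  list(positions_um = x, intensities = y,
       truth = list(fwhm_um = fwhm_um, sigma_um = sigma,
                    amplitude = amplitude, baseline = baseline))
}

#' Simulate a cohort of centrosome-crescent configurations
#'
#' Generates `n_cells` cells on a circle of the given radius: each cell gets
#' a crescent of angular extent theta1 (uniform in `theta1_range_deg`) at a
#' uniform orientation, and a centrosome placed at a clockwise angle theta2
#' from the first crescent edge. Exactly `round(n_cells * inside_fraction)`
#' cells have `theta2` drawn inside `[0, theta1]` (within the fan); the rest
#' strictly outside.
#'
#' @param n_cells Number of cells (>= 1).
#' @param theta1_range_deg Length-2 range for the crescent extent, within
#'   (0, 360).
#' @param inside_fraction Fraction of cells with the centrosome inside the
#'   fan, in `[0, 1]`.
#' @param seed Integer seed.
#' @param radius_um Cell radius used to place edge points (default 5).
#' @return List: `cohort` (data frame `cell_id, cx, cy, eax, eay, ebx, eby,
#'   sx, sy` in um) and `truth` (per-cell theta1, theta2, within flag, and
#'   the constructed inside fraction).
#' @export
make_fan_cohort <- function(n_cells, theta1_range_deg = c(60, 120),
                            inside_fraction = 0.8, seed = 1L,
                            radius_um = 5) {
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("n_cells must be >= 1")
  .check_scalar(inside_fraction, "inside_fraction", 0, 1)
  if (any(theta1_range_deg <= 0) || any(theta1_range_deg >= 358))
    stop("theta1_range_deg must lie within (0, 358) so that an outside sector exists")
  set.seed(seed)
  n_in <- round(n_cells * inside_fraction)
  inside <- sample(c(rep(TRUE, n_in), rep(FALSE, n_cells - n_in)))
  th1 <- stats::runif(n_cells, theta1_range_deg[1], theta1_range_deg[2])
  th2 <- ifelse(inside,
                stats::runif(n_cells, 0, th1),
                stats::runif(n_cells, th1 + 1, 359))
  base <- stats::runif(n_cells, 0, 360)  # orientation of edge_a
  rows <- lapply(seq_len(n_cells), function(i) {
    ea <- radius_um * .cw_dir(base[i])
    eb <- radius_um * .cw_dir(base[i] + th1[i])
    ct <- 0.6 * radius_um * .cw_dir(base[i] + th2[i])
    data.frame(cell_id = i, cx = 0, cy = 0, eax = ea[1], eay = ea[2],
               ebx = eb[1], eby = eb[2], sx = ct[1], sy = ct[2])
  })
  list(cohort = do.call(rbind, rows),
       truth = list(theta1_deg = th1, theta2_deg = th2, within_fan = inside,
                    inside_fraction = n_in / n_cells))
}
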