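test_that("Sobel edge enhancement: constant field, step edge, input checks", {
  expect_true(all(edge_enhance(matrix(5, 10, 10)) == 0))
  step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  em <- edge_enhance(step)
  # maximal response on the two columns flanking the step
  expect_true(all(em[, 4] == max(em)))
  expect_true(all(em[, 5] == max(em)))
  expect_true(all(em[, c(1, 2, 7, 8)] == 0))
  expect_error(edge_enhance(array(1, c(3, 3, 3))), "2-D")
  expect_error(edge_enhance(1:10), "2-D|matrix")
})

test_that("edge map of a synthetic lattice coincides with the line mask", {
  mesh <- make_meshwork_image(0.4, 0.053, 0.1, noise_sd = 0.05, seed = 5)
  em <- edge_enhance(mesh$image)
  sel <- em > 0.5 * max(em)
  # compare against the mask grown by one pixel (Sobel responds on borders)
  grow <- function(m) {
    g <- m
    g[-1, ] <- g[-1, ] | m[-nrow(m), ]
    g[-nrow(m), ] <- g[-nrow(m), ] | m[-1, ]
    g[, -1] <- g[, -1] | m[, -ncol(m)]
    g[, -ncol(m)] <- g[, -ncol(m)] | m[, -1]
    g
  }
  mask <- grow(mesh$mask)
  iou <- sum(sel & mask) / sum(sel | mask)
  expect_gt(iou, 0.7)
})

test_that("contour lengths are polyline arc lengths", {
  expect_equal(contour_lengths(rbind(c(0, 0), c(0.3, 0))), 0.3)
  expect_equal(contour_lengths(rbind(c(0, 0), c(0.3, 0), c(0.3, 0.4))), 0.7)
  expect_error(contour_lengths(matrix(c(1, 2), 1)), "at least 2 points")
  # rigid motion invariance
  set.seed(2)
  tr <- cbind(cumsum(stats::runif(10)), cumsum(stats::rnorm(10)))
  L0 <- contour_lengths(tr)
  phi <- 1.1; Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  expect_equal(contour_lengths(tr %*% t(Rm) +
                                 matrix(c(4, -2), 10, 2, byrow = TRUE)),
               L0, tolerance = 1e-12)
})

test_that("noiseless lattice traces all have the pitch length", {
  mesh <- make_meshwork_image(0.4, 0.053, 0.1, noise_sd = 0, seed = 1)
  lens <- contour_lengths(mesh$polylines)
  expect_true(all(abs(lens - 0.4) <= 0.053))
  expect_equal(length(lens), mesh$truth$n_edges)
})

test_that("length density is a normalized KDE whose mode tracks the sample", {
  set.seed(31)
  x <- stats::rnorm(1000, 2, 0.3)
  d <- length_density(x)
  expect_s3_class(d, "density_curve")
  expect_lt(abs(d$grid[which.max(d$density)] - 2), 0.05)
  integ <- sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_lt(abs(integ - 1), 1e-3)
  expect_error(length_density(stats::runif(9)), "at least 10")
})

test_that("comb samples produce density maxima near multiples of the spacing", {
  cl <- make_comb_lengths(754, 0.4, 0.05, k = 7, seed = 3)
  d <- length_density(cl$lengths_um)
  peaks <- d$grid[which(diff(sign(diff(d$density))) == -2) + 1]
  peaks <- peaks[d$density[match(peaks, d$grid)] > 0.1 * max(d$density)]
  # every prominent peak sits near a comb tooth
  offs <- abs(peaks / 0.4 - round(peaks / 0.4)) * 0.4
  expect_true(all(offs < 0.06))
  expect_gte(length(peaks), 5L)
})

test_that("fitting an exact 7-Gaussian comb density recovers means to 1e-3", {
  grid <- seq(0, 3.2, length.out = 512)
  mu <- 0.4 * (1:7)
  y <- rowSums(vapply(1:7, function(j)
    0.5 * exp(-(grid - mu[j])^2 / (2 * 0.05^2)), numeric(512)))
  d <- structure(list(grid = grid, density = y, bandwidth_um = 0.05,
                      n = 754L), class = "density_curve")
  fit <- fit_k_gaussians(d, k = 7)
  expect_true(fit$converged)
  expect_equal(fit$components$mean_um, mu, tolerance = 1e-3)
  expect_equal(fit$peak_interval_mean_um, 0.4, tolerance = 1e-3)
  expect_lt(fit$peak_interval_sd_um, 1e-3)
})

test_that("k = 1 on a single-Gaussian density recovers the component exactly", {
  grid <- seq(0, 2, length.out = 256)
  y <- 1.3 * exp(-(grid - 0.9)^2 / (2 * 0.12^2))
  d <- structure(list(grid = grid, density = y, bandwidth_um = 0.1,
                      n = 100L), class = "density_curve")
  fit <- fit_k_gaussians(d, k = 1)
  expect_equal(fit$components$amplitude, 1.3, tolerance = 1e-6)
  expect_equal(fit$components$mean_um, 0.9, tolerance = 1e-6)
  expect_equal(fit$components$sd_um, 0.12, tolerance = 1e-6)
})

test_that("residual does not increase when k grows with nested initialization", {
  cl <- make_comb_lengths(500, 0.4, 0.04, k = 5, seed = 8)
  d <- length_density(cl$lengths_um)
  f5 <- fit_k_gaussians(d, k = 5, seed = 8)
  init6 <- list(amplitude = c(f5$components$amplitude, 1e-8),
                mean_um = c(f5$components$mean_um,
                            max(d$grid) - d$bandwidth_um),
                sd_um = c(f5$components$sd_um, d$bandwidth_um))
  f6 <- fit_k_gaussians(d, k = 6, init = init6, seed = 8)
  expect_lte(f6$rss, f5$rss * (1 + 1e-8))
})

test_that("peak interval summarizes consecutive mean differences", {
  expect_equal(peak_interval(c(0.4, 0.8, 1.2)),
               c(mean_um = 0.4, sd_um = 0), tolerance = 1e-12)
  pi_ <- peak_interval(0.38 * (1:7))
  expect_equal(unname(pi_["mean_um"]), 0.38, tolerance = 1e-12)
  expect_lt(pi_["sd_um"], 1e-12)
  expect_error(peak_interval(c(0.8, 0.4)), "increasing")
  expect_error(peak_interval(c(0.4, 0.4)), "increasing")
  expect_error(peak_interval(0.4), "at least 2")
})

test_that("spectral analysis finds a cosine modulation at its frequency", {
  grid <- seq(0, 3, length.out = 512)
  base <- exp(-(grid - 1.4)^2 / (2 * 0.7^2))
  y <- base * (1 + 0.3 * cos(2 * pi * grid / 0.42))
  d <- structure(list(grid = grid, density = y / sum(y) / diff(grid)[1],
                      bandwidth_um = 0.05, n = 500L),
                 class = "density_curve")
  sp <- spectral_periodicity(d)
  bin <- diff(sp$frequencies)[1]
  expect_lt(abs(sp$major_frequency_um_inv - 1 / 0.42), bin + 1e-9)
  expect_true(sp$periodic)
  expect_equal(sp$implied_interval_um, 1 / sp$major_frequency_um_inv)
})

test_that("an aperiodic single-Gaussian density is flagged", {
  grid <- seq(0, 3, length.out = 512)
  y <- exp(-(grid - 1.5)^2 / (2 * 0.5^2))
  d <- structure(list(grid = grid, density = y, bandwidth_um = 0.05,
                      n = 500L), class = "density_curve")
  sp <- spectral_periodicity(d)
  expect_false(sp$periodic)
})

test_that("spectral analysis rejects non-uniform grids", {
  d <- structure(list(grid = cumsum(stats::runif(128, 0.5, 1.5)),
                      density = stats::runif(128), bandwidth_um = 0.1,
                      n = 100L), class = "density_curve")
  expect_error(spectral_periodicity(d), "uniform")
})

test_that("comb fit and spectral route agree on moderately smoothed combs", {
  for (s in 1:3) {
    cl <- make_comb_lengths(754, 0.38, 0.06 * 0.38, k = 7, seed = s)
    d <- length_density(cl$lengths_um, bandwidth = 0.09)
    fit <- fit_k_gaussians(d, k = 7, seed = s)
    sp <- spectral_periodicity(d)
    bin <- diff(sp$frequencies)[1]
    expect_lt(abs(sp$major_frequency_um_inv - 1 / fit$peak_interval_mean_um),
              bin + 1e-9)
  }
})

test_that("segment length statistics and the truncated-Gaussian check", {
  two <- data.frame(x1_um = c(0, 1), y1_um = c(0, 1),
                    x2_um = c(0.39, 1), y2_um = c(0, 1.39))
  st2 <- segment_length_stats(two)
  expect_equal(st2$lengths_um, c(0.39, 0.39))
  expect_equal(st2$mean_um, 0.39)
  expect_error(segment_length_stats(
    data.frame(x1_um = 0, y1_um = 0, x2_um = 0, y2_um = 0)), "zero-length")
  # 194 draws emulating the STED segment sample, averaged over seeds
  means <- vapply(1:20, function(s) {
    set.seed(s)
    x <- stats::rnorm(194, 0.39, 0.09)
    while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), 0.39, 0.09)
    segment_length_stats(x)$mean_um
  }, 1)
  expect_lt(abs(mean(means) - 0.39), 0.02)
  # the single-Gaussian histogram fit tracks the sample location
  set.seed(40)
  x <- stats::rnorm(500, 0.39, 0.09)
  st <- segment_length_stats(x[x > 0])
  expect_false(is.null(st$gaussian_fit))
  expect_equal(st$gaussian_fit$mean_um, 0.39, tolerance = 0.03)
})

test_that("segment width FWHM: analytic conversion and degenerate profiles", {
  cp <- make_cross_profile(2 * sqrt(2 * log(2)) * 0.1, 1, 0, 0.01, 0)
  w <- segment_width_fwhm(cp$positions_um, cp$intensities)
  expect_equal(w$sigma_um, 0.1, tolerance = 1e-7)
  expect_equal(w$fwhm_um / w$sigma_um, 2 * sqrt(2 * log(2)), tolerance = 1e-12)
  # baseline does not bias the width
  cpb <- make_cross_profile(0.23, 1, 0.2, 0.02, 0)
  wb <- segment_width_fwhm(cpb$positions_um, cpb$intensities)
  expect_equal(wb$fwhm_um, 0.23, tolerance = 0.23 * 0.01)
  expect_equal(wb$baseline, 0.2, tolerance = 1e-4)
  expect_error(segment_width_fwhm(1:10, rep(1, 10)), "no interior peak")
  expect_error(segment_width_fwhm(1:10, 1:10), "no interior peak")
  expect_error(segment_width_fwhm(1:5, c(1, 2, 3, 2, 1)), "at least 7")
})
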