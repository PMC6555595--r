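test_that("circumradius handles exact, collinear and duplicate cases", {
  expect_equal(circumradius(c(1, 0), c(0, 1), c(-1, 0)), 1)
  expect_error(circumradius(c(0, 0), c(1, 0), c(2, 0)), "collinear")
  expect_error(circumradius(c(0, 0), c(0, 0), c(1, 1)), "duplicate")
})

test_that("circumradius recovers 1000 random generating circles to 1e-9", {
  set.seed(101)
  for (i in 1:1000) {
    r <- stats::runif(1, 0.5, 20)
    ctr <- stats::runif(2, -10, 10)
    th <- sort(stats::runif(3, 0, 2 * pi))
    if (min(diff(th)) < 0.05) next  # nearly coincident angles are rejected cases
    pts <- cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
    expect_equal(circumradius(pts[1, ], pts[2, ], pts[3, ]), r,
                 tolerance = 1e-9)
  }
})

test_that("circumradius is rigid-motion invariant and scale equivariant", {
  p <- list(c(0.3, 0.1), c(1.2, 0.9), c(0.4, 1.7))
  r0 <- circumradius(p[[1]], p[[2]], p[[3]])
  phi <- 0.83; Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  tr <- c(5, -3)
  pr <- lapply(p, function(v) as.vector(Rm %*% v) + tr)
  expect_equal(circumradius(pr[[1]], pr[[2]], pr[[3]]), r0, tolerance = 1e-12)
  ps <- lapply(p, function(v) 2.5 * v)
  expect_equal(circumradius(ps[[1]], ps[[2]], ps[[3]]), 2.5 * r0,
               tolerance = 1e-12)
})

test_that("a 30 um contour with one 3 um island partitions as expected", {
  r <- 30 / (2 * pi)
  tr <- membrane_trace(circle_trace(r, n = 3000),
                       island_spans = cbind(2, 5))
  parts <- partition_regions(tr)
  expect_equal(sum(parts$region_class == "island"), 1L)
  isl <- parts[parts$region_class == "island", ]
  expect_equal(isl$length_um, 3)
  nb <- parts[parts$region_class == "neighboring", ]
  expect_equal(nrow(nb), 2L)
  expect_equal(sort(nb$length_um), c(5, 5))
  nn <- parts[parts$region_class == "non_neighboring", ]
  expect_equal(nrow(nn), 4L)
  # the inscribed-polygon contour is a hair shorter than the nominal 30 um
  expect_equal(sort(nn$length_um), c(30 - 3 - 10 - 15, 5, 5, 5),
               tolerance = 1e-4)
  # arcs within 5 um of the island edges are exactly the neighboring zones
  expect_equal(sort(c(nb$start_um, nb$end_um)), c(5, 10, 27, 32),
               tolerance = 1e-4)
})

test_that("regions are mutually exclusive and cover the whole contour", {
  set.seed(5)
  for (i in 1:10) {
    L <- stats::runif(1, 20, 40)
    r <- L / (2 * pi)
    s1 <- stats::runif(1, 0, L / 3)
    spans <- cbind(s1, s1 + stats::runif(1, 1.2, 3))
    tr <- membrane_trace(circle_trace(r, n = 1500), island_spans = spans)
    parts <- partition_regions(tr)
    expect_equal(sum(parts$length_um), L, tolerance = 1e-5)
    # no overlaps: sorted segment starts meet previous segment ends
    arcs <- parts[order(parts$start_um), ]
    expect_true(all(diff(arcs$start_um) >=
                      arcs$length_um[-nrow(arcs)] - 1e-9))
    expect_true(all(parts$length_um[parts$region_class != "island"] <=
                      5 + 1e-9))
  }
})

test_that("sub-threshold island spans yield no island region", {
  r <- 30 / (2 * pi)
  tr <- membrane_trace(circle_trace(r, n = 1000),
                       island_spans = cbind(2, 2.8))
  parts <- partition_regions(tr)
  expect_false("island" %in% parts$region_class)
})

test_that("traces without islands split into non_island_cell compartments", {
  r <- 30 / (2 * pi)
  tr <- membrane_trace(circle_trace(r, n = 1000))
  parts <- partition_regions(tr)
  expect_true(all(parts$region_class == "non_island_cell"))
  expect_equal(nrow(parts), 6L)  # 30 um at <= 5 um per compartment
  expect_true(all(parts$length_um <= 5 + 1e-9))
})

test_that("region radius recovers the generating circle exactly", {
  r <- 1.70
  tr <- membrane_trace(circle_trace(r, n = 2000),
                       island_spans = cbind(1, 4))
  meas <- region_radius(tr, 1, 4, "island")
  expect_equal(meas$radius_um, 1.70, tolerance = 1e-12)
  # placement does not matter on a noiseless circle
  for (s in c(0, 3.7, 8)) {
    m2 <- region_radius(tr, s, s + 3, "region")
    expect_equal(m2$radius_um, r, tolerance = 1e-12)
  }
})

test_that("region radius on a wrapping region and a straight region", {
  r <- 5
  L <- 2 * pi * r
  tr <- membrane_trace(circle_trace(r, n = 2000))
  m <- region_radius(tr, L - 2, L + 2, "region")  # wraps the origin
  expect_equal(m$radius_um, r, tolerance = 1e-10)
  straight <- membrane_trace(rbind(cbind(seq(0, 10, by = 0.1), 0),
                                   cbind(seq(10, 0, by = -0.1), 1e-7)))
  ms <- region_radius(straight, 0, 5, "region")
  expect_true(is.na(ms$radius_um))
  expect_match(ms$note, "infinite radius")
})

test_that("jittered arcs recover the radius within Monte-Carlo tolerance", {
  # empirical spread of the estimator under 0.02 um jitter, 1000 draws
  r_true <- 4
  est <- vapply(1:1000, function(s) {
    a <- make_arc_points(r_true, theta_start = 0, theta_mid = 30,
                         theta_end = 60, jitter_sd = 0.02, seed = s)
    tryCatch(circumradius(a$points[1, ], a$points[2, ], a$points[3, ]),
             error = function(e) NA_real_)
  }, 1)
  est <- est[!is.na(est)]
  tol <- 3 * stats::sd(est)
  expect_lt(abs(stats::median(est) - r_true), tol)
  expect_gt(mean(abs(est - r_true) < tol), 0.95)
})

test_that("curvature comparison: identical groups give KS statistic 0, p 1", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  cc <- curvature_compare(g)
  expect_equal(cc$tests$ks_statistic, 0)
  expect_equal(cc$tests$p_value, 1)
  expect_equal(cc$summary$median, c(2.5, 2.5))
})

test_that("shifted radius distributions are detected at n = 80 per group", {
  set.seed(9)
  detected <- vapply(1:20, function(i) {
    a <- stats::rlnorm(80, log(1.7), 0.4)
    b <- stats::rlnorm(80, log(4.0), 0.4)
    curvature_compare(list(island = a, non_neighboring = b))$tests$p_value
  }, 1)
  expect_true(all(detected < 0.01))
})

test_that("measure_trace_curvature measures islands and controls, not neighbors", {
  r <- 30 / (2 * pi)
  tr <- membrane_trace(circle_trace(r, n = 3000), island_spans = cbind(2, 5),
                       cell_id = "c1")
  meas <- measure_trace_curvature(tr)
  expect_false("neighboring" %in% meas$region_class)
  expect_true(all(c("island", "non_neighboring") %in% meas$region_class))
  expect_true(all(abs(meas$radius_um - r) < 1e-9))
})
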