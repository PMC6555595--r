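# Independent oracles used to cross-check pipeline operations.

# Exhaustive O(n^2) ASI: every cyclic half-window summed by an explicit loop.
brute_force_asi <- function(x) {
  n <- length(x)
  h <- n %/% 2L
  total <- sum(x)
  best <- 0
  for (i in seq_len(n)) {
    s <- 0
    for (j in 0:(h - 1L)) s <- s + x[((i - 1L + j) %% n) + 1L]
    best <- max(best, abs(2 * s - total) / total)
  }
  best
}

# Polygon area by fan triangulation from the first vertex (convex polygons).
triangulation_area <- function(xy) {
  n <- nrow(xy)
  a <- 0
  for (i in 2:(n - 1L)) {
    v1 <- xy[i, ] - xy[1, ]
    v2 <- xy[i + 1L, ] - xy[1, ]
    a <- a + (v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  abs(a)
}

# Two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# enumeration: sum the probabilities of all tables with the observed margins
# that are no more probable than the observed one.
fisher_enumeration_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random convex polygon: points on an ellipse at sorted random angles.
random_convex_polygon <- function(n, rx = 1, ry = 1) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  cbind(rx * cos(th), ry * sin(th))
}

# Closed circular membrane trace with a given number of vertices.
circle_trace <- function(radius, n = 720L, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
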