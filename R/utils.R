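# Internal geometry / numeric helpers shared across modules.

# Cumulative arc length of a polyline given as an n x 2 matrix.
# closed = TRUE appends the segment from the last vertex back to the first.
.arc_lengths <- function(xy, closed = FALSE) {
  xy <- .as_xy(xy)
  d <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
  if (closed) d <- c(d, sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2)))
  c(0, cumsum(d))
}

.as_xy <- function(xy) {
  if (is.data.frame(xy)) xy <- as.matrix(xy[, 1:2])
  if (!is.matrix(xy) || ncol(xy) < 2 || !is.numeric(xy))
    stop("coordinates must be an n x 2 numeric matrix", call. = FALSE)
  xy[, 1:2, drop = FALSE]
}

# Point on a (closed) polyline at arc position s, by linear interpolation.
.point_at_arc <- function(xy, s, closed = TRUE) {
  xy <- .as_xy(xy)
  cum <- .arc_lengths(xy, closed = closed)
  total <- cum[length(cum)]
  s <- s %% total
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  seg <- pmin(seg, length(cum) - 1L)
  i2 <- ifelse(seg == nrow(xy), 1L, seg + 1L)
  w <- (s - cum[seg]) / pmax(cum[seg + 1L] - cum[seg], .Machine$double.eps)
  cbind(xy[seg, 1] + w * (xy[i2, 1] - xy[seg, 1]),
        xy[seg, 2] + w * (xy[i2, 2] - xy[seg, 2]))
}

# Geodesic distance between two arc positions on a closed contour of length L.
.arc_dist <- function(a, b, total) {
  d <- abs(a - b) %% total
  pmin(d, total - d)
}

# Clockwise angle (degrees, [0, 360)) from vector u to vector v in image
# coordinates (x right, y down): the cross product x1*y2 - y1*x2 is positive
# for a rotation that appears clockwise on screen.
.cw_angle_deg <- function(u, v) {
  ang <- atan2(u[1] * v[2] - u[2] * v[1], u[1] * v[1] + u[2] * v[2])
  (ang * 180 / pi) %% 360
}

# Unit direction at clockwise screen angle phi (degrees) from the +x axis,
# image coordinates (y down).
.cw_dir <- function(phi_deg) {
  r <- phi_deg * pi / 180
  c(cos(r), sin(r))
}

.next_pow2 <- function(n) 2L^ceiling(log2(n))

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Bilinear interpolation into an image matrix. Coordinates are in pixel
# units with 0-based pixel centres: (0, 0) is the centre of img[1, 1],
# x runs along columns and y along rows. Out-of-bounds points return NA.
.bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x >= 0 & y >= 0 & x <= nc - 1 & y <= nr - 1
  x0 <- pmax(pmin(x0, nc - 2L), 0); y0 <- pmax(pmin(y0, nr - 2L), 0)
  v <- img[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, x0 + 2)] * fx * (1 - fy) +
    img[cbind(y0 + 2, x0 + 1)] * (1 - fx) * fy +
    img[cbind(y0 + 2, x0 + 2)] * fx * fy
  v[!ok] <- NA_real_
  v
}

# Evaluate expr under a temporary RNG state so that internal randomness
# (e.g. fit restarts) neither depends on nor disturbs the caller's stream.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}
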