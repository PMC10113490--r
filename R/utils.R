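# Internal helpers shared across modules.

#' Signed area of a closed polygon (shoelace formula)
#'
#' @param x,y Vertex coordinates of a simple polygon; the closing edge
#'   from the last vertex back to the first is implied.
#' @return Signed area; positive for counter-clockwise orientation.
#' @keywords internal
polygon_area <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# log-spaced sequence, inclusive endpoints
log_seq <- function(from, to, length.out) {
  stopifnot(from > 0, to > from, length.out >= 2)
  out <- exp(seq(log(from), log(to), length.out = length.out))
  out[1] <- from
  out[length.out] <- to
  out
}

# minimum distance between two polylines (vertex-to-segment, both ways)
min_polyline_distance <- function(ax, ay, bx, by) {
  min(points_to_segments(ax, ay, bx, by),
      points_to_segments(bx, by, ax, ay))
}

# distance from each point (px,py) to the nearest segment of polyline (qx,qy)
points_to_segments <- function(px, py, qx, qy) {
  m <- length(qx)
  x1 <- qx[-m]; y1 <- qy[-m]
  x2 <- qx[-1]; y2 <- qy[-1]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- .Machine$double.eps
  best <- rep(Inf, length(px))
  for (i in seq_along(px)) {
    t <- pmin(1, pmax(0, ((px[i] - x1) * dx + (py[i] - y1) * dy) / len2))
    d2 <- (x1 + t * dx - px[i])^2 + (y1 + t * dy - py[i])^2
    best[i] <- sqrt(min(d2))
  }
  best
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch, cached per n)
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n, a = -1, b = 1) {
  key <- as.character(n)
  ref <- .gl_cache[[key]]
  if (is.null(ref)) {
    if (n == 1) {
      x <- 0; w <- 2
    } else {
      i <- seq_len(n - 1)
      beta <- i / sqrt(4 * i^2 - 1)
      J <- matrix(0, n, n)
      J[cbind(i, i + 1)] <- beta
      J[cbind(i + 1, i)] <- beta
      e <- eigen(J, symmetric = TRUE)
      x <- e$values
      w <- 2 * e$vectors[1, ]^2
    }
    ref <- list(x = x, w = w)
    .gl_cache[[key]] <- ref
  }
  list(nodes = (b - a) / 2 * ref$x + (a + b) / 2,
       weights = (b - a) / 2 * ref$w)
}

# stop with a classed condition, tidyverse-style
ath_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "atheromech_error"))
}

`%||%` <- rlang::`%||%`
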