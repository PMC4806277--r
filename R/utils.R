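# internal helpers shared across modules

# evaluate expr with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# shift a matrix by (dr, dc), filling vacated cells
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# separable Gaussian smoothing with replicate edge padding
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(x, n, dim) {
    if (dim == 1) rbind(x[rep(1, n), , drop = FALSE], x, x[rep(nrow(x), n), , drop = FALSE])
    else cbind(x[, rep(1, n), drop = FALSE], x, x[, rep(ncol(x), n), drop = FALSE])
  }
  mp <- pad(m, r, 1)
  acc <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) acc <- acc + k[i] * mp[i:(i + nrow(m) - 1), , drop = FALSE]
  mp <- pad(acc, r, 2)
  acc <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) acc <- acc + k[i] * mp[, i:(i + ncol(m) - 1), drop = FALSE]
  acc
}

# central-difference gradients; x = columns, y = rows (increasing downward)
gradient_xy <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  if (nc >= 3) gx[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  if (nc >= 2) { gx[, 1] <- m[, 2] - m[, 1]; gx[, nc] <- m[, nc] - m[, nc - 1] }
  if (nr >= 3) gy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  if (nr >= 2) { gy[1, ] <- m[2, ] - m[1, ]; gy[nr, ] <- m[nr, ] - m[nr - 1, ] }
  list(x = gx, y = gy)
}

# polygon area by the shoelace formula (points n x 2, closed implicitly)
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# vectorized even-odd point-in-polygon (ray casting)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
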