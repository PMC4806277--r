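# Independent brute-force oracles and small fixture builders.
# These deliberately use the slowest, most literal formulation of each
# operation so they share no code path with the implementation.

# Minkowski erosion by the closed Euclidean disk: a pixel survives iff
# every disk offset lands on a foreground pixel inside the image.
brute_erode <- function(mask, r) {
  if (r <= 0) return(mask)
  offs <- expand.grid(di = -ceiling(r):ceiling(r), dj = -ceiling(r):ceiling(r))
  offs <- offs[offs$di^2 + offs$dj^2 <= r^2, ]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j]) next
    ri <- i + offs$di; cj <- j + offs$dj
    inside <- ri >= 1 & cj >= 1 & ri <= nrow(mask) & cj <= ncol(mask)
    out[i, j] <- all(inside) && all(mask[cbind(ri, cj)])
  }
  out
}

# flood-fill connected-component count
brute_count <- function(mask, conn = 8, min_area = 1) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  offs <- if (conn == 8) expand.grid(di = -1:1, dj = -1:1)[-5, ]
          else data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  k <- 0L
  areas <- integer(0)
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0) next
    k <- k + 1L
    queue <- list(c(i, j)); lab[i, j] <- k; area <- 0L
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      area <- area + 1L
      for (o in seq_len(nrow(offs))) {
        ri <- p[1] + offs$di[o]; cj <- p[2] + offs$dj[o]
        if (ri >= 1 && cj >= 1 && ri <= nrow(mask) && cj <= ncol(mask) &&
            mask[ri, cj] && lab[ri, cj] == 0L) {
          lab[ri, cj] <- k
          queue[[length(queue) + 1L]] <- c(ri, cj)
        }
      }
    }
    areas <- c(areas, area)
  }
  sum(areas >= min_area)
}

# exhaustive Otsu: class weights and means computed from scratch per cut
brute_otsu <- function(counts) {
  n <- length(counts)
  best <- -Inf; best_t <- 1L
  total <- sum(counts)
  for (t in seq_len(n - 1)) {
    c0 <- counts[1:t]; c1 <- counts[(t + 1):n]
    w0 <- sum(c0) / total; w1 <- sum(c1) / total
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((1:t) * c0) / sum(c0)
    mu1 <- sum(((t + 1):n) * c1) / sum(c1)
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_t <- t }
  }
  best_t
}

# double-loop Haralick statistics
brute_glcm_features <- function(cm) {
  L <- nrow(cm)
  contrast <- 0; energy <- 0; homog <- 0
  mi <- 0; mj <- 0
  for (i in 1:L) for (j in 1:L) { mi <- mi + i * cm[i, j]; mj <- mj + j * cm[i, j] }
  si2 <- 0; sj2 <- 0; cov <- 0
  for (i in 1:L) for (j in 1:L) {
    contrast <- contrast + (i - j)^2 * cm[i, j]
    energy <- energy + cm[i, j]^2
    homog <- homog + cm[i, j] / (1 + abs(i - j))
    si2 <- si2 + (i - mi)^2 * cm[i, j]
    sj2 <- sj2 + (j - mj)^2 * cm[i, j]
    cov <- cov + (i - mi) * (j - mj) * cm[i, j]
  }
  r <- if (si2 > 0 && sj2 > 0) cov / sqrt(si2 * sj2) else 0
  c(contrast = contrast, correlation = r, energy = energy, homogeneity = homog)
}

# scalar closed-form sRGB (D65) -> CIELAB
closed_form_lab <- function(r, g, b) {
  lin <- function(u) ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  rgb <- lin(c(r, g, b) / 255)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% rgb)
  wn <- c(0.95047, 1, 1.08883)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz / wn)
  c(L = 116 * fx[2] - 16, a = 500 * (fx[1] - fx[2]), b = 200 * (fx[2] - fx[3]))
}

# geometry builders ----------------------------------------------------------

disk_mask <- function(H, W, cy, cx, r) {
  rows <- matrix(seq_len(H), H, W); cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

ellipse_mask <- function(H, W, cy, cx, a, b, phi = 0) {
  rows <- matrix(seq_len(H), H, W); cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  X <- cols - cx; Y <- rows - cy
  u <- X * cos(phi) + Y * sin(phi); v <- -X * sin(phi) + Y * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

flat_lab <- function(H, W, L = 50, a = 0, b = 0) {
  lab_image(matrix(L, H, W), matrix(a, H, W), matrix(b, H, W))
}

iou <- function(a, b) sum(a & b) / sum(a | b)

random_blob <- function(H = 48, W = 48, n_disks = 3, rmax = 8) {
  m <- matrix(FALSE, H, W)
  for (i in seq_len(n_disks)) {
    m <- m | disk_mask(H, W, sample(12:(H - 12), 1), sample(12:(W - 12), 1),
                       sample(3:rmax, 1))
  }
  m
}
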