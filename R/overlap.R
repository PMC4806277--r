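#' Fibonacci erosion schedule
#'
#' Disk radii for the erosion schedule that probes whether a segmented
#' region contains one grain or several overlapping grains: the first
#' `n_terms` Fibonacci numbers starting 0, 1, 1, 2, 3, ... (the default
#' 21 terms end at 6765).
#'
#' @param n_terms Number of terms (default 21).
#' @return Integer vector of disk radii (class `erosion_schedule`).
#' @export
fibonacci_schedule <- function(n_terms = 21L) {
  if (n_terms < 2) stop("n_terms must be at least 2")
  f <- integer(n_terms)
  f[1] <- 0L; f[2] <- 1L
  if (n_terms > 2) for (k in 3:n_terms) f[k] <- f[k - 1] + f[k - 2]
  structure(f, class = "erosion_schedule")
}

#' Erode a mask with a Euclidean disk
#'
#' Morphological erosion with the closed Euclidean disk of radius `r`
#' (a pixel belongs to the disk iff its centre distance is at most
#' `r`); pixels outside the image count as background. Radius 0 is the
#' identity.
#'
#' @param mask Logical matrix.
#' @param r Disk radius in pixels.
#' @return Logical matrix.
#' @export
erode_disk <- function(mask, r) {
  if (r <= 0) return(mask)
  .edt_sq(mask) > r^2
}

#' Erosion profile of a region under a radius schedule
#'
#' Erodes the original region mask with a disk of every scheduled
#' radius and counts the surviving 8-connected objects of at least
#' `min_object_area` pixels. Counting stops (padding zeros) once the
#' mask empties. `initial_count` is the count at radius 0 and
#' `final_count` the count at the last radius with at least one object.
#'
#' @param region Logical matrix (nonempty).
#' @param schedule Radii from [fibonacci_schedule()].
#' @param min_object_area Minimum object area counted (default 8,
#'   guarding against speckle fragments).
#' @return An `erosion_profile`: list with `radii`, `counts`,
#'   `initial_count`, `final_count`.
#' @export
erosion_profile <- function(region, schedule = fibonacci_schedule(),
                            min_object_area = 8L) {
  if (!any(region)) stop("empty region")
  # crop to the bounding box: everything beyond is background anyway
  rr <- range(which(rowSums(region) > 0))
  cc <- range(which(colSums(region) > 0))
  crop <- region[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  d2 <- .edt_sq(crop)
  radii <- as.integer(schedule)
  counts <- integer(length(radii))
  for (i in seq_along(radii)) {
    m <- d2 > radii[i]^2
    if (!any(m)) break # all later counts stay zero
    lab <- .label_cc(m, 8L)
    k <- attr(lab, "n_components")
    if (k > 0) {
      areas <- tabulate(lab[lab > 0], k)
      counts[i] <- sum(areas >= min_object_area)
    }
    if (counts[i] == 0L) break # erosion is monotone; count cannot recover
  }
  nz <- which(counts > 0)
  structure(list(radii = radii, counts = counts,
                 initial_count = counts[1],
                 final_count = if (length(nz)) counts[max(nz)] else 0L),
            class = "erosion_profile")
}

#' @export
print.erosion_profile <- function(x, ...) {
  cat("<erosion_profile>\n")
  cat("  radii :", paste(x$radii, collapse = " "), "\n")
  cat("  counts:", paste(x$counts, collapse = " "), "\n")
  cat(sprintf("  initial=%d final=%d\n", x$initial_count, x$final_count))
  invisible(x)
}

#' Classify a region as isolated (Case I) or overlapping (Case II)
#'
#' A region is Case II exactly when the object count at the end of the
#' erosion schedule differs from the count at its start: overlapping
#' near-elliptical grains split apart under deep disk erosion, while
#' isolated (convex) grains never change their count.
#'
#' @param profile An `erosion_profile`.
#' @return `"CASE_I"` or `"CASE_II"`.
#' @export
classify_case <- function(profile) {
  if (!inherits(profile, "erosion_profile")) stop("profile must be an erosion_profile")
  if (profile$final_count != profile$initial_count) "CASE_II" else "CASE_I"
}

#' Recover per-grain seeds from an overlapping region
#'
#' Takes the eroded fragments at the first radius showing the region's
#' revealed grain count (the state just before the fragments
#' disappear), then dilates all fragments simultaneously with
#' unit-radius disk steps, clipped to the region, stopping one step
#' before any two fragments would become 8-connected.
#'
#' The revealed count is the final count of the profile or, if larger,
#' the maximum count attained at any radius: disk erosion can only
#' split components, never merge them, so a transient count increase
#' is unambiguous evidence of overlap even when sub-pixel size
#' differences make one fragment outlive another at the deepest
#' scheduled radius.
#'
#' @param region Logical region mask.
#' @param profile Its `erosion_profile`.
#' @param schedule The schedule used for the profile.
#' @param min_object_area As in [erosion_profile()].
#' @return List of disjoint logical seed masks (full image size).
#' @export
extract_seeds <- function(region, profile, schedule = fibonacci_schedule(),
                          min_object_area = 8L) {
  counts <- profile$counts
  split_seen <- max(counts) > profile$initial_count
  if (classify_case(profile) != "CASE_II" && !split_seen)
    stop("extract_seeds requires an overlapping (Case II) region")
  nz <- which(counts > 0)
  target <- max(profile$final_count, max(counts))
  start_idx <- nz[which(counts[nz] == target)[1]]
  r_seed <- profile$radii[start_idx]

  lab_full <- label_components(erode_disk(region, r_seed), conn = 8L)
  k <- attr(lab_full, "n_components")
  areas <- tabulate(lab_full[lab_full > 0], k)
  keep <- which(areas >= min_object_area)
  lab <- matrix(match(lab_full, keep, nomatch = 0L), nrow(lab_full))

  lab <- grow_labels(lab, region)
  lapply(seq_along(keep), function(i) lab == i)
}

# simultaneous unit-radius (4-neighbour) dilation of a label image inside
# `region`, stopping one step before two labels would touch (8-adjacency)
grow_labels <- function(lab, region) {
  n4 <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  n8 <- c(n4, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  touching <- function(l) {
    for (o in n8) {
      s <- shift_mat(l, o[1], o[2], 0L)
      if (any(l > 0L & s > 0L & l != s)) return(TRUE)
    }
    FALSE
  }
  repeat {
    lo <- hi <- matrix(0L, nrow(lab), ncol(lab))
    for (o in n4) {
      s <- shift_mat(lab, o[1], o[2], 0L)
      pos <- s > 0L
      lo[pos] <- ifelse(lo[pos] == 0L, s[pos], pmin(lo[pos], s[pos]))
      hi[pos] <- pmax(hi[pos], s[pos])
    }
    cand <- lab == 0L & region & hi > 0L
    if (any(cand & lo != hi)) break      # a pixel claimed by two fragments
    if (!any(cand)) break                # fragments fill the region
    new_lab <- lab
    new_lab[cand] <- hi[cand]
    if (touching(new_lab)) break         # would make two fragments adjacent
    lab <- new_lab
  }
  lab
}

#' Gradient vector flow field of a binary region
#'
#' The edge map is the squared gradient magnitude of the Gaussian-
#' smoothed mask, normalized to `[0, 1]`; its gradient is diffused by
#' the generalized GVF iteration
#' `u <- u + dt * (mu * lap(u) - (u - f_x) * (f_x^2 + f_y^2))`
#' (likewise for `v`), giving an external force with a capture range
#' much larger than the raw edge gradient.
#'
#' @param region Logical matrix.
#' @param mu Diffusion (regularization) weight, default 0.2.
#' @param n_iter Diffusion iterations, default 200.
#' @param sigma Gaussian smoothing scale of the edge map in pixels,
#'   default 1.5.
#' @return A `gvf_field`: list with `u`, `v` (x- and y-force planes),
#'   `mu`, `iterations`.
#' @export
gvf_field <- function(region, mu = 0.2, n_iter = 200L, sigma = 1.5) {
  if (!is.finite(mu) || !is.finite(n_iter) || !is.finite(sigma))
    stop("gvf parameters must be finite")
  if (mu < 0 || n_iter < 1 || sigma <= 0) stop("invalid gvf parameters")
  sm <- gaussian_blur(region * 1.0, sigma)
  g <- gradient_xy(sm)
  f <- g$x^2 + g$y^2
  if (max(f) > 0) f <- f / max(f)
  gf <- gradient_xy(f)
  fx <- gf$x; fy <- gf$y
  b <- fx^2 + fy^2
  u <- fx; v <- fy
  dt <- if (mu > 0) min(1, 1 / (4 * mu)) else 1
  lap <- function(m) {
    shift_mat(m, 1, 0, 0) + shift_mat(m, -1, 0, 0) +
      shift_mat(m, 0, 1, 0) + shift_mat(m, 0, -1, 0) - 4 * m
  }
  for (i in seq_len(n_iter)) {
    u <- u + dt * (mu * lap(u) - b * (u - fx))
    v <- v + dt * (mu * lap(v) - b * (v - fy))
  }
  structure(list(u = u, v = v, mu = mu, iterations = n_iter),
            class = "gvf_field")
}

#' Trace the outer boundary of a mask
#'
#' Moore-neighbour tracing of the 8-connected outer border, returning
#' the ordered boundary pixel centres as (x = column, y = row) pairs.
#'
#' @param mask Logical matrix with a single nonempty component.
#' @return Numeric matrix `n x 2` (columns `x`, `y`).
#' @export
trace_boundary <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  # start: top-most, then left-most foreground pixel
  start <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
  if (nrow(idx) == 1) return(matrix(c(start[2], start[1]), 1, 2,
                                    dimnames = list(NULL, c("x", "y"))))
  # clockwise Moore neighbourhood starting W
  offs <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                 ncol = 2, byrow = TRUE) # (dr, dc): W NW N NE E SE S SW
  inside <- function(r, c) r >= 1 && c >= 1 && r <= nrow(mask) && c <= ncol(mask) && mask[r, c]
  path_r <- integer(0); path_c <- integer(0)
  cur <- start
  dir_start <- 1L # begin scanning at W (the backtrack side of the start pixel)
  first_state <- NULL
  repeat {
    found <- FALSE
    for (s in 0:7) {
      d <- ((dir_start - 1L + s) %% 8L) + 1L
      r <- cur[1] + offs[d, 1]; c <- cur[2] + offs[d, 2]
      if (inside(r, c)) {
        state <- c(cur[1], cur[2], d)
        if (is.null(first_state)) first_state <- state
        else if (all(state == first_state)) return(cbind(x = path_c, y = path_r))
        path_r <- c(path_r, cur[1]); path_c <- c(path_c, cur[2])
        cur <- c(r, c)
        # next scan starts from the neighbour after the backtrack direction
        dir_start <- ((d + 4L - 1L + 1L) %% 8L) + 1L
        found <- TRUE
        break
      }
    }
    if (!found) { # isolated pixel reached (should not happen for one component)
      path_r <- c(path_r, cur[1]); path_c <- c(path_c, cur[2])
      return(cbind(x = path_c, y = path_r))
    }
    if (length(path_r) > 4 * sum(mask) + 8) stop("boundary tracing failed to close")
  }
}

# resample a closed polygon to n points of uniform arc length
resample_closed <- function(p, n) {
  q <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(diff(q[, 1])^2 + diff(q[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) return(p[rep(1, n), , drop = FALSE])
  s <- seq(0, total, length.out = n + 1)[-(n + 1)]
  xi <- stats::approx(cum, q[, 1], xout = s)$y
  yi <- stats::approx(cum, q[, 2], xout = s)$y
  cbind(xi, yi)
}

# bilinear interpolation of a plane at real (x = col, y = row) points
interp_bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  dx <- x - x0; dy <- y - y0
  m00 <- m[cbind(y0, x0)]; m01 <- m[cbind(y0, x0 + 1)]
  m10 <- m[cbind(y0 + 1, x0)]; m11 <- m[cbind(y0 + 1, x0 + 1)]
  m00 * (1 - dx) * (1 - dy) + m01 * dx * (1 - dy) +
    m10 * (1 - dx) * dy + m11 * dx * dy
}

#' Evolve an active contour under a GVF field
#'
#' Initializes the contour as the seed's boundary polygon resampled to
#' uniform arc length and iterates the semi-implicit snake update with
#' tension `alpha`, rigidity `beta`, step size `gamma` and external
#' force `kappa * (u, v)`; the contour is re-resampled every 10
#' iterations.
#'
#' @param seed Logical seed mask (nonempty).
#' @param field A `gvf_field` matching the seed's image size.
#' @param alpha Tension (first-derivative) weight, default 0.1.
#' @param beta Rigidity (second-derivative) weight, default 0.05.
#' @param gamma Implicit time step, default 1.
#' @param kappa External force weight, default 2.
#' @param n_iter Iterations, default 200.
#' @param n_points Contour points, default 64.
#' @return A `snake_contour`: closed contour points `n x 2` (x, y).
#' @export
evolve_snake <- function(seed, field, alpha = 0.1, beta = 0.05, gamma = 1,
                         kappa = 2, n_iter = 200L, n_points = 64L) {
  if (!any(seed)) stop("empty seed")
  if (!all(dim(seed) == dim(field$u))) stop("field shape does not match seed")
  p <- resample_closed(trace_boundary(seed), n_points)
  n <- n_points
  # pentadiagonal internal-energy matrix (circulant)
  a2 <- beta; a1 <- -alpha - 4 * beta; a0 <- 2 * alpha + 6 * beta
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, i] <- a0
    A[i, (i %% n) + 1] <- a1
    A[i, ((i - 2) %% n) + 1] <- a1
    A[i, ((i + 1) %% n) + 1] <- a2
    A[i, ((i - 3) %% n) + 1] <- a2
  }
  inv <- solve(diag(n) + gamma * A)
  for (it in seq_len(n_iter)) {
    fx <- interp_bilinear(field$u, p[, 1], p[, 2])
    fy <- interp_bilinear(field$v, p[, 1], p[, 2])
    p <- cbind(inv %*% (p[, 1] + gamma * kappa * fx),
               inv %*% (p[, 2] + gamma * kappa * fy))
    if (it %% 10 == 0) p <- resample_closed(p, n)
  }
  if (polygon_area(p) < 10) stop("snake collapsed")
  structure(p, class = "snake_contour", dimnames = list(NULL, c("x", "y")))
}

#' Partition a region among snake contours
#'
#' Assigns every region pixel to the contour whose interior contains
#' it; pixels inside several contours, or none, go to the contour with
#' the nearest centroid. The result is a disjoint partition of the
#' region, one mask per grain.
#'
#' @param region Logical region mask.
#' @param contours List of at least two `snake_contour`s.
#' @return List of disjoint logical masks whose union equals `region`.
#' @export
separate_region <- function(region, contours) {
  if (length(contours) < 2) stop("need at least 2 contours")
  idx <- which(region, arr.ind = TRUE)
  px <- idx[, 2]; py <- idx[, 1]
  inside <- vapply(contours, function(ct) point_in_polygon(px, py, ct),
                   logical(length(px)))
  inside <- matrix(inside, ncol = length(contours))
  n_in <- rowSums(inside)
  centroids <- t(vapply(contours, colMeans, c(0, 0)))
  d2 <- vapply(seq_along(contours), function(k)
    (px - centroids[k, 1])^2 + (py - centroids[k, 2])^2, numeric(length(px)))
  d2 <- matrix(d2, ncol = length(contours))
  assign <- integer(length(px))
  one <- n_in == 1
  assign[one] <- max.col(inside[one, , drop = FALSE], ties.method = "first")
  assign[!one] <- max.col(-d2[!one, , drop = FALSE], ties.method = "first")
  masks <- lapply(seq_along(contours), function(k) {
    m <- matrix(FALSE, nrow(region), ncol(region))
    m[idx[assign == k, , drop = FALSE]] <- TRUE
    m
  })
  connect_partition(masks, region)
}

# reattach stranded fragments: each output mask keeps its largest
# component; smaller components are merged into the adjacent mask with
# the longest shared border (within a connected region such a neighbour
# always exists, so every final mask is connected)
connect_partition <- function(masks, region) {
  n8 <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
             c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (pass in 1:10) {
    moved <- FALSE
    for (k in seq_along(masks)) {
      lab <- label_components(masks[[k]], 8L)
      nc <- attr(lab, "n_components")
      if (nc <= 1) next
      areas <- tabulate(lab[lab > 0], nc)
      main <- which.max(areas)
      for (comp in setdiff(seq_len(nc), main)) {
        frag <- lab == comp
        ring <- matrix(FALSE, nrow(frag), ncol(frag))
        for (o in n8) ring <- ring | shift_mat(frag, o[1], o[2], FALSE)
        ring <- ring & !frag
        border <- vapply(seq_along(masks), function(j)
          if (j == k) 0L else sum(ring & masks[[j]]), 0L)
        if (max(border) > 0) {
          j <- which.max(border)
          masks[[j]] <- masks[[j]] | frag
          masks[[k]] <- masks[[k]] & !frag
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  masks
}
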