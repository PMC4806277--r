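#' Label connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @param conn Connectivity, 4 or 8 (default 8).
#' @return Integer matrix of labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, conn = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask), conn %in% c(4L, 8L))
  .label_cc(mask, as.integer(conn))
}

#' Mean-shift clustering of the (a*, b*) colour plane
#'
#' Every pixel is represented by its chromaticity vector `(a, b)` and
#' iterated to a local density mode: each step replaces the point by the
#' count-weighted mean of all pixel values within `bandwidth` (flat
#' kernel), until the displacement falls below `tol`. Converged modes
#' closer than `bandwidth / 2` are merged. The stain of interest is
#' chromatic (purple) against a pale background, so lightness is
#' deliberately excluded from the feature.
#'
#' Pixels whose `(a, b)` values fall in the same 0.5-unit bin share one
#' trajectory; this is a pure speed device and does not change the
#' contract at the bandwidths of interest.
#'
#' @param lab A `lab_image`.
#' @param bandwidth Kernel radius `h` in native a/b units (default 25,
#'   chosen so a stained grain plus background yield two or three modes).
#' @param tol Convergence displacement (default 0.1).
#' @param max_iter Maximum iterations per trajectory (default 100).
#' @return A `mode_map`: list with `labels` (H x W integer matrix,
#'   values `1..k`) and `modes` (k x 2 matrix of (a, b) mode centres,
#'   ordered by decreasing pixel support).
#' @export
mean_shift_modes <- function(lab, bandwidth = 25, tol = 0.1, max_iter = 100L) {
  if (!inherits(lab, "lab_image")) stop("lab must be a lab_image")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  d <- dim(lab$L)
  if (prod(d) == 0) stop("empty image")
  a <- as.vector(lab$a); b <- as.vector(lab$b)

  # one trajectory per 0.5-unit (a,b) bin
  key <- paste(round(a * 2L), round(b * 2L))
  grp <- match(key, unique(key))
  n_bins <- max(grp)
  cnt <- tabulate(grp, n_bins)
  pa <- vapply(split(a, grp), mean, 0)[as.character(seq_len(n_bins))]
  pb <- vapply(split(b, grp), mean, 0)[as.character(seq_len(n_bins))]
  pts <- cbind(unname(pa), unname(pb)) # data support (fixed)
  pos <- pts                           # trajectory positions (moving)

  h2 <- bandwidth^2
  active <- rep(TRUE, n_bins)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    idx <- which(active)
    # chunk to bound the distance-matrix memory
    for (block in split(idx, ceiling(seq_along(idx) / 1024))) {
      dx <- outer(pos[block, 1], pts[, 1], "-")
      dy <- outer(pos[block, 2], pts[, 2], "-")
      within <- (dx * dx + dy * dy) <= h2
      w <- sweep(within, 2, cnt, "*")
      tot <- rowSums(w)
      newx <- (w %*% pts[, 1]) / tot
      newy <- (w %*% pts[, 2]) / tot
      moved <- sqrt((newx - pos[block, 1])^2 + (newy - pos[block, 2])^2)
      pos[block, 1] <- newx
      pos[block, 2] <- newy
      active[block] <- moved >= tol
    }
  }

  # merge converged modes closer than bandwidth/2 (transitive chaining)
  uniq <- unique(round(pos / tol)) * tol
  assign_uniq <- match(paste(round(pos[, 1] / tol), round(pos[, 2] / tol)),
                       paste(round(uniq[, 1] / tol), round(uniq[, 2] / tol)))
  m <- nrow(uniq)
  parent <- seq_len(m)
  findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  merge_r2 <- (bandwidth / 2)^2
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (sum((uniq[i, ] - uniq[j, ])^2) <= merge_r2) {
        ri <- findp(i); rj <- findp(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(m), findp, 0L)
  cluster_of_traj <- match(root, unique(root))[assign_uniq]
  k <- max(cluster_of_traj)

  # weighted mode centres and size ordering
  wts <- tapply(cnt, cluster_of_traj, sum)
  ma <- tapply(pos[, 1] * cnt, cluster_of_traj, sum) / wts
  mb <- tapply(pos[, 2] * cnt, cluster_of_traj, sum) / wts
  ord <- order(-wts)
  rank <- match(seq_len(k), ord)
  labels_px <- rank[cluster_of_traj[grp]]
  modes <- cbind(a = as.numeric(ma)[ord], b = as.numeric(mb)[ord])

  structure(list(labels = matrix(labels_px, d[1], d[2]), modes = modes),
            class = "mode_map")
}

#' @export
print.mode_map <- function(x, ...) {
  cat(sprintf("<mode_map %d x %d, %d modes>\n",
              nrow(x$labels), ncol(x$labels), nrow(x$modes)))
  invisible(x)
}

#' Otsu threshold of a histogram
#'
#' Exhaustively maximizes the between-class variance over all cut
#' points of a histogram; returns the index `t` such that bins
#' `1..t` form the low class and `t+1..n` the high class.
#'
#' @param counts Nonnegative histogram counts.
#' @return Integer cut index in `1..(length(counts) - 1)`.
#' @export
otsu_threshold <- function(counts) {
  n <- length(counts)
  if (n < 2 || sum(counts) == 0) stop("histogram must have mass in at least 2 bins")
  p <- counts / sum(counts)
  x <- seq_len(n)
  w0 <- cumsum(p)[-n]
  w1 <- 1 - w0
  m0 <- cumsum(p * x)[-n]
  mt <- sum(p * x)
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n - 1)
  sigma_b[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  which.max(sigma_b)
}

#' Binarize the pollen region from a mode map
#'
#' Builds the mode-value image (each pixel replaced by the a*
#' coordinate of its mean-shift mode), applies Otsu's threshold on its
#' 256-bin histogram over the native a* range, keeps the side with the
#' higher mean a* (the purple stain is strongly red-chromatic), and
#' fills interior holes.
#'
#' @param lab A `lab_image` (consistency-checked against `modemap`).
#' @param modemap A `mode_map` from [mean_shift_modes()].
#' @return Logical foreground mask.
#' @export
binarize_pollen <- function(lab, modemap) {
  if (!inherits(modemap, "mode_map")) stop("modemap must be a mode_map")
  if (!all(dim(lab) == dim(modemap$labels))) stop("modemap inconsistent with lab")
  if (nrow(modemap$modes) < 2) stop("nothing to threshold: single-mode map")
  amode <- matrix(modemap$modes[modemap$labels, 1], nrow(modemap$labels))
  breaks <- seq(-128, 127, length.out = 257)
  bin <- matrix(pmin(pmax(findInterval(amode, breaks, all.inside = TRUE), 1L), 256L),
                nrow(amode))
  counts <- tabulate(bin, 256L)
  t_cut <- otsu_threshold(counts)
  low <- bin <= t_cut
  mean_low <- mean(amode[low]); mean_high <- mean(amode[!low])
  fg <- if (mean_high >= mean_low) !low else low
  fill_holes(fg)
}

#' Fill interior holes of a binary mask
#'
#' A hole is a background component (4-connected, matching 8-connected
#' foreground) not touching the image border.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with holes set to `TRUE`.
#' @export
fill_holes <- function(mask) {
  lab <- label_components(!mask, conn = 4L)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  mask | !(lab %in% c(0L, border_labels))
}

#' Extract connected foreground regions
#'
#' 8-connected components of the mask with at least `min_region_area`
#' pixels, sorted by decreasing area.
#'
#' @param mask Logical matrix.
#' @param min_region_area Minimum component area in pixels (default 150,
#'   rejecting debris well below the smallest grain section).
#' @return A `region_set`: list of regions, each with `mask` (logical,
#'   full image size), `bbox` (`r1, r2, c1, c2`) and `area`.
#' @export
extract_regions <- function(mask, min_region_area = 150L) {
  lab <- label_components(mask, conn = 8L)
  k <- attr(lab, "n_components")
  regions <- list()
  if (k > 0) {
    areas <- tabulate(lab[lab > 0], k)
    keep <- which(areas >= min_region_area)
    keep <- keep[order(-areas[keep])]
    regions <- lapply(keep, function(id) {
      m <- lab == id
      rr <- range(which(rowSums(m) > 0))
      cc <- range(which(colSums(m) > 0))
      list(mask = m, bbox = c(r1 = rr[1], r2 = rr[2], c1 = cc[1], c2 = cc[2]),
           area = sum(m))
    })
  }
  structure(regions, class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set of %d region(s), areas: %s>\n", length(x),
              paste(vapply(x, function(r) r$area, 0), collapse = ", ")))
  invisible(x)
}
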