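#' Shape descriptors of a grain mask
#'
#' Area `A` is the foreground pixel count; perimeter `P` is the length
#' of the closed polygon through the traced border pixel centres;
#' roundness `R = 4*pi*A / P^2` (1 for an ideal circle); compactness
#' `C = A / P^2`; `MA`/`mA` are the longer and shorter sides of the
#' axis-aligned bounding box.
#'
#' @param mask Logical matrix with exactly one 8-connected component.
#' @return Named numeric vector `MA, mA, A, P, R, C`.
#' @export
shape_features <- function(mask) {
  if (!any(mask)) stop("empty mask")
  lab <- label_components(mask, conn = 8L)
  if (attr(lab, "n_components") != 1L) stop("mask must have exactly one component")
  A <- sum(mask)
  bnd <- trace_boundary(mask)
  q <- rbind(bnd, bnd[1, , drop = FALSE])
  P <- sum(sqrt(diff(q[, 1])^2 + diff(q[, 2])^2))
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  sides <- c(diff(rr) + 1, diff(cc) + 1)
  c(MA = max(sides), mA = min(sides), A = A, P = P,
    R = 4 * pi * A / P^2, C = A / P^2)
}

#' First-order intensity statistics of a region
#'
#' Mean, sample median, population variance (divisor `N`), standard
#' deviation, and Shannon entropy in bits over an `n_bins` histogram of
#' the channel's native range.
#'
#' @param values Numeric vector of region intensities (nonempty).
#' @param n_bins Histogram bins for the entropy (default 256).
#' @param value_range Native channel range for binning; defaults to the
#'   observed range.
#' @return Named numeric vector `mean, median, var, sd, entropy`.
#' @export
first_order_features <- function(values, n_bins = 256L, value_range = NULL) {
  if (length(values) < 1) stop("empty input")
  if (is.null(value_range)) value_range <- range(values)
  mu <- mean(values)
  m <- median(values)
  v <- mean((values - mu)^2)
  if (diff(value_range) == 0) {
    S <- 0
  } else {
    breaks <- seq(value_range[1], value_range[2], length.out = n_bins + 1)
    bin <- pmin(pmax(findInterval(values, breaks, all.inside = TRUE), 1L), n_bins)
    p <- tabulate(bin, n_bins)
    p <- p[p > 0] / length(values)
    S <- -sum(p * log2(p))
  }
  c(mean = mu, median = m, var = v, sd = sqrt(v), entropy = S)
}

#' Grey-level co-occurrence matrix of a masked channel
#'
#' Quantizes the channel to `levels` equal-width bins over its native
#' range and accumulates co-occurrences of pixel pairs at the four
#' offsets (0, 45, 90, 135 degrees) at the given distance, with both
#' pixels inside the mask; the matrix is symmetrized, averaged over
#' offsets, and normalized to sum 1.
#'
#' @param channel Numeric matrix of intensities.
#' @param mask Logical matrix (at least 2 pixels).
#' @param levels Quantization levels (default 32).
#' @param distance Pair offset distance in pixels (default 1).
#' @param value_range Native channel range; defaults to observed range.
#' @return `levels x levels` normalized co-occurrence matrix.
#' @export
glcm <- function(channel, mask, levels = 32L, distance = 1L, value_range = NULL) {
  if (sum(mask) < 2) stop("region too small for any valid pair")
  if (is.null(value_range)) value_range <- range(channel[mask])
  lo <- value_range[1]; hi <- value_range[2]
  q <- if (hi > lo) {
    pmin(pmax(floor((channel - lo) / (hi - lo) * levels) + 1L, 1L), levels)
  } else matrix(1L, nrow(channel), ncol(channel))
  offs <- list(c(0L, distance), c(-distance, distance),
               c(-distance, 0L), c(-distance, -distance))
  acc <- matrix(0, levels, levels)
  any_pair <- FALSE
  for (o in offs) {
    q2 <- shift_mat(q, -o[1], -o[2], NA_integer_)      # value at p + offset
    m2 <- shift_mat(mask, -o[1], -o[2], FALSE)
    ok <- mask & m2 & !is.na(q2)
    if (!any(ok)) next
    any_pair <- TRUE
    tab <- table(factor(q[ok], levels = seq_len(levels)),
                 factor(q2[ok], levels = seq_len(levels)))
    acc <- acc + tab + t(tab)
  }
  if (!any_pair) stop("region too small for any valid pair")
  out <- acc / sum(acc)
  dimnames(out) <- NULL
  as.matrix(out)
}

#' Haralick statistics of a normalized co-occurrence matrix
#'
#' Contrast `sum((i-j)^2 c)`, correlation (0 when either marginal
#' standard deviation vanishes), energy `sum(c^2)`, and local
#' homogeneity `sum(c / (1 + |i-j|))`.
#'
#' @param c_mat Normalized nonnegative co-occurrence matrix.
#' @return Named numeric vector `contrast, correlation, energy,
#'   homogeneity`.
#' @export
glcm_features <- function(c_mat) {
  L <- nrow(c_mat)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  cm <- sum((i - j)^2 * c_mat)
  pi_ <- rowSums(c_mat); pj <- colSums(c_mat)
  mi <- sum(seq_len(L) * pi_); mj <- sum(seq_len(L) * pj)
  si <- sqrt(sum((seq_len(L) - mi)^2 * pi_))
  sj <- sqrt(sum((seq_len(L) - mj)^2 * pj))
  r <- if (si * sj > 0) sum((i - mi) * (j - mj) * c_mat) / (si * sj) else 0
  e <- sum(c_mat^2)
  hl <- sum(c_mat / (1 + abs(i - j)))
  c(contrast = cm, correlation = r, energy = e, homogeneity = hl)
}

# native CIELAB channel ranges used for histograms and quantization
lab_channel_ranges <- function() {
  list(L = c(0, 100), a = c(-128, 127), b = c(-128, 127))
}

#' The 33-dimensional grain descriptor
#'
#' Concatenates 6 shape features, 5 first-order statistics per CIELAB
#' channel, and 4 co-occurrence statistics per CIELAB channel, in the
#' frozen order `MA, mA, A, P, R, C`, then `mean, median, var, sd,
#' entropy` for L*, a*, b*, then `contrast, correlation, energy,
#' homogeneity` for L*, a*, b*.
#'
#' @param grain_mask Logical mask with a single component.
#' @param lab The `lab_image` the grain was segmented from.
#' @param glcm_levels,glcm_distance Co-occurrence quantization (defaults
#'   32 levels, distance 1).
#' @return Named numeric vector of length 33.
#' @export
feature_vector <- function(grain_mask, lab, glcm_levels = 32L, glcm_distance = 1L) {
  if (!all(dim(grain_mask) == dim(lab))) stop("mask and image sizes differ")
  ranges <- lab_channel_ranges()
  out <- shape_features(grain_mask)
  for (ch in c("L", "a", "b")) {
    f <- first_order_features(lab[[ch]][grain_mask], 256L, ranges[[ch]])
    names(f) <- paste0(ch, "_", names(f))
    out <- c(out, f)
  }
  for (ch in c("L", "a", "b")) {
    g <- glcm_features(glcm(lab[[ch]], grain_mask, glcm_levels, glcm_distance,
                            ranges[[ch]]))
    names(g) <- paste0(ch, "_", names(g))
    out <- c(out, g)
  }
  stopifnot(length(out) == 33L)
  out
}

#' Names of the 33 descriptor entries, in frozen order
#' @return Character vector of length 33.
#' @export
feature_names <- function() {
  c("MA", "mA", "A", "P", "R", "C",
    as.vector(t(outer(c("L", "a", "b"),
                      c("mean", "median", "var", "sd", "entropy"), paste, sep = "_"))),
    as.vector(t(outer(c("L", "a", "b"),
                      c("contrast", "correlation", "energy", "homogeneity"),
                      paste, sep = "_"))))
}
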