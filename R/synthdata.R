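#' Per-class generative parameters of the synthetic pollen classes
#'
#' Twelve airborne-pollen classes with fixed class-conditional
#' parameters: mean equivalent diameter (pixels, at the package's
#' nominal scale of 0.5 um/pixel, spanning 15-37 um), semi-axis ratio,
#' mean stain colour in CIELAB (purple: high a*, negative b*), exine
#' ring width and per-channel texture noise. The parameters are spread
#' so the classes are statistically separable by shape, colour and
#' texture.
#'
#' @return Data frame with one row per class.
#' @export
pollen_classes <- function() {
  data.frame(
    class = 1:12,
    name = c("Acacia farnesiana", "Medicago sativa", "Chenopodium murale",
             "Cynodon dactylon", "Helianthus ciliaris", "Morus alba",
             "Carya illinoinensis", "Olea europaea", "Prosopis glandulosa",
             "Salix spp.", "Schinus molle", "Sorghum halepense"),
    diam = c(30, 34, 38, 42, 46, 50, 54, 58, 62, 66, 70, 74),
    ratio = c(0.95, 0.90, 0.97, 0.92, 0.89, 0.96, 0.91, 0.94, 0.98, 0.88, 0.93, 0.90),
    L = c(46, 42, 50, 44, 40, 52, 38, 48, 45, 41, 49, 43),
    a = c(36, 40, 32, 38, 34, 30, 42, 28, 37, 33, 39, 31),
    b = c(-26, -22, -28, -18, -30, -24, -20, -32, -27, -21, -25, -29),
    exine_w = c(2, 0, 3, 0, 2, 0, 4, 2, 0, 3, 0, 4),
    noise_sd = c(1.5, 2.0, 2.5, 1.8, 3.0, 1.2, 2.2, 2.8, 1.6, 2.4, 2.0, 2.6)
  )
}

# radius of an ellipse (semi-axes a >= b, rotation phi) along direction theta
ellipse_radius <- function(a, b, phi, theta) {
  psi <- theta - phi
  1 / sqrt(cos(psi)^2 / a^2 + sin(psi)^2 / b^2)
}

#' Sample a synthetic slide scene
#'
#' Draws a deterministic scene specification: grains grouped into
#' isolated singletons (Case I) or overlapping clusters of two or
#' three grains of the same class (Case II, same-species clumping),
#' plus low-chroma clutter blobs emulating mounting-medium debris on a
#' pale background. Overlapping neighbours are placed at a centre
#' separation of 0.82-0.90 times the sum of their directional ellipse
#' radii, so cluster members genuinely intersect while remaining at
#' least 0.8 times the sum of semi-minor axes apart.
#'
#' @param seed Integer seed (full determinism).
#' @param n_grains Number of grains (>= 1).
#' @param p_overlap Probability that the next grains form an
#'   overlapping cluster.
#' @param image_size `c(height, width)` in pixels (default the nominal
#'   video frame, 208 x 278).
#' @return A `scene_spec`.
#' @export
sample_scene <- function(seed, n_grains, p_overlap = 0.5,
                         image_size = c(208L, 278L)) {
  if (n_grains < 1) stop("n_grains must be >= 1")
  if (p_overlap < 0 || p_overlap > 1) stop("p_overlap must be in [0, 1]")
  classes <- pollen_classes()
  H <- image_size[1]; W <- image_size[2]
  with_seed(seed, {
    # partition grains into clusters
    sizes <- integer(0)
    remaining <- n_grains
    while (remaining > 0) {
      if (remaining >= 2 && runif(1) < p_overlap) {
        k <- min(sample(2:3, 1), remaining)
      } else k <- 1L
      sizes <- c(sizes, k)
      remaining <- remaining - k
    }
    grains <- list()
    cluster_of <- integer(0)
    for (ci in seq_along(sizes)) {
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        # a large-species cluster may be unplaceable in a crowded frame;
        # periodically redraw the class so only feasible scenes are kept
        if (attempt %% 25L == 1L) {
          cl <- sample.int(12L, 1)
          p <- classes[cl, ]
          base_d <- p$diam + rnorm(1, 0, 1.5)
        }
        members <- list()
        ok <- TRUE
        for (gi in seq_len(sizes[ci])) {
          d <- max(16, base_d + runif(1, -1, 1)) # near-equal sizes in a clump
          ratio <- min(1, p$ratio + runif(1, -0.02, 0.02))
          a <- (d / 2) / sqrt(ratio); b <- (d / 2) * sqrt(ratio)
          phi <- runif(1, 0, pi)
          if (gi == 1) {
            margin <- a + 10
            if (2 * margin >= min(H, W)) { ok <- FALSE; break }
            cx <- runif(1, margin, W - margin)
            cy <- runif(1, margin, H - margin)
            theta_prev <- runif(1, 0, 2 * pi)
          } else {
            prev <- members[[gi - 1]]
            theta <- if (gi == 2) theta_prev else theta_prev + runif(1, -pi / 6, pi / 6)
            f <- runif(1, 0.82, 0.90)
            sep <- f * (ellipse_radius(prev$a, prev$b, prev$phi, theta) +
                          ellipse_radius(a, b, phi, theta))
            cx <- prev$cx + sep * cos(theta)
            cy <- prev$cy + sep * sin(theta)
            theta_prev <- theta
            if (cx < a + 10 || cx > W - a - 10 || cy < a + 10 || cy > H - a - 10) {
              ok <- FALSE; break
            }
          }
          members[[gi]] <- list(cx = cx, cy = cy, a = a, b = b, phi = phi,
                                class = cl,
                                color = c(L = p$L, a = p$a, b = p$b),
                                exine_w = p$exine_w, noise_sd = p$noise_sd)
        }
        if (ok && sizes[ci] == 3) {
          # keep the chain open: ends must not merge into a ring
          g1 <- members[[1]]; g3 <- members[[3]]
          dd <- sqrt((g1$cx - g3$cx)^2 + (g1$cy - g3$cy)^2)
          if (dd < 1.05 * (g1$a + g3$a)) ok <- FALSE
        }
        if (ok) { # clearance from previously placed clusters
          for (m in members) {
            for (j in seq_along(grains)) {
              g <- grains[[j]]
              dd <- sqrt((m$cx - g$cx)^2 + (m$cy - g$cy)^2)
              lim <- if (cluster_of[j] == ci) 0 else m$a + g$a + 15
              if (dd < lim) { ok <- FALSE; break }
            }
            if (!ok) break
          }
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place grains within bounds after 1000 attempts")
      for (m in members) {
        grains[[length(grains) + 1L]] <- m
        cluster_of <- c(cluster_of, ci)
      }
    }
    # clutter blobs away from grains
    n_clutter <- sample(2:5, 1)
    clutter <- list()
    for (i in seq_len(n_clutter)) {
      for (attempt in seq_len(200L)) {
        ca <- runif(1, 5, 15); cb <- ca * runif(1, 0.5, 0.9)
        cx <- runif(1, ca + 2, W - ca - 2); cy <- runif(1, ca + 2, H - ca - 2)
        clear <- all(vapply(grains, function(g)
          sqrt((cx - g$cx)^2 + (cy - g$cy)^2) >= ca + g$a + 8, TRUE))
        if (clear) {
          clutter[[length(clutter) + 1L]] <- list(
            cx = cx, cy = cy, a = ca, b = cb, phi = runif(1, 0, pi),
            color = c(L = runif(1, 84, 92), a = runif(1, 3, 8), b = runif(1, 1, 8)),
            noise_sd = 1)
          break
        }
      }
    }
    structure(list(
      image_size = c(H, W), grains = grains, cluster_of = cluster_of,
      cluster_sizes = sizes, clutter = clutter,
      background = c(L = 92 + runif(1, -1.5, 1.5), a = 2, b = 2),
      seed = as.integer(seed)
    ), class = "scene_spec")
  })
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec seed=%d: %d grain(s) in %d cluster(s), %d clutter blob(s)>\n",
              x$seed, length(x$grains), length(x$cluster_sizes), length(x$clutter)))
  invisible(x)
}

# anti-aliased coverage fraction of an ellipse over the pixel grid (3x3
# subsamples per pixel), restricted to its bounding box
ellipse_coverage <- function(g, H, W) {
  r1 <- max(1L, floor(g$cy - g$a - 2)); r2 <- min(H, ceiling(g$cy + g$a + 2))
  c1 <- max(1L, floor(g$cx - g$a - 2)); c2 <- min(W, ceiling(g$cx + g$a + 2))
  rows <- r1:r2; cols <- c1:c2
  sub <- c(-1, 0, 1) / 3
  alpha <- matrix(0, length(rows), length(cols))
  rho_c <- NULL
  cphi <- cos(g$phi); sphi <- sin(g$phi)
  for (dy in sub) for (dx in sub) {
    X <- matrix(cols, length(rows), length(cols), byrow = TRUE) + dx - g$cx
    Y <- matrix(rows, length(rows), length(cols)) + dy - g$cy
    u <- X * cphi + Y * sphi
    v <- -X * sphi + Y * cphi
    rho <- sqrt((u / g$a)^2 + (v / g$b)^2)
    if (dy == 0 && dx == 0) rho_c <- rho
    alpha <- alpha + (rho <= 1)
  }
  list(rows = rows, cols = cols, alpha = alpha / 9, rho = rho_c)
}

#' Render a synthetic scene
#'
#' Rasterizes the scene in CIELAB (anti-aliased ellipses, optional
#' darker exine rings, per-grain Gaussian texture noise, clutter,
#' noisy background), converts to 8-bit sRGB, and returns the image
#' together with the exact per-grain ground-truth masks (pixel centres
#' inside the ellipse) and per-grain case labels.
#'
#' @param spec A `scene_spec`.
#' @return List with `image` (`rgb_image`), `masks` (list of logical
#'   matrices, one per grain), `cases` (per-grain `"CASE_I"` /
#'   `"CASE_II"`), `cluster_of` (per-grain cluster index).
#' @export
render_scene <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  with_seed(spec$seed + 104729L, {
    L <- matrix(spec$background["L"], H, W) + matrix(rnorm(H * W, 0, 0.8), H, W)
    a <- matrix(spec$background["a"], H, W) + matrix(rnorm(H * W, 0, 0.8), H, W)
    b <- matrix(spec$background["b"], H, W) + matrix(rnorm(H * W, 0, 0.8), H, W)
    paint <- function(obj, ring_w) {
      cov <- ellipse_coverage(obj, H, W)
      n <- length(cov$rows) * length(cov$cols)
      col_L <- matrix(obj$color["L"] + rnorm(n, 0, obj$noise_sd), length(cov$rows))
      col_a <- matrix(obj$color["a"] + rnorm(n, 0, obj$noise_sd), length(cov$rows))
      col_b <- matrix(obj$color["b"] + rnorm(n, 0, obj$noise_sd), length(cov$rows))
      if (ring_w > 0) {
        ring <- cov$rho > (1 - ring_w / obj$b) & cov$rho <= 1
        col_L[ring] <- col_L[ring] - 12
        col_a[ring] <- col_a[ring] + 8
        col_b[ring] <- col_b[ring] - 6
      }
      al <- cov$alpha
      L[cov$rows, cov$cols] <<- L[cov$rows, cov$cols] * (1 - al) + col_L * al
      a[cov$rows, cov$cols] <<- a[cov$rows, cov$cols] * (1 - al) + col_a * al
      b[cov$rows, cov$cols] <<- b[cov$rows, cov$cols] * (1 - al) + col_b * al
    }
    for (cl in spec$clutter) paint(cl, 0)
    masks <- vector("list", length(spec$grains))
    for (i in seq_along(spec$grains)) {
      g <- spec$grains[[i]]
      paint(g, g$exine_w)
      X <- matrix(seq_len(W), H, W, byrow = TRUE) - g$cx
      Y <- matrix(seq_len(H), H, W) - g$cy
      u <- X * cos(g$phi) + Y * sin(g$phi)
      v <- -X * sin(g$phi) + Y * cos(g$phi)
      masks[[i]] <- (u / g$a)^2 + (v / g$b)^2 <= 1
    }
    csize <- spec$cluster_sizes[spec$cluster_of]
    list(image = lab_to_rgb(lab_image(L, a, b)),
         masks = masks,
         cases = ifelse(csize >= 2, "CASE_II", "CASE_I"),
         cluster_of = spec$cluster_of)
  })
}

#' Generate a labeled synthetic feature dataset
#'
#' Renders isolated grains of each of the 12 classes on small
#' canvases, extracts the 33-dimensional descriptor of each grain from
#' its ground-truth mask, and returns the labeled dataset.
#'
#' @param seed Integer seed.
#' @param n_per_class Grains per class (>= 2).
#' @return A `feature_dataset` with `12 * n_per_class` rows.
#' @export
generate_feature_dataset <- function(seed, n_per_class) {
  if (n_per_class < 2) stop("n_per_class must be >= 2")
  classes <- pollen_classes()
  rows <- list()
  labels <- integer(0)
  for (cl in 1:12) {
    p <- classes[cl, ]
    for (i in seq_len(n_per_class)) {
      sub_seed <- (abs(as.integer(seed)) %% 100000L) * 10000L + cl * 100L + i
      side <- ceiling(p$diam / sqrt(p$ratio)) + 30L
      g <- with_seed(sub_seed, {
        d <- max(16, p$diam + rnorm(1, 0, 1.5))
        ratio <- min(1, p$ratio + runif(1, -0.02, 0.02))
        list(cx = side / 2, cy = side / 2,
             a = (d / 2) / sqrt(ratio), b = (d / 2) * sqrt(ratio),
             phi = runif(1, 0, pi), class = cl,
             color = c(L = p$L, a = p$a, b = p$b),
             exine_w = p$exine_w, noise_sd = p$noise_sd)
      })
      spec <- structure(list(
        image_size = c(side, side), grains = list(g), cluster_of = 1L,
        cluster_sizes = 1L, clutter = list(),
        background = c(L = 92, a = 2, b = 2), seed = sub_seed
      ), class = "scene_spec")
      sc <- render_scene(spec)
      lab <- rgb_to_lab(sc$image)
      rows[[length(rows) + 1L]] <- feature_vector(sc$masks[[1]], lab)
      labels <- c(labels, cl)
    }
  }
  x <- do.call(rbind, rows)
  colnames(x) <- feature_names()
  feature_dataset(x, labels, classes$name)
}
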