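test_that("shape descriptors match the hand-traced oracles", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  f <- shape_features(sq)
  expect_equal(unname(f[c("A", "MA", "mA", "P")]), c(100, 10, 10, 36))
  expect_equal(unname(f["C"]), 100 / 36^2)

  # rasterized circle: close to 1, limited by the ~5% staircase
  # overestimate inherent to chain-length perimeters of smooth curves
  circ <- disk_mask(121, 121, 61, 61, 50)
  fc <- shape_features(circ)
  expect_gte(unname(fc["R"]), 0.90)
  expect_lte(unname(fc["R"]), 1.08)

  expect_error(shape_features(matrix(FALSE, 4, 4)), "empty")
  two <- matrix(FALSE, 10, 10); two[2, 2] <- TRUE; two[8, 8] <- TRUE
  expect_error(shape_features(two), "one component")
})

test_that("C equals R / (4 pi) on arbitrary masks, and roundness drops with eccentricity", {
  set.seed(71)
  for (i in 1:6) {
    m <- random_blob(40, 40, n_disks = 1, rmax = 10)
    f <- shape_features(m)
    expect_equal(unname(f["C"]), unname(f["R"]) / (4 * pi), tolerance = 1e-12)
  }
  area_r <- 20
  rs <- vapply(c(1, 1.5, 2, 3), function(ecc) {
    m <- ellipse_mask(140, 140, 70, 70, area_r * sqrt(ecc), area_r / sqrt(ecc))
    unname(shape_features(m)["R"])
  }, 0)
  expect_true(all(diff(rs) < 0))
})

test_that("first-order statistics match hand arithmetic", {
  cst <- first_order_features(rep(7, 10))
  expect_equal(unname(cst), c(7, 7, 0, 0, 0))
  f <- first_order_features(c(1, 2, 3, 4))
  expect_equal(unname(f[c("mean", "median", "var")]), c(2.5, 2.5, 1.25))
  expect_equal(unname(f["sd"]), sqrt(1.25))
  # two equally-filled bins carry exactly one bit
  f2 <- first_order_features(rep(c(10, 90), each = 8), n_bins = 2,
                             value_range = c(0, 100))
  expect_equal(unname(f2["entropy"]), 1)
  expect_error(first_order_features(numeric(0)), "empty")
})

test_that("co-occurrence matrices are symmetric, normalized, and enumerable by hand", {
  # constant region: all mass on one diagonal cell
  ch <- matrix(5, 4, 4)
  g <- glcm(ch, matrix(TRUE, 4, 4), levels = 8, value_range = c(0, 10))
  expect_equal(sum(g), 1, tolerance = 1e-9)
  expect_equal(sum(diag(g)), 1, tolerance = 1e-9)
  expect_equal(sum(g > 0), 1L)

  # 2x2 checkerboard of two levels: enumerate every ordered pair by hand.
  # 4 horizontal + 4 vertical ordered pairs connect different levels;
  # the 2+2 ordered diagonal pairs connect equal levels.
  ch2 <- matrix(c(0, 1, 1, 0), 2, 2)
  g2 <- glcm(ch2, matrix(TRUE, 2, 2), levels = 2, value_range = c(0, 1))
  hand <- matrix(c(2, 4, 4, 2), 2, 2) / 12
  expect_equal(unclass(g2), hand, tolerance = 1e-12)

  set.seed(81)
  for (i in 1:5) {
    ch3 <- matrix(runif(49, 0, 100), 7, 7)
    m3 <- matrix(runif(49) < 0.8, 7, 7)
    if (sum(m3) < 4) next
    g3 <- glcm(ch3, m3, levels = 8, value_range = c(0, 100))
    expect_equal(sum(g3), 1, tolerance = 1e-9)
    expect_equal(unclass(g3), t(unclass(g3)), tolerance = 1e-12)
  }
  expect_error(glcm(ch, matrix(FALSE, 4, 4)), "too small")
})

test_that("Haralick statistics match the double-loop oracle", {
  L <- 6
  diag_m <- diag(1 / L, L)
  f <- glcm_features(diag_m)
  expect_equal(unname(f[c("contrast", "homogeneity", "energy")]),
               c(0, 1, 1 / L))
  single <- matrix(0, 4, 4); single[3, 3] <- 1
  fs <- glcm_features(single)
  expect_equal(unname(fs), c(0, 0, 1, 1)) # degenerate sigma: r = 0

  set.seed(91)
  for (i in 1:100) {
    m <- matrix(runif(16), 4, 4); m <- (m + t(m)); m <- m / sum(m)
    expect_equal(unname(glcm_features(m)), unname(brute_glcm_features(m)),
                 tolerance = 1e-10)
  }
})

test_that("the grain descriptor has 33 entries and is translation invariant", {
  spec <- sample_scene(seed = 3, n_grains = 1, p_overlap = 0)
  sc <- render_scene(spec)
  lab <- rgb_to_lab(sc$image)
  v <- feature_vector(sc$masks[[1]], lab)
  expect_length(v, 33L)
  expect_identical(names(v), feature_names())

  # translate mask and image content by (5, 7)
  shift_img <- function(m, dr, dc) {
    out <- matrix(m[1, 1], nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  lab_t <- lab_image(shift_img(lab$L, 5, 7), shift_img(lab$a, 5, 7),
                     shift_img(lab$b, 5, 7))
  mask_t <- shift_img(sc$masks[[1]], 5, 7)
  expect_equal(feature_vector(mask_t, lab_t), v, tolerance = 1e-12)
})

test_that("a constant-colour grain has zero entropies and unit energies", {
  m <- disk_mask(40, 40, 20, 20, 12)
  lab <- flat_lab(40, 40, L = 45, a = 35, b = -25)
  v <- feature_vector(m, lab)
  expect_equal(unname(v[c("L_entropy", "a_entropy", "b_entropy")]), c(0, 0, 0))
  expect_equal(unname(v[c("L_energy", "a_energy", "b_energy")]), c(1, 1, 1))
})

test_that("colour features ignore recolouring outside the grain", {
  m <- disk_mask(30, 30, 15, 15, 8)
  set.seed(101)
  mk <- function(bg) {
    L <- matrix(bg, 30, 30); L[m] <- 45
    a <- matrix(bg / 10, 30, 30); a[m] <- 35
    b <- matrix(-bg / 10, 30, 30); b[m] <- -25
    lab_image(L, a, b)
  }
  expect_equal(feature_vector(m, mk(90)), feature_vector(m, mk(10)))
})
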