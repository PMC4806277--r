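test_that("the Fibonacci schedule follows the recurrence and endpoints", {
  expect_equal(unclass(fibonacci_schedule(6)), c(0, 1, 1, 2, 3, 5))
  s21 <- fibonacci_schedule(21)
  expect_length(s21, 21L)
  expect_equal(s21[21], 6765)
  expect_true(all(diff(s21) >= 0))
  expect_equal(unclass(fibonacci_schedule(2)), c(0, 1))
  expect_error(fibonacci_schedule(1), "at least 2")
})

test_that("erosion profiles behave per the pixel-set oracle on disk fixtures", {
  # one convex disk never splits: counts 1,...,1 then 0
  one <- disk_mask(60, 60, 30, 30, 20)
  p1 <- erosion_profile(one)
  expect_equal(p1$initial_count, 1L)
  expect_equal(p1$final_count, 1L)
  nz <- p1$counts[p1$counts > 0]
  expect_true(all(nz == 1L))
  expect_equal(classify_case(p1), "CASE_I")

  # two disjoint disks, far apart
  two <- disk_mask(100, 160, 50, 45, 15) | disk_mask(100, 160, 50, 105, 15)
  p2 <- erosion_profile(two)
  expect_equal(p2$initial_count, 2L)
  expect_equal(p2$final_count, 2L)

  # overlapping union splits under a unit-step schedule before vanishing
  ov <- disk_mask(100, 120, 50, 40, 20) | disk_mask(100, 120, 50, 70, 20)
  p3 <- erosion_profile(ov, 0:25)
  expect_equal(p3$initial_count, 1L)
  expect_true(any(p3$counts == 2L))
  expect_equal(p3$final_count, 2L)
  expect_equal(classify_case(p3), "CASE_II")
  expect_error(erosion_profile(matrix(FALSE, 5, 5)), "empty")
})

test_that("case classification implements the count-change rule", {
  mk <- function(ini, fin) structure(
    list(radii = c(0, 1), counts = c(ini, fin), initial_count = ini,
         final_count = fin), class = "erosion_profile")
  expect_equal(classify_case(mk(1L, 1L)), "CASE_I")
  expect_equal(classify_case(mk(1L, 2L)), "CASE_II")
  expect_equal(classify_case(mk(3L, 3L)), "CASE_I")
})

test_that("erosion profile equals brute-force erosion + labelling on small masks", {
  set.seed(51)
  sched <- c(0L, 1L, 2L, 3L, 5L, 8L, 13L)
  for (i in 1:8) {
    m <- random_blob(40, 40)
    d2 <- NULL
    p <- erosion_profile(m, sched, min_object_area = 2L)
    rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
    crop <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    expected <- integer(length(sched))
    for (k in seq_along(sched)) {
      er <- brute_erode(crop, sched[k])
      if (!any(er)) break
      expected[k] <- brute_count(er, 8, 2)
      if (expected[k] == 0) break
    }
    expect_identical(p$counts, expected)
  }
})

test_that("single convex synthetic grains are always Case I", {
  set.seed(61)
  for (i in 1:6) {
    a <- runif(1, 12, 30); b <- a * runif(1, 0.85, 1)
    m <- ellipse_mask(90, 90, 45, 45, a, b, runif(1, 0, pi))
    expect_equal(classify_case(erosion_profile(m)), "CASE_I")
  }
})

test_that("seed recovery returns disjoint in-region seeds containing the centres", {
  ov <- disk_mask(100, 120, 50, 40, 20) | disk_mask(100, 120, 50, 70, 20)
  p <- erosion_profile(ov, 0:25)
  seeds <- extract_seeds(ov, p, 0:25)
  expect_length(seeds, 2L)
  expect_false(any(seeds[[1]] & seeds[[2]]))
  expect_true(all(!(seeds[[1]] | seeds[[2]]) | ov))
  has_centre <- function(s) s[50, 40] || s[50, 70]
  expect_true(has_centre(seeds[[1]]) && has_centre(seeds[[2]]))
  expect_false(seeds[[1]][50, 40] && seeds[[1]][50, 70])

  # three-grain chain
  chain <- disk_mask(100, 200, 50, 50, 18) | disk_mask(100, 200, 50, 80, 18) |
    disk_mask(100, 200, 50, 110, 18)
  pc <- erosion_profile(chain, 0:25)
  expect_length(extract_seeds(chain, pc, 0:25), 3L)

  # fragments already at touching distance stay unchanged
  frag <- matrix(FALSE, 20, 30)
  frag[8:12, 5:12] <- TRUE; frag[8:12, 14:21] <- TRUE
  lab0 <- matrix(0L, 20, 30)
  lab0[8:12, 5:12] <- 1L; lab0[8:12, 14:21] <- 2L
  expect_identical(pollensep:::grow_labels(lab0, frag), lab0)

  expect_error(extract_seeds(disk_mask(40, 40, 20, 20, 10),
                             erosion_profile(disk_mask(40, 40, 20, 20, 10))),
               "Case II")
})

test_that("GVF reduces to the edge gradient at mu = 0 and vanishes without edges", {
  # straight vertical edge
  m <- matrix(FALSE, 20, 30); m[, 15:30] <- TRUE
  f0 <- gvf_field(m, mu = 0, n_iter = 50, sigma = 1.5)
  sm <- pollensep:::gaussian_blur(m * 1.0, 1.5)
  g <- pollensep:::gradient_xy(sm)
  f <- g$x^2 + g$y^2; f <- f / max(f)
  gf <- pollensep:::gradient_xy(f)
  strong <- gf$x^2 + gf$y^2 > 1e-8
  expect_equal(f0$u[strong], gf$x[strong], tolerance = 1e-12)
  expect_equal(f0$v[strong], gf$y[strong], tolerance = 1e-12)

  # constant mask: no edges, zero field
  fc <- gvf_field(matrix(TRUE, 10, 10), mu = 0.2, n_iter = 10, sigma = 1)
  expect_true(all(fc$u == 0) && all(fc$v == 0))
  expect_error(gvf_field(m, mu = NA), "finite")
})

test_that("GVF vectors outside a disk point toward its boundary", {
  m <- disk_mask(80, 80, 40, 40, 15)
  fld <- gvf_field(m)
  rows <- matrix(1:80, 80, 80); cols <- matrix(1:80, 80, 80, byrow = TRUE)
  d <- sqrt((rows - 40)^2 + (cols - 40)^2)
  ring <- which(d >= 19.5 & d <= 20.5)
  inward <- (40 - cols[ring]) * fld$u[ring] + (40 - rows[ring]) * fld$v[ring]
  mag <- sqrt(fld$u[ring]^2 + fld$v[ring]^2)
  expect_gte(mean(inward[mag > 0] > 0), 0.95)
})

test_that("snakes expand a concentric seed to the region boundary", {
  region <- disk_mask(80, 80, 40, 40, 20)
  seed <- disk_mask(80, 80, 40, 40, 8)
  fld <- gvf_field(region)
  ct <- evolve_snake(seed, fld)
  expect_equal(pollensep:::polygon_area(ct), sum(region), tolerance = 0.1)
})

test_that("pure tension shrinks the contour perimeter monotonically", {
  seed <- disk_mask(60, 60, 30, 30, 15)
  fld <- gvf_field(disk_mask(60, 60, 30, 30, 22))
  per <- function(ct) {
    q <- rbind(ct, ct[1, ]); sum(sqrt(diff(q[, 1])^2 + diff(q[, 2])^2))
  }
  p_seq <- vapply(c(5L, 15L, 25L), function(n)
    per(evolve_snake(seed, fld, alpha = 0.2, beta = 0, kappa = 0, n_iter = n)),
    0)
  expect_true(all(diff(p_seq) < 0))
})

test_that("two snakes separate a two-disk region close to ground truth", {
  region <- disk_mask(100, 120, 50, 40, 20) | disk_mask(100, 120, 50, 70, 20)
  gt1 <- disk_mask(100, 120, 50, 40, 20); gt2 <- disk_mask(100, 120, 50, 70, 20)
  p <- erosion_profile(region, 0:25)
  seeds <- extract_seeds(region, p, 0:25)
  fld <- gvf_field(region)
  cts <- lapply(seeds, function(s) evolve_snake(s, fld))
  # contour interiors barely overlap and each covers its own disk
  grid <- which(region | TRUE, arr.ind = TRUE)
  ins <- lapply(cts, function(ct)
    matrix(pollensep:::point_in_polygon(grid[, 2], grid[, 1], ct), 100, 120))
  both <- sum(ins[[1]] & ins[[2]])
  expect_lt(both / min(sum(ins[[1]]), sum(ins[[2]])), 0.2)
  cover1 <- max(sum(ins[[1]] & gt1) / sum(gt1), sum(ins[[2]] & gt1) / sum(gt1))
  cover2 <- max(sum(ins[[1]] & gt2) / sum(gt2), sum(ins[[2]] & gt2) / sum(gt2))
  expect_gte(cover1, 0.8); expect_gte(cover2, 0.8)

  parts <- separate_region(region, cts)
  expect_false(any(parts[[1]] & parts[[2]]))
  expect_identical(parts[[1]] | parts[[2]], region)
  expect_gte(max(iou(parts[[1]], gt1), iou(parts[[2]], gt1)), 0.8)
  expect_gte(max(iou(parts[[1]], gt2), iou(parts[[2]], gt2)), 0.8)
})

test_that("separate_region honours disjoint contour interiors exactly", {
  region <- matrix(TRUE, 30, 60)
  sq <- function(cx, w) cbind(x = c(cx - w, cx + w, cx + w, cx - w),
                              y = c(5, 5, 25, 25))
  parts <- separate_region(region, list(sq(15, 12), sq(45, 12)))
  expect_identical(parts[[1]] | parts[[2]], region)
  expect_false(any(parts[[1]] & parts[[2]]))
  # pixels strictly inside the first square went to the first mask
  expect_true(all(parts[[1]][10:20, 6:26]))
  expect_error(separate_region(region, list(sq(15, 12))), "at least 2")
})
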