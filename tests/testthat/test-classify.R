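blob_dataset <- function(n_per_class = 10, k = 3, sigma = 0.5, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(seq_len(k * 4) * 10, k, 4)
    x <- do.call(rbind, lapply(seq_len(k), function(c_)
      matrix(rnorm(n_per_class * 4, centers[c_, ], sigma), n_per_class, 4,
             byrow = TRUE)))
    feature_dataset(x, rep(seq_len(k), each = n_per_class),
                    paste0("class", seq_len(k)))
  })
}

test_that("stratified folds partition samples with balanced classes", {
  labels <- rep(1:12, each = 10)
  folds <- stratified_folds(labels, 2, seed = 4)
  expect_length(folds, 2L)
  expect_equal(sort(unlist(folds)), seq_along(labels))
  for (f in folds) {
    expect_length(f, 60L)
    expect_true(all(table(labels[f]) == 5L))
  }

  labels5 <- rep(1:4, each = 25)
  folds5 <- stratified_folds(labels5, 5, seed = 9)
  expect_equal(sort(lengths(folds5)), rep(20L, 5))
  expect_equal(sort(unlist(folds5)), 1:100)
  expect_identical(stratified_folds(labels5, 5, seed = 9), folds5)
  expect_false(identical(stratified_folds(labels5, 5, seed = 10), folds5))

  expect_warning(stratified_folds(c(1, 1, 1, 2), 3, seed = 1), "fewer than")
  expect_error(stratified_folds(labels, 1, seed = 1), "at least 2")
})

test_that("all three learners solve well-separated blobs perfectly", {
  ds <- blob_dataset()
  for (lrn in c("MLP", "RTF", "BN")) {
    cm <- cross_validate(ds, lrn, s = 2, seed = 5)
    expect_equal(sum(cm), 30)
    expect_equal(sum(diag(cm)), 30)
  }
  expect_error(cross_validate(ds, "SVM", 2, 1), "arg")
})

test_that("cross-validation predicts each sample exactly once and is seeded", {
  ds <- blob_dataset(n_per_class = 8, sigma = 5)
  cm1 <- cross_validate(ds, "RTF", s = 4, seed = 3)
  expect_equal(sum(cm1), nrow(ds$x))
  expect_equal(rowSums(unclass(cm1)), table(factor(ds$labels))[],
               ignore_attr = TRUE)
  expect_identical(cross_validate(ds, "RTF", s = 4, seed = 3), cm1)
})

test_that("confusion metrics implement the indicator formulas", {
  perfect <- confusion_matrix(matrix(c(50, 0, 0, 50), 2, 2))
  m <- confusion_metrics(perfect)
  expect_equal(m$per_class$TPR, c(1, 1))
  expect_equal(m$per_class$PPV, c(1, 1))
  expect_equal(m$per_class$F1, c(1, 1))
  expect_equal(m$per_class$FPR, c(0, 0))

  cm <- confusion_matrix(matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE))
  r <- confusion_metrics(cm)
  expect_equal(r$per_class$TP, c(8, 9))
  expect_equal(r$per_class$FN, c(2, 1))
  expect_equal(r$per_class$FP, c(1, 2))
  expect_equal(r$per_class$TN, c(9, 8))
  expect_equal(r$per_class$TPR, c(8 / 10, 9 / 10))
  expect_equal(r$per_class$PPV, c(8 / 9, 9 / 11))
  expect_equal(r$per_class$FPR, c(1 / 10, 2 / 10))
  expect_error(confusion_metrics(matrix(0, 3, 3)), "all-zero")
})

test_that("weighted TPR equals trace/total and metrics survive relabelling", {
  set.seed(111)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    cm <- matrix(rpois(k * k, 3), k, k) + diag(rpois(k, 20))
    m <- confusion_metrics(cm)
    expect_equal(unname(m$weighted["TPR"]), sum(diag(cm)) / sum(cm))
    p <- sample(k)
    mp <- confusion_metrics(cm[p, p])
    expect_equal(sort(mp$per_class$F1), sort(m$per_class$F1))
    expect_equal(mp$weighted, m$weighted)
  }
})

test_that("ARFF files round-trip and carry the nominal class attribute", {
  ds <- generate_feature_dataset(seed = 2, n_per_class = 2)
  path <- withr::local_tempfile(fileext = ".arff")
  write_arff(ds, path)
  lines <- readLines(path)
  expect_true(any(grepl("^@relation", lines)))
  expect_length(grep("^@attribute", lines), 34L)
  class_line <- grep("^@attribute class", lines, value = TRUE)
  for (nm in pollen_classes()$name)
    expect_true(grepl(nm, class_line, fixed = TRUE))

  back <- read_arff(path)
  expect_equal(back$x, ds$x, ignore_attr = TRUE, tolerance = 1e-6)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$class_names, ds$class_names)
})

test_that("ARFF parsing rejects missing values and empty data", {
  small <- feature_dataset(matrix(1:4, 2, 2), c(1L, 2L), c("x", "y"))
  path <- withr::local_tempfile(fileext = ".arff")
  write_arff(small, path)
  lines <- readLines(path)
  data_at <- grep("^@data", lines)
  writeLines(c(lines[1:data_at], "1,?,x"), path)
  expect_error(read_arff(path), "missing value at line")
  writeLines(lines[1:data_at], path)
  expect_error(read_arff(path), "no samples")
  expect_error(read_arff(file.path(tempdir(), "absent.arff")), "not found")
})

test_that("feature_dataset enforces its invariants", {
  expect_error(feature_dataset(matrix(1, 2, 3), 1L, "a"), "match rows")
  expect_error(feature_dataset(matrix(NA_real_, 1, 1), 1L, "a"), "missing")
  expect_error(feature_dataset(matrix(1, 1, 1), 5L, c("a", "b")), "1\\.\\.2")
})
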