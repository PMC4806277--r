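#' Construct a labeled feature dataset
#'
#' @param x Numeric matrix, samples in rows (33 descriptor columns for
#'   the pollen pipeline, but any width is accepted).
#' @param labels Integer class labels in `1..length(class_names)`.
#' @param class_names Character vector of class names.
#' @return A `feature_dataset`.
#' @export
feature_dataset <- function(x, labels, class_names) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (nrow(x) != length(labels)) stop("labels length must match rows of x")
  if (anyNA(x) || anyNA(labels)) stop("missing values are not allowed")
  if (any(labels < 1 | labels > length(class_names)))
    stop("labels must lie in 1..", length(class_names))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, labels = labels, class_names = class_names),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset: %d samples x %d features, %d classes>\n",
              nrow(x$x), ncol(x$x), length(x$class_names)))
  invisible(x)
}

#' Stratified s-fold partition
#'
#' Partitions sample indices into `s` folds with per-class counts
#' differing by at most one across folds; deterministic for a given
#' seed. Classes with fewer than `s` members trigger a warning and are
#' spread over as many folds as they have members.
#'
#' @param labels Class label vector.
#' @param s Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `s` disjoint integer index vectors covering all
#'   samples.
#' @export
stratified_folds <- function(labels, s, seed) {
  if (s < 2) stop("s must be at least 2")
  n <- length(labels)
  fold_of <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < s)
        warning("class ", cl, " has fewer than s = ", s, " members")
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- ((offset + seq_along(idx) - 1L) %% s) + 1L
      offset <- offset + length(idx) # rotate start fold to balance sizes
    }
  })
  lapply(seq_len(s), function(k) which(fold_of == k))
}

train_learner <- function(learner, x, y, n_classes, seed) {
  switch(learner,
    MLP = {
      mu <- colMeans(x)
      sg <- apply(x, 2, sd); sg[sg == 0] <- 1
      xs <- scale(x, mu, sg)
      y_ind <- nnet::class.ind(factor(y, levels = seq_len(n_classes)))
      fit <- with_seed(seed, nnet::nnet(
        xs, y_ind, size = ceiling((ncol(x) + n_classes) / 2),
        softmax = TRUE, maxit = 500L, decay = 5e-4, MaxNWts = 100000L,
        trace = FALSE))
      list(predict = function(newx) {
        p <- predict(fit, scale(newx, mu, sg))
        max.col(p, ties.method = "first")
      })
    },
    RTF = {
      df <- data.frame(x, check.names = FALSE)
      df$.class <- factor(y, levels = seq_len(n_classes))
      fit <- ranger::ranger(
        dependent.variable.name = ".class", data = df,
        num.trees = 100L, mtry = max(1L, floor(sqrt(ncol(x)))),
        min.node.size = 1L, seed = seed)
      list(predict = function(newx) {
        as.integer(predict(fit, data.frame(newx, check.names = FALSE))$predictions)
      })
    },
    BN = {
      fit <- e1071::naiveBayes(x, factor(y, levels = seq_len(n_classes)),
                               laplace = 1)
      list(predict = function(newx) as.integer(predict(fit, newx)))
    },
    stop("unknown learner: ", learner)
  )
}

#' Cross-validated confusion matrix
#'
#' Runs stratified s-fold cross validation of one of three learners —
#' a single-hidden-layer multilayer perceptron (`"MLP"`, on
#' standardized inputs), a random forest of 100 unpruned trees
#' (`"RTF"`), or a naive-structure Bayes network with Laplace smoothing
#' (`"BN"`) — and accumulates the actual-by-predicted counts over the
#' held-out folds.
#'
#' @param ds A `feature_dataset`.
#' @param learner One of `"MLP"`, `"RTF"`, `"BN"`.
#' @param s Number of folds.
#' @param seed Integer seed controlling folds and learner randomness.
#' @return A `confusion_matrix` (K x K integer matrix, rows = actual).
#' @export
cross_validate <- function(ds, learner = c("MLP", "RTF", "BN"), s = 2L, seed = 1L) {
  learner <- match.arg(learner)
  k <- length(ds$class_names)
  folds <- stratified_folds(ds$labels, s, seed)
  cm <- matrix(0L, k, k, dimnames = list(actual = ds$class_names,
                                         predicted = ds$class_names))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    if (!length(test)) next
    train <- setdiff(seq_along(ds$labels), test)
    model <- train_learner(learner, ds$x[train, , drop = FALSE],
                           ds$labels[train], k, seed * 1000L + f)
    pred <- model$predict(ds$x[test, , drop = FALSE])
    for (i in seq_along(test))
      cm[ds$labels[test[i]], pred[i]] <- cm[ds$labels[test[i]], pred[i]] + 1L
  }
  confusion_matrix(cm)
}

#' Construct a confusion matrix object
#'
#' @param counts Square matrix of nonnegative integer counts, rows =
#'   actual class, columns = predicted class.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  structure(counts, class = c("confusion_matrix", class(unclass(counts))))
}

#' Quality indicators from a confusion matrix
#'
#' Per class `k`: `TP = cm[k,k]`, `FN` = rest of row `k`, `FP` = rest
#' of column `k`, `TN` = remainder; recall `TPR = TP/(TP+FN)`,
#' precision `PPV = TP/(TP+FP)`, fallout `FPR = FP/(FP+TN)` and the
#' F-measure (harmonic mean of precision and recall). Summary rows are
#' support-weighted averages, so the weighted TPR equals
#' `trace / total`.
#'
#' @param cm A `confusion_matrix` (or plain square count matrix).
#' @return A `metrics_report`: list with `per_class` (data frame) and
#'   `weighted` (named vector `TPR, PPV, F1, FPR`).
#' @export
confusion_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  total <- sum(cm)
  if (total == 0) stop("all-zero confusion matrix")
  k <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  tpr <- safe_div(tp, tp + fn)
  ppv <- safe_div(tp, tp + fp)
  fpr <- safe_div(fp, fp + tn)
  f1 <- ifelse(ppv + tpr > 0, 2 * ppv * tpr / (ppv + tpr), 0)
  support <- rowSums(cm)
  w <- support / total
  per_class <- data.frame(
    class = if (!is.null(rownames(cm))) rownames(cm) else as.character(seq_len(k)),
    support = support, TP = tp, FP = fp, FN = fn, TN = tn,
    TPR = tpr, PPV = ppv, FPR = fpr, F1 = f1, row.names = NULL)
  weighted <- c(TPR = sum(w * tpr), PPV = sum(w * ppv),
                F1 = sum(w * f1), FPR = sum(w * fpr))
  structure(list(per_class = per_class, weighted = weighted),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> weighted:",
      paste(sprintf("%s=%.3f", names(x$weighted), x$weighted), collapse = " "), "\n")
  invisible(x)
}

#' Write a feature dataset as an ARFF file
#'
#' Numeric attributes plus a nominal class attribute listing every
#' class name; round-trips losslessly through [read_arff()].
#'
#' @param ds A `feature_dataset`.
#' @param path Output path.
#' @param relation Relation name (default "pollen_features").
#' @return `path`, invisibly.
#' @export
write_arff <- function(ds, path, relation = "pollen_features") {
  df <- data.frame(ds$x, check.names = FALSE)
  df$class <- factor(ds$class_names[ds$labels], levels = ds$class_names)
  foreign::write.arff(df, path, relation = relation)
  invisible(path)
}

#' Read a feature dataset from an ARFF file
#'
#' Expects numeric attributes followed by a nominal class attribute;
#' missing values are rejected with the offending line number.
#'
#' @param path ARFF file.
#' @return A `feature_dataset`.
#' @export
read_arff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  data_at <- grep("^\\s*@data\\s*$", lines, ignore.case = TRUE)
  if (!length(data_at)) stop("parse error: no @data section")
  body <- lines[-seq_len(data_at[1])]
  nonempty <- which(trimws(body) != "" & !startsWith(trimws(body), "%"))
  if (!length(nonempty)) stop("no samples")
  missing_rows <- nonempty[grepl("(^|,)\\s*\\?\\s*(,|$)", body[nonempty])]
  if (length(missing_rows))
    stop("parse error: missing value at line ", data_at[1] + missing_rows[1])
  df <- foreign::read.arff(path)
  if (!ncol(df) || !is.factor(df[[ncol(df)]]))
    stop("parse error: last attribute must be the nominal class")
  cls <- df[[ncol(df)]]
  # preserve the declared level order of the nominal class attribute
  # (read.arff sorts levels alphabetically)
  attr_lines <- grep("^\\s*@attribute", lines[seq_len(data_at[1])],
                     ignore.case = TRUE, value = TRUE)
  decl <- regmatches(attr_lines, regexpr("\\{[^}]*\\}", attr_lines))
  if (length(decl)) {
    lv <- trimws(strsplit(gsub("[{}]", "", decl[length(decl)]), ",")[[1]])
    lv <- gsub("^'(.*)'$", "\\1", lv)
    if (setequal(lv, levels(cls))) cls <- factor(as.character(cls), levels = lv)
  }
  x <- as.matrix(df[, -ncol(df), drop = FALSE])
  if (!is.numeric(x)) stop("parse error: non-numeric feature attribute")
  feature_dataset(x, as.integer(cls), levels(cls))
}
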