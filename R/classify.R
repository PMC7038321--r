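#' Reference classifier specification
#'
#' The four benchmark classifiers with their fixed hyperparameters: an RBF
#' (Gaussian-kernel) support vector machine with `gamma = 6.4`; a
#' nonparametric naive Bayes whose per-feature class densities are Gaussian
#' kernel density estimates (Silverman bandwidth); a decision tree grown
#' with the Gini diversity index and a bounded node count; and a k-nearest
#' neighbour classifier with `k = 13` under cosine distance. SVM and KNN
#' inputs are column-standardized (fit on the training fold, applied to the
#' validation fold).
#'
#' @param kind One of `"svm_rbf"`, `"naive_bayes_kernel"`,
#'   `"decision_tree"`, `"knn"`.
#' @param gamma RBF kernel coefficient (SVM).
#' @param k_neighbors Neighbourhood size (KNN).
#' @param max_depth Maximum tree depth; depth 6 bounds the tree at 127
#'   nodes.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "naive_bayes_kernel",
                                     "decision_tree", "knn"),
                            gamma = 6.4, k_neighbors = 13L, max_depth = 6L) {
  kind <- match.arg(kind)
  structure(
    list(kind = kind, gamma = gamma, k_neighbors = as.integer(k_neighbors),
         max_depth = as.integer(max_depth),
         standardize = kind %in% c("svm_rbf", "knn")),
    class = "classifier_spec"
  )
}

# ---- individual classifiers ------------------------------------------------

fit_predict <- function(spec, x_train, y_train, x_test) {
  switch(
    spec$kind,
    svm_rbf = {
      fit <- e1071::svm(x_train, factor(y_train, levels = c(0, 1)),
                        kernel = "radial", gamma = spec$gamma, scale = FALSE)
      as.integer(as.character(stats::predict(fit, x_test)))
    },
    naive_bayes_kernel = kde_nb_predict(x_train, y_train, x_test),
    decision_tree = {
      df_tr <- as.data.frame(x_train)
      df_tr$.y <- factor(y_train, levels = c(0, 1))
      fit <- rpart::rpart(
        .y ~ ., data = df_tr, method = "class",
        parms = list(split = "gini"),
        control = rpart::rpart.control(cp = 0, minsplit = 2, minbucket = 1,
                                       maxdepth = spec$max_depth, xval = 0)
      )
      as.integer(as.character(stats::predict(fit, as.data.frame(x_test),
                                             type = "class")))
    },
    knn = knn_cosine_predict(x_train, y_train, x_test, spec$k_neighbors)
  )
}

# Naive Bayes with per-feature Gaussian kernel density estimates
# (Silverman's rule-of-thumb bandwidth per class and feature).
kde_nb_predict <- function(x_train, y_train, x_test) {
  classes <- c(0L, 1L)
  logprior <- vapply(classes, function(cl) log(mean(y_train == cl)), numeric(1))
  scale_guard <- stats::sd(as.numeric(x_train))
  if (!is.finite(scale_guard) || scale_guard == 0) scale_guard <- 1
  loglik <- matrix(0, nrow(x_test), length(classes))
  for (ci in seq_along(classes)) {
    vals <- x_train[y_train == classes[ci], , drop = FALSE]
    for (j in seq_len(ncol(x_train))) {
      v <- vals[, j]
      bw <- stats::bw.nrd0(v)
      if (!is.finite(bw) || bw <= 0) bw <- 1e-3 * scale_guard
      dens <- vapply(x_test[, j],
                     function(q) mean(stats::dnorm(q, v, bw)),
                     numeric(1))
      loglik[, ci] <- loglik[, ci] + log(pmax(dens, 1e-300))
    }
    loglik[, ci] <- loglik[, ci] + logprior[ci]
  }
  classes[max.col(loglik, ties.method = "first")]
}

# KNN under cosine distance; ties in the vote resolve toward the class with
# the larger summed similarity, then toward class 0.
knn_cosine_predict <- function(x_train, y_train, x_test, k) {
  unit_rows <- function(m) {
    nrm <- sqrt(rowSums(m^2))
    nrm[nrm == 0] <- 1
    m / nrm
  }
  k <- min(k, nrow(x_train))
  sim <- unit_rows(x_test) %*% t(unit_rows(x_train))
  apply(sim, 1, function(s) {
    nb <- order(s, decreasing = TRUE)[seq_len(k)]
    votes <- y_train[nb]
    n1 <- sum(votes == 1)
    n0 <- k - n1
    if (n1 != n0) {
      if (n1 > n0) 1L else 0L
    } else {
      s1 <- sum(s[nb][votes == 1])
      s0 <- sum(s[nb][votes == 0])
      if (s1 > s0) 1L else 0L
    }
  })
}

# ---- metrics ---------------------------------------------------------------

#' F1 score from sensitivity and precision
#'
#' `F1 = 2 * sensitivity * precision / (sensitivity + precision)`, the
#' harmonic mean reported alongside the benchmark classifiers.
#'
#' @param sensitivity,precision Fractions in `[0, 1]`.
#' @return The F1 score, or `NA` when the denominator is 0.
#' @export
f1_score <- function(sensitivity, precision) {
  den <- sensitivity + precision
  ifelse(den > 0, 2 * sensitivity * precision / den, NA_real_)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity is the ability to detect the target class (patients with
#' Parkinsonian tremor, label 1), specificity the ability to identify
#' healthy subjects, precision the probability that a positive call is
#' correct. Ratios with zero denominators are reported as `NA`.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (total > 0).
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1` and the four counts.
#' @export
#' @examples
#' metrics_from_confusion(tp = 10, fp = 0, tn = 10, fn = 0)
metrics_from_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || sum(counts) == 0) {
    tf_abort("confusion counts must be non-negative with a positive total",
             "tf_error_invalid_parameter")
  }
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  tibble(
    accuracy = (tp + tn) / sum(counts),
    sensitivity = sens, specificity = spec, precision = prec,
    f1 = if (is.na(sens) || is.na(prec)) NA_real_ else f1_score(sens, prec),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

# ---- cross-validation ------------------------------------------------------

# seeded stratified fold assignment: rows are shuffled within class and
# fold ids dealt cyclically, continuing the cycle across classes so both
# per-class and overall fold sizes differ by at most 1
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    ordered <- unlist(lapply(unique(y), function(cl) sample(which(y == cl))))
    fold[ordered] <- rep_len(seq_len(k), length(y))
  })
  fold
}

#' Cross-validated classifier benchmark
#'
#' Stratified k-fold cross-validation (seeded) of one reference classifier
#' on a feature table. Validation accuracy is the mean of per-fold
#' accuracies; sensitivity, specificity, precision and F1 come from the
#' confusion counts pooled over all validation folds, with the disease
#' class (label 1) as target. With `group_by = "subject"` whole subjects
#' are assigned to folds, avoiding leakage of subject identity between
#' training and validation measurements.
#'
#' @param features A tibble from [build_features()]: feature columns
#'   `f3.50`...`f7.50` plus `label` (and `subject_id` for grouped folds).
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param group_by `"measurement"` (default) or `"subject"`.
#' @return A list of class `metrics_report`; see [tidy()] / [glance()].
#' @export
crossvalidate <- function(features, spec = classifier_spec("decision_tree"),
                          k = 5L, seed = 1L,
                          group_by = c("measurement", "subject")) {
  group_by <- match.arg(group_by)
  stopifnot(inherits(spec, "classifier_spec"))
  y <- features$label
  if (length(unique(y)) < 2L) {
    tf_abort("cross-validation needs both classes present", "tf_error_invalid_parameter")
  }
  if (nrow(features) < k) {
    tf_abort("fewer rows than folds", "tf_error_invalid_parameter")
  }
  x <- as.matrix(features[, grep("^f[0-9]", names(features)), drop = FALSE])

  if (group_by == "subject") {
    subj <- unique(features[, c("subject_id", "label")])
    subj_fold <- stratified_folds(subj$label, k, seed)
    fold <- subj_fold[match(features$subject_id, subj$subject_id)]
  } else {
    fold <- stratified_folds(y, k, seed)
  }

  fold_rows <- list()
  for (f in sort(unique(fold))) {
    test <- fold == f
    mu_sd <- NULL
    x_tr <- x[!test, , drop = FALSE]
    x_te <- x[test, , drop = FALSE]
    if (spec$standardize) {
      mu <- colMeans(x_tr)
      s <- apply(x_tr, 2, stats::sd)
      s[s == 0] <- 1
      x_tr <- sweep(sweep(x_tr, 2, mu, "-"), 2, s, "/")
      x_te <- sweep(sweep(x_te, 2, mu, "-"), 2, s, "/")
    }
    pred <- fit_predict(spec, x_tr, y[!test], x_te)
    truth <- y[test]
    fold_rows[[f]] <- tibble(
      fold = f,
      tp = sum(pred == 1 & truth == 1),
      fp = sum(pred == 1 & truth == 0),
      tn = sum(pred == 0 & truth == 0),
      fn = sum(pred == 0 & truth == 1)
    )
  }
  folds <- dplyr::bind_rows(fold_rows)
  fold_acc <- (folds$tp + folds$tn) /
    (folds$tp + folds$tn + folds$fp + folds$fn)
  pooled <- metrics_from_confusion(sum(folds$tp), sum(folds$fp),
                                   sum(folds$tn), sum(folds$fn))
  structure(
    list(
      kind = spec$kind, k = k, seed = seed, n = nrow(features),
      val_accuracy = mean(fold_acc),
      sensitivity = pooled$sensitivity, specificity = pooled$specificity,
      precision = pooled$precision, f1 = pooled$f1,
      folds = folds
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s, %d-fold CV on %d measurements\n",
              x$kind, x$k, x$n))
  cat(sprintf("  val_accuracy %.4f | sensitivity %.4f | specificity %.4f | precision %.4f | F1 %.4f\n",
              x$val_accuracy, x$sensitivity, x$specificity, x$precision,
              x$f1))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A tibble with one row per metric (`metric`, `value`).
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble(
    metric = c("val_accuracy", "sensitivity", "specificity", "precision", "f1"),
    value = c(x$val_accuracy, x$sensitivity, x$specificity, x$precision, x$f1)
  )
}

#' One-row summary of a cross-validation report
#'
#' @inheritParams tidy.metrics_report
#' @return A one-row tibble.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(
    classifier = x$kind, k = x$k, n = x$n,
    val_accuracy = x$val_accuracy, sensitivity = x$sensitivity,
    specificity = x$specificity, precision = x$precision, f1 = x$f1
  )
}
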