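# medium synthetic cohort shared across the CV tests
cv_features <- local({
  design <- cohort_design(tibble::tibble(
    subject_id = c(sprintf("H%d", 1:6), sprintf("P%d", 1:3)),
    group = c(rep("healthy", 6), rep("pd", 3)),
    ftmtrs_tremor = c(rep(0L, 6), 2L, 3L, 4L),
    n_sessions = 1L
  ))
  prm <- default_cohort_params()
  simulate_cohort(design, prm$healthy, prm$pd, seed = 7) |>
    exclude_thumbs() |>
    preprocess() |>
    build_features()
})

test_that("stratified folds partition the data with near-equal sizes", {
  y <- cv_features$label
  fold <- tremorforce:::stratified_folds(y, 5, seed = 1)
  expect_length(fold, length(y))
  expect_setequal(unique(fold), 1:5)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  # stratification: each fold's class mix differs from the global by < 1 case
  for (f in 1:5) {
    expect_lte(abs(sum(y[fold == f]) - sum(y) / 5), 1)
  }
})

test_that("a separable synthetic cohort is classified accurately by the tree", {
  for (s in 1:10) {
    rep <- crossvalidate(cv_features, classifier_spec("decision_tree"),
                         k = 5, seed = s)
    expect_gte(rep$val_accuracy, 0.9)
  }
})

test_that("all four reference classifiers run and report coherent metrics", {
  for (kind in c("svm_rbf", "naive_bayes_kernel", "decision_tree", "knn")) {
    rep <- crossvalidate(cv_features, classifier_spec(kind), k = 5, seed = 3)
    expect_s3_class(rep, "metrics_report")
    expect_true(rep$val_accuracy >= 0 && rep$val_accuracy <= 1)
    counts <- colSums(rep$folds[, c("tp", "fp", "tn", "fn")])
    expect_equal(sum(counts), nrow(cv_features))  # every row validated once
    g <- glance(rep)
    expect_equal(g$val_accuracy, rep$val_accuracy)
    td <- tidy(rep)
    expect_equal(td$value[td$metric == "f1"], rep$f1)
  }
})

test_that("random labels on identical feature rows score at the majority rate", {
  set.seed(99)
  n <- 60
  x <- matrix(1, n, 41)
  colnames(x) <- sprintf("f%.2f", feature_grid())
  labels <- sample(c(rep(1L, 24), rep(0L, 36)))
  df <- dplyr::bind_cols(tibble::tibble(label = labels), tibble::as_tibble(x))
  rep <- crossvalidate(df, classifier_spec("decision_tree"), k = 5, seed = 1)
  expect_lte(abs(rep$val_accuracy - 0.6), 0.1)  # majority-class rate 36/60
})

test_that("leave-one-out on 10 rows returns finite metrics", {
  small <- cv_features[c(1:5, 68:72), ]
  rep <- crossvalidate(small, classifier_spec("knn", k_neighbors = 3),
                       k = 10, seed = 1)
  expect_true(is.finite(rep$val_accuracy))
  expect_equal(sum(rep$folds$tp + rep$folds$fp + rep$folds$tn + rep$folds$fn),
               10)
})

test_that("cosine KNN is invariant to per-row scaling of the query", {
  xtr <- matrix(rnorm(26 * 5), 26, 5)
  ytr <- rep(c(0L, 1L), 13)
  xte <- matrix(rnorm(4 * 5), 4, 5)
  p1 <- tremorforce:::knn_cosine_predict(xtr, ytr, xte, 13)
  p2 <- tremorforce:::knn_cosine_predict(xtr, ytr, 10 * xte, 13)
  expect_identical(p1, p2)
})

test_that("degenerate CV inputs are rejected", {
  one_class <- cv_features[cv_features$label == 0, ]
  expect_error(crossvalidate(one_class, classifier_spec("knn")),
               class = "tf_error_invalid_parameter")
  expect_error(crossvalidate(cv_features[1:3, ], classifier_spec("knn"), k = 5),
               class = "tf_error_invalid_parameter")
})

test_that("subject-grouped folds keep each subject in a single fold", {
  rep <- crossvalidate(cv_features, classifier_spec("decision_tree"),
                       k = 3, seed = 2, group_by = "subject")
  expect_s3_class(rep, "metrics_report")
  fold <- tremorforce:::stratified_folds(
    unique(cv_features[, c("subject_id", "label")])$label, 3, seed = 2)
  expect_length(fold, 9)  # 9 subjects
})
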