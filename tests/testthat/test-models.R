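# Classifier suite and evaluation: separable/null fixtures, determinism,
# confusion arithmetic, calibration, leakage guard.

make_separable <- function(n = 80, seed = 50) {
  set.seed(seed)
  lab <- rep(c(0, 1), each = n / 2)
  tibble::tibble(a = lab * 4 + rnorm(n, sd = 0.3),
                 b = -lab * 3 + rnorm(n, sd = 0.3),
                 label = lab)
}

test_that("all seven models separate a linearly separable fixture", {
  df <- make_separable()
  suite <- fit_models(df[c("a", "b")], df$label, seed = 1)
  expect_s3_class(suite, "model_suite")
  probs <- predict(suite, df[c("a", "b")])
  for (alg in c("LG", "RF", "DT", "SVM", "Ada", "KNN", "DNN")) {
    expect_gt(auc(df$label, probs[[alg]]), 0.95, label = alg)
  }
})

test_that("shuffled labels give chance-level test AUC", {
  set.seed(51)
  n <- 200
  x <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  lab <- sample(rep(c(0, 1), each = n / 2))
  tr <- 1:140; te <- 141:200
  suite <- fit_models(x[tr, ], lab[tr], seed = 2)
  probs <- predict(suite, x[te, ])
  aucs <- vapply(probs, function(p) auc(lab[te], p), numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("the DNN is deterministic given the seed", {
  df <- make_separable(n = 60, seed = 52)
  s1 <- fit_models(df[c("a", "b")], df$label, algorithms = "DNN", seed = 7)
  s2 <- fit_models(df[c("a", "b")], df$label, algorithms = "DNN", seed = 7)
  p1 <- predict(s1, df[c("a", "b")])$DNN
  p2 <- predict(s2, df[c("a", "b")])$DNN
  expect_identical(p1, p2)
})

test_that("confusion-matrix metrics match hand arithmetic", {
  # internal-test-style matrix: TP 20, FN 0, TN 46, FP 17
  y <- c(rep(1, 20), rep(0, 63))
  p <- c(rep(0.9, 20), rep(0.9, 17), rep(0.1, 46))
  r <- evaluate_probs(y, p, threshold = 0.5)
  expect_equal(r$metrics$sensitivity * 100, 100.0)
  expect_equal(r$metrics$specificity * 100, 73.0, tolerance = 0.05)
  cm <- r$confusion
  expect_equal(unname(cm["1", "1"]), 20)
  expect_equal(unname(cm["1", "0"]), 17)
  # internal consistency of confusion-derived metrics
  expect_equal(r$metrics$recall, r$metrics$sensitivity)
  expect_equal(r$metrics$f1,
               2 * r$metrics$precision * r$metrics$recall /
                 (r$metrics$precision + r$metrics$recall), tolerance = 1e-12)
  expect_equal(r$metrics$accuracy, (20 + 46) / 83, tolerance = 1e-12)
})

test_that("perfect and trivially calibrated classifiers behave", {
  y <- c(rep(0, 10), rep(1, 10))
  p <- c(rep(0, 10), rep(1, 10))
  r <- evaluate_probs(y, p, threshold = 0.5)
  expect_equal(r$metrics$auc, 1)
  expect_equal(r$metrics$calibration_error, 0)

  # constant 0.5 on balanced labels is calibrated by construction
  expect_equal(ece(y, rep(0.5, 20)), 0)
  expect_equal(auc(y, rep(0.5, 20)), 0.5)

  expect_error(evaluate_probs(rep(1, 5), runif(5), 0.5), "single-class")
})

test_that("youden threshold maximizes sensitivity + specificity", {
  y <- c(0, 0, 0, 0, 1, 1, 1)
  p <- c(0.1, 0.2, 0.3, 0.7, 0.6, 0.8, 0.9)
  thr <- youden_threshold(y, p)
  grid <- sort(unique(p))
  j <- vapply(grid, function(t) {
    mean(p[y == 1] >= t) - mean(p[y == 0] >= t)
  }, numeric(1))
  expect_equal(mean(p[y == 1] >= thr) - mean(p[y == 0] >= thr), max(j))
})

test_that("training metrics are untouched by test-set changes", {
  df <- make_separable(n = 100, seed = 53)
  set.seed(53)
  idx <- sample(100)
  tr <- df[idx[1:70], ]; te <- df[idx[71:100], ]
  suite <- fit_models(tr[c("a", "b")], tr$label, algorithms = c("LG", "DNN"),
                      seed = 3)
  ev1 <- evaluate_suite(suite, list(
    train = list(data = tr[c("a", "b")], labels = tr$label),
    test = list(data = te[c("a", "b")], labels = te$label)))
  te_perm <- te[sample(nrow(te)), ]
  te_perm$a <- te_perm$a + rnorm(30)
  ev2 <- evaluate_suite(suite, list(
    train = list(data = tr[c("a", "b")], labels = tr$label),
    test = list(data = te_perm[c("a", "b")], labels = te_perm$label)))
  expect_equal(ev1[ev1$split == "train", ], ev2[ev2$split == "train", ])
})

test_that("tidy and glance methods return tibbles", {
  df <- make_separable(n = 40, seed = 54)
  suite <- fit_models(df[c("a", "b")], df$label, algorithms = c("LG", "KNN"),
                      seed = 1)
  expect_s3_class(tidy(suite), "tbl_df")
  r <- evaluate_probs(df$label, predict(suite, df[c("a", "b")])$LG, 0.5)
  expect_s3_class(glance(r), "tbl_df")
  expect_equal(nrow(tidy(r)), ncol(r$metrics))
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  set.seed(55)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    p <- rnorm(40) + y
    ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(y, p), ref, tolerance = 1e-12)
  }
})
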