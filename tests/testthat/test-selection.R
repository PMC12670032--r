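# Three-step feature selection: stratified split arithmetic, ICC filter,
# univariate filter calibration and power, tree top-k.

test_that("stratified 7:3 split reproduces the cohort arithmetic", {
  lab <- c(rep(1, 65), rep(0, 210))
  sp <- stratified_split(lab, 0.7, seed = 4)
  expect_equal(sum(sp == "train"), 192)
  expect_equal(sum(sp == "test"), 83)
  expect_equal(sum(lab == 1 & sp == "train"), 45)
  expect_equal(sum(lab == 1 & sp == "test"), 20)

  lab10 <- rep(c(0, 1), 5)
  sp10 <- stratified_split(lab10, 0.7, seed = 1)
  expect_equal(sum(sp10 == "train"), 7)
  expect_setequal(unique(lab10[sp10 == "test"]), c(0, 1))
  expect_setequal(unique(lab10[sp10 == "train"]), c(0, 1))

  s1 <- stratified_split(lab, 0.7, seed = 1)
  s2 <- stratified_split(lab, 0.7, seed = 2)
  expect_false(identical(s1, s2))
  expect_equal(sum(s1 == "test"), sum(s2 == "test"))
  expect_identical(stratified_split(lab, 0.7, seed = 1), s1)

  expect_error(stratified_split(c(1, 0, 0, 0), 0.7, seed = 1), "2 members")
})

test_that("the ICC filter keeps reproducible features only", {
  set.seed(30)
  base <- matrix(rnorm(50 * 4), 50, 4,
                 dimnames = list(NULL, paste0("f", 1:4)))
  identical_ratings <- list(r1 = as.data.frame(base), r2 = as.data.frame(base))
  out <- icc_filter(identical_ratings)
  expect_true(all(out$icc == 1))
  expect_true(all(out$retained))

  # second rater shuffled across cases: agreement destroyed
  shuffled <- list(r1 = as.data.frame(base),
                   r2 = as.data.frame(base[sample(50), ]))
  out2 <- icc_filter(shuffled)
  expect_true(all(!out2$retained))

  expect_error(icc_filter(list(r1 = as.data.frame(base))), "repeats")
})

test_that("univariate filter is calibrated under the null and powered", {
  set.seed(31)
  n0 <- 30; n1 <- 15
  lab <- c(rep(0, n0), rep(1, n1))
  nullx <- as.data.frame(matrix(rnorm((n0 + n1) * 1000), n0 + n1, 1000))
  out <- univariate_filter(nullx, lab)
  frac <- mean(out$retained)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)

  # constant feature excluded with a reason
  cx <- data.frame(flat = rep(1, n0 + n1), ok = rnorm(n0 + n1))
  oc <- univariate_filter(cx, lab)
  expect_false(oc$retained[oc$feature == "flat"])
  expect_match(oc$reason[oc$feature == "flat"], "constant")

  # 2-SD mean shift at the cohort's group sizes: essentially always kept
  set.seed(32)
  lab2 <- c(rep(0, 147), rep(1, 45))
  shift <- data.frame(s = rnorm(192) + 2 * (lab2 == 1))
  expect_true(univariate_filter(shift, lab2)$retained[1])
})

test_that("tree importance returns exactly k names, separability first", {
  set.seed(33)
  n <- 120
  lab <- rep(c(0, 1), each = n / 2)
  x <- as.data.frame(matrix(rnorm(n * 30), n, 30))
  names(x) <- sprintf("noise%02d", 1:30)
  x$signal <- lab * 10 + rnorm(n, sd = 0.01)  # perfectly separating
  keep <- tree_topk(x, lab, k = 20, seed = 1)
  expect_length(keep, 20)
  expect_equal(keep[1], "signal")

  # k equal to the feature count: identity set
  small <- x[, 1:5]
  expect_setequal(tree_topk(small, lab, k = 5, seed = 1), names(small))
  expect_warning(got <- tree_topk(small, lab, k = 10, seed = 1), "returning all")
  expect_setequal(got, names(small))
})

test_that("selection counts are non-increasing across the three steps", {
  set.seed(34)
  n <- 60
  lab <- rep(c(0, 1), each = n / 2)
  x <- as.data.frame(matrix(rnorm(n * 80), n, 80))
  names(x) <- sprintf("f%02d", 1:80)
  x$f01 <- x$f01 + 2 * (lab == 1)
  x$f02 <- x$f02 - 1.5 * (lab == 1)
  rat <- list(r1 = x, r2 = as.data.frame(x + matrix(rnorm(n * 80, sd = 0.05), n, 80)))
  rep <- select_features(x, lab, ratings = rat, k = 20)
  cts <- rep$counts
  expect_true(cts["input"] >= cts["icc"])
  expect_true(cts["icc"] >= cts["univariate"])
  expect_true(cts["univariate"] >= cts["tree"])
  expect_equal(unname(cts["tree"]), min(20, unname(cts["univariate"])))
  expect_true(all(rep$selected %in% names(x)))
})
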