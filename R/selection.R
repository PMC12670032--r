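# Staged feature selection: stratified split, ICC reproducibility filter,
# univariate difference filter, tree-importance top-k.

#' Stratified train/test split
#'
#' Deterministic given `seed`. The test partition holds
#' `ceiling((1 - ratio) * N)` cases, allocated per class by largest-remainder
#' apportionment so class prevalence is preserved (e.g. 275 cases with 65
#' positives at 7:3 give 192 train / 83 test with 45/20 positives).
#'
#' @param labels Binary (0/1) label vector, one per case.
#' @param ratio Training fraction, default 0.7.
#' @param seed RNG seed.
#' @return Character vector `"train"`/`"test"` of the same length.
#' @export
stratified_split <- function(labels, ratio = 0.7, seed = 1) {
  labels <- as.integer(labels)
  n <- length(labels)
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab < 2)) stopf("each class needs at least 2 members to split")
  # round away float fuzz (0.3 * 10 is not exactly 3) before the ceiling
  n_test <- ceiling(round((1 - ratio) * n, 9))
  frac <- setNames(round((1 - ratio) * as.numeric(tab), 9), names(tab))
  base <- floor(frac)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(frac - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  split <- rep("train", n)
  with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- which(labels == cl)
      take <- base[as.character(cl)]
      if (take > 0) split[sample(idx, take)] <- "test"
    }
  })
  split
}

#' ICC reproducibility filter
#'
#' Computes ICC(2,1) per feature across repeated segmentations (two or more
#' rating tables over the same cases) and retains features whose ICC reaches
#' `threshold`. Call once with intra-observer repeats and once with
#' inter-observer repeats, then intersect, to mirror the usual intra- AND
#' inter-observer rule.
#'
#' @param ratings Named list of >= 2 data frames (cases x features) with
#'   identical row order and feature columns.
#' @param threshold Retention threshold, default 0.800.
#' @return Tibble: `feature`, `icc`, `retained`.
#' @export
icc_filter <- function(ratings, threshold = 0.800) {
  if (!is.list(ratings) || length(ratings) < 2) {
    stopf("ICC requires repeats: supply at least two rating tables")
  }
  feats <- Reduce(intersect, lapply(ratings, names))
  feats <- setdiff(feats, "case_id")
  iccs <- vapply(feats, function(f) {
    m <- do.call(cbind, lapply(ratings, function(r) r[[f]]))
    ok <- complete.cases(m)
    if (sum(ok) < 2) return(NA_real_)
    icc21(m[ok, , drop = FALSE])
  }, numeric(1))
  tibble::tibble(feature = feats, icc = unname(iccs),
                 retained = !is.na(iccs) & iccs >= threshold)
}

#' Univariate difference filter
#'
#' Per feature: Shapiro-Wilk normality in both label groups (alpha 0.05)
#' gates a Student t test (normal in both) versus a Mann-Whitney U test;
#' features with P < `alpha` are retained. No multiplicity correction.
#' Constant features are excluded with a logged reason.
#'
#' @param data Data frame / tibble of feature columns (training split only).
#' @param labels Binary label vector.
#' @param alpha Significance level, default 0.05.
#' @return Tibble: `feature`, `test` ("t", "wilcox" or "none"), `p`,
#'   `retained`, `reason`.
#' @export
univariate_filter <- function(data, labels, alpha = 0.05) {
  labels <- as.integer(labels)
  if (min(table(labels)) < 3) stopf("both classes need >= 3 cases")
  feats <- setdiff(names(data), c("case_id", "label", "split"))
  res <- lapply(feats, function(f) {
    x <- data[[f]]
    g0 <- x[labels == 0 & !is.na(x)]
    g1 <- x[labels == 1 & !is.na(x)]
    if (length(g0) < 3 || length(g1) < 3) {
      return(list(f, "none", NA_real_, FALSE, "too few non-missing values"))
    }
    if (sd(x, na.rm = TRUE) == 0) {
      return(list(f, "none", NA_real_, FALSE, "constant feature"))
    }
    normal <- function(v) {
      if (length(unique(v)) < 3) return(FALSE)
      tryCatch(shapiro.test(v)$p.value >= 0.05, error = function(e) FALSE)
    }
    if (normal(g0) && normal(g1)) {
      p <- tryCatch(t.test(g0, g1, var.equal = TRUE)$p.value,
                    error = function(e) NA_real_)
      tst <- "t"
    } else {
      p <- tryCatch(suppressWarnings(wilcox.test(g0, g1)$p.value),
                    error = function(e) NA_real_)
      tst <- "wilcox"
    }
    list(f, tst, p, !is.na(p) && p < alpha, NA_character_)
  })
  tibble::tibble(
    feature = vapply(res, `[[`, character(1), 1),
    test = vapply(res, `[[`, character(1), 2),
    p = vapply(res, `[[`, numeric(1), 3),
    retained = vapply(res, `[[`, logical(1), 4),
    reason = vapply(res, `[[`, character(1), 5))
}

#' Tree-importance top-k selection
#'
#' Fits one impurity-based (Gini) classification tree on the training
#' features and ranks features by their impurity-reduction importance.
#' Features the tree never uses score 0; ties (including the all-zero tie)
#' break by canonical name order, so the result is deterministic.
#'
#' @param data Training feature data frame.
#' @param labels Binary labels.
#' @param k Number of features to keep, default 20.
#' @param seed RNG seed (rpart surrogate handling), default 1.
#' @return Character vector of `min(k, ncol)` feature names (warns when
#'   fewer than `k` features were supplied).
#' @export
tree_topk <- function(data, labels, k = 20, seed = 1) {
  feats <- setdiff(names(data), c("case_id", "label", "split"))
  if (length(feats) < k) {
    warnf("only %d features supplied; returning all", length(feats))
    return(sort(feats))
  }
  df <- as.data.frame(data[feats])
  # syntactic surrogate names; mapped back after the fit
  safe <- paste0("f", seq_along(feats))
  names(df) <- safe
  df$.y <- factor(labels)
  fit <- with_seed(seed, rpart::rpart(
    .y ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(cp = 0, minsplit = 4, minbucket = 2,
                                   maxsurrogate = 0, maxcompete = 0,
                                   xval = 0)))
  imp <- fit$variable.importance
  scores <- setNames(rep(0, length(feats)), feats)
  if (!is.null(imp)) {
    scores[feats[match(names(imp), safe)]] <- imp
  }
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(k)]
}

#' Run the full three-step selection
#'
#' Step 1: ICC reproducibility filter (intra- and inter-observer tables).
#' Step 2: univariate difference filter on the training split.
#' Step 3: tree-importance top-k. Counts are non-increasing by construction.
#'
#' @param train Data frame of training-split features.
#' @param labels Training labels.
#' @param ratings Optional named list of rating tables for step 1 (skipped
#'   with a note if `NULL`, e.g. when no repeated masks exist).
#' @param icc_threshold,alpha,k,seed Stage parameters (0.800, 0.05, 20, 1).
#' @return List of class `selection_report`: `selected`, per-step tibbles,
#'   `counts`.
#' @export
select_features <- function(train, labels, ratings = NULL,
                            icc_threshold = 0.800, alpha = 0.05, k = 20,
                            seed = 1) {
  feats0 <- setdiff(names(train), c("case_id", "label", "split"))
  if (!is.null(ratings)) {
    step1 <- icc_filter(ratings, threshold = icc_threshold)
    keep1 <- intersect(feats0, step1$feature[step1$retained])
  } else {
    step1 <- NULL
    keep1 <- feats0
  }
  step2 <- univariate_filter(train[keep1], labels, alpha = alpha)
  keep2 <- step2$feature[step2$retained]
  keep3 <- if (length(keep2) > 0) {
    tree_topk(train[keep2], labels, k = min(k, length(keep2)), seed = seed)
  } else character(0)
  structure(list(
    selected = keep3,
    icc = step1, univariate = step2,
    counts = c(input = length(feats0), icc = length(keep1),
               univariate = length(keep2), tree = length(keep3))),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> counts:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = " "), "\n")
  cat("selected:", paste(head(x$selected, 5), collapse = ", "),
      if (length(x$selected) > 5) "...\n" else "\n")
  invisible(x)
}
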