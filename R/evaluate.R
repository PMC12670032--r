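# Model evaluation: ROC/AUC, Youden operating point frozen on training,
# confusion-matrix metrics, expected calibration error.

#' ROC curve points
#'
#' FPR/TPR at every distinct score cutoff (ties grouped), ordered from (0,0)
#' to (1,1).
#'
#' @param y Binary labels.
#' @param p Scores/probabilities.
#' @return Tibble: `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(y, p) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("AUC undefined: single-class data")
  ord <- order(p, decreasing = TRUE)
  ys <- y[ord]; ps <- p[ord]
  grp <- !duplicated(ps, fromLast = TRUE)  # last index of each tied block
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  P <- sum(ys); N <- length(ys) - P
  tibble::tibble(
    threshold = c(Inf, ps[grp]),
    fpr = c(0, fp[grp] / N),
    tpr = c(0, tp[grp] / P))
}

# Trapezoidal AUC over the tie-grouped ROC (equals the rank statistic with
# ties counted 1/2).
auc_trapezoid <- function(y, p) {
  r <- roc_points(y, p)
  sum(diff(r$fpr) * (head(r$tpr, -1) + r$tpr[-1]) / 2)
}

#' Trapezoidal AUC
#'
#' @inheritParams roc_points
#' @return AUC in [0, 1].
#' @export
auc <- function(y, p) auc_trapezoid(y, p)

#' Youden-optimal threshold on a ROC
#'
#' The cutoff maximizing sensitivity + specificity - 1; ties resolve to the
#' highest threshold.
#'
#' @inheritParams roc_points
#' @return Numeric threshold (classify positive when `p >= threshold`).
#' @export
youden_threshold <- function(y, p) {
  r <- roc_points(y, p)
  j <- r$tpr - r$fpr
  best <- which(j == max(j))
  th <- r$threshold[best[1]]
  if (!is.finite(th)) th <- max(p) + 1e-9
  th
}

#' Expected calibration error (10 equal-width bins)
#'
#' Mean absolute gap between predicted probability and observed event
#' frequency, weighted by bin occupancy.
#'
#' @inheritParams roc_points
#' @param bins Number of equal-width probability bins, default 10.
#' @return ECE in [0, 1].
#' @export
ece <- function(y, p, bins = 10) {
  y <- as.integer(y)
  b <- pmin(pmax(ceiling(p * bins), 1), bins)
  e <- 0
  for (k in seq_len(bins)) {
    in_b <- b == k
    if (!any(in_b)) next
    e <- e + sum(in_b) / length(y) * abs(mean(p[in_b]) - mean(y[in_b]))
  }
  e
}

#' Evaluate predicted probabilities on one split
#'
#' AUC by trapezoidal ROC; the confusion matrix at the supplied threshold
#' (Youden-optimal on training, frozen across splits) yields sensitivity,
#' specificity, accuracy, precision, recall and F1; calibration error is the
#' 10-bin ECE. All confusion-derived metrics are mutually consistent by
#' construction.
#'
#' @param y Binary labels (both classes must be present).
#' @param p Predicted probabilities.
#' @param threshold Operating threshold (positive when `p >= threshold`).
#' @return Object of class `model_report`: list with `metrics` (tibble),
#'   `confusion` (2x2 matrix), `roc` (tibble), `threshold`.
#' @export
evaluate_probs <- function(y, p, threshold) {
  y <- as.integer(y)
  if (length(y) == 0) stopf("empty split")
  if (length(unique(y)) < 2) stopf("AUC undefined: single-class split")
  a <- auc_trapezoid(y, p)
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / length(y)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && prec + sens > 0) 2 * prec * sens / (prec + sens)
        else NA_real_
  cm <- matrix(c(tn, fp, fn, tp), 2, 2,
               dimnames = list(pred = c("0", "1"), truth = c("0", "1")))
  metrics <- tibble::tibble(
    auc = a, sensitivity = sens, specificity = spec, accuracy = acc,
    precision = prec, recall = sens, f1 = f1,
    calibration_error = ece(y, p))
  structure(list(metrics = metrics, confusion = cm,
                 roc = roc_points(y, p), threshold = threshold),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<model_report> AUC %.3f | sens %.1f%% spec %.1f%% ",
                     "acc %.1f%% F1 %.3f | ECE %.3f @thr %.3f\n"),
              m$auc, 100 * m$sensitivity, 100 * m$specificity,
              100 * m$accuracy, m$f1, m$calibration_error, x$threshold))
  invisible(x)
}

#' Evaluate a fitted suite on named data splits
#'
#' Per algorithm: the operating threshold is set by the Youden index on the
#' training split, then frozen for every other split.
#'
#' @param suite A `model_suite` from [fit_models()].
#' @param splits Named list of lists, each with `data` (features) and
#'   `labels`; must include a `train` element.
#' @return Tibble: `algorithm`, `split`, `threshold`, and the metric columns.
#' @export
evaluate_suite <- function(suite, splits) {
  if (!"train" %in% names(splits)) stopf("splits must include 'train'")
  rows <- list()
  probs <- lapply(splits, function(sp) predict(suite, sp$data))
  for (alg in suite$algorithms) {
    thr <- youden_threshold(splits$train$labels, probs$train[[alg]])
    for (spn in names(splits)) {
      rep <- evaluate_probs(splits[[spn]]$labels, probs[[spn]][[alg]], thr)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(algorithm = alg, split = spn, threshold = thr),
        rep$metrics)
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
tidy.model_suite <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithms,
                 n_features = length(x$features),
                 seed = x$seed)
}

#' @export
glance.model_report <- function(x, ...) x$metrics

#' @export
tidy.model_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' Broom-style generics
#'
#' `tidy()` and `glance()` methods are provided for fitted suites and model
#' reports; the generics are re-exported here to avoid a hard broom
#' dependency.
#' @param x Object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
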