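# Seven-classifier suite: LG, RF, DT, SVM, Ada, KNN, DNN.
# Features are standardized from training statistics; every learner exposes
# calibrated-ish probabilities through a common predict surface.

ALGORITHMS <- c("LG", "RF", "DT", "SVM", "Ada", "KNN", "DNN")

#' Fit the classifier suite
#'
#' Standardizes features with training means/SDs (train-split medians having
#' been imputed upstream), then fits the requested probabilistic classifiers
#' with fixed seeds: logistic regression (`LG`), random forest (`RF`,
#' ranger), decision tree (`DT`, rpart), RBF support vector machine with
#' Platt probabilities (`SVM`, e1071), AdaBoost with depth-1 stumps (`Ada`),
#' k-nearest neighbours with vote-share probabilities (`KNN`, k = 5), and a
#' small multilayer perceptron (`DNN`: hidden layers 64/32, ReLU, dropout
#' 0.2, Adam, early stopping on a 20% train-internal validation split by
#' AUC).
#'
#' @param data Data frame of selected training features.
#' @param labels Binary (0/1) training labels.
#' @param algorithms Subset of `c("LG","RF","DT","SVM","Ada","KNN","DNN")`.
#' @param seed RNG seed shared across learners.
#' @return Object of class `model_suite`.
#' @export
fit_models <- function(data, labels, algorithms = ALGORITHMS, seed = 1) {
  x <- as.matrix(as.data.frame(data[setdiff(names(data), c("case_id", "label", "split"))]))
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stopf("non-finite feature values after imputation")
  y <- as.integer(labels)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)

  models <- list()
  for (alg in algorithms) {
    models[[alg]] <- with_seed(seed, switch(alg,
      LG = {
        df <- data.frame(xs); df$.y <- y
        suppressWarnings(glm(.y ~ ., family = binomial(), data = df))
      },
      RF = ranger::ranger(
        x = xs, y = factor(y), probability = TRUE, num.trees = 500,
        seed = seed, num.threads = 1),
      DT = {
        df <- data.frame(xs); df$.y <- factor(y)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = 0.01, xval = 0))
      },
      SVM = e1071::svm(x = xs, y = factor(y), kernel = "radial",
                       probability = TRUE),
      Ada = ada_fit(xs, y, n_rounds = 50),
      KNN = list(x = xs, y = y, k = 5),
      DNN = mlp_fit(xs, y, hidden = c(64, 32), dropout = 0.2,
                    val_frac = 0.2, seed = seed)))
  }
  structure(list(models = models, center = ctr, scale = scl,
                 features = colnames(x), algorithms = algorithms,
                 seed = seed),
            class = "model_suite")
}

#' Predicted positive-class probabilities from a fitted suite
#'
#' @param object A `model_suite`.
#' @param newdata Data frame containing the suite's feature columns.
#' @param ... Unused.
#' @return Tibble with one probability column per algorithm.
#' @export
predict.model_suite <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata[object$features]))
  storage.mode(x) <- "double"
  xs <- scale(x, center = object$center, scale = object$scale)
  out <- lapply(object$algorithms, function(alg) {
    m <- object$models[[alg]]
    switch(alg,
      LG = as.numeric(predict(m, newdata = data.frame(xs), type = "response")),
      RF = predict(m, data = xs, num.threads = 1)$predictions[, "1"],
      DT = predict(m, newdata = data.frame(xs), type = "prob")[, "1"],
      SVM = {
        pr <- predict(m, xs, probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      },
      Ada = ada_predict(m, xs),
      KNN = knn_predict(m, xs),
      DNN = mlp_predict(m, xs))
  })
  names(out) <- object$algorithms
  tibble::as_tibble(out)
}

#' @export
print.model_suite <- function(x, ...) {
  cat(sprintf("<model_suite> %d features, algorithms: %s\n",
              length(x$features), paste(x$algorithms, collapse = ", ")))
  invisible(x)
}

# --- AdaBoost.M1 with rpart stumps ------------------------------------------

ada_fit <- function(x, y, n_rounds = 50) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  yy <- ifelse(y == 1, 1, -1)
  df <- data.frame(x)
  df$.y <- factor(y)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0,
                                                       maxsurrogate = 0,
                                                       maxcompete = 0))
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w[pred != yy])
    if (err <= 0) { stumps[[m]] <- fit; alphas[m] <- 10; break }
    if (err >= 0.5) break
    a <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit; alphas[m] <- a
    w <- w * exp(-a * yy * pred)
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {
    # no usable weak learner: fall back to the base rate
    return(list(stumps = list(), alphas = numeric(0), base = mean(y)))
  }
  list(stumps = stumps, alphas = alphas, base = mean(y))
}

ada_predict <- function(model, x) {
  if (length(model$stumps) == 0) return(rep(model$base, nrow(x)))
  df <- data.frame(x)
  f <- rep(0, nrow(x))
  for (m in seq_along(model$stumps)) {
    pred <- ifelse(predict(model$stumps[[m]], df, type = "class") == "1", 1, -1)
    f <- f + model$alphas[m] * pred
  }
  plogis(2 * f / sum(model$alphas))
}

# --- k-nearest neighbours ----------------------------------------------------

knn_predict <- function(model, xnew) {
  k <- min(model$k, nrow(model$x))
  apply(xnew, 1, function(q) {
    d <- sqrt(colSums((t(model$x) - q)^2))
    nb <- order(d, seq_along(d))[seq_len(k)]  # index tie-break: deterministic
    mean(model$y[nb])
  })
}

# --- multilayer perceptron ---------------------------------------------------

# Two hidden layers with ReLU, inverted dropout, Adam on binary
# cross-entropy, early stopping on validation AUC with best-weight restore.
mlp_fit <- function(x, y, hidden = c(64, 32), dropout = 0.2, lr = 1e-2,
                    epochs = 300, batch = 16, patience = 30, val_frac = 0.2,
                    seed = 1) {
  n <- nrow(x); p <- ncol(x)
  n_val <- max(2, floor(val_frac * n))
  vi <- sample.int(n, n_val)      # RNG already seeded by caller
  # guarantee both classes in validation when possible
  if (length(unique(y[vi])) < 2 && length(unique(y)) == 2) {
    add <- c(which(y == 0)[1], which(y == 1)[1])
    vi <- unique(c(vi[-1], add))
  }
  tri <- setdiff(seq_len(n), vi)
  if (length(tri) < 2) { tri <- seq_len(n); vi <- seq_len(n) }

  sizes <- c(p, hidden, 1)
  init <- function(fanin, fanout) {
    matrix(rnorm(fanin * fanout, sd = sqrt(2 / fanin)), fanin, fanout)
  }
  W <- list(init(sizes[1], sizes[2]), init(sizes[2], sizes[3]),
            init(sizes[3], sizes[4]))
  b <- list(rep(0, sizes[2]), rep(0, sizes[3]), rep(0, sizes[4]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(z) z * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; epsi <- 1e-8; t_step <- 0

  forward <- function(X, train = FALSE) {
    a1 <- pmax(sweep(X %*% W[[1]], 2, b[[1]], "+"), 0)
    if (train && dropout > 0) {
      m1 <- matrix(runif(length(a1)) > dropout, nrow(a1)) / (1 - dropout)
      a1 <- a1 * m1
    } else m1 <- NULL
    a2 <- pmax(sweep(a1 %*% W[[2]], 2, b[[2]], "+"), 0)
    if (train && dropout > 0) {
      m2 <- matrix(runif(length(a2)) > dropout, nrow(a2)) / (1 - dropout)
      a2 <- a2 * m2
    } else m2 <- NULL
    z3 <- sweep(a2 %*% W[[3]], 2, b[[3]], "+")
    list(a1 = a1, a2 = a2, p = plogis(as.numeric(z3)), m1 = m1, m2 = m2)
  }

  best_auc <- -Inf; best_loss <- Inf; best <- list(W = W, b = b); wait <- 0
  xtr <- x[tri, , drop = FALSE]; ytr <- y[tri]
  xval <- x[vi, , drop = FALSE]; yval <- y[vi]
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(ytr))
    for (start in seq(1, length(ord), by = batch)) {
      bi <- ord[start:min(start + batch - 1, length(ord))]
      X <- xtr[bi, , drop = FALSE]; Y <- ytr[bi]
      fw <- forward(X, train = TRUE)
      nb <- length(bi)
      d3 <- matrix((fw$p - Y) / nb, ncol = 1)
      gW3 <- t(fw$a2) %*% d3; gb3 <- colSums(d3)
      d2 <- (d3 %*% t(W[[3]])) * (fw$a2 > 0)
      if (!is.null(fw$m2)) d2 <- d2 * fw$m2
      gW2 <- t(fw$a1) %*% d2; gb2 <- colSums(d2)
      d1 <- (d2 %*% t(W[[2]])) * (fw$a1 > 0)
      if (!is.null(fw$m1)) d1 <- d1 * fw$m1
      gW1 <- t(X) %*% d1; gb1 <- colSums(d1)
      gW <- list(gW1, gW2, gW3); gb <- list(gb1, gb2, gb3)
      t_step <- t_step + 1
      for (l in 1:3) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        mhW <- mW[[l]] / (1 - beta1^t_step); vhW <- vW[[l]] / (1 - beta2^t_step)
        mhb <- mb[[l]] / (1 - beta1^t_step); vhb <- vb[[l]] / (1 - beta2^t_step)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + epsi)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + epsi)
      }
    }
    pv <- forward(xval)$p
    auc <- if (length(unique(yval)) == 2) auc_trapezoid(yval, pv) else 0.5
    loss <- -mean(yval * log(pv + 1e-12) + (1 - yval) * log(1 - pv + 1e-12))
    # selection by validation AUC; ties (tiny validation sets saturate the
    # AUC quickly) broken by validation cross-entropy
    if (auc > best_auc + 1e-6 ||
        (auc > best_auc - 1e-6 && loss < best_loss - 1e-6)) {
      best_auc <- auc; best_loss <- loss
      best <- list(W = W, b = b); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  list(W = best$W, b = best$b, val_auc = best_auc)
}

mlp_predict <- function(model, x) {
  a1 <- pmax(sweep(x %*% model$W[[1]], 2, model$b[[1]], "+"), 0)
  a2 <- pmax(sweep(a1 %*% model$W[[2]], 2, model$b[[2]], "+"), 0)
  plogis(as.numeric(sweep(a2 %*% model$W[[3]], 2, model$b[[3]], "+")))
}

#' Train-median imputation
#'
#' Replaces `NA`s in every feature column with the training-split median of
#' that column (leakage-safe: statistics come from the training rows only).
#'
#' @param data Feature data frame (all splits).
#' @param train_rows Logical/integer index of training rows.
#' @return List: `data` (imputed), `medians`.
#' @export
impute_train_median <- function(data, train_rows) {
  feats <- setdiff(names(data), c("case_id", "label", "split"))
  med <- vapply(feats, function(f) {
    m <- median(data[[f]][train_rows], na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, numeric(1))
  for (f in feats) {
    v <- data[[f]]
    v[is.na(v)] <- med[[f]]
    data[[f]] <- v
  }
  list(data = data, medians = med)
}
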