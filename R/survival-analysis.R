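# Survival analysis: Kaplan-Meier with medians, restricted mean survival
# time with integrated-Greenwood variance, log-rank, univariable Cox.

#' Kaplan-Meier estimate with Greenwood CIs and median survival
#'
#' Product-limit estimator per group (via `survival::survfit`); the median
#' is the first time the survival curve drops to 0.5 or below, with its 95%
#' CI from the times at which the confidence band crosses 0.5
#' (Brookmeyer-Crowley construction). A median is reported as `NA` while the
#' curve stays above 0.5.
#'
#' @param records Data frame with time/event columns.
#' @param time,event Column names, defaults `"time"` / `"event"`.
#' @param group Optional grouping column name.
#' @return List of class `km_fit`: `curve` (tibble: group, time, n_risk,
#'   n_event, surv, lower, upper), `median` (tibble: group, median, lcl,
#'   ucl), and the underlying `survfit` object.
#' @export
km_estimate <- function(records, time = "time", event = "event",
                        group = NULL) {
  tt <- records[[time]]
  if (any(tt < 0)) stopf("negative survival times")
  ev <- as.integer(records[[event]])
  g <- if (is.null(group)) factor(rep("all", length(tt))) else
    factor(records[[group]])
  fit <- survival::survfit(survival::Surv(tt, ev) ~ g)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) factor(rep(levels(g)[1], length(sm$time)))
            else sm$strata
  curve <- tibble::tibble(
    group = sub("^g=", "", as.character(strata)),
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    surv = sm$surv, lower = sm$lower, upper = sm$upper)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, 1, length(tab),
                                       dimnames = list(levels(g)[1], names(tab)))
  med <- tibble::tibble(
    group = sub("^g=", "", rownames(tab)),
    median = unname(tab[, "median"]),
    lcl = unname(tab[, "0.95LCL"]), ucl = unname(tab[, "0.95UCL"]))
  structure(list(curve = curve, median = med, survfit = fit),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  print(x$median)
  invisible(x)
}

#' Restricted mean survival time (area under KM up to tau)
#'
#' RMST is the area under the Kaplan-Meier curve from 0 to `tau` (months);
#' its variance uses the standard integrated-Greenwood formula. With a
#' grouping column, per-group RMSTs plus their difference (group 2 - group
#' 1) with a normal-approximation P value are returned. If `tau` exceeds the
#' last observed time in a group, the estimate is truncated there with a
#' warning.
#'
#' @inheritParams km_estimate
#' @param tau Truncation time in months (36 and 60 give the 3- and 5-year
#'   summaries).
#' @return Tibble: `group`, `rmst`, `se`, `lcl`, `ucl` (95%), and for
#'   two-group input an extra row `"diff"` with the difference and `p`.
#' @export
rmst <- function(records, tau, time = "time", event = "event", group = NULL) {
  if (nrow(records) == 0) stopf("empty group")
  g <- if (is.null(group)) rep("all", nrow(records)) else
    as.character(records[[group]])
  lv <- sort(unique(g))
  one <- function(sub) {
    tt <- sub[[time]]; ev <- as.integer(sub[[event]])
    if (length(tt) == 0) stopf("empty group")
    tmax <- max(tt)
    tau_g <- tau
    if (tau > tmax) {
      warnf("tau=%g exceeds last observed time %g; truncating", tau, tmax)
      tau_g <- tmax
    }
    fit <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    st <- fit$time; ss <- fit$surv; nr <- fit$n.risk; nd <- fit$n.event
    keep <- st <= tau_g
    stk <- st[keep]; ssk <- ss[keep]
    grid <- c(0, stk, tau_g)
    svals <- c(1, ssk)               # S on [t_i, t_{i+1}) is the post-jump value
    area <- sum(diff(grid) * svals)
    # integrated Greenwood: Var = sum_i A_i^2 d_i / (n_i (n_i - d_i)),
    # A_i = int_{t_i}^{tau} S(u) du
    evt <- which(keep & nd > 0)
    v <- 0
    if (length(evt) > 0) {
      A <- vapply(st[evt], function(ti) {
        later <- stk > ti
        gi <- c(ti, stk[later], tau_g)
        si <- c(ssk[match(ti, stk)], ssk[later])
        sum(diff(gi) * si)
      }, numeric(1))
      di <- nd[evt]; ni <- nr[evt]
      ok <- ni > di
      v <- sum((A[ok]^2) * di[ok] / (ni[ok] * (ni[ok] - di[ok])))
    }
    c(rmst = area, se = sqrt(v))
  }
  rows <- lapply(lv, function(l) {
    r <- one(records[g == l, , drop = FALSE])
    tibble::tibble(group = l, rmst = r[["rmst"]], se = r[["se"]],
                   lcl = r[["rmst"]] - qnorm(0.975) * r[["se"]],
                   ucl = r[["rmst"]] + qnorm(0.975) * r[["se"]], p = NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  if (length(lv) == 2) {
    d <- out$rmst[2] - out$rmst[1]
    se <- sqrt(out$se[1]^2 + out$se[2]^2)
    out <- dplyr::bind_rows(out, tibble::tibble(
      group = "diff", rmst = d, se = se,
      lcl = d - qnorm(0.975) * se, ucl = d + qnorm(0.975) * se,
      p = 2 * pnorm(-abs(d / se))))
  }
  out
}

#' Two-group log-rank test
#'
#' @inheritParams km_estimate
#' @param group Grouping column name (exactly two nonempty groups).
#' @return Tibble: `chisq`, `df`, `p`.
#' @export
logrank <- function(records, time = "time", event = "event", group = "group") {
  g <- factor(records[[group]])
  if (nlevels(droplevels(g)) < 2) stopf("log-rank needs two nonempty groups")
  sd <- survival::survdiff(
    survival::Surv(records[[time]], as.integer(records[[event]])) ~ g)
  df <- length(sd$n) - 1
  tibble::tibble(chisq = sd$chisq, df = df,
                 p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Univariable (or small multivariable) Cox proportional hazards
#'
#' Partial-likelihood fit with the Efron tie approximation; Wald CIs and P
#' values. Errors on collinear/degenerate designs and on monotone-likelihood
#' (complete separation) fits; warns when events are scarce (< 10 per
#' covariate).
#'
#' @inheritParams km_estimate
#' @param covariates Character vector of covariate column names.
#' @return Tibble: `term`, `hr`, `lcl`, `ucl`, `p`, `n_events`.
#' @export
cox_hr <- function(records, covariates, time = "time", event = "event") {
  X <- as.data.frame(records[covariates])
  num <- X[vapply(X, is.numeric, logical(1))]
  if (ncol(num) > 1 && qr(as.matrix(num))$rank < ncol(num)) {
    stopf("collinear covariates in Cox design")
  }
  df <- cbind(data.frame(.t = records[[time]],
                         .e = as.integer(records[[event]])), X)
  nev <- sum(df$.e)
  if (nev < 10 * length(covariates)) {
    warnf("only %d events for %d covariate(s); Cox estimates may be unstable",
          nev, length(covariates))
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(.t, .e) ~", paste(covariates, collapse = " + ")))
  fit <- tryCatch(survival::coxph(fml, data = df, ties = "efron"),
                  warning = function(w) {
                    if (grepl("infinite|converge", conditionMessage(w))) {
                      stopf("monotone likelihood / separation in Cox fit: %s",
                            conditionMessage(w))
                    }
                    suppressWarnings(survival::coxph(fml, data = df,
                                                     ties = "efron"))
                  })
  if (anyNA(coef(fit))) stopf("degenerate Cox design (NA coefficients)")
  s <- summary(fit)
  tibble::tibble(term = rownames(s$coefficients),
                 hr = s$coefficients[, "exp(coef)"],
                 lcl = s$conf.int[, "lower .95"],
                 ucl = s$conf.int[, "upper .95"],
                 p = s$coefficients[, "Pr(>|z|)"],
                 n_events = nev)
}
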