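# Heterogeneity quantification: coefficient of variation of each radiomic
# feature across habitats, per region and sequence.

REGION_NAMES <- c("ITH", "Peri3", "Peri5", "Peri7")

#' Coefficient of variation across habitats
#'
#' Sample SD divided by the absolute mean, after pairwise exclusion of
#' missing values. Returns `NA` when fewer than two values survive or when
#' the absolute mean falls below `eps` (guard against explosive ratios near
#' zero). 0 indicates complete homogeneity; the CV is invariant to positive
#' rescaling of the feature and to habitat order.
#'
#' @param values Numeric feature values across habitats (may contain `NA`).
#' @param eps Near-zero-mean guard, default 1e-8.
#' @return A single non-negative number, or `NA`.
#' @export
cv <- function(values, eps = 1e-8) {
  v <- values[!is.na(values)]
  if (length(v) < 2) return(NA_real_)
  m <- mean(v)
  if (abs(m) < eps) return(NA_real_)
  sd(v) / abs(m)
}

#' Assemble the 1712-entry heterogeneity vector for one case
#'
#' Applies [cv()] column-wise to each region's habitat feature table. Names
#' follow `ITH_{seq}_{class}_{feature}` for the intratumoral region and
#' `PTH_{region}_{seq}_{class}_{feature}` for the peritumoral bands, giving
#' exactly 428 x 4 = 1712 uniquely named values. Missing cells stay `NA`
#' here; cohort-median imputation belongs to the modeling stage.
#'
#' @param tables Named list of habitat feature tables (from
#'   [extract_per_habitat()]) with names `ITH`, `Peri3`, `Peri5`, `Peri7`.
#' @param case_id Optional case id recorded as an attribute.
#' @param eps Passed to [cv()].
#' @return Named numeric vector of length 1712.
#' @export
heterogeneity_vector <- function(tables, case_id = NULL, eps = 1e-8) {
  missing_reg <- setdiff(REGION_NAMES, names(tables))
  if (length(missing_reg) > 0) {
    stopf("missing region table(s): %s", paste(missing_reg, collapse = ", "))
  }
  out <- numeric(0)
  for (reg in REGION_NAMES) {
    tab <- tables[[reg]]
    featcols <- setdiff(names(tab), "habitat")
    cvs <- vapply(featcols, function(cn) cv(tab[[cn]], eps = eps), numeric(1))
    prefix <- if (reg == "ITH") "ITH_" else paste0("PTH_", reg, "_")
    names(cvs) <- paste0(prefix, featcols)
    out <- c(out, cvs)
  }
  if (anyDuplicated(names(out))) stopf("duplicate heterogeneity feature names")
  attr(out, "case_id") <- case_id
  out
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' standard ANOVA decomposition: targets (cases) in rows, raters (observers
#' or habitat-count settings) in columns.
#'
#' @param x Numeric matrix, cases x raters (>= 2 columns), no `NA`.
#' @return ICC value; `NA` if the ANOVA terms are degenerate.
#' @export
icc21 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (k < 2 || n < 2) stopf("ICC requires >= 2 cases and >= 2 raters")
  if (anyNA(x)) return(NA_real_)
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)      # between targets
  ssc <- n * sum((colm - grand)^2)      # between raters
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (!is.finite(den) || den <= 0) return(NA_real_)
  (msr - mse) / den
}

#' Stability of heterogeneity features across habitat-count settings
#'
#' Recomputes selected heterogeneity features for each case at every habitat
#' count in `K_list`, then treats the K settings as raters and the cases as
#' targets in an ICC(2,1) per feature.
#'
#' @param cases List of case objects, each with `stack` (a [volume_stack])
#'   and `mask` (tumor mask) — e.g. elements of
#'   `generate_cohort(...)$cases`.
#' @param K_list Habitat counts, default `c(30, 40, 50, 60, 70)`.
#' @param features Character vector of heterogeneity feature names (in the
#'   `ITH_...` / `PTH_...` convention) to assess; default: all first-order
#'   ITH features.
#' @param distances Band distances mm, default `c(3, 5, 7)`.
#' @param settings Extraction settings.
#' @param compactness,seed Passed to [encode_habitats()].
#' @return Tibble with columns `feature`, `icc` (`NA` where degenerate).
#' @export
stability_analysis <- function(cases, K_list = c(30, 40, 50, 60, 70),
                               features = NULL, distances = c(3, 5, 7),
                               settings = extraction_settings(),
                               compactness = 0.1, seed = 20406) {
  if (length(K_list) < 2) stopf("need at least two K settings")
  if (length(cases) < 5) stopf("need at least five cases")
  if (is.null(features)) {
    features <- paste0("ITH_", as.vector(outer(
      SEQ_NAMES, FEATURE_MANIFEST$firstorder,
      function(s, f) paste0(s, "_firstorder_", f))))
  }
  need <- parse_het_names(features)
  vals <- array(NA_real_, c(length(cases), length(K_list), length(features)),
                dimnames = list(NULL, NULL, features))
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    regions <- make_peritumoral_bands(cs$mask, cs$stack$spacing, distances)
    for (ki in seq_along(K_list)) {
      for (reg in unique(need$region)) {
        mask <- if (reg == "ITH") regions$tumor else
          regions[[paste0("peri", sub("Peri", "", reg))]]
        hm <- encode_habitats(cs$stack, mask, K = K_list[ki],
                              compactness = compactness, seed = seed,
                              region_name = reg)
        sub <- need[need$region == reg, , drop = FALSE]
        tab <- extract_per_habitat(cs$stack, hm, settings,
                                   classes = unique(sub$class),
                                   sequences = unique(sub$sequence))
        for (r in seq_len(nrow(sub))) {
          vals[ci, ki, sub$full[r]] <- cv(tab[[sub$column[r]]])
        }
      }
    }
  }
  icc <- vapply(features, function(f) {
    m <- vals[, , f]
    if (anyNA(m)) return(NA_real_)
    if (all(apply(m, 2, sd) == 0) && all(m == m[1, 1])) return(NA_real_)
    icc21(m)
  }, numeric(1))
  tibble::tibble(feature = features, icc = unname(icc))
}

# Split heterogeneity names into region / sequence / class / feature parts.
parse_het_names <- function(features) {
  rows <- lapply(features, function(f) {
    parts <- strsplit(f, "_")[[1]]
    if (parts[1] == "ITH") {
      region <- "ITH"; rest <- parts[-1]
    } else if (parts[1] == "PTH") {
      region <- parts[2]; rest <- parts[-(1:2)]
    } else stopf("unrecognised heterogeneity feature name: %s", f)
    data.frame(full = f, region = region, sequence = rest[1], class = rest[2],
               column = paste(rest, collapse = "_"))
  })
  do.call(rbind, rows)
}

#' Heterogeneity vectors for a whole cohort
#'
#' Runs bands -> habitats -> per-habitat extraction -> [heterogeneity_vector()]
#' for each case and binds the results into a cases x 1712 tibble.
#'
#' @param cases List of case objects (`stack`, `mask`, optional `label`).
#' @param K Habitat count, default 50.
#' @param distances Band distances mm, default `c(3, 5, 7)`.
#' @param settings Extraction settings.
#' @param compactness,seed Passed to [encode_habitats()].
#' @param progress Print per-case progress (default FALSE).
#' @return Tibble: `case_id`, then 1712 heterogeneity columns.
#' @export
cohort_heterogeneity <- function(cases, K = 50, distances = c(3, 5, 7),
                                 settings = extraction_settings(),
                                 compactness = 0.1, seed = 20406,
                                 progress = FALSE) {
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    hv <- case_heterogeneity(cs$stack, cs$mask, K = K, distances = distances,
                             settings = settings, compactness = compactness,
                             seed = seed)
    rows[[i]] <- tibble::as_tibble(c(
      list(case_id = cs$stack$case_id), as.list(hv)))
    if (progress) message(sprintf("case %d/%d done", i, length(cases)))
  }
  dplyr::bind_rows(rows)
}

#' Heterogeneity vector for a single case from stack + tumor mask
#'
#' @inheritParams cohort_heterogeneity
#' @param stack A [volume_stack].
#' @param tumor Logical tumor mask.
#' @return Named numeric vector of length 1712.
#' @export
case_heterogeneity <- function(stack, tumor, K = 50, distances = c(3, 5, 7),
                               settings = extraction_settings(),
                               compactness = 0.1, seed = 20406) {
  regions <- make_peritumoral_bands(tumor, stack$spacing, distances)
  tables <- list()
  reg_masks <- c(list(ITH = regions$tumor),
                 setNames(lapply(distances, function(d) regions[[paste0("peri", d)]]),
                          paste0("Peri", distances)))
  for (reg in names(reg_masks)) {
    hm <- encode_habitats(stack, reg_masks[[reg]], K = K,
                          compactness = compactness, seed = seed,
                          region_name = reg)
    tables[[reg]] <- extract_per_habitat(stack, hm, settings)
  }
  heterogeneity_vector(tables, case_id = stack$case_id)
}
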