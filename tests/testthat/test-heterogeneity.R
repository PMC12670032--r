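# Coefficient-of-variation heterogeneity: hand values, invariances, the
# 1712-entry bookkeeping, and ICC stability machinery.

test_that("cv matches hand arithmetic and its guards", {
  expect_equal(cv(c(1, 2, 3)), 0.5)         # sample SD 1, mean 2
  expect_equal(cv(c(7, 7, 7)), 0)
  expect_equal(cv(c(2, 4, 6)), cv(c(1, 2, 3)))       # scale invariance
  expect_equal(cv(c(3, 1, 2)), cv(c(1, 2, 3)))       # order-free
  expect_equal(cv(-c(1, 2, 3)), 0.5)                 # |mean| convention
  expect_true(is.na(cv(c(1))))                       # < 2 values
  expect_true(is.na(cv(c(NA, 5, NA))))               # pairwise exclusion
  expect_equal(cv(c(NA, 1, 2, 3)), 0.5)
  expect_true(is.na(cv(c(-1, 1))))                   # near-zero mean guard
})

make_region_tables <- function(tab) {
  list(ITH = tab, Peri3 = tab, Peri5 = tab, Peri7 = tab)
}

test_that("the heterogeneity vector has exactly 1712 unique names", {
  set.seed(1)
  cols <- paste0(rep(c("T2", "PRE", "AP", "HBP"), each = 107), "_",
                 feature_manifest())
  tab <- tibble::as_tibble(matrix(rexp(5 * 428) + 1, 5, 428,
                                  dimnames = list(NULL, cols)))
  tab <- dplyr::bind_cols(tibble::tibble(habitat = 1:5), tab)
  hv <- heterogeneity_vector(make_region_tables(tab))
  expect_length(hv, 1712)
  expect_false(anyDuplicated(names(hv)) > 0)
  expect_true(all(hv >= 0, na.rm = TRUE))
  expect_true(any(grepl("^ITH_AP_firstorder_", names(hv))))
  expect_true(any(grepl("^PTH_Peri5_AP_firstorder_", names(hv))))

  # identical habitat rows -> complete homogeneity
  tab0 <- tab
  tab0[, -1] <- tab0[rep(1, 5), -1]
  hv0 <- heterogeneity_vector(make_region_tables(tab0))
  expect_true(all(abs(hv0) < 1e-12, na.rm = TRUE))

  # permuting habitat rows changes nothing
  hvp <- heterogeneity_vector(make_region_tables(tab[c(3, 1, 5, 2, 4), ]))
  expect_equal(hv, hvp, ignore_attr = TRUE)

  expect_error(heterogeneity_vector(list(ITH = tab)), "Peri3")
})

test_that("vector length is 1712 regardless of habitat count", {
  cs <- generate_case(tiny_spec(), 1L, seed = 21)
  hv5 <- case_heterogeneity(cs$stack, cs$mask, K = 5)
  hv9 <- case_heterogeneity(cs$stack, cs$mask, K = 9)
  expect_length(hv5, 1712)
  expect_length(hv9, 1712)
  expect_identical(names(hv5), names(hv9))
})

test_that("ICC(2,1) matches the ANOVA-table oracle", {
  m <- matrix(c(1, 2, 3, 4, 2, 3, 4, 6), 4, 2)
  expect_equal(icc21(m), aov_icc21(m), tolerance = 1e-12)

  set.seed(14)
  m2 <- matrix(rnorm(30), 10, 3)
  expect_equal(icc21(m2), aov_icc21(m2), tolerance = 1e-10)

  # perfect agreement
  base <- rnorm(8)
  expect_equal(icc21(cbind(base, base, base)), 1)

  # independently re-randomized raters: near-zero agreement at n=50
  set.seed(15)
  shuf <- replicate(4, rnorm(50))
  expect_lt(abs(icc21(shuf)), 0.2)
})

test_that("stability analysis recomputes features across K settings", {
  cases <- lapply(1:5, function(i) generate_case(tiny_spec(), i %% 2, seed = 40 + i))
  feats <- c("ITH_AP_firstorder_Mean", "ITH_T2_firstorder_Variance",
             "PTH_Peri5_AP_firstorder_Mean")
  st <- stability_analysis(cases, K_list = c(4, 6), features = feats)
  expect_equal(st$feature, feats)
  expect_true(all(is.na(st$icc) | (st$icc >= -1 & st$icc <= 1 + 1e-9)))
  expect_error(stability_analysis(cases, K_list = 5), "two K")
  expect_error(stability_analysis(cases[1:2], K_list = c(4, 6)), "five cases")
})
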