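# Radiomic feature extraction: manifest bookkeeping, hand-computed
# first-order values, brute-force texture-matrix oracles, degenerate ROIs.

test_that("the manifest defines 107 uniquely named features in 7 classes", {
  fm <- feature_manifest()
  expect_length(fm, 107)
  expect_false(anyDuplicated(fm) > 0)
  counts <- vapply(habheter:::FEATURE_MANIFEST, length, integer(1))
  expect_equal(unname(counts[c("firstorder", "shape", "glcm", "glrlm",
                               "glszm", "gldm", "ngtdm")]),
               c(18L, 14L, 24L, 16L, 16L, 14L, 5L))
})

test_that("first-order statistics match hand arithmetic", {
  v <- array(c(1, 1, 2, 3), c(2, 2, 1))
  roi <- array(TRUE, c(2, 2, 1))
  f <- extract_features(v, roi, c(1, 1, 1))
  expect_length(f, 107)
  expect_equal(f[["firstorder_Mean"]], 1.75)
  expect_equal(f[["firstorder_Energy"]], 15)
  expect_equal(f[["firstorder_Range"]], 2)
  expect_equal(f[["firstorder_RootMeanSquared"]], sqrt(15 / 4))

  const <- extract_features(array(5, c(3, 3, 2)), array(TRUE, c(3, 3, 2)),
                            c(1, 1, 1))
  expect_equal(const[["firstorder_Variance"]], 0)
  expect_equal(const[["firstorder_Range"]], 0)
  expect_true(is.na(const[["firstorder_Skewness"]]))
})

test_that("degenerate ROIs yield missing texture, never silent zeros", {
  v <- array(rnorm(64), c(4, 4, 4))
  roi <- array(FALSE, c(4, 4, 4)); roi[1, 1, 1] <- TRUE
  f <- extract_features(v, roi, c(1, 1, 3))
  expect_true(all(is.na(f[grep("^(glcm|glrlm|glszm|gldm|ngtdm)_", names(f))])))
  expect_equal(f[["firstorder_Mean"]], v[1, 1, 1])
  expect_equal(f[["firstorder_Variance"]], 0)

  expect_error(extract_features(v, array(FALSE, c(4, 4, 4)), c(1, 1, 3)),
               "empty")
})

test_that("texture matrices agree with brute-force loops", {
  set.seed(42)
  d <- c(5, 4, 3)
  lev <- array(sample(0:3, prod(d), replace = TRUE), d)
  ng <- 3L
  expect_equal(unclass(habheter:::cpp_glcm(as.integer(lev), d, ng)),
               unclass(bf_glcm(lev, ng)), ignore_attr = TRUE)
  expect_equal(unclass(habheter:::cpp_gldm(as.integer(lev), d, ng, 0L)),
               unclass(bf_gldm(lev, ng, 0)), ignore_attr = TRUE)

  # run lengths on a constant 6-voxel line: the x direction sees one run of
  # length 6; each of the other 12 directions sees six runs of length 1
  line <- array(0L, c(6, 1, 1)); line[, 1, 1] <- 1L
  P <- habheter:::cpp_glrlm(as.integer(line), c(6L, 1L, 1L), 1L)
  expect_equal(P[1, 6], 1)
  expect_equal(P[1, 1], 72)
  expect_equal(sum(P), 73)

  # size zones: two separate plateaus of the same level
  zlev <- array(0L, c(7, 1, 1)); zlev[1:2, 1, 1] <- 1L; zlev[5:7, 1, 1] <- 1L
  zones <- habheter:::cpp_glszm_zones(as.integer(zlev), c(7L, 1L, 1L))
  expect_equal(sort(zones[, 2]), c(2, 3))

  # NGTDM on a 1D ramp: middle voxels see symmetric neighbours
  rlev <- array(0L, c(3, 1, 1)); rlev[, 1, 1] <- c(1L, 2L, 3L)
  M <- habheter:::cpp_ngtdm(as.integer(rlev), c(3L, 1L, 1L), 3L)
  expect_equal(M[, 1], c(1, 1, 1))
  expect_equal(M[, 2], c(abs(1 - 2), abs(2 - 2), abs(3 - 2)))
})

test_that("extraction is deterministic and translation-invariant", {
  set.seed(9)
  d <- c(12, 12, 6)
  v <- array(rnorm(prod(d)), d)
  roi <- array(FALSE, d); roi[3:6, 3:6, 2:3] <- TRUE
  f1 <- extract_features(v, roi, c(1, 1, 3))
  f2 <- extract_features(v, roi, c(1, 1, 3))
  expect_identical(f1, f2)

  # translate ROI and content by the same offset
  v2 <- array(0, d); roi2 <- array(FALSE, d)
  v2[6:9, 5:8, 3:4] <- v[3:6, 3:6, 2:3]
  roi2[6:9, 5:8, 3:4] <- TRUE
  f3 <- extract_features(v2, roi2, c(1, 1, 3))
  nonshape <- grep("^shape_", names(f1), invert = TRUE)
  expect_equal(f1[nonshape], f3[nonshape], tolerance = 1e-12)
})

test_that("intensity rescaling acts as expected on first-order features", {
  set.seed(10)
  v <- array(rnorm(200), c(10, 10, 2))
  roi <- array(TRUE, c(10, 10, 2))
  f1 <- extract_features(v, roi, c(1, 1, 3), classes = "firstorder")
  f2 <- extract_features(2 * v, roi, c(1, 1, 3), classes = "firstorder")
  expect_equal(f2[["firstorder_Mean"]], 2 * f1[["firstorder_Mean"]])
  expect_equal(f2[["firstorder_Energy"]], 4 * f1[["firstorder_Energy"]])
  expect_equal(f2[["firstorder_Variance"]], 4 * f1[["firstorder_Variance"]])
})

test_that("per-habitat tables have 428 columns with shared shape block", {
  cs <- generate_case(tiny_spec(), 0L, seed = 5)
  hm <- encode_habitats(cs$stack, cs$mask, K = 6)
  tab <- extract_per_habitat(cs$stack, hm)
  expect_equal(dim(tab), c(6L, 429L))  # habitat id + 428 features
  expect_equal(sum(grepl("^(T2|PRE|AP|HBP)_", names(tab))), 428)
  # geometry is sequence-independent
  for (feat in c("shape_MeshVolume", "shape_SurfaceArea", "shape_Flatness")) {
    expect_identical(tab[[paste0("T2_", feat)]], tab[[paste0("AP_", feat)]])
    expect_identical(tab[[paste0("PRE_", feat)]], tab[[paste0("HBP_", feat)]])
  }
})

test_that("a single habitat reproduces whole-region extraction", {
  cs <- generate_case(tiny_spec(), 0L, seed = 6)
  wt <- extract_whole_tumor(cs$stack, cs$mask)
  expect_length(wt, 428)
  tab <- extract_per_habitat(cs$stack, cs$mask)  # mask treated as 1 habitat
  expect_equal(unlist(tab[1, -1]), wt, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("tiny habitats flag texture as missing but keep first order", {
  st <- constant_stack(value = 0)
  set.seed(2)
  st$volumes$AP[] <- rnorm(length(st$volumes$AP))
  roi <- array(FALSE, c(32, 32, 12)); roi[5:6, 5, 5] <- TRUE  # 2 voxels
  f <- extract_features(st$volumes$AP, roi, c(1, 1, 3))
  expect_true(all(is.na(f[grep("^glcm_", names(f))])))
  expect_false(is.na(f[["firstorder_Mean"]]))
})
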