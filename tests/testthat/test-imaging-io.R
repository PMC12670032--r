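# NIfTI round-trips, grid resampling and intensity normalization.

test_that("a written case round-trips through NIfTI and load_case", {
  dir <- withr::local_tempdir()
  d <- c(16, 16, 8)
  set.seed(7)
  arrs <- setNames(lapply(1:4, function(i) array(rnorm(prod(d)), d)),
                   c("T2", "PRE", "AP", "HBP"))
  mask <- array(FALSE, d); mask[6:11, 6:11, 3:6] <- TRUE
  paths <- vapply(names(arrs), function(s) {
    p <- file.path(dir, paste0(s, ".nii.gz"))
    write_volume(arrs[[s]], p, c(1, 1, 3)); p
  }, character(1))
  mp <- file.path(dir, "mask.nii.gz")
  write_volume(mask, mp, c(1, 1, 3))

  lc <- load_case(paths, mp, normalize = FALSE)
  expect_s3_class(lc$stack, "volume_stack")
  expect_named(lc$stack$volumes, c("T2", "PRE", "AP", "HBP"))
  for (s in names(arrs)) {
    expect_equal(lc$stack$volumes[[s]], arrs[[s]], tolerance = 1e-6)
  }
  expect_identical(lc$mask, mask)
})

test_that("load_case rejects missing sequences and empty masks", {
  dir <- withr::local_tempdir()
  d <- c(8, 8, 4)
  p <- file.path(dir, "vol.nii.gz")
  write_volume(array(0, d), p, c(1, 1, 3))
  mp <- file.path(dir, "mask.nii.gz")
  write_volume(array(FALSE, d), mp, c(1, 1, 3))
  expect_error(load_case(c(T2 = p, PRE = p, AP = p), mp),
               "missing sequence.*HBP")
  expect_error(load_case(c(T2 = p, PRE = p, AP = p, HBP = p), mp,
                         normalize = FALSE),
               "empty mask")
})

test_that("resampling follows spacing arithmetic and preserves value sets", {
  v <- array(rnorm(1000), c(10, 10, 10))
  out <- resample_volume(v, spacing = c(2, 2, 3), target_spacing = c(1, 1, 3))
  expect_identical(dim(out), c(20L, 20L, 10L))

  # already on target: identity
  expect_identical(resample_volume(v, c(1, 1, 3), c(1, 1, 3)), v)

  # nearest keeps masks binary
  m <- array(sample(c(0, 1), 500, replace = TRUE), c(10, 10, 5))
  mr <- resample_volume(m, c(2, 2, 6), c(1, 1, 3), method = "nearest")
  expect_true(all(mr %in% c(0, 1)))

  # idempotence on the target grid
  r1 <- resample_volume(v, c(1.7, 1.7, 4), c(1, 1, 3))
  r2 <- resample_volume(r1, c(1, 1, 3), c(1, 1, 3))
  expect_equal(r1, r2, tolerance = 1e-5)

  expect_error(resample_volume(v, c(0, 1, 3)), "spacing")
})

test_that("normalization gives z-scores and is affine-invariant", {
  set.seed(11)
  v <- array(rnorm(400, mean = 12, sd = 7), c(10, 10, 4))
  nv <- normalize_volume(v)
  expect_equal(mean(nv), 0, tolerance = 1e-6)
  expect_equal(sd(nv), 1, tolerance = 1e-6)

  expect_equal(normalize_volume(3 * v + 11), nv, tolerance = 1e-10)

  expect_equal(as.vector(normalize_volume(array(c(3, 5, 7), c(3, 1, 1)))),
               c(-1, 0, 1))

  expect_error(normalize_volume(array(5, c(4, 4, 2))), "constant volume")
})
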