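# Peritumoral band construction against a brute-force physical-distance
# oracle, plus nesting/monotonicity properties.

test_that("bands equal the brute-force anisotropic distance transform", {
  sp <- c(1, 1, 3)
  set.seed(3)
  for (rep in 1:3) {
    d <- c(20, 20, 8)
    tumor <- array(FALSE, d)
    ctr <- cbind(sample(6:14, 3), sample(6:14, 3), sample(3:6, 3))
    for (k in 1:3) tumor[ctr[k, 1] + (-1:1), ctr[k, 2] + (-1:1), ctr[k, 3]] <- TRUE
    bands <- suppressWarnings(make_peritumoral_bands(tumor, sp, c(3, 5, 7)))
    bf <- bf_distance_map(tumor, sp)
    for (dd in c(3, 5, 7)) {
      expect_identical(bands[[paste0("peri", dd)]],
                       (bf <= dd + 1e-9) & !tumor,
                       label = sprintf("rep %d band %d", rep, dd))
    }
  }
})

test_that("a single-voxel tumor gives the analytic anisotropic ball", {
  d <- c(15, 15, 9)
  tumor <- array(FALSE, d); tumor[8, 8, 5] <- TRUE
  bands <- make_peritumoral_bands(tumor, c(1, 1, 3), 3)
  bf <- bf_distance_map(tumor, c(1, 1, 3))
  expect_identical(bands$peri3, (bf <= 3 + 1e-9) & !tumor)
  # 3 mm with 3 mm slices: one slice up/down plus the in-plane disc
  expect_equal(sum(bands$peri3), sum(bf <= 3 + 1e-9) - 1)
})

test_that("bands nest, grow monotonically and exclude the tumor", {
  tumor <- ellipsoid_region(semi = c(6, 6, 6))
  bands <- make_peritumoral_bands(tumor, c(1, 1, 3), c(3, 5, 7))
  expect_true(all(!(bands$peri3 & tumor)))
  expect_true(all(bands$peri5[bands$peri3]))
  expect_true(all(bands$peri7[bands$peri5]))
  counts <- c(sum(bands$peri3), sum(bands$peri5), sum(bands$peri7))
  expect_true(all(diff(counts) >= 0))
})

test_that("zero distance yields an empty band and borders warn", {
  d <- c(12, 12, 6)
  tumor <- array(FALSE, d); tumor[6, 6, 3] <- TRUE
  bands <- make_peritumoral_bands(tumor, c(1, 1, 3), 0)
  expect_equal(sum(bands$peri0), 0)

  border <- array(FALSE, d); border[1, 6, 3] <- TRUE
  expect_warning(make_peritumoral_bands(border, c(1, 1, 3), 3), "border")

  expect_error(make_peritumoral_bands(array(FALSE, d), c(1, 1, 3), 3),
               "empty")
})
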