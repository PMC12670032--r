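# Masked SLIC habitat encoding: exact-count guarantee, compact tiling,
# determinism.

test_that("K is capped at the region voxel count", {
  st <- constant_stack()
  reg <- array(FALSE, c(32, 32, 12))
  reg[10:14, 10:13, 5:6] <- TRUE  # 40 voxels
  hm <- encode_habitats(st, reg, K = 50)
  expect_equal(hm$K_eff, 40)
  expect_equal(sort(unique(hm$labels[hm$labels > 0])), 1:40)
  expect_true(all(habitat_sizes(hm) == 1))
})

test_that("a homogeneous region tiles into compact near-equal habitats", {
  st <- constant_stack()
  reg <- ellipsoid_region(semi = c(10, 10, 12))
  hm <- encode_habitats(st, reg, K = 8)
  sz <- habitat_sizes(hm)
  expect_length(sz, 8)
  expect_true(all(sz > 0))
  expect_lt(max(sz) / min(sz), 3)
})

test_that("the habitat count equals K across the studied K settings", {
  st <- constant_stack()
  reg <- ellipsoid_region(semi = c(10, 10, 12))
  for (K in c(30, 40, 50, 60, 70)) {
    hm <- encode_habitats(st, reg, K = K)
    expect_equal(hm$K_eff, K)
    sz <- habitat_sizes(hm)
    expect_length(sz, K)
    expect_true(all(sz > 0))
    # label support is exactly the region; ids consecutive from 1
    expect_identical(hm$labels > 0, reg)
    expect_identical(sort(unique(as.vector(hm$labels[hm$labels > 0]))), 1:K)
  }
})

test_that("habitats are connected components", {
  st <- constant_stack()
  reg <- ellipsoid_region(semi = c(9, 9, 10))
  hm <- encode_habitats(st, reg, K = 25)
  comps <- habheter:::cpp_label_components(as.integer(hm$labels), dim(hm$labels))
  expect_equal(max(comps), 25)
})

test_that("encoding is deterministic and input errors are caught", {
  cs <- generate_case(tiny_spec(), 1L, seed = 77)
  h1 <- encode_habitats(cs$stack, cs$mask, K = 12)
  h2 <- encode_habitats(cs$stack, cs$mask, K = 12)
  expect_identical(h1$labels, h2$labels)

  expect_error(encode_habitats(cs$stack, cs$mask, K = 0), "K")
  expect_error(encode_habitats(cs$stack, array(FALSE, dim(cs$mask)), K = 5),
               "empty")
})
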