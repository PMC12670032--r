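# Habitat encoding: masked multichannel SLIC supervoxels with an exact
# cluster-count guarantee.

#' Encode a region into K habitats
#'
#' Runs a masked SLIC supervoxel clustering on the four normalized sequence
#' channels, with the spatial term measured in physical mm (so the 3 mm slice
#' spacing is honoured), then enforces exactly `K_eff = min(K, n_voxels)`
#' connected, nonempty habitats by deterministic merge-smallest /
#' split-largest post-processing. Habitat ids are consecutive from 1, ordered
#' by each habitat's first voxel in array order; voxels outside the region
#' are labelled 0.
#'
#' Cluster seeds are placed by deterministic farthest-point sampling in
#' physical space, so the encoding is reproducible run-to-run; `seed` is kept
#' in the interface for forward compatibility and recorded in the result.
#'
#' @param stack A [volume_stack] of normalized sequences.
#' @param region Logical 3D region mask (tumor or a peritumoral band).
#' @param K Requested habitat count (default 50).
#' @param compactness SLIC compactness weight on z-scored channels
#'   (default 0.1).
#' @param seed Seed recorded with the encoding (default 20406).
#' @param iters SLIC iterations (default 10).
#' @param region_name Label stored with the map (e.g. `"ITH"`, `"Peri5"`).
#' @return An object of class `habitat_map`: list with `labels` (integer 3D
#'   array), `region_name`, `K_requested`, `K_eff`, `spacing`, `seed`.
#' @export
encode_habitats <- function(stack, region, K = 50, compactness = 0.1,
                            seed = 20406, iters = 10, region_name = "ITH") {
  if (K < 1) stopf("K must be >= 1")
  check_same_dim(region, stack$volumes[[1]], "region mask and stack")
  idx <- which(region)
  n <- length(idx)
  if (n < 1) stopf("region is empty")
  K_eff <- min(K, n)
  d <- stack$dim
  spacing <- stack$spacing
  labels <- array(0L, d)

  if (K_eff == n) {
    labels[idx] <- seq_len(n)
    return(new_habitat_map(labels, region_name, K, K_eff, spacing, seed))
  }

  xyz <- voxel_coords_mm(idx, d, spacing)
  S <- (n * prod(spacing) / K_eff)^(1 / 3)

  seeds <- farthest_point_seeds(xyz, K_eff)
  chan <- do.call(cbind, lapply(stack$volumes, as.vector))
  centers <- cbind(chan[idx[seeds], , drop = FALSE], xyz[seeds, , drop = FALSE])

  res <- cpp_slic_assign(chan, as.logical(region), d, spacing, centers,
                         S, compactness, as.integer(iters))
  labels[idx] <- res$labels[idx]
  labels <- enforce_habitat_count(labels, region, K_eff, chan, d, spacing)
  new_habitat_map(labels, region_name, K, K_eff, spacing, seed)
}

new_habitat_map <- function(labels, region_name, K, K_eff, spacing, seed) {
  structure(list(labels = labels, region_name = region_name,
                 K_requested = K, K_eff = K_eff, spacing = spacing,
                 seed = seed),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  sz <- tabulate(x$labels[x$labels > 0], nbins = x$K_eff)
  cat(sprintf("<habitat_map> %s: K=%d (requested %d), sizes %d-%d voxels\n",
              x$region_name, x$K_eff, x$K_requested, min(sz), max(sz)))
  invisible(x)
}

# Deterministic farthest-point sampling: start at the point nearest the
# centroid, greedily add the point with maximal distance to the chosen set.
farthest_point_seeds <- function(xyz, K) {
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  d0 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
  sel <- integer(K)
  sel[1] <- which.min(d0)
  mind <- (xyz[, 1] - xyz[sel[1], 1])^2 + (xyz[, 2] - xyz[sel[1], 2])^2 +
    (xyz[, 3] - xyz[sel[1], 3])^2
  if (K > 1) {
    for (k in 2:K) {
      sel[k] <- which.max(mind)
      dd <- (xyz[, 1] - xyz[sel[k], 1])^2 + (xyz[, 2] - xyz[sel[k], 2])^2 +
        (xyz[, 3] - xyz[sel[k], 3])^2
      mind <- pmin(mind, dd)
    }
  }
  sel
}

# Enforce exactly K connected nonempty clusters: relabel connected
# components, fold the smallest into its best face-adjacent neighbour (C++
# union-find pass) while too many, and split the largest (peeling its voxel
# farthest from the component centroid) while too few. Errors if the count
# cannot be reached in bounded iterations.
enforce_habitat_count <- function(labels, region, K, chan, d, spacing,
                                  max_iter = 1000) {
  comp <- array(cpp_label_components(as.integer(labels), d), d)
  for (iter in seq_len(max_iter)) {
    comp <- array(cpp_merge_to_k(as.integer(comp), d, as.integer(K)), d)
    ncomp <- max(comp)
    if (ncomp == K) break
    if (ncomp > K) {
      stopf("habitat count enforcement stuck: %d disconnected pieces for K=%d",
            ncomp, K)
    }
    # too few: split the largest component by peeling its farthest voxel
    sizes <- tabulate(comp[comp > 0], nbins = ncomp)
    big <- which.max(sizes)
    vi <- which(comp == big)
    if (length(vi) < 2) stopf("cannot split further to reach K=%d habitats", K)
    xyz <- voxel_coords_mm(vi, d, spacing)
    ctr <- colMeans(xyz)
    far <- which.max((xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
                       (xyz[, 3] - ctr[3])^2)
    comp[vi[far]] <- ncomp + 1L
    comp <- array(cpp_label_components(as.integer(comp), d), d)
  }
  ncomp <- max(comp)
  if (ncomp != K) {
    stopf("habitat count enforcement did not converge: %d vs K=%d", ncomp, K)
  }
  comp
}

#' Habitat sizes in voxels
#'
#' @param hmap A `habitat_map`.
#' @return Integer vector of length `K_eff`.
#' @export
habitat_sizes <- function(hmap) {
  tabulate(hmap$labels[hmap$labels > 0], nbins = hmap$K_eff)
}

#' Write a habitat map as a NIfTI label volume
#'
#' @param hmap A `habitat_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_habitat_map <- function(hmap, path) {
  write_volume(hmap$labels, path, hmap$spacing)
}
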