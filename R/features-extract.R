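# Extraction drivers: one ROI/sequence -> 107 features; habitat maps and
# whole tumors -> 428-column tables (107 x 4 sequences).

#' Extraction settings
#'
#' @param bin_width Fixed discretisation bin width on (z-scored) intensities,
#'   default 0.1.
#' @param gldm_alpha GLDM dependence tolerance in grey levels, default 0.
#' @param min_texture_voxels ROIs smaller than this get `NA` for all texture
#'   classes (default 3; texture is undefined on degenerate ROIs).
#' @return List of settings.
#' @export
extraction_settings <- function(bin_width = 0.1, gldm_alpha = 0,
                                min_texture_voxels = 3) {
  list(bin_width = bin_width, gldm_alpha = gldm_alpha,
       min_texture_voxels = min_texture_voxels)
}

# Crop an ROI's bounding box out of a volume; returns list(vals, lev, dim).
crop_roi <- function(volume, roi) {
  idx <- which(roi, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  sub_v <- volume[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                  rng[1, 3]:rng[2, 3], drop = FALSE]
  sub_m <- roi[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
               rng[1, 3]:rng[2, 3], drop = FALSE]
  list(v = sub_v, m = sub_m)
}

#' Extract the 107-feature radiomic set for one ROI on one sequence
#'
#' First-order statistics are computed on the raw (typically z-scored)
#' intensities; shape from the mask geometry; the five texture classes on
#' grey levels discretised at fixed bin width, with matrices accumulated
#' over the 13 unique 3D directions. On ROIs smaller than
#' `settings$min_texture_voxels`, texture values (and moment ratios that are
#' undefined on constant data) are returned as `NA`, never silently zero.
#'
#' @param volume 3D intensity array (one sequence).
#' @param roi Logical ROI mask, congruent with `volume`, nonempty.
#' @param spacing Voxel spacing mm.
#' @param settings From [extraction_settings()].
#' @param classes Feature classes to compute (default all 7).
#' @return Named numeric vector, names `{class}_{feature}` (107 for all
#'   classes).
#' @export
extract_features <- function(volume, roi, spacing,
                             settings = extraction_settings(),
                             classes = names(FEATURE_MANIFEST)) {
  check_same_dim(volume, roi, "volume and roi")
  n <- sum(roi)
  if (n < 1) stopf("ROI is empty")
  out <- numeric(0)
  cr <- crop_roi(volume, roi)
  x <- cr$v[cr$m]
  texture_ok <- n >= settings$min_texture_voxels

  lev <- array(0L, dim(cr$m))
  ng <- 1L
  if (texture_ok && any(c("glcm", "glrlm", "glszm", "gldm", "ngtdm") %in% classes)) {
    lev[cr$m] <- discretize_roi(x, settings$bin_width)
    ng <- max(lev)
  }
  dims <- dim(lev)

  for (cl in classes) {
    vals <- switch(cl,
      firstorder = fo_features(x, prod(spacing), settings$bin_width),
      shape = shape_features(cr$m, spacing),
      glcm = if (texture_ok) glcm_features(cpp_glcm(as.integer(lev), dims, ng))
             else setNames(rep(NA_real_, 24), FEATURE_MANIFEST$glcm),
      glrlm = if (texture_ok) glrlm_features(cpp_glrlm(as.integer(lev), dims, ng), n)
              else setNames(rep(NA_real_, 16), FEATURE_MANIFEST$glrlm),
      glszm = if (texture_ok) glszm_features(cpp_glszm_zones(as.integer(lev), dims), n)
              else setNames(rep(NA_real_, 16), FEATURE_MANIFEST$glszm),
      gldm = if (texture_ok)
               gldm_features(cpp_gldm(as.integer(lev), dims, ng, settings$gldm_alpha))
             else setNames(rep(NA_real_, 14), FEATURE_MANIFEST$gldm),
      ngtdm = if (texture_ok) ngtdm_features(cpp_ngtdm(as.integer(lev), dims, ng), n)
              else setNames(rep(NA_real_, 5), FEATURE_MANIFEST$ngtdm),
      stopf("unknown feature class %s", cl))
    names(vals) <- paste0(cl, "_", FEATURE_MANIFEST[[cl]])
    out <- c(out, vals)
  }
  out
}

#' Extract per-habitat feature table (428 columns)
#'
#' One row per habitat; columns `{sequence}_{class}_{feature}` for the four
#' sequences. Shape features are computed once per habitat mask and
#' replicated across sequences (geometry is sequence-independent).
#'
#' @param stack A [volume_stack].
#' @param hmap A `habitat_map` (or a logical mask, treated as one habitat).
#' @param settings From [extraction_settings()].
#' @param classes Feature classes (default all 7).
#' @param sequences Sequences to extract (default all 4).
#' @return Tibble with `habitat` id column plus feature columns.
#' @export
extract_per_habitat <- function(stack, hmap, settings = extraction_settings(),
                                classes = names(FEATURE_MANIFEST),
                                sequences = SEQ_NAMES) {
  if (inherits(hmap, "habitat_map")) {
    labels <- hmap$labels
    K <- hmap$K_eff
  } else {
    labels <- array(0L, dim(hmap)); labels[hmap] <- 1L
    K <- 1L
  }
  spacing <- stack$spacing
  shape_in <- "shape" %in% classes
  other <- setdiff(classes, "shape")
  rows <- vector("list", K)
  for (h in seq_len(K)) {
    roi <- labels == h
    row <- c(habitat = h)
    shp <- if (shape_in) {
      cr <- crop_roi(stack$volumes[[1]], roi)
      sv <- shape_features(cr$m, spacing)
      names(sv) <- paste0("shape_", FEATURE_MANIFEST$shape)
      sv
    } else NULL
    for (s in sequences) {
      vals <- if (length(other)) {
        extract_features(stack$volumes[[s]], roi, spacing, settings, other)
      } else numeric(0)
      if (shape_in) vals <- append_in_manifest_order(vals, shp, classes)
      names(vals) <- paste0(s, "_", names(vals))
      row <- c(row, vals)
    }
    rows[[h]] <- row
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# Reinsert the (shared) shape block so each sequence's columns follow the
# canonical manifest order.
append_in_manifest_order <- function(vals, shp, classes) {
  want <- feature_manifest(classes)
  all <- c(vals, shp)
  all[want[want %in% names(all)]]
}

#' Extract whole-tumor features (428 values, no habitat segmentation)
#'
#' The conventional radiomics baseline: the 107-feature set per sequence over
#' the entire tumor mask.
#'
#' @param stack A [volume_stack].
#' @param tumor Logical tumor mask.
#' @param settings From [extraction_settings()].
#' @return Named numeric vector of length 428, names
#'   `{sequence}_{class}_{feature}`.
#' @export
extract_whole_tumor <- function(stack, tumor, settings = extraction_settings()) {
  tab <- extract_per_habitat(stack, tumor, settings)
  v <- as.numeric(tab[1, -1])
  names(v) <- names(tab)[-1]
  v
}
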