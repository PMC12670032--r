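# Peritumoral band construction by anisotropic Euclidean distance.

#' Physical distance map to a mask (mm)
#'
#' Exact Euclidean distance from every voxel centre to the nearest foreground
#' voxel centre, honouring anisotropic spacing (separable squared-distance
#' transform). Foreground voxels have distance 0.
#'
#' @param mask Logical 3D array.
#' @param spacing Voxel spacing in mm.
#' @return Numeric 3D array of distances in mm.
#' @export
distance_map <- function(mask, spacing) {
  if (!any(mask)) stopf("distance_map: empty mask")
  d2 <- cpp_edt_sq(as.logical(mask), dim(mask), as.numeric(spacing))
  array(sqrt(d2), dim(mask))
}

#' Peritumoral band masks at fixed physical distances
#'
#' Each band at distance `d` is the set of voxels outside the tumor whose
#' Euclidean distance (mm, anisotropic) to the tumor is at most `d`:
#' cumulative 0-d shells, so bands nest (`peri3` within `peri5` within
#' `peri7`). Bands are clipped at the image bounds; a tumor touching the
#' border triggers a warning.
#'
#' @param tumor Logical 3D tumor mask (nonempty).
#' @param spacing Voxel spacing in mm.
#' @param distances Positive increasing distances in mm, default `c(3, 5, 7)`.
#' @return An object of class `region_mask_set`: list with `tumor`, one
#'   logical mask per band (named `peri3`, `peri5`, ...), `distances_mm` and
#'   `spacing`.
#' @export
make_peritumoral_bands <- function(tumor, spacing, distances = c(3, 5, 7)) {
  if (!any(tumor)) stopf("tumor mask is empty")
  if (any(distances < 0) || is.unsorted(distances, strictly = TRUE) && length(distances) > 1) {
    stopf("distances must be non-negative and strictly increasing")
  }
  d <- dim(tumor)
  border <- any(tumor[c(1, d[1]), , ]) || any(tumor[, c(1, d[2]), ]) ||
    any(tumor[, , c(1, d[3])])
  if (border) warnf("tumor touches the image border; peritumoral bands are clipped")
  dist <- distance_map(tumor, spacing)
  bands <- lapply(distances, function(dd) {
    b <- (dist <= dd + 1e-9) & !tumor
    b
  })
  names(bands) <- paste0("peri", distances)
  for (i in seq_along(bands)) {
    if (distances[i] > 0 && !any(bands[[i]])) {
      stopf("band peri%s is empty after clipping", distances[i])
    }
  }
  structure(c(list(tumor = tumor), bands,
              list(distances_mm = distances, spacing = as.numeric(spacing))),
            class = "region_mask_set")
}

#' @export
print.region_mask_set <- function(x, ...) {
  ns <- vapply(x[c("tumor", paste0("peri", x$distances_mm))], sum, numeric(1))
  cat("<region_mask_set>", paste(sprintf("%s=%d", names(ns), as.integer(ns)),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Write a region mask set as NIfTI files
#'
#' Writes `<prefix>_tumor.nii.gz` and `<prefix>_peri<d>.nii.gz` for each band.
#'
#' @param regions A `region_mask_set`.
#' @param prefix Output path prefix.
#' @return Character vector of paths written, invisibly.
#' @export
write_region_masks <- function(regions, prefix) {
  nm <- c("tumor", paste0("peri", regions$distances_mm))
  paths <- character(0)
  for (n in nm) {
    p <- paste0(prefix, "_", n, ".nii.gz")
    write_volume(regions[[n]], p, regions$spacing)
    paths <- c(paths, p)
  }
  invisible(paths)
}
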