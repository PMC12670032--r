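# NIfTI ingestion, grid checks, resampling and intensity normalization.

SEQ_NAMES <- c("T2", "PRE", "AP", "HBP")

#' Construct a multisequence volume stack
#'
#' Bundles the four co-registered sequences (T2-weighted, precontrast T1,
#' arterial phase, hepatobiliary phase) into a single object with shared grid
#' metadata. All four arrays must have identical dimensions; spacing is in mm.
#'
#' @param case_id Case identifier.
#' @param volumes Named list of 3D numeric arrays; names must be exactly
#'   `T2`, `PRE`, `AP`, `HBP`.
#' @param spacing Numeric length-3 voxel spacing `(dx, dy, dz)` in mm.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(case_id, volumes, spacing) {
  missing_seq <- setdiff(SEQ_NAMES, names(volumes))
  if (length(missing_seq) > 0) {
    stopf("missing sequence(s): %s", paste(missing_seq, collapse = ", "))
  }
  volumes <- volumes[SEQ_NAMES]
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("spacing must be three positive numbers")
  }
  d <- dim(volumes[[1]])
  if (length(d) != 3) stopf("volumes must be 3D arrays")
  for (s in SEQ_NAMES) check_same_dim(volumes[[s]], volumes[[1]], paste0("sequence ", s))
  structure(
    list(case_id = case_id, volumes = volumes, spacing = spacing, dim = d),
    class = "volume_stack"
  )
}

#' @export
print.volume_stack <- function(x, ...) {
  cat(sprintf("<volume_stack> case %s: %s voxels @ %s mm, sequences %s\n",
              x$case_id, paste(x$dim, collapse = "x"),
              paste(x$spacing, collapse = "x"),
              paste(names(x$volumes), collapse = "/")))
  invisible(x)
}

#' Load one case (four sequences plus tumor mask) from NIfTI files
#'
#' Reads the four sequence volumes and the binary tumor mask, checks grid
#' congruence (within tolerance), resamples everything to the reference
#' 1 x 1 x 3 mm grid (linear for images, nearest-neighbour for the mask) and
#' z-score normalizes each sequence.
#'
#' @param paths Named character vector/list of NIfTI paths with names
#'   `T2`, `PRE`, `AP`, `HBP`.
#' @param mask_path Path to the binary tumor mask NIfTI.
#' @param case_id Case identifier (default: basename of the mask).
#' @param target_spacing Reference spacing in mm, default `c(1, 1, 3)`.
#' @param normalize Z-score normalize each resampled sequence (default TRUE).
#' @param tol Grid-congruence tolerance in mm (default 1e-3).
#' @return List with elements `stack` (a [volume_stack]) and `mask` (logical
#'   3D array). The original spacing is kept in attribute `original_spacing`.
#' @export
load_case <- function(paths, mask_path, case_id = NULL,
                      target_spacing = c(1, 1, 3), normalize = TRUE,
                      tol = 1e-3) {
  paths <- as.list(paths)
  missing_seq <- setdiff(SEQ_NAMES, names(paths))
  if (length(missing_seq) > 0) {
    stopf("missing sequence(s): %s", paste(missing_seq, collapse = ", "))
  }
  for (p in c(unlist(paths[SEQ_NAMES]), mask_path)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  imgs <- lapply(paths[SEQ_NAMES], RNifti::readNifti)
  msk <- RNifti::readNifti(mask_path)
  sp <- lapply(imgs, function(im) RNifti::pixdim(im)[1:3])
  ref <- sp[[1]]
  for (s in SEQ_NAMES) {
    if (!identical(dim(imgs[[s]])[1:3], dim(imgs[[1]])[1:3])) {
      stopf("sequence %s grid differs in shape", s)
    }
    if (max(abs(sp[[s]] - ref)) > tol) {
      stopf("sequence %s spacing differs beyond tolerance %g mm", s, tol)
    }
  }
  if (!identical(dim(msk)[1:3], dim(imgs[[1]])[1:3])) {
    stopf("mask grid differs in shape from the image grid")
  }
  mask_arr <- array(as.vector(msk) > 0.5, dim(msk)[1:3])
  if (!any(mask_arr)) stopf("empty mask: no foreground voxels in %s", mask_path)

  vols <- lapply(imgs, function(im) array(as.vector(im), dim(im)[1:3]))
  rs <- lapply(vols, resample_volume, spacing = ref,
               target_spacing = target_spacing, method = "linear")
  mask_rs <- resample_volume(mask_arr * 1, spacing = ref,
                             target_spacing = target_spacing,
                             method = "nearest") > 0.5
  if (!any(mask_rs)) stopf("empty mask after resampling")
  if (normalize) rs <- lapply(rs, normalize_volume)
  st <- volume_stack(case_id %||% sub("\\.nii(\\.gz)?$", "", basename(mask_path)),
                     rs, target_spacing)
  attr(st, "original_spacing") <- ref
  list(stack = st, mask = mask_rs)
}

#' Write a 3D array as NIfTI with given voxel spacing
#'
#' @param arr 3D numeric or logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, path, spacing) {
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a 3D volume to a target voxel spacing
#'
#' Output grid dimensions are `round(dim * spacing / target_spacing)` (at
#' least 1), preserving the physical extent to within one voxel. Voxel
#' centres sit at `index * spacing` so a volume already on the target grid is
#' returned unchanged, and resampling is idempotent.
#'
#' @param vol 3D numeric array.
#' @param spacing Current spacing in mm.
#' @param target_spacing Target spacing in mm (default `c(1, 1, 3)`).
#' @param method `"linear"` (images) or `"nearest"` (masks/labels).
#' @return Resampled 3D array.
#' @export
resample_volume <- function(vol, spacing, target_spacing = c(1, 1, 3),
                            method = c("linear", "nearest")) {
  method <- match.arg(method)
  spacing <- as.numeric(spacing)
  target_spacing <- as.numeric(target_spacing)
  if (any(spacing <= 0) || any(target_spacing <= 0)) {
    stopf("non-positive spacing")
  }
  d <- dim(vol)
  if (all(abs(spacing - target_spacing) < 1e-12)) return(vol)
  nd <- pmax(1L, as.integer(round(d * spacing / target_spacing)))

  # coordinates of output voxel centres in input index units
  ux <- (seq_len(nd[1]) - 1) * target_spacing[1] / spacing[1]
  uy <- (seq_len(nd[2]) - 1) * target_spacing[2] / spacing[2]
  uz <- (seq_len(nd[3]) - 1) * target_spacing[3] / spacing[3]

  if (method == "nearest") {
    ix <- pmin(pmax(round(ux) + 1, 1), d[1])
    iy <- pmin(pmax(round(uy) + 1, 1), d[2])
    iz <- pmin(pmax(round(uz) + 1, 1), d[3])
    return(vol[ix, iy, iz, drop = FALSE])
  }

  # trilinear: clamp to the grid, separable gather of the 8 corners
  x0 <- pmin(pmax(floor(ux), 0), d[1] - 1); fx <- pmin(pmax(ux - x0, 0), 1)
  y0 <- pmin(pmax(floor(uy), 0), d[2] - 1); fy <- pmin(pmax(uy - y0, 0), 1)
  z0 <- pmin(pmax(floor(uz), 0), d[3] - 1); fz <- pmin(pmax(uz - z0, 0), 1)
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1); z1 <- pmin(z0 + 1, d[3] - 1)
  g <- function(ix, iy, iz) vol[cbind(rep(ix + 1, times = nd[2] * nd[3]),
                                      rep(rep(iy + 1, each = nd[1]), times = nd[3]),
                                      rep(iz + 1, each = nd[1] * nd[2]))]
  wx <- rep(fx, times = nd[2] * nd[3])
  wy <- rep(rep(fy, each = nd[1]), times = nd[3])
  wz <- rep(fz, each = nd[1] * nd[2])
  out <- g(x0, y0, z0) * (1 - wx) * (1 - wy) * (1 - wz) +
         g(x1, y0, z0) * wx       * (1 - wy) * (1 - wz) +
         g(x0, y1, z0) * (1 - wx) * wy       * (1 - wz) +
         g(x1, y1, z0) * wx       * wy       * (1 - wz) +
         g(x0, y0, z1) * (1 - wx) * (1 - wy) * wz +
         g(x1, y0, z1) * wx       * (1 - wy) * wz +
         g(x0, y1, z1) * (1 - wx) * wy       * wz +
         g(x1, y1, z1) * wx       * wy       * wz
  array(out, nd)
}

#' Z-score normalize a volume
#'
#' Subtracts the mean and divides by the sample SD computed over `scope`
#' (the whole volume by default), so the scoped voxels have mean 0 and SD 1.
#' Invariant to positive affine rescaling of the input.
#'
#' @param vol 3D numeric array.
#' @param scope Optional logical array selecting the voxels that define the
#'   statistics; default all voxels.
#' @return Normalized array.
#' @export
normalize_volume <- function(vol, scope = NULL) {
  v <- if (is.null(scope)) as.vector(vol) else vol[scope]
  if (length(v) < 2) stopf("normalization scope needs at least 2 voxels")
  s <- sd(v)
  if (!is.finite(s) || s == 0) stopf("constant volume: zero variance in scope")
  (vol - mean(v)) / s
}

#' Read a per-case YAML manifest
#'
#' The manifest maps case ids to per-sequence NIfTI paths and a mask path:
#' a top-level `cases` list whose entries have `case_id`, `mask` and a
#' `sequences` map with keys `T2`, `PRE`, `AP`, `HBP`. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest path.
#' @return Tibble with columns `case_id`, `T2`, `PRE`, `AP`, `HBP`, `mask`,
#'   and optionally `mask2` (second observer).
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  rows <- lapply(man$cases, function(cs) {
    out <- list(case_id = cs$case_id)
    for (s in SEQ_NAMES) out[[s]] <- resolve(cs$sequences[[s]])
    out$mask <- resolve(cs$mask)
    out$mask2 <- if (!is.null(cs$mask2)) resolve(cs$mask2) else NA_character_
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}
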