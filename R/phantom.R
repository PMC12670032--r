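# Synthetic multisequence phantom cohorts: ellipsoidal tumors with Gaussian
# random-field texture, class-linked intra-/peri-tumoral heterogeneity,
# observer-perturbed masks and Weibull survival times.

#' Phantom cohort specification
#'
#' Defines the simulation conditions for synthetic cases. Texture is a
#' Gaussian random field (GRF) with correlation length `corr_length_mm`;
#' high-heterogeneity (label 1) cases receive a larger texture variance in
#' the tumor and, more strongly, in the peritumoral band, plus more
#' large-scale subregion structure. Survival follows a Weibull
#' proportional-hazards model with a class log hazard ratio.
#'
#' @param shape Grid dimensions, default `c(64, 64, 24)`.
#' @param spacing Voxel spacing mm, default `c(1, 1, 3)`.
#' @param radius_range_mm In-plane tumor semi-axis range, default `c(8, 13)`.
#' @param corr_length_mm GRF correlation length, default 4.
#' @param sigma2_low Texture variance for the low-heterogeneity class,
#'   default 0.25.
#' @param sigma2_ratio High/low texture-variance ratio in the tumor, default
#'   1.5 (mild intratumoral class effect).
#' @param sigma2_ratio_peri High/low ratio in the peritumoral band, default 6:
#'   the class effect is deliberately much stronger peritumorally, mirroring
#'   cohorts in which peritumoral heterogeneity dominates the class signal.
#' @param subregion_contrast Length-2 weight of the long-range "subregion"
#'   field relative to the fine texture for the high and low class, default
#'   `c(1, 0.4)`: the high class is patchier (more habitat-like structure).
#' @param peri_gradient Amplitude of the peritumoral enhancement halo (an
#'   exponentially decaying intensity offset outside the tumor, 10 mm decay
#'   constant), default 1.
#' @param prevalence Fraction of label-1 cases, default 0.25.
#' @param weibull_shape,weibull_scale Baseline Weibull survival (months);
#'   defaults 1.3 and 60.
#' @param hr_os,hr_rfs Class hazard ratios for overall and recurrence-free
#'   survival, defaults 2.79 and 2.17.
#' @param censor_range_mo Administrative censoring window (months), default
#'   `c(24, 84)`.
#' @param jitter_mm Observer mask perturbation amplitude (mm), default 1.
#' @param seed Base seed, default 20406.
#' @return A `phantom_spec` object (list).
#' @export
phantom_spec <- function(shape = c(64, 64, 24), spacing = c(1, 1, 3),
                         radius_range_mm = c(8, 13), corr_length_mm = 4,
                         sigma2_low = 0.25, sigma2_ratio = 1.5,
                         sigma2_ratio_peri = 6,
                         subregion_contrast = c(1, 0.4), peri_gradient = 1,
                         prevalence = 0.25, weibull_shape = 1.3,
                         weibull_scale = 60, hr_os = 2.79, hr_rfs = 2.17,
                         censor_range_mo = c(24, 84), jitter_mm = 1,
                         seed = 20406) {
  if (prevalence <= 0 || prevalence >= 1) stopf("prevalence must be in (0,1)")
  if (sigma2_low <= 0) stopf("sigma2_low must be positive")
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               radius_range_mm = radius_range_mm,
               corr_length_mm = corr_length_mm, sigma2_low = sigma2_low,
               sigma2_ratio = sigma2_ratio,
               sigma2_ratio_peri = sigma2_ratio_peri,
               subregion_contrast = subregion_contrast,
               peri_gradient = peri_gradient, prevalence = prevalence,
               weibull_shape = weibull_shape, weibull_scale = weibull_scale,
               hr_os = hr_os, hr_rfs = hr_rfs,
               censor_range_mo = censor_range_mo, jitter_mm = jitter_mm,
               seed = seed)
  class(spec) <- "phantom_spec"
  spec
}

# Unit-variance Gaussian random field via FFT spectral smoothing of white
# noise with a Gaussian kernel of physical correlation length ell (mm).
grf3d <- function(dim, spacing, ell_mm) {
  w <- array(rnorm(prod(dim)), dim)
  ax <- function(n, sp) {
    f <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / (n * sp)
    if (n == 1) f <- 0
    f
  }
  fx <- ax(dim[1], spacing[1]); fy <- ax(dim[2], spacing[2]); fz <- ax(dim[3], spacing[3])
  k2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
  filt <- exp(-2 * (pi * ell_mm)^2 * k2)
  g <- Re(fft(fft(w) * filt, inverse = TRUE)) / prod(dim)
  s <- sd(g)
  if (s == 0) return(g)
  (g - mean(g)) / s
}

# Ellipsoid mask from semi-axes (mm) and centre (mm).
ellipsoid_mask <- function(dim, spacing, center_mm, semi_mm) {
  x <- (seq_len(dim[1]) - 1) * spacing[1]
  y <- (seq_len(dim[2]) - 1) * spacing[2]
  z <- (seq_len(dim[3]) - 1) * spacing[3]
  q <- outer(outer(((x - center_mm[1]) / semi_mm[1])^2,
                   ((y - center_mm[2]) / semi_mm[2])^2, "+"),
             ((z - center_mm[3]) / semi_mm[3])^2, "+")
  q <= 1
}

#' Generate one synthetic case
#'
#' Builds four co-registered sequence channels as distinct affine mixes of a
#' shared GRF texture plus channel-specific noise and tumor contrast;
#' heterogeneity (GRF amplitude and subregion structure) is scaled by class
#' inside the tumor and, more strongly, in the 0-7 mm peritumoral band.
#' Produces two observer mask variants (smooth perturbations of the true
#' boundary) and Weibull survival times with class-proportional hazards.
#'
#' @param spec A [phantom_spec].
#' @param class_label 0 (low heterogeneity) or 1 (high).
#' @param seed Per-case seed.
#' @param case_id Case identifier.
#' @return List with `stack` ([volume_stack] of normalized channels),
#'   `mask` (true tumor mask), `masks` (list of the two observer variants),
#'   `survival` (one-row tibble), `label`.
#' @export
generate_case <- function(spec, class_label, seed, case_id = sprintf("case%04d", seed)) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sp <- spec$spacing
  with_seed(seed, {
    rr <- spec$radius_range_mm
    semi <- c(runif(1, rr[1], rr[2]), runif(1, rr[1], rr[2]),
              runif(1, 0.6 * rr[1], 0.8 * rr[2]))
    ext <- d * sp
    if (any(2 * semi + 16 > ext)) stopf("tumor larger than volume allows")
    ctr <- ext / 2 + runif(3, -2, 2)
    tumor <- ellipsoid_mask(d, sp, ctr, semi)
    if (!any(tumor)) stopf("degenerate tumor")

    dist_out <- array(sqrt(cpp_edt_sq(as.logical(tumor), d, sp)), d)
    peri <- dist_out > 0 & dist_out <= 7

    s2t <- spec$sigma2_low * if (class_label == 1) spec$sigma2_ratio else 1
    s2p <- spec$sigma2_low * if (class_label == 1) spec$sigma2_ratio_peri else 1

    g_shared <- grf3d(d, sp, spec$corr_length_mm)       # fine texture
    g_blob <- grf3d(d, sp, 2.5 * spec$corr_length_mm)   # subregion structure
    blob_amp <- spec$subregion_contrast[if (class_label == 1) 1 else 2]

    # texture amplitude field; class effect stronger in the band
    amp <- array(0.15, d)                                # mild background texture
    amp[tumor] <- sqrt(s2t)
    amp[peri] <- sqrt(s2p) * (1 - dist_out[peri] / 7 * 0.3)
    tex <- amp * (g_shared + blob_amp * g_blob) / sqrt(1 + blob_amp^2)

    # smooth background anatomy + peritumoral enhancement halo
    bg <- 0.3 * grf3d(d, sp, 12)
    grad <- spec$peri_gradient * exp(-dist_out / 10)
    grad[tumor] <- 0

    contrast <- c(T2 = 1.0, PRE = -0.8, AP = 1.2, HBP = -1.0)
    mix <- c(T2 = 1.0, PRE = 0.8, AP = 1.2, HBP = 0.9)
    vols <- lapply(SEQ_NAMES, function(s) {
      # magnitude-MR-like noise: right-skewed at the voxel scale
      v <- bg + mix[[s]] * tex + grad * sign(contrast[[s]]) +
        0.15 * (array(rexp(prod(d)), d) - 1)
      v[tumor] <- v[tumor] + contrast[[s]]
      normalize_volume(v)
    })
    names(vols) <- SEQ_NAMES
    stack <- volume_stack(case_id, vols, sp)

    masks <- lapply(1:2, function(o) {
      if (spec$jitter_mm <= 0) return(tumor)
      jn <- grf3d(d, sp, 6) * spec$jitter_mm
      dist_in <- array(sqrt(cpp_edt_sq(as.logical(!tumor), d, sp)), d)
      sdist <- dist_out - dist_in  # signed distance: negative inside
      m <- sdist <= jn
      if (!any(m)) tumor else m
    })

    u_os <- runif(1); u_rfs <- runif(1)
    lp_os <- log(spec$hr_os) * class_label
    lp_rfs <- log(spec$hr_rfs) * class_label
    t_os <- spec$weibull_scale * (-log(u_os) / exp(lp_os))^(1 / spec$weibull_shape)
    t_rfs <- spec$weibull_scale * 0.8 *
      (-log(u_rfs) / exp(lp_rfs))^(1 / spec$weibull_shape)
    cens <- runif(1, spec$censor_range_mo[1], spec$censor_range_mo[2])
    surv <- tibble::tibble(
      case_id = case_id,
      time_os = min(t_os, cens), event_os = as.integer(t_os <= cens),
      time_rfs = min(t_rfs, cens), event_rfs = as.integer(t_rfs <= cens)
    )
    list(stack = stack, mask = tumor, masks = masks, survival = surv,
         label = as.integer(class_label))
  })
}

#' Generate a phantom cohort
#'
#' Label counts follow the spec prevalence deterministically
#' (`round(prevalence * n)` positives). Cases are generated with per-case
#' seeds derived from `spec$seed`. If `dir` is given, volumes and masks are
#' written as NIfTI with a YAML manifest in the layout [load_case] /
#' [read_manifest] consume; otherwise cases stay in memory.
#'
#' @param spec A [phantom_spec].
#' @param n_cases Number of cases.
#' @param dir Optional output directory.
#' @param keep_cases Keep generated cases in the returned list (default TRUE
#'   when `dir` is NULL).
#' @return List with `cohort` (tibble: case_id, label, survival columns),
#'   `cases` (list or NULL), `manifest` (path or NA).
#' @export
generate_cohort <- function(spec, n_cases, dir = NULL,
                            keep_cases = is.null(dir)) {
  n_pos <- round(spec$prevalence * n_cases)
  labels <- c(rep(1L, n_pos), rep(0L, n_cases - n_pos))
  # deterministic interleave so splits/subsets stay balanced-ish
  labels <- labels[with_seed(spec$seed, sample.int(n_cases))]
  cases <- vector("list", n_cases)
  rows <- vector("list", n_cases)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(cases = list())
  for (i in seq_len(n_cases)) {
    cid <- sprintf("case%04d", i)
    cs <- generate_case(spec, labels[i], seed = spec$seed + i, case_id = cid)
    rows[[i]] <- dplyr::mutate(cs$survival, label = cs$label)
    if (!is.null(dir)) {
      seq_paths <- list()
      for (s in SEQ_NAMES) {
        p <- file.path(dir, sprintf("%s_%s.nii.gz", cid, s))
        write_volume(cs$stack$volumes[[s]], p, spec$spacing)
        seq_paths[[s]] <- basename(p)
      }
      mp1 <- file.path(dir, sprintf("%s_mask.nii.gz", cid))
      mp2 <- file.path(dir, sprintf("%s_mask_obs2.nii.gz", cid))
      write_volume(cs$masks[[1]], mp1, spec$spacing)
      write_volume(cs$masks[[2]], mp2, spec$spacing)
      man$cases[[i]] <- list(case_id = cid, sequences = seq_paths,
                             mask = basename(mp1), mask2 = basename(mp2))
    }
    if (keep_cases) cases[[i]] <- cs
  }
  manifest <- NA_character_
  if (!is.null(dir)) {
    manifest <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(man, manifest)
  }
  list(cohort = dplyr::bind_rows(rows), cases = if (keep_cases) cases else NULL,
       manifest = manifest, spec = spec)
}
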