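# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Physical voxel-centre coordinates (mm) for linear indices into an array.
voxel_coords_mm <- function(idx, dim, spacing) {
  idx0 <- idx - 1L
  x <- idx0 %% dim[1]
  y <- (idx0 %/% dim[1]) %% dim[2]
  z <- idx0 %/% (dim[1] * dim[2])
  cbind(x * spacing[1], y * spacing[2], z * spacing[3])
}

check_same_dim <- function(a, b, what = "arrays") {
  if (!identical(dim(a), dim(b))) {
    stopf("%s have mismatched dimensions: %s vs %s", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}
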