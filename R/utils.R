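# Internal helpers shared across modules: classed conditions, scoped RNG,
# and the distance kernels every cutoff test in the package funnels through.

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("parch_validation_error", "parch_error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("parch_io_error", "parch_error")))
}

warn_parch <- function(...) {
  warning(warningCondition(paste0(...), class = "parch_warning"))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_validation("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop_validation("coordinate matrix must have 3 columns")
    return(x)
  }
  if (is.numeric(x)) {
    if (length(x) %% 3L != 0L) stop_validation("xyz vector length must be a multiple of 3")
    return(matrix(x, ncol = 3L, byrow = TRUE))
  }
  stop_validation("coordinates must be an n x 3 matrix or a flat xyz vector")
}

# Minimum-image displacement for an orthorhombic box; `d` is a length-3 column
# set (matrix n x 3). box = NULL means open boundaries.
min_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# Squared distances from every row of `a` (n x 3) to every row of `b` (m x 3),
# returned as an n x m matrix. Used by the brute-force oracles and as the final
# pair test inside the cell list (identical arithmetic on both paths).
dist2_matrix <- function(a, b, box = NULL) {
  a <- as_xyz_matrix(a); b <- as_xyz_matrix(b)
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  out
}

# For each row of `pts`, squared distance to the nearest row of `ref`.
min_dist2 <- function(pts, ref, box = NULL) {
  d2 <- dist2_matrix(pts, ref, box)
  apply(d2, 1L, min)
}

check_box <- function(box) {
  if (is.null(box)) return(NULL)
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop_validation("box must be three positive orthorhombic edge lengths (Angstrom)")
  box
}

`%||%` <- function(a, b) if (is.null(a)) b else a
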