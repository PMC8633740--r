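# Voxel-grid helpers shared by the simulator and the analysis stages.
# A "mask" is a 3D logical (or 0/1) array; voxelwise data are stored either
# as full arrays (x, y, z[, t]) or as mask-vectorized matrices (voxel x time).

#' Ellipsoidal brain-like mask
#'
#' Builds a binary mask on a small voxel grid: an axis-aligned ellipsoid
#' inscribed in the grid, shrunk by `margin` voxels on every axis. This is the
#' default spatial domain of the synthetic-study generator; it is small enough
#' for desk-scale permutation testing yet large enough to hold 8-10 separated
#' network blobs.
#'
#' @param dim integer vector of length 3, grid shape (default `c(16, 16, 12)`).
#' @param margin shrink of the ellipsoid semi-axes, in voxels.
#' @return logical 3D array of dimension `dim`.
#' @export
#' @examples
#' m <- ellipsoid_mask(c(12, 12, 10))
#' sum(m)
ellipsoid_mask <- function(dim = c(16L, 16L, 12L), margin = 0.5) {
  stopifnot(length(dim) == 3L, all(dim >= 3L))
  ctr <- (dim + 1) / 2
  semi <- pmax(dim / 2 - margin, 1)
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  d2 <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2
  array(d2 <= 1, dim = dim)
}

# voxel x time matrix of the in-mask data of a 4D array
mask_matrix <- function(data4d, mask) {
  dm <- dim(data4d)
  stopifnot(length(dm) == 4L, all(dm[1:3] == dim(mask)))
  m <- matrix(data4d, nrow = prod(dm[1:3]), ncol = dm[4])
  m[as.logical(mask), , drop = FALSE]
}

# inverse of mask_matrix: fill a 4D array (zeros outside mask)
unmask_matrix <- function(mat, mask) {
  dm <- dim(mask)
  out <- matrix(0, nrow = prod(dm), ncol = ncol(mat))
  out[as.logical(mask), ] <- mat
  array(out, dim = c(dm, ncol(mat)))
}

# single volume versions
mask_vector <- function(vol, mask) as.vector(vol)[as.logical(mask)]

unmask_vector <- function(v, mask) {
  out <- numeric(length(mask))
  out[as.logical(mask)] <- v
  array(out, dim = dim(mask))
}

# Voxels of `mask` that touch the outside under 6-connectivity (boundary shell).
mask_boundary_shell <- function(mask) {
  dm <- dim(mask)
  stopifnot(length(dm) == 3L)
  padded <- array(FALSE, dm + 2L)
  padded[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- as.logical(mask)
  core <- padded[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
  core & !(
    padded[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    padded[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    padded[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
    padded[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
    padded[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
    padded[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seeds (kept below .Machine$integer.max) derived from a
# master seed; every stochastic stage draws its own seed from this stream so
# one study seed pins the whole analysis.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(master_seed %% 2147483647L))
  sample.int(2147483646L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(expr)
}
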