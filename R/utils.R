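# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based coordinate arrays for a 3-D grid, first axis fastest
grid_coords <- function(dims) {
  list(
    i = array(rep(seq_len(dims[1]) - 1L, times = dims[2] * dims[3]), dims),
    j = array(rep(rep(seq_len(dims[2]) - 1L, each = dims[1]), times = dims[3]), dims),
    k = array(rep(seq_len(dims[3]) - 1L, each = dims[1] * dims[2]), dims)
  )
}

# logical sphere: voxels whose (0-based) centre lies within `radius` of `center`
sphere_mask <- function(dims, center, radius) {
  g <- grid_coords(dims)
  (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2 <= radius^2
}

ellipsoid_mask <- function(dims, center, semi_axes) {
  g <- grid_coords(dims)
  ((g$i - center[1]) / semi_axes[1])^2 +
    ((g$j - center[2]) / semi_axes[2])^2 +
    ((g$k - center[3]) / semi_axes[3])^2 <= 1
}

# 0-based voxel coordinates (m x 3) for 1-based linear indices
lin_to_coord <- function(lin, dims) {
  arrayInd(lin, dims) - 1L
}

# map voxel coordinates (0-based, m x 3) through a 4x4 affine -> mm (m x 3)
voxel_to_world <- function(coords, affine) {
  coords <- matrix(coords, ncol = 3)
  h <- cbind(coords, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

# set the RNG deterministically when `seed` is given, restoring state on exit
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
}
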