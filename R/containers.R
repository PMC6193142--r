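#' 3D density volume
#'
#' A 3D raster of densities with an isotropic voxel size.  By package
#' convention the filament axis lies along the third array index (z) and the
#' rotation centre is the grid point `(n + 1) / 2` on every axis, so that
#' rotations by multiples of 90 degrees map the grid onto itself.
#'
#' @param data numeric 3D array `[x, y, z]`.
#' @param voxel_size voxel edge length in Angstrom.
#' @return An object of class `em_volume`: the array with a `voxel_size`
#'   attribute.
#' @export
em_volume <- function(data, voxel_size) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  stopifnot_scalar(voxel_size, "voxel_size")
  if (voxel_size <= 0) stop("'voxel_size' must be positive")
  structure(data, voxel_size = as.numeric(voxel_size), class = "em_volume")
}

#' @export
print.em_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<em_volume> %d x %d x %d voxels, %.3g A/voxel\n",
              d[1], d[2], d[3], voxel_size(x)))
  cat(sprintf("  density range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Voxel or pixel size accessor
#' @param x an `em_volume`, `particle_stack` or image with a size attribute.
#' @return Size in Angstrom per voxel/pixel.
#' @export
voxel_size <- function(x) {
  v <- attr(x, "voxel_size") %||% attr(x, "pixel_size")
  if (is.null(v)) stop("object carries no voxel/pixel size")
  v
}

#' Stack of same-sized 2D particle images
#'
#' @param data numeric 3D array `[x, y, particle]`; images are square.
#' @param pixel_size pixel size in Angstrom.
#' @return An object of class `particle_stack`.
#' @export
particle_stack <- function(data, pixel_size) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array [x, y, n]")
  if (dim(data)[1] != dim(data)[2]) stop("particle images must be square")
  stopifnot_scalar(pixel_size, "pixel_size")
  structure(data, pixel_size = as.numeric(pixel_size),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<particle_stack> %d particles of %d x %d px, %.3g A/px\n",
              d[3], d[1], d[2], voxel_size(x)))
  invisible(x)
}

#' Number of particles in a stack
#' @param stack a `particle_stack`.
#' @export
n_particles <- function(stack) dim(stack)[3]

#' Extract one particle image
#' @param stack a `particle_stack`.
#' @param i particle index.
#' @export
particle <- function(stack, i) stack[, , i, drop = TRUE]

# strip class/attrs to a plain array (internal)
as_plain_array <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

new_records <- function(n) {
  data.frame(psi = numeric(n), dx = numeric(n), dy = numeric(n),
             phi = numeric(n), ref = integer(n), score = numeric(n),
             flagged = logical(n))
}

check_records <- function(records, n) {
  need <- c("psi", "dx", "dy", "phi", "ref", "score")
  if (!all(need %in% names(records)))
    stop("alignment records need columns: ", paste(need, collapse = ", "))
  if (nrow(records) != n)
    stop(sprintf("records (%d rows) do not match stack (%d particles)",
                 nrow(records), n))
  invisible(records)
}
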