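#' Voxel grid specification
#'
#' A regular, isotropic voxel grid. Coordinates are in mm, voxel-centered
#' and 0-based externally (voxel i covers \code{[i*h, (i+1)*h)} from the
#' grid origin). The z-axis is the hemisphere symmetry axis: the chest-wall
#' plane is at z = 0 and the breast apex lies at maximal z-depth.
#'
#' @param shape integer vector of 3 positive voxel counts (2 allowed for
#'   the planar acoustic mode).
#' @param voxel_size voxel edge length in mm (> 0).
#' @param origin corner coordinates in mm (default the origin).
#' @return object of class \code{grid_spec}.
#' @export
grid_spec <- function(shape, voxel_size, origin = rep(0, length(shape))) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L) || any(shape < 1))
    stopf("shape must be 2 or 3 positive integers")
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stopf("voxel_size must be > 0")
  structure(list(shape = shape, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %s voxels, %.4g mm voxels, extent %s mm\n",
              paste(x$shape, collapse = "x"), x$voxel_size,
              paste(format(x$shape * x$voxel_size), collapse = " x ")))
  invisible(x)
}

grid_extent <- function(grid) grid$shape * grid$voxel_size

same_grid <- function(a, b)
  all(a$shape == b$shape) && isTRUE(all.equal(a$voxel_size, b$voxel_size))
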