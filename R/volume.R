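#' 3D image volume with physical voxel size
#'
#' The unit every pipeline stage consumes and produces: a numeric 3D array
#' indexed `[y, x, z]` carrying the voxel size in micrometres.  `x`
#' (dimension 2) is the illumination axis, `z` (dimension 3) the detection
#' axis.  The physical coordinate of a voxel center is
#' `(index - 1) * voxel_size`.
#'
#' @param data numeric 3D array, dim `(ny, nx, nz)`.
#' @param voxel_size_um voxel size in micrometres, length-3 `(x, y, z)`.
#'   Default `c(0.645, 0.645, 1)`, the acquisition raster of a 10x/0.3 NA
#'   SPIM with 1 um slice spacing.
#' @return an `image_volume` object.
#' @export
image_volume <- function(data, voxel_size_um = c(0.645, 0.645, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("image_volume: `data` must be a 3D array, got %s",
          paste(dim(data), collapse = "x"))
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 3L ||
      any(!is.finite(voxel_size_um)) || any(voxel_size_um <= 0))
    stopf("image_volume: `voxel_size_um` must be 3 positive numbers (x, y, z)")
  storage.mode(data) <- "double"
  structure(data, voxel_size_um = stats::setNames(as.numeric(voxel_size_um),
                                                  c("x", "y", "z")),
            class = c("image_volume", "array"))
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x); vs <- voxel_size(x)
  cat(sprintf("<image_volume> %d x %d x %d voxels [y,x,z], voxel %g x %g x %g um\n",
              d[1], d[2], d[3], vs["x"], vs["y"], vs["z"]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Voxel size of an image volume
#' @param vol an `image_volume`.
#' @return named numeric `(x, y, z)` in micrometres.
#' @export
voxel_size <- function(vol) {
  vs <- attr(vol, "voxel_size_um")
  if (is.null(vs)) stopf("volume carries no voxel-size metadata")
  vs
}

# rebuild an image_volume with the same metadata but new data
vol_like <- function(data, template) {
  image_volume(array(as.numeric(data), dim(template)), voxel_size(template))
}

as_array3 <- function(vol) {
  a <- unclass(vol)
  attr(a, "voxel_size_um") <- NULL
  a
}

# physical coordinates (um) of voxel centers along each array axis
axis_coords <- function(dims, vs) {
  list(y = (seq_len(dims[1]) - 1) * vs["y"],
       x = (seq_len(dims[2]) - 1) * vs["x"],
       z = (seq_len(dims[3]) - 1) * vs["z"])
}
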