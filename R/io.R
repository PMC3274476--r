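# Stack I/O: multi-page TIFF (pages = z-slices) plus a JSON sidecar carrying
# voxel size, axis order and provenance.  Integer TIFFs are converted to
# float in [0,1] by dividing by the dtype maximum (the behaviour of the
# underlying reader).

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image volume as multi-page TIFF
#'
#' Float data is written as 32-bit float, one page per z-slice, with a JSON
#' sidecar recording voxel size, axis order and the producing command line.
#' Data outside `[0, 1]` (the storage range of the TIFF writer) is affinely
#' rescaled; the offset and scale go into the sidecar and [read_stack()]
#' undoes them.
#'
#' @param vol an `image_volume`.
#' @param path output TIFF path.
#' @param command optional provenance string stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path, command = NULL) {
  if (length(dim(vol)) != 3L)
    stopf("write_stack: need a 3D volume, got %d dims", length(dim(vol)))
  vs <- voxel_size(vol)
  arr <- as_plain_array(vol)
  rng <- range(arr)
  offset <- 0; scale <- 1
  if (rng[1] < 0 || rng[2] > 1) {
    offset <- rng[1]
    scale <- max(rng[2] - rng[1], .Machine$double.eps)
    arr <- (arr - offset) / scale
  }
  pages <- lapply(seq_len(dim(arr)[3]), function(iz) arr[, , iz])
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  if (!isTRUE(ok) && !is.numeric(ok)) stopf("write_stack: could not write %s", path)
  side <- list(voxel_size_um = as.list(vs), axis_order = "y,x,z",
               n_slices = dim(arr)[3],
               data_offset = offset, data_scale = scale,
               command = if (is.null(command)) NA else command,
               producer = paste0("spimpipe ",
                                 as.character(utils::packageVersion("spimpipe"))))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Pages load as z-slices in `[y, x, z]` order.  Voxel size is resolved
#' from TIFF resolution tags, then the JSON sidecar, then the explicit
#' override (each overriding the previous); missing everywhere is an error.
#' Integer data arrives scaled to `[0, 1]` (divided by the dtype maximum).
#'
#' @param path TIFF path.
#' @param voxel_size_um optional `(x, y, z)` override.
#' @return an `image_volume`.
#' @export
read_stack <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stopf("read_stack: no such file: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stopf("read_stack: cannot read %s: %s",
                                              path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stopf("read_stack: inconsistent page shapes in %s", path)
  d2 <- dims[[1]]
  if (length(d2) == 3L) {           # drop any channel axis of size 1
    if (d2[3] != 1L) stopf("read_stack: only single-channel stacks supported")
    pages <- lapply(pages, function(p) p[, , 1])
    d2 <- d2[1:2]
  }
  arr <- array(unlist(pages, use.names = FALSE), c(d2[1], d2[2], length(pages)))

  vs <- c(x = NA_real_, y = NA_real_, z = NA_real_)
  info <- attributes(pages[[1]])
  # resolution tags give in-plane size only (pixels per unit)
  if (!is.null(info$x.resolution) && info$x.resolution > 0) {
    unit_um <- if (identical(info$resolution.unit, "cm")) 1e4 else 25.4e3
    vs["x"] <- unit_um / info$x.resolution
    if (!is.null(info$y.resolution) && info$y.resolution > 0)
      vs["y"] <- unit_um / info$y.resolution
  }
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    sv <- side$voxel_size_um
    if (!is.null(sv)) for (ax in c("x", "y", "z"))
      if (!is.null(sv[[ax]])) vs[ax] <- as.numeric(sv[[ax]])
    if (!is.null(side$data_scale) && !is.null(side$data_offset))
      arr <- arr * as.numeric(side$data_scale) + as.numeric(side$data_offset)
  }
  if (!is.null(voxel_size_um)) {
    ov <- as.numeric(voxel_size_um)
    if (length(ov) != 3L) stopf("read_stack: voxel_size_um override must have 3 values")
    vs[c("x", "y", "z")] <- ifelse(is.na(ov), vs[c("x", "y", "z")], ov)
  }
  if (any(is.na(vs)))
    stopf("read_stack: voxel size missing for axis %s (no resolution tags, sidecar or override)",
          paste(names(vs)[is.na(vs)], collapse = ", "))
  image_volume(arr, vs)
}
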