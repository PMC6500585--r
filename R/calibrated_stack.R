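#' Calibrated 3D intensity stack
#'
#' The basic container shared by all measurement methods: a 3D array of
#' non-negative intensities in `(z, y, x)` order together with the physical
#' voxel dimensions in micrometres. All public APIs speak physical units
#' (um, um^2, um^3); array indices are an internal detail. The physical
#' coordinate of voxel `(k, j, i)` (0-based) is `(k*dz, j*dy, i*dx)`.
#'
#' @param voxels 3D numeric array, dimensions `(z, y, x)`; a matrix is
#'   promoted to a single-slice stack. Values must be non-negative.
#' @param dx,dy lateral pixel size in um.
#' @param dz axial step between optical sections in um.
#' @param name identifier carried through to output tables.
#' @return An object of class `calibrated_stack` with elements `voxels`,
#'   `dx`, `dy`, `dz`, `name`.
#' @examples
#' s <- calibrated_stack(array(0, c(3, 8, 8)), dx = 375/1024, dy = 375/1024, dz = 1.5)
#' stack_extent(s)  # physical extent in um, (z, y, x)
#' @export
calibrated_stack <- function(voxels, dx, dy = dx, dz, name = "stack") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (z, y, x)")
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stop("voxel intensities must be finite and non-negative")
  for (v in list(dx = dx, dy = dy, dz = dz))
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("dx, dy, dz must be positive scalars (um)")
  structure(list(voxels = voxels, dx = dx, dy = dy, dz = dz,
                 name = as.character(name)),
            class = "calibrated_stack")
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<calibrated_stack '%s'> %d x %d x %d voxels (z,y,x), %.4g x %.4g x %.4g um/voxel\n",
              x$name, d[1], d[2], d[3], x$dz, x$dy, x$dx))
  cat(sprintf("  physical extent: %.4g x %.4g x %.4g um, intensity range [%g, %g]\n",
              d[1] * x$dz, d[2] * x$dy, d[3] * x$dx,
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @rdname calibrated_stack
#' @param stack a `calibrated_stack`.
#' @export
stack_extent <- function(stack) {
  d <- dim(stack$voxels)
  c(z = d[1] * stack$dz, y = d[2] * stack$dy, x = d[3] * stack$dx)
}

#' Voxel volume in cubic micrometres
#' @param stack a `calibrated_stack`.
#' @export
voxel_volume <- function(stack) stack$dx * stack$dy * stack$dz

#' Region of interest with half-open integer bounds
#'
#' Bounds are 0-based and half-open on the upper side (`z0 <= k < z1`), so
#' boxes partition a stack without overlap or gaps.
#'
#' @param z0,z1,y0,y1,x0,x1 integer bounds, lower inclusive, upper exclusive.
#' @return A `region_box` object.
#' @export
region_box <- function(z0, z1, y0, y1, x0, x1) {
  b <- c(z0 = z0, z1 = z1, y0 = y0, y1 = y1, x0 = x0, x1 = x1)
  if (any(b != round(b))) stop("region_box bounds must be integers")
  if (z0 < 0 || y0 < 0 || x0 < 0) stop("region_box lower bounds must be >= 0")
  if (z1 <= z0 || y1 <= y0 || x1 <= x0)
    stop("region_box requires lower < upper on each axis")
  structure(as.list(b), class = "region_box")
}

#' Load a multi-page grayscale TIFF as a calibrated stack
#'
#' Reads an 8- or 16-bit single-channel multi-page TIFF and attaches the
#' supplied spatial calibration. Integer intensities are preserved
#' bit-exactly (stored values, not normalised floats).
#'
#' @param path path to the TIFF file.
#' @param dx,dy lateral pixel size in um (e.g. `375/1024` for a 1024 px,
#'   375 um field of view).
#' @param dz axial step in um (e.g. 1.5).
#' @param name identifier; defaults to the file name.
#' @return A [calibrated_stack()].
#' @export
load_stack <- function(path, dx, dy = dx, dz, name = basename(path)) {
  if (!file.exists(path)) stop("cannot read TIFF: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop("multi-channel TIFF: extract a single channel (e.g. the DAPI ",
         "channel) before loading; load_stack() expects one sample per pixel")
  shp <- vapply(pages, dim, integer(2))
  if (ncol(shp) > 1 && any(shp != shp[, 1]))
    stop("all TIFF pages must share the same y*x shape")
  vox <- array(0, c(length(pages), shp[1, 1], shp[2, 1]))
  for (k in seq_along(pages)) vox[k, , ] <- pages[[k]]
  calibrated_stack(vox, dx = dx, dy = dy, dz = dz, name = name)
}

#' Write a calibrated stack as a multi-page 16-bit grayscale TIFF
#'
#' Intensities are stored as integers (rounded, clipped to `[0, 65535]`), so
#' a write/read round trip is lossless for integer data up to 16 bit.
#'
#' @param stack a [calibrated_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  v <- round(stack$voxels)
  if (max(v) > 65535) stop("intensities exceed 16-bit range")
  pages <- lapply(seq_len(dim(v)[1]), function(k) v[k, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Crop a stack to a region box
#'
#' Used to restrict measurements to a tissue of interest (e.g. the root
#' cortex) before volumetric analysis. Calibration is unchanged.
#'
#' @param stack a [calibrated_stack()].
#' @param box a [region_box()] within the stack bounds.
#' @return The cropped [calibrated_stack()].
#' @export
crop <- function(stack, box) {
  stopifnot(inherits(box, "region_box"))
  d <- dim(stack$voxels)
  if (box$z1 > d[1] || box$y1 > d[2] || box$x1 > d[3])
    stop("region_box exceeds stack bounds")
  calibrated_stack(
    stack$voxels[(box$z0 + 1):box$z1, (box$y0 + 1):box$y1,
                 (box$x0 + 1):box$x1, drop = FALSE],
    dx = stack$dx, dy = stack$dy, dz = stack$dz,
    name = paste0(stack$name, "[crop]"))
}

#' Maximum-intensity projection along z
#'
#' @param stack a [calibrated_stack()].
#' @return A 2D matrix (y, x) of per-pixel maxima; lateral calibration is the
#'   stack's `dy`/`dx`.
#' @export
max_projection <- function(stack) {
  apply(stack$voxels, c(2, 3), max)
}
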