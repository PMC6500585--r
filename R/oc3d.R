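#' Global intensity threshold for a stack
#'
#' One threshold per stack separates bright nuclear voxels from darker
#' background, exactly as a whole-stack threshold in interactive analysis.
#' Because staining intensity falls with depth, a single global threshold is
#' a documented failure mode for deep nuclei; it is kept deliberately (the
#' per-substack alternative lives in [run_rsd()]'s substack workflow).
#'
#' @param stack a [calibrated_stack()].
#' @param method `"otsu"` (histogram-based, computed over all voxels) or
#'   `"manual"`.
#' @param value manual threshold (required when `method = "manual"`); voxels
#'   with intensity `>= value` are foreground.
#' @return A list: `mask` (3D logical array) and `threshold` (the value used).
#' @export
global_threshold <- function(stack, method = c("otsu", "manual"),
                             value = NULL) {
  method <- match.arg(method)
  v <- stack$voxels
  if (method == "manual") {
    if (is.null(value)) stop("manual thresholding requires `value`")
    if (value < min(v) || value > max(v))
      warning("manual threshold outside the intensity range")
    thr <- value
  } else {
    rng <- range(v)
    if (rng[1] == rng[2])
      stop("constant-intensity stack: Otsu is undefined; supply a manual value")
    thr <- EBImage::otsu(matrix(v, nrow = dim(v)[1]), range = rng,
                         levels = 1024L)
  }
  list(mask = v >= thr, threshold = unname(thr))
}

# count of lattice points inside (or on) the 2D convex hull of pixel set
# (jj, ii); used by the lobedness score
hull_fill_count <- function(jj, ii) {
  n <- length(jj)
  if (n <= 2L) return(n)
  h <- grDevices::chull(ii, jj)
  hx <- ii[h]; hy <- jj[h]
  if (length(h) <= 2L) return(length(unique(paste(jj, ii))))
  gx <- seq(min(ii), max(ii)); gy <- seq(min(jj), max(jj))
  px <- rep(gx, each = length(gy)); py <- rep(gy, length(gx))
  inside <- rep(TRUE, length(px))
  m <- length(hx)
  for (e in seq_len(m)) {
    x1 <- hx[e]; y1 <- hy[e]
    x2 <- hx[if (e == m) 1L else e + 1L]; y2 <- hy[if (e == m) 1L else e + 1L]
    # chull returns vertices clockwise; interior has non-positive cross product
    inside <- inside &
      ((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)) <= 1e-9
  }
  sum(inside)
}

# lobedness = 1 - voxels / slice-wise convex-hull fill; near 0 for convex
# objects, clearly positive for laterally touching nuclei merged into one
# component
lobedness_score <- function(idx_zyx) {
  hull_total <- 0L
  for (k in unique(idx_zyx[, 1])) {
    sel <- idx_zyx[, 1] == k
    hull_total <- hull_total + hull_fill_count(idx_zyx[sel, 2], idx_zyx[sel, 3])
  }
  1 - nrow(idx_zyx) / hull_total
}

#' Label 3D connected components and measure them
#'
#' Foreground voxels are grouped into connected components (26- or
#' 6-connectivity); each component's volume is its voxel count times the
#' physical voxel volume, exactly. Components touching the stack border are
#' flagged (possible truncation), and a lobedness score flags single
#' components likely to be clusters of touching nuclei.
#'
#' @param mask 3D logical array (z, y, x).
#' @param stack the [calibrated_stack()] the mask came from (supplies
#'   calibration).
#' @param connectivity 26 (faces, edges, corners) or 6 (faces only).
#' @return A list: `labels` (3D integer array, 0 = background) and `objects`
#'   (data.frame: object_id, voxel_count, volume_um3, centroid_z/y/x_um,
#'   bbox bounds, touches_border, lobedness, excluded, exclude_reason).
#' @export
label_components_3d <- function(mask, stack, connectivity = 26L) {
  stopifnot(identical(dim(mask), dim(stack$voxels)))
  labels <- label3d_cpp(as.logical(mask), dim(mask), as.integer(connectivity))
  nlab <- max(labels)
  d <- dim(mask)
  empty <- data.frame(object_id = integer(), voxel_count = integer(),
                      volume_um3 = numeric(), centroid_z_um = numeric(),
                      centroid_y_um = numeric(), centroid_x_um = numeric(),
                      z0 = integer(), z1 = integer(), y0 = integer(),
                      y1 = integer(), x0 = integer(), x1 = integer(),
                      touches_border = logical(), lobedness = numeric(),
                      excluded = logical(), exclude_reason = character())
  if (nlab == 0L) return(list(labels = labels, objects = empty))
  idx <- which(labels > 0L, arr.ind = TRUE)   # (z, y, x), 1-based
  lab <- labels[labels > 0L]
  vv <- voxel_volume(stack)
  rows <- lapply(seq_len(nlab), function(id) {
    pts <- idx[lab == id, , drop = FALSE]
    nvox <- nrow(pts)
    ctr <- colMeans(pts) - 1           # back to 0-based index space
    data.frame(
      object_id = id, voxel_count = nvox, volume_um3 = nvox * vv,
      centroid_z_um = ctr[1] * stack$dz, centroid_y_um = ctr[2] * stack$dy,
      centroid_x_um = ctr[3] * stack$dx,
      z0 = min(pts[, 1]) - 1L, z1 = max(pts[, 1]),
      y0 = min(pts[, 2]) - 1L, y1 = max(pts[, 2]),
      x0 = min(pts[, 3]) - 1L, x1 = max(pts[, 3]),
      touches_border = any(pts[, 1] %in% c(1L, d[1])) ||
        any(pts[, 2] %in% c(1L, d[2])) || any(pts[, 3] %in% c(1L, d[3])),
      lobedness = lobedness_score(pts),
      excluded = FALSE, exclude_reason = "",
      row.names = NULL)
  })
  list(labels = labels, objects = do.call(rbind, rows))
}

#' Flag objects for exclusion without deleting them
#'
#' Mirrors the audit-friendly reading of the manual curation step: nothing is
#' removed, exclusion flags carry machine-readable reasons (`size`, `border`,
#' `lobed`) so counts can always be reconstructed.
#'
#' @param objects the `objects` data.frame from [label_components_3d()].
#' @param min_volume,max_volume inclusion band in um^3 (defaults bracket the
#'   plant-nucleus range; smaller components are typically fungal nuclei).
#' @param drop_border flag border-touching objects (`FALSE` by default:
#'   truncation is flagged upstream, not silently dropped).
#' @param drop_lobed flag high-lobedness objects (likely touching-nuclei
#'   clusters).
#' @param lobedness_threshold score above which an object counts as lobed.
#' @return `objects` with `excluded`/`exclude_reason` filled in.
#' @export
filter_objects <- function(objects, min_volume = 15, max_volume = 250,
                           drop_border = FALSE, drop_lobed = TRUE,
                           lobedness_threshold = 0.08) {
  stopifnot(min_volume < max_volume)
  reason <- character(nrow(objects))
  bad_size <- objects$volume_um3 < min_volume | objects$volume_um3 > max_volume
  reason[bad_size] <- "size"
  if (drop_border)
    reason[reason == "" & objects$touches_border] <- "border"
  if (drop_lobed)
    reason[reason == "" & objects$lobedness > lobedness_threshold] <- "lobed"
  objects$excluded <- reason != ""
  objects$exclude_reason <- reason
  objects
}

#' Merge a stack with its label map for visual control
#'
#' @param stack a [calibrated_stack()].
#' @param labels 3D integer label array of the same shape.
#' @return An `overlay_stack`: list with `intensity` and `labels` arrays plus
#'   calibration, writable with [write_overlay()].
#' @export
overlay_map <- function(stack, labels) {
  if (!identical(dim(stack$voxels), dim(labels)))
    stop("label map shape does not match the stack")
  structure(list(intensity = stack$voxels, labels = labels,
                 dx = stack$dx, dy = stack$dy, dz = stack$dz,
                 name = stack$name),
            class = "overlay_stack")
}

#' @rdname overlay_map
#' @param overlay an `overlay_stack`.
#' @param path output TIFF path; pages alternate intensity, label per slice.
#' @export
write_overlay <- function(overlay, path) {
  d <- dim(overlay$intensity)
  pages <- vector("list", 2L * d[1])
  for (k in seq_len(d[1])) {
    pages[[2 * k - 1]] <- pmin(round(overlay$intensity[k, , ]), 65535) / 65535
    pages[[2 * k]] <- pmin(overlay$labels[k, , ], 65535) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Volumetric nuclear measurement (threshold + 3D components + voxel sums)
#'
#' The full object-counting pipeline: one global threshold, 3D
#' connected-component labeling, voxel-sum volumes, and exclusion flagging.
#' The returned table holds included nuclei only; the audit list retains
#' every component with its flag.
#'
#' @param stack a [calibrated_stack()].
#' @param threshold `"otsu"` or `"manual"`.
#' @param threshold_value manual threshold value.
#' @param connectivity 26 or 6.
#' @inheritParams filter_objects
#' @return A list: `table` (data.frame sample_id, method, volume_um3,
#'   centroid_z/y/x_um), `objects` (all components with flags), `labels`,
#'   `threshold`, `excluded_counts` (named vector by reason).
#' @export
run_object_counter <- function(stack, threshold = "otsu",
                               threshold_value = NULL, connectivity = 26L,
                               min_volume = 15, max_volume = 250,
                               drop_border = FALSE, drop_lobed = TRUE,
                               lobedness_threshold = 0.08) {
  th <- global_threshold(stack, method = threshold, value = threshold_value)
  comp <- label_components_3d(th$mask, stack, connectivity = connectivity)
  obj <- filter_objects(comp$objects, min_volume = min_volume,
                        max_volume = max_volume, drop_border = drop_border,
                        drop_lobed = drop_lobed,
                        lobedness_threshold = lobedness_threshold)
  keep <- obj[!obj$excluded, , drop = FALSE]
  tab <- data.frame(sample_id = rep(stack$name, nrow(keep)),
                    method = rep("oc3d", nrow(keep)),
                    object_id = keep$object_id,
                    volume_um3 = keep$volume_um3,
                    centroid_z_um = keep$centroid_z_um,
                    centroid_y_um = keep$centroid_y_um,
                    centroid_x_um = keep$centroid_x_um,
                    row.names = NULL)
  excl <- table(factor(obj$exclude_reason[obj$excluded],
                       levels = c("size", "border", "lobed")))
  list(table = tab, objects = obj, labels = comp$labels,
       threshold = th$threshold,
       excluded_counts = setNames(as.integer(excl), names(excl)))
}
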