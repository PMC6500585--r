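#' Split a stack into consecutive substacks
#'
#' Sectioning the z-stack into thinner series of optical sections prevents
#' distinct nuclei that share x-y coordinates from overlapping in a single
#' projection. Substacks are consecutive and non-overlapping; the last one
#' may be shorter.
#'
#' @param stack a [calibrated_stack()].
#' @param thickness substack thickness in slices (>= 1). The default of 6
#'   slices (9 um at a 1.5 um z-step, about one nuclear diameter) makes it
#'   rare for one nucleus to span two substacks while distinct nuclei rarely
#'   overlap axially within one.
#' @return List of [calibrated_stack()]s covering all slices.
#' @export
split_substacks <- function(stack, thickness = 6L) {
  stopifnot(thickness >= 1)
  nz <- dim(stack$voxels)[1]
  d <- dim(stack$voxels)
  starts <- seq(0L, nz - 1L, by = thickness)
  lapply(seq_along(starts), function(s) {
    box <- region_box(starts[s], min(starts[s] + thickness, nz),
                      0L, d[2], 0L, d[3])
    sub <- crop(stack, box)
    sub$name <- sprintf("%s[sub%d]", stack$name, s)
    sub
  })
}

#' Brightest-point projection of a substack
#'
#' Equivalent to a brightest-point 3D rendering viewed at zero rotation:
#' the per-pixel maximum over the substack's slices.
#'
#' @param substack a [calibrated_stack()].
#' @return 2D matrix (y, x).
#' @export
project_brightest <- function(substack) max_projection(substack)

#' Build a binary nucleus-candidate mask from a projection
#'
#' Contrast is stretched to the full dynamic range, a rolling-ball style
#' background (grayscale opening with a disc much larger than any nucleus,
#' computed on a downscaled copy for large radii) is subtracted, and the
#' result is thresholded (Otsu by default).
#'
#' @param projection 2D matrix (y, x).
#' @param dx,dy lateral pixel size in um.
#' @param rolling_ball_radius background structuring-element radius in um;
#'   must exceed the largest nuclear radius (default 20).
#' @param threshold `"otsu"` (computed over candidate-foreground pixels,
#'   i.e. above 2% of the maximum, so the empty background does not dominate
#'   the histogram) or a numeric value on the stretched,
#'   background-subtracted scale (0..1).
#' @return Binary matrix; all-`FALSE` (with a warning) for a constant image.
#' @export
build_mask <- function(projection, dx, dy = dx, rolling_ball_radius = 20,
                       threshold = "otsu") {
  rng <- range(projection)
  if (rng[1] == rng[2]) {
    warning("constant projection: returning an empty mask")
    return(matrix(FALSE, nrow(projection), ncol(projection)))
  }
  img <- (projection - rng[1]) / (rng[2] - rng[1])
  r_px <- rolling_ball_radius / sqrt(dx * dy)
  shrink <- max(1L, floor(r_px / 8))
  if (shrink > 1L) {
    small <- EBImage::resize(img, ceiling(nrow(img) / shrink),
                             ceiling(ncol(img) / shrink))
    r_small <- max(2L, round(r_px / shrink))
    bg <- EBImage::opening(small, EBImage::makeBrush(2L * r_small + 1L, "disc"))
    bg <- EBImage::resize(bg, nrow(img), ncol(img))
  } else {
    bg <- EBImage::opening(img, EBImage::makeBrush(2L * max(2L, round(r_px)) + 1L, "disc"))
  }
  net <- pmax(img - bg, 0)
  if (max(net) == 0) {
    warning("projection is indistinguishable from its background: empty mask")
    return(matrix(FALSE, nrow(projection), ncol(projection)))
  }
  thr <- if (identical(threshold, "otsu")) {
    # Otsu over candidate-foreground pixels only: the vast empty background
    # otherwise dominates the histogram and drags the split far below the
    # nuclear half-maximum, inflating every measured area
    fg <- net[net > 0.02 * max(net)]
    EBImage::otsu(matrix(fg, ncol = 1), range = c(0, max(fg)), levels = 1024L)
  } else threshold
  structure(net > thr, threshold = unname(thr))
}

#' Smooth, fill holes and watershed-separate a mask
#'
#' A 3x3 mean filter (re-binarised at 0.5) removes pixel noise, holes are
#' filled, and touching convex blobs are split by a distance-transform
#' watershed.
#'
#' @param mask binary matrix.
#' @return Integer label matrix (0 = background); touching objects receive
#'   distinct labels.
#' @export
refine_mask <- function(mask) {
  m <- EBImage::filter2(mask * 1, matrix(1 / 9, 3, 3)) >= 0.5
  m <- EBImage::fillHull(m * 1)
  if (sum(m) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::watershed(EBImage::distmap(m), tolerance = 1, ext = 1)
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

# chain-code perimeter with Vossepoel-Smeulders corner-corrected weights;
# the raw pixel-edge perimeter overestimates and would wrongly reject small
# discs at the circularity gate
contour_perimeter_px <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(0)
  nxt <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  step <- nxt - xy
  diag_step <- step[, 1] != 0 & step[, 2] != 0
  ne <- sum(!diag_step)
  no <- sum(diag_step)
  dirs <- atan2(step[, 2], step[, 1])
  nc <- sum(dirs != c(dirs[-1], dirs[1]))
  0.980 * ne + 1.406 * no - 0.091 * nc
}

#' Measure and gate connected particles in a mask
#'
#' Components are measured (area = pixel count x pixel area, perimeter from
#' corner-corrected boundary tracing, circularity `4*pi*A/P^2` clamped to 1)
#' and only those inside both the circularity and size gates are returned.
#' The default gates -- circularity 0.7..1 and area 15..150 um^2 -- exclude
#' elongated wall staining and small fungal nuclei respectively.
#'
#' @param mask binary matrix or integer label matrix from [refine_mask()].
#' @param dx,dy lateral pixel size in um.
#' @param circularity length-2 inclusive gate on `4*pi*A/P^2`.
#' @param size length-2 inclusive gate on area in um^2.
#' @param substack_index carried into the output (for deduplication).
#' @return data.frame: object_id, substack_index, centroid_y_um,
#'   centroid_x_um, area_um2, perimeter_um, circularity.
#' @export
analyze_particles <- function(mask, dx, dy = dx, circularity = c(0.7, 1),
                              size = c(15, 150), substack_index = 1L) {
  labels <- if (is.logical(mask) || all(mask %in% c(0, 1)))
    matrix(as.integer(EBImage::bwlabel(mask * 1)), nrow(mask), ncol(mask))
  else mask
  nlab <- max(labels)
  out <- list()
  if (nlab > 0) {
    contours <- EBImage::ocontour(labels)
    px_area <- dx * dy
    px_len <- sqrt(dx * dy)
    for (id in seq_len(nlab)) {
      pts <- which(labels == id, arr.ind = TRUE)
      if (nrow(pts) == 0) next
      a <- nrow(pts) * px_area
      p_px <- contour_perimeter_px(contours[[id]])
      circ <- if (p_px > 0) min(1, 4 * pi * a / (p_px * px_len)^2) else 1
      if (a < size[1] || a > size[2]) next
      if (circ < circularity[1] || circ > circularity[2]) next
      out[[length(out) + 1L]] <- data.frame(
        object_id = id, substack_index = substack_index,
        centroid_y_um = (mean(pts[, 1]) - 1) * dy,
        centroid_x_um = (mean(pts[, 2]) - 1) * dx,
        area_um2 = a, perimeter_um = p_px * px_len, circularity = circ)
    }
  }
  if (!length(out))
    return(data.frame(object_id = integer(), substack_index = integer(),
                      centroid_y_um = numeric(), centroid_x_um = numeric(),
                      area_um2 = numeric(), perimeter_um = numeric(),
                      circularity = numeric()))
  do.call(rbind, out)
}

#' Deduplicate surface objects across adjacent substacks
#'
#' A nucleus spanning a substack boundary appears in two consecutive
#' projections with nearly coincident centroids; of any such pair within
#' `merge_radius`, the larger-area record (closer to the equatorial section)
#' is kept. Greedy by decreasing area, so the rule is idempotent.
#'
#' @param objects data.frame from [analyze_particles()] rows.
#' @param merge_radius lateral merge distance in um (default 3).
#' @return Deduplicated data.frame, object_id renumbered.
#' @export
dedup_surface_objects <- function(objects, merge_radius = 3) {
  if (nrow(objects) <= 1) {
    if (nrow(objects) == 1) objects$object_id <- 1L
    return(objects)
  }
  ord <- order(-objects$area_um2, objects$substack_index, objects$object_id)
  obj <- objects[ord, , drop = FALSE]
  keep <- logical(nrow(obj))
  for (k in seq_len(nrow(obj))) {
    kept <- which(keep)
    clash <- FALSE
    if (length(kept)) {
      adj <- abs(obj$substack_index[kept] - obj$substack_index[k]) <= 1
      if (any(adj)) {
        dd <- sqrt((obj$centroid_y_um[kept][adj] - obj$centroid_y_um[k])^2 +
                     (obj$centroid_x_um[kept][adj] - obj$centroid_x_um[k])^2)
        clash <- any(dd <= merge_radius)
      }
    }
    keep[k] <- !clash
  }
  res <- obj[keep, , drop = FALSE]
  res <- res[order(res$substack_index, res$object_id), , drop = FALSE]
  res$object_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Round-surface-detector pipeline: cross-section areas from projections
#'
#' Splits the stack into substacks, projects each at its brightest point,
#' builds and refines a mask, measures circularity- and size-gated particles,
#' and deduplicates records of nuclei that straddle substack boundaries.
#'
#' @param stack a [calibrated_stack()].
#' @param thickness substack thickness in slices.
#' @param circularity,size gates, see [analyze_particles()].
#' @param rolling_ball_radius,threshold see [build_mask()].
#' @param merge_radius see [dedup_surface_objects()].
#' @return List: `objects` (deduplicated data.frame, one nucleus one record),
#'   `thresholds` (per-substack values used), `table` (MeasurementTable rows
#'   with `area_um2`).
#' @export
run_rsd <- function(stack, thickness = 6L, circularity = c(0.7, 1),
                    size = c(15, 150), rolling_ball_radius = 20,
                    threshold = "otsu", merge_radius = 3) {
  subs <- split_substacks(stack, thickness)
  thresholds <- numeric(length(subs))
  parts <- vector("list", length(subs))
  for (s in seq_along(subs)) {
    proj <- project_brightest(subs[[s]])
    mask <- withCallingHandlers(
      build_mask(proj, dx = stack$dx, dy = stack$dy,
                 rolling_ball_radius = rolling_ball_radius,
                 threshold = threshold),
      warning = function(w) invokeRestart("muffleWarning"))
    thresholds[s] <- if (is.null(attr(mask, "threshold"))) NA_real_
                     else attr(mask, "threshold")
    labs <- refine_mask(mask)
    parts[[s]] <- analyze_particles(labs, dx = stack$dx, dy = stack$dy,
                                    circularity = circularity, size = size,
                                    substack_index = s)
  }
  objects <- dedup_surface_objects(do.call(rbind, parts), merge_radius)
  tab <- data.frame(sample_id = rep(stack$name, nrow(objects)),
                    method = rep("rsd", nrow(objects)),
                    object_id = objects$object_id,
                    area_um2 = objects$area_um2,
                    centroid_y_um = objects$centroid_y_um,
                    centroid_x_um = objects$centroid_x_um,
                    row.names = NULL)
  list(objects = objects, table = tab, thresholds = thresholds)
}
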