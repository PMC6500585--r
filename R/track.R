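#' Detect nuclear blobs in one optical section
#'
#' Laplacian-of-Gaussian detection at the scale matching a nominal blob
#' diameter (default 10 um, the upper end of plant nuclear sizes). Local
#' maxima of the scale-normalised response become detections. Each detection
#' carries a brightness-weighted quality score (the LoG response at the
#' maximum) and a per-detection diameter estimated from the half-maximum
#' support of the background-subtracted intensity around the peak -- the
#' nominal scale fixes *where* to look, the data fix each section's diameter.
#'
#' @param slice_image 2D numeric matrix (y, x).
#' @param dx,dy lateral pixel size in um.
#' @param estimated_diameter nominal blob diameter in um.
#' @return data.frame: `y_um`, `x_um`, `diameter_um`, `quality` (one row per
#'   detection; zero rows when nothing is found).
#' @export
detect_blobs <- function(slice_image, dx, dy = dx, estimated_diameter = 10) {
  stopifnot(is.matrix(slice_image), dx > 0, dy > 0, estimated_diameter > 0)
  px <- sqrt(dx * dy)
  sigma <- estimated_diameter / (2 * sqrt(2)) / px   # LoG scale in pixels
  half <- max(2L, ceiling(3 * sigma))
  ax <- seq(-half, half)
  g <- exp(-ax^2 / (2 * sigma^2))
  # separable LoG: (x^2 + y^2 - 2 sigma^2) / sigma^4 * G, scale-normalised
  G <- outer(g, g)
  r2 <- outer(ax^2, ax^2, `+`)
  log_kernel <- (r2 - 2 * sigma^2) / sigma^4 * G
  log_kernel <- log_kernel - mean(log_kernel)        # zero response on flats
  resp <- -sigma^2 * EBImage::filter2(slice_image, log_kernel)

  d <- dim(resp)
  if (d[1] < 3 || d[2] < 3) return(empty_blobs())
  core <- resp[2:(d[1] - 1), 2:(d[2] - 1)]
  is_max <- core > 0
  for (dj in -1:1) for (di in -1:1) {
    if (dj == 0 && di == 0) next
    is_max <- is_max &
      core >= resp[(2 + dj):(d[1] - 1 + dj), (2 + di):(d[2] - 1 + di)]
  }
  # strict on one side of each tie so plateau maxima yield one detection
  for (dj in -1:1) for (di in -1:1) {
    if (dj > 0 || (dj == 0 && di >= 0)) next
    is_max <- is_max &
      core > resp[(2 + dj):(d[1] - 1 + dj), (2 + di):(d[2] - 1 + di)]
  }
  peaks <- which(is_max, arr.ind = TRUE) + 1L   # back to full-image indices
  if (nrow(peaks) == 0) return(empty_blobs())

  out <- lapply(seq_len(nrow(peaks)), function(p) {
    j <- peaks[p, 1]; i <- peaks[p, 2]
    w <- max(2L, ceiling(0.75 * estimated_diameter / px))
    jj <- max(1, j - w):min(d[1], j + w)
    ii <- max(1, i - w):min(d[2], i + w)
    win <- slice_image[jj, ii]
    border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
    bg <- median(border)
    net <- pmax(win - bg, 0)
    pk <- max(net)
    if (pk <= 0) return(NULL)
    sup <- net >= pk / 2
    area_px <- sum(sup)
    wj <- rowSums(net); wi <- colSums(net)
    cy <- sum(jj * wj) / sum(wj)
    cx <- sum(ii * wi) / sum(wi)
    data.frame(y_um = (cy - 1) * dy, x_um = (cx - 1) * dx,
               diameter_um = 2 * sqrt(area_px * dx * dy / pi),
               quality = resp[j, i])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_blobs() else out[order(-out$quality), , drop = FALSE]
}

empty_blobs <- function() {
  data.frame(y_um = numeric(), x_um = numeric(), diameter_um = numeric(),
             quality = numeric())
}

#' Keep only detections at or above a quality threshold
#'
#' @param blobs data.frame from [detect_blobs()].
#' @param threshold minimum quality score; detections with
#'   `quality >= threshold` are kept, in their original order.
#' @return Filtered data.frame.
#' @export
filter_quality <- function(blobs, threshold) {
  blobs[blobs$quality >= threshold, , drop = FALSE]
}

# 1D Otsu split of detection qualities (default track-level gate when the
# user supplies no threshold)
otsu_split <- function(q) {
  if (length(q) < 3 || diff(range(q)) == 0) return(min(q, 0))
  EBImage::otsu(matrix(q, ncol = 1), range = range(q), levels = 512L)
}

#' Link per-slice detections into z-tracks
#'
#' Detections on consecutive(-ish) slices whose lateral centroids lie within
#' `max_link_distance` are chained into one track -- the operational reading
#' of "the same x-y centroid position across the z-stack". Assignment is
#' greedy on increasing centroid distance, ties broken by lower track id then
#' detection order, so linking is deterministic. Every detection belongs to
#' at most one track.
#'
#' @param blobs_by_slice list (ordered by slice) of [detect_blobs()] frames.
#' @param max_link_distance maximum lateral centroid displacement in um
#'   between linked detections (default 5, half the nominal nuclear
#'   diameter).
#' @param max_gap number of consecutive empty slices a track may bridge
#'   (default 0: strictly adjacent sections).
#' @return List of `nuclear_track` objects; each holds `track_id` and a
#'   `detections` data.frame (slice_index, y_um, x_um, diameter_um, quality)
#'   sorted by slice with no duplicate slices.
#' @export
link_tracks <- function(blobs_by_slice, max_link_distance = 5, max_gap = 0L) {
  tracks <- list()            # each: list(last_slice, rows = data.frame)
  for (s in seq_along(blobs_by_slice)) {
    det <- blobs_by_slice[[s]]
    if (is.null(det) || nrow(det) == 0) next
    det$slice_index <- s
    open <- which(vapply(tracks, function(t)
      s - t$last_slice >= 1 && s - t$last_slice <= 1 + max_gap, logical(1)))
    if (length(open) && nrow(det)) {
      last_y <- vapply(tracks[open], function(t) tail(t$rows$y_um, 1), 0)
      last_x <- vapply(tracks[open], function(t) tail(t$rows$x_um, 1), 0)
      dist <- sqrt(outer(det$y_um, last_y, `-`)^2 +
                     outer(det$x_um, last_x, `-`)^2)
      cand <- which(dist <= max_link_distance, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dist[cand], open[cand[, 2]], cand[, 1])
        used_det <- logical(nrow(det)); used_trk <- logical(length(open))
        for (r in ord) {
          di <- cand[r, 1]; ti <- cand[r, 2]
          if (used_det[di] || used_trk[ti]) next
          used_det[di] <- TRUE; used_trk[ti] <- TRUE
          t_id <- open[ti]
          tracks[[t_id]]$rows <- rbind(tracks[[t_id]]$rows, det[di, ])
          tracks[[t_id]]$last_slice <- s
        }
        det <- det[!used_det, , drop = FALSE]
      }
    }
    for (di in seq_len(nrow(det)))
      tracks[[length(tracks) + 1L]] <- list(last_slice = s,
                                            rows = det[di, , drop = FALSE])
  }
  lapply(seq_along(tracks), function(k) {
    rows <- tracks[[k]]$rows
    rownames(rows) <- NULL
    structure(list(track_id = k,
                   detections = rows[order(rows$slice_index),
                                     c("slice_index", "y_um", "x_um",
                                       "diameter_um", "quality")]),
              class = "nuclear_track")
  })
}

#' Equatorial cross-section area of a tracked nucleus
#'
#' The largest per-section diameter d_max across the track approximates the
#' equatorial diameter; the cross-section area is `pi * (d_max / 2)^2`.
#'
#' @param track a `nuclear_track`.
#' @return Area in um^2.
#' @export
track_area <- function(track) {
  if (nrow(track$detections) == 0) stop("track has no detections")
  dmax <- max(track$detections$diameter_um)
  pi * (dmax / 2)^2
}

#' Cavalieri slab-sum volume of a tracked nucleus
#'
#' Each section contributes a circular slab `pi * (d_i / 2)^2 * dz`; the
#' volume is their sum. Tracks spanning fewer than `min_slices` optical
#' sections return `NA`: such nuclei are likely truncated at the top or
#' bottom of the stack and are excluded from volume estimates.
#'
#' @param track a `nuclear_track`.
#' @param dz axial step in um.
#' @param min_slices minimum number of sections for a volume (default 3).
#' @return Volume in um^3, or `NA_real_` when the track is too short.
#' @export
track_volume <- function(track, dz = 1.5, min_slices = 3L) {
  stopifnot(dz > 0)
  di <- track$detections$diameter_um
  if (length(di) < min_slices) return(NA_real_)
  sum(pi * (di / 2)^2 * dz)
}

#' @export
print.nuclear_track <- function(x, ...) {
  cat(sprintf("<nuclear_track %d> %d sections, d_max = %.2f um, area = %.2f um^2\n",
              x$track_id, nrow(x$detections), max(x$detections$diameter_um),
              track_area(x)))
  invisible(x)
}

#' Slice-track measurement pipeline
#'
#' Detect blobs on every optical section, gate on quality (Otsu split of the
#' per-stack quality distribution unless a threshold is given), link along z,
#' and tabulate per-track area and slab-sum volume.
#'
#' @param stack a [calibrated_stack()].
#' @param estimated_diameter nominal blob diameter, um.
#' @param quality_threshold numeric threshold, or `NULL` for the Otsu default.
#' @param max_link_distance,max_gap see [link_tracks()].
#' @param min_slices see [track_volume()].
#' @return List: `tracks`, `table` (data.frame track_id, n_slices, d_max_um,
#'   area_um2, volume_um3 with `NA` for excluded volumes, centroid_y/x_um),
#'   `quality_threshold` used.
#' @export
run_slice_track <- function(stack, estimated_diameter = 10,
                            quality_threshold = NULL,
                            max_link_distance = 5, max_gap = 0L,
                            min_slices = 3L) {
  nz <- dim(stack$voxels)[1]
  blobs <- lapply(seq_len(nz), function(k)
    detect_blobs(stack$voxels[k, , ], dx = stack$dx, dy = stack$dy,
                 estimated_diameter = estimated_diameter))
  allq <- unlist(lapply(blobs, function(b) b$quality))
  thr <- if (is.null(quality_threshold)) {
    if (length(allq)) otsu_split(allq) else 0
  } else quality_threshold
  blobs <- lapply(blobs, filter_quality, threshold = thr)
  tracks <- link_tracks(blobs, max_link_distance = max_link_distance,
                        max_gap = max_gap)
  tab <- do.call(rbind, lapply(tracks, function(t) {
    data.frame(track_id = t$track_id, n_slices = nrow(t$detections),
               d_max_um = max(t$detections$diameter_um),
               area_um2 = track_area(t),
               volume_um3 = track_volume(t, dz = stack$dz,
                                         min_slices = min_slices),
               centroid_y_um = mean(t$detections$y_um),
               centroid_x_um = mean(t$detections$x_um))
  }))
  if (is.null(tab))
    tab <- data.frame(track_id = integer(), n_slices = integer(),
                      d_max_um = numeric(), area_um2 = numeric(),
                      volume_um3 = numeric(), centroid_y_um = numeric(),
                      centroid_x_um = numeric())
  list(tracks = tracks, table = tab, quality_threshold = unname(thr))
}
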