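#' Match detections against phantom ground truth
#'
#' Detections and truth objects are paired greedily by nearest centroid
#' within `match_radius` (3D when the detection table carries a z centroid,
#' lateral otherwise; lateral matching suits projection-based methods).
#' Unmatched truth objects are misses; unmatched detections are false
#' positives. Relative measurement errors are computed for matched pairs:
#' volumes against the analytic ellipsoid volume, areas against the analytic
#' equatorial area `pi * r_y * r_x`.
#'
#' @param truth phantom truth data.frame (plant nuclei are the targets;
#'   fungal nuclei and wall artifacts are expected exclusions and any
#'   detection matching one counts as a false positive).
#' @param table a method's measurement table with `centroid_*_um` columns and
#'   `volume_um3` and/or `area_um2`.
#' @param match_radius pairing distance in um (default 5).
#' @return List: `recall`, `precision`, `n_matched`, `errors` (data.frame per
#'   matched pair with relative errors), `unmatched_truth_ids`.
#' @export
benchmark_methods <- function(truth, table, match_radius = 5) {
  targets <- truth[truth$kind == "plant_nucleus", , drop = FALSE]
  nd <- nrow(table)
  use_z <- "centroid_z_um" %in% names(table)
  if (nd == 0 || nrow(targets) == 0)
    return(list(recall = if (nrow(targets)) 0 else NA_real_,
                precision = if (nd) 0 else NA_real_,
                n_matched = 0L,
                errors = data.frame(), unmatched_truth_ids = targets$id))
  dist <- outer(table$centroid_y_um, targets$center_y_um, `-`)^2 +
    outer(table$centroid_x_um, targets$center_x_um, `-`)^2
  if (use_z)
    dist <- dist + outer(table$centroid_z_um, targets$center_z_um, `-`)^2
  dist <- sqrt(dist)
  cand <- which(dist <= match_radius, arr.ind = TRUE)
  cand <- cand[order(dist[cand]), , drop = FALSE]
  det_used <- logical(nd); tru_used <- logical(nrow(targets))
  pairs <- list()
  for (r in seq_len(nrow(cand))) {
    d <- cand[r, 1]; t <- cand[r, 2]
    if (det_used[d] || tru_used[t]) next
    det_used[d] <- TRUE; tru_used[t] <- TRUE
    row <- data.frame(truth_id = targets$id[t], distance_um = dist[d, t])
    if ("volume_um3" %in% names(table))
      row$volume_rel_error <- (table$volume_um3[d] - targets$true_volume_um3[t]) /
        targets$true_volume_um3[t]
    if ("area_um2" %in% names(table)) {
      true_area <- pi * targets$r_y_um[t] * targets$r_x_um[t]
      row$area_rel_error <- (table$area_um2[d] - true_area) / true_area
    }
    pairs[[length(pairs) + 1L]] <- row
  }
  errors <- if (length(pairs)) do.call(rbind, pairs) else data.frame()
  list(recall = sum(tru_used) / nrow(targets),
       precision = sum(det_used) / nd,
       n_matched = sum(tru_used),
       errors = errors,
       unmatched_truth_ids = targets$id[!tru_used])
}

#' End-to-end pipeline: measure, class, compare, report
#'
#' Runs the selected measurement methods on one input (a TIFF stack or a
#' generated phantom), writes per-method measurement tables, Sturges class
#' tables and -- for phantom runs -- a per-method benchmark against ground
#' truth. Every output is stamped with package version, seed and the full
#' parameter set, and is bit-reproducible from the config.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   `input` (either `list(tiff=, dx=, dy=, dz=)` or
#'   `list(phantom = <phantom_config args>)`), `methods` (subset of
#'   `c("track", "rsd", "oc3d")`), optional per-method parameter lists
#'   (`track`, `rsd`, `oc3d`), `stats` (`width`, `anchor`), `seed`,
#'   `output_dir`.
#' @return List: `tables` (per-method data.frames), `classes` (per-method
#'   Sturges class tables for volume methods), `benchmark` (phantom runs
#'   only), `paths` of files written, `config` as run.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("input", "methods", "output_dir"))
    if (is.null(config[[field]])) stop("config is missing `", field, "`")
  bad <- setdiff(config$methods, c("track", "rsd", "oc3d"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(config$input$phantom)) {
    pc <- do.call(phantom_config, c(config$input$phantom, list(seed = seed)))
    ph <- generate_phantom(pc)
    stack <- ph$stack; truth <- ph$truth
  } else if (!is.null(config$input$tiff)) {
    inp <- config$input
    stack <- load_stack(inp$tiff, dx = inp$dx,
                        dy = if (is.null(inp$dy)) inp$dx else inp$dy,
                        dz = inp$dz)
  } else stop("config$input needs `phantom` or `tiff`")

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage `", name, "` failed on input `", stack$name, "`: ",
           conditionMessage(e), call. = FALSE))
  }
  tables <- list(); classes <- list(); benchmark <- list(); paths <- character()
  meta <- c(sprintf("# nucsize %s", as.character(utils::packageVersion("nucsize"))),
            sprintf("# seed: %d", seed),
            sprintf("# input: %s", stack$name))
  stats_cfg <- config$stats
  width <- if (is.null(stats_cfg$width)) 25 else stats_cfg$width
  anchor <- if (is.null(stats_cfg$anchor)) 20 else stats_cfg$anchor

  for (m in config$methods) {
    res <- switch(m,
      track = run_stage("track", function()
        do.call(run_slice_track, c(list(stack), config$track))),
      rsd = run_stage("rsd", function()
        do.call(run_rsd, c(list(stack), config$rsd))),
      oc3d = run_stage("oc3d", function()
        do.call(run_object_counter, c(list(stack), config$oc3d))))
    tab <- res$table
    tables[[m]] <- tab
    p <- file.path(config$output_dir, paste0(m, "_measurements.csv"))
    writeLines(meta, p)
    suppressWarnings(write.table(tab, p, sep = ",", row.names = FALSE,
                                 append = TRUE))
    paths <- c(paths, p)
    if ("volume_um3" %in% names(tab)) {
      v <- tab$volume_um3[!is.na(tab$volume_um3)]
      cl <- bin_classes(v, width = width, anchor = anchor)
      classes[[m]] <- cl$classes
      pc <- file.path(config$output_dir, paste0(m, "_classes.csv"))
      writeLines(meta, pc)
      suppressWarnings(write.table(cl$classes, pc, sep = ",",
                                   row.names = FALSE, append = TRUE))
      paths <- c(paths, pc)
    }
    if (!is.null(truth))
      benchmark[[m]] <- benchmark_methods(truth, tab)
  }

  report <- list(
    version = as.character(utils::packageVersion("nucsize")),
    seed = seed, input = stack$name, methods = config$methods,
    parameters = config[setdiff(names(config), c("input", "output_dir"))],
    counts = lapply(tables, nrow),
    benchmark = lapply(benchmark, function(b)
      list(recall = b$recall, precision = b$precision,
           n_matched = b$n_matched,
           median_abs_volume_error =
             if (nrow(b$errors) && "volume_rel_error" %in% names(b$errors))
               median(abs(b$errors$volume_rel_error)) else NULL,
           median_abs_area_error =
             if (nrow(b$errors) && "area_rel_error" %in% names(b$errors))
               median(abs(b$errors$area_rel_error)) else NULL)))
  pj <- file.path(config$output_dir, "report.json")
  jsonlite::write_json(report, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, pj)
  list(tables = tables, classes = classes, benchmark = benchmark,
       paths = paths, config = config, truth = truth)
}
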