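#' Configuration for the synthetic root-section phantom
#'
#' The phantom emulates the salient properties of DAPI-stained thick root
#' sections imaged by confocal microscopy: bright, roughly ellipsoidal plant
#' nuclei whose equatorial cross-sections span ~15-150 um^2 and volumes
#' ~15-220 um^3; much smaller fungal nuclei (~1 um radius); faint elongated
#' wall-like staining artifacts; depth-dependent intensity attenuation; and
#' photon (Poisson) plus read (Gaussian) noise. Every rendered object is
#' accompanied by exact ground truth, so detection and measurement accuracy
#' can be quantified without real images.
#'
#' Plant-nucleus volumes are drawn from a lognormal mixture whose components
#' sit near 30, 55, 80 and 105 um^3, mirroring a population with recursive
#' ploidy doubling; the equatorial radius is floored so the equatorial area
#' stays above the ~15 um^2 size gate that separates plant from fungal
#' nuclei.
#'
#' @param shape integer vector `(n_slices, ny, nx)`.
#' @param dx,dy,dz voxel calibration in um. Defaults match a 1024 px = 375 um
#'   field of view and a 1.5 um z-step.
#' @param n_plant,n_fungal,n_wall object counts per kind.
#' @param volume_components,volume_weights,volume_sdlog lognormal mixture for
#'   plant-nucleus volumes (um^3): component medians, mixing weights, and the
#'   common log-scale sd.
#' @param min_separation minimum centre-to-centre distance between any two
#'   objects, um.
#' @param attenuation_um depth attenuation length L in um: intensity is
#'   multiplied by `exp(-z/L)`. `Inf` disables attenuation.
#' @param poisson_noise logical; add photon shot noise.
#' @param read_noise_sd sd of additive Gaussian read noise (intensity counts);
#'   0 disables.
#' @param peak_plant,peak_fungal,peak_wall peak intensities (counts).
#' @param band_y optional `c(lo, hi)` in um: confine object centres to this
#'   lateral band (a "cortex band" for crop tests).
#' @param seed integer; fixes the generated stack bit-exactly.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(30L, 256L, 256L),
                           dx = 375 / 1024, dy = dx, dz = 1.5,
                           n_plant = 20L, n_fungal = 5L, n_wall = 3L,
                           volume_components = c(30, 55, 80, 105),
                           volume_weights = c(0.45, 0.27, 0.17, 0.11),
                           volume_sdlog = 0.12,
                           min_separation = 12,
                           attenuation_um = 45,
                           poisson_noise = TRUE,
                           read_noise_sd = 20,
                           peak_plant = 3000, peak_fungal = 2400,
                           peak_wall = 800,
                           band_y = NULL,
                           seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1),
            n_plant >= 0, n_fungal >= 0, n_wall >= 0,
            min_separation >= 0, attenuation_um > 0,
            length(volume_components) == length(volume_weights),
            all(volume_components > 0), all(volume_weights > 0),
            volume_sdlog >= 0)
  structure(list(shape = as.integer(shape), dx = dx, dy = dy, dz = dz,
                 n_plant = n_plant, n_fungal = n_fungal, n_wall = n_wall,
                 volume_components = volume_components,
                 volume_weights = volume_weights / sum(volume_weights),
                 volume_sdlog = volume_sdlog,
                 min_separation = min_separation,
                 attenuation_um = attenuation_um,
                 poisson_noise = poisson_noise,
                 read_noise_sd = read_noise_sd,
                 peak_plant = peak_plant, peak_fungal = peak_fungal,
                 peak_wall = peak_wall, band_y = band_y, seed = seed),
            class = "phantom_config")
}

# run `expr` under a seeded, restored RNG so generation never disturbs the
# caller's random stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# super-Gaussian ellipsoid profile: half-maximum falls exactly on the
# ellipsoid surface (m = 1) and the edge is steep, emulating sharply bounded
# chromatin-filled nuclei
render_object <- function(vox, cfg, center, radii, peak) {
  d <- dim(vox)
  reach <- 1.8
  k0 <- max(1L, floor((center[1] - reach * radii[1]) / cfg$dz) + 1L)
  k1 <- min(d[1], ceiling((center[1] + reach * radii[1]) / cfg$dz) + 1L)
  j0 <- max(1L, floor((center[2] - reach * radii[2]) / cfg$dy) + 1L)
  j1 <- min(d[2], ceiling((center[2] + reach * radii[2]) / cfg$dy) + 1L)
  i0 <- max(1L, floor((center[3] - reach * radii[3]) / cfg$dx) + 1L)
  i1 <- min(d[3], ceiling((center[3] + reach * radii[3]) / cfg$dx) + 1L)
  if (k0 > k1 || j0 > j1 || i0 > i1) return(vox)
  zz <- ((k0:k1) - 1) * cfg$dz
  yy <- ((j0:j1) - 1) * cfg$dy
  xx <- ((i0:i1) - 1) * cfg$dx
  mz2 <- ((zz - center[1]) / radii[1])^2
  my2 <- ((yy - center[2]) / radii[2])^2
  mx2 <- ((xx - center[3]) / radii[3])^2
  m2 <- outer(outer(mz2, my2, `+`), mx2, `+`)
  att <- if (is.finite(cfg$attenuation_um)) exp(-zz / cfg$attenuation_um) else rep(1, length(zz))
  blob <- peak * exp(-log(2) * m2^2) * att  # att recycles along z (first dim)
  vox[k0:k1, j0:j1, i0:i1] <- vox[k0:k1, j0:j1, i0:i1] + blob
  vox
}

draw_plant_geometry <- function(cfg) {
  comp <- sample.int(length(cfg$volume_components), 1, prob = cfg$volume_weights)
  V <- rlnorm(1, meanlog = log(cfg$volume_components[comp]),
              sdlog = cfg$volume_sdlog)
  V <- min(max(V, 15), 220)
  s <- runif(1, 0.7, 1.0)                  # rz / rx aspect
  rx <- (3 * V / (4 * pi * s))^(1 / 3)
  rx <- max(rx, sqrt(15.5 / pi))           # keep equatorial area above the gate
  rz <- 3 * V / (4 * pi * rx^2)
  list(radii = c(rz, rx, rx), volume = V)
}

#' Generate a calibrated phantom stack with exact ground truth
#'
#' Objects are placed by rejection sampling at the configured minimum
#' separation, rendered as steep-edged ellipsoidal blobs whose half-maximum
#' isosurface is exactly the true ellipsoid, attenuated with depth, and
#' optionally degraded with Poisson and Gaussian noise. Truth-table volumes
#' are analytic (`4/3*pi*rz*ry*rx`), not measured from the render.
#'
#' @param config a [phantom_config()].
#' @return A list with `stack` (a [calibrated_stack()]) and `truth`
#'   (data.frame: id, kind, center_z/y/x_um, r_z/y/x_um, true_volume_um3,
#'   peak).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  with_seed(cfg$seed, {
    extent <- cfg$shape * c(cfg$dz, cfg$dy, cfg$dx)
    kinds <- c(rep("plant_nucleus", cfg$n_plant),
               rep("fungal_nucleus", cfg$n_fungal),
               rep("wall_artifact", cfg$n_wall))
    centers <- matrix(NA_real_, length(kinds), 3)
    truth <- vector("list", length(kinds))
    for (o in seq_along(kinds)) {
      geom <- switch(kinds[o],
        plant_nucleus = {
          g <- draw_plant_geometry(cfg)
          c(g$radii, cfg$peak_plant, g$volume)
        },
        fungal_nucleus = {
          r <- runif(3, 0.8, 1.2)
          c(r, cfg$peak_fungal, 4 / 3 * pi * prod(r))
        },
        wall_artifact = {
          r <- c(0.6, 0.6, runif(1, 6, 12))   # long thin bar along x
          c(r, cfg$peak_wall, 4 / 3 * pi * prod(r))
        })
      radii <- geom[1:3]
      placed <- FALSE
      for (try in seq_len(5000L)) {
        margin <- radii + c(cfg$dz, 1, 1)
        ylim <- if (is.null(cfg$band_y)) c(margin[2], extent[2] - margin[2])
                else c(cfg$band_y[1] + margin[2], cfg$band_y[2] - margin[2])
        if (ylim[1] >= ylim[2] || 2 * margin[1] >= extent[1] ||
            2 * margin[3] >= extent[3])
          stop("phantom packing infeasible: object of extent ",
               paste(signif(2 * radii, 3), collapse = "x"),
               " um does not fit the stack/band")
        ctr <- c(runif(1, margin[1], extent[1] - margin[1]),
                 runif(1, ylim[1], ylim[2]),
                 runif(1, margin[3], extent[3] - margin[3]))
        ok <- o == 1 ||
          all(sqrt(colSums((t(centers[seq_len(o - 1), , drop = FALSE]) - ctr)^2)) >=
                cfg$min_separation)
        if (ok) { centers[o, ] <- ctr; placed <- TRUE; break }
      }
      if (!placed)
        stop("phantom packing infeasible: could not place object ", o,
             " at min_separation = ", cfg$min_separation, " um")
      truth[[o]] <- data.frame(
        id = o, kind = kinds[o],
        center_z_um = centers[o, 1], center_y_um = centers[o, 2],
        center_x_um = centers[o, 3],
        r_z_um = radii[1], r_y_um = radii[2], r_x_um = radii[3],
        true_volume_um3 = geom[5], peak = geom[4])
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(id = integer(), kind = character(), center_z_um = numeric(),
                 center_y_um = numeric(), center_x_um = numeric(),
                 r_z_um = numeric(), r_y_um = numeric(), r_x_um = numeric(),
                 true_volume_um3 = numeric(), peak = numeric())

    vox <- array(0, cfg$shape)
    for (o in seq_len(nrow(truth)))
      vox <- render_object(vox, cfg,
                           unlist(truth[o, c("center_z_um", "center_y_um",
                                             "center_x_um")]),
                           unlist(truth[o, c("r_z_um", "r_y_um", "r_x_um")]),
                           truth$peak[o])
    if (cfg$poisson_noise) vox[] <- rpois(length(vox), lambda = vox)
    if (cfg$read_noise_sd > 0)
      vox[] <- vox + rnorm(length(vox), sd = cfg$read_noise_sd)
    vox[vox < 0] <- 0
    vox[] <- round(pmin(vox, 65535))
    list(stack = calibrated_stack(vox, dx = cfg$dx, dy = cfg$dy, dz = cfg$dz,
                                  name = sprintf("phantom_seed%d", cfg$seed)),
         truth = truth)
  })
}

#' Write a phantom to disk (TIFF stack + CSV truth table)
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(phantom$stack$name, ".tif"))
  csv <- file.path(dir, paste0(phantom$stack$name, "_truth.csv"))
  write_stack(phantom$stack, tif)
  write.csv(phantom$truth, csv, row.names = FALSE)
  invisible(c(stack = tif, truth = csv))
}

#' Reproducible samples from the size distributions used in testing
#'
#' Lognormal and gamma are the two candidate families for nuclear size
#' distributions; this draws i.i.d. samples for statistics tests.
#'
#' @param distribution `"lognormal"` or `"gamma"`.
#' @param params named list: `meanlog`/`sdlog` for lognormal (sdlog >= 0),
#'   `shape`/`rate` (or `shape`/`scale`) for gamma, all positive.
#' @param n sample size, >= 1.
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_population <- function(distribution = c("lognormal", "gamma"),
                              params, n, seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(n >= 1)
  with_seed(seed, {
    if (distribution == "lognormal") {
      if (is.null(params$sdlog) || params$sdlog < 0)
        stop("lognormal requires sdlog >= 0")
      rlnorm(n, meanlog = params$meanlog, sdlog = params$sdlog)
    } else {
      shape <- params$shape
      if (is.null(shape) || shape <= 0) stop("gamma requires shape > 0")
      if (!is.null(params$scale)) {
        if (params$scale <= 0) stop("gamma scale must be > 0")
        rgamma(n, shape = shape, scale = params$scale)
      } else {
        if (is.null(params$rate) || params$rate <= 0)
          stop("gamma rate must be > 0")
        rgamma(n, shape = shape, rate = params$rate)
      }
    }
  })
}
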