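# fixture builders and independent oracles shared across test files

# noise-free, non-attenuated phantom of mid-sized, well-separated plant nuclei
clean_phantom <- function(n_plant = 10, seed = 42,
                          volume_components = c(55, 80, 105),
                          shape = c(30L, 256L, 256L), ...) {
  generate_phantom(phantom_config(
    shape = shape, n_plant = n_plant, n_fungal = 0L, n_wall = 0L,
    volume_components = volume_components,
    volume_weights = rep(1, length(volume_components)),
    poisson_noise = FALSE, read_noise_sd = 0, attenuation_um = Inf,
    seed = seed, ...))
}

# rasterized sphere/ellipsoid mask on a (z, y, x) grid with voxel sizes
# (dz, dy, dx); a voxel is inside when its centre is inside the surface
raster_ellipsoid <- function(dims, cal, center, radii) {
  zz <- (seq_len(dims[1]) - 1) * cal[1]
  yy <- (seq_len(dims[2]) - 1) * cal[2]
  xx <- (seq_len(dims[3]) - 1) * cal[3]
  m2 <- outer(outer(((zz - center[1]) / radii[1])^2,
                    ((yy - center[2]) / radii[2])^2, `+`),
              ((xx - center[3]) / radii[3])^2, `+`)
  m2 <= 1
}

# brute-force flood-fill labeling oracle (pure R, queue-based)
flood_fill_oracle <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  labels <- array(0L, d)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      k <- (v - 1) %% d[1] + 1
      j <- ((v - 1) %/% d[1]) %% d[2] + 1
      i <- (v - 1) %/% (d[1] * d[2]) + 1
      for (o in seq_len(nrow(offs))) {
        k2 <- k + offs$dz[o]; j2 <- j + offs$dy[o]; i2 <- i + offs$dx[o]
        if (k2 < 1 || k2 > d[1] || j2 < 1 || j2 > d[2] ||
            i2 < 1 || i2 > d[3]) next
        w <- (i2 - 1) * d[1] * d[2] + (j2 - 1) * d[1] + k2
        if (mask[w] && labels[w] == 0L) {
          labels[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

# two labelings describe the same partition iff the label-pair mapping is a
# bijection on foreground voxels
same_partition <- function(a, b) {
  fg <- a > 0
  if (!identical(fg, b > 0)) return(FALSE)
  pairs <- unique(cbind(a[fg], b[fg]))
  !any(duplicated(pairs[, 1])) && !any(duplicated(pairs[, 2]))
}

# closed-form lognormal skewness for scale parameter sigma
lognormal_skewness <- function(sigma) {
  w <- exp(sigma^2)
  (w + 2) * sqrt(w - 1)
}

# Kruskal-Wallis H by the textbook rank formula (independent of kruskal.test)
kw_h_oracle <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# exact two-sided p of a 2x2 above/not-above median table by hypergeometric
# enumeration (sum of probabilities of tables at most as likely as observed)
median_exact_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  probs <- stats::dhyper(0:min(m, k), m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
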