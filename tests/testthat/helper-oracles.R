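# Independent oracles and fixture builders used across tests. Each oracle is
# a deliberately naive implementation kept separate from the package's code
# paths.

# Brute-force double-loop MSD.
msd_ref <- function(x, y, dt) {
  N <- length(x)
  vapply(seq_len(N - 1), function(n) {
    acc <- 0
    for (i in seq_len(N - n)) {
      acc <- acc + (x[i + n] - x[i])^2 + (y[i + n] - y[i])^2
    }
    acc / (N - n)
  }, numeric(1))
}

# Quadratic-time DBSCAN on a full distance matrix, inclusive neighborhood,
# border points assigned to the cluster of their lowest-indexed core
# neighbor.
dbscan_ref <- function(x, y, eps, min_pts) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    stack <- i
    while (length(stack)) {
      p <- stack[1]; stack <- stack[-1]
      if (labels[p] != 0L) next
      labels[p] <- cl
      stack <- c(stack, nb[[p]][core[nb[[p]]] & labels[nb[[p]]] == 0L])
    }
  }
  for (i in which(!core & labels == 0L)) {
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  labels
}

# Naive 2D a-trous smoothing by explicit loops with whole-sample mirroring.
atrous_smooth_ref <- function(m, step) {
  w <- c(1, 4, 6, 4, 1) / 16
  offs <- (-2:2) * step
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  nr <- nrow(m); nc <- ncol(m)
  tmp <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (k in 1:5) acc <- acc + w[k] * m[refl(r + offs[k], nr), c]
    tmp[r, c] <- acc
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (k in 1:5) acc <- acc + w[k] * tmp[r, refl(c + offs[k], nc)]
    out[r, c] <- acc
  }
  out
}

# Random gapless track as a plain data frame.
random_track <- function(n, seed) {
  set.seed(seed)
  data.frame(frame = 0:(n - 1), x = cumsum(rnorm(n, 0, 0.1)),
             y = cumsum(rnorm(n, 0, 0.1)))
}

# Spots on a jittered grid with guaranteed separation, inside a margin.
spaced_spots <- function(n, extent_nm, spacing_nm, amplitude, seed,
                         jitter_nm = spacing_nm / 6) {
  set.seed(seed)
  per_row <- floor(extent_nm / spacing_nm)
  stopifnot(per_row^2 >= n)
  g <- expand.grid(ix = seq_len(per_row), iy = seq_len(per_row))
  g <- g[seq_len(n), ]
  data.frame(
    x_nm = (g$ix - 0.5) * spacing_nm + runif(n, -jitter_nm, jitter_nm),
    y_nm = (g$iy - 0.5) * spacing_nm + runif(n, -jitter_nm, jitter_nm),
    amplitude = amplitude)
}

# Synthetic pair of segmentation masks with a planted fraction of
# overlapping clusters: n spot pairs on a grid; a fraction of B spots sit on
# their A partner, the rest are displaced well beyond the apposition range.
planted_coloc_masks <- function(n, frac_overlap, seed,
                                pixel_size_nm = 100, spacing_px = 16,
                                displace_px = 6) {
  set.seed(seed)
  per_row <- ceiling(sqrt(n))
  dim_px <- per_row * spacing_px + spacing_px
  overlap <- sample(c(rep(TRUE, round(n * frac_overlap)),
                      rep(FALSE, n - round(n * frac_overlap))))
  g <- expand.grid(ix = seq_len(per_row), iy = seq_len(per_row))[seq_len(n), ]
  ax <- (g$ix) * spacing_px; ay <- (g$iy) * spacing_px
  bx <- ax + ifelse(overlap, 0, displace_px)
  by <- ay
  mk <- function(cx, cy) {
    spots <- data.frame(x_nm = (cx - 1) * pixel_size_nm,
                        y_nm = (cy - 1) * pixel_size_nm,
                        amplitude = 5000)
    img <- render_synthetic_image(image_sim_spec(
      shape = c(dim_px, dim_px), pixel_size_nm = pixel_size_nm,
      psf_sigma_nm = 1.2 * pixel_size_nm, spots = spots, background = 0))
    segment_clusters(img, pixel_size_nm = pixel_size_nm)
  }
  list(A = mk(ax, ay), B = mk(bx, by), planted_fraction = mean(overlap))
}
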