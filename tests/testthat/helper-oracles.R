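# Independent brute-force oracles used to pin down the image primitives.

# Otsu by direct enumeration: for every cut between adjacent distinct pixel
# values, compute the two-class weights and means from the raw pixels and
# maximize the between-class variance; report the midpoint of the winning cut.
oracle_otsu <- function(img) {
  v <- as.vector(img)
  vals <- sort(unique(v))
  best <- -Inf
  bestk <- 1L
  for (k in seq_len(length(vals) - 1L)) {
    lo <- v[v <= vals[k]]
    hi <- v[v > vals[k]]
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; bestk <- k }
  }
  (vals[bestk] + vals[bestk + 1L]) / 2
}

reflect_index <- function(i, n) {
  i <- ifelse(i < 0, -i - 1, i)
  ifelse(i >= n, 2 * n - i - 1, i)
}

# Disk-footprint median by literal neighborhood enumeration with reflection.
oracle_median_disk <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  out <- img
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- reflect_index(r - 1 + offs$dr, nr) + 1
    cc <- reflect_index(c - 1 + offs$dc, nc) + 1
    out[r, c] <- median(img[cbind(rr, cc)])
  }
  out
}

# Count of foreground neighbors (8-connectivity) by direct enumeration.
oracle_neighbor_count <- function(mask, r, c) {
  n <- 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && cc >= 1 && rr <= nrow(mask) && cc <= ncol(mask) &&
        mask[rr, cc]) n <- n + 1
  }
  n
}

# Random blob masks (thresholded smoothed noise) for thinning properties.
random_blob_mask <- function(nr, nc, seed) {
  set.seed(seed)
  f <- tubequant::smooth_image(matrix(rnorm(nr * nc), nr, nc), 2)
  f > quantile(f, 0.8)
}

count_components <- function(mask) {
  if (!any(mask)) return(0L)
  fs <- label_and_filter_short(mask, min_feature_px = 1L, connectivity = 8L)
  nrow(fs$flags)
}

# One synthetic scene holding a single straight tube of known length.
straight_tube_scene <- function(length_px, seed, tube_amplitude = 1000,
                                read_noise_sd = 200, pixel_size = 0.1,
                                shape = c(128L, 128L)) {
  scene_spec(image_shape = shape, pixel_size = pixel_size, n_tubes = 1L,
             length_distribution = dist_fixed(length_px * pixel_size),
             curvature = 0, psf_sigma = 1.3, tube_amplitude = tube_amplitude,
             background_level = 500, illumination_gradient = 0.2,
             read_noise_sd = read_noise_sd, shot_noise = TRUE, seed = seed)
}
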