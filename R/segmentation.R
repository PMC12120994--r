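as_intensity <- function(x) {
  if (inherits(x, "micrograph")) x$intensity
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a micrograph or a numeric matrix", call. = FALSE)
}

#' Segmentation pipeline configuration
#'
#' Parameters of the micrograph-to-lengths procedure. The median-filter
#' footprint radius defaults to 15 px, the midpoint of the 10-20 px range
#' appropriate for removing tube-scale bright features while preserving the
#' slowly varying illumination background. Thinning, short-feature removal
#' (< `min_feature_px` skeleton pixels) and branch-point pruning run with
#' 8-connectivity by default.
#'
#' @param median_radius disk radius of the background median filter, pixels
#'   (1-100).
#' @param gaussian_sigma sigma of the pre-subtraction Gaussian smoothing,
#'   pixels; 0 disables smoothing.
#' @param threshold_method one of `"otsu"`, `"yen"`, `"triangle"`.
#' @param min_feature_px minimum skeleton pixel count of a measurable
#'   feature.
#' @param connectivity 4 or 8, used for labeling and branch detection.
#' @param length_metric `"pixel_count"` (skeleton pixel count) or
#'   `"geodesic"` (step sum along the skeleton path, sqrt(2) per diagonal
#'   move).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(median_radius = 15L,
                            gaussian_sigma = 1,
                            threshold_method = c("otsu", "yen", "triangle"),
                            min_feature_px = 3L,
                            connectivity = 8L,
                            length_metric = c("pixel_count", "geodesic")) {
  if (median_radius < 1 || median_radius > 100)
    stop("median_radius must lie in [1, 100]", call. = FALSE)
  stopifnot_scalar_pos(gaussian_sigma, "gaussian_sigma", strict = FALSE)
  threshold_method <- match.arg(threshold_method)
  if (min_feature_px < 1) stop("min_feature_px must be >= 1", call. = FALSE)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  length_metric <- match.arg(length_metric)
  structure(list(median_radius = as.integer(median_radius),
                 gaussian_sigma = gaussian_sigma,
                 threshold_method = threshold_method,
                 min_feature_px = as.integer(min_feature_px),
                 connectivity = as.integer(connectivity),
                 length_metric = length_metric),
            class = "pipeline_config")
}

#' Estimate the image background by disk-footprint median filtering
#'
#' A median filter with a footprint much larger than the tube width removes
#' the bright tubes and leaves the smooth (possibly uneven) illumination
#' field, which is then subtracted from the smoothed image. Edges are
#' handled by reflection.
#'
#' @param img a [micrograph] or numeric matrix.
#' @param median_radius disk radius in pixels (>= 1).
#' @return A numeric matrix of the same shape.
#' @export
estimate_background <- function(img, median_radius = 15L) {
  x <- as_intensity(img)
  if (median_radius < 1) stop("median_radius must be >= 1", call. = FALSE)
  .cpp_median_disk(x, as.integer(median_radius))
}

#' Gaussian smoothing
#'
#' @param img a [micrograph] or numeric matrix.
#' @param gaussian_sigma sigma in pixels; 0 returns the input unchanged.
#' @return A numeric matrix of the same shape.
#' @export
smooth_image <- function(img, gaussian_sigma = 1) {
  x <- as_intensity(img)
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0", call. = FALSE)
  .cpp_gaussian_blur(x, gaussian_sigma)
}

#' Subtract the background estimate from the smoothed image
#'
#' Negative residuals are clipped to 0 so that downstream histogram
#' thresholding sees a non-negative intensity distribution.
#'
#' @param smoothed numeric matrix (Gaussian-smoothed image).
#' @param background numeric matrix (median-filter background).
#' @return Clipped difference, same shape.
#' @export
subtract_background <- function(smoothed, background) {
  a <- as_intensity(smoothed); b <- as_intensity(background)
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  pmax(a - b, 0)
}

# Maximize between-class variance over the candidate cuts between adjacent
# distinct values; the returned threshold is the midpoint of the maximizing
# cut, so both classes sit strictly on either side of it.
otsu_from_counts <- function(vals, counts) {
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * vals)
  mu_t <- mu[length(mu)]
  j <- seq_len(length(vals) - 1L)
  sb <- (mu_t * omega[j] - mu[j])^2 / (omega[j] * (1 - omega[j]))
  k <- which.max(sb)
  (vals[k] + vals[k + 1L]) / 2
}

yen_from_counts <- function(vals, counts) {
  p <- counts / sum(counts)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- sum(p^2) - P1sq
  j <- seq_len(length(vals) - 1L)
  crit <- rep(-Inf, length(j))
  ok <- P1[j] > 0 & P1[j] < 1 & P1sq[j] > 0 & P2sq[j] > 0
  crit[ok] <- -log(P1sq[j][ok] * P2sq[j][ok]) +
    2 * log(P1[j][ok] * (1 - P1[j][ok]))
  k <- which.max(crit)
  (vals[k] + vals[k + 1L]) / 2
}

#' Automatic histogram threshold (Otsu, Yen, Triangle)
#'
#' Computes a global intensity threshold on the background-subtracted image.
#' For Otsu the returned value exactly maximizes the between-class variance
#' over all candidate thresholds; candidates are the distinct pixel values
#' (the foreground mask `intensity > t` can only change there) unless the
#' image has more than `nbins` distinct values, in which case the histogram
#' is binned. Ties resolve to the lowest maximizing value.
#'
#' @param img a [micrograph] or numeric matrix with at least two distinct
#'   values.
#' @param method `"otsu"`, `"yen"` or `"triangle"`.
#' @param nbins histogram resolution used for many-valued images and for the
#'   triangle method (which is defined on an equal-width histogram).
#' @return A scalar threshold within the image's intensity range.
#' @export
compute_threshold <- function(img, method = c("otsu", "yen", "triangle"),
                              nbins = 256L) {
  method <- match.arg(method)
  v <- as.vector(as_intensity(img))
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("degenerate histogram: image is constant", call. = FALSE)
  if (method == "triangle") {
    br <- seq(rng[1], rng[2], length.out = nbins + 1L)
    h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), nbins),
                  nbins)
    centers <- (br[-1] + br[-length(br)]) / 2
    return(triangle_threshold(centers, h))
  }
  tab <- table(v)
  vals <- as.numeric(names(tab))
  counts <- as.numeric(tab)
  if (length(vals) > nbins) {
    br <- seq(rng[1], rng[2], length.out = nbins + 1L)
    bin <- pmin(findInterval(v, br, rightmost.closed = TRUE), nbins)
    counts <- tabulate(bin, nbins)
    vals <- (br[-1] + br[-length(br)]) / 2
    keep <- counts > 0
    vals <- vals[keep]; counts <- counts[keep]
  }
  switch(method,
         otsu = otsu_from_counts(vals, counts),
         yen = yen_from_counts(vals, counts))
}

# Classic triangle construction: a line from the histogram peak to the far
# end of the longer tail; the threshold sits at the bin whose histogram
# point is furthest from that line.
triangle_threshold <- function(centers, h) {
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  peak <- which.max(h)
  if ((peak - lo) >= (hi - peak)) { end <- lo } else { end <- hi }
  if (abs(end - peak) < 2) return(centers[peak])
  ix <- if (end > peak) peak:end else end:peak
  px <- centers[peak]; py <- h[peak]
  ex <- centers[end];  ey <- 0
  dx <- ex - px; dy <- ey - py
  nrm <- sqrt(dx^2 + dy^2)
  d <- abs(dx * (py - h[ix]) - (px - centers[ix]) * dy) / nrm
  centers[ix][which.max(d)]
}

#' Binarize an image at a threshold
#'
#' @param img a [micrograph] or numeric matrix.
#' @param threshold scalar; the mask is `intensity > threshold`.
#' @return A logical matrix.
#' @export
binarize <- function(img, threshold) {
  as_intensity(img) > threshold
}

#' Thin a binary mask to unit thickness
#'
#' Zhang-Suen two-subiteration thinning run to convergence: every feature is
#' reduced to a 1-pixel-thick skeleton, connected components are preserved,
#' and the operation is idempotent.
#'
#' @param mask logical (or 0/1) matrix.
#' @return A logical matrix.
#' @export
thin_mask <- function(mask) {
  m <- .cpp_thin(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  m != 0L
}

#' Label skeleton features and flag those shorter than the minimum
#'
#' Connected components of the skeleton are labeled; components with fewer
#' than `min_feature_px` pixels are flagged `too_short` and excluded from
#' measurement, since such fragments cannot be identified as nanotubes.
#'
#' @param skeleton logical matrix, 1 px thick.
#' @param min_feature_px minimum pixel count to keep (default 3).
#' @param connectivity 4 or 8.
#' @return An object of class `feature_set`.
#' @export
label_and_filter_short <- function(skeleton, min_feature_px = 3L,
                                   connectivity = 8L) {
  m <- matrix(as.integer(skeleton != 0), nrow(skeleton), ncol(skeleton))
  lab <- .cpp_label(m, as.integer(connectivity))
  nlab <- max(lab)
  feats <- vector("list", nlab)
  if (nlab > 0) {
    idx <- which(lab > 0)
    labs <- lab[idx]
    nr <- nrow(lab)
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    sp <- split(seq_along(idx), labs)
    for (k in seq_len(nlab))
      feats[[k]] <- cbind(row = rows[sp[[k]]], col = cols[sp[[k]]])
  }
  npx <- vapply(feats, nrow, integer(1))
  flags <- data.frame(feature_id = seq_len(nlab), n_px = npx,
                      too_short = npx < min_feature_px,
                      branched = logical(nlab))
  flags$retained <- !flags$too_short
  structure(list(skeleton = m, labels = lab, features = feats, flags = flags,
                 min_feature_px = as.integer(min_feature_px),
                 connectivity = as.integer(connectivity)),
            class = "feature_set")
}

#' Flag and exclude intersecting (branched) features
#'
#' A branch pixel is a skeleton pixel with more than two neighbors under the
#' configured connectivity; overlapping or crossing filaments produce such
#' pixels, and since the individual lengths in an intersection cannot be
#' resolved, the entire component is excluded.
#'
#' @param features a [label_and_filter_short()] `feature_set`.
#' @return The `feature_set` with `branched` and `retained` flags updated.
#' @export
remove_branched <- function(features) {
  stopifnot(inherits(features, "feature_set"))
  nb <- .cpp_neighbor_count(features$skeleton, features$connectivity)
  branch_labels <- unique(features$labels[features$labels > 0 & nb > 2])
  features$flags$branched <- features$flags$feature_id %in% branch_labels
  features$flags$retained <- !features$flags$too_short & !features$flags$branched
  features
}

#' @export
print.feature_set <- function(x, ...) {
  f <- x$flags
  cat(sprintf("<feature_set> %d features: %d retained, %d too short (<%d px), %d branched\n",
              nrow(f), sum(f$retained), sum(f$too_short), x$min_feature_px,
              sum(f$branched)))
  invisible(x)
}

# Step-sum length along a 1-px-thick non-branching path; diagonal moves
# weighted sqrt(2). Falls back to n - 1 if the walk cannot cover the
# component (does not occur for properly thinned skeletons).
geodesic_length <- function(coords) {
  n <- nrow(coords)
  if (n <= 1) return(0)
  key <- paste(coords[, 1], coords[, 2])
  pos <- seq_len(n)
  names(pos) <- key
  off <- cbind(rep(-1:1, each = 3), rep(-1:1, 3))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), ]
  nbrs <- function(i) {
    k <- paste(coords[i, 1] + off[, 1], coords[i, 2] + off[, 2])
    unname(pos[k[k %in% key]])
  }
  deg <- vapply(seq_len(n), function(i) length(nbrs(i)), integer(1))
  start <- if (any(deg == 1)) which(deg == 1)[1] else 1L
  visited <- rep(FALSE, n)
  visited[start] <- TRUE
  cur <- start; total <- 0
  for (step in seq_len(n - 1L)) {
    cand <- nbrs(cur)
    cand <- cand[!visited[cand]]
    if (length(cand) == 0) break
    # prefer axis-aligned moves so staircases are walked pixel by pixel
    dr <- abs(coords[cand, 1] - coords[cur, 1])
    dc <- abs(coords[cand, 2] - coords[cur, 2])
    j <- which.min(dr + dc)
    total <- total + if (dr[j] + dc[j] == 2) sqrt(2) else 1
    visited[cand[j]] <- TRUE
    cur <- cand[j]
  }
  if (!all(visited)) return(n - 1)
  # closed loop: add the returning step
  if (deg[start] == 2 && n > 2) {
    dr <- abs(coords[cur, 1] - coords[start, 1])
    dc <- abs(coords[cur, 2] - coords[start, 2])
    if (dr <= 1 && dc <= 1)
      total <- total + if (dr + dc == 2) sqrt(2) else 1
  }
  total
}

#' Measure lengths of retained features
#'
#' The `pixel_count` metric reports the number of skeleton pixels, matching
#' a region-properties measurement of a thinned feature; the `geodesic`
#' metric sums the inter-pixel steps along the skeleton path with weight
#' sqrt(2) for diagonal moves, which tracks the true arc length of oblique
#' filaments more closely.
#'
#' @param features a `feature_set` (after [remove_branched()]).
#' @param pixel_size micrometers per pixel (> 0).
#' @param length_metric `"pixel_count"` or `"geodesic"`.
#' @param image_id label copied into the records.
#' @return Data frame with columns `image_id`, `feature_id`, `length_px`,
#'   `length_um`, one row per retained feature.
#' @export
measure_lengths <- function(features, pixel_size,
                            length_metric = c("pixel_count", "geodesic"),
                            image_id = "img") {
  stopifnot(inherits(features, "feature_set"))
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  length_metric <- match.arg(length_metric)
  keep <- which(features$flags$retained)
  len_px <- vapply(keep, function(k) {
    if (length_metric == "pixel_count") as.numeric(features$flags$n_px[k])
    else geodesic_length(features$features[[k]])
  }, numeric(1))
  data.frame(image_id = rep(image_id, length(keep)),
             feature_id = features$flags$feature_id[keep],
             length_px = len_px,
             length_um = len_px * pixel_size)
}

#' Run the full micrograph-to-lengths pipeline
#'
#' Stages, in order: median-filter background estimation, Gaussian
#' smoothing, background subtraction (clipped at 0), automatic thresholding,
#' binarization, thinning to 1 px, removal of features shorter than
#' `min_feature_px`, removal of branched (intersecting) features, and length
#' measurement. A constant residual image (degenerate histogram) skips the
#' image with a warning and returns zero records.
#'
#' @param img a [micrograph].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, writes `records_<id>.csv`,
#'   `params_<id>.csv` (the full config snapshot, threshold used, feature
#'   counts) and a diagnostic overlay `overlay_<id>.png` marking measured
#'   features.
#' @return An object of class `tube_segmentation`: list with `records`,
#'   `features`, `threshold`, `config`, `image_id`.
#' @export
run_pipeline <- function(img, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(img, "micrograph"), inherits(config, "pipeline_config"))
  bg <- estimate_background(img, config$median_radius)
  sm <- smooth_image(img, config$gaussian_sigma)
  resid <- subtract_background(sm, bg)
  thr <- tryCatch(compute_threshold(resid, config$threshold_method),
                  error = function(e) NA_real_)
  if (is.na(thr)) {
    warning(sprintf("image '%s': degenerate intensity histogram; skipped",
                    img$image_id))
    empty <- data.frame(image_id = character(0), feature_id = integer(0),
                        length_px = numeric(0), length_um = numeric(0))
    res <- structure(list(records = empty, features = NULL,
                          threshold = NA_real_, config = config,
                          image_id = img$image_id),
                     class = "tube_segmentation")
    if (!is.null(out_dir)) write_pipeline_outputs(res, img, out_dir)
    return(res)
  }
  mask <- binarize(resid, thr)
  skel <- thin_mask(mask)
  fs <- label_and_filter_short(skel, config$min_feature_px,
                               config$connectivity)
  fs <- remove_branched(fs)
  records <- measure_lengths(fs, img$pixel_size, config$length_metric,
                             image_id = img$image_id)
  res <- structure(list(records = records, features = fs, threshold = thr,
                        config = config, image_id = img$image_id),
                   class = "tube_segmentation")
  if (!is.null(out_dir)) write_pipeline_outputs(res, img, out_dir)
  res
}

#' @export
print.tube_segmentation <- function(x, ...) {
  cat(sprintf("<tube_segmentation '%s'> threshold %.4g, %d measured features\n",
              x$image_id, x$threshold, nrow(x$records)))
  if (nrow(x$records) > 0)
    cat(sprintf("  length range %.3g - %.3g um (mean %.3g um)\n",
                min(x$records$length_um), max(x$records$length_um),
                mean(x$records$length_um)))
  invisible(x)
}

# Diagnostic overlay: grayscale image with measured skeletons in red and
# excluded (branched/short) skeleton pixels in blue.
pipeline_overlay <- function(seg, img) {
  g <- img$intensity / max(1, max(img$intensity))
  arr <- array(rep(g, 3), c(dim(g), 3))
  fs <- seg$features
  if (!is.null(fs)) {
    for (k in seq_len(nrow(fs$flags))) {
      coords <- fs$features[[k]]
      ch <- if (fs$flags$retained[k]) c(1, 0, 0) else c(0, 0, 1)
      for (d in 1:3) arr[cbind(coords, d)] <- ch[d]
    }
  }
  arr
}

write_pipeline_outputs <- function(seg, img, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  id <- gsub("[^A-Za-z0-9_.-]", "_", seg$image_id)
  write.csv(seg$records, file.path(out_dir, paste0("records_", id, ".csv")),
            row.names = FALSE)
  nflag <- if (is.null(seg$features)) c(0L, 0L, 0L) else
    c(sum(seg$features$flags$too_short), sum(seg$features$flags$branched),
      sum(seg$features$flags$retained))
  params <- data.frame(image_id = seg$image_id,
                       median_radius = seg$config$median_radius,
                       gaussian_sigma = seg$config$gaussian_sigma,
                       threshold_method = seg$config$threshold_method,
                       min_feature_px = seg$config$min_feature_px,
                       connectivity = seg$config$connectivity,
                       length_metric = seg$config$length_metric,
                       threshold_value = seg$threshold,
                       n_too_short = nflag[1], n_branched = nflag[2],
                       n_measured = nflag[3])
  write.csv(params, file.path(out_dir, paste0("params_", id, ".csv")),
            row.names = FALSE)
  png::writePNG(pipeline_overlay(seg, img),
                file.path(out_dir, paste0("overlay_", id, ".png")))
  invisible(out_dir)
}
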