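#' Length distribution specifications
#'
#' Small constructors describing how synthetic nanotube lengths are drawn.
#' Nanotube populations growing by tile addition are expected to be
#' exponentially distributed in length, so `dist_exponential()` is the
#' default throughout; `dist_fixed()` and `dist_values()` exist for
#' controlled experiments where exact lengths are needed.
#'
#' @param mean mean length in micrometers (exponential).
#' @param value the single length in micrometers every tube receives.
#' @param values explicit vector of lengths in micrometers, recycled over
#'   tubes in order.
#' @return A list of class `length_dist`.
#' @examples
#' sample_lengths(dist_fixed(5), 4)
#' @export
dist_exponential <- function(mean) {
  stopifnot_scalar_pos(mean, "mean")
  structure(list(type = "exponential", mean = mean), class = "length_dist")
}

#' @rdname dist_exponential
#' @export
dist_fixed <- function(value) {
  stopifnot_scalar_pos(value, "value")
  structure(list(type = "fixed", value = value), class = "length_dist")
}

#' @rdname dist_exponential
#' @export
dist_values <- function(values) {
  if (!is.numeric(values) || length(values) == 0 || any(values <= 0))
    stop("'values' must be a non-empty vector of positive lengths", call. = FALSE)
  structure(list(type = "values", values = as.numeric(values)),
            class = "length_dist")
}

#' Draw nanotube lengths from a distribution specification
#'
#' @param distribution a [dist_exponential()], [dist_fixed()] or
#'   [dist_values()] specification.
#' @param n number of lengths to draw (`n = 0` gives an empty vector).
#' @param seed optional integer seed; when given, the caller's RNG state is
#'   left untouched.
#' @return Numeric vector of `n` positive lengths in micrometers.
#' @export
sample_lengths <- function(distribution, n, seed = NULL) {
  if (!inherits(distribution, "length_dist"))
    stop("'distribution' must be a length_dist specification", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop("'n' must be a single non-negative integer", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    switch(distribution$type,
      exponential = rexp(n, rate = 1 / distribution$mean),
      fixed = rep(distribution$value, n),
      values = rep_len(distribution$values, n))
  })
}

#' Synthetic scene specification
#'
#' Describes one synthetic epifluorescence field of view: surface-adsorbed
#' fluorescently labeled nanotubes modelled as worm-like piecewise-linear
#' polylines (one 1-pixel step per segment, per-step bend drawn uniformly in
#' +/- `curvature` degrees), rendered through a Gaussian point-spread
#' function onto an unevenly illuminated background with Poisson shot noise
#' and Gaussian read noise.
#'
#' Defaults emulate a bright Cy3-labelled preparation imaged at high
#' magnification: 0.065 um pixels, a PSF sigma of 1.3 px (~85 nm), tubes of
#' exponential mean length 3 um, and a 20% corner-to-corner illumination
#' gradient.
#'
#' @param image_shape integer vector `c(rows, cols)` in pixels.
#' @param pixel_size micrometers per pixel.
#' @param n_tubes number of tubes to place.
#' @param length_distribution a `length_dist` specification (micrometers).
#' @param curvature maximum bend per 1-px step, degrees; 0 gives straight
#'   tubes.
#' @param psf_sigma Gaussian PSF sigma in pixels; 0 disables blurring.
#' @param tube_amplitude approximate on-tube peak intensity above background,
#'   in camera counts.
#' @param background_level mean background intensity, counts.
#' @param illumination_gradient fractional corner-to-corner change of the
#'   background plane (0 = flat).
#' @param read_noise_sd Gaussian read-noise standard deviation, counts.
#' @param shot_noise logical; apply Poisson noise to signal + background.
#' @param seed integer seed; identical specs render bit-identical images.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(512L, 512L),
                       pixel_size = 0.065,
                       n_tubes = 25L,
                       length_distribution = dist_exponential(3),
                       curvature = 8,
                       psf_sigma = 1.3,
                       tube_amplitude = 8000,
                       background_level = 2000,
                       illumination_gradient = 0.2,
                       read_noise_sd = 200,
                       shot_noise = TRUE,
                       seed = NULL) {
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop("image_shape must be c(rows, cols) with both >= 8", call. = FALSE)
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  if (n_tubes < 0 || n_tubes != floor(n_tubes))
    stop("n_tubes must be a non-negative integer", call. = FALSE)
  if (!inherits(length_distribution, "length_dist"))
    stop("length_distribution must be a length_dist specification", call. = FALSE)
  stopifnot_scalar_pos(curvature, "curvature", strict = FALSE)
  stopifnot_scalar_pos(psf_sigma, "psf_sigma", strict = FALSE)
  stopifnot_scalar_pos(tube_amplitude, "tube_amplitude")
  stopifnot_scalar_pos(background_level, "background_level")
  stopifnot_scalar_pos(illumination_gradient, "illumination_gradient", strict = FALSE)
  stopifnot_scalar_pos(read_noise_sd, "read_noise_sd", strict = FALSE)
  structure(list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
                 n_tubes = as.integer(n_tubes),
                 length_distribution = length_distribution,
                 curvature = curvature, psf_sigma = psf_sigma,
                 tube_amplitude = tube_amplitude,
                 background_level = background_level,
                 illumination_gradient = illumination_gradient,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise), seed = seed),
            class = "scene_spec")
}

# Worm-like polyline: unit steps, heading increments uniform in +/- curvature.
# Returns an (n_steps + 1) x 2 matrix of (row, col) sub-pixel coordinates.
make_polyline <- function(start, theta0, length_px, curvature) {
  n_steps <- max(1L, ceiling(length_px))
  step <- length_px / n_steps
  bends <- if (n_steps > 1)
    runif(n_steps - 1L, -curvature, curvature) * pi / 180 else numeric(0)
  theta <- theta0 + cumsum(c(0, bends))
  rbind(start,
        cbind(start[1] + cumsum(step * sin(theta)),
              start[2] + cumsum(step * cos(theta))))
}

polyline_length <- function(P) {
  d <- diff(P)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

# TRUE if any segment of P properly crosses any segment of Q.
polylines_cross <- function(P, Q) {
  if (max(P[, 1]) < min(Q[, 1]) || min(P[, 1]) > max(Q[, 1]) ||
      max(P[, 2]) < min(Q[, 2]) || min(P[, 2]) > max(Q[, 2])) return(FALSE)
  a1r <- P[-nrow(P), 1]; a1c <- P[-nrow(P), 2]
  dar <- diff(P[, 1]);   dac <- diff(P[, 2])
  b1r <- Q[-nrow(Q), 1]; b1c <- Q[-nrow(Q), 2]
  dbr <- diff(Q[, 1]);   dbc <- diff(Q[, 2])
  nA <- length(a1r); nB <- length(b1r)
  # cross products of segment direction with endpoint offsets, all pairs
  B1r <- matrix(b1r, nA, nB, byrow = TRUE); B1c <- matrix(b1c, nA, nB, byrow = TRUE)
  B2r <- B1r + matrix(dbr, nA, nB, byrow = TRUE)
  B2c <- B1c + matrix(dbc, nA, nB, byrow = TRUE)
  d1 <- dar * (B1c - a1c) - dac * (B1r - a1r)
  d2 <- dar * (B2c - a1c) - dac * (B2r - a1r)
  A1r <- matrix(a1r, nA, nB); A1c <- matrix(a1c, nA, nB)
  DBr <- matrix(dbr, nA, nB, byrow = TRUE); DBc <- matrix(dbc, nA, nB, byrow = TRUE)
  d3 <- DBr * (A1c - B1c) - DBc * (A1r - B1r)
  d4 <- DBr * (A1c + matrix(dac, nA, nB) - B1c) -
        DBc * (A1r + matrix(dar, nA, nB) - B1r)
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Render a synthetic micrograph with exact ground truth
#'
#' Places each tube by rejection sampling (uniform position and orientation;
#' a polyline leaving the frame is re-drawn, up to 100 attempts, so
#' boundary-clipped tubes never occur and ground-truth lengths stay exact).
#' Tubes are deposited as arc-length-uniform point masses quantized on a 4x
#' supersampled grid, convolved with the Gaussian PSF, scaled so an isolated
#' straight tube peaks near `tube_amplitude`, and added to a linear
#' background plane; Poisson shot noise and Gaussian read noise are then
#' applied and the result is quantized to the 16-bit range.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements `micrograph` (a [micrograph]) and
#'   `ground_truth` (data frame with `tube_id`, `true_length_um`,
#'   `crosses_another`, `n_vertices`; per-tube polyline vertex matrices in
#'   `attr(, "vertices")`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  diag_px <- sqrt(nr^2 + nc^2)
  with_seed(spec$seed, {
    lengths_um <- sample_lengths(spec$length_distribution, spec$n_tubes)
    lengths_px <- lengths_um / spec$pixel_size
    polylines <- vector("list", spec$n_tubes)
    for (i in seq_len(spec$n_tubes)) {
      if (lengths_px[i] > diag_px)
        warning(sprintf("tube %d (%.1f px) is longer than the image diagonal",
                        i, lengths_px[i]))
      placed <- FALSE
      for (att in seq_len(100L)) {
        start <- c(runif(1, 1, nr - 2), runif(1, 1, nc - 2))
        P <- make_polyline(start, runif(1, 0, 2 * pi), lengths_px[i],
                           spec$curvature)
        if (all(P[, 1] >= 1 & P[, 1] <= nr - 2 &
                P[, 2] >= 1 & P[, 2] <= nc - 2)) {
          polylines[[i]] <- P; placed <- TRUE; break
        }
      }
      if (!placed)
        stop(sprintf("failed to place tube %d (length %.1f px) in a %d x %d frame after 100 attempts",
                     i, lengths_px[i], nr, nc))
    }

    # deposit point masses (arc spacing 1/8 px, positions snapped to the 4x grid)
    canvas <- matrix(0, nr, nc)
    S <- 4L; delta <- 1 / (2 * S)
    for (P in polylines) {
      for (s in seq_len(nrow(P) - 1L)) {
        seg <- P[s + 1L, ] - P[s, ]
        len <- sqrt(sum(seg^2))
        if (len == 0) next
        npts <- max(1L, ceiling(len / delta))
        tt <- (seq_len(npts) - 0.5) / npts
        rr <- (floor((P[s, 1] + tt * seg[1]) * S) + 0.5) / S
        cc <- (floor((P[s, 2] + tt * seg[2]) * S) + 0.5) / S
        ri <- pmin(pmax(floor(rr), 0), nr - 1) + 1L
        ci <- pmin(pmax(floor(cc), 0), nc - 1) + 1L
        idx <- (ci - 1L) * nr + ri
        agg <- rowsum(rep(len / npts, npts), group = idx)
        ii <- as.integer(rownames(agg))
        canvas[ii] <- canvas[ii] + agg[, 1]
      }
    }
    tube_field <- if (spec$psf_sigma > 0)
      .cpp_gaussian_blur(canvas, spec$psf_sigma) * sqrt(2 * pi) * spec$psf_sigma
    else canvas

    rgrad <- (seq_len(nr) - 1) / max(1, nr - 1)
    cgrad <- (seq_len(nc) - 1) / max(1, nc - 1)
    plane <- (outer(rgrad, cgrad, `+`) / 2 - 0.5) * spec$illumination_gradient
    background <- spec$background_level * (1 + plane)

    clean <- spec$tube_amplitude * tube_field + background
    img <- if (spec$shot_noise) {
      matrix(rpois(length(clean), pmax(clean, 0)), nr, nc)
    } else clean
    if (spec$read_noise_sd > 0)
      img <- img + rnorm(length(img), 0, spec$read_noise_sd)
    img <- matrix(pmin(pmax(round(img), 0), 65535), nr, nc)

    crosses <- rep(FALSE, spec$n_tubes)
    if (spec$n_tubes > 1) {
      for (i in seq_len(spec$n_tubes - 1L))
        for (j in seq(i + 1L, spec$n_tubes))
          if (polylines_cross(polylines[[i]], polylines[[j]]))
            crosses[i] <- crosses[j] <- TRUE
    }
    gt <- data.frame(
      tube_id = seq_len(spec$n_tubes),
      true_length_um = vapply(polylines, function(P)
        polyline_length(P) * spec$pixel_size, numeric(1)),
      crosses_another = crosses,
      n_vertices = vapply(polylines, nrow, integer(1)))
    if (spec$n_tubes == 0)
      gt <- data.frame(tube_id = integer(0), true_length_um = numeric(0),
                       crosses_another = logical(0), n_vertices = integer(0))
    attr(gt, "vertices") <- polylines
    list(micrograph = micrograph(img, pixel_size = spec$pixel_size,
                                 bit_depth = 16L, image_id = "synthetic"),
         ground_truth = gt)
  })
}

#' Write synthetic ground truth as CSV
#'
#' Vertices are serialized as `row:col` pairs separated by `|`.
#'
#' @param ground_truth the `ground_truth` element of [render_scene()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  verts <- attr(ground_truth, "vertices")
  out <- ground_truth
  out$vertices <- vapply(seq_len(nrow(out)), function(i) {
    P <- verts[[i]]
    paste(sprintf("%.4f:%.4f", P[, 1], P[, 2]), collapse = "|")
  }, character(1))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Simulate a UV-absorbance melting curve
#'
#' Models hyperchromicity as a sum of sigmoidal transitions,
#' `A(T) = baseline + sum_i amplitude_i / (1 + exp(-(T - center_i) / width_i))`,
#' with independent Gaussian noise per replicate per temperature. Defaults
#' emulate a two-transition DX-tile nanotube melt (sticky-end disassembly
#' near 40 C followed by tile melting near 62 C) measured in 6 replicates
#' every 1 C from 20 to 90 C.
#'
#' @param transition_centers transition midpoints, degrees C.
#' @param transition_widths sigmoid width parameters, degrees C (all > 0).
#' @param amplitudes absorbance step of each transition, AU.
#' @param baseline low-temperature absorbance, AU.
#' @param noise_sd replicate noise standard deviation, AU.
#' @param n_replicates number of replicate absorbance columns.
#' @param temperature_grid ascending temperatures, degrees C.
#' @param seed optional integer seed.
#' @return A [melting_curve].
#' @export
make_melting_curve <- function(transition_centers = c(40, 62),
                               transition_widths = c(2, 2.5),
                               amplitudes = c(0.05, 0.12),
                               baseline = 0.6,
                               noise_sd = 0.004,
                               n_replicates = 6L,
                               temperature_grid = 20:90,
                               seed = NULL) {
  if (length(transition_centers) != length(transition_widths) ||
      length(transition_centers) != length(amplitudes))
    stop("centers, widths and amplitudes must have equal length", call. = FALSE)
  if (length(transition_widths) && any(transition_widths <= 0))
    stop("transition widths must be > 0", call. = FALSE)
  if (is.unsorted(temperature_grid, strictly = TRUE))
    stop("temperature_grid must be strictly ascending", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  stopifnot_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  mean_curve <- rep(baseline, length(temperature_grid))
  for (i in seq_along(transition_centers))
    mean_curve <- mean_curve + amplitudes[i] /
      (1 + exp(-(temperature_grid - transition_centers[i]) / transition_widths[i]))
  with_seed(seed, {
    ab <- matrix(mean_curve, nrow = length(temperature_grid),
                 ncol = n_replicates)
    if (noise_sd > 0)
      ab <- ab + matrix(rnorm(length(ab), 0, noise_sd), nrow = nrow(ab))
    melting_curve(temperature_grid, ab)
  })
}
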