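#' Length sample
#'
#' A collection of measured nanotube lengths from one replicate at one
#' timepoint — the unit on which all growth statistics operate.
#'
#' @param lengths numeric vector of lengths in micrometers, all > 0.
#' @param replicate_id text label of the replicate.
#' @param timepoint timepoint label (text or number).
#' @return An object of class `length_sample`.
#' @export
length_sample <- function(lengths, replicate_id = "r1", timepoint = NA) {
  if (!is.numeric(lengths)) stop("lengths must be numeric", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all lengths must be finite and > 0", call. = FALSE)
  structure(list(lengths = as.numeric(lengths),
                 replicate_id = as.character(replicate_id),
                 timepoint = timepoint),
            class = "length_sample")
}

#' @export
print.length_sample <- function(x, ...) {
  cat(sprintf("<length_sample '%s'%s> n = %d, mean %.3g um\n",
              x$replicate_id,
              if (is.na(x$timepoint[1])) "" else paste0(" @ ", x$timepoint),
              length(x$lengths),
              if (length(x$lengths)) mean(x$lengths) else NA))
  invisible(x)
}

#' Average nanotube length with replicate error
#'
#' Computes the mean length of every replicate, their unweighted grand mean,
#' and — as the error bar — the standard deviation across the replicate
#' means, the convention used when reporting average length over
#' experimental replicates.
#'
#' @param samples a [length_sample] or list of them (one per replicate).
#' @return An object of class `growth_summary` with fields
#'   `replicate_means`, `grand_mean`, `error`, `n_total`,
#'   `single_replicate`.
#' @export
mean_length <- function(samples) {
  if (inherits(samples, "length_sample")) samples <- list(samples)
  if (length(samples) == 0) stop("need at least one sample", call. = FALSE)
  for (s in samples) {
    if (!inherits(s, "length_sample"))
      stop("samples must be length_sample objects", call. = FALSE)
    if (length(s$lengths) == 0)
      stop(sprintf("replicate '%s' is empty", s$replicate_id), call. = FALSE)
  }
  rmeans <- vapply(samples, function(s) mean(s$lengths), numeric(1))
  names(rmeans) <- vapply(samples, function(s) s$replicate_id, character(1))
  single <- length(rmeans) == 1L
  structure(list(replicate_means = rmeans,
                 grand_mean = mean(rmeans),
                 error = if (single) 0 else sd(rmeans),
                 n_total = sum(vapply(samples, function(s)
                   length(s$lengths), numeric(1))),
                 single_replicate = single),
            class = "growth_summary")
}

#' @export
print.growth_summary <- function(x, ...) {
  cat(sprintf("<growth_summary> mean length %.3g +/- %.3g um (%d replicates, %d nanotubes)%s\n",
              x$grand_mean, x$error, length(x$replicate_means), x$n_total,
              if (x$single_replicate) " [single replicate: error 0 by convention]" else ""))
  invisible(x)
}

#' @export
coef.growth_summary <- function(object, ...) {
  c(grand_mean = object$grand_mean, error = object$error)
}

check_edges <- function(x, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly ascending", call. = FALSE)
  if (length(bin_edges) < 2) stop("need at least two bin edges", call. = FALSE)
  if (length(x) && (any(x < bin_edges[1]) || any(x >= bin_edges[length(bin_edges)])))
    stop("data outside bin edges; extend the last edge", call. = FALSE)
}

#' Frequency histogram of nanotube lengths
#'
#' Counts per half-open bin `[lo, hi)`; a value on an interior edge falls in
#' the upper bin.
#'
#' @param sample a [length_sample].
#' @param bin_edges ascending edges covering all data.
#' @return An object of class `length_histogram` with `bin_edges` and
#'   `counts` (and `length_fractions = NULL`).
#' @export
frequency_histogram <- function(sample, bin_edges) {
  stopifnot(inherits(sample, "length_sample"))
  x <- sample$lengths
  check_edges(x, bin_edges)
  nb <- length(bin_edges) - 1L
  counts <- tabulate(findInterval(x, bin_edges), nb)
  structure(list(bin_edges = bin_edges, counts = counts,
                 length_fractions = NULL, n = length(x)),
            class = "length_histogram")
}

#' Length-fraction histogram
#'
#' The fraction of the total summed nanotube length contributed by each
#' length bin: `fraction_b = sum(lengths in b) / sum(all lengths)`. Unlike
#' the count histogram this weighs long tubes by their length, showing how
#' the mass of the population shifts toward longer tubes as growth proceeds.
#'
#' @inheritParams frequency_histogram
#' @return A `length_histogram` with `counts` and `length_fractions`
#'   (fractions sum to 1).
#' @export
length_fraction_histogram <- function(sample, bin_edges) {
  stopifnot(inherits(sample, "length_sample"))
  x <- sample$lengths
  if (length(x) == 0) stop("empty sample", call. = FALSE)
  check_edges(x, bin_edges)
  nb <- length(bin_edges) - 1L
  bin <- findInterval(x, bin_edges)
  counts <- tabulate(bin, nb)
  sums <- vapply(seq_len(nb), function(b) sum(x[bin == b]), numeric(1))
  structure(list(bin_edges = bin_edges, counts = counts,
                 length_fractions = sums / sum(x), n = length(x)),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("<length_histogram> %d bins over [%.3g, %.3g) um, n = %d\n",
              length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], x$n))
  invisible(x)
}

#' Empirical complementary cumulative distribution of lengths
#'
#' At each observed length x the CCDF reports `P(length > x)` — the
#' likelihood of finding a nanotube larger than x. For a population growing
#' by single-tile addition the lengths are exponentially distributed, so the
#' CCDF is a straight line in a semilog plot; after mean-normalization
#' ([normalize_ccdf()]) any exponential CCDF collapses on the line of slope
#' -1, making deviations (e.g. excess long tubes from end-joining of
#' existing nanotubes) directly visible.
#'
#' @param sample a [length_sample] (non-empty).
#' @return Object of class `ccdf` with `x` (sorted lengths), `survival`,
#'   and `sample_mean`; `normalized_x` is NULL until [normalize_ccdf()].
#' @export
empirical_ccdf <- function(sample) {
  stopifnot(inherits(sample, "length_sample"))
  x <- sort(sample$lengths)
  n <- length(x)
  if (n == 0) stop("empty sample", call. = FALSE)
  # P(X > x_i): strict inequality, so ties share the survival of their last;
  # findInterval on the sorted vector counts values <= x_i
  surv <- (n - findInterval(x, x)) / n
  structure(list(x = x, survival = surv, sample_mean = mean(x),
                 normalized_x = NULL, fit = NULL),
            class = "ccdf")
}

#' Normalize a CCDF by its sample mean
#'
#' Divides the length axis by the sample mean (survival values unchanged);
#' exponential samples then collapse on the semilog line of slope -1
#' regardless of their mean.
#'
#' @param ccdf a [empirical_ccdf()] result.
#' @return The `ccdf` with `normalized_x` filled in.
#' @export
normalize_ccdf <- function(ccdf) {
  stopifnot(inherits(ccdf, "ccdf"))
  if (!is.finite(ccdf$sample_mean) || ccdf$sample_mean <= 0)
    stop("sample mean must be > 0", call. = FALSE)
  ccdf$normalized_x <- ccdf$x / ccdf$sample_mean
  ccdf
}

#' Fit a straight line to the semilog CCDF
#'
#' Least-squares fit of `ln(survival)` versus length (or mean-normalized
#' length when available) over the points whose length lies within the
#' given quantile range; zero-survival points are excluded since their log
#' is undefined. The default range `[0, 0.99]` drops the noisy extreme
#' tail. For an exponential sample the slope estimates `-1/mean` on the raw
#' axis and `-1` on the normalized axis.
#'
#' @param ccdf a `ccdf` object.
#' @param fit_range length quantile bounds, e.g. `c(0, 0.99)`.
#' @param axis `"auto"` (normalized if present), `"raw"`, or
#'   `"normalized"`.
#' @return Object of class `ccdf_fit` with `slope`, `intercept`,
#'   `n_points`, `axis`, `fit_range`.
#' @export
fit_semilog_slope <- function(ccdf, fit_range = c(0, 0.99),
                              axis = c("auto", "raw", "normalized")) {
  stopifnot(inherits(ccdf, "ccdf"))
  axis <- match.arg(axis)
  if (axis == "auto") axis <- if (is.null(ccdf$normalized_x)) "raw" else "normalized"
  xx <- if (axis == "normalized") {
    if (is.null(ccdf$normalized_x)) stop("CCDF is not normalized", call. = FALSE)
    ccdf$normalized_x
  } else ccdf$x
  if (length(fit_range) != 2 || fit_range[1] < 0 || fit_range[2] > 1 ||
      fit_range[1] >= fit_range[2])
    stop("fit_range must be quantile bounds within [0, 1]", call. = FALSE)
  qb <- quantile(xx, fit_range, names = FALSE)
  keep <- ccdf$survival > 0 & xx >= qb[1] & xx <= qb[2]
  if (sum(keep) < 3)
    stop("fewer than 3 usable points in the fit range", call. = FALSE)
  fit <- lm(log(ccdf$survival[keep]) ~ xx[keep])
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n_points = sum(keep), axis = axis, fit_range = fit_range),
            class = "ccdf_fit")
}

#' @export
print.ccdf_fit <- function(x, ...) {
  cat(sprintf("<ccdf_fit> semilog slope %.4f (intercept %.4f), %d points, %s axis\n",
              x$slope, x$intercept, x$n_points, x$axis))
  invisible(x)
}

#' @export
coef.ccdf_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
print.ccdf <- function(x, ...) {
  cat(sprintf("<ccdf> n = %d, mean %.3g um%s\n", length(x$x), x$sample_mean,
              if (is.null(x$normalized_x)) "" else ", mean-normalized"))
  invisible(x)
}

#' Plot a CCDF on a semilog axis
#'
#' @param x a `ccdf` object.
#' @param reference_mean if non-NULL, overlay the exponential model CCDF of
#'   this mean (use 1 for a normalized plot).
#' @param ... passed to [plot()].
#' @export
plot.ccdf <- function(x, reference_mean = NULL, ...) {
  xx <- if (is.null(x$normalized_x)) x$x else x$normalized_x
  keep <- x$survival > 0
  plot(xx[keep], x$survival[keep], log = "y",
       xlab = if (is.null(x$normalized_x)) "length (um)" else "length / mean",
       ylab = "P(length > x)", pch = 16, cex = 0.4, ...)
  if (!is.null(reference_mean)) {
    grid_x <- seq(0, max(xx), length.out = 200)
    lines(grid_x, exponential_reference(reference_mean, grid_x), col = 2)
  }
  invisible(x)
}

#' Exponential model CCDF
#'
#' `exp(-x / mean)`, the survival function of the exponential length model,
#' for overlay against empirical CCDFs.
#'
#' @param mean distribution mean (> 0), micrometers.
#' @param x evaluation grid.
#' @return Survival values on `x`.
#' @export
exponential_reference <- function(mean, x) {
  stopifnot_scalar_pos(mean, "mean")
  exp(-x / mean)
}

#' Write growth statistics to CSV files
#'
#' @param samples list of [length_sample] replicates.
#' @param out_dir output directory (created if needed).
#' @param bin_width histogram bin width, micrometers.
#' @param fit_range CCDF fit quantile bounds.
#' @return Invisible list with the computed `summary`, `histogram`, `ccdf`
#'   and `fit` objects.
#' @export
write_statistics <- function(samples, out_dir, bin_width = 1,
                             fit_range = c(0, 0.99)) {
  if (inherits(samples, "length_sample")) samples <- list(samples)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gs <- mean_length(samples)
  pooled <- length_sample(unlist(lapply(samples, `[[`, "lengths")),
                          replicate_id = "pooled")
  edges <- seq(0, ceiling(max(pooled$lengths) / bin_width) * bin_width +
                 bin_width, by = bin_width)
  hist <- length_fraction_histogram(pooled, edges)
  cc <- normalize_ccdf(empirical_ccdf(pooled))
  fit <- fit_semilog_slope(cc, fit_range)
  write.csv(data.frame(replicate = names(gs$replicate_means),
                       mean_um = gs$replicate_means),
            file.path(out_dir, "replicate_means.csv"), row.names = FALSE)
  write.csv(data.frame(grand_mean_um = gs$grand_mean, error_um = gs$error,
                       n = gs$n_total),
            file.path(out_dir, "summary.csv"), row.names = FALSE)
  write.csv(data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                       count = hist$counts,
                       length_fraction = hist$length_fractions),
            file.path(out_dir, "histogram.csv"), row.names = FALSE)
  write.csv(data.frame(x_um = cc$x, survival = cc$survival,
                       normalized_x = cc$normalized_x),
            file.path(out_dir, "ccdf.csv"), row.names = FALSE)
  write.csv(data.frame(slope = fit$slope, intercept = fit$intercept,
                       n_points = fit$n_points, axis = fit$axis),
            file.path(out_dir, "ccdf_fit.csv"), row.names = FALSE)
  invisible(list(summary = gs, histogram = hist, ccdf = cc, fit = fit))
}
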