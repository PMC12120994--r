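#' Melting curve container
#'
#' Absorbance at 260 nm versus temperature, with one column per replicate.
#'
#' @param temperatures strictly ascending temperatures, degrees C.
#' @param absorbance numeric matrix (rows = temperatures, cols = replicates)
#'   or a vector for a single replicate.
#' @return An object of class `melting_curve`.
#' @export
melting_curve <- function(temperatures, absorbance) {
  if (is.vector(absorbance)) absorbance <- matrix(absorbance, ncol = 1)
  if (!is.matrix(absorbance) || !is.numeric(absorbance))
    stop("absorbance must be a numeric matrix or vector", call. = FALSE)
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing", call. = FALSE)
  if (nrow(absorbance) != length(temperatures))
    stop("absorbance rows must match temperatures", call. = FALSE)
  if (anyNA(absorbance))
    stop("ragged replicates: missing absorbance values", call. = FALSE)
  structure(list(temperatures = as.numeric(temperatures),
                 absorbance = absorbance,
                 n_replicates = ncol(absorbance)),
            class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("<melting_curve> %d temperatures (%g-%g C), %d replicate(s)\n",
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures), x$n_replicates))
  invisible(x)
}

#' Average replicate absorbance curves
#'
#' @param curve a [melting_curve].
#' @return Data frame with `temperature_C` and the pointwise mean
#'   `absorbance`.
#' @export
average_replicates <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  data.frame(temperature_C = curve$temperatures,
             absorbance = rowMeans(curve$absorbance))
}

#' Derivative of absorbance with temperature
#'
#' Optional moving-average smoothing followed by centered finite
#' differences (one-sided at the endpoints). Melting transitions appear as
#' maxima of this derivative.
#'
#' @param series data frame from [average_replicates()], or a
#'   [melting_curve] (replicates are averaged first).
#' @param smoothing_window moving-average window in points (odd; 1 disables
#'   smoothing). Default 3.
#' @return Data frame with `temperature_C` and `dA_dT` (AU per degree C).
#' @export
derivative_curve <- function(series, smoothing_window = 3L) {
  if (inherits(series, "melting_curve")) series <- average_replicates(series)
  tt <- series$temperature_C
  a <- series$absorbance
  n <- length(a)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (smoothing_window < 1 || smoothing_window %% 2 == 0)
    stop("smoothing_window must be a positive odd integer", call. = FALSE)
  if (smoothing_window > 1) {
    h <- (smoothing_window - 1) / 2
    a <- vapply(seq_len(n), function(i)
      mean(a[max(1, i - h):min(n, i + h)]), numeric(1))
  }
  d <- numeric(n)
  d[1] <- (a[2] - a[1]) / (tt[2] - tt[1])
  d[n] <- (a[n] - a[n - 1]) / (tt[n] - tt[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (a[i + 1] - a[i - 1]) / (tt[i + 1] - tt[i - 1])
  }
  data.frame(temperature_C = tt, dA_dT = d)
}

#' Detect melting temperatures from the derivative curve
#'
#' Finds interior local maxima of dA/dT, ranks them by height, and accepts
#' peaks greedily subject to a minimum mutual separation; the
#' `n_transitions` accepted peaks are reported in ascending temperature
#' order. For DX-tile nanotubes two transitions are expected: sticky-end
#' disassembly (Tm1) followed by tile melting (Tm2).
#'
#' @param derivative data frame from [derivative_curve()] (or a
#'   [melting_curve], in which case replicates are averaged and
#'   differentiated with the default window first).
#' @param n_transitions number of transitions to report (default 2).
#' @param min_separation minimum distance between reported peaks, degrees C.
#' @return Object of class `tm_result`: data frame with `transition`,
#'   `Tm_C`, `peak_height`.
#' @export
detect_tm <- function(derivative, n_transitions = 2L, min_separation = 5) {
  if (inherits(derivative, "melting_curve"))
    derivative <- derivative_curve(derivative)
  if (n_transitions < 1) stop("n_transitions must be >= 1", call. = FALSE)
  tt <- derivative$temperature_C
  d <- derivative$dA_dT
  n <- length(d)
  i <- 2:(n - 1)
  is_max <- d[i] >= d[i - 1] & d[i] > d[i + 1]
  cand <- i[is_max]
  cand <- cand[order(d[cand], decreasing = TRUE)]
  picked <- integer(0)
  for (k in cand) {
    if (length(picked) == n_transitions) break
    if (all(abs(tt[k] - tt[picked]) >= min_separation))
      picked <- c(picked, k)
  }
  if (length(picked) < n_transitions)
    stop(sprintf("requested %d transitions but only %d detectable maxima found",
                 n_transitions, length(picked)), call. = FALSE)
  picked <- picked[order(tt[picked])]
  structure(data.frame(transition = seq_along(picked),
                       Tm_C = tt[picked],
                       peak_height = d[picked]),
            class = c("tm_result", "data.frame"))
}

#' @export
print.tm_result <- function(x, ...) {
  cat("<tm_result>\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  Tm%d = %.1f C (dA/dT = %.4g AU/C)\n",
                x$transition[i], x$Tm_C[i], x$peak_height[i]))
  invisible(x)
}

#' Write / read melting curves as CSV
#'
#' Column 1 is `temperature_C`; columns 2..n+1 are replicate absorbances.
#'
#' @param curve a [melting_curve].
#' @param path CSV path.
#' @return `path` (write) or a [melting_curve] (read).
#' @export
write_melting_csv <- function(curve, path) {
  stopifnot(inherits(curve, "melting_curve"))
  df <- data.frame(temperature_C = curve$temperatures, curve$absorbance)
  names(df)[-1] <- paste0("rep", seq_len(curve$n_replicates))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_melting_csv
#' @export
read_melting_csv <- function(path) {
  df <- read.csv(path)
  melting_curve(df[[1]], as.matrix(df[, -1, drop = FALSE]))
}
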