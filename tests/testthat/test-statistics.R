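test_that("mean_length aggregates replicates as mean of means", {
  one <- mean_length(length_sample(c(2, 4)))
  expect_equal(one$grand_mean, 3)
  expect_equal(one$error, 0)
  expect_true(one$single_replicate)

  three <- mean_length(list(length_sample(c(3, 3), "a"),
                            length_sample(c(4, 4), "b"),
                            length_sample(c(5, 5), "c")))
  expect_equal(three$grand_mean, 4)
  expect_equal(three$error, 1)  # sd of {3,4,5}
  expect_false(three$single_replicate)

  same <- mean_length(lapply(1:3, function(i) length_sample(c(1, 2), i)))
  expect_equal(same$error, 0)
  # grand mean bracketed by replicate means
  expect_gte(same$grand_mean, min(same$replicate_means))
  expect_lte(same$grand_mean, max(same$replicate_means))

  expect_error(mean_length(list(length_sample(1, "ok"),
                                structure(list(lengths = numeric(0),
                                               replicate_id = "bad"),
                                          class = "length_sample"))),
               "'bad' is empty")
})

test_that("frequency histogram uses half-open bins", {
  s <- length_sample(c(1, 3))
  h <- frequency_histogram(s, c(0, 2, 4))
  expect_equal(h$counts, c(1L, 1L))
  expect_equal(sum(h$counts), 2)

  # a value on an interior edge lands in the upper bin
  h2 <- frequency_histogram(length_sample(2), c(0, 2, 4))
  expect_equal(h2$counts, c(0L, 1L))

  expect_error(frequency_histogram(length_sample(5), c(0, 2, 4)), "outside")
  expect_error(frequency_histogram(s, c(2, 1)), "ascending")
})

test_that("length fractions weight bins by summed length", {
  s <- length_sample(c(1, 3))
  h <- length_fraction_histogram(s, c(0, 2, 4))
  expect_equal(h$length_fractions, c(0.25, 0.75))

  h1 <- length_fraction_histogram(length_sample(1.5), c(0, 2, 4))
  expect_equal(h1$length_fractions, c(1, 0))

  set.seed(2)
  for (i in 1:5) {
    x <- length_sample(rexp(200, 1 / 3) + 1e-6)
    hh <- length_fraction_histogram(x, seq(0, 100, by = 1))
    expect_equal(sum(hh$length_fractions), 1, tolerance = 1e-9)
    expect_equal(sum(hh$counts), 200)
  }
})

test_that("empirical CCDF counts strict exceedances", {
  cc <- empirical_ccdf(length_sample(c(1, 2, 3)))
  expect_equal(cc$survival, c(2 / 3, 1 / 3, 0))

  expect_equal(empirical_ccdf(length_sample(7))$survival, 0)
  expect_equal(empirical_ccdf(length_sample(c(2, 2, 2)))$survival,
               c(0, 0, 0))

  # monotone non-increasing, in [0, 1], and with ties handled strictly
  set.seed(8)
  x <- length_sample(round(rexp(500, 1), 1) + 0.05)
  cc2 <- empirical_ccdf(x)
  expect_true(all(diff(cc2$survival) <= 0))
  expect_true(all(cc2$survival >= 0 & cc2$survival <= 1))
})

test_that("mean-normalization rescales the axis only", {
  s <- length_sample(c(1, 3))  # mean 2
  cc <- normalize_ccdf(empirical_ccdf(s))
  expect_equal(cc$normalized_x, c(0.5, 1.5))
  expect_equal(cc$survival, empirical_ccdf(s)$survival)
  expect_equal(mean(cc$normalized_x), 1, tolerance = 1e-9)

  unit <- length_sample(c(0.5, 1.5))  # already unit mean
  ccu <- normalize_ccdf(empirical_ccdf(unit))
  expect_equal(ccu$normalized_x, ccu$x)
})

test_that("semilog fits recover known slopes", {
  # points placed exactly on exp(-x) and exp(-2x)
  mk <- function(rate) {
    x <- seq(0.1, 4, by = 0.1)
    structure(list(x = x, survival = exp(-rate * x), sample_mean = mean(x),
                   normalized_x = NULL, fit = NULL), class = "ccdf")
  }
  expect_equal(fit_semilog_slope(mk(1), c(0, 1))$slope, -1, tolerance = 1e-9)
  expect_equal(fit_semilog_slope(mk(2), c(0, 1))$slope, -2, tolerance = 1e-9)

  # a large exponential sample on the raw axis estimates -1/mean
  s <- length_sample(sample_lengths(dist_exponential(3), 5e4, seed = 12))
  raw <- fit_semilog_slope(empirical_ccdf(s), axis = "raw")
  expect_lt(abs(raw$slope / (-1 / 3) - 1), 0.10)

  # too few usable points
  tiny <- empirical_ccdf(length_sample(c(1, 2)))
  expect_error(fit_semilog_slope(tiny), "fewer than 3")
})

test_that("normalized exponential CCDF slopes concentrate at -1", {
  hits <- vapply(1:100, function(s) {
    x <- length_sample(sample_lengths(dist_exponential(2.5), 1e4, seed = s))
    f <- fit_semilog_slope(normalize_ccdf(empirical_ccdf(x)))
    abs(f$slope + 1) <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the exponential reference curve has its closed form", {
  expect_equal(exponential_reference(3, 0), 1)
  expect_equal(exponential_reference(2, 2), exp(-1))
  x <- seq(0.5, 10, by = 0.5)
  s1 <- log(exponential_reference(2, x))
  s2 <- log(exponential_reference(4, x))
  expect_equal(s1 / s2, rep(2, length(x)), tolerance = 1e-9)  # slope halves
  expect_error(exponential_reference(0, 1), "positive")
})

test_that("write_statistics emits a consistent set of CSVs", {
  out <- withr::local_tempdir()
  samples <- lapply(1:3, function(i)
    length_sample(sample_lengths(dist_exponential(3), 400, seed = i),
                  replicate_id = paste0("r", i)))
  res <- write_statistics(samples, out)
  for (f in c("summary.csv", "replicate_means.csv", "histogram.csv",
              "ccdf.csv", "ccdf_fit.csv"))
    expect_true(file.exists(file.path(out, f)))
  h <- read.csv(file.path(out, "histogram.csv"))
  expect_equal(sum(h$length_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(h$count), 1200)
  s <- read.csv(file.path(out, "summary.csv"))
  expect_equal(s$grand_mean_um, res$summary$grand_mean)
})
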