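test_that("median background matches brute-force disk medians", {
  # constants are fixed points
  expect_equal(estimate_background(matrix(100, 12, 12), 5),
               matrix(100, 12, 12))

  # an isolated bright pixel vanishes under a large disk
  img <- matrix(10, 21, 21); img[11, 11] <- 1000
  expect_equal(estimate_background(img, 10), matrix(10, 21, 21))

  # linear ramp: symmetric disk medians leave the interior unchanged
  ramp <- matrix(rep(1:15, each = 15), 15, 15)
  bg <- estimate_background(ramp, 3)
  expect_equal(bg[, 4:12], ramp[, 4:12])

  # full equivalence with the enumeration oracle on a random image
  set.seed(31)
  rnd <- matrix(sample(0:50, 15 * 13, replace = TRUE), 15, 13)
  expect_equal(estimate_background(rnd, 3), oracle_median_disk(rnd, 3))

  expect_error(estimate_background(rnd, 0), ">= 1")
})

test_that("gaussian smoothing preserves mass and flattens peaks", {
  img <- matrix(7, 9, 9)
  expect_equal(smooth_image(img, 2), img)

  spike <- matrix(0, 21, 21); spike[11, 11] <- 100
  sm <- smooth_image(spike, 1)
  expect_lt(max(sm), 100)
  expect_equal(sum(sm), 100, tolerance = 1e-9)  # reflection conserves mass
  expect_identical(smooth_image(spike, 0), spike)
  expect_error(smooth_image(spike, -1), ">= 0")
})

test_that("background subtraction clips at zero", {
  a <- matrix(50, 5, 5); b <- matrix(30, 5, 5)
  expect_equal(subtract_background(a, b), matrix(20, 5, 5))
  expect_equal(subtract_background(b, a), matrix(0, 5, 5))
  expect_equal(subtract_background(a, a), matrix(0, 5, 5))
  expect_error(subtract_background(a, matrix(0, 4, 5)), "shape")
})

test_that("otsu threshold equals exhaustive between-class variance search", {
  img <- matrix(c(rep(0, 128), rep(255, 128)), 16, 16)
  thr <- compute_threshold(img, "otsu")
  expect_gt(thr, 0); expect_lt(thr, 255)
  expect_identical(thr, oracle_otsu(img))

  img2 <- matrix(c(rep(10, 90), rep(200, 10)), 10, 10)
  thr2 <- compute_threshold(img2, "otsu")
  expect_gt(thr2, 10); expect_lt(thr2, 200)
  expect_identical(thr2, oracle_otsu(img2))

  set.seed(17)
  for (i in 1:10) {
    rnd <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    expect_identical(compute_threshold(rnd, "otsu"), oracle_otsu(rnd))
  }

  expect_error(compute_threshold(matrix(5, 8, 8), "otsu"), "degenerate")
})

test_that("yen and triangle thresholds separate a bimodal image", {
  set.seed(4)
  img <- matrix(c(rnorm(900, 20, 3), rnorm(100, 150, 5)), 50, 20)
  for (m in c("yen", "triangle")) {
    thr <- compute_threshold(img, m)
    # the threshold must fall in the valley: all bright-mode pixels above it,
    # nearly all background pixels below it
    expect_lt(thr, 140)
    expect_true(all(img[901:1000] > thr))
    expect_lt(mean(img[1:900] > thr), 0.05)
  }
})

test_that("binarize applies a strict greater-than rule", {
  img <- matrix(c(0, 100, 0, 100), 2, 2)
  expect_equal(binarize(img, 50), matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  expect_false(any(binarize(img, 100)))
  expect_true(all(binarize(img, -1)))
})

test_that("thinning reduces to 1 px, preserves topology, and is idempotent", {
  expect_false(any(thin_mask(matrix(FALSE, 8, 8))))

  # an already-thin line is untouched
  line <- matrix(FALSE, 5, 9); line[3, 2:6] <- TRUE
  expect_equal(thin_mask(line), line)

  # 3x7 rectangle collapses to a single path along the long axis mid-row
  rect <- matrix(FALSE, 7, 11); rect[3:5, 3:9] <- TRUE
  sk <- thin_mask(rect)
  w <- which(sk, arr.ind = TRUE)
  expect_equal(unique(w[, "row"]), 4L)
  expect_gte(nrow(w), 5)
  expect_equal(count_components(sk), 1L)

  for (s in 1:5) {
    m <- random_blob_mask(48, 48, s)
    sk <- thin_mask(m)
    expect_identical(thin_mask(sk), sk)                    # idempotent
    expect_equal(count_components(sk), count_components(m))  # topology
    # 1 px thick: no fully occupied 2x2 neighborhood
    blocks <- sk[-1, -1] & sk[-nrow(sk), -1] & sk[-1, -ncol(sk)] &
      sk[-nrow(sk), -ncol(sk)]
    expect_false(any(blocks))
  }
})

test_that("short features are flagged and excluded", {
  m <- matrix(FALSE, 12, 24)
  m[2, 2:3] <- TRUE      # 2 px
  m[5, 2:4] <- TRUE      # 3 px
  m[8, 2:11] <- TRUE     # 10 px
  fs <- label_and_filter_short(m, min_feature_px = 3)
  expect_equal(sort(fs$flags$n_px[fs$flags$retained]), c(3L, 10L))
  expect_equal(fs$flags$n_px[fs$flags$too_short], 2L)

  empty <- label_and_filter_short(matrix(FALSE, 4, 4))
  expect_equal(nrow(empty$flags), 0)

  all_long <- label_and_filter_short(m, min_feature_px = 2)
  expect_true(all(all_long$flags$retained))
})

test_that("branch-point detection excludes intersecting features", {
  # plus sign: center pixel has 4 neighbors
  plus <- matrix(FALSE, 9, 9)
  plus[5, 2:8] <- TRUE; plus[2:8, 5] <- TRUE
  fs <- remove_branched(label_and_filter_short(plus))
  expect_true(all(fs$flags$branched))
  expect_equal(oracle_neighbor_count(plus, 5, 5), 4)

  # straight diagonal: every pixel has <= 2 neighbors, retained
  diag_m <- matrix(FALSE, 10, 10)
  diag_m[cbind(2:9, 2:9)] <- TRUE
  fs2 <- remove_branched(label_and_filter_short(diag_m))
  expect_false(any(fs2$flags$branched))
  expect_true(all(fs2$flags$retained))

  # X-crossing plus a separate straight line: only the line survives
  m <- matrix(FALSE, 16, 16)
  m[cbind(2:8, 2:8)] <- TRUE; m[cbind(8:2, 2:8)] <- TRUE  # X
  m[13, 3:12] <- TRUE                                      # line
  fs3 <- remove_branched(label_and_filter_short(m))
  expect_equal(sum(fs3$flags$retained), 1)
  expect_equal(fs3$flags$n_px[fs3$flags$retained], 10L)
})

test_that("length metrics measure skeleton paths as specified", {
  m <- matrix(FALSE, 6, 14); m[3, 3:12] <- TRUE  # horizontal 10 px
  fs <- remove_branched(label_and_filter_short(m))
  rec <- measure_lengths(fs, pixel_size = 0.107)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$length_um, 1.07, tolerance = 1e-12)

  d <- matrix(FALSE, 14, 14); d[cbind(3:12, 3:12)] <- TRUE  # diagonal 10 px
  fsd <- remove_branched(label_and_filter_short(d))
  recd <- measure_lengths(fsd, pixel_size = 1, length_metric = "geodesic")
  expect_equal(recd$length_px, 9 * sqrt(2), tolerance = 1e-12)

  recp <- measure_lengths(fsd, pixel_size = 1, length_metric = "pixel_count")
  expect_equal(recp$length_px, 10)

  expect_error(measure_lengths(fsd, pixel_size = 0), "positive")
})

test_that("the assembled pipeline measures a clean synthetic tube", {
  # noise-free, evenly lit background-only scene: degenerate residual,
  # zero records
  sp0 <- scene_spec(image_shape = c(96, 96), pixel_size = 0.1, n_tubes = 0,
                    read_noise_sd = 0, shot_noise = FALSE,
                    illumination_gradient = 0, seed = 1)
  sc0 <- render_scene(sp0)
  expect_warning(seg0 <- run_pipeline(sc0$micrograph), "degenerate")
  expect_equal(nrow(seg0$records), 0)

  # a bright 5 um tube at low noise comes back within 5%
  sp1 <- scene_spec(image_shape = c(128, 128), pixel_size = 0.1, n_tubes = 1,
                    length_distribution = dist_fixed(5), curvature = 0,
                    tube_amplitude = 8000, read_noise_sd = 50, seed = 21)
  sc1 <- render_scene(sp1)
  seg1 <- run_pipeline(sc1$micrograph,
                       pipeline_config(length_metric = "geodesic"))
  expect_equal(nrow(seg1$records), 1)
  expect_lt(abs(seg1$records$length_um / 5 - 1), 0.05)
})

test_that("a crossing pair is excluded while an isolated tube is measured", {
  # find a seed whose ground truth has exactly one crossing pair (crossing in
  # the interior of both tubes, so the skeletons merge into a branched
  # component rather than meeting end-to-end) plus one free tube
  interior_cross <- function(P, Q) {
    cum_p <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
    cum_q <- c(0, cumsum(sqrt(rowSums(diff(Q)^2))))
    for (i in seq_len(nrow(P) - 1)) for (j in seq_len(nrow(Q) - 1)) {
      a <- P[i, ]; b <- P[i + 1, ]; c_ <- Q[j, ]; d <- Q[j + 1, ]
      den <- (b[1] - a[1]) * (d[2] - c_[2]) - (b[2] - a[2]) * (d[1] - c_[1])
      if (abs(den) < 1e-12) next
      t <- ((c_[1] - a[1]) * (d[2] - c_[2]) - (c_[2] - a[2]) * (d[1] - c_[1])) / den
      u <- ((c_[1] - a[1]) * (b[2] - a[2]) - (c_[2] - a[2]) * (b[1] - a[1])) / den
      if (t > 0 && t < 1 && u > 0 && u < 1) {
        fp <- (cum_p[i] + t) / max(cum_p)
        fq <- (cum_q[j] + u) / max(cum_q)
        if (fp > 0.2 && fp < 0.8 && fq > 0.2 && fq < 0.8) return(TRUE)
      }
    }
    FALSE
  }
  found <- NULL
  for (s in 1:200) {
    sp <- scene_spec(image_shape = c(128, 128), pixel_size = 0.1, n_tubes = 3,
                     length_distribution = dist_fixed(4), curvature = 0,
                     tube_amplitude = 8000, read_noise_sd = 50, seed = s)
    sc <- render_scene(sp)
    if (sum(sc$ground_truth$crosses_another) == 2) {
      v <- attr(sc$ground_truth, "vertices")
      xi <- which(sc$ground_truth$crosses_another)
      if (interior_cross(v[[xi[1]]], v[[xi[2]]])) { found <- sc; break }
    }
  }
  expect_false(is.null(found))
  seg <- run_pipeline(found$micrograph,
                      pipeline_config(length_metric = "geodesic"))
  expect_equal(nrow(seg$records), 1)
  iso <- found$ground_truth$true_length_um[!found$ground_truth$crosses_another]
  expect_lt(abs(seg$records$length_um / iso - 1), 0.15)
})

test_that("length-metric biases have the expected sign and size", {
  # Straight tubes at random orientations: the geodesic step sum is nearly
  # unbiased on average (+8% staircase overcount at worst orientations vs a
  # few px of end retraction), while the pixel count reads short — a line at
  # 45 deg holds only L/sqrt(2) pixels, about -10% averaged over angles,
  # plus the end retraction.
  errs <- vapply(1:15, function(i) {
    sc <- render_scene(straight_tube_scene(30 + 3 * i, seed = 800 + i,
                                           tube_amplitude = 4000))
    seg <- run_pipeline(sc$micrograph,
                        pipeline_config(length_metric = "geodesic"))
    if (nrow(seg$records) != 1) return(c(NA, NA))
    pc <- measure_lengths(seg$features, pixel_size = 0.1,
                          length_metric = "pixel_count")
    truth <- sc$ground_truth$true_length_um
    c(geo = seg$records$length_um / truth - 1, pix = pc$length_um / truth - 1)
  }, numeric(2))
  expect_gte(sum(!is.na(errs[1, ])), 13)
  expect_lt(abs(mean(errs[1, ], na.rm = TRUE)), 0.05)
  m_pix <- mean(errs[2, ], na.rm = TRUE)
  expect_lt(m_pix, 0)       # systematic undercount
  expect_gt(m_pix, -0.15)   # bounded by the geometry above
})

test_that("measured features always satisfy the structural invariants", {
  sp <- scene_spec(image_shape = c(160, 160), pixel_size = 0.1, n_tubes = 8,
                   seed = 13)
  seg <- run_pipeline(render_scene(sp)$micrograph)
  f <- seg$features$flags
  expect_true(all(f$n_px[f$retained] >= 3))
  nb <- tubequant:::.cpp_neighbor_count(seg$features$skeleton, 8L)
  for (k in f$feature_id[f$retained]) {
    coords <- seg$features$features[[k]]
    expect_true(all(nb[coords] <= 2))
  }
})

test_that("a uniform intensity offset does not change the measurement", {
  sp <- scene_spec(image_shape = c(128, 128), pixel_size = 0.1, n_tubes = 4,
                   tube_amplitude = 4000, seed = 9)
  sc <- render_scene(sp)
  img1 <- sc$micrograph
  img2 <- micrograph(pmin(img1$intensity + 500, 65535), img1$pixel_size,
                     image_id = "offset")
  r1 <- run_pipeline(img1)$records
  r2 <- run_pipeline(img2)$records
  expect_equal(r1$length_um, r2$length_um)
})

test_that("pipeline outputs are written when requested", {
  out <- withr::local_tempdir()
  sp <- scene_spec(image_shape = c(96, 96), pixel_size = 0.1, n_tubes = 2,
                   seed = 6)
  sc <- render_scene(sp)
  sc$micrograph$image_id <- "demo"
  run_pipeline(sc$micrograph, out_dir = out)
  expect_true(file.exists(file.path(out, "records_demo.csv")))
  params <- read.csv(file.path(out, "params_demo.csv"))
  expect_equal(params$median_radius, 15)
  expect_true(is.finite(params$threshold_value))
  expect_true(file.exists(file.path(out, "overlay_demo.png")))
})
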