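# Illumination correction, segmentation, ring geometry, sensor measurement.

test_that("illumination bias: flat field, known gradient, error cases", {
  # flat: surface == 1 within 1%
  flat <- matrix(100, 80, 80)
  b <- estimate_illumination_bias(list(flat))
  expect_lt(max(abs(b$surface - 1)), 0.01)
  expect_equal(b$background, 100, tolerance = 1e-6)
  # known quadratic bias on a cell-free frame: relative error < 2%
  surf <- cycleflow:::cf_bias_surface(80, 80, 0.2, seed = 31)
  frame <- 100 * surf
  b2 <- estimate_illumination_bias(list(frame))
  expect_lt(max(abs(b2$surface / surf - 1)), 0.02)
  expect_error(estimate_illumination_bias(list()), "no frames")
})

test_that("flatten_and_subtract implements image/surface - background", {
  surf <- matrix(runif(400, 0.8, 1.2), 20, 20)
  bias <- list(surface = surf, background = 30)
  img <- surf * 30
  expect_equal(flatten_and_subtract(img, bias), matrix(0, 20, 20))
  # identity bias
  id <- list(surface = matrix(1, 20, 20), background = 0)
  x <- matrix(runif(400), 20, 20)
  expect_equal(flatten_and_subtract(x, id), x)
  expect_error(flatten_and_subtract(matrix(0, 5, 5), bias), "shape")
  # clipping at zero
  expect_true(all(flatten_and_subtract(img * 0.5, bias) >= 0))
})

test_that("corrected generator frames have near-zero background", {
  cfg <- tiny_movie_config(n_cells = 2, n_frames = 1, seed = 13,
                           bias_amplitude = 0.2, noise_sd = 3)
  mv <- render_movie(cfg)
  fr <- corrected_first_frame(mv)
  # cell-free pixels (far from both nuclei) should average ~0 within noise
  tc <- mv$truth$cells[mv$truth$cells$frame == 1, ]
  nr <- nrow(fr$marker)
  yy <- matrix(rep(seq_len(nr), ncol(fr$marker)), nr)
  xx <- matrix(rep(seq_len(ncol(fr$marker)), each = nr), nr)
  far <- rep(TRUE, length(xx))
  for (i in seq_len(nrow(tc)))
    far <- far & (sqrt((xx - tc$x[i])^2 + (yy - tc$y[i])^2) > 25)
  expect_lt(abs(mean(fr$marker[far]) - mean(pmax(rnorm(1e5, 0, 3), 0))),
            cfg$noise_sd)
})

test_that("segmentation finds well-separated nuclei accurately", {
  expect_equal(nrow(segment_nuclei(matrix(0, 60, 60), 0.65)), 0)
  cfg <- sim_movie_config(field_size_px = c(300, 300), n_frames = 1,
                          n_cells_initial = 10, motion_sd_px = 0, seed = 41)
  mv <- render_movie(cfg)
  fr <- corrected_first_frame(mv)
  det <- segment_nuclei(fr$marker, cfg$pixel_size_um)
  tc <- mv$truth$cells
  expect_equal(nrow(det), 10)
  for (i in seq_len(10)) {
    j <- which.min((det$x - tc$x[i])^2 + (det$y - tc$y[i])^2)
    expect_lt(sqrt((det$x[j] - tc$x[i])^2 + (det$y[j] - tc$y[i])^2), 1)
    expect_lt(abs(det$area_px2[j] / tc$area_px2[i] - 1), 0.1)
  }
})

test_that("touching nuclei are split", {
  # two nuclei whose boundaries are ~3 px apart
  cfg <- tiny_movie_config(n_cells = 0, n_frames = 1, seed = 1)
  r <- sqrt(200 / pi)
  plan_t <- data.frame(cell = c("a", "b"), frame = 1L,
                       x = c(60 - r - 1.5, 60 + r + 1.5), y = 60,
                       area_px2 = 200, aspect = 1, activity = 0.5,
                       fate = "x")
  fr <- cycleflow:::cf_render_frame(plan_t, cfg, matrix(1, 120, 120), 1, 1)
  b <- list(surface = matrix(1, 120, 120), background = cfg$background)
  det <- segment_nuclei(flatten_and_subtract(fr$marker, b), cfg$pixel_size_um)
  expect_equal(nrow(det), 2)
  expect_equal(sort(det$x), sort(plan_t$x), tolerance = 0.05)
})

test_that("ring geometry invariants hold exhaustively", {
  # isolated circular nucleus radius ~5 um at 0.65 um/px
  cfg <- tiny_movie_config(n_cells = 1, n_frames = 1, seed = 19)
  mv <- render_movie(cfg)
  fr <- corrected_first_frame(mv)
  det <- segment_nuclei(fr$marker, cfg$pixel_size_um)
  ring <- make_cytoplasmic_ring(det, 1)
  expect_false(ring$empty)
  # exhaustive distance check of every ring pixel via the EDT
  pix_list <- attr(det, "pix")
  nr <- 120
  mask <- matrix(FALSE, 120, 120); mask[pix_list[[1]]] <- TRUE
  dmap <- cycleflow:::.cf_edt(mask) * cfg$pixel_size_um
  dd <- dmap[ring$pix]
  expect_true(all(dd > 2 & dd <= 10))
  expect_false(any(ring$pix %in% pix_list[[1]]))
})

test_that("ring excludes the neighbourhood of other nuclei", {
  # second nucleus ~12 um from the first nucleus boundary
  cfg <- tiny_movie_config(n_cells = 0, n_frames = 1, seed = 1)
  px <- cfg$pixel_size_um
  r <- sqrt(200 / pi)  # px
  gap_px <- 12 / px
  plan_t <- data.frame(cell = c("a", "b"), frame = 1L,
                       x = c(40, 40 + 2 * r + gap_px), y = 60,
                       area_px2 = 200, aspect = 1, activity = 0.5, fate = "x")
  fr <- cycleflow:::cf_render_frame(plan_t, cfg, matrix(1, 120, 120), 1, 1)
  b <- list(surface = matrix(1, 120, 120), background = cfg$background)
  det <- segment_nuclei(flatten_and_subtract(fr$marker, b), px)
  expect_equal(nrow(det), 2)
  i <- which.min(det$x)
  ring <- make_cytoplasmic_ring(det, i)
  pix_list <- attr(det, "pix")
  other <- matrix(FALSE, 120, 120)
  other[pix_list[[which.max(det$x)]]] <- TRUE
  d_oth <- cycleflow:::.cf_edt(other) * px
  expect_true(all(d_oth[ring$pix] > 10))
})

test_that("fully crowded nucleus yields an empty, flagged ring", {
  # central nucleus surrounded by four neighbours well inside 10 um
  cfg <- tiny_movie_config(n_cells = 0, n_frames = 1, seed = 1)
  px <- cfg$pixel_size_um
  r <- sqrt(150 / pi)
  off <- 2 * r + 4
  plan_t <- data.frame(cell = letters[1:5], frame = 1L,
                       x = 60 + c(0, off, -off, 0, 0),
                       y = 60 + c(0, 0, 0, off, -off),
                       area_px2 = 150, aspect = 1, activity = 0.5, fate = "x")
  fr <- cycleflow:::cf_render_frame(plan_t, cfg, matrix(1, 120, 120), 1, 1)
  b <- list(surface = matrix(1, 120, 120), background = cfg$background)
  det <- segment_nuclei(flatten_and_subtract(fr$marker, b), px)
  ctr <- which.min((det$x - 60)^2 + (det$y - 60)^2)
  ring <- make_cytoplasmic_ring(det, ctr)
  expect_true(ring$empty)
  m <- measure_sensor(matrix(1, 120, 120), det, ctr, ring)
  expect_true(is.na(m$cyto_median))
  expect_equal(m$flag, "empty_ring")
})

test_that("measure_sensor applies the background-exclusion rule", {
  # synthetic detections with hand-built masks
  nr <- 40
  img <- matrix(0, nr, nr)
  nuc_pix <- which(matrix(rep(1:nr, nr), nr) <= 5)[1:25]
  det <- cycleflow:::cf_detections(list(nuc_pix), nr, nr, 1, img)
  ring <- list(pix = 600:699, n_pixels = 100, empty = FALSE)
  img[nuc_pix] <- 200
  img[600:699] <- 100
  m <- measure_sensor(img, det, 1, ring, background_sd = 5)
  expect_equal(m$cyto_median, 100)
  # half the ring at background: excluded from the median
  img[600:649] <- 0
  m2 <- measure_sensor(img, det, 1, ring, background_sd = 2.5, k = 2)
  expect_equal(m2$cyto_median, 100)
  expect_equal(m2$n_excluded, 50L)
  # too few surviving pixels -> flagged missing
  img[600:699] <- 0
  img[600:602] <- 100
  m3 <- measure_sensor(img, det, 1, ring, background_sd = 2.5)
  expect_true(is.na(m3$cyto_median))
  expect_equal(m3$flag, "too_few_pixels")
})

test_that("CDK2 activity ratio arithmetic and scale invariance", {
  expect_equal(compute_cdk2_activity(100, 100), 1.0)
  expect_equal(compute_cdk2_activity(0, 100), 0.0)
  expect_equal(compute_cdk2_activity(60, 100), 0.6)
  expect_true(is.na(compute_cdk2_activity(50, 0)))
  expect_true(is.na(compute_cdk2_activity(NA, 100)))
  # scale invariance of the measured activity under c * image
  mv <- render_single_cell(seed = 23)
  fr <- corrected_first_frame(mv)
  m1 <- measure_frame(fr$marker, fr$sensor, mv$config$pixel_size_um,
                      background_sd = 1e-6)
  m2 <- measure_frame(fr$marker, fr$sensor * 7.3, mv$config$pixel_size_um,
                      background_sd = 1e-6)
  expect_equal(m1$activity, m2$activity, tolerance = 1e-12)
})

test_that("segmentation recall/precision >= 0.95 on a default noisy movie", {
  cfg <- sim_fate_cohort_config(n_cells = 12, n_frames = 30, seed = 37,
                                field_size_px = c(320, 320), noise_sd = 10,
                                first_mitosis_frames = c(5, 20))
  res <- run_movie_pipeline(cfg)
  seg <- evaluate_segmentation(res$measurements, res$truth)
  expect_gte(seg$recall, 0.95)
  expect_gte(seg$precision, 0.95)
})
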