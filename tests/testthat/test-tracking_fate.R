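# Tracking, mitosis calling, fate classification, summaries.

test_that("a static cell yields a single full-length track", {
  det <- data.frame(frame = 1:10, x = 50, y = 50, area_um2 = 80)
  tr <- track_nuclei(det, pixel_size_um = 0.65)
  expect_equal(length(unique(tr$track)), 1)
  expect_equal(sum(tr$track == tr$track[1]), 10)
})

test_that("steps beyond the gate terminate tracks instead of misjoining", {
  # both cells jump far beyond max_step_um in one frame
  det <- rbind(data.frame(frame = 1, x = c(10, 100), y = 10, area_um2 = 80),
               data.frame(frame = 2, x = c(40, 130), y = 60, area_um2 = 80))
  tr <- track_nuclei(det, pixel_size_um = 1, max_step_um = 10)
  # four singleton tracks: nothing was joined across the jump
  expect_equal(length(unique(tr$track)), 4)
  # and the area gate alone blocks a half-sized successor in place
  det2 <- rbind(data.frame(frame = 1, x = 10, y = 10, area_um2 = 100),
                data.frame(frame = 2, x = 10, y = 10, area_um2 = 50))
  tr2 <- track_nuclei(det2, pixel_size_um = 1)
  expect_equal(length(unique(tr2$track)), 2)
})

test_that("mitosis band rule accepts/rejects by daughter area fractions", {
  mk_case <- function(d1, d2) {
    det <- rbind(
      data.frame(frame = 1:3, x = 50, y = 50, area_um2 = 100),
      data.frame(frame = 4:6, x = 46, y = 50, area_um2 = d1),
      data.frame(frame = 4:6, x = 54, y = 50, area_um2 = d2))
    tracked <- track_nuclei(det, pixel_size_um = 0.65)
    detect_mitosis(tracked, pixel_size_um = 0.65)
  }
  # 50/50: centre of the band
  res <- mk_case(50, 50)
  expect_equal(nrow(res$events), 1)
  expect_true(res$events$accepted)
  # 60/40: 0.60 outside [0.45, 0.55]
  res2 <- mk_case(60, 40)
  expect_equal(nrow(res2$events), 1)
  expect_false(res2$events$accepted)
  # boundary values are inclusive
  res3 <- mk_case(45, 55)
  expect_true(res3$events$accepted)
  res4 <- mk_case(44.9, 55)
  expect_false(res4$events$accepted)
})

test_that("band-rule decision equals direct interval evaluation (oracle)", {
  band <- c(0.45, 0.55)
  fr <- (40:60) / 100
  for (f1 in fr) for (f2 in c(0.45, 0.5, 0.56)) {
    det <- rbind(
      data.frame(frame = 1:2, x = 50, y = 50, area_um2 = 100),
      data.frame(frame = 3:4, x = 46, y = 50, area_um2 = 100 * f1),
      data.frame(frame = 3:4, x = 54, y = 50, area_um2 = 100 * f2))
    tracked <- track_nuclei(det, pixel_size_um = 0.65)
    res <- detect_mitosis(tracked, pixel_size_um = 0.65, band = band)
    oracle <- f1 >= band[1] && f1 <= band[2] && f2 >= band[1] && f2 <= band[2]
    expect_equal(res$events$accepted, oracle,
                 info = sprintf("f1=%.2f f2=%.2f", f1, f2))
  }
})

test_that("scheduled divisions are detected on a small synthetic movie", {
  cfg <- sim_fate_cohort_config(n_cells = 8, n_frames = 45, seed = 55,
                                field_size_px = c(300, 300), noise_sd = 5,
                                first_mitosis_frames = c(5, 25))
  res <- run_movie_pipeline(cfg)
  dv <- evaluate_divisions(res$mitoses, res$tracked, res$truth)
  expect_equal(dv$n_detected_true, dv$n_true)
  expect_equal(dv$n_false_positive, 0)
  # lineage conservation: every accepted event consumes one track, adds two
  tr <- res$mitoses$tracks
  n_acc <- sum(res$mitoses$events$accepted)
  expect_equal(sum(!is.na(tr$parent)), 2 * n_acc)
})

test_that("G2-arrest window rule: cycling / arrested / censored", {
  expect_equal(classify_g2_arrest(10, 38, 60), "cycling")     # 28 h gap
  expect_equal(classify_g2_arrest(10, NA, 41.5), "arrested")  # 31.5 h, none
  expect_equal(classify_g2_arrest(10, NA, 30), "censored")    # only 20 h seen
  # boundary: exactly 30 h gap is within the window
  expect_equal(classify_g2_arrest(0, 30, 60), "cycling")
  # a second mitosis after the window still means arrest was called
  expect_equal(classify_g2_arrest(0, 35, 60), "arrested")
  expect_error(classify_g2_arrest(NA, 10, 60), "not applicable")
})

test_that("post-mitotic fate thresholds follow the 0.6 / 2 h rule", {
  tt <- seq(0, 30 * 60, by = 12)
  mk <- function(vals) classify_post_mitotic_fate(tt, vals, anaphase_min = 0)
  expect_equal(mk(rep(0.8, length(tt))), "cdk2_increasing")
  # 0.4 at 2 h rising to 0.7 by 6 h
  v <- ifelse(tt < 240, 0.4, 0.7)
  expect_equal(mk(v), "transient_g0")
  expect_equal(mk(rep(0.3, length(tt))), "prolonged_g0")
  # exactly 0.6 counts as low
  expect_equal(mk(rep(0.6, length(tt))), "prolonged_g0")
  # trace ends before anaphase + 2 h: censored
  expect_true(is.na(classify_post_mitotic_fate(0:5 * 12, rep(0.8, 6), 0)))
})

test_that("constant-activity traces recover the threshold boundary", {
  tt <- seq(0, 600, by = 12)
  for (a in (6:18) / 20) {
    got <- classify_post_mitotic_fate(tt, rep(a, length(tt)), 0)
    expect_equal(got, if (a > 0.6) "cdk2_increasing" else "prolonged_g0")
  }
})

test_that("intermitotic times and histogram", {
  it <- intermitotic_times(c(10, 5, 8), c(30, NA, 26))
  expect_equal(sort(it$durations_h), c(18, 20))
  expect_equal(it$n_censored, 1)
  expect_equal(sum(it$histogram$count), 2)
  # 18 and 20 fall into the (16,18] and (18,20] bins
  expect_equal(it$histogram$count[it$histogram$bin_right == 18], 1)
  # no completed lineages
  it0 <- intermitotic_times(c(1, 2), c(NA, NA))
  expect_equal(length(it0$durations_h), 0)
  expect_equal(it0$n_censored, 2)
  # synthetic cohort with 18 h scheduled cycles: histogram mode at 18 h
  cfg <- sim_fate_cohort_config(n_cells = 10, n_frames = 140, seed = 71,
                                field_size_px = c(320, 320), noise_sd = 5,
                                first_mitosis_frames = c(4, 20),
                                intermitotic_h = 18,
                                fate_probs = c(cdk2_increasing = 1,
                                               transient_g0 = 0,
                                               prolonged_g0 = 0,
                                               g2_arrest = 0))
  res <- run_movie_pipeline(cfg)
  f <- res$fates
  per_lineage <- f[!duplicated(f$mother) & !is.na(f$second_mitosis_h), ]
  it2 <- intermitotic_times(per_lineage$anaphase_h,
                            per_lineage$second_mitosis_h)
  expect_gt(length(it2$durations_h), 3)
  mode_bin <- it2$histogram[which.max(it2$histogram$count), ]
  expect_true(mode_bin$bin_left < 18 && 18 <= mode_bin$bin_right)
})

test_that("heat-map rows are sorted by first mitosis, invariant to order", {
  mk <- function(id, fm) list(track = id, time_min = seq(0, 120, 12),
                              activity = rep(0.5, 11),
                              first_mitosis_min = fm)
  traces <- list(mk(1, 300), mk(2, 120), mk(3, NA))
  hm <- heatmap_matrix(traces)
  expect_equal(hm$order, c(2, 1, 3))
  hm2 <- heatmap_matrix(rev(traces))
  expect_equal(hm2$matrix, hm$matrix)
  expect_equal(nrow(hm$matrix), 3)
})

test_that("average activity pools non-missing values pointwise", {
  t1 <- list(track = 1, time_min = c(0, 12, 24), activity = c(0.2, 0.2, NA),
             first_mitosis_min = 0)
  t2 <- list(track = 2, time_min = c(0, 12, 24), activity = c(0.6, 0.6, 0.9),
             first_mitosis_min = 0)
  av <- average_activity(list(t1, t2))
  expect_equal(av$mean, c(0.4, 0.4, 0.9))
  expect_equal(av$n, c(2, 2, 1))
  # identical traces: dispersion zero
  av2 <- average_activity(list(t2, t2))
  expect_equal(av2$sd, c(0, 0, 0))
  expect_error(average_activity(list()), "length")
})

test_that("anaphase-aligned mean of an arrest cohort stays below 0.6", {
  # prolonged-G0 traces synthesised directly from the trajectory generator
  traces <- lapply(1:8, function(i) {
    ana <- i * 60
    tr <- generate_cdk2_trajectory("prolonged_g0", ana, ana + 1200)
    list(track = i, time_min = tr$time_min, activity = tr$activity,
         first_mitosis_min = ana)
  })
  av <- average_activity(traces, alignment = "anaphase")
  post <- av[av$time_min > 120, ]
  expect_true(all(post$mean < 0.6))
})

test_that("track end reasons balance the lineage ledger", {
  cfg <- sim_fate_cohort_config(n_cells = 6, n_frames = 40, seed = 77,
                                field_size_px = c(280, 280), noise_sd = 5,
                                first_mitosis_frames = c(5, 15))
  res <- run_movie_pipeline(cfg)
  ends <- classify_track_ends(res$tracked, res$mitoses)
  expect_true(all(ends$end_reason %in%
                    c("division", "death", "lost", "end-of-movie")))
  expect_equal(sum(ends$end_reason == "division"),
               sum(res$mitoses$events$accepted))
})
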