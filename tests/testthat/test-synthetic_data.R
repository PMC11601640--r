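# Generators: prescribed trajectories, movie ground truth, tables.

test_that("CDK2 trajectories satisfy their fate definitions", {
  # prolonged G0 never exceeds 0.6 after anaphase
  tr <- generate_cdk2_trajectory("prolonged_g0", 60, 2400)
  expect_lt(max(tr$activity[tr$time_min >= 60]), 0.6)
  # immediate re-entry exceeds 0.6 by anaphase + 2 h
  tr <- generate_cdk2_trajectory("cdk2_increasing", 0, 600)
  expect_gt(tr$activity[tr$time_min == 120], 0.6)
  # transient G0 with the default 6 h crossing: below at 2 h, above at 6 h
  tr <- generate_cdk2_trajectory("transient_g0", 0, 600)
  expect_lt(tr$activity[tr$time_min == 120], 0.6)
  expect_gte(tr$activity[tr$time_min == 360], 0.6)
  # G2 arrest rises but plateaus below the pre-mitotic peak
  tr <- generate_cdk2_trajectory("g2_arrest", 0, 2400)
  expect_gt(max(tr$activity), 0.6)
  expect_lt(max(tr$activity), cdk2_params()$peak)
  expect_error(generate_cdk2_trajectory("not_a_fate", 0, 100), "unknown fate")
  expect_error(generate_cdk2_trajectory("g2_arrest", 100, 100), "horizon")
})

test_that("transient crossing time is configurable and honoured", {
  p <- cdk2_params(transient_cross_h = 8)
  tr <- generate_cdk2_trajectory("transient_g0", 0, 900, params = p)
  f <- approxfun(tr$time_min, tr$activity)
  expect_lt(f(120), 0.6)
  expect_lt(f(8 * 60 - 24), 0.6)
  expect_gte(f(8 * 60 + 12), 0.6)
})

test_that("empty movie renders pure background with empty truth", {
  cfg <- tiny_movie_config(n_cells = 0, seed = 5)
  mv <- render_movie(cfg)
  expect_equal(dim(mv$stack), c(120, 120, 2, 3))
  # blurred channels with no cells are flat background
  expect_equal(max(abs(mv$stack[, , 1, 1] - cfg$background)), 0, tolerance = 1e-9)
  expect_equal(nrow(mv$truth$cells), 0)
})

test_that("rendered sensor reproduces the prescribed activity ratio", {
  mv <- render_single_cell()  # prolonged G0 -> activity 0.35 post-anaphase
  # measure directly on the ground-truth geometry, before any pipeline step
  tc <- mv$truth$cells[mv$truth$cells$frame == 1, ]
  sensor <- mv$stack[, , 2, 1] - mv$config$background
  nr <- nrow(sensor)
  yy <- matrix(rep(seq_len(nr), ncol(sensor)), nr)
  xx <- matrix(rep(seq_len(ncol(sensor)), each = nr), nr)
  r <- sqrt(tc$area_px2 / pi)
  d <- sqrt((xx - tc$x)^2 + (yy - tc$y)^2)
  nuc <- median(sensor[d < 0.7 * r])
  cyt <- median(sensor[d > r + 4 & d < r + 9])
  expect_equal(cyt / nuc, tc$activity, tolerance = 0.05)
})

test_that("rendered-activity fidelity holds across the dynamic range", {
  # render single frames at fixed prescribed activities via the frame
  # renderer and check the measured ratio within 5% across [0.2, 1.5]
  cfg <- tiny_movie_config(n_cells = 1, n_frames = 1, seed = 17)
  bias <- matrix(1, 120, 120)
  for (act in c(0.2, 0.5, 0.8, 1.1, 1.5)) {
    plan_t <- data.frame(cell = "1", frame = 1L, x = 60, y = 60,
                         area_px2 = 200, aspect = 1.05, activity = act,
                         fate = "cdk2_increasing")
    fr <- cycleflow:::cf_render_frame(plan_t, cfg, bias, 1, noise_seed = 1)
    b <- list(surface = bias, background = cfg$background)
    m <- measure_frame(flatten_and_subtract(fr$marker, b),
                       flatten_and_subtract(fr$sensor, b),
                       cfg$pixel_size_um, background_sd = 1e-6)
    expect_equal(m$activity, act, tolerance = 0.05 * max(act, 1))
  }
  # pipeline-level fidelity (bias estimated, not given)
  mv <- render_single_cell()
  fr <- corrected_first_frame(mv)
  m <- measure_frame(fr$marker, fr$sensor, mv$config$pixel_size_um,
                     background_sd = 1e-6)
  expect_equal(m$activity, mv$truth$cells$activity[1], tolerance = 0.05)
})

test_that("division schedule passes through to ground truth", {
  div <- data.frame(cell = "1", frame = 10, frac1 = 0.5, frac2 = 0.5)
  cfg <- tiny_movie_config(n_cells = 1, n_frames = 14, seed = 2,
                           division_schedule = div)
  mv <- render_movie(cfg)
  expect_equal(nrow(mv$truth$divisions), 1)
  expect_equal(mv$truth$divisions$frame, 10)
  # daughters appear at frame 10 with the scheduled area fractions
  d10 <- mv$truth$cells[mv$truth$cells$frame == 10, ]
  mom <- mv$truth$cells[mv$truth$cells$frame == 9, ]
  expect_setequal(d10$cell, c("1.1", "1.2"))
  expect_equal(sort(d10$area_px2 / mom$area_px2), c(0.5, 0.5))
})

test_that("movie generator is deterministic and conserves cells", {
  cfg <- sim_fate_cohort_config(n_cells = 6, n_frames = 40, seed = 9,
                                field_size_px = c(260, 260), noise_sd = 3,
                                first_mitosis_frames = c(5, 12))
  m1 <- render_movie(cfg)
  m2 <- render_movie(cfg)
  expect_identical(m1$stack, m2$stack)
  expect_identical(m1$truth$cells, m2$truth$cells)
  # conservation: cells at frame t = initial + 2*divisions<=t - divided - dead
  tc <- m1$truth$cells
  div <- m1$truth$divisions
  for (f in c(1, 10, 20, 40)) {
    n_obs <- length(unique(tc$cell[tc$frame == f]))
    n_div <- if (is.null(div)) 0 else sum(div$frame <= f)
    expect_equal(n_obs, 6 + n_div)  # each division: -1 mother +2 daughters
  }
})

test_that("invalid movie schedules are rejected", {
  expect_error(tiny_movie_config(division_schedule = data.frame(
    cell = "1", frame = 99, frac1 = 0.5, frac2 = 0.5)), "n_frames")
  expect_error(tiny_movie_config(division_schedule = data.frame(
    cell = "1", frame = 2, frac1 = 1.2, frac2 = 0.5)), "fractions")
  expect_error(tiny_movie_config(fate_assignment = c("1" = "bogus")),
               "unknown fate")
})

test_that("CN table generator: clean consensus, determinism, null effect", {
  g <- sim_cn_tables(n_models = 6, samples_per_model = 4, n_genes = 5,
                     noise_sd = 0, perturb_frac = 0, seed = 21)
  cons <- consensus_table(g$cn)
  key <- paste(cons$gene, cons$model)
  tkey <- paste(g$truth$gene, g$truth$model)
  expect_equal(cons$status[match(tkey, key)], g$truth$class)
  expect_false(any(cons$tie))
  # determinism
  g2 <- sim_cn_tables(n_models = 6, samples_per_model = 4, n_genes = 5,
                      noise_sd = 0, perturb_frac = 0, seed = 21)
  expect_identical(g, g2)
  # effect 1: expression carries no CN signal
  g3 <- sim_cn_tables(n_models = 40, samples_per_model = 4, n_genes = 1,
                      expression_effect = 1, noise_sd = 0.3, seed = 22)
  cons3 <- consensus_table(g3$cn, g3$fpkm)
  an <- cn_expression_anova(cons3$mean_fpkm, cons3$status)
  expect_gt(an$p, 0.001)  # null construction: no real effect
  expect_error(sim_cn_tables(samples_per_model = 0), "samples_per_model")
})

test_that("PK generator: default design, exact decay, LLOQ flags", {
  pk <- sim_pk_profile(lambda_true = 0.5, c0 = 100, lognormal_sd = 0,
                       n_animals = 1, seed = 3)
  expect_equal(length(unique(pk$time_h)), 8)  # 8-point sampling design
  # noiseless: log-linear regression recovers lambda to machine precision
  fit <- terminal_lambda(pk$time_h, pk$conc)
  expect_equal(fit$lambda, 0.5, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # c0 below LLOQ: everything flagged
  pk2 <- sim_pk_profile(lambda_true = 0.5, c0 = 0.5, lognormal_sd = 0,
                        lloq = 1, seed = 3)
  expect_true(all(pk2$lloq_flag))
  expect_error(sim_pk_profile(lambda_true = -1), "lambda_true")
  expect_error(sim_pk_profile(times = c(2, 1)), "increasing")
})

test_that("EdU/DNA generator respects phase composition", {
  g1 <- sim_edu_dna(c(G1 = 50, S = 0, G2M = 0), seed = 4)
  expect_true(all(g1$true_phase == "G1"))
  # zero spread: perfectly separable, gating recovers every phase
  pop <- sim_edu_dna(c(G1 = 60, S = 40, G2M = 30), spread = 0,
                     edu_neg_sd = 0, seed = 5)
  nd <- normalize_dna(pop$dna)
  thr <- set_edu_threshold(pop$edu)
  g <- gate_phases(nd$dna_n, pop$edu, nd$gates, edu_threshold = thr)
  expect_equal(g$phase, pop$true_phase)
})

test_that("TMT generator: spikes, flags, missingness behave as designed", {
  expect_error(sim_tmt_matrix(spike_up = 1:5, spike_down = 3:8), "disjoint")
  g <- sim_tmt_matrix(n_proteins = 300, spike_up = 1:10, spike_down = 11:20,
                      effect_log2 = 3, sd = 0.1, missing_rate = 0,
                      peptide_counts = 5L, frac_reverse = 0, frac_site = 0,
                      frac_contaminant = 0, seed = 6)
  ch <- names(g$groups)
  filt <- tmt_transform_filter(tmt_clean(g$matrix), ch)
  norm <- tmt_median_normalize(filt, ch)
  res <- tmt_differential(norm, ch[g$groups == "treated"],
                          ch[g$groups == "control"])
  # strong clean spikes all pass the stated thresholds
  expect_setequal(res$id[res$class == "up"], g$matrix$id[1:10])
  expect_setequal(res$id[res$class == "down"], g$matrix$id[11:20])
  # a fully missing protein is removed by the completeness filter
  g2 <- g
  g2$matrix[21, ch] <- NA
  filt2 <- tmt_transform_filter(tmt_clean(g2$matrix), ch)
  expect_false(g2$matrix$id[21] %in% filt2$id)
})
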