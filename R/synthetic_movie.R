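#' CDK2 trajectory parameters
#'
#' Shape parameters of the piecewise prescribed CDK2-activity trajectories
#' used by the movie generator. Activity is the cytoplasmic/nuclear sensor
#' ratio: it collapses to a post-mitotic baseline at anaphase and then
#' evolves according to the cell's fate.
#'
#' @param baseline activity immediately after anaphase (default 0.3).
#' @param peak pre-mitotic activity plateau (default 1.0).
#' @param rise_rate_per_h linear rise rate of cycling cells (activity units
#'   per hour; default 0.25, so a re-entering cell crosses 0.6 well before
#'   two hours post-anaphase).
#' @param quiescent_level level held during G0 (default 0.35).
#' @param transient_cross_h time after anaphase at which a transient-G0 cell
#'   crosses 0.6 (default 6 h).
#' @param prolonged_drift total slow upward drift of a prolonged-G0 cell over
#'   30 h (default 0.1; keeps activity below 0.5 at all times).
#' @param arrest_plateau plateau reached by a G2-arrested cell that rises but
#'   never divides again (default 0.9).
#' @return named list of parameters.
#' @export
cdk2_params <- function(baseline = 0.3, peak = 1.0, rise_rate_per_h = 0.25,
                        quiescent_level = 0.35, transient_cross_h = 6,
                        prolonged_drift = 0.1, arrest_plateau = 0.9) {
  stopifnot(baseline > 0, peak > baseline, rise_rate_per_h > 0,
            quiescent_level < 0.6, transient_cross_h > 2)
  list(baseline = baseline, peak = peak, rise_rate_per_h = rise_rate_per_h,
       quiescent_level = quiescent_level, transient_cross_h = transient_cross_h,
       prolonged_drift = prolonged_drift, arrest_plateau = arrest_plateau)
}

cf_fates <- c("cdk2_increasing", "transient_g0", "prolonged_g0", "g2_arrest")

# Closure over time (minutes since movie start) for one cell's prescribed
# activity. Pre-anaphase the mother ramps toward the pre-mitotic peak; at
# anaphase activity drops to the baseline and follows the fate.
cdk2_trajectory_fun <- function(fate, anaphase_min, params = cdk2_params()) {
  force(anaphase_min)  # evaluate now: closures outlive their call sites
  if (!fate %in% cf_fates)
    stop("unknown fate label: '", fate, "' (expected one of ",
         paste(cf_fates, collapse = ", "), ")")
  p <- params
  rate_min <- p$rise_rate_per_h / 60
  function(t_min) {
    t <- as.numeric(t_min)
    pre <- t < anaphase_min
    out <- numeric(length(t))
    # mother segment: linear ramp from 0.6 to the peak at anaphase
    if (any(pre)) {
      if (anaphase_min > 0) {
        out[pre] <- pmin(p$peak, 0.6 + (p$peak - 0.6) * t[pre] / anaphase_min)
      } else out[pre] <- p$peak
    }
    dt <- t[!pre] - anaphase_min  # minutes since anaphase
    out[!pre] <- switch(fate,
      cdk2_increasing = pmin(p$peak, p$baseline + rate_min * dt),
      g2_arrest = pmin(p$arrest_plateau, p$baseline + rate_min * dt),
      prolonged_g0 = pmin(0.59, p$quiescent_level +
                            p$prolonged_drift * pmin(dt, 1800) / 1800),
      transient_g0 = {
        rise_start <- p$transient_cross_h * 60 -
          (0.6 - p$quiescent_level) / rate_min
        pmin(p$peak, ifelse(dt <= rise_start, p$quiescent_level,
                            p$quiescent_level + rate_min * (dt - rise_start)))
      })
    out
  }
}

#' Generate a prescribed CDK2-activity trajectory
#'
#' Piecewise trajectory for a cell of a given post-mitotic fate: activity
#' drops to a baseline at anaphase; an immediately re-entering cell
#' (`cdk2_increasing`) rises past 0.6 before two hours post-anaphase and
#' climbs toward the pre-mitotic peak; a `transient_g0` cell stays below 0.6
#' at two hours and crosses it at a configurable later time; a
#' `prolonged_g0` cell never exceeds 0.6; a `g2_arrest` cell rises but
#' plateaus without a second division.
#'
#' @param fate one of `"cdk2_increasing"`, `"transient_g0"`,
#'   `"prolonged_g0"`, `"g2_arrest"`.
#' @param anaphase_min anaphase time in minutes since movie start.
#' @param horizon_min last sampled time (must exceed `anaphase_min`).
#' @param dt_min sampling interval in minutes (default 12, the acquisition
#'   cadence).
#' @param params [cdk2_params()].
#' @return data.frame with `time_min` and `activity`.
#' @export
generate_cdk2_trajectory <- function(fate, anaphase_min, horizon_min,
                                     dt_min = 12, params = cdk2_params()) {
  if (horizon_min <= anaphase_min)
    stop("horizon_min must exceed anaphase_min")
  f <- cdk2_trajectory_fun(fate, anaphase_min, params)
  tt <- seq(0, horizon_min, by = dt_min)
  data.frame(time_min = tt, activity = f(tt))
}

#' Movie generator configuration
#'
#' Describes a two-channel synthetic time-lapse: channel 1 is a nuclear
#' marker (constant level inside smooth-edged elliptical nuclei), channel 2
#' is a translocation sensor partitioned between nucleus and a perinuclear
#' cytoplasm so that (cytoplasmic median - background)/(nuclear median -
#' background) equals the cell's prescribed CDK2 activity. A smooth
#' multiplicative illumination bias and additive Gaussian noise are applied.
#'
#' @param field_size_px c(rows, cols) of each frame.
#' @param pixel_size_um pixel size in micrometres (default 0.65, a 20x
#'   objective with binning).
#' @param frame_interval_min acquisition cadence in minutes (default 12).
#' @param n_frames number of frames.
#' @param n_cells_initial number of cells at frame 1.
#' @param division_schedule data.frame with columns `cell` (id), `frame`
#'   (1-based anaphase frame: first frame on which the daughters appear),
#'   `frac1`, `frac2` (daughter/mother area fractions in (0,1)). Daughters
#'   of cell `i` get ids `"i.1"` and `"i.2"` and may themselves appear in
#'   the schedule.
#' @param death_schedule data.frame with columns `cell`, `frame`.
#' @param fate_assignment named character vector mapping cell id to the fate
#'   of its daughters (see [generate_cdk2_trajectory()]); the fate shapes the
#'   daughters' prescribed activity.
#' @param bias_amplitude amplitude of the multiplicative illumination bias
#'   (0 = flat field).
#' @param noise_sd additive Gaussian noise sd, in intensity units.
#' @param seed integer; fully determines the output.
#' @param nucleus_radius_um mean nuclear radius (default 5.2 um, ~85 um2).
#' @param motion_sd_px per-frame random-walk step sd (default 2 px).
#' @param background camera background level (default 50).
#' @param marker_level nuclear-marker amplitude above background (default 500).
#' @param sensor_level nuclear sensor amplitude above background (default 200).
#' @param cyto_extent_um how far the rendered cytoplasm reaches beyond the
#'   nuclear boundary (default 10 um, covering the measurement ring;
#'   because the ring excludes pixels within 10 um of another nucleus, an
#'   admissible ring pixel can never contain a neighbour's cytoplasm).
#' @param daughter_growth_h hours a newborn daughter takes to regrow to the
#'   mother's area (default 16).
#' @param traj_params [cdk2_params()].
#' @return object of class `cf_movie_config`.
#' @export
sim_movie_config <- function(field_size_px = c(240, 240), pixel_size_um = 0.65,
                             frame_interval_min = 12, n_frames = 30,
                             n_cells_initial = 10,
                             division_schedule = NULL, death_schedule = NULL,
                             fate_assignment = NULL,
                             bias_amplitude = 0, noise_sd = 0, seed = 1,
                             nucleus_radius_um = 5.2, motion_sd_px = 2,
                             background = 50, marker_level = 500,
                             sensor_level = 200, cyto_extent_um = 10,
                             daughter_growth_h = 16,
                             traj_params = cdk2_params()) {
  stopifnot(length(field_size_px) == 2, all(field_size_px > 32),
            pixel_size_um > 0, frame_interval_min > 0, n_frames >= 1,
            n_cells_initial >= 0, bias_amplitude >= 0, noise_sd >= 0)
  if (!is.null(division_schedule)) {
    stopifnot(all(c("cell", "frame", "frac1", "frac2") %in%
                    names(division_schedule)))
    if (any(division_schedule$frame > n_frames))
      stop("division frames must be <= n_frames")
    if (any(division_schedule$frame < 2))
      stop("division frames must be >= 2 (the mother must be observable)")
    fr <- c(division_schedule$frac1, division_schedule$frac2)
    if (any(fr <= 0 | fr >= 1))
      stop("daughter area fractions must lie in (0, 1)")
    division_schedule$cell <- as.character(division_schedule$cell)
  }
  if (!is.null(death_schedule)) {
    stopifnot(all(c("cell", "frame") %in% names(death_schedule)))
    if (any(death_schedule$frame > n_frames))
      stop("death frames must be <= n_frames")
    death_schedule$cell <- as.character(death_schedule$cell)
  }
  if (!is.null(fate_assignment)) {
    bad <- setdiff(unname(fate_assignment), cf_fates)
    if (length(bad)) stop("unknown fate label(s): ", paste(bad, collapse = ", "))
  }
  structure(list(
    field_size_px = as.integer(field_size_px), pixel_size_um = pixel_size_um,
    frame_interval_min = frame_interval_min, n_frames = as.integer(n_frames),
    n_cells_initial = as.integer(n_cells_initial),
    division_schedule = division_schedule, death_schedule = death_schedule,
    fate_assignment = fate_assignment,
    bias_amplitude = bias_amplitude, noise_sd = noise_sd, seed = seed,
    nucleus_radius_um = nucleus_radius_um, motion_sd_px = motion_sd_px,
    background = background, marker_level = marker_level,
    sensor_level = sensor_level, cyto_extent_um = cyto_extent_um,
    daughter_growth_h = daughter_growth_h, traj_params = traj_params),
    class = "cf_movie_config")
}

# Smooth multiplicative illumination surface: seeded random quadratic in
# normalised coordinates, scaled so max|deviation| = amplitude, mean ~ 1.
cf_bias_surface <- function(nr, nc, amplitude, seed) {
  if (amplitude == 0) return(matrix(1, nr, nc))
  set.seed(child_seed(seed, "bias"))
  co <- runif(5, -1, 1)
  x <- matrix(rep(seq(-1, 1, length.out = nc), each = nr), nr, nc)
  y <- matrix(rep(seq(-1, 1, length.out = nr), nc), nr, nc)
  q <- co[1] * x + co[2] * y + co[3] * x * y + co[4] * x^2 + co[5] * y^2
  q <- q - mean(q)
  q <- q / max(abs(q))
  1 + amplitude * q
}

# Follow f1 before switch_min, f2 from it on (a daughter's own division).
cf_stitch_traj <- function(f1, f2, switch_min) {
  force(f1); force(f2); force(switch_min)
  function(t) ifelse(t < switch_min, f1(t), f2(t))
}

# Plan the movie in two phases: (A) a cell registry (birth/end frames, area
# trajectories, activity closures, lineage) from the schedules; (B) a joint
# position simulation over frames -- a bounded (tethered) random walk with
# pairwise repulsion so nuclei never overlap, which keeps segmentation
# merges out of the stated world. All RNG is driven by config$seed.
cf_plan_movie <- function(config) {
  set.seed(child_seed(config$seed, "plan"))
  nr <- config$field_size_px[1]; nc <- config$field_size_px[2]
  px <- config$pixel_size_um
  r_px <- config$nucleus_radius_um / px
  margin <- ceiling(r_px + 4)
  nfr <- config$n_frames
  dt <- config$frame_interval_min
  growth_frames <- max(1, round(config$daughter_growth_h * 60 / dt))

  div <- config$division_schedule
  dth <- config$death_schedule
  fates <- config$fate_assignment
  schedule_division <- function(id) {
    if (is.null(div)) return(NULL)
    i <- match(id, div$cell)
    if (is.na(i)) NULL else div[i, ]
  }
  schedule_death <- function(id) {
    if (is.null(dth)) return(NULL)
    i <- match(id, dth$cell)
    if (is.na(i)) NULL else dth[i, ]
  }
  fate_of <- function(id) {
    if (!is.null(fates) && id %in% names(fates)) fates[[id]] else
      "cdk2_increasing"
  }

  # ---- phase A: registry -------------------------------------------------
  reg <- list()      # per cell: id, birth, end, end_type, areas, act, ...
  divisions <- list(); deaths <- list()
  area0 <- pi * r_px^2
  queue <- lapply(seq_len(config$n_cells_initial), function(i) {
    id <- as.character(i)
    d <- schedule_division(id)
    ana <- if (is.null(d)) Inf else (d$frame - 1) * dt
    list(id = id, birth = 1L, parent = NA_character_,
         area_birth = area0 * runif(1, 0.9, 1.1), grow = FALSE,
         fate_label = fate_of(id),
         act = cdk2_trajectory_fun(fate_of(id), anaphase_min = ana,
                                   params = config$traj_params))
  })
  while (length(queue)) {
    cl <- queue[[1]]; queue <- queue[-1]
    d <- schedule_division(cl$id)
    de <- schedule_death(cl$id)
    end <- nfr; end_type <- "end"
    if (!is.null(d)) { end <- d$frame - 1L; end_type <- "division" }
    if (!is.null(de) && de$frame - 1L < end) {
      end <- de$frame - 1L; end_type <- "death"; d <- NULL
    }
    if (end < cl$birth) next
    frames <- seq.int(cl$birth, end)
    ages <- frames - cl$birth
    areas <- if (cl$grow) {
      cl$area_birth + (cl$area_target - cl$area_birth) *
        pmin(1, ages / growth_frames)
    } else rep(cl$area_birth, length(frames))
    am <- areas[length(areas)]
    # death: two shrinking frames before disappearance
    if (end_type == "death") {
      nshrink <- min(2L, nfr - end)
      if (nshrink > 0) {
        frames <- c(frames, seq.int(end + 1L, end + nshrink))
        areas <- c(areas, am * c(0.7, 0.48)[seq_len(nshrink)])
      }
      deaths[[length(deaths) + 1L]] <- data.frame(
        cell = cl$id, frame = end + 1L, stringsAsFactors = FALSE)
    }
    reg[[length(reg) + 1L]] <- list(
      id = cl$id, parent = cl$parent, birth = cl$birth,
      last = frames[length(frames)], frames = frames, areas = areas,
      aspect = runif(1, 0.9, 1.12), fate_label = cl$fate_label,
      act = cl$act, end_type = end_type)
    if (!is.null(d) && end_type == "division") {
      fate_d <- fate_of(cl$id)
      theta <- runif(1, 0, pi)
      rd <- sqrt(am * max(d$frac1, d$frac2) / pi)
      off <- rd + 3.5  # centre offset: clean gap between daughter boundaries
      ana_min <- (d$frame - 1) * dt
      for (k in 1:2) {
        did <- paste0(cl$id, ".", k)
        dd <- schedule_division(did)
        ana2 <- if (is.null(dd)) Inf else (dd$frame - 1) * dt
        fr <- if (k == 1) d$frac1 else d$frac2
        actf <- cdk2_trajectory_fun(fate_d, anaphase_min = ana_min,
                                    params = config$traj_params)
        actf2 <- if (is.finite(ana2)) {
          cf_stitch_traj(actf,
                         cdk2_trajectory_fun(fate_of(did), anaphase_min = ana2,
                                             params = config$traj_params),
                         ana2)
        } else actf
        queue[[length(queue) + 1L]] <- list(
          id = did, birth = d$frame, parent = cl$id,
          area_birth = am * fr, grow = TRUE, area_target = am,
          fate_label = fate_d, act = actf2,
          birth_offset = c(cos(theta), sin(theta)) * off *
            (if (k == 1) 1 else -1))
      }
      divisions[[length(divisions) + 1L]] <- data.frame(
        cell = cl$id, frame = d$frame, frac1 = d$frac1, frac2 = d$frac2,
        daughter1 = paste0(cl$id, ".1"), daughter2 = paste0(cl$id, ".2"),
        stringsAsFactors = FALSE)
    }
    if (!is.null(cl$birth_offset))
      reg[[length(reg)]]$birth_offset <- cl$birth_offset
  }

  ncell <- length(reg)
  empty_plan <- data.frame(cell = character(0), frame = integer(0),
                           x = numeric(0), y = numeric(0),
                           area_px2 = numeric(0), aspect = numeric(0),
                           activity = numeric(0), fate = character(0))
  if (!ncell)
    return(list(cells = empty_plan,
                divisions = NULL, deaths = NULL))
  ids <- vapply(reg, `[[`, character(1), "id")
  birth <- as.integer(vapply(reg, function(r) as.numeric(r$birth), numeric(1)))
  last <- vapply(reg, function(r) as.integer(max(r$frames)), integer(1))
  parent <- vapply(reg, function(r) r$parent %||% NA_character_, character(1))

  # ---- phase B: joint position simulation --------------------------------
  # tethered random walk (pull eta toward the anchor) + pairwise repulsion
  eta <- 0.08
  posx <- matrix(NA_real_, ncell, nfr)
  posy <- matrix(NA_real_, ncell, nfr)
  anchor <- matrix(NA_real_, ncell, 2)
  area_at <- function(i, f) {
    r <- reg[[i]]
    r$areas[match(f, r$frames)]
  }
  # initial dart-throwing placement
  n0 <- sum(birth == 1L)
  if (n0 > 0) {
    min_sep <- 2.9 * r_px
    xs <- numeric(0); ys <- numeric(0); tries <- 0
    while (length(xs) < n0 && tries < n0 * 500) {
      tries <- tries + 1
      x <- runif(1, margin, nc - margin); y <- runif(1, margin, nr - margin)
      if (!length(xs) || min(sqrt((xs - x)^2 + (ys - y)^2)) > min_sep) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    if (length(xs) < n0)
      stop("could not place ", n0, " cells in the field; enlarge field_size_px")
    k <- which(birth == 1L)
    anchor[k, 1] <- xs; anchor[k, 2] <- ys
  }
  for (f in seq_len(nfr)) {
    alive <- which(birth <= f & last >= f)
    for (i in alive) {
      if (f == birth[i]) {
        if (is.na(anchor[i, 1])) {
          # daughter: anchor at mother's final position plus the offset
          pm <- match(parent[i], ids)
          mx <- posx[pm, f - 1L]; my <- posy[pm, f - 1L]
          off <- reg[[i]]$birth_offset %||% c(0, 0)
          anchor[i, ] <- c(mx + off[1], my + off[2])
        }
        posx[i, f] <- anchor[i, 1]; posy[i, f] <- anchor[i, 2]
      } else {
        posx[i, f] <- posx[i, f - 1L] +
          eta * (anchor[i, 1] - posx[i, f - 1L]) +
          rnorm(1, 0, config$motion_sd_px)
        posy[i, f] <- posy[i, f - 1L] +
          eta * (anchor[i, 2] - posy[i, f - 1L]) +
          rnorm(1, 0, config$motion_sd_px)
      }
    }
    # clamping to the margin can collapse a daughter pair's separation, so
    # alternate repulsion and clamping
    for (outer in 1:2) {
    if (length(alive) > 1) {
      rads <- sqrt(vapply(alive, function(i) area_at(i, f), numeric(1)) / pi)
      for (pass in 1:3) {
        xa <- posx[alive, f]; ya <- posy[alive, f]
        dx <- outer(xa, xa, "-"); dy <- outer(ya, ya, "-")
        dist <- sqrt(dx^2 + dy^2)
        minsep <- outer(rads, rads, "+") * 1.15 + 3
        diag(dist) <- Inf
        viol <- which(dist < minsep & upper.tri(dist), arr.ind = TRUE)
        if (!nrow(viol)) break
        for (v in seq_len(nrow(viol))) {
          a <- viol[v, 1]; b <- viol[v, 2]
          d0 <- max(dist[a, b], 1e-6)
          push <- (minsep[a, b] - d0) / 2
          ux <- (xa[b] - xa[a]) / d0; uy <- (ya[b] - ya[a]) / d0
          if (d0 < 1e-5) { ux <- 1; uy <- 0 }
          ia <- alive[a]; ib <- alive[b]
          posx[ia, f] <- posx[ia, f] - ux * push
          posy[ia, f] <- posy[ia, f] - uy * push
          posx[ib, f] <- posx[ib, f] + ux * push
          posy[ib, f] <- posy[ib, f] + uy * push
        }
      }
    }
    posx[alive, f] <- pmin(pmax(posx[alive, f], margin), nc - margin)
    posy[alive, f] <- pmin(pmax(posy[alive, f], margin), nr - margin)
    }
  }

  rows <- lapply(seq_len(ncell), function(i) {
    r <- reg[[i]]
    data.frame(cell = r$id, frame = r$frames,
               x = posx[i, r$frames], y = posy[i, r$frames],
               area_px2 = r$areas, aspect = r$aspect,
               activity = r$act((r$frames - 1) * dt),
               fate = r$fate_label, stringsAsFactors = FALSE)
  })
  plan <- do.call(rbind, rows)
  plan <- plan[order(plan$frame, plan$cell), ]
  rownames(plan) <- NULL
  list(cells = plan,
       divisions = if (length(divisions)) do.call(rbind, divisions) else NULL,
       deaths = if (length(deaths)) do.call(rbind, deaths) else NULL)
}

# Render one frame (marker, sensor) from the plan; deterministic given the
# per-frame noise seed.
cf_render_frame <- function(plan_t, config, bias, frame, noise_seed) {
  nr <- config$field_size_px[1]; nc <- config$field_size_px[2]
  px <- config$pixel_size_um
  marker <- matrix(0, nr, nc); sensor <- matrix(0, nr, nc)
  ext <- config$cyto_extent_um / px
  if (nrow(plan_t)) for (i in seq_len(nrow(plan_t))) {
    a <- sqrt(plan_t$area_px2[i] * plan_t$aspect[i] / pi)
    b <- plan_t$area_px2[i] / (pi * a)
    cx <- plan_t$x[i]; cy <- plan_t$y[i]
    r_out <- max(a, b) + ext
    j0 <- max(1, floor(cx - r_out - 1)); j1 <- min(nc, ceiling(cx + r_out + 1))
    i0 <- max(1, floor(cy - r_out - 1)); i1 <- min(nr, ceiling(cy + r_out + 1))
    if (j1 < j0 || i1 < i0) next
    jj <- j0:j1; ii <- i0:i1
    X <- matrix(rep(jj, each = length(ii)), length(ii), length(jj))
    Y <- matrix(rep(ii, length(jj)), length(ii), length(jj))
    # anti-aliased coverage: signed pixel distance from the ellipse edge,
    # linear ramp over one pixel -- gives sub-pixel control of the rendered
    # area so scheduled daughter/mother fractions are honoured exactly
    cov_ellipse <- function(sa, sb) {
      q <- sqrt(((X - cx) / sa)^2 + ((Y - cy) / sb)^2)
      d <- (q - 1) * sqrt(sa * sb)
      pmin(1, pmax(0, 0.5 - d))
    }
    w_nuc <- cov_ellipse(a, b)
    w_out <- cov_ellipse(a + ext, b + ext)
    w_cyt <- pmax(w_out - w_nuc, 0)
    m <- marker[ii, jj]; s <- sensor[ii, jj]
    m <- pmax(m, config$marker_level * w_nuc)
    s <- pmax(s, config$sensor_level * w_nuc,
              plan_t$activity[i] * config$sensor_level * w_cyt)
    marker[ii, jj] <- m; sensor[ii, jj] <- s
  }
  marker <- .cf_gaussian_blur(marker, 1.0)
  sensor <- .cf_gaussian_blur(sensor, 1.0)
  marker <- (marker + config$background) * bias
  sensor <- (sensor + config$background) * bias
  if (config$noise_sd > 0) {
    set.seed(noise_seed)
    marker <- marker + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    sensor <- sensor + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  }
  list(marker = marker, sensor = sensor)
}

#' Render a synthetic two-channel movie
#'
#' Materialises the configured movie as an array and its ground truth. For
#' long movies prefer [stream_movie()], which renders one frame at a time.
#'
#' @param config [sim_movie_config()].
#' @return list with `stack` (array `[row, col, channel, frame]`, channel 1
#'   marker / channel 2 sensor), `truth` (list: `cells` per-frame table with
#'   position, nuclear area, prescribed activity and fate; `divisions`;
#'   `deaths`; `bias` field; `background`), and `config`.
#' @export
render_movie <- function(config) {
  stopifnot(inherits(config, "cf_movie_config"))
  nr <- config$field_size_px[1]; nc <- config$field_size_px[2]
  stack <- array(0, dim = c(nr, nc, 2, config$n_frames))
  truth <- NULL
  cb <- function(frame, marker, sensor, truth_frame) {
    stack[, , 1, frame] <<- marker
    stack[, , 2, frame] <<- sensor
  }
  truth <- stream_movie(config, cb)
  list(stack = stack, truth = truth, config = config)
}

#' Stream a synthetic movie frame by frame
#'
#' Renders each frame and hands it to `callback(frame, marker, sensor,
#' truth_frame)`; frames are discarded afterwards, so arbitrarily long
#' movies fit in memory.
#'
#' @param config [sim_movie_config()].
#' @param callback function of (frame index, marker matrix, sensor matrix,
#'   per-frame ground-truth data.frame).
#' @return the ground-truth list (invisibly compatible with
#'   [render_movie()]'s `truth` element).
#' @export
stream_movie <- function(config, callback) {
  stopifnot(inherits(config, "cf_movie_config"))
  plan <- cf_plan_movie(config)
  nr <- config$field_size_px[1]; nc <- config$field_size_px[2]
  bias <- cf_bias_surface(nr, nc, config$bias_amplitude, config$seed)
  by_frame <- split(plan$cells, factor(plan$cells$frame,
                                       levels = seq_len(config$n_frames)))
  for (f in seq_len(config$n_frames)) {
    pt <- by_frame[[f]]
    if (is.null(pt)) pt <- plan$cells[0, ]
    fr <- cf_render_frame(pt, config, bias, f,
                          noise_seed = child_seed(config$seed, paste0("n", f)))
    callback(f, fr$marker, fr$sensor, pt)
  }
  list(cells = plan$cells, divisions = plan$divisions, deaths = plan$deaths,
       bias = bias, background = config$background)
}

#' Build a fate-cohort movie configuration
#'
#' Convenience builder for end-to-end benchmarks: every initial cell divides
#' once early in the movie with daughter area fractions drawn inside the
#' acceptance band, fates are assigned in the requested proportions, and
#' cells whose daughters re-enter the cycle divide a second time after a
#' set intermitotic interval (G2-arrested lineages do not).
#'
#' @param n_cells number of initial cells.
#' @param fate_probs named probabilities over the four fate labels.
#' @param first_mitosis_frames frame window for the first anaphase.
#' @param intermitotic_h interval to the second anaphase for re-entering
#'   lineages (default 18 h).
#' @param frac_range daughter area fractions drawn uniformly in this range
#'   (default c(0.46, 0.54), inside the 45-55% band).
#' @param seed integer seed.
#' @param ... passed on to [sim_movie_config()].
#' @return `cf_movie_config`.
#' @export
sim_fate_cohort_config <- function(n_cells = 40,
                                   fate_probs = c(cdk2_increasing = 0.3,
                                                  transient_g0 = 0.25,
                                                  prolonged_g0 = 0.25,
                                                  g2_arrest = 0.2),
                                   first_mitosis_frames = c(6, 30),
                                   intermitotic_h = 18,
                                   frac_range = c(0.46, 0.54),
                                   seed = 1, ...) {
  stopifnot(abs(sum(fate_probs) - 1) < 1e-8,
            all(names(fate_probs) %in% cf_fates))
  set.seed(child_seed(seed, "cohort"))
  ids <- as.character(seq_len(n_cells))
  fates <- sample(names(fate_probs), n_cells, TRUE, prob = fate_probs)
  names(fates) <- ids
  f1 <- sample(seq(first_mitosis_frames[1], first_mitosis_frames[2]),
               n_cells, TRUE)
  div <- data.frame(cell = ids, frame = f1,
                    frac1 = runif(n_cells, frac_range[1], frac_range[2]),
                    frac2 = runif(n_cells, frac_range[1], frac_range[2]))
  args <- list(...)
  dt <- args$frame_interval_min %||% 12
  # second division of daughter .1 for lineages that re-enter the cycle
  re <- ids[fates %in% c("cdk2_increasing", "transient_g0")]
  if (length(re)) {
    f2 <- f1[match(re, ids)] + round(intermitotic_h * 60 / dt)
    keep <- rep(TRUE, length(re))
    nfr <- args$n_frames %||% 30
    keep <- f2 <= nfr
    if (any(keep)) {
      div2 <- data.frame(cell = paste0(re[keep], ".1"), frame = f2[keep],
                         frac1 = runif(sum(keep), frac_range[1], frac_range[2]),
                         frac2 = runif(sum(keep), frac_range[1], frac_range[2]))
      fates2 <- rep("cdk2_increasing", sum(keep))
      names(fates2) <- div2$cell
      fates <- c(fates, fates2)
      div <- rbind(div, div2)
    }
  }
  do.call(sim_movie_config,
          c(list(n_cells_initial = n_cells, division_schedule = div,
                 fate_assignment = fates, seed = seed), args))
}
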