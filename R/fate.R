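#' Classify the post-mitotic cell-cycle fate of a trace
#'
#' Cells are categorised by their CDK2 activity two hours after anaphase:
#' activity strictly greater than the threshold means immediate cell-cycle
#' re-entry (`cdk2_increasing`); below it at two hours but rising above the
#' threshold later within the viewing time means a transient G0
#' (`transient_g0`); never exceeding it means a prolonged G0
#' (`prolonged_g0`). Activity exactly at the threshold counts as low.
#'
#' @param time_min,activity the trace (minutes since movie start; NA
#'   activities allowed).
#' @param anaphase_min anaphase time (minutes).
#' @param threshold activity threshold (default 0.6).
#' @param delay_h readout delay after anaphase (default 2 h).
#' @param method `"nearest"` reads the single nearest frame (12-min cadence
#'   keeps the error under 6 min); `"median3"` takes the median of the three
#'   nearest frames.
#' @return one of `"cdk2_increasing"`, `"transient_g0"`, `"prolonged_g0"`,
#'   or NA (censored: the trace ends before anaphase + delay).
#' @export
classify_post_mitotic_fate <- function(time_min, activity, anaphase_min,
                                       threshold = 0.6, delay_h = 2,
                                       method = c("nearest", "median3")) {
  method <- match.arg(method)
  t_read <- anaphase_min + delay_h * 60
  ok <- !is.na(activity)
  if (!any(ok) || max(time_min[ok]) < t_read) return(NA_character_)
  tt <- time_min[ok]; aa <- activity[ok]
  a2 <- if (method == "nearest") {
    aa[which.min(abs(tt - t_read))]
  } else {
    median(aa[order(abs(tt - t_read))[seq_len(min(3, length(aa)))]])
  }
  if (a2 > threshold) return("cdk2_increasing")
  later <- tt > t_read
  if (any(aa[later] > threshold)) "transient_g0" else "prolonged_g0"
}

#' Classify G2 arrest of a lineage
#'
#' A lineage with an observed first mitosis is arrested in G2 if no second
#' mitosis occurs for more than `window_h` hours afterwards; it is cycling
#' if a second mitosis occurs within the window; it is censored if
#' observation ends before the window elapses.
#'
#' @param first_mitosis_h time of the first mitosis (h).
#' @param second_mitosis_h time of the second mitosis, NA if none observed.
#' @param observed_until_h end of observation for the lineage (h).
#' @param window_h arrest window (default 30 h).
#' @return `"cycling"`, `"arrested"`, or `"censored"`.
#' @export
classify_g2_arrest <- function(first_mitosis_h, second_mitosis_h = NA,
                               observed_until_h, window_h = 30) {
  if (is.na(first_mitosis_h)) stop("no first mitosis: not applicable")
  if (!is.na(second_mitosis_h) &&
      second_mitosis_h - first_mitosis_h <= window_h) return("cycling")
  if (observed_until_h - first_mitosis_h > window_h) return("arrested")
  "censored"
}

#' Intermitotic times and histogram
#'
#' Durations between the first and second mitosis per lineage; lineages
#' whose observation ends before a second mitosis are excluded from the
#' histogram and counted as censored.
#'
#' @param first_mitosis_h,second_mitosis_h vectors per lineage (NA second
#'   mitosis = censored).
#' @param bin_width_h histogram bin width (default 2 h).
#' @return list: `durations_h`, `histogram` (data.frame bin_left, bin_right,
#'   count), `n_censored`.
#' @export
intermitotic_times <- function(first_mitosis_h, second_mitosis_h,
                               bin_width_h = 2) {
  stopifnot(length(first_mitosis_h) == length(second_mitosis_h))
  ok <- !is.na(second_mitosis_h) & !is.na(first_mitosis_h)
  dur <- second_mitosis_h[ok] - first_mitosis_h[ok]
  if (length(dur)) {
    top <- ceiling(max(dur) / bin_width_h) * bin_width_h
    breaks <- seq(0, max(top, bin_width_h), by = bin_width_h)
    cnt <- as.vector(table(cut(dur, breaks, right = TRUE,
                               include.lowest = TRUE)))
    hist <- data.frame(bin_left = head(breaks, -1), bin_right = breaks[-1],
                       count = cnt)
  } else {
    hist <- data.frame(bin_left = numeric(0), bin_right = numeric(0),
                       count = integer(0))
  }
  list(durations_h = dur, histogram = hist, n_censored = sum(!ok))
}

#' Heat-map matrix of CDK2 traces sorted by first mitosis
#'
#' Rows are cells ordered by the time of their first mitosis relative to
#' movie start; cells with no mitosis come last, ordered by track start.
#' Columns are frames; missing values stay NA.
#'
#' @param traces list of traces, each a list with `track`, `time_min`,
#'   `activity`, `first_mitosis_min` (NA if none), `start_min`.
#' @param n_frames number of columns; default spans all traces.
#' @param frame_interval_min cadence (default 12).
#' @return list: `matrix` (cells x frames), `order` (track ids row by row).
#' @export
heatmap_matrix <- function(traces, n_frames = NULL, frame_interval_min = 12) {
  if (!length(traces))
    return(list(matrix = matrix(numeric(0), 0, 0), order = integer(0)))
  if (is.null(n_frames))
    n_frames <- max(vapply(traces, function(tr)
      max(tr$time_min) / frame_interval_min + 1, numeric(1)))
  fm <- vapply(traces, function(tr)
    if (is.null(tr$first_mitosis_min) || is.na(tr$first_mitosis_min))
      Inf else tr$first_mitosis_min, numeric(1))
  st <- vapply(traces, function(tr) min(tr$time_min), numeric(1))
  ids <- vapply(traces, function(tr) tr$track, numeric(1))
  ord <- order(fm, st, ids)
  mat <- matrix(NA_real_, length(traces), n_frames)
  for (r in seq_along(ord)) {
    tr <- traces[[ord[r]]]
    cols <- round(tr$time_min / frame_interval_min) + 1
    keep <- cols >= 1 & cols <= n_frames
    mat[r, cols[keep]] <- tr$activity[keep]
  }
  rownames(mat) <- as.character(ids[ord])
  list(matrix = mat, order = ids[ord])
}

#' Average CDK2 activity across traces
#'
#' Pointwise mean (and sd, n) over non-missing values, either on the shared
#' movie time base or aligned to each trace's anaphase.
#'
#' @param traces as in [heatmap_matrix()]; for anaphase alignment each trace
#'   needs `first_mitosis_min` (its anaphase).
#' @param alignment `"movie"` or `"anaphase"`.
#' @param frame_interval_min cadence (default 12).
#' @return data.frame: time_min, mean, sd, n (time relative to alignment
#'   origin).
#' @export
average_activity <- function(traces, alignment = c("movie", "anaphase"),
                             frame_interval_min = 12) {
  alignment <- match.arg(alignment)
  stopifnot(length(traces) >= 1)
  pts <- list()
  for (tr in traces) {
    t0 <- if (alignment == "anaphase") {
      if (is.null(tr$first_mitosis_min) || is.na(tr$first_mitosis_min)) next
      tr$first_mitosis_min
    } else 0
    pts[[length(pts) + 1L]] <- data.frame(
      t = round((tr$time_min - t0) / frame_interval_min),
      a = tr$activity)
  }
  if (!length(pts)) stop("no alignable traces")
  all <- do.call(rbind, pts)
  agg <- lapply(split(all$a, all$t), function(v) {
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) sd(v) else if (length(v) == 1) 0 else NA_real_,
      n = length(v))
  })
  out <- data.frame(time_min = as.numeric(names(agg)) * frame_interval_min,
                    do.call(rbind, agg))
  out <- out[order(out$time_min), ]
  rownames(out) <- NULL
  out
}

#' Assemble lineage traces and fate calls from tracked measurements
#'
#' Joins measured activities onto tracks, stitches each accepted mitosis to
#' its daughters, and produces one fate call per observed anaphase together
#' with the lineage-level G2-arrest status. "Second mitosis" means a
#' division of either daughter lineage.
#'
#' @param tracked output of [track_nuclei()] whose rows carry `activity`.
#' @param mitoses output of [detect_mitosis()].
#' @param frame_interval_min cadence (default 12).
#' @param threshold,delay_h,window_h see [classify_post_mitotic_fate()] and
#'   [classify_g2_arrest()].
#' @return data.frame, one row per accepted anaphase: mother, daughter,
#'   anaphase_h, fate, g2_status, second_mitosis_h.
#' @export
call_fates <- function(tracked, mitoses, frame_interval_min = 12,
                       threshold = 0.6, delay_h = 2, window_h = 30) {
  d <- as.data.frame(tracked)
  ev <- mitoses$events[mitoses$events$accepted, , drop = FALSE]
  tr <- mitoses$tracks
  last_h <- (max(d$frame) - 1) * frame_interval_min / 60
  out <- list()
  trace_of <- function(id) {
    ix <- which(d$track == id)
    ix <- ix[order(d$frame[ix])]
    list(time_min = (d$frame[ix] - 1) * frame_interval_min,
         activity = d$activity[ix])
  }
  # first accepted division within a daughter's descendant lineage
  next_division_h <- function(daughter) {
    ids <- daughter
    best <- Inf
    while (length(ids)) {
      hit <- ev[ev$mother %in% ids, , drop = FALSE]
      if (nrow(hit))
        best <- min(best, (hit$anaphase_frame - 1) * frame_interval_min / 60)
      ids <- tr$track[tr$parent %in% ids]
    }
    if (is.finite(best)) best else NA_real_
  }
  for (e in seq_len(nrow(ev))) {
    ana_min <- (ev$anaphase_frame[e] - 1) * frame_interval_min
    for (dg in c(ev$daughter1[e], ev$daughter2[e])) {
      trc <- trace_of(dg)
      fate <- classify_post_mitotic_fate(trc$time_min, trc$activity,
                                         ana_min, threshold, delay_h)
      second <- next_division_h(dg)
      observed <- max(c(trc$time_min / 60, last_h))
      g2 <- classify_g2_arrest(ana_min / 60, second, observed, window_h)
      out[[length(out) + 1L]] <- data.frame(
        mother = ev$mother[e], daughter = dg, anaphase_h = ana_min / 60,
        fate = fate, g2_status = g2, second_mitosis_h = second)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(mother = integer(0), daughter = integer(0),
               anaphase_h = numeric(0), fate = character(0),
               g2_status = character(0), second_mitosis_h = numeric(0))
}
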