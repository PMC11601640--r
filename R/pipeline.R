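#' Run the imaging pipeline over a synthetic movie
#'
#' Streams the configured movie frame by frame: the illumination bias is
#' estimated from the first frame (the field is constant over a session),
#' every frame is flattened and background-subtracted, nuclei are segmented
#' and CDK2 activity measured, detections are linked into tracks, mitoses
#' are called by the daughter-size rule and fates classified.
#'
#' @param config [sim_movie_config()].
#' @param threshold,delay_h,window_h fate parameters (defaults 0.6, 2 h,
#'   30 h).
#' @param ... passed to [segment_nuclei()].
#' @return list: `measurements` (per frame/detection), `tracked`, `mitoses`,
#'   `track_ends`, `fates`, `truth`, `bias`.
#' @export
run_movie_pipeline <- function(config, threshold = 0.6, delay_h = 2,
                               window_h = 30, ...) {
  meas <- vector("list", config$n_frames)
  bias <- NULL
  bg_sd <- 0
  seg_args <- list(...)
  cb <- function(f, marker, sensor, truth_frame) {
    if (is.null(bias)) {
      bias <<- estimate_illumination_bias(list(marker))
      bg_sd <<- max(config$noise_sd, 1e-6)
    }
    mk <- flatten_and_subtract(marker, bias)
    sn <- flatten_and_subtract(sensor, bias)
    meas[[f]] <<- do.call(measure_frame,
                          c(list(mk, sn, config$pixel_size_um,
                                 background_sd = bg_sd, frame = f), seg_args))
  }
  truth <- stream_movie(config, cb)
  measurements <- do.call(rbind, meas)
  tracked <- track_nuclei(measurements, config$pixel_size_um)
  mitoses <- detect_mitosis(tracked, config$pixel_size_um)
  ends <- classify_track_ends(tracked, mitoses)
  fates <- call_fates(tracked, mitoses,
                      frame_interval_min = config$frame_interval_min,
                      threshold = threshold, delay_h = delay_h,
                      window_h = window_h)
  list(measurements = measurements, tracked = tracked, mitoses = mitoses,
       track_ends = ends, fates = fates, truth = truth, bias = bias)
}

# one-to-one greedy matching of two point sets within a tolerance;
# returns number of matched pairs
cf_match_points <- function(x1, y1, x2, y2, tol) {
  if (!length(x1) || !length(x2)) return(0L)
  dm <- sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
  ok <- dm <= tol
  n <- 0L
  used1 <- rep(FALSE, length(x1)); used2 <- rep(FALSE, length(x2))
  ord <- order(dm)
  for (k in ord) {
    if (dm[k] > tol) break
    i <- (k - 1) %% length(x1) + 1
    j <- (k - 1) %/% length(x1) + 1
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE; n <- n + 1L
  }
  n
}

#' Segmentation recall and precision against ground truth
#'
#' Matches detections to true cell positions one-to-one within a pixel
#' tolerance, per frame.
#'
#' @param measurements pipeline detections (frame, x, y).
#' @param truth ground-truth list from the movie generator.
#' @param tol_px matching tolerance (default 5 px).
#' @param frames frames to evaluate (default all).
#' @return list: recall, precision, n_true, n_detected, n_matched.
#' @export
evaluate_segmentation <- function(measurements, truth, tol_px = 5,
                                  frames = NULL) {
  tc <- truth$cells
  if (is.null(frames)) frames <- sort(unique(tc$frame))
  n_true <- n_det <- n_match <- 0L
  for (f in frames) {
    tt <- tc[tc$frame == f, ]
    dd <- measurements[measurements$frame == f, ]
    n_true <- n_true + nrow(tt)
    n_det <- n_det + nrow(dd)
    n_match <- n_match + cf_match_points(tt$x, tt$y, dd$x, dd$y, tol_px)
  }
  list(recall = n_match / n_true, precision = n_match / n_det,
       n_true = n_true, n_detected = n_det, n_matched = n_match)
}

#' Division detection performance against the schedule
#'
#' Matches accepted mitosis events to scheduled divisions by anaphase frame
#' (within `frame_tol`) and mother position, and counts accepted events
#' with no scheduled counterpart as false positives.
#'
#' @param mitoses pipeline mitoses (`$events`).
#' @param tracked tracked detections (for mother positions).
#' @param truth ground-truth list.
#' @param frame_tol frames of slack (default 1).
#' @param tol_px positional tolerance of the mother centroid (default 15).
#' @return list: n_true, n_detected_true, n_false_positive, recall.
#' @export
evaluate_divisions <- function(mitoses, tracked, truth, frame_tol = 1,
                               tol_px = 15) {
  ev <- mitoses$events[mitoses$events$accepted, , drop = FALSE]
  tdiv <- truth$divisions
  if (is.null(tdiv) || !nrow(tdiv))
    return(list(n_true = 0L, n_detected_true = 0L,
                n_false_positive = nrow(ev), recall = NA_real_))
  d <- as.data.frame(tracked)
  # mother last position per event
  mx <- my <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    ix <- which(d$track == ev$mother[i])
    ix <- ix[which.max(d$frame[ix])]
    mx[i] <- d$x[ix]; my[i] <- d$y[ix]
  }
  # true mother position at its last frame
  tc <- truth$cells
  matched_ev <- rep(FALSE, nrow(ev))
  n_hit <- 0L
  for (j in seq_len(nrow(tdiv))) {
    rows <- tc[tc$cell == tdiv$cell[j] & tc$frame == tdiv$frame[j] - 1, ]
    if (!nrow(rows)) next
    cand <- which(!matched_ev &
                    abs(ev$anaphase_frame - tdiv$frame[j]) <= frame_tol)
    if (!length(cand)) next
    dist <- sqrt((mx[cand] - rows$x[1])^2 + (my[cand] - rows$y[1])^2)
    if (min(dist) <= tol_px) {
      matched_ev[cand[which.min(dist)]] <- TRUE
      n_hit <- n_hit + 1L
    }
  }
  list(n_true = nrow(tdiv), n_detected_true = n_hit,
       n_false_positive = sum(!matched_ev), recall = n_hit / nrow(tdiv))
}

#' Fate-call confusion matrix against ground truth
#'
#' Matches each called daughter to the ground-truth daughter nearest its
#' first tracked position and tabulates called vs true post-mitotic
#' category. Ground-truth `g2_arrest` cells re-enter the cycle after the
#' first mitosis, so their true post-mitotic category is `cdk2_increasing`.
#'
#' @param fates pipeline fate calls.
#' @param tracked tracked detections.
#' @param truth ground-truth list.
#' @param tol_px matching tolerance (default 10 px).
#' @return list: `confusion` (true x called matrix), `diag_rate` per true
#'   class, `n_matched`.
#' @export
evaluate_fates <- function(fates, tracked, truth, tol_px = 10) {
  cats <- c("cdk2_increasing", "transient_g0", "prolonged_g0")
  to_cat <- function(f) ifelse(f == "g2_arrest", "cdk2_increasing", f)
  d <- as.data.frame(tracked)
  tc <- truth$cells
  conf <- matrix(0L, 3, 3, dimnames = list(true = cats, called = cats))
  n_matched <- 0L
  for (i in seq_len(nrow(fates))) {
    if (is.na(fates$fate[i])) next
    ix <- which(d$track == fates$daughter[i])
    ix <- ix[which.min(d$frame[ix])]
    f0 <- d$frame[ix]
    cand <- tc[tc$frame == f0, ]
    if (!nrow(cand)) next
    dist <- sqrt((cand$x - d$x[ix])^2 + (cand$y - d$y[ix])^2)
    j <- which.min(dist)
    if (dist[j] > tol_px) next
    true_cat <- to_cat(cand$fate[j])
    if (!true_cat %in% cats) next
    conf[true_cat, fates$fate[i]] <- conf[true_cat, fates$fate[i]] + 1L
    n_matched <- n_matched + 1L
  }
  diag_rate <- diag(conf) / pmax(rowSums(conf), 1L)
  list(confusion = conf, diag_rate = diag_rate, n_matched = n_matched)
}
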