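#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour assignment frame to frame: candidate links are
#' gated by a maximum step (in micrometres) and a maximum relative nuclear
#' area change (which stops a mother from being linked to a half-sized
#' daughter at anaphase); links are taken in increasing distance order.
#' Unmatched detections open new tracks; a track unmatched for more than
#' `max_gap_frames` frames closes.
#'
#' @param detections data.frame with columns `frame`, `x`, `y` (pixels),
#'   `area_um2`, and any measurement columns (carried through).
#' @param pixel_size_um pixel size (um).
#' @param max_step_um maximum centroid displacement per frame (default 10).
#' @param max_gap_frames frames a track survives unmatched (default 0).
#' @param max_area_change maximum |relative| area change per link
#'   (default 0.35).
#' @return data.frame of the input rows with a `track` column, plus
#'   attribute `tracks`: data.frame (track, start_frame, end_frame, parent).
#' @export
track_nuclei <- function(detections, pixel_size_um, max_step_um = 10,
                         max_gap_frames = 0, max_area_change = 0.35) {
  d <- detections[order(detections$frame), , drop = FALSE]
  d$track <- NA_integer_
  if (!nrow(d)) {
    attr(d, "tracks") <- data.frame(track = integer(0), start_frame = integer(0),
                                    end_frame = integer(0), parent = NA_integer_)
    return(d)
  }
  frames <- sort(unique(d$frame))
  rows_by_frame <- split(seq_len(nrow(d)), d$frame)
  next_id <- 0L
  # active tracks: id, row of last detection, last frame
  act_id <- integer(0); act_row <- integer(0); act_frame <- integer(0)
  log_band <- log1p(max_area_change)

  for (f in frames) {
    rows <- rows_by_frame[[as.character(f)]]
    alive <- act_frame >= f - 1L - max_gap_frames
    act_id <- act_id[alive]; act_row <- act_row[alive]; act_frame <- act_frame[alive]
    matched_det <- rep(FALSE, length(rows))
    matched_tr <- rep(FALSE, length(act_id))
    if (length(act_id) && length(rows)) {
      px <- pixel_size_um
      dx <- outer(d$x[act_row], d$x[rows], "-") * px
      dy <- outer(d$y[act_row], d$y[rows], "-") * px
      dist <- sqrt(dx^2 + dy^2)
      gap <- f - act_frame  # >= 1
      lim <- max_step_um * gap
      ratio <- abs(log(outer(d$area_um2[act_row], d$area_um2[rows],
                             function(a, b) b / a)))
      ok <- dist <= lim & ratio <= log_band
      if (any(ok)) {
        ord <- order(dist[ok])
        cand <- which(ok, arr.ind = TRUE)[ord, , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          ti <- cand[r, 1]; di <- cand[r, 2]
          if (matched_tr[ti] || matched_det[di]) next
          matched_tr[ti] <- TRUE; matched_det[di] <- TRUE
          d$track[rows[di]] <- act_id[ti]
          act_row[ti] <- rows[di]; act_frame[ti] <- f
        }
      }
    }
    if (any(!matched_det)) {
      new_rows <- rows[!matched_det]
      ids <- next_id + seq_along(new_rows)
      next_id <- next_id + length(new_rows)
      d$track[new_rows] <- ids
      act_id <- c(act_id, ids)
      act_row <- c(act_row, new_rows)
      act_frame <- c(act_frame, rep(f, length(new_rows)))
    }
  }
  tr <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$track), function(ix) {
    data.frame(track = d$track[ix[1]],
               start_frame = min(d$frame[ix]), end_frame = max(d$frame[ix]))
  }))
  tr <- tr[order(tr$track), ]
  tr$parent <- NA_integer_
  rownames(tr) <- NULL
  attr(d, "tracks") <- tr
  d
}

#' Detect mitoses by the daughter-size rule
#'
#' A track that ends at frame f while two tracks start at frame f + 1 within
#' the capture radius of its last position is an anaphase candidate. The
#' event is accepted iff both daughter first-frame nuclear areas divided by
#' the mother last-frame area lie inside the acceptance band (default
#' [0.45, 0.55], both ends inclusive). Accepted events set lineage links;
#' rejected candidates are recorded with their fractions.
#'
#' @param tracked output of [track_nuclei()].
#' @param pixel_size_um pixel size (um).
#' @param band inclusive daughter/mother area-fraction band.
#' @param capture_radius_um capture radius around the mother's last centroid
#'   (default 20 um).
#' @return list: `events` data.frame (mother, daughter1, daughter2,
#'   anaphase_frame, frac1, frac2, accepted), `tracks` track table with
#'   `parent` filled in for accepted daughters.
#' @export
detect_mitosis <- function(tracked, pixel_size_um, band = c(0.45, 0.55),
                           capture_radius_um = 20) {
  tr <- attr(tracked, "tracks")
  d <- as.data.frame(tracked)
  last_frame <- max(d$frame)
  ev <- list()
  first_rows <- vapply(split(seq_len(nrow(d)), d$track), function(ix)
    ix[which.min(d$frame[ix])], integer(1))
  last_rows <- vapply(split(seq_len(nrow(d)), d$track), function(ix)
    ix[which.max(d$frame[ix])], integer(1))
  track_of <- as.integer(names(first_rows))

  for (m in seq_len(nrow(tr))) {
    f_end <- tr$end_frame[m]
    if (f_end >= last_frame) next
    mrow <- last_rows[match(tr$track[m], track_of)]
    starters <- which(tr$start_frame == f_end + 1L)
    if (length(starters) < 2) next
    srows <- first_rows[match(tr$track[starters], track_of)]
    dist <- sqrt((d$x[srows] - d$x[mrow])^2 +
                 (d$y[srows] - d$y[mrow])^2) * pixel_size_um
    near <- starters[dist <= capture_radius_um]
    if (length(near) < 2) next
    if (length(near) > 2)
      near <- near[order(dist[match(near, starters)])[1:2]]
    nrows <- first_rows[match(tr$track[near], track_of)]
    fr <- d$area_um2[nrows] / d$area_um2[mrow]
    accepted <- all(fr >= band[1] & fr <= band[2])
    ev[[length(ev) + 1L]] <- data.frame(
      mother = tr$track[m], daughter1 = tr$track[near[1]],
      daughter2 = tr$track[near[2]], anaphase_frame = f_end + 1L,
      frac1 = fr[1], frac2 = fr[2], accepted = accepted)
    if (accepted) tr$parent[near] <- tr$track[m]
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(mother = integer(0), daughter1 = integer(0),
               daughter2 = integer(0), anaphase_frame = integer(0),
               frac1 = numeric(0), frac2 = numeric(0), accepted = logical(0))
  list(events = events, tracks = tr)
}

#' Classify track end reasons
#'
#' Accepted divisions end as `division`; a track whose final nuclear area
#' drops by more than half of its running median without an accepted split
#' ends as `death` (nuclear condensation surrogate); a track reaching the
#' last frame ends as `end-of-movie`; anything else is `lost`.
#'
#' @param tracked output of [track_nuclei()].
#' @param mitoses output of [detect_mitosis()].
#' @param death_area_drop relative drop calling death (default 0.5).
#' @return the track table with an `end_reason` column.
#' @export
classify_track_ends <- function(tracked, mitoses, death_area_drop = 0.5) {
  d <- as.data.frame(tracked)
  tr <- mitoses$tracks
  last_frame <- max(d$frame)
  div_mothers <- mitoses$events$mother[mitoses$events$accepted]
  tr$end_reason <- "lost"
  for (i in seq_len(nrow(tr))) {
    if (tr$track[i] %in% div_mothers) { tr$end_reason[i] <- "division"; next }
    if (tr$end_frame[i] >= last_frame) { tr$end_reason[i] <- "end-of-movie"; next }
    ar <- d$area_um2[d$track == tr$track[i]]
    if (length(ar) >= 3 &&
        ar[length(ar)] < (1 - death_area_drop) * median(ar[-length(ar)]))
      tr$end_reason[i] <- "death"
  }
  tr
}
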