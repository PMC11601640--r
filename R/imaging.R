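#' Otsu threshold
#'
#' Histogram-based two-class variance maximisation; used as the default
#' foreground threshold for nuclear segmentation and background detection.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins histogram bins (default 256).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1]) / diff(rng) * n_bins)),
                n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Estimate the illumination bias field
#'
#' The optical illumination bias is derived empirically by sampling
#' cell-free (background) pixels across frames and fitting a smooth
#' low-order polynomial surface to them. The fitted surface is normalised
#' to mean 1; the scalar global background is the mean corrected background
#' intensity.
#'
#' @param frames list of intensity matrices (all the same size).
#' @param degree polynomial degree of the surface (default 2).
#' @param sample_frac fraction of background pixels sampled per frame.
#' @param min_bg_frac minimum fraction of pixels that must be background;
#'   below it the fit is refused (frames fully covered by cells).
#' @return object of class `cf_bias`: list(surface, background).
#' @export
estimate_illumination_bias <- function(frames, degree = 2, sample_frac = 0.25,
                                       min_bg_frac = 0.05) {
  if (!length(frames)) stop("no frames supplied")
  if (is.matrix(frames)) frames <- list(frames)
  dm <- dim(frames[[1]])
  nr <- dm[1]; nc <- dm[2]
  xs <- ys <- vs <- numeric(0)
  for (fr in frames) {
    if (!all(dim(fr) == dm)) stop("frames differ in size")
    thr <- otsu_threshold(fr)
    bg <- which(fr < thr)
    if (length(bg) >= min_bg_frac * length(fr) &&
        mean(fr[fr >= thr]) / max(mean(fr[bg]), .Machine$double.eps) >= 1.5) {
      # cells present: keep background pixels well clear of blurred edges
      d <- .cf_edt(fr >= thr)
      bg <- which(d > 5 & fr < thr)
    } else {
      # the split separates nothing (cell-free frame): use all pixels
      bg <- seq_along(fr)
    }
    if (length(bg) < min_bg_frac * length(fr))
      stop("frames are fully covered by cells; cannot sample background")
    keep <- bg[runif(length(bg)) < sample_frac]
    if (!length(keep)) keep <- bg
    ys <- c(ys, (keep - 1) %% nr + 1)
    xs <- c(xs, (keep - 1) %/% nr + 1)
    vs <- c(vs, fr[keep])
  }
  xn <- (xs - 1) / (nc - 1) * 2 - 1
  yn <- (ys - 1) / (nr - 1) * 2 - 1
  dat <- data.frame(v = vs, x = xn, y = yn)
  fit <- lm(v ~ poly(x, degree, raw = TRUE) + poly(y, degree, raw = TRUE) +
              I(x * y), data = dat)
  gx <- (seq_len(nc) - 1) / (nc - 1) * 2 - 1
  gy <- (seq_len(nr) - 1) / (nr - 1) * 2 - 1
  grid <- expand.grid(y = gy, x = gx)
  surf <- matrix(predict(fit, grid), nr, nc)
  if (any(surf <= 0)) stop("fitted illumination surface is not positive")
  m <- mean(surf)
  surface <- surf / m
  background <- mean(vs / (surf[cbind(ys, xs)] / m))
  structure(list(surface = surface, background = background),
            class = "cf_bias")
}

#' Flatten an image and subtract the global background
#'
#' `corrected = image / surface - background`, clipped at zero.
#'
#' @param image intensity matrix.
#' @param bias `cf_bias` from [estimate_illumination_bias()], or a list with
#'   `surface` and `background`.
#' @return corrected matrix.
#' @export
flatten_and_subtract <- function(image, bias) {
  if (!all(dim(image) == dim(bias$surface)))
    stop("image and bias surface shapes differ")
  pmax(image / bias$surface - bias$background, 0)
}

#' Segment nuclei from a bias-corrected marker image
#'
#' Foreground by (Otsu) thresholding, 8-connected labelling, and splitting
#' of oversized components along their principal axis (two-means on pixel
#' coordinates with deterministic extreme-point initialisation). Detections
#' outside the area bounds are discarded.
#'
#' @param img bias-corrected nuclear-marker matrix.
#' @param pixel_size_um pixel size (um).
#' @param min_area_um2,max_area_um2 area bounds (default 20, 400 um2).
#' @param split_above_um2 components larger than this are split in two
#'   (default 150 um2, ~1.7x a typical nucleus).
#' @param threshold optional fixed threshold; default Otsu.
#' @param subpixel refine areas by flux integration (default TRUE): for a
#'   blurred uniform-intensity nucleus the point-spread function conserves
#'   total intensity, so area = (integrated intensity near the mask) /
#'   (plateau intensity) recovers the sub-pixel area far more precisely
#'   than pixel counting; contested pixels between touching nuclei are
#'   assigned to the nearer mask.
#' @return object of class `cf_detections`: data.frame (label, x, y,
#'   area_px2, area_um2, marker_median) with attributes `pix` (list of
#'   linear pixel indices per detection), `dim`, `pixel_size_um`.
#' @export
segment_nuclei <- function(img, pixel_size_um, min_area_um2 = 20,
                           max_area_um2 = 400, split_above_um2 = 150,
                           threshold = NULL, subpixel = TRUE) {
  nr <- nrow(img); nc <- ncol(img)
  um2 <- pixel_size_um^2
  if (is.null(threshold)) {
    threshold <- otsu_threshold(img)
    # guard: a blank frame has no bimodality; require real contrast
    if (threshold <= 0 ||
        mean(img[img > threshold]) < 2 * max(mean(img[img <= threshold]), 1e-12))
      return(cf_detections(list(), nr, nc, pixel_size_um, img))
  }
  mask <- img > threshold
  if (!any(mask)) return(cf_detections(list(), nr, nc, pixel_size_um, img))
  lab <- .cf_label_components(mask)
  idx <- which(lab > 0)
  comp <- split(idx, lab[idx])

  pieces <- list()
  for (pix in comp) {
    if (length(pix) * um2 > split_above_um2) {
      yy <- (pix - 1) %% nr + 1
      xx <- (pix - 1) %/% nr + 1
      ctr <- c(mean(xx), mean(yy))
      cc <- cbind(xx - ctr[1], yy - ctr[2])
      pc <- eigen(crossprod(cc) / length(pix), symmetric = TRUE)$vectors[, 1]
      proj <- cc %*% pc
      c1 <- which.min(proj); c2 <- which.max(proj)
      centers <- rbind(c(xx[c1], yy[c1]), c(xx[c2], yy[c2]))
      for (it in 1:10) {
        d1 <- (xx - centers[1, 1])^2 + (yy - centers[1, 2])^2
        d2 <- (xx - centers[2, 1])^2 + (yy - centers[2, 2])^2
        g <- d1 <= d2
        newc <- rbind(c(mean(xx[g]), mean(yy[g])),
                      c(mean(xx[!g]), mean(yy[!g])))
        if (all(abs(newc - centers) < 1e-6)) break
        centers <- newc
      }
      pieces <- c(pieces, list(pix[g], pix[!g]))
    } else pieces <- c(pieces, list(pix))
  }
  areas <- lengths(pieces) * um2
  pieces <- pieces[areas >= min_area_um2 & areas <= max_area_um2]
  cf_detections(pieces, nr, nc, pixel_size_um, img, subpixel = subpixel)
}

cf_detections <- function(pieces, nr, nc, pixel_size_um, img,
                          subpixel = FALSE) {
  n <- length(pieces)
  df <- data.frame(label = seq_len(n), x = numeric(n), y = numeric(n),
                   area_px2 = numeric(n), area_um2 = numeric(n),
                   marker_median = numeric(n))
  labmat <- matrix(0L, nr, nc)
  for (i in seq_len(n)) labmat[pieces[[i]]] <- i
  for (i in seq_len(n)) {
    pix <- pieces[[i]]
    df$y[i] <- mean((pix - 1) %% nr + 1)
    df$x[i] <- mean((pix - 1) %/% nr + 1)
    df$area_px2[i] <- length(pix)
    df$marker_median[i] <- median(img[pix])
    if (subpixel) {
      # flux-conserving sub-pixel area: integrate intensity over a 3-px
      # dilation of the mask, contested pixels going to the nearer nucleus
      yy <- (pix - 1) %% nr + 1
      xx <- (pix - 1) %/% nr + 1
      i0 <- max(1, min(yy) - 4); i1 <- min(nr, max(yy) + 4)
      j0 <- max(1, min(xx) - 4); j1 <- min(nc, max(xx) + 4)
      lc <- labmat[i0:i1, j0:j1, drop = FALSE]
      crop <- img[i0:i1, j0:j1, drop = FALSE]
      d_this <- .cf_edt(lc == i)
      oth <- lc != 0L & lc != i
      d_oth <- if (any(oth)) .cf_edt(oth) else NULL
      zone <- d_this <= 3
      if (!is.null(d_oth)) zone <- zone & d_this <= d_oth
      # plateau from the eroded interior: edge pixels are blur-diluted and
      # would bias the level (and hence the area) for small nuclei
      d_in <- .cf_edt(lc != i)
      interior <- lc == i & d_in > 2.5
      plateau <- if (sum(interior) >= 5) median(crop[interior]) else
        quantile(crop[lc == i], 0.9, names = FALSE)
      df$area_px2[i] <- sum(crop[zone]) / max(plateau, .Machine$double.eps)
    }
    df$area_um2[i] <- df$area_px2[i] * pixel_size_um^2
  }
  structure(df, pix = pieces, labmat = labmat, dim_frame = c(nr, nc),
            pixel_size_um = pixel_size_um,
            class = c("cf_detections", "data.frame"))
}

#' Cytoplasmic ring mask for one detection
#'
#' Pixels whose Euclidean distance to the parent nuclear mask lies in
#' (inner, outer] micrometres, excluding every nuclear mask and any pixel
#' within `exclude_um` of another nucleus. An empty ring (crowding) is
#' flagged, not measured as zero.
#'
#' @param detections `cf_detections` for the frame.
#' @param i index of the parent detection.
#' @param inner_um,outer_um ring band, default (2, 10] um.
#' @param exclude_um neighbour-exclusion radius (default 10 um).
#' @return list: `pix` (linear indices), `n_pixels`, `empty` flag.
#' @export
make_cytoplasmic_ring <- function(detections, i, inner_um = 2, outer_um = 10,
                                  exclude_um = 10) {
  pix_list <- attr(detections, "pix")
  dm <- attr(detections, "dim_frame")
  px <- attr(detections, "pixel_size_um")
  nr <- dm[1]; nc <- dm[2]
  parent <- pix_list[[i]]
  labmat <- attr(detections, "labmat")
  pad <- ceiling((outer_um + exclude_um) / px) + 1
  yy <- (parent - 1) %% nr + 1
  xx <- (parent - 1) %/% nr + 1
  i0 <- max(1, min(yy) - pad); i1 <- min(nr, max(yy) + pad)
  j0 <- max(1, min(xx) - pad); j1 <- min(nc, max(xx) + pad)
  cnr <- i1 - i0 + 1; cnc <- j1 - j0 + 1
  labcrop <- labmat[i0:i1, j0:j1, drop = FALSE]
  pmask <- labcrop == i
  omask <- labcrop != 0L & !pmask
  d_par <- .cf_edt(pmask) * px
  d_oth <- if (any(omask)) .cf_edt(omask) * px else
    matrix(Inf, cnr, cnc)
  ring <- d_par > inner_um & d_par <= outer_um & !pmask & !omask &
    d_oth > exclude_um
  ridx <- which(ring)
  ry <- (ridx - 1) %% cnr + i0
  rx <- (ridx - 1) %/% cnr + j0
  pix <- (rx - 1) * nr + ry
  list(pix = pix, n_pixels = length(pix), empty = length(pix) == 0)
}

#' Measure nuclear and cytoplasmic sensor intensities
#'
#' Nuclear median over the nuclear mask; cytoplasmic median over ring pixels
#' whose intensity is distinguishable from background (> k * background sd
#' after subtraction). Too few surviving pixels flag the cytoplasmic value
#' missing.
#'
#' @param sensor bias-corrected sensor matrix.
#' @param detections `cf_detections`; `i` parent index.
#' @param ring ring from [make_cytoplasmic_ring()].
#' @param background_sd robust background sd of the corrected image.
#' @param k background-indistinguishability multiplier (default 2).
#' @param min_pixels minimum surviving ring pixels (default 5).
#' @return list: `nuclear_median`, `cyto_median` (NA when flagged),
#'   `n_used`, `n_excluded`, `flag`.
#' @export
measure_sensor <- function(sensor, detections, i, ring, background_sd = 0,
                           k = 2, min_pixels = 5) {
  pix_list <- attr(detections, "pix")
  nuc <- median(sensor[pix_list[[i]]])
  if (ring$empty)
    return(list(nuclear_median = nuc, cyto_median = NA_real_, n_used = 0L,
                n_excluded = 0L, flag = "empty_ring"))
  v <- sensor[ring$pix]
  keep <- v > k * background_sd
  if (sum(keep) < min_pixels)
    return(list(nuclear_median = nuc, cyto_median = NA_real_,
                n_used = sum(keep), n_excluded = sum(!keep),
                flag = "too_few_pixels"))
  list(nuclear_median = nuc, cyto_median = median(v[keep]),
       n_used = sum(keep), n_excluded = sum(!keep), flag = "ok")
}

#' CDK2 activity from nuclear and cytoplasmic medians
#'
#' The sensor leaves the nucleus as CDK2 activity rises, so activity is read
#' as cytoplasmic/nuclear median on the background-subtracted scale. Missing
#' inputs or a non-positive nuclear median propagate to a missing activity.
#'
#' @param cyto_median,nuclear_median medians from [measure_sensor()].
#' @return activity ratio (NA when undefined).
#' @export
compute_cdk2_activity <- function(cyto_median, nuclear_median) {
  out <- cyto_median / nuclear_median
  out[is.na(cyto_median) | is.na(nuclear_median) | nuclear_median <= 0] <-
    NA_real_
  out
}

#' Per-frame measurement pipeline
#'
#' Segments nuclei on the corrected marker image and measures CDK2 activity
#' for every detection on the corrected sensor image.
#'
#' @param marker,sensor bias-corrected matrices.
#' @param pixel_size_um pixel size.
#' @param background_sd robust background sd used for the
#'   background-indistinguishability rule.
#' @param frame frame index copied into the output.
#' @param ... passed to [segment_nuclei()].
#' @return data.frame: frame, label, x, y, area_px2, area_um2, nuc_median,
#'   cyto_median, activity, flag.
#' @export
measure_frame <- function(marker, sensor, pixel_size_um, background_sd = 0,
                          frame = 1L, ...) {
  det <- segment_nuclei(marker, pixel_size_um, ...)
  n <- nrow(det)
  out <- data.frame(frame = rep(frame, n), label = det$label,
                    x = det$x, y = det$y, area_px2 = det$area_px2,
                    area_um2 = det$area_um2,
                    nuc_median = NA_real_, cyto_median = NA_real_,
                    activity = NA_real_, flag = rep("ok", n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ring <- make_cytoplasmic_ring(det, i)
    m <- measure_sensor(sensor, det, i, ring, background_sd = background_sd)
    out$nuc_median[i] <- m$nuclear_median
    out$cyto_median[i] <- m$cyto_median
    out$activity[i] <- compute_cdk2_activity(m$cyto_median, m$nuclear_median)
    out$flag[i] <- m$flag
  }
  out
}

# Robust background sd of a corrected image (clipped-at-zero aware): median
# absolute deviation of the below-Otsu pixels.
cf_background_sd <- function(img) {
  thr <- otsu_threshold(img)
  bg <- img[img < thr]
  if (!length(bg)) return(0)
  stats::mad(bg, center = median(bg))
}
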