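#' Linear trapezoidal AUC
#'
#' AUC from time zero to the last observation by the linear trapezoidal
#' method: sum of (t[i+1] - t[i]) * (C[i] + C[i+1]) / 2.
#'
#' @param times strictly increasing times (h).
#' @param conc concentrations.
#' @return AUC0-t (conc x h).
#' @export
auc_trapezoid <- function(times, conc) {
  if (length(times) < 2) stop("need >= 2 points")
  if (length(times) != length(conc)) stop("times and conc differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sum(diff(times) * (head(conc, -1) + tail(conc, -1)) / 2)
}

#' Terminal rate constant by log-linear regression
#'
#' Ordinary least squares of ln C on t over a tail of at least three
#' positive-concentration points; lambda is minus the slope. The tail is
#' selected automatically as the suffix (length >= 3, excluding Tmax) with
#' the best adjusted r-squared, or supplied explicitly. A non-positive
#' lambda (non-decaying tail) is flagged not reportable.
#'
#' @param times,conc the profile (times strictly increasing).
#' @param tail_n optional explicit number of terminal points to use.
#' @return list: `lambda` (1/h, NA when not estimable), `n`, `r2`, `adj_r2`,
#'   `reportable` flag.
#' @export
terminal_lambda <- function(times, conc, tail_n = NULL) {
  keep <- conc > 0
  tt <- times[keep]; cc <- conc[keep]
  n <- length(tt)
  empty <- list(lambda = NA_real_, n = 0L, r2 = NA_real_, adj_r2 = NA_real_,
                reportable = FALSE)
  if (n < 3) return(empty)
  i_tmax <- which.max(cc)
  fit_tail <- function(ix) {
    x <- tt[ix]; y <- log(cc[ix])
    sx <- sum(x); sy <- sum(y); m <- length(ix)
    sxx <- sum(x^2) - sx^2 / m
    if (sxx == 0) return(NULL)
    sxy <- sum(x * y) - sx * sy / m
    slope <- sxy / sxx
    yhat <- mean(y) + slope * (x - mean(x))
    sst <- sum((y - mean(y))^2)
    sse <- sum((y - yhat)^2)
    r2 <- if (sst == 0) 1 else 1 - sse / sst
    adj <- if (m > 2) 1 - (1 - r2) * (m - 1) / (m - 2) else r2
    list(slope = slope, n = m, r2 = r2, adj_r2 = adj)
  }
  if (!is.null(tail_n)) {
    if (tail_n < 3) stop("tail must use at least 3 points")
    cands <- list(seq.int(n - tail_n + 1, n))
  } else {
    starts <- if (i_tmax + 1 <= n - 2) seq.int(i_tmax + 1, n - 2) else
      integer(0)
    if (!length(starts)) return(empty)
    cands <- lapply(starts, function(s) seq.int(s, n))
  }
  fits <- Filter(Negate(is.null), lapply(cands, fit_tail))
  if (!length(fits)) return(empty)
  # constant tail: slope 0 everywhere -> flagged not reportable
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "adj_r2"))]]
  lambda <- -best$slope
  list(lambda = lambda, n = best$n, r2 = best$r2, adj_r2 = best$adj_r2,
       reportable = lambda > 0)
}

#' Extrapolate AUC to infinity
#'
#' AUC0-inf = AUC0-t + C_last / lambda, where t is the time of the last
#' measurable concentration.
#'
#' @param auc0t AUC to the last measurable point.
#' @param c_last last measurable concentration (>= 0).
#' @param lambda terminal rate constant (> 0).
#' @return list: `auc_inf`, `pct_extrapolated`.
#' @export
auc_extrapolate <- function(auc0t, c_last, lambda) {
  if (is.na(lambda) || lambda <= 0)
    return(list(auc_inf = NA_real_, pct_extrapolated = NA_real_))
  if (c_last < 0) stop("c_last must be >= 0")
  auc_inf <- auc0t + c_last / lambda
  list(auc_inf = auc_inf,
       pct_extrapolated = 100 * (c_last / lambda) / auc_inf)
}

#' Terminal half-life
#'
#' t1/2 = 0.693 / lambda. The printed constant 0.693 is used verbatim
#' rather than ln 2 (a 0.0147% difference), matching the conventional NCA
#' formula.
#'
#' @param lambda terminal rate constant (1/h), > 0.
#' @return half-life (h); NA when lambda is missing or non-positive.
#' @export
half_life <- function(lambda) {
  ifelse(is.na(lambda) | lambda <= 0, NA_real_, 0.693 / lambda)
}

#' Non-compartmental analysis of a concentration-time profile
#'
#' Destructive-sampling design: concentrations are averaged across animals
#' per nominal time (naive pooling), then Cmax/Tmax are read from the mean
#' profile, AUC0-t by the linear trapezoidal method, lambda by log-linear
#' tail regression, AUC0-inf by extrapolation and t1/2 = 0.693/lambda.
#' Below-LLOQ handling (default policy): values before or at Tmax are set
#' to zero; time points after Tmax with no quantifiable value terminate the
#' profile at the last quantifiable point.
#'
#' @param profile data.frame: time_h, conc, lloq_flag (logical), optionally
#'   animal, analyte, matrix.
#' @param lloq_policy `"zero_before_exclude_after"` (default) or `"keep"`
#'   (use all values as-is).
#' @param tail_n passed to [terminal_lambda()].
#' @return list of class `cf_nca`: cmax, tmax_h, auc0t, auc_inf,
#'   pct_extrapolated, lambda, half_life_h, n_lambda, r2, n_timepoints,
#'   analyte, matrix.
#' @export
summarize_nca <- function(profile, lloq_policy = c("zero_before_exclude_after",
                                                   "keep"), tail_n = NULL) {
  lloq_policy <- match.arg(lloq_policy)
  stopifnot(all(c("time_h", "conc") %in% names(profile)))
  flag <- if ("lloq_flag" %in% names(profile)) profile$lloq_flag else
    rep(FALSE, nrow(profile))
  if (all(flag)) {
    out <- structure(list(cmax = NA_real_, tmax_h = NA_real_,
                          auc0t = NA_real_, auc_inf = NA_real_,
                          pct_extrapolated = NA_real_, lambda = NA_real_,
                          half_life_h = NA_real_, n_lambda = 0L,
                          r2 = NA_real_, n_timepoints = 0L,
                          diagnostic = "all observations below LLOQ"),
                     class = "cf_nca")
    return(out)
  }
  tp <- sort(unique(profile$time_h))
  mean_q <- vapply(tp, function(t) {
    v <- profile$conc[profile$time_h == t & !flag]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  if (lloq_policy == "keep") {
    mean_all <- vapply(tp, function(t)
      mean(profile$conc[profile$time_h == t]), numeric(1))
    times <- tp; conc <- mean_all
  } else {
    i_tmax <- which.max(ifelse(is.na(mean_q), -Inf, mean_q))
    conc <- mean_q; times <- tp
    before <- seq_along(tp) <= i_tmax
    conc[before & is.na(conc)] <- 0
    keep <- !is.na(conc)
    # profile terminates at the last quantifiable point
    last_q <- max(which(keep))
    keep[seq_along(keep) > last_q] <- FALSE
    times <- times[keep]; conc <- conc[keep]
  }
  cmax <- max(conc); tmax <- times[which.max(conc)]
  auc0t <- if (length(times) >= 2) auc_trapezoid(times, conc) else NA_real_
  lam <- terminal_lambda(times, conc, tail_n = tail_n)
  lambda <- if (lam$reportable) lam$lambda else NA_real_
  ext <- auc_extrapolate(auc0t, conc[length(conc)], lambda)
  structure(list(cmax = cmax, tmax_h = tmax, auc0t = auc0t,
                 auc_inf = ext$auc_inf,
                 pct_extrapolated = ext$pct_extrapolated,
                 lambda = lambda, half_life_h = half_life(lambda),
                 n_lambda = lam$n, r2 = lam$r2,
                 n_timepoints = length(times),
                 analyte = profile$analyte[1] %||% NA,
                 matrix = profile$matrix[1] %||% NA),
            class = "cf_nca")
}
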