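#' Remove flagged protein groups
#'
#' Drops protein groups flagged reverse (decoy match), only-identified-by-
#' site, or potential contaminant, logging the removal counts.
#'
#' @param mat data.frame with logical columns `reverse`, `only_by_site`,
#'   `contaminant` (absent columns are treated as all-FALSE).
#' @return the filtered data.frame; attribute `removed` holds the counts.
#' @export
tmt_clean <- function(mat) {
  get <- function(nm) if (nm %in% names(mat)) mat[[nm]] else
    rep(FALSE, nrow(mat))
  rv <- get("reverse"); os <- get("only_by_site"); ct <- get("contaminant")
  drop <- rv | os | ct
  out <- mat[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(reverse = sum(rv), only_by_site = sum(os),
                            contaminant = sum(ct), total = sum(drop))
  out
}

#' Log2 transform with completeness and peptide filters
#'
#' Reporter intensities are log2 transformed; protein groups with any
#' missing (or non-positive) value across the channels, or with fewer than
#' `min_peptides` unique+razor peptides, are removed.
#'
#' @param mat cleaned data.frame; intensity columns named in `channels`.
#' @param channels character vector of intensity column names.
#' @param min_peptides minimum unique+razor peptide count (default 2).
#' @param peptide_col name of the peptide-count column (default "peptides").
#' @return data.frame with the same non-channel columns and log2 intensities.
#' @export
tmt_transform_filter <- function(mat, channels, min_peptides = 2,
                                 peptide_col = "peptides") {
  stopifnot(all(channels %in% names(mat)))
  x <- as.matrix(mat[, channels, drop = FALSE])
  complete <- rowSums(is.na(x) | x <= 0) == 0
  pep <- if (peptide_col %in% names(mat)) mat[[peptide_col]] else
    rep(Inf, nrow(mat))
  keep <- complete & pep >= min_peptides
  out <- mat[keep, , drop = FALSE]
  out[, channels] <- log2(as.matrix(out[, channels, drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Median normalisation within TMT channels
#'
#' Subtracts each channel's median from that channel; afterwards every
#' channel median is zero.
#'
#' @param mat data.frame from [tmt_transform_filter()].
#' @param channels intensity column names.
#' @return normalised data.frame.
#' @export
tmt_median_normalize <- function(mat, channels) {
  if (!nrow(mat)) stop("empty matrix")
  for (ch in channels) mat[[ch]] <- mat[[ch]] - median(mat[[ch]])
  mat
}

#' Per-protein differential test and threshold classification
#'
#' Two-sample t-test per protein on normalised log2 values;
#' Log2FC = mean(groupA) - mean(groupB) (treated minus control).
#' Classification: `up` if Log2FC >= fc_cut and -log10 p >= logp_cut;
#' `down` if Log2FC <= -fc_cut and -log10 p >= logp_cut; else `unchanged`
#' (both thresholds inclusive). The default test is the equal-variance
#' Student's t; Welch is available. Proteins with zero within-group variance
#' in both groups and equal means get p = 1. Raw p-values are used by
#' default (no multiple-testing correction); Benjamini-Hochberg is
#' available via `adjust`.
#'
#' @param mat normalised data.frame with an `id` column.
#' @param group_a,group_b channel column names of the two groups (>= 2
#'   each); group A is the treated group.
#' @param var_equal pooled-variance Student's t (default TRUE).
#' @param fc_cut absolute Log2FC threshold (default 1.0).
#' @param logp_cut -log10 p threshold (default 2.0).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: id, log2fc, t, df, p, neg_log10_p, class.
#' @export
tmt_differential <- function(mat, group_a, group_b, var_equal = TRUE,
                             fc_cut = 1.0, logp_cut = 2.0,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need >= 2 channels per group")
  A <- as.matrix(mat[, group_a, drop = FALSE])
  B <- as.matrix(mat[, group_b, drop = FALSE])
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, var); vb <- apply(B, 1, var)
  lfc <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(mat))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- lfc / se
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se == 0
  p[degenerate & lfc == 0] <- 1          # identical groups
  p[degenerate & lfc != 0] <- 0          # exact separation, zero variance
  tstat[degenerate] <- ifelse(lfc[degenerate] == 0, 0,
                              sign(lfc[degenerate]) * Inf)
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  nlp <- -log10(p)
  cls <- ifelse(lfc >= fc_cut & nlp >= logp_cut, "up",
                ifelse(lfc <= -fc_cut & nlp >= logp_cut, "down", "unchanged"))
  data.frame(id = mat$id, log2fc = lfc, t = tstat, df = df, p = p,
             neg_log10_p = nlp, class = cls, stringsAsFactors = FALSE)
}

#' Overlap of differential protein sets
#'
#' Venn counts of two protein-group id sets drawn from two comparisons
#' (e.g. proteins up in comparison 1 vs down in comparison 2).
#'
#' @param ids1,ids2 character vectors of protein-group ids.
#' @return list: n1, n2, n_intersection, intersection, only1, only2.
#' @export
tmt_overlap <- function(ids1, ids2) {
  ids1 <- unique(ids1); ids2 <- unique(ids2)
  common <- intersect(ids1, ids2)
  list(n1 = length(ids1), n2 = length(ids2),
       n_intersection = length(common), intersection = common,
       only1 = setdiff(ids1, ids2), only2 = setdiff(ids2, ids1))
}

#' Read a MaxQuant-style protein-groups table
#'
#' Thin TSV reader mapping the canonical column names ("Reporter intensity
#' corrected <i>", "Razor + unique peptides", "Reverse", "Only identified by
#' site", "Potential contaminant", marked with "+") onto the columns the
#' filtering functions expect.
#'
#' @param path TSV file path.
#' @return data.frame with id, reverse, only_by_site, contaminant, peptides
#'   and one `reporter_<i>` column per reporter channel.
#' @export
read_protein_groups <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  plus <- function(nm) if (nm %in% names(raw))
    !is.na(raw[[nm]]) & raw[[nm]] == "+" else rep(FALSE, nrow(raw))
  rep_cols <- grep("^Reporter intensity corrected", names(raw), value = TRUE)
  out <- data.frame(
    id = raw[["Protein IDs"]] %||% raw[["id"]] %||% seq_len(nrow(raw)),
    reverse = plus("Reverse"),
    only_by_site = plus("Only identified by site"),
    contaminant = plus("Potential contaminant"),
    peptides = raw[["Razor + unique peptides"]] %||% NA_integer_,
    stringsAsFactors = FALSE)
  for (i in seq_along(rep_cols))
    out[[paste0("reporter_", i)]] <- as.numeric(raw[[rep_cols[i]]])
  out
}
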