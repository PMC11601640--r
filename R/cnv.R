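cf_cn_levels <- c("loss", "diploid", "gain", "amplification")
cf_cn_rank <- c(loss = 0, diploid = 1, gain = 2, amplification = 3)

#' Call categorical copy-number status
#'
#' Thresholds applied literally: CN = 2 is diploid, CN in (2, 5) is gain,
#' CN >= 5 is amplification. Values below 2 fall outside the three-class
#' scheme and are mapped to a flagged `loss` category. Non-integer CN (e.g.
#' from segment means) is permitted; equality with 2 is tested to 1e-9.
#'
#' @param cn numeric copy number(s), >= 0.
#' @return character vector of statuses.
#' @export
call_cn_status <- function(cn) {
  if (any(is.na(cn))) stop("missing copy-number values")
  if (any(cn < 0)) stop("copy number must be >= 0")
  ifelse(abs(cn - 2) < 1e-9, "diploid",
         ifelse(cn < 2, "loss",
                ifelse(cn < 5, "gain", "amplification")))
}

#' Majority-vote consensus status
#'
#' Modal status across the samples of one model. Ties are broken toward the
#' higher-rank (more severe) status and flagged. `loss` votes fall outside
#' the three-class scheme: they are excluded from the vote (their count is
#' reported) unless every vote is a loss.
#'
#' @param statuses character vector of per-sample statuses.
#' @return list: `status`, `tie` (logical), `votes` (table),
#'   `n_loss_excluded`.
#' @export
consensus_by_majority <- function(statuses) {
  if (!length(statuses)) stop("empty vote set")
  bad <- setdiff(statuses, cf_cn_levels)
  if (length(bad)) stop("unknown status: ", paste(bad, collapse = ", "))
  n_loss <- sum(statuses == "loss")
  votes <- statuses[statuses != "loss"]
  if (!length(votes))
    return(list(status = "loss", tie = FALSE,
                votes = table(factor(statuses, cf_cn_levels)),
                n_loss_excluded = 0L))
  tb <- table(factor(votes, c("diploid", "gain", "amplification")))
  top <- names(tb)[tb == max(tb)]
  tie <- length(top) > 1
  status <- top[which.max(cf_cn_rank[top])]
  list(status = status, tie = tie, votes = tb, n_loss_excluded = n_loss)
}

#' Model-level expression
#'
#' Arithmetic mean FPKM across the samples of one model; missing values are
#' excluded and counted.
#'
#' @param fpkm numeric vector (NA allowed).
#' @return list: `mean_fpkm` (NA if all missing), `n_used`, `n_missing`.
#' @export
model_expression <- function(fpkm) {
  n_missing <- sum(is.na(fpkm))
  v <- fpkm[!is.na(fpkm)]
  list(mean_fpkm = if (length(v)) mean(v) else NA_real_,
       n_used = length(v), n_missing = n_missing)
}

#' Build the gene x model consensus table
#'
#' Applies [call_cn_status()] per sample and [consensus_by_majority()] per
#' gene and model; joins the model-level mean FPKM when an expression table
#' is given.
#'
#' @param cn data.frame: gene, sample, model, cn.
#' @param fpkm optional data.frame: gene, sample, model, fpkm.
#' @return data.frame: gene, model, status, tie, n_loss_excluded
#'   (+ mean_fpkm, n_missing when fpkm given).
#' @export
consensus_table <- function(cn, fpkm = NULL) {
  stopifnot(all(c("gene", "sample", "model", "cn") %in% names(cn)))
  cn$status <- call_cn_status(cn$cn)
  key <- interaction(cn$gene, cn$model, drop = TRUE)
  rows <- lapply(split(cn, key), function(g) {
    cons <- consensus_by_majority(g$status)
    data.frame(gene = g$gene[1], model = g$model[1], status = cons$status,
               tie = cons$tie, n_loss_excluded = cons$n_loss_excluded)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(fpkm)) {
    kf <- interaction(fpkm$gene, fpkm$model, drop = TRUE)
    ex <- do.call(rbind, lapply(split(fpkm, kf), function(g) {
      m <- model_expression(g$fpkm)
      data.frame(gene = g$gene[1], model = g$model[1],
                 mean_fpkm = m$mean_fpkm, n_missing = m$n_missing)
    }))
    out <- merge(out, ex, by = c("gene", "model"), all.x = TRUE, sort = FALSE)
  }
  out[order(out$gene, out$model), ]
}

#' Per-gene amplification frequency along a chromosome
#'
#' Percentage of models amplified per gene, ordered by gene start
#' coordinate, with an optional loess trend (local regression with tricube
#' weights, the standard smoother).
#'
#' @param consensus data.frame from [consensus_table()].
#' @param annotation data.frame: gene, chrom, start (1-based).
#' @param span loess span (default 0.3).
#' @param smooth fit the loess trend (default TRUE; needs >= 10 genes).
#' @return data.frame ordered by start: gene, chrom, start, n_models,
#'   n_amplified, pct_amplified (+ loess column when smoothed). Genes
#'   missing from the annotation are dropped with a warning.
#' @export
amplification_frequency <- function(consensus, annotation, span = 0.3,
                                    smooth = TRUE) {
  per_gene <- lapply(split(consensus, consensus$gene), function(g)
    data.frame(gene = g$gene[1], n_models = nrow(g),
               n_amplified = sum(g$status == "amplification")))
  freq <- do.call(rbind, per_gene)
  freq$pct_amplified <- 100 * freq$n_amplified / freq$n_models
  miss <- setdiff(freq$gene, annotation$gene)
  if (length(miss)) {
    warning(length(miss), " gene(s) missing annotation; excluded")
    freq <- freq[!freq$gene %in% miss, , drop = FALSE]
  }
  out <- merge(freq, annotation[, c("gene", "chrom", "start")], by = "gene")
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  if (smooth && nrow(out) >= 10) {
    fit <- stats::loess(pct_amplified ~ start, data = out, span = span,
                        degree = 1)
    out$loess <- predict(fit)
  }
  out
}

#' One-way ANOVA of expression across copy-number classes
#'
#' Fixed-effects one-way ANOVA of model-level mean expression grouped by
#' consensus status.
#'
#' @param values numeric expression values (one per model).
#' @param groups status per model.
#' @return list: `F`, `p`, `df` (between, within), `group_n` (named counts).
#' @export
cn_expression_anova <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(as.character(groups[ok]))
  if (nlevels(groups) < 2) stop("ANOVA undefined for a single group")
  if (length(values) < 3) stop("need >= 3 observations")
  fit <- stats::lm(values ~ groups)
  an <- stats::anova(fit)
  list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
       df = an$Df, group_n = table(groups))
}
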