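#' Simulate PDX copy-number and expression tables
#'
#' Emulates a cohort of patient-derived xenograft (PDX) models, each
#' sequenced as several samples. Per gene and model a latent copy-number
#' class (diploid / gain / amplification) is drawn; sample-level numeric CN
#' values are consistent with the class except for a configurable perturbed
#' minority; model-level expression follows
#' FPKM = baseline * effect^rank * lognormal noise, where rank is 0/1/2 for
#' diploid/gain/amplification.
#'
#' Default class probabilities mirror the cohort composition reported for
#' the amplicon gene of interest in 58 models (22 diploid, 31 gain,
#' 5 amplified).
#'
#' @param n_models number of PDX models (default 58).
#' @param samples_per_model samples per model (default 4, must be >= 1).
#' @param n_genes number of genes.
#' @param class_probs probabilities of (diploid, gain, amplification); must
#'   sum to 1.
#' @param expression_effect multiplicative expression effect per class rank
#'   (1 = expression independent of CN).
#' @param noise_sd lognormal sdlog of FPKM noise.
#' @param perturb_frac fraction of samples whose CN is drawn from a
#'   different class (default 0.1).
#' @param baseline_fpkm baseline FPKM of a diploid model (default 10).
#' @param chrom chromosome name used in the generated annotation.
#' @param seed integer seed; fully determines the output.
#' @return list: `cn` (gene, sample, model, cn), `fpkm` (gene, sample, model,
#'   fpkm), `truth` (gene, model, class), `annotation` (gene, chrom, start).
#' @export
sim_cn_tables <- function(n_models = 58, samples_per_model = 4, n_genes = 50,
                          class_probs = c(diploid = 22, gain = 31,
                                          amplification = 5) / 58,
                          expression_effect = 2, noise_sd = 0.3,
                          perturb_frac = 0.1, baseline_fpkm = 10,
                          chrom = "chr3", seed = 1) {
  if (samples_per_model < 1) stop("samples_per_model must be >= 1")
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  set.seed(child_seed(seed, "cn"))
  classes <- c("diploid", "gain", "amplification")
  genes <- sprintf("G%03d", seq_len(n_genes))
  models <- sprintf("PDX%03d", seq_len(n_models))

  draw_cn <- function(cl, n) switch(cl,
    diploid = rep(2, n),
    gain = sample(3:4, n, TRUE),
    amplification = sample(5:8, n, TRUE))

  truth <- expand.grid(gene = genes, model = models, stringsAsFactors = FALSE)
  truth$class <- sample(classes, nrow(truth), TRUE, prob = class_probs)

  rows_cn <- vector("list", nrow(truth))
  rows_fp <- vector("list", nrow(truth))
  rank <- c(diploid = 0, gain = 1, amplification = 2)
  for (i in seq_len(nrow(truth))) {
    cl <- truth$class[i]
    n <- samples_per_model
    cn <- draw_cn(cl, n)
    n_pert <- rbinom(1, n, perturb_frac)
    # never perturb a strict majority away from the latent class
    n_pert <- min(n_pert, floor((n - 1) / 2))
    if (n_pert > 0) {
      other <- sample(setdiff(classes, cl), n_pert, TRUE)
      idx <- sample(n, n_pert)
      cn[idx] <- vapply(other, function(o) draw_cn(o, 1), numeric(1))
    }
    mu <- baseline_fpkm * expression_effect^rank[[cl]]
    fp <- mu * rlnorm(n, -noise_sd^2 / 2, noise_sd)
    samp <- paste0(truth$model[i], "-S", seq_len(n))
    rows_cn[[i]] <- data.frame(gene = truth$gene[i], sample = samp,
                               model = truth$model[i], cn = cn)
    rows_fp[[i]] <- data.frame(gene = truth$gene[i], sample = samp,
                               model = truth$model[i], fpkm = fp)
  }
  ann <- data.frame(gene = genes, chrom = chrom,
                    start = sort(sample.int(2e8, n_genes)))
  list(cn = do.call(rbind, rows_cn), fpkm = do.call(rbind, rows_fp),
       truth = truth, annotation = ann)
}

#' Simulate a concentration-time pharmacokinetic profile
#'
#' Mono-exponential decay C(t) = c0 * exp(-lambda_true * t) with per-animal
#' lognormal noise. Sampling defaults to the standard 8-point design
#' (0.083, 0.25, 0.5, 1, 2, 4, 7, 24 h). Values below the lower limit of
#' quantitation keep their true value but are flagged, so LLOQ-handling
#' policies can be tested against truth.
#'
#' @param lambda_true true elimination rate constant (1/h), must be > 0.
#' @param c0 concentration at dose time (ng/mL).
#' @param times sampling times in hours, strictly increasing, >= 0.
#' @param n_animals animals per time point (default 3, destructive sampling).
#' @param lognormal_sd sdlog of the multiplicative noise.
#' @param lloq lower limit of quantitation (default 1 ng/mL).
#' @param analyte,matrix labels copied into the output.
#' @param seed integer seed.
#' @return data.frame: analyte, matrix, animal, time_h, conc, lloq_flag.
#' @export
sim_pk_profile <- function(lambda_true = 0.2, c0 = 1000,
                           times = c(0.083, 0.25, 0.5, 1, 2, 4, 7, 24),
                           n_animals = 3, lognormal_sd = 0.2, lloq = 1,
                           analyte = "drug", matrix = "plasma", seed = 1) {
  if (lambda_true <= 0) stop("lambda_true must be > 0")
  if (any(times < 0) || any(diff(times) <= 0))
    stop("times must be strictly increasing and >= 0")
  set.seed(child_seed(seed, "pk"))
  out <- expand.grid(animal = seq_len(n_animals), time_h = times)
  mu <- c0 * exp(-lambda_true * out$time_h)
  noise <- if (lognormal_sd > 0)
    rlnorm(nrow(out), 0, lognormal_sd) else rep(1, nrow(out))
  out$conc <- mu * noise
  out$lloq_flag <- out$conc < lloq
  data.frame(analyte = analyte, matrix = matrix, out,
             stringsAsFactors = FALSE)
}

#' Simulate an EdU / DNA-content single-cell population
#'
#' G1 cells centre at DNA = 2N and are EdU-negative; S cells span
#' (2N, 4N) and are EdU-positive; G2/M cells centre at 4N and are
#' EdU-negative. Channel spread is lognormal; `spread = 0` gives perfectly
#' separable populations.
#'
#' @param n_per_phase named counts, e.g. `c(G1 = 100, S = 100, G2M = 100)`.
#' @param dna_2n DNA-stain signal of a 2N cell (default 100).
#' @param edu_neg_mean,edu_neg_sd Gaussian EdU background of negative cells.
#' @param edu_pos_mean mean EdU signal of S cells (default 1000).
#' @param spread lognormal sdlog applied to DNA and positive-EdU signals
#'   (default 0.05).
#' @param condition condition label copied to every row.
#' @param seed integer seed.
#' @return data.frame: cell_id, dna, edu, condition, true_phase.
#' @export
sim_edu_dna <- function(n_per_phase = c(G1 = 100, S = 100, G2M = 100),
                        dna_2n = 100, edu_neg_mean = 100, edu_neg_sd = 10,
                        edu_pos_mean = 1000, spread = 0.05,
                        condition = "control", seed = 1) {
  stopifnot(all(n_per_phase >= 0),
            all(names(n_per_phase) %in% c("G1", "S", "G2M")))
  set.seed(child_seed(seed, "edu"))
  ln <- function(mu, n) if (spread > 0) mu * rlnorm(n, 0, spread) else rep(mu, n)
  mk <- function(phase, n) {
    if (n == 0) return(NULL)
    dna <- switch(phase,
      G1 = ln(dna_2n, n),
      S = ln(1, n) * runif(n, dna_2n * 1.15, dna_2n * 1.85),
      G2M = ln(2 * dna_2n, n))
    edu <- switch(phase,
      G1 = , G2M = pmax(0, rnorm(n, edu_neg_mean, edu_neg_sd)),
      S = ln(edu_pos_mean, n))
    data.frame(dna = dna, edu = edu, true_phase = if (phase == "G2M")
      "G2/M" else phase, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Filter(Negate(is.null), lapply(
    names(n_per_phase), function(p) mk(p, n_per_phase[[p]]))))
  if (is.null(out)) out <- data.frame(dna = numeric(0), edu = numeric(0),
                                      true_phase = character(0))
  data.frame(cell_id = seq_len(nrow(out)), out, condition = condition,
             stringsAsFactors = FALSE)
}

#' Simulate a TMT reporter-intensity protein-group matrix
#'
#' Two groups of channels (treated vs control). Spiked-up proteins are
#' shifted by `+effect_log2` and spiked-down proteins by `-effect_log2` in
#' the treated group. Missing values, unique+razor peptide counts and
#' decoy/contaminant flags are assigned so the cleaning and completeness
#' filters can be tested against truth.
#'
#' @param n_proteins number of protein groups.
#' @param n_channels_per_group channels per group (default 3).
#' @param spike_up,spike_down disjoint integer index sets of spiked proteins.
#' @param effect_log2 log2 shift applied to spiked proteins.
#' @param sd per-channel log2 noise sd.
#' @param missing_rate probability a measurement is missing.
#' @param peptide_counts optional integer vector of unique+razor peptide
#'   counts per protein (recycled); default draws from 1..30 with P(1) ~ 10%.
#' @param frac_reverse,frac_site,frac_contaminant fractions of rows flagged
#'   reverse / only-identified-by-site / potential contaminant.
#' @param base_log2_mean,base_log2_sd distribution of baseline abundances.
#' @param group_labels labels of (treated, control) groups.
#' @param seed integer seed.
#' @return list: `matrix` (data.frame with id, flag columns, peptide counts,
#'   one reporter-intensity column per channel), `groups` (channel -> group
#'   label), `truth` (spiked index sets).
#' @export
sim_tmt_matrix <- function(n_proteins = 2000, n_channels_per_group = 3,
                           spike_up = integer(0), spike_down = integer(0),
                           effect_log2 = 2, sd = 0.25, missing_rate = 0.02,
                           peptide_counts = NULL,
                           frac_reverse = 0.01, frac_site = 0.01,
                           frac_contaminant = 0.02,
                           base_log2_mean = 20, base_log2_sd = 2,
                           group_labels = c("treated", "control"), seed = 1) {
  if (length(intersect(spike_up, spike_down)))
    stop("spike_up and spike_down must be disjoint")
  set.seed(child_seed(seed, "tmt"))
  ng <- n_channels_per_group
  channels <- c(paste0(group_labels[1], "_", seq_len(ng)),
                paste0(group_labels[2], "_", seq_len(ng)))
  groups <- setNames(rep(group_labels, each = ng), channels)

  base <- rnorm(n_proteins, base_log2_mean, base_log2_sd)
  shift <- numeric(n_proteins)
  shift[spike_up] <- effect_log2
  shift[spike_down] <- -effect_log2
  log2m <- matrix(rnorm(n_proteins * 2 * ng, 0, sd), n_proteins, 2 * ng) + base
  log2m[, seq_len(ng)] <- log2m[, seq_len(ng)] + shift
  intens <- 2^log2m
  if (missing_rate > 0)
    intens[matrix(runif(length(intens)) < missing_rate,
                  n_proteins, 2 * ng)] <- NA
  colnames(intens) <- channels

  if (is.null(peptide_counts))
    peptide_counts <- sample(c(1L, 2:30), n_proteins, TRUE,
                             prob = c(0.1, rep(0.9 / 29, 29)))
  peptide_counts <- rep_len(peptide_counts, n_proteins)

  flag_n <- function(frac) {
    v <- rep(FALSE, n_proteins)
    k <- round(frac * n_proteins)
    if (k > 0) v[sample.int(n_proteins, k)] <- TRUE
    v
  }
  mat <- data.frame(id = sprintf("P%05d", seq_len(n_proteins)),
                    reverse = flag_n(frac_reverse),
                    only_by_site = flag_n(frac_site),
                    contaminant = flag_n(frac_contaminant),
                    peptides = as.integer(peptide_counts),
                    stringsAsFactors = FALSE)
  mat <- cbind(mat, as.data.frame(intens))
  list(matrix = mat, groups = groups,
       truth = list(spike_up = spike_up, spike_down = spike_down,
                    effect_log2 = effect_log2))
}
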