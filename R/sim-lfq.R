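#' Configuration for the synthetic LFQ proteomics generator
#'
#' Describes a proximity-labeling LFQ experiment: a background proteome
#' measured across conditions in replicates, with a known set of proteins
#' truly enriched ("spiked") in each non-control condition, heterogeneous
#' per-protein replicate variance, intensity-dependent (missing-not-at-
#' random, MNAR) dropout, and a companion control spectral-count table in
#' which a flagged subset of proteins behaves like recurrent
#' affinity-purification contaminants.
#'
#' The MNAR model is logistic left-censoring,
#' `P(missing) = plogis(-missing_slope * (I - missing_midpoint))`, the
#' standard assumption behind left-shifted (MinProb-style) imputation.
#' Per-protein replicate variances follow a scaled inverse chi-square
#' distribution `replicate_sd^2 * var_prior_df / chisq(var_prior_df)`, the
#' generating model of empirical-Bayes variance moderation.
#'
#' @param n_background Number of background (null) proteins.
#' @param n_spiked_per_condition Number of proteins truly enriched in each
#'   non-control condition.
#' @param n_conditions Number of conditions (>= 2); the last condition is
#'   the no-probe control.
#' @param n_replicates Replicates per condition (default 3, the paper-style
#'   triplicate design).
#' @param baseline_mean,baseline_sd Log2-intensity distribution of protein
#'   baselines (defaults 25 and 2, typical LFQ log2 scale).
#' @param effect_log2fc True log2 fold change of spiked proteins in their
#'   condition (default 1.5).
#' @param replicate_sd Typical within-replicate log2 SD (prior scale of the
#'   variance distribution; default 0.2, technical-triplicate grade).
#' @param var_prior_df Degrees of freedom of the per-protein variance
#'   distribution (default 12; smaller = more heterogeneous).
#' @param missing_slope,missing_midpoint Logistic MNAR parameters
#'   (defaults 3 and 21; `missing_midpoint = -Inf` disables missingness).
#' @param n_controls Number of simulated control experiments for the
#'   spectral-count table (default 10).
#' @param contaminant_fraction Fraction of background proteins flagged as
#'   recurrent contaminants (default 0.05).
#' @param keratin_fraction Fraction flagged as keratins (default 0.005).
#' @param seed Integer seed.
#' @return An object of class `lfq_sim_config`.
#' @export
lfq_sim_config <- function(n_background = 2000, n_spiked_per_condition = 40,
                           n_conditions = 2, n_replicates = 3,
                           baseline_mean = 25, baseline_sd = 2,
                           effect_log2fc = 1.5, replicate_sd = 0.2,
                           var_prior_df = 12,
                           missing_slope = 3, missing_midpoint = 21,
                           n_controls = 10, contaminant_fraction = 0.05,
                           keratin_fraction = 0.005, seed = 1) {
  if (n_background < 0 || n_spiked_per_condition < 0 || n_conditions < 2 ||
      n_replicates < 2 || n_controls < 1)
    stop("non-positive or out-of-range counts in LFQ simulation config")
  if (!is.finite(effect_log2fc)) stop("effect_log2fc must be finite")
  if (replicate_sd <= 0 || baseline_sd < 0)
    stop("replicate_sd must be positive")
  structure(list(n_background = n_background,
                 n_spiked_per_condition = n_spiked_per_condition,
                 n_conditions = n_conditions, n_replicates = n_replicates,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 effect_log2fc = effect_log2fc, replicate_sd = replicate_sd,
                 var_prior_df = var_prior_df, missing_slope = missing_slope,
                 missing_midpoint = missing_midpoint, n_controls = n_controls,
                 contaminant_fraction = contaminant_fraction,
                 keratin_fraction = keratin_fraction, seed = seed),
            class = "lfq_sim_config")
}

# MNAR missingness probability; midpoint = -Inf disables dropout entirely.
mnar_prob <- function(intensity, slope, midpoint) {
  if (identical(midpoint, -Inf)) return(rep(0, length(intensity)))
  stats::plogis(-slope * (intensity - midpoint))
}

#' Generate a synthetic LFQ dataset with known ground truth
#'
#' Produces an [intensity_table()] with the design
#' `n_conditions x n_replicates`, a control spectral-count table in which
#' a flagged subset of proteins is present in most simulated controls
#' with high counts (so a CRAPome-style filter has true positives), and a
#' ground-truth object for recovery testing.
#'
#' @param cfg An [lfq_sim_config()].
#' @return List with elements `table` (intensity_table), `counts`
#'   (spectral-count data frame: `protein`, `keratin`, one count column
#'   per control experiment), and `truth` (list: `spiked` data frame with
#'   `protein`, `condition`, `effect_log2fc`; `contaminants`; `keratins`;
#'   `protein_sd`).
#' @export
generate_lfq_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "lfq_sim_config"))
  set.seed(derive_seed(cfg$seed, "lfq_sim"))

  conds <- c(paste0("target", seq_len(cfg$n_conditions - 1L)), "control")
  n_spiked_total <- cfg$n_spiked_per_condition * (cfg$n_conditions - 1L)
  n_prot <- cfg$n_background + n_spiked_total
  proteins <- sprintf("P%05d", seq_len(n_prot))
  spiked <- if (n_spiked_total > 0) {
    data.frame(protein = proteins[seq_len(n_spiked_total)],
               condition = rep(conds[seq_len(cfg$n_conditions - 1L)],
                               each = cfg$n_spiked_per_condition),
               effect_log2fc = cfg$effect_log2fc)
  } else {
    data.frame(protein = character(), condition = character(),
               effect_log2fc = numeric())
  }

  design <- data.frame(
    sample = paste0(rep(conds, each = cfg$n_replicates), "_rep",
                    rep(seq_len(cfg$n_replicates), cfg$n_conditions)),
    condition = rep(conds, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), cfg$n_conditions))

  baseline <- stats::rnorm(n_prot, cfg$baseline_mean, cfg$baseline_sd)
  prot_sd <- sqrt(cfg$replicate_sd^2 * cfg$var_prior_df /
                    stats::rchisq(n_prot, cfg$var_prior_df))

  latent <- matrix(0, n_prot, nrow(design),
                   dimnames = list(proteins, design$sample))
  for (j in seq_len(nrow(design))) {
    mu <- baseline
    hit <- match(proteins, spiked$protein)
    boost <- !is.na(hit) & spiked$condition[ifelse(is.na(hit), 1L, hit)] ==
      design$condition[j]
    mu[boost] <- mu[boost] + cfg$effect_log2fc
    latent[, j] <- stats::rnorm(n_prot, mu, prot_sd)
  }
  p_miss <- mnar_prob(latent, cfg$missing_slope, cfg$missing_midpoint)
  stopifnot(all(p_miss >= 0 & p_miss <= 1))
  observed <- latent
  observed[stats::runif(length(latent)) < p_miss] <- NA

  # control spectral counts: contaminants recur at high counts
  n_contam <- round(cfg$contaminant_fraction * cfg$n_background)
  n_ker <- round(cfg$keratin_fraction * cfg$n_background)
  bg_pool <- proteins[(n_spiked_total + 1L):n_prot]
  contam <- sample(bg_pool, n_contam)
  keratins <- sample(setdiff(bg_pool, contam), n_ker)
  counts <- matrix(0L, n_prot, cfg$n_controls,
                   dimnames = list(proteins,
                                   paste0("ctrl", seq_len(cfg$n_controls))))
  pres_p <- stats::runif(n_prot, 0.05, 0.35)
  pres_p[proteins %in% contam] <- stats::runif(n_contam, 0.6, 1.0)
  for (j in seq_len(cfg$n_controls)) {
    present <- stats::runif(n_prot) < pres_p
    cnt <- 1L + stats::rpois(n_prot, 3)
    hi <- present & proteins %in% contam
    cnt[hi] <- round(stats::runif(sum(hi), 16, 100))
    counts[present, j] <- cnt[present]
  }
  counts_df <- data.frame(protein = proteins,
                          keratin = proteins %in% keratins, counts,
                          check.names = FALSE)

  list(table = intensity_table(observed, design),
       counts = counts_df,
       truth = list(spiked = spiked, contaminants = contam,
                    keratins = keratins, protein_sd = prot_sd,
                    baseline = baseline, conditions = conds))
}

#' Generate a synthetic protein annotation table
#'
#' Flags each protein independently per category at the stated fractions
#' (e.g. nuclear "main"/"additional" localization, nucleolar rim,
#' paraspeckle, external-list membership).
#'
#' @param proteins Character vector of protein identifiers.
#' @param category_fractions Named numeric vector of per-category flag
#'   probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data frame with column `protein` and one logical column per
#'   category.
#' @export
generate_annotation_table <- function(proteins, category_fractions, seed = 1) {
  if (is.null(names(category_fractions)) ||
      any(!nzchar(names(category_fractions))))
    stop("unknown category: category_fractions must be a named vector")
  if (any(category_fractions < 0 | category_fractions > 1))
    stop("category fractions must lie in [0, 1]")
  set.seed(derive_seed(seed, "annot_sim"))
  out <- data.frame(protein = proteins)
  for (cat in names(category_fractions)) {
    out[[cat]] <- stats::runif(length(proteins)) < category_fractions[[cat]]
  }
  out
}
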