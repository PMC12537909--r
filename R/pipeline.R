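#' Pooled within-condition variances of an intensity table
#'
#' Residual variance of each protein around its condition means, pooled
#' across all conditions, with `n_samples - n_conditions` degrees of
#' freedom; the input to [fit_moderation()].
#'
#' @param tbl A complete [intensity_table()].
#' @return List with `variances` and `dfs`.
#' @export
protein_variances <- function(tbl) {
  stopifnot(inherits(tbl, "intensity_table"))
  if (anyNA(tbl$intensity)) stop("table contains missing cells")
  m <- tbl$intensity
  conds <- unique(tbl$design$condition)
  ss <- rep(0, nrow(m))
  for (cc in conds) {
    cols <- tbl$design$sample[tbl$design$condition == cc]
    sub <- m[, cols, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  df <- ncol(m) - length(conds)
  list(variances = ss / df, dfs = df)
}

#' Full pipeline configuration
#'
#' Collects every stage parameter with its default in one serializable
#' object.  A single global seed deterministically derives per-stage
#' sub-seeds (see [derive_seed()]), so stages can be rerun independently
#' with identical results.
#'
#' @param stages Stages to run, in dependency order; subset of
#'   `c("simulate", "lfq", "ppi")`.
#' @param seed Global integer seed.
#' @param lfq_sim Named list of overrides for [lfq_sim_config()].
#' @param net_sim Named list of overrides for [net_sim_config()].
#' @param fc_thr,p_thr,z_thr Shortlisting thresholds (defaults 1.5,
#'   0.05, 1).
#' @param q,sd_scale MinProb imputation parameters (defaults 0.01, 1).
#' @param freq_thr,count_thr Contaminant-filter thresholds (defaults
#'   0.5, 15).
#' @param normalize Median-center samples before testing (default TRUE).
#' @param cutoffs Interaction score cutoffs (default
#'   `c(0.4, 0.7, 0.9)`).
#' @param n_samples Simulated proteomes per null (default 100).
#' @param profile_length Line-profile length in micrometres (default
#'   1.5; recorded for image-stage tooling).
#' @param annotation_fractions Category flag probabilities for the
#'   synthetic annotation table.
#' @param out_dir Optional output directory for the report, log and
#'   tables.
#' @return An object of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "lfq", "ppi"), seed = 1,
                       lfq_sim = list(), net_sim = list(),
                       fc_thr = 1.5, p_thr = 0.05, z_thr = 1,
                       q = 0.01, sd_scale = 1,
                       freq_thr = 0.5, count_thr = 15, normalize = TRUE,
                       cutoffs = c(0.4, 0.7, 0.9), n_samples = 100,
                       profile_length = 1.5,
                       annotation_fractions = c(nuclear_main = 0.6,
                                                nuclear_additional = 0.15,
                                                nucleolar_rim = 0.1,
                                                paraspeckle = 0.05),
                       out_dir = NULL) {
  stopifnot(all(stages %in% c("simulate", "lfq", "ppi")),
            fc_thr > 0, p_thr > 0, p_thr <= 1, q > 0, q < 1,
            all(cutoffs >= 0 & cutoffs <= 1), n_samples >= 1,
            profile_length > 0)
  structure(list(stages = stages, seed = seed, lfq_sim = lfq_sim,
                 net_sim = net_sim, fc_thr = fc_thr, p_thr = p_thr,
                 z_thr = z_thr, q = q, sd_scale = sd_scale,
                 freq_thr = freq_thr, count_thr = count_thr,
                 normalize = normalize, cutoffs = cutoffs,
                 n_samples = n_samples, profile_length = profile_length,
                 annotation_fractions = annotation_fractions,
                 out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `read_run_config` returns the reconstructed `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$annotation_fractions <- as.list(x$annotation_fractions)
  writeLines(yaml::as.yaml(x), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$annotation_fractions <- unlist(x$annotation_fractions)
  x$cutoffs <- as.numeric(x$cutoffs)
  do.call(run_config, x)
}

#' Run the simulation / enrichment / interaction pipeline
#'
#' Executes the selected stages in dependency order on synthetic data
#' with known truth: data generation, contaminant and replicate
#' filtering, imputation, moderated-t shortlisting with nuclear
#' filtering, and resampling-based interaction enrichment of the
#' shortlist at each score cutoff.  Produces a machine-readable report
#' (stage-by-stage survivor counts, shortlist, enrichment results)
#' stamped with the hash of the configuration that produced it; the
#' report content is fully determined by config + seed.
#'
#' @param cfg A [run_config()].
#' @return The report (list, class `run_report`).  When `cfg$out_dir` is
#'   set, also writes `report.json`, `run.log` and the simulated tables
#'   there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  log_lines <- character()
  logit <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }
  # output location does not change the scientific identity of a run
  hashed <- unclass(cfg)[setdiff(names(cfg), "out_dir")]
  report <- list(package = "proxitome",
                 config_hash = config_hash(hashed), seed = cfg$seed,
                 stages = list())

  # --- simulate ---------------------------------------------------------
  sim_cfg <- do.call(lfq_sim_config,
                     c(cfg$lfq_sim,
                       list(seed = derive_seed(cfg$seed, "stage_sim"))))
  sim <- generate_lfq_dataset(sim_cfg)
  proteins <- rownames(sim$table$intensity)
  annot <- generate_annotation_table(proteins, cfg$annotation_fractions,
                                     seed = derive_seed(cfg$seed, "stage_annot"))
  # force truly spiked proteins to carry nuclear annotation, as real
  # compartment residents would
  annot$nuclear_main[annot$protein %in% sim$truth$spiked$protein] <- TRUE
  net_cfg <- do.call(net_sim_config,
                     c(cfg$net_sim,
                       list(n_proteins = length(proteins),
                            seed = derive_seed(cfg$seed, "stage_net"))))
  net <- generate_ppi_network(net_cfg)
  # share the identifier space: module-1 nodes map onto the spiked
  # proteins first, so the true compartment proteome is interaction-dense
  nodes <- names(net$truth$module_assignment)
  ord <- order(net$truth$module_assignment != 1)
  mapping <- character(length(nodes))
  mapping[ord] <- c(sim$truth$spiked$protein,
                    setdiff(proteins, sim$truth$spiked$protein))
  names(mapping) <- nodes
  net$edges$protein_a <- unname(mapping[net$edges$protein_a])
  net$edges$protein_b <- unname(mapping[net$edges$protein_b])
  report$stages$simulate <- list(
    n_proteins = length(proteins),
    n_spiked = nrow(sim$truth$spiked),
    n_edges = nrow(net$edges))
  logit("simulate: ", length(proteins), " proteins, ",
        nrow(net$edges), " network edges")
  if (!"lfq" %in% cfg$stages) {
    return(finish_report(report, cfg, log_lines, t0, sim = sim, net = net))
  }

  # --- lfq --------------------------------------------------------------
  kept <- crapome_filter(proteins, sim$counts, cfg$freq_thr, cfg$count_thr)
  tbl <- subset_proteins(sim$table, kept)
  s1 <- list(filter = "crapome", input = length(proteins),
             kept = length(kept), removed = length(proteins) - length(kept))
  tbl2 <- replicate_presence_filter(tbl)
  s2 <- list(filter = "replicate_presence", input = nrow(tbl$intensity),
             kept = nrow(tbl2$intensity),
             removed = nrow(tbl$intensity) - nrow(tbl2$intensity))
  if (cfg$normalize) tbl2 <- normalize_median(tbl2)
  tbl3 <- impute_minprob(tbl2, q = cfg$q, sd_scale = cfg$sd_scale,
                         seed = derive_seed(cfg$seed, "stage_impute"))
  pv <- protein_variances(tbl3)
  mp <- fit_moderation(pv$variances, pv$dfs)
  conds <- unique(tbl3$design$condition)
  stats <- pvalue_z(moderated_t(tbl3, conds[1], "control", mp))
  sl <- shortlist(stats, fc_thr = cfg$fc_thr, p_thr = cfg$p_thr,
                  z_thr = cfg$z_thr)
  sl_nuc <- filter_nuclear(sl, annot)
  report$stages$lfq <- list(
    filters = list(s1, s2,
                   list(filter = "shortlist", input = nrow(stats),
                        kept = nrow(sl), removed = nrow(stats) - nrow(sl)),
                   list(filter = "nuclear", input = nrow(sl),
                        kept = nrow(sl_nuc), removed = nrow(sl) - nrow(sl_nuc))),
    moderation = list(d0 = mp$d0, s0_sq = mp$s0_sq),
    shortlist = sl_nuc$protein)
  logit("lfq: ", nrow(sl_nuc), " shortlisted proteins (d0 = ",
        signif(mp$d0, 4), ")")
  if (!"ppi" %in% cfg$stages) {
    return(finish_report(report, cfg, log_lines, t0, sim = sim, net = net))
  }

  # --- ppi --------------------------------------------------------------
  background <- rownames(tbl2$intensity)
  set <- intersect(sl_nuc$protein, background)
  enr <- lapply(cfg$cutoffs, function(cut) {
    obs <- count_edges(set, net$edges, cut)
    null <- sample_null(background, length(set), net$edges, cut,
                        n_samples = cfg$n_samples,
                        seed = derive_seed(cfg$seed,
                                           paste0("stage_ppi_", cut)))
    et <- enrichment_test(obs, null)
    list(cutoff = cut, observed = et$observed,
         null_median = et$null_median, fold = et$fold, p = et$p)
  })
  names(enr) <- paste0("cutoff_", cfg$cutoffs)
  report$stages$ppi <- list(set_size = length(set),
                            background_size = length(background),
                            enrichment = enr)
  logit("ppi: set of ", length(set), " vs background ", length(background))
  finish_report(report, cfg, log_lines, t0, sim = sim, net = net)
}

# Write report/log/tables if requested; attach class.
finish_report <- function(report, cfg, log_lines, t0, sim = NULL,
                          net = NULL) {
  class(report) <- c("run_report", "list")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    writeLines(c(paste0("# proxitome ",
                        as.character(utils::packageVersion("proxitome")),
                        " seed=", cfg$seed,
                        " config_hash=", report$config_hash),
                 log_lines,
                 sprintf("# elapsed %.1f s", elapsed)),
               file.path(cfg$out_dir, "run.log"))
    if (!is.null(sim)) {
      write_intensity_tsv(sim$table,
                          file.path(cfg$out_dir, "intensity.tsv"))
      write_tsv(sim$counts, file.path(cfg$out_dir, "spectral_counts.tsv"))
      write_tsv(sim$truth$spiked, file.path(cfg$out_dir, "truth_spiked.tsv"))
    }
    if (!is.null(net))
      write_tsv(net$edges, file.path(cfg$out_dir, "edges.tsv"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (config ", substr(x$config_hash, 1, 8), ", seed ",
      x$seed, ")\n", sep = "")
  for (nm in names(x$stages)) cat("  stage: ", nm, "\n", sep = "")
  invisible(x)
}
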