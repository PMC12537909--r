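#' Contaminant filter against control spectral counts
#'
#' Removes keratins and proteins behaving like recurrent
#' affinity-purification contaminants in a CRAPome-style control
#' compendium.  A protein is removed iff it is flagged as keratin, or it
#' appears in strictly more than `freq_thr` of all control experiments
#' AND its mean spectral count over the protein-positive controls is
#' strictly greater than `count_thr`.  Proteins absent from the count
#' table are treated as never observed in controls and retained (with a
#' message).
#'
#' @param proteins Character vector of candidate protein identifiers.
#' @param counts Spectral-count data frame: column `protein`, optional
#'   logical column `keratin`, and one numeric count column per control
#'   experiment (zero = not observed).
#' @param freq_thr Presence-fraction threshold (default 0.5, strict `>`).
#' @param count_thr Mean-count threshold over positive controls
#'   (default 15, strict `>`).
#' @param keratin_flags Optional logical vector along `proteins` (or
#'   character vector of keratin identifiers) overriding the `keratin`
#'   column.
#' @return Character vector of retained proteins (original order), with
#'   attribute `removed` naming the excluded proteins.
#' @export
crapome_filter <- function(proteins, counts, freq_thr = 0.5, count_thr = 15,
                           keratin_flags = NULL) {
  stopifnot(freq_thr >= 0, freq_thr <= 1, count_thr >= 0)
  cnt_cols <- setdiff(names(counts), c("protein", "keratin"))
  m <- as.matrix(counts[, cnt_cols, drop = FALSE])
  if (any(m < 0)) stop("spectral counts must be >= 0")
  rownames(m) <- counts$protein

  if (is.null(keratin_flags)) {
    ker <- if (!is.null(counts$keratin)) counts$protein[counts$keratin] else character()
    is_ker <- proteins %in% ker
  } else if (is.character(keratin_flags)) {
    is_ker <- proteins %in% keratin_flags
  } else {
    stopifnot(length(keratin_flags) == length(proteins))
    is_ker <- as.logical(keratin_flags)
  }

  hit <- match(proteins, rownames(m))
  missing_ctrl <- is.na(hit)
  if (any(missing_ctrl))
    message(sum(missing_ctrl),
            " protein(s) absent from the control count table; retained")
  presence <- rep(0, length(proteins))
  mean_pos <- rep(0, length(proteins))
  found <- which(!missing_ctrl)
  if (length(found)) {
    sub <- m[hit[found], , drop = FALSE]
    pos <- sub > 0
    presence[found] <- rowMeans(pos)
    np <- rowSums(pos)
    mean_pos[found] <- ifelse(np > 0, rowSums(sub) / pmax(np, 1), 0)
  }
  remove <- is_ker | (presence > freq_thr & mean_pos > count_thr)
  kept <- proteins[!remove]
  attr(kept, "removed") <- proteins[remove]
  kept
}

#' Replicate-presence filter
#'
#' Keeps a protein iff it was identified in all replicates of at least
#' one condition (no missing cells for that condition).
#'
#' @param tbl An [intensity_table()].
#' @return Filtered [intensity_table()] with attribute `removed`.
#' @export
replicate_presence_filter <- function(tbl) {
  stopifnot(inherits(tbl, "intensity_table"))
  conds <- unique(tbl$design$condition)
  if (nrow(tbl$intensity) == 0) return(tbl)
  complete_any <- rep(FALSE, nrow(tbl$intensity))
  for (cc in conds) {
    cols <- tbl$design$sample[tbl$design$condition == cc]
    complete_any <- complete_any |
      rowSums(is.na(tbl$intensity[, cols, drop = FALSE])) == 0
  }
  out <- intensity_table(tbl$intensity[complete_any, , drop = FALSE],
                         tbl$design)
  attr(out, "removed") <- rownames(tbl$intensity)[!complete_any]
  out
}

#' Per-sample median centering on the log2 scale
#'
#' Subtracts each sample's median observed log2 intensity and re-adds the
#' grand median, aligning sample distributions while preserving the
#' overall intensity scale.  Missing cells are untouched.
#'
#' @param tbl An [intensity_table()].
#' @return Normalized [intensity_table()].
#' @export
normalize_median <- function(tbl) {
  stopifnot(inherits(tbl, "intensity_table"))
  med <- apply(tbl$intensity, 2, stats::median, na.rm = TRUE)
  m <- sweep(tbl$intensity, 2, med - stats::median(med))
  intensity_table(m, tbl$design)
}

#' Left-censored (MinProb) imputation of missing LFQ intensities
#'
#' Replaces each missing cell with a random draw from a Gaussian centred
#' at the per-sample `q`-quantile of that sample's observed values, with
#' spread `sd_scale` times the median protein-wise SD of observed values
#' - the classic model for intensities missing because they fell below
#' the detection limit.  Observed cells are never altered.
#'
#' @param tbl An [intensity_table()].
#' @param q Quantile of the observed per-sample distribution used as the
#'   imputation centre (default 0.01).
#' @param sd_scale Multiplier of the median protein-wise SD (default 1).
#' @param seed Integer seed; imputation is deterministic given the seed.
#' @return Complete [intensity_table()].
#' @export
impute_minprob <- function(tbl, q = 0.01, sd_scale = 1, seed = 1) {
  stopifnot(inherits(tbl, "intensity_table"), q > 0, q < 1, sd_scale > 0)
  m <- tbl$intensity
  if (!anyNA(m)) return(tbl)
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0))
    stop("sample(s) with no observed values: ",
         paste(colnames(m)[n_obs == 0], collapse = ", "))
  row_sd <- apply(m, 1, stats::sd, na.rm = TRUE)
  sd_imp <- sd_scale * stats::median(row_sd, na.rm = TRUE)
  if (!is.finite(sd_imp) || sd_imp <= 0) sd_imp <- sd_scale * 0.1
  set.seed(derive_seed(seed, "impute_minprob"))
  for (j in seq_len(ncol(m))) {
    miss <- which(is.na(m[, j]))
    if (!length(miss)) next
    centre <- stats::quantile(m[, j], q, na.rm = TRUE, names = FALSE)
    m[miss, j] <- stats::rnorm(length(miss), centre, sd_imp)
  }
  intensity_table(m, tbl$design)
}
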