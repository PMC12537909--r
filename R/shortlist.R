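#' Shortlist significantly enriched proteins
#'
#' Applies the compartment-proteome shortlisting rule to per-protein
#' differential statistics computed against the no-probe control: keep a
#' protein iff its fold change is at least `fc_thr` (`2^log2fc >= fc_thr`,
#' inclusive), its unadjusted two-sided p-value is strictly below
#' `p_thr`, its p-value-based Z-score strictly exceeds `z_thr`, and -
#' when statistics for a competing compartment (or cell line) are
#' supplied - its Z-score strictly exceeds the Z-score of the same
#' protein in the competitor.  Proteins absent from the competitor table
#' are treated as `Z_competitor = -Inf` (they pass the cross rule).
#'
#' @param stats_target `differential_stats` for the compartment of
#'   interest, with `z` filled (see [pvalue_z()]).
#' @param stats_competitor Optional `differential_stats` for the
#'   competing comparison.
#' @param fc_thr Fold-change threshold on the natural scale (default 1.5;
#'   inclusive `>=`).
#' @param p_thr P-value threshold (default 0.05; strict `<`).
#' @param z_thr Z-score threshold (default 1; strict `>`).
#' @return An object of class `shortlist`: the retained rows of
#'   `stats_target` ordered by decreasing Z, with attribute `provenance`
#'   recording each filter and the count surviving it.
#' @export
shortlist <- function(stats_target, stats_competitor = NULL, fc_thr = 1.5,
                      p_thr = 0.05, z_thr = 1) {
  stopifnot(all(c("protein", "log2fc", "p", "z") %in% names(stats_target)))
  if (anyNA(stats_target$z))
    stop("z column not filled; run pvalue_z() first")
  n0 <- nrow(stats_target)
  keep <- 2^stats_target$log2fc >= fc_thr &
    stats_target$p < p_thr &
    stats_target$z > z_thr
  prov <- list(list(filter = "fc_p_z", fc_thr = fc_thr, p_thr = p_thr,
                    z_thr = z_thr, input = n0, kept = sum(keep)))
  if (!is.null(stats_competitor)) {
    hit <- match(stats_target$protein, stats_competitor$protein)
    z_comp <- ifelse(is.na(hit), -Inf, stats_competitor$z[hit])
    if (anyNA(hit))
      message(sum(is.na(hit)),
              " protein(s) absent from competitor stats; treated as Z = -Inf")
    keep2 <- keep & stats_target$z > z_comp
    prov <- c(prov, list(list(filter = "cross_z", input = sum(keep),
                              kept = sum(keep2))))
    keep <- keep2
  }
  out <- stats_target[keep, , drop = FALSE]
  out <- out[order(-out$z), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("shortlist", "differential_stats", "data.frame")
  attr(out, "provenance") <- prov
  out
}

#' Filter a shortlist for nuclear localization
#'
#' Keeps a protein iff any nuclear annotation flag is true in either the
#' "main" or the "additional" localization columns.  Unannotated proteins
#' are dropped with a warning.
#'
#' @param sl A [shortlist()] (or any `differential_stats` data frame).
#' @param annot Annotation data frame with a `protein` column and logical
#'   category columns.
#' @param nuclear_categories Columns counted as nuclear evidence
#'   (default `c("nuclear_main", "nuclear_additional")`; missing columns
#'   are ignored).
#' @return Filtered object of the same class, with provenance extended.
#' @export
filter_nuclear <- function(sl, annot,
                           nuclear_categories = c("nuclear_main",
                                                  "nuclear_additional")) {
  stopifnot("protein" %in% names(annot))
  cats <- intersect(nuclear_categories, names(annot))
  if (!length(cats)) stop("no nuclear annotation columns found")
  hit <- match(sl$protein, annot$protein)
  if (anyNA(hit))
    warning(sum(is.na(hit)), " unannotated protein(s) dropped")
  flag <- rep(FALSE, nrow(sl))
  found <- !is.na(hit)
  if (any(found)) {
    fm <- as.matrix(annot[hit[found], cats, drop = FALSE])
    fm[is.na(fm)] <- FALSE
    flag[found] <- rowSums(fm) > 0
  }
  prov <- attr(sl, "provenance")
  out <- sl[flag, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(sl)
  attr(out, "provenance") <- c(prov, list(list(filter = "nuclear",
                                               input = nrow(sl),
                                               kept = nrow(out))))
  out
}
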