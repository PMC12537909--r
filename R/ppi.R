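#' Count interaction edges inside a protein set
#'
#' Number of unique unordered protein pairs with both endpoints in the
#' set and confidence score strictly greater than `score_cutoff`.  Edges
#' from sources without scores (`NA` score) are counted when
#' `include_unscored = TRUE` (cutoff ignored for them), matching the use
#' of interaction resources that provide supported pairs rather than
#' confidence scores.
#'
#' @param protein_set Character vector of proteins.
#' @param edges Edge data frame: `protein_a`, `protein_b`, `score`
#'   (may be `NA`), optional `source`.
#' @param score_cutoff Score cutoff in `[0, 1]` (strict `>`).
#' @param include_unscored Whether `NA`-score edges count (default FALSE).
#' @return Integer edge count.
#' @export
count_edges <- function(protein_set, edges, score_cutoff = 0.7,
                        include_unscored = FALSE) {
  stopifnot(score_cutoff >= 0, score_cutoff <= 1)
  if (!length(protein_set) || !nrow(edges)) return(0L)
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  inside <- a %in% protein_set & b %in% protein_set & a != b
  score_ok <- if (is.null(edges$score)) rep(TRUE, nrow(edges)) else
    ifelse(is.na(edges$score), include_unscored, edges$score > score_cutoff)
  keep <- inside & score_ok
  length(unique(paste(a[keep], b[keep], sep = "\r")))
}

#' Null distribution of edge counts over simulated proteomes
#'
#' Repeatedly samples protein sets of the observed size at random
#' (without replacement within each draw, independently across draws)
#' from the background pool - the mass-spec-detectable (nuclear)
#' proteome - and counts interaction edges in each simulated proteome.
#'
#' @param background Character vector: the sampling pool.
#' @param set_size Size of each simulated proteome.
#' @param edges Edge table as in [count_edges()].
#' @param score_cutoff Score cutoff (strict `>`).
#' @param n_samples Number of simulated proteomes (default 100).
#' @param seed Integer seed.
#' @param include_unscored Passed to [count_edges()].
#' @return An object of class `null_distribution`: list with `counts`,
#'   `set_size`, `n_samples`, `cutoff`, `seed`.
#' @export
sample_null <- function(background, set_size, edges, score_cutoff = 0.7,
                        n_samples = 100, seed = 1,
                        include_unscored = FALSE) {
  if (set_size > length(background))
    stop("set_size exceeds the background pool")
  set.seed(derive_seed(seed, "ppi_null"))
  counts <- vapply(seq_len(n_samples), function(i) {
    count_edges(sample(background, set_size), edges, score_cutoff,
                include_unscored)
  }, integer(1))
  structure(list(counts = counts, set_size = set_size,
                 n_samples = n_samples, cutoff = score_cutoff, seed = seed),
            class = "null_distribution")
}

#' One-sample Wilcoxon signed-rank test
#'
#' Two-sided test of whether values `x` are symmetrically distributed
#' around `mu`.  Differences equal to zero are dropped (standard
#' Wilcoxon convention); absolute differences are ranked with average
#' ranks for ties.  For `n <= 12` non-zero differences the p-value is
#' exact, enumerating all `2^n` sign assignments; otherwise the normal
#' approximation with tie correction is used, without continuity
#' correction.
#'
#' @param x Numeric vector.
#' @param mu Hypothesized center.
#' @param exact_max Largest n for which the exact enumeration is used
#'   (default 12).
#' @return List with `statistic` (V, sum of positive ranks), `p`,
#'   `n` (non-zero differences), `method` ("exact" or "normal").
#' @export
signed_rank_test <- function(x, mu = 0, exact_max = 12) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p = 1, n = 0L, method = "exact"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact distribution of V over all 2^n equiprobable sign assignments
    vals <- 0
    for (ri in r) vals <- c(vals, vals + ri)
    ev <- sum(r) / 2
    p <- min(1, 2 * min(mean(vals <= v + 1e-9), mean(vals >= v - 1e-9)))
    list(statistic = v, p = p, n = n, method = "exact")
  } else {
    mu_v <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) return(list(statistic = v, p = 1, n = n,
                                 method = "normal"))
    z <- (v - mu_v) / sqrt(sigma2)
    list(statistic = v, p = min(1, 2 * stats::pnorm(-abs(z))), n = n,
         method = "normal")
  }
}

#' Interaction enrichment of an observed proteome against its null
#'
#' Compares the observed edge count with the simulated-proteome null:
#' fold enrichment is observed over the null median, and the two-sided
#' p-value is a one-sample Wilcoxon signed-rank test of the null counts
#' against the observed value (see [signed_rank_test()]).
#'
#' @param observed Observed edge count.
#' @param null A [sample_null()] result.
#' @return An object of class `enrichment_result`: list with `observed`,
#'   `null_median`, `fold` (`NA` and `fold_defined = FALSE` when the null
#'   median is zero), `p`, `cutoff`, `n_samples`.
#' @export
enrichment_test <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  med <- stats::median(null$counts)
  fold_defined <- med > 0
  sr <- signed_rank_test(null$counts, mu = observed)
  structure(list(observed = observed, null_median = med,
                 fold = if (fold_defined) observed / med else NA_real_,
                 fold_defined = fold_defined, p = sr$p,
                 statistic = sr$statistic, method = sr$method,
                 cutoff = null$cutoff, n_samples = null$n_samples),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: %d observed edges vs null median %.1f (cutoff > %s)\n  fold = %s, two-sided signed-rank P = %.3g (%s, n = %d)\n",
    x$observed, x$null_median, format(x$cutoff),
    if (x$fold_defined) sprintf("%.2f", x$fold) else "undefined",
    x$p, x$method, x$n_samples))
  invisible(x)
}

#' Combined two-source interaction network for a protein set
#'
#' Builds the union network of a protein set across several interaction
#' resources: for score-bearing sources, edges above the source's cutoff
#' are kept; for unscored sources, all supported pairs are kept.  A pair
#' supported by two sources yields one node pair with two tagged links.
#' Isolated proteins are omitted; node degree is the number of distinct
#' interaction partners in the union.
#'
#' @param protein_set Character vector of proteins.
#' @param edge_tables Named list of edge data frames (`protein_a`,
#'   `protein_b`, `score`, `source`); names are used as source tags when
#'   a table lacks a `source` column.
#' @param cutoffs Named numeric vector of score cutoffs per source;
#'   sources not named (or `NA`) are treated as unscored and kept whole.
#' @param category_flags Optional annotation data frame (`protein` +
#'   logical columns) merged onto the nodes.
#' @return An object of class `network_view`: list with `nodes`
#'   (`protein`, `degree`, categories) and `edges` (`protein_a`,
#'   `protein_b`, `score`, `source`).
#' @export
build_combined_network <- function(protein_set, edge_tables, cutoffs = NULL,
                                   category_flags = NULL) {
  if (is.data.frame(edge_tables)) edge_tables <- list(edges = edge_tables)
  all_edges <- list()
  for (nm in names(edge_tables)) {
    et <- edge_tables[[nm]]
    if (!nrow(et)) next
    src <- if (!is.null(et$source)) et$source else nm
    a <- pmin(et$protein_a, et$protein_b)
    b <- pmax(et$protein_a, et$protein_b)
    score <- if (!is.null(et$score)) et$score else NA_real_
    cut <- if (!is.null(cutoffs) && nm %in% names(cutoffs)) cutoffs[[nm]] else NA_real_
    keep <- a %in% protein_set & b %in% protein_set & a != b
    if (!is.na(cut)) keep <- keep & !is.na(score) & score > cut
    df <- data.frame(protein_a = a[keep], protein_b = b[keep],
                     score = rep_len(score, length(a))[keep],
                     source = rep_len(src, length(a))[keep])
    df <- df[!duplicated(df[, c("protein_a", "protein_b", "source")]), ]
    all_edges[[nm]] <- df
  }
  edges <- do.call(rbind, all_edges)
  if (is.null(edges) || !nrow(edges)) {
    return(structure(list(nodes = data.frame(protein = character(),
                                             degree = integer()),
                          edges = data.frame(protein_a = character(),
                                             protein_b = character(),
                                             score = numeric(),
                                             source = character())),
                     class = "network_view"))
  }
  rownames(edges) <- NULL
  pairs <- unique(edges[, c("protein_a", "protein_b")])
  nodes <- sort(unique(c(pairs$protein_a, pairs$protein_b)))
  degree <- vapply(nodes, function(p) {
    length(unique(c(pairs$protein_b[pairs$protein_a == p],
                    pairs$protein_a[pairs$protein_b == p])))
  }, integer(1))
  nd <- data.frame(protein = nodes, degree = unname(degree))
  if (!is.null(category_flags)) {
    hit <- match(nd$protein, category_flags$protein)
    for (cc in setdiff(names(category_flags), "protein"))
      nd[[cc]] <- category_flags[[cc]][hit]
  }
  structure(list(nodes = nd, edges = edges), class = "network_view")
}

#' Export a network view as GraphML
#'
#' @param view A [build_combined_network()] result.
#' @param path Output path.
#' @export
write_network_graphml <- function(view, path) {
  g <- igraph::graph_from_data_frame(view$edges, directed = FALSE,
                                     vertices = view$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
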