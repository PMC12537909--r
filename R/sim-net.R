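#' Configuration for the synthetic scored interaction network generator
#'
#' Community-structured random graph: proteins are partitioned into
#' modules; within-module pairs receive edges with probability `p_within`
#' and higher confidence scores, between-module pairs with `p_between`
#' and lower scores.  Scores live on `[0, 1]` (Beta-distributed around the
#' stated means), mimicking STRING-style confidence scores.
#'
#' @param n_proteins Number of proteins.
#' @param n_modules Number of modules (communities).
#' @param p_within,p_between Edge probabilities (`p_within >= p_between`).
#' @param score_within_mean,score_between_mean Mean edge scores on
#'   `[0, 1]` for the two pair types (defaults 0.8 and 0.4).
#' @param score_concentration Beta concentration of the score
#'   distributions (default 10).
#' @param source Source tag attached to every edge (default
#'   `"string-like"`).
#' @param seed Integer seed.
#' @return An object of class `net_sim_config`.
#' @export
net_sim_config <- function(n_proteins = 500, n_modules = 5,
                           p_within = 0.2, p_between = 0.01,
                           score_within_mean = 0.8, score_between_mean = 0.4,
                           score_concentration = 10,
                           source = "string-like", seed = 1) {
  if (p_within < 0 || p_within > 1 || p_between < 0 || p_between > 1)
    stop("edge probabilities must lie in [0, 1]")
  if (p_within < p_between) stop("p_within must be >= p_between")
  if (score_within_mean < 0 || score_within_mean > 1 ||
      score_between_mean < 0 || score_between_mean > 1)
    stop("score means must lie in [0, 1]")
  stopifnot(n_proteins >= 2, n_modules >= 1)
  structure(list(n_proteins = n_proteins, n_modules = n_modules,
                 p_within = p_within, p_between = p_between,
                 score_within_mean = score_within_mean,
                 score_between_mean = score_between_mean,
                 score_concentration = score_concentration,
                 source = source, seed = seed),
            class = "net_sim_config")
}

#' Generate a community-structured scored protein-interaction network
#'
#' @param cfg A [net_sim_config()].
#' @return List with `edges` (data frame `protein_a`, `protein_b`,
#'   `score`, `source`; undirected, `protein_a < protein_b`, no
#'   self-edges, no duplicate pairs) and `truth` (list with
#'   `module_assignment` named by protein and the config).
#' @export
generate_ppi_network <- function(cfg) {
  stopifnot(inherits(cfg, "net_sim_config"))
  set.seed(derive_seed(cfg$seed, "net_sim"))
  proteins <- sprintf("N%05d", seq_len(cfg$n_proteins))
  modules <- sample(rep_len(seq_len(cfg$n_modules), cfg$n_proteins))
  names(modules) <- proteins

  idx <- utils::combn(cfg$n_proteins, 2L)
  same <- modules[idx[1, ]] == modules[idx[2, ]]
  p <- ifelse(same, cfg$p_within, cfg$p_between)
  keep <- stats::runif(ncol(idx)) < p
  mean_s <- ifelse(same[keep], cfg$score_within_mean, cfg$score_between_mean)
  kk <- cfg$score_concentration
  score <- stats::rbeta(sum(keep), mean_s * kk, (1 - mean_s) * kk)
  edges <- data.frame(protein_a = proteins[idx[1, keep]],
                      protein_b = proteins[idx[2, keep]],
                      score = score,
                      source = rep_len(cfg$source, sum(keep)))
  list(edges = edges,
       truth = list(module_assignment = modules, config = cfg))
}
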