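#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by hypergeometric point-probability summation: with
#' margins fixed, every table at least as unlikely as the observed one
#' (point probability less than or equal to the observed probability,
#' within a small relative tolerance) contributes to p - the standard
#' minimum-likelihood two-sided rule.  The odds ratio is the conditional
#' maximum-likelihood estimate under the noncentral hypergeometric
#' model, obtained by solving `E_psi[A] = a`.
#'
#' @param a,b,c,d Cell counts of the 2x2 table (rows: in set / out of
#'   set; columns: in category / out of category).
#' @return List with `p`, `odds_ratio` (0 or `Inf` at the support
#'   boundary), and the `table`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n_set <- a + b          # first-row margin
  k_cat <- a + c          # first-column margin
  n_tot <- a + b + c + d
  if (n_tot == 0) return(list(p = 1, odds_ratio = NA_real_,
                              table = matrix(c(a, c, b, d), 2)))
  lo <- max(0L, n_set - (n_tot - k_cat))
  hi <- min(n_set, k_cat)
  supp <- lo:hi
  probs <- stats::dhyper(supp, k_cat, n_tot - k_cat, n_set)
  p_obs <- stats::dhyper(a, k_cat, n_tot - k_cat, n_set)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))

  or <- if (hi == lo) {
    NA_real_                      # degenerate margin: OR not identifiable
  } else if (a == lo) {
    0
  } else if (a == hi) {
    Inf
  } else {
    lw0 <- stats::dhyper(supp, k_cat, n_tot - k_cat, n_set, log = TRUE)
    cond_mean <- function(logpsi) {
      lw <- lw0 + supp * logpsi
      w <- exp(lw - max(lw))
      sum(supp * w) / sum(w)
    }
    f <- function(logpsi) cond_mean(logpsi) - a
    exp(stats::uniroot(f, c(-50, 50), tol = 1e-10)$root)
  }
  list(p = p, odds_ratio = or,
       table = matrix(c(a, c, b, d), 2,
                      dimnames = list(set = c("in", "out"),
                                      category = c("in", "out"))))
}

#' Annotation-category enrichment of a protein set (Fisher's exact test)
#'
#' Tests whether a protein set overlaps an annotation category more than
#' expected, against an explicit background universe.  The background
#' must be supplied and is typically the mass-spec-detectable (and,
#' where applicable, nuclear) protein pool - testing against the whole
#' annotation universe silently inflates enrichment and is refused by
#' design.
#'
#' @param protein_set Character vector, must be a subset of `background`.
#' @param category Character vector of category members; entries outside
#'   the background are ignored.
#' @param background Character vector: the universe.
#' @return An object of class `overlap_result`: list with the 2x2
#'   `counts` (`set_cat`, `set_only`, `cat_only`, `neither`),
#'   `odds_ratio`, `p`, `background_size`, `degenerate` flag (empty set
#'   or empty category).
#' @export
fisher_overlap <- function(protein_set, category, background) {
  protein_set <- unique(protein_set)
  background <- unique(background)
  bad <- setdiff(protein_set, background)
  if (length(bad))
    stop("protein set not contained in background: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "")
  category <- intersect(unique(category), background)
  a <- length(intersect(protein_set, category))
  b <- length(protein_set) - a
  c <- length(category) - a
  d <- length(background) - a - b - c
  ft <- fisher_exact_2x2(a, b, c, d)
  structure(list(counts = c(set_cat = a, set_only = b, cat_only = c,
                            neither = d),
                 odds_ratio = ft$odds_ratio, p = ft$p,
                 background_size = length(background),
                 degenerate = length(protein_set) == 0 ||
                   length(category) == 0),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap_result: %d/%d set proteins in category (%d of %d background)\n  odds ratio = %s, two-sided Fisher P = %.3g%s\n",
    x$counts["set_cat"], x$counts["set_cat"] + x$counts["set_only"],
    x$counts["set_cat"] + x$counts["cat_only"], x$background_size,
    format(x$odds_ratio, digits = 3), x$p,
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Venn overlap of two protein sets with a Fisher significance test
#'
#' Reports the four Venn region counts of two sets within a background
#' and the [fisher_overlap()] result of set A against membership in set
#' B (the association test behind "significant overlap" Venn diagrams).
#'
#' @param set_a,set_b Character vectors, subsets of `background`.
#' @param background Character vector: the universe.
#' @return An `overlap_result` with an extra `regions` element
#'   (`both`, `a_only`, `b_only`, `neither`).
#' @export
venn_overlap <- function(set_a, set_b, background) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  background <- unique(background)
  for (s in list(set_a, set_b)) {
    bad <- setdiff(s, background)
    if (length(bad))
      stop("set not contained in background: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  res <- fisher_overlap(set_a, set_b, background)
  res$regions <- c(both = length(intersect(set_a, set_b)),
                   a_only = length(setdiff(set_a, set_b)),
                   b_only = length(setdiff(set_b, set_a)),
                   neither = length(background) -
                     length(union(set_a, set_b)))
  res
}
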