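#' Inverse of the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration; used when
#' moment-matching the prior degrees of freedom of the variance model.
#'
#' @param y Positive numeric vector.
#' @return Numeric vector `x` with `trigamma(x) = y`.
#' @keywords internal
trigamma_inverse <- function(y) {
  out <- numeric(length(y))
  for (i in seq_along(y)) {
    yy <- y[i]
    if (!is.finite(yy) || yy <= 0) { out[i] <- Inf; next }
    if (yy > 1e7) { out[i] <- 1 / sqrt(yy); next }
    if (yy < 1e-6) { out[i] <- 1 / yy; next }
    x <- 0.5 + 1 / yy
    for (it in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    out[i] <- x
  }
  out
}

#' Empirical-Bayes hyperparameters of the variance prior
#'
#' Fits the scaled-F model underlying variance moderation: per-protein
#' sample variances are assumed to follow `s0_sq * chisq_d0 / d0` times a
#' chi-square with the residual degrees of freedom, and the prior
#' `(d0, s0_sq)` is estimated by moment-matching the distribution of
#' `log(s^2)` (mean and variance of the log variances, corrected by
#' digamma/trigamma terms).  When the observed log-variance dispersion
#' does not exceed what the residual degrees of freedom alone explain,
#' `d0` is flagged infinite and `s0_sq` is the mean variance.
#'
#' @param variances Per-protein sample variances (length >= 3).
#' @param dfs Residual degrees of freedom per protein (scalar or vector).
#' @return An object of class `moderation_params`: list with `d0`,
#'   `s0_sq`, and logical `degenerate` (all variances zero).
#' @export
fit_moderation <- function(variances, dfs) {
  dfs <- rep_len(dfs, length(variances))
  ok <- dfs > 0 & is.finite(variances) & variances >= 0
  if (sum(ok) < 3)
    stop("need at least 3 proteins with positive degrees of freedom")
  v <- variances[ok]
  d <- dfs[ok]
  if (all(v == 0)) {
    return(structure(list(d0 = Inf, s0_sq = 0, degenerate = TRUE),
                     class = "moderation_params"))
  }
  if (max(v) - min(v) <= 1e-12 * max(v)) {
    return(structure(list(d0 = Inf, s0_sq = mean(v), degenerate = FALSE),
                     class = "moderation_params"))
  }
  pos <- v > 0
  e <- log(v[pos]) - digamma(d[pos] / 2) + log(d[pos] / 2)
  evar <- stats::var(e) - mean(trigamma(d[pos] / 2))
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s0_sq <- mean(v)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, degenerate = FALSE),
            class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat(sprintf("moderation_params: d0 = %s, s0_sq = %.4g%s\n",
              format(x$d0), x$s0_sq,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Moderated two-sample t statistics between two conditions
#'
#' For each protein, computes the log2 fold change `meanA - meanB`, the
#' pooled within-group variance with `d = nA + nB - 2` degrees of
#' freedom, the posterior (moderated) variance
#' `s2_post = (d0 * s0_sq + d * s2) / (d0 + d)`, the moderated t
#' statistic `t = log2fc / (s_post * sqrt(1/nA + 1/nB))`, and the
#' two-sided p-value on `d0 + d` degrees of freedom.  With `d0 = 0` this
#' is the ordinary pooled two-sample t test; p-values are deliberately
#' NOT adjusted for multiple testing, matching the shortlisting
#' convention.
#'
#' @param tbl A complete (post-imputation) [intensity_table()].
#' @param cond_a,cond_b Condition labels; the fold change is A minus B.
#' @param params A [fit_moderation()] result (or list with `d0`,
#'   `s0_sq`).
#' @return A `differential_stats` data frame: `protein`, `log2fc`, `t`,
#'   `df`, `p`, `z` (`z` is `NA` until [pvalue_z()] is applied).
#' @export
moderated_t <- function(tbl, cond_a, cond_b, params) {
  stopifnot(inherits(tbl, "intensity_table"))
  if (anyNA(tbl$intensity))
    stop("intensity table contains unimputed missing cells")
  cols_a <- tbl$design$sample[tbl$design$condition == cond_a]
  cols_b <- tbl$design$sample[tbl$design$condition == cond_b]
  if (length(cols_a) < 2 || length(cols_b) < 2)
    stop("both conditions need at least 2 replicates")
  a <- tbl$intensity[, cols_a, drop = FALSE]
  b <- tbl$intensity[, cols_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  fc <- rowMeans(a) - rowMeans(b)
  s2 <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) /
    (na + nb - 2)
  d <- na + nb - 2
  d0 <- params$d0
  s0 <- params$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + d * s2) / (d0 + d)
  tt <- fc / sqrt(s2_post * (1 / na + 1 / nb))
  df_tot <- d0 + d
  p <- 2 * stats::pt(-abs(tt), df = df_tot)
  p[fc == 0] <- 1
  out <- data.frame(protein = rownames(tbl$intensity), log2fc = fc,
                    t = tt, df = df_tot, p = p, z = NA_real_,
                    row.names = NULL)
  class(out) <- c("differential_stats", "data.frame")
  out
}

#' P-value-based Z-score
#'
#' Fills the `z` column of a differential-stats table with the signed
#' normal quantile of the unadjusted two-sided p-value:
#' `Z = qnorm(1 - p/2) * sign(log2fc)`.  For a fixed sign, Z is monotone
#' decreasing in p; `p = 1` gives `Z = 0`.  Zero p-values are clipped to
#' the smallest representable positive double (with a message).
#'
#' @param stats A `differential_stats` data frame from [moderated_t()].
#' @return The same data frame with `z` filled.
#' @export
pvalue_z <- function(stats) {
  stopifnot(all(c("p", "log2fc") %in% names(stats)))
  p <- stats$p
  if (any(p <= 0)) {
    message(sum(p <= 0), " zero p-value(s) clipped")
    p[p <= 0] <- .Machine$double.xmin
  }
  stats$z <- stats::qnorm(p / 2, lower.tail = FALSE) * sign(stats$log2fc)
  stats
}
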