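# Shared fixture builders; everything is generated in code at test time.

# Small LFQ dataset for filter/statistics tests.
small_lfq <- function(seed = 1, ...) {
  generate_lfq_dataset(lfq_sim_config(n_background = 300,
                                      n_spiked_per_condition = 15,
                                      effect_log2fc = 2, seed = seed, ...))
}

# Complete (no-missing) intensity table built directly from a matrix.
complete_table <- function(m, n_rep = 3, conds = c("target1", "control")) {
  design <- data.frame(
    sample = paste0(rep(conds, each = n_rep), "_rep",
                    rep(seq_len(n_rep), length(conds))),
    condition = rep(conds, each = n_rep),
    replicate = rep(seq_len(n_rep), length(conds)))
  colnames(m) <- design$sample
  if (is.null(rownames(m))) rownames(m) <- sprintf("P%04d", seq_len(nrow(m)))
  intensity_table(m, design)
}

# Spectral-count table from explicit presence / count patterns.
counts_from_pattern <- function(proteins, pattern) {
  # pattern: list per protein of integer counts across controls
  m <- do.call(rbind, pattern)
  data.frame(protein = proteins, keratin = FALSE, m)
}

# Deterministic spot table in micrometres.
spot_df <- function(z, y, x, intensity = 1, isolated = TRUE) {
  data.frame(spot = seq_along(z), z = z, y = y, x = x,
             z_um = z, y_um = y, x_um = x,
             intensity = intensity, isolated = isolated, channel = "fish")
}

# Wobbly-ellipse nucleus masks for partition property sweeps.
random_blob_mask <- function(seed, n = 96) {
  set.seed(seed)
  cy <- n / 2 + stats::runif(1, -5, 5)
  cx <- n / 2 + stats::runif(1, -5, 5)
  r0 <- stats::runif(1, n / 5, n / 3.2)
  a1 <- stats::runif(1, 0, 0.25); ph1 <- stats::runif(1, 0, 2 * pi)
  a2 <- stats::runif(1, 0, 0.15); ph2 <- stats::runif(1, 0, 2 * pi)
  yy <- matrix(rep(seq_len(n), n), n)
  xx <- t(yy)
  th <- atan2(yy - cy, xx - cx)
  rr <- sqrt((yy - cy)^2 + (xx - cx)^2)
  rad <- r0 * (1 + a1 * sin(3 * th + ph1) + a2 * sin(5 * th + ph2))
  rr <= rad
}
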