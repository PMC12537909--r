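test_that("null design carries no true effects", {
  sim <- generate_lfq_dataset(lfq_sim_config(n_background = 50,
                                             n_spiked_per_condition = 0,
                                             seed = 3))
  expect_equal(nrow(sim$truth$spiked), 0L)
  expect_equal(nrow(sim$table$intensity), 50L)
})

test_that("degenerate MNAR settings produce a complete table", {
  sim <- generate_lfq_dataset(lfq_sim_config(n_background = 80,
                                             n_spiked_per_condition = 5,
                                             missing_slope = 0,
                                             missing_midpoint = -Inf,
                                             seed = 2))
  expect_false(anyNA(sim$table$intensity))
})

test_that("the generator is deterministic given seed and config", {
  a <- generate_lfq_dataset(lfq_sim_config(n_background = 60, seed = 11))
  b <- generate_lfq_dataset(lfq_sim_config(n_background = 60, seed = 11))
  expect_identical(a, b)
  c <- generate_lfq_dataset(lfq_sim_config(n_background = 60, seed = 12))
  expect_false(identical(a$table$intensity, c$table$intensity))
})

test_that("design, spike shift and contaminants match the configuration", {
  cfg <- lfq_sim_config(n_background = 400, n_spiked_per_condition = 30,
                        effect_log2fc = 2, n_conditions = 3,
                        missing_midpoint = -Inf, seed = 5)
  sim <- generate_lfq_dataset(cfg)
  expect_equal(ncol(sim$table$intensity), 3 * 3)
  expect_equal(nrow(sim$table$intensity), 400 + 2 * 30)
  expect_true(all(sim$truth$spiked$protein %in%
                    rownames(sim$table$intensity)))
  # spiked proteins shifted by ~effect in their own condition
  sp <- sim$truth$spiked[sim$truth$spiked$condition == "target1", ]
  cols_t <- sim$table$design$sample[sim$table$design$condition == "target1"]
  cols_c <- sim$table$design$sample[sim$table$design$condition == "control"]
  shift <- rowMeans(sim$table$intensity[sp$protein, cols_t]) -
    rowMeans(sim$table$intensity[sp$protein, cols_c])
  expect_equal(mean(shift), 2, tolerance = 0.15)
  # contaminant truth gives the CRAPome filter true positives
  expect_gt(length(sim$truth$contaminants), 0)
  kept <- suppressMessages(crapome_filter(rownames(sim$table$intensity),
                                          sim$counts))
  # recurrent contaminants are mostly caught (presence is binomial over
  # a finite number of controls), keratins always
  expect_gte(mean(sim$truth$contaminants %in% attr(kept, "removed")), 0.85)
  expect_true(all(sim$truth$keratins %in% attr(kept, "removed")))
  expect_false(any(sim$truth$spiked$protein %in% attr(kept, "removed")))
})

test_that("missingness is non-increasing across latent intensity deciles", {
  sim <- generate_lfq_dataset(lfq_sim_config(n_background = 3000,
                                             n_spiked_per_condition = 0,
                                             missing_slope = 1.5,
                                             missing_midpoint = 23,
                                             seed = 8))
  dec <- cut(sim$truth$baseline,
             stats::quantile(sim$truth$baseline, 0:10 / 10),
             include.lowest = TRUE, labels = FALSE)
  rate <- tapply(rowMeans(is.na(sim$table$intensity)), dec, mean)
  expect_true(all(diff(rate) <= 0.02))  # monotone up to decile noise
  expect_lt(rate[10], rate[1])
})

test_that("annotation flags honor fractions, bounds and determinism", {
  prot <- sprintf("P%04d", 1:1000)
  a0 <- generate_annotation_table(prot, c(nuclear_main = 0), seed = 1)
  expect_false(any(a0$nuclear_main))
  a1 <- generate_annotation_table(prot, c(nuclear_main = 1), seed = 1)
  expect_true(all(a1$nuclear_main))
  a3 <- generate_annotation_table(prot, c(cat = 0.3), seed = 4)
  expect_gte(sum(a3$cat), qbinom(0.005, 1000, 0.3))
  expect_lte(sum(a3$cat), qbinom(0.995, 1000, 0.3))
  expect_identical(a3, generate_annotation_table(prot, c(cat = 0.3), seed = 4))
  expect_error(generate_annotation_table(prot, 0.3), "named")
  expect_error(generate_annotation_table(prot, c(cat = 1.2)), "\\[0, 1\\]")
})

test_that("intensity tables round-trip through TSV with design sidecar", {
  sim <- small_lfq(seed = 21)
  path <- tempfile(fileext = ".tsv")
  write_intensity_tsv(sim$table, path)
  back <- read_intensity_tsv(path)
  expect_equal(back$intensity, sim$table$intensity, tolerance = 1e-12)
  expect_equal(back$design$condition, sim$table$design$condition)
  unlink(c(path, paste0(path, ".design.tsv")))
})
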