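# One halo-positive focus in the stack center.
halo_stack <- function(k, noise_sd = 0, seed = 1, amplitude = 50) {
  foci <- data.frame(z = 8, y = 48, x = 48, count = 3, channel = "fish",
                     halo = TRUE)
  generate_image_stack(image_sim_config(stack_shape = c(16, 96, 96),
                                        foci_spec = foci,
                                        halo_decay_rate = k,
                                        halo_amplitude = amplitude,
                                        noise_sd = noise_sd, seed = seed))
}

test_that("the decay rate of a noiseless halo is recovered within 5%", {
  k0 <- 5
  out <- halo_stack(k0)
  start <- c(8 * 0.22, 48 * 0.065, 48 * 0.065)
  fit <- line_profile_decay(out$stack, start, c(0, 0, 1), length_um = 1.5)
  expect_true(fit$converged)
  expect_lt(abs(fit$k - k0) / k0, 0.05)
})

test_that("profiles are max-normalized per channel", {
  out <- halo_stack(4)
  start <- c(8 * 0.22, 48 * 0.065, 48 * 0.065)
  fit <- line_profile_decay(out$stack, start, c(0, 1, 1), length_um = 1.2)
  expect_equal(unname(apply(fit$profile, 2, max)), c(1, 1))
  expect_true(all(fit$profile >= 0 & fit$profile <= 1))
})

test_that("constant profiles are flagged as degenerate", {
  stk <- image_stack(array(3, c(8, 40, 40, 2)), c(0.22, 0.065, 0.065),
                     c("fish", "biotin"))
  fit <- line_profile_decay(stk, c(0.9, 1.3, 0.2), c(0, 0, 1),
                            length_um = 1.5)
  expect_false(fit$converged)
  expect_true(is.na(fit$k))
})

test_that("lines leaving the volume are refused", {
  out <- halo_stack(4)
  expect_error(line_profile_decay(out$stack, c(8 * 0.22, 3, 6),
                                  c(0, 0, 1), length_um = 5), "volume")
})

test_that("fitted rates order correctly for distinct halo decay rates", {
  ok <- 0
  for (s in 1:20) {
    f1 <- halo_stack(6, noise_sd = 0.5, seed = s)
    f2 <- halo_stack(3, noise_sd = 0.5, seed = s + 1000)
    start <- c(8 * 0.22, 48 * 0.065, 48 * 0.065)
    k1 <- line_profile_decay(f1$stack, start, c(0, 0, 1))$k
    k2 <- line_profile_decay(f2$stack, start, c(0, 0, 1))$k
    if (is.finite(k1) && is.finite(k2) && k1 > k2) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("near-focus intensity separates enriched from control foci", {
  # "if" channel carries halos only at group-1 foci
  pos <- expand.grid(y = seq(12, 84, by = 24), x = seq(12, 84, by = 24))
  n <- nrow(pos)
  foci <- data.frame(z = 8, y = pos$y, x = pos$x, count = 1,
                     channel = "fish",
                     halo = rep(c(TRUE, FALSE), length.out = n))
  out <- generate_image_stack(image_sim_config(
    stack_shape = c(16, 96, 96), foci_spec = foci,
    channels = c("fish", "if"), halo_channel = "if",
    halo_decay_rate = 4, halo_amplitude = 30, noise_sd = 0.5, seed = 3))
  ft <- out$truth$focus_truth
  ft$group <- ifelse(ft$halo, "HRE+", "HRE-")
  res <- intensity_near_focus(out$stack, "if", ft, radius_um = 0.3)
  expect_gt(res$group_means["HRE+"], res$group_means["HRE-"])
  expect_lt(res$p, 0.05)
  # uniform image: equal means, p ~ 1
  stk <- image_stack(array(2, c(16, 96, 96, 1)), c(0.22, 0.065, 0.065),
                     "if")
  res_u <- intensity_near_focus(stk, "if", ft, radius_um = 0.3)
  expect_equal(unname(diff(res_u$group_means)), 0)
  expect_equal(res_u$p, 1)
  ft$group <- "one"
  expect_error(intensity_near_focus(out$stack, "if", ft, 0.3), "two groups")
})

test_that("labeling efficiency counts biotin-positive foci", {
  pos <- expand.grid(y = c(24, 72), x = seq(10, 90, by = 20))
  halo <- rep(c(TRUE, FALSE), c(7, 3))
  foci <- data.frame(z = 8, y = pos$y, x = pos$x, count = 1,
                     channel = "fish", halo = halo)
  out <- generate_image_stack(image_sim_config(
    stack_shape = c(16, 96, 96), foci_spec = foci,
    halo_decay_rate = 5, halo_amplitude = 50, noise_sd = 0.3, seed = 8))
  ft <- label_foci(out$stack, out$truth$focus_truth, radius_um = 0.2,
                   threshold = 5)
  eff <- labeling_efficiency(ft)
  expect_equal(eff$fraction, 0.7)
  expect_equal(eff$n_labeled, 7L)
  expect_length(eff$labeled_intensity, 7L)
  # degenerate edges
  all_lab <- data.frame(labeled = c(TRUE, TRUE))
  expect_equal(labeling_efficiency(all_lab)$fraction, 1)
  none <- data.frame(labeled = logical(0))
  expect_warning(res0 <- labeling_efficiency(none), "undefined")
  expect_false(res0$defined)
})

test_that("apparent efficiency is a guarded ratio of percentages", {
  expect_equal(apparent_efficiency(40, 80)$ratio, 0.5)
  expect_equal(apparent_efficiency(50, 50)$ratio, 1)
  res <- apparent_efficiency(60, 50)
  expect_equal(res$ratio, 1.2)
  expect_true(res$over_unity)
  expect_error(apparent_efficiency(10, 0), "positive")
})
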