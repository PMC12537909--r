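# Stack with isolated single molecules on a grid, for detection tests.
calibration_stack <- function(seed = 1, noise_sd = 0, cv = 0,
                              counts = rep(1, 9)) {
  pos <- expand.grid(y = c(20, 45, 70), x = c(20, 45, 70))
  foci <- data.frame(z = 8, y = pos$y, x = pos$x,
                     count = counts, channel = "fish")
  generate_image_stack(image_sim_config(stack_shape = c(16, 90, 90),
                                        foci_spec = foci,
                                        unit_intensity_cv = cv,
                                        noise_sd = noise_sd,
                                        halo_on = FALSE, seed = seed))
}

test_that("a zero image yields no spots", {
  stk <- image_stack(array(0, c(6, 20, 20, 1)), c(0.22, 0.065, 0.065),
                     "fish")
  expect_equal(nrow(detect_spots(stk, "fish")), 0L)
})

test_that("well-separated molecules are recovered with sub-voxel accuracy", {
  out <- calibration_stack(seed = 2, noise_sd = 0.5, cv = 0.2)
  spots <- detect_spots(out$stack, "fish", threshold = 0.2)
  truth <- out$truth$focus_truth
  expect_gte(nrow(spots), ceiling(0.95 * nrow(truth)))
  D <- as.matrix(dist(rbind(as.matrix(truth[, c("z", "y", "x")]),
                            as.matrix(spots[, c("z", "y", "x")]))))
  D <- D[seq_len(nrow(truth)), nrow(truth) + seq_len(nrow(spots)),
         drop = FALSE]
  nearest <- apply(D, 1, min)
  expect_true(all(nearest < 1))     # positional error below one voxel
})

test_that("rescaling intensities does not move detections", {
  out <- calibration_stack(seed = 3)
  s1 <- detect_spots(out$stack, "fish", threshold = 0.2)
  doubled <- image_stack(unclass(out$stack) * 2,
                         attr(out$stack, "voxel_size"),
                         attr(out$stack, "channels"))
  s2 <- detect_spots(doubled, "fish", threshold = 0.2)
  expect_equal(s1[, c("z", "y", "x")], s2[, c("z", "y", "x")])
  expect_equal(s2$intensity, 2 * s1$intensity, tolerance = 1e-9)
})

test_that("calibration returns the median of isolated spots", {
  sp <- spot_df(z = seq(0, 10, length.out = 12) * 5,
                y = seq_len(12) * 5, x = seq_len(12) * 5, intensity = 7)
  expect_equal(calibrate_unit_intensity(sp), 7)
  expect_error(calibrate_unit_intensity(sp[1:5, ]), "at least 10")
  # lognormal intensities: sample median near the distribution median
  set.seed(4)
  v <- rlnorm(200, log(500), 0.2)
  sp2 <- spot_df(z = runif(200, 0, 100), y = runif(200, 0, 100),
                 x = runif(200, 0, 100), intensity = v)
  expect_lt(abs(calibrate_unit_intensity(sp2) - 500) / 500, 0.05)
})

test_that("decomposition rounds the intensity ratio with a floor of one", {
  expect_equal(decompose_focus(100, 100), 1L)
  expect_equal(decompose_focus(40, 100), 1L)
  expect_equal(decompose_focus(c(590, 610, 951), 100), c(6L, 6L, 10L))
  expect_error(decompose_focus(0, 100), "positive")
  expect_error(decompose_focus(100, 0), "reference")
})

test_that("single-linkage focus grouping merges chains within radius", {
  # chain a-b-c with consecutive gaps < radius, ends > radius apart
  sp <- spot_df(z = c(0, 0, 0), y = c(0, 0.4, 0.8), x = c(0, 0, 0))
  foci <- cluster_foci(sp, radius = 0.5)
  expect_equal(nrow(foci), 1L)
  expect_equal(foci$n_spots, 3L)
  # brute-force transitive closure oracle on a random instance
  set.seed(11)
  sp2 <- spot_df(z = runif(20, 0, 2), y = runif(20, 0, 2),
                 x = runif(20, 0, 2))
  r <- 0.35
  foci2 <- cluster_foci(sp2, radius = r)
  D <- as.matrix(dist(sp2[, c("z_um", "y_um", "x_um")]))
  adj <- D <= r
  reach <- adj
  for (k in 1:20) reach <- reach | (reach %*% adj > 0)
  oracle_groups <- match(apply(reach, 1, function(row)
    paste(which(row), collapse = ",")),
    unique(apply(reach, 1, function(row)
      paste(which(row), collapse = ","))))
  got <- attr(foci2, "assignment")
  expect_equal(length(unique(got)), length(unique(oracle_groups)))
  expect_true(all(tapply(oracle_groups, got, function(g)
    length(unique(g))) == 1))
})

test_that("two distant molecules form two single foci; empty input is empty", {
  sp <- spot_df(z = c(0, 0), y = c(0, 3), x = c(0, 0))
  foci <- cluster_foci(sp, radius = 0.5)
  expect_equal(nrow(foci), 2L)
  expect_true(all(foci$class == "single"))
  expect_equal(nrow(cluster_foci(sp[0, ], radius = 0.5)), 0L)
  # counts from decomposition drive the cluster class
  sp$count <- c(5L, 1L)
  foci2 <- cluster_foci(sp, radius = 0.5)
  expect_equal(sort(foci2$class), c("cluster", "single"))
})

test_that("mutual-nearest-neighbor matching equals the brute-force oracle", {
  a <- spot_df(z = c(0, 1, 2), y = c(0, 0, 0), x = c(0, 0, 0))
  m <- colocalize(a, a, max_dist = 0.1)
  expect_equal(m$index_a, 1:3)
  expect_equal(m$index_b, 1:3)
  expect_equal(nrow(colocalize(a, a[0, ], 1)), 0L)

  set.seed(21)
  sa <- spot_df(z = runif(15), y = runif(15), x = runif(15))
  sb <- spot_df(z = runif(12), y = runif(12), x = runif(12))
  got <- colocalize(sa, sb, max_dist = 0.3)
  D <- as.matrix(dist(rbind(as.matrix(sa[, c("z_um", "y_um", "x_um")]),
                            as.matrix(sb[, c("z_um", "y_um", "x_um")]))))
  D <- D[1:15, 15 + (1:12)]
  oracle <- do.call(rbind, lapply(1:15, function(i) {
    j <- which.min(D[i, ])
    if (which.min(D[, j]) == i && D[i, j] <= 0.3)
      data.frame(index_a = i, index_b = j) else NULL
  }))
  expect_equal(got$index_a, oracle$index_a)
  expect_equal(got$index_b, oracle$index_b)
  expect_true(!anyDuplicated(got$index_b))
})

test_that("molecule counts are recovered exactly on noiseless foci", {
  out <- calibration_stack(seed = 6, counts = c(1, 1, 1, 1, 2, 3, 6, 9, 1))
  spots <- detect_spots(out$stack, "fish", threshold = 0.05)
  ref <- calibrate_unit_intensity(spots, min_isolated = 4)
  truth <- out$truth$focus_truth
  D <- outer(truth$z, spots$z, "-")^2 + outer(truth$y, spots$y, "-")^2 +
    outer(truth$x, spots$x, "-")^2
  hit <- apply(D, 1, which.min)
  counts <- decompose_focus(spots$intensity[hit], ref)
  expect_equal(counts, truth$count)
})
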