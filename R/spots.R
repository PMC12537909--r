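# --- separable Gaussian filtering on 3-D arrays ------------------------------

# Truncated, edge-renormalized 1-D Gaussian convolution matrix.
gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma))
  idx <- seq_len(n)
  K <- matrix(0, n, n)
  for (i in idx) {
    j <- max(1L, i - half):min(n, i + half)
    w <- stats::dnorm(j - i, sd = sigma)
    K[i, j] <- w / sum(w)
  }
  K
}

# Smooth a 3-D array with an axis-separable Gaussian (sigma in voxels).
gauss_smooth3 <- function(arr, sigma) {
  d <- dim(arr)
  stopifnot(length(d) == 3L, length(sigma) == 3L)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    K <- gauss_kernel_matrix(da[1], sigma[ax])
    a <- array(K %*% matrix(a, da[1]), da)
    arr <- aperm(a, order(perm))
  }
  arr
}

# Logical array of strict 26-neighborhood local maxima.
local_maxima3 <- function(arr) {
  d <- dim(arr)
  res <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    shifted <- array(-Inf, d)
    z1 <- max(1, 1 + dz):min(d[1], d[1] + dz)
    y1 <- max(1, 1 + dy):min(d[2], d[2] + dy)
    x1 <- max(1, 1 + dx):min(d[3], d[3] + dx)
    shifted[z1, y1, x1] <- arr[z1 - dz, y1 - dy, x1 - dx]
    res <- res & (arr > shifted | (arr == shifted &
                                     (dz < 0 | (dz == 0 & dy < 0) |
                                        (dz == 0 & dy == 0 & dx < 0))))
  }
  res
}

#' Detect diffraction-limited spots in one channel of a stack
#'
#' Difference-of-Gaussians band-pass response at the PSF scale, strict
#' local maxima above a threshold set relative to the maximum response
#' (so globally rescaling the image does not move detections), sub-voxel
#' refinement by background-subtracted intensity-weighted centroid, and
#' integrated intensity over a local window after subtracting the median
#' of the window shell.  A spot is flagged isolated when no other
#' detection lies within twice the PSF sigma along every axis -
#' isolated spots serve as single-molecule intensity standards.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name to analyze.
#' @param sigma PSF sigma in voxels per axis (default `c(1.2, 1.5, 1.5)`).
#' @param threshold Relative detection threshold as a fraction of the
#'   maximum band-pass response (default 0.1).  Ignored when
#'   `threshold_abs` is given.
#' @param threshold_abs Optional absolute response threshold.
#' @return A `spot_table` data frame: `spot`, `z`, `y`, `x` (continuous
#'   0-based voxel coordinates), `z_um`, `y_um`, `x_um`, `intensity`
#'   (integrated, background-subtracted), `isolated`, `channel`.
#' @export
detect_spots <- function(stack, channel, sigma = c(1.2, 1.5, 1.5),
                         threshold = 0.1, threshold_abs = NULL) {
  stopifnot(inherits(stack, "image_stack"), all(sigma > 0))
  img <- stack_channel(stack, channel)
  vs <- attr(stack, "voxel_size")
  d <- dim(img)
  empty <- data.frame(spot = integer(), z = numeric(), y = numeric(),
                      x = numeric(), z_um = numeric(), y_um = numeric(),
                      x_um = numeric(), intensity = numeric(),
                      isolated = logical(), channel = character())
  if (max(img) <= 0) return(empty)
  dog <- gauss_smooth3(img, sigma) - gauss_smooth3(img, 1.6 * sigma)
  thr <- if (!is.null(threshold_abs)) threshold_abs else
    threshold * max(dog)
  if (max(dog) <= 0) return(empty)
  cand <- which(local_maxima3(dog) & dog >= thr, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)

  wc <- pmax(1L, ceiling(2 * sigma))   # centroid window half-width
  wi <- pmax(2L, ceiling(3 * sigma))   # integration window half-width
  n <- nrow(cand)
  pos <- matrix(NA_real_, n, 3)
  intens <- numeric(n)
  for (s in seq_len(n)) {
    ctr <- cand[s, ]
    zi <- max(1, ctr[1] - wi[1]):min(d[1], ctr[1] + wi[1])
    yi <- max(1, ctr[2] - wi[2]):min(d[2], ctr[2] + wi[2])
    xi <- max(1, ctr[3] - wi[3]):min(d[3], ctr[3] + wi[3])
    block <- img[zi, yi, xi, drop = FALSE]
    inner <- array(FALSE, dim(block))
    inner[pmax(1, 2):pmax(1, length(zi) - 1),
          pmax(1, 2):pmax(1, length(yi) - 1),
          pmax(1, 2):pmax(1, length(xi) - 1)] <- TRUE
    bg <- stats::median(block[!inner])
    intens[s] <- sum(block - bg)
    zc <- max(1, ctr[1] - wc[1]):min(d[1], ctr[1] + wc[1])
    yc <- max(1, ctr[2] - wc[2]):min(d[2], ctr[2] + wc[2])
    xc <- max(1, ctr[3] - wc[3]):min(d[3], ctr[3] + wc[3])
    w <- pmax(img[zc, yc, xc, drop = FALSE] - bg, 0)
    if (sum(w) <= 0) w[] <- 1
    # voxel with R index j spans [j-1, j); its center is at j - 0.5
    pos[s, 1] <- sum(w * rep(zc - 0.5, times = length(yc) * length(xc))) / sum(w)
    grid_y <- rep(rep(yc - 0.5, each = length(zc)), times = length(xc))
    pos[s, 2] <- sum(w * grid_y) / sum(w)
    pos[s, 3] <- sum(w * rep(xc - 0.5, each = length(zc) * length(yc))) / sum(w)
  }
  keep <- intens > 0
  pos <- pos[keep, , drop = FALSE]
  intens <- intens[keep]
  n <- nrow(pos)
  if (!n) return(empty)
  isolated <- rep(TRUE, n)
  if (n > 1) {
    for (s in seq_len(n)) {
      dzyx <- abs(sweep(pos[-s, , drop = FALSE], 2, pos[s, ]))
      close_by <- dzyx[, 1] <= 2 * sigma[1] & dzyx[, 2] <= 2 * sigma[2] &
        dzyx[, 3] <= 2 * sigma[3]
      isolated[s] <- !any(close_by)
    }
  }
  data.frame(spot = seq_len(n), z = pos[, 1], y = pos[, 2], x = pos[, 3],
             z_um = pos[, 1] * vs[1], y_um = pos[, 2] * vs[2],
             x_um = pos[, 3] * vs[3], intensity = intens,
             isolated = isolated, channel = channel)
}

#' Single-molecule reference intensity from isolated spots
#'
#' The median integrated intensity of isolated spots - diffraction-
#' limited detections with no neighbor within twice the PSF - serves as
#' the single-molecule intensity standard for dense-focus decomposition.
#'
#' @param spots A `spot_table` from [detect_spots()].
#' @param min_isolated Minimum number of isolated spots required
#'   (default 10).
#' @return Reference intensity (numeric scalar).
#' @export
calibrate_unit_intensity <- function(spots, min_isolated = 10) {
  iso <- spots$intensity[spots$isolated]
  if (length(iso) < min_isolated)
    stop("need at least ", min_isolated, " isolated spots for calibration (",
         length(iso), " found)")
  stats::median(iso)
}

#' Decompose a dense focus into single-molecule equivalents
#'
#' Converts the integrated intensity of a (possibly dense) RNA focus
#' into a molecule count by dividing by the single-molecule reference
#' intensity and rounding to the nearest integer, floored at one
#' molecule.
#'
#' @param intensity Integrated intensity of the focus region (vectorized).
#' @param reference Single-molecule reference intensity
#'   (see [calibrate_unit_intensity()]).
#' @return Integer molecule count(s), each >= 1.
#' @export
decompose_focus <- function(intensity, reference) {
  if (reference <= 0) stop("reference intensity must be positive")
  if (any(intensity <= 0)) stop("focus intensity must be positive")
  pmax(1L, as.integer(round(intensity / reference)))
}

#' Group decomposed molecules into foci by single-linkage clustering
#'
#' Allocates single-molecule detections to compartments: spots closer
#' than `radius` (micrometres, single linkage - chains merge) form one
#' focus.  A focus is classed `"cluster"` when its total molecule count
#' reaches `min_spots`, else `"single"`.
#'
#' @param spots `spot_table` with `z_um`, `y_um`, `x_um`; an optional
#'   `count` column (from [decompose_focus()]) defaults to 1 per spot.
#' @param radius Linkage radius in micrometres.
#' @param min_spots Minimum molecule count for the `"cluster"` class
#'   (default 2, so `"single"` is equivalent to count 1).
#' @return A `focus_table` data frame: `focus`, `z_um`, `y_um`, `x_um`
#'   (member centroid), `n_spots`, `count`, `class`; attribute
#'   `assignment` maps each spot row to its focus id.
#' @export
cluster_foci <- function(spots, radius, min_spots = 2) {
  stopifnot(radius > 0)
  n <- nrow(spots)
  counts <- if (!is.null(spots$count)) spots$count else rep(1L, n)
  if (n == 0) {
    out <- data.frame(focus = integer(), z_um = numeric(), y_um = numeric(),
                      x_um = numeric(), n_spots = integer(),
                      count = integer(), class = character())
    attr(out, "assignment") <- integer(0)
    return(out)
  }
  grp <- if (n == 1) 1L else {
    hc <- stats::hclust(stats::dist(spots[, c("z_um", "y_um", "x_um")]),
                        method = "single")
    stats::cutree(hc, h = radius)
  }
  ids <- sort(unique(grp))
  out <- do.call(rbind, lapply(ids, function(g) {
    m <- grp == g
    data.frame(focus = g, z_um = mean(spots$z_um[m]),
               y_um = mean(spots$y_um[m]), x_um = mean(spots$x_um[m]),
               n_spots = sum(m), count = sum(counts[m]))
  }))
  out$class <- ifelse(out$count >= min_spots, "cluster", "single")
  attr(out, "assignment") <- grp
  out
}

#' Mutual-nearest-neighbor colocalization of two spot channels
#'
#' Matches spots across two channels sharing a coordinate frame: spot i
#' in A is matched to spot j in B iff each is the other's nearest
#' neighbor and their distance does not exceed `max_dist` micrometres.
#' Mutuality makes the matching one-to-one.
#'
#' @param spots_a,spots_b `spot_table`s with `z_um`, `y_um`, `x_um`.
#' @param max_dist Maximum matching distance in micrometres.
#' @return Data frame `index_a`, `index_b`, `dist`; attributes
#'   `matched_a` and `matched_b` are per-spot logical flags.
#' @export
colocalize <- function(spots_a, spots_b, max_dist) {
  na <- nrow(spots_a); nb <- nrow(spots_b)
  empty <- data.frame(index_a = integer(), index_b = integer(),
                      dist = numeric())
  if (na == 0 || nb == 0) {
    attr(empty, "matched_a") <- rep(FALSE, na)
    attr(empty, "matched_b") <- rep(FALSE, nb)
    return(empty)
  }
  D <- pairwise_dist(as.matrix(spots_a[, c("z_um", "y_um", "x_um")]),
                     as.matrix(spots_b[, c("z_um", "y_um", "x_um")]))
  nn_a <- apply(D, 1, which.min)
  nn_b <- apply(D, 2, which.min)
  ia <- which(nn_b[nn_a] == seq_len(na) &
                D[cbind(seq_len(na), nn_a)] <= max_dist)
  out <- data.frame(index_a = ia, index_b = nn_a[ia],
                    dist = D[cbind(ia, nn_a[ia])])
  attr(out, "matched_a") <- seq_len(na) %in% out$index_a
  attr(out, "matched_b") <- seq_len(nb) %in% out$index_b
  out
}
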