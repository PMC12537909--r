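# Trilinear interpolation of a 3-D array at continuous voxel coordinates
# (0-based; the center of the voxel with R index j is at j - 0.5).
interp3 <- function(arr, pts) {
  d <- dim(arr)
  n <- nrow(pts)
  out <- numeric(n)
  g <- sweep(pts, 2, c(0.5, 0.5, 0.5))  # index-space coordinates (R centers)
  for (ax in 1:3) g[, ax] <- pmin(pmax(g[, ax], 0), d[ax] - 1)
  lo <- floor(g)
  fr <- g - lo
  for (i in seq_len(n)) {
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dz) fr[i, 1] else 1 - fr[i, 1]) *
        (if (dy) fr[i, 2] else 1 - fr[i, 2]) *
        (if (dx) fr[i, 3] else 1 - fr[i, 3])
      if (w == 0) next
      acc <- acc + w * arr[min(lo[i, 1] + dz + 1, d[1]),
                           min(lo[i, 2] + dy + 1, d[2]),
                           min(lo[i, 3] + dx + 1, d[3])]
    }
    out[i] <- acc
  }
  out
}

#' Max-normalized line profiles with exponential decay-rate fit
#'
#' Samples intensities of one or more channels along a virtual line with
#' sub-voxel (trilinear) interpolation, normalizes each channel to its
#' maximum along the line, and fits an exponential decay model
#' `I(x) = A * exp(-k * x) + c` to the labeling channel by nonlinear
#' least squares.  The fit window starts at the labeling channel's
#' half-maximum crossing beyond its peak - the compartment edge - so
#' the decay rate `k` (1/um) measures how fast the label falls off
#' outside the compartment; larger `k` means less signal diffusion.
#'
#' @param stack An [image_stack()].
#' @param start Line start in micrometres `(z, y, x)`.
#' @param direction Direction vector `(z, y, x)` (any norm).
#' @param length_um Line length in micrometres (default 1.5).
#' @param channels Channels to profile (default: all).
#' @param fit_channel Channel fitted for decay (default `"biotin"`).
#' @param step_um Sampling step (default half the smallest lateral voxel
#'   size).
#' @return An object of class `profile_fit`: list with `distance_um`,
#'   `profile` (matrix, one max-normalized column per channel), `k`,
#'   `amplitude`, `offset`, `residual` (RMS of the fit), `converged`,
#'   `anchor_um`.
#' @export
line_profile_decay <- function(stack, start, direction, length_um = 1.5,
                               channels = NULL, fit_channel = "biotin",
                               step_um = NULL) {
  stopifnot(inherits(stack, "image_stack"), length_um > 0,
            length(start) == 3L, length(direction) == 3L)
  vs <- attr(stack, "voxel_size")
  if (is.null(channels)) channels <- attr(stack, "channels")
  if (is.null(step_um)) step_um <- min(vs[2:3]) / 2
  u <- direction / sqrt(sum(direction^2))
  tt <- seq(0, length_um, by = step_um)
  pts_um <- cbind(start[1] + tt * u[1], start[2] + tt * u[2],
                  start[3] + tt * u[3])
  d <- dim(stack)
  pts_vox <- sweep(pts_um, 2, vs, "/")
  inside <- pts_vox[, 1] >= 0 & pts_vox[, 1] <= d[1] &
    pts_vox[, 2] >= 0 & pts_vox[, 2] <= d[2] &
    pts_vox[, 3] >= 0 & pts_vox[, 3] <= d[3]
  if (!all(inside)) stop("line leaves the image volume")

  prof <- sapply(channels, function(ch)
    interp3(stack_channel(stack, ch), pts_vox))
  prof <- matrix(prof, ncol = length(channels),
                 dimnames = list(NULL, channels))
  norm <- sweep(prof, 2, pmax(apply(prof, 2, max), .Machine$double.eps), "/")

  y <- prof[, fit_channel]
  res <- list(distance_um = tt, profile = norm, k = NA_real_,
              amplitude = NA_real_, offset = NA_real_,
              residual = NA_real_, converged = FALSE, anchor_um = NA_real_)
  class(res) <- "profile_fit"
  if (max(y) - min(y) <= 1e-9 * max(abs(y), 1)) return(res)  # flat profile

  i_max <- which.max(y)
  half <- min(y) + (y[i_max] - min(y)) / 2
  after <- which(seq_along(y) > i_max & y <= half)
  a0 <- if (length(after)) after[1] else i_max
  if (length(y) - a0 < 4) a0 <- max(1, length(y) - 4)
  xx <- tt[a0:length(tt)] - tt[a0]
  yy <- y[a0:length(y)]

  c0 <- min(yy)
  a_init <- max(yy) - c0
  pos <- yy - c0 > a_init * 1e-3
  k0 <- if (sum(pos) >= 2) {
    fit0 <- stats::lm(log(yy[pos] - c0 + a_init * 1e-6) ~ xx[pos])
    max(0.1, -unname(stats::coef(fit0)[2]))
  } else 1
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ A * exp(-k * xx) + c0f,
                      start = list(A = a_init, k = k0, c0f = c0),
                      lower = c(0, 1e-6, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    res$residual <- sqrt(mean((yy - mean(yy))^2))
    return(res)
  }
  cf <- stats::coef(fit)
  res$k <- unname(cf["k"])
  res$amplitude <- unname(cf["A"])
  res$offset <- unname(cf["c0f"])
  res$residual <- sqrt(mean(stats::residuals(fit)^2))
  res$converged <- TRUE
  res$anchor_um <- tt[a0]
  res
}

#' @export
print.profile_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("profile_fit: k = %.3f 1/um (A = %.3g, offset = %.3g, RMS = %.3g)\n",
                x$k, x$amplitude, x$offset, x$residual))
  } else {
    cat("profile_fit: degenerate or non-convergent fit\n")
  }
  invisible(x)
}

# Mean intensity of voxels whose centers lie within radius_um of a point.
sphere_mean <- function(img, vs, center_um, radius_um) {
  d <- dim(img)
  ctr_vox <- center_um / vs
  lo <- pmax(1L, floor(ctr_vox - radius_um / vs) + 1L)
  hi <- pmin(d, ceiling(ctr_vox + radius_um / vs) + 1L)
  if (any(lo > hi)) return(NA_real_)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  dz2 <- ((zi - 0.5) * vs[1] - center_um[1])^2
  dy2 <- ((yi - 0.5) * vs[2] - center_um[2])^2
  dx2 <- ((xi - 0.5) * vs[3] - center_um[3])^2
  r2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
  block <- img[zi, yi, xi, drop = FALSE]
  sel <- r2 <= radius_um^2
  if (!any(sel)) return(NA_real_)
  mean(block[sel])
}

#' Per-focus mean intensity near foci, compared between two focus classes
#'
#' Quantifies a channel (typically immunofluorescence) within a sphere
#' of `radius_um` around each focus centroid and compares the two focus
#' groups (e.g. repeat-expansion-positive vs -negative transcripts) with
#' a two-sided Wilcoxon rank-sum test.  Spheres clipped at the image
#' border are reported with a message.
#'
#' @param stack An [image_stack()].
#' @param channel Channel to quantify.
#' @param foci `focus_table` with `z_um`, `y_um`, `x_um` and a `group`
#'   column with exactly two levels.
#' @param radius_um Sphere radius in micrometres.
#' @return List with `values` (foci plus `mean_intensity`),
#'   `group_means` (named), and two-sided rank-sum `p`.
#' @export
intensity_near_focus <- function(stack, channel, foci, radius_um) {
  stopifnot(inherits(stack, "image_stack"), "group" %in% names(foci))
  groups <- unique(foci$group)
  if (length(groups) != 2) stop("foci must be classed into exactly two groups")
  if (any(table(factor(foci$group, groups)) == 0))
    stop("empty focus group")
  img <- stack_channel(stack, channel)
  vs <- attr(stack, "voxel_size")
  ext_um <- dim(img) * vs
  clipped <- 0L
  vals <- vapply(seq_len(nrow(foci)), function(i) {
    ctr <- c(foci$z_um[i], foci$y_um[i], foci$x_um[i])
    if (any(ctr - radius_um < 0) || any(ctr + radius_um > ext_um))
      clipped <<- clipped + 1L
    sphere_mean(img, vs, ctr, radius_um)
  }, numeric(1))
  if (clipped > 0)
    message(clipped, " focus sphere(s) clipped at the image border")
  foci$mean_intensity <- vals
  g1 <- vals[foci$group == groups[1]]
  g2 <- vals[foci$group == groups[2]]
  p <- if (length(unique(c(g1, g2))) < 2) 1 else
    stats::wilcox.test(g1, g2, alternative = "two.sided",
                       exact = FALSE)$p.value
  gm <- c(mean(g1, na.rm = TRUE), mean(g2, na.rm = TRUE))
  names(gm) <- as.character(groups)
  list(values = foci, group_means = gm, p = p)
}
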