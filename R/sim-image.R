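#' Multi-channel 3-D image stack container
#'
#' Intensities are stored as a 4-D array `[z, y, x, channel]`.  Voxel
#' indices are 0-based; a voxel with index `i` spans `[i, i + 1)` in
#' continuous voxel units, so its center sits at `i + 0.5` and the
#' physical position of a continuous coordinate `v` is `v * voxel_size`
#' micrometres.
#'
#' @param data Numeric 4-D array `[z, y, x, channel]`, non-negative.
#' @param voxel_size Numeric length-3 vector, micrometres per voxel along
#'   `(z, y, x)`.
#' @param channels Character vector of channel roles (e.g. `"fish"`,
#'   `"biotin"`, `"if"`, `"dapi"`).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size, channels) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(channels) == dim(data)[4])
  if (min(data) < 0) stop("intensities must be non-negative")
  structure(data, voxel_size = as.numeric(voxel_size),
            channels = as.character(channels), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("image_stack: %d x %d x %d voxels (z,y,x), channels: %s\n",
              d[1], d[2], d[3],
              paste(attr(x, "channels"), collapse = ", ")))
  invisible(x)
}

#' Extract one channel of a stack as a plain 3-D array `[z, y, x]`
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @return Numeric 3-D array.
#' @export
stack_channel <- function(stack, channel) {
  ch <- match(channel, attr(stack, "channels"))
  if (is.na(ch)) stop("unknown channel: ", channel)
  d <- dim(stack)
  array(stack[, , , ch], d[1:3])
}

#' Configuration for the synthetic microscopy stack generator
#'
#' Emulates diffraction-limited single-molecule RNA FISH acquisitions:
#' each molecule is rendered as a 3-D Gaussian point-spread function
#' whose integrated intensity is lognormal around a unit brightness; a
#' focus of molecule count `k` sums `k` molecules at jittered positions;
#' optionally a labeling channel receives an isotropic exponential halo
#' `I(r) = A * exp(-halo_decay_rate * r)` around halo-positive foci
#' (emulating diffusion of the activated biotin label away from the
#' RNA-positive compartment); Gaussian camera noise is added last.
#'
#' @param stack_shape Integer length-3, voxels along `(z, y, x)`.
#' @param voxel_size Micrometres per voxel `(z, y, x)`; default
#'   `c(0.22, 0.065, 0.065)` (0.22 um optical sections, 100x camera
#'   pixels).
#' @param psf_sigma Gaussian PSF sigma in voxels per axis `(z, y, x)`;
#'   default `c(1.2, 1.5, 1.5)`.
#' @param unit_intensity_mean Mean integrated intensity of one molecule
#'   (default 500).
#' @param unit_intensity_cv Coefficient of variation of molecule
#'   intensities (lognormal; default 0.2).
#' @param foci_spec Data frame with columns `z`, `y`, `x` (continuous
#'   0-based voxel coordinates), `count` (molecules, >= 1), `channel`,
#'   and optionally `halo` (logical).  `NULL` for an empty stack.
#' @param jitter_sd SD (voxels) of molecule position jitter inside a
#'   focus (default 0.3).
#' @param halo_on Whether halo-positive foci render a halo (default TRUE).
#' @param halo_decay_rate Halo decay rate, 1/um (default 5).
#' @param halo_amplitude Halo peak intensity (default 50).
#' @param halo_channel Channel receiving the halo (default `"biotin"`).
#' @param noise_sd Gaussian camera noise SD (default 1).
#' @param channels Channel roles of the stack (default
#'   `c("fish", "biotin")`).
#' @param nucleus_ellipse Optional list `center = c(y, x)`,
#'   `semi = c(ry, rx)` in voxels describing the nuclear outline used for
#'   2-D masks.
#' @param seed Integer seed.
#' @return An object of class `image_sim_config`.
#' @export
image_sim_config <- function(stack_shape = c(12, 96, 96),
                             voxel_size = c(0.22, 0.065, 0.065),
                             psf_sigma = c(1.2, 1.5, 1.5),
                             unit_intensity_mean = 500,
                             unit_intensity_cv = 0.2,
                             foci_spec = NULL, jitter_sd = 0.3,
                             halo_on = TRUE, halo_decay_rate = 5,
                             halo_amplitude = 50, halo_channel = "biotin",
                             noise_sd = 1, channels = c("fish", "biotin"),
                             nucleus_ellipse = NULL, seed = 1) {
  stopifnot(length(stack_shape) == 3L, all(stack_shape >= 4),
            all(voxel_size > 0))
  if (any(psf_sigma <= 0)) stop("psf_sigma must be positive")
  if (halo_on && halo_decay_rate <= 0)
    stop("halo_decay_rate must be positive when halo_on")
  if (!is.null(foci_spec)) {
    stopifnot(all(c("z", "y", "x", "count", "channel") %in% names(foci_spec)))
    if (any(foci_spec$count < 1)) stop("molecule_count must be >= 1")
    if (is.null(foci_spec$halo)) foci_spec$halo <- FALSE
    inb <- foci_spec$z >= 0 & foci_spec$z <= stack_shape[1] &
      foci_spec$y >= 0 & foci_spec$y <= stack_shape[2] &
      foci_spec$x >= 0 & foci_spec$x <= stack_shape[3]
    if (!all(inb)) stop("focus outside stack bounds")
    if (!all(foci_spec$channel %in% channels)) stop("unknown focus channel")
  }
  structure(list(stack_shape = stack_shape, voxel_size = voxel_size,
                 psf_sigma = psf_sigma,
                 unit_intensity_mean = unit_intensity_mean,
                 unit_intensity_cv = unit_intensity_cv,
                 foci_spec = foci_spec, jitter_sd = jitter_sd,
                 halo_on = halo_on, halo_decay_rate = halo_decay_rate,
                 halo_amplitude = halo_amplitude,
                 halo_channel = halo_channel, noise_sd = noise_sd,
                 channels = channels, nucleus_ellipse = nucleus_ellipse,
                 seed = seed),
            class = "image_sim_config")
}

# Add one molecule (integrated Gaussian) into a 3-D array; returns array.
render_molecule <- function(arr, pos, sigma, intensity) {
  d <- dim(arr)
  w <- vector("list", 3L)
  idx <- vector("list", 3L)
  for (ax in 1:3) {
    lo <- max(0L, floor(pos[ax] - 5 * sigma[ax]))
    hi <- min(d[ax] - 1L, ceiling(pos[ax] + 5 * sigma[ax]))
    if (lo > hi) return(arr)
    i <- lo:hi
    # exact integral of the axis Gaussian over each voxel [i, i+1)
    w[[ax]] <- stats::pnorm((i + 1 - pos[ax]) / sigma[ax]) -
      stats::pnorm((i - pos[ax]) / sigma[ax])
    idx[[ax]] <- i + 1L
  }
  blk <- intensity * (w[[1]] %o% w[[2]] %o% w[[3]])
  arr[idx[[1]], idx[[2]], idx[[3]]] <-
    arr[idx[[1]], idx[[2]], idx[[3]]] + blk
  arr
}

#' Generate a synthetic multi-channel image stack with known truth
#'
#' @param cfg An [image_sim_config()].
#' @return List with `stack` (an [image_stack()]) and `truth` (list:
#'   `focus_truth` data frame with per-focus position, channel, true
#'   molecule count and halo flag; `molecule_intensity` drawn integrated
#'   intensities; `true_decay_rate`; the config).
#' @export
generate_image_stack <- function(cfg) {
  stopifnot(inherits(cfg, "image_sim_config"))
  set.seed(derive_seed(cfg$seed, "image_sim"))
  d <- cfg$stack_shape
  nc <- length(cfg$channels)
  arrs <- lapply(seq_len(nc), function(i) array(0, d))
  names(arrs) <- cfg$channels

  sdlog <- sqrt(log(1 + cfg$unit_intensity_cv^2))
  meanlog <- log(cfg$unit_intensity_mean) - sdlog^2 / 2
  fs <- cfg$foci_spec
  mol_int <- numeric(0)
  if (!is.null(fs) && nrow(fs) > 0) {
    for (i in seq_len(nrow(fs))) {
      k <- fs$count[i]
      ints <- if (cfg$unit_intensity_cv > 0) {
        stats::rlnorm(k, meanlog, sdlog)
      } else rep(cfg$unit_intensity_mean, k)
      mol_int <- c(mol_int, ints)
      for (m in seq_len(k)) {
        jit <- if (k > 1) stats::rnorm(3, 0, cfg$jitter_sd) else c(0, 0, 0)
        pos <- c(fs$z[i], fs$y[i], fs$x[i]) + jit
        arrs[[fs$channel[i]]] <-
          render_molecule(arrs[[fs$channel[i]]], pos, cfg$psf_sigma, ints[m])
      }
    }
    if (cfg$halo_on && any(fs$halo)) {
      vz <- ((seq_len(d[1]) - 0.5) * cfg$voxel_size[1])
      vy <- ((seq_len(d[2]) - 0.5) * cfg$voxel_size[2])
      vx <- ((seq_len(d[3]) - 0.5) * cfg$voxel_size[3])
      for (i in which(fs$halo)) {
        cz <- fs$z[i] * cfg$voxel_size[1]
        cy <- fs$y[i] * cfg$voxel_size[2]
        cx <- fs$x[i] * cfg$voxel_size[3]
        r <- sqrt(outer(outer((vz - cz)^2, (vy - cy)^2, "+"),
                        (vx - cx)^2, "+"))
        halo <- cfg$halo_amplitude * exp(-cfg$halo_decay_rate * r)
        halo[r > 9 / cfg$halo_decay_rate] <- 0
        arrs[[cfg$halo_channel]] <- arrs[[cfg$halo_channel]] + halo
      }
    }
  }

  out <- array(0, c(d, nc))
  for (i in seq_len(nc)) {
    a <- arrs[[i]]
    if (cfg$noise_sd > 0)
      a <- pmax(a + stats::rnorm(length(a), 0, cfg$noise_sd), 0)
    out[, , , i] <- a
  }
  focus_truth <- if (!is.null(fs) && nrow(fs) > 0) {
    data.frame(focus = seq_len(nrow(fs)), z = fs$z, y = fs$y, x = fs$x,
               z_um = fs$z * cfg$voxel_size[1],
               y_um = fs$y * cfg$voxel_size[2],
               x_um = fs$x * cfg$voxel_size[3],
               count = fs$count, channel = fs$channel, halo = fs$halo)
  } else {
    data.frame(focus = integer(), z = numeric(), y = numeric(),
               x = numeric(), z_um = numeric(), y_um = numeric(),
               x_um = numeric(), count = integer(), channel = character(),
               halo = logical())
  }
  list(stack = image_stack(out, cfg$voxel_size, cfg$channels),
       truth = list(focus_truth = focus_truth,
                    molecule_intensity = mol_int,
                    true_decay_rate = if (cfg$halo_on) cfg$halo_decay_rate else NA_real_,
                    config = cfg))
}

#' Elliptical 2-D nucleus mask from an image simulation config
#'
#' @param cfg An [image_sim_config()] with a `nucleus_ellipse`.
#' @return Logical matrix `(y, x)`.
#' @export
nucleus_mask <- function(cfg) {
  ne <- cfg$nucleus_ellipse
  if (is.null(ne)) stop("config has no nucleus_ellipse")
  d <- cfg$stack_shape
  yy <- (seq_len(d[2]) - 0.5 - ne$center[1]) / ne$semi[1]
  xx <- (seq_len(d[3]) - 0.5 - ne$center[2]) / ne$semi[2]
  outer(yy^2, xx^2, "+") <= 1
}

#' Write an image stack as a multi-page 32-bit float TIFF
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2,
#' ...).  Values are scaled into `[0, 1]` for storage; the scale factor,
#' dimensions, channel roles and voxel size are recorded in a JSON
#' sidecar (`<path>.meta.json`) so [read_image_stack()] can reverse the
#' transformation.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @export
write_image_stack <- function(stack, path) {
  d <- dim(stack)
  scale <- max(stack, 1e-12)
  pages <- list()
  for (ch in seq_len(d[4]))
    for (z in seq_len(d[1]))
      pages[[length(pages) + 1L]] <- matrix(stack[z, , , ch] / scale,
                                            d[2], d[3])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(nz = d[1], ny = d[2], nx = d[3],
                            channels = attr(stack, "channels"),
                            voxel_size = attr(stack, "voxel_size"),
                            scale = scale),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path Path to the TIFF.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  arr <- array(0, c(meta$nz, meta$ny, meta$nx, length(meta$channels)))
  p <- 1L
  for (ch in seq_along(meta$channels))
    for (z in seq_len(meta$nz)) {
      arr[z, , , ch] <- pages[[p]] * meta$scale
      p <- p + 1L
    }
  image_stack(arr, meta$voxel_size, meta$channels)
}
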