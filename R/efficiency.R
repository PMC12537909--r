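#' Flag foci as proximity-labeled from the biotin channel
#'
#' A focus counts as labeled when the mean intensity of the labeling
#' (biotin) channel within `radius_um` of its centroid exceeds
#' `threshold`.
#'
#' @param stack An [image_stack()].
#' @param foci `focus_table` with `z_um`, `y_um`, `x_um`.
#' @param channel Labeling channel (default `"biotin"`).
#' @param radius_um Quantification radius in micrometres (default 0.25).
#' @param threshold Intensity threshold above which a focus is labeled.
#' @return `foci` with logical `labeled` and numeric `label_intensity`
#'   columns.
#' @export
label_foci <- function(stack, foci, channel = "biotin", radius_um = 0.25,
                       threshold) {
  img <- stack_channel(stack, channel)
  vs <- attr(stack, "voxel_size")
  foci$label_intensity <- vapply(seq_len(nrow(foci)), function(i)
    sphere_mean(img, vs, c(foci$z_um[i], foci$y_um[i], foci$x_um[i]),
                radius_um), numeric(1))
  foci$labeled <- !is.na(foci$label_intensity) &
    foci$label_intensity > threshold
  foci
}

#' Proximity-labeling efficiency
#'
#' Fraction of RNA-FISH-positive foci that carry detectable biotin
#' label, together with the per-focus label intensities of the labeled
#' foci.
#'
#' @param foci `focus_table` with a logical `labeled` column (see
#'   [label_foci()]) and optionally `label_intensity`.
#' @return List with `fraction` (in `[0, 1]`; `NA` with
#'   `defined = FALSE` when there are no foci), `n_foci`, `n_labeled`,
#'   `labeled_intensity`.
#' @export
labeling_efficiency <- function(foci) {
  if (is.null(foci$labeled)) stop("foci lack a 'labeled' flag")
  n <- nrow(foci)
  if (n == 0) {
    warning("no foci: labeling efficiency undefined")
    return(list(fraction = NA_real_, defined = FALSE, n_foci = 0L,
                n_labeled = 0L, labeled_intensity = numeric(0)))
  }
  lab <- foci$labeled
  list(fraction = mean(lab), defined = TRUE, n_foci = n,
       n_labeled = sum(lab),
       labeled_intensity = if (!is.null(foci$label_intensity))
         foci$label_intensity[lab] else numeric(0))
}

#' Apparent labeling efficiency
#'
#' Ratio of the percentage of proximity-labeled RNA-FISH foci to the
#' percentage of the corresponding foci colocalizing with the repeat
#' probe in dual-color RNA-FISH - the denominator corrects for foci the
#' labeling probe cannot reach.  A ratio above one is possible (the two
#' percentages come from different experiments) and is flagged.
#'
#' @param hypro_pct Percentage of labeled foci.
#' @param coloc_pct Percentage of colocalizing foci (> 0).
#' @return List with `ratio` and logical `over_unity`.
#' @export
apparent_efficiency <- function(hypro_pct, coloc_pct) {
  if (coloc_pct == 0) stop("colocalization percentage must be positive")
  r <- hypro_pct / coloc_pct
  list(ratio = r, over_unity = r > 1)
}
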