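#' Protein-by-sample log2 intensity table
#'
#' Container for label-free quantification (LFQ) data: a numeric matrix of
#' log2 intensities (proteins as rows, samples as columns, `NA` = not
#' detected) together with the experimental design mapping each sample to
#' exactly one condition and replicate.
#'
#' @param intensity Numeric matrix with protein identifiers as row names
#'   and sample names as column names.  `NA` marks missing (not detected).
#' @param design Data frame with columns `sample`, `condition`,
#'   `replicate`; one row per column of `intensity`, in matching order.
#' @return An object of class `intensity_table`.
#' @export
intensity_table <- function(intensity, design) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if ((nrow(intensity) > 0 && is.null(rownames(intensity))) ||
      is.null(colnames(intensity)))
    stop("intensity must have protein row names and sample column names")
  if (anyDuplicated(rownames(intensity)))
    stop("duplicate protein identifiers are an input error")
  stopifnot(is.data.frame(design),
            all(c("sample", "condition", "replicate") %in% names(design)))
  if (!identical(as.character(design$sample), colnames(intensity)))
    stop("design$sample must match intensity column names in order")
  if (anyDuplicated(design$sample))
    stop("every sample must be assigned to exactly one condition")
  if (any(!is.finite(intensity[!is.na(intensity)])))
    stop("intensities must be finite where present")
  structure(list(intensity = intensity, design = design),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d proteins x %d samples (%d conditions), %.1f%% missing\n",
              nrow(x$intensity), ncol(x$intensity),
              length(unique(x$design$condition)),
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$intensity)

#' Subset an intensity table to a set of proteins
#'
#' @param tbl An [intensity_table()].
#' @param proteins Character vector of protein identifiers to keep
#'   (order preserved from the table).
#' @return An `intensity_table` restricted to `proteins`.
#' @export
subset_proteins <- function(tbl, proteins) {
  keep <- rownames(tbl$intensity) %in% proteins
  intensity_table(tbl$intensity[keep, , drop = FALSE], tbl$design)
}

#' Write an intensity table as TSV with a design sidecar
#'
#' The main table has proteins as rows and samples as columns with empty
#' fields for missing values; the design is written to
#' `<path>.design.tsv`.
#'
#' @param tbl An [intensity_table()].
#' @param path Output path for the intensity TSV.
#' @export
write_intensity_tsv <- function(tbl, path) {
  df <- data.frame(protein = rownames(tbl$intensity), tbl$intensity,
                   check.names = FALSE)
  write_tsv(df, path)
  write_tsv(tbl$design, paste0(path, ".design.tsv"))
}

#' Read an intensity table written by [write_intensity_tsv()]
#'
#' @param path Path to the intensity TSV.
#' @return An [intensity_table()].
#' @export
read_intensity_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$protein
  design <- read_tsv(paste0(path, ".design.tsv"))
  design$sample <- as.character(design$sample)
  intensity_table(m, design)
}
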