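#' Count annealing sites of an antisense probe in a tandem repeat
#'
#' For a single-oligonucleotide FISH probe targeting a tandem repeat
#' (e.g. an 18-mer against the GGGGCC hexanucleotide repeat expansion in
#' C9orf72 intron 1), the number of probe molecules that can bind one
#' transcript is limited by the number of non-overlapping annealing
#' positions.  The target repeat region is rendered explicitly, all exact
#' annealing start positions of the probe are located on it, and the
#' maximum set of mutually non-overlapping positions is selected by greedy
#' interval scheduling (earliest-end-first, which is optimal for interval
#' scheduling).
#'
#' The probe is given in the orientation of its own sequence; it anneals
#' where its reverse complement matches the target, so the search pattern
#' is `reverseComplement(probe)`.
#'
#' @param n_copies Number of tandem copies of the repeat unit.
#' @param repeat_unit Repeat unit on the sense (target RNA/DNA) strand.
#'   Default `"GGGGCC"`.
#' @param probe Antisense probe sequence.  Default is the 18-mer antisense
#'   to three repeat units.
#' @return List with `n_sites` (maximum non-overlapping annealing
#'   positions), `n_matches` (all annealing start positions) and
#'   `target_length` (nt).
#' @examples
#' probe_annealing_sites(10)$n_sites  # floor(60 / 18) = 3
#' @export
probe_annealing_sites <- function(n_copies, repeat_unit = "GGGGCC",
                                  probe = NULL) {
  stopifnot(n_copies >= 1, nchar(repeat_unit) >= 1)
  if (is.null(probe)) {
    probe <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(strrep(repeat_unit, 3L))))
  }
  target <- Biostrings::DNAString(strrep(repeat_unit, n_copies))
  pattern <- Biostrings::reverseComplement(Biostrings::DNAString(probe))
  hits <- Biostrings::matchPattern(pattern, target)
  starts <- Biostrings::start(hits)
  ends <- Biostrings::end(hits)
  # greedy interval scheduling on (start, end), earliest end first
  ord <- order(ends)
  n_sites <- 0L
  last_end <- 0L
  for (i in ord) {
    if (starts[i] > last_end) {
      n_sites <- n_sites + 1L
      last_end <- ends[i]
    }
  }
  list(n_sites = n_sites, n_matches = length(starts),
       target_length = length(target))
}
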