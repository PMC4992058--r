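#' Sequence composition statistics: G+C, CpG, and dinucleotide odds
#'
#' Computes, per sequence, the G+C percentage, the CpG dinucleotide
#' percentage, and two observed/expected odds ratios with expected counts
#' taken from the sequence's own mononucleotide frequencies
#' (Gardiner-Garden style):
#' \deqn{\mathrm{CpG\ odds} = \frac{\#CG}{(L-1)\,(n_C/L)(n_G/L)}, \qquad
#'  \mathrm{CpA/TpG\ odds} = \frac{\#CA + \#TG}
#'   {(L-1)\,[(n_C/L)(n_A/L) + (n_T/L)(n_G/L)]}.}
#' CpG depletion relative to expectation marks historic germline
#' methylation, whose deamination products CpA/TpG are then in excess.
#' Case-insensitive; ambiguous bases (N etc.) are excluded from base
#' counts, from the effective length L, and from dinucleotide tallies (a
#' pair containing an ambiguous base is not counted on either side of the
#' odds).
#'
#' @param sequences Character vector of DNA sequences, a
#'   [Biostrings::DNAStringSet], or a single string. Names become
#'   `region_id`s.
#' @return A tibble with one row per sequence: `region_id`, `length`
#'   (unambiguous bases), `gc_percent`, `cpg_percent`, `cpg_odds`,
#'   `cpa_tpg_odds`, and `degenerate` (`TRUE` when an expected count is
#'   zero, in which case the odds are `NA`).
#' @examples
#' sequence_stats("ACGT")
#' @export
sequence_stats <- function(sequences) {
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  }
  if (any(Biostrings::width(sequences) < 2)) {
    abort("Sequences must have length >= 2.")
  }
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(sequences))

  mono <- Biostrings::letterFrequency(sequences, c("A", "C", "G", "T"))
  # dinucleotideFrequency only tallies pairs of unambiguous bases
  di <- Biostrings::dinucleotideFrequency(sequences)
  L <- rowSums(mono)
  pairs <- rowSums(di) # valid dinucleotide positions (L - 1 when no Ns)
  if (any(L < 2)) {
    abort("Sequences must contain at least two unambiguous bases.")
  }

  fa <- mono[, "A"] / L; fc <- mono[, "C"] / L
  fg <- mono[, "G"] / L; ft <- mono[, "T"] / L
  exp_cpg <- pairs * fc * fg
  exp_cpa_tpg <- pairs * (fc * fa + ft * fg)

  tibble::tibble(
    region_id = ids,
    length = as.integer(unname(L)),
    gc_percent = unname(100 * (mono[, "C"] + mono[, "G"]) / L),
    cpg_percent = unname(100 * di[, "CG"] / pairs),
    cpg_odds = unname(ifelse(exp_cpg > 0, di[, "CG"] / exp_cpg, NA_real_)),
    cpa_tpg_odds = unname(ifelse(exp_cpa_tpg > 0,
                                 (di[, "CA"] + di[, "TG"]) / exp_cpa_tpg,
                                 NA_real_)),
    degenerate = unname(exp_cpg == 0 | exp_cpa_tpg == 0))
}

#' Sequence statistics for regions of a FASTA genome
#'
#' Fetches each region's sequence from an (indexed or plain) FASTA file and
#' applies [sequence_stats()].
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, `region_id`;
#'   0-based half-open).
#' @param fasta_path Path to a FASTA file containing the region
#'   chromosomes.
#' @return The [sequence_stats()] tibble keyed by `region_id`.
#' @export
region_sequence_stats <- function(regions, fasta_path) {
  regions <- as_regions(regions)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chrom <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(paste0("Chromosome(s) absent from FASTA: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  seqs <- Biostrings::DNAStringSet(purrr::pmap(
    list(regions$chrom, regions$start, regions$end),
    function(chrom, start, end) {
      Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end)
    }))
  names(seqs) <- regions$region_id
  sequence_stats(seqs)
}
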