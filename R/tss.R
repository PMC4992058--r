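#' Build TSS windows from a transcript table
#'
#' Extracts the 5'-end of every transcript, merges transcripts that share
#' TSS coordinate, strand and gene name, and expands each merged TSS into a
#' window of `2 * halfwidth` bases, `[TSS - halfwidth, TSS + halfwidth)` in
#' 0-based half-open coordinates. When expression is available the
#' representative transcript of a merged group is the one with the highest
#' first-exon read count (ties broken by lexicographic `transcript_id`).
#'
#' Note the half-open convention gives windows of exactly `2 * halfwidth`
#' bases (1500 by default); pipelines using inclusive +/-halfwidth windows
#' (1501 bases) will differ by one base at the right edge.
#'
#' @param transcripts Data frame with columns `gene_id`, `gene_name`,
#'   `transcript_id`, `chrom`, `strand` (`+`/`-`), `tss` (0-based
#'   coordinate) and optionally `first_exon_count`.
#' @param halfwidth Window half-width in bases.
#' @return A region tibble (`chrom`, `start`, `end`, `strand`, `region_id`,
#'   `gene_id`, `gene_name`, `transcript_id`) with one row per merged TSS,
#'   ordered by chromosome, TSS and strand. Windows that would start before
#'   the chromosome origin are clipped to 0 with a warning.
#' @examples
#' tx <- tibble::tibble(gene_id = "g1", gene_name = "G1",
#'                      transcript_id = c("t1", "t2"), chrom = "chr1",
#'                      strand = "+", tss = 10000,
#'                      first_exon_count = c(5, 9))
#' build_tss_windows(tx) # one window, representative t2
#' @export
build_tss_windows <- function(transcripts, halfwidth = 750L) {
  stopifnot(is.data.frame(transcripts))
  missing_cols <- setdiff(c("gene_id", "gene_name", "transcript_id",
                            "chrom", "strand", "tss"), names(transcripts))
  if (length(missing_cols) > 0) {
    abort(paste0("`transcripts` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(transcripts$strand %in% c("+", "-"))) {
    abort("Transcript `strand` must be '+' or '-'.")
  }
  if (any(transcripts$tss < 0)) abort("`tss` must be non-negative.")
  tx <- tibble::as_tibble(transcripts)
  if (!"first_exon_count" %in% names(tx)) tx$first_exon_count <- 0L

  merged <- tx |>
    dplyr::arrange(dplyr::desc(.data$first_exon_count),
                   .data$transcript_id) |>
    dplyr::distinct(.data$chrom, .data$tss, .data$strand, .data$gene_name,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$tss, .data$strand)

  start <- merged$tss - halfwidth
  if (any(start < 0)) {
    warn(sprintf("%d window(s) clipped at the chromosome origin.",
                 sum(start < 0)))
    start <- pmax(start, 0)
  }
  tibble::tibble(chrom = merged$chrom, start = start,
                 end = merged$tss + halfwidth, strand = merged$strand,
                 region_id = sprintf("tss_%s_%d_%s", merged$chrom,
                                     merged$tss, merged$strand),
                 gene_id = merged$gene_id, gene_name = merged$gene_name,
                 transcript_id = merged$transcript_id)
}
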