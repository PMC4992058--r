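# Readers and writers for the package's plain-text interchange formats.
# Coordinates on disk follow BED: 0-based half-open.

#' Read and write region count tables
#'
#' Count tables are TSV with header columns `region_id`, optionally
#' `chrom`/`start`/`end`, and the counts `r` (control) and `s` (treatment).
#'
#' @param path File path.
#' @return `read_counts_tsv()`: a tibble validated for [enrich()].
#' @export
read_counts_tsv <- function(path) {
  as_region_counts(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_counts_tsv
#' @param counts Count table to write.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read regions from a BED3/BED6 file
#'
#' @param path BED file path (3 to 6 columns, no header).
#' @return A region tibble `chrom`, `start`, `end`, `region_id`, `score`,
#'   `strand`. Missing name fields are replaced by `region_<i>`.
#' @export
read_regions_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  if (ncol(bed) < 3) abort("BED input needs at least 3 columns.")
  nm <- c("chrom", "start", "end", "region_id", "score", "strand")
  names(bed) <- nm[seq_len(min(ncol(bed), 6))]
  if (!"region_id" %in% names(bed) || all(is.na(bed$region_id))) {
    bed$region_id <- sprintf("region_%d", seq_len(nrow(bed)))
  }
  if (!"score" %in% names(bed)) bed$score <- 0
  if (!"strand" %in% names(bed)) bed$strand <- "."
  as_regions(bed[, c("chrom", "start", "end", "region_id", "score",
                     "strand")])
}

#' Read a transcript table for TSS-window construction
#'
#' Expects a TSV with header `gene_id`, `gene_name`, `transcript_id`,
#' `chrom`, `strand`, `tss` and optionally `first_exon_count`.
#'
#' @param path File path.
#' @return A tibble suitable for [build_tss_windows()].
#' @export
read_transcript_table <- function(path) {
  tx <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("gene_id", "gene_name", "transcript_id", "chrom", "strand",
              "tss")
  missing_cols <- setdiff(needed, names(tx))
  if (length(missing_cols) > 0) {
    abort(paste0("Transcript table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  tx
}

#' Write enrichment results and tracks
#'
#' `write_enrichment_tsv()` writes the per-region results of a
#' `rechip_enrich` object. `write_bedgraph()` writes a 4-column bedGraph of
#' the normalized enrichment (values rounded to 4 decimals).
#' `write_calls_bed()` writes the regions called at one FDR as BED6 with
#' score `round(1000 * min(1, e_norm))` clamped to \[0, 1000\] and strand
#' '.'. The track writers need region coordinates: supply a region tibble
#' whose `region_id`s match the fitted counts.
#'
#' @param result A `rechip_enrich` object.
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(result, path) {
  stopifnot(inherits(result, "rechip_enrich"))
  readr::write_tsv(augment(result), path)
  invisible(path)
}

#' @rdname write_enrichment_tsv
#' @param regions Region tibble with `chrom`, `start`, `end`, `region_id`.
#' @export
write_bedgraph <- function(result, regions, path) {
  stopifnot(inherits(result, "rechip_enrich"))
  regions <- as_regions(regions)
  res <- dplyr::inner_join(regions, augment(result), by = "region_id")
  if (nrow(res) < nrow(augment(result))) {
    warn("Some fitted regions are absent from `regions`; they are omitted.")
  }
  out <- res |>
    dplyr::transmute(.data$chrom, .data$start, .data$end,
                     value = round(dplyr::coalesce(.data$e_norm, 0), 4))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_tsv
#' @param fdr FDR threshold whose calls to export (must be one of the
#'   thresholds used in [enrich()]).
#' @export
write_calls_bed <- function(result, regions, path, fdr = 0.01) {
  stopifnot(inherits(result, "rechip_enrich"))
  col <- paste0("called_q", format(fdr, scientific = FALSE))
  res <- augment(result)
  if (!col %in% names(res)) {
    abort(sprintf("No calls at FDR %g in this result.", fdr))
  }
  regions <- as_regions(regions)
  out <- dplyr::inner_join(regions, res, by = "region_id") |>
    dplyr::filter(.data[[col]]) |>
    dplyr::transmute(.data$chrom, .data$start, .data$end, .data$region_id,
                     score = pmax(0, pmin(1000, round(
                       1000 * pmin(1, dplyr::coalesce(.data$e_norm, 0))))),
                     strand = ".")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_tsv
#' @export
write_fit_json <- function(result, path) {
  stopifnot(inherits(result, "rechip_enrich"))
  jsonlite::write_json(as.list(glance(result)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
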