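#' Run enrichment calling end to end
#'
#' Orchestrates counting (optional), mixture fitting, significance testing
#' and track export. Treatment and control may be given either as SAM/BAM
#' paths plus a region set, or as a pre-made count table.
#'
#' @param treatment,control SAM/BAM paths (with `regions`), or `NULL` when
#'   `counts` is supplied.
#' @param regions Region tibble (required with alignment input; optional
#'   with `counts`, used for track export).
#' @param counts Pre-made count table (`region_id`, `r`, `s`).
#' @param out_prefix If non-`NULL`, writes `<prefix>_fit.json`,
#'   `<prefix>_results.tsv`, `<prefix>_enrichment.bedGraph` (with regions)
#'   and one `<prefix>_calls_q<f>.bed` per FDR threshold.
#' @param mapq_min,tlen_range,exclude_flag,point Counting filters, see
#'   [filter_fragments()] and [count_fragments()].
#' @inheritParams enrich
#' @return The `rechip_enrich` object, invisibly when writing files.
#' @export
run_enrich <- function(treatment = NULL, control = NULL, regions = NULL,
                       counts = NULL, out_prefix = NULL,
                       mapq_min = 20L, tlen_range = c(120L, 240L),
                       exclude_flag = 1024L,
                       point = c("midpoint", "start"),
                       epsilon = 0.001, max_iter = 1000L, n_starts = 10L,
                       seed = NULL, p_filter = 1e-4,
                       fdr = c(0.001, 0.01, 0.1), estimate_pi0 = FALSE) {
  point <- match.arg(point)
  if (is.null(counts)) {
    if (is.null(treatment) || is.null(control) || is.null(regions)) {
      abort("Supply either `counts`, or `treatment` + `control` + `regions`.")
    }
    counts <- count_pair(treatment, control, regions, mapq_min = mapq_min,
                         tlen_range = tlen_range,
                         exclude_flag = exclude_flag, point = point)
  }
  result <- enrich(counts, epsilon = epsilon, max_iter = max_iter,
                   n_starts = n_starts, seed = seed, p_filter = p_filter,
                   fdr = fdr, estimate_pi0 = estimate_pi0)
  if (!is.null(out_prefix)) {
    write_fit_json(result, paste0(out_prefix, "_fit.json"))
    write_enrichment_tsv(result, paste0(out_prefix, "_results.tsv"))
    if (!is.null(regions)) {
      write_bedgraph(result, regions, paste0(out_prefix,
                                             "_enrichment.bedGraph"))
      for (f in fdr) {
        write_calls_bed(result, regions,
                        paste0(out_prefix, "_calls_q",
                               format(f, scientific = FALSE), ".bed"),
                        fdr = f)
      }
    }
    return(invisible(result))
  }
  result
}

#' Run co-occupancy classification end to end
#'
#' Joins per-track enrichment calls on `region_id`, classifies each region
#' into the eight co-occupancy classes, and optionally maps promoter
#' classes to genes.
#'
#' @param call_tracks Named list of per-track calls. Each element is either
#'   a `rechip_enrich` object or a data frame `region_id`, `call`
#'   (logical). Core names: `A`, `B`, `reBA`, `reAB`; six-ratio mode also
#'   needs `reBA_over_B` and `reAB_over_A`.
#' @param fdr FDR threshold applied when elements are `rechip_enrich`
#'   objects.
#' @param mode Passed to [classify_regions()].
#' @param gene_map Optional tibble `region_id`, `gene_id` for gene-level
#'   classes.
#' @param out_prefix If non-`NULL`, writes `<prefix>_classes.tsv` (and
#'   `<prefix>_gene_classes.tsv` with a gene map).
#' @return A list with `regions` (classified region tibble), `summary`
#'   (class counts, including the number of discarded `low_cooccupancy`
#'   regions and irregular call combinations), and `genes` (or `NULL`).
#' @export
run_classify <- function(call_tracks, fdr = 0.01,
                         mode = c("core", "six_ratio"), gene_map = NULL,
                         out_prefix = NULL) {
  mode <- match.arg(mode)
  needed <- c("A", "B", "reBA", "reAB")
  if (mode == "six_ratio") needed <- c(needed, "reBA_over_B", "reAB_over_A")
  missing_tracks <- setdiff(needed, names(call_tracks))
  if (length(missing_tracks) > 0) {
    abort(paste0("Missing call tracks: ",
                 paste(missing_tracks, collapse = ", ")))
  }
  as_calls <- function(x, name) {
    if (inherits(x, "rechip_enrich")) {
      res <- augment(x)
      return(tibble::tibble(region_id = res$region_id,
                            call = call_enriched(res$qvalue, fdr)))
    }
    stopifnot(is.data.frame(x), all(c("region_id", "call") %in% names(x)))
    tibble::as_tibble(x)[, c("region_id", "call")]
  }
  tracks <- purrr::imap(call_tracks[needed], as_calls)
  ids <- tracks[[1]]$region_id
  for (nm in needed[-1]) {
    if (!setequal(tracks[[nm]]$region_id, ids)) {
      offending <- c(setdiff(tracks[[nm]]$region_id, ids),
                     setdiff(ids, tracks[[nm]]$region_id))
      abort(sprintf("Region sets differ across call tracks (first mismatch: %s).",
                    offending[1]))
    }
  }
  calls <- purrr::reduce(purrr::imap(tracks, function(x, nm) {
    setNames(x, c("region_id", nm))
  }), dplyr::inner_join, by = "region_id")

  classified <- classify_regions(calls, mode = mode)
  summary <- classified |>
    dplyr::count(.data$class, .drop = FALSE, name = "n_regions") |>
    dplyr::mutate(discarded = .data$class == "low_cooccupancy")
  genes <- NULL
  if (!is.null(gene_map)) {
    stopifnot(all(c("region_id", "gene_id") %in% names(gene_map)))
    genes <- classified |>
      dplyr::inner_join(tibble::as_tibble(gene_map), by = "region_id") |>
      classify_genes()
  }
  if (!is.null(out_prefix)) {
    readr::write_tsv(classified, paste0(out_prefix, "_classes.tsv"))
    if (!is.null(genes)) {
      readr::write_tsv(genes, paste0(out_prefix, "_gene_classes.tsv"))
    }
  }
  list(regions = classified, summary = summary, genes = genes,
       n_irregular = sum(classified$irregular))
}
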