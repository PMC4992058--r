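#' Published TSS co-occupancy class sizes in CD4+ central memory T cells
#'
#' Class sizes of the seven retained co-occupancy classes over 72,480
#' transcription start sites at FDR 0.01 (A = H3K4me3, B = H3K27me3), as
#' reported for primary human CD4+ central memory T cells. Shipped as a
#' reference input for comparing the reChIP-based classification against
#' the classical co-enrichment intersection approach.
#'
#' @return A tibble `class`, `n_tss`.
#' @export
tcm_tss_class_sizes <- function() {
  readr::read_tsv(system.file("extdata", "tcm_tss_class_sizes.tsv",
                              package = "rechipr"),
                  show_col_types = FALSE)
}

#' Co-enrichment versus reChIP: intersection diagnostics
#'
#' Quantifies how the classical intersection of two primary ChIP call sets
#' ("bivalent = enriched in both H3K4me3 and H3K27me3") performs relative
#' to reChIP-resolved classes. Regions the intersection labels bivalent are
#' the full-bivalent plus pseudo-bivalent classes, so its false-positive
#' fraction is `pseudo / (full_bivalent + pseudo)`. Truly co-occupied
#' regions comprise the full and the two partial classes, of which the
#' intersection recovers only the full class: the missed fraction is
#' `(A_partial + B_partial) / (full_bivalent + A_partial + B_partial)`.
#'
#' @param class_sizes Data frame `class`, `n_tss` (defaults to
#'   [tcm_tss_class_sizes()]).
#' @return A one-row tibble with `false_positive_pct` and `missed_pct`.
#' @export
coenrichment_diagnostics <- function(class_sizes = tcm_tss_class_sizes()) {
  n <- setNames(class_sizes$n_tss, class_sizes$class)
  needed <- c("full_bivalent", "pseudo", "A_partial", "B_partial")
  if (!all(needed %in% names(n))) {
    abort("`class_sizes` must contain the full, pseudo and partial classes.")
  }
  tibble::tibble(
    false_positive_pct = 100 * n[["pseudo"]] /
      (n[["full_bivalent"]] + n[["pseudo"]]),
    missed_pct = 100 * (n[["A_partial"]] + n[["B_partial"]]) /
      (n[["full_bivalent"]] + n[["A_partial"]] + n[["B_partial"]]))
}
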