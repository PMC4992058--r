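# Ideal over-input call pattern (A, B, reBA, reAB) for each of the eight
# co-occupancy classes. A and B are the two primary ChIPs (e.g. H3K4me3 and
# H3K27me3); reBA / reAB are the reciprocal sequential ChIPs.
core_class_patterns <- function() {
  list(
    unmodified      = c(A = FALSE, B = FALSE, reBA = FALSE, reAB = FALSE),
    B_only          = c(A = FALSE, B = TRUE,  reBA = FALSE, reAB = FALSE),
    A_only          = c(A = TRUE,  B = FALSE, reBA = FALSE, reAB = FALSE),
    pseudo          = c(A = TRUE,  B = TRUE,  reBA = FALSE, reAB = FALSE),
    low_cooccupancy = c(A = FALSE, B = FALSE, reBA = TRUE,  reAB = TRUE),
    B_partial       = c(A = FALSE, B = TRUE,  reBA = TRUE,  reAB = TRUE),
    A_partial       = c(A = TRUE,  B = FALSE, reBA = TRUE,  reAB = TRUE),
    full_bivalent   = c(A = TRUE,  B = TRUE,  reBA = TRUE,  reAB = TRUE)
  )
}

#' The eight co-occupancy class labels
#'
#' Ordered from no occupancy to full co-occupancy: `unmodified` (no call),
#' `B_only`, `A_only`, `pseudo` (both primaries, no reChIP — marks on
#' different cells or alleles), `low_cooccupancy` (reChIPs only),
#' `B_partial`, `A_partial` (one primary plus both reChIPs — population
#' heterogeneity), `full_bivalent` (all four).
#'
#' @return Character vector of the eight labels.
#' @export
cooccupancy_classes <- function() names(core_class_patterns())

classify_one <- function(A, B, reBA, reAB) {
  if (reBA && reAB) {
    if (A && B) return("full_bivalent")
    if (A) return("A_partial")
    if (B) return("B_partial")
    return("low_cooccupancy")
  }
  if (!reBA && !reAB) {
    if (A && B) return("pseudo")
    if (A) return("A_only")
    if (B) return("B_only")
    return("unmodified")
  }
  NA_character_ # exactly one reChIP: irregular, resolved by caller
}

#' Classify regions into co-occupancy classes
#'
#' Maps per-region boolean enrichment calls for the two primary ChIPs over
#' input (`A`, `B`) and the two reciprocal reChIPs over input (`reBA`,
#' `reAB`) to the eight co-occupancy classes. Co-occupancy requires both
#' reciprocal reChIPs: the eight named patterns cover the call combinations
#' where the two reChIP calls agree. Combinations with exactly one reChIP
#' call (not interpretable as co-occupancy) are resolved by discounting the
#' lone reChIP call and re-classifying; such regions carry `irregular =
#' TRUE`.
#'
#' With `mode = "six_ratio"`, two additional reChIP-over-primary-ChIP call
#' columns (`reBA_over_B`, `reAB_over_A`) refine the bivalent classes:
#' `full_bivalent` requires all six calls, `A_partial` requires A, both
#' reChIPs over input and the A-reChIP over the B primary (with B and the
#' B-reChIP-over-A not enriched), symmetrically for `B_partial`; patterns
#' not matching these fall back to the four-call rule.
#'
#' @param calls Data frame with `region_id` and logical columns `A`, `B`,
#'   `reBA`, `reAB` (plus `reBA_over_B`, `reAB_over_A` for the six-ratio
#'   mode).
#' @param mode `"core"` (four over-input calls, default) or `"six_ratio"`.
#' @return The input tibble plus `class` (factor over
#'   [cooccupancy_classes()]) and `irregular` (logical).
#' @examples
#' calls <- tibble::tibble(region_id = c("x", "y"),
#'                         A = c(TRUE, TRUE), B = c(TRUE, TRUE),
#'                         reBA = c(TRUE, FALSE), reAB = c(TRUE, FALSE))
#' classify_regions(calls)$class # full_bivalent, pseudo
#' @export
classify_regions <- function(calls, mode = c("core", "six_ratio")) {
  mode <- match.arg(mode)
  core_cols <- c("A", "B", "reBA", "reAB")
  missing_cols <- setdiff(c("region_id", core_cols), names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0("`calls` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  calls <- tibble::as_tibble(calls)
  if (any(vapply(calls[core_cols], function(x) any(is.na(x)), logical(1)))) {
    abort("Missing values in the core call columns.")
  }

  cls <- purrr::pmap_chr(calls[core_cols], function(A, B, reBA, reAB) {
    classify_one(A, B, reBA, reAB)
  })
  irregular <- is.na(cls)
  if (any(irregular)) {
    # discount the lone reChIP call, re-classify
    cls[irregular] <- purrr::pmap_chr(
      calls[irregular, core_cols],
      function(A, B, reBA, reAB) classify_one(A, B, FALSE, FALSE))
  }

  if (mode == "six_ratio") {
    ext_cols <- c("reBA_over_B", "reAB_over_A")
    if (!all(ext_cols %in% names(calls))) {
      abort("Six-ratio mode needs columns reBA_over_B and reAB_over_A.")
    }
    six <- purrr::pmap_chr(
      calls[c(core_cols, ext_cols)],
      function(A, B, reBA, reAB, reBA_over_B, reAB_over_A) {
        if (A && B && reBA && reAB && reBA_over_B && reAB_over_A) {
          return("full_bivalent")
        }
        # A-partial: A enriched, both reChIPs over input, the A-directed
        # reChIP enriched over the B primary; B side quiet.
        if (A && !B && reBA && reAB && reAB_over_A && !reBA_over_B) {
          return("A_partial")
        }
        if (!A && B && reBA && reAB && reBA_over_B && !reAB_over_A) {
          return("B_partial")
        }
        NA_character_
      })
    cls <- dplyr::coalesce(six, cls)
  }

  calls$class <- factor(cls, levels = cooccupancy_classes())
  calls$irregular <- irregular
  calls
}

#' Drop regions without signal in every track
#'
#' Regions with a zero count in the control or in any supplied (re)ChIP
#' track carry no usable signal and are removed before classification.
#'
#' @param counts Data frame with `region_id` and one count column per track
#'   (control and all (re)ChIPs).
#' @return The rows where every count column is positive.
#' @export
drop_unobserved_regions <- function(counts) {
  stopifnot(is.data.frame(counts), "region_id" %in% names(counts))
  num <- dplyr::select(tibble::as_tibble(counts), -"region_id")
  keep <- Reduce(`&`, lapply(num, function(x) x > 0))
  counts[keep, , drop = FALSE]
}

#' Map promoter classes to a gene class
#'
#' A gene inherits the class of its promoters through a fixed decision
#' tree: the first class present in the order `A_only` > `A_partial` >
#' `pseudo` > `full_bivalent` > `B_partial` > `B_only` wins; a gene with no
#' classified promoter (or only `low_cooccupancy` promoters, which the tree
#' ignores) is `unmodified`. The result is invariant to promoter order and
#' multiplicity.
#'
#' @param region_classes Data frame with columns `gene_id` and `class`
#'   (values from [cooccupancy_classes()]).
#' @return A tibble `gene_id`, `class` with one row per gene.
#' @export
classify_genes <- function(region_classes) {
  stopifnot(is.data.frame(region_classes),
            all(c("gene_id", "class") %in% names(region_classes)))
  precedence <- c("A_only", "A_partial", "pseudo", "full_bivalent",
                  "B_partial", "B_only")
  region_classes |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(class = {
      present <- precedence[precedence %in% as.character(.data$class)]
      if (length(present) == 0) "unmodified" else present[1]
    }, .groups = "drop") |>
    dplyr::mutate(class = factor(.data$class,
                                 levels = c(precedence, "unmodified")))
}

#' Per-gene coefficient of variation and most-variable selection
#'
#' The coefficient of variation normalizes expression variability across
#' genes: CV = sample standard deviation (n-1 denominator) / mean, on the
#' original expression scale. Genes with non-positive mean are excluded
#' from ranking and flagged. `top_k` marks the k largest-CV genes; ties at
#' the cutoff are all included, so the realized selection may exceed k.
#'
#' @param expression Data frame with a `gene_id` column and one numeric
#'   column per sample (>= 2 samples).
#' @param top_k Optional number of most-variable genes to mark.
#' @return A tibble `gene_id`, `mean`, `sd`, `cv`, `excluded`, and — when
#'   `top_k` is given — logical `top`.
#' @export
expression_cv <- function(expression, top_k = NULL) {
  stopifnot(is.data.frame(expression), "gene_id" %in% names(expression))
  mat <- as.matrix(dplyr::select(tibble::as_tibble(expression), -"gene_id"))
  if (ncol(mat) < 2) {
    abort("Need at least two samples to compute a coefficient of variation.")
  }
  mu <- rowMeans(mat)
  sdev <- apply(mat, 1, sd)
  excluded <- mu <= 0
  cv <- ifelse(excluded, NA_real_, sdev / mu)
  out <- tibble::tibble(gene_id = expression$gene_id, mean = mu, sd = sdev,
                        cv = cv, excluded = excluded)
  if (!is.null(top_k)) {
    ranked <- sort(cv[!is.na(cv)], decreasing = TRUE)
    if (length(ranked) == 0) {
      out$top <- FALSE
    } else {
      cutoff <- ranked[min(top_k, length(ranked))]
      out$top <- !is.na(cv) & cv >= cutoff
    }
  }
  out
}

#' Class over-representation in a gene set
#'
#' For each co-occupancy class, tests whether genes of that class are over-
#' or under-represented in a gene set relative to a background universe,
#' with a two-sided Fisher's exact test on the 2x2 table (in-set & in-class,
#' in-set & other, out-of-set & in-class, out-of-set & other). The odds
#' ratio reported is the sample cross-product ratio ad/bc (0/Inf for empty
#' cells, flagged).
#'
#' @param gene_classes Data frame `gene_id`, `class`.
#' @param gene_set Character vector of gene ids (e.g. the most variable
#'   genes).
#' @param background Character vector of gene ids forming the universe;
#'   defaults to all genes in `gene_classes`.
#' @return A tibble with one row per class: counts `set_in_class`,
#'   `set_other`, `bg_in_class`, `bg_other`, the `odds_ratio`, two-sided
#'   `pvalue`, and `zero_cell` flag.
#' @export
class_set_enrichment <- function(gene_classes, gene_set,
                                 background = NULL) {
  stopifnot(is.data.frame(gene_classes),
            all(c("gene_id", "class") %in% names(gene_classes)))
  if (is.null(background)) background <- unique(gene_classes$gene_id)
  if (length(background) == 0 || length(gene_set) == 0) {
    abort("`gene_set` and `background` must be non-empty.")
  }
  gc <- gene_classes |>
    tibble::as_tibble() |>
    dplyr::filter(.data$gene_id %in% background) |>
    dplyr::mutate(in_set = .data$gene_id %in% gene_set)
  purrr::map_dfr(unique(as.character(gc$class)), function(cl) {
    in_class <- as.character(gc$class) == cl
    a <- sum(gc$in_set & in_class)
    b <- sum(gc$in_set & !in_class)
    c_ <- sum(!gc$in_set & in_class)
    d <- sum(!gc$in_set & !in_class)
    or <- (a * d) / (b * c_) # 0/Inf convention via IEEE division
    p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2,
                                   byrow = TRUE))$p.value
    tibble::tibble(class = cl, set_in_class = a, set_other = b,
                   bg_in_class = c_, bg_other = d, odds_ratio = or,
                   pvalue = p, zero_cell = any(c(a, b, c_, d) == 0))
  })
}
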