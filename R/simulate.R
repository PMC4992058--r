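#' Simulate paired region counts from the binomial mixture
#'
#' Draws, for each region, a latent component (background with probability
#' `p_b`), a total count `n` from the chosen distribution, a treatment count
#' `s ~ Binomial(n, theta)` with the component's theta, and sets the control
#' count `r = n - s`. The latent labels are returned alongside so parameter
#' recovery and false-discovery behaviour can be checked against ground
#' truth.
#'
#' @param n_regions Number of regions to simulate.
#' @param p_b Background mixture proportion in \[0, 1\].
#' @param theta_b,theta_e Component treatment-read proportions in (0, 1).
#' @param totals Totals model: `"poisson"` (Poisson(`mean_total`) truncated at
#'   1), `"fixed"` (all totals equal `fixed_total`), or `"empirical"`
#'   (sampled with replacement from `totals_pool`).
#' @param mean_total Mean of the Poisson totals model.
#' @param fixed_total Common total for the fixed model.
#' @param totals_pool Integer vector for the empirical model.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return A list with `counts` (tibble: `region_id`, `r`, `s`, `n`) and
#'   `truth` (tibble: `region_id`, `component` in
#'   \{"background", "enrichment"\}, plus the generating parameters as
#'   attributes).
#' @examples
#' sim <- simulate_region_counts(100, 0.9, 0.4, 0.7, seed = 1)
#' table(sim$truth$component)
#' @export
simulate_region_counts <- function(n_regions, p_b, theta_b, theta_e,
                                   totals = c("poisson", "fixed", "empirical"),
                                   mean_total = 100, fixed_total = 100,
                                   totals_pool = NULL, seed = NULL) {
  totals <- match.arg(totals)
  if (n_regions < 1) abort("`n_regions` must be at least 1.")
  if (!is.finite(p_b) || p_b < 0 || p_b > 1) abort("`p_b` must lie in [0, 1].")
  check_params(max(p_b, 1e-12), theta_b, theta_e)

  out <- with_seed(seed, {
    component <- ifelse(runif(n_regions) < p_b, "background", "enrichment")
    n <- switch(totals,
      poisson = {
        # Poisson truncated at >= 1 by resampling zeros
        x <- rpois(n_regions, mean_total)
        while (any(x == 0)) x[x == 0] <- rpois(sum(x == 0), mean_total)
        x
      },
      fixed = rep(as.integer(fixed_total), n_regions),
      empirical = {
        if (is.null(totals_pool) || length(totals_pool) == 0) {
          abort("`totals_pool` must be supplied for the empirical totals model.")
        }
        sample(as.integer(totals_pool), n_regions, replace = TRUE)
      })
    theta <- ifelse(component == "background", theta_b, theta_e)
    s <- rbinom(n_regions, n, theta)
    list(component = component, n = n, s = s)
  })

  ids <- sprintf("region_%05d", seq_len(n_regions))
  counts <- tibble::tibble(region_id = ids,
                           r = out$n - out$s, s = out$s, n = out$n)
  truth <- tibble::tibble(region_id = ids, component = out$component)
  attr(truth, "params") <- list(p_b = p_b, theta_b = theta_b,
                                theta_e = theta_e, totals = totals, seed = seed)
  list(counts = counts, truth = truth)
}

#' Simulate paired-end alignments as SAM records
#'
#' Builds a valid SAM file from a table of fragment specifications: one
#' proper read pair per fragment with consistent mates, signed template
#' lengths (positive on the leftmost mate), and the requested mapping
#' quality and extra flag bits on both mates. Intended as a fixture
#' generator for the fragment filters and midpoint counting.
#'
#' @param fragments Data frame with columns `chrom`, `pos` (0-based leftmost
#'   fragment position), `tlen` (fragment/template length, > 0), `mapq`, and
#'   optionally `flags` (extra flag bits OR-ed onto the proper-pair flags,
#'   e.g. 1024 for duplicates; default 0).
#' @param chrom_sizes Named integer vector of chromosome lengths for the SAM
#'   header.
#' @param path Output SAM path.
#' @param read_length Read length used for both mates; capped at the
#'   template length.
#' @return `path`, invisibly. Fragments are written in input order.
#' @export
simulate_alignments <- function(fragments, chrom_sizes, path,
                                read_length = 50L) {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "pos", "tlen", "mapq") %in% names(fragments)))
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "")) {
    abort("`chrom_sizes` must be a named vector of chromosome lengths.")
  }
  fragments <- tibble::as_tibble(fragments)
  if (!"flags" %in% names(fragments)) fragments$flags <- 0L
  if (any(fragments$tlen <= 0)) abort("Fragment `tlen` must be positive.")
  bad_chrom <- setdiff(unique(fragments$chrom), names(chrom_sizes))
  if (length(bad_chrom) > 0) {
    abort(paste0("Fragment chromosome(s) absent from `chrom_sizes`: ",
                 paste(bad_chrom, collapse = ", ")))
  }
  over <- fragments$pos + fragments$tlen >
    unname(chrom_sizes[fragments$chrom])
  if (any(over)) {
    abort(sprintf("Fragment %d extends past the end of its chromosome.",
                  which(over)[1]))
  }

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                      as.integer(chrom_sizes)))
  rl <- pmin(as.integer(read_length), as.integer(fragments$tlen))
  pos1 <- as.integer(fragments$pos) + 1L           # SAM is 1-based
  pos2 <- as.integer(fragments$pos + fragments$tlen) - rl + 1L
  qname <- sprintf("frag%06d", seq_len(nrow(fragments)))
  extra <- as.integer(fragments$flags)
  # 99  = paired, proper, mate reverse, first in pair
  # 147 = paired, proper, reverse, second in pair
  rec <- function(name, flag, chrom, pos, mapq, cigar, mpos, tlen, len) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s",
            name, flag, chrom, pos, mapq, cigar, mpos, tlen,
            strrep("A", len), strrep("I", len))
  }
  lines1 <- rec(qname, 99L + extra, fragments$chrom, pos1, fragments$mapq,
                paste0(rl, "M"), pos2, as.integer(fragments$tlen), rl)
  lines2 <- rec(qname, 147L + extra, fragments$chrom, pos2, fragments$mapq,
                paste0(rl, "M"), pos1, -as.integer(fragments$tlen), rl)
  writeLines(c(header, as.vector(rbind(lines1, lines2))), path)
  invisible(path)
}

#' Simulate a DNA sequence with a target G+C content
#'
#' Draws i.i.d. bases with `P(C) = P(G) = gc_target / 2` and
#' `P(A) = P(T) = (1 - gc_target) / 2`. Because bases are independent, the
#' observed/expected CpG odds of long simulated sequences concentrate
#' around 1.
#'
#' @param length Sequence length (>= 1).
#' @param gc_target Target G+C fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return A single character string over A, C, G, T.
#' @export
simulate_dna <- function(length, gc_target = 0.5, seed = NULL) {
  if (length < 1) abort("`length` must be at least 1.")
  if (!is.finite(gc_target) || gc_target < 0 || gc_target > 1) {
    abort("`gc_target` must lie in [0, 1].")
  }
  probs <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
             G = gc_target / 2, T = (1 - gc_target) / 2)
  with_seed(seed, {
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = "")
  })
}

#' Simulate correlated enrichment-call tracks from latent region states
#'
#' Assigns each region one of the eight co-occupancy pattern labels and
#' generates the four over-input call tracks (A, B, reBA, reAB) from the
#' label's ideal pattern, flipping each call independently with probability
#' `1 - detection`. This produces realistic imperfect call sets for testing
#' the classifier; it makes no claim of matching any particular biology.
#'
#' @param n_regions Number of regions.
#' @param class_probs Named probabilities over the eight labels (see
#'   [cooccupancy_classes()]); defaults to uniform.
#' @param detection Per-track probability that a call matches the latent
#'   pattern.
#' @param seed Integer seed.
#' @return A list with `calls` (tibble: `region_id`, logical `A`, `B`,
#'   `reBA`, `reAB`) and `truth` (tibble: `region_id`, `class`).
#' @export
simulate_call_tracks <- function(n_regions, class_probs = NULL,
                                 detection = 1, seed = NULL) {
  patterns <- core_class_patterns()
  labels <- names(patterns)
  if (is.null(class_probs)) {
    class_probs <- setNames(rep(1 / length(labels), length(labels)), labels)
  }
  stopifnot(all(names(class_probs) %in% labels))
  with_seed(seed, {
    cls <- sample(names(class_probs), n_regions, replace = TRUE,
                  prob = class_probs)
    ideal <- do.call(rbind, patterns[cls])
    flip <- matrix(runif(length(ideal)) > detection, nrow = n_regions)
    calls <- xor(ideal, flip)
    ids <- sprintf("region_%05d", seq_len(n_regions))
    list(calls = tibble::tibble(region_id = ids,
                                A = calls[, 1], B = calls[, 2],
                                reBA = calls[, 3], reAB = calls[, 4]),
         truth = tibble::tibble(region_id = ids, class = cls))
  })
}
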