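#' Call enrichment of a treatment library over a control
#'
#' End-to-end enrichment calling on a table of paired (control, treatment)
#' region counts: fits the binomial mixture by EM ([fit_mixture()]), tests
#' each region against the fitted background ([enrichment_pvalues()]),
#' removes discrete tests that cannot reach significance
#' ([tmethod_filter()]), converts the retained p-values to q-values
#' ([enrich_qvalues()]), computes regularized and normalized log enrichment
#' ([regularized_enrichment()]), and thresholds calls at each requested FDR.
#'
#' @inheritParams fit_mixture
#' @param p_filter T-method retention threshold on the minimal achievable
#'   p-value.
#' @param fdr Numeric vector of FDR thresholds at which to produce boolean
#'   calls.
#' @param estimate_pi0 Passed to [enrich_qvalues()].
#' @return An object of class `rechip_enrich` wrapping the `mixture_fit` and
#'   a per-region results tibble (see [augment.rechip_enrich()]).
#' @examples
#' sim <- simulate_region_counts(1000, p_b = 0.9, theta_b = 0.4,
#'                               theta_e = 0.7, seed = 7)
#' res <- enrich(sim$counts, seed = 7)
#' res
#' dplyr::count(augment(res), called_q0.01)
#' @export
enrich <- function(counts, epsilon = 0.001, max_iter = 1000L,
                   n_starts = 10L, seed = NULL, p_filter = 1e-4,
                   fdr = c(0.001, 0.01, 0.1), estimate_pi0 = FALSE) {
  fit <- fit_mixture(counts, epsilon = epsilon, max_iter = max_iter,
                     n_starts = n_starts, seed = seed)
  counts <- fit$counts
  pvals <- enrichment_pvalues(counts, fit$theta_b)
  keep <- tmethod_filter(counts, fit$theta_b, p_threshold = p_filter)
  qvals <- enrich_qvalues(pvals, keep, estimate_pi0 = estimate_pi0)
  scores <- regularized_enrichment(fit)

  results <- dplyr::bind_cols(
    counts,
    tibble::tibble(posterior_b = fit$posterior_b, pvalue = pvals,
                   filter_pass = keep, qvalue = qvals),
    dplyr::select(scores, "e_star", "e_norm"))
  for (f in fdr) {
    results[[paste0("called_q", format(f, scientific = FALSE))]] <-
      call_enriched(qvals, f)
  }
  structure(list(fit = fit, results = results, fdr = fdr,
                 p_filter = p_filter),
            class = "rechip_enrich")
}

#' @export
print.rechip_enrich <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  T-method filter (p <= %g): %d of %d regions retained\n",
              x$p_filter, sum(x$results$filter_pass), nrow(x$results)))
  for (f in x$fdr) {
    col <- paste0("called_q", format(f, scientific = FALSE))
    cat(sprintf("  called at FDR %g: %d\n", f, sum(x$results[[col]])))
  }
  invisible(x)
}

#' Tidy the fitted mixture components
#'
#' @param x A `rechip_enrich` or `mixture_fit` object.
#' @param ... Unused.
#' @return A two-row tibble, one per mixture component, with columns
#'   `component`, `weight` and `theta` (treatment-read proportion).
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(component = c("background", "enrichment"),
                 weight = c(x$p_b, 1 - x$p_b),
                 theta = c(x$theta_b, x$theta_e))
}

#' @rdname tidy.mixture_fit
#' @export
tidy.rechip_enrich <- function(x, ...) tidy(x$fit)

#' One-row model summary
#'
#' @param x A `rechip_enrich` or `mixture_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `p_b`, `theta_b`, `theta_e`, `loglik`,
#'   `iterations`, `converged` and `n_regions`.
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(p_b = x$p_b, theta_b = x$theta_b, theta_e = x$theta_e,
                 loglik = x$loglik, iterations = x$iterations,
                 converged = x$converged, n_regions = x$n_regions)
}

#' @rdname glance.mixture_fit
#' @export
glance.rechip_enrich <- function(x, ...) glance(x$fit)

#' Per-region enrichment results
#'
#' @param x A `rechip_enrich` object.
#' @param ... Unused.
#' @return A tibble with one row per region: the input counts plus
#'   `posterior_b`, `pvalue`, `filter_pass`, `qvalue` (`NA` when filtered
#'   out), `e_star`, `e_norm`, and one logical `called_q<f>` column per FDR
#'   threshold.
#' @export
augment.rechip_enrich <- function(x, ...) x$results

#' Diagnostic plots for an enrichment fit
#'
#' @param object A `rechip_enrich` object.
#' @param type One of `"fit"` (counts coloured by background posterior),
#'   `"trace"` (EM log-likelihood trace) or `"enrichment"` (histogram of the
#'   normalized enrichment).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rechip_enrich <- function(object, type = c("fit", "trace",
                                                    "enrichment"), ...) {
  type <- match.arg(type)
  res <- object$results
  if (type == "fit") {
    ggplot2::ggplot(res, ggplot2::aes(x = .data$r, y = .data$s,
                                      colour = .data$posterior_b)) +
      ggplot2::geom_point(alpha = 0.5, size = 0.8) +
      ggplot2::scale_colour_viridis_c(name = "P(background)") +
      ggplot2::labs(x = "control count", y = "treatment count") +
      ggplot2::theme_minimal()
  } else if (type == "trace") {
    trace <- tibble::tibble(iteration = seq_along(object$fit$loglik_trace),
                            loglik = object$fit$loglik_trace)
    ggplot2::ggplot(trace, ggplot2::aes(x = .data$iteration,
                                        y = .data$loglik)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "EM iteration", y = "log-likelihood") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(res, ggplot2::aes(x = .data$e_norm)) +
      ggplot2::geom_histogram(bins = 60) +
      ggplot2::labs(x = "normalized enrichment e", y = "regions") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
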