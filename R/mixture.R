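#' @importFrom rlang .data abort warn .env
#' @importFrom stats dbinom pbinom p.adjust rbinom rpois runif sd setNames
NULL

# Validate a counts data frame: needs region_id, r, s; adds n = r + s.
# Returns a tibble with columns region_id, r, s, n.
as_region_counts <- function(counts) {
  if (!is.data.frame(counts)) {
    abort("`counts` must be a data frame with columns region_id, r, s.")
  }
  missing_cols <- setdiff(c("region_id", "r", "s"), names(counts))
  if (length(missing_cols) > 0) {
    abort(paste0("`counts` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(counts$r < 0) || any(counts$s < 0)) {
    abort("Counts `r` and `s` must be non-negative.")
  }
  if (anyDuplicated(counts$region_id)) {
    abort("`region_id` values must be unique.")
  }
  dplyr::mutate(tibble::as_tibble(counts),
                r = as.numeric(.data$r),
                s = as.numeric(.data$s),
                n = .data$r + .data$s)
}

check_params <- function(p_b, theta_b, theta_e) {
  if (!is.finite(p_b) || p_b < 0 || p_b > 1) {
    abort("`p_b` must lie in [0, 1].")
  }
  if (!is.finite(theta_b) || theta_b <= 0 || theta_b >= 1 ||
      !is.finite(theta_e) || theta_e <= 0 || theta_e >= 1) {
    abort("`theta_b` and `theta_e` must lie strictly inside (0, 1).")
  }
  invisible(NULL)
}

# Per-region log mixture density log(p_B Bin(s; n, tB) + (1-p_B) Bin(s; n, tE)),
# computed by log-sum-exp on log pmfs; regions with n = 0 contribute 0.
mixture_log_density <- function(s, n, p_b, theta_b, theta_e) {
  lb <- dbinom(s, n, theta_b, log = TRUE)
  le <- dbinom(s, n, theta_e, log = TRUE)
  if (p_b == 1) {
    out <- lb
  } else if (p_b == 0) {
    out <- le
  } else {
    a <- log(p_b) + lb
    b <- log1p(-p_b) + le
    m <- pmax(a, b)
    out <- m + log(exp(a - m) + exp(b - m))
  }
  out[n == 0] <- 0
  out
}

#' Log-likelihood of the binomial mixture model
#'
#' Evaluates the log-likelihood of paired (control, treatment) counts under a
#' two-component binomial mixture. Conditional on the per-region total
#' \eqn{n_i = r_i + s_i}, the treatment count follows
#' \eqn{s_i \sim p_B\,\mathrm{Bin}(n_i, \theta_B) +
#' (1 - p_B)\,\mathrm{Bin}(n_i, \theta_E)}, where \eqn{\theta_B} and
#' \eqn{\theta_E} are the treatment-read proportions in the background and
#' enrichment components and \eqn{p_B} the background mixture weight.
#'
#' @param counts Data frame with columns `region_id`, `r` (control count) and
#'   `s` (treatment count).
#' @param p_b Background mixture proportion in \[0, 1\].
#' @param theta_b,theta_e Component treatment-read proportions, each in (0, 1).
#' @return A single number: the summed log-likelihood. Regions with
#'   \eqn{n_i = 0} contribute zero.
#' @examples
#' counts <- tibble::tibble(region_id = "a", r = 1, s = 1)
#' mixture_loglik(counts, p_b = 1, theta_b = 0.5, theta_e = 0.9) # log(0.5)
#' @export
mixture_loglik <- function(counts, p_b, theta_b, theta_e) {
  check_params(p_b, theta_b, theta_e)
  counts <- as_region_counts(counts)
  if (nrow(counts) == 0) abort("`counts` must be non-empty.")
  sum(mixture_log_density(counts$s, counts$n, p_b, theta_b, theta_e))
}

#' Posterior probability of the background component
#'
#' Computes, for every region, the posterior probability \eqn{z_i} that its
#' counts were generated by the background component:
#' \deqn{z_i = \frac{p_B \mathrm{Bin}(s_i; n_i, \theta_B)}
#'   {p_B \mathrm{Bin}(s_i; n_i, \theta_B) +
#'    (1-p_B) \mathrm{Bin}(s_i; n_i, \theta_E)}.}
#' Regions with \eqn{n_i = 0} carry no information and get \eqn{z_i = p_B}.
#'
#' @inheritParams mixture_loglik
#' @return Numeric vector of posteriors in \[0, 1\], one per region.
#' @export
posterior_background <- function(counts, p_b, theta_b, theta_e) {
  check_params(p_b, theta_b, theta_e)
  counts <- as_region_counts(counts)
  if (p_b == 1) return(rep(1, nrow(counts)))
  if (p_b == 0) return(rep(0, nrow(counts)))
  lb <- log(p_b) + dbinom(counts$s, counts$n, theta_b, log = TRUE)
  le <- log1p(-p_b) + dbinom(counts$s, counts$n, theta_e, log = TRUE)
  z <- 1 / (1 + exp(le - lb))
  z[counts$n == 0] <- p_b
  z
}

# One EM run from a given start; returns list(p_b, theta_b, theta_e, trace, z,
# converged, iterations). Counts must already be validated; informative =
# logical mask of regions with n > 0.
em_run <- function(s, n, informative, p_b, theta_b, theta_e,
                   epsilon, max_iter) {
  n_inf <- sum(informative)
  clip <- function(x) pmin(pmax(x, 1e-9), 1 - 1e-9)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  z <- rep(p_b, length(s))
  for (iter in seq_len(max_iter)) {
    # E-step
    lb <- log(clip(p_b)) + dbinom(s, n, theta_b, log = TRUE)
    le <- log(clip(1 - p_b)) + dbinom(s, n, theta_e, log = TRUE)
    m <- pmax(lb, le)
    ld <- m + log(exp(lb - m) + exp(le - m))
    z <- exp(lb - ld)
    z[!informative] <- p_b
    ll <- sum(ld[informative])
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= epsilon) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step (regions with n = 0 excluded from all sums)
    zi <- z[informative]
    si <- s[informative]
    ni <- n[informative]
    p_b <- sum(zi) / n_inf
    theta_b <- clip(sum(zi * si) / sum(zi * ni))
    theta_e <- clip(sum((1 - zi) * si) / sum((1 - zi) * ni))
  }
  list(p_b = p_b, theta_b = theta_b, theta_e = theta_e, trace = trace,
       z = z, converged = converged, iterations = length(trace))
}

#' Fit the binomial mixture by expectation-maximization
#'
#' Estimates \eqn{(p_B, \theta_B, \theta_E)} by EM, running one deterministic
#' start plus `n_starts` jittered restarts and keeping the run with the
#' highest final log-likelihood. The deterministic start places both
#' \eqn{\theta} symmetrically around the pooled treatment proportion
#' \eqn{s_{tot}/(r_{tot}+s_{tot})} at offset 0.1 with \eqn{p_B = 0.9}.
#' Components are relabelled after fitting so that
#' \eqn{\theta_B \le \theta_E} ("background" is the lower-treatment
#' component); posteriors are flipped accordingly.
#'
#' @inheritParams mixture_loglik
#' @param epsilon Convergence tolerance on the absolute change of the
#'   log-likelihood between iterations.
#' @param max_iter Maximum number of EM iterations per start.
#' @param n_starts Number of additional random restarts.
#' @param seed Optional integer seed for the restart jitter.
#' @return An object of class `mixture_fit`: a list with elements `p_b`,
#'   `theta_b`, `theta_e`, `posterior_b` (per-region background posterior),
#'   `loglik_trace`, `loglik`, `iterations`, `converged`, `epsilon`,
#'   `n_regions` (regions with \eqn{n > 0}) and `counts` (the validated
#'   input).
#' @examples
#' sim <- simulate_region_counts(500, p_b = 0.9, theta_b = 0.4,
#'                               theta_e = 0.7, seed = 1)
#' fit <- fit_mixture(sim$counts, seed = 1)
#' glance(fit)
#' @export
fit_mixture <- function(counts, epsilon = 0.001, max_iter = 1000L,
                        n_starts = 10L, seed = NULL) {
  counts <- as_region_counts(counts)
  informative <- counts$n > 0
  if (sum(informative) < 2) {
    abort("Need at least two regions with positive total counts.")
  }
  if (sum(counts$s) == 0 || sum(counts$r) == 0) {
    abort(paste("Model is unidentifiable: both libraries must contain reads",
                "across the region set."))
  }
  if (epsilon <= 0) abort("`epsilon` must be positive.")

  clip <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  theta0 <- sum(counts$s) / sum(counts$n)
  starts <- list(c(p_b = 0.9,
                   theta_b = clip(theta0 - 0.1),
                   theta_e = clip(theta0 + 0.1)))
  if (n_starts > 0) {
    jitter <- with_seed(seed, {
      lapply(seq_len(n_starts), function(i) {
        tb <- clip(theta0 + runif(1, -0.25, 0.25))
        te <- clip(theta0 + runif(1, -0.25, 0.25))
        c(p_b = runif(1, 0.5, 0.99),
          theta_b = min(tb, te), theta_e = max(tb, te))
      })
    })
    starts <- c(starts, jitter)
  }

  runs <- lapply(starts, function(st) {
    run <- em_run(counts$s, counts$n, informative,
                  st[["p_b"]], st[["theta_b"]], st[["theta_e"]],
                  epsilon, max_iter)
    # enforce theta_b <= theta_e by component swap
    if (run$theta_b > run$theta_e) {
      tmp <- run$theta_b
      run$theta_b <- run$theta_e
      run$theta_e <- tmp
      run$p_b <- 1 - run$p_b
      run$z <- 1 - run$z
    }
    run
  })
  # Testing against the background presumes it describes the bulk of
  # regions; solutions whose "background" holds a vanishing share are
  # degenerate for enrichment calling (pseudo counts and tests driven by a
  # handful of regions). Prefer the best majority-background solution; fall
  # back to the overall maximum only when no start yields one.
  lls <- vapply(runs, function(r) dplyr::last(r$trace), numeric(1))
  majority <- vapply(runs, function(r) r$p_b >= 0.5, logical(1))
  best <- if (any(majority)) {
    runs[majority][[which.max(lls[majority])]]
  } else {
    runs[[which.max(lls)]]
  }
  if (!best$converged) {
    warn(sprintf("EM did not converge within %d iterations; returning best iterate.",
                 max_iter))
  }
  structure(
    list(p_b = best$p_b, theta_b = best$theta_b, theta_e = best$theta_e,
         posterior_b = best$z, loglik_trace = best$trace,
         loglik = dplyr::last(best$trace), iterations = best$iterations,
         converged = best$converged, epsilon = epsilon,
         n_regions = sum(informative), counts = counts),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component binomial mixture fit\n")
  cat(sprintf("  regions (n > 0): %d\n", x$n_regions))
  cat(sprintf("  p_B = %.4f, theta_B = %.4f, theta_E = %.4f\n",
              x$p_b, x$theta_b, x$theta_e))
  cat(sprintf("  log-likelihood %.4f after %d iterations (%s)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' One-sided enrichment p-values against the fitted background
#'
#' Tests every region for treatment enrichment over the background component:
#' the p-value is the upper tail \eqn{P(S \ge s_i \mid n_i, \hat\theta_B)} of
#' the binomial distribution. Regions with \eqn{n_i = 0} get p = 1.
#'
#' @inheritParams mixture_loglik
#' @param theta_b Background treatment-read proportion (typically the fitted
#'   value), in (0, 1).
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
enrichment_pvalues <- function(counts, theta_b) {
  if (!is.finite(theta_b) || theta_b <= 0 || theta_b >= 1) {
    abort("`theta_b` must lie strictly inside (0, 1).")
  }
  counts <- as_region_counts(counts)
  p <- pbinom(counts$s - 1, counts$n, theta_b, lower.tail = FALSE)
  p[counts$n == 0] <- 1
  pmin(p, 1)
}

#' T-method filter for discrete tests
#'
#' Discrete one-sided binomial tests with small totals cannot reach
#' significance no matter how extreme the observation; keeping them inflates
#' multiple-testing corrections. The filter retains a region only if its
#' minimal achievable p-value, \eqn{\hat\theta_B^{\,n_i}} (all \eqn{n_i} reads
#' in the treatment), is at most `p_threshold`.
#'
#' @inheritParams enrichment_pvalues
#' @param p_threshold Retention threshold on the minimal achievable p-value.
#' @return Logical vector: `TRUE` where the region is retained. Regions with
#'   \eqn{n_i = 0} are always dropped unless `p_threshold >= 1`.
#' @export
tmethod_filter <- function(counts, theta_b, p_threshold = 1e-4) {
  if (!is.finite(theta_b) || theta_b <= 0 || theta_b >= 1) {
    abort("`theta_b` must lie strictly inside (0, 1).")
  }
  counts <- as_region_counts(counts)
  # log-scale comparison: min achievable p = theta_b ^ n
  counts$n * log(theta_b) <= log(p_threshold)
}

#' q-values on a retained subset
#'
#' Applies the monotone step-up transform to the p-values of the retained
#' regions only; filtered-out entries are returned as `NA`. With `pi0 = 1`
#' (the default) this equals Benjamini-Hochberg adjusted p-values. Setting
#' `estimate_pi0 = TRUE` scales them by a fixed-lambda (0.5) estimate of the
#' null proportion.
#'
#' @param pvalues Numeric vector of p-values.
#' @param keep Logical vector marking the retained subset (same length).
#' @param estimate_pi0 If `TRUE`, multiply BH values by
#'   \eqn{\hat\pi_0 = \min(1, \#\{p > \lambda\} / ((1-\lambda) m))} with
#'   \eqn{\lambda = 0.5}.
#' @return Numeric vector of q-values, `NA` outside the retained subset.
#' @export
enrich_qvalues <- function(pvalues, keep = rep(TRUE, length(pvalues)),
                           estimate_pi0 = FALSE) {
  stopifnot(length(pvalues) == length(keep))
  q <- rep(NA_real_, length(pvalues))
  if (!any(keep)) {
    warn("No regions retained by the filter; all q-values are NA.")
    return(q)
  }
  p <- pvalues[keep]
  pi0 <- 1
  if (estimate_pi0) {
    lambda <- 0.5
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  }
  q[keep] <- pmin(1, pi0 * p.adjust(p, method = "BH"))
  q
}

#' Background pseudo counts
#'
#' Posterior-weighted average control and treatment counts of the background
#' component, used to regularize log-enrichment at low coverage.
#'
#' @inheritParams mixture_loglik
#' @param posterior_b Per-region background posterior probabilities
#'   \eqn{z_i}.
#' @return A list with elements `pseudo_r` and `pseudo_s`:
#'   \eqn{\sum z_i r_i / \sum z_i} and \eqn{\sum z_i s_i / \sum z_i}.
#' @export
pseudo_counts <- function(counts, posterior_b) {
  counts <- as_region_counts(counts)
  stopifnot(length(posterior_b) == nrow(counts))
  zsum <- sum(posterior_b)
  if (zsum <= 0) {
    abort("Degenerate background: all posterior weights are zero.")
  }
  list(pseudo_r = sum(posterior_b * counts$r) / zsum,
       pseudo_s = sum(posterior_b * counts$s) / zsum)
}

#' Regularized and normalized log enrichment
#'
#' The regularized log enrichment shifts the pseudo-count-stabilized log
#' ratio so the background component sits at zero:
#' \deqn{e^*_i = \log_2\frac{s_i + \tilde s}{r_i + \tilde r} -
#'   \log_2\frac{\tilde s}{\tilde r},}
#' with \eqn{(\tilde r, \tilde s)} the background pseudo counts. The
#' normalized enrichment divides by the log average enrichment factor — the
#' log odds ratio between the enrichment and background components — so that
#' a fully enriched region scores close to 1:
#' \deqn{e_i = e^*_i \Big/ \log_2\frac{\theta_E/(1-\theta_E)}
#'   {\theta_B/(1-\theta_B)}.}
#'
#' @param fit A `mixture_fit` object from [fit_mixture()].
#' @param counts Optional counts table; defaults to the counts the model was
#'   fitted on.
#' @return A tibble with columns `region_id`, `e_star`, `e_norm`. `e_norm` is
#'   `NA` when \eqn{\hat\theta_B = \hat\theta_E} (no enrichment component).
#' @export
regularized_enrichment <- function(fit, counts = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  # pseudo counts characterize the fitted background, so they always come
  # from the counts the model was fitted on
  ps <- pseudo_counts(fit$counts, fit$posterior_b)
  counts <- if (is.null(counts)) fit$counts else as_region_counts(counts)
  if (ps$pseudo_r <= 0 || ps$pseudo_s <= 0) {
    abort("Degenerate background: pseudo counts must be positive.")
  }
  e_star <- log2((counts$s + ps$pseudo_s) / (counts$r + ps$pseudo_r)) -
    log2(ps$pseudo_s / ps$pseudo_r)
  denom <- log2((fit$theta_e / (1 - fit$theta_e)) /
                  (fit$theta_b / (1 - fit$theta_b)))
  e_norm <- if (denom > 0) e_star / denom else rep(NA_real_, length(e_star))
  tibble::tibble(region_id = counts$region_id,
                 e_star = e_star, e_norm = e_norm)
}

#' Threshold q-values into enrichment calls
#'
#' @param qvalues Numeric vector of q-values (`NA` = filtered out).
#' @param fdr Target false discovery rate, strictly inside (0, 1).
#' @return Logical vector: `TRUE` where the q-value is defined and at most
#'   `fdr`.
#' @export
call_enriched <- function(qvalues, fdr) {
  if (!is.numeric(fdr) || length(fdr) != 1 || !is.finite(fdr) ||
      fdr <= 0 || fdr >= 1) {
    abort("`fdr` must be a single number strictly inside (0, 1).")
  }
  !is.na(qvalues) & qvalues <= fdr
}
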