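# Independent oracles used to freeze expected values. These deliberately use
# naive arithmetic (choose(), ^, explicit loops) rather than the package's
# vectorized log-space code paths.

# Direct per-region mixture pmf summation in log space.
oracle_mixture_loglik <- function(r, s, p_b, theta_b, theta_e) {
  total <- 0
  for (i in seq_along(r)) {
    n <- r[i] + s[i]
    if (n == 0) next
    pmf_b <- choose(n, s[i]) * theta_b^s[i] * (1 - theta_b)^(n - s[i])
    pmf_e <- choose(n, s[i]) * theta_e^s[i] * (1 - theta_e)^(n - s[i])
    total <- total + log(p_b * pmf_b + (1 - p_b) * pmf_e)
  }
  total
}

# Direct posterior via the two pmfs.
oracle_posterior <- function(r, s, p_b, theta_b, theta_e) {
  vapply(seq_along(r), function(i) {
    n <- r[i] + s[i]
    if (n == 0) return(p_b)
    pmf_b <- choose(n, s[i]) * theta_b^s[i] * (1 - theta_b)^(n - s[i])
    pmf_e <- choose(n, s[i]) * theta_e^s[i] * (1 - theta_e)^(n - s[i])
    p_b * pmf_b / (p_b * pmf_b + (1 - p_b) * pmf_e)
  }, numeric(1))
}

# Exhaustive upper-tail binomial p-value.
oracle_upper_tail <- function(s, n, theta) {
  if (n == 0) return(1)
  sum(vapply(s:n, function(k) choose(n, k) * theta^k * (1 - theta)^(n - k),
             numeric(1)))
}

# Exhaustive grid search over (p_b, theta_b, theta_e) at a fixed step,
# restricted to theta_b <= theta_e. Returns the best log-likelihood.
oracle_grid_loglik <- function(counts, step = 0.01) {
  thetas <- seq(step, 1 - step, by = step)
  pbs <- seq(0, 1, by = step)
  s <- counts$s
  n <- counts$r + counts$s
  # pmf per theta, rows = regions; mixture evaluated for every weight at once
  pmf <- vapply(thetas, function(th) dbinom(s, n, th), numeric(length(s)))
  best <- -Inf
  for (ib in seq_along(thetas)) {
    for (ie in ib:length(thetas)) {
      ll <- colSums(log(outer(pmf[, ib], pbs) + outer(pmf[, ie], 1 - pbs)))
      m <- max(ll)
      if (m > best) best <- m
    }
  }
  best
}

# Two-sided Fisher p by enumeration over all tables with the observed
# margins: sum hypergeometric probabilities <= that of the observed table.
oracle_fisher_two_sided <- function(a, b, c_, d) {
  m <- a + c_          # column 1 total
  k <- a + b           # row 1 total
  n_tot <- a + b + c_ + d
  avals <- max(0, k - (n_tot - m)):min(k, m)
  probs <- vapply(avals, function(x) {
    choose(m, x) * choose(n_tot - m, k - x) / choose(n_tot, k)
  }, numeric(1))
  p_obs <- probs[avals == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive double-loop point-in-interval tally (0-based half-open regions).
oracle_count_in_regions <- function(midpoints, chroms, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(chroms == regions$chrom[i] &
          midpoints >= regions$start[i] & midpoints < regions$end[i])
  }, integer(1))
}

# Small deterministic counts fixture shared across tests.
make_counts <- function(r, s, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("reg%03d", seq_along(r))
  tibble::tibble(region_id = ids, r = r, s = s)
}
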