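test_that("mixture log-likelihood matches closed forms and the pmf oracle", {
  # degenerate one-component case: Bin(2, 0.5) at s = 1 has pmf 0.5
  one <- make_counts(r = 1, s = 1)
  expect_equal(mixture_loglik(one, p_b = 1, theta_b = 0.5, theta_e = 0.9),
               log(0.5))

  # equal thetas collapse the mixture regardless of the weight
  cts <- make_counts(r = c(3, 0, 10), s = c(2, 5, 0))
  expect_equal(mixture_loglik(cts, 0.5, 0.3, 0.3),
               mixture_loglik(cts, 1, 0.3, 0.5))

  # 10 fixed regions against the brute-force oracle
  set.seed(42)
  r <- c(5, 2, 9, 0, 7, 3, 1, 8, 4, 6)
  s <- c(1, 6, 0, 4, 2, 7, 3, 5, 9, 8)
  cts10 <- make_counts(r, s)
  expect_equal(mixture_loglik(cts10, 0.8, 0.4, 0.7),
               oracle_mixture_loglik(r, s, 0.8, 0.4, 0.7))

  # regions with n = 0 contribute nothing
  with_zero <- make_counts(r = c(5, 0), s = c(3, 0))
  expect_equal(mixture_loglik(with_zero, 0.8, 0.4, 0.7),
               mixture_loglik(make_counts(5, 3), 0.8, 0.4, 0.7))

  expect_error(mixture_loglik(cts10, 0.8, 0, 0.7), "inside")
  expect_error(mixture_loglik(cts10, 1.2, 0.4, 0.7), "\\[0, 1\\]")
})

test_that("background posteriors match the direct pmf ratio", {
  cts <- make_counts(r = c(2, 5, 1), s = c(3, 0, 7))
  # indistinguishable components give z = p_b everywhere
  expect_equal(posterior_background(cts, 0.7, 0.4, 0.4), rep(0.7, 3))
  # pure background gives certainty
  expect_equal(posterior_background(cts, 1, 0.4, 0.7), rep(1, 3))

  extreme <- make_counts(r = 0, s = 20)
  expect_equal(posterior_background(extreme, 0.9, 0.3, 0.7),
               oracle_posterior(0, 20, 0.9, 0.3, 0.7))

  mixed <- make_counts(r = c(10, 0, 3), s = c(4, 0, 12))
  z <- posterior_background(mixed, 0.85, 0.35, 0.65)
  expect_equal(z, oracle_posterior(c(10, 0, 3), c(4, 0, 12),
                                   0.85, 0.35, 0.65))
  expect_true(all(z >= 0 & z <= 1))
  expect_equal(z[2], 0.85) # n = 0 falls back to the prior weight
})

test_that("EM recovers simulated parameters and its trace never decreases", {
  sim <- simulate_region_counts(20000, p_b = 0.9, theta_b = 0.4,
                                theta_e = 0.7, seed = 11)
  fit <- fit_mixture(sim$counts, seed = 11)
  expect_lt(abs(fit$theta_b - 0.4), 0.01)
  expect_lt(abs(fit$theta_e - 0.7), 0.01)
  expect_lt(abs(fit$p_b - 0.9), 0.02)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_lte(abs(diff(utils::tail(fit$loglik_trace, 2))), fit$epsilon)
  expect_true(all(fit$posterior_b >= 0 & fit$posterior_b <= 1))
  expect_lte(fit$theta_b, fit$theta_e)
})

test_that("EM on pure background recovers the pooled proportion", {
  sim <- simulate_region_counts(10000, p_b = 1, theta_b = 0.5,
                                theta_e = 0.6, seed = 3)
  fit <- fit_mixture(sim$counts, seed = 3)
  pooled <- sum(sim$counts$s) / sum(sim$counts$n)
  expect_lt(abs(fit$theta_b - pooled), 0.01)
  expect_gte(fit$p_b, 0.95)
})

test_that("EM matches an exhaustive grid-search oracle on small instances", {
  for (seed in 1:3) {
    sim <- simulate_region_counts(40, p_b = 0.8, theta_b = 0.35,
                                  theta_e = 0.65, mean_total = 40,
                                  seed = seed)
    fit <- fit_mixture(sim$counts, epsilon = 1e-8, max_iter = 5000,
                       seed = seed)
    expect_gte(fit$loglik, oracle_grid_loglik(sim$counts) - 1e-6)
  }
})

test_that("EM rejects unidentifiable inputs", {
  expect_error(fit_mixture(make_counts(r = c(0, 0), s = c(0, 0))),
               "positive total")
  expect_error(fit_mixture(make_counts(r = c(5, 3), s = c(0, 0))),
               "unidentifiable")
})

test_that("enrichment p-values are exact binomial upper tails", {
  cts <- make_counts(r = c(10, 0, 3, 5), s = c(0, 10, 7, 0))
  p <- enrichment_pvalues(cts, theta_b = 0.5)
  expect_equal(p[1], 1)               # s = 0
  expect_equal(p[2], 0.5^10)          # all reads in treatment
  expect_equal(p[3], 0.171875)        # (120 + 45 + 10 + 1) / 1024
  expect_equal(p[3], oracle_upper_tail(7, 10, 0.5))
  zero <- make_counts(r = 0, s = 0)
  expect_equal(enrichment_pvalues(zero, 0.5), 1)
})

test_that("T-method filter keeps only tests that can reach significance", {
  cts <- make_counts(r = c(5, 10, 0), s = c(5, 10, 0)) # n = 10, 20, 0
  keep <- tmethod_filter(cts, theta_b = 0.5, p_threshold = 1e-4)
  expect_equal(keep, c(FALSE, TRUE, FALSE)) # 0.5^10 ≈ 9.8e-4, 0.5^20 ≈ 9.5e-7
  expect_true(all(tmethod_filter(cts, 0.5, p_threshold = 1)))
})

test_that("q-values are BH on the retained subset and permutation-invariant", {
  q <- enrich_qvalues(c(0.01, 0.02, 0.03), rep(TRUE, 3))
  expect_equal(q, rep(0.03, 3)) # min over step-up of p * m / rank
  expect_equal(enrich_qvalues(0.2, TRUE), 0.2)

  p <- c(0.5, 0.001, 0.04, 0.2, 0.9)
  keep <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  q1 <- enrich_qvalues(p, keep)
  expect_true(all(is.na(q1[!keep])))
  perm <- c(4, 2, 5, 1, 3)
  q2 <- enrich_qvalues(p[perm], keep[perm])
  expect_equal(q2, q1[perm])
  # monotone in p within the retained set
  ord <- order(p[keep])
  expect_true(all(diff(q1[keep][ord]) >= 0))
  expect_warning(enrich_qvalues(p, rep(FALSE, 5)), "No regions retained")
})

test_that("pseudo counts are posterior-weighted background means", {
  cts <- make_counts(r = c(4, 100), s = c(6, 300))
  ps <- pseudo_counts(cts, posterior_b = c(1, 0))
  expect_equal(ps$pseudo_r, 4)
  expect_equal(ps$pseudo_s, 6)

  cts2 <- make_counts(r = c(2, 4, 6), s = c(1, 3, 5))
  ps2 <- pseudo_counts(cts2, posterior_b = rep(1, 3))
  expect_equal(ps2$pseudo_r, 4)
  expect_equal(ps2$pseudo_s, 3)
  expect_error(pseudo_counts(cts2, rep(0, 3)), "Degenerate")

  # with known truth labels, pseudo counts track background-component means
  sim <- simulate_region_counts(5000, 0.8, 0.3, 0.8, seed = 5)
  fit <- fit_mixture(sim$counts, seed = 5)
  ps3 <- pseudo_counts(sim$counts, fit$posterior_b)
  bg <- sim$counts[sim$truth$component == "background", ]
  expect_lt(abs(ps3$pseudo_r - mean(bg$r)), 2)
  expect_lt(abs(ps3$pseudo_s - mean(bg$s)), 2)
})

test_that("regularized enrichment is shifted, normalized and monotone", {
  sim <- simulate_region_counts(4000, 0.9, 0.4, 0.7, seed = 9)
  fit <- fit_mixture(sim$counts, seed = 9)
  ps <- pseudo_counts(fit$counts, fit$posterior_b)

  # a region at exactly the background ratio scores e* = 0
  k <- 3
  probe <- make_counts(r = k * ps$pseudo_r, s = k * ps$pseudo_s,
                       ids = "probe")
  e <- regularized_enrichment(fit, counts = probe)
  expect_equal(e$e_star, 0)

  # strictly increasing in s at fixed n
  n_fix <- 80
  ladder <- make_counts(r = n_fix - (0:n_fix), s = 0:n_fix)
  el <- regularized_enrichment(fit, counts = ladder)
  expect_true(all(diff(el$e_star) > 0))

  # construct counts hitting the component odds ratio: e_norm = 1
  odds <- (fit$theta_e / (1 - fit$theta_e)) /
    (fit$theta_b / (1 - fit$theta_b))
  target_ratio <- (ps$pseudo_s / ps$pseudo_r) * odds
  r0 <- 50
  s0 <- target_ratio * (r0 + ps$pseudo_r) - ps$pseudo_s
  point <- make_counts(r = r0, s = s0, ids = "odds_point")
  ep <- regularized_enrichment(fit, counts = point)
  expect_equal(ep$e_norm, 1, tolerance = 1e-10)

  # background regions sit near zero on average
  scores <- regularized_enrichment(fit)
  bg <- fit$posterior_b >= 0.99
  expect_lt(abs(mean(scores$e_star[bg])), 0.05)
})

test_that("call thresholding respects definedness and the FDR contract", {
  q <- c(0.005, 0.02, NA)
  expect_equal(call_enriched(q, 0.01), c(TRUE, FALSE, FALSE))
  expect_error(call_enriched(q, 1.0), "inside")
  expect_error(call_enriched(q, 0), "inside")
})

test_that("broom methods expose parameters and per-region results", {
  sim <- simulate_region_counts(500, 0.9, 0.4, 0.7, seed = 2)
  res <- enrich(sim$counts, seed = 2)
  td <- tidy(res)
  expect_equal(td$component, c("background", "enrichment"))
  expect_equal(sum(td$weight), 1)
  gl <- glance(res)
  expect_named(gl, c("p_b", "theta_b", "theta_e", "loglik", "iterations",
                     "converged", "n_regions"))
  au <- augment(res)
  expect_equal(nrow(au), 500)
  expect_true(all(is.na(au$qvalue) == !au$filter_pass))
  expect_true(all(au$qvalue[au$called_q0.01] <= 0.01, na.rm = TRUE))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(ggplot2::autoplot(res, "trace"), "ggplot")
})
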