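all_call_combos <- function() {
  tidyr::expand_grid(A = c(FALSE, TRUE), B = c(FALSE, TRUE),
                     reBA = c(FALSE, TRUE), reAB = c(FALSE, TRUE)) |>
    dplyr::mutate(region_id = sprintf("combo%02d", dplyr::row_number()),
                  .before = 1)
}

test_that("the classifier is total over all 16 call combinations", {
  combos <- classify_regions(all_call_combos())
  expect_false(any(is.na(combos$class)))

  # the eight concordant-reChIP patterns map exactly
  expected <- function(A, B, reBA, reAB) {
    if (reBA && reAB) {
      if (A && B) "full_bivalent" else if (A) "A_partial"
      else if (B) "B_partial" else "low_cooccupancy"
    } else if (!reBA && !reAB) {
      if (A && B) "pseudo" else if (A) "A_only"
      else if (B) "B_only" else "unmodified"
    } else {
      NA_character_
    }
  }
  regular <- !combos$irregular
  expect_equal(sum(regular), 8)
  for (i in which(regular)) {
    expect_equal(as.character(combos$class[i]),
                 expected(combos$A[i], combos$B[i], combos$reBA[i],
                          combos$reAB[i]))
  }

  # the 8 discordant combinations drop the lone reChIP call
  for (i in which(combos$irregular)) {
    expect_equal(as.character(combos$class[i]),
                 expected(combos$A[i], combos$B[i], FALSE, FALSE))
  }

  # exactly eight labels exist; seven remain once low co-occupancy is
  # discarded
  expect_length(cooccupancy_classes(), 8)
  expect_length(setdiff(cooccupancy_classes(), "low_cooccupancy"), 7)
  expect_setequal(as.character(classify_regions(all_call_combos())$class),
                  setdiff(cooccupancy_classes(), "low_cooccupancy") |>
                    union("low_cooccupancy") |> intersect(
                      as.character(combos$class)))
})

test_that("headline pattern examples classify as named", {
  calls <- tibble::tibble(
    region_id = c("full", "pseudo", "low", "bonly"),
    A = c(TRUE, TRUE, FALSE, FALSE),
    B = c(TRUE, TRUE, FALSE, TRUE),
    reBA = c(TRUE, FALSE, TRUE, FALSE),
    reAB = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.character(classify_regions(calls)$class),
               c("full_bivalent", "pseudo", "low_cooccupancy", "B_only"))
  expect_error(classify_regions(calls[, -2]), "missing columns")
})

test_that("six-ratio mode refines the bivalent classes", {
  calls <- tibble::tibble(
    region_id = c("full6", "apart6", "bpart6", "fallback"),
    A = c(TRUE, TRUE, FALSE, TRUE),
    B = c(TRUE, FALSE, TRUE, TRUE),
    reBA = c(TRUE, TRUE, TRUE, FALSE),
    reAB = c(TRUE, TRUE, TRUE, FALSE),
    reBA_over_B = c(TRUE, FALSE, TRUE, FALSE),
    reAB_over_A = c(TRUE, TRUE, FALSE, FALSE))
  got <- classify_regions(calls, mode = "six_ratio")
  expect_equal(as.character(got$class),
               c("full_bivalent", "A_partial", "B_partial", "pseudo"))
})

test_that("gene classes follow the decision-tree precedence", {
  mk <- function(classes) {
    tibble::tibble(gene_id = "g", class = classes)
  }
  expect_equal(as.character(classify_genes(mk(c("B_only", "A_only")))$class),
               "A_only")
  expect_equal(as.character(classify_genes(
    mk(c("full_bivalent", "B_partial", "B_only")))$class), "full_bivalent")
  expect_equal(as.character(classify_genes(
    mk(c("pseudo", "full_bivalent")))$class), "pseudo")
  expect_equal(as.character(classify_genes(
    mk("low_cooccupancy"))$class), "unmodified")
  expect_equal(as.character(classify_genes(
    tibble::tibble(gene_id = character(), class = character()))$class),
    character())

  # order and multiplicity of promoters are irrelevant
  many <- tibble::tibble(gene_id = "g",
                         class = c("B_only", "B_only", "A_partial",
                                   "unmodified"))
  shuffled <- many[c(3, 1, 4, 2), ]
  expect_equal(classify_genes(many), classify_genes(shuffled))
})

test_that("zero-signal regions are removed before classification", {
  counts <- tibble::tibble(region_id = c("a", "b", "c"),
                           input = c(5, 0, 3), chip_a = c(2, 4, 1),
                           rechip = c(1, 2, 0))
  expect_equal(drop_unobserved_regions(counts)$region_id, "a")
})

test_that("coefficient of variation uses the n-1 convention and scales out", {
  expr <- tibble::tibble(gene_id = c("flat", "ramp", "neg"),
                         s1 = c(2, 1, -1), s2 = c(2, 2, 0), s3 = c(2, 3, -2))
  cv <- expression_cv(expr)
  expect_equal(cv$cv[1], 0)
  expect_equal(cv$cv[2], 0.5) # sd 1, mean 2
  expect_true(cv$excluded[3])
  expect_true(is.na(cv$cv[3]))

  scaled <- expr
  scaled[, -1] <- expr[, -1] * 7
  expect_equal(expression_cv(scaled)$cv, cv$cv)
  expect_error(expression_cv(expr[, 1:2]), "two samples")

  # ties at the cutoff are all kept
  tied <- tibble::tibble(gene_id = c("a", "b", "c"),
                         s1 = c(1, 1, 5), s2 = c(3, 3, 5.1))
  sel <- expression_cv(tied, top_k = 1)
  expect_equal(sum(sel$top), 2)
})

test_that("set enrichment matches ad/bc and the enumeration oracle", {
  classes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    class = c(rep("full_bivalent", 10), rep("unmodified", 90)))
  gene_set <- sprintf("g%03d", 1:10) # 5 bivalent + 5 unmodified
  gene_set <- c(sprintf("g%03d", 1:5), sprintf("g%03d", 11:15))
  res <- class_set_enrichment(classes, gene_set)
  biv <- res[res$class == "full_bivalent", ]
  expect_equal(biv$odds_ratio, 17) # [[5,5],[5,85]]: 5*85 / (5*5)
  expect_equal(biv$pvalue, oracle_fisher_two_sided(5, 5, 5, 85))

  # balanced table: no association
  bal <- tibble::tibble(gene_id = sprintf("g%d", 1:40),
                        class = rep(c("pseudo", "unmodified"), 20))
  res_bal <- class_set_enrichment(bal, sprintf("g%d", 1:20))
  expect_equal(res_bal$odds_ratio, c(1, 1))
  expect_equal(res_bal$pvalue, c(1, 1))

  # random small tables against exhaustive enumeration
  set.seed(17)
  for (i in 1:10) {
    n_genes <- sample(20:50, 1)
    cls <- sample(c("A_only", "B_only"), n_genes, replace = TRUE)
    gc <- tibble::tibble(gene_id = sprintf("g%02d", seq_len(n_genes)),
                         class = cls)
    gs <- sample(gc$gene_id, sample(5:15, 1))
    res_i <- class_set_enrichment(gc, gs)
    for (j in seq_len(nrow(res_i))) {
      expect_equal(res_i$pvalue[j],
                   oracle_fisher_two_sided(res_i$set_in_class[j],
                                           res_i$set_other[j],
                                           res_i$bg_in_class[j],
                                           res_i$bg_other[j]),
                   tolerance = 1e-10)
    }
  }
  expect_error(class_set_enrichment(classes, character()), "non-empty")
})

test_that("simulated call tracks carry their latent classes at full detection", {
  sim <- simulate_call_tracks(400, detection = 1, seed = 8)
  got <- classify_regions(sim$calls)
  expect_equal(as.character(got$class), sim$truth$class)
  # determinism
  sim2 <- simulate_call_tracks(400, detection = 1, seed = 8)
  expect_equal(sim, sim2)
  # imperfect detection produces some irregular regions but stays total
  noisy <- simulate_call_tracks(400, detection = 0.8, seed = 9)
  cls <- classify_regions(noisy$calls)
  expect_false(any(is.na(cls$class)))
})
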