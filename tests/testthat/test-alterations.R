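test_that("alteration calling matches the exhaustive truth table", {
  grid <- expand.grid(cn = c(-2L, -1L, 0L, 1L, 2L, NA), mut = c(TRUE, FALSE))
  want <- ifelse(!is.na(grid$cn) & grid$cn %in% c(-2L, 2L), TRUE, grid$mut)
  expect_identical(call_alteration(grid$cn, grid$mut), want)
  # both channels missing: not evaluable
  expect_identical(call_alteration(NA_integer_, NA), NA)
  expect_error(call_alteration(3L, FALSE), "\\{-2\\.\\.2\\}")
})

test_that("non-synonymous classification follows the MAF dialect", {
  expect_true(classify_nonsynonymous("Missense_Mutation"))
  expect_false(classify_nonsynonymous("Silent"))
  expect_false(classify_nonsynonymous("3'UTR"))
  expect_true(classify_nonsynonymous("frame_shift_del"))  # case-normalized
  expect_warning(res <- classify_nonsynonymous("Weird_Class"),
                 "unknown variant classification")
  expect_false(res)
})

test_that("per-gene prevalence counts altered over evaluable, with strata conserved", {
  cn <- matrix(c(-2L, -1L, 0L), 3, 1, dimnames = list(c("T1", "T2", "T3"), "NF2"))
  muts <- data.frame(sample_id = "T3", gene_symbol = "NF2",
                     variant_classification = "Missense_Mutation")
  alt <- alteration_matrix(cn, muts, mutation_samples = rownames(cn))
  prev <- gene_prevalence(alt)
  expect_equal(prev$prevalence, 2 / 3)

  strat <- gene_prevalence(alt, strata = c(T1 = "epi", T2 = "epi", T3 = "bi"))
  overall <- strat[strat$stratum == "overall", ]
  per <- strat[strat$stratum != "overall", ]
  expect_equal(sum(per$n_altered), overall$n_altered)
  expect_equal(sum(per$n_evaluable), overall$n_evaluable)

  # all-wildtype: zero prevalence
  wt <- alteration_matrix(matrix(0L, 2, 2,
                                 dimnames = list(c("T1", "T2"), c("A", "B"))))
  expect_true(all(gene_prevalence(wt)$prevalence == 0))
})

test_that("panel prevalence is the per-sample OR over panel genes", {
  cn <- matrix(c(-2L, 0L, 0L, 0L,   0L, 2L, 0L, 0L,   0L, 0L, -1L, 1L),
               4, 3, dimnames = list(sprintf("T%d", 1:4), c("NF2", "LATS2", "BAP1")))
  alt <- alteration_matrix(cn)
  pp <- panel_prevalence(alt, c("NF2", "LATS2", "BAP1"))
  expect_equal(pp$fraction, 0.5)     # T1 (NF2 del) and T2 (LATS2 amp) only

  single <- panel_prevalence(alt, "NF2")
  prev <- gene_prevalence(alt)
  expect_equal(single$fraction, prev$prevalence[prev$gene == "NF2"])
  expect_gte(pp$fraction, single$fraction)   # enlarging never decreases

  expect_error(panel_prevalence(alt, c("NF2", "TP53")), "absent.*TP53")
})

test_that("prevalence matches a per-cell brute-force recount on random fixtures", {
  set.seed(5)
  for (i in 1:10) {
    n_s <- sample(3:10, 1); n_g <- sample(2:10, 1)
    samples <- sprintf("T%02d", seq_len(n_s))
    genes <- sprintf("G%02d", seq_len(n_g))
    cn <- matrix(sample(c(-2:2, NA), n_s * n_g, replace = TRUE), n_s, n_g,
                 dimnames = list(samples, genes))
    mut <- matrix(runif(n_s * n_g) < 0.2, n_s, n_g,
                  dimnames = list(samples, genes))
    idx <- which(mut, arr.ind = TRUE)
    muts <- data.frame(sample_id = samples[idx[, 1]],
                       gene_symbol = genes[idx[, 2]],
                       variant_classification = "Nonsense_Mutation")
    alt <- alteration_matrix(cn, muts, mutation_samples = samples,
                             genes = genes)
    prev <- gene_prevalence(alt)
    for (g in genes) {
      hand <- vapply(samples, function(s)
        isTRUE(cn[s, g] %in% c(-2L, 2L)) || mut[s, g], logical(1))
      expect_equal(prev$n_altered[prev$gene == g], sum(hand))
      expect_equal(prev$n_evaluable[prev$gene == g], n_s)
    }
  }
})

test_that("predictor ranking tests events against a diploid-wildtype reference", {
  set.seed(21)
  n <- 60
  samples <- sprintf("T%02d", 1:n)
  cn <- matrix(0L, n, 3, dimnames = list(samples, c("NF2", "G1", "G2")))
  cn[1:15, "NF2"] <- -2L
  cn[sample(n, 8), "G1"] <- 2L
  cn[16:20, "NF2"] <- 1L                       # shallow: excluded under strict
  scores <- setNames(rnorm(n, 0, 0.05), samples)
  scores[1:15] <- scores[1:15] + 0.3           # NF2 deletions score higher
  alt <- alteration_matrix(cn)
  rp <- rank_predictors(alt, scores)
  expect_identical(rp$gene[which(rp$rank == 1L)], "NF2")
  expect_identical(rp$n_reference[rp$gene == "NF2"], as.integer(n - 20))
  expect_true(all(rp$q_value[rp$tested] >= rp$p_value[rp$tested]))
  expect_identical(sort(rp$rank[rp$tested]), seq_len(sum(rp$tested)))
  # G2 never altered: skipped with a reason
  expect_false(rp$tested[rp$gene == "G2"])
  expect_match(rp$reason[rp$gene == "G2"], "too few altered")

  # degenerate: every sample altered leaves no reference group
  cn2 <- matrix(c(rep(-2L, n), rep(-2L, 10), rep(0L, n - 10)), n, 2,
                dimnames = list(samples, c("A", "B")))
  all_alt <- alteration_matrix(cn2)
  ra <- rank_predictors(all_alt, scores)
  expect_match(ra$reason[ra$gene == "A"], "no reference group")
  expect_true(ra$tested[ra$gene == "B"])
  expect_error(rank_predictors(all_alt, scores, events = "A"),
               "no event was testable")

  # permuting sample order leaves the ranking unchanged
  perm <- sample(n)
  alt_p <- alteration_matrix(cn[perm, , drop = FALSE])
  rp_p <- rank_predictors(alt_p, scores)
  expect_identical(rp$gene[order(rp$rank)], rp_p$gene[order(rp_p$rank)])
  expect_equal(rp$p_value[match(rp_p$gene, rp$gene)], rp_p$p_value)
})
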