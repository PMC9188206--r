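test_that("fractional ranks follow the mean-tie SPSS convention", {
  expect_equal(fractional_ranks(c(D = 1, C = 2, B = 3, A = 5)),
               c(D = 0.25, C = 0.5, B = 0.75, A = 1.0))
  expect_equal(fractional_ranks(c(X = 5, Y = 5, Z = 2)),
               c(X = 2.5 / 3, Y = 2.5 / 3, Z = 1 / 3))
  expect_equal(unname(fractional_ranks(rep(3, 4))), rep(0.625, 4))
  expect_error(fractional_ranks(c(a = 1)), "at least 2")
  expect_error(fractional_ranks(c(a = 1, b = NA)), "missing values")
})

test_that("deR of one sample is the Rp - Rn rank separation", {
  sig <- der_signature(c("A", "B"), c("C", "D"))
  r <- fractional_ranks(c(A = 5, B = 3, C = 2, D = 1))
  s <- der_score_sample(r, sig)
  expect_equal(s$Rp, 0.875)
  expect_equal(s$Rn, 0.375)
  expect_equal(s$deR, 0.5)            # perfect separation hits the bound

  r2 <- fractional_ranks(c(A = 1, B = 3, C = 2, D = 4))
  expect_equal(der_score_sample(r2, sig)$deR, -0.25)

  r3 <- fractional_ranks(c(A = 2, B = 2, C = 2, D = 2))
  expect_equal(der_score_sample(r3, sig)$deR, 0)

  expect_error(der_score_sample(fractional_ranks(c(A = 1, B = 2)), sig),
               "no measured negative effectors.*C, D")
})

test_that("matrix scoring reproduces per-sample scores and bookkeeping", {
  sig <- der_signature(c("A", "B"), c("C", "D"))
  mat <- expression_matrix(rbind(s1 = c(A = 5, B = 3, C = 2, D = 1),
                                 s2 = c(A = 1, B = 2, C = 3, D = 5)))
  sc <- der_score_matrix(mat, sig)
  expect_equal(sc$deR, c(0.5, -0.5))
  expect_identical(sc$n_pos_used, c(2L, 2L))
  expect_true(all(is.na(sc$error)))
})

test_that("scoring is invariant under strictly monotone transforms and gene order", {
  set.seed(3)
  inst <- random_score_instance()
  base <- der_score_matrix(inst$mat, inst$sig)
  expect_equal(der_score_matrix(exp(inst$mat), inst$sig)$deR, base$deR)
  expect_equal(der_score_matrix(3 * inst$mat + 7, inst$sig)$deR, base$deR)
  perm <- sample(ncol(inst$mat))
  expect_equal(der_score_matrix(inst$mat[, perm, drop = FALSE],
                                inst$sig)$deR, base$deR)
})

test_that("samples with an unmeasurable direction get a reported error row", {
  sig <- der_signature(c("A", "B"), c("C", "D"))
  mat <- expression_matrix(rbind(s1 = c(A = 5, B = 3, C = 2, D = 1),
                                 s2 = c(A = 1, B = 2, C = NA, D = NA)))
  sc <- suppressWarnings(der_score_matrix(mat, sig))
  expect_true(is.na(sc$deR[2]))
  expect_match(sc$error[2], "negative effectors")
  expect_equal(sc$deR[1], 0.5)
})

test_that("all-genes rank universe widens the deR range", {
  set.seed(9)
  sig <- der_signature("A", "B")
  mat <- expression_matrix(rbind(s1 = c(A = 10, g1 = 5, g2 = 4, B = 1)))
  eff <- der_score_matrix(mat, sig, rank_universe = "effectors")
  all <- der_score_matrix(mat, sig, rank_universe = "all")
  expect_equal(eff$deR, 0.5)
  expect_equal(all$deR, 1.0 - 0.25)   # ranks over 4 genes: 4/4 - 1/4
})

test_that("group comparison is an exact rank-sum test for small untied groups", {
  v <- c(a1 = 0.4, a2 = 0.45, a3 = 0.5, b1 = -0.5, b2 = -0.45, b3 = -0.4)
  g <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  cmp <- compare_groups(v, g, "A", "B")
  expect_equal(cmp$p_value, 0.1)      # 2 / C(6,3) extreme arrangements
  expect_equal(cmp$median_difference, 0.9)

  swapped <- compare_groups(v, g, "B", "A")
  expect_equal(swapped$p_value, cmp$p_value)
  expect_equal(swapped$median_difference, -cmp$median_difference)

  same <- compare_groups(c(v[1:3], x1 = 0.4, x2 = 0.45, x3 = 0.5),
                         c(g[1:3], x1 = "B", x2 = "B", x3 = "B"), "A", "B")
  expect_equal(same$p_value, 1.0)
  expect_equal(same$median_difference, 0)

  expect_error(compare_groups(v[1:5], g[1:5], "A", "B"), "at least 3")
})

test_that("group summaries carry Student-t 95% confidence limits", {
  v <- c(s1 = 0.1, s2 = 0.2, s3 = 0.3, t1 = 0.5)
  g <- c(s1 = "grp", s2 = "grp", s3 = "grp", t1 = "solo")
  gs <- group_summary(v, g)
  grp <- gs[gs$group == "grp", ]
  half <- qt(0.975, df = 2) * sd(c(0.1, 0.2, 0.3)) / sqrt(3)
  expect_equal(grp$mean_deR, 0.2)
  expect_equal(grp$ci_upper - grp$mean_deR, half)
  expect_true(grp$ci_lower <= grp$mean_deR && grp$mean_deR <= grp$ci_upper)

  solo <- gs[gs$group == "solo", ]
  expect_false(solo$ci_defined)
  expect_true(is.na(solo$ci_lower))

  # CI width shrinks as 1/sqrt(n) at fixed spread
  big <- group_summary(setNames(rep(c(0.1, 0.2, 0.3), 4),
                                sprintf("r%d", 1:12)),
                       setNames(rep("grp", 12), sprintf("r%d", 1:12)))
  expect_lt(big$ci_upper - big$ci_lower, grp$ci_upper - grp$ci_lower)
})

test_that("cohorts are ranked by mean deR with lexicographic tie-break", {
  v <- c(m1 = 0.4, m2 = 0.5, l1 = -0.1, l2 = 0.0)
  co <- c(m1 = "meso", m2 = "meso", l1 = "lung", l2 = "lung")
  rk <- rank_cohorts(v, co)
  expect_identical(rk$cohort, c("meso", "lung"))
  expect_identical(rk$rank, 1:2)

  tied <- rank_cohorts(c(a = 1, b = 1), c(a = "zeta", b = "alpha"))
  expect_identical(tied$cohort, c("alpha", "zeta"))

  shifted <- rank_cohorts(v + 5, co)
  expect_identical(shifted$cohort, rk$cohort)
})
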