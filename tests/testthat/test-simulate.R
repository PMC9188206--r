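test_that("simulators are pure functions of (config, seed)", {
  a <- simulate_cohort(n_samples = 20, n_genes = 40, n_pos = 5, n_neg = 5,
                       seed = 13)
  b <- simulate_cohort(n_samples = 20, n_genes = 40, n_pos = 5, n_neg = 5,
                       seed = 13)
  expect_identical(a$expression, b$expression)
  expect_identical(a$activity, b$activity)
  c_ <- simulate_cohort(n_samples = 20, n_genes = 40, n_pos = 5, n_neg = 5,
                        seed = 14)
  expect_false(identical(a$expression, c_$expression))

  e1 <- simulate_experiments(n_experiments = 3, n_genes = 30, n_pos = 4,
                             n_neg = 4, seed = 5)
  e2 <- simulate_experiments(n_experiments = 3, n_genes = 30, n_pos = 4,
                             n_neg = 4, seed = 5)
  expect_identical(lapply(e1$experiments, `[[`, "table"),
                   lapply(e2$experiments, `[[`, "table"))

  probs <- data.frame(gene = c("NF2", "TP53"), p_del = 0.3, p_amp = 0.1,
                      p_mut = 0.2)
  act <- setNames(rnorm(30), sprintf("S%04d", 1:30))
  s1 <- simulate_alterations(probs, act, seed = 2)
  s2 <- simulate_alterations(probs, act, seed = 2)
  expect_identical(s1$cn, s2$cn)
  expect_identical(s1$mutations, s2$mutations)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_cohort(n_samples = 5, n_genes = 10, n_pos = 2,
                            n_neg = 2, seed = 1))
  expect_identical(runif(1), before)
})

test_that("realized alteration prevalences sit within 3 binomial SDs of config", {
  n <- 500
  probs <- data.frame(gene = c("A", "B"), p_del = c(0.2, 0.05),
                      p_amp = c(0, 0.1), p_mut = c(0.1, 0.3))
  sim <- simulate_alterations(probs, setNames(rnorm(n), sprintf("S%04d", 1:n)),
                              seed = 31)
  for (i in 1:2) {
    p_evt <- 1 - (1 - probs$p_del[i]) * (1 - probs$p_amp[i]) *
      (1 - probs$p_mut[i])
    tol <- 3 * sqrt(p_evt * (1 - p_evt) / n)
    expect_lt(abs(mean(sim$events[, probs$gene[i]]) - p_evt), tol)
  }
  expect_true(all(sim$cn %in% c(-2L, 0L, 2L)))
})

test_that("realized planted effect sizes track the configured shift", {
  sim <- simulate_cohort(n_samples = 400, n_genes = 30, n_pos = 5, n_neg = 5,
                         effect_size = 1.5, noise_sd = 1, seed = 8)
  # per-gene regression of expression on activity recovers the slope
  slopes <- apply(sim$expression[, sim$signature$positive], 2,
                  function(y) coef(lm(y ~ sim$activity))[2])
  se <- 1 / sqrt(400 * var(sim$activity))
  expect_true(all(abs(slopes - 1.5) < 3 * se + 0.05))
  slopes_n <- apply(sim$expression[, sim$signature$negative], 2,
                    function(y) coef(lm(y ~ sim$activity))[2])
  expect_true(all(abs(slopes_n + 1.5) < 3 * se + 0.05))
})

test_that("alteration coupling shifts latent activity before expression", {
  probs <- data.frame(gene = "NF2", p_del = 0.5, p_amp = 0, p_mut = 0)
  base <- setNames(rep(0, 200), sprintf("S%04d", 1:200))
  sim <- simulate_alterations(probs, base, coupling = c(NF2 = 1.5), seed = 4)
  hit <- sim$events[, "NF2"]
  expect_true(all(sim$activity[hit] == 1.5))
  expect_true(all(sim$activity[!hit] == 0))

  expect_error(
    simulate_alterations(probs, base, coupling = c(BAP1 = 1), seed = 4),
    "unknown gene.*BAP1")
})

test_that("invalid simulator configs fail before any draw", {
  expect_error(simulate_cohort(n_genes = 5, n_pos = 4, n_neg = 4, seed = 1),
               "exceed")
  expect_error(simulate_cohort(noise_sd = 0, seed = 1), "positive")
  expect_error(simulate_experiments(n_experiments = 2, signs = c(1L, 2L),
                                    seed = 1), "signs")
  expect_error(simulate_cohort(n_samples = 5, n_genes = 10, n_pos = 2,
                               n_neg = 2, seed = NULL), "seed is required")
})

test_that("single-experiment collections cannot support a signature", {
  se <- simulate_experiments(n_experiments = 1, n_genes = 50, n_pos = 5,
                             n_neg = 5, planted_p_scale = 1e-4, seed = 6)
  expect_error(derive_signature(se$experiments, min_support = 2),
               "no effectors retained")
})
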