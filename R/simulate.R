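#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed) || !is.finite(seed))
    stop("a seed is required for every simulation", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

sim_gene_names <- function(n_pos, n_neg, n_null) {
  c(sprintf("POS%03d", seq_len(n_pos)),
    sprintf("NEG%03d", seq_len(n_neg)),
    if (n_null > 0L) sprintf("NULL%04d", seq_len(n_null)))
}

#' Simulate an expression cohort with a latent activity level
#'
#' Each sample carries a latent YAP1-TEAD activity drawn from
#' `Normal(activity_mean, activity_sd)` (or supplied via `activity`, e.g.
#' after alteration coupling — see [simulate_alterations()]). Expression of
#' gene g in sample s is
#' `baseline_g + direction_g * effect_size * activity_s + Normal(0, noise_sd)`
#' with `direction_g` +1 for planted positive effectors, -1 for negative
#' ones, 0 for null genes, and gene baselines drawn once from
#' `Normal(0, baseline_sd)`. Effect sizes are therefore in within-gene
#' noise-SD units, keeping recovery thresholds unit-free. Runs are
#' bit-identical for a given seed.
#'
#' @param n_samples,n_genes cohort dimensions (default 200 x 1000).
#' @param n_pos,n_neg planted effector counts (default 50 each).
#' @param activity_mean,activity_sd latent activity distribution (standard
#'   normal by default).
#' @param effect_size expression shift per unit activity (default 1).
#' @param noise_sd residual SD (default 1).
#' @param baseline_sd SD of per-gene baselines (default 1).
#' @param activity optional latent activity vector overriding the random
#'   draw (length `n_samples`).
#' @param seed mandatory RNG seed.
#' @return list: `expression` (samples x genes matrix), `activity` (named),
#'   `signature` (the planted [der_signature()]), `config`.
#' @export
simulate_cohort <- function(n_samples = 200L, n_genes = 1000L,
                            n_pos = 50L, n_neg = 50L,
                            activity_mean = 0, activity_sd = 1,
                            effect_size = 1, noise_sd = 1, baseline_sd = 1,
                            activity = NULL, seed) {
  if (n_pos + n_neg > n_genes)
    stop("effector counts exceed n_genes", call. = FALSE)
  if (activity_sd <= 0 || noise_sd <= 0)
    stop("activity_sd and noise_sd must be positive", call. = FALSE)
  if (!is.null(activity) && length(activity) != n_samples)
    stop("activity must have length n_samples", call. = FALSE)
  with_seed(seed, {
    genes <- sim_gene_names(n_pos, n_neg, n_genes - n_pos - n_neg)
    samples <- sprintf("S%04d", seq_len(n_samples))
    if (is.null(activity))
      activity <- stats::rnorm(n_samples, activity_mean, activity_sd)
    activity <- stats::setNames(as.numeric(activity), samples)
    direction <- c(rep(1, n_pos), rep(-1, n_neg),
                   rep(0, n_genes - n_pos - n_neg))
    baseline <- stats::rnorm(n_genes, 0, baseline_sd)
    expr <- matrix(stats::rnorm(n_samples * n_genes, 0, noise_sd),
                   n_samples, n_genes, dimnames = list(samples, genes))
    expr <- expr + outer(activity, direction * effect_size) +
      matrix(baseline, n_samples, n_genes, byrow = TRUE)
    list(expression = expr, activity = activity,
         signature = der_signature(genes[direction == 1],
                                   genes[direction == -1],
                                   name = "planted"),
         config = list(n_samples = n_samples, n_genes = n_genes,
                       n_pos = n_pos, n_neg = n_neg,
                       effect_size = effect_size, noise_sd = noise_sd,
                       baseline_sd = baseline_sd, seed = seed))
  })
}

#' Simulate a collection of oriented perturbation experiments
#'
#' Emulates a set of knockout/over-expression contrasts: planted effectors
#' receive effects whose sign is consistent with each experiment's
#' perturbation orientation (`effect = perturbation_sign * direction *
#' |Normal(effect_mean, effect_sd)|`) and small p-values drawn as
#' `planted_p_scale * Beta(0.5, 20)`; null genes receive small centered
#' effects and Uniform(0, 1) p-values. P-values are simulated directly
#' rather than through replicate-level tests, keeping the generator fast and
#' its null exact. "Strong planting" corresponds to `planted_p_scale`
#' around 1e-4 with `effect_mean >= 2`.
#'
#' @param n_experiments number of contrasts (default 6).
#' @param signs perturbation signs per experiment (default alternating
#'   -1/+1).
#' @param n_genes genes per table (default 1000).
#' @param n_pos,n_neg planted effector counts (default 50 each).
#' @param effect_mean,effect_sd magnitude distribution of planted log fold
#'   changes (default 2 and 0.25).
#' @param null_effect_sd SD of null-gene effects (default 0.2).
#' @param planted_p_scale multiplier on planted Beta(0.5, 20) p-values
#'   (default 1).
#' @param seed mandatory RNG seed.
#' @return list: `experiments` (list of [de_experiment()]), `truth`
#'   (planted positive/negative gene sets), `config`.
#' @export
simulate_experiments <- function(n_experiments = 6L,
                                 signs = rep(c(-1L, 1L),
                                             length.out = n_experiments),
                                 n_genes = 1000L, n_pos = 50L, n_neg = 50L,
                                 effect_mean = 2, effect_sd = 0.25,
                                 null_effect_sd = 0.2,
                                 planted_p_scale = 1, seed) {
  if (length(signs) != n_experiments || !all(signs %in% c(-1L, 1L)))
    stop("signs must be +1/-1 and match n_experiments", call. = FALSE)
  if (n_pos + n_neg > n_genes)
    stop("effector counts exceed n_genes", call. = FALSE)
  with_seed(seed, {
    genes <- sim_gene_names(n_pos, n_neg, n_genes - n_pos - n_neg)
    direction <- c(rep(1, n_pos), rep(-1, n_neg),
                   rep(0, n_genes - n_pos - n_neg))
    experiments <- lapply(seq_len(n_experiments), function(i) {
      planted <- direction != 0
      effect <- numeric(n_genes)
      effect[planted] <- signs[i] * direction[planted] *
        abs(stats::rnorm(sum(planted), effect_mean, effect_sd))
      effect[!planted] <- stats::rnorm(sum(!planted), 0, null_effect_sd)
      p <- numeric(n_genes)
      p[planted] <- planted_p_scale * stats::rbeta(sum(planted), 0.5, 20)
      p[!planted] <- stats::runif(sum(!planted))
      de_experiment(sprintf("SIM_EXP%02d", i), signs[i],
                    gene = genes, effect = effect, p = p)
    })
    list(experiments = experiments,
         truth = list(positive = genes[direction == 1],
                      negative = genes[direction == -1]),
         config = list(n_experiments = n_experiments, signs = signs,
                       n_genes = n_genes, n_pos = n_pos, n_neg = n_neg,
                       effect_mean = effect_mean,
                       planted_p_scale = planted_p_scale, seed = seed))
  })
}

#' Simulate alteration tables coupled to latent activity
#'
#' Draws, per sample and gene, independent Bernoulli deep-deletion,
#' amplification and non-synonymous-mutation events at the configured
#' per-gene probabilities (deletion and amplification are mutually
#' exclusive; deletion wins a double draw). Genes named in `coupling` add
#' their stated activity shift to every sample that carries any of their
#' events; the returned `activity` must then be fed to [simulate_cohort()]
#' so that alteration effects propagate into expression (coupling happens
#' before expression generation).
#'
#' @param probs data.frame with columns `gene`, `p_del`, `p_amp`, `p_mut`
#'   (probabilities in `[0, 1]`).
#' @param base_activity named numeric vector of pre-alteration latent
#'   activity (names become sample ids).
#' @param coupling named numeric vector of activity shifts (names must
#'   appear in `probs$gene`), e.g. `c(NF2 = 1.5)` for an NF2-like tumor
#'   suppressor.
#' @param seed mandatory RNG seed.
#' @return list: `cn` (samples x genes GISTIC-style matrix), `mutations`
#'   (MAF-minimal data.frame), `activity` (shifted), `events` (logical
#'   ground-truth samples x genes matrix), `config`.
#' @export
simulate_alterations <- function(probs, base_activity,
                                 coupling = numeric(0), seed) {
  stopifnot(is.data.frame(probs),
            all(c("gene", "p_del", "p_amp", "p_mut") %in% names(probs)))
  pmat <- as.matrix(probs[, c("p_del", "p_amp", "p_mut")])
  if (any(pmat < 0 | pmat > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  unknown <- setdiff(names(coupling), probs$gene)
  if (length(unknown) > 0L)
    stop("coupling references unknown gene(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  samples <- names(base_activity)
  if (is.null(samples))
    samples <- sprintf("S%04d", seq_along(base_activity))
  genes <- as.character(probs$gene)
  n <- length(base_activity)
  with_seed(seed, {
    draw <- function(p) matrix(stats::runif(n * length(genes)) <
                                 rep(p, each = n),
                               n, length(genes),
                               dimnames = list(samples, genes))
    del <- draw(probs$p_del)
    amp <- draw(probs$p_amp) & !del
    mut <- draw(probs$p_mut)
    cn <- matrix(0L, n, length(genes), dimnames = list(samples, genes))
    cn[del] <- -2L
    cn[amp] <- 2L
    events <- del | amp | mut
    activity <- as.numeric(base_activity)
    for (g in names(coupling))
      activity <- activity + coupling[[g]] * events[, g]
    mut_idx <- which(mut, arr.ind = TRUE)
    mutations <- data.frame(
      sample_id = samples[mut_idx[, 1L]],
      gene_symbol = genes[mut_idx[, 2L]],
      variant_classification = rep("Missense_Mutation", nrow(mut_idx)),
      stringsAsFactors = FALSE)
    mutations <- mutations[order(mutations$sample_id,
                                 mutations$gene_symbol), , drop = FALSE]
    rownames(mutations) <- NULL
    list(cn = cn, mutations = mutations,
         activity = stats::setNames(activity, samples),
         events = events,
         config = list(probs = probs, coupling = coupling, seed = seed))
  })
}

#' Simulate a full multi-omic cohort (alterations driving expression)
#'
#' Convenience wrapper enforcing the pipeline order: draw base latent
#' activity, draw alterations and apply their activity coupling, then
#' generate expression from the shifted activity.
#'
#' @inheritParams simulate_cohort
#' @inheritParams simulate_alterations
#' @param ... further arguments passed to [simulate_cohort()].
#' @return list combining the outputs of [simulate_alterations()] and
#'   [simulate_cohort()]: `expression`, `activity` (shifted), `signature`,
#'   `cn`, `mutations`, `events`.
#' @export
simulate_multiomic_cohort <- function(probs, coupling = numeric(0),
                                      n_samples = 200L,
                                      activity_mean = 0, activity_sd = 1,
                                      seed, ...) {
  with_seed(seed, {
    base <- stats::rnorm(n_samples, activity_mean, activity_sd)
  })
  names(base) <- sprintf("S%04d", seq_len(n_samples))
  alt <- simulate_alterations(probs, base, coupling = coupling,
                              seed = seed + 1L)
  coh <- simulate_cohort(n_samples = n_samples, activity = alt$activity,
                         seed = seed + 2L, ...)
  list(expression = coh$expression, activity = alt$activity,
       signature = coh$signature, cn = alt$cn, mutations = alt$mutations,
       events = alt$events,
       config = list(cohort = coh$config, alterations = alt$config))
}
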