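# Independent brute-force oracles. Deliberately share no code with the
# package: fractional ranks come from the counting formula
# (#smaller + (#equal + 1)/2) / n rather than rank().

oracle_fractional_ranks <- function(x) {
  n <- length(x)
  r <- vapply(x, function(v) (sum(x < v) + (sum(x == v) + 1) / 2) / n,
              numeric(1))
  names(r) <- names(x)
  r
}

oracle_der <- function(values, pos, neg) {
  pos <- intersect(pos, names(values))
  neg <- intersect(neg, names(values))
  r <- oracle_fractional_ranks(values[c(pos, neg)])
  mean(r[pos]) - mean(r[neg])
}

# Exhaustive recount of the retention rule: per gene and direction, count
# experiments significant at alpha with matching oriented sign.
oracle_derive <- function(experiments, alpha = 0.01, min_support = 2,
                          policy = "strict") {
  genes <- sort(unique(unlist(lapply(experiments,
                                     function(e) e$table$gene))))
  count_dir <- function(g, d) {
    sum(vapply(experiments, function(e) {
      i <- match(g, e$table$gene)
      if (is.na(i)) return(FALSE)
      eff <- e$table$effect[i]
      e$table$p[i] < alpha && eff != 0 &&
        (e$perturbation_sign * sign(eff)) == d
    }, logical(1)))
  }
  keep <- function(conc, disc) {
    conc >= min_support &&
      if (policy == "strict") disc == 0 else conc > disc
  }
  pos <- genes[vapply(genes, function(g)
    keep(count_dir(g, 1), count_dir(g, -1)), logical(1))]
  neg <- genes[vapply(genes, function(g)
    keep(count_dir(g, -1), count_dir(g, 1)), logical(1))]
  list(positive = pos, negative = neg)
}

# Toy three-experiment fixture used across the derivation tests:
# G1 concordant-positive in 2/3 experiments, G2 concordant-negative in 2,
# G3 significant only once, G4 significant in opposite directions.
toy_experiments <- function() {
  list(
    de_experiment("E1", -1L,
                  gene = c("G1", "G2", "G3", "G4"),
                  effect = c(-2.0, 1.5, -1.0, -1.2),
                  p = c(0.001, 0.002, 0.005, 0.004)),
    de_experiment("E2", +1L,
                  gene = c("G1", "G2", "G3", "G4"),
                  effect = c(1.8, -1.1, 0.4, -0.9),
                  p = c(0.003, 0.004, 0.5, 0.006)),
    de_experiment("E3", +1L,
                  gene = c("G1", "G2", "G3", "G4"),
                  effect = c(0.2, -0.3, 0.6, 0.5),
                  p = c(0.2, 0.3, 0.4, 0.3)))
}

random_score_instance <- function() {
  n_pos <- sample(1:5, 1)
  n_neg <- sample(1:5, 1)
  n_samples <- sample(1:8, 1)
  genes <- c(sprintf("P%d", seq_len(n_pos)), sprintf("N%d", seq_len(n_neg)))
  vals <- if (stats::runif(1) < 0.5)
    matrix(sample(1:4, n_samples * length(genes), replace = TRUE),
           n_samples, length(genes))       # discrete: forces ties
  else
    matrix(stats::rnorm(n_samples * length(genes)),
           n_samples, length(genes))
  dimnames(vals) <- list(sprintf("s%d", seq_len(n_samples)), genes)
  list(mat = vals,
       sig = der_signature(genes[seq_len(n_pos)],
                           genes[n_pos + seq_len(n_neg)]))
}
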