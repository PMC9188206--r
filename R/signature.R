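#' One oriented perturbation differential-expression contrast
#'
#' Wraps a precomputed differential-expression table (perturbed vs control)
#' together with the direction in which the perturbation is expected to move
#' YAP1-TEAD activity: `perturbation_sign = -1` for interventions expected to
#' decrease activity (e.g. a YAP1 knockout) and `+1` for interventions
#' expected to increase it (e.g. a Hippo-gene knockout or constitutively
#' active YAP1-S127A). Differential expression itself is upstream of this
#' package: the table is consumed as published.
#'
#' @param experiment_id label, e.g. a GEO series/contrast id.
#' @param perturbation_sign `+1` or `-1` (see above).
#' @param gene character vector of gene symbols, one row per gene.
#' @param effect signed log fold change, perturbed vs control.
#' @param p p-value in `[0, 1]`.
#' @param tissue free-text metadata.
#' @return object of class `de_experiment`.
#' @export
de_experiment <- function(experiment_id, perturbation_sign, gene, effect, p,
                          tissue = "") {
  if (!perturbation_sign %in% c(-1L, 1L))
    stop("perturbation_sign must be +1 or -1", call. = FALSE)
  gene <- as.character(gene)
  if (anyDuplicated(gene))
    stop("duplicated gene rows in experiment ", experiment_id, ": ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "),
         call. = FALSE)
  if (length(effect) != length(gene) || length(p) != length(gene))
    stop("gene, effect and p must have equal length", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  structure(list(experiment_id = as.character(experiment_id),
                 tissue = tissue,
                 perturbation_sign = as.integer(perturbation_sign),
                 table = data.frame(gene = gene, effect = as.numeric(effect),
                                    p = as.numeric(p),
                                    stringsAsFactors = FALSE)),
            class = "de_experiment")
}

#' @export
print.de_experiment <- function(x, ...) {
  cat(sprintf("<de_experiment> %s (sign %+d, %d genes)\n",
              x$experiment_id, x$perturbation_sign, nrow(x$table)))
  invisible(x)
}

#' Read a differential-expression table from TSV
#'
#' @param path TSV with columns `gene`, `logFC`, `pvalue` (or `effect`, `p`).
#' @inheritParams de_experiment
#' @return a [de_experiment()].
#' @export
read_de_table <- function(path, perturbation_sign,
                          experiment_id = basename(path), tissue = "") {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit) == 0L)
      stop("missing column (one of: ", paste(cands, collapse = ", "),
           ") in ", path, call. = FALSE)
    df[[hit[1L]]]
  }
  de_experiment(experiment_id, perturbation_sign,
                gene = pick(c("gene", "gene_symbol")),
                effect = pick(c("logFC", "effect")),
                p = pick(c("pvalue", "p")), tissue = tissue)
}

#' Orient a contrast's effects onto the activity axis
#'
#' Converts each gene's perturbed-vs-control effect into the direction its
#' RNA level moves per unit of YAP1-TEAD activity: a gene that goes down when
#' activity is forced down behaves as a positive effector, so
#' `oriented_direction = perturbation_sign * sign(effect)`. A zero effect
#' orients to 0 and never contributes support.
#'
#' @param exp a [de_experiment()].
#' @return data.frame with columns `gene`, `oriented_direction` (+1/-1/0),
#'   `p` (carried through unchanged).
#' @export
orient_effects <- function(exp) {
  stopifnot(inherits(exp, "de_experiment"))
  data.frame(gene = exp$table$gene,
             oriented_direction = as.integer(exp$perturbation_sign *
                                               sign(exp$table$effect)),
             p = exp$table$p,
             stringsAsFactors = FALSE)
}

#' Derive the two-part effector signature from oriented contrasts
#'
#' A gene is retained as a positive (negative) effector when it is
#' significantly modulated, at raw `p < alpha`, in the expected direction in
#' at least `min_support` experiments. "Consistently" is enforced by
#' `conflict_policy`: under `"strict"` (default) a single significant
#' observation in the opposite direction excludes the gene; under
#' `"majority"` it is retained if concordant significant observations
#' outnumber discordant ones. Genes absent from a contrast's table contribute
#' neither support nor conflict. No multiplicity adjustment is applied at
#' this step.
#'
#' @param experiments list of [de_experiment()] objects.
#' @param alpha raw significance threshold (default 0.01).
#' @param min_support minimum concordant significant experiments (default 2).
#' @param conflict_policy `"strict"` or `"majority"`.
#' @param name name given to the derived signature.
#' @return a [der_signature()] whose `provenance` records, per candidate
#'   gene, the count and ids of significant supporting experiments in each
#'   direction.
#' @export
derive_signature <- function(experiments, alpha = 0.01, min_support = 2L,
                             conflict_policy = c("strict", "majority"),
                             name = "derived") {
  conflict_policy <- match.arg(conflict_policy)
  if (length(experiments) == 0L)
    stop("at least one experiment is required", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (min_support < 1L) stop("min_support must be >= 1", call. = FALSE)

  hits <- do.call(rbind, lapply(experiments, function(e) {
    o <- orient_effects(e)
    keep <- o$p < alpha & o$oriented_direction != 0L
    if (!any(keep)) return(NULL)
    data.frame(gene = o$gene[keep], dir = o$oriented_direction[keep],
               experiment_id = e$experiment_id, stringsAsFactors = FALSE)
  }))

  empty_sig_error <- function()
    stop("no effectors retained: no gene met p < ", alpha, " in the same ",
         "direction in at least ", min_support, " experiments", call. = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) empty_sig_error()

  genes <- sort(unique(hits$gene))
  n_pos <- vapply(genes, function(g)
    sum(hits$gene == g & hits$dir == 1L), integer(1L))
  n_neg <- vapply(genes, function(g)
    sum(hits$gene == g & hits$dir == -1L), integer(1L))
  ids_for <- function(g, d)
    paste(sort(hits$experiment_id[hits$gene == g & hits$dir == d]),
          collapse = ";")

  retain <- function(n_conc, n_disc) {
    if (n_conc < min_support) return(FALSE)
    if (conflict_policy == "strict") n_disc == 0L else n_conc > n_disc
  }
  in_pos <- mapply(retain, n_pos, n_neg)
  in_neg <- mapply(retain, n_neg, n_pos)

  provenance <- data.frame(
    gene = genes, n_pos = n_pos, n_neg = n_neg,
    pos_experiments = vapply(genes, ids_for, character(1L), d = 1L),
    neg_experiments = vapply(genes, ids_for, character(1L), d = -1L),
    retained_positive = in_pos, retained_negative = in_neg,
    stringsAsFactors = FALSE, row.names = NULL)

  if (!any(in_pos) && !any(in_neg)) empty_sig_error()
  der_signature(genes[in_pos], genes[in_neg], name = name,
                provenance = provenance)
}

#' Summarize a derived signature
#'
#' @param sig a [der_signature()] with provenance (i.e. from
#'   [derive_signature()]).
#' @return data.frame with one row per retained gene: `gene`, `direction`
#'   (`"positive"`/`"negative"`), `support`, `experiments` (ids, `;`-joined).
#' @export
signature_summary <- function(sig) {
  stopifnot(inherits(sig, "der_signature"))
  if (is.null(sig$provenance))
    stop("signature carries no provenance; derive it with derive_signature()",
         call. = FALSE)
  pv <- sig$provenance
  pos <- pv[pv$gene %in% sig$positive, , drop = FALSE]
  neg <- pv[pv$gene %in% sig$negative, , drop = FALSE]
  rbind(
    data.frame(gene = pos$gene, direction = "positive",
               support = pos$n_pos, experiments = pos$pos_experiments,
               stringsAsFactors = FALSE),
    data.frame(gene = neg$gene, direction = "negative",
               support = neg$n_neg, experiments = neg$neg_experiments,
               stringsAsFactors = FALSE))
}
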