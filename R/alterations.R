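#' Is a variant classification non-synonymous?
#'
#' Membership test against the dialect's protein-altering classes
#' (missense, nonsense, nonstop, frameshift, in-frame indel, splice site,
#' translation start site). A classification outside the dialect's full
#' vocabulary raises a warning and conservatively returns `FALSE`.
#'
#' @param variant_classification character vector.
#' @param dialect currently only `"maf-minimal"`.
#' @return logical vector.
#' @export
classify_nonsynonymous <- function(variant_classification,
                                   dialect = "maf-minimal") {
  dialect <- match.arg(dialect)
  x <- normalize_variant_classification(variant_classification)
  unknown <- setdiff(unique(x), maf_variant_vocabulary())
  if (length(unknown) > 0L)
    warning("unknown variant classification(s), treated as synonymous: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  x %in% nonsynonymous_classes()
}

#' Call genetic alteration from copy-number state and mutation status
#'
#' A gene is altered in a sample iff it carries a deep deletion (GISTIC -2),
#' an amplification (GISTIC +2), or a non-synonymous mutation. Shallow
#' events (GISTIC -1/+1) alone never qualify. A cell with missing
#' copy-number but known mutation status is evaluable through the mutation
#' alone; a cell missing both is `NA` (not evaluable).
#'
#' @param cn integer vector in \{-2..2\} or `NA`.
#' @param mutated_nonsyn logical vector (`NA` = mutation status unknown).
#' @return logical vector (`NA` where not evaluable).
#' @export
call_alteration <- function(cn, mutated_nonsyn) {
  if (any(!is.na(cn) & !(cn %in% (-2:2))))
    stop("copy-number values must lie in {-2..2} or be missing",
         call. = FALSE)
  cn_hit <- !is.na(cn) & cn %in% c(-2L, 2L)
  mut_hit <- !is.na(mutated_nonsyn) & mutated_nonsyn
  out <- cn_hit | mut_hit
  out[!cn_hit & !mut_hit & is.na(cn) & is.na(mutated_nonsyn)] <- NA
  out
}

#' Assemble an alteration matrix from copy-number and mutation tables
#'
#' Aligns a GISTIC-style thresholded copy-number matrix and a MAF-style
#' mutation table onto a common samples x genes grid and derives per-cell
#' altered status via [call_alteration()]. Samples listed in
#' `mutation_samples` (default: every sample seen in either input) are taken
#' as mutation-profiled, so absence from the mutation table means wildtype
#' rather than unknown for them.
#'
#' @param cn samples x genes integer matrix (see
#'   [read_copy_number_table()]), or `NULL`.
#' @param mutations data.frame as from [read_mutation_table()], or `NULL`.
#' @param mutation_samples character vector of mutation-profiled samples.
#' @param genes optional gene universe; defaults to the union of genes seen.
#' @param dialect passed to [classify_nonsynonymous()].
#' @return object of class `alteration_matrix`: list with samples x genes
#'   matrices `cn` (integer), `mutated` (logical) and `altered` (logical,
#'   `NA` = not evaluable).
#' @export
alteration_matrix <- function(cn = NULL, mutations = NULL,
                              mutation_samples = NULL, genes = NULL,
                              dialect = "maf-minimal") {
  if (is.null(cn) && is.null(mutations))
    stop("need at least one of copy-number or mutation input", call. = FALSE)
  if (!is.null(cn)) cn <- validate_copy_number(cn)
  samples <- unique(c(if (!is.null(cn)) rownames(cn),
                      if (!is.null(mutations)) mutations$sample_id,
                      mutation_samples))
  if (is.null(genes))
    genes <- unique(c(if (!is.null(cn)) colnames(cn),
                      if (!is.null(mutations)) mutations$gene_symbol))
  if (is.null(mutation_samples))
    mutation_samples <- if (is.null(mutations)) character(0) else samples

  cn_full <- matrix(NA_integer_, length(samples), length(genes),
                    dimnames = list(samples, genes))
  if (!is.null(cn)) {
    rs <- intersect(samples, rownames(cn))
    gs <- intersect(genes, colnames(cn))
    cn_full[rs, gs] <- cn[rs, gs]
  }

  mut_full <- matrix(NA, length(samples), length(genes),
                     dimnames = list(samples, genes))
  mut_full[intersect(mutation_samples, samples), ] <- FALSE
  if (!is.null(mutations) && nrow(mutations) > 0L) {
    nonsyn <- classify_nonsynonymous(mutations$variant_classification,
                                     dialect = dialect)
    hit <- mutations[nonsyn & mutations$gene_symbol %in% genes, ,
                     drop = FALSE]
    if (nrow(hit) > 0L)
      mut_full[cbind(hit$sample_id, hit$gene_symbol)] <- TRUE
  }

  altered <- matrix(call_alteration(as.vector(cn_full), as.vector(mut_full)),
                    length(samples), length(genes),
                    dimnames = list(samples, genes))
  structure(list(cn = cn_full, mutated = mut_full, altered = altered),
            class = "alteration_matrix")
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat(sprintf("<alteration_matrix> %d samples x %d genes, %d altered cells\n",
              nrow(x$altered), ncol(x$altered),
              sum(x$altered, na.rm = TRUE)))
  invisible(x)
}

#' Per-gene alteration prevalence, optionally stratified
#'
#' Prevalence is the altered fraction over evaluable samples (cells with
#' neither copy-number nor mutation information are excluded from the
#' denominator). With strata, per-stratum rows are emitted alongside the
#' overall ones; stratified counts sum to the overall counts.
#'
#' @param alt an [alteration_matrix()].
#' @param strata optional sample-to-group assignment (named character vector
#'   or data.frame `sample_id`/`group`).
#' @return data.frame: `gene`, `stratum` (`"overall"` or a group label),
#'   `n_altered`, `n_evaluable`, `prevalence`.
#' @export
gene_prevalence <- function(alt, strata = NULL) {
  stopifnot(inherits(alt, "alteration_matrix"))
  one_stratum <- function(m, label) {
    data.frame(gene = colnames(m), stratum = label,
               n_altered = colSums(m, na.rm = TRUE),
               n_evaluable = colSums(!is.na(m)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- one_stratum(alt$altered, "overall")
  if (!is.null(strata)) {
    g <- group_vector(strata)
    for (gr in sort(unique(g))) {
      rows <- intersect(names(g)[g == gr], rownames(alt$altered))
      out <- rbind(out,
                   one_stratum(alt$altered[rows, , drop = FALSE], gr))
    }
  }
  out$prevalence <- ifelse(out$n_evaluable > 0,
                           out$n_altered / out$n_evaluable, NA_real_)
  out
}

#' Fraction of samples with at least one altered panel gene
#'
#' @param alt an [alteration_matrix()].
#' @param panel character vector of genes; all must be present.
#' @return list with `fraction`, `n_hit`, `n_evaluable`.
#' @export
panel_prevalence <- function(alt, panel) {
  stopifnot(inherits(alt, "alteration_matrix"))
  missing <- setdiff(panel, colnames(alt$altered))
  if (length(missing) > 0L)
    stop("panel genes absent from alteration matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sub <- alt$altered[, panel, drop = FALSE]
  evaluable <- rowSums(!is.na(sub)) > 0L
  hit <- apply(sub[evaluable, , drop = FALSE], 1L,
               function(r) any(r, na.rm = TRUE))
  list(fraction = if (any(evaluable)) mean(hit) else NA_real_,
       n_hit = sum(hit), n_evaluable = sum(evaluable))
}

#' Rank genetic events as predictors of the deR score
#'
#' For each tested gene, samples carrying the event are compared with a
#' reference group on their deR scores by a two-sided rank-sum test (see
#' [compare_groups()]). The event definition defaults to any alteration
#' (deep deletion, amplification or non-synonymous mutation);
#' `"mut_or_del"` restricts to deletion-type events (deep deletion or
#' mutation, the definition used for NF2-style comparisons) and
#' `"mut_or_amp"` to amplification-type ones. Under the `"strict"` reference
#' policy the reference group is diploid wildtype (copy-number exactly 0 and
#' no known non-synonymous mutation) and samples with shallow events (-1/+1)
#' are excluded from the comparison; `"inclusive"` uses every non-event
#' evaluable sample.
#' P-values are Benjamini-Hochberg adjusted across tested events; events are
#' ranked by ascending p, ties by descending absolute median difference,
#' then lexicographically.
#'
#' @param alt an [alteration_matrix()].
#' @param scores deR scores (see [compare_groups()]).
#' @param events genes to test (default: all genes in `alt`).
#' @param reference_policy `"strict"` or `"inclusive"`.
#' @param event_type `"any"`, `"mut_or_del"` or `"mut_or_amp"`.
#' @param min_group_size events with fewer altered or reference samples are
#'   skipped with a reason (default 3).
#' @return data.frame, one row per requested event, ordered by rank for
#'   tested events (skipped events trail with `NA` rank): `gene`,
#'   `n_altered`, `n_reference`, `statistic`, `p_value`, `q_value`,
#'   `median_difference`, `rank`, `tested`, `reason`.
#' @export
rank_predictors <- function(alt, scores, events = colnames(alt$altered),
                            reference_policy = c("strict", "inclusive"),
                            event_type = c("any", "mut_or_del", "mut_or_amp"),
                            min_group_size = 3L) {
  stopifnot(inherits(alt, "alteration_matrix"))
  reference_policy <- match.arg(reference_policy)
  event_type <- match.arg(event_type)
  v <- score_vector(scores)
  samples <- intersect(rownames(alt$altered), names(v)[!is.na(v)])
  missing <- setdiff(events, colnames(alt$altered))
  if (length(missing) > 0L)
    stop("events absent from alteration matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)

  rows <- lapply(events, function(gene) {
    cn <- alt$cn[samples, gene]
    mut <- alt$mutated[samples, gene]
    mut_known <- !is.na(mut) & mut
    event <- switch(event_type,
      any = call_alteration(cn, mut) %in% TRUE,
      mut_or_del = (!is.na(cn) & cn == -2L) | mut_known,
      mut_or_amp = (!is.na(cn) & cn == 2L) | mut_known)
    ref <- if (reference_policy == "strict")
      !is.na(cn) & cn == 0L & !mut_known
    else
      !(call_alteration(cn, mut) %in% TRUE) & !is.na(call_alteration(cn, mut))
    base <- data.frame(gene = gene, n_altered = sum(event),
                       n_reference = sum(ref), statistic = NA_real_,
                       p_value = NA_real_, q_value = NA_real_,
                       median_difference = NA_real_, rank = NA_integer_,
                       tested = FALSE, reason = NA_character_,
                       stringsAsFactors = FALSE)
    if (sum(event) < min_group_size) {
      base$reason <- if (sum(ref) == 0L && sum(event) == length(samples))
        "no reference group" else "too few altered samples"
      return(base)
    }
    if (sum(ref) < min_group_size) {
      base$reason <- if (sum(ref) == 0L) "no reference group"
                     else "too few reference samples"
      return(base)
    }
    grp <- c(rep("event", sum(event)), rep("reference", sum(ref)))
    names(grp) <- c(samples[event], samples[ref])
    cmp <- compare_groups(v, grp, "event", "reference")
    base$statistic <- cmp$statistic
    base$p_value <- cmp$p_value
    base$median_difference <- cmp$median_difference
    base$tested <- TRUE
    base
  })
  out <- do.call(rbind, rows)
  if (!any(out$tested))
    stop("no event was testable (all skipped)", call. = FALSE)
  out$q_value[out$tested] <- stats::p.adjust(out$p_value[out$tested],
                                             method = "BH")
  tested <- out[out$tested, , drop = FALSE]
  ord <- order(tested$p_value, -abs(tested$median_difference), tested$gene)
  tested <- tested[ord, , drop = FALSE]
  tested$rank <- seq_len(nrow(tested))
  out <- rbind(tested, out[!out$tested, , drop = FALSE])
  rownames(out) <- NULL
  out
}
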