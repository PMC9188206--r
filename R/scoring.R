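#' Fractional ranks within one sample
#'
#' Ranks the measured abundances ascending, giving ties the mean of their
#' integer ranks, and divides by the number of measured values, so ranks lie
#' in (0, 1] (the SPSS fractional-rank convention). Ties are exact
#' floating-point equality only; no epsilon snapping is applied, so
#' pre-rounded input may tie deliberately.
#'
#' @param values named numeric vector of one sample's measured abundances
#'   (`NA`s must be removed by the caller; at least 2 values).
#' @return named numeric vector of fractional ranks in (0, 1].
#' @export
fractional_ranks <- function(values) {
  if (anyNA(values))
    stop("missing values must be dropped before ranking", call. = FALSE)
  n <- length(values)
  if (n < 2L)
    stop("fractional ranks need at least 2 measured values", call. = FALSE)
  rank(values, ties.method = "average") / n
}

#' deR score of one ranked sample
#'
#' The difference-of-effector-ranks score: `deR = Rp - Rn`, where `Rp` is the
#' mean fractional rank of the measured positive effectors and `Rn` that of
#' the negative ones. It measures the average rank separation between
#' positive and negative effectors of YAP1-TEAD transcription within the
#' sample; with ranks computed over the effector union it is bounded in
#' [-0.5, 0.5], hitting a bound only at perfect separation.
#'
#' @param ranks fractional ranks from [fractional_ranks()] (named).
#' @param sig a [der_signature()].
#' @return list with `Rp`, `Rn`, `deR`, `n_pos_used`, `n_neg_used`.
#' @export
der_score_sample <- function(ranks, sig) {
  stopifnot(inherits(sig, "der_signature"))
  pos <- intersect(sig$positive, names(ranks))
  neg <- intersect(sig$negative, names(ranks))
  if (length(pos) == 0L || length(neg) == 0L) {
    missing_dir <- if (length(pos) == 0L) "positive" else "negative"
    missing_genes <- if (length(pos) == 0L) sig$positive else sig$negative
    stop("no measured ", missing_dir, " effectors (need one of: ",
         paste(missing_genes, collapse = ", "), ")", call. = FALSE)
  }
  Rp <- mean(ranks[pos])
  Rn <- mean(ranks[neg])
  list(Rp = Rp, Rn = Rn, deR = Rp - Rn,
       n_pos_used = length(pos), n_neg_used = length(neg))
}

#' deR scores for every sample of an expression matrix
#'
#' For each sample, missing values are dropped, the rank universe is
#' restricted to the signature's effector genes (default; `"all"` ranks over
#' every measured gene for sensitivity analysis), fractional ranks are
#' computed, and the deR score is taken. Scoring is invariant under any
#' strictly increasing transform of a sample's abundances.
#'
#' @param mat samples x genes matrix (see [expression_matrix()]).
#' @param sig a [der_signature()].
#' @param rank_universe `"effectors"` (default) or `"all"`.
#' @param coverage_floor warn when fewer than this fraction of either
#'   effector set is measured matrix-wide (default 0.5).
#' @return data.frame with one row per sample: `sample_id`, `n_pos_used`,
#'   `n_neg_used`, `Rp`, `Rn`, `deR`, `error` (NA, or the reason a sample
#'   could not be scored — its numeric columns are then NA).
#' @export
der_score_matrix <- function(mat, sig,
                             rank_universe = c("effectors", "all"),
                             coverage_floor = 0.5) {
  rank_universe <- match.arg(rank_universe)
  mat <- validate_expression_matrix(mat)
  stopifnot(inherits(sig, "der_signature"))

  pos_meas <- intersect(sig$positive, colnames(mat))
  neg_meas <- intersect(sig$negative, colnames(mat))
  if (length(pos_meas) == 0L || length(neg_meas) == 0L)
    stop("signature direction with zero genes in the matrix (",
         length(pos_meas), " positive, ", length(neg_meas),
         " negative measured)", call. = FALSE)
  cov_pos <- length(pos_meas) / length(sig$positive)
  cov_neg <- length(neg_meas) / length(sig$negative)
  if (cov_pos < coverage_floor || cov_neg < coverage_floor)
    warning(sprintf(
      "low signature coverage: %d/%d positive, %d/%d negative effectors measured",
      length(pos_meas), length(sig$positive),
      length(neg_meas), length(sig$negative)), call. = FALSE)

  universe <- if (rank_universe == "effectors")
    c(pos_meas, neg_meas) else colnames(mat)

  rows <- lapply(rownames(mat), function(s) {
    x <- mat[s, universe]
    x <- x[!is.na(x)]
    res <- tryCatch({
      r <- fractional_ranks(x)
      der_score_sample(r, sig)
    }, error = function(e) conditionMessage(e))
    if (is.character(res))
      data.frame(sample_id = s, n_pos_used = NA_integer_,
                 n_neg_used = NA_integer_, Rp = NA_real_, Rn = NA_real_,
                 deR = NA_real_, error = res, stringsAsFactors = FALSE)
    else
      data.frame(sample_id = s, n_pos_used = res$n_pos_used,
                 n_neg_used = res$n_neg_used, Rp = res$Rp, Rn = res$Rn,
                 deR = res$deR, error = NA_character_,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("sample_id", "deR") %in% names(scores)))
    stats::setNames(scores$deR, scores$sample_id)
  } else scores
}

group_vector <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", "group") %in% names(labels)))
    stats::setNames(as.character(labels$group), labels$sample_id)
  } else stats::setNames(as.character(labels), names(labels))
}

#' Rank-sum comparison of deR scores between two groups
#'
#' Two-sided Mann-Whitney rank-sum test (a rank-based test, coherent with the
#' rank-based score): exact enumeration when both groups have at most 8
#' samples and no ties straddle them, normal approximation with tie
#' correction otherwise.
#'
#' @param scores a score data.frame from [der_score_matrix()] or a named
#'   numeric vector of deR values.
#' @param labels sample-to-group assignment: named character vector or
#'   data.frame with columns `sample_id`, `group`.
#' @param group_a,group_b the two group labels to compare.
#' @return list with `statistic` (U for `group_a`), `p_value` (two-sided),
#'   `median_difference` (`median(A) - median(B)`), `n_a`, `n_b`.
#' @export
compare_groups <- function(scores, labels, group_a, group_b) {
  v <- score_vector(scores)
  g <- group_vector(labels)
  a <- v[names(g)[g == group_a]]
  b <- v[names(g)[g == group_b]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("both groups need at least 3 scored samples (got ",
         length(a), " and ", length(b), ")", call. = FALSE)
  exact <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_difference = stats::median(a) - stats::median(b),
       n_a = length(a), n_b = length(b))
}

#' Per-group deR summaries with 95% confidence limits
#'
#' Mean with a Student-t 95% confidence interval (the symmetric confidence
#' limits used on pharmacodynamic time-course plots) and median, per group.
#' A single-sample group yields a point estimate with the CI flagged
#' undefined (`NA` bounds, `ci_defined = FALSE`).
#'
#' @inheritParams compare_groups
#' @param conf_level confidence level (default 0.95).
#' @return data.frame: `group`, `n`, `mean_deR`, `ci_lower`, `ci_upper`,
#'   `ci_defined`, `median_deR`.
#' @export
group_summary <- function(scores, labels, conf_level = 0.95) {
  v <- score_vector(scores)
  g <- group_vector(labels)
  groups <- sort(unique(g))
  rows <- lapply(groups, function(gr) {
    x <- v[names(g)[g == gr]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) stop("group '", gr, "' has no scored samples",
                              call. = FALSE)
    m <- mean(x)
    if (length(x) >= 2L) {
      half <- stats::qt(1 - (1 - conf_level) / 2, df = length(x) - 1L) *
        stats::sd(x) / sqrt(length(x))
      ci <- c(m - half, m + half); defined <- TRUE
    } else {
      ci <- c(NA_real_, NA_real_); defined <- FALSE
    }
    data.frame(group = gr, n = length(x), mean_deR = m,
               ci_lower = ci[1L], ci_upper = ci[2L], ci_defined = defined,
               median_deR = stats::median(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank cohorts by mean deR
#'
#' Orders cohorts by descending mean deR (the comparison behind "highest
#' signature scores among all indications"); ties break lexicographically on
#' the cohort label.
#'
#' @inheritParams compare_groups
#' @param cohort_labels sample-to-cohort assignment, same forms as `labels`.
#' @return data.frame ordered by rank: `cohort`, `n`, `mean_deR`,
#'   `median_deR`, `rank`.
#' @export
rank_cohorts <- function(scores, cohort_labels) {
  v <- score_vector(scores)
  g <- group_vector(cohort_labels)
  cohorts <- unique(g)
  if (length(cohorts) < 2L) stop("need at least 2 cohorts", call. = FALSE)
  rows <- lapply(cohorts, function(co) {
    x <- v[names(g)[g == co]]
    x <- x[!is.na(x)]
    data.frame(cohort = co, n = length(x), mean_deR = mean(x),
               median_deR = stats::median(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_deR, out$cohort), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
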