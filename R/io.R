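#' Construct and validate an expression matrix
#'
#' The in-memory representation of an expression matrix is a plain numeric
#' matrix with samples as rows and genes as columns, carrying unique row and
#' column names. Values may be on any monotone abundance scale (counts, TPM,
#' normalized intensities): downstream scoring is rank-based and scale-free.
#' Missing values are permitted and dropped per sample at scoring time.
#'
#' @param values numeric matrix, samples x genes.
#' @param sample_ids,gene_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return validated numeric matrix (samples x genes) with dimnames.
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(sample_ids) || is.null(gene_ids))
    stop("sample and gene identifiers are required", call. = FALSE)
  rownames(values) <- as.character(sample_ids)
  colnames(values) <- as.character(gene_ids)
  validate_expression_matrix(values)
}

#' @rdname expression_matrix
#' @export
validate_expression_matrix <- function(values) {
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("expression matrix needs at least 1 sample and 2 genes", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated gene ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  values
}

read_id_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  if (ncol(raw) < 2L) stop("expected an id column plus data columns in ", path,
                           call. = FALSE)
  ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, function(col) as.numeric(col), numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 as.matrix(body)[bad[1L, 1L], bad[1L, 2L]],
                 ids[bad[1L, 1L]], colnames(body)[bad[1L, 2L]], path),
         call. = FALSE)
  }
  rownames(num) <- ids
  num
}

#' Read an expression matrix from TSV
#'
#' On disk the dominant convention stores genes as rows and samples as
#' columns; the in-memory orientation is always samples x genes. Blank cells
#' and `NA` are read as missing.
#'
#' @param path TSV file: one id column (first), one header row, numeric body.
#' @param orientation `"genes_as_rows"` (default) or `"samples_as_rows"`,
#'   describing the file layout.
#' @return numeric matrix, samples x genes (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_as_rows",
                                                   "samples_as_rows")) {
  orientation <- match.arg(orientation)
  num <- read_id_matrix(path)
  if (orientation == "genes_as_rows") num <- t(num)
  validate_expression_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' @param mat samples x genes numeric matrix.
#' @param path output path.
#' @param orientation on-disk layout, as in [read_expression_matrix()].
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path,
                                    orientation = c("genes_as_rows",
                                                    "samples_as_rows")) {
  orientation <- match.arg(orientation)
  mat <- validate_expression_matrix(mat)
  out <- if (orientation == "genes_as_rows") t(mat) else mat
  df <- data.frame(id = rownames(out), out, check.names = FALSE)
  names(df)[1L] <- if (orientation == "genes_as_rows") "gene_id" else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-part effector signature
#'
#' A signature is a pair of disjoint gene sets: positive effectors (RNA up
#' when YAP1-TEAD activity is up) and negative effectors (RNA down when
#' activity is up), optionally with per-gene derivation provenance.
#'
#' @param positive,negative character vectors of gene symbols (case-sensitive,
#'   no alias resolution).
#' @param name signature name used as the GMT set-name stem.
#' @param provenance optional data.frame of per-gene support bookkeeping, as
#'   produced by [derive_signature()].
#' @return object of class `der_signature`.
#' @export
der_signature <- function(positive, negative, name = "signature",
                          provenance = NULL) {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  both <- intersect(positive, negative)
  if (length(both) > 0L)
    stop("positive and negative effector sets overlap: ",
         paste(both, collapse = ", "), call. = FALSE)
  structure(list(positive = positive, negative = negative,
                 name = name, provenance = provenance),
            class = "der_signature")
}

#' @export
print.der_signature <- function(x, ...) {
  cat(sprintf("<der_signature> %s: %d positive / %d negative effectors\n",
              x$name, length(x$positive), length(x$negative)))
  invisible(x)
}

#' Read / write a two-part signature as GMT
#'
#' Standard GMT carries one direction per line; a two-part signature is
#' stored as two lines whose set names end in `_POS` and `_NEG` with a common
#' stem. Member order is not meaningful.
#'
#' @param path GMT file path.
#' @return `read_gmt()`: a [der_signature()]; `write_gmt()`: `path`,
#'   invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[[`, character(1L), 1L)
  pos_i <- grep("_POS$", names_)
  neg_i <- grep("_NEG$", names_)
  if (length(pos_i) != 1L || length(neg_i) != 1L)
    stop("GMT must contain exactly one _POS and one _NEG set; found ",
         length(pos_i), " and ", length(neg_i), call. = FALSE)
  get_genes <- function(f) if (length(f) > 2L) unique(f[-(1:2)]) else character(0)
  stem <- sub("_POS$", "", names_[pos_i])
  der_signature(get_genes(fields[[pos_i]]), get_genes(fields[[neg_i]]),
                name = stem)
}

#' @rdname read_gmt
#' @param sig a [der_signature()]; both sets must be non-empty on write.
#' @export
write_gmt <- function(sig, path) {
  stopifnot(inherits(sig, "der_signature"))
  if (length(sig$positive) == 0L || length(sig$negative) == 0L)
    stop("refusing to write a signature with an empty effector set",
         call. = FALSE)
  lines <- c(
    paste(c(paste0(sig$name, "_POS"), "positive effectors", sig$positive),
          collapse = "\t"),
    paste(c(paste0(sig$name, "_NEG"), "negative effectors", sig$negative),
          collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal MAF-style mutation table
#'
#' Accepts either MAF column names (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`) or plain ones (`sample_id`, `gene_symbol`,
#' `variant_classification`). Rows are preserved verbatim (several mutations
#' per gene per sample are allowed); classification strings are normalized to
#' the dialect's canonical capitalization by case-insensitive match, unknown
#' strings are left as given.
#'
#' @param path TSV path.
#' @param dialect currently only `"maf-minimal"`.
#' @return data.frame with columns `sample_id`, `gene_symbol`,
#'   `variant_classification`.
#' @export
read_mutation_table <- function(path, dialect = "maf-minimal") {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit) == 0L)
      stop("missing required column (one of: ",
           paste(cands, collapse = ", "), ") in ", path, call. = FALSE)
    df[[hit[1L]]]
  }
  out <- data.frame(
    sample_id = as.character(pick(c("Tumor_Sample_Barcode", "sample_id"))),
    gene_symbol = as.character(pick(c("Hugo_Symbol", "gene_symbol"))),
    variant_classification =
      normalize_variant_classification(
        as.character(pick(c("Variant_Classification",
                            "variant_classification")))),
    stringsAsFactors = FALSE)
  out
}

#' @rdname read_mutation_table
#' @param x character vector of classification strings.
#' @export
normalize_variant_classification <- function(x) {
  vocab <- maf_variant_vocabulary()
  idx <- match(toupper(x), toupper(vocab))
  ifelse(is.na(idx), x, vocab[idx])
}

#' MAF variant-classification vocabulary
#'
#' The controlled vocabulary of the minimal MAF dialect, with the subset
#' counted as non-synonymous (protein-altering) for alteration calling.
#'
#' @return character vector of canonical classification strings.
#' @export
maf_variant_vocabulary <- function() {
  c(nonsynonymous_classes(),
    "Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
    "IGR", "RNA", "lincRNA", "De_novo_Start_InFrame",
    "De_novo_Start_OutOfFrame", "Start_Codon_SNP")
}

#' @rdname maf_variant_vocabulary
#' @export
nonsynonymous_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

#' Read / write a GISTIC-style thresholded copy-number table
#'
#' The on-disk layout follows GISTIC `all_thresholded.by_genes`: gene rows,
#' sample columns, integer calls in \{-2, -1, 0, 1, 2\} (-2 deep deletion,
#' +2 amplification). Blank cells are missing. Any other value is rejected
#' with the offending cell named.
#'
#' @param path TSV path.
#' @return integer matrix, samples x genes, possibly with `NA`.
#' @export
read_copy_number_table <- function(path) {
  num <- t(read_id_matrix(path))
  validate_copy_number(num, where = path)
}

#' @rdname read_copy_number_table
#' @param cn samples x genes integer matrix.
#' @export
write_copy_number_table <- function(cn, path) {
  cn <- validate_copy_number(cn)
  out <- t(cn)
  df <- data.frame(gene_id = rownames(out), out, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_copy_number <- function(cn, where = "copy-number table") {
  bad <- which(!is.na(cn) & !(cn %in% (-2:2)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "copy-number value %s outside {-2..2} at sample '%s', gene '%s' in %s",
      format(cn[bad[1L, , drop = FALSE]]),
      rownames(cn)[bad[1L, 1L]], colnames(cn)[bad[1L, 2L]], where),
      call. = FALSE)
  storage.mode(cn) <- "integer"
  cn
}
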