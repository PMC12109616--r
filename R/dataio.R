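#' Construct an expression dataset
#'
#' A light container for one cohort's genes-by-samples abundance matrix,
#' together with a record of the preprocessing already applied. All pipeline
#' stages consume this class; values are expected on a log2-like scale after
#' [preprocess_expression()].
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty dimnames.
#' @param cohort_id Single string naming the cohort.
#' @param log2,quantile Logical flags recording which transforms have already
#'   been applied to `values`.
#' @return An object of class `expr_dataset`: a list with elements
#'   `cohort_id`, `values`, and `preprocessing`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' ds <- expression_dataset(m, "toy")
#' dim(ds$values)
#' @export
expression_dataset <- function(values, cohort_id, log2 = FALSE, quantile = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_format("`values` must be a numeric matrix (genes x samples)")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop_format("expression matrix must carry gene and sample ids as dimnames")
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop_format("duplicate gene id(s): %s", paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop_format("duplicate sample id(s): %s", paste(dup_s, collapse = ", "))
  if (any(!is.finite(values)))
    stop_format("expression matrix contains non-finite values")
  structure(
    list(
      cohort_id = as.character(cohort_id),
      values = values,
      preprocessing = list(log2 = isTRUE(log2), quantile = isTRUE(quantile))
    ),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset '%s'> %d genes x %d samples (log2: %s, quantile: %s)\n",
    x$cohort_id, nrow(x$values), ncol(x$values),
    x$preprocessing$log2, x$preprocessing$quantile
  ))
  invisible(x)
}

#' Read and write expression matrices
#'
#' Tab-separated text with a header row of sample ids and gene ids in the
#' first column. Duplicate ids, non-numeric cells, and missing values are
#' rejected with an error naming the offending row or column; the compendium-style
#' inputs are dense after upstream processing, so missingness is treated as a
#' format defect rather than silently imputed.
#'
#' @param path Path to a TSV file.
#' @param cohort_id Cohort label stored in the returned dataset; defaults to
#'   the file name without extension.
#' @param log2,quantile Preprocessing provenance flags to record (for files
#'   that were already transformed upstream).
#' @return `read_expression()` returns an [expression_dataset()];
#'   `write_expression()` returns `path` invisibly.
#' @export
read_expression <- function(path, cohort_id = NULL, log2 = FALSE, quantile = FALSE) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop_format("%s: need a header line and at least one gene row", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop_format("%s: malformed header (no sample columns)", path)
  sample_ids <- header[-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(header))) {
    bad <- which(widths != length(header))[1]
    stop_format("%s: row %d has %d fields, expected %d", path, bad + 1, widths[bad], length(header))
  }
  gene_ids <- vapply(body, `[[`, character(1), 1)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(sample_ids)))
  )
  vals <- matrix(vals, nrow = length(sample_ids)) # genes in columns here
  bad_cell <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad_cell)) {
    stop_format(
      "%s: non-numeric or missing value at gene '%s', sample '%s'",
      path, gene_ids[bad_cell[1, 2]], sample_ids[bad_cell[1, 1]]
    )
  }
  m <- t(vals)
  dimnames(m) <- list(gene_ids, sample_ids)
  expression_dataset(
    m,
    cohort_id = cohort_id %||% sub("\\.[^.]*$", "", basename(path)),
    log2 = log2, quantile = quantile
  )
}

#' @param ds An [expression_dataset()].
#' @rdname read_expression
#' @export
write_expression <- function(ds, path) {
  stopifnot(inherits(ds, "expr_dataset"))
  df <- data.frame(gene = rownames(ds$values), ds$values, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Preprocess an expression dataset
#'
#' Applies `log2(x + 1)` and/or quantile normalization (every sample's sorted
#' values are forced onto the mean quantile profile; tied ranks receive the
#' mean of the tied quantile means). Provenance flags in the returned dataset
#' record what has been applied so downstream stages can refuse raw input.
#'
#' @param ds An [expression_dataset()].
#' @param log2 Apply the log2(x+1) transform. Requires non-negative values.
#' @param quantile Apply quantile normalization across samples.
#' @return The transformed [expression_dataset()].
#' @export
preprocess_expression <- function(ds, log2 = FALSE, quantile = FALSE) {
  stopifnot(inherits(ds, "expr_dataset"))
  m <- ds$values
  lg <- ds$preprocessing$log2
  qn <- ds$preprocessing$quantile
  if (isTRUE(log2)) {
    if (any(m < 0))
      stop_domain("log2 preprocessing requires non-negative values (min = %g)", min(m))
    m <- base::log2(m + 1)
    lg <- TRUE
  }
  if (isTRUE(quantile)) {
    m <- limma::normalizeQuantiles(m, ties = TRUE)
    qn <- TRUE
  }
  out <- expression_dataset(m, ds$cohort_id, log2 = lg, quantile = qn)
  out
}

#' Read and write clinical tables
#'
#' TSV with required columns `sample_id`, `time`, `event`; any further
#' columns are carried along as covariates. Times must be non-negative and
#' events coded 0/1.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per sample.
#' @export
read_clinical <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop_format("%s: missing clinical column(s): %s", path, paste(miss, collapse = ", "))
  validate_clinical(tbl)
}

validate_clinical <- function(tbl) {
  if (anyDuplicated(tbl$sample_id))
    stop_format("duplicate sample_id in clinical table: %s",
                tbl$sample_id[duplicated(tbl$sample_id)][1])
  if (any(!is.finite(tbl$time)) || any(tbl$time < 0))
    stop_format("clinical `time` must be finite and non-negative")
  if (!all(tbl$event %in% c(0, 1)))
    stop_format("clinical `event` must be coded 0/1")
  as_tibble(tbl)
}

#' @param tbl A clinical tibble.
#' @rdname read_clinical
#' @export
write_clinical <- function(tbl, path) {
  readr::write_tsv(validate_clinical(tbl), path)
  invisible(path)
}

#' Read and write MAF-like mutation tables
#'
#' Reads a tab-separated mutation table and drops records whose variant
#' classification is in `excluded_classes` (non-coding annotation classes
#' such as "Silent", "Intron", or "IGR" carry no functional signal for the
#' screens). Column names vary across MAF dialects, so common synonyms are
#' mapped; additional synonyms can be supplied via `column_map`. The
#' classification vocabulary is deliberately not validated against a fixed
#' enum, because source dialects disagree.
#'
#' @param path Path to a TSV file.
#' @param excluded_classes Character vector of variant classes to drop.
#' @param column_map Named list mapping the canonical names `sample_id`,
#'   `gene`, `variant_classification` to the column names used in the file.
#' @return A tibble with columns `sample_id`, `gene`,
#'   `variant_classification`. The number of dropped records is reported via
#'   a message and stored in the `"n_excluded"` attribute.
#' @export
read_mutations <- function(path,
                           excluded_classes = c("Silent", "Intron", "IGR"),
                           column_map = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  synonyms <- list(
    sample_id = c("sample_id", "Tumor_Sample_Barcode", "sample", "SampleID"),
    gene = c("gene", "Hugo_Symbol", "gene_symbol"),
    variant_classification = c("variant_classification", "Variant_Classification", "variant_class")
  )
  for (nm in names(column_map %||% list())) synonyms[[nm]] <- c(column_map[[nm]], synonyms[[nm]])
  picked <- lapply(synonyms, function(cands) intersect(cands, names(tbl))[1])
  miss <- names(picked)[vapply(picked, function(x) is.na(x) || is.null(x), logical(1))]
  if (length(miss))
    stop_format("%s: missing required mutation column(s): %s", path, paste(miss, collapse = ", "))
  out <- tibble(
    sample_id = as.character(tbl[[picked$sample_id]]),
    gene = as.character(tbl[[picked$gene]]),
    variant_classification = as.character(tbl[[picked$variant_classification]])
  )
  filter_mutations(out, excluded_classes)
}

#' @param tbl A mutation tibble with the canonical three columns.
#' @rdname read_mutations
#' @export
filter_mutations <- function(tbl, excluded_classes = c("Silent", "Intron", "IGR")) {
  stopifnot(all(c("sample_id", "gene", "variant_classification") %in% names(tbl)))
  keep <- !(tbl$variant_classification %in% excluded_classes)
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    inform(sprintf("dropped %d mutation record(s) in excluded classes", n_excluded))
  out <- as_tibble(tbl[keep, , drop = FALSE])
  attr(out, "n_excluded") <- n_excluded
  out
}

#' @rdname read_mutations
#' @export
write_mutations <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read and write gene-set collections (GMT)
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a set are de-duplicated; duplicate set names are
#' an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with a parallel
#'   `"description"` attribute, class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop_format("%s: line %d has fewer than 3 tab-separated fields", path, short[1])
  nms <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nms))
    stop_format("%s: duplicate gene-set name '%s'", path, nms[duplicated(nms)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  gene_set_collection(sets, descriptions = vapply(fields, `[[`, character(1), 2))
}

#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @rdname read_gmt
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_format("gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop_format("duplicate gene-set name '%s'", names(sets)[duplicated(names(sets))][1])
  if (any(lengths(sets) == 0))
    stop_format("empty gene set '%s'", names(sets)[lengths(sets) == 0][1])
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(sets,
            description = descriptions %||% rep("", length(sets)),
            class = "gene_set_collection")
}

#' @param gsc A `gene_set_collection`.
#' @rdname read_gmt
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  desc <- attr(gsc, "description")
  lines <- vapply(seq_along(gsc), function(i) {
    paste(c(names(gsc)[i], desc[i], gsc[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
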