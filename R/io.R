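#' Read a delimited expression matrix
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; remaining cells numeric.  Duplicated gene or sample
#' identifiers are an error (the offenders are named), as are non-numeric
#' cells (reported with their row/column coordinates).  Missing values are
#' rejected unless `impute = TRUE`, in which case they are replaced by the
#' gene's mean across samples.
#'
#' @param path Path to the file.
#' @param dialect Field separator: `"tab"`, `"comma"` or `"auto"`
#'   (default; by file extension, `.csv` = comma).
#' @param impute Impute missing cells with the gene mean (default FALSE).
#'
#' @return A numeric matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames.
#' @export
read_expression <- function(path, dialect = c("auto", "tab", "comma"),
                            impute = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  sep <- switch(dialect,
    tab = "\t",
    comma = ",",
    auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  )
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character",
                   quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("expected gene ids plus at least one sample",
                          call. = FALSE)
  gene_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop(sprintf("duplicated gene id(s): %s",
                 paste(dup_g, collapse = ", ")), call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop(sprintf("duplicated sample id(s): %s",
                 paste(dup_s, collapse = ", ")), call. = FALSE)
  }
  cells <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !is.na(cells) &
                 !(trimws(cells) %in% c("", "NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at gene '%s', sample '%s' (value '%s')",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                 cells[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  if (anyNA(vals)) {
    if (!impute) {
      miss <- which(is.na(vals), arr.ind = TRUE)
      stop(sprintf(
        "missing value at gene '%s', sample '%s' (set impute = TRUE to use gene means)",
        gene_ids[miss[1, 1]], sample_ids[miss[1, 2]]), call. = FALSE)
    }
    for (i in which(rowSums(is.na(vals)) > 0)) {
      mu <- mean(vals[i, ], na.rm = TRUE)
      if (is.nan(mu)) stop(sprintf("gene '%s' has no observed values",
                                   gene_ids[i]), call. = FALSE)
      vals[i, is.na(vals[i, ])] <- mu
    }
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  vals
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression()]: gene ids in the first column (header
#' `gene_id`), sample ids as the remaining header fields.
#'
#' @param X Numeric matrix, genes x samples.
#' @param path Output path.
#' @param dialect `"tab"` (default) or `"comma"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path, dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  X <- as_matrix(X)
  sep <- if (dialect == "tab") "\t" else ","
  gene_ids <- rownames(X)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(X)))
  sample_ids <- colnames(X)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(X)))
  # %.17g keeps full double precision so values round-trip exactly
  chr <- matrix(sprintf("%.17g", X), nrow(X))
  df <- data.frame(gene_id = gene_ids, chr, check.names = FALSE)
  colnames(df) <- c("gene_id", sample_ids)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample labels
#'
#' Two-column delimited text: `sample_id`, `label`.
#'
#' @param path File path.
#' @param labels Vector of labels, optionally named by sample id.
#' @param sample_ids Sample identifiers (defaults to names of `labels`).
#' @param dialect `"tab"` (default) or `"comma"`.
#' @return `read_labels()` returns a named vector of labels;
#'   `write_labels()` returns `path` invisibly.
#' @export
read_labels <- function(path, dialect = c("auto", "tab", "comma")) {
  dialect <- match.arg(dialect)
  sep <- switch(dialect,
    tab = "\t", comma = ",",
    auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs columns sample_id, label",
                          call. = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path, sample_ids = names(labels),
                         dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tab") "\t" else ","
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_along(labels))
  write.table(data.frame(sample_id = sample_ids, label = unname(labels)),
              path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
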