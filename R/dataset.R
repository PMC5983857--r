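#' Gene-by-feature dataset
#'
#' Container for one omics dataset: a numeric matrix with genes on the rows and
#' features (tissues, pathways, diseases, ...) on the columns, plus a `kind`
#' flag that governs how the dataset is standardized and which association
#' measure is used during dimensionality reduction.
#'
#' Three kinds are supported, matching the three value shapes found in
#' gene-attribute compendia such as the Harmonizome:
#' \describe{
#'   \item{quantitative-filled}{dense continuous values, e.g. microarray
#'     expression; columns are z-scored.}
#'   \item{quantitative-sparse}{continuous values with structural zeros meaning
#'     "absent", e.g. immunohistochemistry scores; columns are scaled by their
#'     mean so zeros are preserved.}
#'   \item{categorical-sparse}{binary membership values, e.g. curated pathway
#'     annotations; left untouched by standardization.}
#' }
#'
#' @param values Numeric gene x feature matrix.
#' @param genes Character vector of gene/target identifiers (row labels).
#' @param feature_labels Character vector of feature labels (column labels).
#' @param kind One of `"quantitative-filled"`, `"quantitative-sparse"`,
#'   `"categorical-sparse"`.
#' @param name Dataset name.
#' @param is_human Whether the dataset describes human genes (used by the
#'   classifier's aggregation exclusions).
#' @param n_genes_total Total gene count of the source dataset (defaults to
#'   `nrow(values)`); used by the small-dataset aggregation exclusion.
#' @return An object of class `gene_feature_dataset`.
#' @export
gene_feature_dataset <- function(values, genes, feature_labels, kind, name,
                                 is_human = TRUE, n_genes_total = nrow(values)) {
  kind <- match.arg(kind, dataset_kinds())
  values <- as.matrix(values)
  if (nrow(values) != length(genes)) {
    stop("number of rows of `values` must equal length of `genes`")
  }
  if (ncol(values) != length(feature_labels)) {
    stop("number of columns of `values` must equal length of `feature_labels`")
  }
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (anyDuplicated(feature_labels)) stop("duplicate feature labels")
  if (kind == "categorical-sparse" && !all(values %in% c(0, 1))) {
    stop("categorical-sparse values must be 0/1")
  }
  dimnames(values) <- list(genes, feature_labels)
  structure(
    list(
      name = name, kind = kind, genes = genes,
      feature_labels = feature_labels, values = values,
      raw_values = NULL, is_human = is_human,
      n_genes_total = n_genes_total, standardized = FALSE
    ),
    class = "gene_feature_dataset"
  )
}

dataset_kinds <- function() {
  c("quantitative-filled", "quantitative-sparse", "categorical-sparse")
}

#' @export
print.gene_feature_dataset <- function(x, ...) {
  cat(sprintf(
    "gene_feature_dataset '%s' (%s%s): %d genes x %d features%s\n",
    x$name, x$kind, if (x$is_human) "" else ", non-human",
    length(x$genes), length(x$feature_labels),
    if (isTRUE(x$standardized)) ", standardized" else ""
  ))
  invisible(x)
}

#' Standardize a dataset according to its kind
#'
#' Quantitative filled-in columns are z-scored (mean 0, population SD 1; the
#' population convention makes standardization exactly idempotent).
#' Quantitative sparse columns are divided by their column mean, a scaling that
#' preserves zeros (absences) and gives every column mean 1. Categorical
#' columns are left unchanged. The pre-standardization matrix is kept in
#' `raw_values` so raw-scale features (e.g. expression entropy) can still be
#' computed afterwards.
#'
#' Degenerate columns (zero variance for the filled kind, zero mean for the
#' sparse kind) cannot be standardized; they are dropped with a warning.
#'
#' @param ds A [gene_feature_dataset()].
#' @return The standardized dataset.
#' @export
standardize <- function(ds) {
  stopifnot(inherits(ds, "gene_feature_dataset"))
  if (ds$kind != "categorical-sparse" && !all(is.finite(ds$values))) {
    stop("quantitative values must be finite")
  }
  if (is.null(ds$raw_values)) ds$raw_values <- ds$values
  if (ds$kind == "quantitative-filled") {
    mu <- colMeans(ds$values)
    n <- nrow(ds$values)
    sd_ <- apply(ds$values, 2, stats::sd) * sqrt((n - 1) / n)
    bad <- sd_ == 0
    if (any(bad)) {
      warning(sprintf(
        "dropping %d zero-variance column(s) in '%s': %s",
        sum(bad), ds$name, paste(ds$feature_labels[bad], collapse = ", ")
      ))
    }
    keep <- !bad
    ds$values <- sweep(
      sweep(ds$values[, keep, drop = FALSE], 2, mu[keep]),
      2, sd_[keep], "/"
    )
    ds$feature_labels <- ds$feature_labels[keep]
  } else if (ds$kind == "quantitative-sparse") {
    mu <- colMeans(ds$values)
    bad <- mu == 0
    if (any(bad)) {
      warning(sprintf(
        "dropping %d zero-mean column(s) in '%s': %s",
        sum(bad), ds$name, paste(ds$feature_labels[bad], collapse = ", ")
      ))
    }
    keep <- !bad
    ds$values <- sweep(ds$values[, keep, drop = FALSE], 2, mu[keep], "/")
    ds$feature_labels <- ds$feature_labels[keep]
  }
  ds$standardized <- TRUE
  ds
}

#' Append per-gene mean and standard deviation as extra features
#'
#' Adds two columns, `"mean"` and `"stdv"`, holding each gene's mean and
#' standard deviation (population convention, matching the column
#' standardization) across the dataset's current (typically standardized)
#' columns. These row summaries carry interpretable information
#' such as how broadly and how variably a gene is expressed across tissues.
#'
#' @param ds A [gene_feature_dataset()], normally already standardized.
#' @param use_raw Compute the summaries on `raw_values` instead of the current
#'   (standardized) values.
#' @return The dataset with the summary columns appended last.
#' @export
append_row_summaries <- function(ds, use_raw = FALSE) {
  stopifnot(inherits(ds, "gene_feature_dataset"))
  src <- if (use_raw) ds$raw_values %||% ds$values else ds$values
  if (any(c("mean", "stdv") %in% ds$feature_labels)) {
    stop("dataset already has 'mean'/'stdv' columns")
  }
  m <- rowMeans(src)
  ds$values <- cbind(ds$values, mean = m)
  ds$feature_labels <- c(ds$feature_labels, "mean")
  if (ncol(src) < 2) {
    warning(sprintf(
      "dataset '%s' has a single feature column; 'stdv' summary omitted",
      ds$name
    ))
  } else {
    m <- ncol(src)
    s <- apply(src, 1, stats::sd) * sqrt((m - 1) / m)
    ds$values <- cbind(ds$values, stdv = s)
    ds$feature_labels <- c(ds$feature_labels, "stdv")
  }
  ds
}

#' Append expression entropy as an extra feature
#'
#' For each gene, entropy is `H = sum_i P_i log2(1 / P_i)` with
#' `P_i = E_i / sum(E_i)`, where `E_i` are the un-log-transformed raw values
#' (e.g. expression across tissues). Low entropy indicates tissue-specific
#' expression; the maximum, `log2(n_features)`, indicates uniform expression.
#' Genes with all-zero raw values get entropy 0.
#'
#' @param ds A [gene_feature_dataset()] whose raw values are nonnegative
#'   (expression-like data).
#' @return The dataset with an `"entropy"` column appended.
#' @export
append_entropy <- function(ds) {
  stopifnot(inherits(ds, "gene_feature_dataset"))
  raw <- ds$raw_values %||% ds$values
  if (any(raw < 0)) {
    stop("entropy requires nonnegative raw values")
  }
  if ("entropy" %in% ds$feature_labels) stop("dataset already has an 'entropy' column")
  h <- apply(raw, 1, row_entropy)
  ds$values <- cbind(ds$values, entropy = h)
  ds$feature_labels <- c(ds$feature_labels, "entropy")
  ds
}

row_entropy <- function(e) {
  tot <- sum(e)
  if (tot == 0) {
    return(0)
  }
  p <- e[e > 0] / tot
  -sum(p * log2(p))
}

#' Drop features with insufficient coverage of outcome-labeled targets
#'
#' Retains only columns with at least `min_nonzero` non-zero values among the
#' labeled targets present in the dataset. For standardized filled-in data any
#' value different from exactly zero counts as non-zero; for sparse kinds,
#' stored zeros are absences.
#'
#' @param ds A [gene_feature_dataset()].
#' @param labeled_targets Identifiers of targets with clinical outcomes.
#' @param min_nonzero Minimum number of non-zero labeled values (default 3).
#' @return The filtered dataset.
#' @export
coverage_filter <- function(ds, labeled_targets, min_nonzero = 3) {
  stopifnot(inherits(ds, "gene_feature_dataset"))
  rows <- ds$genes %in% labeled_targets
  nz <- colSums(ds$values[rows, , drop = FALSE] != 0)
  keep <- nz >= min_nonzero
  ds$values <- ds$values[, keep, drop = FALSE]
  if (!is.null(ds$raw_values)) {
    raw_keep <- colnames(ds$raw_values) %in% ds$feature_labels[keep]
    ds$raw_values <- ds$raw_values[, raw_keep, drop = FALSE]
  }
  ds$feature_labels <- ds$feature_labels[keep]
  ds
}

#' Read a gene-attribute matrix from a delimited text file
#'
#' Expects a tab-delimited layout with gene symbols in the first column, gene
#' identifiers in the second, and features in the remaining columns. Both a
#' plain single-header TSV and the three-line-header dialect used by "cleaned"
#' gene-attribute exports (two extra metadata header lines whose first field is
#' empty or `#`) are accepted; the dialect is sniffed automatically.
#'
#' @param path Path to the TSV file.
#' @param kind Dataset kind; see [gene_feature_dataset()].
#' @param name Dataset name (defaults to the file name).
#' @param is_human,n_genes_total Passed to [gene_feature_dataset()].
#' @return A [gene_feature_dataset()].
#' @export
read_feature_matrix <- function(path, kind, name = basename(path),
                                is_human = TRUE, n_genes_total = NULL) {
  lines <- readLines(path)
  probe <- lines[seq.int(2, length.out = min(2, length(lines) - 1))]
  first_field <- vapply(
    strsplit(probe, "\t", fixed = TRUE),
    function(x) if (length(x)) x[[1]] else "", character(1)
  )
  is_meta <- first_field %in% c("", "#") | startsWith(first_field, "#")
  n_meta <- if (all(is_meta)) length(is_meta) else (which(!is_meta)[1] - 1L)
  body <- if (n_meta > 0) lines[-seq.int(2, 1 + n_meta)] else lines
  df <- utils::read.delim(
    text = paste(body, collapse = "\n"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (ncol(df) < 3) stop("expected >= 3 columns: symbol, id, features")
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(values) <- "double"
  gene_feature_dataset(
    values,
    genes = as.character(df[[2]]), feature_labels = colnames(values),
    kind = kind, name = name, is_human = is_human,
    n_genes_total = n_genes_total %||% nrow(values)
  )
}

#' Write a gene-attribute matrix as a single-header TSV
#'
#' @param ds A [gene_feature_dataset()].
#' @param path Output path.
#' @param raw Write `raw_values` instead of the current values.
#' @export
write_feature_matrix <- function(ds, path, raw = FALSE) {
  stopifnot(inherits(ds, "gene_feature_dataset"))
  vals <- if (raw) ds$raw_values %||% ds$values else ds$values
  df <- data.frame(
    symbol = ds$genes, gene_id = ds$genes, vals,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
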