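#' Pairwise feature association matrix
#'
#' Spearman rank correlation for quantitative filled-in datasets; the cosine
#' coefficient for sparse or categorical datasets (where rank correlation is
#' dominated by tied zeros). The matrix is symmetric with unit diagonal; an
#' all-zero column has cosine association 0 with every other column.
#'
#' @param ds A [gene_feature_dataset()] with at least two features.
#' @return A feature x feature matrix of association coefficients `r`.
#' @export
pairwise_association <- function(ds) {
  stopifnot(inherits(ds, "gene_feature_dataset"))
  x <- ds$values
  if (ncol(x) < 2) stop("need at least 2 features")
  if (ds$kind == "quantitative-filled") {
    r <- stats::cor(x, method = "spearman")
  } else {
    nrm <- sqrt(colSums(x^2))
    r <- crossprod(x) / outer(nrm, nrm)
    r[!is.finite(r)] <- 0 # zero vectors
  }
  diag(r) <- 1
  dimnames(r) <- list(ds$feature_labels, ds$feature_labels)
  r
}

#' Replace groups of correlated features with representative features
#'
#' Thresholds the squared pairwise association matrix at `r2_threshold`
#' (squaring first, so anticorrelated features group together), orders
#' features by decreasing number of correlated neighbours (ties broken by
#' original column order), and greedily forms groups: each yet-ungrouped seed
#' absorbs its yet-ungrouped correlated neighbours, judged on the original
#' association matrix (no recomputation against group means). A group
#' containing the dataset `"mean"` summary column is represented by the
#' dataset mean itself; any other group is represented by the plain average of
#' its member columns, labeled by the seed feature.
#'
#' @param ds A [gene_feature_dataset()] (including its `"mean"` column if
#'   computed).
#' @param r2_threshold Squared-association grouping threshold (default 0.5).
#' @return A `reduced_dataset`: list with the source dataset and a list of
#'   feature groups (`representative_label`, `member_labels`, `values`,
#'   `is_dataset_mean`).
#' @export
reduce_features <- function(ds, r2_threshold = 0.5) {
  stopifnot(inherits(ds, "gene_feature_dataset"))
  p <- ncol(ds$values)
  if (p == 1) {
    groups <- list(list(
      representative_label = ds$feature_labels, member_labels = ds$feature_labels,
      values = ds$values[, 1], is_dataset_mean = FALSE, seed_r2 = 1
    ))
  } else {
    r2 <- pairwise_association(ds)^2
    adj <- r2 >= r2_threshold
    diag(adj) <- FALSE
    ord <- order(-colSums(adj), seq_len(p))
    grouped <- logical(p)
    groups <- list()
    for (i in ord) {
      if (grouped[i]) next
      members <- c(i, which(adj[, i] & !grouped & seq_len(p) != i))
      grouped[members] <- TRUE
      mean_idx <- match("mean", ds$feature_labels[members])
      if (!is.na(mean_idx)) {
        rep_lab <- "mean"
        vals <- ds$values[, members[mean_idx]]
        is_mean <- TRUE
      } else {
        rep_lab <- ds$feature_labels[i]
        vals <- rowMeans(ds$values[, members, drop = FALSE])
        is_mean <- FALSE
      }
      groups[[length(groups) + 1L]] <- list(
        representative_label = rep_lab,
        member_labels = ds$feature_labels[members],
        values = vals, is_dataset_mean = is_mean,
        seed_r2 = unname(r2[members, i])
      )
    }
  }
  structure(list(source = ds, groups = groups), class = "reduced_dataset")
}

#' @export
print.reduced_dataset <- function(x, ...) {
  cat(sprintf(
    "reduced_dataset '%s': %d features -> %d groups\n",
    x$source$name, ncol(x$source$values), length(x$groups)
  ))
  invisible(x)
}

#' Gene x representative-feature matrix of a reduced dataset
#'
#' @param rd A [reduce_features()] result.
#' @return Numeric matrix, genes on rows, one column per feature group.
#' @export
reduced_values <- function(rd) {
  stopifnot(inherits(rd, "reduced_dataset"))
  m <- vapply(rd$groups, `[[`, numeric(length(rd$source$genes)), "values")
  m <- matrix(m, nrow = length(rd$source$genes))
  dimnames(m) <- list(
    rd$source$genes,
    vapply(rd$groups, `[[`, character(1), "representative_label")
  )
  m
}

#' Write group membership as a TSV
#'
#' One row per group: representative label, `";"`-joined member labels, and
#' the members' squared association with the group seed.
#'
#' @param rd A [reduce_features()] result.
#' @param path Output path.
#' @export
write_groups <- function(rd, path) {
  df <- data.frame(
    representative = vapply(rd$groups, `[[`, character(1), "representative_label"),
    members = vapply(rd$groups, function(g) paste(g$member_labels, collapse = ";"), character(1)),
    r2_to_seed = vapply(rd$groups, function(g) paste(signif(g$seed_r2, 4), collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
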