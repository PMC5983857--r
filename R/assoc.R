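#' Difference between success and failure group means
#'
#' The test statistic used throughout the screening stage:
#' `mean(values[success]) - mean(values[failure])`.
#'
#' @param values Numeric vector of one feature's values for labeled targets.
#' @param labels Character vector (`"success"` / `"failure"`), aligned with
#'   `values`.
#' @return The difference of means.
#' @export
diff_of_means <- function(values, labels) {
  s <- labels == "success"
  f <- labels == "failure"
  if (!any(s) || !any(f)) {
    stop("need at least one success and one failure with values")
  }
  mean(values[s]) - mean(values[f])
}

# --- permutation machinery ---------------------------------------------------

# strata: NULL, or a vector of stratum ids aligned with `ind`
split_strata <- function(n, strata) {
  if (is.null(strata)) list(seq_len(n)) else unname(split(seq_len(n), strata))
}

n_labelings <- function(ind, strata = NULL) {
  parts <- split_strata(length(ind), strata)
  prod(vapply(parts, function(ix) choose(length(ix), sum(ind[ix])), numeric(1)))
}

# all labelings preserving per-stratum success counts, as a L x n logical matrix
enumerate_indicators <- function(ind, strata = NULL) {
  n <- length(ind)
  parts <- split_strata(n, strata)
  per <- lapply(parts, function(ix) {
    k <- sum(ind[ix])
    ch <- utils::combn(length(ix), k)
    m <- matrix(FALSE, ncol(ch), length(ix))
    for (r in seq_len(ncol(ch))) m[r, ch[, r]] <- TRUE
    m
  })
  counts <- vapply(per, nrow, integer(1))
  total <- prod(counts)
  out <- matrix(FALSE, total, n)
  idx <- rep(1L, length(per))
  block <- 1L
  for (s in seq_along(per)) {
    reps_inner <- block
    reps_outer <- total / (block * counts[s])
    rows <- rep(rep(seq_len(counts[s]), each = reps_inner), times = reps_outer)
    out[, parts[[s]]] <- per[[s]][rows, , drop = FALSE]
    block <- block * counts[s]
  }
  out
}

# n_perm random labelings preserving per-stratum success counts
sample_indicators <- function(ind, strata = NULL, n_perm) {
  n <- length(ind)
  parts <- split_strata(n, strata)
  out <- matrix(FALSE, n_perm, n)
  for (ix in parts) {
    k <- sum(ind[ix])
    if (k == 0L || k == length(ix)) {
      out[, ix[ind[ix]]] <- TRUE
      next
    }
    for (i in seq_len(n_perm)) {
      out[i, ix[sample.int(length(ix), k)]] <- TRUE
    }
  }
  out
}

# indicator matrix -> weight matrix so that W %*% X gives difference of means
indicator_weights <- function(indmat) {
  ks <- rowSums(indmat)
  kf <- ncol(indmat) - ks
  indmat / ks - (1 - indmat) / kf
}

#' Convert a target-class map into permutation strata
#'
#' Builds the stratum id of every target for within-class-stratified
#' permutation. Targets listed under several classes get their first listed
#' class. Unclassified targets either share one pooled stratum (default; an
#' own-stratum policy would freeze their labels and destroy power) or each
#' form their own stratum.
#'
#' @param class_map Data frame with columns `target_id`, `class`.
#' @param targets Target identifiers to map.
#' @param unclassified `"pooled-stratum"` or `"own-stratum"`.
#' @return Character vector of stratum ids, named by target.
#' @export
strata_from_class_map <- function(class_map, targets,
                                  unclassified = c("pooled-stratum", "own-stratum")) {
  unclassified <- match.arg(unclassified)
  cls <- class_map$class[match(targets, class_map$target_id)]
  if (unclassified == "pooled-stratum") {
    cls[is.na(cls)] <- ".unclassified"
  } else {
    cls[is.na(cls)] <- paste0(".own.", targets[is.na(cls)])
  }
  names(cls) <- targets
  cls
}

#' Permutation test for outcome association of one feature
#'
#' Tests the difference between success and failure means against a null
#' distribution obtained by shuffling the success/failure labels. When
#' `strata` is supplied, labels are shuffled independently within each
#' stratum, preserving the within-stratum success/failure counts, so features
#' that merely discriminate between strata (e.g. target classes) cannot be
#' significant. When the number of distinct labelings is at most `n_perm` the
#' null is enumerated exhaustively and the p-value is exact; otherwise
#' `n_perm` Monte-Carlo permutations are drawn and the add-one convention
#' `p = (1 + #extreme) / (1 + n_perm)` is used, so the p-value is never zero.
#'
#' @param values Numeric feature values for labeled targets.
#' @param labels `"success"` / `"failure"` labels aligned with `values`.
#' @param n_perm Number of permutations (default `1e5`).
#' @param strata Optional stratum ids aligned with `values`.
#' @param seed Optional integer seed for the Monte-Carlo draw.
#' @param feature_label Label carried into the result.
#' @return A `perm_result` list: `feature_label`, `observed_diff`, `sign`,
#'   `p_raw`, `p_adj` (equal to `p_raw` for a single test), `significant`,
#'   `n_perm` (permutations actually used), `exhaustive`.
#' @export
permutation_test <- function(values, labels, n_perm = 1e5, strata = NULL,
                             seed = NULL, feature_label = "feature") {
  if (n_perm < 1) stop("n_perm must be >= 1")
  res <- screen_features(matrix(values, ncol = 1, dimnames = list(NULL, feature_label)),
    labels,
    n_perm = n_perm, strata = strata, seed = seed
  )
  structure(
    list(
      feature_label = feature_label,
      observed_diff = res$observed_diff[1],
      sign = res$sign[1],
      p_raw = res$p_raw[1],
      p_adj = res$p_adj[1],
      significant = res$significant[1],
      n_perm = res$n_perm[1],
      exhaustive = res$method[1] == "exhaustive"
    ),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "perm_result '%s': diff = %.4g, p = %.4g (%s, %d labelings)\n",
    x$feature_label, x$observed_diff, x$p_raw,
    if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$n_perm
  ))
  invisible(x)
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-down adjustment `min(1, cummin m c(m) p_(i) / i)` with
#' `c(m) = sum_{k<=m} 1/k`, valid under arbitrary dependence between the
#' p-values; a thin validating wrapper around [stats::p.adjust()].
#'
#' @param p Raw p-values in `(0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
by_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BY")
}

#' Screen all features of a dataset for outcome association
#'
#' Runs the permutation test of [permutation_test()] on every representative
#' feature of a reduced dataset, using one common set of label permutations
#' for the whole dataset, then applies Benjamini-Yekutieli adjustment within
#' the dataset and flags features with adjusted p below `alpha`.
#'
#' @param ds A `reduced_dataset`, `gene_feature_dataset`, or plain numeric
#'   matrix (targets on rows).
#' @param outcomes A `target_outcomes` data.frame (or named label vector).
#' @param alpha Within-dataset FDR level (default 0.05).
#' @param n_perm Permutations per screen (default `1e5`).
#' @param strata Optional: stratum ids named by target (see
#'   [strata_from_class_map()]), or a `class_map` data.frame.
#' @param seed Optional integer seed.
#' @return A `screen_result` data.frame with one row per feature:
#'   `feature_label`, `observed_diff`, `sign`, `p_raw`, `p_adj`,
#'   `significant`, `n_perm`, `method`.
#' @export
screen_dataset <- function(ds, outcomes, alpha = 0.05, n_perm = 1e5,
                           strata = NULL, seed = NULL) {
  x <- if (inherits(ds, "reduced_dataset")) {
    reduced_values(ds)
  } else if (inherits(ds, "gene_feature_dataset")) {
    ds$values
  } else {
    as.matrix(ds)
  }
  lv <- if (is.data.frame(outcomes)) {
    outcome_vector(outcomes, rownames(x) %||% outcomes$target_id)
  } else {
    outcomes
  }
  if (!is.null(rownames(x))) lv <- lv[rownames(x)]
  keep <- lv %in% c("success", "failure")
  x <- x[keep, , drop = FALSE]
  lv <- lv[keep]
  if (is.data.frame(strata)) {
    strata <- strata_from_class_map(strata, rownames(x) %||% as.character(seq_len(nrow(x))))
  } else if (!is.null(strata) && !is.null(names(strata)) && !is.null(rownames(x))) {
    strata <- strata[rownames(x)]
    strata[is.na(strata)] <- ".unclassified"
  }
  screen_features(x, lv, alpha = alpha, n_perm = n_perm, strata = strata, seed = seed)
}

# core screening routine on an aligned matrix + label vector
screen_features <- function(x, labels, alpha = 0.05, n_perm = 1e5,
                            strata = NULL, seed = NULL) {
  x <- as.matrix(x)
  if (ncol(x) == 0 || nrow(x) == 0) {
    return(empty_screen_result())
  }
  stopifnot(all(labels %in% c("success", "failure")))
  ind <- labels == "success"
  if (!any(ind) || all(ind)) {
    stop("need both outcome classes to screen")
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- as.numeric(indicator_weights(matrix(ind, nrow = 1)) %*% x)
  total <- n_labelings(ind, strata)
  exhaustive <- is.finite(total) && total <= n_perm
  indmat <- if (exhaustive) {
    enumerate_indicators(ind, strata)
  } else {
    sample_indicators(ind, strata, n_perm)
  }
  null_stats <- indicator_weights(indmat) %*% x
  thr <- abs(obs) * (1 - 1e-12)
  extreme <- sweep(abs(null_stats), 2, thr, ">=")
  p_raw <- if (exhaustive) {
    colMeans(extreme)
  } else {
    (1 + colSums(extreme)) / (1 + n_perm)
  }
  p_adj <- by_adjust(p_raw)
  out <- data.frame(
    feature_label = colnames(x) %||% sprintf("f%d", seq_len(ncol(x))),
    observed_diff = obs,
    sign = ifelse(obs >= 0, 1, -1),
    p_raw = p_raw,
    p_adj = p_adj,
    significant = p_adj < alpha,
    n_perm = if (exhaustive) as.integer(total) else as.integer(n_perm),
    method = if (exhaustive) "exhaustive" else "monte-carlo",
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

empty_screen_result <- function() {
  out <- data.frame(
    feature_label = character(), observed_diff = numeric(), sign = numeric(),
    p_raw = numeric(), p_adj = numeric(), significant = logical(),
    n_perm = integer(), method = character(), stringsAsFactors = FALSE
  )
  class(out) <- c("screen_result", "data.frame")
  out
}
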