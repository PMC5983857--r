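#' Bootstrap replication probabilities for screened features
#'
#' Estimates, for every representative feature of a dataset, the probability
#' that its significance finding replicates on a resampled set of targets.
#' Three schemes probe different failure modes:
#' \describe{
#'   \item{bootstrap}{plain resampling with replacement of the labeled
#'     targets; tests robustness to sample variation.}
#'   \item{class-holdout}{members of outcome-correlated target classes
#'     (`excluded_classes`) are removed from the pool before resampling;
#'     tests whether a finding depends on one historically lucky or unlucky
#'     gene family.}
#'   \item{within-class-permutation}{plain resampling, but each round's screen
#'     shuffles labels only within target classes (`strata`); tests whether a
#'     finding generalizes across classes rather than discriminating between
#'     them.}
#' }
#' Each round draws a sample equal in size to the (possibly class-excluded)
#' labeled set and reruns the full within-dataset screen (same `alpha`, BY
#' family = all representative features). Rounds with fewer than two targets
#' of either outcome are redrawn; more than 10% redraws triggers a warning.
#'
#' @param ds A `reduced_dataset` (or matrix; see [screen_dataset()]).
#' @param outcomes A `target_outcomes` data.frame.
#' @param scheme One of `"bootstrap"`, `"class-holdout"`,
#'   `"within-class-permutation"`.
#' @param class_map Data frame `target_id`/`class`; needed by the holdout and
#'   stratified schemes.
#' @param excluded_classes Classes excluded from the resampling pool
#'   (class-holdout scheme).
#' @param n_boot Number of bootstrap rounds (default 1000).
#' @param alpha Within-dataset FDR level per round.
#' @param n_perm Permutations per feature per round.
#' @param pass_threshold Replication probability required to pass
#'   (default 0.8).
#' @param seed Optional integer seed.
#' @return A `replication_report` data.frame: `feature_label`, `scheme`,
#'   `replication_probability`, `n_boot`, `pass`.
#' @export
bootstrap_replication <- function(ds, outcomes,
                                  scheme = c(
                                    "bootstrap", "class-holdout",
                                    "within-class-permutation"
                                  ),
                                  class_map = NULL, excluded_classes = NULL,
                                  n_boot = 1000, alpha = 0.05, n_perm = 1e4,
                                  pass_threshold = 0.8, seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  x <- if (inherits(ds, "reduced_dataset")) reduced_values(ds) else as.matrix(ds)
  lv <- outcome_vector(outcomes, rownames(x))
  keep <- lv %in% c("success", "failure")
  x <- x[keep, , drop = FALSE]
  lv <- lv[keep]
  ids <- rownames(x)

  if (scheme == "class-holdout") {
    if (is.null(class_map) || is.null(excluded_classes)) {
      stop("class-holdout scheme needs `class_map` and `excluded_classes`")
    }
    held <- class_map$target_id[class_map$class %in% excluded_classes]
    pool <- which(!ids %in% held)
  } else {
    pool <- seq_along(ids)
  }
  if (length(unique(lv[pool])) < 2) {
    stop("labels must contain both classes after exclusion")
  }
  strata <- NULL
  if (scheme == "within-class-permutation") {
    if (is.null(class_map)) stop("within-class-permutation scheme needs `class_map`")
    strata <- strata_from_class_map(class_map, ids)
  }

  n_sig <- numeric(ncol(x))
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      take <- pool[sample.int(length(pool), length(pool), replace = TRUE)]
      if (sum(lv[take] == "success") >= 2 && sum(lv[take] == "failure") >= 2) break
      redraws <- redraws + 1L
    }
    res <- screen_features(x[take, , drop = FALSE], lv[take],
      alpha = alpha, n_perm = n_perm,
      strata = if (is.null(strata)) NULL else strata[take]
    )
    n_sig <- n_sig + res$significant
  }
  if (redraws > 0.1 * n_boot) {
    warning(sprintf(
      "%d of %d bootstrap rounds redrawn for a degenerate outcome split",
      redraws, n_boot
    ))
  }
  out <- data.frame(
    feature_label = colnames(x),
    scheme = scheme,
    replication_probability = n_sig / n_boot,
    n_boot = as.integer(n_boot),
    pass = n_sig / n_boot > pass_threshold,
    stringsAsFactors = FALSE
  )
  class(out) <- c("replication_report", "data.frame")
  attr(out, "redraws") <- redraws
  out
}

#' Test target classes for association with clinical outcome
#'
#' Builds a binary membership feature per class and runs the difference-of-
#' means permutation test against the success/failure labels, adjusting over
#' all classes as one BY family. Classes with no labeled members are skipped
#' with a warning.
#'
#' @param class_map Data frame `target_id`/`class`.
#' @param outcomes A `target_outcomes` data.frame.
#' @param alpha FDR level.
#' @param n_perm Permutations per class.
#' @param seed Optional integer seed.
#' @return A `class_association` data.frame: `class_label`, `n_members`,
#'   `n_success`, `observed_diff`, `sign`, `p_raw`, `p_adj`, `significant`.
#' @export
class_outcome_tests <- function(class_map, outcomes, alpha = 0.05,
                                n_perm = 1e4, seed = NULL) {
  lab <- labeled_ids(outcomes)
  lv <- outcome_vector(outcomes, lab)
  classes <- unique(class_map$class)
  empty <- classes[!vapply(
    classes,
    function(cl) any(class_map$target_id[class_map$class == cl] %in% lab),
    logical(1)
  )]
  if (length(empty)) {
    warning(
      "skipping class(es) with no labeled members: ",
      paste(empty, collapse = ", ")
    )
    classes <- setdiff(classes, empty)
  }
  if (!length(classes)) {
    return(data.frame(
      class_label = character(), n_members = integer(),
      n_success = integer(), observed_diff = numeric(), sign = numeric(),
      p_raw = numeric(), p_adj = numeric(), significant = logical()
    ))
  }
  memb <- vapply(
    classes,
    function(cl) as.numeric(lab %in% class_map$target_id[class_map$class == cl]),
    numeric(length(lab))
  )
  memb <- matrix(memb, nrow = length(lab), dimnames = list(lab, classes))
  res <- screen_features(memb, lv, alpha = alpha, n_perm = n_perm, seed = seed)
  data.frame(
    class_label = classes,
    n_members = colSums(memb),
    n_success = colSums(memb[lv == "success", , drop = FALSE]),
    observed_diff = res$observed_diff,
    sign = res$sign,
    p_raw = res$p_raw,
    p_adj = res$p_adj,
    significant = res$significant,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Test outcome-correlated classes against outcome-correlated features
#'
#' For each (class, feature) pair, permutation-tests the difference of the
#' feature's means between class members and non-members among labeled
#' targets, with BY adjustment across all pairs. A significant pair marks a
#' feature that may merely be a surrogate indicator of a historically
#' successful or unsuccessful gene family.
#'
#' @param ds A `reduced_dataset` (or matrix) holding the features.
#' @param significant_classes Class labels to test.
#' @param significant_features Feature labels to test.
#' @param class_map Data frame `target_id`/`class`.
#' @param outcomes A `target_outcomes` data.frame.
#' @param alpha FDR level.
#' @param n_perm Permutations per pair.
#' @param seed Optional integer seed.
#' @return Data frame: `class_label`, `feature_label`, `observed_diff`,
#'   `sign`, `p_raw`, `p_adj`, `significant`.
#' @export
class_feature_tests <- function(ds, significant_classes, significant_features,
                                class_map, outcomes, alpha = 0.05,
                                n_perm = 1e4, seed = NULL) {
  if (!length(significant_classes) || !length(significant_features)) {
    return(data.frame(
      class_label = character(), feature_label = character(),
      observed_diff = numeric(), sign = numeric(), p_raw = numeric(),
      p_adj = numeric(), significant = logical()
    ))
  }
  if (!is.null(seed)) set.seed(seed)
  x <- if (inherits(ds, "reduced_dataset")) reduced_values(ds) else as.matrix(ds)
  lab <- intersect(rownames(x), labeled_ids(outcomes))
  x <- x[lab, significant_features, drop = FALSE]
  rows <- list()
  for (cl in significant_classes) {
    memb <- ifelse(lab %in% class_map$target_id[class_map$class == cl],
      "success", "failure" # members vs non-members
    )
    if (length(unique(memb)) < 2) next
    res <- screen_features(x, memb, alpha = alpha, n_perm = n_perm)
    rows[[cl]] <- data.frame(
      class_label = cl, feature_label = res$feature_label,
      observed_diff = res$observed_diff, sign = res$sign,
      p_raw = res$p_raw, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- by_adjust(out$p_raw) # one family across all pairs
  out$significant <- out$p_adj < alpha
  out
}
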