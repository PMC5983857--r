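#' Pool out-of-fold test predictions by repetition
#'
#' Each repetition of the outer loop gives every labeled target exactly one
#' out-of-fold prediction (cycles of the same repetition have disjoint test
#' sets). Returns a targets x repetitions matrix of predicted success
#' probabilities; null-model cycles leave `NA`s.
#'
#' @param cycles A `cv_result`.
#' @return Numeric matrix, labeled targets on rows, repetitions on columns.
#' @export
pooled_test_predictions <- function(cycles) {
  reps <- sort(unique(vapply(cycles, `[[`, numeric(1), "rep")))
  ids <- sort(unique(unlist(lapply(cycles, `[[`, "test_ids"))))
  m <- matrix(NA_real_, length(ids), length(reps), dimnames = list(ids, reps))
  for (cy in cycles) {
    if (isTRUE(cy$null_model)) next
    m[names(cy$test_pred), as.character(cy$rep)] <- cy$test_pred
  }
  m
}

#' Average unlabeled-target predictions by repetition
#'
#' Unlabeled targets receive up to `outer_folds` predictions per repetition
#' (one per cycle); they are averaged to a single value per repetition.
#'
#' @param cycles A `cv_result`.
#' @return Numeric matrix, unlabeled targets on rows, repetitions on columns.
#' @export
pooled_unlabeled_predictions <- function(cycles) {
  reps <- sort(unique(vapply(cycles, `[[`, numeric(1), "rep")))
  ids <- sort(unique(unlist(lapply(cycles, function(cy) names(cy$unlabeled_pred)))))
  if (!length(ids)) {
    return(matrix(NA_real_, 0, length(reps), dimnames = list(NULL, reps)))
  }
  sums <- matrix(0, length(ids), length(reps), dimnames = list(ids, reps))
  n <- sums
  for (cy in cycles) {
    if (isTRUE(cy$null_model) || !length(cy$unlabeled_pred)) next
    j <- as.character(cy$rep)
    sums[names(cy$unlabeled_pred), j] <- sums[names(cy$unlabeled_pred), j] + cy$unlabeled_pred
    n[names(cy$unlabeled_pred), j] <- n[names(cy$unlabeled_pred), j] + 1
  }
  out <- sums / n
  out[n == 0] <- NA_real_
  out
}

confusion_stats <- function(pred, y, threshold) {
  pos <- pred >= threshold
  tp <- sum(pos & y)
  fp <- sum(pos & !y)
  tn <- sum(!pos & !y)
  fn <- sum(!pos & y)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  tpr <- tp / (tp + fn)
  fpr <- fp / (fp + tn)
  fnr <- fn / (tp + fn)
  tnr <- tn / (fp + tn)
  ppv <- tp / (tp + fp)
  fomr <- fn / (fn + tn)
  c(
    TP = tp, FP = fp, TN = tn, FN = fn,
    TPR = tpr, FPR = fpr, FNR = fnr, TNR = tnr,
    MCR = (fp + fn) / length(y), ACC = (tp + tn) / length(y),
    FDR = fp / (tp + fp), PPV = ppv,
    FOMR = fomr, NPV = tn / (fn + tn),
    AUROC = auroc(pred, y), AUPR = aupr(pred, y),
    PLR = tpr / fpr, NLR = fnr / tnr,
    DOR = (tpr / fpr) / (fnr / tnr), RR = ppv / fomr,
    MCC = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  )
}

#' Per-repetition classifier performance statistics
#'
#' Pools each repetition's out-of-fold predictions, computes the confusion
#' matrix at the probability `threshold` plus rate, likelihood-ratio, rank
#' (AUROC, AUPR) and correlation (MCC) statistics, and summarizes each
#' statistic by its 2.5th, 50th and 97.5th percentiles across repetitions.
#' Repetitions whose pooled predictions cover only one class are skipped with
#' a warning.
#'
#' @param cycles A `cv_result`.
#' @param outcomes A `target_outcomes` data.frame.
#' @param threshold Probability cutoff for the confusion matrix (default 0.5,
#'   the natural operating point after class-weighted training).
#' @return A `performance_stats` list with `per_rep` (repetitions x
#'   statistics) and `summary` (statistics x percentiles).
#' @export
repetition_stats <- function(cycles, outcomes, threshold = 0.5) {
  m <- pooled_test_predictions(cycles)
  lv <- outcome_vector(outcomes, rownames(m))
  y <- lv == "success"
  rows <- list()
  for (j in seq_len(ncol(m))) {
    pred <- m[, j]
    ok <- !is.na(pred)
    if (length(unique(y[ok])) < 2) {
      warning(sprintf("repetition %s has a single outcome class; skipped", colnames(m)[j]))
      next
    }
    rows[[length(rows) + 1L]] <- confusion_stats(pred[ok], y[ok], threshold)
  }
  per_rep <- do.call(rbind, rows)
  qs <- apply(per_rep, 2, stats::quantile,
    probs = c(0.025, 0.5, 0.975), na.rm = TRUE
  )
  summary <- data.frame(
    statistic = colnames(per_rep),
    p2.5 = qs[1, ], median = qs[2, ], p97.5 = qs[3, ],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(per_rep = per_rep, summary = summary, threshold = threshold),
    class = "performance_stats"
  )
}

#' @export
print.performance_stats <- function(x, ...) {
  cat(sprintf(
    "performance_stats over %d repetitions (threshold %.2f)\n",
    nrow(x$per_rep), x$threshold
  ))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Kernel density estimates of predicted success probabilities
#'
#' Fits a Gaussian-kernel KDE with Silverman's bandwidth to the log-odds of
#' each group's predicted probabilities (probabilities are clipped to
#' `[1e-6, 1 - 1e-6]` so log-odds stay finite), then transforms the density
#' back to the probability scale by the change of variables
#' `pdf(x) = pdf(y) |dy/dx|` with `y = logit(x)`, i.e. dividing by
#' `x (1 - x)`. Groups with fewer than 3 values are skipped.
#'
#' @param predictions Named list of numeric probability vectors, e.g. one
#'   element each for success, failure and unlabeled targets.
#' @return A named list of `density_estimate` lists (`log_odds`,
#'   `density_log_odds`, `probability`, `density_probability`, `bandwidth`).
#' @export
probability_densities <- function(predictions) {
  out <- list()
  for (g in names(predictions)) {
    v <- predictions[[g]]
    v <- v[!is.na(v)]
    if (length(v) < 3) next
    lo <- logit(clip_prob(v))
    d <- stats::density(lo, bw = "nrd0", kernel = "gaussian")
    x <- stats::plogis(d$x)
    out[[g]] <- structure(
      list(
        group = g, log_odds = d$x, density_log_odds = d$y,
        probability = x, density_probability = d$y / (x * (1 - x)),
        bandwidth = d$bw
      ),
      class = "density_estimate"
    )
  }
  out
}

#' Scan probability cutoffs for maximum median predictive values
#'
#' Over the grid of observed prediction values, computes each repetition's
#' positive predictive value (targets at or above the cutoff) and negative
#' predictive value (targets below it), takes medians across repetitions, and
#' reports the cutoffs maximizing median PPV and median NPV. PPV ties resolve
#' toward the cutoff classifying more targets positive (the smaller cutoff);
#' NPV ties toward classifying more targets negative (the larger cutoff).
#' Also reported: counts of unlabeled targets whose median prediction lies
#' beyond each chosen cutoff, and the fraction of repetitions whose NPV at
#' the chosen cutoff exceeds `reference_failure_rate` (the historical failure
#' rate the NPV is meant to beat).
#'
#' @param pred Targets x repetitions prediction matrix
#'   ([pooled_test_predictions()]).
#' @param outcomes A `target_outcomes` data.frame.
#' @param unlabeled_pred Optional unlabeled-target prediction matrix
#'   ([pooled_unlabeled_predictions()]).
#' @param reference_failure_rate Failure-rate benchmark; defaults to the
#'   labeled failure fraction.
#' @return A `cutoff_scan` list: the scan table, `ppv_cutoff`, `npv_cutoff`,
#'   `n_unlabeled_above_ppv`, `n_unlabeled_below_npv`,
#'   `frac_reps_npv_above_reference`.
#' @export
cutoff_scan <- function(pred, outcomes, unlabeled_pred = NULL,
                        reference_failure_rate = NULL) {
  if (ncol(pred) < 2) stop("need predictions from at least 2 repetitions")
  lv <- outcome_vector(outcomes, rownames(pred))
  y <- lv == "success"
  if (is.null(reference_failure_rate)) {
    reference_failure_rate <- mean(!y)
  }
  grid <- sort(unique(as.numeric(pred[!is.na(pred)])))
  med_ppv <- med_npv <- numeric(length(grid))
  npv_mat <- matrix(NA_real_, length(grid), ncol(pred))
  for (i in seq_along(grid)) {
    c0 <- grid[i]
    ppv_r <- npv_r <- rep(NA_real_, ncol(pred))
    for (j in seq_len(ncol(pred))) {
      p <- pred[, j]
      ok <- !is.na(p)
      pos <- p[ok] >= c0
      yy <- y[ok]
      if (any(pos)) ppv_r[j] <- mean(yy[pos])
      if (any(!pos)) npv_r[j] <- mean(!yy[!pos])
    }
    med_ppv[i] <- stats::median(ppv_r, na.rm = TRUE)
    med_npv[i] <- stats::median(npv_r, na.rm = TRUE)
    npv_mat[i, ] <- npv_r
  }
  ppv_i <- which(med_ppv >= max(med_ppv, na.rm = TRUE) - 1e-12)[1] # smaller cutoff
  npv_ok <- which(!is.na(med_npv))
  npv_i <- npv_ok[which(med_npv[npv_ok] >= max(med_npv, na.rm = TRUE) - 1e-12)]
  npv_i <- npv_i[length(npv_i)] # larger cutoff
  n_above <- n_below <- 0L
  if (!is.null(unlabeled_pred) && nrow(unlabeled_pred)) {
    med_u <- apply(unlabeled_pred, 1, stats::median, na.rm = TRUE)
    n_above <- sum(med_u >= grid[ppv_i], na.rm = TRUE)
    n_below <- sum(med_u < grid[npv_i], na.rm = TRUE)
  }
  structure(
    list(
      scan = data.frame(cutoff = grid, median_ppv = med_ppv, median_npv = med_npv),
      ppv_cutoff = grid[ppv_i], npv_cutoff = grid[npv_i],
      max_median_ppv = med_ppv[ppv_i], max_median_npv = med_npv[npv_i],
      n_unlabeled_above_ppv = n_above, n_unlabeled_below_npv = n_below,
      frac_reps_npv_above_reference =
        mean(npv_mat[npv_i, ] > reference_failure_rate, na.rm = TRUE),
      reference_failure_rate = reference_failure_rate
    ),
    class = "cutoff_scan"
  )
}

#' Pairwise target-ranking consistency across repetitions
#'
#' For each ordered target pair (A, B), the fraction of repetitions in which
#' B's predicted success probability strictly exceeds A's. A pair is counted
#' as confidently separated when the fraction reaches a consistency threshold
#' (0.95 and 0.99 are reported) and the targets' median predictions differ by
#' at least `min_diff` or by at least a `min_fold`-fold ratio.
#'
#' @param pred Targets x repetitions prediction matrix; rows with any `NA`
#'   are dropped.
#' @param min_diff Minimum difference of median predictions (default 0.1).
#' @param min_fold Minimum fold change of median predictions (default 2).
#' @return A `consistency_result` list: `fraction` (matrix; entry (A, B) is
#'   the fraction of repetitions with B above A), `median` (per-target median
#'   predictions), and `pair_counts`, a data.frame of qualifying ordered-pair
#'   counts for both separation rules at both consistency thresholds.
#' @export
pairwise_consistency <- function(pred, min_diff = 0.1, min_fold = 2) {
  keep <- rowSums(is.na(pred)) == 0
  pred <- pred[keep, , drop = FALSE]
  n <- nrow(pred)
  r <- ncol(pred)
  frac <- matrix(0, n, n, dimnames = list(rownames(pred), rownames(pred)))
  for (j in seq_len(r)) {
    frac <- frac + outer(pred[, j], pred[, j], "<")
  }
  frac <- frac / r
  diag(frac) <- 0
  med <- apply(pred, 1, stats::median)
  dmat <- outer(med, med, function(a, b) b - a)
  fmat <- outer(med, med, function(a, b) b / pmax(a, .Machine$double.eps))
  sep_diff <- dmat >= min_diff
  sep_fold <- fmat >= min_fold
  pair_counts <- expand.grid(
    separation = c("diff", "fold"), consistency = c(0.95, 0.99),
    stringsAsFactors = FALSE
  )
  pair_counts$count <- mapply(function(sp, th) {
    sep <- if (sp == "diff") sep_diff else sep_fold
    sum(sep & frac >= th & row(frac) != col(frac))
  }, pair_counts$separation, pair_counts$consistency)
  structure(
    list(fraction = frac, median = med, pair_counts = pair_counts,
         min_diff = min_diff, min_fold = min_fold),
    class = "consistency_result"
  )
}

#' Mean predicted success probability over a two-feature plane
#'
#' Averages, over all cycles whose selected features include the given pair,
#' the refit model's predicted success probability on a rectangular grid
#' spanning the observed ranges of the two features; any additional selected
#' features are held at their observed median. Requires a cross-validation
#' run with `keep_models = TRUE`.
#'
#' @param cycles A `cv_result` whose cycles carry fitted models.
#' @param feature_pair Character vector of two aggregated feature labels.
#' @param feature_values Targets x features matrix of the aggregated feature
#'   values (used for grid bounds, medians, and example locations).
#' @param outcomes A `target_outcomes` data.frame (example locations).
#' @param n_grid Grid resolution per axis.
#' @return A `projection_grid` list: `x`, `y` (grid axes), `mean_probability`
#'   (matrix), `n_cycles`, and `examples` (feature values and labels of the
#'   labeled targets).
#' @export
feature_projection_grid <- function(cycles, feature_pair, feature_values,
                                    outcomes, n_grid = 25) {
  stopifnot(length(feature_pair) == 2)
  fx <- feature_pair[1]
  fy <- feature_pair[2]
  qualifying <- Filter(function(cy) {
    !isTRUE(cy$null_model) && !is.null(cy$model) &&
      all(feature_pair %in% cy$selection$selected_features)
  }, cycles)
  xs <- seq(min(feature_values[, fx]), max(feature_values[, fx]), length.out = n_grid)
  ys <- seq(min(feature_values[, fy]), max(feature_values[, fy]), length.out = n_grid)
  if (!length(qualifying)) {
    warning("no cycle selected both features; empty grid")
    return(structure(
      list(
        x = xs, y = ys,
        mean_probability = matrix(NA_real_, n_grid, n_grid), n_cycles = 0L
      ),
      class = "projection_grid"
    ))
  }
  grid <- expand.grid(x = xs, y = ys)
  acc <- numeric(nrow(grid))
  meds <- apply(feature_values, 2, stats::median)
  for (cy in qualifying) {
    feats <- cy$selection$selected_features
    nd <- matrix(rep(meds[feats], each = nrow(grid)),
      nrow = nrow(grid),
      dimnames = list(NULL, feats)
    )
    nd[, fx] <- grid$x
    nd[, fy] <- grid$y
    acc <- acc + predict_model(cy$selection$model_type, cy$model, nd)
  }
  lv <- outcome_vector(outcomes, rownames(feature_values))
  lab <- lv %in% c("success", "failure")
  structure(
    list(
      x = xs, y = ys,
      mean_probability = matrix(acc / length(qualifying), n_grid, n_grid),
      n_cycles = length(qualifying),
      examples = data.frame(
        x = feature_values[lab, fx], y = feature_values[lab, fy],
        label = lv[lab], stringsAsFactors = FALSE
      )
    ),
    class = "projection_grid"
  )
}
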