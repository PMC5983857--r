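#' Nested cross-validation configuration
#'
#' Defaults mirror the full-scale analysis: an outer loop of 5-fold
#' cross-validation repeated 200 times (1000 train-test cycles), an inner
#' model/feature-selection loop of 5-fold cross-validation repeated 20 times,
#' strict univariate selection (within-class-stratified permutation test with
#' `1e4` permutations, BY-adjusted p < 0.05 within each dataset), and the
#' 95%-of-maximum parsimony rule preferring logistic regression. Desk-scale
#' runs reduce `outer_reps`, `inner_reps`, `n_perm_univariate` and `rf_ntree`.
#'
#' @param outer_folds,outer_reps Outer cross-validation geometry.
#' @param inner_folds,inner_reps Inner cross-validation geometry.
#' @param univariate `"strict"` (BY-adjusted p < alpha) or `"weak"` (nominal
#'   p < alpha, no correction).
#' @param alpha Univariate selection level.
#' @param n_perm_univariate Permutations for the univariate screens.
#' @param selection_tolerance Fraction of the maximum inner AUROC and AUPR a
#'   candidate model must reach (default 0.95).
#' @param min_genes Datasets with fewer total genes are excluded during
#'   feature aggregation.
#' @param human_only Exclude features from non-human datasets during
#'   aggregation.
#' @param fallback_datasets Dataset names whose features are used only when no
#'   other dataset yields significant features (low-coverage fallback).
#' @param rf_ntree Random forest size; the forest's impurity importance drives
#'   incremental elimination.
#' @param r2_threshold Squared-cosine threshold for cross-dataset redundancy
#'   grouping during aggregation.
#' @param keep_models Store fitted final models inside each cycle (needed for
#'   [feature_projection_grid()]).
#' @param seed Optional integer seed for the whole routine.
#' @return A `cv_config` list.
#' @export
cv_config <- function(outer_folds = 5, outer_reps = 200, inner_folds = 5,
                      inner_reps = 20, univariate = c("strict", "weak"),
                      alpha = 0.05, n_perm_univariate = 1e4,
                      selection_tolerance = 0.95, min_genes = 2000,
                      human_only = TRUE, fallback_datasets = character(),
                      rf_ntree = 200, r2_threshold = 0.5,
                      keep_models = FALSE, seed = NULL) {
  univariate <- match.arg(univariate)
  stopifnot(
    outer_folds >= 2, inner_folds >= 2, outer_reps >= 1, inner_reps >= 1,
    selection_tolerance > 0, selection_tolerance <= 1
  )
  structure(as.list(environment()), class = "cv_config")
}

# outcome-stratified fold assignment; both classes present in every fold
stratified_folds <- function(labels, k, max_tries = 100) {
  for (try in seq_len(max_tries)) {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      fold[ix] <- sample_safe(rep(seq_len(k), length.out = length(ix)))
    }
    tab <- table(factor(fold, levels = seq_len(k)), labels)
    if (all(tab > 0)) {
      return(fold)
    }
  }
  stop("could not build folds with both outcome classes in every fold")
}

#' Univariate feature selection on training targets
#'
#' Screens a reduced dataset on the training targets only, shuffling outcome
#' labels within target classes. Strict mode keeps features with BY-adjusted
#' p below `alpha`; weak mode keeps features with nominal p below `alpha` and
#' no correction.
#'
#' @param rd A `reduced_dataset`.
#' @param train_outcomes `target_outcomes` restricted to training targets.
#' @param strata Stratum ids named by target (see [strata_from_class_map()]).
#' @param config A [cv_config()].
#' @return List with `selected` (feature labels) and `screen` (the full
#'   [screen_dataset()] table).
#' @export
univariate_select <- function(rd, train_outcomes, strata, config) {
  res <- screen_dataset(rd, train_outcomes,
    alpha = config$alpha,
    n_perm = config$n_perm_univariate, strata = strata
  )
  selected <- if (config$univariate == "strict") {
    res$feature_label[res$p_adj < config$alpha]
  } else {
    res$feature_label[res$p_raw < config$alpha]
  }
  list(selected = selected, screen = res)
}

#' Aggregate selected features from several datasets into one matrix
#'
#' Applies the aggregation exclusions (non-human datasets, datasets below
#' `min_genes`, and low-coverage fallback datasets unless nothing else
#' survived), builds a target x feature matrix of the selected representative
#' features with `dataset::feature` provenance labels, drops targets with any
#' missing value, min-max scales every column with parameters fitted on the
#' training targets only, and removes cross-dataset redundancy by cosine
#' grouping at `r2_threshold` on the training rows, keeping per group the
#' feature with the smallest training univariate p (ties: larger absolute
#' observed difference).
#'
#' @param selections Per-dataset results of [univariate_select()], named by
#'   dataset.
#' @param reduced_list Named list of `reduced_dataset`s.
#' @param train_ids Training target identifiers; scaling and grouping are
#'   fitted on these rows only.
#' @param config A [cv_config()].
#' @return An `aggregated_features` list (`values`, `feature_labels`,
#'   `provenance`, `dropped_targets`, `scaling`) or `NULL` when every feature
#'   is excluded (the null-model marker).
#' @export
aggregate_features <- function(selections, reduced_list, train_ids, config) {
  ds_names <- names(reduced_list)
  eligible <- vapply(ds_names, function(nm) {
    ds <- reduced_list[[nm]]$source
    (!config$human_only || ds$is_human) && ds$n_genes_total >= config$min_genes
  }, logical(1))
  has_sel <- vapply(ds_names, function(nm) length(selections[[nm]]$selected) > 0, logical(1))
  use <- eligible & has_sel
  primary <- use & !(ds_names %in% config$fallback_datasets)
  use <- if (any(primary)) primary else use # fallback only if nothing else
  if (!any(use)) {
    return(NULL)
  }

  cols <- list()
  meta <- list()
  for (nm in ds_names[use]) {
    rv <- reduced_values(reduced_list[[nm]])
    sc <- selections[[nm]]$screen
    for (f in selections[[nm]]$selected) {
      key <- paste0(nm, "::", f)
      v <- rv[, f]
      cols[[key]] <- v
      i <- match(f, sc$feature_label)
      meta[[key]] <- c(p = sc$p_raw[i], absdiff = abs(sc$observed_diff[i]))
    }
  }
  targets <- Reduce(union, lapply(cols, names))
  m <- vapply(cols, function(v) v[match(targets, names(v))], numeric(length(targets)))
  m <- matrix(m, nrow = length(targets), dimnames = list(targets, names(cols)))
  complete <- rowSums(is.na(m)) == 0
  dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  tr <- intersect(train_ids, rownames(m))
  if (length(tr) < 2) {
    return(NULL)
  }

  # min-max scaling fitted on training targets only
  lo <- apply(m[tr, , drop = FALSE], 2, min)
  hi <- apply(m[tr, , drop = FALSE], 2, max)
  keep <- hi > lo
  if (!any(keep)) {
    return(NULL)
  }
  m <- sweep(sweep(m[, keep, drop = FALSE], 2, lo[keep]), 2, (hi - lo)[keep], "/")
  meta <- meta[keep]

  # cross-dataset redundancy: cosine grouping on training rows
  if (ncol(m) > 1) {
    xt <- m[tr, , drop = FALSE]
    nrm <- sqrt(colSums(xt^2))
    r <- crossprod(xt) / outer(nrm, nrm)
    r[!is.finite(r)] <- 0
    diag(r) <- 1
    adj <- r^2 >= config$r2_threshold
    diag(adj) <- FALSE
    p <- ncol(m)
    ord <- order(-colSums(adj), seq_len(p))
    grouped <- logical(p)
    keep_cols <- integer(0)
    for (i in ord) {
      if (grouped[i]) next
      members <- c(i, which(adj[, i] & !grouped & seq_len(p) != i))
      grouped[members] <- TRUE
      ps <- vapply(members, function(j) meta[[j]][["p"]], numeric(1))
      ad <- vapply(members, function(j) meta[[j]][["absdiff"]], numeric(1))
      best <- members[order(ps, -ad)][1]
      keep_cols <- c(keep_cols, best)
    }
    keep_cols <- sort(keep_cols)
    m <- m[, keep_cols, drop = FALSE]
    meta <- meta[keep_cols]
  }

  structure(
    list(
      values = m, feature_labels = colnames(m),
      provenance = colnames(m), dropped_targets = dropped,
      scaling = list(min = lo[keep], max = hi[keep])
    ),
    class = "aggregated_features"
  )
}

# class weights inversely proportional to class size (sum n over 2 n_c)
class_weights <- function(y) {
  n <- length(y)
  tab <- table(y)
  w <- n / (length(tab) * tab[as.character(y)])
  as.numeric(w)
}

fit_model <- function(type, x, y, config) {
  # y: logical success indicator
  if (type == "logistic-regression") {
    df <- data.frame(x, check.names = FALSE)
    df$.y <- as.numeric(y)
    suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial(), weights = class_weights(y))
    )
  } else {
    yf <- factor(ifelse(y, "success", "failure"), levels = c("failure", "success"))
    cw <- table(yf)
    randomForest::randomForest(
      x = as.data.frame(x, check.names = FALSE), y = yf,
      ntree = config$rf_ntree,
      classwt = c(failure = 1 / cw[["failure"]], success = 1 / cw[["success"]])
    )
  }
}

predict_model <- function(type, fit, x) {
  if (type == "logistic-regression") {
    as.numeric(stats::predict(fit, newdata = data.frame(x, check.names = FALSE), type = "response"))
  } else {
    as.numeric(stats::predict(fit, newdata = as.data.frame(x, check.names = FALSE), type = "prob")[, "success"])
  }
}

rf_importance <- function(fit) {
  imp <- fit$importance[, "MeanDecreaseGini"]
  imp
}

# one inner-CV evaluation of both model types on the given feature columns;
# returns mean AUROC/AUPR per model and mean RF impurity importance
inner_cv_eval <- function(x, y, config) {
  reps_auroc <- matrix(NA_real_, config$inner_reps, 2,
    dimnames = list(NULL, c("logistic-regression", "random-forest"))
  )
  reps_aupr <- reps_auroc
  imp_sum <- numeric(ncol(x))
  n_imp <- 0L
  for (r in seq_len(config$inner_reps)) {
    fold <- stratified_folds(ifelse(y, "s", "f"), config$inner_folds)
    pred <- matrix(NA_real_, length(y), 2)
    for (k in seq_len(config$inner_folds)) {
      tr <- fold != k
      lr <- fit_model("logistic-regression", x[tr, , drop = FALSE], y[tr], config)
      rf <- fit_model("random-forest", x[tr, , drop = FALSE], y[tr], config)
      pred[!tr, 1] <- predict_model("logistic-regression", lr, x[!tr, , drop = FALSE])
      pred[!tr, 2] <- predict_model("random-forest", rf, x[!tr, , drop = FALSE])
      imp_sum <- imp_sum + rf_importance(rf)
      n_imp <- n_imp + 1L
    }
    reps_auroc[r, 1] <- auroc(pred[, 1], y)
    reps_auroc[r, 2] <- auroc(pred[, 2], y)
    reps_aupr[r, 1] <- aupr(pred[, 1], y)
    reps_aupr[r, 2] <- aupr(pred[, 2], y)
  }
  list(
    auroc = colMeans(reps_auroc, na.rm = TRUE),
    aupr = colMeans(reps_aupr, na.rm = TRUE),
    importance = imp_sum / n_imp
  )
}

#' Incremental feature elimination with inner cross-validation
#'
#' Starting from all features, repeatedly evaluates logistic regression and
#' random forest by inner cross-validation (class-weighted fits; AUROC and
#' AUPR averaged over `inner_reps` repetitions of `inner_folds`-fold CV),
#' then drops the feature with the lowest mean random-forest impurity
#' importance (ties: the later column), down to a single feature. Candidates
#' are all (model type, step) pairs with AUROC and AUPR within
#' `selection_tolerance` of their respective maxima; the qualifying logistic
#' regression with fewest features is selected, else the qualifying random
#' forest with fewest features.
#'
#' @param x Training feature matrix (targets x features, min-max scaled).
#' @param y Logical success indicator aligned with `x` rows.
#' @param config A [cv_config()].
#' @return A `model_selection` list: `model_type`, `selected_features`, and
#'   `path`, a data.frame of per-step inner-CV metrics.
#' @export
incremental_elimination <- function(x, y, config) {
  stopifnot(ncol(x) >= 1)
  active <- colnames(x)
  steps <- list()
  while (length(active) >= 1) {
    ev <- inner_cv_eval(x[, active, drop = FALSE], y, config)
    steps[[length(steps) + 1L]] <- list(
      features = active,
      auroc = ev$auroc, aupr = ev$aupr
    )
    if (length(active) == 1) break
    # ties broken by dropping the later column
    drop_i <- which(ev$importance <= min(ev$importance))
    active <- active[-max(drop_i)]
  }
  max_auroc <- max(vapply(steps, function(s) max(s$auroc), numeric(1)))
  max_aupr <- max(vapply(steps, function(s) max(s$aupr), numeric(1)))
  path <- do.call(rbind, lapply(steps, function(s) {
    data.frame(
      k = length(s$features),
      model_type = c("logistic-regression", "random-forest"),
      auroc = as.numeric(s$auroc), aupr = as.numeric(s$aupr),
      features = paste(s$features, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  qual <- path$auroc >= config$selection_tolerance * max_auroc &
    path$aupr >= config$selection_tolerance * max_aupr
  pick_from <- function(rows) rows[order(path$k[rows])][1]
  lr_rows <- which(qual & path$model_type == "logistic-regression")
  rf_rows <- which(qual & path$model_type == "random-forest")
  chosen <- if (length(lr_rows)) pick_from(lr_rows) else pick_from(rf_rows)
  structure(
    list(
      model_type = path$model_type[chosen],
      selected_features = strsplit(path$features[chosen], ";", fixed = TRUE)[[1]],
      path = path
    ),
    class = "model_selection"
  )
}

#' Refit the selected model and predict test and unlabeled targets
#'
#' @param selection A [incremental_elimination()] result.
#' @param agg An [aggregate_features()] result.
#' @param y_train Named logical success indicator for training targets.
#' @param test_ids,unlabeled_ids Target identifiers to predict; targets absent
#'   from the aggregated matrix (missing a selected feature) are omitted.
#' @param config A [cv_config()].
#' @return A `train_test_cycle` list: `selection`, `test_pred`,
#'   `unlabeled_pred` (named probability vectors), and optionally `model`.
#' @export
fit_and_predict <- function(selection, agg, y_train, test_ids, unlabeled_ids,
                            config) {
  feats <- selection$selected_features
  m <- agg$values[, feats, drop = FALSE]
  tr <- intersect(names(y_train), rownames(m))
  fit <- fit_model(selection$model_type, m[tr, , drop = FALSE], y_train[tr], config)
  pred_for <- function(ids) {
    ids <- intersect(ids, rownames(m))
    if (!length(ids)) {
      return(stats::setNames(numeric(0), character(0)))
    }
    stats::setNames(
      predict_model(selection$model_type, fit, m[ids, , drop = FALSE]), ids
    )
  }
  structure(
    list(
      selection = selection,
      test_pred = pred_for(test_ids),
      unlabeled_pred = pred_for(unlabeled_ids),
      model = if (config$keep_models) fit else NULL
    ),
    class = "train_test_cycle"
  )
}

#' Nested cross-validation over reduced datasets
#'
#' The outer loop repeats outcome-stratified `outer_folds`-fold partitioning
#' of the labeled targets `outer_reps` times, yielding
#' `outer_reps * outer_folds` train-test cycles. Within each cycle, entirely
#' on the training targets: univariate within-class-stratified selection per
#' dataset ([univariate_select()]), aggregation with exclusions and train-
#' fitted min-max scaling ([aggregate_features()]), incremental feature
#' elimination with inner CV ([incremental_elimination()]), and finally a
#' refit on the full training set with prediction of the held-out test
#' targets and of all unlabeled targets ([fit_and_predict()]). Cycles where
#' no dataset yields a significant feature are recorded as null models.
#'
#' @param reduced_list Named list of `reduced_dataset`s (coverage-filtered and
#'   reduced).
#' @param outcomes A `target_outcomes` data.frame over all targets.
#' @param class_map Data frame `target_id`/`class` for stratified univariate
#'   selection.
#' @param config A [cv_config()].
#' @return A `cv_result` list of cycles; each cycle has `rep`, `fold`,
#'   `test_ids`, `null_model`, and for non-null cycles the fields of
#'   [fit_and_predict()].
#' @export
outer_cv <- function(reduced_list, outcomes, class_map, config) {
  stopifnot(inherits(config, "cv_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(names(reduced_list))) {
    names(reduced_list) <- vapply(reduced_list, function(r) r$source$name, character(1))
  }
  lab <- labeled_ids(outcomes)
  lv <- outcome_vector(outcomes, lab)
  if (min(table(lv)) < config$outer_folds) {
    stop("need at least `outer_folds` targets of each outcome")
  }
  all_ids <- Reduce(union, lapply(reduced_list, function(r) r$source$genes))
  unlabeled <- setdiff(all_ids, lab)
  strata_all <- strata_from_class_map(class_map, lab)

  cycles <- list()
  for (rep_i in seq_len(config$outer_reps)) {
    fold <- stratified_folds(lv, config$outer_folds)
    for (k in seq_len(config$outer_folds)) {
      test_ids <- lab[fold == k]
      train_ids <- lab[fold != k]
      cyc <- run_cycle(
        reduced_list, outcomes, train_ids, test_ids,
        unlabeled, strata_all, config
      )
      cyc$rep <- rep_i
      cyc$fold <- k
      cycles[[length(cycles) + 1L]] <- cyc
    }
  }
  structure(cycles, class = "cv_result")
}

run_cycle <- function(reduced_list, outcomes, train_ids, test_ids,
                      unlabeled, strata_all, config) {
  train_out <- outcomes[outcomes$target_id %in% train_ids, , drop = FALSE]
  selections <- lapply(reduced_list, function(rd) {
    present <- intersect(train_ids, rd$source$genes)
    univariate_select(
      rd, train_out[train_out$target_id %in% present, , drop = FALSE],
      strata_all, config
    )
  })
  agg <- aggregate_features(selections, reduced_list, train_ids, config)
  if (is.null(agg)) {
    return(structure(
      list(null_model = TRUE, test_ids = test_ids, test_pred = NULL),
      class = "train_test_cycle"
    ))
  }
  lv <- outcome_vector(outcomes, rownames(agg$values))
  tr <- rownames(agg$values)[rownames(agg$values) %in% train_ids]
  y_train <- stats::setNames(lv[tr] == "success", tr)
  selection <- incremental_elimination(
    agg$values[tr, , drop = FALSE], unname(y_train), config
  )
  cyc <- fit_and_predict(selection, agg, y_train, test_ids, unlabeled, config)
  cyc$null_model <- FALSE
  cyc$test_ids <- test_ids
  cyc$feature_ranges <- list(
    min = apply(agg$values, 2, min),
    max = apply(agg$values, 2, max)
  )
  cyc
}

#' @export
print.cv_result <- function(x, ...) {
  nulls <- sum(vapply(x, function(c) isTRUE(c$null_model), logical(1)))
  cat(sprintf(
    "cv_result: %d train-test cycles (%d null models)\n",
    length(x), nulls
  ))
  invisible(x)
}

#' Per-cycle summary table of a cross-validation run
#'
#' One row per train-test cycle: repetition, fold, selected model type,
#' number and labels of selected features, and test AUROC/AUPR of the cycle's
#' own test fold.
#'
#' @param cycles A `cv_result`.
#' @param outcomes A `target_outcomes` data.frame.
#' @return A data.frame.
#' @export
cycle_summary <- function(cycles, outcomes) {
  do.call(rbind, lapply(cycles, function(cy) {
    if (isTRUE(cy$null_model)) {
      return(data.frame(
        rep = cy$rep, fold = cy$fold, model_type = "null", n_features = 0L,
        features = "", test_auroc = NA_real_, test_aupr = NA_real_,
        stringsAsFactors = FALSE
      ))
    }
    lv <- outcome_vector(outcomes, names(cy$test_pred))
    yy <- lv == "success"
    data.frame(
      rep = cy$rep, fold = cy$fold,
      model_type = cy$selection$model_type,
      n_features = length(cy$selection$selected_features),
      features = paste(cy$selection$selected_features, collapse = ";"),
      test_auroc = auroc(cy$test_pred, yy),
      test_aupr = aupr(cy$test_pred, yy),
      stringsAsFactors = FALSE
    )
  }))
}
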