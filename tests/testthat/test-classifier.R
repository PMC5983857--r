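cheap_config <- function(...) {
  args <- utils::modifyList(
    list(
      outer_folds = 5, outer_reps = 2, inner_folds = 3, inner_reps = 2,
      n_perm_univariate = 300, min_genes = 100, rf_ntree = 40, seed = 17
    ),
    list(...)
  )
  do.call(cv_config, args)
}

test_that("outer CV produces outer_reps x outer_folds cycles with partitioning test sets", {
  s <- small_study()
  cc <- cheap_config()
  cv <- outer_cv(s$reduced, s$outcomes, s$study$class_map, cc)
  expect_length(cv, 10)
  for (r in 1:2) {
    cyc <- Filter(function(cy) cy$rep == r, cv)
    tests <- unlist(lapply(cyc, `[[`, "test_ids"))
    expect_setequal(tests, s$labeled) # each rep's test folds partition the labeled set
    expect_equal(length(tests), length(s$labeled))
  }
})

test_that("a two-fold single-repetition split yields two cycles partitioning the targets", {
  fx <- confound_fixture()
  rd <- structure(
    list(
      source = gene_feature_dataset(fx$x, rownames(fx$x), colnames(fx$x),
        "quantitative-filled", "fix",
        n_genes_total = 5000
      ),
      groups = lapply(colnames(fx$x), function(f) {
        list(
          representative_label = f, member_labels = f,
          values = fx$x[, f], is_dataset_mean = FALSE
        )
      })
    ),
    class = "reduced_dataset"
  )
  cc <- cv_config(
    outer_folds = 2, outer_reps = 1, inner_folds = 2, inner_reps = 1,
    n_perm_univariate = 200, rf_ntree = 30, seed = 3
  )
  cv <- outer_cv(list(fix = rd), fx$outcomes, fx$class_map, cc)
  expect_length(cv, 2)
  expect_setequal(
    unlist(lapply(cv, `[[`, "test_ids")),
    fx$outcomes$target_id
  )
  # no test-target leakage into training predictions
  expect_length(intersect(names(cv[[1]]$test_pred), names(cv[[2]]$test_pred)), 0)
})

test_that("univariate selection is stricter with BY correction than without", {
  s <- small_study()
  strata <- strata_from_class_map(s$study$class_map, s$labeled)
  train <- s$outcomes[s$outcomes$target_id %in% s$labeled, ]
  strict <- univariate_select(s$reduced$expr, train, strata, cheap_config())
  weak <- univariate_select(s$reduced$expr, train, strata, cheap_config(univariate = "weak"))
  expect_true(all(strict$selected %in% weak$selected))
  expect_gte(length(weak$selected), length(strict$selected))
})

test_that("weak selection on null features approximates the nominal rate", {
  set.seed(44)
  ids <- sprintf("T%03d", 1:80)
  labels <- outcomes_from(stats::setNames(rep(c("success", "failure"), c(60, 20)), ids))
  x <- matrix(rnorm(80 * 100), 80, dimnames = list(ids, sprintf("n%03d", 1:100)))
  res <- screen_dataset(x, labels, n_perm = 400, seed = 12)
  n_weak <- sum(res$p_raw < 0.05)
  expect_gt(n_weak, 0)
  expect_lt(n_weak, 15) # ~5 expected of 100 at nominal alpha
  expect_lte(sum(res$significant), 1) # BY keeps the family nearly empty
})

test_that("aggregation applies the exclusion rules", {
  fx <- confound_fixture()
  mk_rd <- function(name, cols, n_total = 5000, human = TRUE) {
    ds <- gene_feature_dataset(fx$x[, cols, drop = FALSE], rownames(fx$x),
      cols, "quantitative-filled", name,
      is_human = human, n_genes_total = n_total
    )
    reduce_features(ds, r2_threshold = 0.99)
  }
  reduced <- list(
    big = mk_rd("big", c("genuine", "null1")),
    mouse = mk_rd("mouse", "null2", human = FALSE),
    tiny = mk_rd("tiny", "null3", n_total = 100)
  )
  sel <- list(
    big = list(selected = c("genuine", "null1"), screen = data.frame(
      feature_label = c("genuine", "null1"), p_raw = c(0.001, 0.2),
      observed_diff = c(2, 0.1)
    )),
    mouse = list(selected = "null2", screen = data.frame(
      feature_label = "null2", p_raw = 0.01, observed_diff = 1
    )),
    tiny = list(selected = "null3", screen = data.frame(
      feature_label = "null3", p_raw = 0.01, observed_diff = 1
    ))
  )
  cc <- cheap_config(min_genes = 2000)
  agg <- aggregate_features(sel, reduced, fx$outcomes$target_id, cc)
  # non-human and small datasets contribute nothing
  expect_true(all(startsWith(agg$feature_labels, "big::")))
  expect_true("big::genuine" %in% agg$feature_labels)
  # training columns scaled into [0, 1]
  expect_true(all(agg$values >= 0 & agg$values <= 1))
})

test_that("fallback datasets are used only when nothing else is significant", {
  fx <- confound_fixture()
  mk_rd <- function(name, cols) {
    ds <- gene_feature_dataset(fx$x[, cols, drop = FALSE], rownames(fx$x),
      cols, "quantitative-filled", name,
      n_genes_total = 5000
    )
    reduce_features(ds, r2_threshold = 0.99)
  }
  reduced <- list(main = mk_rd("main", "genuine"), low = mk_rd("low", "null1"))
  sel_both <- list(
    main = list(selected = "genuine", screen = data.frame(
      feature_label = "genuine", p_raw = 0.001, observed_diff = 2
    )),
    low = list(selected = "null1", screen = data.frame(
      feature_label = "null1", p_raw = 0.02, observed_diff = 1
    ))
  )
  cc <- cheap_config(fallback_datasets = "low", min_genes = 100)
  agg <- aggregate_features(sel_both, reduced, fx$outcomes$target_id, cc)
  expect_identical(agg$feature_labels, "main::genuine")
  # with nothing from the primary dataset, the fallback steps in
  sel_fb <- sel_both
  sel_fb$main$selected <- character()
  agg_fb <- aggregate_features(sel_fb, reduced, fx$outcomes$target_id, cc)
  expect_identical(agg_fb$feature_labels, "low::null1")
  # and with nothing anywhere, the null-model marker
  sel_none <- sel_fb
  sel_none$low$selected <- character()
  expect_null(aggregate_features(sel_none, reduced, fx$outcomes$target_id, cc))
})

test_that("cross-dataset grouping keeps the best-correlated representative", {
  # two datasets carrying the same planted signal: one representative survives
  fx <- confound_fixture()
  dup <- fx$x[, "genuine"] + rnorm(nrow(fx$x), sd = 0.05)
  mk_rd <- function(name, x) {
    ds <- gene_feature_dataset(as.matrix(x), rownames(fx$x), colnames(as.matrix(x)),
      "quantitative-filled", name,
      n_genes_total = 5000
    )
    reduce_features(ds, r2_threshold = 0.99)
  }
  reduced <- list(
    d1 = mk_rd("d1", matrix(fx$x[, "genuine"], dimnames = list(NULL, "genuine"), ncol = 1)),
    d2 = mk_rd("d2", matrix(dup, dimnames = list(NULL, "genuine2"), ncol = 1))
  )
  sel <- list(
    d1 = list(selected = "genuine", screen = data.frame(
      feature_label = "genuine", p_raw = 0.001, observed_diff = 2
    )),
    d2 = list(selected = "genuine2", screen = data.frame(
      feature_label = "genuine2", p_raw = 0.01, observed_diff = 1.9
    ))
  )
  agg <- aggregate_features(sel, reduced, fx$outcomes$target_id, cheap_config(min_genes = 100))
  expect_identical(agg$feature_labels, "d1::genuine") # smaller training p wins
})

test_that("elimination keeps an informative feature over null ones", {
  set.seed(55)
  n <- 90
  y <- rep(c(TRUE, FALSE), c(60, 30))
  x <- cbind(
    signal = rnorm(n) + 1.6 * y,
    matrix(rnorm(n * 4), n, dimnames = list(NULL, sprintf("null%d", 1:4)))
  )
  x <- apply(x, 2, function(v) (v - min(v)) / diff(range(v)))
  cc <- cheap_config()
  hits <- 0
  for (i in 1:5) {
    set.seed(i)
    sel <- incremental_elimination(x, y, cc)
    hits <- hits + ("signal" %in% sel$selected_features)
  }
  expect_gte(hits, 4) # informative feature survives elimination in >= 80% of runs
})

test_that("a single feature is selected with the logistic-regression preference", {
  set.seed(56)
  y <- rep(c(TRUE, FALSE), c(30, 15))
  x <- matrix((rnorm(45) + 1.5 * y), dimnames = list(NULL, "only"), ncol = 1)
  x <- (x - min(x)) / diff(range(x))
  sel <- incremental_elimination(x, y, cheap_config())
  expect_identical(sel$selected_features, "only")
  # both model types qualify on a strong single feature: LR preferred
  lr_rows <- sel$path[sel$path$model_type == "logistic-regression", ]
  tol <- 0.95
  if (any(lr_rows$auroc >= tol * max(sel$path$auroc) &
    lr_rows$aupr >= tol * max(sel$path$aupr))) {
    expect_identical(sel$model_type, "logistic-regression")
  }
})

test_that("training steps are blind to test-target feature values", {
  s <- small_study()
  cc <- cheap_config()
  lab <- s$labeled
  lv <- outcome_vector(s$outcomes, lab)
  set.seed(cc$seed)
  fold <- targetscreen:::stratified_folds(lv, cc$outer_folds)
  test_ids <- lab[fold == 1]
  train_ids <- lab[fold != 1]
  strata <- strata_from_class_map(s$study$class_map, lab)
  scramble <- function(red) {
    lapply(red, function(rd) {
      rows <- rd$source$genes %in% test_ids
      rd$groups <- lapply(rd$groups, function(g) {
        g$values[rows] <- sample(g$values)[seq_len(sum(rows))]
        g
      })
      rd
    })
  }
  run_steps <- function(red) {
    set.seed(1234)
    train_out <- s$outcomes[s$outcomes$target_id %in% train_ids, ]
    selections <- lapply(red, function(rd) univariate_select(rd, train_out, strata, cc))
    agg <- aggregate_features(selections, red, train_ids, cc)
    tr <- intersect(train_ids, rownames(agg$values))
    sel <- incremental_elimination(
      agg$values[tr, , drop = FALSE],
      unname(outcome_vector(s$outcomes, tr) == "success"), cc
    )
    list(
      selected = lapply(selections, `[[`, "selected"),
      features = agg$feature_labels, model = sel$model_type,
      chosen = sel$selected_features
    )
  }
  ref <- run_steps(s$reduced)
  noisy <- run_steps(scramble(s$reduced))
  expect_identical(ref, noisy)
})

test_that("cycle summaries report models, features and test performance", {
  s <- small_study()
  cv <- small_cv()$cycles
  cs <- cycle_summary(cv, s$outcomes)
  expect_equal(nrow(cs), length(cv))
  expect_true(all(cs$model_type %in% c("logistic-regression", "random-forest", "null")))
  ok <- cs$model_type != "null"
  expect_true(all(cs$test_auroc[ok] >= 0 & cs$test_auroc[ok] <= 1))
  # the planted row-summary features dominate selection
  feats <- unlist(strsplit(cs$features[ok], ";"))
  short <- sub("^.*::", "", feats)
  expect_gt(mean(short %in% c("mean", "stdv")), 0.5)
})
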