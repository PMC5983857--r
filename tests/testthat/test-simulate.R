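test_that("same seed gives byte-identical studies, different seeds differ", {
  cfg <- simulation_config(
    seed = 11, n_success = 20, n_fail = 10, n_unlabeled = 30,
    datasets = list(dataset_spec("d", "quantitative-filled", n_genes = 40, n_features = 5)),
    planted_effects = list(), class_structure = list()
  )
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
  cfg2 <- simulation_config(
    seed = 12, n_success = 20, n_fail = 10, n_unlabeled = 30,
    datasets = cfg$datasets, planted_effects = list(), class_structure = list()
  )
  expect_false(identical(simulate_study(cfg2)$datasets$d$values, a$datasets$d$values))
})

test_that("marginal success fraction is exact and class counts are as configured", {
  st <- simulate_study(simulation_config(seed = 4))
  s <- outcome_summary(st$labels)
  expect_identical(s$n_success, 259L)
  expect_identical(s$n_fail, 72L)
  expect_equal(s$success_rate, 259 / 331)
  # success-enriched GPCR-like class: 62/70; failure-pure integrin-like: 0/3
  lv <- st$labels$label[match(st$class_map$target_id, st$labels$target_id)]
  gp <- lv[st$class_map$class == "GPCR-like"]
  expect_length(gp, 70)
  expect_identical(sum(gp == "success"), 62L)
  ig <- lv[st$class_map$class == "integrin-like"]
  expect_length(ig, 3)
  expect_identical(sum(ig == "success"), 0L)
})

test_that("every labeled target appears in at least one dataset", {
  st <- simulate_study(simulation_config(seed = 8))
  lab <- st$labels$target_id[st$labels$label != "unlabeled"]
  in_any <- Reduce(union, lapply(st$datasets, `[[`, "genes"))
  expect_true(all(lab %in% in_any))
})

test_that("with no planted effect, success-failure differences are null-like", {
  # |z| of the group-mean difference stays small across features and seeds
  for (seed in c(1, 2)) {
    cfg <- simulation_config(
      seed = seed, n_success = 40, n_fail = 40, n_unlabeled = 20,
      datasets = list(dataset_spec("d", "quantitative-filled",
        n_genes = 100,
        n_features = 8, coverage = 1
      )),
      planted_effects = list(), class_structure = list()
    )
    st <- simulate_study(cfg)
    ds <- st$datasets$d
    lv <- st$labels$label[match(ds$genes, st$labels$target_id)]
    z <- apply(ds$values, 2, function(v) {
      d <- mean(v[lv == "success"]) - mean(v[lv == "failure"])
      d / sqrt(stats::var(v[lv == "success"]) / 40 + stats::var(v[lv == "failure"]) / 40)
    })
    expect_true(all(abs(z) < 4))
  }
})

test_that("a planted delta = 2 row-mean effect is detectable by an off-pipeline t-test", {
  cfg <- simulation_config(
    seed = 0, n_success = 60, n_fail = 20, n_unlabeled = 40,
    datasets = list(dataset_spec("d", "quantitative-filled",
      n_genes = 120,
      n_features = 10, coverage = 1
    )),
    planted_effects = list(planted_effect("d", "row-mean", delta = 2, sign = 1)),
    class_structure = list()
  )
  st <- simulate_study(cfg)
  ds <- st$datasets$d
  lv <- st$labels$label[match(ds$genes, st$labels$target_id)]
  rm_ <- rowMeans(ds$values)
  p <- stats::t.test(rm_[lv == "success"], rm_[lv == "failure"])$p.value
  expect_lt(p, 0.001)
  expect_gt(mean(rm_[lv == "success"]), mean(rm_[lv == "failure"]))
})

test_that("planted effect signs follow the configuration", {
  st <- small_study()$study
  ds <- st$datasets$expr
  lv <- st$labels$label[match(ds$genes, st$labels$target_id)]
  rm_ <- rowMeans(ds$values)
  rs <- apply(ds$values, 1, stats::sd)
  expect_lt(mean(rm_[lv == "success"]), mean(rm_[lv == "failure"])) # low mean
  expect_gt(mean(rs[lv == "success"]), mean(rs[lv == "failure"])) # high stdv
})

test_that("correlated block r-squared converges to block_r2 at large n_genes", {
  sp <- dataset_spec("d", "quantitative-filled",
    n_genes = 2000, n_features = 8,
    n_correlated_blocks = 1, block_size = 4, block_r2 = 0.6
  )
  set.seed(5)
  v <- targetscreen:::simulate_values(sp, 2000)
  r2 <- stats::cor(v[, 1:4])^2
  off <- r2[upper.tri(r2)]
  expect_true(all(abs(off - 0.6) < 0.1))
  # features outside the block stay uncorrelated
  expect_lt(max(abs(stats::cor(v[, 5:8])[upper.tri(diag(4))])), 0.1)
})

test_that("invalid configurations are rejected", {
  ds <- list(dataset_spec("d", "quantitative-filled", n_genes = 20, n_features = 3))
  expect_error(
    simulation_config(n_success = 3, n_fail = 2, datasets = ds),
    "at least 6"
  )
  expect_error(
    simulation_config(
      n_success = 10, n_fail = 10, datasets = ds,
      planted_effects = list(planted_effect("nope", "row-mean", 1))
    ),
    "unknown dataset"
  )
  expect_error(class_spec("c", 5, 1.2), "success_rate")
  expect_error(
    simulation_config(
      n_success = 10, n_fail = 10,
      datasets = list(dataset_spec("c", "categorical-sparse", n_genes = 20, n_features = 3)),
      planted_effects = list(planted_effect("c", "row-mean", 1))
    ),
    "not supported"
  )
})

test_that("generated asset records round-trip to the planted labels", {
  st <- small_study()$study
  scored <- score_targets(filter_assets(st$asset_table), universe = st$labels$target_id)
  expect_identical(scored$label, st$labels$label)
})

test_that("write_study emits readable delimited files", {
  st <- small_study()$study
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_assets(file.path(dir, "assets.tsv"))
  expect_equal(nrow(back), nrow(st$asset_table))
  ds <- read_feature_matrix(file.path(dir, "dataset_expr.tsv"), "quantitative-filled")
  expect_equal(unname(ds$values), unname(st$datasets$expr$values), tolerance = 1e-8)
  expect_identical(ds$genes, st$datasets$expr$genes)
})
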