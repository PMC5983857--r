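test_that("AUROC matches pair counting and an independent implementation", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, TRUE, FALSE, TRUE)), 2 / 3)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(1:4, c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_true(is.na(auroc(1:3, c(TRUE, TRUE, TRUE))))
  set.seed(61)
  for (i in 1:3) {
    y <- rbinom(60, 1, 0.4)
    s <- rnorm(60) + 0.8 * y
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(auroc(s, y == 1), ref, tolerance = 1e-12)
  }
})

test_that("AUPR matches a brute-force average-precision oracle", {
  brute_ap <- function(scores, y) {
    o <- order(scores, decreasing = TRUE)
    y <- y[o]
    scores <- scores[o]
    ap <- 0
    prev_rec <- 0
    for (t in unique(scores)) {
      sel <- scores >= t
      prec <- mean(y[sel])
      rec <- sum(y[sel]) / sum(y)
      ap <- ap + (rec - prev_rec) * prec
      prev_rec <- rec
    }
    ap
  }
  set.seed(62)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.5) == 1
    s <- round(rnorm(40), 1) # ties on purpose
    expect_equal(aupr(s, y), brute_ap(s, y), tolerance = 1e-12)
  }
  expect_equal(aupr(c(0.9, 0.8, 0.2), c(TRUE, TRUE, FALSE)), 1)
})

test_that("random scores give AUROC near 0.5 and AUPR near prevalence", {
  set.seed(63)
  y <- rep(c(TRUE, FALSE), c(259, 72))
  aucs <- replicate(200, auroc(runif(331), y))
  expect_lt(abs(mean(aucs) - 0.5), 3 * stats::sd(aucs) / sqrt(200) + 0.01)
  auprs <- replicate(200, aupr(runif(331), y))
  expect_lt(abs(mean(auprs) - 259 / 331), 0.03)
})

test_that("confusion statistics match closed-form arithmetic", {
  # predictions engineered to give TP=3, FP=1, TN=2, FN=0 at threshold 0.5
  pred <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.1)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  st <- targetscreen:::confusion_stats(pred, y, 0.5)
  expect_equal(unname(st["TP"]), 3)
  expect_equal(unname(st["FP"]), 1)
  expect_equal(unname(st["TN"]), 2)
  expect_equal(unname(st["FN"]), 0)
  expect_equal(unname(st["PPV"]), 0.75)
  expect_equal(unname(st["MCC"]), sqrt(0.5), tolerance = 1e-6)
  expect_equal(unname(st["MCC"]), 0.7071, tolerance = 1e-4)
  expect_equal(unname(st["ACC"]), 5 / 6)
  expect_equal(unname(st["RR"]), unname(st["PPV"] / st["FOMR"]))
})

test_that("repetition statistics pool folds and report monotone percentiles", {
  s <- small_study()
  ps <- repetition_stats(small_cv()$cycles, s$outcomes)
  expect_equal(nrow(ps$per_rep), 4)
  expect_true(all(ps$summary$p2.5 <= ps$summary$median + 1e-12))
  expect_true(all(ps$summary$median <= ps$summary$p97.5 + 1e-12))
  med_auroc <- ps$summary$median[ps$summary$statistic == "AUROC"]
  expect_gt(med_auroc, 0.5) # planted signal beats chance
  tp <- ps$per_rep[, c("TP", "FP", "TN", "FN")]
  expect_true(all(rowSums(tp) == length(s$labeled)))
})

test_that("probability densities integrate to one on both scales", {
  set.seed(64)
  dens <- probability_densities(list(
    success = stats::plogis(rnorm(300, 1)),
    failure = stats::plogis(rnorm(300, -1)),
    tiny = c(0.5, 0.6) # skipped: fewer than 3 values
  ))
  expect_setequal(names(dens), c("success", "failure"))
  for (d in dens) {
    int_lo <- sum(diff(d$log_odds) * (utils::head(d$density_log_odds, -1) +
      utils::tail(d$density_log_odds, -1)) / 2)
    expect_equal(int_lo, 1, tolerance = 0.02)
    ord <- order(d$probability)
    int_p <- sum(diff(d$probability[ord]) * (utils::head(d$density_probability[ord], -1) +
      utils::tail(d$density_probability[ord], -1)) / 2)
    expect_equal(int_p, 1, tolerance = 0.02)
  }
})

test_that("a symmetric log-odds sample gives a density symmetric about one half", {
  d <- probability_densities(list(g = stats::plogis(c(-2, -1, -0.5, 0.5, 1, 2))))$g
  at <- function(p) stats::approx(d$probability, d$density_probability, xout = p)$y
  for (p in c(0.2, 0.35, 0.42)) {
    expect_equal(at(p), at(1 - p), tolerance = 1e-6)
  }
})

test_that("cutoff scan finds perfect PPV at the tie-breaking cutoff", {
  # two repetitions of perfectly separated predictions
  pred <- cbind(rep1 = c(0.9, 0.8, 0.2, 0.1), rep2 = c(0.85, 0.95, 0.15, 0.05))
  rownames(pred) <- sprintf("T%d", 1:4)
  out <- outcomes_from(stats::setNames(
    c("success", "success", "failure", "failure"), rownames(pred)
  ))
  cs <- cutoff_scan(pred, out)
  expect_equal(cs$max_median_ppv, 1)
  # ties resolve toward classifying more targets positive: smallest such cutoff
  expect_equal(cs$ppv_cutoff, min(cs$scan$cutoff[cs$scan$median_ppv == 1], na.rm = TRUE))
  expect_equal(cs$max_median_npv, 1)
  expect_equal(cs$n_unlabeled_above_ppv, 0L)
})

test_that("random predictions give median PPV near the base success rate", {
  set.seed(65)
  n <- 200
  y <- rep(c("success", "failure"), c(150, 50))
  ids <- sprintf("T%03d", 1:n)
  out <- outcomes_from(stats::setNames(y, ids))
  pred <- matrix(runif(n * 21), n, 21, dimnames = list(ids, NULL))
  cs <- cutoff_scan(pred, out)
  mid <- cs$scan[cs$scan$cutoff > 0.4 & cs$scan$cutoff < 0.6, ]
  expect_lt(abs(mean(mid$median_ppv) - 0.75), 0.05)
})

test_that("pairwise consistency fractions match hand enumeration", {
  pred <- rbind(
    A = c(0.1, 0.2, 0.3, 0.4),
    B = c(0.2, 0.3, 0.2, 0.5),
    C = c(0.9, 0.8, 0.85, 0.7)
  )
  pc <- pairwise_consistency(pred)
  expect_equal(pc$fraction["A", "B"], 3 / 4)
  expect_equal(pc$fraction["B", "A"], 1 / 4)
  expect_equal(pc$fraction["A", "C"], 1)
  expect_equal(pc$fraction["C", "A"], 0)
  expect_equal(unname(diag(pc$fraction)), rep(0, 3))
  # ties are strict: identical vectors give zero both ways
  pc2 <- pairwise_consistency(rbind(X = c(0.5, 0.6), Y = c(0.5, 0.6)))
  expect_equal(pc2$fraction["X", "Y"], 0)
  expect_equal(pc2$fraction["Y", "X"], 0)
  # transposition symmetry of the prediction matrix
  expect_equal(pc$fraction["A", "B"] + pc$fraction["B", "A"], 1)
  # qualifying-pair counts: C is above A and B by both rules with full consistency
  counts <- pc$pair_counts
  expect_equal(counts$count[counts$separation == "diff" & counts$consistency == 0.99], 2)
  expect_equal(counts$count[counts$separation == "fold" & counts$consistency == 0.99], 2)
})

test_that("the projection grid spans observed ranges and tracks the planted direction", {
  s <- small_study()
  cvr <- small_cv()
  cycles <- cvr$cycles
  feats <- c("expr::mean", "expr::stdv")
  qual <- Filter(
    function(cy) !isTRUE(cy$null_model) && all(feats %in% cy$selection$selected_features),
    cycles
  )
  expect_gt(length(qual), 0) # deterministic under the cached seed
  rv <- reduced_values(s$reduced$expr)[, c("mean", "stdv")]
  colnames(rv) <- feats
  rv <- apply(rv, 2, function(x) (x - min(x)) / diff(range(x)))
  grid <- feature_projection_grid(cycles, feats, rv, s$outcomes, n_grid = 11)
  expect_equal(range(grid$x), range(rv[, 1]))
  expect_equal(range(grid$y), range(rv[, 2]))
  expect_gt(grid$n_cycles, 0)
  # planted truth: successes sit at low mean / high stdv
  lowmean_highstdv <- grid$mean_probability[1, 11]
  highmean_lowstdv <- grid$mean_probability[11, 1]
  expect_gt(lowmean_highstdv, highmean_lowstdv)
})

test_that("an empty projection comes back with a warning", {
  s <- small_study()
  rv <- matrix(runif(20), 10, 2, dimnames = list(sprintf("T%d", 1:10), c("a", "b")))
  expect_warning(
    g <- feature_projection_grid(small_cv()$cycles, c("a", "b"), rv, s$outcomes),
    "no cycle"
  )
  expect_equal(g$n_cycles, 0L)
})
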