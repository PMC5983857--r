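# Shared fixtures, built in code. The small study / CV run are cached so
# several test files can reuse them without re-simulating.

toy_assets <- function() {
  asset_table(
    asset_id = sprintf("A%d", 1:6),
    target_ids = c("G1;G2", "G3", "G4", "G1", "G3", "G5"),
    indication = c("pain", "melanoma", "asthma", "pain", "asthma", "epilepsy"),
    indication_class = c("other", "cancer", "other", "other", "other", "other"),
    outcome = c(
      "Succeeded", "Succeeded", "Failed-PhaseII",
      "Succeeded", "Failed-PhaseIII", "Failed-PhaseIII"
    ),
    target_species = "human"
  )
}

# small quantitative-filled dataset with named genes
toy_dataset <- function(values, kind = "quantitative-filled", name = "toy") {
  values <- as.matrix(values)
  gene_feature_dataset(
    values,
    genes = sprintf("G%d", seq_len(nrow(values))),
    feature_labels = colnames(values) %||% sprintf("f%d", seq_len(ncol(values))),
    kind = kind, name = name
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# outcomes object from a label vector named by target
outcomes_from <- function(labels) {
  out <- data.frame(
    target_id = names(labels), label = unname(labels),
    stringsAsFactors = FALSE
  )
  class(out) <- c("target_outcomes", "data.frame")
  out
}

# planted-confound fixture used by assoc/robustness/acceptance tests:
# one genuine delta = 2 feature, one feature driven purely by a
# success-enriched class, plus null features, for 60 + 20 labeled targets
confound_fixture <- function(seed = 42, n_s = 60, n_f = 20, n_null = 4,
                             class_size = 30, class_success = 29) {
  set.seed(seed)
  n <- n_s + n_f
  ids <- sprintf("T%03d", seq_len(n))
  labels <- stats::setNames(rep(c("success", "failure"), c(n_s, n_f)), ids)
  in_class <- c(
    sample(which(labels == "success"), class_success),
    sample(which(labels == "failure"), class_size - class_success)
  )
  class_map <- data.frame(
    target_id = ids[in_class], class = "enriched-like",
    stringsAsFactors = FALSE
  )
  genuine <- stats::rnorm(n) + 2 * (labels == "success")
  class_driven <- as.numeric(seq_len(n) %in% in_class) + stats::rnorm(n, sd = 0.05)
  x <- cbind(
    genuine = genuine, class_driven = class_driven,
    matrix(stats::rnorm(n * n_null), n,
      dimnames = list(NULL, sprintf("null%d", seq_len(n_null)))
    )
  )
  rownames(x) <- ids
  list(x = x, outcomes = outcomes_from(labels), class_map = class_map)
}

# small default-structure study + prepared reduced datasets (cached)
small_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) {
      return(cache)
    }
    cfg <- simulation_config(
      seed = 303, n_success = 60, n_fail = 20, n_unlabeled = 80,
      datasets = list(
        dataset_spec("expr", "quantitative-filled",
          n_genes = 150, n_features = 15, row_effect = 0.85,
          gene_scale_sd = 0.5, coverage = 1
        ),
        dataset_spec("annot", "categorical-sparse",
          n_genes = 140, n_features = 12, sparsity = 0.8
        )
      ),
      planted_effects = list(
        planted_effect("expr", "row-mean", delta = 1.5, sign = -1),
        planted_effect("expr", "row-stdv", delta = 1.5, sign = 1)
      ),
      class_structure = list(class_spec("GPCR-like", 20, 0.9))
    )
    st <- simulate_study(cfg)
    lab <- st$labels$target_id[st$labels$label != "unlabeled"]
    red <- lapply(st$datasets, function(ds) {
      reduce_features(coverage_filter(append_row_summaries(standardize(ds)), lab))
    })
    cache <<- list(study = st, outcomes = st$labels, labeled = lab, reduced = red)
    cache
  }
})

# cheap nested-CV run on the small study (cached)
small_cv <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) {
      return(cache)
    }
    s <- small_study()
    cc <- cv_config(
      outer_folds = 5, outer_reps = 4, inner_folds = 3, inner_reps = 2,
      n_perm_univariate = 300, min_genes = 100, rf_ntree = 40,
      seed = 99, keep_models = TRUE
    )
    cache <<- list(cycles = outer_cv(s$reduced, s$outcomes, s$study$class_map, cc), config = cc)
    cache
  }
})
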