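#' Specification of one simulated gene-by-feature dataset
#'
#' @param name Dataset name.
#' @param kind Value shape; see [gene_feature_dataset()].
#' @param n_genes Number of genes (rows) in the dataset.
#' @param n_features Number of features (columns).
#' @param n_correlated_blocks Number of leading feature blocks that share a
#'   latent gene factor, producing pairwise squared correlation `block_r2`.
#' @param block_size Features per correlated block.
#' @param block_r2 Target pairwise squared correlation within a block.
#' @param sparsity Expected fraction of structural zeros (sparse kinds only).
#' @param coverage Fraction of outcome-labeled targets covered by the dataset.
#' @param is_human Species flag carried through to the dataset.
#' @param value_mean,value_sd Location and scale of the raw value distribution.
#' @param row_effect Share of latent variance contributed by a per-gene
#'   baseline shared across all features. A positive share makes every column
#'   correlate with the dataset's row-mean summary, the way tissues in an
#'   expression atlas all track a gene's overall expression level. The
#'   baseline is drawn right-skewed (standardized lognormal), as gene
#'   expression levels are.
#' @param gene_scale_sd Lognormal sdlog of a per-gene noise-scale multiplier;
#'   positive values give genes heterogeneous, right-skewed variability
#'   across features (tissue-specific versus flat expression profiles).
#' @return A `dataset_spec` list.
#' @export
dataset_spec <- function(name, kind, n_genes, n_features,
                         n_correlated_blocks = 0, block_size = 4,
                         block_r2 = 0.6, sparsity = 0.7, coverage = 0.95,
                         is_human = TRUE, value_mean = 5, value_sd = 2,
                         row_effect = 0, gene_scale_sd = 0) {
  kind <- match.arg(kind, dataset_kinds())
  stopifnot(
    n_genes >= 1, n_features >= 1, block_r2 >= 0, block_r2 <= 1,
    sparsity >= 0, sparsity < 1, coverage > 0, coverage <= 1,
    n_correlated_blocks * block_size <= n_features,
    row_effect >= 0, row_effect < 1, gene_scale_sd >= 0
  )
  structure(as.list(environment()), class = "dataset_spec")
}

#' Planted outcome effect
#'
#' Describes a shift, in pooled-standard-deviation units, of a feature's
#' success-group mean relative to its failure-group mean. The effect is applied
#' additively on the raw (pre-standardization) value scale. Roles `"row-mean"`
#' and `"row-stdv"` perturb whole gene rows so that the planted signal lands in
#' the appended row-summary features; `"named-feature"` perturbs a single
#' column.
#'
#' @param dataset Name of the dataset the effect applies to.
#' @param role `"row-mean"`, `"row-stdv"`, or `"named-feature"`.
#' @param delta Effect size in pooled-SD units.
#' @param sign `+1` (successes higher) or `-1` (successes lower).
#' @param feature Column label, required when `role = "named-feature"`.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(dataset, role = c("row-mean", "row-stdv", "named-feature"),
                           delta, sign = 1, feature = NULL) {
  role <- match.arg(role)
  stopifnot(delta >= 0, sign %in% c(-1, 1))
  if (role == "named-feature" && is.null(feature)) {
    stop("a named-feature effect needs `feature`")
  }
  structure(
    list(dataset = dataset, role = role, delta = delta, sign = sign, feature = feature),
    class = "planted_effect"
  )
}

#' Target-class specification
#'
#' @param name Class (gene family) name.
#' @param size Number of labeled targets in the class.
#' @param success_rate Fraction of class members that are successes; the
#'   realized counts are exact (`round(size * success_rate)` successes).
#' @return A `class_spec` list.
#' @export
class_spec <- function(name, size, success_rate) {
  stopifnot(size >= 1, success_rate >= 0, success_rate <= 1)
  structure(
    list(name = name, size = size, success_rate = success_rate),
    class = "class_spec"
  )
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the clinical-outcome screen: 259
#' successful and 72 failed targets, a success-enriched GPCR-like class
#' (62/70 successes), a failure-pure integrin-like class (3/3 failures), one
#' dense tissue-expression atlas carrying planted low-mean / high-variance
#' success effects, one quantitative-sparse evidence-score dataset, and one
#' categorical annotation dataset.
#'
#' @param seed Integer seed; the whole study is deterministic given it.
#' @param n_success,n_fail,n_unlabeled Target counts (labeled total must be
#'   at least 6).
#' @param datasets List of [dataset_spec()]s.
#' @param planted_effects List of [planted_effect()]s.
#' @param class_structure List of [class_spec()]s.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_success = 259, n_fail = 72,
                              n_unlabeled = 669,
                              datasets = default_dataset_specs(),
                              planted_effects = default_planted_effects(),
                              class_structure = default_class_structure()) {
  if (n_success + n_fail < 6) stop("need at least 6 labeled targets")
  if (inherits(datasets, "dataset_spec")) datasets <- list(datasets)
  if (inherits(planted_effects, "planted_effect")) planted_effects <- list(planted_effects)
  if (inherits(class_structure, "class_spec")) class_structure <- list(class_structure)
  ds_names <- vapply(datasets, `[[`, character(1), "name")
  if (anyDuplicated(ds_names)) stop("duplicate dataset names")
  for (pe in planted_effects) {
    if (!pe$dataset %in% ds_names) {
      stop(sprintf("planted effect references unknown dataset '%s'", pe$dataset))
    }
    kind <- datasets[[match(pe$dataset, ds_names)]]$kind
    if (kind == "categorical-sparse" && pe$role != "named-feature") {
      stop("row-summary effects are not supported on categorical-sparse datasets")
    }
  }
  n_class <- sum(vapply(class_structure, `[[`, numeric(1), "size"))
  if (n_class > n_success + n_fail) stop("class sizes exceed labeled target count")
  structure(
    list(
      seed = as.integer(seed), n_success = n_success, n_fail = n_fail,
      n_unlabeled = n_unlabeled, datasets = datasets,
      planted_effects = planted_effects, class_structure = class_structure
    ),
    class = "simulation_config"
  )
}

#' @rdname simulation_config
#' @export
default_dataset_specs <- function() {
  list(
    dataset_spec("tissue_expression_atlas", "quantitative-filled",
      n_genes = 900, n_features = 30, n_correlated_blocks = 2,
      block_size = 4, block_r2 = 0.6, row_effect = 0.85, gene_scale_sd = 0.5
    ),
    dataset_spec("protein_evidence_scores", "quantitative-sparse",
      n_genes = 800, n_features = 25, sparsity = 0.6
    ),
    dataset_spec("pathway_annotations", "categorical-sparse",
      n_genes = 850, n_features = 40, sparsity = 0.9
    )
  )
}

#' @rdname simulation_config
#' @export
default_planted_effects <- function() {
  list(
    planted_effect("tissue_expression_atlas", "row-mean", delta = 1, sign = -1),
    planted_effect("tissue_expression_atlas", "row-stdv", delta = 1, sign = 1)
  )
}

#' @rdname simulation_config
#' @export
default_class_structure <- function() {
  list(
    class_spec("GPCR-like", size = 70, success_rate = 62 / 70),
    class_spec("integrin-like", size = 3, success_rate = 0)
  )
}

#' Simulate a complete target-outcome study
#'
#' Generates, deterministically from the configured seed: (1) an asset-level
#' outcome table whose filtered-and-scored labels equal the planted
#' success/failure assignment (plus decoy records that the filters must
#' remove), (2) one raw [gene_feature_dataset()] per configured spec with
#' correlated feature blocks and planted outcome effects, and (3) a
#' target-class membership table with the configured per-class success rates.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_study` list with elements `asset_table`, `datasets`,
#'   `class_map`, `labels` (the planted per-target labels), `truth` (planted
#'   effect locations and directions), and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_lab <- config$n_success + config$n_fail
  n_all <- n_lab + config$n_unlabeled
  ids <- sprintf("T%05d", seq_len(n_all))
  label <- c(
    rep("success", config$n_success), rep("failure", config$n_fail),
    rep("unlabeled", config$n_unlabeled)
  )
  labels <- data.frame(target_id = ids, label = label, stringsAsFactors = FALSE)
  class(labels) <- c("target_outcomes", "data.frame")
  attr(labels, "summary") <- outcome_summary(labels)

  class_map <- assign_classes(labels, config$class_structure)
  datasets <- simulate_datasets(config, labels)
  assets <- simulate_assets(labels)

  truth <- do.call(rbind, lapply(config$planted_effects, function(pe) {
    data.frame(
      dataset = pe$dataset,
      feature = switch(pe$role,
        "row-mean" = "mean",
        "row-stdv" = "stdv",
        "named-feature" = pe$feature
      ),
      role = pe$role, delta = pe$delta, sign = pe$sign,
      stringsAsFactors = FALSE
    )
  })) %||% data.frame(
    dataset = character(), feature = character(), role = character(),
    delta = numeric(), sign = numeric()
  )

  structure(
    list(
      asset_table = assets, datasets = datasets, class_map = class_map,
      labels = labels, truth = truth, config = config
    ),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  s <- attr(x$labels, "summary")
  cat(sprintf(
    "simulated_study: %d success / %d failure / %d unlabeled targets, %d dataset(s), %d planted effect(s)\n",
    s$n_success, s$n_fail, sum(x$labels$label == "unlabeled"),
    length(x$datasets), nrow(x$truth)
  ))
  invisible(x)
}

assign_classes <- function(labels, class_structure) {
  succ_pool <- labels$target_id[labels$label == "success"]
  fail_pool <- labels$target_id[labels$label == "failure"]
  rows <- list()
  for (cs in class_structure) {
    k_s <- round(cs$size * cs$success_rate)
    k_f <- cs$size - k_s
    if (k_s > length(succ_pool) || k_f > length(fail_pool)) {
      stop(sprintf("not enough unassigned targets for class '%s'", cs$name))
    }
    take_s <- sample_safe(succ_pool, k_s)
    take_f <- sample_safe(fail_pool, k_f)
    succ_pool <- setdiff(succ_pool, take_s)
    fail_pool <- setdiff(fail_pool, take_f)
    rows[[cs$name]] <- data.frame(
      target_id = c(take_s, take_f), class = cs$name,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows) %||%
    data.frame(target_id = character(), class = character())
  rownames(out) <- NULL
  out
}

simulate_datasets <- function(config, labels) {
  lab_ids <- labeled_ids(labels)
  unlab_ids <- setdiff(labels$target_id, lab_ids)
  covered <- lapply(config$datasets, function(sp) {
    n_cov <- min(round(sp$coverage * length(lab_ids)), sp$n_genes)
    sample_safe(lab_ids, n_cov)
  })
  # every labeled target must appear in at least one dataset
  missing <- setdiff(lab_ids, unique(unlist(covered)))
  if (length(missing)) covered[[1]] <- union(covered[[1]], missing)

  datasets <- vector("list", length(config$datasets))
  for (i in seq_along(config$datasets)) {
    sp <- config$datasets[[i]]
    lab_in <- covered[[i]]
    n_fill <- sp$n_genes - length(lab_in)
    if (n_fill > length(unlab_ids)) {
      stop(sprintf("dataset '%s': not enough unlabeled targets to fill %d genes", sp$name, sp$n_genes))
    }
    genes <- sample_safe(c(lab_in, sample_safe(unlab_ids, n_fill)))
    values <- simulate_values(sp, length(genes))
    rownames(values) <- genes
    effects <- Filter(function(pe) pe$dataset == sp$name, config$planted_effects)
    values <- apply_planted_effects(values, sp, effects, labels)
    # intensity-like data stays nonnegative after perturbation
    if (sp$kind == "quantitative-filled") values <- pmax(values, 0)
    datasets[[i]] <- gene_feature_dataset(
      values,
      genes = genes,
      feature_labels = colnames(values), kind = sp$kind, name = sp$name,
      is_human = sp$is_human, n_genes_total = sp$n_genes
    )
  }
  names(datasets) <- vapply(config$datasets, `[[`, character(1), "name")
  datasets
}

# latent correlated Gaussian, transformed per kind via a Gaussian copula so
# correlated blocks survive the sparse transforms
simulate_values <- function(sp, n_genes) {
  z <- matrix(stats::rnorm(n_genes * sp$n_features), n_genes, sp$n_features)
  if (sp$n_correlated_blocks > 0) {
    rho <- sqrt(sp$block_r2) # pairwise correlation whose square is block_r2
    for (b in seq_len(sp$n_correlated_blocks)) {
      cols <- ((b - 1) * sp$block_size + 1):(b * sp$block_size)
      f <- stats::rnorm(n_genes)
      z[, cols] <- sqrt(rho) * f + sqrt(1 - rho) * z[, cols]
    }
  }
  if (sp$gene_scale_sd > 0) {
    s_g <- stats::rlnorm(n_genes, 0, sp$gene_scale_sd)
    z <- z * (s_g / sqrt(mean(s_g^2)))
  }
  if (sp$row_effect > 0) {
    a_g <- as.numeric(scale(stats::rlnorm(n_genes, 0, 1)))
    z <- sqrt(sp$row_effect) * a_g + sqrt(1 - sp$row_effect) * z
  }
  fl <- sprintf("f%02d", seq_len(sp$n_features))
  if (sp$kind == "quantitative-filled") {
    mu <- stats::rnorm(sp$n_features, sp$value_mean, 1)
    sd_ <- sp$value_sd * stats::runif(sp$n_features, 0.7, 1.3)
    v <- sweep(sweep(z, 2, sd_, "*"), 2, mu, "+")
  } else if (sp$kind == "quantitative-sparse") {
    u <- stats::pnorm(z)
    q0 <- pmin(pmax(sp$sparsity * stats::runif(sp$n_features, 0.8, 1.2), 0), 0.98)
    v <- matrix(0, n_genes, sp$n_features)
    for (j in seq_len(sp$n_features)) {
      present <- u[, j] > q0[j]
      v[present, j] <- stats::qlnorm(
        (u[present, j] - q0[j]) / (1 - q0[j]),
        meanlog = log(sp$value_mean), sdlog = 0.6
      )
    }
  } else { # categorical-sparse
    u <- stats::pnorm(z)
    p1 <- pmin(pmax((1 - sp$sparsity) * stats::runif(sp$n_features, 0.5, 1.5), 0.01), 0.9)
    v <- sweep(u, 2, 1 - p1, ">") * 1
  }
  colnames(v) <- fl
  v
}

apply_planted_effects <- function(values, sp, effects, labels) {
  if (!length(effects)) {
    return(values)
  }
  lv <- outcome_vector(labels, rownames(values))
  s_rows <- which(lv == "success")
  f_rows <- which(lv == "failure")
  for (pe in effects) {
    if (pe$role == "row-mean") {
      rm_ <- rowMeans(values)
      s <- pooled_sd(rm_[s_rows], rm_[f_rows])
      shift <- pe$sign * pe$delta * s
      if (sp$kind == "quantitative-sparse") {
        # preserve structural zeros: spread the shift over nonzero entries
        blk <- values[s_rows, , drop = FALSE]
        nz <- blk != 0
        frac <- pmax(rowMeans(nz), 1e-3)
        blk <- blk + nz * (shift / frac)
        blk[nz] <- pmax(blk[nz], 1e-6)
        values[s_rows, ] <- blk
      } else {
        values[s_rows, ] <- values[s_rows, , drop = FALSE] + shift
      }
    } else if (pe$role == "row-stdv") {
      rs <- apply(values, 1, stats::sd)
      s <- pooled_sd(rs[s_rows], rs[f_rows])
      for (g in s_rows) {
        old <- rs[g]
        if (old <= 0) next
        new <- max(old + pe$sign * pe$delta * s, 0.05 * old)
        m <- mean(values[g, ])
        values[g, ] <- m + (values[g, ] - m) * (new / old)
      }
    } else { # named-feature
      j <- match(pe$feature, colnames(values))
      if (is.na(j)) stop(sprintf("planted feature '%s' not in dataset '%s'", pe$feature, sp$name))
      col <- values[, j]
      s <- pooled_sd(col[s_rows], col[f_rows])
      shift <- pe$sign * pe$delta * s
      if (sp$kind == "categorical-sparse") {
        # realize the mean shift by flipping success entries
        n_flip <- min(round(abs(shift) * length(s_rows)), length(s_rows))
        from <- if (shift > 0) 0 else 1
        cand <- s_rows[col[s_rows] == from]
        flip <- sample_safe(cand, min(n_flip, length(cand)))
        values[flip, j] <- 1 - from
      } else if (sp$kind == "quantitative-sparse") {
        nz <- s_rows[col[s_rows] != 0]
        if (length(nz)) {
          values[nz, j] <- pmax(col[nz] + shift * length(s_rows) / length(nz), 0)
        }
      } else {
        values[s_rows, j] <- col[s_rows] + shift
      }
    }
  }
  values
}

pooled_sd <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) {
    return(stats::sd(c(a, b)))
  }
  sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
}

indications <- function() {
  c(
    "hypertension", "type 2 diabetes", "rheumatoid arthritis", "asthma",
    "major depression", "epilepsy", "osteoporosis", "psoriasis",
    "chronic pain", "heart failure"
  )
}

# asset records that reproduce the planted labels after filter + score,
# plus decoys removed by each of the four filters
simulate_assets <- function(labels) {
  rows <- list()
  k <- 0L
  add <- function(target, outcome, ind_class = "other", species = "human",
                  extra_target = NULL) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(
      asset_id = sprintf("A%06d", k),
      target_ids = paste(c(target, extra_target), collapse = ";"),
      indication = sample_safe(indications(), 1),
      indication_class = ind_class,
      outcome = outcome,
      target_species = species,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(labels))) {
    tid <- labels$target_id[i]
    lab <- labels$label[i]
    if (lab == "success") {
      add(tid, "Succeeded")
      for (j in seq_len(stats::rpois(1, 0.5))) add(tid, "Failed-PhaseIII")
    } else if (lab == "failure") {
      for (j in seq_len(1 + stats::rpois(1, 0.3))) add(tid, "Failed-PhaseIII")
      # decoys: successes that the filters must remove
      u <- stats::runif(1)
      if (u < 0.15) {
        add(tid, "Succeeded", ind_class = "cancer")
      } else if (u < 0.25) {
        add(tid, "Succeeded", extra_target = sample_safe(labels$target_id, 1))
      } else if (u < 0.3) {
        add(tid, "Succeeded", species = "non-human")
      }
    } else if (stats::runif(1) < 0.3) {
      # unlabeled targets may still have non-qualifying records
      add(tid, sample_safe(c(
        "InProgress-PhaseIII", "InProgress-PhaseII",
        "Failed-PhaseII", "Failed-PhaseI", "Failed-Withdrawn"
      ), 1))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("asset_table", "data.frame")
  out
}

#' Write a simulated study to delimited text files
#'
#' Writes `assets.tsv`, `classes.tsv`, `labels.tsv` and one
#' `dataset_<name>.tsv` per dataset into `dir`, in the formats read by
#' [read_assets()] and [read_feature_matrix()].
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_assets(study$asset_table, file.path(dir, "assets.tsv"))
  utils::write.table(study$class_map, file.path(dir, "classes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(study$labels, file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  for (ds in study$datasets) {
    write_feature_matrix(ds, file.path(dir, sprintf("dataset_%s.tsv", ds$name)))
  }
  invisible(dir)
}
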