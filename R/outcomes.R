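#' Construct an asset-level clinical outcome table
#'
#' One row per asset (drug or drug candidate) record: its target(s), the
#' indication pursued, the indication class (used for the cancer exclusion),
#' the net outcome of the effort, and the species of the target. Multiple
#' targets are separated by `";"` in `target_ids`.
#'
#' @param asset_id Character asset identifiers.
#' @param target_ids Character; one or more gene identifiers per asset,
#'   `";"`-separated.
#' @param indication Character indication names.
#' @param indication_class Character; `"cancer"` records are excluded by
#'   [filter_assets()].
#' @param outcome One of `"Succeeded"`, `"InProgress-Preclinical"`,
#'   `"InProgress-PhaseI"`, `"InProgress-PhaseII"`, `"InProgress-PhaseIII"`,
#'   `"Failed-Preclinical"`, `"Failed-PhaseI"`, `"Failed-PhaseII"`,
#'   `"Failed-PhaseIII"`, `"Failed-Withdrawn"`.
#' @param target_species `"human"` or `"non-human"`.
#' @return A `data.frame` with class `asset_table`.
#' @export
asset_table <- function(asset_id, target_ids, indication, indication_class,
                        outcome, target_species = "human") {
  bad <- !outcome %in% asset_outcomes()
  if (any(bad)) {
    stop(
      "unknown outcome value(s): ",
      paste(unique(outcome[bad]), collapse = ", ")
    )
  }
  df <- data.frame(
    asset_id = as.character(asset_id),
    target_ids = as.character(target_ids),
    indication = as.character(indication),
    indication_class = as.character(indication_class),
    outcome = as.character(outcome),
    target_species = as.character(target_species),
    stringsAsFactors = FALSE
  )
  class(df) <- c("asset_table", "data.frame")
  df
}

asset_outcomes <- function() {
  c(
    "Succeeded",
    paste0("InProgress-", c("Preclinical", "PhaseI", "PhaseII", "PhaseIII")),
    paste0("Failed-", c("Preclinical", "PhaseI", "PhaseII", "PhaseIII", "Withdrawn"))
  )
}

split_targets <- function(target_ids) {
  strsplit(as.character(target_ids), ";", fixed = TRUE)
}

#' Filter asset records down to the outcome-informative subset
#'
#' Retains, in their original order, only records with (1) exactly one target
#' (selective assets), (2) a human target, (3) a non-cancer indication, and
#' (4) a decisive phase III outcome (`Succeeded` or `Failed-PhaseIII`).
#' Assets with multiple targets are removed because a trial outcome cannot be
#' attributed unambiguously to a single target; failures before phase III are
#' removed because they are more often due to safety or exposure than to lack
#' of target efficacy.
#'
#' @param records An [asset_table()].
#' @return The filtered [asset_table()].
#' @export
filter_assets <- function(records) {
  targets <- split_targets(records$target_ids)
  n_targets <- vapply(
    targets,
    function(x) sum(nzchar(trimws(x))), integer(1)
  )
  if (any(n_targets == 0)) {
    stop(
      "record(s) with no target: ",
      paste(records$asset_id[n_targets == 0], collapse = ", ")
    )
  }
  keep <- n_targets == 1 &
    records$target_species == "human" &
    records$indication_class != "cancer" &
    records$outcome %in% c("Succeeded", "Failed-PhaseIII")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score each target's net phase III outcome
#'
#' Best-outcome-wins aggregation over the (already filtered) records of each
#' target: a target with at least one `Succeeded` record is a success; a
#' target with no successes and at least one `Failed-PhaseIII` record is a
#' failure; every other member of `universe` is unlabeled.
#'
#' @param records A filtered [asset_table()] (see [filter_assets()]).
#' @param universe Gene identifiers to label; defaults to the targets present
#'   in `records`.
#' @return A `target_outcomes` data.frame with columns `target_id` and
#'   `label` (`"success"`, `"failure"`, `"unlabeled"`), carrying an
#'   `"summary"` attribute with `n_success`, `n_fail` and `success_rate`.
#' @export
score_targets <- function(records, universe = NULL) {
  tid <- vapply(split_targets(records$target_ids), `[`, character(1), 1)
  universe <- universe %||% unique(tid)
  succ <- unique(tid[records$outcome == "Succeeded"])
  fail3 <- unique(tid[records$outcome == "Failed-PhaseIII"])
  label <- rep("unlabeled", length(universe))
  label[universe %in% fail3] <- "failure"
  label[universe %in% succ] <- "success"
  out <- data.frame(
    target_id = as.character(universe), label = label,
    stringsAsFactors = FALSE
  )
  class(out) <- c("target_outcomes", "data.frame")
  attr(out, "summary") <- outcome_summary(out)
  out
}

#' Summarize labeled-target counts and success rate
#'
#' @param outcomes A `target_outcomes` data.frame.
#' @return A list with `n_success`, `n_fail` and
#'   `success_rate = n_success / (n_success + n_fail)`.
#' @export
outcome_summary <- function(outcomes) {
  n_s <- sum(outcomes$label == "success")
  n_f <- sum(outcomes$label == "failure")
  list(n_success = n_s, n_fail = n_f, success_rate = n_s / (n_s + n_f))
}

#' @export
print.target_outcomes <- function(x, ...) {
  s <- attr(x, "summary") %||% outcome_summary(x)
  cat(sprintf(
    "target_outcomes: %d success, %d failure, %d unlabeled (success rate %.1f%%)\n",
    s$n_success, s$n_fail, sum(x$label == "unlabeled"), 100 * s$success_rate
  ))
  invisible(x)
}

# named label vector ("success"/"failure"/"unlabeled") for the given ids
outcome_vector <- function(outcomes, ids = outcomes$target_id) {
  v <- outcomes$label[match(ids, outcomes$target_id)]
  v[is.na(v)] <- "unlabeled"
  names(v) <- ids
  v
}

labeled_ids <- function(outcomes) {
  outcomes$target_id[outcomes$label %in% c("success", "failure")]
}

#' Read / write asset tables
#'
#' Tab-delimited round trip for [asset_table()] objects; the header documents
#' the expected columns.
#'
#' @param path File path.
#' @return `read_assets()` returns an [asset_table()].
#' @export
read_assets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(
    "asset_id", "target_ids", "indication", "indication_class",
    "outcome", "target_species"
  )
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("asset table misses column(s): ", paste(missing, collapse = ", "))
  }
  do.call(asset_table, df[needed])
}

#' @param records An [asset_table()].
#' @rdname read_assets
#' @export
write_assets <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
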