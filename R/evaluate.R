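## Six-outcome evaluation of predictions against ground truth, and the
## four-way taxonomy of query/reference cell-type overlap used to stage
## benchmarks.

outcome_levels <- c("correct", "correct_partial", "correct_unclassified",
                    "failed", "wrong", "wrong_unclassified")

#' Synonym table for cell-type labels
#'
#' Datasets name the same cell type differently ("bipolar" vs "BP");
#' synonym groups make such labels equivalent during evaluation.
#' `partial_pairs` lists coarse/fine label pairs ("photoreceptor" vs
#' "rod") that count as partially correct. By default both are empty.
#'
#' @param groups List of character vectors; the labels within a vector are
#'   treated as the same cell type. A label may appear in only one group.
#' @param partial_pairs Data frame with columns `coarse` and `fine`.
#' @return An object of class `synonym_table`.
#' @export
synonym_table <- function(groups = list(), partial_pairs = NULL) {
  all_lab <- unlist(groups)
  if (anyDuplicated(all_lab)) {
    stop("label(s) in more than one synonym group: ",
         paste(unique(all_lab[duplicated(all_lab)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(partial_pairs)) {
    partial_pairs <- data.frame(coarse = character(), fine = character(),
                                stringsAsFactors = FALSE)
  }
  structure(list(groups = groups,
                 partial_pairs = partial_pairs[, c("coarse", "fine")]),
            class = "synonym_table")
}

#' Read a synonym table from TSV
#'
#' Two required columns, `canonical` and `alias`, plus an optional logical
#' `partial` column: a row flagged partial records a coarse/fine pair
#' (canonical = coarse, alias = fine) instead of a synonym.
#'
#' @param path Path to the TSV.
#' @return A [synonym_table()].
#' @export
read_synonym_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("canonical", "alias") %in% names(df))) {
    stop("synonym table needs columns canonical, alias", call. = FALSE)
  }
  part <- if ("partial" %in% names(df)) {
    as.logical(df$partial)
  } else rep(FALSE, nrow(df))
  syn <- df[!part, , drop = FALSE]
  by_canon <- split(syn$alias, syn$canonical)
  groups <- Map(function(canon, aliases) unique(c(canon, aliases)),
                names(by_canon), by_canon)
  synonym_table(unname(groups),
                data.frame(coarse = df$canonical[part],
                           fine = df$alias[part], stringsAsFactors = FALSE))
}

canonical_label <- function(label, syn) {
  for (g in syn$groups) if (label %in% g) return(g[1])
  label
}

is_partial_pair <- function(a, b, syn) {
  pp <- syn$partial_pairs
  any((pp$coarse == a & pp$fine == b) | (pp$coarse == b & pp$fine == a))
}

#' Classify a prediction into one of six outcomes
#'
#' Given the true label of a query cluster, the prediction, and the set of
#' cell types the reference actually contains, the outcome is: `correct`
#' (assigned an equivalent label), `correct_partial` (assigned a
#' coarse/fine partner of the truth), `failed` (unassigned although the
#' truth is in the reference), `correct_unclassified` (unassigned and the
#' truth is absent from the reference), `wrong` (assigned a different label
#' while the truth was available), `wrong_unclassified` (assigned although
#' the truth is absent from the reference). The first three count as
#' successes. Labels are compared after synonym resolution.
#'
#' @param truth True cell-type label (non-empty).
#' @param predicted Predicted label, or `""` when status is unassigned.
#' @param status `"assigned"` or `"unassigned"`.
#' @param ref_types Character vector of the cell types present in the
#'   reference.
#' @param syn A [synonym_table()]; default empty.
#' @return One of the six outcome strings.
#' @export
classify_outcome <- function(truth, predicted, status, ref_types,
                             syn = synonym_table()) {
  stopifnot(nzchar(truth))
  ct <- canonical_label(truth, syn)
  in_ref <- ct %in% vapply(ref_types, canonical_label, character(1),
                           syn = syn)
  if (status == "unassigned") {
    return(if (in_ref) "failed" else "correct_unclassified")
  }
  cp <- canonical_label(predicted, syn)
  if (cp == ct) return("correct")
  if (is_partial_pair(cp, ct, syn)) return("correct_partial")
  if (in_ref) "wrong" else "wrong_unclassified"
}

#' Evaluate a prediction table against ground truth
#'
#' @param predictions Data frame from [annotate_clusters()].
#' @param truth Named character vector: query cluster id -> true label.
#' @param ref_types Cell types present in the reference.
#' @param syn A [synonym_table()].
#' @return Data frame with columns `query_cluster`, `truth`, `predicted`,
#'   `status`, `outcome`.
#' @export
evaluate_predictions <- function(predictions, truth, ref_types,
                                 syn = synonym_table()) {
  missing <- setdiff(predictions$query_cluster, names(truth))
  if (length(missing)) {
    stop("no truth label for cluster(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- predictions[, c("query_cluster", "status", "predicted_cell_type")]
  names(out)[3] <- "predicted"
  out$truth <- unname(truth[out$query_cluster])
  out$outcome <- mapply(classify_outcome, out$truth, out$predicted,
                        out$status,
                        MoreArgs = list(ref_types = ref_types, syn = syn))
  out[, c("query_cluster", "truth", "predicted", "status", "outcome")]
}

#' Composition of evaluation outcomes
#'
#' @param outcomes Character vector of outcome labels.
#' @return Named list: the six outcome fractions (summing to 1), `success`
#'   (correct + correct_partial + correct_unclassified), and `n`.
#' @export
summarize_outcomes <- function(outcomes) {
  if (length(outcomes) == 0L) stop("no outcomes to summarize", call. = FALSE)
  bad <- setdiff(outcomes, outcome_levels)
  if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  frac <- as.list(table(factor(outcomes, levels = outcome_levels)) /
                    length(outcomes))
  frac <- lapply(frac, as.numeric)
  frac$success <- frac$correct + frac$correct_partial +
    frac$correct_unclassified
  frac$n <- length(outcomes)
  frac
}

#' Scenario type of a query/reference cell-type pairing
#'
#' Type 1: identical type sets. Type 2: query types are a strict subset of
#' the reference. Type 3: reference types are a strict subset of the query.
#' Type 4: disjoint sets. A partial, non-nested overlap is outside the
#' taxonomy and raises an error.
#'
#' @param types_query,types_ref Non-empty character vectors of cell types.
#' @return Integer 1-4.
#' @export
scenario_type <- function(types_query, types_ref) {
  q <- unique(types_query); r <- unique(types_ref)
  if (length(q) == 0L || length(r) == 0L) {
    stop("type sets must be non-empty", call. = FALSE)
  }
  if (setequal(q, r)) return(1L)
  if (all(q %in% r)) return(2L)
  if (all(r %in% q)) return(3L)
  if (length(intersect(q, r)) == 0L) return(4L)
  stop("query and reference cell types overlap partially without nesting; ",
       "construct nested (type 1-3) or disjoint (type 4) scenarios",
       call. = FALSE)
}
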