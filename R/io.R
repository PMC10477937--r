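## On-disk formats: TSV matrices (first column "gene"), marker tables,
## reference-bundle directories, prediction tables. All text is UTF-8,
## tab-delimited, "." decimal; numerics are written at 12 significant
## digits. Orientation is fixed (genes in rows): a transposed file is a
## user error, never silently fixed.

fmt_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

#' Read a cluster profile from TSV
#'
#' Expects a tab-separated file whose header starts with the literal column
#' `gene` followed by cluster names, one gene per row. Duplicate gene rows
#' are collapsed by keeping the row with the highest total expression (a
#' warning reports how many were dropped).
#'
#' @param path Path to the TSV file.
#' @param species Species of the gene symbols (`"human"`, `"mouse"`,
#'   `"unknown"`).
#' @return A [cluster_profile()].
#' @export
read_cluster_profile <- function(path, species = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "gene") {
    stop("expected a TSV whose first column is named \"gene\": ", path,
         call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = c("character"),
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0L) stop("empty matrix in ", path, call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at gene '%s', cluster '%s' in %s",
                 df[[1]][bad[1]], colnames(vals)[bad[2]], path),
         call. = FALSE)
  }
  rownames(num) <- df[[1]]
  colnames(num) <- colnames(vals)
  if (anyDuplicated(rownames(num))) {
    tot <- rowSums(num)
    keep <- !logical(nrow(num))
    for (g in unique(rownames(num)[duplicated(rownames(num))])) {
      idx <- which(rownames(num) == g)
      keep[idx[-which.max(tot[idx])]] <- FALSE
    }
    warning(sum(!keep), " duplicate gene row(s) collapsed in ", path,
            " (kept the highest-total row)", call. = FALSE)
    num <- num[keep, , drop = FALSE]
  }
  cluster_profile(num, species = species)
}

#' Write a cluster profile to TSV
#'
#' @param x A [cluster_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_profile <- function(x, path) {
  validate_cluster_profile(x)
  v <- x$values
  lines <- c(paste(c("gene", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i], fmt_num(v[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

write_marker_set <- function(x, path) {
  validate_marker_set(x)
  lines <- c("cluster\tgene\tscore\trank",
             sprintf("%s\t%s\t%s\t%d", x$cluster, x$gene, fmt_num(x$score),
                     as.integer(x$rank)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_marker_set <- function(path, role) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  marker_set(df, role = role)
}

#' Write a reference bundle to a directory
#'
#' Serializes the bundle as a plain directory of TSV/JSON files (`er.tsv`,
#' `ersub.tsv`, `background.tsv`, `markers_bg.tsv`, `markers_main.tsv`,
#' `markers_sub.tsv`, `sub_to_main.tsv`, `meta.json`) so it is inspectable
#' and diff-able. [read_reference_bundle()] reverses the operation.
#'
#' @param bundle A [reference_bundle()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written (the manifest), invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  validate_reference_bundle(bundle)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  write_cluster_profile(bundle$er, file.path(dir, "er.tsv"))
  write_cluster_profile(bundle$ersub, file.path(dir, "ersub.tsv"))
  write_cluster_profile(bundle$background, file.path(dir, "background.tsv"))
  write_marker_set(bundle$markers_bg, file.path(dir, "markers_bg.tsv"))
  write_marker_set(bundle$markers_main, file.path(dir, "markers_main.tsv"))
  write_marker_set(bundle$markers_sub, file.path(dir, "markers_sub.tsv"))
  s2m <- bundle$sub_to_main
  writeLines(c("sub\tmain", sprintf("%s\t%s", names(s2m), unname(s2m))),
             file.path(dir, "sub_to_main.tsv"), useBytes = TRUE)
  meta <- bundle$meta
  meta$species <- bundle$er$species
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- c("er.tsv", "ersub.tsv", "background.tsv", "markers_bg.tsv",
                "markers_main.tsv", "markers_sub.tsv", "sub_to_main.tsv",
                "meta.json")
  invisible(file.path(dir, manifest))
}

#' Read a reference bundle from a directory
#'
#' @param dir Directory written by [write_reference_bundle()].
#' @return A [reference_bundle()].
#' @export
read_reference_bundle <- function(dir) {
  need <- c("er.tsv", "ersub.tsv", "background.tsv", "markers_bg.tsv",
            "markers_main.tsv", "markers_sub.tsv", "sub_to_main.tsv",
            "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("not a reference bundle, missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  species <- if (is.null(meta$species)) "unknown" else meta$species
  s2m_df <- utils::read.table(file.path(dir, "sub_to_main.tsv"), header = TRUE,
                              sep = "\t", quote = "", stringsAsFactors = FALSE,
                              comment.char = "")
  s2m <- stats::setNames(as.character(s2m_df$main), as.character(s2m_df$sub))
  reference_bundle(
    er = read_cluster_profile(file.path(dir, "er.tsv"), species),
    ersub = read_cluster_profile(file.path(dir, "ersub.tsv"), species),
    sub_to_main = s2m,
    markers_main = read_marker_set(file.path(dir, "markers_main.tsv"), "main"),
    markers_sub = read_marker_set(file.path(dir, "markers_sub.tsv"), "sub"),
    background = read_cluster_profile(file.path(dir, "background.tsv"), species),
    markers_bg = read_marker_set(file.path(dir, "markers_bg.tsv"), "bg"),
    meta = meta)
}

prediction_columns <- c("query_cluster", "status", "predicted_cell_type",
                        "predicted_subcluster", "best_corr_m1", "best_corr_m2",
                        "cutoff_m1", "cutoff_m2", "decided_by")

#' Write a prediction table to TSV
#'
#' Rows are sorted by `query_cluster`; unassigned clusters carry the literal
#' status `"unassigned"` and empty label fields.
#'
#' @param records Data frame of predictions as returned by
#'   [annotate_clusters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path) {
  if (!all(prediction_columns %in% names(records))) {
    stop("prediction table lacks required columns", call. = FALSE)
  }
  if (anyDuplicated(records$query_cluster)) {
    stop("duplicate query_cluster ids in prediction table", call. = FALSE)
  }
  records <- records[order(records$query_cluster), prediction_columns]
  num <- c("best_corr_m1", "best_corr_m2", "cutoff_m1", "cutoff_m2")
  out <- records
  for (cc in num) out[[cc]] <- ifelse(is.na(records[[cc]]), "",
                                      fmt_num(records[[cc]]))
  lines <- c(paste(prediction_columns, collapse = "\t"),
             do.call(sprintf, c(list(paste(rep("%s", 9), collapse = "\t")),
                                lapply(out, as.character))))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#' @param path Path to the TSV.
#' @return Data frame with the standard prediction columns.
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "",
                          colClasses = "character")
  for (cc in c("best_corr_m1", "best_corr_m2", "cutoff_m1", "cutoff_m2")) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  df
}
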