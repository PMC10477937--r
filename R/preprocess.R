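#' Raw counts with cluster labels
#'
#' Container for a genes x cells matrix of raw integer counts plus a cluster
#' (or cell-type) label for every cell.
#'
#' @param counts Non-negative integer matrix, genes in rows, cells in
#'   columns, with row and column names. Sparse `dgCMatrix` input is
#'   densified.
#' @param cluster_of Named character vector mapping every cell id to its
#'   cluster label.
#' @return An object of class `counts_with_labels`.
#' @export
counts_with_labels <- function(counts, cluster_of) {
  if (methods::is(counts, "sparseMatrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix (genes x cells)", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene and cell names", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  cells <- colnames(counts)
  missing <- setdiff(cells, names(cluster_of))
  if (length(missing)) {
    stop(length(missing), " cell(s) have no cluster label (e.g. ",
         missing[1], ")", call. = FALSE)
  }
  cluster_of <- cluster_of[cells]
  if ("unassigned" %in% cluster_of) {
    stop("\"unassigned\" is a reserved label and cannot be a cluster id",
         call. = FALSE)
  }
  structure(list(counts = counts, cluster_of = cluster_of),
            class = "counts_with_labels")
}

#' @export
print.counts_with_labels <- function(x, ...) {
  cat(sprintf("<counts_with_labels> %d genes x %d cells, %d clusters\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cluster_of))))
  invisible(x)
}

#' Aggregate cells to pseudobulk cluster profiles
#'
#' Sums raw counts over the cells of each cluster, normalizes each cluster's
#' summed vector by its total, multiplies by `scale` and takes `log(1 + x)`.
#' The sum-then-normalize order means
#' `sum(exp(value) - 1)` equals `scale` exactly for every cluster.
#'
#' @param data A [counts_with_labels()].
#' @param scale Positive scale factor; default `1e5`.
#' @param species Species tag for the returned profile.
#' @return A [cluster_profile()] with one column per cluster.
#' @export
aggregate_and_normalize <- function(data, scale = 1e5, species = "unknown") {
  stopifnot(inherits(data, "counts_with_labels"), scale > 0)
  grp <- factor(data$cluster_of, levels = unique(data$cluster_of))
  summed <- t(rowsum(t(data$counts), grp))  # genes x clusters
  totals <- colSums(summed)
  if (any(totals == 0)) {
    stop("cluster(s) with zero total counts: ",
         paste(colnames(summed)[totals == 0], collapse = ", "), call. = FALSE)
  }
  vals <- log1p(sweep(summed, 2, totals, "/") * scale)
  cluster_profile(vals, species = species)
}

#' Detect the species of a gene-symbol list
#'
#' Compares the query symbols against human and mouse symbol universes
#' (case-insensitively, after deduplication) and returns the species whose
#' overlap ratio strictly exceeds `threshold`. If both exceed it, the higher
#' ratio wins; if neither does (or the ratios tie), `"warning"` is returned
#' so the user can review the input.
#'
#' @param gene_ids Character vector of query gene symbols.
#' @param human_universe,mouse_universe Character vectors of known symbols.
#' @param threshold Overlap fraction that must be exceeded; default 0.5.
#' @return `"human"`, `"mouse"`, or `"warning"`.
#' @export
detect_species <- function(gene_ids, human_universe, mouse_universe,
                           threshold = 0.5) {
  if (length(gene_ids) == 0L) stop("empty gene list", call. = FALSE)
  if (length(human_universe) == 0L || length(mouse_universe) == 0L) {
    stop("symbol universes must be non-empty", call. = FALSE)
  }
  ids <- unique(toupper(gene_ids))
  rh <- mean(ids %in% toupper(human_universe))
  rm_ <- mean(ids %in% toupper(mouse_universe))
  if (rh <= threshold && rm_ <= threshold) return("warning")
  if (rh > rm_) "human" else if (rm_ > rh) "mouse" else "warning"
}

#' Read a two-column human/mouse ortholog table
#'
#' Expects a TSV with header `human<TAB>mouse`. Pairs are filtered to
#' one-to-one orthologs: any symbol appearing in more than one pair (within
#' its species, case-insensitively) removes all its pairs.
#'
#' @param path Path to the TSV file.
#' @return An object of class `ortholog_map`: a data frame with columns
#'   `human` and `mouse`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("human", "mouse") %in% names(df))) {
    stop("ortholog table must have header \"human\\tmouse\"", call. = FALSE)
  }
  ortholog_map(df)
}

#' @rdname read_ortholog_map
#' @param pairs Data frame with character columns `human` and `mouse`.
#' @export
ortholog_map <- function(pairs) {
  pairs <- data.frame(human = as.character(pairs$human),
                      mouse = as.character(pairs$mouse),
                      stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  hu <- toupper(pairs$human); mo <- toupper(pairs$mouse)
  keep <- !(hu %in% hu[duplicated(hu)]) & !(mo %in% mo[duplicated(mo)])
  dropped <- sum(!keep)
  out <- structure(pairs[keep, , drop = FALSE],
                   class = c("ortholog_map", "data.frame"))
  attr(out, "n_dropped") <- dropped
  rownames(out) <- NULL
  out
}

#' Convert a profile's gene symbols to the other species
#'
#' Replaces gene symbols via one-to-one ortholog pairs; genes without a
#' one-to-one partner are dropped (their count is reported in a message).
#' Expression values are never altered. Symbol matching is
#' case-insensitive; the ortholog table's casing is used on output.
#'
#' @param profile A [cluster_profile()] with known species different from
#'   `target_species`.
#' @param map An [ortholog_map()].
#' @param target_species `"human"` or `"mouse"`.
#' @param min_genes Minimum number of genes that must survive mapping;
#'   fewer is treated as an insufficient-overlap error. Default 100.
#' @return A [cluster_profile()] in the target species.
#' @export
map_orthologs <- function(profile, map, target_species, min_genes = 100) {
  target_species <- match.arg(target_species, c("human", "mouse"))
  if (profile$species == "unknown") {
    stop("profile species is unknown; run detect_species() first",
         call. = FALSE)
  }
  if (profile$species == target_species) {
    stop("profile is already in the target species", call. = FALSE)
  }
  from <- profile$species; to <- target_species
  key <- stats::setNames(map[[to]], toupper(map[[from]]))
  hits <- key[toupper(profile_genes(profile))]
  keep <- !is.na(hits)
  n_dropped <- sum(!keep)
  if (sum(keep) < min_genes) {
    stop(sprintf(paste0("only %d gene(s) have one-to-one orthologs ",
                        "(minimum %d); query/reference species mismatch?"),
                 sum(keep), min_genes), call. = FALSE)
  }
  if (n_dropped > 0) {
    message(n_dropped, " gene(s) without a one-to-one ortholog dropped")
  }
  vals <- profile$values[keep, , drop = FALSE]
  rownames(vals) <- unname(hits[keep])
  cluster_profile(vals, species = to)
}

#' Read raw counts from MatrixMarket or dense TSV
#'
#' `read_counts_mtx()` reads the standard MTX trio (matrix, gene ids,
#' cell barcodes, one id per line); `read_counts_tsv()` reads a dense TSV in
#' the same layout as [read_cluster_profile()] (first column `gene`).
#'
#' @param mtx,genes,cells Paths to the MatrixMarket file and the row/column
#'   id files.
#' @param labels Named character vector or path to a two-column TSV
#'   (`cell_id<TAB>cluster`) of per-cell cluster labels.
#' @return A [counts_with_labels()].
#' @export
read_counts_mtx <- function(mtx, genes, cells, labels) {
  m <- as.matrix(Matrix::readMM(mtx))
  rownames(m) <- readLines(genes)
  colnames(m) <- readLines(cells)
  counts_with_labels(m, resolve_labels(labels))
}

#' @rdname read_counts_mtx
#' @param path Path to the dense counts TSV.
#' @export
read_counts_tsv <- function(path, labels) {
  p <- read_cluster_profile(path)  # reuses parsing; "clusters" are cells here
  counts_with_labels(p$values, resolve_labels(labels))
}

resolve_labels <- function(labels) {
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    df <- utils::read.table(labels, header = TRUE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, comment.char = "",
                            colClasses = "character")
    if (ncol(df) < 2L) stop("label file needs two columns", call. = FALSE)
    return(stats::setNames(df[[2]], df[[1]]))
  }
  labels
}

write_counts_tsv <- function(data, counts_path, labels_path) {
  v <- data$counts
  lines <- c(paste(c("gene", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i], as.character(v[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, counts_path, useBytes = TRUE)
  writeLines(c("cell_id\tcluster",
               sprintf("%s\t%s", names(data$cluster_of),
                       unname(data$cluster_of))),
             labels_path, useBytes = TRUE)
  invisible(counts_path)
}
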