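#' Cluster expression profile
#'
#' A `cluster_profile` holds average log-normalized expression for a set of
#' clusters: a dense genes x clusters matrix on the log(1 + CPM-at-1e5)
#' scale, plus the species the gene symbols belong to. The same container is
#' used for query clusters, background clusters, reference cell types and
#' reference sub-clusters.
#'
#' @param values Numeric matrix, genes in rows and clusters in columns, with
#'   row and column names. All values must be finite and non-negative.
#' @param species One of `"human"`, `"mouse"`, `"unknown"`.
#' @return An object of class `cluster_profile` with elements `values` and
#'   `species`.
#' @export
cluster_profile <- function(values, species = "unknown") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x clusters)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and cluster column names",
         call. = FALSE)
  }
  species <- match.arg(species, c("unknown", "human", "mouse"))
  x <- structure(list(values = values, species = species),
                 class = "cluster_profile")
  validate_cluster_profile(x)
  x
}

validate_cluster_profile <- function(x) {
  v <- x$values
  if (nrow(v) == 0L || ncol(v) == 0L) {
    stop("cluster profile is empty", call. = FALSE)
  }
  if (anyDuplicated(rownames(v))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(v))) {
    stop("duplicate cluster ids: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "),
         call. = FALSE)
  }
  if ("unassigned" %in% colnames(v)) {
    stop("\"unassigned\" is a reserved label and cannot be a cluster id",
         call. = FALSE)
  }
  if (!all(is.finite(v))) stop("expression values must be finite", call. = FALSE)
  if (any(v < 0)) stop("expression values must be non-negative", call. = FALSE)
  invisible(x)
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("<cluster_profile> %d genes x %d clusters, species = %s\n",
              nrow(x$values), ncol(x$values), x$species))
  invisible(x)
}

#' Gene and cluster identifiers of a profile
#' @param x A `cluster_profile`.
#' @return Character vector of ids in storage order.
#' @export
profile_genes <- function(x) rownames(x$values)

#' @rdname profile_genes
#' @export
profile_clusters <- function(x) colnames(x$values)

#' Marker gene set
#'
#' Per-cluster ranked marker genes with their specificity scores. `role`
#' records which profile the set was computed on: `"bg"` for background
#' clusters, `"main"` for reference cell types, `"sub"` for refined
#' sub-clusters.
#'
#' @param entries Data frame with columns `cluster`, `gene`, `score`, `rank`.
#' @param role One of `"bg"`, `"main"`, `"sub"`.
#' @return An object of class `marker_set` (a data frame).
#' @export
marker_set <- function(entries, role = c("bg", "main", "sub")) {
  role <- match.arg(role)
  need <- c("cluster", "gene", "score", "rank")
  if (!is.data.frame(entries) || !all(need %in% names(entries))) {
    stop("`entries` must have columns cluster, gene, score, rank", call. = FALSE)
  }
  entries <- entries[, need]
  entries$cluster <- as.character(entries$cluster)
  entries$gene <- as.character(entries$gene)
  rownames(entries) <- NULL
  x <- structure(entries, class = c("marker_set", "data.frame"))
  attr(x, "role") <- role
  validate_marker_set(x)
  x
}

validate_marker_set <- function(x) {
  for (cl in unique(x$cluster)) {
    e <- x[x$cluster == cl, ]
    e <- e[order(e$rank), ]
    if (!identical(as.integer(e$rank), seq_len(nrow(e)))) {
      stop("marker ranks for cluster '", cl, "' are not 1..n without gaps",
           call. = FALSE)
    }
    if (is.unsorted(-e$score)) {
      stop("marker scores for cluster '", cl,
           "' are not non-increasing with rank", call. = FALSE)
    }
  }
  invisible(x)
}

#' Genes of a marker set, optionally for one cluster
#' @param x A `marker_set`.
#' @param cluster Optional cluster id; default all clusters.
#' @return Character vector of unique gene ids (rank order preserved within
#'   a cluster).
#' @export
marker_genes <- function(x, cluster = NULL) {
  if (!is.null(cluster)) x <- x[x$cluster %in% cluster, , drop = FALSE]
  unique(x$gene[order(x$cluster, x$rank)])
}

#' Reference bundle
#'
#' The preprocessed representation of an annotated reference dataset used by
#' [annotate_clusters()]: corrected cell-type expression (`er`), refined
#' sub-cluster expression (`ersub`), the sub-cluster to cell-type map, the
#' background cluster profile used for cutoff calibration, and the three
#' marker sets computed on background clusters, main cell types, and
#' sub-clusters.
#'
#' @param er `cluster_profile` of corrected main cell-type expression.
#' @param ersub `cluster_profile` of sub-cluster expression.
#' @param sub_to_main Named character vector, names = sub-cluster ids,
#'   values = main cell-type ids.
#' @param markers_main,markers_sub,markers_bg `marker_set` objects.
#' @param background `cluster_profile` of background cluster expression.
#' @param meta Named list of free-form metadata (species, build parameters).
#' @return An object of class `reference_bundle`.
#' @export
reference_bundle <- function(er, ersub, sub_to_main, markers_main, markers_sub,
                             background, markers_bg, meta = list()) {
  x <- structure(list(er = er, ersub = ersub, sub_to_main = sub_to_main,
                      markers_main = markers_main, markers_sub = markers_sub,
                      background = background, markers_bg = markers_bg,
                      meta = meta),
                 class = "reference_bundle")
  validate_reference_bundle(x)
  x
}

validate_reference_bundle <- function(x) {
  subs <- profile_clusters(x$ersub)
  missing <- setdiff(subs, names(x$sub_to_main))
  if (length(missing)) {
    stop("sub-clusters missing from sub_to_main: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unname(x$sub_to_main[subs]), profile_clusters(x$er))
  if (length(bad)) {
    stop("sub_to_main maps to unknown cell types: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sp <- c(x$er$species, x$ersub$species, x$background$species)
  if (length(unique(sp)) != 1L) {
    stop("er, ersub and background must share one species", call. = FALSE)
  }
  checks <- list(main = list(x$markers_main, x$er),
                 sub  = list(x$markers_sub, x$ersub),
                 bg   = list(x$markers_bg, x$background))
  for (nm in names(checks)) {
    ms <- checks[[nm]][[1]]; pr <- checks[[nm]][[2]]
    if (!all(ms$gene %in% profile_genes(pr))) {
      stop("markers_", nm, " contains genes absent from its profile",
           call. = FALSE)
    }
    if (!all(ms$cluster %in% profile_clusters(pr))) {
      stop("markers_", nm, " refers to unknown clusters", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat(sprintf(paste0("<reference_bundle> %d cell types, %d sub-clusters, ",
                     "%d background clusters, species = %s\n"),
              ncol(x$er$values), ncol(x$ersub$values),
              ncol(x$background$values), x$er$species))
  invisible(x)
}
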