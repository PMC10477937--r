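## Building a reference bundle from an annotated dataset plus a background
## atlas: co-embed reference and background cells, cluster them jointly,
## average the joint clusters (Eb), redistribute reference cell types over
## the joint clusters (Wb), correct the cell-type expression (Er = Eb %*%
## Wb), refine sub-clusters within each main cell type, and score marker
## genes on each profile.

#' Joint clustering of reference and background cells
#'
#' @param combined_cluster_of Named character vector: cell id -> combined
#'   cluster id (reference and background cells together).
#' @param source_of Named character vector: cell id -> `"reference"` or
#'   `"background"`.
#' @param ref_celltype_of Named character vector: reference cell id -> its
#'   annotated cell type.
#' @return An object of class `joint_clustering`.
#' @export
joint_clustering <- function(combined_cluster_of, source_of, ref_celltype_of) {
  ref_cells <- names(source_of)[source_of == "reference"]
  miss_cl <- setdiff(ref_cells, names(combined_cluster_of))
  miss_ct <- setdiff(ref_cells, names(ref_celltype_of))
  if (length(miss_cl) || length(miss_ct)) {
    stop("every reference cell needs a combined cluster and a cell type",
         call. = FALSE)
  }
  structure(list(combined_cluster_of = combined_cluster_of,
                 source_of = source_of,
                 ref_celltype_of = ref_celltype_of),
            class = "joint_clustering")
}

#' Cell-type redistribution weights over combined clusters
#'
#' For each reference cell type, the fraction of its cells that landed in
#' each combined cluster after joint clustering. Rows are combined cluster
#' ids, columns are cell types; every column sums to one.
#'
#' @param jc A [joint_clustering()].
#' @return Numeric matrix (combined clusters x cell types).
#' @export
compute_weight_matrix <- function(jc) {
  stopifnot(inherits(jc, "joint_clustering"))
  ref_cells <- names(jc$source_of)[jc$source_of == "reference"]
  types <- unique(unname(jc$ref_celltype_of[ref_cells]))
  clusters <- sort(unique(unname(jc$combined_cluster_of)))
  tab <- table(factor(jc$combined_cluster_of[ref_cells], levels = clusters),
               factor(jc$ref_celltype_of[ref_cells], levels = types))
  wb <- unclass(tab)
  tot <- colSums(wb)
  if (any(tot == 0)) {
    stop("cell type(s) with zero cells: ",
         paste(types[tot == 0], collapse = ", "), call. = FALSE)
  }
  wb <- sweep(wb, 2, tot, "/")
  dimnames(wb) <- list(clusters, types)
  wb
}

#' Correct reference cell-type expression against the background
#'
#' Computes `Er = Eb %*% Wb`: each cell type's corrected profile is the
#' weight-matrix average of the combined-cluster profiles it spreads over.
#'
#' @param eb [cluster_profile()] of combined-cluster expression.
#' @param wb Weight matrix from [compute_weight_matrix()]; its rows must
#'   match `eb`'s clusters.
#' @return A [cluster_profile()] with one column per cell type.
#' @export
correct_reference_expression <- function(eb, wb) {
  stopifnot(inherits(eb, "cluster_profile"), is.matrix(wb))
  missing <- setdiff(rownames(wb), profile_clusters(eb))
  extra <- setdiff(profile_clusters(eb), rownames(wb))
  if (length(missing) || length(extra)) {
    stop("cluster ids of Eb and Wb do not match; missing from Eb: [",
         paste(missing, collapse = ", "), "], missing from Wb: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  wb <- wb[profile_clusters(eb), , drop = FALSE]
  cluster_profile(eb$values %*% wb, species = eb$species)
}

# Euclidean k-nearest-neighbour graph + modularity community detection.
# Brute-force distances are fine at the cell counts this package targets
# (clustering runs once per reference build).
community_partition <- function(coords, k = 15, resolution = 1,
                                seed = 7) {
  n <- nrow(coords)
  if (n == 1L) return(stats::setNames("1", rownames(coords)))
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(coords))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    edges[[i]] <- rbind(i, nb)
  }
  el <- t(do.call(cbind, edges))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  stats::setNames(as.character(igraph::membership(comm)), rownames(coords))
}

# PCA scores via the cell-cell Gram matrix (cells << genes in our sizes).
# Input: cells x features; per-feature standardization optional.
pca_scores <- function(x, rank = 30, standardize = TRUE) {
  x <- sweep(x, 2, colMeans(x), "-")
  if (standardize) {
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    x <- sweep(x, 2, s, "/")
  }
  rank <- min(rank, nrow(x) - 1L, ncol(x))
  gram <- tcrossprod(x)
  eig <- eigen(gram, symmetric = TRUE)
  keep <- seq_len(rank)
  sweep(eig$vectors[, keep, drop = FALSE], 2,
        sqrt(pmax(eig$values[keep], 0)), "*")
}

# Per-cell log-normalized expression: log1p(scale * count / cell_total).
lognorm_cells <- function(counts, scale = 1e5) {
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  }
  log1p(sweep(counts, 2, tot, "/") * scale)
}

#' Refine sub-clusters within each main cell type
#'
#' Cells are split by their main cell-type label and, within each type,
#' partitioned by community detection on a k-nearest-neighbour graph of the
#' supplied embedding. Sub-cluster ids are `"<maintype>::<k>"`, so the
#' sub-to-main map is recoverable from the id prefix. Main types with fewer
#' than `min_cells` cells are kept as a single sub-cluster (with a
#' warning), since singleton sub-clusters destabilize correlations.
#'
#' @param ref_counts A [counts_with_labels()] whose labels are main cell
#'   types.
#' @param embedding Numeric matrix of per-cell coordinates (cells x dims)
#'   with cell ids as row names, covering all reference cells.
#' @param resolution Community-detection resolution; default 0.3. A
#'   resolution of 0 yields one sub-cluster per main type.
#' @param min_cells Main types below this size are not split; default 10.
#' @param knn_k Neighbours in the graph; default 15.
#' @param seed Seed for the community detection; default 7.
#' @return Named character vector: cell id -> sub-cluster id.
#' @export
refine_subclusters <- function(ref_counts, embedding, resolution = 0.3,
                               min_cells = 10, knn_k = 15, seed = 7) {
  stopifnot(inherits(ref_counts, "counts_with_labels"))
  cells <- colnames(ref_counts$counts)
  missing <- setdiff(cells, rownames(embedding))
  if (length(missing)) {
    stop("embedding does not cover ", length(missing), " cell(s)",
         call. = FALSE)
  }
  out <- character(0)
  for (ct in unique(unname(ref_counts$cluster_of))) {
    members <- cells[ref_counts$cluster_of[cells] == ct]
    if (length(members) < min_cells || resolution <= 0) {
      if (length(members) < min_cells) {
        warning("main type '", ct, "' has ", length(members),
                " cells (< ", min_cells, "); kept as one sub-cluster",
                call. = FALSE)
      }
      sub <- stats::setNames(rep("1", length(members)), members)
    } else {
      sub <- community_partition(embedding[members, , drop = FALSE],
                                 k = knn_k, resolution = resolution,
                                 seed = seed)
    }
    # renumber communities 1..m in order of first appearance for stability
    ids <- unique(unname(sub))
    sub <- stats::setNames(as.character(match(unname(sub), ids)), names(sub))
    out <- c(out, stats::setNames(paste0(ct, "::", unname(sub)), names(sub)))
  }
  out[cells]
}

#' Marker-gene specificity scores for one cluster
#'
#' Scores every gene by the cosine similarity between its cross-cluster
#' expression vector and the one-hot indicator of the target cluster:
#' `score(g, k) = e[g, k] / sqrt(sum_j e[g, j]^2)`. A gene expressed only
#' in cluster `k` scores 1; a gene expressed uniformly across `m` clusters
#' scores `1/sqrt(m)`; an all-zero gene scores 0. Genes are ranked by
#' descending score, ties broken by higher expression in the cluster, then
#' by gene id.
#'
#' @param profile A [cluster_profile()] with at least two clusters.
#' @param cluster Target cluster id.
#' @return Data frame with columns `gene`, `score`, `rank`, ordered by rank.
#' @export
marker_score <- function(profile, cluster) {
  stopifnot(inherits(profile, "cluster_profile"))
  if (ncol(profile$values) < 2L) {
    stop("marker scoring needs at least two clusters", call. = FALSE)
  }
  if (!cluster %in% profile_clusters(profile)) {
    stop("unknown cluster: ", cluster, call. = FALSE)
  }
  e <- profile$values
  norms <- sqrt(rowSums(e^2))
  score <- ifelse(norms > 0, e[, cluster] / norms, 0)
  ord <- order(-score, -e[, cluster], rownames(e))
  data.frame(gene = rownames(e)[ord], score = unname(score[ord]),
             rank = seq_len(nrow(e)), stringsAsFactors = FALSE)
}

#' Select top marker genes for every cluster of a profile
#'
#' @param profile A [cluster_profile()].
#' @param n_per_cluster Markers kept per cluster (a gene may serve several
#'   clusters); if larger than the gene count, all genes are taken with a
#'   warning. Default 50.
#' @param role Marker-set role (`"bg"`, `"main"`, `"sub"`).
#' @return A [marker_set()].
#' @export
select_markers <- function(profile, n_per_cluster = 50,
                           role = c("bg", "main", "sub")) {
  role <- match.arg(role)
  stopifnot(n_per_cluster >= 1)
  n_genes <- nrow(profile$values)
  if (n_per_cluster > n_genes) {
    warning("n_per_cluster (", n_per_cluster, ") exceeds gene count (",
            n_genes, "); taking all genes", call. = FALSE)
    n_per_cluster <- n_genes
  }
  parts <- lapply(profile_clusters(profile), function(cl) {
    sc <- marker_score(profile, cl)[seq_len(n_per_cluster), ]
    cbind(cluster = cl, sc, stringsAsFactors = FALSE)
  })
  marker_set(do.call(rbind, parts), role = role)
}

#' Build a reference bundle from annotated counts and a background atlas
#'
#' Runs the full reference-preparation pipeline: (1) co-embed reference and
#' background cells (user-supplied embedding, or joint PCA on standardized
#' log-normalized expression as the default); (2) jointly cluster all cells
#' on the embedding; (3) average per-cell log-normalized expression within
#' each combined cluster (Eb); (4) compute the cell-type redistribution
#' weights Wb and the corrected cell-type expression Er = Eb %*% Wb;
#' (5) refine sub-clusters within each main type and build their
#' pseudobulk profile (Er-sub); (6) score the three marker sets
#' (background clusters, main cell types, sub-clusters).
#'
#' @param ref_counts [counts_with_labels()] whose labels are the annotated
#'   main cell types.
#' @param bg_counts [counts_with_labels()] of the background atlas (labels
#'   are only used as metadata; joint clusters are recomputed).
#' @param embedding Optional joint embedding (cells x dims, row names = cell
#'   ids covering reference and background cells). When `NULL`, joint PCA
#'   with `pca_rank` components is computed.
#' @param resolution Sub-cluster refinement resolution; default 0.3.
#' @param joint_resolution Joint-clustering resolution; default 1.
#' @param markers_n Markers per cluster for all three sets; default 50.
#' @param knn_k Neighbours for the cluster graphs; default 15.
#' @param pca_rank Components of the fallback joint PCA; default 30.
#' @param scale Normalization scale factor; default 1e5.
#' @param species Species tag recorded in the bundle.
#' @param name Reference name recorded in the metadata.
#' @param seed Clustering seed, recorded in the metadata; default 7.
#' @return A [reference_bundle()].
#' @export
build_reference <- function(ref_counts, bg_counts, embedding = NULL,
                            resolution = 0.3, joint_resolution = 1,
                            markers_n = 50, knn_k = 15, pca_rank = 30,
                            scale = 1e5, species = "unknown",
                            name = "reference", seed = 7) {
  stopifnot(inherits(ref_counts, "counts_with_labels"))
  if (!inherits(bg_counts, "counts_with_labels") ||
      ncol(bg_counts$counts) == 0L) {
    stop("background counts are empty", call. = FALSE)
  }
  shared <- intersect(rownames(ref_counts$counts), rownames(bg_counts$counts))
  if (length(shared) < 2L) {
    stop("reference and background share too few genes", call. = FALSE)
  }
  ref_m <- ref_counts$counts[shared, , drop = FALSE]
  bg_m <- bg_counts$counts[shared, , drop = FALSE]
  if (length(intersect(colnames(ref_m), colnames(bg_m)))) {
    stop("reference and background cell ids overlap", call. = FALSE)
  }
  all_counts <- cbind(ref_m, bg_m)
  logn <- lognorm_cells(all_counts, scale = scale)

  embedding_source <- "user"
  if (is.null(embedding)) {
    embedding_source <- sprintf("joint_pca_%d", pca_rank)
    embedding <- pca_scores(t(logn), rank = pca_rank)
    rownames(embedding) <- colnames(all_counts)
  }
  missing <- setdiff(colnames(all_counts), rownames(embedding))
  if (length(missing)) {
    stop("embedding does not cover ", length(missing), " cell(s)",
         call. = FALSE)
  }

  part <- community_partition(
    embedding[colnames(all_counts), , drop = FALSE],
    k = knn_k, resolution = joint_resolution, seed = seed)
  combined <- stats::setNames(paste0("bgc", unname(part)), names(part))
  jc <- joint_clustering(
    combined_cluster_of = combined,
    source_of = stats::setNames(
      rep(c("reference", "background"), c(ncol(ref_m), ncol(bg_m))),
      colnames(all_counts)),
    ref_celltype_of = ref_counts$cluster_of[colnames(ref_m)])

  # Eb: mean per-cell log-normalized expression within each combined cluster
  grp <- factor(combined[colnames(all_counts)])
  eb_vals <- t(rowsum(t(logn), grp) / as.vector(table(grp)))
  eb <- cluster_profile(eb_vals, species = species)

  wb <- compute_weight_matrix(jc)
  er <- correct_reference_expression(eb, wb)

  sub_of <- refine_subclusters(
    counts_with_labels(ref_m, ref_counts$cluster_of[colnames(ref_m)]),
    embedding, resolution = resolution, knn_k = knn_k, seed = seed)
  ersub <- aggregate_and_normalize(
    counts_with_labels(ref_m, sub_of), scale = scale, species = species)
  sub_to_main <- stats::setNames(
    sub("::[^:]*$", "", profile_clusters(ersub)), profile_clusters(ersub))

  main_profile <- aggregate_and_normalize(
    counts_with_labels(ref_m, ref_counts$cluster_of[colnames(ref_m)]),
    scale = scale, species = species)

  markers_bg <- select_markers(eb, markers_n, role = "bg")
  markers_main <- select_markers(main_profile, markers_n, role = "main")
  markers_sub <- if (ncol(ersub$values) >= 2L) {
    select_markers(ersub, markers_n, role = "sub")
  } else {
    # degenerate: a single sub-cluster has no contrast; reuse main markers
    marker_set(transform(as.data.frame(markers_main),
                         cluster = profile_clusters(ersub)[1]), role = "sub")
  }

  reference_bundle(
    er = er, ersub = ersub, sub_to_main = sub_to_main,
    markers_main = markers_main, markers_sub = markers_sub,
    background = eb, markers_bg = markers_bg,
    meta = list(name = name, species = species, markers_n = markers_n,
                resolution = resolution, joint_resolution = joint_resolution,
                knn_k = knn_k, seed = seed, scale = scale,
                embedding = embedding_source,
                n_ref_cells = ncol(ref_m), n_bg_cells = ncol(bg_m),
                built = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}
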