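## The three-stage annotation algorithm. Module 1 calibrates a correlation
## cutoff against the background atlas and screens out query clusters that
## match nothing in the reference. Module 2 matches the survivors to
## reference sub-clusters under a second adaptive cutoff. Module 3 breaks
## ties between sub-clusters of different cell types with one-sided
## Wilcoxon rank-sum tests on their marker genes.

#' Pearson correlations between two profiles on a marker gene set
#'
#' Restricts both profiles to the shared marker genes and returns the
#' cluster-by-cluster Pearson correlation matrix of the log-normalized
#' expression vectors. A zero-variance vector yields correlation 0 (with a
#' warning) rather than NA.
#'
#' @param a,b [cluster_profile()] objects.
#' @param genes Character vector of marker genes to correlate on.
#' @param min_genes Minimum shared markers required; fewer raises an error
#'   of class `clustann_overlap_error` (usually a species or reference
#'   mismatch). Default 30.
#' @return Numeric matrix, `a`'s clusters in rows, `b`'s in columns.
#' @export
correlation_matrix <- function(a, b, genes, min_genes = 30) {
  genes <- unique(genes)
  shared <- intersect(genes, intersect(profile_genes(a), profile_genes(b)))
  if (length(shared) < min_genes) {
    stop(structure(class = c("clustann_overlap_error", "error", "condition"),
                   list(message = sprintf(
                     paste0("only %d marker gene(s) shared between profiles ",
                            "(minimum %d); check species and gene ",
                            "harmonization"),
                     length(shared), min_genes), call = NULL)))
  }
  x <- a$values[shared, , drop = FALSE]
  y <- b$values[shared, , drop = FALSE]
  sdx <- apply(x, 2, stats::sd); sdy <- apply(y, 2, stats::sd)
  if (any(sdx == 0) || any(sdy == 0)) {
    warning("zero-variance expression vector(s); correlations set to 0",
            call. = FALSE)
  }
  cc <- suppressWarnings(stats::cor(x, y))
  cc[!is.finite(cc)] <- 0
  cc
}

#' Module 1: background-calibrated screening
#'
#' Pools the correlations between every query cluster and every background
#' cluster (on background markers), derives the adaptive cutoff from their
#' mixture decomposition, then tests each query cluster's best correlation
#' with the corrected reference cell types (same marker set) against that
#' cutoff. Clusters whose correlations with all reference cell types fall
#' below the cutoff are finalized as unassigned.
#'
#' @param eq Query [cluster_profile()].
#' @param bundle A [reference_bundle()].
#' @param clamp_lo,clamp_hi Cutoff clamp range; defaults 0.4 / 0.6.
#' @param min_genes Minimum shared marker genes; default 30.
#' @param min_fit_n Minimum pooled coefficients for the mixture fit;
#'   default 50.
#' @return List with `cutoff` (a `cutoff_result`), `fit`, `best_corr`
#'   (named per query cluster), `pass` (named logical), and the full
#'   query-vs-reference correlation matrix `corr_er`.
#' @export
module1_screen <- function(eq, bundle, clamp_lo = 0.4, clamp_hi = 0.6,
                           min_genes = 30, min_fit_n = 50) {
  bg_genes <- marker_genes(bundle$markers_bg)
  corr_bg <- correlation_matrix(eq, bundle$background, bg_genes, min_genes)
  est <- estimate_cutoff(as.vector(corr_bg), clamp_lo, clamp_hi,
                         min_n = min_fit_n)
  corr_er <- correlation_matrix(eq, bundle$er, bg_genes, min_genes)
  best <- apply(corr_er, 1, max)
  list(cutoff = est$cutoff, fit = est$fit, best_corr = best,
       pass = best >= est$cutoff$cutoff, corr_er = corr_er,
       corr_bg = corr_bg)
}

#' Module 2: sub-cluster assignment
#'
#' Correlates query clusters with reference sub-clusters on main-cell-type
#' markers, derives a second adaptive cutoff from the pooled coefficients,
#' and disposes of each screened-in query cluster: no sub-cluster above the
#' cutoff means unassigned; exactly one above (or several, all of one cell
#' type) assigns that cell type; several above from different cell types
#' forwards the top three sub-clusters to module 3.
#'
#' @inheritParams module1_screen
#' @param passing Character vector of query clusters that survived module 1.
#' @return List with `cutoff`, `fit`, `corr_sub` (full matrix),
#'   `best_corr`, and `disposition`: a named list per passing cluster with
#'   elements `action` (`"unassigned"`, `"assigned"`, `"module3"`),
#'   `cell_type`, `sub_cluster`, and `candidates` (data frame of the top
#'   sub-clusters for module 3).
#' @export
module2_assign <- function(eq, bundle, passing, clamp_lo = 0.4,
                           clamp_hi = 0.6, min_genes = 30, min_fit_n = 50) {
  main_genes <- marker_genes(bundle$markers_main)
  corr_sub <- correlation_matrix(eq, bundle$ersub, main_genes, min_genes)
  est <- estimate_cutoff(as.vector(corr_sub), clamp_lo, clamp_hi,
                         min_n = min_fit_n)
  cutoff <- est$cutoff$cutoff
  disposition <- list()
  for (q in passing) {
    cc <- corr_sub[q, ]
    above <- names(cc)[cc >= cutoff]
    if (length(above) == 0L) {
      disposition[[q]] <- list(action = "unassigned")
      next
    }
    # descending correlation, ties by sub-cluster id
    above <- above[order(-cc[above], above)]
    mains <- unique(unname(bundle$sub_to_main[above]))
    if (length(above) == 1L || length(mains) == 1L) {
      disposition[[q]] <- list(action = "assigned",
                               cell_type = mains[1],
                               sub_cluster = above[1])
    } else {
      top <- utils::head(above, 3L)
      disposition[[q]] <- list(
        action = "module3",
        candidates = data.frame(sub_cluster = top,
                                correlation = unname(cc[top]),
                                stringsAsFactors = FALSE))
    }
  }
  list(cutoff = est$cutoff, fit = est$fit, corr_sub = corr_sub,
       best_corr = apply(corr_sub, 1, max), disposition = disposition)
}

#' One-sided Wilcoxon rank-sum p-value
#'
#' Tests whether `x` tends to be greater than `y`. When both groups have at
#' most `exact_max` values the p-value is computed by exact enumeration of
#' all rank assignments (valid under ties); otherwise by the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Group-size limit for exact enumeration; default 10.
#' @return P-value for the alternative "x stochastically greater than y".
#' @export
rank_sum_p_greater <- function(x, y, exact_max = 10) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) return(1)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    cmb <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(r[cmb], nrow = nx)) - nx * (nx + 1) / 2
    mean(us >= u - 1e-9)
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    ties <- table(r)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    z <- (u - mu - 0.5) / sqrt(sig2)
    stats::pnorm(z, lower.tail = FALSE)
  }
}

#' Module 3: rank-test disambiguation between candidate sub-clusters
#'
#' For every ordered pair of candidates (A, B), tests whether the query
#' cluster expresses A's sub-cluster markers higher than B's with a
#' one-sided rank-sum test (markers shared by both candidates are excluded
#' from that comparison). Each candidate is scored by the sum of
#' `-log10(p)` over its own pairwise tests; the highest score wins, ties
#' broken by module-2 correlation.
#'
#' @param eq_column Named numeric vector: the query cluster's expression.
#' @param candidates Data frame with columns `sub_cluster`, `correlation`.
#' @param markers_sub The bundle's sub-cluster [marker_set()].
#' @param min_markers Candidates with fewer usable markers in the query
#'   gene set are dropped; if fewer than two remain, the
#'   highest-correlation candidate wins with a warning. Default 5.
#' @return List with `winner` (sub-cluster id), `scores` (named numeric),
#'   and `pvalues` (data frame of pairwise tests), or `pvalues = NULL` if
#'   the fallback was taken.
#' @export
module3_resolve <- function(eq_column, candidates, markers_sub,
                            min_markers = 5) {
  stopifnot(nrow(candidates) >= 2L)
  marker_lists <- lapply(candidates$sub_cluster, function(s) {
    intersect(unique(markers_sub$gene[markers_sub$cluster == s]),
              names(eq_column))
  })
  names(marker_lists) <- candidates$sub_cluster
  usable <- vapply(marker_lists, length, integer(1)) >= min_markers
  if (sum(usable) < 2L) {
    warning("fewer than two candidates with enough usable markers; ",
            "falling back to the highest-correlation candidate",
            call. = FALSE)
    best <- candidates$sub_cluster[which.max(candidates$correlation)]
    return(list(winner = best, scores = NULL, pvalues = NULL))
  }
  cand <- candidates[usable, , drop = FALSE]
  marker_lists <- marker_lists[cand$sub_cluster]
  scores <- stats::setNames(numeric(nrow(cand)), cand$sub_cluster)
  pv <- list()
  for (a in cand$sub_cluster) {
    for (b in cand$sub_cluster) {
      if (a == b) next
      ga <- setdiff(marker_lists[[a]], marker_lists[[b]])
      gb <- setdiff(marker_lists[[b]], marker_lists[[a]])
      p <- rank_sum_p_greater(eq_column[ga], eq_column[gb])
      scores[a] <- scores[a] + (-log10(max(p, .Machine$double.xmin)))
      pv[[length(pv) + 1L]] <- data.frame(greater = a, lesser = b, p = p,
                                          stringsAsFactors = FALSE)
    }
  }
  # winner: max aggregate significance, ties by module-2 correlation
  ord <- order(-scores, -cand$correlation[match(names(scores),
                                                cand$sub_cluster)])
  list(winner = names(scores)[ord[1]], scores = scores,
       pvalues = do.call(rbind, pv))
}

#' Annotate query clusters against a reference bundle
#'
#' Runs the full prediction pipeline: species harmonization (when query and
#' reference species differ and an ortholog map is supplied), module 1
#' screening, module 2 sub-cluster assignment, and module 3 rank-test
#' disambiguation. Returns exactly one record per query cluster.
#'
#' @param query Query [cluster_profile()] of average log-normalized
#'   expression per cluster.
#' @param bundle A [reference_bundle()].
#' @param ortholog Optional [ortholog_map()] for cross-species queries.
#' @param clamp_lo,clamp_hi Cutoff clamp range; defaults 0.4 / 0.6.
#' @param min_genes Minimum shared marker genes for correlations;
#'   default 30.
#' @param min_fit_n Minimum pooled coefficients for a mixture fit;
#'   default 50.
#' @param min_markers3 Minimum usable markers per module-3 candidate;
#'   default 5.
#' @param min_mapped_genes Minimum genes that must survive ortholog
#'   mapping for cross-species queries; default 100.
#' @return Data frame with columns `query_cluster`, `status`
#'   (`"assigned"`/`"unassigned"`), `predicted_cell_type`,
#'   `predicted_subcluster`, `best_corr_m1`, `best_corr_m2`, `cutoff_m1`,
#'   `cutoff_m2`, `decided_by`; module-3 pairwise p-values are attached as
#'   the `candidate_pvalues` attribute (a named list).
#' @export
annotate_clusters <- function(query, bundle, ortholog = NULL,
                              clamp_lo = 0.4, clamp_hi = 0.6,
                              min_genes = 30, min_fit_n = 50,
                              min_markers3 = 5, min_mapped_genes = 100) {
  stopifnot(inherits(query, "cluster_profile"),
            inherits(bundle, "reference_bundle"))
  if (clamp_lo > clamp_hi) stop("clamp_lo must be <= clamp_hi", call. = FALSE)
  ref_species <- bundle$er$species
  if (query$species != "unknown" && ref_species != "unknown" &&
      query$species != ref_species) {
    if (is.null(ortholog)) {
      stop("query species (", query$species, ") differs from reference (",
           ref_species, "); supply an ortholog map", call. = FALSE)
    }
    query <- map_orthologs(query, ortholog, ref_species,
                           min_genes = min_mapped_genes)
  }

  m1 <- module1_screen(query, bundle, clamp_lo, clamp_hi, min_genes,
                       min_fit_n)
  passing <- names(m1$pass)[m1$pass]
  m2 <- module2_assign(query, bundle, passing, clamp_lo, clamp_hi,
                       min_genes, min_fit_n)

  qids <- profile_clusters(query)
  n <- length(qids)
  rec <- data.frame(
    query_cluster = qids,
    status = rep("unassigned", n),
    predicted_cell_type = "",
    predicted_subcluster = "",
    best_corr_m1 = unname(m1$best_corr[qids]),
    best_corr_m2 = unname(m2$best_corr[qids]),
    cutoff_m1 = m1$cutoff$cutoff,
    cutoff_m2 = m2$cutoff$cutoff,
    decided_by = rep("module1", n),
    stringsAsFactors = FALSE)
  pvals <- stats::setNames(vector("list", n), qids)

  for (i in seq_len(n)) {
    q <- qids[i]
    if (!m1$pass[q]) next
    disp <- m2$disposition[[q]]
    if (disp$action == "unassigned") {
      rec$decided_by[i] <- "module2"
    } else if (disp$action == "assigned") {
      rec$status[i] <- "assigned"
      rec$predicted_cell_type[i] <- disp$cell_type
      rec$predicted_subcluster[i] <- disp$sub_cluster
      rec$decided_by[i] <- "module2"
    } else {
      res <- module3_resolve(query$values[, q], disp$candidates,
                             bundle$markers_sub, min_markers = min_markers3)
      rec$status[i] <- "assigned"
      rec$predicted_cell_type[i] <- unname(bundle$sub_to_main[res$winner])
      rec$predicted_subcluster[i] <- res$winner
      # the fallback path resolves by module-2 correlation, not by the tests
      rec$decided_by[i] <- if (is.null(res$pvalues)) "module2" else "module3"
      pvals[[q]] <- res$pvalues
    }
  }
  attr(rec, "candidate_pvalues") <- pvals
  attr(rec, "cutoff_m1") <- m1$cutoff
  attr(rec, "cutoff_m2") <- m2$cutoff
  rec
}
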