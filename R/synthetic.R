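## Self-contained synthetic data with known ground truth. Counts follow a
## negative-binomial model with log-normal gene means and fold-elevated
## marker genes per cell type; query/reference pairs realize the four
## overlap scenarios (equal, query-subset, reference-subset, disjoint)
## with an independent multi-type background and a platform effect on the
## query pseudobulk.

#' Recipe for a synthetic benchmark scenario
#'
#' @param n_types Cell types in the base set; default 5.
#' @param markers_per_type Dedicated marker genes per type; default 40.
#' @param n_genes Total genes; must accommodate disjoint marker blocks for
#'   all simulated types (3x `n_types` in [make_pair()]); default 2000.
#' @param cells_per_type Cells simulated per type; default 50.
#' @param marker_fold Fold elevation of a type's markers; default 8.
#' @param type_effect_sdlog SD (log scale) of the per-gene, per-type
#'   biological effect that differentiates cell types transcriptome-wide
#'   beyond their dedicated markers; 0 disables it. Default 1.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed); default 4.
#' @param platform_noise_sd SD of the Gaussian platform effect added to the
#'   query pseudobulk on the log scale; default 0.2.
#' @param scenario Overlap scenario 1-4; default 1.
#' @param seed RNG seed; default 1.
#' @return An object of class `scenario_spec` (a list).
#' @export
scenario_spec <- function(n_types = 5, markers_per_type = 40, n_genes = 2000,
                          cells_per_type = 50, marker_fold = 8,
                          type_effect_sdlog = 1, dispersion = 4,
                          platform_noise_sd = 0.2, scenario = 1, seed = 1) {
  stopifnot(n_types >= 1, markers_per_type >= 1, n_genes >= 1,
            cells_per_type >= 1, marker_fold >= 1, dispersion > 0,
            type_effect_sdlog >= 0, platform_noise_sd >= 0,
            scenario %in% 1:4)
  if (n_genes < n_types * markers_per_type) {
    stop("n_genes must be at least n_types * markers_per_type", call. = FALSE)
  }
  structure(list(n_types = n_types, markers_per_type = markers_per_type,
                 n_genes = n_genes, cells_per_type = cells_per_type,
                 marker_fold = marker_fold,
                 type_effect_sdlog = type_effect_sdlog,
                 dispersion = dispersion,
                 platform_noise_sd = platform_noise_sd,
                 scenario = as.integer(scenario), seed = as.integer(seed)),
            class = "scenario_spec")
}

# Gene means and disjoint marker blocks for n_total types. Drawn from the
# current RNG state so callers control the seed.
make_world <- function(spec, n_total) {
  if (spec$n_genes < n_total * spec$markers_per_type) {
    stop("n_genes too small for ", n_total, " types with ",
         spec$markers_per_type, " markers each", call. = FALSE)
  }
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  mu <- stats::rlnorm(spec$n_genes, meanlog = 0, sdlog = 1)
  picked <- sample.int(spec$n_genes, n_total * spec$markers_per_type)
  markers <- split(picked, rep(seq_len(n_total), each = spec$markers_per_type))
  names(markers) <- sprintf("T%02d", seq_len(n_total))
  # per-(gene, type) biological effect: cell types diverge transcriptome-wide,
  # not only at their dedicated markers
  type_effect <- matrix(stats::rlnorm(spec$n_genes * n_total, 0,
                                      spec$type_effect_sdlog),
                        nrow = spec$n_genes,
                        dimnames = list(genes, names(markers)))
  list(genes = genes, mu = mu, markers = markers,
       type_effect = type_effect, types = names(markers))
}

# Negative-binomial cells for the given types under a world.
sim_cells <- function(world, spec, types, prefix) {
  n_cells <- length(types) * spec$cells_per_type
  counts <- matrix(0L, nrow = spec$n_genes, ncol = n_cells,
                   dimnames = list(world$genes,
                                   sprintf("%s%04d", prefix,
                                           seq_len(n_cells))))
  labels <- character(n_cells)
  j <- 0L
  for (t in types) {
    m <- world$mu * world$type_effect[, t]
    m[world$markers[[t]]] <- m[world$markers[[t]]] * spec$marker_fold
    for (i in seq_len(spec$cells_per_type)) {
      j <- j + 1L
      counts[, j] <- stats::rnbinom(spec$n_genes, mu = m,
                                    size = spec$dispersion)
      labels[j] <- t
    }
  }
  counts_with_labels(counts, stats::setNames(labels, colnames(counts)))
}

#' Simulate labeled single-cell counts
#'
#' Each cell of type `t` draws gene counts from a negative binomial whose
#' mean is the gene's log-normal baseline times the type's per-gene
#' biological effect, multiplied by `marker_fold` for the type's dedicated
#' marker genes. Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [scenario_spec()].
#' @return List with `data` (a [counts_with_labels()] whose labels are the
#'   true types) and `truth` (named vector: cluster id -> true type;
#'   clusters coincide with types here).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  world <- make_world(spec, spec$n_types)
  data <- sim_cells(world, spec, world$types, prefix = "cell")
  list(data = data,
       truth = stats::setNames(world$types, world$types),
       world = world)
}

#' Simulate a query/reference/background triple for one scenario
#'
#' The base types play the query; the reference's types are chosen by the
#' scenario (equal, superset, subset, or disjoint); the background is an
#' independent simulation of all base types plus `2 * n_types` additional
#' types, mimicking a broad atlas that contains both matching and
#' unrelated cell types. The query is a pseudobulk profile with i.i.d.
#' Gaussian platform noise added on the log scale.
#'
#' @param spec A [scenario_spec()] with `scenario` set.
#' @return List with `query` (a [cluster_profile()], clusters `q01`, ...),
#'   `truth` (query cluster -> true type), `ref_counts` and `bg_counts`
#'   ([counts_with_labels()]), `types_query`, `types_ref`.
#' @export
make_pair <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n <- spec$n_types
  world <- make_world(spec, 3L * n)
  base <- world$types[seq_len(n)]
  extra <- world$types[(n + 1L):(3L * n)]
  sub <- base[seq_len(max(1L, n - 2L))]
  sets <- switch(spec$scenario,
                 list(q = base, r = base),
                 list(q = sub, r = base),
                 list(q = base, r = sub),
                 list(q = base, r = extra[seq_len(n)]))

  ref_counts <- sim_cells(world, spec, sets$r, prefix = "ref")
  bg_counts <- sim_cells(world, spec, world$types, prefix = "bg")

  q_cells <- sim_cells(world, spec, sets$q, prefix = "qc")
  q_profile <- aggregate_and_normalize(q_cells)
  qids <- sprintf("q%02d", seq_along(sets$q))
  truth <- stats::setNames(profile_clusters(q_profile), qids)
  v <- q_profile$values
  v <- pmax(v + matrix(stats::rnorm(length(v), 0, spec$platform_noise_sd),
                       nrow(v)), 0)
  colnames(v) <- qids
  list(query = cluster_profile(v),
       truth = truth,
       ref_counts = ref_counts, bg_counts = bg_counts,
       types_query = sets$q, types_ref = sets$r, spec = spec)
}

#' Run one synthetic scenario end to end
#'
#' Builds the reference bundle from the pair's reference and background
#' counts, annotates the query, and evaluates the outcomes against the
#' generator's ground truth.
#'
#' @param spec A [scenario_spec()].
#' @param ... Passed to [build_reference()] (e.g. `markers_n`).
#' @return List with `pair`, `bundle`, `predictions`, `outcomes` (data
#'   frame), and `summary` (from [summarize_outcomes()]).
#' @export
run_scenario <- function(spec, ...) {
  pair <- make_pair(spec)
  bundle <- build_reference(pair$ref_counts, pair$bg_counts, ...)
  pred <- annotate_clusters(pair$query, bundle)
  outcomes <- evaluate_predictions(pred, pair$truth,
                                   ref_types = pair$types_ref)
  list(pair = pair, bundle = bundle, predictions = pred,
       outcomes = outcomes, summary = summarize_outcomes(outcomes$outcome))
}
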