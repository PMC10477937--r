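# Fixtures are built in code; nothing is read from disk except what a test
# itself writes to a tempdir.

# Deterministic genes x clusters matrix: flat baseline with an elevated
# block per cluster plus a tiny deterministic jitter (avoids zero variance
# and exact ties without randomness).
block_matrix <- function(n_genes, clusters, blocks, base = 1, high = 6) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  v <- matrix(base, n_genes, length(clusters),
              dimnames = list(genes, clusters))
  for (j in seq_along(clusters)) v[blocks[[j]], j] <- high
  v + outer(seq_len(n_genes), seq_along(clusters)) * 1e-4
}

# Hand-built bundle: 3 cell types (A, B, C; A split in two sub-clusters)
# against a 6-cluster background whose first three clusters resemble the
# cell types. 60 genes, 10-gene marker blocks.
tiny_bundle <- function() {
  blocks6 <- split(1:60, rep(1:6, each = 10))
  bg <- cluster_profile(block_matrix(60, paste0("b", 1:6), blocks6))
  er <- cluster_profile(block_matrix(60, c("A", "B", "C"), blocks6[1:3]))
  ersub_vals <- block_matrix(60, c("A::1", "A::2", "B::1", "C::1"),
                             list(1:10, 1:10, 11:20, 21:30))
  ersub_vals[6:10, "A::2"] <- 9  # second half of A's block marks A::2
  ersub <- cluster_profile(ersub_vals)
  reference_bundle(
    er = er, ersub = ersub,
    sub_to_main = c("A::1" = "A", "A::2" = "A", "B::1" = "B", "C::1" = "C"),
    markers_main = select_markers(er, 10, "main"),
    markers_sub = select_markers(ersub, 10, "sub"),
    background = bg,
    markers_bg = select_markers(bg, 10, "bg"),
    meta = list(name = "tiny"))
}

# Query profile matching the bundle's cell types exactly (columns = er).
tiny_query <- function(bundle = tiny_bundle()) {
  v <- bundle$er$values
  colnames(v) <- paste0("q", colnames(v))
  cluster_profile(v)
}

small_spec <- function(scenario = 1, seed = 1) {
  scenario_spec(n_types = 3, markers_per_type = 15, n_genes = 600,
                cells_per_type = 30, scenario = scenario, seed = seed)
}

# mixture_fit built by hand for closed-form cutoff checks
manual_fit <- function(means, sds, weights = rep(1 / length(means),
                                                 length(means))) {
  structure(list(k = length(means), weights = weights, means = means,
                 sds = sds, loglik = NA_real_, criterion = NA_real_,
                 n = 1000L),
            class = "mixture_fit")
}
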