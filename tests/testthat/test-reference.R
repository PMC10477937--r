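make_jc <- function(cluster_of, celltype_of) {
  cells <- names(celltype_of)
  joint_clustering(cluster_of,
                   setNames(ifelse(names(cluster_of) %in% cells,
                                   "reference", "background"),
                            names(cluster_of)),
                   celltype_of)
}

test_that("weight matrix matches hand counts and is column-stochastic", {
  cells <- sprintf("cell%02d", 1:10)
  jc <- make_jc(setNames(c(rep("A", 7), rep("B", 3)), cells),
                setNames(rep("T", 10), cells))
  wb <- compute_weight_matrix(jc)
  expect_equal(unname(wb[, "T"]), c(0.7, 0.3))
  # a type entirely in one cluster is one-hot
  jc2 <- make_jc(setNames(rep("A", 5), cells[1:5]),
                 setNames(rep("T", 5), cells[1:5]))
  expect_equal(unname(compute_weight_matrix(jc2)[, "T"]), 1)
})

test_that("weight matrix equals a brute-force tally on random assignments", {
  set.seed(31)
  cells <- sprintf("cell%03d", 1:200)
  cl <- setNames(sample(paste0("c", 1:6), 200, replace = TRUE), cells)
  ct <- setNames(sample(paste0("T", 1:4), 200, replace = TRUE), cells)
  wb <- compute_weight_matrix(make_jc(cl, ct))
  for (t in paste0("T", 1:4)) {
    members <- cells[ct == t]
    for (c in rownames(wb)) {
      expect_equal(wb[c, t], sum(cl[members] == c) / length(members))
    }
  }
  expect_equal(unname(colSums(wb)), rep(1, 4), tolerance = 1e-9)
})

test_that("expression correction is the Eb x Wb product", {
  set.seed(32)
  eb_vals <- matrix(runif(50 * 8, 0, 5), 50, 8,
                    dimnames = list(sprintf("g%02d", 1:50), paste0("c", 1:8)))
  eb <- cluster_profile(eb_vals)
  # one-hot weights reproduce background columns bit-exactly
  wb1 <- diag(8)[, 1:3]
  dimnames(wb1) <- list(paste0("c", 1:8), paste0("T", 1:3))
  er1 <- correct_reference_expression(eb, wb1)
  expect_identical(unname(er1$values[, "T2"]), unname(eb_vals[, "c2"]))
  # a 50/50 column is the plain average
  wb2 <- matrix(0, 8, 1, dimnames = list(paste0("c", 1:8), "T"))
  wb2[c("c1", "c2"), 1] <- 0.5
  er2 <- correct_reference_expression(eb, wb2)
  expect_equal(unname(er2$values[, "T"]),
               unname((eb_vals[, "c1"] + eb_vals[, "c2"]) / 2))
  # random weights match a naive triple loop
  wb3 <- matrix(runif(8 * 3), 8, 3,
                dimnames = list(paste0("c", 1:8), paste0("T", 1:3)))
  wb3 <- sweep(wb3, 2, colSums(wb3), "/")
  er3 <- correct_reference_expression(eb, wb3)
  naive <- matrix(0, 50, 3)
  for (g in 1:50) for (t in 1:3) {
    for (c in 1:8) naive[g, t] <- naive[g, t] + eb_vals[g, c] * wb3[c, t]
  }
  expect_equal(unname(er3$values), naive, tolerance = 1e-10)
  # mismatched ids are reported
  rownames(wb3) <- paste0("x", 1:8)
  expect_error(correct_reference_expression(eb, wb3), "do not match")
})

test_that("marker scores are the one-hot cosine with documented ties", {
  v <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("c", 1:4)))
  v["g1", "c1"] <- 3          # exclusive to c1
  v["g2", ] <- 2              # uniform across 4 clusters
  v["g4", c("c1", "c2")] <- 1 # shared by two
  sc <- marker_score(cluster_profile(v), "c1")
  s <- setNames(sc$score, sc$gene)
  expect_equal(unname(s["g1"]), 1)
  expect_equal(unname(s["g2"]), 0.5)       # 1/sqrt(4)
  expect_equal(unname(s["g3"]), 0)         # all-zero gene, never NaN
  expect_equal(unname(s["g4"]), 1 / sqrt(2))
  expect_identical(sc$gene[1:2], c("g1", "g4"))
})

test_that("marker ranking matches a brute-force cosine oracle", {
  set.seed(33)
  v <- matrix(rexp(100 * 5), 100, 5,
              dimnames = list(sprintf("g%03d", 1:100), paste0("c", 1:5)))
  p <- cluster_profile(v)
  for (cl in c("c1", "c4")) {
    sc <- marker_score(p, cl)
    oracle <- vapply(rownames(v), function(g) {
      e <- v[g, ]
      onehot <- as.numeric(colnames(v) == cl)
      sum(e * onehot) / (sqrt(sum(e^2)) * sqrt(sum(onehot^2)))
    }, numeric(1))
    expect_equal(setNames(sc$score, sc$gene), oracle[sc$gene],
                 tolerance = 1e-12)
    expect_identical(sc$gene, names(sort(-oracle, method = "radix"))[1:100])
  }
  # scale invariance: scaling a gene's row leaves its scores unchanged
  v2 <- v; v2["g005", ] <- v2["g005", ] * 17
  expect_equal(marker_score(cluster_profile(v2), "c2")$score[
                 match("g005", marker_score(cluster_profile(v2), "c2")$gene)],
               marker_score(p, "c2")$score[
                 match("g005", marker_score(p, "c2")$gene)])
})

test_that("marker selection keeps top-n per cluster", {
  v <- block_matrix(10, c("a", "b"), list(1:3, 4:6))
  ms <- select_markers(cluster_profile(v), 3, role = "main")
  expect_identical(nrow(ms), 6L)
  expect_true(all(ms$gene %in% rownames(v)))
  ms1 <- select_markers(cluster_profile(v), 1, role = "main")
  expect_in(ms1$gene[ms1$cluster == "a"], c("g001", "g002", "g003"))
  expect_in(ms1$gene[ms1$cluster == "b"], c("g004", "g005", "g006"))
  expect_warning(select_markers(cluster_profile(v), 99, role = "main"),
                 "taking all")
})

test_that("sub-cluster refinement recovers well-separated blobs", {
  set.seed(34)
  n <- 60
  emb <- rbind(matrix(rnorm(n * 2, 0, 1), n, 2),
               matrix(rnorm(n * 2, 10, 1), n, 2))
  rownames(emb) <- sprintf("cell%03d", 1:(2 * n))
  counts <- matrix(rpois(20 * 2 * n, 3), 20, 2 * n,
                   dimnames = list(sprintf("g%02d", 1:20), rownames(emb)))
  cwl <- counts_with_labels(counts, setNames(rep("T", 2 * n), rownames(emb)))
  sub <- refine_subclusters(cwl, emb, resolution = 0.3)
  expect_identical(sort(unique(sub)), c("T::1", "T::2"))
  truth <- rep(c(1, 2), each = n)
  agree <- max(mean((sub == "T::1") == (truth == 1)),
               mean((sub == "T::1") == (truth == 2)))
  expect_gte(agree, 0.99)
  # tiny types are never split
  small <- counts_with_labels(counts[, 1:5],
                              setNames(rep("S", 5), colnames(counts)[1:5]))
  expect_warning(s5 <- refine_subclusters(small, emb), "one sub-cluster")
  expect_identical(unique(unname(s5)), "S::1")
  # resolution 0 collapses each type to a single sub-cluster
  s0 <- refine_subclusters(cwl, emb, resolution = 0)
  expect_identical(unique(unname(s0)), "T::1")
})

test_that("build_reference produces a consistent bundle on synthetic data", {
  pair <- make_pair(small_spec(seed = 5))
  bundle <- build_reference(pair$ref_counts, pair$bg_counts, markers_n = 30)
  expect_s3_class(bundle, "reference_bundle")
  expect_setequal(profile_clusters(bundle$er), pair$types_ref)
  expect_true(all(bundle$sub_to_main %in% pair$types_ref))
  # corrected expression tracks naive per-type averages of the reference
  logn <- log1p(sweep(pair$ref_counts$counts, 2,
                      colSums(pair$ref_counts$counts), "/") * 1e5)
  for (t in pair$types_ref) {
    naive <- rowMeans(logn[, pair$ref_counts$cluster_of == t, drop = FALSE])
    expect_gt(cor(bundle$er$values[, t], naive), 0.99)
  }
  expect_error(build_reference(pair$ref_counts, NULL), "empty")
})
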