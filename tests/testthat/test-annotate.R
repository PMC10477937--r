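test_that("marker-restricted correlations behave like Pearson should", {
  b <- tiny_bundle()
  own <- marker_genes(b$markers_main)
  self <- correlation_matrix(b$er, b$er, own, min_genes = 10)
  expect_equal(unname(diag(self)), rep(1, 3))
  # affine transforms of a profile leave correlations at 1
  shifted <- cluster_profile(2 * b$er$values + 1)
  expect_equal(unname(diag(correlation_matrix(shifted, b$er, own,
                                              min_genes = 10))),
               rep(1, 3))
  # matches the textbook covariance formula on a random pair
  set.seed(41)
  x <- runif(40); y <- runif(40)
  g <- sprintf("g%02d", 1:40)
  pa <- cluster_profile(matrix(x, 40, 1, dimnames = list(g, "a")))
  pb <- cluster_profile(matrix(y, 40, 1, dimnames = list(g, "b")))
  cc <- correlation_matrix(pa, pb, g, min_genes = 30)[1, 1]
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cc, oracle, tolerance = 1e-12)
})

test_that("insufficient marker overlap and zero variance are handled", {
  b <- tiny_bundle()
  expect_error(correlation_matrix(b$er, b$er, paste0("nope", 1:40)),
               class = "clustann_overlap_error")
  flat <- b$er$values
  flat[, "A"] <- 2  # zero variance
  expect_warning(
    cc <- correlation_matrix(cluster_profile(flat), b$er,
                             marker_genes(b$markers_main), min_genes = 10),
    "zero-variance")
  expect_equal(unname(cc["A", ]), rep(0, 3))
})

test_that("module 1 screens out clusters unrelated to the reference", {
  b <- tiny_bundle()
  q <- tiny_query(b)
  # add a noise cluster correlated with nothing
  set.seed(42)
  noise <- matrix(rexp(60, 1), 60, 1,
                  dimnames = list(profile_genes(q), "qNoise"))
  q2 <- cluster_profile(cbind(q$values, noise))
  m1 <- module1_screen(q2, b, min_genes = 10)
  expect_true(all(m1$pass[c("qA", "qB", "qC")]))
  expect_false(m1$pass["qNoise"])
  expect_gte(m1$cutoff$cutoff, m1$cutoff$clamp_lo)
  expect_lte(m1$cutoff$cutoff, m1$cutoff$clamp_hi)
})

test_that("module 2 assigns directly when candidates agree on one type", {
  b <- tiny_bundle()
  q <- tiny_query(b)
  m2 <- module2_assign(q, b, profile_clusters(q), min_genes = 10)
  # qA correlates with both A::1 and A::2 -> same main type, no module 3
  expect_identical(m2$disposition[["qA"]]$action, "assigned")
  expect_identical(m2$disposition[["qA"]]$cell_type, "A")
  expect_identical(m2$disposition[["qB"]]$action, "assigned")
  expect_identical(m2$disposition[["qB"]]$cell_type, "B")
})

test_that("candidate sets cap at the top three sub-clusters", {
  # one main type per sub-cluster, five sub-clusters above the cutoff
  blocks <- split(1:50, rep(1:5, each = 10))
  ersub <- cluster_profile(block_matrix(60, paste0(LETTERS[1:5], "::1"),
                                        blocks))
  er <- cluster_profile(block_matrix(60, LETTERS[1:5], blocks))
  bg <- cluster_profile(block_matrix(60, paste0("b", 1:6),
                                     split(1:60, rep(1:6, each = 10))))
  b5 <- reference_bundle(
    er, ersub, setNames(LETTERS[1:5], paste0(LETTERS[1:5], "::1")),
    select_markers(er, 10, "main"), select_markers(ersub, 10, "sub"),
    bg, select_markers(bg, 10, "bg"))
  # a query equally similar to all five types
  v <- matrix(4, 60, 1, dimnames = list(profile_genes(er), "q1"))
  v[1:50, 1] <- 5 + seq_len(50) * 1e-3
  q <- cluster_profile(v)
  m2 <- module2_assign(q, b5, "q1", min_genes = 10)
  disp <- m2$disposition[["q1"]]
  if (disp$action == "module3") {
    expect_lte(nrow(disp$candidates), 3L)
    expect_true(all(diff(disp$candidates$correlation) <= 0))
  } else {
    succeed()  # cutoff excluded all but one type; cap not exercised
  }
})

test_that("rank-sum p-values match exact enumeration and wilcox.test", {
  # tie-free 4 vs 4: exact enumeration equals wilcox.test's exact p
  x <- c(5.1, 4.7, 6.2, 5.9); y <- c(1.2, 2.4, 0.7, 3.3)
  expect_equal(rank_sum_p_greater(x, y),
               wilcox.test(x, y, alternative = "greater",
                           exact = TRUE)$p.value)
  expect_equal(rank_sum_p_greater(y, x),
               wilcox.test(y, x, alternative = "greater",
                           exact = TRUE)$p.value)
  # with ties: compare against a hand-rolled enumeration over C(8,4)
  xt <- c(3, 3, 5, 2); yt <- c(3, 1, 2, 2)
  r <- rank(c(xt, yt))
  u_obs <- sum(r[1:4]) - 10
  cmb <- combn(8, 4)
  us <- apply(cmb, 2, function(idx) sum(r[idx]) - 10)
  expect_equal(rank_sum_p_greater(xt, yt), mean(us >= u_obs - 1e-9))
  # large groups: normal approximation with ties matches wilcox.test
  set.seed(43)
  xl <- round(rnorm(25, 1), 1); yl <- round(rnorm(30), 1)
  expect_equal(rank_sum_p_greater(xl, yl),
               wilcox.test(xl, yl, alternative = "greater", exact = FALSE,
                           correct = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("module 3 picks the candidate whose markers dominate", {
  ms <- marker_set(data.frame(
    cluster = rep(c("A::1", "B::1"), each = 20),
    gene = sprintf("g%03d", 1:40),
    score = rep(seq(1, 0.5, length.out = 20), 2),
    rank = rep(1:20, 2)), role = "sub")
  eq <- setNames(c(rep(5, 20), rep(0.1, 20)), sprintf("g%03d", 1:40))
  cands <- data.frame(sub_cluster = c("A::1", "B::1"),
                      correlation = c(0.8, 0.79))
  res <- module3_resolve(eq, cands, ms)
  expect_identical(res$winner, "A::1")
  expect_gt(res$scores["A::1"], res$scores["B::1"])
  expect_true(all(c("greater", "lesser", "p") %in% names(res$pvalues)))
  # swapping the expression values flips the winner
  eq_flip <- setNames(rev(unname(eq)), names(eq))
  expect_identical(module3_resolve(eq_flip, cands, ms)$winner, "B::1")
  # shared markers are excluded from both sides, so duplicating a marker
  # across candidates cannot change the outcome
  ms_dup <- marker_set(data.frame(
    cluster = c(ms$cluster, "A::1", "B::1"),
    gene = c(ms$gene, "g021", "g021"),
    score = c(ms$score, 0.4, 0.4),
    rank = c(ms$rank, 21, 21)), role = "sub")
  expect_identical(module3_resolve(eq, cands, ms_dup)$winner, "A::1")
})

test_that("module 3 falls back to correlation when markers run out", {
  ms <- marker_set(data.frame(cluster = c("A::1", "B::1"),
                              gene = c("g001", "g002"),
                              score = c(1, 1), rank = c(1, 1)),
                   role = "sub")
  eq <- setNames(c(1, 2), c("g001", "g002"))
  cands <- data.frame(sub_cluster = c("A::1", "B::1"),
                      correlation = c(0.7, 0.9))
  expect_warning(res <- module3_resolve(eq, cands, ms), "falling back")
  expect_identical(res$winner, "B::1")
  expect_null(res$pvalues)
})

test_that("self-annotation assigns every cluster its own type", {
  b <- tiny_bundle()
  q <- tiny_query(b)
  pred <- annotate_clusters(q, b, min_genes = 10)
  expect_identical(nrow(pred), 3L)
  expect_true(all(pred$status == "assigned"))
  expect_identical(pred$predicted_cell_type,
                   sub("^q", "", pred$query_cluster))
})

test_that("predictions are invariant to query cluster order", {
  b <- tiny_bundle()
  q <- tiny_query(b)
  q_perm <- cluster_profile(q$values[, c(3, 1, 2)])
  p1 <- annotate_clusters(q, b, min_genes = 10)
  p2 <- annotate_clusters(q_perm, b, min_genes = 10)
  p2 <- p2[match(p1$query_cluster, p2$query_cluster), ]
  rownames(p2) <- NULL
  attributes(p1)[c("candidate_pvalues", "cutoff_m1", "cutoff_m2")] <- NULL
  attributes(p2)[c("candidate_pvalues", "cutoff_m1", "cutoff_m2")] <- NULL
  expect_equal(p1, p2)
})

test_that("raising the clamp bounds never rescues an unassigned cluster", {
  b <- tiny_bundle()
  q <- tiny_query(b)
  set.seed(44)
  noise <- matrix(rexp(120, 1), 60, 2,
                  dimnames = list(profile_genes(q), c("qN1", "qN2")))
  q2 <- cluster_profile(cbind(q$values, noise))
  n_lo <- sum(annotate_clusters(q2, b, clamp_lo = 0.3, clamp_hi = 0.5,
                                min_genes = 10)$status == "unassigned")
  n_hi <- sum(annotate_clusters(q2, b, clamp_lo = 0.5, clamp_hi = 0.7,
                                min_genes = 10)$status == "unassigned")
  expect_gte(n_hi, n_lo)
})

test_that("reported correlations are reproducible from bundle and query", {
  b <- tiny_bundle()
  q <- tiny_query(b)
  pred <- annotate_clusters(q, b, min_genes = 10)
  corr_er <- correlation_matrix(q, b$er, marker_genes(b$markers_bg),
                                min_genes = 10)
  expect_equal(pred$best_corr_m1,
               unname(apply(corr_er, 1, max)[pred$query_cluster]))
  corr_sub <- correlation_matrix(q, b$ersub, marker_genes(b$markers_main),
                                 min_genes = 10)
  expect_equal(pred$best_corr_m2,
               unname(apply(corr_sub, 1, max)[pred$query_cluster]))
})

test_that("cross-species annotation needs an ortholog map", {
  b <- tiny_bundle()
  b$er$species <- "human"; b$ersub$species <- "human"
  b$background$species <- "human"
  q <- tiny_query(b)
  q$species <- "mouse"
  expect_error(annotate_clusters(q, b, min_genes = 10), "ortholog")
  map <- ortholog_map(data.frame(human = profile_genes(b$er),
                                 mouse = profile_genes(q)))
  pred <- annotate_clusters(q, b, ortholog = map, min_genes = 10,
                            min_mapped_genes = 10)
  expect_true(all(pred$status == "assigned"))
})
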