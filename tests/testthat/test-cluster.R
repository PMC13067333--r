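test_that("stat_map matches textbook formulas", {
  set.seed(1)
  a <- matrix(rnorm(5 * 4), 5, 4)
  b <- matrix(rnorm(5 * 4), 5, 4)
  st <- stat_map(a, b, kind = "paired_t")
  for (j in 1:4)
    expect_equal(st$stat[j], unname(t.test(a[, j], b[, j],
                                           paired = TRUE)$statistic),
                 tolerance = 1e-12)
  expect_equal(st$df, 4)
  # a = b gives the all-zero map
  expect_true(all(stat_map(a, a, kind = "paired_t")$stat == 0))
  # independent pooled t
  g <- stat_map(a, b, kind = "independent_t")
  for (j in 1:4)
    expect_equal(g$stat[j], unname(t.test(a[, j], b[, j],
                                          var.equal = TRUE)$statistic),
                 tolerance = 1e-12)
  # correlation: scores identical to one column give r = 1 there
  r <- stat_map(a, scores = a[, 2], kind = "pearson_r")
  expect_equal(r$stat[2], 1, tolerance = 1e-12)
  for (j in 1:4)
    expect_equal(r$stat[j], cor(a[, 2], a[, j]), tolerance = 1e-12)
  # zero-variance cells are flagged with statistic 0
  a0 <- a; a0[, 3] <- 5
  s0 <- stat_map(a0, kind = "one_sample_t")
  expect_true(s0$flagged[3])
  expect_equal(s0$stat[3], 0)
})

test_that("cluster formation agrees with a brute-force flood fill", {
  lay <- sensor_layout(12)
  adj <- adjacency_graph(lay)
  dims <- c(12, 3, 4)
  set.seed(42)
  for (rep in 1:15) {
    stat <- rnorm(prod(dims), sd = 2)
    cl <- form_clusters(stat, 1.5, adj, dims)
    sgn <- as.integer(sign(stat) * (abs(stat) > 1.5))
    ref <- flood_fill_clusters(sgn, dims, adj$neighbors)
    # identical partitions (labels may be permuted)
    expect_equal(cl$labels > 0, ref > 0)
    expect_equal(length(unique(cl$labels[cl$labels > 0])),
                 length(unique(ref[ref > 0])))
    tab <- table(cl$labels[cl$labels > 0], ref[ref > 0])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    # masses consistent with membership
    for (k in seq_along(cl$mass))
      expect_equal(cl$mass[k], sum(stat[cl$labels == k]), tolerance = 1e-12)
  }
})

test_that("crafted geometries produce the expected clusters", {
  adj <- chain_adjacency(3)
  dims <- c(3, 3, 3)
  # a full 3x3x3 suprathreshold block is one cluster with mass = block sum
  stat <- rep(2, 27)
  cl <- form_clusters(stat, 1.5, adj, dims)
  expect_length(cl$mass, 1)
  expect_equal(cl$mass, 54)
  # an isolated suprathreshold cell forms a singleton cluster
  stat2 <- rep(0, 27); stat2[14] <- 3
  cl2 <- form_clusters(stat2, 1.5, adj, dims)
  expect_equal(cl2$mass, 3)
  expect_equal(which(cl2$labels == 1), 14)
  # two suprathreshold cells on non-adjacent nodes are two clusters
  stat3 <- rep(0, 27); stat3[c(1, 3)] <- 3
  expect_length(form_clusters(stat3, 1.5, adj, dims)$mass, 2)
  # opposite signs never merge
  stat4 <- rep(0, 27); stat4[1] <- 3; stat4[2] <- -3
  expect_length(form_clusters(stat4, 1.5, adj, dims)$mass, 2)
  # axis adjacency toggles
  stat5 <- rep(0, 27); stat5[c(4, 13)] <- 3 # same node, adjacent freq/time
  expect_length(form_clusters(stat5, 1.5, adj, dims,
                              freq_adj = FALSE, time_adj = FALSE)$mass, 2)
})

test_that("permutation p-values behave under enumeration, symmetry, relabeling", {
  lay <- sensor_layout(8)
  adj <- adjacency_graph(lay)
  set.seed(2)
  X <- matrix(rnorm(3 * 8, mean = 1.5), 3, 8)
  # n = 3 paired: exhaustive 2^3 sign flips, p on a 1/8 grid
  expect_warning(res <- permutation_p(X, kind = "one_sample_t",
                                      adjacency = adj, dims = c(8, 1, 1),
                                      n_perm = 1000, seed = 1),
                 "exhaustively")
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 8)
  expect_true(all(abs(res$clusters$p_perm * 9 -
                        round(res$clusters$p_perm * 9)) < 1e-12))

  # exchange symmetry: swapping groups flips signs, keeps p
  set.seed(3)
  A <- matrix(rnorm(6 * 8, 1), 6, 8); B <- matrix(rnorm(6 * 8), 6, 8)
  r1 <- permutation_p(A, B, kind = "independent_t", adjacency = adj,
                      dims = c(8, 1, 1), n_perm = 500, seed = 5)
  r2 <- permutation_p(B, A, kind = "independent_t", adjacency = adj,
                      dims = c(8, 1, 1), n_perm = 500, seed = 5)
  expect_equal(r1$stat, -r2$stat)
  o1 <- r1$clusters[order(r1$clusters$mass), ]
  o2 <- r2$clusters[order(-r2$clusters$mass), ]
  expect_equal(o1$mass, -o2$mass)
  # p agrees up to permutation resampling noise
  expect_lt(max(abs(o1$p_perm - o2$p_perm)), 0.07)

  # node relabeling leaves masses and p unchanged
  set.seed(4)
  X2 <- matrix(rnorm(8 * 8, 0.8), 8, 8)
  perm <- sample(8)
  adj_perm <- adj
  adj_perm$neighbors <- lapply(perm, function(i)
    sort(match(adj$neighbors[[i]], perm)))
  ra <- permutation_p(X2, kind = "one_sample_t", adjacency = adj,
                      dims = c(8, 1, 1), n_perm = 100, seed = 6)
  rb <- permutation_p(X2[, perm], kind = "one_sample_t", adjacency = adj_perm,
                      dims = c(8, 1, 1), n_perm = 100, seed = 6)
  expect_equal(sort(ra$clusters$mass), sort(rb$clusters$mass))
  expect_equal(sort(ra$clusters$p_perm), sort(rb$clusters$p_perm))
  # p bounded below by 1/(n_perm + 1)
  expect_true(all(ra$clusters$p_perm >= 1 / 101))
})

test_that("an injected patch is detected with high probability", {
  lay <- sensor_layout(16)
  adj <- adjacency_graph(lay)
  patch_nodes <- c(1, adj$neighbors[[1]][1:3])
  set.seed(8)
  hits <- mean(replicate(25, {
    X <- matrix(rnorm(16 * 160), 16, 160)
    idx <- as.vector(outer(patch_nodes, (4:6 - 1) * 16, `+`))
    X[, idx] <- X[, idx] + 1.5
    res <- permutation_p(X, kind = "one_sample_t", adjacency = adj,
                         dims = c(16, 1, 10), n_perm = 200,
                         seed = sample.int(1e6, 1))
    sig <- res$clusters[res$clusters$p_perm <= 0.05 & res$clusters$sign > 0, ]
    nrow(sig) > 0 && any(idx %in% unlist(res$members[sig$id]))
  }))
  expect_gte(hits, 0.9)
})
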