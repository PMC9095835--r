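test_that("the pooled t-map matches hand and t.test oracles", {
  a <- matrix(c(1, 2, 3), ncol = 1)
  b <- matrix(c(4, 5, 6), ncol = 1)
  expect_equal(two_sample_tmap(a, b), -3 / sqrt(2 / 3), tolerance = 1e-12)

  set.seed(19)
  x <- matrix(stats::rnorm(8 * 5), 8)
  y <- matrix(stats::rnorm(6 * 5), 6)
  got <- two_sample_tmap(x, y)
  oracle <- vapply(1:5, function(j) {
    stats::t.test(x[, j], y[, j], var.equal = TRUE)$statistic
  }, numeric(1))
  expect_equal(got, oracle, ignore_attr = TRUE, tolerance = 1e-12)

  expect_equal(two_sample_tmap(y, x), -two_sample_tmap(x, y), tolerance = 1e-12)
  expect_equal(two_sample_tmap(x, x), rep(0, 5))

  cst <- matrix(1, 3, 2)
  expect_warning(t0 <- two_sample_tmap(cst, cst), "zero pooled variance")
  expect_equal(t0, c(0, 0))
  expect_error(two_sample_tmap(x[1, , drop = FALSE], y), ">= 2 subjects")
})

test_that("cluster permutation is deterministic, connected and seed-sensitive", {
  adj <- grid_adjacency(4, 4)
  set.seed(31)
  a <- matrix(stats::rnorm(12 * 16), 12)
  b <- matrix(stats::rnorm(12 * 16), 12)
  b[, c(1, 2, 5, 6)] <- b[, c(1, 2, 5, 6)] + 2 # planted connected patch

  r1 <- cluster_permutation(a, b, adj, n_perm = 300, seed = 5)
  r2 <- cluster_permutation(a, b, adj, n_perm = 300, seed = 5)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$null_max_mass, r2$null_max_mass)

  # every reported cluster is connected under the adjacency (BFS check)
  for (mem in r1$members) {
    cc <- tcdeeg:::components_of(adj, mem)
    expect_equal(cc$n_comp, 1)
  }
  # p-values live in (1/(n+1), 1]
  expect_true(all(r1$clusters$p >= 1 / 301 & r1$clusters$p <= 1))
  # the planted negative-direction patch is found
  neg <- r1$clusters[r1$clusters$sign == -1, ]
  expect_gte(nrow(neg), 1)
  expect_lt(min(neg$p), 0.05)
})

test_that("tiny designs fall back to exact enumeration with a notice", {
  adj <- grid_adjacency(2, 3)
  set.seed(3)
  a <- matrix(stats::rnorm(3 * 6), 3)
  b <- matrix(stats::rnorm(3 * 6) + 1.5, 3)
  expect_message(r <- cluster_permutation(a, b, adj, n_perm = 100, seed = 1),
                 "exact enumeration")
  expect_true(r$exact)
  expect_equal(r$n_perm, choose(6, 3))
  expect_message(r2 <- cluster_permutation(a, b, adj, n_perm = 100, seed = 9),
                 "exact")
  expect_identical(r$clusters, r2$clusters) # seed-independent when exact
})

test_that("BH-FDR matches the step-up definition", {
  f <- bh_fdr(c(0.01, 0.02, 0.03, 0.5))
  expect_equal(f$p_adjusted, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(f$rejected, c(TRUE, TRUE, TRUE, FALSE))

  expect_false(any(bh_fdr(rep(1, 5))$rejected))
  one <- bh_fdr(0.04)
  expect_equal(one$p_adjusted, 0.04)
  expect_true(one$rejected)
  expect_equal(length(bh_fdr(numeric(0))$p), 0)
  expect_error(bh_fdr(c(0.5, 0)), "in \\(0, 1\\]")

  # oracle equivalence on random vectors of every length up to 10
  set.seed(23)
  for (m in 1:10) {
    for (rep in 1:20) {
      p <- stats::runif(m)^2
      got <- bh_fdr(p)
      oracle <- brute_bh(p)
      expect_equal(got$p_adjusted, oracle$adjusted, tolerance = 1e-12)
      expect_identical(got$rejected, oracle$rejected)
    }
  }
  # adjusted p is monotone nondecreasing in raw-p order
  p <- stats::runif(50)
  adj <- bh_fdr(p)$p_adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("scalp-level Bonferroni uses the 0.05/7 threshold", {
  mk <- function(p) structure(list(clusters = data.frame(p = p)),
                              class = "cluster_stat_result")
  res <- stats::setNames(lapply(c(0.006, 0.01, 0.0071, 1, 1, 1, 1), mk),
                         band_names())
  res[[4]] <- mk(numeric(0)) # band with no clusters
  out <- scalp_band_bonferroni(res)
  expect_equal(out$threshold, rep(0.05 / 7, 7))
  expect_true(out$significant[1]) # 0.006 < 0.05/7
  expect_false(out$significant[2]) # 0.01 > 0.05/7
  expect_true(out$significant[3]) # 0.0071 < 0.0071428... (exact threshold)
  expect_equal(out$min_p[4], 1)
  expect_error(scalp_band_bonferroni(res[1:6]), "exactly 7")
})

test_that("partial Spearman removes the covariate and keeps the plain rho otherwise", {
  set.seed(41)
  n <- 200
  x <- stats::rnorm(n)
  y <- 0.5 * x + stats::rnorm(n)
  cov_ind <- stats::rnorm(n)
  plain <- brute_spearman(x, y)
  part <- partial_spearman(x, y, cov_ind)
  expect_lt(abs(part$rho - plain), 0.05)
  expect_lt(part$p, 0.001)

  n2 <- 500
  x2 <- stats::rnorm(n2)
  z2 <- stats::rnorm(n2)
  expect_warning(conf <- partial_spearman(x2, z2, z2), # y IS the covariate
                 "entirely")
  expect_lt(abs(conf$rho), 0.05)
  # near-degenerate but not exact: formula path, still ~0
  near <- partial_spearman(x2, z2 + 1e-4 * stats::rnorm(n2), z2)
  expect_lt(abs(near$rho), 0.1)

  x3 <- stats::rnorm(20)
  perf <- partial_spearman(x3, x3, stats::rnorm(20))
  expect_equal(perf$rho, 1, tolerance = 1e-9)
  expect_true(perf$clipped)
  expect_true(is.finite(perf$p))

  expect_message(red <- partial_spearman(x3, x3 + stats::rnorm(20), rep(1, 20)),
                 "plain Spearman")
  expect_error(partial_spearman(x3[1:3], x3[1:3], x3[1:3]), "n >= 5")
})

test_that("mesh and channel adjacency are symmetric without self-loops", {
  adj <- mesh_adjacency(fix("tiny_mesh"))
  expect_equal(adj$n, 42)
  for (i in seq_len(adj$n)) {
    expect_false(i %in% adj$neighbors[[i]])
    for (j in adj$neighbors[[i]]) expect_true(i %in% adj$neighbors[[j]])
  }
  ch <- channel_adjacency(fix("tiny_montage"))
  expect_equal(ch$n, 16)
  expect_true(all(lengths(ch$neighbors) >= 1))
  for (i in seq_len(ch$n)) {
    for (j in ch$neighbors[[i]]) expect_true(i %in% ch$neighbors[[j]])
  }
})
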