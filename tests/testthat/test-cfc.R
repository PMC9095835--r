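mk_series <- function(rel) {
  # rel: epoch x band x node
  structure(list(rel = rel, bands = band_names(), n_epochs = dim(rel)[1],
                 n_nodes = dim(rel)[3]),
            class = "epoch_power_series")
}

rand_series <- function(n_ep = 12, n_nodes = 4, seed = 1) {
  set.seed(seed)
  raw <- array(stats::runif(n_ep * 7 * n_nodes, 0.1, 1), c(n_ep, 7, n_nodes))
  tot <- apply(raw, c(1, 3), sum)
  for (b in 1:7) raw[, b, ] <- raw[, b, ] / tot
  dimnames(raw) <- list(NULL, band_names(), NULL)
  mk_series(raw)
}

test_that("whole-brain low power is the node mean per epoch", {
  s <- rand_series()
  got <- whole_brain_low_power(s, "theta")
  brute <- vapply(seq_len(s$n_epochs), function(e) {
    mean(s$rel[e, "theta", ])
  }, numeric(1))
  expect_equal(got, brute, tolerance = 1e-12)

  # two nodes with shares 0.2 and 0.4 average to 0.3
  rel <- array(0.1, c(10, 7, 2), dimnames = list(NULL, band_names(), NULL))
  rel[, "theta", 1] <- 0.2
  rel[, "theta", 2] <- 0.4
  expect_equal(whole_brain_low_power(mk_series(rel), "theta"), rep(0.3, 10))

  # all nodes identical: the mean equals any node's series
  rel2 <- rand_series(n_nodes = 1)$rel[, , c(1, 1, 1)]
  dimnames(rel2) <- list(NULL, band_names(), NULL)
  s2 <- mk_series(rel2)
  expect_equal(whole_brain_low_power(s2, "alpha1"), s2$rel[, "alpha1", 1])

  expect_error(whole_brain_low_power(s, "beta"), "theta, alpha1, alpha2")
})

test_that("Spearman coupling matches hand-computed rank correlations", {
  low <- c(1, 2, 3, 4, 5)
  gamma <- c(3, 1, 2, 5, 4)
  out <- cfc_spearman(low, matrix(gamma), min_epochs = 5)
  expect_equal(out$rho, 0.6) # 1 - 6*8/(5*24)
  expect_equal(out$z, atanh(0.6))

  perfect <- cfc_spearman(low, cbind(low, rev(low)), min_epochs = 5)
  expect_equal(perfect$rho, c(1, -1))
  expect_true(all(is.finite(perfect$z)))

  set.seed(2)
  x <- stats::rnorm(40)
  y <- matrix(stats::rnorm(80), 40)
  got <- cfc_spearman(x, y)
  expect_equal(got$rho, c(brute_spearman(x, y[, 1]), brute_spearman(x, y[, 2])),
               tolerance = 1e-12)
  expect_equal(got$n_epochs, rep(40, 2))
})

test_that("coupling is invariant under monotone transforms of either series", {
  set.seed(4)
  x <- stats::rexp(30)
  y <- matrix(stats::rnorm(30), 30)
  base <- cfc_spearman(x, y)$rho
  expect_equal(cfc_spearman(exp(x), y)$rho, base, tolerance = 1e-12)
  expect_equal(cfc_spearman(rank(x), y)$rho, base, tolerance = 1e-12)
  expect_equal(cfc_spearman(x, matrix(rank(y)))$rho, base, tolerance = 1e-12)
})

test_that("degenerate constant series are flagged missing with a warning", {
  x <- stats::rnorm(12)
  y <- cbind(stats::rnorm(12), rep(1, 12))
  expect_warning(out <- cfc_spearman(x, y), "constant")
  expect_true(is.na(out$rho[2]))
  expect_false(is.na(out$rho[1]))

  expect_warning(out2 <- cfc_spearman(rep(2, 12), y[, 1, drop = FALSE]),
                 "constant low-band")
  expect_true(all(is.na(out2$rho)))

  expect_error(cfc_spearman(x[1:5], y[1:5, ]), ">= 10")
  expect_error(cfc_spearman(x, y[1:5, ]), "epoch counts")
})

test_that("Fisher Z is the clipped atanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_true(is.finite(fisher_z(1)) && is.finite(fisher_z(-1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.2), "<= 1")
})

test_that("the epoch power series normalizes after node aggregation", {
  # vertex-level per-epoch band power through a 2-node atlas
  atl <- atlas(c(1, 1, 2), c("L_T", "L_O"), c("DMN", "Other"))
  set.seed(9)
  abs_p <- array(stats::runif(5 * 3 * 7, 0.5, 2), c(5, 3, 7))
  bp <- structure(list(absolute = abs_p, bands = band_names(),
                       per_epoch = TRUE, level = "vertex"),
                  class = "band_power")
  s <- epoch_power_series(bp, atl)
  sums <- apply(s$rel, c(1, 3), sum)
  expect_equal(as.vector(sums), rep(1, 10), tolerance = 1e-10)
  # node 2 is vertex 3: its share equals the vertex's own share
  expect_equal(as.numeric(s$rel[1, 2, 2]), abs_p[1, 3, 2] / sum(abs_p[1, 3, ]),
               tolerance = 1e-12)
})

test_that("cfc_table evaluates the three low bands against gamma1", {
  s <- rand_series(n_ep = 15, n_nodes = 3, seed = 11)
  tab <- cfc_table(s)
  expect_equal(nrow(tab), 9)
  expect_equal(unique(tab$low_band), c("theta", "alpha1", "alpha2"))
  one <- cfc_spearman(whole_brain_low_power(s, "alpha2"), s$rel[, "gamma1", ],
                      low_band = "alpha2")
  expect_equal(tab[tab$low_band == "alpha2", "rho"], one$rho)
})
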