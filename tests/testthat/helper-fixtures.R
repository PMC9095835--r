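# Shared fixtures, built once per test run. Everything is generated in code;
# the "tiny" geometry keeps per-test simulations fast, the default 642-vertex
# setup is reserved for the localization and end-to-end checks.

fix <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!exists(name, envir = cache)) {
      val <- switch(name,
        sphere = sphere_model(),
        tiny_mesh = build_toy_mesh(1, 70),          # 42 vertices
        tiny_montage = place_electrodes(16, 90),
        tiny_lf = compute_lead_field(fix("tiny_mesh"), fix("tiny_montage"),
                                     fix("sphere")),
        tiny_atlas = toy_atlas(fix("tiny_mesh"), 6),
        mesh642 = build_toy_mesh(3, 70),
        montage32 = place_electrodes(32, 90),
        lf642 = compute_lead_field(fix("mesh642"), fix("montage32"),
                                   fix("sphere")),
        atlas20 = toy_atlas(fix("mesh642"), 20),
        stop("unknown fixture: ", name)
      )
      assign(name, val, envir = cache)
    }
    get(name, envir = cache)
  }
})

# Independent oracle for the sphere forward model: monopole surface kernel as
# a truncated Legendre series, dipole potential by central finite difference
# along the moment direction. Shares no code with dipole_potential().
series_dipole_potential <- function(b, q, r, a, sigma, nmax = 300, eps = 1e-5) {
  mono <- function(bb) {
    bnorm <- sqrt(sum(bb^2))
    cg <- sum(bb * r) / (bnorm * sqrt(sum(r^2)))
    t <- bnorm / a
    p0 <- 1
    p1 <- cg
    s <- 0
    for (n in 1:nmax) {
      pn <- if (n == 1) p1 else ((2 * n - 1) * cg * p1 - (n - 1) * p0) / n
      if (n >= 2) {
        p0 <- p1
        p1 <- pn
      }
      s <- s + (2 * n + 1) / n * t^n * pn
    }
    s / (4 * pi * sigma * a)
  }
  qn <- sqrt(sum(q^2))
  qu <- q / qn
  qn * (mono(b + eps * qu) - mono(b - eps * qu)) / (2 * eps)
}

# Brute-force Spearman rank correlation (average ranks), independent of cor().
brute_spearman <- function(x, y) {
  rx <- rank(x) - mean(rank(x))
  ry <- rank(y) - mean(rank(y))
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

# Step-up BH definition, evaluated literally: reject the largest k with
# p_(k) <= k*q/m; adjusted p by the textbook cumulative-minimum formula.
brute_bh <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- rev(cummin(rev(ranked * m / seq_len(m))))
  adj <- pmin(adj, 1)
  k <- which(ranked <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  out_adj <- numeric(m)
  out_adj[o] <- adj
  list(adjusted = out_adj, rejected = reject)
}

# grid adjacency for cluster-permutation calibration tests
grid_adjacency <- function(nrow, ncol) {
  n <- nrow * ncol
  nb <- vector("list", n)
  idx <- function(r, c) (r - 1) * ncol + c
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      i <- idx(r, c)
      if (r > 1) nb[[i]] <- c(nb[[i]], idx(r - 1, c))
      if (r < nrow) nb[[i]] <- c(nb[[i]], idx(r + 1, c))
      if (c > 1) nb[[i]] <- c(nb[[i]], idx(r, c - 1))
      if (c < ncol) nb[[i]] <- c(nb[[i]], idx(r, c + 1))
    }
  }
  tcdeeg:::new_adjacency(nb)
}

# epoch-power pairs from the generator's copula mechanism, for estimator
# calibration: amplitudes exp(s*u), exp(s*v) with corr(u,v) targeting rho.
copula_power_pairs <- function(n, rho, s = 0.6) {
  r <- spearman_to_latent(rho)
  g <- stats::rnorm(n)
  u <- r * g + sqrt(1 - r^2) * stats::rnorm(n)
  cbind(low = exp(s * u)^2, gamma = exp(s * g)^2)
}
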