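# Group-difference inference: pooled-variance t-maps, cluster-based
# Monte-Carlo permutation with max-cluster-mass null, BH-FDR, scalp-level
# Bonferroni across bands, and age-controlled partial Spearman correlations.

#' Adjacency from a cortical mesh
#'
#' Vertices are neighbors when they share a mesh edge.
#' @param mesh a `cortical_mesh`
#' @return An `adjacency_graph`: list of neighbor index vectors.
#' @export
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  nb <- vector("list", mesh$n_vertices)
  for (i in seq_len(nrow(e))) {
    nb[[e[i, 1]]] <- c(nb[[e[i, 1]]], e[i, 2])
    nb[[e[i, 2]]] <- c(nb[[e[i, 2]]], e[i, 1])
  }
  new_adjacency(nb)
}

#' Adjacency from an electrode montage
#'
#' Channels are neighbors when their Euclidean distance is below
#' `factor` times the median nearest-neighbor distance.
#' @param montage an `electrode_montage`
#' @param factor distance threshold multiplier (default 1.3)
#' @return An `adjacency_graph`.
#' @export
channel_adjacency <- function(montage, factor = 1.3) {
  d <- as.matrix(stats::dist(montage$positions))
  diag(d) <- Inf
  thr <- factor * stats::median(apply(d, 1, min))
  nb <- lapply(seq_len(nrow(d)), function(i) which(d[i, ] <= thr))
  new_adjacency(nb)
}

new_adjacency <- function(nb) {
  nb <- lapply(nb, function(x) sort(unique(as.integer(x))))
  for (i in seq_along(nb)) {
    if (i %in% nb[[i]]) stop_param("adjacency must have no self-loops")
  }
  structure(list(neighbors = nb, n = length(nb)), class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  comp <- length(unique(components_of(x, seq_len(x$n))$comp))
  cat(sprintf("adjacency_graph: %d locations, %d connected component(s)\n",
              x$n, comp))
  invisible(x)
}

# connected components of the subgraph induced by `members` (BFS)
components_of <- function(adj, members) {
  inset <- logical(adj$n)
  inset[members] <- TRUE
  comp <- integer(adj$n)
  k <- 0L
  for (s in members) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in adj$neighbors[[v]]) {
        if (inset[w] && comp[w] == 0L) {
          comp[w] <- k
          queue <- c(queue, w)
        }
      }
    }
  }
  list(comp = comp[members], members = members, n_comp = k)
}

#' Two-sample pooled-variance t-map
#'
#' Per location, the Student two-sample t statistic (group A minus group B,
#' pooled variance). Locations with zero pooled variance get t = 0 with a
#' warning.
#'
#' @param group_a,group_b subject x location matrices
#' @return numeric t value per location
#' @export
two_sample_tmap <- function(group_a, group_b) {
  a <- as.matrix(group_a)
  b <- as.matrix(group_b)
  if (ncol(a) != ncol(b)) stop_param("location sets differ between groups")
  na <- nrow(a)
  nb <- nrow(b)
  if (na < 2 || nb < 2) stop_param("need >= 2 subjects per group")
  ssq <- function(x, m, n) colSums(x^2) - n * m^2
  ma <- colMeans(a)
  mb <- colMeans(b)
  sp2 <- (ssq(a, ma, na) + ssq(b, mb, nb)) / (na + nb - 2)
  sp2 <- pmax(sp2, 0) # guard tiny negative rounding
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  if (any(se == 0)) {
    warning(sprintf("%d location(s) with zero pooled variance set to t = 0",
                    sum(se == 0)), call. = FALSE)
    t[se == 0] <- 0
  }
  t
}

#' Cluster-based Monte-Carlo permutation test
#'
#' Observed clusters are connected sets of locations whose |t| exceeds the
#' per-tail critical value (positive and negative families formed separately
#' at `alpha_per_tail`); the cluster statistic is the sum of member t values
#' (cluster mass). The null distribution is the maximum absolute cluster mass
#' over random relabelings of subjects; each observed cluster's Monte-Carlo
#' p is (1 + #\{null >= |mass|\}) / (n_perm + 1). When the total number of
#' distinct relabelings is at most `n_perm`, all of them are enumerated
#' exactly instead (with a message).
#'
#' @param group_a,group_b subject x location matrices
#' @param adjacency an `adjacency_graph` covering all locations
#' @param n_perm number of Monte-Carlo permutations (default 2000)
#' @param alpha_per_tail cluster-forming tail probability (default 0.025)
#' @param seed integer seed for the permutation generator
#' @return A `cluster_stat_result`: `tmap`, `clusters` (data.frame: sign,
#'   mass, p, and a list column `members`), `null_max_mass`, `n_perm`,
#'   `exact`, `seed`.
#' @export
cluster_permutation <- function(group_a, group_b, adjacency, n_perm = 2000,
                                alpha_per_tail = 0.025, seed = 1) {
  a <- as.matrix(group_a)
  b <- as.matrix(group_b)
  if (adjacency$n != ncol(a)) {
    stop_param("adjacency covers %d locations, data has %d", adjacency$n,
               ncol(a))
  }
  x <- rbind(a, b)
  na <- nrow(a)
  nn <- nrow(x)
  df <- nn - 2
  tcrit <- stats::qt(1 - alpha_per_tail, df)

  tmap_for <- function(idx_a) {
    in_a <- logical(nn)
    in_a[idx_a] <- TRUE
    suppressWarnings(two_sample_tmap(x[in_a, , drop = FALSE],
                                     x[!in_a, , drop = FALSE]))
  }
  clusters_of <- function(t) {
    out <- list()
    for (sgn in c(1, -1)) {
      members <- which(sgn * t > tcrit)
      if (length(members) == 0) next
      cc <- components_of(adjacency, members)
      for (k in seq_len(cc$n_comp)) {
        mem <- members[cc$comp == k]
        out[[length(out) + 1]] <- list(sign = sgn, members = mem,
                                       mass = sum(t[mem]))
      }
    }
    out
  }

  t_obs <- tmap_for(seq_len(na))
  obs <- clusters_of(t_obs)

  n_total <- choose(nn, na)
  exact <- n_total <= n_perm
  if (exact) {
    message(sprintf(
      "only %d distinct relabelings; using exact enumeration instead of %d permutations",
      n_total, n_perm))
    assignments <- utils::combn(nn, na, simplify = FALSE)
  } else {
    assignments <- with_seed(seed, lapply(seq_len(n_perm), function(i) {
      sample.int(nn, na)
    }))
  }
  null_max <- vapply(assignments, function(idx) {
    cl <- clusters_of(tmap_for(idx))
    if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
  }, numeric(1))

  pvals <- vapply(obs, function(cl) {
    if (exact) {
      sum(null_max >= abs(cl$mass)) / n_total
    } else {
      (1 + sum(null_max >= abs(cl$mass))) / (length(null_max) + 1)
    }
  }, numeric(1))

  clusters <- if (length(obs) == 0) {
    data.frame(sign = integer(0), mass = numeric(0), p = numeric(0))
  } else {
    data.frame(sign = vapply(obs, `[[`, numeric(1), "sign"),
               mass = vapply(obs, `[[`, numeric(1), "mass"),
               p = pvals)
  }
  clusters <- clusters[order(-abs(clusters$mass)), , drop = FALSE]
  members <- lapply(obs, `[[`, "members")[order(-abs(vapply(obs, `[[`,
                                                            numeric(1), "mass")))]
  structure(
    list(tmap = t_obs, clusters = clusters, members = members,
         null_max_mass = null_max, n_perm = length(null_max),
         alpha_per_tail = alpha_per_tail, exact = exact, seed = seed),
    class = "cluster_stat_result"
  )
}

#' @export
print.cluster_stat_result <- function(x, ...) {
  cat(sprintf(
    "cluster_stat_result: %d cluster(s), %s with %d relabelings (alpha/tail %g)\n",
    nrow(x$clusters), if (x$exact) "exact enumeration" else "Monte-Carlo",
    x$n_perm, x$alpha_per_tail))
  if (nrow(x$clusters) > 0) {
    print(data.frame(sign = x$clusters$sign,
                     size = lengths(x$members),
                     mass = round(x$clusters$mass, 3),
                     p = signif(x$clusters$p, 3)))
  }
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values (via `stats::p.adjust(method = "BH")`) and the
#' rejection mask at level `q`.
#'
#' @param pvalues raw p-values in (0, 1]
#' @param q FDR level (default 0.05)
#' @return An `fdr_result`: `p`, `p_adjusted`, `rejected`, `q`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) {
    return(structure(list(p = numeric(0), p_adjusted = numeric(0),
                          rejected = logical(0), q = q), class = "fdr_result"))
  }
  if (any(pvalues <= 0 | pvalues > 1)) stop_param("p-values must be in (0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  structure(list(p = pvalues, p_adjusted = adj, rejected = adj <= q, q = q),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("fdr_result: %d / %d rejected at q = %g\n",
              sum(x$rejected), length(x$p), x$q))
  invisible(x)
}

#' Scalp-level Bonferroni report across the seven bands
#'
#' Evaluates each band's smallest cluster p against the Bonferroni-adjusted
#' level `alpha / 7`.
#'
#' @param band_results named list of exactly 7 `cluster_stat_result`s (one
#'   per band)
#' @param alpha overall level (default 0.05, so the per-band level is 0.05/7)
#' @return data.frame: band, min_p, threshold, significant
#' @export
scalp_band_bonferroni <- function(band_results, alpha = 0.05) {
  if (length(band_results) != 7) {
    stop_param("expected exactly 7 band results (got %d)", length(band_results))
  }
  thr <- alpha / 7
  min_p <- vapply(band_results, function(r) {
    if (nrow(r$clusters) == 0) 1 else min(r$clusters$p)
  }, numeric(1))
  data.frame(band = names(band_results) %||% band_names(), min_p = min_p,
             threshold = thr, significant = min_p < thr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Age-controlled partial Spearman correlation
#'
#' Rank-transforms x, y and the covariate (average ranks), then computes the
#' partial Pearson correlation of the rank vectors given the rank covariate,
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)), with a
#' two-sided p from the t approximation on n - 3 degrees of freedom. A
#' constant covariate reduces to the plain Spearman correlation (with a
#' message), using n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors (length >= 5)
#' @param covariate numeric nuisance variable, e.g. age
#' @return list with `rho` (partial Spearman), `p`, `n`, `clipped` (TRUE when
#'   |rho| was clipped away from 1 for the p-value)
#' @export
partial_spearman <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) stop_param("length mismatch")
  if (n < 5) stop_param("need n >= 5")
  if (!all(is.finite(covariate))) stop_param("covariate must be finite")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(covariate) == 0) {
    message("constant covariate: returning plain Spearman correlation")
    rho <- stats::cor(rx, ry)
    df <- n - 2
  } else {
    rz <- rank(covariate)
    rxy <- stats::cor(rx, ry)
    rxz <- stats::cor(rx, rz)
    ryz <- stats::cor(ry, rz)
    den2 <- (1 - rxz^2) * (1 - ryz^2)
    if (den2 < 1e-12) {
      # the covariate explains x or y entirely: nothing left to correlate
      warning("covariate rank-explains x or y entirely; partial rho set to 0",
              call. = FALSE)
      return(list(rho = 0, p = 1, n = n, clipped = FALSE))
    }
    rho <- (rxy - rxz * ryz) / sqrt(den2)
    df <- n - 3
  }
  clipped <- abs(rho) > 1 - 1e-7
  r <- sign(rho) * pmin(abs(rho), 1 - 1e-7)
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(rho = rho, p = p, n = n, clipped = clipped)
}
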