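# Power-power cross-frequency coupling: whole-brain low-band relative power
# vs node-level gamma1 relative power across 2-s epochs, Spearman + Fisher Z.

#' Build the per-epoch node-level relative power series
#'
#' Aggregates per-epoch vertex band power to atlas nodes (vertex mean), then
#' normalizes each epoch x node cell to band shares summing to 1.
#'
#' @param bp a per-epoch `band_power` at vertex (or channel) level
#' @param atlas an [atlas()]; omit (NULL) if `bp` is already node-level
#' @return An `epoch_power_series`: `rel` is an epoch x band x node array of
#'   relative power.
#' @export
epoch_power_series <- function(bp, atlas = NULL) {
  if (!inherits(bp, "band_power") || !bp$per_epoch) {
    stop_param("expected a per-epoch band_power object")
  }
  d <- dim(bp$absolute) # epoch x location x band
  if (!is.null(atlas)) {
    n_nodes <- atlas$n_nodes
    agg <- array(0, dim = c(d[1], n_nodes, d[3]))
    for (e in seq_len(d[1])) {
      agg[e, , ] <- aggregate_vertices(bp$absolute[e, , , drop = TRUE], atlas)
    }
  } else {
    agg <- bp$absolute
    n_nodes <- d[2]
  }
  tot <- apply(agg, c(1, 2), sum)
  if (any(tot <= 0)) stop_param("zero total band power in some epoch/node cells")
  rel <- agg / array(tot, dim = dim(agg))
  rel <- aperm(rel, c(1, 3, 2)) # epoch x band x node
  dimnames(rel) <- list(NULL, bp$bands, NULL)
  structure(list(rel = rel, bands = bp$bands, n_epochs = d[1],
                 n_nodes = n_nodes),
            class = "epoch_power_series")
}

#' Whole-brain low-band power series
#'
#' Per epoch, the mean of one low band's relative power across all nodes.
#'
#' @param series an [epoch_power_series()]
#' @param band one of "theta", "alpha1", "alpha2"
#' @return numeric vector, one value per epoch
#' @export
whole_brain_low_power <- function(series, band) {
  if (!band %in% c("theta", "alpha1", "alpha2")) {
    stop_param("band must be one of theta, alpha1, alpha2 (got %s)", band)
  }
  apply(series$rel[, band, , drop = FALSE], 1, mean)
}

#' Spearman power-power coupling per node
#'
#' Rank correlation (average ranks for ties) between a whole-brain low-band
#' power series and each node's gamma series across epochs, with Fisher Z.
#' Nodes with a constant series get an NA row with a warning.
#'
#' @param low_series per-epoch scalar series
#' @param gamma_series epoch x node matrix of gamma-band relative power
#' @param low_band label stored in the output (default "theta")
#' @param min_epochs minimum series length (default 10 for coupling analyses;
#'   lower it only for raw rank-correlation use)
#' @return data.frame: low_band, node, rho, z, n_epochs
#' @export
cfc_spearman <- function(low_series, gamma_series, low_band = "theta",
                         min_epochs = 10) {
  gamma_series <- as.matrix(gamma_series)
  n <- length(low_series)
  if (nrow(gamma_series) != n) stop_param("epoch counts differ")
  if (n < min_epochs) stop_param("need >= %d epochs for CFC (got %d)", min_epochs, n)
  if (anyNA(low_series) || anyNA(gamma_series)) stop_param("missing values")
  rho <- rep(NA_real_, ncol(gamma_series))
  if (stats::sd(low_series) == 0) {
    warning("constant low-band series: all correlations undefined", call. = FALSE)
  } else {
    const <- apply(gamma_series, 2, stats::sd) == 0
    if (any(const)) {
      warning(sprintf("%d node(s) with constant gamma series flagged missing",
                      sum(const)), call. = FALSE)
    }
    ok <- which(!const)
    rho[ok] <- suppressWarnings(
      stats::cor(low_series, gamma_series[, ok, drop = FALSE],
                 method = "spearman")[1, ]
    )
  }
  data.frame(low_band = low_band, node = seq_len(ncol(gamma_series)),
             rho = rho, z = fisher_z(rho), n_epochs = n,
             stringsAsFactors = FALSE)
}

#' Fisher Z-transform of a correlation
#'
#' z = atanh(rho), with |rho| clipped at 1 - 1e-7 so perfect correlations map
#' to a large finite value.
#'
#' @param rho correlation(s) in [-1, 1] (NA passed through)
#' @return numeric z value(s)
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) > 1, na.rm = TRUE)) stop_param("|rho| must be <= 1")
  atanh(sign(rho) * pmin(abs(rho), 1 - 1e-7))
}

#' Full CFC table over the three low bands
#'
#' @param series an [epoch_power_series()]
#' @param low_bands low bands to evaluate (default theta, alpha1, alpha2)
#' @param gamma_band the high band (default "gamma1"; "gamma2" available)
#' @return data.frame: low_band, node, rho, z, n_epochs
#' @export
cfc_table <- function(series, low_bands = c("theta", "alpha1", "alpha2"),
                      gamma_band = "gamma1") {
  gamma <- t(series$rel[, gamma_band, ]) # node x epoch -> transpose below
  gamma <- t(gamma)
  do.call(rbind, lapply(low_bands, function(lb) {
    cfc_spearman(whole_brain_low_power(series, lb), gamma, low_band = lb)
  }))
}
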