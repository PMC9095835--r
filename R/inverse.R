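# Depth-weighted L2 minimum-norm inverse with identity noise covariance.

#' Construct a depth-weighted minimum-norm inverse operator
#'
#' Builds the linear kernel K = R L' (L R L' + lambda2 * c * I)^-1 with
#' source prior R = diag(||l_i||^(-2*gamma)) normalized to unit mean,
#' lambda2 = 1/snr^2 and identity noise covariance scaled by
#' c = trace(L R L') / n_channels so that snr is dimensionless. gamma = 0
#' recovers the classic (Tikhonov) minimum norm.
#'
#' @param leadfield a [compute_lead_field()] object or a bare gain matrix
#' @param depth_exponent depth-weighting exponent gamma in [0, 1] (default 0.5)
#' @param snr assumed amplitude signal-to-noise ratio (default 3); the
#'   regularization is lambda2 = 1/snr^2
#' @return An `inverse_operator` with the `kernel` (n_sources x n_channels),
#'   the parameters, and the gain it was built from.
#' @export
make_inverse_operator <- function(leadfield, depth_exponent = 0.5, snr = 3) {
  gain <- if (inherits(leadfield, "lead_field")) leadfield$gain else as.matrix(leadfield)
  if (!is.numeric(depth_exponent) || depth_exponent < 0 || depth_exponent > 1) {
    stop_param("depth_exponent must be in [0, 1]")
  }
  if (snr <= 0) stop_param("snr must be positive")
  cn <- sqrt(colSums(gain^2))
  if (any(cn == 0)) {
    stop_param("degenerate source(s) with zero-norm lead-field column: %s",
               paste(which(cn == 0), collapse = ", "))
  }
  r_diag <- cn^(-2 * depth_exponent)
  r_diag <- r_diag / mean(r_diag)
  lambda2 <- 1 / snr^2
  grl <- sweep(gain, 2, r_diag, `*`) # L R
  m <- grl %*% t(gain)               # L R L'
  scale <- sum(diag(m)) / nrow(m)
  kernel <- t(grl) %*% solve(m + lambda2 * scale * diag(nrow(m)))
  structure(
    list(kernel = kernel, depth_exponent = depth_exponent, snr = snr,
         lambda2 = lambda2, noise_covariance = "identity",
         source_prior = r_diag, gain = gain),
    class = "inverse_operator"
  )
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf(
    "inverse_operator: %d sources x %d channels (gamma = %g, snr = %g, lambda2 = %g)\n",
    nrow(x$kernel), ncol(x$kernel), x$depth_exponent, x$snr, x$lambda2
  ))
  invisible(x)
}

#' Apply an inverse operator to epoched sensor data
#'
#' Linear map of each epoch's sensor matrix to vertex current-density time
#' series (pA*m): currents = kernel %*% data.
#'
#' @param op an `inverse_operator`
#' @param epochs an `epoched_recording` (or a bare channels x samples matrix,
#'   treated as one epoch)
#' @return A `source_estimate` with `currents` (epoch x vertex x sample
#'   array, pA*m) and `fs`.
#' @export
apply_inverse <- function(op, epochs) {
  if (is.matrix(epochs)) {
    epochs <- list(epochs = array(epochs, c(1, dim(epochs))), fs = NA_real_,
                   kept_epoch_ids = 0L)
  }
  dims <- dim(epochs$epochs)
  if (dims[2] != ncol(op$kernel)) {
    stop_param("channel mismatch: kernel expects %d channels, data has %d",
               ncol(op$kernel), dims[2])
  }
  n_src <- nrow(op$kernel)
  currents <- array(0, dim = c(dims[1], n_src, dims[3]))
  for (e in seq_len(dims[1])) {
    currents[e, , ] <- op$kernel %*% epochs$epochs[e, , ]
  }
  structure(
    list(currents = currents, fs = epochs$fs,
         kept_epoch_ids = epochs$kept_epoch_ids %||% (seq_len(dims[1]) - 1L),
         units = "pA*m"),
    class = "source_estimate"
  )
}

#' @export
print.source_estimate <- function(x, ...) {
  d <- dim(x$currents)
  cat(sprintf("source_estimate: %d epochs x %d vertices x %d samples (%s)\n",
              d[1], d[2], d[3], x$units))
  invisible(x)
}
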