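# Spectral estimation on the 0.5 Hz grid: per-epoch Hann periodograms,
# Welch averaging, band power tables, cortical smoothing, peak alpha frequency.

new_spectrum <- function(freqs, power, per_epoch, level, fs) {
  structure(list(freqs = freqs, power = power, per_epoch = per_epoch,
                 level = level, fs = fs),
            class = "eeg_spectrum")
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  if (x$per_epoch) {
    d <- dim(x$power)
    cat(sprintf("eeg_spectrum (per-epoch): %d epochs x %d locations x %d freqs [%g..%g Hz]\n",
                d[1], d[2], d[3], min(x$freqs), max(x$freqs)))
  } else {
    cat(sprintf("eeg_spectrum (averaged): %d locations x %d freqs [%g..%g Hz]\n",
                nrow(x$power), ncol(x$power), min(x$freqs), max(x$freqs)))
  }
  invisible(x)
}

# One-sided Hann periodogram of the columns of a samples x series matrix.
# Linear detrend, periodic Hann taper, taper-power normalization; returns
# power spectral density in input-units^2/Hz on the fs/n grid.
hann_periodogram <- function(x, fs) {
  n <- nrow(x)
  tt <- seq_len(n)
  q <- qr.Q(qr(cbind(1, tt)))
  x <- x - q %*% crossprod(q, x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  xw <- x * w
  co <- stats::mvfft(xw)
  nf <- n %/% 2 + 1
  p <- (Mod(co[seq_len(nf), , drop = FALSE])^2) * (2 / (fs * sum(w^2)))
  p[1, ] <- p[1, ] / 2
  if (n %% 2 == 0) p[nf, ] <- p[nf, ] / 2
  list(freqs = (seq_len(nf) - 1) * fs / n, power = p)
}

epochs_array <- function(x) {
  if (inherits(x, "epoched_recording")) {
    list(arr = x$epochs, fs = x$fs, level = "channel")
  } else if (inherits(x, "source_estimate")) {
    list(arr = x$currents, fs = x$fs, level = "vertex")
  } else {
    stop_param("expected an epoched_recording or source_estimate")
  }
}

#' Per-epoch Hann periodogram spectra
#'
#' Each 2-s epoch is linearly detrended, tapered with a Hann window and
#' Fourier transformed; squared magnitudes (taper-power normalized, one-sided
#' density) give the per-epoch spectrum on the 0.5 Hz grid.
#'
#' @param epochs an `epoched_recording` or `source_estimate`
#' @return A per-epoch `eeg_spectrum` (power: epoch x location x frequency).
#' @export
epoch_fft_power <- function(epochs) {
  ea <- epochs_array(epochs)
  d <- dim(ea$arr)
  if (abs(d[3] / ea$fs - 2) > 1e-9) {
    stop_param("epochs must be 2 s long for the 0.5 Hz grid (got %.3f s)",
               d[3] / ea$fs)
  }
  nf <- d[3] %/% 2 + 1
  power <- array(0, dim = c(d[1], d[2], nf))
  freqs <- NULL
  for (e in seq_len(d[1])) {
    x <- matrix(ea$arr[e, , ], nrow = d[2]) # channels x samples
    pg <- hann_periodogram(t(x), ea$fs)
    power[e, , ] <- t(pg$power)
    freqs <- pg$freqs
  }
  new_spectrum(freqs, power, per_epoch = TRUE, level = ea$level, fs = ea$fs)
}

#' Welch power spectral density
#'
#' Mean of Hann-tapered, 50%-overlapping segment periodograms. Accepts a
#' locations x samples matrix, a `subject_recording`, or a `source_estimate`
#' (whose epochs are concatenated in temporal order before segmentation).
#'
#' @param x input series (see above)
#' @param fs sampling rate, Hz (taken from the object when available)
#' @param window_s segment length, seconds (default 2, the 0.5 Hz grid)
#' @param overlap fractional overlap between segments (default 0.5)
#' @return An averaged `eeg_spectrum` (power: location x frequency).
#' @export
welch_psd <- function(x, fs = NULL, window_s = 2, overlap = 0.5) {
  level <- "channel"
  if (inherits(x, "subject_recording")) {
    fs <- x$fs
    x <- x$data
  } else if (inherits(x, "source_estimate")) {
    fs <- x$fs
    d <- dim(x$currents)
    x <- matrix(aperm(x$currents, c(3, 1, 2)), nrow = d[1] * d[3], ncol = d[2])
    x <- t(x)
    level <- "vertex"
  }
  x <- as.matrix(x)
  if (is.null(fs)) stop_param("fs required for a bare matrix input")
  nwin <- round(window_s * fs)
  step <- max(1, round(nwin * (1 - overlap)))
  n <- ncol(x)
  if (n < 2 * nwin - step) stop_param("input too short for >= 2 Welch segments")
  starts <- seq(1, n - nwin + 1, by = step)
  acc <- NULL
  freqs <- NULL
  for (s in starts) {
    pg <- hann_periodogram(t(x[, s + seq_len(nwin) - 1, drop = FALSE]), fs)
    acc <- if (is.null(acc)) pg$power else acc + pg$power
    freqs <- pg$freqs
  }
  new_spectrum(freqs, t(acc / length(starts)), per_epoch = FALSE,
               level = level, fs = fs)
}

#' @export
plot.eeg_spectrum <- function(x, locations = NULL, xlim = c(2, 90), ...) {
  p <- if (x$per_epoch) apply(x$power, c(2, 3), mean) else x$power
  if (is.null(locations)) locations <- seq_len(min(nrow(p), 8))
  keep <- x$freqs >= xlim[1] & x$freqs <= xlim[2]
  graphics::matplot(x$freqs[keep], t(log10(pmax(p[locations, keep, drop = FALSE],
                                                .Machine$double.xmin))),
                    type = "l", lty = 1, xlab = "frequency (Hz)",
                    ylab = "log10 power", ...)
  invisible(x)
}

#' Absolute band power
#'
#' Sums spectral power over the grid frequencies of each band, using the
#' half-open convention `low <= f < high` (10.0 Hz belongs to alpha2; 55 Hz
#' upward falls in the notch gap).
#'
#' @param spec an `eeg_spectrum` (per-epoch or averaged)
#' @param bands band table from [frequency_bands()]
#' @return A `band_power` object: `absolute` is epoch x location x band (per
#'   epoch input) or location x band (averaged input).
#' @export
band_power <- function(spec, bands = frequency_bands()) {
  masks <- lapply(seq_len(nrow(bands)), function(i) {
    m <- band_mask(spec$freqs, bands$low[i], bands$high[i])
    if (!any(m)) {
      stop_param("spectrum grid does not cover band %s [%g, %g)",
                 bands$band[i], bands$low[i], bands$high[i])
    }
    need_max <- bands$high[i] - 0.5
    if (max(spec$freqs) < need_max - 1e-9) {
      stop_param("spectrum grid does not cover band %s [%g, %g)",
                 bands$band[i], bands$low[i], bands$high[i])
    }
    m
  })
  nb <- nrow(bands)
  if (spec$per_epoch) {
    d <- dim(spec$power)
    abs_p <- array(0, dim = c(d[1], d[2], nb))
    for (b in seq_len(nb)) {
      abs_p[, , b] <- apply(spec$power[, , masks[[b]], drop = FALSE], c(1, 2), sum)
    }
  } else {
    abs_p <- do.call(cbind, lapply(masks, function(m) {
      rowSums(spec$power[, m, drop = FALSE])
    }))
  }
  structure(list(absolute = abs_p, bands = bands$band, per_epoch = spec$per_epoch,
                 level = spec$level),
            class = "band_power")
}

#' Relative band power, averaged over epochs
#'
#' Per epoch and location, each band's absolute power is divided by the
#' summed power of all seven bands; the shares are then averaged over
#' epochs. Averaged (non-epoch) input yields the share of the averaged
#' spectrum directly.
#'
#' @param bp a `band_power` object
#' @return A `band_power_table` with matrices `absolute` and `relative`
#'   (location x band; absolute is the epoch mean for per-epoch input) and
#'   `n_epochs`.
#' @export
relative_power <- function(bp) {
  if (!inherits(bp, "band_power")) stop_param("expected a band_power object")
  if (bp$per_epoch) {
    d <- dim(bp$absolute)
    tot <- apply(bp$absolute, c(1, 2), sum)
    if (any(tot <= 0)) {
      stop_param("zero total band power in %d epoch/location cells",
                 sum(tot <= 0))
    }
    rel <- bp$absolute / array(tot, dim = d)
    relative <- apply(rel, c(2, 3), mean)
    absolute <- apply(bp$absolute, c(2, 3), mean)
    n_epochs <- d[1]
  } else {
    tot <- rowSums(bp$absolute)
    if (any(tot <= 0)) stop_param("zero total band power at some locations")
    relative <- bp$absolute / tot
    absolute <- bp$absolute
    n_epochs <- 1L
  }
  colnames(relative) <- colnames(absolute) <- bp$bands
  structure(list(absolute = absolute, relative = relative,
                 n_epochs = n_epochs, level = bp$level, bands = bp$bands),
            class = "band_power_table")
}

#' @export
print.band_power_table <- function(x, ...) {
  cat(sprintf("band_power_table (%s level): %d locations x %d bands, %d epochs\n",
              x$level, nrow(x$relative), ncol(x$relative), x$n_epochs))
  invisible(x)
}

#' @export
as.data.frame.band_power_table <- function(x, ...) {
  n <- nrow(x$relative)
  data.frame(
    location = rep(seq_len(n), times = length(x$bands)),
    band = rep(x$bands, each = n),
    absolute = as.vector(x$absolute),
    relative = as.vector(x$relative),
    n_epochs = x$n_epochs,
    level = x$level,
    stringsAsFactors = FALSE
  )
}

#' Gaussian smoothing of a vertex map on the cortical mesh
#'
#' Gaussian kernel (given FWHM, mm) over geodesic distances (shortest path
#' along mesh edges). The symmetric kernel is balanced to doubly-stochastic
#' form by Sinkhorn scaling, so constant maps are fixed points and the map
#' mean (total mass) is preserved.
#'
#' @param values numeric vertex map (length = n_vertices)
#' @param mesh a `cortical_mesh`
#' @param fwhm_mm kernel full width at half maximum, mm (default 3);
#'   `fwhm_mm = 0` is the identity
#' @return The smoothed vertex map.
#' @export
smooth_on_cortex <- function(values, mesh, fwhm_mm = 3) {
  if (length(values) != mesh$n_vertices) {
    stop_param("values length %d != n_vertices %d", length(values),
               mesh$n_vertices)
  }
  if (!all(is.finite(values))) stop_param("values must be finite")
  if (fwhm_mm < 0) stop_param("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(values)
  w <- smoothing_weights(mesh, fwhm_mm)
  as.vector(w %*% values)
}

smoothing_weights <- function(mesh, fwhm_mm) {
  d <- geodesic_distances(mesh)
  if (any(!is.finite(d))) stop_param("mesh is disconnected; cannot smooth")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  w <- exp(-d^2 / (2 * sigma^2))
  w[d > 4 * sigma] <- 0
  # Sinkhorn balancing: symmetric scaling to doubly-stochastic
  for (i in 1:200) {
    s <- rowSums(w)
    if (max(abs(s - 1)) < 1e-13) break
    inv <- 1 / sqrt(s)
    w <- w * outer(inv, inv)
  }
  w
}

geodesic_distances <- function(mesh) {
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::distances(g, weights = len)
}

#' Peak alpha frequency
#'
#' Per location, the grid frequency of the largest local maximum of the
#' logarithmic power spectrum inside the search window (default 6-14 Hz). A
#' local maximum must be strictly greater than both neighboring grid bins;
#' locations with no interior local maximum get `NA` with `missing = TRUE`.
#'
#' @param spec an averaged `eeg_spectrum`
#' @param window 2-vector search window in Hz (default `c(6, 14)`)
#' @return A data.frame with `location`, `paf_hz`, `missing`.
#' @export
compute_paf <- function(spec, window = c(6, 14)) {
  if (spec$per_epoch) stop_param("compute_paf expects a trial-averaged spectrum")
  f <- spec$freqs
  if (min(f) > window[1] || max(f) < window[2]) {
    stop_param("spectrum grid does not cover the %g-%g Hz window",
               window[1], window[2])
  }
  in_win <- which(f >= window[1] - 1e-9 & f <= window[2] + 1e-9)
  n_loc <- nrow(spec$power)
  paf <- rep(NA_real_, n_loc)
  for (i in seq_len(n_loc)) {
    lp <- log(pmax(spec$power[i, ], .Machine$double.xmin))
    cand <- in_win[in_win > 1 & in_win < length(f)]
    is_peak <- lp[cand] > lp[cand - 1] & lp[cand] > lp[cand + 1]
    peaks <- cand[is_peak]
    if (length(peaks) > 0) paf[i] <- f[peaks[which.max(lp[peaks])]]
  }
  data.frame(location = seq_len(n_loc), paf_hz = paf, missing = is.na(paf))
}
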