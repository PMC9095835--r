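# Deterministic signal conditioning: zero-phase high-pass + line-noise notch,
# average reference, 2-s epoching with amplitude rejection and an 80-s budget.

#' Construct a subject recording
#'
#' @param data channels x samples numeric matrix, microvolts
#' @param fs sampling rate, Hz
#' @param labels channel labels (default "E001", ...)
#' @param subject_id,group,sex optional metadata strings
#' @return A `subject_recording`.
#' @export
subject_recording <- function(data, fs, labels = NULL, subject_id = NA_character_,
                              group = NA_character_, sex = NA_character_) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop_param("recording contains non-finite values")
  if (fs <= 0) stop_param("fs must be positive")
  if (is.null(labels)) labels <- sprintf("E%03d", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) stop_param("one label per channel required")
  structure(
    list(data = data, fs = fs, labels = labels, subject_id = subject_id,
         group = group, sex = sex, log = list()),
    class = "subject_recording"
  )
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf(
    "subject_recording: %d channels x %d samples @ %g Hz (%.1f s)%s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    if (!is.na(x$subject_id)) paste0(" [", x$subject_id, "]") else ""
  ))
  invisible(x)
}

log_step <- function(rec, step, ...) {
  rec$log <- c(rec$log, list(c(list(step = step), list(...))))
  rec
}

# Split a designed transfer function into second-order sections (biquads) by
# pairing conjugate roots. The direct transfer-function form of a high-order
# Butterworth filter with a cutoff far below Nyquist loses ~9 digits to
# coefficient cancellation; the biquad cascade keeps filtering linear to
# machine precision.
tf_to_sos <- function(filt) {
  pair_up <- function(coefs) {
    r <- polyroot(rev(coefs))
    tol <- 1e-5 * pmax(1, Mod(r))
    upper <- r[Im(r) > tol]
    realr <- sort(Re(r[abs(Im(r)) <= tol]))
    pairs <- lapply(upper, function(u) c(1, -2 * Re(u), Mod(u)^2))
    i <- 1
    while (i + 1 <= length(realr)) {
      pairs[[length(pairs) + 1]] <-
        c(1, -(realr[i] + realr[i + 1]), realr[i] * realr[i + 1])
      i <- i + 2
    }
    if (i == length(realr)) {
      pairs[[length(pairs) + 1]] <- c(1, -realr[i], 0)
    }
    pairs
  }
  bz <- pair_up(filt$b)
  az <- pair_up(filt$a)
  ident <- c(1, 0, 0)
  nsec <- max(length(bz), length(az))
  gain <- filt$b[1] / filt$a[1]
  lapply(seq_len(nsec), function(k) {
    g <- if (k == 1) gain else 1
    signal::Arma(b = g * (if (k <= length(bz)) bz[[k]] else ident),
                 a = if (k <= length(az)) az[[k]] else ident)
  })
}

# forward-backward biquad-cascade filtering with odd-reflection padding so
# startup transients decay inside the padding, not in the data
zero_phase <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- c(front, x, back)
  for (sec in tf_to_sos(filt)) {
    y <- signal::filtfilt(sec, y)
  }
  y[pad + seq_len(n)]
}

#' Zero-phase high-pass and line-noise notch filtering
#'
#' 4th-order Butterworth sections applied forward-backward
#' (\code{signal::filtfilt} with odd-reflection padding), so the net filter
#' has zero phase and no edge transients: a 2 Hz high-pass followed by
#' 55-65 Hz band-stop sections at the line-noise fundamental and its
#' harmonics up to Nyquist.
#'
#' @param rec a `subject_recording`
#' @param hp_hz high-pass edge, Hz (default 2)
#' @param notch 2-vector band-stop edges, Hz (default c(55, 65))
#' @return The filtered `subject_recording`.
#' @export
highpass_notch <- function(rec, hp_hz = 2, notch = c(55, 65)) {
  fs <- rec$fs
  nyq <- fs / 2
  if (fs <= 2 * notch[2]) {
    stop_param("sampling rate %g Hz too low for a %g-%g Hz notch", fs,
               notch[1], notch[2])
  }
  pad <- round(3 * fs) # ~3 s: several high-pass time constants at 2 Hz
  hp <- signal::butter(4, hp_hz / nyq, type = "high")
  out <- t(apply(rec$data, 1, function(x) zero_phase(hp, x, pad)))
  # band-stop at the line-noise fundamental and harmonics below Nyquist
  center <- mean(notch)
  half <- diff(notch) / 2
  k <- 1
  while (k * center + half < nyq) {
    bs <- signal::butter(4, c(k * center - half, k * center + half) / nyq,
                         type = "stop")
    out <- t(apply(out, 1, function(x) zero_phase(bs, x, pad)))
    k <- k + 1
  }
  rec$data <- out
  log_step(rec, "highpass_notch", hp_hz = hp_hz, notch = notch)
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean is zero at each sample. Idempotent.
#'
#' @param rec a `subject_recording`
#' @return The re-referenced `subject_recording`.
#' @export
average_reference <- function(rec) {
  if (nrow(rec$data) < 2) stop_param("average reference needs >= 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  log_step(rec, "average_reference")
}

#' Epoch a recording and select the first 80 s of clean data
#'
#' Divides the recording into consecutive non-overlapping epochs of
#' `epoch_s` seconds, drops epochs containing any sample exceeding
#' `reject_abs_uV` in absolute value, and keeps the earliest
#' `budget_s / epoch_s` surviving epochs in temporal order.
#'
#' @param rec a `subject_recording`
#' @param epoch_s epoch length, seconds (default 2)
#' @param reject_abs_uV absolute-amplitude rejection threshold, microvolts
#'   (default 100)
#' @param budget_s total retained duration, seconds (default 80)
#' @return An `epoched_recording` with `epochs` (epoch x channel x sample
#'   array), `fs`, `epoch_s`, `kept_epoch_ids` (0-based epoch indices) and
#'   the provenance `log`.
#' @export
epoch_and_select <- function(rec, epoch_s = 2, reject_abs_uV = 100,
                             budget_s = 80) {
  fs <- rec$fs
  n_per <- round(epoch_s * fs)
  n_total <- floor(ncol(rec$data) / n_per)
  need <- round(budget_s / epoch_s)
  keep <- integer(0)
  for (e in seq_len(n_total) - 1L) {
    seg <- rec$data[, e * n_per + seq_len(n_per), drop = FALSE]
    if (max(abs(seg)) <= reject_abs_uV) keep <- c(keep, e)
    if (length(keep) == need) break
  }
  if (length(keep) < need) {
    stop_param(
      "insufficient clean data: %d clean epochs available, %d required (short by %d)",
      length(keep), need, need - length(keep)
    )
  }
  epochs <- array(0, dim = c(need, nrow(rec$data), n_per))
  for (i in seq_along(keep)) {
    epochs[i, , ] <- rec$data[, keep[i] * n_per + seq_len(n_per)]
  }
  structure(
    list(
      epochs = epochs, fs = fs, epoch_s = epoch_s,
      kept_epoch_ids = keep, labels = rec$labels,
      subject_id = rec$subject_id, group = rec$group, sex = rec$sex,
      log = c(rec$log, list(list(step = "epoch_and_select", epoch_s = epoch_s,
                                 reject_abs_uV = reject_abs_uV,
                                 budget_s = budget_s)))
    ),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf(
    "epoched_recording: %d epochs x %d channels x %d samples @ %g Hz\n",
    dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3], x$fs
  ))
  invisible(x)
}

#' Run the standard preprocessing chain
#'
#' Convenience wrapper: [highpass_notch()], [average_reference()],
#' [epoch_and_select()] with the default parameters of each step.
#'
#' @inheritParams epoch_and_select
#' @inheritParams highpass_notch
#' @return An `epoched_recording`.
#' @export
preprocess_recording <- function(rec, hp_hz = 2, notch = c(55, 65),
                                 epoch_s = 2, reject_abs_uV = 100,
                                 budget_s = 80) {
  rec <- highpass_notch(rec, hp_hz = hp_hz, notch = notch)
  rec <- average_reference(rec)
  epoch_and_select(rec, epoch_s = epoch_s, reject_abs_uV = reject_abs_uV,
                   budget_s = budget_s)
}
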