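# Synthetic two-group EEG cohorts with known thalamocortical-dysrhythmia-like
# ground truth: 1/f-profiled band-limited source noise per atlas node, a
# dominant alpha oscillation at a subject-specific peak frequency, localized
# gamma elevation on designated focus nodes, and a Gaussian-copula epoch-wise
# coupling between low-band and gamma1 amplitudes of controllable sign.

#' Specify a synthetic group
#'
#' @param label group label, e.g. "control" or "affected"
#' @param n_subjects number of subjects (>= 1)
#' @param paf_mean,paf_sd mean and SD (Hz) of the subject-level peak alpha
#'   frequency; `paf_mean` must lie in 6..14
#' @param band_gain named multiplicative source-amplitude factor per band
#'   (all seven bands, all > 0); defaults to 1 everywhere
#' @param gamma_focus_nodes integer node ids receiving extra gamma1 gain
#' @param gamma_focus_gain multiplicative gamma1 gain on the focus nodes
#' @param cfc_rho named target Spearman correlation between each low band's
#'   (theta, alpha1, alpha2) epoch amplitude and the gamma1 epoch amplitude,
#'   each in [-0.95, 0.95]
#' @param noise_sd white sensor noise SD, microvolts
#' @param peak_gain amplitude factor of the alpha-peak oscillation relative
#'   to the 1/f background at the peak frequency
#' @param amp_mod_sd SD of the log-amplitude epoch modulation (the copula
#'   scale `s` in amplitude = exp(s * u))
#' @param source_scale overall source amplitude, pA*m per vertex at 1 Hz
#'   before the 1/f profile
#' @param sex optional sex label for all subjects of the group
#' @return A `group_spec`.
#' @export
group_spec <- function(label, n_subjects, paf_mean = 9.5, paf_sd = 0.5,
                       band_gain = NULL, gamma_focus_nodes = integer(0),
                       gamma_focus_gain = 1, cfc_rho = NULL, noise_sd = 0.5,
                       peak_gain = 3, amp_mod_sd = 0.6, source_scale = 600,
                       sex = NA_character_) {
  bn <- band_names()
  bg <- stats::setNames(rep(1, 7), bn)
  if (!is.null(band_gain)) {
    if (is.null(names(band_gain)) || !all(names(band_gain) %in% bn)) {
      stop_param("band_gain must be named with band names")
    }
    bg[names(band_gain)] <- band_gain
  }
  if (any(bg <= 0)) stop_param("all band_gain values must be > 0")
  rho <- stats::setNames(rep(0, 3), c("theta", "alpha1", "alpha2"))
  if (!is.null(cfc_rho)) {
    if (is.null(names(cfc_rho)) || !all(names(cfc_rho) %in% names(rho))) {
      stop_param("cfc_rho must be named with low bands (theta, alpha1, alpha2)")
    }
    rho[names(cfc_rho)] <- cfc_rho
  }
  if (any(abs(rho) > 0.95)) stop_param("|cfc_rho| must be <= 0.95")
  if (paf_mean < 6 || paf_mean > 14) stop_param("paf_mean must be in [6, 14]")
  if (n_subjects < 1) stop_param("n_subjects must be >= 1")
  structure(
    list(label = label, n_subjects = as.integer(n_subjects),
         paf_mean = paf_mean, paf_sd = paf_sd, band_gain = bg,
         gamma_focus_nodes = as.integer(gamma_focus_nodes),
         gamma_focus_gain = gamma_focus_gain, cfc_rho = rho,
         noise_sd = noise_sd, peak_gain = peak_gain,
         amp_mod_sd = amp_mod_sd, source_scale = source_scale, sex = sex),
    class = "group_spec"
  )
}

#' Shipped group presets
#'
#' Two `group_spec` presets mirroring the directional spectral signatures of
#' thalamocortical dysrhythmia: `"control"` (PAF 9.2 Hz, flat band gains,
#' mildly positive theta-gamma1 coupling +0.2) and `"affected"` (PAF 7.8 Hz,
#' elevated theta gain 1.5, reduced alpha2 gain 0.6, gamma1 elevation 1.8 on
#' the supplied focus nodes, inverse theta-gamma1 coupling -0.4).
#'
#' @param which `"control"` or `"affected"`
#' @param n_subjects subjects in the group (default 10)
#' @param gamma_focus_nodes node ids for the localized gamma elevation
#'   (typically the temporal/parietal/occipital nodes of the atlas in use);
#'   only used by the affected preset
#' @return A `group_spec`.
#' @export
preset_group_spec <- function(which = c("control", "affected"),
                              n_subjects = 10,
                              gamma_focus_nodes = integer(0)) {
  which <- match.arg(which)
  if (which == "control") {
    group_spec("control", n_subjects, paf_mean = 9.2, paf_sd = 0.5,
               cfc_rho = c(theta = 0.2))
  } else {
    group_spec("affected", n_subjects, paf_mean = 7.8, paf_sd = 0.5,
               band_gain = c(theta = 1.5, alpha2 = 0.6),
               gamma_focus_nodes = gamma_focus_nodes,
               gamma_focus_gain = 1.8,
               cfc_rho = c(theta = -0.4))
  }
}

#' Latent-normal correlation for a target Spearman correlation
#'
#' For a bivariate normal copula, the Spearman correlation of any monotone
#' transforms of the latents is (6/pi) asin(r/2); the exact inverse is
#' r = 2 sin(pi * rho / 6).
#'
#' @param rho target Spearman correlation in [-1, 1]
#' @return the latent Pearson correlation r
#' @export
spearman_to_latent <- function(rho) {
  if (any(abs(rho) > 1)) stop_param("|rho| must be <= 1")
  2 * sin(pi * rho / 6)
}

#' Simulate one synthetic subject
#'
#' Per atlas node, the source signal is a sum over the seven canonical bands
#' of band-limited Gaussian noise (synthesized exactly on the 0.5 Hz grid),
#' each band's amplitude scaled by 1/(band center) before `band_gain`, plus a
#' dominant alpha oscillation of ~2 Hz bandwidth centered on the subject's
#' drawn peak alpha frequency. Per 2-s epoch, a latent Gaussian copula scales
#' the low-band and gamma1 amplitudes so their epoch-power rank correlation
#' targets `cfc_rho` (negative targets drive them in opposition); gamma1 gain
#' is multiplied by `gamma_focus_gain` on the focus nodes only. Node signals
#' are copied to member vertices, mapped to sensors through the lead field,
#' and white sensor noise is added.
#'
#' @param spec a [group_spec()]
#' @param leadfield a [compute_lead_field()] object
#' @param atlas an [atlas()] for the lead field's mesh
#' @param duration recording length, seconds (>= 100)
#' @param fs sampling rate, Hz (Nyquist must exceed 90 Hz for gamma2)
#' @param seed integer seed; same seed and spec give a bit-identical recording
#' @param subject_id optional id string
#' @return list with `recording` (a `subject_recording`) and `truth` (a
#'   `ground_truth`: drawn PAF, node x band mean source amplitudes, per-epoch
#'   amplitude multipliers, realized low-band/gamma1 Spearman correlations,
#'   and the seed).
#' @export
simulate_subject <- function(spec, leadfield, atlas, duration = 120, fs = 500,
                             seed = 1, subject_id = NULL) {
  if (duration < 100) stop_param("duration must be >= 100 s (got %g)", duration)
  if (fs / 2 <= 90) stop_param("fs too low for gamma2: Nyquist %g < 90 Hz", fs / 2)
  if (max(c(0, spec$gamma_focus_nodes)) > atlas$n_nodes) {
    stop_param("gamma_focus_nodes outside the atlas node range")
  }
  bands <- frequency_bands()
  n_ep <- floor(duration / 2)
  n <- round(2 * fs)
  nf <- n %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * 0.5
  n_nodes <- atlas$n_nodes

  with_seed(seed, {
    paf <- min(13, max(6, stats::rnorm(1, spec$paf_mean, spec$paf_sd)))

    # epoch-wise latent copula: gamma1 driver g, low bands correlated with g
    g <- stats::rnorm(n_ep)
    lat <- matrix(stats::rnorm(n_ep * 8), n_ep, 8)
    colnames(lat) <- c(band_names(), "peak")
    lat[, "gamma1"] <- g
    for (lb in names(spec$cfc_rho)) {
      r <- spearman_to_latent(spec$cfc_rho[[lb]])
      lat[, lb] <- r * g + sqrt(1 - r^2) * lat[, lb]
    }
    mult <- exp(spec$amp_mod_sd * lat) # epoch x component amplitude multipliers

    # per-component per-node base amplitudes (time-domain SD, pA*m)
    centers <- c(bands$center, paf)
    lows <- c(bands$low, paf - 1)
    highs <- c(bands$high, paf + 1)
    gains <- c(spec$band_gain, peak = spec$peak_gain)
    base <- outer(rep(1, n_nodes), spec$source_scale * gains / centers)
    base[spec$gamma_focus_nodes, which(bands$band == "gamma1")] <-
      base[spec$gamma_focus_nodes, which(bands$band == "gamma1")] *
      spec$gamma_focus_gain
    colnames(base) <- c(band_names(), "peak")

    node_sig <- matrix(0, n_nodes, n_ep * n)
    for (e in seq_len(n_ep)) {
      coef <- matrix(0 + 0i, n, n_nodes)
      for (b in seq_len(8)) {
        rows <- which(band_mask(freqs, lows[b], highs[b]) & freqs > 0 &
                        freqs < fs / 2)
        if (length(rows) == 0) next
        z <- matrix(stats::rnorm(length(rows) * n_nodes), length(rows)) +
          1i * matrix(stats::rnorm(length(rows) * n_nodes), length(rows))
        amp <- base[, b] * mult[e, b] # per node
        # scale for unit time-domain variance per unit amp:
        # var(x) = 2 * nb * E|z|^2 / n^2 with E|z|^2 = 2
        sc <- n / (2 * sqrt(length(rows)))
        coef[rows, ] <- coef[rows, ] +
          z * sc * matrix(amp, length(rows), n_nodes, byrow = TRUE)
      }
      full <- coef
      full[n - (2:nf) + 2, ] <- Conj(coef[2:nf, ])
      x <- Re(stats::mvfft(full, inverse = TRUE)) / n
      node_sig[, (e - 1) * n + seq_len(n)] <- t(x)
    }

    # map node signals to sensors through member vertices
    a_mat <- matrix(0, ncol(leadfield$gain), n_nodes)
    a_mat[cbind(seq_along(atlas$vertex2node), atlas$vertex2node)] <- 1
    g_node <- leadfield$gain %*% a_mat
    sensor <- g_node %*% node_sig
    if (spec$noise_sd > 0) {
      sensor <- sensor + matrix(stats::rnorm(length(sensor), sd = spec$noise_sd),
                                nrow(sensor))
    }

    realized_rho <- sapply(c("theta", "alpha1", "alpha2"), function(lb) {
      stats::cor(mult[, lb]^2, mult[, "gamma1"]^2, method = "spearman")
    })

    if (is.null(subject_id)) subject_id <- sprintf("%s_s%03d", spec$label, seed %% 1000L)
    rec <- subject_recording(sensor, fs, labels = leadfield$montage$labels,
                             subject_id = subject_id, group = spec$label,
                             sex = spec$sex)
    truth <- structure(
      list(subject_id = subject_id, group = spec$label, paf = paf,
           node_band_amplitude = base[, 1:7] * exp(spec$amp_mod_sd^2 / 2),
           amp_multipliers = mult, realized_rho = realized_rho,
           target_rho = spec$cfc_rho, seed = seed),
      class = "ground_truth"
    )
    list(recording = rec, truth = truth)
  })
}

#' Simulate a multi-group cohort
#'
#' Per-subject seeds are derived deterministically from `master_seed`, so the
#' same call reproduces the identical cohort.
#'
#' @param specs list of [group_spec()] objects (labels must be unique)
#' @param leadfield,atlas,duration,fs as in [simulate_subject()]
#' @param master_seed integer master seed
#' @return A `cohort`: list with `subjects` (list of
#'   `list(recording, truth)`) and a `manifest` data.frame (subject_id,
#'   group, sex, seed).
#' @export
simulate_cohort <- function(specs, leadfield, atlas, duration = 120, fs = 500,
                            master_seed = 1) {
  if (length(specs) == 0) stop_param("specs must be non-empty")
  labels <- vapply(specs, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stop_param("duplicate group labels in specs")
  subjects <- list()
  manifest <- NULL
  idx <- 0L
  for (sp in specs) {
    for (k in seq_len(sp$n_subjects)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", sp$label, k)
      seed <- derive_seed(master_seed, idx)
      subjects[[sid]] <- simulate_subject(sp, leadfield, atlas, duration, fs,
                                          seed = seed, subject_id = sid)
      manifest <- rbind(manifest, data.frame(
        subject_id = sid, group = sp$label, sex = sp$sex, seed = seed,
        stringsAsFactors = FALSE
      ))
    }
  }
  if (anyDuplicated(manifest$subject_id)) stop_param("duplicate subject ids")
  structure(list(subjects = subjects, manifest = manifest,
                 master_seed = master_seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects in %d group(s) [%s], master seed %d\n",
              nrow(x$manifest), length(unique(x$manifest$group)),
              paste(unique(x$manifest$group), collapse = ", "),
              x$master_seed))
  invisible(x)
}

#' Write a cohort manifest and ground truth as JSON/CSV
#'
#' @param cohort a `cohort`
#' @param dir output directory
#' @export
write_cohort_manifest <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  gt <- do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$truth$subject_id, group = s$truth$group,
               paf = s$truth$paf,
               realized_rho_theta = s$truth$realized_rho[["theta"]],
               realized_rho_alpha1 = s$truth$realized_rho[["alpha1"]],
               realized_rho_alpha2 = s$truth$realized_rho[["alpha2"]],
               seed = s$truth$seed, stringsAsFactors = FALSE)
  }))
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
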