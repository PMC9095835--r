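# The tiny geometry (42 vertices, 16 channels, 6 nodes) keeps these fast;
# generator physics is identical at every scale.

tiny_sim <- function(spec, duration = 120, fs = 500, seed = 1) {
  simulate_subject(spec, fix("tiny_lf"), fix("tiny_atlas"), duration, fs, seed)
}

test_that("the same seed and spec give a bit-identical recording", {
  sp <- preset_group_spec("control", 1)
  a <- tiny_sim(sp, seed = 42)
  b <- tiny_sim(sp, seed = 42)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$amp_multipliers, b$truth$amp_multipliers)
  c <- tiny_sim(sp, seed = 43)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("paf_sd = 0 pins the ground-truth PAF exactly", {
  sp <- group_spec("g", 1, paf_mean = 9.5, paf_sd = 0)
  for (seed in 1:3) expect_equal(tiny_sim(sp, seed = seed)$truth$paf, 9.5)
})

test_that("uncoupled bands have near-zero realized theta-gamma1 correlation", {
  sp <- group_spec("g", 1, cfc_rho = c(theta = 0), noise_sd = 0)
  sim <- tiny_sim(sp, duration = 200) # 100 epochs
  m <- sim$truth$amp_multipliers
  rho <- brute_spearman(m[, "theta"]^2, m[, "gamma1"]^2)
  expect_lt(abs(rho), 0.2)
  expect_equal(sim$truth$realized_rho[["theta"]], rho, tolerance = 1e-12)
})

test_that("copula calibration hits the target Spearman on stored amplitudes", {
  for (target in c(-0.6, 0, 0.6)) {
    sp <- group_spec("g", 1, cfc_rho = c(theta = target))
    rhos <- vapply(1:50, function(seed) {
      sim <- simulate_subject(sp, fix("tiny_lf"), fix("tiny_atlas"),
                              duration = 400, fs = 250, seed = seed)
      sim$truth$realized_rho[["theta"]]
    }, numeric(1))
    expect_lt(abs(mean(rhos) - target), 0.1)
  }
})

test_that("the source spectrum peaks within one bin of the drawn PAF", {
  sp <- group_spec("g", 1, paf_mean = 10.6, paf_sd = 1, noise_sd = 0)
  for (seed in 1:5) {
    sim <- tiny_sim(sp, seed = seed)
    psd <- welch_psd(sim$recording)
    mean_spec <- tcdeeg:::new_spectrum(psd$freqs, rbind(colMeans(psd$power)),
                                       FALSE, "channel", psd$fs)
    win <- psd$freqs >= 6 & psd$freqs <= 14
    peak <- psd$freqs[win][which.max(mean_spec$power[1, win])]
    expect_lte(abs(peak - sim$truth$paf), 0.5)
  }
})

test_that("noiseless sensor data lies exactly in the lead-field column space", {
  sp <- group_spec("g", 1, noise_sd = 0)
  sim <- tiny_sim(sp, seed = 3)
  g <- fix("tiny_lf")$gain
  x <- sim$recording$data[, 1:2000]
  resid <- x - qr.fitted(qr(g), x)
  expect_lt(max(abs(resid)) / max(abs(x)), 1e-9)
})

test_that("parameter errors are raised before any simulation", {
  sp <- preset_group_spec("control", 1)
  expect_error(tiny_sim(sp, duration = 80), ">= 100")
  expect_error(tiny_sim(sp, fs = 150), "Nyquist")
  expect_error(group_spec("g", 1, cfc_rho = c(theta = 0.99)), "0.95")
  expect_error(group_spec("g", 1, paf_mean = 5), "6, 14")
  expect_error(group_spec("g", 0), "n_subjects")
  expect_error(group_spec("g", 1, band_gain = c(nope = 2)), "named")
})

test_that("cohorts are counted, seeded and reproducible from the master seed", {
  specs <- list(preset_group_spec("control", 5),
                preset_group_spec("affected", 5))
  co <- simulate_cohort(specs, fix("tiny_lf"), fix("tiny_atlas"),
                        duration = 100, fs = 250, master_seed = 7)
  expect_equal(length(co$subjects), 10)
  expect_equal(nrow(co$manifest), 10)
  co2 <- simulate_cohort(specs, fix("tiny_lf"), fix("tiny_atlas"),
                         duration = 100, fs = 250, master_seed = 7)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$subjects[[3]]$recording$data,
                   co2$subjects[[3]]$recording$data)

  dup <- list(preset_group_spec("control", 2), preset_group_spec("control", 2))
  expect_error(simulate_cohort(dup, fix("tiny_lf"), fix("tiny_atlas")),
               "duplicate")
})

test_that("preset PAF means differ by the expected 1.4 Hz at paf_sd = 0", {
  ctl <- group_spec("control", 3, paf_mean = 9.2, paf_sd = 0)
  aff <- group_spec("affected", 3, paf_mean = 7.8, paf_sd = 0)
  co <- simulate_cohort(list(ctl, aff), fix("tiny_lf"), fix("tiny_atlas"),
                        duration = 100, fs = 250, master_seed = 1)
  pafs <- vapply(co$subjects, function(s) s$truth$paf, numeric(1))
  grp <- co$manifest$group
  expect_equal(mean(pafs[grp == "control"]) - mean(pafs[grp == "affected"]),
               1.4, tolerance = 1e-12)
})

test_that("cohort manifest and ground truth are written as plain text", {
  specs <- list(preset_group_spec("control", 2))
  co <- simulate_cohort(specs, fix("tiny_lf"), fix("tiny_atlas"),
                        duration = 100, fs = 250, master_seed = 3)
  d <- withr::local_tempdir()
  write_cohort_manifest(co, d)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(length(man), 2)
  gt <- utils::read.csv(file.path(d, "ground_truth.csv"))
  expect_equal(nrow(gt), 2)
  expect_true(all(c("paf", "realized_rho_theta", "seed") %in% names(gt)))
})
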