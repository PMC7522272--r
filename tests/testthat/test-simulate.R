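test_that("study_config validates acquisition and days", {
  expect_s3_class(study_config(), "study_config")
  expect_error(study_config(acquisition_s = 0.2), "2 cardiac cycles")
  expect_error(study_config(days = integer(0)), "days")
  expect_error(study_config(drift = list(vrp = c(dc = NA), vep = c(dc = 0))),
               "finite")
})

test_that("simulate_frame_sequence is seeded, periodic and mask-partitioned", {
  cfg <- small_config(seed = 9)
  a <- simulate_frame_sequence(cfg, seed = 9)
  b <- simulate_frame_sequence(cfg, seed = 9)
  expect_identical(a$frames$frames, b$frames$frames)
  expect_identical(a$masks$vessel, b$masks$vessel)

  # 4 s at 30 Hz -> 120 frames; vessel coverage within 10-30%
  expect_equal(dim(a$frames$frames)[3], 120)
  frac <- mean(a$masks$vessel)
  expect_gte(frac, 0.10); expect_lte(frac, 0.30)
  expect_true(all(a$masks$vessel | a$masks$tissue))

  # dominant period of the region-mean vessel series: 240 bpm at 30 Hz
  # is 7.5 frames (oracle: autocorrelation of the generated series)
  cfg0 <- small_config(noise_sd = 0, seed = 9)
  s <- simulate_frame_sequence(cfg0, seed = 9)
  ser <- extract_region_waveforms(s$frames, s$masks)
  per <- lsfgpwf:::dominant_period(ser$MV)
  expect_equal(per, 7.5, tolerance = 0.5 / 7.5)

  expect_error(
    simulate_frame_sequence(cfg, template_vessel = tri_spec(100, dc = 20),
                            template_tissue = tri_spec(100, dc = 28)),
    "vessel template dc")
})

test_that("noise-free compartment fidelity: PWF matches template closed forms", {
  cfg <- study_config(frame_rate_hz = 120, noise_sd = 0, seed = 13)
  tpl <- gamma_spec(2000, dc = 45, ac = 12, rf = 0.35)
  sim <- simulate_frame_sequence(cfg, template_vessel = tpl, seed = 13)
  ser <- extract_region_waveforms(sim$frames, sim$masks)
  n_out <- 30L
  p <- compute_pwf(synchronize_cycles(ser$MV, 120, n_out = n_out))
  ref <- compute_pwf(cardiac_cycle(
    make_pulse_template(gamma_spec(n_out, dc = 45, ac = 12, rf = 0.35)),
    0.25))
  # amplitude-type parameters within 2 AC / n_frames (absolute)
  tol_amp <- 2 * 12 / n_out
  for (nm in c("mbr", "mbr_max", "mbr_min", "ac")) {
    expect_lt(abs(p[[nm]] - ref[[nm]]), tol_amp, label = nm)
  }
  expect_equal(p$f, 0.25, tolerance = 0.02)
})

test_that("longitudinal study has the stated layout and ground truth", {
  cfg <- small_config(seed = 31)
  ds <- simulate_longitudinal_study(cfg)
  # every rabbit: baseline_sessions baseline records and all regions per day
  tab <- table(ds$rabbit_id[ds$is_baseline], ds$region[ds$is_baseline])
  expect_true(all(tab == cfg$baseline_sessions))
  tab2 <- table(ds$rabbit_id, ds$day)
  expect_true(all(tab2[, -1] == 3))
  gt <- attr(ds, "ground_truth")
  expect_equal(nrow(gt), nrow(ds))
  # AC strictly below baseline at day 28 for every rabbit (by construction)
  for (r in unique(gt$rabbit_id)) {
    g <- gt[gt$rabbit_id == r & gt$region == "MA", ]
    expect_lt(max(g$ac[g$day == 28]), min(g$ac[g$day == 0]))
  }
  # exact identities hold in the generated records
  expect_equal(ds$ri, ds$ac / ds$mbr_max, tolerance = 1e-12)
  expect_equal(ds$bos, (2 - ds$ac / ds$mbr) * 100, tolerance = 1e-12)
  expect_equal(ds$w, ds$bot / 100 * ds$f, tolerance = 1e-12)
})

test_that("zero drift and zero noise reproduce baseline forever", {
  drift0 <- lapply(default_drift(), function(v) v * 0)
  cfg <- small_config(seed = 8, drift = drift0, session_cv = 0, noise_sd = 0)
  ds <- simulate_longitudinal_study(cfg)
  for (pp in c("mbr", "ac", "bos", "bot", "fr", "fai", "ri")) {
    ma <- ds[ds$region == "MA", pp]
    expect_equal(max(ma) - min(ma), 0, tolerance = 1e-9, label = pp)
  }
})

test_that("longitudinal simulation is deterministic given the seed", {
  cfg <- small_config(seed = 77)
  a <- simulate_longitudinal_study(cfg)
  b <- simulate_longitudinal_study(cfg)
  expect_identical(a, b)
  ta <- simulate_longitudinal_study(cfg, level = "timeseries")
  tb <- simulate_longitudinal_study(cfg, level = "timeseries")
  expect_identical(ta, tb)
  expect_true(all(c("frame_index", "time_s", "mbr") %in% names(ta)))
})

test_that("timeseries level drives the analysis pipeline sensibly", {
  cfg <- study_config(n_rabbits = 2L, days = c(1, 10, 19, 28),
                      baseline_sessions = 2L, seed = 15, noise_sd = 0.2)
  ts <- simulate_longitudinal_study(cfg, level = "timeseries")
  g <- ts[ts$rabbit_id == 1 & ts$session == 1 & ts$region == "MV", ]
  p <- compute_pwf(synchronize_cycles(g$mbr, cfg$frame_rate_hz))
  expect_gt(p$mbr, 30); expect_lt(p$mbr, 60)
  expect_gt(p$ri, 0.1); expect_lt(p$ri, 0.5)
  nba <- attr(ts, "nba")
  expect_true(all(nba$nba_total >= 0 & nba$nba_total <= 19))
})
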