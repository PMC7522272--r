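test_that("synchronize_cycles recovers period and amplitude of a sinusoid", {
  t <- (0:119) / 30
  s <- 35 + 5 * sin(2 * pi * t / 0.3)
  cyc <- synchronize_cycles(s, 30)
  expect_s3_class(cyc, "cardiac_cycle")
  expect_equal(cyc$f, 0.3, tolerance = 0.02 / 0.3)
  expect_equal(min(cyc$samples), 30, tolerance = 0.3 / 30)
  expect_equal(max(cyc$samples), 40, tolerance = 0.3 / 40)
})

test_that("synchronize_cycles is near-exact on identical repeated cycles", {
  tp <- make_pulse_template(pulse_template_spec(35, 10, 0.5, "triangular", 30))
  cyc <- synchronize_cycles(rep(tp, 4), 30, n_out = 30)
  expect_equal(cyc$f, 1)
  # beat averaging of identical triangles: sub-frame fiducial alignment may
  # shave the sharp peak by at most one interpolation step
  expect_lt(max(abs(cyc$samples - tp)), 10 / 30 + 1e-9)
  expect_equal(mean(cyc$samples), mean(tp), tolerance = 1e-2)
  expect_equal(which.min(cyc$samples), 1L)
})

test_that("synchronize_cycles rejects aperiodic input", {
  expect_error(synchronize_cycles(rep(35, 120), 30), "constant")
  expect_error(synchronize_cycles(35 + 0.01 * (1:120), 30),
               "synchronization error")
  expect_error(synchronize_cycles(c(35, 36), 30), "too short")
})

test_that("waveform_extrema scans max, min, mean and peak time", {
  cyc <- cardiac_cycle(c(30, 35, 40, 35, 30, 30, 30, 30), 1)
  ex <- waveform_extrema(cyc)
  expect_equal(ex$mbr_max, 40)
  expect_equal(ex$mbr_min, 30)
  expect_equal(ex$ac, 10)
  expect_equal(ex$dc, mean(cyc$samples))
  expect_equal(ex$t_peak, 2 / 8)
  # plateau peak: first maximum wins
  cyc2 <- cardiac_cycle(c(30, 40, 40, 40, 30, 30, 30, 30), 1)
  expect_equal(waveform_extrema(cyc2)$t_peak, 1 / 8)
})

test_that("blowout score follows (2 - AC/DC) x 100", {
  expect_equal(blowout_score(list(ac = 0, dc = 35)), 200)
  expect_equal(blowout_score(list(ac = 35, dc = 35)), 100)
  expect_equal(blowout_score(list(ac = 10, dc = 40)), 175)
  expect_error(blowout_score(list(ac = 10, dc = 0)), "DC")
})

test_that("blowout time interpolates half-level crossings", {
  # symmetric triangle spends exactly half the cycle above the half level
  bt <- blowout_time(tri_cycle(1000))
  expect_equal(bt$bot, 50, tolerance = 1e-9)
  # flat cycle: whole beat at the half level, BOT 100 by convention
  flat <- cardiac_cycle(rep(35, 16), 1)
  expect_equal(blowout_time(flat)$bot, 100)
  expect_equal(blowout_time(flat)$w, 1)
  # rectangular pulse high for 30% of the cycle
  n <- 100
  y <- c(rep(40, 30), rep(30, 70))
  rect <- cardiac_cycle(c(y[-1], y[1]), 1) # rotate so cycle starts at min
  bt3 <- blowout_time(rect)
  expect_equal(bt3$bot, 30, tolerance = 100 / n / 30)
})

test_that("subdivide_waveform splits the cycle into four aggregate areas", {
  areas <- subdivide_waveform(tri_cycle(1000))
  expect_equal(areas$s1_under, 17.5, tolerance = 1e-4)
  expect_equal(areas$rise_above, 2.5, tolerance = 1e-4)
  expect_equal(areas$fall_under, 17.5, tolerance = 1e-4)
  expect_equal(areas$fall_above, 2.5, tolerance = 1e-4)
  expect_error(subdivide_waveform(cardiac_cycle(rep(35, 16), 1)),
               "degenerate phase")
  # partition identity holds for any shape
  g <- cardiac_cycle(make_pulse_template(gamma_spec(200)), 0.8)
  ga <- subdivide_waveform(g)
  ex <- waveform_extrema(g)
  expect_equal(ga$s1_under + ga$rise_above, ga$t2 * ex$mbr_max,
               tolerance = 1e-12)
  expect_equal(ga$fall_under + ga$fall_above, (ga$t4 - ga$t2) * ex$mbr_max,
               tolerance = 1e-12)
})

test_that("rising and falling rates are the 25-scaled area ratios", {
  areas <- subdivide_waveform(tri_cycle(1000))
  expect_equal(rising_rate(areas), 175, tolerance = 1e-3)
  expect_equal(falling_rate(areas), 25 / 7, tolerance = 1e-3)
  expect_equal(rising_rate(list(s1_under = 3, rise_above = 3)), 25)
  expect_equal(falling_rate(list(fall_above = 3, fall_under = 3)), 25)
  expect_error(rising_rate(list(s1_under = 3, rise_above = 0)), "rise")
  expect_error(falling_rate(list(fall_above = 3, fall_under = 0)), "FR")
  # for triangles the area ratios cancel the rise fraction: RR and FR are
  # invariant to it (oracle: numeric areas on two templates)
  rr_of_tri <- function(rf) rising_rate(subdivide_waveform(
    cardiac_cycle(make_pulse_template(tri_spec(1000, rf = rf)), 1)))
  expect_equal(rr_of_tri(0.2), rr_of_tri(0.5), tolerance = 1e-3)
  # an upstroke that climbs earlier (lower rise curvature) fills more of its
  # rectangle, so RR is strictly larger
  rr_of_k <- function(k) rising_rate(subdivide_waveform(cardiac_cycle(
    make_pulse_template(pulse_template_spec(35, 10, 0.4, "gamma_like", 1000,
                                            rise_power = k)), 1)))
  expect_gt(rr_of_k(1), rr_of_k(4))
  # a sharper drop hugs the trough sooner, so FR is strictly larger
  fr_of_l <- function(l) falling_rate(subdivide_waveform(cardiac_cycle(
    make_pulse_template(pulse_template_spec(35, 10, 0.4, "gamma_like", 1000,
                                            fall_rate = l)), 1)))
  expect_gt(fr_of_l(5), fr_of_l(2))
})

test_that("flow acceleration index is the maximum frame-to-frame rise", {
  cyc <- cardiac_cycle(c(30, 34, 40, 38, 33, 30, 30, 30), 1)
  expect_equal(flow_acceleration_index(cyc), 6)
  expect_equal(flow_acceleration_index(cardiac_cycle(rep(35, 8), 1)), 0)
  # linearity: scale by k and shift by c
  cyc2 <- cardiac_cycle(2 * cyc$samples + 7, 1)
  expect_equal(flow_acceleration_index(cyc2), 12)
})

test_that("acceleration time index is percent time-to-peak", {
  expect_equal(acceleration_time_index(tri_cycle(1000)), 50)
  g <- cardiac_cycle(make_pulse_template(gamma_spec(200, rf = 0.3)), 1)
  expect_equal(acceleration_time_index(g), 30, tolerance = (100 / 200) / 30)
  first <- cardiac_cycle(c(30, 40, 39, 38, 36, 34, 32, 31), 1)
  expect_equal(acceleration_time_index(first), 100 / 8)
})

test_that("resistive index is AC over MBRmax", {
  expect_equal(resistivity_index(list(mbr_max = 40, mbr_min = 30, ac = 10)),
               0.25)
  expect_equal(resistivity_index(list(mbr_max = 40, mbr_min = 40, ac = 0)), 0)
  expect_equal(resistivity_index(list(mbr_max = 40, mbr_min = 0, ac = 40)), 1)
  expect_error(resistivity_index(list(mbr_max = 0, ac = 0)), "MBRmax")
})

test_that("fit_quadratic recovers exact and noisy polynomials", {
  t <- seq(0, 1, length.out = 50)
  f1 <- fit_quadratic(t, t^2)
  expect_equal(c(f1$a, f1$b, f1$c), c(1, 0, 0), tolerance = 1e-9)
  expect_lt(f1$rmse, 1e-10)
  f2 <- fit_quadratic(t, 30 + 20 * t)
  expect_equal(c(f2$a, f2$b, f2$c), c(0, 20, 30), tolerance = 1e-9)
  expect_error(fit_quadratic(c(0, 1), c(1, 2)), "underdetermined")
  # noisy quadratic: coefficients within 3 standard errors of truth
  # (oracle: the normal-equations solve is lm itself; truth 2t^2 - t + 5)
  set.seed(101)
  y <- 2 * t^2 - t + 5 + rnorm(50, sd = 0.1)
  f3 <- fit_quadratic(t, y)
  X <- cbind(1, t, t^2)
  se <- sqrt(diag(solve(crossprod(X))) * sum((y - X %*% c(f3$c, f3$b, f3$a))^2) / 47)
  expect_lt(abs(f3$a - 2), 3 * se[3])
  expect_lt(abs(f3$b - -1), 3 * se[2])
  expect_lt(abs(f3$c - 5), 3 * se[1])
})

test_that("S1/S2 trend-line areas match their closed forms", {
  cyc <- tri_cycle(1000)
  expect_equal(as.numeric(s1_area(cyc)), 17.5, tolerance = 1e-3)
  fr <- falling_rate(subdivide_waveform(cyc))
  expect_equal(as.numeric(s2_area(cyc, fr = fr)), 2.5, tolerance = 1e-3)
  # with FR forced to the balance constant 25, S2 is the raw fit integral
  expect_equal(as.numeric(s2_area(cyc, fr = 25)), 17.5, tolerance = 1e-3)
  # quadratic-fit integral vs trapezoid oracle on the gamma_like rising limb
  g <- cardiac_cycle(make_pulse_template(gamma_spec(200, rf = 0.4)), 1)
  ex <- waveform_extrema(g)
  p <- ex$peak_index
  ts <- (seq_len(g$n) - 1) * g$f / g$n
  trap <- sum(diff(ts[1:p]) * (g$samples[1:(p - 1)] + g$samples[2:p]) / 2)
  expect_equal(as.numeric(s1_area(g)), trap, tolerance = 0.05)
})

test_that("compute_pwf aggregates all parameters consistently", {
  p <- compute_pwf(tri_cycle(1000))
  expect_equal(p$bos, TRI_EXPECT$bos, tolerance = 0.01)
  expect_equal(p$bot, TRI_EXPECT$bot, tolerance = 0.01)
  expect_equal(p$ri, TRI_EXPECT$ri, tolerance = 0.01)
  expect_equal(p$ati, TRI_EXPECT$ati, tolerance = 0.01)
  expect_equal(p$rr, TRI_EXPECT$rr, tolerance = 0.01)
  expect_equal(p$fr, TRI_EXPECT$fr, tolerance = 0.01)
  expect_equal(p$s1_area, TRI_EXPECT$s1, tolerance = 0.01)
  expect_equal(p$s2_area, TRI_EXPECT$s2, tolerance = 0.01)
  # exact internal identities
  expect_equal(p$ri, p$ac / p$mbr_max, tolerance = 1e-12)
  expect_equal(p$bos, 200 - 100 * p$ac / p$mbr, tolerance = 1e-12)
  expect_equal(p$bot, 100 * p$w / p$f, tolerance = 1e-12)
  expect_error(compute_pwf(cardiac_cycle(rep(35, 16), 1)),
               "compute_pwf failed at")
})

test_that("amplitude scaling leaves shape parameters invariant", {
  for (spec in list(tri_spec(400), gamma_spec(400, rf = 0.4))) {
    cyc <- cardiac_cycle(make_pulse_template(spec), 0.8)
    p1 <- compute_pwf(cyc)
    p2 <- compute_pwf(cardiac_cycle(2 * cyc$samples, 0.8))
    for (nm in c("bos", "bot", "rr", "fr", "ri", "ati")) {
      expect_equal(p2[[nm]], p1[[nm]], tolerance = 1e-9, label = nm)
    }
    for (nm in c("mbr", "mbr_max", "mbr_min", "ac", "fai", "s1_area",
                 "s2_area")) {
      expect_equal(p2[[nm]], 2 * p1[[nm]], tolerance = 1e-9, label = nm)
    }
  }
})

test_that("shrinking AC at fixed DC raises BOS and lowers RI strictly", {
  acs <- c(12, 9, 6, 3)
  ps <- lapply(acs, function(a)
    compute_pwf(cardiac_cycle(make_pulse_template(tri_spec(500, ac = a)), 1)))
  bos <- vapply(ps, `[[`, numeric(1), "bos")
  ri <- vapply(ps, `[[`, numeric(1), "ri")
  expect_true(all(diff(bos) > 0))
  expect_true(all(diff(ri) < 0))
})
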