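#' One normalized cardiac-cycle waveform
#'
#' Container for a region-mean MBR waveform normalized to a single cardiac
#' cycle: `N` samples on the grid t_i = i * F / N (the first sample sits at
#' the cycle onset, which by convention is the waveform minimum), with `F`
#' the cycle duration in seconds.
#'
#' @param samples Numeric vector of MBR values (AU), length >= 8, finite and
#'   non-negative.
#' @param f Cycle duration F in seconds, > 0.
#' @return An object of class `cardiac_cycle`.
#' @export
cardiac_cycle <- function(samples, f) {
  if (!is.numeric(samples) || length(samples) < 8L) {
    stop("a cardiac cycle needs at least 8 samples", call. = FALSE)
  }
  if (any(!is.finite(samples)) || any(samples < 0)) {
    stop("cycle samples must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0) {
    stop("cycle duration F must be a positive number", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), f = as.numeric(f),
                 n = length(samples)),
            class = "cardiac_cycle")
}

#' @export
print.cardiac_cycle <- function(x, ...) {
  cat(sprintf("<cardiac_cycle> N=%d samples over F=%.4g s; MBR %.3g..%.3g AU\n",
              x$n, x$f, min(x$samples), max(x$samples)))
  invisible(x)
}

## sample times t_i = (i-1) * F / N
cycle_times <- function(cycle) (seq_len(cycle$n) - 1) * cycle$f / cycle$n

#' Synchronize a pulsatile series to one cardiac cycle
#'
#' Detects the dominant cardiac period of a region-mean MBR series by
#' autocorrelation, marks one fiducial per beat at the mid-level crossing
#' of the systolic upstroke (the steepest, hence least jittery, landmark;
#' located to sub-frame precision by linear interpolation), linearly
#' resamples each complete fiducial-to-fiducial segment to `n_out` points,
#' averages the segments pointwise, and finally rotates the averaged cycle
#' so that it starts at its minimum (the cycle-onset convention used by
#' every downstream parameter). `F` is the mean beat duration.
#'
#' @param series Numeric MBR time series spanning at least two cardiac
#'   cycles.
#' @param frame_rate_hz Sampling rate of `series` in Hz.
#' @param n_out Number of samples in the normalized cycle (default 30,
#'   minimum 8).
#' @return A [cardiac_cycle()] with attribute `n_segments` (beats averaged)
#'   and `period_frames` (estimated period).
#' @export
synchronize_cycles <- function(series, frame_rate_hz, n_out = 30L) {
  if (n_out < 8L) stop("n_out must be at least 8", call. = FALSE)
  n <- length(series)
  if (n < 16L || !all(is.finite(series))) {
    stop("synchronization error: series too short or non-finite",
         call. = FALSE)
  }
  if (stats::sd(series) == 0) {
    stop("synchronization error: series is constant, no cardiac periodicity",
         call. = FALSE)
  }

  period <- dominant_period(series)
  if (is.na(period) || n < 2 * period) {
    stop("synchronization error: no dominant cardiac period detectable",
         call. = FALSE)
  }

  # light smoothing so sample noise does not create spurious crossings
  win <- max(3L, 2L * floor(period / 12) + 1L)
  sm <- stats::filter(series, rep(1 / win, win), sides = 2)
  sm[is.na(sm)] <- series[is.na(sm)]
  sm <- as.numeric(sm)

  mid <- (max(sm) + min(sm)) / 2
  up <- which(sm[-n] < mid & sm[-1L] >= mid)
  marks <- numeric(0)
  for (i in up) {
    frac <- (mid - sm[i]) / (sm[i + 1L] - sm[i])
    cand <- i + frac
    if (!length(marks) || cand - marks[length(marks)] >= 0.5 * period) {
      marks <- c(marks, cand)
    }
  }
  if (length(marks) < 2L) {
    stop("synchronization error: fewer than one complete cycle located",
         call. = FALSE)
  }

  segs <- cbind(marks[-length(marks)], marks[-1L])
  out <- matrix(NA_real_, nrow = nrow(segs), ncol = n_out)
  for (j in seq_len(nrow(segs))) {
    a <- segs[j, 1]; b <- segs[j, 2]
    u <- a + (seq_len(n_out) - 1) * (b - a) / n_out
    out[j, ] <- stats::approx(seq_len(n), series, xout = u)$y
  }
  f <- mean(segs[, 2] - segs[, 1]) / frame_rate_hz
  avg <- colMeans(out)
  # rotate so the cycle starts at its minimum
  k <- which.min(avg)
  avg <- c(avg[k:n_out], avg[seq_len(k - 1L)])
  cyc <- cardiac_cycle(pmax(avg, 0), f)
  attr(cyc, "n_segments") <- nrow(segs)
  attr(cyc, "period_frames") <- period
  cyc
}

## Dominant period in frames from the autocorrelation function, refined by
## parabolic interpolation. Returns NA when no credible peak exists.
dominant_period <- function(series) {
  n <- length(series)
  lag_max <- floor(n / 2)
  ac <- as.numeric(stats::acf(series, lag.max = lag_max, plot = FALSE,
                              demean = TRUE)$acf)[-1L] # drop lag 0
  if (length(ac) < 3L) return(NA_real_)
  k <- 2:(length(ac) - 1L)
  peaks <- k[ac[k] > ac[k - 1L] & ac[k] >= ac[k + 1L]]
  peaks <- peaks[ac[peaks] > 0.2]
  if (!length(peaks)) return(NA_real_)
  # smallest lag comparable to the strongest peak = the fundamental
  best <- max(ac[peaks])
  lag <- min(peaks[ac[peaks] >= 0.8 * best])
  # parabolic refinement for non-integer periods
  y0 <- ac[lag - 1L]; y1 <- ac[lag]; y2 <- ac[lag + 1L]
  den <- y0 - 2 * y1 + y2
  delta <- if (abs(den) > .Machine$double.eps) 0.5 * (y0 - y2) / den else 0
  lag + max(-0.5, min(0.5, delta))
}

#' Waveform extrema and mean level
#'
#' Scans a normalized cycle for MBRmax, MBRmin, their difference AC, the
#' cycle mean DC, and the time of the (first) peak.
#'
#' @param cycle A [cardiac_cycle()].
#' @return List with `mbr_max`, `mbr_min`, `ac`, `dc`, `t_peak` (s) and
#'   `peak_index` (1-based sample index).
#' @export
waveform_extrema <- function(cycle) {
  stopifnot(inherits(cycle, "cardiac_cycle"))
  y <- cycle$samples
  i <- which.max(y)
  list(mbr_max = max(y), mbr_min = min(y), ac = max(y) - min(y),
       dc = mean(y), t_peak = (i - 1) * cycle$f / cycle$n, peak_index = i)
}

#' Blowout score (BOS)
#'
#' Vessel-resistance index `(2 - AC/DC) * 100`: how much blood flow is
#' maintained through the cycle relative to its mean. A flat waveform gives
#' 200, a waveform whose swing equals its mean gives 100.
#'
#' @param ex Extrema list from [waveform_extrema()], or any list with `ac`
#'   and `dc`.
#' @return BOS (percent-like score).
#' @export
blowout_score <- function(ex) {
  if (!is.finite(ex$dc) || ex$dc <= 0) {
    stop("BOS undefined: DC must be positive", call. = FALSE)
  }
  (2 - ex$ac / ex$dc) * 100
}

#' Blowout time (BOT) and half width
#'
#' Fraction of the cardiac cycle during which MBR stays at or above the
#' half level `MBRmin + AC/2`. Crossing times are located by linear
#' interpolation on the closed cycle (the onset value is repeated at t = F);
#' samples exactly at the half level count as above. `W` is the total time
#' above the level, and `BOT = 100 * W / F`. A flat cycle (AC = 0) sits at
#' its own half level for the whole beat, so `W = F` and `BOT = 100` by
#' convention.
#'
#' @param cycle A [cardiac_cycle()].
#' @param ex Optional extrema (recomputed if missing).
#' @return List with `w` (s) and `bot` (percent).
#' @export
blowout_time <- function(cycle, ex = waveform_extrema(cycle)) {
  f <- cycle$f; n <- cycle$n
  if (ex$ac == 0) return(list(w = f, bot = 100))
  half <- ex$mbr_min + ex$ac / 2
  y <- c(cycle$samples, cycle$samples[1L]) - half
  dt <- f / n
  w <- 0
  for (i in seq_len(n)) {
    y0 <- y[i]; y1 <- y[i + 1L]
    if (y0 >= 0 && y1 >= 0) {
      w <- w + dt
    } else if (y0 >= 0 && y1 < 0) {
      w <- w + dt * y0 / (y0 - y1)
    } else if (y0 < 0 && y1 >= 0) {
      w <- w + dt * y1 / (y1 - y0)
    }
  }
  list(w = w, bot = 100 * w / f)
}

#' Subdivide the waveform into rising/falling areas
#'
#' Splits the cycle at the peak time T2 and integrates by the trapezoid rule
#' (closing the cycle with the onset value at T4 = F). Four aggregate areas
#' are produced against the baseline y = 0: the area under the curve on the
#' rising limb (`s1_under`), its complement inside the rectangle of height
#' MBRmax (`rise_above`), and the same pair for the falling limb
#' (`fall_under`, `fall_above`). These aggregates are the operands of the
#' rising/falling-rate and S1/S2-area computations. `w` is the half width
#' from [blowout_time()].
#'
#' @param cycle A [cardiac_cycle()].
#' @param ex Optional extrema.
#' @return List with `t0`, `t2`, `t4`, `s1_under`, `rise_above`,
#'   `fall_under`, `fall_above`, `w`.
#' @export
subdivide_waveform <- function(cycle, ex = waveform_extrema(cycle)) {
  p <- ex$peak_index
  if (p <= 1L || ex$t_peak >= cycle$f) {
    stop("degenerate phase: waveform peak must lie strictly inside the cycle",
         call. = FALSE)
  }
  ts <- c(cycle_times(cycle), cycle$f)
  ys <- c(cycle$samples, cycle$samples[1L])
  t2 <- ex$t_peak
  s1_under <- trapz(ts[1:p], ys[1:p])
  fall_under <- trapz(ts[p:(cycle$n + 1L)], ys[p:(cycle$n + 1L)])
  list(t0 = 0, t2 = t2, t4 = cycle$f,
       s1_under = s1_under,
       rise_above = t2 * ex$mbr_max - s1_under,
       fall_under = fall_under,
       fall_above = (cycle$f - t2) * ex$mbr_max - fall_under,
       w = blowout_time(cycle, ex)$w)
}

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)

#' Rising rate (RR)
#'
#' Area-ratio index of the upstroke: `25 * s1_under / rise_above`, the area
#' under the rising limb against its complement inside the MBRmax rectangle,
#' scaled by the constant C = 25 used for colour balance in LSFG software.
#'
#' @param areas Output of [subdivide_waveform()].
#' @return RR.
#' @export
rising_rate <- function(areas) {
  if (areas$rise_above <= 0) {
    stop("RR undefined: instantaneous rise (zero above-curve rising area)",
         call. = FALSE)
  }
  25 * areas$s1_under / areas$rise_above
}

#' Falling rate (FR)
#'
#' Area-ratio index of the downstroke: `25 * fall_above / fall_under`. With
#' this identification the S2 area, `(integral of the falling limb) * FR /
#' 25`, equals `fall_above` exactly when the quadratic fit is exact.
#'
#' @param areas Output of [subdivide_waveform()].
#' @return FR.
#' @export
falling_rate <- function(areas) {
  if (areas$fall_under <= 0) {
    stop("FR undefined: zero under-curve falling area", call. = FALSE)
  }
  25 * areas$fall_above / areas$fall_under
}

#' Flow acceleration index (FAI)
#'
#' Maximum consecutive-frame increase of MBR over the normalized cycle,
#' `max_i (y[i+1] - y[i])`, in AU per frame.
#'
#' @param cycle A [cardiac_cycle()].
#' @return FAI (AU/frame); 0 for a constant cycle.
#' @export
flow_acceleration_index <- function(cycle) {
  max(diff(cycle$samples), 0)
}

#' Acceleration time index (ATI)
#'
#' Percent of the cycle elapsed at the waveform peak, `100 * t_peak / F`.
#' The LSFG literature names ATI but prints no formula; this is the
#' conventional acceleration-time construction and is documented as a
#' package definition, not a published one.
#'
#' @param cycle A [cardiac_cycle()].
#' @param ex Optional extrema.
#' @return ATI (percent).
#' @export
acceleration_time_index <- function(cycle, ex = waveform_extrema(cycle)) {
  100 * ex$t_peak / cycle$f
}

#' Resistive index (RI)
#'
#' `(MBRmax - MBRmin) / MBRmax = AC / MBRmax`, the ocular analogue of the
#' Doppler resistive index; lies in [0, 1] for non-negative waveforms.
#'
#' @param ex Extrema list.
#' @return RI (dimensionless).
#' @export
resistivity_index <- function(ex) {
  if (!is.finite(ex$mbr_max) || ex$mbr_max <= 0) {
    stop("RI undefined: MBRmax must be positive", call. = FALSE)
  }
  ex$ac / ex$mbr_max
}

#' Least-squares quadratic fit
#'
#' Fits `y = a t^2 + b t + c` by ordinary least squares; used as the
#' second-order trend line from which the S1/S2 areas are integrated in
#' closed form.
#'
#' @param t,y Numeric vectors (at least 3 distinct time points).
#' @return List with `a`, `b`, `c`, `rmse`.
#' @export
fit_quadratic <- function(t, y) {
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(unique(t)) < 3L) {
    stop("underdetermined fit: need at least 3 distinct time points",
         call. = FALSE)
  }
  X <- cbind(1, t, t^2)
  co <- stats::lm.fit(X, y)$coefficients
  res <- y - X %*% co
  list(a = unname(co[3L]), b = unname(co[2L]), c = unname(co[1L]),
       rmse = sqrt(mean(res^2)))
}

## closed-form integral of the fitted quadratic over [lo, hi]
quad_integral <- function(fit, lo, hi) {
  Fq <- function(t) fit$a * t^3 / 3 + fit$b * t^2 / 2 + fit$c * t
  Fq(hi) - Fq(lo)
}

#' S1 area of the rising limb
#'
#' Fits the second-order trend line to the rising-limb samples [T0, T2] and
#' integrates the fitted polynomial in closed form over that interval.
#'
#' @param cycle A [cardiac_cycle()].
#' @param ex Optional extrema.
#' @return S1 area (AU s) with attribute `fit` (the quadratic fit).
#' @export
s1_area <- function(cycle, ex = waveform_extrema(cycle)) {
  p <- ex$peak_index
  if (p <= 1L) {
    stop("degenerate phase: S1 needs an interior peak", call. = FALSE)
  }
  ts <- cycle_times(cycle)
  fit <- fit_quadratic(ts[1:p], cycle$samples[1:p])
  structure(quad_integral(fit, 0, ex$t_peak), fit = fit)
}

#' S2 area of the falling limb
#'
#' Fits the trend line to the falling-limb samples [T2, T4] (the cycle is
#' closed with the onset value at T4 = F), integrates it in closed form, and
#' scales by `FR / 25`. Under an exact fit this returns the above-curve
#' falling area.
#'
#' @param cycle A [cardiac_cycle()].
#' @param ex Optional extrema.
#' @param fr Falling rate; computed from the waveform when missing.
#' @return S2 area (AU s) with attribute `fit`.
#' @export
s2_area <- function(cycle, ex = waveform_extrema(cycle),
                    fr = falling_rate(subdivide_waveform(cycle, ex))) {
  p <- ex$peak_index
  if (p <= 1L || ex$t_peak >= cycle$f) {
    stop("degenerate phase: S2 needs an interior peak", call. = FALSE)
  }
  ts <- c(cycle_times(cycle), cycle$f)
  ys <- c(cycle$samples, cycle$samples[1L])
  fit <- fit_quadratic(ts[p:(cycle$n + 1L)], ys[p:(cycle$n + 1L)])
  structure(quad_integral(fit, ex$t_peak, cycle$f) * fr / 25, fit = fit)
}

#' Compute the full set of pulse-waveform parameters
#'
#' Runs extrema, blowout score/time, subdivision, rising/falling rates, flow
#' acceleration index, acceleration time index, resistive index, and the
#' S1/S2 trend-line areas on one normalized cycle.
#'
#' @param cycle A [cardiac_cycle()].
#' @return Object of class `pwf_parameters`: a named list with `mbr` (the
#'   cycle-mean DC, reported as "MBR"), `mbr_max`, `mbr_min`, `ac`, `bos`,
#'   `bot`, `rr`, `fr`, `fai`, `ati`, `ri`, `s1_area`, `s2_area`, `w`, `f`,
#'   `n_frames`.
#' @export
compute_pwf <- function(cycle) {
  stopifnot(inherits(cycle, "cardiac_cycle"))
  ex <- waveform_extrema(cycle)
  wrap <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("compute_pwf failed at %s: %s", what, conditionMessage(e)),
           call. = FALSE)
    })
  }
  bos <- wrap("BOS", blowout_score(ex))
  bt <- wrap("BOT", blowout_time(cycle, ex))
  areas <- wrap("waveform subdivision", subdivide_waveform(cycle, ex))
  rr <- wrap("RR", rising_rate(areas))
  fr <- wrap("FR", falling_rate(areas))
  fai <- flow_acceleration_index(cycle)
  ati <- acceleration_time_index(cycle, ex)
  ri <- wrap("RI", resistivity_index(ex))
  s1 <- wrap("S1 area", as.numeric(s1_area(cycle, ex)))
  s2 <- wrap("S2 area", as.numeric(s2_area(cycle, ex, fr)))
  structure(
    list(mbr = ex$dc, mbr_max = ex$mbr_max, mbr_min = ex$mbr_min, ac = ex$ac,
         bos = bos, bot = bt$bot, rr = rr, fr = fr, fai = fai, ati = ati,
         ri = ri, s1_area = s1, s2_area = s2, w = bt$w, f = cycle$f,
         n_frames = cycle$n),
    class = "pwf_parameters"
  )
}

#' @export
print.pwf_parameters <- function(x, ...) {
  cat("<pwf_parameters>\n")
  cat(sprintf("  MBR (DC) %.3f AU  [%.3f, %.3f], AC %.3f\n",
              x$mbr, x$mbr_min, x$mbr_max, x$ac))
  cat(sprintf("  BOS %.2f  BOT %.2f  RR %.2f  FR %.3f\n",
              x$bos, x$bot, x$rr, x$fr))
  cat(sprintf("  FAI %.3f AU/frame  ATI %.2f%%  RI %.3f\n",
              x$fai, x$ati, x$ri))
  cat(sprintf("  S1 %.3f  S2 %.3f AU s  W %.3f s of F %.3f s (N=%d)\n",
              x$s1_area, x$s2_area, x$w, x$f, x$n_frames))
  invisible(x)
}

#' @export
as.data.frame.pwf_parameters <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
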