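#' Pulse template specification
#'
#' Describes one idealized single-cycle MBR pulse: a mean level `dc`, a
#' peak-to-trough amplitude `ac`, the fraction of the cycle spent rising to
#' the peak, and a waveform family. The cycle starts at the waveform minimum
#' (the convention used for cardiac-cycle synchronization throughout the
#' package) and samples are laid on the grid t_i = i/n_frames, i = 0..n-1.
#'
#' Both families are normalized so that the sample minimum is `dc - ac/2`
#' and the maximum `dc + ac/2`. For the `triangular` family the cycle mean
#' equals `dc` exactly in the continuous limit; for `gamma_like` (power-law
#' rise, exponential fall) the mean sits below `dc` because the pulse is
#' peaked.
#'
#' @param dc Mean MBR level, arbitrary units (AU). Must satisfy `dc > ac/2`
#'   so the waveform stays positive.
#' @param ac Peak-to-trough amplitude (AU), `>= 0`.
#' @param rise_fraction Fraction of the cycle from onset to peak, in (0, 1).
#' @param shape `"triangular"` (piecewise linear) or `"gamma_like"`
#'   (gamma-density-like rise, exponential fall).
#' @param n_frames Samples per cycle, a positive integer.
#' @param rise_power Sharpness of the `gamma_like` rise (ignored for
#'   triangular); larger is steeper near onset.
#' @param fall_rate Decay rate of the `gamma_like` fall in units of inverse
#'   fall duration; larger values hug the trough sooner.
#' @return An object of class `pulse_template_spec`.
#' @export
pulse_template_spec <- function(dc, ac, rise_fraction = 0.5,
                                shape = c("triangular", "gamma_like"),
                                n_frames = 30L,
                                rise_power = 3, fall_rate = 3) {
  shape <- match.arg(shape)
  if (!is.numeric(n_frames) || length(n_frames) != 1L ||
      is.na(n_frames) || n_frames < 1) {
    stop("invalid pulse template spec: n_frames must be a positive integer",
         call. = FALSE)
  }
  n_frames <- as.integer(round(n_frames))
  if (!is.finite(dc) || !is.finite(ac) || ac < 0) {
    stop("invalid pulse template spec: ac must be finite and >= 0",
         call. = FALSE)
  }
  if (dc <= ac / 2) {
    stop("invalid pulse template spec: need dc > ac/2 so MBR stays positive",
         call. = FALSE)
  }
  if (!is.finite(rise_fraction) || rise_fraction <= 0 || rise_fraction >= 1) {
    stop("invalid pulse template spec: rise_fraction must lie in (0, 1)",
         call. = FALSE)
  }
  structure(
    list(dc = dc, ac = ac, rise_fraction = rise_fraction, shape = shape,
         n_frames = n_frames, rise_power = rise_power, fall_rate = fall_rate),
    class = "pulse_template_spec"
  )
}

#' @export
print.pulse_template_spec <- function(x, ...) {
  cat(sprintf(
    "<pulse_template_spec> %s: dc=%g AU, ac=%g AU, rise=%.2f, n=%d\n",
    x$shape, x$dc, x$ac, x$rise_fraction, x$n_frames))
  invisible(x)
}

## Unit pulse shape on phase in [0,1): 0 at onset, 1 at the peak
## (phase = rise_fraction). Vectorized over `phase`.
pulse_unit_shape <- function(spec, phase) {
  rf <- spec$rise_fraction
  phase <- phase %% 1
  s <- numeric(length(phase))
  rising <- phase <= rf
  if (spec$shape == "triangular") {
    s[rising] <- phase[rising] / rf
    s[!rising] <- (1 - phase[!rising]) / (1 - rf)
  } else {
    k <- spec$rise_power
    u <- phase[rising] / rf
    s[rising] <- u^k * exp(k * (1 - u))
    U <- 1 - rf
    lam <- spec$fall_rate / U
    v <- phase[!rising] - rf
    # exponential fall rescaled to hit 0 exactly at the next onset
    s[!rising] <- (exp(-lam * v) - exp(-lam * U)) / (1 - exp(-lam * U))
  }
  s
}

## Evaluate the template in MBR units at arbitrary cycle phase.
pulse_eval <- function(spec, phase) {
  spec$dc - spec$ac / 2 + spec$ac * pulse_unit_shape(spec, phase)
}

#' Sample one cycle of a pulse template
#'
#' Emits `n_frames` MBR samples over one cycle on the grid t_i = i/n_frames.
#' The minimum sample is `dc - ac/2` (attained at the onset, t = 0) and the
#' peak is at index `round(rise_fraction * n_frames)` (0-based).
#'
#' @param spec A [pulse_template_spec()].
#' @return Numeric vector of length `spec$n_frames`.
#' @export
make_pulse_template <- function(spec) {
  if (!inherits(spec, "pulse_template_spec")) {
    spec <- do.call(pulse_template_spec, as.list(spec))
  }
  n <- spec$n_frames
  pulse_eval(spec, (seq_len(n) - 1) / n)
}

#' Percent stenosis from vessel diameters
#'
#' Degree of arterial narrowing from the pre-ligation diameter and the
#' residual lumen diameter, `100 * (1 - d_residual / d_baseline)`. Tying a
#' ~2 mm common carotid artery down to a 0.5 mm lumen gives 75%.
#'
#' @param d_baseline Baseline vessel diameter (mm), `> 0`.
#' @param d_residual Residual lumen diameter (mm), in `[0, d_baseline]`.
#' @return Percent stenosis in `[0, 100]`.
#' @export
percent_stenosis <- function(d_baseline, d_residual) {
  if (!is.numeric(d_baseline) || !is.numeric(d_residual) ||
      any(!is.finite(d_baseline)) || any(!is.finite(d_residual))) {
    stop("diameters must be finite numbers", call. = FALSE)
  }
  if (any(d_baseline <= 0)) {
    stop("d_baseline must be positive", call. = FALSE)
  }
  if (any(d_residual < 0) || any(d_residual > d_baseline)) {
    stop("d_residual must lie in [0, d_baseline]", call. = FALSE)
  }
  100 * (1 - d_residual / d_baseline)
}
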