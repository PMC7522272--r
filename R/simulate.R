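#' Longitudinal study configuration
#'
#' Parameters of a synthetic carotid-stenosis LSFG study: cohort size,
#' acquisition settings, the measurement-day schedule, the day at which the
#' vessel-resistance phase (VRP) hands over to the vessel-elasticity phase
#' (VEP), per-parameter drift rates, and noise levels. Defaults mirror the
#' modelled study: 10 rabbits, heart rate 240 bpm, 30 Hz frames, 4-s
#' acquisitions, 8 pre-surgery baseline sessions, daily follow-up to day 28
#' with the VRP ending at day 19.
#'
#' `drift` holds per-day log-scale drift rates (so -0.025 is a 2.5% daily
#' decline) for the directly drifted parameters, one vector per phase; see
#' [default_drift()]. `session_cv` is the session-to-session coefficient of
#' variation of the PWF parameters; `noise_sd` is additive per-pixel frame
#' noise in AU; `nba_effect_size` scales the NBA-vs-day slope.
#'
#' @param n_rabbits Number of animals.
#' @param heart_rate_bpm Heart rate (beats/min).
#' @param frame_rate_hz Frame rate (Hz).
#' @param acquisition_s Acquisition length (s); must cover >= 2 cardiac
#'   cycles.
#' @param baseline_sessions Pre-surgery sessions per rabbit.
#' @param days Post-surgery measurement days.
#' @param vrp_end_day Last day of the VRP regime.
#' @param drift List with elements `vrp` and `vep`, named per-day log drift
#'   rates.
#' @param noise_sd Per-pixel additive frame noise (AU).
#' @param session_cv Relative session noise on PWF parameters.
#' @param nba_effect_size NBA slope scale (points/day at default 0.5).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_rabbits = 10L,
                         heart_rate_bpm = 240,
                         frame_rate_hz = 30,
                         acquisition_s = 4,
                         baseline_sessions = 8L,
                         days = 1:28,
                         vrp_end_day = 19L,
                         drift = default_drift(),
                         noise_sd = 0.5,
                         session_cv = 0.03,
                         nba_effect_size = 0.5,
                         seed = 1L) {
  cycles <- acquisition_s * heart_rate_bpm / 60
  if (!is.finite(cycles) || cycles < 2) {
    stop("invalid config: the acquisition must span at least 2 cardiac cycles",
         call. = FALSE)
  }
  if (length(days) < 1L) {
    stop("invalid config: days must be non-empty", call. = FALSE)
  }
  vals <- unlist(drift)
  if (any(!is.finite(vals))) {
    stop("invalid config: drift magnitudes must be finite", call. = FALSE)
  }
  structure(
    list(n_rabbits = as.integer(n_rabbits),
         heart_rate_bpm = heart_rate_bpm, frame_rate_hz = frame_rate_hz,
         acquisition_s = acquisition_s,
         baseline_sessions = as.integer(baseline_sessions),
         days = as.integer(days), vrp_end_day = as.integer(vrp_end_day),
         drift = drift, noise_sd = noise_sd, session_cv = session_cv,
         nba_effect_size = nba_effect_size, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Default per-day drift rates for the two impairment regimes
#'
#' Log-scale daily drift of the directly generated PWF parameters. During
#' the VRP, amplitude (AC) collapses while mean flow (DC) holds, so BOS
#' rises and FAI/RI/AC fall with BOT and FR flat; during the VEP, mean flow
#' falls faster than amplitude, so BOS also declines, together with BOT, FR,
#' FAI, RI and AC. The study this emulates reports only directions and
#' significance, not magnitudes, so these rates are chosen to make the
#' directions recoverable at realistic session noise (see the methods
#' vignette).
#'
#' @return List with per-phase named rate vectors.
#' @export
default_drift <- function() {
  list(
    vrp = c(dc = 0,      ac = -0.025, ri = -0.02,  fai = -0.025,
            bot = 0,     fr = 0,      rr = 0,      ati = 0),
    vep = c(dc = -0.03,  ac = -0.01,  ri = -0.015, fai = -0.02,
            bot = -0.015, fr = -0.015, rr = -0.005, ati = -0.005)
  )
}

## Baseline pulse templates per ONH region: vessels are bright, tissue dim.
region_templates <- function(n_frames = 200L) {
  list(
    MV = pulse_template_spec(dc = 45, ac = 45 * 0.28, rise_fraction = 0.35,
                             shape = "triangular", n_frames = n_frames),
    MT = pulse_template_spec(dc = 28, ac = 28 * 0.28, rise_fraction = 0.35,
                             shape = "triangular", n_frames = n_frames)
  )
}

#' Simulate one LSFG frame-sequence acquisition
#'
#' Builds an ROI-sized stack in which every pixel repeats its compartment's
#' pulse template at the configured heart rate, sampled at the frame rate,
#' plus i.i.d. Gaussian noise. The vessel compartment is a deterministic
#' seeded branching-line pattern covering 10-30% of the ROI; the returned
#' ground-truth masks partition the ROI.
#'
#' @param config A [study_config()].
#' @param template_vessel,template_tissue [pulse_template_spec()]s; the
#'   vessel template must have the larger `dc` (vessels are bright in MBR
#'   maps).
#' @param seed Seed for mask jitter, phase, and noise (default from config).
#' @param shape ROI size in pixels, `c(rows, cols)`.
#' @param phase0 Cardiac phase at the first frame, in [0,1); `NULL` draws it
#'   at random.
#' @return List with `frames` (an [mbr_frames()]), `masks` (ground-truth
#'   [region_masks()]), and `phase0`.
#' @export
simulate_frame_sequence <- function(config,
                                    template_vessel = region_templates()$MV,
                                    template_tissue = region_templates()$MT,
                                    seed = config$seed,
                                    shape = c(48L, 48L),
                                    phase0 = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (template_vessel$dc <= template_tissue$dc) {
    stop("vessel template dc must exceed tissue template dc", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nt <- round(config$frame_rate_hz * config$acquisition_s)
  if (is.null(phase0)) phase0 <- stats::runif(1)
  vmask <- draw_vessel_mask(shape[1L], shape[2L])
  phase <- phase0 + (seq_len(nt) - 1) / config$frame_rate_hz *
    config$heart_rate_bpm / 60
  v_series <- pulse_eval(template_vessel, phase)
  t_series <- pulse_eval(template_tissue, phase)
  frames <- array(0, dim = c(shape[1L], shape[2L], nt))
  v <- as.vector(vmask)
  for (k in seq_len(nt)) {
    frames[, , k] <- ifelse(vmask, v_series[k], t_series[k])
  }
  if (config$noise_sd > 0) {
    frames <- frames + stats::rnorm(length(frames), sd = config$noise_sd)
  }
  frames <- pmax(frames, 0)
  list(frames = mbr_frames(frames, config$frame_rate_hz,
                           config$acquisition_s),
       masks = region_masks(vmask, !vmask),
       phase0 = phase0)
}

## Deterministic (given the RNG state) branching-line vessel pattern:
## a trunk descending through the ROI with a few side branches, rasterized
## by distance-to-segment, with the stroke width tuned so that vessel
## pixels cover 10-30% of the ROI.
draw_vessel_mask <- function(nr, nc) {
  jit <- function(s) stats::runif(1, -s, s)
  trunk_x <- nc * (0.5 + jit(0.08))
  segs <- list(
    c(1, trunk_x, nr * 0.45, nc * (0.45 + jit(0.05))),
    c(nr * 0.45, nc * (0.45 + jit(0.05)), nr, nc * (0.55 + jit(0.08))),
    c(nr * 0.30, nc * 0.47, nr * 0.75, nc * (0.15 + jit(0.05))),
    c(nr * 0.40, nc * 0.48, nr * 0.85, nc * (0.85 + jit(0.05))),
    c(nr * 0.60, nc * 0.52, nr * 0.95, nc * (0.30 + jit(0.05)))
  )
  px <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dmin <- rep(Inf, nrow(px))
  for (s in segs) {
    dmin <- pmin(dmin, dist_to_segment(px$r, px$c, s[1], s[2], s[3], s[4]))
  }
  lo <- 0.1; hi <- max(nr, nc)
  for (i in 1:30) { # bisect stroke width into the 10-30% coverage band
    w <- (lo + hi) / 2
    frac <- mean(dmin <= w)
    if (frac < 0.10) lo <- w else if (frac > 0.30) hi <- w else break
  }
  matrix(dmin <= w, nrow = nr, ncol = nc)
}

dist_to_segment <- function(pr, pc, r0, c0, r1, c1) {
  vr <- r1 - r0; vc <- c1 - c0
  len2 <- vr^2 + vc^2
  t <- pmax(0, pmin(1, ((pr - r0) * vr + (pc - c0) * vc) / len2))
  sqrt((pr - (r0 + t * vr))^2 + (pc - (c0 + t * vc))^2)
}

## Ground-truth multiplicative drift factor for one parameter at one day.
drift_factor <- function(rate_vrp, rate_vep, day, vrp_end) {
  exp(rate_vrp * pmin(day, vrp_end) + rate_vep * pmax(0, day - vrp_end))
}

#' Simulate a full longitudinal carotid-stenosis study
#'
#' Generates per-rabbit, per-session, per-region PWF records with known
#' ground truth: 8 (by default) pre-surgery baseline sessions, then one
#' session per post-surgery day, drifting through a vessel-resistance
#' regime (BOS up; FAI, RI, AC down; BOT, FR flat) until `vrp_end_day` and
#' a vessel-elasticity regime (BOS, BOT, FR, FAI, RI, AC all down)
#' afterwards. NBA totals rise with day so that their rank correlation with
#' BOS is positive and with RI negative.
#'
#' Two output levels are available. `"pwf"` (default) drifts the PWF
#' parameters directly with exact internal identities (BOS = (2-AC/DC)x100,
#' RI = AC/MBRmax, MBRmax = AC/RI, W = BOT x F/100); this is the generator
#' used by the statistical layer. `"timeseries"` emits per-session region
#' MBR series from drifted pulse templates (DC and AC drift; shape fixed)
#' for driving the synchronization/analysis pipeline end to end; at the
#' waveform level BOT and FR are geometric consequences of the template, so
#' only the amplitude-driven sign pattern is reproduced there (see the
#' methods vignette).
#'
#' @param config A [study_config()].
#' @param level `"pwf"` or `"timeseries"`.
#' @return For `"pwf"`: a `data.frame` with columns `rabbit_id`, `day`,
#'   `is_baseline`, `region`, the 16 PWF columns of [compute_pwf()], and
#'   `nba_total`, with attribute `ground_truth` (noise-free parameter
#'   values and `phase` per record). For `"timeseries"`: a long
#'   `data.frame` (`rabbit_id`, `day`, `is_baseline`, `region`,
#'   `frame_index`, `time_s`, `mbr`) plus the same `nba` attribute.
#' @export
simulate_longitudinal_study <- function(config, level = c("pwf", "timeseries")) {
  stopifnot(inherits(config, "study_config"))
  level <- match.arg(level)
  if (!is.null(config$seed)) set.seed(config$seed)
  sessions <- data.frame(
    day = c(rep(0L, config$baseline_sessions), config$days),
    is_baseline = c(rep(TRUE, config$baseline_sessions),
                    rep(FALSE, length(config$days)))
  )
  sessions$session <- seq_len(nrow(sessions))
  grid <- expand.grid(rabbit_id = seq_len(config$n_rabbits),
                      session = sessions$session,
                      region = c("MA", "MV", "MT"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- merge(grid, sessions, by = "session")
  grid <- grid[order(grid$rabbit_id, grid$session, grid$region), ]
  rownames(grid) <- NULL

  nba <- simulate_nba_totals(config, sessions)
  if (level == "pwf") {
    out <- simulate_pwf_records(config, grid)
    out$nba_total <- nba$nba_total[match(
      paste(out$rabbit_id, out$session),
      paste(nba$rabbit_id, nba$session))]
    return(out)
  }
  out <- simulate_timeseries_records(config, grid)
  attr(out, "nba") <- nba
  out
}

## Baseline PWF vectors per region, computed once from the region templates
## so parameter-space records stay consistent with the waveform model.
baseline_pwf <- function() {
  tpl <- region_templates(n_frames = 400L)
  f0 <- 0.25
  pv <- compute_pwf(cardiac_cycle(make_pulse_template(tpl$MV), f0))
  pt <- compute_pwf(cardiac_cycle(make_pulse_template(tpl$MT), f0))
  # MA: area-weighted mix at a nominal 20% vessel fraction
  mix <- function(a, b) 0.2 * a + 0.8 * b
  ma <- cardiac_cycle(mix(make_pulse_template(tpl$MV),
                          make_pulse_template(tpl$MT)), f0)
  pa <- compute_pwf(ma)
  list(MA = pa, MV = pv, MT = pt)
}

simulate_pwf_records <- function(config, grid) {
  base <- baseline_pwf()
  n <- nrow(grid)
  d <- grid$day
  gt <- grid[c("rabbit_id", "day", "is_baseline", "region", "session")]
  gt$phase <- ifelse(d == 0, "NORMAL",
                     ifelse(d <= config$vrp_end_day, "VRP", "VEP"))
  free <- c("dc", "ac", "ri", "bot", "fr", "fai", "rr", "ati")
  rates <- config$drift
  bvals <- sapply(grid$region, function(rg) {
    p <- base[[rg]]
    c(dc = p$mbr, ac = p$ac, ri = p$ri, bot = p$bot, fr = p$fr,
      fai = p$fai, rr = p$rr, ati = p$ati)
  })
  # ground truth = baseline x regime drift; RI is tied below its geometric
  # ceiling AC/DC so MBRmax = AC/RI stays above DC
  gtv <- sapply(free, function(pp) {
    bvals[pp, ] * drift_factor(rates$vrp[[pp]], rates$vep[[pp]], d,
                               config$vrp_end_day)
  })
  # records are parameter summaries: RI drifts freely and MBRmax = AC/RI is
  # derived, so the RI identity is exact; MBRmax need not bracket DC
  obs <- gtv * exp(matrix(stats::rnorm(n * length(free), sd = config$session_cv),
                          nrow = n))
  f <- 60 / config$heart_rate_bpm * exp(stats::rnorm(n, sd = config$session_cv / 3))
  derive <- function(m) {
    mbr_max <- m[, "ac"] / m[, "ri"]
    data.frame(
      mbr = m[, "dc"], mbr_max = mbr_max, mbr_min = mbr_max - m[, "ac"],
      ac = m[, "ac"], bos = (2 - m[, "ac"] / m[, "dc"]) * 100,
      bot = m[, "bot"], rr = m[, "rr"], fr = m[, "fr"], fai = m[, "fai"],
      ati = m[, "ati"], ri = m[, "ri"]
    )
  }
  obs_df <- derive(obs)
  gt_df <- derive(gtv)
  # S1/S2 track the mean-flow and amplitude drifts respectively
  s1b <- sapply(grid$region, function(rg) base[[rg]]$s1_area)
  s2b <- sapply(grid$region, function(rg) base[[rg]]$s2_area)
  obs_df$s1_area <- s1b * obs[, "dc"] / bvals["dc", ]
  obs_df$s2_area <- s2b * obs[, "ac"] / bvals["ac", ]
  gt_df$s1_area <- s1b * gtv[, "dc"] / bvals["dc", ]
  gt_df$s2_area <- s2b * gtv[, "ac"] / bvals["ac", ]
  obs_df$w <- obs_df$bot / 100 * f
  obs_df$f <- f
  obs_df$n_frames <- 30L
  gt_df$w <- gt_df$bot / 100 * (60 / config$heart_rate_bpm)
  gt_df$f <- 60 / config$heart_rate_bpm
  out <- cbind(grid[c("rabbit_id", "day", "is_baseline", "region", "session")],
               obs_df)
  attr(out, "ground_truth") <- cbind(gt, gt_df)
  out
}

simulate_nba_totals <- function(config, sessions) {
  grid <- expand.grid(rabbit_id = seq_len(config$n_rabbits),
                      session = sessions$session,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- merge(grid, sessions, by = "session")
  expected <- ifelse(grid$day == 0, 0, config$nba_effect_size * grid$day)
  raw <- round(expected + stats::rnorm(nrow(grid), sd = 1.5))
  grid$nba_total <- pmax(0L, pmin(19L, as.integer(raw)))
  grid[order(grid$rabbit_id, grid$session),
       c("rabbit_id", "session", "day", "is_baseline", "nba_total")]
}

#' Decompose NBA totals into item-level scoring sheets
#'
#' Distributes each session's target total across the 11 rubric items
#' (respecting per-item maxima) in a seeded random order, producing the
#' item-level CSV consumed by the scoring stage. Re-scoring the sheet
#' reproduces the totals exactly.
#'
#' @param nba Data frame with `rabbit_id`, `day`, `nba_total` (and
#'   optionally `session`).
#' @return Item-level data frame in the `nba_items` schema.
#' @export
nba_items_from_totals <- function(nba) {
  items <- names(NBA_ITEM_MAX)
  mat <- matrix(0L, nrow = nrow(nba), ncol = length(items),
                dimnames = list(NULL, items))
  for (i in seq_len(nrow(nba))) {
    remaining <- min(nba$nba_total[i], 19L)
    for (it in sample(items)) {
      take <- min(remaining, NBA_ITEM_MAX[[it]])
      mat[i, it] <- take
      remaining <- remaining - take
      if (remaining == 0L) break
    }
  }
  out <- data.frame(rabbit_id = nba$rabbit_id, day = nba$day,
                    session = nba$session %||% seq_len(nrow(nba)))
  out <- cbind(out, as.data.frame(mat))
  out$is_dead <- nba$nba_total >= 20L
  out
}

simulate_timeseries_records <- function(config, grid) {
  # per-session region series from drifted templates; regions of a session
  # share the cardiac phase, and MA is the 20/80 vessel/tissue mix
  nt <- round(config$frame_rate_hz * config$acquisition_s)
  t_s <- (seq_len(nt) - 1) / config$frame_rate_hz
  rates <- config$drift
  tpl <- region_templates()
  sess <- unique(grid[c("rabbit_id", "session", "day", "is_baseline")])
  res <- vector("list", nrow(sess) * 3L)
  k <- 0L
  for (i in seq_len(nrow(sess))) {
    d <- sess$day[i]
    fdc <- drift_factor(rates$vrp[["dc"]], rates$vep[["dc"]], d,
                        config$vrp_end_day) *
      exp(stats::rnorm(1, sd = config$session_cv))
    fac <- drift_factor(rates$vrp[["ac"]], rates$vep[["ac"]], d,
                        config$vrp_end_day) *
      exp(stats::rnorm(1, sd = config$session_cv))
    phase0 <- stats::runif(1)
    hr <- config$heart_rate_bpm * exp(stats::rnorm(1, sd = config$session_cv / 3))
    phase <- phase0 + t_s * hr / 60
    mk <- function(spec) {
      s2 <- spec; s2$dc <- spec$dc * fdc; s2$ac <- min(spec$ac * fac,
                                                       1.9 * s2$dc)
      pulse_eval(s2, phase)
    }
    mv <- mk(tpl$MV); mt <- mk(tpl$MT)
    ma <- 0.2 * mv + 0.8 * mt
    for (rg in c("MA", "MV", "MT")) {
      y <- switch(rg, MA = ma, MV = mv, MT = mt)
      if (config$noise_sd > 0) {
        y <- y + stats::rnorm(nt, sd = config$noise_sd)
      }
      k <- k + 1L
      res[[k]] <- data.frame(
        rabbit_id = sess$rabbit_id[i], day = d,
        is_baseline = sess$is_baseline[i], region = rg,
        session = sess$session[i],
        frame_index = seq_len(nt) - 1L, time_s = t_s, mbr = pmax(y, 0))
    }
  }
  do.call(rbind, res)
}
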