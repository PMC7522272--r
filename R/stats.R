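#' Normalize a PWF parameter to its baseline
#'
#' Divides each rabbit/region's parameter values by the mean of that
#' rabbit/region's baseline (pre-surgery) sessions, so baseline sessions
#' normalize to mean 1.0 and post-surgery values are expressed as fold
#' change from the animal's own baseline.
#'
#' @param dataset Data frame with columns `rabbit_id`, `day`, `is_baseline`,
#'   `region`, and the parameter column.
#' @param parameter Name of the parameter column.
#' @return The dataset with added columns `baseline_mean` and `norm`.
#' @export
normalize_to_baseline <- function(dataset, parameter) {
  if (!parameter %in% names(dataset)) {
    stop("unknown parameter column: ", parameter, call. = FALSE)
  }
  key <- interaction(dataset$rabbit_id, dataset$region, drop = TRUE)
  base <- tapply(dataset[[parameter]][dataset$is_baseline],
                 key[dataset$is_baseline], mean)
  bm <- as.numeric(base[as.character(key)])
  if (any(is.na(bm))) {
    stop("normalization error: some rabbit/region has no baseline sessions",
         call. = FALSE)
  }
  if (any(bm <= 0)) {
    stop("normalization error: non-positive baseline mean", call. = FALSE)
  }
  dataset$baseline_mean <- bm
  dataset$norm <- dataset[[parameter]] / bm
  dataset
}

#' Remove outliers by Tukey fences
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` with quartiles by
#' linear interpolation (R quantile type 7). With fewer than 4 values the
#' rule is skipped and everything is kept.
#'
#' @param values Numeric vector.
#' @return List with `kept`, `removed_indices`, `fences`, and `skipped`.
#' @export
remove_outliers <- function(values) {
  ok <- which(is.finite(values))
  if (length(ok) < 4L) {
    return(list(kept = values, removed_indices = integer(0),
                fences = c(NA_real_, NA_real_), skipped = TRUE))
  }
  q <- stats::quantile(values[ok], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  fences <- c(q[1L] - 1.5 * iqr, q[2L] + 1.5 * iqr)
  out <- which(values < fences[1L] | values > fences[2L])
  list(kept = if (length(out)) values[-out] else values,
       removed_indices = out, fences = fences, skipped = FALSE)
}

#' One-way repeated-measures test across timepoints
#'
#' Runs a one-way repeated-measures ANOVA on a complete rabbits x
#' timepoints matrix, falling back to Friedman's rank test when the
#' additive-model residuals fail Shapiro-Wilk normality at `alpha`. For the
#' ANOVA branch, sphericity is checked by Mauchly's test on orthonormal
#' contrasts and Greenhouse-Geisser-corrected degrees of freedom are used
#' when it rejects.
#'
#' @param mat Numeric matrix, rows = subjects (>= 3), columns = timepoints
#'   (>= 3), complete cases.
#' @param alpha Normality/sphericity gate level.
#' @return List with `statistic`, `df`, `p`, `method` (`"rm_anova"` or
#'   `"friedman"`), `normality_p`, and for the ANOVA branch `gg_epsilon`
#'   and `mauchly_p`.
#' @export
rm_test <- function(mat, alpha = 0.05) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3L || k < 3L || any(!is.finite(mat))) {
    stop("rm_test needs a complete matrix with >= 3 subjects and >= 3 ",
         "timepoints", call. = FALSE)
  }
  row_m <- rowMeans(mat); col_m <- colMeans(mat); g <- mean(mat)
  resid <- mat - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + g
  ss_time <- n * sum((col_m - g)^2)
  ss_err <- sum(resid^2)
  if (ss_time + ss_err < .Machine$double.eps * n * k * max(1, g^2)) {
    stop("degenerate test: no within-subject variance", call. = FALSE)
  }
  norm_p <- tryCatch(stats::shapiro.test(as.numeric(resid))$p.value,
                     error = function(e) 0)
  if (norm_p < alpha) {
    fr <- stats::friedman.test(mat)
    return(list(statistic = unname(fr$statistic), df = unname(fr$parameter),
                p = fr$p.value, method = "friedman", normality_p = norm_p))
  }
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  if (ss_err <= 0) {
    stop("degenerate test: zero error variance", call. = FALSE)
  }
  f_stat <- (ss_time / df1) / (ss_err / df2)
  sp <- mauchly_sphericity(mat)
  eps <- 1
  if (!is.na(sp$p) && sp$p < alpha) eps <- sp$gg_epsilon
  p <- stats::pf(f_stat, eps * df1, eps * df2, lower.tail = FALSE)
  list(statistic = f_stat, df = c(eps * df1, eps * df2), p = p,
       method = "rm_anova", normality_p = norm_p,
       gg_epsilon = eps, mauchly_p = sp$p)
}

## Mauchly's sphericity test and Greenhouse-Geisser epsilon from the
## covariance of orthonormal within-subject contrasts.
mauchly_sphericity <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  C <- stats::contr.helmert(k)
  C <- C %*% diag(1 / sqrt(colSums(C^2)), k - 1, k - 1)
  S <- stats::cov(mat %*% C)
  tr <- sum(diag(S))
  gg <- tr^2 / ((k - 1) * sum(S^2))
  ev_ok <- tr > 0 && det(S) > 0
  if (!ev_ok || n - 1 <= k - 1) {
    return(list(p = NA_real_, gg_epsilon = max(gg, 1 / (k - 1))))
  }
  W <- det(S) / (tr / (k - 1))^(k - 1)
  d <- k - 1
  f <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
  chi <- -(n - 1) * f * log(W)
  df <- d * (d + 1) / 2 - 1
  list(p = stats::pchisq(chi, df, lower.tail = FALSE),
       gg_epsilon = min(1, max(gg, 1 / d)))
}

#' Correlation with a normality-gated method choice
#'
#' Pearson's correlation when both margins pass Shapiro-Wilk normality at
#' `alpha`, Spearman's rank correlation otherwise (or when forced).
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @param force_method `NULL` for the automatic gate, else `"pearson"` or
#'   `"spearman"`.
#' @param alpha Normality gate level.
#' @return List with `r`, `p`, `method`, `n`.
#' @export
correlate <- function(x, y, force_method = NULL, alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("correlate needs at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  if (is.null(force_method)) {
    swp <- function(v) {
      v <- if (length(v) > 5000) v[seq(1, length(v), length.out = 5000)] else v
      tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
    }
    method <- if (swp(x) < alpha || swp(y) < alpha) "spearman" else "pearson"
  } else {
    method <- match.arg(force_method, c("pearson", "spearman"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, method = method, n = n)
}

#' Multivariate (multiple) regression of NBA on PWF parameters
#'
#' Ordinary least squares of the NBA score on a set of PWF predictors,
#' reporting unstandardized coefficients B with standard errors,
#' standardized coefficients beta (from z-scored predictors and response),
#' the multiple correlation R, and the overall F test.
#'
#' @param pwf_matrix Numeric matrix or data frame of predictors (no
#'   constant columns, full rank, n > p + 1).
#' @param nba_vector Response vector.
#' @return List with `coefficients` (data.frame: term, B, SE_B, beta, t,
#'   p), `R`, `R2`, `F`, `df`, `p`.
#' @export
multivariate_fit <- function(pwf_matrix, nba_vector) {
  X <- as.matrix(pwf_matrix)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(nba_vector)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("predictor/response length mismatch", call. = FALSE)
  if (n <= p + 1L) {
    stop("multivariate_fit needs n > p + 1 observations", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1L) {
    dropped <- colnames(X)[setdiff(seq_len(p), qrX$pivot[seq_len(qrX$rank)] - 1L)]
    stop("collinearity error: rank-deficient design; offending columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(y ~ ., data = data.frame(y = y, X, check.names = FALSE))
  sm <- summary(fit)
  co <- sm$coefficients[-1L, , drop = FALSE]
  beta <- co[, 1L] * sds / stats::sd(y)
  res <- data.frame(term = colnames(X), B = co[, 1L], SE_B = co[, 2L],
                    beta = beta, t = co[, 3L], p = co[, 4L],
                    row.names = NULL)
  fstat <- sm$fstatistic
  list(coefficients = res, R = sqrt(sm$r.squared), R2 = sm$r.squared,
       F = unname(fstat[1L]), df = unname(fstat[2:3]),
       p = stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
}

#' Per-parameter linear trends over a day window
#'
#' Baseline-normalizes each parameter, pools all rabbits' post-surgery
#' values inside the window, and fits `norm ~ day` by least squares. The
#' slope's two-sided t test at `alpha` later decides "up" / "down" / "flat"
#' in [classify_phase()].
#'
#' @param dataset PWF data frame (schema of [simulate_longitudinal_study()]).
#' @param parameters Character vector of parameter columns.
#' @param window `c(first_day, last_day)`, inclusive.
#' @param region Region to analyse (default `"MA"`).
#' @return Data frame `parameter`, `slope`, `se`, `t`, `p`, `n`,
#'   `window_lo`, `window_hi`; class `trend_summary`.
#' @export
fit_trends <- function(dataset, parameters, window, region = "MA") {
  stopifnot(length(window) == 2L, window[1L] <= window[2L])
  rows <- lapply(parameters, function(pp) {
    nd <- normalize_to_baseline(dataset, pp)
    sel <- !nd$is_baseline & nd$region == region &
      nd$day >= window[1L] & nd$day <= window[2L]
    d <- nd[sel, ]
    if (length(unique(d$day)) < 3L) {
      stop("trend window must contain >= 3 timepoints for ", pp,
           call. = FALSE)
    }
    fit <- summary(stats::lm(norm ~ day, data = d))$coefficients
    data.frame(parameter = pp, slope = fit["day", 1L], se = fit["day", 2L],
               t = fit["day", 3L], p = fit["day", 4L], n = nrow(d),
               window_lo = window[1L], window_hi = window[2L])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trend_summary", class(out))
  out
}

#' Classify the vessel state from six parameter trends
#'
#' Applies the two-stage reading of chronic-stenosis ocular hemodynamics: a
#' slope is "up"/"down" when its two-sided t test rejects at `alpha` with
#' the corresponding sign, else "flat". The window is labelled
#' - `VRP` (vessel resistance phase) when BOS is up, FAI/RI/AC are down,
#'   and BOT and FR are not down;
#' - `VEP` (vessel elasticity phase) when all six are down;
#' - `NORMAL` when all six are flat;
#' - `INDETERMINATE` otherwise.
#'
#' @param trends A `trend_summary` (from [fit_trends()]) covering BOS, BOT,
#'   FR, FAI, RI and AC.
#' @param alpha Significance level for the slope tests.
#' @return Character label with attribute `directions`.
#' @export
classify_phase <- function(trends, alpha = 0.05) {
  need <- c("bos", "bot", "fr", "fai", "ri", "ac")
  idx <- match(need, tolower(trends$parameter))
  if (any(is.na(idx))) {
    stop("classify_phase needs trends for BOS, BOT, FR, FAI, RI and AC; ",
         "missing: ", paste(need[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  tr <- trends[idx, ]
  dir <- ifelse(tr$p < alpha & tr$slope > 0, "up",
                ifelse(tr$p < alpha & tr$slope < 0, "down", "flat"))
  names(dir) <- need
  label <- if (dir["bos"] == "up" && all(dir[c("fai", "ri", "ac")] == "down") &&
               all(dir[c("bot", "fr")] != "down")) {
    "VRP"
  } else if (all(dir == "down")) {
    "VEP"
  } else if (all(dir == "flat")) {
    "NORMAL"
  } else {
    "INDETERMINATE"
  }
  structure(label, directions = dir)
}

#' Run the longitudinal statistical battery
#'
#' For each region and parameter: baseline-normalized repeated-measures
#' test across days, correlation with the NBA score, and per-window phase
#' classification; plus one multivariate regression of NBA on the PWF set
#' per region.
#'
#' @param pwf PWF data frame (with `nba_total`, as produced by
#'   [simulate_longitudinal_study()], or merged from a separate NBA table).
#' @param parameters Parameter columns to analyse.
#' @param phase_windows List of `c(lo, hi)` day windows to classify.
#' @param alpha Significance level.
#' @return List with `tests`, `correlations`, `regressions`, `phases`.
#' @export
run_stats <- function(pwf,
                      parameters = c("mbr", "bos", "bot", "rr", "fr", "fai",
                                     "ati", "ri", "ac"),
                      phase_windows = list(),
                      alpha = 0.05) {
  regions <- sort(unique(pwf$region))
  tests <- list(); cors <- list()
  for (rg in regions) {
    sub <- pwf[pwf$region == rg, ]
    for (pp in parameters) {
      nd <- normalize_to_baseline(sub, pp)
      post <- nd[!nd$is_baseline, ]
      mat <- tapply(post$norm, list(post$rabbit_id, post$day), mean)
      res <- tryCatch({
        m <- mat[stats::complete.cases(mat), , drop = FALSE]
        rt <- rm_test(m, alpha = alpha)
        data.frame(test = "rm", region = rg, parameter = pp,
                   statistic = rt$statistic, p = rt$p, method = rt$method)
      }, error = function(e) NULL)
      tests[[paste(rg, pp)]] <- res
      if ("nba_total" %in% names(pwf)) {
        ct <- tryCatch(correlate(sub[[pp]], sub$nba_total), error = function(e) NULL)
        if (!is.null(ct)) {
          cors[[paste(rg, pp)]] <- data.frame(
            test = "correlation", region = rg, parameter = pp,
            statistic = ct$r, p = ct$p, method = ct$method)
        }
      }
    }
  }
  regr <- lapply(regions, function(rg) {
    sub <- pwf[pwf$region == rg, ]
    if (!"nba_total" %in% names(sub)) return(NULL)
    tryCatch(multivariate_fit(sub[parameters], sub$nba_total),
             error = function(e) NULL)
  })
  names(regr) <- regions
  phases <- lapply(phase_windows, function(w) {
    tr <- fit_trends(pwf, c("bos", "bot", "fr", "fai", "ri", "ac"), w)
    lab <- classify_phase(tr, alpha = alpha)
    list(window = w, label = as.character(lab),
         directions = attr(lab, "directions"), trends = tr)
  })
  list(tests = do.call(rbind, tests), correlations = do.call(rbind, cors),
       regressions = regr, phases = phases)
}
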