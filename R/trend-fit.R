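# FOOOF-style decomposition of a power spectrum into an aperiodic trend
# (one of the closed forms in eval_trend) plus Gaussian oscillatory peaks.
#
# All trend fitting happens on log10 power: EEG spectra span 4+ decades and
# a least-squares loss in linear power would be dominated by the lowest
# frequency bins.

default_tau_bounds <- function(trend_form, tau_r) {
  b <- list(tau1 = c(0.002, 0.2), tau2 = c(2e-4, 0.005))
  if (trend_form == "diff_exp_plus_const")
    b$tau1[1] <- max(b$tau1[1], tau_r * 1.05)
  b
}

# Raw trend evaluation on the optimiser's transformed parameter vector,
# bypassing object construction/validation (called thousands of times per
# fit).
eval_trend_raw <- function(trend_form, th, f, tau_r) {
  switch(trend_form,
    two_lorentzian = 10^th[1] * lorentzian(f, 10^th[2]) +
      10^th[3] * lorentzian(f, 10^th[4]),
    lorentzian_plus_const = 10^(th[1] + th[2]) * lorentzian(f, 10^th[2]) +
      10^th[3],
    diff_exp_plus_const = 10^th[1] * (tau_r - 10^th[2])^2 *
      lorentzian(f, tau_r) * lorentzian(f, 10^th[2]) + 10^th[3])
}

# Least-squares trend fit in log10-power space with multi-start
# Levenberg-Marquardt. `mask` selects the frequency bins entering the loss.
# `fixed` pins parameters (natural scale) by name: "A1", "lam" (and for the
# two-Lorentzian form "A2"); pinned parameters leave the optimisation.
fit_trend_core <- function(freq, power, trend_form, bounds, tau_r, mask = NULL,
                           start = NULL, fixed = NULL, smear_hw = 0,
                           weights = NULL, loss = "log") {
  if (is.null(mask)) mask <- rep(TRUE, length(freq))
  if (is.null(weights)) weights <- rep(1, length(freq))
  wt <- weights[mask]
  f <- freq[mask]; lp <- log10(power[mask]); pw <- power[mask]
  scale <- max(power[mask])
  tiny <- scale * 1e-12

  make_params <- function(th) {
    switch(trend_form,
      two_lorentzian = trend_params("two_lorentzian", A1 = 10^th[1],
        tau1 = 10^th[2], A2 = 10^th[3], tau2 = 10^th[4]),
      lorentzian_plus_const = trend_params("lorentzian_plus_const", A1 = 10^th[1],
        tau1 = 10^th[2], lam = 10^th[3]),
      diff_exp_plus_const = trend_params("diff_exp_plus_const", A1 = 10^th[1],
        tau1 = 10^th[2], lam = 10^th[3], tau_r = tau_r))
  }
  if (smear_hw > 0) {
    # spectral-window smearing: the estimator reports the average of the
    # true spectrum over +/- smear_hw around each bin (multitaper bandwidth
    # W = NW / T); fit the identically smeared model. 7-point Gauss-Legendre.
    gl_x <- c(-0.9491079123427585, -0.7415311855993944, -0.4058451513773972,
              0, 0.4058451513773972, 0.7415311855993944, 0.9491079123427585)
    gl_w <- c(0.1294849661688697, 0.2797053914892767, 0.3818300505051189,
              0.4179591836734694, 0.3818300505051189, 0.2797053914892767,
              0.1294849661688697) / 2
    f_nodes <- pmax(outer(f, gl_x * smear_hw, "+"), 0)
    model_fn <- function(th) {
      m <- eval_trend_raw(trend_form, th, as.vector(f_nodes), tau_r)
      as.vector(matrix(m, nrow = length(f)) %*% gl_w)
    }
  } else {
    model_fn <- function(th) eval_trend_raw(trend_form, th, f, tau_r)
  }
  sqw <- sqrt(wt)
  resid_fn <- if (loss == "log") {
    function(th) sqw * (log10(model_fn(th) + tiny) - lp)
  } else {
    # Whittle deviance residuals for periodogram data: per bin
    # 2 (p/m - log(p/m) - 1), scaled by the bin's degrees-of-freedom
    # weight; asymptotically unbiased where log-least-squares is not
    function(th) {
      m <- model_fn(th) + tiny
      r <- pw / m
      sqw * sqrt(2 * pmax(r - log(r) - 1, 0)) * sign(r - 1)
    }
  }

  t1b <- log10(bounds$tau1)
  lo_f <- min(f[f > 0]); hi_f <- max(f)
  lam0 <- max(mean(10^lp[f >= 0.8 * hi_f]), tiny)
  A10 <- max(mean(10^lp[f <= 2 * lo_f]) - lam0, tiny)

  starts <- list(); lower <- NULL; upper <- NULL
  t1_grid <- seq(t1b[1], t1b[2], length.out = if (is.null(start)) 5 else 3)
  if (trend_form == "two_lorentzian") {
    t2b <- log10(bounds$tau2)
    lower <- c(log10(tiny), t1b[1], log10(tiny), t2b[1])
    upper <- c(log10(scale * 1e3), t1b[2], log10(scale * 1e3), t2b[2])
    for (t1 in t1_grid)
      starts[[length(starts) + 1]] <- c(log10(A10), t1, log10(lam0), mean(t2b))
  } else {
    # amplitude convention differs per form; derive A1 start from DC value
    dc_gain <- if (trend_form == "lorentzian_plus_const") function(tau) tau
               else function(tau) (tau_r - tau)^2
    lower <- c(-Inf, t1b[1], log10(tiny))
    upper <- c(Inf, t1b[2], log10(scale * 1e6))
    for (t1 in t1_grid)
      starts[[length(starts) + 1]] <- c(log10(A10 / dc_gain(10^t1)), t1, log10(lam0))
  }
  if (!is.null(start)) starts <- c(list(start), starts)

  # pin any fixed parameters, optimising only over the free coordinates
  par_names <- if (trend_form == "two_lorentzian")
    c("A1", "tau1", "A2", "tau2") else c("A1", "tau1", "lam")
  fix_idx <- integer(0); fix_val <- numeric(0)
  if (!is.null(fixed) && length(fixed)) {
    fix_idx <- match(names(fixed), par_names)
    if (anyNA(fix_idx)) stop("unknown fixed parameter", call. = FALSE)
    fix_val <- log10(pmax(unlist(fixed), 1e-300))
  }
  free_idx <- setdiff(seq_along(par_names), fix_idx)
  to_full <- function(thf) {
    v <- numeric(length(par_names))
    v[fix_idx] <- fix_val; v[free_idx] <- thf
    v
  }
  resid_free <- function(thf) resid_fn(to_full(thf))

  run_lm <- function(s, maxit) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = s[free_idx], fn = resid_free,
                         lower = lower[free_idx], upper = upper[free_idx],
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit, ftol = 1e-14, ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = to_full(unname(fit$par)), objective = sum(fit$fvec^2))
  }
  best <- NULL
  for (s in starts) {
    fit <- run_lm(s, 60)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best)) stop("trend fit failed from every start", call. = FALSE)
  # polish the winner
  pol <- run_lm(best$par, 300)
  if (!is.null(pol) && pol$objective <= best$objective) best <- pol
  list(params = make_params(best$par), par = best$par, objective = best$objective)
}

gauss_eval <- function(f, th) th[2] * exp(-(f - th[1])^2 / (2 * th[3]^2))

# Fit one Gaussian to the working residual around its maximum at index i.
# `resid` is in the chosen peak space; `w_init` from the half-height extent
# of the dB residual; widths are capped at `max_width` (narrowband peaks).
fit_one_gaussian <- function(f, resid, i, w_init, max_width) {
  c0 <- f[i]; h0 <- resid[i]
  w_min <- min(diff(f)) / 2
  w0 <- min(max(w_init, w_min), max_width)
  win <- abs(f - c0) <= 4 * w0
  obj <- function(th) sum((gauss_eval(f[win], th) - resid[win])^2)
  fit <- stats::nlminb(c(c0, h0, w0), obj,
                       lower = c(max(min(f), c0 - 2 * w0), 0, w_min),
                       upper = c(min(max(f), c0 + 2 * w0), 2 * h0, max_width))
  fit$par
}

# half-height extent (in Hz) of the dB residual around index i
half_height_width <- function(f, resid_db, i) {
  h <- resid_db[i]
  above <- resid_db >= h / 2
  lo <- i; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i; while (hi < length(f) && above[hi + 1]) hi <- hi + 1
  (f[hi] - f[lo]) / 2.355
}

#' Fit an aperiodic trend plus Gaussian peaks to a spectrum
#'
#' Iterative FOOOF-style decomposition: (1) a robust trend fit in log10-power
#' space that down-weights putative peak regions; (2) detection of residual
#' peaks above a threshold, fitted as Gaussians largest-first; (3) a trend
#' refit on the peak-subtracted spectrum; repeated to convergence.
#'
#' For raw spectra (`peak_space = "linear"`) peaks are parameterised as
#' additive spectral density above the trend, so that an independent additive
#' signal component leaves peak heights of other components unchanged. For
#' detrended spectra use `peak_space = "db"`.
#'
#' @param spectrum a [new_spectrum()] object (>= 20 points in the fit range).
#' @param trend_form trend model, see [trend_params()].
#' @param bounds named list of `c(lower, upper)` bounds in seconds for `tau1`
#'   (and `tau2` for the two-Lorentzian form). Defaults cover the
#'   physiological range; for propofol data use `tau1 = c(0.010, 0.075)`.
#' @param max_peaks maximum number of Gaussian peaks (default 6).
#' @param peak_threshold detection threshold in residual standard deviations
#'   (default 2).
#' @param min_peak_height minimum detectable peak height as a fraction of the
#'   trend at the peak centre (default 0.05, i.e. 5 percent above trend;
#'   equivalently ~0.2 dB). Guards against fitting numerical fit residue as
#'   peaks.
#' @param max_peak_width maximum Gaussian SD of a peak, Hz (default 4).
#'   Restricts peaks to narrowband features so broadband trend error is never
#'   absorbed into a peak.
#' @param f_range optional `c(lo, hi)` Hz restriction of the fit range.
#' @param peak_space `"linear"` or `"db"`: space in which peak Gaussians are
#'   parameterised.
#' @param tau_r fixed inhibitory rise time for `diff_exp_plus_const`, s.
#' @param max_iter,tol outer-loop convergence controls (relative parameter
#'   change below `tol`, default 1e-4, or `max_iter` iterations).
#' @param init optional warm start: the `trend` of a previous `trend_fit`
#'   on a comparable spectrum (thins the internal multi-start grid).
#' @param fixed optional named list pinning trend parameters on their
#'   natural scale (e.g. `list(A1 = 120)`); pinned parameters are excluded
#'   from the optimisation.
#' @param smear_hw half-width (Hz) of the estimator's spectral window; when
#'   positive, the model is averaged over +/- `smear_hw` around each bin
#'   before comparison, matching multitaper smoothing (W = NW / T). Leave 0
#'   for unsmoothed spectra.
#' @param loss `"log"` (least squares on log10 power, FOOOF practice) or
#'   `"whittle"` (deviance residuals of the Whittle periodogram likelihood,
#'   which avoids the small-sample bias of log least squares on noisy
#'   window spectra).
#' @param weights optional per-bin fit weights (degrees of freedom); taken
#'   from the spectrum's `bin_count` attribute (set by
#'   [log_bin_spectrum()]) when present.
#' @return a list of class `trend_fit` with elements `trend` ([trend_params()]),
#'   `peaks` (list of [peak_params()]), `diagnostics` (convergence flag,
#'   iterations, log10 RMSE) and `freq` (fitted range).
#' @export
fit_trend_and_peaks <- function(spectrum, trend_form = "two_lorentzian",
                                bounds = NULL, max_peaks = 6,
                                peak_threshold = 2, min_peak_height = 0.05,
                                max_peak_width = 4, f_range = NULL,
                                peak_space = c("linear", "db"),
                                tau_r = 0.004, max_iter = 50, tol = 1e-4,
                                init = NULL, fixed = NULL, smear_hw = 0,
                                loss = c("log", "whittle"), weights = NULL) {
  loss <- match.arg(loss)
  spectrum <- as_spectrum(spectrum)
  peak_space <- match.arg(peak_space)
  keep <- spectrum$freq > 0
  if (!is.null(f_range)) keep <- keep & spectrum$freq >= f_range[1] &
    spectrum$freq <= f_range[2]
  # degrees-of-freedom weights matter for the Whittle likelihood; the log
  # loss keeps equal weight per (log-spaced) bin
  wts <- weights
  if (is.null(wts) && loss == "whittle") wts <- attr(spectrum, "bin_count")
  if (is.null(wts)) wts <- rep(1, length(spectrum$freq))
  wts <- wts[keep]
  f <- spectrum$freq[keep]; p <- spectrum$power[keep]
  if (length(f) < 20) stop("need >= 20 frequency points in the fit range",
                           call. = FALSE)
  if (all(p == 0) || any(!is.finite(p)))
    stop("spectrum is all-zero or non-finite", call. = FALSE)
  p <- pmax(p, max(p) * 1e-15)

  b <- default_tau_bounds(trend_form, tau_r)
  if (!is.null(bounds)) b[names(bounds)] <- bounds

  init_par <- NULL
  if (!is.null(init) && inherits(init, "trend_params") &&
      init$trend_form == trend_form) {
    init_par <- switch(trend_form,
      two_lorentzian = log10(c(init$A1, init$tau1, init$A2, init$tau2)),
      lorentzian_plus_const = log10(c(init$A1, init$tau1, max(init$lam, 1e-300))),
      diff_exp_plus_const = log10(c(init$A1, init$tau1, max(init$lam, 1e-300))))
    init_par[2] <- min(max(init_par[2], log10(b$tau1[1])), log10(b$tau1[2]))
  }
  # robust initial trend: fit, drop the bins far above the model, refit
  core <- fit_trend_core(f, p, trend_form, b, tau_r, start = init_par,
                         fixed = fixed, smear_hw = smear_hw, weights = wts,
                         loss = loss)
  r <- log10(p) - log10(eval_trend(core$params, f)$power)
  mask <- r <= stats::quantile(r, 0.85)
  core <- fit_trend_core(f, p, trend_form, b, tau_r, mask = mask,
                         start = core$par, fixed = fixed, smear_hw = smear_hw,
                         weights = wts, loss = loss)

  floor_db <- 10 * log10(1 + min_peak_height)
  rmse_of <- function(core, peaks) {
    trend <- eval_trend(core$params, f)$power
    model <- if (peak_space == "linear") trend + eval_peaks(peaks, f)
             else trend * 10^(eval_peaks(peaks, f) / 10)
    sqrt(mean((log10(pmax(model, max(p) * 1e-15)) - log10(p))^2))
  }

  prev_par <- core$par
  peaks <- list()
  best <- list(core = core, peaks = peaks, rmse = rmse_of(core, peaks))
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    trend <- eval_trend(core$params, f)$power
    # detect on the dB residual (homoscedastic across the dynamic range),
    # fit each Gaussian in the requested peak space
    peaks <- list()
    p_work <- p
    repeat {
      resid_db <- 10 * (log10(p_work) - log10(trend))
      thr <- max(peak_threshold * stats::sd(resid_db), floor_db)
      i <- which.max(resid_db)
      if (length(peaks) >= max_peaks || resid_db[i] <= thr) break
      w0 <- half_height_width(f, resid_db, i)
      work <- if (peak_space == "linear") p_work - trend else resid_db
      th <- fit_one_gaussian(f, work, i, w0, max_peak_width)
      if (th[2] <= 0) break
      peaks[[length(peaks) + 1]] <- peak_params(th[1], th[2], th[3])
      g <- gauss_eval(f, th)
      p_work <- if (peak_space == "linear") pmax(p_work - g, p * 1e-6)
                else p_work / 10^(g / 10)
    }
    core <- fit_trend_core(f, p_work, trend_form, b, tau_r,
                           start = core$par, fixed = fixed,
                           smear_hw = smear_hw, weights = wts, loss = loss)
    r <- rmse_of(core, peaks)
    if (r < best$rmse) best <- list(core = core, peaks = peaks, rmse = r)
    delta <- max(abs(core$par - prev_par) / pmax(abs(prev_par), 1e-8))
    prev_par <- core$par
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  structure(list(
    trend = best$core$params,
    peaks = best$peaks,
    freq = range(f),
    peak_space = peak_space,
    diagnostics = list(converged = converged, n_iter = iter,
                       rmse_log10 = best$rmse)),
    class = "trend_fit")
}

#' Detrend a spectrum by a fitted (or model) trend
#'
#' Divisive detrending (`mode = "divide"`) expresses power relative to the
#' trend and is the appropriate correction when the trend change is
#' multiplicative (a change in postsynaptic kinetics). Subtractive detrending
#' (`mode = "subtract"`) removes an additive, independent aperiodic component.
#'
#' @param spectrum a [new_spectrum()] object.
#' @param trend a `spectrum` on the identical frequency grid (strictly
#'   positive), e.g. `eval_trend(fit$trend, spectrum$freq)`.
#' @param mode `"divide"` or `"subtract"`.
#' @param as_db if `TRUE` (divide only) return `10 log10(ratio)` in dB.
#' @return for `divide` a data frame `freq`/`power` with the ratio (or dB);
#'   for `subtract` a [new_spectrum()] clipped at zero.
#' @export
detrend <- function(spectrum, trend, mode = c("divide", "subtract"),
                    as_db = FALSE) {
  spectrum <- as_spectrum(spectrum); trend <- as_spectrum(trend)
  mode <- match.arg(mode)
  if (length(spectrum$freq) != length(trend$freq) ||
      any(abs(spectrum$freq - trend$freq) > 1e-9))
    stop("frequency grids of spectrum and trend do not match", call. = FALSE)
  if (any(trend$power <= 0)) stop("trend must be strictly positive", call. = FALSE)
  if (mode == "divide") {
    r <- spectrum$power / trend$power
    if (as_db) r <- 10 * log10(r)
    structure(data.frame(freq = spectrum$freq, power = r),
              class = c(if (!as_db) "spectrum", "data.frame"))
  } else {
    new_spectrum(spectrum$freq, pmax(spectrum$power - trend$power, 0))
  }
}

#' Power-law slope of a spectrum
#'
#' Ordinary least-squares regression of `log10(power)` on `log10(f)` over a
#' frequency range; the spectral exponent `beta` is minus the slope, i.e. the
#' spectrum is summarised as `10^alpha / f^beta`.
#'
#' @param spectrum a [new_spectrum()] object, strictly positive over `f_range`.
#' @param f_range fit range in Hz, default `c(1, 40)`.
#' @return list of class `slope_fit` with `alpha`, `beta`, `f_range`,
#'   `residual_rms`.
#' @export
fit_slope <- function(spectrum, f_range = c(1, 40)) {
  spectrum <- as_spectrum(spectrum)
  if (f_range[1] <= 0) stop("f_range must start above 0 Hz", call. = FALSE)
  keep <- spectrum$freq >= f_range[1] & spectrum$freq <= f_range[2]
  if (sum(keep) < 5) stop("fewer than 5 points in f_range", call. = FALSE)
  f <- spectrum$freq[keep]; p <- spectrum$power[keep]
  if (any(p <= 0)) stop("spectrum must be strictly positive over f_range",
                        call. = FALSE)
  fit <- stats::lm.fit(cbind(1, log10(f)), log10(p))
  structure(list(alpha = unname(fit$coefficients[1]),
                 beta = -unname(fit$coefficients[2]),
                 f_range = f_range,
                 residual_rms = sqrt(mean(fit$residuals^2))),
            class = "slope_fit")
}
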