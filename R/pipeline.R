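# The experimental analysis chain for propofol-induction EEG: multitaper
# spectrogram, per-window inhibitory-timescale (tau1) tracking, divisive
# detrending, band power, rescaled time, and group sign tests.

#' Cohort record: one subject's EEG with event times
#'
#' @param subject_id identifier.
#' @param eeg numeric vector, uV (single channel).
#' @param fs sampling rate, Hz (default 1024).
#' @param t_infusion propofol infusion onset, s.
#' @param t_loc loss of consciousness, s (`t_infusion < t_loc`).
#' @param weight body weight, kg.
#' @param infusion_rate mg kg^-1 min^-1 (typical induction protocol: 1).
#' @param truth optional list of ground-truth trajectories (synthetic data).
#' @return object of class `cohort_record`.
#' @export
cohort_record <- function(subject_id, eeg, fs = 1024, t_infusion, t_loc,
                          weight = 70, infusion_rate = 1, truth = NULL) {
  if (t_infusion >= t_loc) stop("t_infusion must precede t_loc", call. = FALSE)
  structure(list(subject_id = subject_id, eeg = as.numeric(eeg), fs = fs,
                 t_infusion = t_infusion, t_loc = t_loc, weight = weight,
                 infusion_rate = infusion_rate, truth = truth),
            class = "cohort_record")
}

#' Read / write single-channel EEG as TSV
#'
#' Layout: header `time_s\tamplitude_uv`; event times and sampling rate are
#' stored in a JSON side-car `paste0(path, ".json")`.
#'
#' @param x a [cohort_record()].
#' @param path TSV path.
#' @return `read_eeg_tsv` returns a [cohort_record()].
#' @export
write_eeg_tsv <- function(x, path) {
  stopifnot(inherits(x, "cohort_record"))
  d <- data.frame(time_s = (seq_along(x$eeg) - 1) / x$fs,
                  amplitude_uv = x$eeg)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(subject_id = x$subject_id, fs = x$fs, t_infusion = x$t_infusion,
         t_loc = x$t_loc, weight = x$weight, infusion_rate = x$infusion_rate),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eeg_tsv
#' @export
read_eeg_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cohort_record(meta$subject_id, d$amplitude_uv, fs = meta$fs,
                t_infusion = meta$t_infusion, t_loc = meta$t_loc,
                weight = meta$weight, infusion_rate = meta$infusion_rate)
}

#' Rescale time to align infusion onset and loss of consciousness
#'
#' `t -> (t - t_loc) / (t_loc - t_infusion)`: infusion onset maps to -1 and
#' LOC to 0, so subjects with different infusion-to-LOC latencies share a
#' common axis.
#'
#' @param times numeric times, s.
#' @param t_infusion infusion onset, s.
#' @param t_loc loss of consciousness, s.
#' @return rescaled times.
#' @export
rescale_time <- function(times, t_infusion, t_loc) {
  if (t_infusion >= t_loc) stop("t_infusion must precede t_loc", call. = FALSE)
  (times - t_loc) / (t_loc - t_infusion)
}

#' Track the inhibitory timescale tau1 across a spectrogram
#'
#' Fits the difference-of-exponentials trend (rise fixed at `tau_r`) plus
#' Gaussian peaks to each spectrogram window over `f_range` (frequencies
#' below ~3 Hz are excluded: there the trend is coloured by slow neural
#' dynamics rather than synaptic kinetics), after filling the line-noise
#' band. Windows can be subsampled with `stride`; skipped or failed windows
#' are linearly interpolated. The baseline tau1 is the mean over
#' pre-infusion windows and the fold change is `tau1 / baseline`.
#'
#' @param spectrogram a [new_spectrogram()].
#' @param t_infusion infusion onset, s (baseline = windows ending before it).
#' @param f_range trend fit range, Hz (default 3-100: the lower cut excludes
#'   the dynamics-coloured band, the long upper tail pins the noise floor;
#'   the mains band inside the range is filled before fitting).
#' @param tau1_bounds bounds for tau1, s (default 10-75 ms, the propofol
#'   regime).
#' @param tau_r fixed synaptic rise time, s (default 4 ms).
#' @param stride fit every `stride`-th window (default 1).
#' @param t_smooth temporal smoothing, s: each fitted spectrum is the mean
#'   over spectrogram windows within `t_smooth / 2` of the window centre
#'   (default 10 s). The inhibitory timescale drifts over minutes, so a few
#'   seconds of smoothing suppresses single-window estimator noise (which
#'   otherwise biases the weakly identified large-tau1 fits) without
#'   distorting the trajectory. Set to 0 for strictly per-window fits.
#' @param line_noise mains frequency filled before fitting; NULL to skip.
#' @param exclude_bands list of `c(lo, hi)` Hz bands removed from the trend
#'   fit (default the alpha/beta rhythm band 8-30 Hz): the synaptic trend is
#'   constrained by the flanking frequencies, so known rhythm bands need not
#'   be separated from the trend by peak fitting at all. Set to `list()` to
#'   rely on Gaussian peak removal alone.
#' @param n_per_decade log-binning density of the window spectra before
#'   fitting (equal weight per decade; also denoises).
#' @param max_peaks,max_iter fit controls passed to [fit_trend_and_peaks()].
#' @param smear_hw half-width of the spectral window built into the fitted
#'   model, Hz; defaults to the multitaper bandwidth `nw / window` recorded
#'   in the spectrogram metadata (0 if absent). Without it, spectral-window
#'   smoothing of a steep Lorentzian knee reads as a shorter timescale.
#' @param fix_lam if TRUE (default), the high-frequency floor `lam` is
#'   estimated once from the averaged pre-infusion spectrum and pinned in
#'   every window fit. The floor is a property of the recording (amplifier
#'   noise, fast excitatory timescales), and freeing it per window leaves
#'   the three trend parameters degenerate in short windows.
#' @param loss fit loss for the window fits: `"whittle"` (default, the
#'   periodogram likelihood; unbiased on noisy window spectra) or `"log"`.
#' @param fix_A1 if TRUE, additionally pin the trend amplitude `A1` at its
#'   baseline estimate, leaving tau1 as the only free trend parameter per
#'   window. Appropriate when the synaptic drive is assumed stationary and
#'   only the kinetics drift (the premise of kinetic detrending); off by
#'   default.
#' @return data frame of class `tau1_track`: `time`, `tau1` (s), `A1`,
#'   `lam`, `fitted` (logical), `fold`; attribute `baseline` (s).
#' @export
track_tau1 <- function(spectrogram, t_infusion, f_range = c(3, 100),
                       tau1_bounds = c(0.010, 0.075), tau_r = 0.004,
                       stride = 1, t_smooth = 10, line_noise = 60,
                       exclude_bands = list(c(8, 30)),
                       n_per_decade = 40, max_peaks = 3, max_iter = 4,
                       fix_lam = TRUE, fix_A1 = FALSE, smear_hw = NULL,
                       loss = "whittle") {
  stopifnot(inherits(spectrogram, "spectrogram"))
  if (is.null(smear_hw)) {
    smear_hw <- if (!is.null(spectrogram$meta$nw) &&
                    !is.null(spectrogram$meta$window))
      spectrogram$meta$nw / spectrogram$meta$window else 0
  }
  nt <- length(spectrogram$times)
  sel <- seq(1L, nt, by = stride)
  tau1 <- A1 <- lam <- rep(NA_real_, nt)

  prep <- function(pw) {
    sp <- new_spectrum(spectrogram$freq, pw)
    if (!is.null(line_noise) && line_noise > min(sp$freq) &&
        line_noise < max(sp$freq))
      sp <- fill_line_noise(sp, center = line_noise)
    if (!is.null(n_per_decade)) sp <- log_bin_spectrum(sp, n_per_decade)
    for (b in exclude_bands) {
      keep <- sp$freq < b[1] | sp$freq > b[2]
      bc <- attr(sp, "bin_count")
      sp <- new_spectrum(sp$freq[keep], sp$power[keep])
      if (!is.null(bc)) attr(sp, "bin_count") <- bc[keep]
    }
    sp
  }
  # the high-frequency floor is a property of the recording, not of the
  # window: estimate it once from the pre-infusion average and pin it
  fixed <- NULL
  if (fix_lam) {
    base_w <- which(spectrogram$times < t_infusion)
    if (length(base_w) >= 3) {
      bfit <- tryCatch(
        fit_trend_and_peaks(prep(rowMeans(spectrogram$power[, base_w,
                                                            drop = FALSE])),
                            "diff_exp_plus_const",
                            bounds = list(tau1 = tau1_bounds),
                            f_range = f_range, tau_r = tau_r,
                            max_peaks = max_peaks, max_iter = max_iter,
                            smear_hw = smear_hw, loss = loss),
        error = function(e) NULL)
      if (!is.null(bfit)) {
        fixed <- list(lam = bfit$trend$lam)
        if (fix_A1) fixed$A1 <- bfit$trend$A1
      }
    }
  }

  prev <- NULL
  for (w in sel) {
    cols <- if (t_smooth > 0)
      which(abs(spectrogram$times - spectrogram$times[w]) <= t_smooth / 2)
    else w
    sp <- prep(rowMeans(spectrogram$power[, cols, drop = FALSE]))
    # deliberately no warm start between windows: chaining initial values
    # drags the fit and lags fast parameter changes
    fit <- tryCatch(
      fit_trend_and_peaks(sp, "diff_exp_plus_const",
                          bounds = list(tau1 = tau1_bounds),
                          f_range = f_range, tau_r = tau_r,
                          max_peaks = max_peaks, max_iter = max_iter,
                          fixed = fixed, smear_hw = smear_hw, loss = loss),
      error = function(e) NULL)
    if (!is.null(fit)) {
      tau1[w] <- fit$trend$tau1; A1[w] <- fit$trend$A1; lam[w] <- fit$trend$lam
    }
  }
  fitted <- !is.na(tau1)
  if (sum(fitted) < 2) stop("tau1 tracking failed on nearly all windows",
                            call. = FALSE)
  # interpolate skipped / failed windows for display and detrending
  fill <- function(v) stats::approx(spectrogram$times[fitted], v[fitted],
                                    xout = spectrogram$times, rule = 2)$y
  tau1_f <- fill(tau1); A1_f <- fill(A1); lam_f <- fill(lam)
  base_sel <- fitted & (spectrogram$times < t_infusion)
  baseline <- if (any(base_sel)) mean(tau1[base_sel]) else mean(tau1[fitted])
  out <- data.frame(time = spectrogram$times, tau1 = tau1_f, A1 = A1_f,
                    lam = lam_f, fitted = fitted, fold = tau1_f / baseline)
  attr(out, "baseline") <- baseline
  class(out) <- c("tau1_track", "data.frame")
  out
}

#' Divisively detrend a spectrogram by its fitted synaptic trend
#'
#' Divides each window's spectrum by the difference-of-exponentials trend
#' fitted by [track_tau1()], yielding power relative to the fitted
#' inhibitory timescale (unitless; multiply-confounded changes such as a
#' tau1 drift are removed, additive oscillatory power remains).
#'
#' @param spectrogram a [new_spectrogram()].
#' @param track a `tau1_track` from [track_tau1()] on the same spectrogram.
#' @return a [new_spectrogram()] of power ratios.
#' @export
detrend_spectrogram <- function(spectrogram, track) {
  stopifnot(inherits(spectrogram, "spectrogram"), inherits(track, "tau1_track"))
  if (nrow(track) != length(spectrogram$times))
    stop("track and spectrogram disagree on window count", call. = FALSE)
  f <- spectrogram$freq
  tau_r <- 0.004
  # vectorised difference-of-exponentials trend over (frequency, window)
  L1 <- 1 / (1 + (2 * pi * outer(f, track$tau1))^2)
  amp <- track$A1 * (tau_r - track$tau1)^2
  trend <- lorentzian(f, tau_r) * L1 *
    matrix(amp, length(f), nrow(track), byrow = TRUE) +
    matrix(track$lam, length(f), nrow(track), byrow = TRUE)
  new_spectrogram(spectrogram$times, f, spectrogram$power / trend,
                  meta = c(spectrogram$meta, list(detrended = TRUE)))
}

#' Per-segment group sign test on rescaled-time series
#'
#' Splits rescaled time into consecutive segments of `segment_length` and,
#' per segment, performs an exact sign test across subjects on the
#' per-subject median of `value - threshold` (right tail by default: is the
#' group median elevated?). Ties (medians exactly at the threshold) are
#' excluded, the standard sign-test convention. No multiple-testing
#' correction is applied unless `adjust = "BH"`.
#'
#' @param series list of per-subject data frames with columns `time`
#'   (rescaled) and `value`.
#' @param segment_length segment width in rescaled-time units (default 0.05).
#' @param threshold null value (default 1, for baseline-normalised power).
#' @param tail `"right"`, `"left"` or `"two"`.
#' @param t_range optional `c(lo, hi)` restriction of rescaled time.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data frame: `seg_start`, `seg_mid`, `n`, `n_pos`, `p`.
#' @export
group_sign_test <- function(series, segment_length = 0.05, threshold = 1,
                            tail = c("right", "left", "two"),
                            t_range = NULL, adjust = c("none", "BH")) {
  tail <- match.arg(tail); adjust <- match.arg(adjust)
  if (length(series) < 5) stop("need at least 5 subjects", call. = FALSE)
  all_t <- unlist(lapply(series, function(d) d$time))
  if (is.null(t_range)) t_range <- range(all_t)
  edges <- seq(floor(t_range[1] / segment_length) * segment_length,
               t_range[2] + segment_length, by = segment_length)
  out <- NULL
  for (k in seq_len(length(edges) - 1)) {
    meds <- vapply(series, function(d) {
      inw <- d$time >= edges[k] & d$time < edges[k + 1]
      if (!any(inw)) return(NA_real_)
      stats::median(d$value[inw])
    }, numeric(1))
    meds <- meds[!is.na(meds)]
    diffs <- meds - threshold
    diffs <- diffs[diffs != 0]
    n <- length(diffs); k_pos <- sum(diffs > 0)
    if (n == 0) next
    p <- switch(tail,
      right = stats::pbinom(k_pos - 1, n, 0.5, lower.tail = FALSE),
      left = stats::pbinom(k_pos, n, 0.5),
      two = min(1, 2 * min(stats::pbinom(k_pos, n, 0.5),
                           stats::pbinom(k_pos - 1, n, 0.5,
                                         lower.tail = FALSE))))
    out <- rbind(out, data.frame(seg_start = edges[k],
                                 seg_mid = edges[k] + segment_length / 2,
                                 n = n, n_pos = k_pos, p = p))
  }
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}

#' Full per-subject propofol analysis
#'
#' Runs the complete chain on one [cohort_record()]: multitaper
#' spectrogram, tau1 tracking, divisive detrending, raw and detrended band
#' power (baseline-normalised), effect-site concentration, and the
#' per-window (Ce, tau1 fold-change) dose-response pairs.
#'
#' @param record a [cohort_record()].
#' @param window,overlap spectrogram settings, s.
#' @param stride tau1 fit stride (see [track_tau1()]).
#' @param f_max spectrogram frequency cut, Hz.
#' @param pk a [pk_params()]; weight is overridden by the record's.
#' @param ... further arguments to [track_tau1()].
#' @return list of class `subject_analysis` with elements `spectrogram`,
#'   `track`, `detrended`, `bands` (list of raw/detrended data frames per
#'   band, with rescaled time), `pk` (Ce trace), `dose` (data frame Ce /
#'   fold).
#' @export
analyze_subject <- function(record, window = 2, overlap = 1.9, stride = 1,
                            f_max = 110, pk = pk_params(), ...) {
  stopifnot(inherits(record, "cohort_record"))
  sg <- multitaper_spectrogram(record$eeg, record$fs, window = window,
                               overlap = overlap, f_max = f_max)
  track <- track_tau1(sg, record$t_infusion, stride = stride, ...)
  dsg <- detrend_spectrogram(sg, track)
  rt <- rescale_time(sg$times, record$t_infusion, record$t_loc)
  base_iv <- c(record$t_infusion - 10, record$t_infusion)
  bands <- list()
  for (b in c("delta", "alpha", "beta")) {
    raw <- band_power(sg, b, baseline = base_iv)
    det <- band_power(dsg, b, baseline = base_iv)
    bands[[b]] <- list(raw = data.frame(time = rt, value = raw$power),
                       detrended = data.frame(time = rt, value = det$power))
  }
  pk$weight <- record$weight
  ce <- marsh_effect_site(pk, record$t_infusion, record$t_loc,
                          rate = record$infusion_rate,
                          t_max = max(sg$times) + 1)
  ce_at <- stats::approx(ce$time, ce$Ce, xout = sg$times, rule = 2)$y
  structure(list(spectrogram = sg, track = track, detrended = dsg,
                 rescaled_times = rt, bands = bands, pk = ce,
                 dose = data.frame(Ce = ce_at, fold = track$fold)),
            class = "subject_analysis")
}
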