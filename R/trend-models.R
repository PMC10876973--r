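#' Aperiodic spectral-trend parameters
#'
#' Parameter set for the closed-form aperiodic trend of an EEG power
#' spectrum. Three functional forms are supported:
#'
#' * `two_lorentzian`: `A1 / (1 + (2 pi tau1 f)^2) + A2 / (1 + (2 pi tau2 f)^2)`,
#'   the sum of a slow (inhibition-governed) and a fast (excitation-governed)
#'   Lorentzian.
#' * `lorentzian_plus_const`: `A1 tau1 / (1 + (2 pi tau1 f)^2) + lam`, a single
#'   slow Lorentzian plus a high-frequency floor.
#' * `diff_exp_plus_const`:
#'   `A1 (tau_r - tau1)^2 / ((1 + (2 pi tau_r f)^2) (1 + (2 pi tau1 f)^2)) + lam`,
#'   the power spectrum of a difference-of-exponentials synaptic current
#'   (rise `tau_r`, decay `tau1`) plus a floor. `tau_r` defaults to 4 ms.
#'
#' Amplitudes are free fit amplitudes in units of spectral density; each form
#' carries its own amplitude convention.
#'
#' @param trend_form one of `"two_lorentzian"`, `"lorentzian_plus_const"`,
#'   `"diff_exp_plus_const"`.
#' @param A1,A2 non-negative amplitudes (spectral density scale). `A2` is used
#'   only by `two_lorentzian`.
#' @param tau1 slow (inhibitory) timescale, seconds.
#' @param tau2 fast (excitatory) timescale, seconds; `two_lorentzian` only.
#' @param tau_r inhibitory rise time, seconds; `diff_exp_plus_const` only.
#' @param lam additive high-frequency floor, spectral density.
#' @return object of class `trend_params`.
#' @export
trend_params <- function(trend_form = c("two_lorentzian", "lorentzian_plus_const",
                                        "diff_exp_plus_const"),
                         A1 = 1, A2 = 0, tau1 = 0.02, tau2 = 0.002,
                         tau_r = 0.004, lam = 0) {
  trend_form <- match.arg(trend_form)
  stop_if_not_scalar(A1, "A1", lower = 0)
  stop_if_not_scalar(lam, "lam", lower = 0)
  stop_if_not_scalar(tau1, "tau1")
  if (tau1 <= 0) stop("tau1 must be > 0", call. = FALSE)
  if (trend_form == "two_lorentzian") {
    stop_if_not_scalar(A2, "A2", lower = 0)
    stop_if_not_scalar(tau2, "tau2")
    if (tau2 <= 0) stop("tau2 must be > 0", call. = FALSE)
  }
  if (trend_form == "diff_exp_plus_const") {
    stop_if_not_scalar(tau_r, "tau_r", lower = 0)
    if (tau1 <= tau_r) stop("tau1 must exceed tau_r", call. = FALSE)
  }
  structure(list(trend_form = trend_form, A1 = A1, A2 = A2, tau1 = tau1,
                 tau2 = tau2, tau_r = tau_r, lam = lam),
            class = "trend_params")
}

lorentzian <- function(f, tau) 1 / (1 + (2 * pi * tau * f)^2)

#' Evaluate an aperiodic trend model
#'
#' Evaluates the closed-form spectral trend of a [trend_params()] object on a
#' frequency grid.
#'
#' @param params a [trend_params()] object.
#' @param freq numeric vector of frequencies, Hz (non-negative, increasing).
#' @return a [new_spectrum()] object.
#' @export
eval_trend <- function(params, freq) {
  stopifnot(inherits(params, "trend_params"))
  if (any(freq < 0)) stop("negative frequencies are not allowed", call. = FALSE)
  p <- params
  pow <- switch(p$trend_form,
    two_lorentzian = p$A1 * lorentzian(freq, p$tau1) + p$A2 * lorentzian(freq, p$tau2),
    lorentzian_plus_const = p$A1 * p$tau1 * lorentzian(freq, p$tau1) + p$lam,
    diff_exp_plus_const = p$A1 * (p$tau_r - p$tau1)^2 *
      lorentzian(freq, p$tau_r) * lorentzian(freq, p$tau1) + p$lam,
    stop("invalid trend_form", call. = FALSE))
  new_spectrum(freq, pow)
}

#' Gaussian peak parameters
#'
#' Narrowband (oscillatory) peaks riding on the aperiodic trend, modelled as
#' Gaussians in frequency: `height * exp(-(f - center)^2 / (2 width^2))`.
#' For raw spectra the height is in linear spectral density (additive above
#' the trend); for detrended spectra it is in dB.
#'
#' @param center peak centre, Hz (> 0).
#' @param height peak height (>= 0); spectral density or dB, see above.
#' @param width Gaussian SD, Hz (> 0).
#' @return object of class `peak_params`.
#' @export
peak_params <- function(center, height, width) {
  stop_if_not_scalar(center, "center"); stop_if_not_scalar(width, "width")
  stop_if_not_scalar(height, "height", lower = 0)
  if (center <= 0 || width <= 0) stop("center and width must be > 0", call. = FALSE)
  structure(list(center = center, height = height, width = width),
            class = "peak_params")
}

eval_peaks <- function(peaks, freq) {
  out <- numeric(length(freq))
  for (pk in peaks)
    out <- out + pk$height * exp(-(freq - pk$center)^2 / (2 * pk$width^2))
  out
}
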