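# Synaptic input generation: inhomogeneous Poisson trains per synapse with a
# shared rate modulation Y(t) applied in counterphase to the apical and basal
# hemispheres of the synapse layout.

#' Rate-modulation specification for synaptic input
#'
#' Describes the common modulation `Y(t)` of per-synapse Poisson rates. The
#' realised rate of a synapse with base rate `lam` is
#' `max(lam * (1 + alpha * Ytilde(t)), 0)`, where `Ytilde = Y` for apical
#' synapses and the counterphase transform of `Y` for basal synapses.
#'
#' Generators:
#' * `"constant"`: `Y == 0`, homogeneous Poisson input.
#' * `"sinusoid"`: `Y = sin(2 pi omega t + k)` with `k = pi` apical and
#'   `k = 0` basal (counterphase rhythm).
#' * `"white"`: standard Gaussian noise per modulation bin.
#' * `"damped"`: underdamped second-order system driven by white noise
#'   (natural frequency `omega` Hz, damping ratio `zeta`), standardised to
#'   zero mean and unit variance.
#' * `"external"`: a user-supplied series (e.g. a branching-network
#'   population rate), standardised; sampled at `fs_series` Hz.
#'
#' @param kind one of `"constant"`, `"sinusoid"`, `"white"`, `"damped"`,
#'   `"external"`.
#' @param alpha modulation strength (>= 0).
#' @param omega frequency parameter, Hz (sinusoid and damped kinds).
#' @param zeta damping ratio for `"damped"` (0 < zeta < 1).
#' @param series numeric series for `"external"`.
#' @param fs_series sampling rate of `series`, Hz.
#' @param counterphase `"negate"` (basal synapses receive `-Y`, keeping the
#'   modulation zero-mean on both hemispheres) or `"one_minus"` (basal
#'   synapses receive `1 - Y`).
#' @return object of class `rate_function`.
#' @export
rate_function <- function(kind = c("constant", "sinusoid", "white", "damped",
                                   "external"),
                          alpha = 0, omega = 10, zeta = 0.2,
                          series = NULL, fs_series = NULL,
                          counterphase = c("negate", "one_minus")) {
  kind <- match.arg(kind)
  counterphase <- match.arg(counterphase)
  stop_if_not_scalar(alpha, "alpha", lower = 0)
  if (kind == "external" && is.null(series))
    stop("external modulation needs `series`", call. = FALSE)
  structure(list(kind = kind, alpha = alpha, omega = omega, zeta = zeta,
                 series = series, fs_series = fs_series,
                 counterphase = counterphase),
            class = "rate_function")
}

# Realise the modulation series Y(t) on a grid of `n` bins of width dt_s.
eval_modulation <- function(rates, n, dt_s) {
  t <- (seq_len(n) - 0.5) * dt_s
  y <- switch(rates$kind,
    constant = rep(0, n),
    sinusoid = sin(2 * pi * rates$omega * t + pi),  # apical phase k = pi
    white = stats::rnorm(n),
    damped = {
      # discretised x'' + 2 zeta w0 x' + w0^2 x = white noise
      w0 <- 2 * pi * rates$omega
      a1 <- 2 - 2 * rates$zeta * w0 * dt_s - (w0 * dt_s)^2
      a2 <- -(1 - 2 * rates$zeta * w0 * dt_s)
      x <- as.numeric(stats::filter(stats::rnorm(n), c(a1, a2),
                                    method = "recursive"))
      (x - mean(x)) / stats::sd(x)
    },
    external = {
      src_t <- (seq_along(rates$series) - 1) / rates$fs_series
      y <- stats::approx(src_t, rates$series, xout = t, rule = 2)$y
      s <- stats::sd(y)
      if (s < 1e-12) rep(0, n) else (y - mean(y)) / s
    })
  y
}

basal_transform <- function(y, counterphase) {
  if (counterphase == "negate") -y else 1 - y
}

# Sample an inhomogeneous Poisson process by binwise counts on the
# modulation grid, then place spikes uniformly within their bin and thin
# them uniformly over the group's synapses.
sample_group_trains <- function(n_syn, lam_hz, alpha, y, dt_s) {
  if (n_syn == 0 || lam_hz <= 0) return(rep(list(numeric(0)), n_syn))
  rate <- pmax(lam_hz * (1 + alpha * y), 0)       # Hz per synapse
  counts <- stats::rpois(length(y), rate * dt_s * n_syn)
  tot <- sum(counts)
  if (tot == 0) return(rep(list(numeric(0)), n_syn))
  bin <- rep(seq_along(y), counts)
  times_ms <- (bin - 1 + stats::runif(tot)) * dt_s * 1000
  syn <- sample.int(n_syn, tot, replace = TRUE)
  out <- rep(list(numeric(0)), n_syn)
  sp <- split(times_ms, factor(syn, levels = seq_len(n_syn)))
  for (i in seq_len(n_syn)) out[[i]] <- sort(sp[[i]])
  out
}

#' Generate synaptic input spike trains
#'
#' Draws per-synapse inhomogeneous Poisson spike trains for a
#' [synapse_layout()]. All synapses of a class share the base rate (`lamE`
#' for excitatory, `lamI` for inhibitory synapses); apical and basal
#' hemispheres receive counterphase copies of the modulation `Y(t)`.
#'
#' @param layout a [synapse_layout()].
#' @param params a [biophys_params()] providing `lamE`, `lamI` (Hz).
#' @param rates a [rate_function()].
#' @param T duration, s.
#' @param dt_mod modulation grid step, ms (default 1 ms). Spike times are
#'   continuous within bins; warn if `rate * dt` exceeds 0.1 anywhere.
#' @param rng_seed integer seed.
#' @return a [spike_raster()] with one train per synapse (layout order).
#' @export
generate_input <- function(layout, params, rates = rate_function("constant"),
                           T = 10, dt_mod = 1, rng_seed = NULL) {
  stopifnot(inherits(layout, "synapse_layout"), inherits(params, "biophys_params"),
            inherits(rates, "rate_function"), T > 0)
  dt_s <- dt_mod / 1000
  n_bins <- max(1L, ceiling(T / dt_s))
  with_seed(rng_seed, {
    y_ap <- eval_modulation(rates, n_bins, dt_s)
    y_ba <- if (rates$kind == "sinusoid")
      sin(2 * pi * rates$omega * (seq_len(n_bins) - 0.5) * dt_s)  # k = 0
    else basal_transform(y_ap, rates$counterphase)
    peak <- max(params$lamE, params$lamI) * (1 + rates$alpha *
                                               max(abs(y_ap), abs(y_ba)))
    if (peak * dt_s > 0.1)
      warning("rate * dt exceeds 0.1; consider a finer dt_mod")
    trains <- rep(list(numeric(0)), length(layout$kind))
    for (kd in c("E", "I")) {
      lam <- if (kd == "E") params$lamE else params$lamI
      for (ap in c(TRUE, FALSE)) {
        idx <- which(layout$kind == kd & layout$apical == ap)
        y <- if (ap) y_ap else y_ba
        trains[idx] <- sample_group_trains(length(idx), lam, rates$alpha,
                                           y, dt_s)
      }
    }
    trains <- lapply(trains, function(v) v[v <= T * 1000])
    spike_raster(trains, as.character(layout$kind), T_ms = T * 1000)
  })
}
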