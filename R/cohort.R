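# Synthetic propofol-induction cohort with known ground truth: the
# statistical structure the analysis chain assumes (a drifting inhibitory
# timescale driven by effect-site pharmacokinetics, rhythms appearing after
# infusion onset, a delta step at LOC, a subcritical low-frequency excess),
# so every pipeline stage is testable without recordings.

#' Ground truth for one synthetic subject
#'
#' Defaults emulate a fixed-rate induction protocol: infusion-to-LOC
#' latency uniform
#' in 95-285 s, baseline tau1 16.7 ms, dose-response EC50 3.7 uM with Hill
#' coefficient 1.6, constant-rate infusion of 1 mg/kg/min at 70 kg.
#' Amplitudes are root-mean-square contributions in uV.
#'
#' @param latency infusion-to-LOC latency, s.
#' @param tau1_base baseline inhibitory timescale, s.
#' @param EC50,hill_n,hill_span Hill dose-response of the tau1 fold change
#'   against effect-site concentration (uM); `hill_span` is the maximal
#'   fold-change increment (default 1.7, saturating near a pre-LOC
#'   timescale of ~43 ms).
#' @param amp_aperiodic RMS of the synaptic aperiodic component at baseline.
#' @param amp_alpha,amp_beta RMS of the alpha (10 Hz) and beta (20 Hz)
#'   rhythms at plateau.
#' @param amp_delta RMS of the delta (1.5 Hz) rhythm after LOC. The default
#'   (35 uV, i.e. ~100 uV peak-to-peak slow waves) makes the rhythm dominate
#'   the delta band at LOC, as anesthetic slow waves do.
#' @param amp_lowfreq RMS of the subcritical low-frequency excess.
#' @param amp_floor RMS of the white measurement-noise floor.
#' @param alpha_delay rhythm onset delay after infusion, s.
#' @param plateau_margin rhythms plateau this long before LOC, s.
#' @param beta_template `"plateau"` (like alpha) or `"rise_fall"` (beta
#'   declines back toward baseline before LOC).
#' @param t_infusion infusion onset, s of record time.
#' @param pad_end record length after LOC, s.
#' @param weight body weight, kg.
#' @return object of class `cohort_truth`.
#' @export
cohort_truth <- function(latency = 135, tau1_base = 0.0167, EC50 = 3.7,
                         hill_n = 1.6, hill_span = 1.7,
                         amp_aperiodic = 20, amp_alpha = 10, amp_beta = 5,
                         amp_delta = 35, amp_lowfreq = 6, amp_floor = 3,
                         alpha_delay = 20, plateau_margin = 30,
                         beta_template = c("plateau", "rise_fall"),
                         t_infusion = 30, pad_end = 30, weight = 70) {
  beta_template <- match.arg(beta_template)
  stopifnot(latency > 0, tau1_base >= 0.010, tau1_base <= 0.075)
  amps <- c(amp_aperiodic, amp_alpha, amp_beta, amp_delta, amp_lowfreq,
            amp_floor)
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  structure(list(latency = latency, tau1_base = tau1_base, EC50 = EC50,
                 hill_n = hill_n, hill_span = hill_span,
                 amp_aperiodic = amp_aperiodic, amp_alpha = amp_alpha,
                 amp_beta = amp_beta, amp_delta = amp_delta,
                 amp_lowfreq = amp_lowfreq, amp_floor = amp_floor,
                 alpha_delay = alpha_delay, plateau_margin = plateau_margin,
                 beta_template = beta_template, t_infusion = t_infusion,
                 pad_end = pad_end, weight = weight),
            class = "cohort_truth")
}

# Aperiodic synaptic component with a slowly drifting decay timescale:
# windowed overlap-add synthesis. Independent noise blocks are shaped in
# the frequency domain to the exact difference-of-exponentials PSD
# (rise tau_r, decay tau1 at the block centre), windowed with a sine
# window (squares sum to one at 50% overlap) and overlap-added. Exact
# spectral shape, no time-discretisation bias; returned unnormalised.
synth_aperiodic <- function(n, fs, tau1_t, tau_r = 0.004, block_s = 8) {
  nb <- 2L * (round(block_s * fs) %/% 2L)
  hop <- nb %/% 2L
  w <- sin(pi * (seq_len(nb) - 0.5) / nb)
  f_k <- pmin(0:(nb - 1), nb - (0:(nb - 1))) * fs / nb
  out <- numeric(n + 2L * nb)
  pos <- 1L
  while (pos <= n + nb) {
    ic <- min(max(pos + hop - nb %/% 2L, 1L), n)   # block centre sample
    tau1 <- tau1_t[ic]
    shape <- sqrt((tau_r - tau1)^2 * lorentzian(f_k, tau_r) *
                    lorentzian(f_k, tau1))
    coef <- shape * complex(real = stats::rnorm(nb),
                            imaginary = stats::rnorm(nb))
    z <- Re(stats::fft(coef, inverse = TRUE)) / sqrt(nb)
    out[pos:(pos + nb - 1L)] <- out[pos:(pos + nb - 1L)] + w * z
    pos <- pos + hop
  }
  out[seq_len(n)]
}

# narrowband oscillation: complex white noise lowpassed with a 4th-order
# Butterworth at bw/2 (compact spectral support, steep band edges so the
# rhythm does not leak into neighbouring analysis bands), heterodyned to
# f0; unit RMS
narrowband_noise <- function(n, fs, f0, bw) {
  bf <- signal::butter(4, (bw / 2) / (fs / 2), type = "low")
  er <- signal::filter(bf, stats::rnorm(n))
  ei <- signal::filter(bf, stats::rnorm(n))
  t <- (seq_len(n) - 1) / fs
  x <- er * cos(2 * pi * f0 * t) - ei * sin(2 * pi * f0 * t)
  as.numeric(x) / stats::sd(x)
}

# piecewise-linear ramp: 0 before t0, 1 after t1
ramp01 <- function(t, t0, t1) pmin(pmax((t - t0) / max(t1 - t0, 1e-9), 0), 1)

#' Synthesise one subject's EEG record
#'
#' Builds a single-channel EEG at `fs` Hz as the sum of independent
#' components: (i) an aperiodic synaptic component — white noise passed
#' through a difference-of-exponentials filter (rise 4 ms, decay
#' `tau1(t)`), with `tau1(t)` driven by the Marsh effect-site concentration
#' through the truth's Hill dose-response; (ii) a subcritical
#' branching-network population-rate trace adding low-frequency power;
#' (iii) alpha (10 Hz) and beta (20 Hz) narrowband rhythms ramping after
#' infusion and plateauing before LOC; (iv) a delta (1.5 Hz) rhythm
#' stepping on at LOC; (v) a white noise floor.
#'
#' @param truth a [cohort_truth()].
#' @param fs sampling rate, Hz (default 1024).
#' @param rng_seed integer seed; records are reproducible given the seed.
#' @param branch_N network size of the low-frequency component's generator.
#' @return a [cohort_record()]; `$truth` carries the generating parameters
#'   plus the realised `tau1_t` and `Ce_t` trajectories (1 s grid).
#' @export
synth_subject <- function(truth, fs = 1024, rng_seed = NULL, branch_N = 200) {
  stopifnot(inherits(truth, "cohort_truth"))
  t_inf <- truth$t_infusion
  t_loc <- t_inf + truth$latency
  t_end <- t_loc + truth$pad_end
  n <- round(t_end * fs)
  t <- (seq_len(n) - 1) / fs

  # tau1 trajectory from the PK + Hill ground truth
  pk <- pk_params(weight = truth$weight)
  ce <- marsh_effect_site(pk, t_inf, t_loc, rate = 1, t_max = t_end)
  fold <- hill_response(ce$Ce, truth$EC50, truth$hill_n, baseline = 1,
                        span = truth$hill_span)
  tau1_tr <- pmin(pmax(truth$tau1_base * fold, 0.010), 0.075)
  tau1_t <- stats::approx(ce$time, tau1_tr, xout = t, rule = 2)$y

  with_seed(rng_seed, {
    aper <- synth_aperiodic(n, fs, tau1_t)
    base_idx <- t < t_inf
    aper <- aper * truth$amp_aperiodic / stats::sd(aper[base_idx])

    lowf <- 0
    if (truth$amp_lowfreq > 0) {
      bp <- branching_params(N = branch_N, m = 0.98, lam0 = 5)
      net <- build_network(bp, rng_seed = child_seed(rng_seed, 21))
      ras <- simulate_branching(net, T = t_end,
                                rng_seed = child_seed(rng_seed, 22))
      pr <- population_rate(ras, bin_ms = 1)
      pr_t <- stats::approx((seq_along(pr) - 0.5) / 1000, pr, xout = t,
                            rule = 2)$y
      lowf <- truth$amp_lowfreq * (pr_t - mean(pr_t)) / stats::sd(pr_t)
    }

    t_plateau <- max(t_loc - truth$plateau_margin, t_inf + truth$alpha_delay + 1)
    ramp_a <- ramp01(t, t_inf + truth$alpha_delay, t_plateau)
    alpha <- truth$amp_alpha * ramp_a * narrowband_noise(n, fs, 10, 1)
    ramp_b <- if (truth$beta_template == "plateau") ramp_a
              else ramp_a * (1 - 0.8 * ramp01(t, t_plateau, t_loc))
    beta <- truth$amp_beta * ramp_b * narrowband_noise(n, fs, 20, 1)
    # delta steps on at LOC (0.5 s raised-cosine edge avoids a click)
    step <- ramp01(t, t_loc - 0.25, t_loc + 0.25)
    step <- (1 - cos(pi * step)) / 2
    delta <- truth$amp_delta * step * narrowband_noise(n, fs, 1.5, 0.5)
    floorn <- truth$amp_floor * stats::rnorm(n)

    eeg <- aper + lowf + alpha + beta + delta + floorn
    truth_out <- unclass(truth)
    grid <- seq(0, t_end, by = 1)
    truth_out$tau1_t <- data.frame(time = grid,
                                   tau1 = stats::approx(t, tau1_t, grid,
                                                        rule = 2)$y)
    truth_out$Ce_t <- ce
    truth_out$components_var <- c(aperiodic = stats::var(aper),
                                  lowfreq = stats::var(lowf),
                                  alpha = stats::var(alpha),
                                  beta = stats::var(beta),
                                  delta = stats::var(delta),
                                  floor = stats::var(floorn))
    cohort_record(paste0("synthetic-", rng_seed), eeg, fs = fs,
                  t_infusion = t_inf, t_loc = t_loc, weight = truth$weight,
                  infusion_rate = 1, truth = truth_out)
  })
}

#' Synthesise a cohort of subjects
#'
#' Independent subjects with jittered ground truths: latency uniform in
#' `latency_range`, 10 percent log-normal jitter on the baseline tau1 and
#' on all component amplitudes.
#'
#' @param n number of subjects (default 14).
#' @param master_seed integer seed controlling the whole cohort.
#' @param latency_range infusion-to-LOC latency range, s.
#' @param jitter_sd log-normal SD of subject-level jitter (default 0.1).
#' @param fs sampling rate, Hz.
#' @param ... overrides passed to [cohort_truth()].
#' @return list with `records` (list of [cohort_record()]) and `truths`
#'   (list of [cohort_truth()]).
#' @export
synth_cohort <- function(n = 14, master_seed = 1, latency_range = c(95, 285),
                         jitter_sd = 0.1, fs = 1024, ...) {
  stopifnot(n >= 1)
  records <- vector("list", n); truths <- vector("list", n)
  for (i in seq_len(n)) {
    truths[[i]] <- with_seed(child_seed(master_seed, i), {
      jit <- function(x) x * stats::rlnorm(1, 0, jitter_sd)
      base <- cohort_truth(latency = stats::runif(1, latency_range[1],
                                                  latency_range[2]), ...)
      base$tau1_base <- min(max(jit(base$tau1_base), 0.010), 0.075)
      for (nm in c("amp_aperiodic", "amp_alpha", "amp_beta", "amp_delta",
                   "amp_lowfreq", "amp_floor"))
        base[[nm]] <- jit(base[[nm]])
      base
    })
    records[[i]] <- synth_subject(truths[[i]], fs = fs,
                                  rng_seed = child_seed(master_seed, 1000 + i))
  }
  list(records = records, truths = truths)
}
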