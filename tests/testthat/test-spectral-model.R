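# Aperiodic trend models: closed-form evaluation, FOOOF-style fitting,
# detrending and power-law slope estimation.

test_that("eval_trend matches closed-form values", {
  # DC value of the two-Lorentzian form is A1 + A2
  p <- trend_params("two_lorentzian", A1 = 1, A2 = 1, tau1 = 0.02, tau2 = 0.002)
  expect_equal(eval_trend(p, 0)$power, 2)

  # half-power point of a single Lorentzian
  p <- trend_params("two_lorentzian", A1 = 3, A2 = 0, tau1 = 0.02, tau2 = 0.002)
  expect_equal(eval_trend(p, 1 / (2 * pi * 0.02))$power, 1.5)

  # high-frequency limit of the difference-of-exponentials form is the floor
  p <- trend_params("diff_exp_plus_const", A1 = 5, tau1 = 0.02, tau_r = 0.004,
                    lam = 0.3)
  expect_equal(eval_trend(p, 1e6)$power, 0.3, tolerance = 1e-6)

  # frozen value from an independent numeric evaluation of the sum of two
  # Lorentzians at A1=2, tau1=20 ms, A2=0.5, tau2=2 ms, f=10 Hz
  p <- trend_params("two_lorentzian", A1 = 2, A2 = 0.5, tau1 = 0.02, tau2 = 0.002)
  expect_equal(eval_trend(p, 10)$power, 1.2676803352775523, tolerance = 1e-12)

  expect_error(eval_trend(p, c(-1, 2)), "negative")
  expect_error(trend_params("not_a_form"))
})

test_that("trend forms agree in their shared limits", {
  f <- seq(0, 100, by = 0.5)
  # two_lorentzian with A2=0 equals lorentzian_plus_const with lam=0 after
  # rescaling A1 by tau1 (amplitude conventions of the two forms)
  tau1 <- 0.02
  a <- eval_trend(trend_params("two_lorentzian", A1 = 2, A2 = 0, tau1 = tau1), f)
  b <- eval_trend(trend_params("lorentzian_plus_const", A1 = 2 / tau1,
                               tau1 = tau1, lam = 0), f)
  expect_equal(a$power, b$power, tolerance = 1e-12)

  # as tau_r -> 0 the difference-of-exponentials trend converges pointwise to
  # A1 * tau1^2 * Lorentzian + lam
  de <- eval_trend(trend_params("diff_exp_plus_const", A1 = 3, tau1 = tau1,
                                tau_r = 1e-6, lam = 0.1), f)
  lim <- 3 * tau1^2 * lorentzian(f, tau1) + 0.1
  expect_lt(max(abs(de$power - lim) / lim), 1e-3)
})

test_that("fit_trend_and_peaks recovers generating parameters", {
  f <- seq(0.5, 100, by = 0.5)
  truth <- trend_params("diff_exp_plus_const", A1 = 400, tau1 = 0.02,
                        tau_r = 0.004, lam = 0.05)
  spec <- eval_trend(truth, f)

  fit <- fit_trend_and_peaks(spec, "diff_exp_plus_const")
  expect_equal(fit$trend$tau1, 0.02, tolerance = 0.02)
  expect_length(fit$peaks, 0)

  # idempotence: refitting the fitted trend reproduces its parameters
  refit <- fit_trend_and_peaks(eval_trend(fit$trend, f), "diff_exp_plus_const")
  expect_equal(refit$trend$tau1, fit$trend$tau1, tolerance = 1e-6)
  expect_equal(refit$trend$A1, fit$trend$A1, tolerance = 1e-6)

  # a flat spectrum is pure floor
  flat <- new_spectrum(f, rep(2.5, length(f)))
  ffit <- fit_trend_and_peaks(flat, "lorentzian_plus_const")
  expect_equal(ffit$trend$lam, 2.5, tolerance = 1e-3)
  expect_lt(ffit$trend$A1 * ffit$trend$tau1, 2.5e-3)

  # trend + one Gaussian peak at 10 Hz: peak recovered
  pk <- peak_params(center = 10, height = 5, width = 1.5)
  spec2 <- new_spectrum(f, spec$power + eval_peaks(list(pk), f))
  fit2 <- fit_trend_and_peaks(spec2, "diff_exp_plus_const")
  expect_gte(length(fit2$peaks), 1)
  expect_lt(abs(fit2$peaks[[1]]$center - 10), 0.5)
  expect_equal(fit2$trend$tau1, 0.02, tolerance = 0.05)

  # bound honoured in the propofol regime
  fit3 <- fit_trend_and_peaks(spec, "diff_exp_plus_const",
                              bounds = list(tau1 = c(0.010, 0.075)))
  expect_gte(fit3$trend$tau1, 0.010)
  expect_lte(fit3$trend$tau1, 0.075)

  expect_error(fit_trend_and_peaks(new_spectrum(f, rep(0, length(f)))),
               "all-zero")
})

test_that("detrending divides, subtracts and converts to dB correctly", {
  f <- seq(1, 60, by = 0.5)
  truth <- trend_params("diff_exp_plus_const", A1 = 400, tau1 = 0.02,
                        tau_r = 0.004, lam = 0.05)
  spec <- eval_trend(truth, f)

  # spectrum == trend, divide in dB -> 0 dB everywhere
  d <- detrend(spec, spec, "divide", as_db = TRUE)
  expect_equal(max(abs(d$power)), 0, tolerance = 1e-12)

  # self-consistency: trend fit of a peakless spectrum detrends to ~1
  fit <- fit_trend_and_peaks(spec, "diff_exp_plus_const")
  ratio <- detrend(spec, eval_trend(fit$trend, f), "divide")
  expect_true(all(ratio$power > 0.9 & ratio$power < 1.1))

  # subtraction recovers an additive Gaussian peak
  pk <- peak_params(10, 5, 1.5)
  spec2 <- new_spectrum(f, spec$power + eval_peaks(list(pk), f))
  resid <- detrend(spec2, spec, "subtract")
  expect_equal(resid$power, eval_peaks(list(pk), f), tolerance = 1e-10)

  expect_error(detrend(spec, new_spectrum(f + 1, spec$power)), "grids")
})

test_that("fit_slope matches analytic and brute-force regressions", {
  f <- seq(1, 40, by = 0.25)
  expect_equal(fit_slope(new_spectrum(f, 1 / f^2))$beta, 2, tolerance = 1e-10)
  expect_equal(fit_slope(new_spectrum(f, rep(3, length(f))))$beta, 0,
               tolerance = 1e-10)

  # frozen values from an independent log-log least-squares computation of an
  # Eq.1-type spectrum (A1=2, tau1=20 ms, A2=0.5, tau2=2 ms) on the 1-40 Hz
  # grid in 0.25 Hz steps
  p <- trend_params("two_lorentzian", A1 = 2, A2 = 0.5, tau1 = 0.02,
                    tau2 = 0.002)
  sf <- fit_slope(eval_trend(p, f))
  expect_equal(sf$beta, 0.5901797849255437, tolerance = 1e-9)
  expect_equal(sf$alpha, 0.6434109307709444, tolerance = 1e-9)

  expect_error(fit_slope(new_spectrum(f, 1 / f^2), f_range = c(39.9, 40)),
               "fewer than 5")
})

test_that("spectral slope is non-decreasing in tau1 at fixed amplitude ratio", {
  # amplitude ratio fixed in the inhibition-dominated regime (A1 >> A2),
  # where the low-frequency trend is governed by the slow timescale
  f <- seq(1, 40, by = 0.25)
  betas <- vapply(c(0.010, 0.020, 0.040), function(t1) {
    p <- trend_params("two_lorentzian", A1 = 2, A2 = 0.1, tau1 = t1,
                      tau2 = 0.002)
    fit_slope(eval_trend(p, f))$beta
  }, numeric(1))
  expect_true(all(diff(betas) >= 0))
})

test_that("spectrum TSV round-trips", {
  f <- seq(1, 50, by = 1)
  s <- new_spectrum(f, 1 / f)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_tsv(s, path)
  s2 <- read_spectrum_tsv(path)
  expect_equal(s2$freq, s$freq)
  expect_equal(s2$power, s$power)
})
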