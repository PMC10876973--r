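# Analysis chain: multitaper estimation, line-noise filling, time
# rescaling, effect-site pharmacokinetics, tau1 tracking, Hill fitting,
# band power and the group sign test.

test_that("multitaper spectra satisfy Parseval and flatness checks", {
  fs <- 256; T <- 30
  t <- (0:(fs * T - 1)) / fs
  a <- 3
  x <- a * sin(2 * pi * 10 * t)
  sp <- multitaper_spectrum(x, fs)
  expect_equal(sp$freq[which.max(sp$power)], 10, tolerance = 0.26)
  tot <- aperspectra:::trapz(sp$freq, sp$power)
  expect_equal(tot, a^2 / 2, tolerance = 0.05)

  set.seed(60)
  wn <- stats::rnorm(fs * T)
  spw <- multitaper_spectrum(wn, fs)
  expect_lt(abs(fit_slope(spw)$beta), 0.05)

  # window bookkeeping: 2 s windows, 1.9 s overlap -> 0.1 s hop
  # (fs chosen so the hop is an integer number of samples)
  sg <- multitaper_spectrogram(stats::rnorm(240 * 12), 240)
  expect_equal(length(sg$times), floor((12 - 2) / 0.1) + 1)
  expect_error(multitaper_spectrogram(stats::rnorm(100)), "fs")
})

test_that("line-noise filling is local and trend-preserving", {
  f <- seq(1, 100, by = 0.5)
  truth <- trend_params("diff_exp_plus_const", A1 = 300, tau1 = 0.02,
                        tau_r = 0.004, lam = 0.05)
  clean <- eval_trend(truth, f)
  # without a mains peak the spectrum passes through almost unchanged
  filled0 <- fill_line_noise(clean)
  off_band <- abs(f - 60) > 2
  expect_equal(filled0$power[off_band], clean$power[off_band],
               tolerance = 1e-12)
  # a 60 Hz spike is replaced to within 10 percent of the true trend
  spiky <- clean$power + 50 * exp(-(f - 60)^2 / 0.2)
  filled <- fill_line_noise(new_spectrum(f, spiky))
  band <- abs(f - 60) <= 2
  expect_lt(max(abs(filled$power[band] / clean$power[band] - 1)), 0.1)
  expect_true(all(diff(filled$power) < 0))  # monotone decay preserved
  expect_error(fill_line_noise(new_spectrum(seq(1, 30), rep(1, 30))),
               "outside")
})

test_that("rescaled time pins infusion at -1 and LOC at 0", {
  expect_equal(rescale_time(255, 120, 255), 0)
  expect_equal(rescale_time(120, 120, 255), -1)
  expect_equal(rescale_time((120 + 255) / 2, 120, 255), -0.5)
  expect_error(rescale_time(1, 100, 50), "precede")
})

test_that("effect-site kinetics behave like a driven linear system", {
  pk <- pk_params(weight = 70)
  # no infusion -> identically zero
  z <- marsh_effect_site(pk, 10, 100, rate = 0)
  expect_equal(max(abs(z$Ce)), 0, tolerance = 1e-12)
  # constant infusion: Ce monotone non-decreasing while the pump runs
  tr <- marsh_effect_site(pk, 10, 150, rate = 1)
  during <- tr$time >= 10 & tr$time <= 150
  expect_true(all(diff(tr$Ce[during]) > -1e-9))
  expect_gt(max(tr$Ce), 0)
  # keo -> infinity collapses the effect site onto plasma
  fast <- marsh_effect_site(pk_params(keo = 1e4), 10, 150, rate = 1)
  late <- fast$time > 20
  expect_lt(max(abs(fast$Ce[late] - fast$Cp[late]) / max(fast$Cp)), 0.01)
  expect_error(pk_params(weight = 0), "weight")
})

test_that("tau1 tracking recovers constant and ramping timescales", {
  f <- seq(0.5, 110, by = 0.5)
  synth_sg <- function(tau1_per_win, noise_sd = 0.02, seed = 1) {
    set.seed(seed)
    P <- vapply(tau1_per_win, function(t1) {
      tr <- eval_trend(trend_params("diff_exp_plus_const", A1 = 5e4,
                                    tau1 = t1, tau_r = 0.004, lam = 0.05), f)
      tr$power * exp(stats::rnorm(length(f), 0, noise_sd))
    }, numeric(length(f)))
    new_spectrogram(seq_along(tau1_per_win) * 2 - 1, f, P)
  }
  # constant truth 20 ms
  sg <- synth_sg(rep(0.020, 40))
  trk <- track_tau1(sg, t_infusion = 1e9, line_noise = NULL)
  expect_equal(mean(trk$tau1), 0.020, tolerance = 0.05)
  # ramp between typical baseline and pre-LOC inhibitory timescales
  ramp <- seq(0.0167, 0.0432, length.out = 40)
  sg2 <- synth_sg(ramp, seed = 2)
  trk2 <- track_tau1(sg2, t_infusion = 1e9, line_noise = NULL)
  expect_equal(mean(trk2$tau1[1:4]), mean(ramp[1:4]), tolerance = 0.1)
  expect_equal(mean(trk2$tau1[37:40]), mean(ramp[37:40]), tolerance = 0.1)
  # baseline fold change is 1 by construction
  trk3 <- track_tau1(sg, t_infusion = 1e9, line_noise = NULL)
  expect_equal(mean(trk3$fold), 1, tolerance = 1e-9)
})

test_that("Hill fitting recovers generating parameters", {
  C <- exp(seq(log(0.2), log(25), length.out = 24))
  y <- hill_response(C, 3.7, 1.6, baseline = 1, span = 1.7)
  fit <- fit_hill(C, y, fix_baseline = 1)
  expect_equal(fit$EC50, 3.7, tolerance = 1e-6)
  expect_equal(fit$n, 1.6, tolerance = 1e-6)
  expect_equal(fit$span, 1.7, tolerance = 1e-6)
  # half-maximal definition
  expect_equal(hill_response(3.7, 3.7, 1.6, 1, 1.7), 1 + 1.7 / 2)
  # 5 percent multiplicative noise: EC50 within 15 percent in the bulk of
  # repetitions
  errs <- vapply(1:40, function(s) {
    set.seed(70 + s)
    yn <- y * exp(stats::rnorm(length(y), 0, 0.05))
    abs(fit_hill(C, yn, fix_baseline = 1)$EC50 / 3.7 - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.15)
  expect_gt(mean(errs < 0.15), 0.8)
  expect_error(fit_hill(c(-1, 1, 2, 3), 1:4), "> 0")
  expect_error(fit_hill(1:3, 1:3), "4 dose")
})

test_that("band power integrates spectrogram bands correctly", {
  f <- seq(0.5, 40, by = 0.5)
  flat <- new_spectrogram(c(1, 2), f, matrix(1, length(f), 2))
  bp <- band_power(flat, "delta")
  expect_equal(bp$power, c(2.5, 2.5))
  # a pure 10 Hz line lands in alpha and not in delta
  line <- matrix(0, length(f), 1); line[f == 10, 1] <- 100
  sg <- new_spectrogram(1, f, line)
  expect_gt(band_power(sg, "alpha")$power, 0)
  expect_equal(band_power(sg, "delta")$power, 0)
  expect_error(band_power(sg, c(200, 300)), "fewer than 2")
})

test_that("group sign test reproduces exact binomial tails", {
  mk <- function(vals) lapply(vals, function(v)
    data.frame(time = seq(0, 0.049, by = 0.01), value = v))
  # all 14 subjects elevated
  r <- group_sign_test(mk(rep(2, 14)), threshold = 1)
  expect_equal(r$p, 0.5^14)
  # 7 of 14 elevated
  r2 <- group_sign_test(mk(rep(c(2, 0.5), 7)), threshold = 1)
  expect_equal(r2$p, sum(stats::dbinom(7:14, 14, 0.5)))
  expect_equal(r2$p, 0.6047363, tolerance = 1e-6)
  # all depressed: right-tail p is 1
  r3 <- group_sign_test(mk(rep(0.5, 14)), threshold = 1)
  expect_equal(r3$p, 1)
  # ties are dropped
  r4 <- group_sign_test(mk(c(rep(1, 4), rep(2, 10))), threshold = 1)
  expect_equal(r4$n, 10)
  expect_equal(r4$p, 0.5^10)
  expect_error(group_sign_test(mk(rep(2, 3))), "at least 5")
})

test_that("eeg and spectrogram TSV round-trips preserve data", {
  rec <- cohort_record("s1", stats::rnorm(512), fs = 256, t_infusion = 0.5,
                       t_loc = 1.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eeg_tsv(rec, path)
  back <- read_eeg_tsv(path)
  expect_equal(back$eeg, rec$eeg, tolerance = 1e-12)
  expect_equal(back$t_loc, 1.5)

  sg <- new_spectrogram(c(1, 1.1), seq(1, 5), matrix(runif(10), 5, 2))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_spectrogram_tsv(sg, p2)
  back2 <- read_spectrogram_tsv(p2)
  expect_equal(back2$power, sg$power, tolerance = 1e-12)
})

test_that("detrending leaves band power flat when only tau1 drifts", {
  # records whose only time-varying ingredient is the inhibitory
  # timescale: raw band power rotates with the trend, but divisively
  # detrended, baseline-normalised power should show no significant
  # elevation in any canonical band at any rescaled-time segment
  ch <- synth_cohort(n = 7, master_seed = 881, amp_alpha = 0,
                     amp_beta = 0, amp_delta = 0, amp_lowfreq = 0)
  det <- list(delta = list(), alpha = list(), beta = list())
  for (i in seq_along(ch$records)) {
    an <- analyze_subject(ch$records[[i]], stride = 20)
    for (b in names(det)) det[[b]][[i]] <- an$bands[[b]]$detrended
  }
  for (b in names(det)) {
    gs <- group_sign_test(det[[b]], t_range = c(-1, 0.15))
    expect_equal(sum(gs$p < 0.05), 0)
  }
})

test_that("spike rasters round-trip through TSV with side-car metadata", {
  ras <- spike_raster(list(c(1.5, 20, 800), numeric(0), 44.25),
                      c("E", "E", "I"),
                      positions = cbind(c(0.1, 0.5, 0.9), c(0.2, 0.6, 0.4)),
                      T_ms = 1000)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_raster_tsv(ras, path)
  back <- read_raster_tsv(path)
  expect_equal(back$trains, ras$trains, tolerance = 1e-12)
  expect_identical(as.character(back$kind), c("E", "E", "I"))
  expect_equal(back$positions, unname(ras$positions), tolerance = 1e-12)
  expect_equal(back$T_ms, 1000)
})
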