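# Spatial subcritical branching network: graph construction, rate
# conservation, avalanche statistics, inhibitory train construction and the
# spike-time tiling coefficient.

# brute-force STTC oracle: literal evaluation of the published formula
sttc_brute <- function(a, b, dt, T_ms) {
  if (!length(a) || !length(b)) return(0)
  prop_near <- function(x, y) mean(vapply(x, function(s) any(abs(y - s) <= dt),
                                          logical(1)))
  # exact union length of the tiling windows by an endpoint sweep
  tiled <- function(x) {
    ev <- rbind(cbind(pmax(x - dt, 0), 1), cbind(pmin(x + dt, T_ms), -1))
    ev <- ev[order(ev[, 1], -ev[, 2]), , drop = FALSE]
    depth <- cumsum(ev[, 2])
    sum(diff(ev[, 1]) * (depth[-length(depth)] > 0)) / T_ms
  }
  PA <- prop_near(a, b); PB <- prop_near(b, a)
  TA <- tiled(a); TB <- tiled(b)
  ((PA - TB) / (1 - PA * TB) + (PB - TA) / (1 - PB * TA)) / 2
}

test_that("network graphs have exact out-degree and local structure", {
  bp <- branching_params(N = 400, kernel_scale = 0.05)
  net <- build_network(bp, rng_seed = 21)
  expect_identical(dim(net$targets), c(400L, 10L))
  expect_true(all(apply(net$targets, 1, function(r) length(unique(r)) == 10)))
  expect_true(all(net$targets != row(net$targets)))  # no self-loops
  # determinism
  net2 <- build_network(bp, rng_seed = 21)
  expect_identical(net$targets, net2$targets)

  # mean target distance shrinks with the kernel scale
  mean_dist <- function(ks, seed) {
    b <- branching_params(N = 400, kernel_scale = ks)
    n <- build_network(b, rng_seed = seed)
    d <- 0
    for (i in 1:400) {
      dd <- aperspectra:::torus_dist(n$positions[i, , drop = FALSE],
                                     n$positions[n$targets[i, ], , drop = FALSE])
      d <- d + mean(dd)
    }
    d / 400
  }
  expect_lt(mean_dist(0.02, 22), mean_dist(0.1, 22))
  expect_lt(mean_dist(0.1, 23), mean_dist(10, 23))
  # a very large kernel scale makes target choice near-uniform:
  # chi-square on in-degree counts
  bflat <- branching_params(N = 400, kernel_scale = 1000)
  nf <- build_network(bflat, rng_seed = 24)
  indeg <- tabulate(as.vector(nf$targets), 400)
  expect_gt(stats::chisq.test(indeg)$p.value, 0.001)
})

test_that("stationary rate equals lam0 across branching numbers", {
  # subcritical identity: baseline lam0 (1 - m) plus mean offspring m per
  # spike gives lam0 for every m < 1
  for (m in c(0, 0.5, 0.9)) {
    bp <- branching_params(N = 500, m = m, lam0 = 5)
    net <- build_network(bp, rng_seed = 31)
    rates <- vapply(1:3, function(s) {
      ras <- simulate_branching(net, T = 20, rng_seed = 310 + s)
      sum(lengths(ras$trains)) / 500 / 20
    }, numeric(1))
    expect_equal(mean(rates), 5, tolerance = 0.08)
  }
})

test_that("rasters are reproducible and autocorrelation grows with m", {
  bp <- branching_params(N = 500, m = 0.9, lam0 = 5)
  net <- build_network(bp, rng_seed = 41)
  r1 <- simulate_branching(net, T = 10, rng_seed = 42)
  r2 <- simulate_branching(net, T = 10, rng_seed = 42)
  expect_identical(r1$trains, r2$trains)

  ac_time <- function(m, seed) {
    bp <- branching_params(N = 500, m = m, lam0 = 5)
    net <- build_network(bp, rng_seed = seed)
    ras <- simulate_branching(net, T = 30, rng_seed = seed + 1)
    pr <- population_rate(ras, bin_ms = 2)
    ac <- stats::acf(pr, lag.max = 100, plot = FALSE)$acf[, 1, 1]
    sum(ac[ac > 0.05])   # crude integrated autocorrelation
  }
  acs <- vapply(c(0, 0.5, 0.9, 0.98), ac_time, numeric(1), seed = 50)
  expect_true(all(diff(acs) > 0))
})

test_that("avalanche sizes are heavier-tailed near criticality", {
  # excursion size: cumulative spike count above the mean level within one
  # contiguous above-mean epoch of the population rate
  sizes <- function(m, seed) {
    bp <- branching_params(N = 500, m = m, lam0 = 5)
    net <- build_network(bp, rng_seed = seed)
    ras <- simulate_branching(net, T = 30, rng_seed = seed + 1)
    cnt <- population_rate(ras, bin_ms = 4) * 500 * 0.004  # counts per bin
    exc <- cnt - mean(cnt)
    runs <- rle(exc > 0)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    vapply(which(runs$values), function(k) sum(exc[starts[k]:ends[k]]),
           numeric(1))
  }
  s0 <- sizes(0, 60); s98 <- sizes(0.98, 60)
  # heavier tail near criticality: the large-excursion quantile blows up
  expect_gt(stats::quantile(s98, 0.99), 5 * stats::quantile(s0, 0.99))
  expect_gt(max(s98), 5 * max(s0))
})

test_that("inhibitory trains follow the requested rate and composition", {
  bp <- branching_params(N = 300, m = 0.5, lam0 = 5, lamI = 8)
  net <- build_network(bp, rng_seed = 71)
  ras <- simulate_branching(net, T = 20, rng_seed = 72)
  full <- attach_inhibitory(ras, bp, rng_seed = 73)
  n_i <- sum(full$kind == "I")
  expect_equal(n_i, round(0.15 * 300 / 0.85))
  r_i <- sum(lengths(full$trains[full$kind == "I"])) / n_i / 20
  expect_lt(abs(r_i - 8), 3 * sqrt(8 / (n_i * 20)))

  # lamI = 0: empty inhibitory trains
  bp0 <- branching_params(N = 300, m = 0.5, lam0 = 5, lamI = 0)
  f0 <- attach_inhibitory(ras, bp0, rng_seed = 74)
  expect_true(all(lengths(f0$trains[f0$kind == "I"]) == 0))

  # m = 0: inhibitory trains are pure Poisson (dispersion of counts ~ 1)
  bpp <- branching_params(N = 300, m = 0, lam0 = 5, lamI = 8)
  netp <- build_network(bpp, rng_seed = 75)
  rasp <- simulate_branching(netp, T = 20, rng_seed = 76)
  fp <- attach_inhibitory(rasp, bpp, rng_seed = 77)
  cnt <- lengths(fp$trains[fp$kind == "I"])
  expect_lt(stats::var(cnt) / mean(cnt), 2)
})

test_that("sttc matches a brute-force oracle and known limits", {
  # identical nonempty trains
  expect_equal(sttc(c(10, 500, 900), c(10, 500, 900), 10, 1000), 1)
  # spec's tiny case
  expect_equal(sttc(10, 100, delta_t = 5, T_ms = 1000),
               sttc_brute(10, 100, 5, 1000), tolerance = 1e-12)
  # random small train pairs against the brute-force formula
  set.seed(81)
  for (k in 1:25) {
    a <- sort(stats::runif(sample(1:8, 1), 0, 500))
    b <- sort(stats::runif(sample(1:8, 1), 0, 500))
    dt <- stats::runif(1, 2, 30)
    expect_equal(sttc(a, b, dt, 500), sttc_brute(a, b, dt, 500),
                 tolerance = 1e-12)
  }
  # independent Poisson trains decorrelate
  set.seed(82)
  a <- sort(stats::runif(200, 0, 40000)); b <- sort(stats::runif(200, 0, 40000))
  expect_lt(abs(sttc(a, b, 10, 40000)), 0.05)
  expect_warning(v <- sttc(numeric(0), c(1, 2), 10, 100), "empty")
  expect_equal(v, 0)
})
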