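# Ensemble EEG power machinery: coherence superposition, signed neuron
# counts on meshes, the mean pairwise correlation integral and total power.

test_that("ensemble_spectrum obeys its closed-form limits", {
  f <- seq(1, 50, by = 1)
  s <- new_spectrum(f, 10 / (1 + (f / 8)^2))
  spectra <- list(s, s, s, s)
  # gamma = 0: plain sum
  e0 <- ensemble_spectrum(spectra, 0)
  expect_equal(e0$power, 4 * s$power, tolerance = 1e-12)
  # gamma = 1 with identical spectra: N^2 scaling
  e1 <- ensemble_spectrum(spectra, 1)
  expect_equal(e1$power, 16 * s$power, tolerance = 1e-12)
  expect_error(ensemble_spectrum(spectra, 1.5), "gamma")
})

test_that("Eq.-2 superposition reproduces the pooled-signal spectrum", {
  # 50 signals correlated through a shared component; coherence estimated from
  # segment-averaged cross-spectra makes the identity exact
  set.seed(30)
  n <- 50; len <- 4096; fs <- 256
  shared <- stats::rnorm(len)
  X <- vapply(seq_len(n), function(i) 0.4 * shared + stats::rnorm(len),
              numeric(len))
  nseg <- 512
  starts <- seq(1, len - nseg + 1, by = nseg)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  nf <- nseg %/% 2
  FT <- array(0i, c(nf, length(starts), n))
  for (s in seq_along(starts)) for (i in seq_len(n)) {
    seg <- X[starts[s]:(starts[s] + nseg - 1), i]
    FT[, s, i] <- stats::fft((seg - mean(seg)) * w)[2:(nf + 1)]
  }
  S <- apply(FT, c(1, 3), function(v) mean(Mod(v)^2)) * 2 / (fs * sum(w^2))
  freq <- (1:nf) * fs / nseg
  spectra <- lapply(seq_len(n), function(i) new_spectrum(freq, S[, i]))
  gamma_f <- function(fq) {
    k <- which.min(abs(freq - fq))
    G <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      cs <- mean(Re(FT[k, , i] * Conj(FT[k, , j])))
      G[i, j] <- G[j, i] <- cs / sqrt(mean(Mod(FT[k, , i])^2) *
                                        mean(Mod(FT[k, , j])^2))
    }
    G
  }
  pooled_sig <- rowSums(X)
  pooled <- vapply(seq_along(starts), function(s) {
    seg <- pooled_sig[starts[s]:(starts[s] + nseg - 1)]
    Mod(stats::fft((seg - mean(seg)) * w)[2:(nf + 1)])^2
  }, numeric(nf))
  pooled <- rowMeans(pooled) * 2 / (fs * sum(w^2))
  test_k <- c(3, 20, 100)
  es <- ensemble_spectrum(spectra, function(fq) gamma_f(fq))
  # de-meaning per segment makes the identity exact up to numeric error
  expect_equal(es$power[test_k], pooled[test_k], tolerance = 1e-6)
})

test_that("signed neuron counts match plane and sphere limits", {
  mesh <- flat_square_mesh(side = 100, n = 10, mu = 100)
  x <- c(50, 50, 0)
  expect_equal(signed_neuron_count(mesh, x, 0), 0)
  for (r in c(5, 12, 25))
    expect_equal(signed_neuron_count(mesh, x, r), 100 * pi * r^2,
                 tolerance = 0.005)
  # nu is non-decreasing in r on a flat convex patch
  nus <- signed_neuron_count(mesh, x, seq(2, 40, by = 2))
  expect_true(all(diff(nus) > 0))

  # closed sphere: for r spanning the whole surface the signed count
  # cancels (integral of cos(theta) over the sphere is zero)
  sph <- icosphere_mesh(radius = 10, subdivisions = 2, mu = 100)
  x0 <- sph$vertices[1, ]
  full <- signed_neuron_count(sph, x0, 25)
  expect_lt(abs(full), 0.01 * sph$mu * sum(sph$areas))
  # ... and the signed count does go negative beyond the equator
  expect_lt(signed_neuron_count(sph, x0, 19),
            signed_neuron_count(sph, x0, 13))
  expect_error(signed_neuron_count(mesh, x, -1), ">= 0")
})

test_that("mean pairwise correlation matches the flat-plane closed form", {
  mesh <- flat_square_mesh(side = 120, n = 12, mu = 100)
  ker <- coupling_kernel(rho_max = 0.1, sigma2 = 64)
  interior <- function(p) all(p[1:2] > 41) && all(p[1:2] < 79)
  res <- mean_pairwise_correlation(mesh, ker, k_samples = 150,
                                   point_filter = interior, rng_seed = 31)
  expected <- ker$rho_max * mesh$mu * pi * ker$sigma2 / (res$N - 1)
  expect_equal(res$rho_bar, expected, tolerance = 0.02)

  # rho_max = 0 gives exactly zero
  res0 <- mean_pairwise_correlation(mesh, coupling_kernel(0, 64),
                                    k_samples = 20, rng_seed = 32)
  expect_equal(res0$rho_bar, 0)

  # large sphere: locally flat limit within 5 percent
  sph <- icosphere_mesh(radius = 60, subdivisions = 3, mu = 100)
  rs <- mean_pairwise_correlation(sph, ker, k_samples = 100, rng_seed = 33)
  exp_s <- ker$rho_max * sph$mu * pi * ker$sigma2 / (rs$N - 1)
  expect_equal(rs$rho_bar, exp_s, tolerance = 0.05)
})

test_that("rho_bar Monte-Carlo error shrinks with the sample count", {
  mesh <- flat_square_mesh(side = 60, n = 6, mu = 100)
  ker <- coupling_kernel(rho_max = 0.2, sigma2 = 16)
  spread <- vapply(c(100, 1600), function(k) {
    vals <- vapply(1:6, function(s)
      mean_pairwise_correlation(mesh, ker, k_samples = k, n_r = 40, h = 1,
                                rng_seed = 40 * s + k)$rho_bar, numeric(1))
    stats::sd(vals)
  }, numeric(1))
  # 16x more samples should shrink the SE roughly 4x; allow generous slack
  # for the 6-replicate SD estimates themselves
  expect_lt(spread[2], spread[1] / 2)
})

test_that("ensemble power follows the correlation identity and is monotone", {
  expect_equal(ensemble_power(1e6, 2, 0), 2e6)
  expect_equal(ensemble_power(1e3, 2, 1), 2 * 1e3^2)
  # level sets over (rho_max, sigma2): power is monotone in both
  mesh <- flat_square_mesh(side = 60, n = 6, mu = 1000)
  grid_pow <- sapply(c(4, 16, 36), function(s2)
    sapply(c(0.05, 0.1, 0.2), function(rm) {
      rb <- mean_pairwise_correlation(mesh, coupling_kernel(rm, s2),
                                      k_samples = 60, rng_seed = 50)$rho_bar
      ensemble_power(1e8, 1, rb)
    }))
  expect_true(all(apply(grid_pow, 2, diff) > 0))
  expect_true(all(apply(grid_pow, 1, diff) > 0))
})

test_that("meshes round-trip through OFF and PLY", {
  sph <- icosphere_mesh(radius = 5, subdivisions = 1, mu = 10)
  for (ext in c("off", "ply")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(sph, path)
    back <- read_mesh(path, mu = 10)
    expect_equal(back$vertices, unname(sph$vertices), tolerance = 1e-6)
    expect_equal(back$faces, unname(sph$faces), ignore_attr = TRUE)
    expect_true(back$watertight)
  }
  expect_false(flat_square_mesh(n = 2)$watertight)
})
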