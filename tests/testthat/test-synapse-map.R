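# Dipole-coherence machinery: spherical embedding by correlation,
# optimality-index perturbation, synapse assignment, the minimal
# correlated-synapse model and dyad dipole correlation.

test_that("embedding places correlated units at small angles", {
  # two perfectly anticorrelated clusters end up on opposite hemispheres
  n <- 40
  C <- rbind(cbind(matrix(0.9, n, n), matrix(-0.9, n, n)),
             cbind(matrix(-0.9, n, n), matrix(0.9, n, n)))
  diag(C) <- 1
  emb <- embed_on_sphere(C, rng_seed = 1)
  ang <- aperspectra:::angular_distance_matrix(emb$points)
  inter <- ang[1:n, n + 1:n]
  expect_gt(mean(inter), pi / 2)

  # block-diagonal 3-cluster matrix: within < between angles; contract met
  B <- matrix(0.05, 90, 90)
  for (k in 0:2) B[k * 30 + 1:30, k * 30 + 1:30] <- 0.6
  diag(B) <- 1
  e3 <- embed_on_sphere(B, rng_seed = 2)
  a3 <- aperspectra:::angular_distance_matrix(e3$points)
  within <- mean(a3[1:30, 1:30][lower.tri(diag(30))])
  between <- mean(a3[1:30, 31:60])
  expect_lt(within, between)
  expect_lt(e3$contract_rho, -0.3)

  expect_error(embed_on_sphere(matrix(c(1, 0.5, 0, 1), 2, 2)), "symmetric")
})

test_that("branching-net STTC embedding meets the rank-correlation contract", {
  bp <- branching_params(N = 300, m = 0.98, lam0 = 5)
  net <- build_network(bp, rng_seed = 3)
  ras <- simulate_branching(net, T = 40, rng_seed = 4)
  M <- sttc_matrix(ras, idx = seq(1, 300, by = 2))
  emb <- embed_on_sphere(M, rng_seed = 5)
  expect_lt(emb$contract_rho, -0.3)
})

test_that("perturbation respects the optimality index", {
  emb <- structure(list(points = runif_sphere(800), contract_rho = NA_real_),
                   class = "sphere_embedding")
  # X = 1: exact identity
  expect_identical(perturb_embedding(emb, 1, rng_seed = 6)$points, emb$points)
  # X = 0: uniform re-scatter (all unit vectors; projections uniform)
  p0 <- perturb_embedding(emb, 0, rng_seed = 7)
  expect_lt(max(abs(sqrt(rowSums(p0$points^2)) - 1)), 1e-9)
  expect_gt(stats::ks.test(p0$points[, 3], "punif", -1, 1)$p.value, 0.01)
  # cosine of displacement relative to the original point is uniform
  disp <- acos(pmin(pmax(rowSums(p0$points * emb$points), -1), 1))
  expect_gt(stats::ks.test(cos(disp), "punif", -1, 1)$p.value, 0.01)
  # mean angular displacement decreases monotonically in X
  mean_disp <- vapply(c(0, 0.25, 0.5, 1), function(X) {
    pp <- perturb_embedding(emb, X, rng_seed = 8)
    mean(acos(pmin(pmax(rowSums(pp$points * emb$points), -1), 1)))
  }, numeric(1))
  expect_true(all(diff(mean_disp) < 0))
})

test_that("synapse assignment is greedy-nearest with stable ties", {
  lay <- synapse_layout(30, 5, rng_seed = 9)
  # one presynaptic unit: everything maps to it
  e1 <- structure(list(points = matrix(c(0, 0, 1), 1), contract_rho = NA),
                  class = "sphere_embedding")
  expect_true(all(assign_synapses(e1, lay, rng_seed = 10) == 1))
  # embedding colocated with the synapse directions: identity mapping
  e2 <- structure(list(points = lay$directions, contract_rho = NA),
                  class = "sphere_embedding")
  expect_identical(assign_synapses(e2, lay, rng_seed = 11),
                   seq_len(nrow(lay$directions)))
  # assigned angular distances beat a random assignment stochastically
  e3 <- structure(list(points = runif_sphere(100), contract_rho = NA),
                  class = "sphere_embedding")
  map <- assign_synapses(e3, lay, rng_seed = 12)
  d_opt <- acos(pmin(pmax(rowSums(lay$directions * e3$points[map, ]), -1), 1))
  set.seed(13)
  d_rand <- replicate(20, {
    m2 <- sample.int(100, nrow(lay$directions), replace = TRUE)
    mean(acos(pmin(pmax(rowSums(lay$directions * e3$points[m2, ]), -1), 1)))
  })
  expect_lt(mean(d_opt), min(d_rand))
  expect_error(assign_synapses(structure(list(points = matrix(0, 0, 3)),
                                         class = "sphere_embedding"), lay),
               "empty")
})

test_that("minimal model hits its target correlations and stays white", {
  lay <- synapse_layout(2, 1,
                        directions = rbind(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0)))
  bio <- biophys_params(lamE = 20, lamI = 20)
  ras <- minimal_correlated_trains(lay, minimal_model_params(R_max = 0.3),
                                   bio, T = 100, rng_seed = 14)
  bins <- function(tr) tabulate(floor(tr) + 1L, 100 * 1000)
  b <- lapply(ras$trains, bins)
  # theta = 0 pair: correlation within +/- 0.03 of R_max over 1e5 bins
  expect_equal(stats::cor(b[[1]], b[[2]]), 0.3, tolerance = 0.1)
  expect_lt(abs(stats::cor(b[[1]], b[[2]]) - 0.3), 0.03)
  # theta = pi/2 pair follows the angular kernel
  expect_lt(abs(stats::cor(b[[1]], b[[3]]) - 0.3 * exp(-pi / 2)), 0.03)
  # no temporal autocorrelation at lag >= 1
  expect_lt(max(abs(stats::acf(b[[1]], lag.max = 5,
                               plot = FALSE)$acf[-1])), 0.02)

  # R_max = 0: independent trains
  ras0 <- minimal_correlated_trains(lay, minimal_model_params(R_max = 0),
                                    bio, T = 50, rng_seed = 15)
  b0 <- lapply(ras0$trains, bins)
  expect_lt(abs(stats::cor(b0[[1]][1:50000], b0[[2]][1:50000])), 3 / sqrt(50000))
})

test_that("dyad dipole correlation rises with R_max and dies under shuffling", {
  la <- synapse_layout(60, 9, rng_seed = 16)
  lb <- synapse_layout(60, 9, rng_seed = 17)
  bio <- biophys_params(lamE = 2, lamI = 5)
  rhos <- vapply(c(0, 0.15, 0.3), function(R) {
    dyad_dipole_correlation(la, lb, bio,
                            minimal = minimal_model_params(R_max = R),
                            T = 20, rng_seed = 18 + round(R * 100))$rho
  }, numeric(1))
  expect_true(all(diff(rhos) > 0))
  expect_lt(abs(rhos[1]), 0.05)
  expect_gt(rhos[3], 0.3)

  # identical layouts fed the very same spike trains: correlation of 1
  shared <- minimal_correlated_trains(la, minimal_model_params(R_max = 0.2),
                                      bio, T = 5, rng_seed = 19)
  same <- dyad_dipole_correlation(la, la, bio,
                                  rasters = list(shared, shared), T = 5,
                                  rng_seed = 19)
  expect_gt(same$rho, 1 - 1e-9)

  r <- dyad_dipole_correlation(la, lb, bio,
                               minimal = minimal_model_params(R_max = 0.3),
                               T = 20, n_shuffle = 4, rng_seed = 20)
  expect_lt(abs(r$rho_shuffled), 0.05)
  expect_gt(r$rho, 5 * abs(r$rho_shuffled))
})
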