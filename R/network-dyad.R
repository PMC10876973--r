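# Network-driven dipole coherence: the full chain from a spatial branching
# network to a pair of postsynaptic dipoles, via STTC-based spherical
# embedding of the presynaptic population and greedy synapse assignment.

#' Dipole correlation of a dyad driven by a branching network
#'
#' Runs the complete coherence chain: (1) simulate a spatial branching
#' network; (2) compute the pairwise STTC matrix of a presynaptic subset;
#' (3) embed the subset on the sphere so correlated units sit at small
#' angles; (4) optionally degrade the embedding with the optimality index
#' `X`; (5) assign each excitatory synapse of both postsynaptic neurons to
#' the nearest embedded unit, so each synapse replays its unit's spike
#' train; (6) simulate both dipoles and correlate their projections.
#' Inhibitory synapses receive independent Poisson input at `lamI`.
#'
#' @param layout_a,layout_b [synapse_layout()] objects of the dyad.
#' @param biophys a [biophys_params()] shared by both neurons.
#' @param m branching number of the presynaptic network.
#' @param n_presyn presynaptic units used for the embedding (subset of the
#'   network).
#' @param N network size.
#' @param T duration, s.
#' @param X optimality index in `[0, 1]` (1 = optimal placement).
#' @param n_shuffle shuffle controls averaged (synapse directions permuted).
#' @param dt dipole integration step, ms.
#' @param rng_seed integer seed.
#' @details The two neurons draw their presynaptic units from disjoint
#'   halves of the embedded population, so any dipole correlation is
#'   mediated by network spike-train correlations between distinct units
#'   (the mechanism of interest) rather than by the same axon contacting
#'   both neurons; with `m = 0` the dyad is then exactly uncoupled.
#' @return list with `rho`, `rho_shuffled`, `contract_rho` (embedding
#'   diagnostic).
#' @export
network_dyad_correlation <- function(layout_a, layout_b, biophys,
                                     m = 0.98, n_presyn = 150, N = 500,
                                     T = 40, X = 1, n_shuffle = 0,
                                     dt = 0.5, rng_seed = NULL) {
  bp <- branching_params(N = N, m = m, lam0 = biophys$lamE)
  net <- build_network(bp, rng_seed = child_seed(rng_seed, 1))
  ras <- simulate_branching(net, T = T, rng_seed = child_seed(rng_seed, 2))
  units <- with_seed(child_seed(rng_seed, 3),
                     sort(sample.int(N, min(n_presyn, N))))
  M <- sttc_matrix(ras, idx = units)
  emb <- embed_on_sphere(M, rng_seed = child_seed(rng_seed, 4))
  if (X < 1) emb <- perturb_embedding(emb, X,
                                      rng_seed = child_seed(rng_seed, 5))

  halves <- list(seq(1, length(units), by = 2), seq(2, length(units), by = 2))
  make_raster <- function(layout, half, seed) {
    sub <- halves[[half]]
    emb_h <- structure(list(points = emb$points[sub, , drop = FALSE],
                            contract_rho = emb$contract_rho),
                       class = "sphere_embedding")
    mapping <- sub[assign_synapses(emb_h, layout, rng_seed = seed)]
    trains <- vector("list", nrow(layout$directions))
    isE <- layout$kind == "E"
    trains[isE] <- ras$trains[units[mapping[isE]]]
    n_i <- sum(!isE)
    if (n_i) {
      ti <- with_seed(child_seed(seed, 1), {
        lapply(seq_len(n_i), function(k)
          sort(stats::runif(stats::rpois(1, biophys$lamI * T), 0, T * 1000)))
      })
      trains[!isE] <- ti
    }
    spike_raster(trains, as.character(layout$kind), T_ms = T * 1000)
  }
  rasters <- list(make_raster(layout_a, 1, child_seed(rng_seed, 6)),
                  make_raster(layout_b, 2, child_seed(rng_seed, 7)))
  res <- dyad_dipole_correlation(layout_a, layout_b, biophys,
                                 rasters = rasters, T = T,
                                 n_shuffle = n_shuffle, dt = dt,
                                 rng_seed = child_seed(rng_seed, 8))
  res$contract_rho <- emb$contract_rho
  res
}
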