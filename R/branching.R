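# Spatial subcritical branching network of binary neurons.
#
# Rule #1: neurons live in a unit square (torus metric) and connect
# preferentially to nearby neurons (exponential kernel).
# Rule #2: each neuron fires a baseline Poisson process at rate
# lam0 * (1 - m); every spike gives each of its d_out targets an independent
# Bernoulli(m / d_out) chance of firing within the following 4 ms.
# The stationary per-neuron rate is therefore lam0 for every m < 1.

#' Branching-network parameters
#'
#' @param N number of (excitatory) neurons.
#' @param m branching number in `[0, 1)`: mean number of spikes triggered
#'   across the network per spike.
#' @param lam0 target stationary rate per neuron, Hz.
#' @param d_out out-degree (default 10).
#' @param kernel_scale length scale of the exponential connection kernel, in
#'   unit-square units (default 0.05).
#' @param inh_fraction fraction of the full network that is inhibitory
#'   (default 0.15); inhibitory units are attached after simulation, see
#'   [attach_inhibitory()].
#' @param lamI inhibitory unit firing rate, Hz.
#' @param dt simulation bin, ms (default 1/32). The bin is a numerical
#'   grid, not a model timescale: coincident scheduled spikes merge within a
#'   bin (binary neurons), so a bin much finer than the 4 ms propagation
#'   window is needed to keep the merging loss negligible in avalanche-dense
#'   regimes near criticality (the subcritical rate identity
#'   `rate = lam0` holds only without merging). The simulation is
#'   event-driven, so the fine grid costs nothing.
#' @param prop_window spike propagation window, ms (default 4).
#' @param k_nearest number of nearby excitatory units pooled per inhibitory
#'   unit (default 20).
#' @return object of class `branching_params`.
#' @export
branching_params <- function(N = 1000, m = 0.98, lam0 = 5, d_out = 10,
                             kernel_scale = 0.05, inh_fraction = 0.15,
                             lamI = 5, dt = 1 / 32, prop_window = 4,
                             k_nearest = 20) {
  stop_if_not_scalar(m, "m", lower = 0)
  if (m >= 1) stop("supercritical branching (m >= 1) is not supported",
                   call. = FALSE)
  stop_if_not_scalar(lam0, "lam0", lower = 0)
  if (d_out < 1) stop("d_out must be >= 1", call. = FALSE)
  if (inh_fraction < 0 || inh_fraction >= 1)
    stop("inh_fraction must be in [0, 1)", call. = FALSE)
  structure(list(N = as.integer(N), m = m, lam0 = lam0,
                 d_out = as.integer(d_out), kernel_scale = kernel_scale,
                 inh_fraction = inh_fraction, lamI = lamI, dt = dt,
                 prop_window = prop_window, k_nearest = as.integer(k_nearest)),
            class = "branching_params")
}

# Pairwise torus distances between rows of a and b (k x 2, n x 2).
torus_dist <- function(a, b) {
  dx <- abs(outer(a[, 1], b[, 1], "-")); dx <- pmin(dx, 1 - dx)
  dy <- abs(outer(a[, 2], b[, 2], "-")); dy <- pmin(dy, 1 - dy)
  sqrt(dx^2 + dy^2)
}

#' Build a spatial branching-network graph
#'
#' Places `N` neurons uniformly at random in the unit square (torus
#' boundary) and samples, for each neuron, exactly `d_out` distinct targets
#' with probability proportional to `exp(-d_ij / kernel_scale)`.
#'
#' @param params a [branching_params()].
#' @param rng_seed integer seed; the graph is deterministic given the seed.
#' @return list of class `branching_net`: `targets` (N x d_out matrix of
#'   neuron indices), `positions` (N x 2), `params`.
#' @export
build_network <- function(params, rng_seed = NULL) {
  stopifnot(inherits(params, "branching_params"))
  N <- params$N
  if (N < params$d_out + 1) stop("N must exceed d_out", call. = FALSE)
  with_seed(rng_seed, {
    pos <- cbind(stats::runif(N), stats::runif(N))
    targets <- matrix(0L, N, params$d_out)
    for (i in seq_len(N)) {
      d <- torus_dist(pos[i, , drop = FALSE], pos)[1, ]
      w <- exp(-d / params$kernel_scale)
      w[i] <- 0
      targets[i, ] <- sample.int(N, params$d_out, prob = w)
    }
    structure(list(targets = targets, positions = pos, params = params),
              class = "branching_net")
  })
}

#' Simulate the branching network
#'
#' Discrete-time simulation in bins of `dt` ms. Each neuron receives a
#' baseline Poisson drive at rate `lam0 * (1 - m)`; each spike schedules, for
#' every out-neighbour, an independent Bernoulli(`m / d_out`) spike placed
#' uniformly within the following `prop_window` ms. A neuron fires at most
#' once per bin (coincident scheduled spikes merge).
#'
#' @param net a [build_network()] result.
#' @param T duration, s.
#' @param rng_seed integer seed; identical seeds give identical rasters.
#' @return a [spike_raster()] of excitatory trains with planar positions.
#' @export
simulate_branching <- function(net, T = 40, rng_seed = NULL) {
  stopifnot(inherits(net, "branching_net"), T > 0)
  p <- net$params
  N <- p$N
  n_bins <- ceiling(T * 1000 / p$dt)
  w_bins <- max(1L, round(p$prop_window / p$dt))
  p_base <- p$lam0 * (1 - p$m) * p$dt / 1000    # per-bin baseline probability
  p_prop <- p$m / p$d_out
  with_seed(rng_seed, {
    res <- .branching_sim_cpp(net$targets, n_bins, w_bins, p_base, p_prop)
    tm <- res$bin * p$dt - p$dt / 2
    trains <- rep(list(numeric(0)), N)
    if (length(res$neuron)) {
      sp <- split(tm, factor(res$neuron, levels = seq_len(N)))
      trains <- lapply(sp, as.numeric)
    }
    spike_raster(trains, rep("E", N), positions = net$positions,
                 T_ms = T * 1000)
  })
}

#' Attach inhibitory spike trains to an excitatory network raster
#'
#' Adds inhibitory units amounting to `inh_fraction` of the full network.
#' Each inhibitory train is a thinned copy of the pooled spikes of its
#' `k_nearest` nearest excitatory units (contributing a fraction `m` of its
#' rate, mirroring the recurrent drive of excitatory units) merged with an
#' independent Poisson process (fraction `1 - m`), for a total rate `lamI`.
#'
#' @param raster an excitatory-only [spike_raster()] with positions.
#' @param params the [branching_params()] used to build the network.
#' @param rng_seed integer seed.
#' @return a [spike_raster()] with the inhibitory trains appended.
#' @export
attach_inhibitory <- function(raster, params, rng_seed = NULL) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(params, "branching_params"))
  if (any(raster$kind != "E")) stop("raster must contain only E units",
                                    call. = FALSE)
  N <- length(raster$trains)
  n_i <- round(params$inh_fraction * N / (1 - params$inh_fraction))
  T_ms <- raster$T_ms
  with_seed(rng_seed, {
    pos_i <- cbind(stats::runif(n_i), stats::runif(n_i))
    trains_i <- vector("list", n_i)
    if (n_i > 0) {
      D <- torus_dist(pos_i, raster$positions)
      for (j in seq_len(n_i)) {
        rate_rec <- params$m * params$lamI
        rate_ind <- (1 - params$m) * params$lamI
        nn <- order(D[j, ])[seq_len(min(params$k_nearest, N))]
        pooled <- sort(unlist(raster$trains[nn], use.names = FALSE))
        tr <- numeric(0)
        if (length(pooled) && rate_rec > 0) {
          # thin the pooled train down to the recurrent rate share
          p_keep <- min(1, rate_rec * T_ms / 1000 / length(pooled))
          tr <- pooled[stats::runif(length(pooled)) < p_keep]
        }
        if (rate_ind > 0) {
          n_ind <- stats::rpois(1, rate_ind * T_ms / 1000)
          tr <- c(tr, stats::runif(n_ind, 0, T_ms))
        }
        trains_i[[j]] <- sort(tr)
      }
    }
    spike_raster(c(raster$trains, trains_i),
                 rep(c("E", "I"), c(N, n_i)),
                 positions = rbind(raster$positions, pos_i), T_ms = T_ms)
  })
}

#' Spike-time tiling coefficient (STTC)
#'
#' Firing-rate-insensitive spike-train correlation:
#' `STTC = ((PA - TB) / (1 - PA TB) + (PB - TA) / (1 - PB TA)) / 2`,
#' where `PA` is the fraction of spikes in A falling within `+/- delta_t` of
#' a spike in B, and `TA` the fraction of the recording tiled by
#' `+/- delta_t` windows around the spikes of A.
#'
#' @param train_a,train_b sorted spike-time vectors, ms, within `[0, T_ms]`.
#' @param delta_t coincidence half-window, ms (default 10).
#' @param T_ms recording duration, ms.
#' @return coefficient in `[-1, 1]`; defined as 0 (with a warning) if either
#'   train is empty.
#' @export
sttc <- function(train_a, train_b, delta_t = 10, T_ms) {
  if (!length(train_a) || !length(train_b)) {
    warning("empty spike train; STTC defined as 0")
    return(0)
  }
  tiled_frac <- function(tr) {
    # merge overlapping windows (trains are sorted)
    starts <- pmax(tr - delta_t, 0); ends <- pmin(tr + delta_t, T_ms)
    n <- length(starts)
    merged <- 0; cur_lo <- starts[1]; cur_hi <- ends[1]
    if (n > 1) for (i in 2:n) {
      if (starts[i] <= cur_hi) cur_hi <- max(cur_hi, ends[i])
      else { merged <- merged + (cur_hi - cur_lo); cur_lo <- starts[i]; cur_hi <- ends[i] }
    }
    merged <- merged + (cur_hi - cur_lo)
    merged / T_ms
  }
  near_frac <- function(a, b) {
    # fraction of spikes in a within +/- delta_t of any spike in b
    i <- findInterval(a, b)
    d_prev <- ifelse(i >= 1, a - b[pmax(i, 1)], Inf)
    d_next <- ifelse(i < length(b), b[pmin(i + 1, length(b))] - a, Inf)
    mean(pmin(d_prev, d_next) <= delta_t)
  }
  TA <- tiled_frac(train_a); TB <- tiled_frac(train_b)
  PA <- near_frac(train_a, train_b); PB <- near_frac(train_b, train_a)
  term <- function(P, T) if (abs(1 - P * T) < 1e-12) 0 else (P - T) / (1 - P * T)
  (term(PA, TB) + term(PB, TA)) / 2
}

#' Pairwise STTC matrix of a raster
#'
#' @param raster a [spike_raster()].
#' @param idx indices of the trains to correlate (default all).
#' @param delta_t coincidence half-window, ms.
#' @return symmetric matrix with unit diagonal.
#' @export
sttc_matrix <- function(raster, idx = NULL, delta_t = 10) {
  stopifnot(inherits(raster, "spike_raster"))
  if (is.null(idx)) idx <- seq_along(raster$trains)
  n <- length(idx)
  T_ms <- raster$T_ms
  trains <- raster$trains[idx]
  # per-train tiled fractions are pair-independent: compute once
  tiled <- vapply(trains, function(tr) {
    if (!length(tr)) return(0)
    starts <- pmax(tr - delta_t, 0); ends <- pmin(tr + delta_t, T_ms)
    gap <- which(starts[-1] > cummax(ends[-length(ends)]))
    seg_start <- c(starts[1], starts[gap + 1])
    seg_end <- c(if (length(gap)) cummax(ends)[gap] else numeric(0),
                 max(ends))
    sum(seg_end - seg_start) / T_ms
  }, numeric(1))
  near <- function(a, b) {
    i <- findInterval(a, b)
    d_prev <- ifelse(i >= 1, a - b[pmax(i, 1)], Inf)
    d_next <- ifelse(i < length(b), b[pmin(i + 1, length(b))] - a, Inf)
    mean(pmin(d_prev, d_next) <= delta_t)
  }
  M <- diag(1, n)
  for (i in seq_len(n - 1)) {
    a <- trains[[i]]
    if (!length(a)) { M[i, ] <- M[, i] <- 0; M[i, i] <- 1; next }
    for (j in (i + 1):n) {
      b <- trains[[j]]
      if (!length(b)) { M[i, j] <- M[j, i] <- 0; next }
      PA <- near(a, b); PB <- near(b, a)
      t1 <- if (abs(1 - PA * tiled[j]) < 1e-12) 0 else
        (PA - tiled[j]) / (1 - PA * tiled[j])
      t2 <- if (abs(1 - PB * tiled[i]) < 1e-12) 0 else
        (PB - tiled[i]) / (1 - PB * tiled[i])
      M[i, j] <- M[j, i] <- (t1 + t2) / 2
    }
  }
  M
}

# Population rate of a raster on a bin grid (Hz per neuron).
population_rate <- function(raster, bin_ms = 1) {
  n_bins <- ceiling(raster$T_ms / bin_ms)
  tm <- unlist(raster$trains, use.names = FALSE)
  counts <- tabulate(pmin(floor(tm / bin_ms) + 1L, n_bins), n_bins)
  counts / length(raster$trains) / (bin_ms / 1000)
}
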