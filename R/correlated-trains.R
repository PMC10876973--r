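# Minimal model of dipole coherence: binary spike trains whose pairwise
# count correlations follow R_max * exp(-theta_ij) for synapses separated by
# an angle theta_ij on the sphere, with no temporal autocorrelation.
# Mechanism: latent Gaussian thresholding (dichotomised Gaussian) per bin.

#' Minimal correlated-synapse model parameters
#'
#' @param R_max maximal synapse-input correlation in `[0, 1)`.
#' @param dt_bin spike bin width, ms (default 1).
#' @return object of class `minimal_model_params`.
#' @export
minimal_model_params <- function(R_max = 0.2, dt_bin = 1) {
  stop_if_not_scalar(R_max, "R_max", lower = 0)
  if (R_max >= 1) stop("R_max must be < 1", call. = FALSE)
  structure(list(R_max = R_max, dt_bin = dt_bin),
            class = "minimal_model_params")
}

# Upper-quadrant probability P(X > z1, Y > z2) of a standard bivariate
# normal with correlation r, via the Drezner-Wesolowsky identity
# Phi2 = Phi(-z1) Phi(-z2) + integral_0^r phi2(z1, z2; t) dt,
# evaluated with Gauss-Legendre quadrature.
bvn_upper <- function(z1, z2, r) {
  base <- stats::pnorm(-z1) * stats::pnorm(-z2)
  if (abs(r) < 1e-14) return(base)
  gl_x <- c(-0.9815606342467192, -0.9041172563704749, -0.7699026741943047,
            -0.5873179542866175, -0.3678314989981802, -0.1252334085114689,
            0.1252334085114689, 0.3678314989981802, 0.5873179542866175,
            0.7699026741943047, 0.9041172563704749, 0.9815606342467192)
  gl_w <- c(0.0471753363865118, 0.1069393259953184, 0.1600783285433462,
            0.2031674267230659, 0.2334925365383548, 0.2491470458134028,
            0.2491470458134028, 0.2334925365383548, 0.2031674267230659,
            0.1600783285433462, 0.1069393259953184, 0.0471753363865118)
  t <- r / 2 * (gl_x + 1)
  dens <- exp(-(z1^2 - 2 * t * z1 * z2 + z2^2) / (2 * (1 - t^2))) /
    (2 * pi * sqrt(1 - t^2))
  base + r / 2 * sum(gl_w * dens)
}

# Latent Gaussian correlation that yields binary correlation `target` for
# thresholded indicators with marginal probabilities p1, p2.
latent_corr_for <- function(target, p1, p2) {
  if (abs(target) < 1e-12) return(0)
  z1 <- stats::qnorm(1 - p1); z2 <- stats::qnorm(1 - p2)
  s12 <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  fn <- function(r) (bvn_upper(z1, z2, r) - p1 * p2) / s12 - target
  upper <- 0.99999
  if (fn(upper) < 0) return(upper)  # target infeasible; clip to maximum
  stats::uniroot(fn, c(0, upper), tol = 1e-10)$root
}

# Nearest positive semidefinite repair by eigenvalue clipping, preserving
# the unit diagonal.
nearest_psd <- function(S, eps = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= eps) return(S)
  v <- pmax(e$values, eps)
  S2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(S2))
  S2 / tcrossprod(d)
}

#' Spike trains with angle-dependent pairwise correlations
#'
#' Generates per-synapse binary spike trains whose within-bin count
#' correlations approximate `R_max * exp(-theta_ij)`, where `theta_ij` is
#' the angular separation of synapses i and j on the sphere, and which are
#' white in time (independent bins, no temporal autocorrelation). The latent
#' Gaussian correlation matrix is obtained by inverting the dichotomised
#' Gaussian relation per pair and repaired to the nearest positive
#' semidefinite matrix if needed.
#'
#' @param layout a [synapse_layout()] (directions give the angles).
#' @param params a [minimal_model_params()].
#' @param biophys a [biophys_params()] providing the per-synapse rates.
#' @param T duration, s.
#' @param rng_seed integer seed.
#' @param chunk_bins bins generated per block (memory control).
#' @return a [spike_raster()] with one train per synapse.
#' @export
minimal_correlated_trains <- function(layout, params, biophys, T = 40,
                                      rng_seed = NULL, chunk_bins = 20000) {
  stopifnot(inherits(layout, "synapse_layout"),
            inherits(params, "minimal_model_params"),
            inherits(biophys, "biophys_params"))
  n <- nrow(layout$directions)
  dt_s <- params$dt_bin / 1000
  p_bin <- ifelse(layout$kind == "E", biophys$lamE, biophys$lamI) * dt_s
  if (any(p_bin >= 1)) stop("rate * bin width must be < 1", call. = FALSE)
  n_bins <- floor(T / dt_s)

  theta <- angular_distance_matrix(layout$directions)
  target <- params$R_max * exp(-theta)
  diag(target) <- 1

  # latent correlations: cache the pair-level root finding on a rounded key
  L <- diag(1, n)
  if (params$R_max > 0) {
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      key <- sprintf("%.4f_%.6f_%.6f", target[i, j],
                     min(p_bin[i], p_bin[j]), max(p_bin[i], p_bin[j]))
      r <- cache[[key]]
      if (is.null(r)) {
        r <- latent_corr_for(round(target[i, j], 4), p_bin[i], p_bin[j])
        cache[[key]] <- r
      }
      L[i, j] <- L[j, i] <- r
    }
    L <- nearest_psd(L)
  }
  U <- chol(L)
  z <- stats::qnorm(1 - p_bin)

  with_seed(rng_seed, {
    spikes <- vector("list", ceiling(n_bins / chunk_bins))
    done <- 0L; blk <- 0L
    while (done < n_bins) {
      blk <- blk + 1L
      nb <- min(chunk_bins, n_bins - done)
      X <- crossprod(U, matrix(stats::rnorm(n * nb), n, nb))
      hit <- which(X > z, arr.ind = TRUE)   # recycles z over rows ✓
      spikes[[blk]] <- cbind(hit[, 1], done + hit[, 2])
      done <- done + nb
    }
    sp <- do.call(rbind, spikes)
    trains <- rep(list(numeric(0)), n)
    if (nrow(sp)) {
      tm <- (sp[, 2] - 0.5) * params$dt_bin
      byn <- split(tm, factor(sp[, 1], levels = seq_len(n)))
      trains <- lapply(byn, function(v) sort(as.numeric(v)))
    }
    spike_raster(trains, as.character(layout$kind), T_ms = n_bins * params$dt_bin)
  })
}

#' Dipole correlation of a postsynaptic dyad
#'
#' Simulates two point neurons driven by shared presynaptic input and
#' returns the Pearson correlation between matched scalar projections of
#' their dipole moments. Input is supplied either as a per-synapse raster
#' pair (`rasters`) or is generated from the minimal correlated-synapse
#' model spanning both neurons' synapses on one sphere.
#'
#' A shuffle control (`n_shuffle > 0`) permutes the synapse directions of
#' both neurons (destroying the geometric alignment of correlated inputs
#' while keeping their temporal correlation) and returns the mean shuffled
#' correlation.
#'
#' @param layout_a,layout_b [synapse_layout()] objects for the two neurons.
#' @param biophys a [biophys_params()] shared by the dyad.
#' @param rasters optional list of two [spike_raster()] objects (one per
#'   neuron, trains in layout order). If `NULL`, trains are generated with
#'   [minimal_correlated_trains()] using `minimal`.
#' @param minimal a [minimal_model_params()] (used when `rasters` is NULL).
#' @param T duration, s.
#' @param axis projection axis: `"z"` (default; the apical axis of the
#'   layout convention), `"mean"` (each neuron's mean synapse direction), or
#'   a unit 3-vector.
#' @param n_shuffle number of shuffle controls to average (0 = none).
#' @param dt integration step, ms.
#' @param rng_seed integer seed.
#' @return list with `rho` (dyad dipole correlation), `rho_shuffled` (mean
#'   over shuffles, or NA).
#' @export
dyad_dipole_correlation <- function(layout_a, layout_b, biophys,
                                    rasters = NULL,
                                    minimal = minimal_model_params(),
                                    T = 40, axis = "z", n_shuffle = 0,
                                    dt = 0.5, rng_seed = NULL) {
  n_a <- nrow(layout_a$directions); n_b <- nrow(layout_b$directions)
  if (is.null(rasters)) {
    joint <- synapse_layout(
      n_e = sum(layout_a$kind == "E") + sum(layout_b$kind == "E"),
      n_i = sum(layout_a$kind == "I") + sum(layout_b$kind == "I"),
      directions = rbind(layout_a$directions[layout_a$kind == "E", , drop = FALSE],
                         layout_b$directions[layout_b$kind == "E", , drop = FALSE],
                         layout_a$directions[layout_a$kind == "I", , drop = FALSE],
                         layout_b$directions[layout_b$kind == "I", , drop = FALSE]))
    ras <- minimal_correlated_trains(joint, minimal, biophys, T = T,
                                     rng_seed = rng_seed)
    # unscramble back into the two layouts (E then I per neuron)
    idx_aE <- seq_len(sum(layout_a$kind == "E"))
    idx_bE <- sum(layout_a$kind == "E") + seq_len(sum(layout_b$kind == "E"))
    nE <- sum(layout_a$kind == "E") + sum(layout_b$kind == "E")
    idx_aI <- nE + seq_len(sum(layout_a$kind == "I"))
    idx_bI <- nE + sum(layout_a$kind == "I") + seq_len(sum(layout_b$kind == "I"))
    rasters <- list(
      spike_raster(ras$trains[c(idx_aE, idx_aI)], as.character(layout_a$kind),
                   T_ms = ras$T_ms),
      spike_raster(ras$trains[c(idx_bE, idx_bI)], as.character(layout_b$kind),
                   T_ms = ras$T_ms))
  }
  proj_axis <- function(layout) {
    if (is.numeric(axis)) return(axis / sqrt(sum(axis^2)))
    if (axis == "z") return(c(0, 0, 1))
    m <- colMeans(layout$directions)
    nrm <- sqrt(sum(m^2))
    if (nrm < 1e-9) c(0, 0, 1) else m / nrm
  }
  run_pair <- function(la, lb, seed_k) {
    qa <- simulate_dipole(biophys, la, rasters[[1]], dt = dt)
    qb <- simulate_dipole(biophys, lb, rasters[[2]], dt = dt)
    sa <- as.vector(qa$Q %*% proj_axis(la))
    sb <- as.vector(qb$Q %*% proj_axis(lb))
    if (stats::sd(sa) < 1e-12 || stats::sd(sb) < 1e-12) return(NA_real_)
    stats::cor(sa, sb)
  }
  rho <- run_pair(layout_a, layout_b, 0)
  rho_sh <- NA_real_
  if (n_shuffle > 0) {
    vals <- vapply(seq_len(n_shuffle), function(k) {
      with_seed(child_seed(rng_seed, 100 + k), {
        la <- layout_a; lb <- layout_b
        la$directions <- la$directions[sample.int(n_a), , drop = FALSE]
        lb$directions <- lb$directions[sample.int(n_b), , drop = FALSE]
        run_pair(la, lb, k)
      })
    }, numeric(1))
    rho_sh <- mean(vals, na.rm = TRUE)
  }
  list(rho = rho, rho_shuffled = rho_sh)
}
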