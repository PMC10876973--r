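# Variance-based (Sobol) sensitivity analysis of the spectral slope with
# respect to the sampled biophysical parameters, via Saltelli sampling and
# Jansen estimators.

#' Sobol sensitivity indices by Saltelli sampling
#'
#' Estimates first-order and total-effect indices (Jansen estimators) of a
#' scalar model over independent uniform(0,1) factors, plus closed
#' second-order interaction indices for requested factor pairs.
#'
#' @param model function taking an `n x d` matrix of uniform(0,1) draws
#'   (columns named per `factors`) and returning `n` scalar outputs.
#' @param factors character vector of factor names (length d).
#' @param n base sample size; the model is evaluated `n * (d + 2 + n_pairs)`
#'   times.
#' @param pairs optional list of 2-element character vectors naming factor
#'   pairs whose second-order interaction index is wanted.
#' @param rng_seed integer seed for the sampling design.
#' @return list with `first` and `total` (named numeric vectors), `second`
#'   (named numeric vector of `S_ij`, names `"a:b"`), and `variance`.
#' @export
sobol_indices <- function(model, factors, n, pairs = list(), rng_seed = NULL) {
  d <- length(factors)
  stopifnot(d >= 1, n >= 2)
  AB <- with_seed(rng_seed, matrix(stats::runif(2 * n * d), 2 * n, d,
                                   dimnames = list(NULL, factors)))
  A <- AB[seq_len(n), , drop = FALSE]
  B <- AB[n + seq_len(n), , drop = FALSE]
  fA <- model(A); fB <- model(B)
  V <- stats::var(c(fA, fB))
  first <- total <- stats::setNames(numeric(d), factors)
  for (i in seq_len(d)) {
    ABi <- A; ABi[, i] <- B[, i]
    fABi <- model(ABi)
    first[i] <- 1 - mean((fB - fABi)^2) / (2 * V)
    total[i] <- mean((fA - fABi)^2) / (2 * V)
  }
  second <- stats::setNames(numeric(length(pairs)),
                            vapply(pairs, paste, "", collapse = ":"))
  for (k in seq_along(pairs)) {
    ij <- match(pairs[[k]], factors)
    if (anyNA(ij)) stop("unknown factor in `pairs`", call. = FALSE)
    ABij <- A; ABij[, ij] <- B[, ij]
    fABij <- model(ABij)
    closed <- 1 - mean((fB - fABij)^2) / (2 * V)
    second[k] <- closed - first[ij[1]] - first[ij[2]]
  }
  list(first = first, total = total, second = second, variance = V)
}

#' Sensitivity of the spectral slope to biophysical parameters
#'
#' Sobol sensitivity analysis of the spectral exponent beta (from
#' [fit_slope()] over 1-40 Hz of the unitary spectrum) with respect to the
#' eight sampled biophysical parameters, including the leak-rate interactions
#' `gL:lamE` and `gL:lamI`.
#'
#' @param n base Saltelli sample size (>= 256); the simulator runs
#'   `n * (8 + 2 + n_pairs)` times, so budget accordingly.
#' @param rng_seed integer seed.
#' @param T,n_trials,dt per-evaluation simulation settings passed to
#'   [unitary_spectrum()].
#' @param layout synapse layout shared across evaluations.
#' @param pairs factor pairs for second-order indices; defaults to the
#'   leak-conductance x input-rate interactions.
#' @param model optional replacement for the simulator (same signature as the
#'   `model` of [sobol_indices()]); used for validating the estimator against
#'   closed-form test functions.
#' @return data frame with one row per parameter (`first`, `total`) and an
#'   attribute `second` with the pairwise interaction indices.
#' @export
slope_sensitivity <- function(n = 256, rng_seed = NULL, T = 4, n_trials = 1,
                              dt = 0.1, layout = NULL,
                              pairs = list(c("gL", "lamE"), c("gL", "lamI")),
                              model = NULL) {
  if (n < 256) stop("n must be >= 256 for stable Sobol estimates", call. = FALSE)
  factors <- names(biophys_ranges())
  if (is.null(model)) {
    if (is.null(layout)) layout <- synapse_layout(500, 75, rng_seed =
                                                    child_seed(rng_seed, 999))
    counter <- new.env(); counter$k <- 0
    model <- function(u) {
      pars <- map_biophys_quantiles(u)
      apply(pars, 1, function(row) {
        counter$k <- counter$k + 1
        p <- biophys_from_row(as.list(row))
        us <- unitary_spectrum(p, layout, T = T, n_trials = n_trials, dt = dt,
                               f_max = 60,
                               rng_seed = child_seed(rng_seed, counter$k))
        fit_slope(us)$beta
      })
    }
  }
  res <- sobol_indices(model, factors, n, pairs = pairs, rng_seed = rng_seed)
  out <- data.frame(param = factors, first = unname(res$first),
                    total = unname(res$total))
  attr(out, "second") <- res$second
  attr(out, "variance") <- res$variance
  out
}
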