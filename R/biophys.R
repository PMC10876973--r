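#' Single-neuron biophysical parameters
#'
#' Parameters of the point-neuron proxy: passive membrane, conductance-based
#' AMPAR (excitatory) and GABAR (inhibitory) synapses with
#' difference-of-exponentials gates, and mean presynaptic rates.
#'
#' Defaults are the reference set used for example spectra: `gL` = 1 mS/cm2,
#' `EL` = -58 mV, `tauE` = 1.8 ms, `gE` = 0.7 nS, `tauI` = 10 ms,
#' `gI` = 0.7 nS. Rise times are fixed at 0.3 ms (AMPAR) and 2 ms (GABAR),
#' reversal potentials at 0 mV (AMPAR) and -80 mV (GABAR).
#'
#' @param lamE,lamI mean input rate per excitatory / inhibitory synapse, Hz.
#'   Reference values 1 and 10 Hz: sparse pyramidal firing versus sustained
#'   fast-spiking interneuron rates, which puts the low-frequency spectrum
#'   in the inhibition-dominated regime the slow-timescale trend describes.
#' @param tauE,tauI decay time constants, ms (AMPAR 1-3.5 ms, GABAR 5-20 ms;
#'   up to 75 ms under propofol).
#' @param gE,gI peak synaptic conductances, nS (0.2-2 nS).
#' @param EL leak reversal potential, mV (-75 to -45).
#' @param gL leak conductance density, mS/cm2 (0.01-5).
#' @param EE,EI synaptic reversal potentials, mV.
#' @param riseE,riseI synaptic rise times, ms.
#' @param Cm membrane capacitance density, uF/cm2.
#' @param area total membrane area of the point neuron, um2. Sets the scale
#'   of the leak and capacitance relative to the synaptic conductances.
#' @return object of class `biophys_params`.
#' @export
biophys_params <- function(lamE = 1, lamI = 10, tauE = 1.8, tauI = 10,
                           gE = 0.7, gI = 0.7, EL = -58, gL = 1,
                           EE = 0, EI = -80, riseE = 0.3, riseI = 2,
                           Cm = 1, area = 20000) {
  p <- list(lamE = lamE, lamI = lamI, tauE = tauE, tauI = tauI, gE = gE,
            gI = gI, EL = EL, gL = gL, EE = EE, EI = EI, riseE = riseE,
            riseI = riseI, Cm = Cm, area = area)
  for (nm in c("lamE", "lamI", "gE", "gI", "gL"))
    stop_if_not_scalar(p[[nm]], nm, lower = 0)
  if (p$tauE <= p$riseE || p$tauI <= p$riseI)
    stop("decay time must exceed rise time for each receptor", call. = FALSE)
  if (!(p$EI < p$EL && p$EL < p$EE))
    stop("reversal potentials must satisfy EI < EL < EE", call. = FALSE)
  structure(p, class = "biophys_params")
}

#' Parameter ranges used when sampling biophysical parameters
#'
#' @return named list of `c(lower, upper)` ranges with an attribute giving the
#'   distribution shape per parameter (log-uniform for conductances and rates,
#'   uniform for time constants and the leak reversal).
#' @export
biophys_ranges <- function() {
  list(lamE = c(0.1, 10), lamI = c(0.1, 10),
       tauE = c(1, 3.5), tauI = c(5, 20),
       gE = c(0.2, 2), gI = c(0.2, 2),
       EL = c(-75, -45), gL = c(0.01, 5))
}

biophys_log_sampled <- c("lamE", "lamI", "gE", "gI", "gL")

# Map a matrix of uniform(0,1) draws (columns named as biophys_ranges) to
# parameter values, respecting the per-parameter distribution shape.
map_biophys_quantiles <- function(u, ranges = biophys_ranges()) {
  out <- u
  for (nm in colnames(u)) {
    r <- ranges[[nm]]
    out[, nm] <- if (nm %in% biophys_log_sampled)
      exp(log(r[1]) + u[, nm] * (log(r[2]) - log(r[1])))
    else r[1] + u[, nm] * (r[2] - r[1])
  }
  out
}

#' Sample biophysical parameter sets
#'
#' Draws `n` independent parameter sets from the sampling distributions:
#' log-uniform over the stated ranges for rates and conductances (`lamE`,
#' `lamI`, `gE`, `gI`, `gL`), uniform for `tauE`, `tauI` and `EL`.
#'
#' @param n number of draws.
#' @param rng_seed integer seed; identical seeds give identical samples.
#' @param ranges optional override of [biophys_ranges()] entries.
#' @return data frame with one row per draw and one column per sampled
#'   parameter.
#' @export
sample_biophys <- function(n, rng_seed = NULL, ranges = NULL) {
  stopifnot(n >= 1)
  rg <- biophys_ranges()
  if (!is.null(ranges)) rg[names(ranges)] <- ranges
  nm <- names(rg)
  u <- with_seed(rng_seed, matrix(stats::runif(n * length(nm)), n,
                                  dimnames = list(NULL, nm)))
  as.data.frame(map_biophys_quantiles(u, rg))
}

# Build a biophys_params from a row of sample_biophys output, keeping the
# non-sampled fields at their defaults.
biophys_from_row <- function(row, ...) {
  do.call(biophys_params, c(as.list(row), list(...)))
}

#' Synapse layout of the point-neuron proxy
#'
#' Synapses are represented by unit direction vectors from the soma (origin),
#' standing in for the position of the synapse on the dendritic tree; each
#' synaptic current contributes to the dipole along its direction. The
#' hemisphere `sign(z) > 0` plays the role of the apical compartment.
#'
#' @param n_e,n_i number of excitatory / inhibitory synapses. Defaults follow
#'   a 1:0.15 inhibitory-to-excitatory count ratio for a 1000 um dendrite at
#'   1 E synapse per um.
#' @param directions optional `(n_e+n_i) x 3` matrix of unit vectors
#'   (excitatory rows first); random uniform directions if omitted.
#' @param balanced if TRUE, random directions are drawn as mirror pairs
#'   (`d` and `d` with z negated), so each class has exactly zero net
#'   apical moment — like a dendritic tree spanning both hemispheres. This
#'   removes the spurious dipole-correlation channel through a layout's net
#'   moment.
#' @param rng_seed seed for random directions.
#' @return object of class `synapse_layout` with `directions`, `kind`
#'   (factor E/I) and `apical` (logical, z > 0).
#' @export
synapse_layout <- function(n_e = 1000, n_i = 150, directions = NULL,
                           balanced = FALSE, rng_seed = NULL) {
  stopifnot(n_e >= 1, n_i >= 1)
  n <- n_e + n_i
  if (is.null(directions)) {
    directions <- with_seed(rng_seed, {
      if (!balanced) runif_sphere(n)
      else {
        mk <- function(k) {
          half <- runif_sphere(ceiling(k / 2))
          m <- rbind(half, half * matrix(c(1, 1, -1), ceiling(k / 2), 3,
                                         byrow = TRUE))
          m[seq_len(k), , drop = FALSE]
        }
        rbind(mk(n_e), mk(n_i))
      }
    })
  } else {
    directions <- as.matrix(directions)
    stopifnot(nrow(directions) == n, ncol(directions) == 3)
    if (any(abs(sqrt(rowSums(directions^2)) - 1) > 1e-9))
      stop("synapse directions must be unit vectors", call. = FALSE)
  }
  structure(list(directions = directions,
                 kind = factor(rep(c("E", "I"), c(n_e, n_i)),
                               levels = c("E", "I")),
                 apical = directions[, 3] > 0),
            class = "synapse_layout")
}

#' Per-synapse spike raster
#'
#' Container for spike trains: a list of sorted spike-time vectors (ms) with
#' an E/I label per train and, optionally, planar positions (for network
#' rasters) or the duration simulated.
#'
#' @param trains list of numeric vectors of spike times, ms, each sorted.
#' @param kind factor or character vector of train labels (`"E"`/`"I"`).
#' @param positions optional matrix of planar positions (network neurons).
#' @param T_ms duration covered by the raster, ms.
#' @return object of class `spike_raster`.
#' @export
spike_raster <- function(trains, kind, positions = NULL, T_ms = NULL) {
  stopifnot(is.list(trains), length(kind) == length(trains))
  for (tr in trains)
    if (length(tr) && (is.unsorted(tr) || any(tr < 0)))
      stop("spike trains must be sorted and non-negative", call. = FALSE)
  if (!is.null(T_ms) && any(unlist(trains, use.names = FALSE) > T_ms))
    stop("spike times exceed the stated duration", call. = FALSE)
  structure(list(trains = unname(trains),
                 kind = factor(kind, levels = c("E", "I")),
                 positions = positions, T_ms = T_ms),
            class = "spike_raster")
}

#' Read / write spike rasters as TSV
#'
#' Layout: header `train_id\tspike_time_ms`, one row per spike. The number of
#' trains and their labels travel in a JSON side-car written next to the TSV.
#'
#' @param x a [spike_raster()].
#' @param path TSV path; the side-car is `paste0(path, ".json")`.
#' @return `read_raster_tsv` returns a [spike_raster()].
#' @export
write_raster_tsv <- function(x, path) {
  stopifnot(inherits(x, "spike_raster"))
  n_sp <- lengths(x$trains)
  d <- data.frame(train_id = rep(seq_along(x$trains), n_sp),
                  spike_time_ms = unlist(x$trains, use.names = FALSE))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(n_trains = length(x$trains), kind = as.character(x$kind),
               T_ms = x$T_ms)
  if (!is.null(x$positions)) meta$positions <- unname(as.matrix(x$positions))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trains <- rep(list(numeric(0)), meta$n_trains)
  if (nrow(d)) {
    sp <- split(d$spike_time_ms, factor(d$train_id, levels = seq_len(meta$n_trains)))
    trains <- lapply(sp, function(v) sort(as.numeric(v)))
  }
  pos <- if (!is.null(meta$positions)) as.matrix(meta$positions) else NULL
  spike_raster(trains, meta$kind, positions = pos, T_ms = meta$T_ms)
}
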