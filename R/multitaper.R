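# Multitaper spectral estimation with discrete prolate spheroidal sequences
# (DPSS), computed from the classic symmetric tridiagonal formulation and
# cached per (length, bandwidth) pair.

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' First `k` DPSS tapers of length `n` with time-bandwidth product `nw`,
#' from the eigenvectors of the symmetric tridiagonal matrix whose top
#' eigenvectors are the Slepian sequences. Tapers are unit-energy and sign
#' conventions fixed (non-negative mean for even orders, positive initial
#' slope for odd orders).
#'
#' @param n taper length, samples.
#' @param nw time-bandwidth product (default 2).
#' @param k number of tapers (default 3, i.e. `2 nw - 1`).
#' @return `n x k` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (t[-1] * (n - t[-1])) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (j %% 2 == 1 && sum(v[, j]) < 0) v[, j] <- -v[, j]
    if (j %% 2 == 0 && v[2, j] - v[1, j] < 0) v[, j] <- -v[, j]
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
  }
  .dpss_cache[[key]] <- v
  v
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper power spectral density: DPSS tapers (default 3
#' tapers, time-bandwidth NW = 2) over 2 s windows advanced by
#' `window - overlap` (default 0.1 s). Per window, taper periodograms are
#' averaged; density units are signal-units^2 per Hz (one-sided).
#'
#' @param x numeric signal, uV.
#' @param fs sampling rate, Hz (required).
#' @param window window length, s (default 2).
#' @param overlap window overlap, s (default 1.9).
#' @param n_tapers number of DPSS tapers (default 3).
#' @param nw time-bandwidth product (default 2, consistent with 3 usable
#'   tapers).
#' @param f_max optional upper frequency cut.
#' @return a [new_spectrogram()]; times are window centres.
#' @export
multitaper_spectrogram <- function(x, fs, window = 2, overlap = 1.9,
                                   n_tapers = 3, nw = 2, f_max = NULL) {
  if (missing(fs) || is.null(fs)) stop("`fs` is required", call. = FALSE)
  nwin <- round(window * fs)
  if (length(x) < nwin) stop("signal shorter than one window", call. = FALSE)
  hop <- max(1L, round((window - overlap) * fs))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  tap <- dpss_tapers(nwin, nw = nw, k = n_tapers)
  nf <- nwin %/% 2L
  freq <- (1:nf) * fs / nwin
  keep <- if (is.null(f_max)) rep(TRUE, nf) else freq <= f_max
  P <- matrix(0, sum(keep), length(starts))
  for (s in seq_along(starts)) {
    seg <- x[starts[s]:(starts[s] + nwin - 1L)]
    seg <- seg - mean(seg)
    acc <- numeric(nf)
    for (j in seq_len(n_tapers)) {
      ft <- stats::fft(seg * tap[, j])[2:(nf + 1L)]
      acc <- acc + Mod(ft)^2
    }
    P[, s] <- (acc / n_tapers * 2 / fs)[keep]
  }
  times <- (starts - 1L) / fs + window / 2
  new_spectrogram(times, freq[keep], P,
                  meta = list(fs = fs, window = window, overlap = overlap,
                              n_tapers = n_tapers, nw = nw))
}

#' Multitaper spectrum of a whole record
#'
#' Convenience wrapper: multitaper PSD per window, averaged over all
#' windows.
#'
#' @inheritParams multitaper_spectrogram
#' @return a [new_spectrum()].
#' @export
multitaper_spectrum <- function(x, fs, window = 2, overlap = 1, n_tapers = 3,
                                nw = 2, f_max = NULL) {
  sg <- multitaper_spectrogram(x, fs, window = window, overlap = overlap,
                               n_tapers = n_tapers, nw = nw, f_max = f_max)
  new_spectrum(sg$freq, rowMeans(sg$power))
}

#' Fill a line-noise band of a spectrum by interpolation
#'
#' Replaces the bins within `center +/- halfwidth` Hz by log-linear
#' interpolation between the flanking bins, leaving all other bins
#' untouched. Used to remove mains (60 Hz) peaks before trend fitting.
#'
#' @param spectrum a [new_spectrum()].
#' @param center notch centre, Hz (default 60).
#' @param halfwidth half-width of the replaced band, Hz (default 2).
#' @return a [new_spectrum()].
#' @export
fill_line_noise <- function(spectrum, center = 60, halfwidth = 2) {
  spectrum <- as_spectrum(spectrum)
  f <- spectrum$freq; p <- spectrum$power
  if (center < min(f) || center > max(f))
    stop("notch centre outside the spectrum range", call. = FALSE)
  band <- which(abs(f - center) <= halfwidth)
  if (!length(band)) return(spectrum)
  lo <- min(band) - 1L; hi <- max(band) + 1L
  if (lo < 1 || hi > length(f)) return(spectrum)  # band touches the edge
  lp <- log(p[c(lo, hi)])
  p[band] <- exp(stats::approx(f[c(lo, hi)], lp, xout = f[band])$y)
  new_spectrum(f, p)
}

#' Band power time series from a spectrogram
#'
#' Trapezoid-integrated power per window over a frequency band. Canonical
#' bands: delta 0.5-3 Hz, alpha 8-15 Hz, beta 15-30 Hz.
#'
#' @param spectrogram a [new_spectrogram()].
#' @param band `c(lo, hi)` Hz, or one of `"delta"`, `"alpha"`, `"beta"`.
#' @param baseline optional `c(t0, t1)` s: divide the series by its mean
#'   over windows whose centres fall in this interval.
#' @return data frame `time` / `power` (power in uV^2, or unitless if
#'   baseline-normalised).
#' @export
band_power <- function(spectrogram, band, baseline = NULL) {
  stopifnot(inherits(spectrogram, "spectrogram"))
  if (is.character(band))
    band <- switch(match.arg(band, c("delta", "alpha", "beta")),
                   delta = c(0.5, 3), alpha = c(8, 15), beta = c(15, 30))
  sel <- spectrogram$freq >= band[1] & spectrogram$freq <= band[2]
  if (sum(sel) < 2) stop("band contains fewer than 2 frequency bins",
                         call. = FALSE)
  f <- spectrogram$freq[sel]
  pw <- apply(spectrogram$power[sel, , drop = FALSE], 2,
              function(col) trapz(f, col))
  if (!is.null(baseline)) {
    bw <- spectrogram$times >= baseline[1] & spectrogram$times <= baseline[2]
    if (!any(bw)) stop("no windows in the baseline interval", call. = FALSE)
    pw <- pw / mean(pw[bw])
  }
  data.frame(time = spectrogram$times, power = pw)
}
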