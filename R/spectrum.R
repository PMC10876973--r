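#' Power spectrum container
#'
#' A `spectrum` is a two-column data frame (`freq`, `power`) holding a
#' one-sided power spectral density: frequencies in Hz (non-negative,
#' strictly increasing) and spectral density in uV^2/Hz (non-negative).
#'
#' @param freq numeric vector of frequencies, Hz.
#' @param power numeric vector of spectral densities, same length as `freq`.
#' @return an object of class `spectrum` (a data frame).
#' @export
new_spectrum <- function(freq, power) {
  freq <- as.numeric(freq); power <- as.numeric(power)
  if (length(freq) != length(power))
    stop("`freq` and `power` must have the same length", call. = FALSE)
  if (anyNA(freq) || any(freq < 0)) stop("frequencies must be >= 0", call. = FALSE)
  if (is.unsorted(freq, strictly = TRUE)) stop("frequencies must be strictly increasing",
                                               call. = FALSE)
  if (anyNA(power) || any(!is.finite(power)) || any(power < 0))
    stop("power must be finite and >= 0", call. = FALSE)
  structure(data.frame(freq = freq, power = power),
            class = c("spectrum", "data.frame"))
}

is_spectrum <- function(x) inherits(x, "spectrum")

as_spectrum <- function(x) {
  if (is_spectrum(x)) return(x)
  if (is.data.frame(x) && all(c("freq", "power") %in% names(x)))
    return(new_spectrum(x$freq, x$power))
  stop("cannot coerce to spectrum", call. = FALSE)
}

#' Read / write spectra as two-column TSV
#'
#' Plain-text persistence for spectra: a header line `freq_hz\tpower` followed
#' by one row per frequency bin.
#'
#' @param path file path.
#' @param x a `spectrum`.
#' @return `read_spectrum_tsv` returns a `spectrum`.
#' @export
read_spectrum_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  new_spectrum(d[[1]], d[[2]])
}

#' @rdname read_spectrum_tsv
#' @export
write_spectrum_tsv <- function(x, path) {
  x <- as_spectrum(x)
  utils::write.table(data.frame(freq_hz = x$freq, power = x$power), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spectrogram container
#'
#' A `spectrogram` bundles window-centre times (s), frequencies (Hz) and a
#' `length(freq) x length(times)` matrix of spectral density (uV^2/Hz).
#'
#' @param times numeric vector of window centres, s.
#' @param freq numeric vector of frequencies, Hz.
#' @param power matrix, `length(freq)` rows by `length(times)` columns.
#' @param meta optional named list of metadata.
#' @return an object of class `spectrogram`.
#' @export
new_spectrogram <- function(times, freq, power, meta = list()) {
  power <- as.matrix(power)
  if (nrow(power) != length(freq) || ncol(power) != length(times))
    stop("power must be length(freq) x length(times)", call. = FALSE)
  if (any(power < 0)) stop("spectrogram power must be >= 0", call. = FALSE)
  structure(list(times = as.numeric(times), freq = as.numeric(freq),
                 power = power, meta = meta),
            class = "spectrogram")
}

#' Read / write spectrograms as TSV
#'
#' Long-format layout with header `time_s\tfreq_hz\tpower`, one row per
#' (window, frequency) cell. This is also the adapter used for externally
#' deposited spectrograms once exported to the same layout.
#'
#' @param path file path.
#' @param x a `spectrogram`.
#' @return `read_spectrogram_tsv` returns a `spectrogram`.
#' @export
read_spectrogram_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  times <- sort(unique(d[[1]])); freq <- sort(unique(d[[2]]))
  p <- matrix(NA_real_, length(freq), length(times))
  p[cbind(match(d[[2]], freq), match(d[[1]], times))] <- d[[3]]
  if (anyNA(p)) stop("incomplete spectrogram grid in ", path, call. = FALSE)
  new_spectrogram(times, freq, p)
}

#' @rdname read_spectrogram_tsv
#' @export
write_spectrogram_tsv <- function(x, path) {
  stopifnot(inherits(x, "spectrogram"))
  d <- data.frame(time_s = rep(x$times, each = length(x$freq)),
                  freq_hz = rep(x$freq, length(x$times)),
                  power = as.vector(x$power))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
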