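# Shared independent oracles used across test files.

# Literal evaluation of the spike-time tiling coefficient formula:
# proportions by per-spike scans, tiled time by an endpoint sweep.
sttc_oracle <- function(a, b, dt, T_ms) {
  if (!length(a) || !length(b)) return(0)
  prop_near <- function(x, y) mean(vapply(x, function(s) any(abs(y - s) <= dt),
                                          logical(1)))
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
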