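# Effect-site propofol concentration from a three-compartment plasma
# pharmacokinetic model with first-order effect-site equilibration, and
# Hill dose-response fitting.

#' Pharmacokinetic parameters (Marsh-type three-compartment model)
#'
#' Rate constants are configuration data taken from the adult propofol
#' model of Marsh et al. (Br J Anaesth 1991): `k10` 0.119, `k12` 0.112,
#' `k13` 0.0419, `k21` 0.055, `k31` 0.0033 per minute, central volume
#' 0.228 L/kg; plasma-to-effect-site equilibration `keo` 1.21 per minute.
#'
#' @param weight body weight, kg.
#' @param keo effect-site equilibration rate constant, min^-1.
#' @param k10,k12,k13,k21,k31 compartment rate constants, min^-1.
#' @param V1_per_kg central compartment volume, L/kg.
#' @return object of class `pk_params`.
#' @export
pk_params <- function(weight = 70, keo = 1.21, k10 = 0.119, k12 = 0.112,
                      k13 = 0.0419, k21 = 0.055, k31 = 0.0033,
                      V1_per_kg = 0.228) {
  p <- list(weight = weight, keo = keo, k10 = k10, k12 = k12, k13 = k13,
            k21 = k21, k31 = k31, V1_per_kg = V1_per_kg)
  for (nm in setdiff(names(p), "weight")) stop_if_not_scalar(p[[nm]], nm)
  if (any(unlist(p[-1]) <= 0)) stop("rate constants must be > 0", call. = FALSE)
  if (weight <= 0) stop("weight must be > 0", call. = FALSE)
  structure(p, class = "pk_params")
}

# molar mass of propofol, g/mol: converts ug/mL (mg/L) to umol/L
PROPOFOL_MW <- 178.27

#' Effect-site propofol concentration under an infusion schedule
#'
#' Integrates the three-compartment plasma model
#' `dA1/dt = I(t) - (k10 + k12 + k13) A1 + k21 A2 + k31 A3` (amounts, mg)
#' with peripheral exchange, then the effect-site equilibration
#' `dCe/dt = keo (Cp - Ce)` with `Cp = A1 / V1`.
#'
#' @param pk a [pk_params()].
#' @param t_infusion infusion start, s.
#' @param t_end infusion end, s.
#' @param rate infusion rate, mg kg^-1 min^-1 (default protocol: 1).
#' @param t_max end of the simulated trace, s (default `t_end + 60`).
#' @param dt output resolution, s.
#' @return data frame `time` (s), `Cp`, `Ce` (umol/L).
#' @export
marsh_effect_site <- function(pk, t_infusion, t_end, rate = 1,
                              t_max = NULL, dt = 0.5) {
  stopifnot(inherits(pk, "pk_params"), t_end > t_infusion)
  if (is.null(t_max)) t_max <- t_end + 60
  V1 <- pk$V1_per_kg * pk$weight
  inf_mg_min <- rate * pk$weight
  deriv <- function(t, y, parms) {
    I <- if (t >= t_infusion / 60 && t < t_end / 60) inf_mg_min else 0
    dA1 <- I - (pk$k10 + pk$k12 + pk$k13) * y[1] + pk$k21 * y[2] +
      pk$k31 * y[3]
    dA2 <- pk$k12 * y[1] - pk$k21 * y[2]
    dA3 <- pk$k13 * y[1] - pk$k31 * y[3]
    dCe <- pk$keo * (y[1] / V1 - y[4])
    list(c(dA1, dA2, dA3, dCe))
  }
  t_min <- seq(0, t_max / 60, by = dt / 60)
  sol <- deSolve::lsoda(c(0, 0, 0, 0), t_min, deriv, NULL, rtol = 1e-8,
                        atol = 1e-10)
  conv <- 1000 / PROPOFOL_MW  # mg/L -> umol/L
  data.frame(time = sol[, 1] * 60,
             Cp = sol[, 2] / V1 * conv,
             Ce = sol[, 5] * conv)
}

#' Hill dose-response curve
#'
#' `response(C) = baseline + span * C^n / (EC50^n + C^n)`.
#'
#' @param C concentrations.
#' @param EC50 half-maximal concentration.
#' @param n Hill coefficient.
#' @param baseline response at zero dose (default 1, fold-change scale).
#' @param span maximal increment above baseline.
#' @return numeric responses.
#' @export
hill_response <- function(C, EC50, n, baseline = 1, span = 1) {
  baseline + span * C^n / (EC50^n + C^n)
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `baseline + span * C^n / (EC50^n + C^n)` with
#' log-parameterised EC50 and n, multi-start over an EC50 grid.
#'
#' @param dose concentrations (> 0), at least 4 points.
#' @param response responses (e.g. fold change of the inhibitory timescale).
#' @param fix_baseline optional fixed baseline (e.g. 1 for fold changes);
#'   fitted if NULL.
#' @return list of class `hill_fit`: `EC50`, `n`, `baseline`, `span`,
#'   `rss`.
#' @export
fit_hill <- function(dose, response, fix_baseline = NULL) {
  stopifnot(length(dose) == length(response))
  if (length(dose) < 4) stop("need at least 4 dose points", call. = FALSE)
  if (any(dose <= 0)) stop("concentrations must be > 0", call. = FALSE)
  r_lo <- stats::quantile(response, 0.05); r_hi <- stats::quantile(response, 0.95)
  span0 <- max(r_hi - r_lo, 1e-6)
  base0 <- if (is.null(fix_baseline)) r_lo else fix_baseline
  obj <- function(th) {
    ec <- exp(th[1]); n <- exp(th[2]); span <- exp(th[3])
    base <- if (is.null(fix_baseline)) th[4] else fix_baseline
    sum((hill_response(dose, ec, n, base, span) - response)^2)
  }
  best <- NULL
  for (ec0 in stats::quantile(dose, c(0.1, 0.3, 0.5, 0.7, 0.9))) {
    th0 <- c(log(ec0), log(1.5), log(span0))
    if (is.null(fix_baseline)) th0 <- c(th0, base0)
    fit <- stats::nlminb(th0, obj, control = list(iter.max = 500))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  th <- best$par
  structure(list(EC50 = exp(th[1]), n = exp(th[2]),
                 baseline = if (is.null(fix_baseline)) th[4] else fix_baseline,
                 span = exp(th[3]), rss = best$objective),
            class = "hill_fit")
}
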