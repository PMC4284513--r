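#' Construct a fluorescence or current trace
#'
#' @param times sample times (s), strictly increasing.
#' @param values fluorescence (arbitrary units) or current (uA).
#' @param pulse_start,pulse_end test-pulse window (s), within the record.
#' @param holding_voltage holding potential (mV, default -80).
#' @return object of class `"ephys_trace"`.
#' @export
ephys_trace <- function(times, values, pulse_start, pulse_end,
                        holding_voltage = -80) {
  stopifnot(length(times) == length(values))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (pulse_start < times[1] || pulse_end > times[length(times)] ||
      pulse_start >= pulse_end)
    stop("pulse window must lie within the record")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 pulse_start = pulse_start, pulse_end = pulse_end,
                 holding_voltage = holding_voltage),
            class = "ephys_trace")
}

#' Baseline-corrected fractional fluorescence change (dF/F)
#'
#' Fits the baseline fluorescence with an ordinary least-squares line over
#' the `baseline_span` seconds (default 2 s, at the holding potential)
#' preceding the pulse, extrapolates that line across the whole record, and
#' returns `(F(t) - F_baseline(t)) / F_baseline(t)` pointwise. A baseline
#' line that reaches zero anywhere in the record makes the division
#' undefined and is an error.
#'
#' @param trace an [ephys_trace()].
#' @param baseline_span seconds of pre-pulse data used for the fit.
#' @return an [ephys_trace()] whose `values` are dF/F (unitless), with the
#'   fitted baseline in attribute `"baseline"`.
#' @export
delta_f_over_f <- function(trace, baseline_span = 2) {
  stopifnot(inherits(trace, "ephys_trace"))
  t <- trace$times
  inb <- which(t >= trace$pulse_start - baseline_span & t < trace$pulse_start)
  if (length(inb) < 2)
    stop("need at least 2 samples in the pre-pulse baseline window")
  fit <- lm(v ~ t, data = data.frame(t = t[inb], v = trace$values[inb]))
  fb <- as.numeric(predict(fit, newdata = data.frame(t = t)))
  if (min(fb) <= 0 && max(fb) >= 0)
    stop("baseline crosses zero within the record: dF/F undefined")
  out <- trace
  out$values <- (trace$values - fb) / fb
  attr(out, "baseline") <- fb
  attr(out, "baseline_fit") <- coef(fit)
  out
}

#' Two-state Boltzmann activation curve
#'
#' `P(V) = 1 / (1 + exp(-z F (V - V1/2) / (R T)))` with voltages in mV
#' (converted to volts internally), `F` and `R` in SI units. Saturates
#' numerically at voltage extremes without overflow.
#'
#' @param v test voltage(s), mV.
#' @param v_half half-activation voltage, mV.
#' @param z apparent gating charge (e), `> 0` for activation.
#' @param temperature absolute temperature (K), default 293.15 (room
#'   temperature).
#' @return activation probability in `(0, 1)`.
#' @export
boltzmann <- function(v, v_half, z, temperature = 293.15) {
  stopifnot(z > 0, temperature > 0)
  plogis(z * .FARADAY_SI * ((v - v_half) / 1000) / (.RGAS_SI * temperature))
}

#' Construct a normalized gating curve (F/V or G/V)
#' @param voltages test voltages (mV), strictly increasing.
#' @param response normalized response (approximately 0..1).
#' @param kind `"FV"` (fluorescence, VSD activation) or `"GV"` (conductance).
#' @return object of class `"gating_curve"`.
#' @export
gating_curve <- function(voltages, response, kind = c("FV", "GV")) {
  kind <- match.arg(kind)
  stopifnot(length(voltages) == length(response))
  if (any(diff(voltages) <= 0)) stop("voltages must be strictly increasing")
  if (any(!is.finite(response))) stop("response values must be finite")
  structure(list(voltages = as.numeric(voltages),
                 response = as.numeric(response), kind = kind),
            class = "gating_curve")
}

#' Fit a Boltzmann function to a gating curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of [boltzmann()] to a normalized F/V or G/V
#' relation. `z` is constrained to `(0, 10]` and `v_half` to the data span
#' +/- 100 mV. Starts are taken at the observed voltages whose response is
#' nearest 0.5, with the slope-derived gating charge
#' `z0 = 4 R T s_max / F` (where `s_max` is the steepest finite-difference
#' slope per volt); the best converged start by residual sum of squares
#' wins. Standard errors come from the fit's curvature.
#'
#' @param curve a [gating_curve()] with at least 4 points spanning the
#'   transition.
#' @param temperature absolute temperature (K).
#' @param weights optional per-point weights.
#' @return object of class `"boltzmann_fit"`: `v_half`, `z`, `v_half_se`,
#'   `z_se`, `rss`, `n`, `temperature`, `kind`.
#' @export
fit_boltzmann <- function(curve, temperature = 293.15, weights = NULL) {
  stopifnot(inherits(curve, "gating_curve"))
  v <- curve$voltages; y <- curve$response
  if (length(v) < 4) stop("need at least 4 points to fit a Boltzmann")
  if (diff(range(y)) == 0)
    stop("degenerate curve: all responses equal, no transition to fit")
  lo <- c(v_half = min(v) - 100, z = 1e-3)
  hi <- c(v_half = max(v) + 100, z = 10)
  ## finite-difference slope (per volt) -> initial gating charge
  sl <- diff(y) / (diff(v) / 1000)
  z0 <- 4 * .RGAS_SI * temperature * max(abs(sl)) / .FARADAY_SI
  z0 <- min(max(z0, 0.2), 8)
  vh0s <- unique(v[order(abs(y - 0.5))][seq_len(min(3, length(v)))])
  starts <- expand.grid(v_half = vh0s, z = unique(c(z0, z0 / 2, z0 * 2, 2)))
  starts$z <- pmin(pmax(starts$z, lo["z"]), hi["z"])
  best <- NULL; errs <- character(0)
  dat <- data.frame(v = v, y = y)
  for (i in seq_len(nrow(starts))) {
    args <- list(y ~ boltzmann(v, v_half, z, temperature = temperature),
                 data = dat,
                 start = list(v_half = starts$v_half[i],
                              z = unname(starts$z[i])),
                 lower = lo, upper = hi,
                 control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(weights)) args$weights <- weights
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
    if (inherits(fit, "error")) { errs <- c(errs, conditionMessage(fit)); next }
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("Boltzmann fit failed from all starts: ",
         paste(unique(errs), collapse = "; "))
  s <- summary(best$fit)$coefficients
  structure(list(v_half = s["v_half", "Estimate"], z = s["z", "Estimate"],
                 v_half_se = s["v_half", "Std. Error"],
                 z_se = s["z", "Std. Error"],
                 rss = best$rss, n = length(v), temperature = temperature,
                 kind = curve$kind),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("%s Boltzmann fit: V1/2 = %.2f +/- %.2f mV, z = %.3f +/- %.3f e (rss %.4g, n %d)\n",
              x$kind, x$v_half, x$v_half_se, x$z, x$z_se, x$rss, x$n))
  invisible(x)
}

#' Midpoint shift between two Boltzmann fits
#'
#' `delta V1/2 = v_half_b - v_half_a` with the SE propagated in quadrature.
#' Negative values are leftward (hyperpolarizing) shifts.
#'
#' @param fit_a,fit_b `boltzmann_fit` objects.
#' @return list with `delta_v_half` (mV) and `se` (mV).
#' @export
curve_shift <- function(fit_a, fit_b) {
  list(delta_v_half = fit_b$v_half - fit_a$v_half,
       se = sqrt(fit_a$v_half_se^2 + fit_b$v_half_se^2))
}

#' Apparent free energy of the closed-to-open transition
#'
#' `dG = z F V1/2` in kcal/mol (`F = 23.0605 kcal/(mol V)`, `V1/2` converted
#' from mV): the chemical potential of the transition at zero voltage under
#' the two-state model. Positive when opening requires depolarization.
#'
#' @param fit a `boltzmann_fit`, or a numeric `v_half` (mV) when `z` is
#'   given.
#' @param z apparent gating charge (e); taken from `fit` when omitted.
#' @return dG (kcal/mol), with propagated SE in attribute `"se"` when the
#'   fit carries standard errors.
#' @export
apparent_dg <- function(fit, z = NULL) {
  if (inherits(fit, "boltzmann_fit")) {
    v <- fit$v_half / 1000
    zz <- fit$z
    dg <- zz * .FARADAY_KCAL_PER_V * v
    attr(dg, "se") <- .FARADAY_KCAL_PER_V *
      sqrt((v * fit$z_se)^2 + (zz * fit$v_half_se / 1000)^2)
    dg
  } else {
    if (is.null(z)) stop("z is required when fit is a bare v_half")
    z * .FARADAY_KCAL_PER_V * fit / 1000
  }
}

#' Double-mutant-cycle coupling energy
#'
#' Non-additivity of the apparent gating free-energy changes: the
#' interaction (coupling) energy is `ddg_double - (ddg_mut1 + ddg_mut2)`,
#' zero when the two mutations act independently. SEs propagate in
#' quadrature.
#'
#' @param ddg1,ddg2 single-mutant free-energy changes (kcal/mol).
#' @param ddg12 double-mutant free-energy change (kcal/mol).
#' @param se1,se2,se12 standard errors (kcal/mol).
#' @return object of class `"cycle_result"`: `ddg_mut1`, `ddg_mut2`,
#'   `ddg_double`, `interaction_energy`, `propagated_se` (kcal/mol).
#' @examples
#' mutant_cycle(0.56, 0.68, 2.60, 0.14, 0.07, 0.13)
#' @export
mutant_cycle <- function(ddg1, ddg2, ddg12, se1 = 0, se2 = 0, se12 = 0) {
  structure(list(ddg_mut1 = ddg1, ddg_mut2 = ddg2, ddg_double = ddg12,
                 interaction_energy = ddg12 - ddg1 - ddg2,
                 propagated_se = sqrt(se1^2 + se2^2 + se12^2)),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf(
    "Mutant cycle: ddG1 %.2f, ddG2 %.2f, ddG12 %.2f -> coupling %.2f +/- %.2f kcal/mol\n",
    x$ddg_mut1, x$ddg_mut2, x$ddg_double, x$interaction_energy,
    x$propagated_se))
  invisible(x)
}
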