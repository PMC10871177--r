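# Seeded isotherm generators with analytically known ground truth.  The
# analytic form is a monotone exponential decay from a zero-pressure
# baseline area to a high-pressure limiting area; binary mixtures add a
# prescribed excess-area profile on top of mole-fraction-weighted ideal
# mixing, so the condensing effect and excess mixing energy implied by a
# generated data set are known in closed form.

#' Analytic isotherm model
#'
#' Pressure--area model
#' \deqn{A(\Pi) = A_{lim} + (A_0 - A_{lim}) e^{-\Pi / \tau}}
#' with baseline (zero-pressure) area \eqn{A_0}, high-pressure limiting
#' area \eqn{A_{lim}} and decay scale \eqn{\tau}; strictly decreasing in
#' pressure before noise.
#'
#' @param baseline_area Area at zero pressure, Angstrom^2/molecule.
#' @param decay_scale Pressure decay scale, mN/m; positive.
#' @param limiting_area High-pressure limiting area, Angstrom^2/molecule;
#'   must satisfy `baseline_area > limiting_area > 0`.
#' @param noise_sd Additive Gaussian noise on generated areas,
#'   Angstrom^2/molecule.
#' @param seed Integer seed for noise reproducibility (`NULL` = use the
#'   current RNG stream).
#' @return An object of class `isotherm_model`.
#' @export
isotherm_model <- function(baseline_area, decay_scale, limiting_area,
                           noise_sd = 0, seed = NULL) {
  check_number(limiting_area, "limiting_area", 0, strict_lower = TRUE)
  check_number(baseline_area, "baseline_area", limiting_area,
               strict_lower = TRUE)
  check_number(decay_scale, "decay_scale", 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  structure(list(baseline_area = baseline_area, decay_scale = decay_scale,
                 limiting_area = limiting_area, noise_sd = noise_sd,
                 seed = seed),
            class = "isotherm_model")
}

model_area <- function(model, pressure) {
  model$limiting_area + (model$baseline_area - model$limiting_area) *
    exp(-pressure / model$decay_scale)
}

#' Generate a pure-lipid isotherm replicate
#'
#' Evaluates the analytic model on a pressure grid and adds seeded Gaussian
#' noise.  With `noise_sd = 0` the curve equals the analytic model exactly.
#'
#' @param model An [isotherm_model].
#' @param pressures Non-negative, strictly increasing pressure grid (mN/m).
#' @param composition,replicate_id,temperature Curve metadata.
#' @return An [isotherm_curve].
#' @export
gen_pure_isotherm <- function(model, pressures, composition = "pure",
                              replicate_id = "r1", temperature = 20) {
  stopifnot(inherits(model, "isotherm_model"))
  if (any(pressures < 0) || any(diff(pressures) <= 0))
    stop_mo("pressure grid must be non-negative and strictly increasing")
  areas <- model_area(model, pressures)
  if (model$noise_sd > 0)
    areas <- areas + with_seed_if(model$seed,
                                  rnorm(length(pressures), 0, model$noise_sd))
  isotherm_curve(pressures, areas, composition = composition,
                 replicate_id = replicate_id, temperature = temperature)
}

#' Ground truth for a synthetic binary mixture
#'
#' Describes the known non-ideality injected into a generated mixture
#' isotherm: the component mole fractions and the excess-area profile
#' \eqn{A_{exc}(\Pi)} added on top of ideal mole-fraction-weighted mixing.
#'
#' @param mole_fractions Numeric length-2 vector, each in (0,1), summing
#'   to 1.  The first entry is `X1` (paired with `pure1` downstream).
#' @param excess_area A single number (constant excess area in
#'   Angstrom^2/molecule) or a function of pressure returning the excess
#'   area.
#' @return An object of class `mixture_ground_truth`.
#' @export
mixture_ground_truth <- function(mole_fractions, excess_area = 0) {
  if (length(mole_fractions) != 2L || any(mole_fractions <= 0) ||
      any(mole_fractions >= 1) || abs(sum(mole_fractions) - 1) > 1e-8)
    stop_mo("mole_fractions must be two values in (0,1) summing to 1")
  f <- if (is.function(excess_area)) excess_area
       else { ea <- check_number(excess_area, "excess_area"); function(p) rep(ea, length(p)) }
  if (!is.finite(f(0)[1])) stop_mo("excess_area profile must be finite at 0")
  structure(list(mole_fractions = mole_fractions, excess_area = f),
            class = "mixture_ground_truth")
}

#' Condensation implied by a mixture ground truth
#'
#' Closed-form percentage condensation a generated noiseless mixture will
#' exhibit at `pressure`: `-100 * excess / ideal`, with
#' `ideal = X1 A1 + X2 A2` evaluated from the pure curves by the same
#' lookup rule used downstream.
#'
#' @param truth A [mixture_ground_truth].
#' @param pure1,pure2 Pure-component [isotherm_curve]s.
#' @param pressure Reference pressure, mN/m.
#' @param mode Lookup mode, see [area_at()].
#' @return Percent condensation (scalar).
#' @export
implied_condensation <- function(truth, pure1, pure2, pressure = 30,
                                 mode = c("floor", "interpolate")) {
  mode <- match.arg(mode)
  X <- truth$mole_fractions
  ideal <- X[1] * area_at(pure1, pressure, mode) +
    X[2] * area_at(pure2, pressure, mode)
  -100 * truth$excess_area(pressure) / ideal
}

#' Generate a binary-mixture isotherm replicate
#'
#' `area(P) = X1 A1(P) + X2 A2(P) + excess(P) + noise`; a zero excess
#' profile yields ideal mixing.  Both pure curves must share an identical
#' pressure grid.
#'
#' @param pure1,pure2 Pure-component [isotherm_curve]s on a shared grid.
#' @param truth A [mixture_ground_truth].
#' @param noise_sd Additive Gaussian noise, Angstrom^2/molecule.
#' @param seed Integer seed (`NULL` = current RNG stream).
#' @param composition,replicate_id Curve metadata.
#' @return An [isotherm_curve] with `mole_fractions` attached.
#' @export
gen_mixture_isotherm <- function(pure1, pure2, truth, noise_sd = 0,
                                 seed = NULL, composition = "mixture",
                                 replicate_id = "r1") {
  stopifnot(inherits(pure1, "isotherm_curve"),
            inherits(pure2, "isotherm_curve"),
            inherits(truth, "mixture_ground_truth"))
  if (length(pure1$pressures) != length(pure2$pressures) ||
      any(abs(pure1$pressures - pure2$pressures) > 1e-9))
    stop_mo("pure curves must share an identical pressure grid")
  check_number(noise_sd, "noise_sd", 0)
  X <- truth$mole_fractions
  p <- pure1$pressures
  areas <- X[1] * pure1$areas + X[2] * pure2$areas + truth$excess_area(p)
  if (noise_sd > 0)
    areas <- areas + with_seed_if(seed, rnorm(length(p), 0, noise_sd))
  isotherm_curve(p, areas, composition = composition,
                 replicate_id = replicate_id,
                 mole_fractions = c(X1 = X[1], X2 = X[2]),
                 temperature = pure1$temperature)
}
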