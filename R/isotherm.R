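# Langmuir monolayer thermodynamics: replicate-averaged pressure--area
# isotherms, the condensing effect at a reference surface pressure, the
# excess free energy of mixing by pressure integration, and a MANOVA
# comparison of isotherm groups via per-replicate regression coefficients.

#' A single pressure--area isotherm
#'
#' One replicate's (or one replicate-averaged) surface pressure vs mean
#' molecular area relation for a named monolayer composition.
#'
#' @param pressures Surface pressures, mN/m; non-negative, strictly
#'   increasing.
#' @param areas Mean molecular areas, Angstrom^2/molecule; positive.
#' @param composition Composition label, e.g. `"d9PC"` or `"d9PC:Chol 2:1"`.
#' @param replicate_id Replicate label.
#' @param mole_fractions Optional named numeric vector of component mole
#'   fractions (must lie in (0,1) and sum to 1).
#' @param temperature Subphase temperature, degrees C.
#' @param sd Optional per-pressure standard deviation of the area (set by
#'   [average_replicates()]).
#' @param n_replicates Number of replicates behind each area value.
#' @return An object of class `isotherm_curve`.
#' @export
isotherm_curve <- function(pressures, areas, composition = "unknown",
                           replicate_id = "r1", mole_fractions = NULL,
                           temperature = 20, sd = NULL, n_replicates = 1L) {
  pressures <- as.numeric(pressures); areas <- as.numeric(areas)
  if (length(pressures) != length(areas) || length(pressures) < 2L)
    stop_mo("need >= 2 matched pressure/area points")
  if (anyNA(pressures) || anyNA(areas))
    stop_mo("isotherm contains missing values")
  if (any(pressures < 0)) stop_mo("pressures must be non-negative")
  if (any(diff(pressures) <= 0)) stop_mo("pressures must be strictly increasing")
  if (any(areas <= 0)) stop_mo("areas must be positive")
  if (!is.null(mole_fractions)) {
    if (any(mole_fractions <= 0) || any(mole_fractions >= 1) ||
        abs(sum(mole_fractions) - 1) > 1e-8)
      stop_mo("mole fractions must lie in (0,1) and sum to 1")
  }
  if (!is.null(sd) && length(sd) != length(areas))
    stop_mo("`sd` must match the pressure grid")
  structure(list(pressures = pressures, areas = areas,
                 composition = composition, replicate_id = replicate_id,
                 mole_fractions = mole_fractions, temperature = temperature,
                 sd = sd, n_replicates = as.integer(n_replicates)),
            class = "isotherm_curve")
}

#' @export
print.isotherm_curve <- function(x, ...) {
  cat(sprintf("<isotherm_curve> %s (%s), %d points, %.1f-%.1f mN/m, %.1f-%.1f A^2%s\n",
              x$composition, x$replicate_id, length(x$pressures),
              min(x$pressures), max(x$pressures), min(x$areas), max(x$areas),
              if (!is.null(x$sd)) sprintf(", n = %d replicates", x$n_replicates)
              else ""))
  invisible(x)
}

#' Read isotherm replicates from CSV
#'
#' Expects the dialect `pressure_mN_m,area_A2,replicate,composition,
#' temperature_C` (comma-separated, dot decimal).  Each distinct
#' (composition, replicate) pair becomes one [isotherm_curve].
#'
#' @param path CSV file path.
#' @return List of `isotherm_curve` objects.
#' @export
read_isotherms <- function(path) {
  if (!file.exists(path)) stop_mo("isotherm file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pressure_mN_m", "area_A2", "replicate", "composition")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_mo("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (!nrow(df)) stop_mo("%s: no data rows", path)
  for (col in c("pressure_mN_m", "area_A2")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop_mo("%s: non-numeric value '%s' in column %s at data line %d",
              path, df[[col]][bad[1]], col, bad[1] + 1L)
    if (anyNA(v))
      stop_mo("%s: missing value in column %s at data line %d",
              path, col, which(is.na(v))[1] + 1L)
    df[[col]] <- v
  }
  temp <- if ("temperature_C" %in% names(df)) df$temperature_C else 20
  df$.temp <- temp
  keys <- unique(df[c("composition", "replicate")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$composition == keys$composition[i] &
              df$replicate == keys$replicate[i], ]
    sub <- sub[order(sub$pressure_mN_m), ]
    isotherm_curve(sub$pressure_mN_m, sub$area_A2,
                   composition = keys$composition[i],
                   replicate_id = as.character(keys$replicate[i]),
                   temperature = sub$.temp[1])
  })
}

#' Write isotherm curves to CSV
#'
#' Inverse of [read_isotherms()].
#'
#' @param curves List of [isotherm_curve] objects (or a single one).
#' @param path Output CSV path.
#' @export
write_isotherms <- function(curves, path) {
  if (inherits(curves, "isotherm_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cv)
    data.frame(pressure_mN_m = cv$pressures, area_A2 = cv$areas,
               replicate = cv$replicate_id, composition = cv$composition,
               temperature_C = cv$temperature)))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Nearest-lower-recorded-pressure lookup ("rounded down to the nearest
# neighbor"): the area at the largest recorded pressure <= the request.
area_floor <- function(curve, pressure) {
  i <- findInterval(pressure, curve$pressures)
  if (any(i == 0L))
    stop_mo("pressure %.3g mN/m below the recorded range (starts at %.3g)",
            pressure[which(i == 0L)[1]], curve$pressures[1])
  curve$areas[i]
}

#' Area at a surface pressure
#'
#' Looks up the mean molecular area at a requested surface pressure.  The
#' default `"floor"` mode takes the value recorded at the largest pressure
#' at or below the request (data "rounded down to the nearest neighbor");
#' `"interpolate"` performs linear interpolation.  Never extrapolates.
#'
#' @param curve An [isotherm_curve].
#' @param pressure Surface pressure(s), mN/m, within the recorded range.
#' @param mode `"floor"` (default) or `"interpolate"`.
#' @return Area(s) in Angstrom^2/molecule.
#' @export
area_at <- function(curve, pressure, mode = c("floor", "interpolate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "isotherm_curve"))
  if (any(pressure > max(curve$pressures) + 1e-12))
    stop_mo("pressure %.3g mN/m beyond the recorded range (ends at %.3g); refusing to extrapolate",
            max(pressure), max(curve$pressures))
  if (mode == "floor") area_floor(curve, pressure)
  else {
    if (any(pressure < curve$pressures[1]))
      stop_mo("pressure %.3g mN/m below the recorded range", min(pressure))
    approx(curve$pressures, curve$areas, xout = pressure)$y
  }
}

# sd of the area at `pressure` (floor lookup); NA when unavailable
sd_at <- function(curve, pressure) {
  if (is.null(curve$sd)) return(rep(NA_real_, length(pressure)))
  curve$sd[findInterval(pressure, curve$pressures)]
}

#' Average isotherm replicates
#'
#' Places all replicates on the union pressure grid clipped to the common
#' (overlapping) pressure range, evaluates each replicate at every grid
#' pressure by nearest-lower-recorded-point lookup, and returns the
#' per-pressure mean with its standard deviation.  A single replicate is
#' returned as-is with the standard deviation flagged unavailable (`NA`).
#'
#' @param curves List of [isotherm_curve] replicates of one composition.
#' @return An [isotherm_curve] carrying per-pressure `sd` and
#'   `n_replicates`.
#' @export
average_replicates <- function(curves) {
  if (inherits(curves, "isotherm_curve")) curves <- list(curves)
  if (!length(curves)) stop_mo("no replicates supplied")
  stopifnot(all(vapply(curves, inherits, logical(1), "isotherm_curve")))
  lo <- max(vapply(curves, function(cv) min(cv$pressures), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$pressures), numeric(1)))
  if (lo >= hi)
    stop_mo("replicates have non-overlapping pressure ranges (%.3g >= %.3g)",
            lo, hi)
  grid <- sort(unique(unlist(lapply(curves, `[[`, "pressures"))))
  grid <- grid[grid >= lo & grid <= hi]
  vals <- vapply(curves, area_floor, numeric(length(grid)), pressure = grid)
  vals <- matrix(vals, nrow = length(grid))
  m <- rowMeans(vals)
  s <- if (length(curves) > 1L) apply(vals, 1L, sd) else rep(NA_real_, length(grid))
  # enforce the averaged-curve monotonicity invariant (running minimum)
  m <- cummin(m)
  isotherm_curve(grid, m, composition = curves[[1]]$composition,
                 replicate_id = sprintf("mean_of_%d", length(curves)),
                 mole_fractions = curves[[1]]$mole_fractions,
                 temperature = curves[[1]]$temperature,
                 sd = s, n_replicates = length(curves))
}

#' Condensing effect of a terpenoid on a phospholipid monolayer
#'
#' The percentage condensation at surface pressure `pressure` (default
#' 30 mN/m):
#' \deqn{c = 100 (1 - A_0 / (X_1 A_1 + X_2 A_2))}
#' where \eqn{A_0} is the mixture's mean molecular area and \eqn{A_1, A_2}
#' the pure-component areas at that pressure, weighted by mole fractions
#' \eqn{X_1, X_2}.  Positive values mean the mixture packs more tightly
#' than the ideal mole-fraction-weighted mean (a condensing, i.e. ordering,
#' interaction); negative values mean area expansion.  The uncertainty is
#' first-order propagation of the replicate standard deviations of
#' \eqn{A_0, A_1, A_2}, treated as independent.
#'
#' @param mix,pure1,pure2 [isotherm_curve] objects (ideally replicate
#'   averages from [average_replicates()], so standard deviations are
#'   available).
#' @param X1 Mole fraction of component 1 (the `pure1` lipid) in the mix.
#' @param X2 Mole fraction of component 2; defaults to `1 - X1`.
#' @param pressure Reference surface pressure, mN/m.
#' @param mode Area lookup mode, see [area_at()].
#' @return A list of class `condensation_result`: `c` (percent), `sd`
#'   (percent, `NA` if no replicate sds), `pressure`, `areas`, and the mole
#'   fractions.
#' @export
condensation <- function(mix, pure1, pure2, X1, X2 = 1 - X1, pressure = 30,
                         mode = c("floor", "interpolate")) {
  mode <- match.arg(mode)
  check_number(X1, "X1", 0, 1); check_number(X2, "X2", 0, 1)
  if (abs(X1 + X2 - 1) > 1e-8) stop_mo("X1 + X2 must equal 1")
  A0 <- area_at(mix, pressure, mode)
  A1 <- area_at(pure1, pressure, mode)
  A2 <- area_at(pure2, pressure, mode)
  D <- X1 * A1 + X2 * A2
  cval <- 100 * (1 - A0 / D)
  # first-order propagation: dc/dA0 = -100/D; dc/dAi = 100*A0*Xi/D^2
  s0 <- sd_at(mix, pressure); s1 <- sd_at(pure1, pressure)
  s2 <- sd_at(pure2, pressure)
  sds <- c(s0, s1, s2)
  grad <- c(-100 / D, 100 * A0 * X1 / D^2, 100 * A0 * X2 / D^2)
  csd <- if (all(is.na(sds))) NA_real_
         else sqrt(sum((grad * ifelse(is.na(sds), 0, sds))^2))
  structure(list(c = cval, sd = csd, pressure = pressure,
                 areas = c(mix = A0, pure1 = A1, pure2 = A2),
                 mole_fractions = c(X1 = X1, X2 = X2),
                 components = c(mix = mix$composition,
                                pure1 = pure1$composition,
                                pure2 = pure2$composition)),
            class = "condensation_result")
}

#' @export
print.condensation_result <- function(x, ...) {
  cat(sprintf("Condensing effect at %.3g mN/m: %.2f%%%s\n", x$pressure, x$c,
              if (is.na(x$sd)) "" else sprintf(" +/- %.2f%%", x$sd)))
  cat(sprintf("  %s vs %.3g x %s + %.3g x %s (A0 = %.2f, ideal = %.2f A^2)\n",
              x$components["mix"], x$mole_fractions["X1"],
              x$components["pure1"], x$mole_fractions["X2"],
              x$components["pure2"], x$areas["mix"],
              sum(x$mole_fractions * x$areas[c("pure1", "pure2")])))
  invisible(x)
}

#' Excess free energy of mixing from isotherms
#'
#' Integrates the excess area
#' \eqn{A_{exc}(\Pi) = A_{mix}(\Pi) - X_1 A_1(\Pi) - X_2 A_2(\Pi)}
#' over surface pressure from 0 to the highest node (default 25 mN/m) by
#' the trapezoidal rule over the node set `{0+, 5, 10, 15, 20, 25}`, and
#' converts to molar energy:
#' \deqn{\Delta G_{exc} = N_A \int_0^{\Pi_{max}} A_{exc}(\Pi)\, d\Pi,}
#' with 1 Angstrom^2 mN/m = 1e-23 J.  Isotherm data start above zero
#' pressure, so the excess area at the 0+ node is held equal to the excess
#' at the lowest measured pressure (configurable via `extend_to_zero`).
#' This is the excess free energy: zero for ideal mixing, negative for
#' favourable lipid--lipid interactions; no ideal-entropy term is added.
#'
#' The uncertainty propagates each node's excess-area standard deviation
#' (pure-component and mixture replicate sds combined in quadrature)
#' through the trapezoid weights, treating nodes as independent.
#'
#' @inheritParams condensation
#' @param pressures Integration nodes in mN/m (strictly increasing).
#' @param extend_to_zero If `TRUE` (default) prepend a 0-pressure node
#'   carrying the excess area of the lowest node.
#' @return A list of class `mixing_energy`: `delta_g` (J/mol), `sd`
#'   (J/mol), `pressure_grid`, `excess_areas` (Angstrom^2/molecule).
#' @export
excess_mixing_energy <- function(mix, pure1, pure2, X1, X2 = 1 - X1,
                                 pressures = c(5, 10, 15, 20, 25),
                                 extend_to_zero = TRUE,
                                 mode = c("floor", "interpolate")) {
  mode <- match.arg(mode)
  check_number(X1, "X1", 0, 1); check_number(X2, "X2", 0, 1)
  if (abs(X1 + X2 - 1) > 1e-8) stop_mo("X1 + X2 must equal 1")
  if (any(diff(pressures) <= 0) || any(pressures <= 0))
    stop_mo("integration nodes must be positive and strictly increasing")
  pmax_needed <- max(pressures)
  for (nm in c("mix", "pure1", "pure2")) {
    cv <- get(nm)
    if (max(cv$pressures) < pmax_needed)
      stop_mo("curve `%s` does not cover %g mN/m", nm, pmax_needed)
  }
  exc_at <- function(p)
    area_at(mix, p, mode) - X1 * area_at(pure1, p, mode) -
      X2 * area_at(pure2, p, mode)
  var_at <- function(p)
    sd_at(mix, p)^2 + X1^2 * sd_at(pure1, p)^2 + X2^2 * sd_at(pure2, p)^2
  grid <- pressures; e <- exc_at(pressures); v <- var_at(pressures)
  if (extend_to_zero && pressures[1] > 0) {
    # isotherms start above zero pressure: hold the excess area constant
    # below the lowest measured pressure common to all three curves
    p_low <- max(vapply(list(mix, pure1, pure2),
                        function(cv) min(cv$pressures), numeric(1)))
    p_low <- min(p_low, pressures[1])
    grid <- c(0, grid); e <- c(exc_at(p_low), e); v <- c(var_at(p_low), v)
  }
  # trapezoid weights: w_i = (x_{i+1} - x_{i-1})/2 with one-sided ends
  n <- length(grid)
  w <- (c(diff(grid), 0) + c(0, diff(grid))) / 2
  AA2_mNm_to_J <- 1e-23               # 1 A^2 * mN/m = 1e-20 m^2 * 1e-3 N/m
  NA_const <- 6.02214076e23
  dg <- sum(w * e) * AA2_mNm_to_J * NA_const
  dg_sd <- if (all(is.na(v))) NA_real_
           else sqrt(sum(w^2 * ifelse(is.na(v), 0, v))) * AA2_mNm_to_J * NA_const
  structure(list(delta_g = dg, sd = dg_sd, pressure_grid = grid,
                 excess_areas = e,
                 mole_fractions = c(X1 = X1, X2 = X2)),
            class = "mixing_energy")
}

#' @export
print.mixing_energy <- function(x, ...) {
  cat(sprintf("Excess free energy of mixing: %.1f J/mol%s (nodes %s mN/m)\n",
              x$delta_g,
              if (is.na(x$sd)) "" else sprintf(" +/- %.1f", x$sd),
              paste(x$pressure_grid, collapse = ",")))
  invisible(x)
}

#' Compare groups of isotherms by regression MANOVA
#'
#' Fits each replicate isotherm with a polynomial regression of area on
#' pressure over a pressure window (default degree 1, i.e. two
#' coefficients: intercept and slope) and performs a one-way multivariate
#' analysis of variance on the coefficient vectors across groups, reporting
#' the Pillai-trace F approximation and p-value.
#'
#' @param groups Named list of groups; each group is a list of
#'   [isotherm_curve] replicates.
#' @param window Pressure window (mN/m) over which to fit, default the
#'   liquid-expanded/condensed region `c(5, 30)`.
#' @param degree Polynomial degree of the per-replicate fit; `degree = 1`
#'   gives the two-coefficient linear model.
#' @return A list of class `isotherm_manova`: `F`, `p`, `df`, `coefficients`
#'   (one row per replicate), `test`.
#' @export
compare_isotherm_groups <- function(groups, window = c(5, 30), degree = 1L) {
  if (length(groups) < 2L) stop_mo("need >= 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L))
    stop_mo("every group needs >= 2 replicates (got %s)",
            paste(sizes, collapse = ", "))
  fit_one <- function(cv) {
    keep <- cv$pressures >= window[1] & cv$pressures <= window[2]
    if (sum(keep) < degree + 1L)
      stop_mo("replicate %s has %d point(s) in the %g-%g mN/m window; need >= %d",
              cv$replicate_id, sum(keep), window[1], window[2], degree + 1L)
    coef(lm(a ~ poly(p, degree, raw = TRUE),
            data = data.frame(p = cv$pressures[keep], a = cv$areas[keep])))
  }
  B <- do.call(rbind, lapply(unlist(groups, recursive = FALSE), fit_one))
  g <- factor(rep(names(groups), sizes))
  fit <- manova(B ~ g)
  sm <- summary(fit, test = "Pillai")$stats
  structure(list(F = unname(sm[1, "approx F"]), p = unname(sm[1, "Pr(>F)"]),
                 df = unname(sm[1, c("num Df", "den Df")]),
                 coefficients = data.frame(group = g, B),
                 test = "Pillai", window = window, degree = degree),
            class = "isotherm_manova")
}

#' @export
print.isotherm_manova <- function(x, ...) {
  cat(sprintf("Isotherm group MANOVA (%s, degree-%d fit over %g-%g mN/m): F = %.3g, p = %.3g\n",
              x$test, x$degree, x$window[1], x$window[2], x$F, x$p))
  invisible(x)
}
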