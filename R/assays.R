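# Cell-assay analytics: growth-rate extraction from phenol-red OD curves,
# lysed-fraction normalization from propidium-iodide plates, and one-way
# ANOVA with Tukey HSD group comparison.

#' Growth curve container
#'
#' @param time_h Time points, hours; strictly increasing.
#' @param od562 Absorbance at 562 nm; positive.  Phenol-red media report
#'   growth as an OD *decline* while the pH indicator changes.
#' @param diet Lipid-diet label.
#' @return Object of class `growth_curve`.
#' @export
growth_curve <- function(time_h, od562, diet = "unknown") {
  time_h <- as.numeric(time_h); od562 <- as.numeric(od562)
  if (length(time_h) != length(od562) || length(time_h) < 2L)
    stop_mo("need >= 2 matched time/OD points")
  if (any(diff(time_h) <= 0)) stop_mo("time must be strictly increasing")
  if (any(od562 <= 0)) stop_mo("OD values must be positive")
  structure(list(time_h = time_h, od562 = od562, diet = diet),
            class = "growth_curve")
}

#' Extract the growth rate from a phenol-red OD curve
#'
#' Fits an ordinary least-squares line to the points whose OD lies in the
#' phenol-red indicative window (default `0.40 <= OD <= 0.75`, closed at
#' both ends) and reports the growth rate as the negative of the fitted
#' slope, together with the fit's R^2.
#'
#' @param curve A [growth_curve].
#' @param od_window Length-2 numeric window of usable OD values (order
#'   irrelevant).
#' @return List of class `growth_rate`: `rate` (OD/h), `slope`,
#'   `r_squared`, `n_points`, `window`.
#' @export
growth_rate <- function(curve, od_window = c(0.75, 0.40)) {
  stopifnot(inherits(curve, "growth_curve"))
  w <- sort(od_window)
  keep <- curve$od562 >= w[1] & curve$od562 <= w[2]
  if (sum(keep) < 3L)
    stop_mo("only %d point(s) inside the OD window [%.2f, %.2f]; need >= 3",
            sum(keep), w[1], w[2])
  fit <- lm(od ~ t, data = data.frame(t = curve$time_h[keep],
                                      od = curve$od562[keep]))
  slope <- unname(coef(fit)[2])
  # noiseless fixtures fit perfectly; summary.lm warns about that
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(rate = -slope, slope = slope,
                 r_squared = r2,
                 n_points = sum(keep), window = w, diet = curve$diet),
            class = "growth_rate")
}

#' @export
print.growth_rate <- function(x, ...) {
  cat(sprintf("Growth rate (%s): %.4f OD/h (R^2 = %.3f, %d points in [%.2f, %.2f])\n",
              x$diet, x$rate, x$r_squared, x$n_points, x$window[1],
              x$window[2]))
  invisible(x)
}

#' Lysis plate container
#'
#' Propidium-iodide fluorescence per sample across a wash-buffer dilution
#' series.  Every sample must include the 0% and 100% buffer anchor wells.
#'
#' @param data Data frame with columns `sample`, `buffer_pct`,
#'   `fluorescence`, and optionally `diet`.
#' @return Object of class `lysis_plate`.
#' @export
lysis_plate <- function(data) {
  need <- c("sample", "buffer_pct", "fluorescence")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_mo("lysis data missing column(s): %s", paste(miss, collapse = ", "))
  for (s in unique(data$sample)) {
    pct <- data$buffer_pct[data$sample == s]
    if (!all(c(0, 100) %in% pct))
      stop_mo("sample %s lacks the 0%% and/or 100%% anchor wells", s)
  }
  structure(list(data = as.data.frame(data)), class = "lysis_plate")
}

#' Fraction of cells lysed under hypoosmotic shock
#'
#' Normalizes each sample's fluorescence to its own 0% and 100%
#' wash-buffer anchor wells:
#' \deqn{f = (F_x - F_0) / (F_{100} - F_0)}
#' and reports the fraction at `report_at` percent buffer (default 80).
#' Values are not clamped; fractions outside `[0, 1]` are flagged.
#'
#' @param plate A [lysis_plate].
#' @param report_at Buffer percentage to report.
#' @return Data frame of class `lysed_fraction`: `sample`, `diet` (if
#'   present), `fraction`, `flagged`.
#' @export
lysed_fraction <- function(plate, report_at = 80) {
  stopifnot(inherits(plate, "lysis_plate"))
  df <- plate$data
  out <- lapply(unique(df$sample), function(s) {
    sub <- df[df$sample == s, ]
    f0 <- sub$fluorescence[sub$buffer_pct == 0][1]
    f100 <- sub$fluorescence[sub$buffer_pct == 100][1]
    if (f100 == f0)
      stop_mo("sample %s: 0%% and 100%% anchors are equal (F = %g)", s, f0)
    fx <- sub$fluorescence[sub$buffer_pct == report_at]
    if (!length(fx))
      stop_mo("sample %s has no %g%% buffer well", s, report_at)
    fr <- (fx[1] - f0) / (f100 - f0)
    data.frame(sample = s,
               diet = if ("diet" %in% names(sub)) sub$diet[1] else NA,
               fraction = fr, flagged = fr < 0 | fr > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("lysed_fraction", "data.frame")
  out
}

#' One-way ANOVA with Tukey HSD across diet groups
#'
#' @param values Numeric response (e.g. growth rates or lysed fractions).
#' @param group Group labels, same length as `values`.
#' @return List of class `group_comparison`: `F`, `p`, `df`, `tukey`
#'   (pairwise table with adjusted p-values), `anova` (the `aov` fit).
#' @export
group_compare <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop_mo("need >= 2 groups")
  tab <- table(group)
  if (any(tab < 2L))
    stop_mo("every group needs >= 2 replicates (got %s)",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  if (length(values) != length(group))
    stop_mo("`values` and `group` lengths differ")
  fit <- aov(values ~ group)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  structure(list(F = sm[1, "F value"], p = sm[1, "Pr(>F)"],
                 df = sm[, "Df"],
                 tukey = data.frame(pair = rownames(tk), tk,
                                    row.names = NULL),
                 anova = fit),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat("Tukey HSD adjusted p-values:\n")
  for (i in seq_len(nrow(x$tukey)))
    cat(sprintf("  %-20s diff = %+.4g, p.adj = %.3g\n", x$tukey$pair[i],
                x$tukey$diff[i], x$tukey$p.adj[i]))
  invisible(x)
}

# CSV readers (dialects: sample,time_h,od562[,diet] and
# sample,buffer_pct,fluorescence[,diet]) ------------------------------------

#' Read growth curves / lysis plates from CSV
#'
#' `read_growth_curves` expects columns `sample,time_h,od562` (optional
#' `diet`) and returns a named list of [growth_curve] objects;
#' `read_lysis_plate` expects `sample,buffer_pct,fluorescence` (optional
#' `diet`) and returns a [lysis_plate].
#'
#' @param path CSV file path.
#' @return See above.
#' @export
read_growth_curves <- function(path) {
  if (!file.exists(path)) stop_mo("growth file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "time_h", "od562")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_mo("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  out <- lapply(unique(df$sample), function(s) {
    sub <- df[df$sample == s, ]
    sub <- sub[order(sub$time_h), ]
    growth_curve(sub$time_h, sub$od562,
                 diet = if ("diet" %in% names(sub)) sub$diet[1] else "unknown")
  })
  names(out) <- unique(df$sample)
  out
}

#' @rdname read_growth_curves
#' @export
read_lysis_plate <- function(path) {
  if (!file.exists(path)) stop_mo("lysis file not found: %s", path)
  lysis_plate(read.csv(path, stringsAsFactors = FALSE))
}
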