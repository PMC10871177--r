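# Seeded assay-fixture generators with known ground truth.

#' Generate a phenol-red growth curve
#'
#' OD declines linearly through the phenol-red indicative range:
#' `od(t) = od_start - rate * t + noise`, so the fitted growth rate on a
#' noiseless curve recovers `rate` exactly.
#'
#' @param rate True growth rate, OD/h (non-negative).
#' @param od_start OD at time zero.
#' @param noise_sd Additive Gaussian noise on OD.
#' @param seed Integer seed (`NULL` = current RNG stream).
#' @param times Sampling times, hours.
#' @param diet Diet label.
#' @return A [growth_curve].
#' @export
gen_growth_curve <- function(rate, od_start = 0.9, noise_sd = 0, seed = NULL,
                             times = seq(0, 10, by = 0.5), diet = "synthetic") {
  check_number(rate, "rate", 0)
  check_number(noise_sd, "noise_sd", 0)
  od <- od_start - rate * times
  if (noise_sd > 0)
    od <- od + with_seed_if(seed, rnorm(length(times), 0, noise_sd))
  od <- pmax(od, 1e-3)              # keep the container's positivity invariant
  growth_curve(times, od, diet = diet)
}

#' Generate a propidium-iodide lysis plate
#'
#' Builds one or more samples over the buffer-dilution series
#' `{0, 20, 40, 60, 80, 100}%`.  The 0% and 100% wells carry the anchor
#' signals `f0` and `f100`; the lysed fraction ramps linearly with buffer
#' percentage so that the 80% well carries exactly `true_fraction`, and
#' the well signal is `f0 + fraction * (f100 - f0) + noise`.
#'
#' @param true_fraction True lysed fraction at 80% buffer, in `[0, 1]`;
#'   one value per sample.
#' @param f0,f100 Anchor fluorescence signals; `f100 > f0` required.
#' @param noise_sd Additive Gaussian noise on non-anchor wells.
#' @param seed Integer seed (`NULL` = current RNG stream).
#' @param buffer_pcts Dilution series (must include 0, 80 and 100).
#' @param diet Diet label(s), recycled over samples.
#' @return A [lysis_plate].
#' @export
gen_lysis_plate <- function(true_fraction, f0 = 100, f100 = 500,
                            noise_sd = 0, seed = NULL,
                            buffer_pcts = c(0, 20, 40, 60, 80, 100),
                            diet = "synthetic") {
  if (f100 <= f0) stop_mo("f100 must exceed f0 (got f0 = %g, f100 = %g)",
                          f0, f100)
  if (any(true_fraction < 0) || any(true_fraction > 1))
    stop_mo("true_fraction must lie in [0, 1]")
  if (!all(c(0, 80, 100) %in% buffer_pcts))
    stop_mo("buffer_pcts must include 0, 80 and 100")
  diet <- rep_len(diet, length(true_fraction))
  rows <- with_seed_if(seed, do.call(rbind, lapply(
    seq_along(true_fraction), function(i) {
      frac <- ifelse(buffer_pcts <= 80,
                     true_fraction[i] * buffer_pcts / 80,
                     true_fraction[i] + (1 - true_fraction[i]) *
                       (buffer_pcts - 80) / 20)
      sig <- f0 + frac * (f100 - f0)
      mid <- !buffer_pcts %in% c(0, 100)
      if (noise_sd > 0)
        sig[mid] <- sig[mid] + rnorm(sum(mid), 0, noise_sd)
      data.frame(sample = sprintf("s%02d", i), buffer_pct = buffer_pcts,
                 fluorescence = sig, diet = diet[i],
                 stringsAsFactors = FALSE)
    })))
  lysis_plate(rows)
}
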