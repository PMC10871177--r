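test_that("replicate averaging uses the union grid and floor lookup", {
  r1 <- hand_curve(c(5, 30, 35), c(60, 48, 45), replicate_id = "r1")
  r2 <- hand_curve(c(5, 30, 35), c(62, 50, 47), replicate_id = "r2")
  r3 <- hand_curve(c(5, 30, 35), c(64, 52, 49), replicate_id = "r3")
  avg <- average_replicates(list(r1, r2, r3))
  expect_equal(area_at(avg, 30), 50)
  expect_equal(sd_at <- avg$sd[avg$pressures == 30], 2)
  expect_equal(avg$n_replicates, 3L)

  # identical replicates -> sd 0 everywhere
  avg0 <- average_replicates(list(r1, r1, r1))
  expect_true(all(avg0$sd == 0))

  # single replicate -> mean = replicate, sd flagged unavailable
  avg1 <- average_replicates(list(r1))
  expect_equal(avg1$areas, r1$areas)
  expect_true(all(is.na(avg1$sd)))

  # union grid clipped to the common range; each replicate evaluated at
  # its largest recorded pressure <= the grid point
  ra <- hand_curve(c(5, 20, 30), c(60, 50, 44))
  rb <- hand_curve(c(10, 25, 35), c(58, 48, 42))
  avg2 <- average_replicates(list(ra, rb))
  expect_equal(avg2$pressures, c(10, 20, 25, 30))
  expect_equal(avg2$areas[avg2$pressures == 25], mean(c(50, 48)))

  # non-overlapping pressure ranges are a distinct error
  expect_error(average_replicates(list(hand_curve(c(1, 5), c(60, 55)),
                                       hand_curve(c(10, 20), c(50, 45)))),
               "non-overlapping")
})

test_that("isotherm CSV reader validates its dialect", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("pressure_mN_m,area_A2,replicate,composition,temperature_C",
               "5,60,r1,PC,20", "10,55,r1,PC,20", "5,61,r2,PC,20",
               "10,56,r2,PC,20"), f)
  curves <- read_isotherms(f)
  expect_length(curves, 2)
  expect_equal(curves[[1]]$areas, c(60, 55))

  fbad <- tempfile(fileext = ".csv")
  writeLines(c("pressure_mN_m,area_A2,replicate,composition,temperature_C",
               "5,60,r1,PC,20", "10,oops,r1,PC,20"), fbad)
  expect_error(read_isotherms(fbad), "non-numeric value 'oops'")

  fempty <- tempfile(fileext = ".csv")
  writeLines("pressure_mN_m,area_A2,replicate,composition,temperature_C",
             fempty)
  expect_error(read_isotherms(fempty), "no data rows")

  fmiss <- tempfile(fileext = ".csv")
  writeLines(c("pressure,area", "5,60"), fmiss)
  expect_error(read_isotherms(fmiss), "missing column")

  # round trip
  f2 <- tempfile(fileext = ".csv")
  write_isotherms(curves, f2)
  back <- read_isotherms(f2)
  expect_equal(back[[1]]$areas, curves[[1]]$areas)
})

test_that("area lookup rounds down and refuses to extrapolate", {
  cv <- hand_curve(c(5, 29.7, 30.4, 35), c(70, 52, 50, 45))
  expect_equal(area_at(cv, 30), 52)            # value at 29.7
  expect_equal(area_at(cv, 30.4), 50)          # exact grid point
  expect_equal(area_at(cv, 30, mode = "interpolate"),
               52 + (50 - 52) * (30 - 29.7) / (30.4 - 29.7))
  expect_error(area_at(cv, 40), "refusing to extrapolate")
  expect_error(area_at(cv, 2), "below the recorded range")
})

test_that("condensation implements the hand formula with propagated error", {
  p1 <- hand_curve(c(0, 30, 40), c(80, 60, 55))
  p2 <- hand_curve(c(0, 30, 40), c(50, 40, 38))
  mk_mix <- function(a30) hand_curve(c(0, 30, 40), c(70, a30, a30 - 5))
  # A0 = 40 vs ideal 50 -> 20%
  expect_equal(condensation(mk_mix(40), p1, p2, X1 = 0.5)$c, 20)
  # A0 = 55 vs ideal 50 -> -10% (negative condensation: area expansion)
  expect_equal(condensation(mk_mix(55), p1, p2, X1 = 0.5)$c, -10)
  # ideal mixing -> exactly 0
  expect_equal(condensation(mk_mix(50), p1, p2, X1 = 0.5)$c, 0)
  # antisymmetry in component order
  c12 <- condensation(mk_mix(44), p1, p2, X1 = 0.3)
  c21 <- condensation(mk_mix(44), p2, p1, X1 = 0.7)
  expect_equal(c12$c, c21$c)
  # mole fractions must sum to 1
  expect_error(condensation(mk_mix(44), p1, p2, X1 = 0.3, X2 = 0.4),
               "must equal 1")
  # sd: first-order propagation agrees with a numeric-gradient oracle
  r <- function(a) hand_curve(c(0, 30), c(a + 20, a))
  reps <- function(a, s) lapply(c(-s, 0, s), function(d) r(a + d))
  mixavg <- average_replicates(reps(44, 2))
  p1avg <- average_replicates(reps(60, 3))
  p2avg <- average_replicates(reps(40, 1))
  got <- condensation(mixavg, p1avg, p2avg, X1 = 0.5)
  cfun <- function(a0, a1, a2) 100 * (1 - a0 / (0.5 * a1 + 0.5 * a2))
  h <- 1e-6
  g <- c((cfun(44 + h, 60, 40) - cfun(44 - h, 60, 40)) / (2 * h),
         (cfun(44, 60 + h, 40) - cfun(44, 60 - h, 40)) / (2 * h),
         (cfun(44, 60, 40 + h) - cfun(44, 60, 40 - h)) / (2 * h))
  sds <- c(sd(c(42, 44, 46)), sd(c(57, 60, 63)), sd(c(39, 40, 41)))
  expect_equal(got$sd, sqrt(sum((g * sds)^2)), tolerance = 1e-6)
})

test_that("excess mixing energy integrates the excess area correctly", {
  pp <- pure_pair()
  # zero excess -> exactly 0
  tr0 <- mixture_ground_truth(c(2/3, 1/3), 0)
  mx0 <- gen_mixture_isotherm(pp$p1, pp$p2, tr0)
  expect_equal(excess_mixing_energy(mx0, pp$p1, pp$p2, X1 = 2/3)$delta_g, 0)

  # constant -1 A^2 over 0-25 mN/m: N_A * 25e-23 J/mol
  tr1 <- mixture_ground_truth(c(0.5, 0.5), -1)
  mx1 <- gen_mixture_isotherm(pp$p1, pp$p2, tr1)
  dg <- excess_mixing_energy(mx1, pp$p1, pp$p2, X1 = 0.5)
  expect_equal(dg$delta_g, -25e-23 * 6.02214076e23, tolerance = 1e-10)

  # piecewise-linear excess profile on the node grid is recovered exactly
  # (trapezoid is exact there); oracle: pracma::trapz on the same nodes
  prof <- function(p) -2 + 0.12 * p          # A^2, linear in pressure
  trl <- mixture_ground_truth(c(0.5, 0.5), prof)
  mxl <- gen_mixture_isotherm(pp$p1, pp$p2, trl)
  dgl <- excess_mixing_energy(mxl, pp$p1, pp$p2, X1 = 0.5)
  nodes <- c(0, 5, 10, 15, 20, 25)
  vals <- prof(c(0.5, 5, 10, 15, 20, 25))    # 0+ node = lowest measured
  expected <- pracma::trapz(nodes, vals) * 1e-23 * 6.02214076e23
  expect_equal(dgl$delta_g, expected, tolerance = 1e-12)

  # uniformly positive excess -> dG > 0; antisymmetry in component order
  trp <- mixture_ground_truth(c(0.5, 0.5), +2)
  mxp <- gen_mixture_isotherm(pp$p1, pp$p2, trp)
  expect_gt(excess_mixing_energy(mxp, pp$p1, pp$p2, X1 = 0.5)$delta_g, 0)
  expect_equal(excess_mixing_energy(mxp, pp$p1, pp$p2, X1 = 0.5)$delta_g,
               excess_mixing_energy(mxp, pp$p2, pp$p1, X1 = 0.5)$delta_g)

  # curves must cover the full node range
  short <- hand_curve(c(0, 10), c(80, 60))
  expect_error(excess_mixing_energy(short, pp$p1, pp$p2, X1 = 0.5),
               "does not cover 25")
})

test_that("isotherm group MANOVA separates distinct groups", {
  p <- seq(1, 35, by = 1)
  mk_group <- function(baseline, seed0, n = 3) lapply(seq_len(n), function(r)
    gen_pure_isotherm(isotherm_model(baseline, 20, 45, noise_sd = 0.5,
                                     seed = seed0 + r), p,
                      replicate_id = paste0("r", r)))
  g1 <- mk_group(90, 10); g2 <- mk_group(70, 20)
  res <- compare_isotherm_groups(list(a = g1, b = g2))
  expect_lt(res$p, 0.05)
  # identical replicate sets in both groups -> F ~ 0
  res0 <- compare_isotherm_groups(list(a = g1, b = g1))
  expect_lt(res0$F, 1e-10)
  # insufficient replicates is an error
  expect_error(compare_isotherm_groups(list(a = g1[1], b = g2)),
               ">= 2 replicates")
  expect_error(compare_isotherm_groups(list(a = g1)), ">= 2 groups")
})
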