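test_that("pure-isotherm generator matches its analytic model", {
  m <- isotherm_model(80, 20, 40)
  # zero-pressure limit and limiting-area asymptote of the analytic form
  cv <- gen_pure_isotherm(m, c(0, 10, 20, 1000))
  expect_equal(cv$areas[1], 80)
  expect_equal(cv$areas[4], 40, tolerance = 1e-12)
  # strictly decreasing before noise
  expect_true(all(diff(cv$areas) < 0))
  # invalid grids are rejected
  expect_error(gen_pure_isotherm(m, c(10, 5)), "strictly increasing")
  expect_error(gen_pure_isotherm(m, c(-1, 5)), "non-negative")
  # model invariants
  expect_error(isotherm_model(40, 20, 80), "baseline_area")
  expect_error(isotherm_model(80, -1, 40), "decay_scale")
})

test_that("generators are bit-reproducible under a fixed seed", {
  m <- isotherm_model(80, 20, 40, noise_sd = 1, seed = 99)
  p <- seq(1, 30)
  expect_identical(gen_pure_isotherm(m, p)$areas, gen_pure_isotherm(m, p)$areas)
  pp <- pure_pair()
  tr <- mixture_ground_truth(c(0.5, 0.5), -2)
  a <- gen_mixture_isotherm(pp$p1, pp$p2, tr, noise_sd = 1, seed = 4)$areas
  b <- gen_mixture_isotherm(pp$p1, pp$p2, tr, noise_sd = 1, seed = 4)$areas
  expect_identical(a, b)
})

test_that("mixture generator implements the mixing rule with known excess", {
  # ideal mixing: mole-fraction-weighted mean at every pressure
  pp <- pure_pair()
  tr0 <- mixture_ground_truth(c(2/3, 1/3), 0)
  mx <- gen_mixture_isotherm(pp$p1, pp$p2, tr0)
  expect_equal(mx$areas, 2/3 * pp$p1$areas + 1/3 * pp$p2$areas)

  # hand case: A1 = 60, A2 = 40 at 30 mN/m, excess -4 -> A0 = 46,
  # downstream condensation 100 - (46/50)*100 = 8%
  p1 <- hand_curve(c(0, 30, 40), c(80, 60, 55), "lipid1")
  p2 <- hand_curve(c(0, 30, 40), c(50, 40, 38), "lipid2")
  tr <- mixture_ground_truth(c(0.5, 0.5), -4)
  mx <- gen_mixture_isotherm(p1, p2, tr)
  expect_equal(area_at(mx, 30), 46)
  cond <- condensation(mx, p1, p2, X1 = 0.5)
  expect_equal(cond$c, 8)
  expect_equal(implied_condensation(tr, p1, p2), 8)

  # mismatched grids are rejected
  p2b <- hand_curve(c(0, 29, 40), c(50, 40, 38))
  expect_error(gen_mixture_isotherm(p1, p2b, tr), "identical pressure grid")
})
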