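test_that("growth-rate extraction recovers known slopes", {
  # noiseless decline of slope -0.05/h -> rate 0.05 exactly
  gr <- growth_rate(gen_growth_curve(0.05, od_start = 0.8))
  expect_equal(gr$rate, 0.05, tolerance = 1e-12)
  expect_equal(gr$r_squared, 1)
  # flat curve inside the window -> rate 0
  flat <- growth_curve(0:5, rep(0.6, 6))
  expect_equal(growth_rate(flat)$rate, 0)
  # window selection is the closed interval [0.40, 0.75]
  edge <- growth_curve(0:3, c(0.80, 0.75, 0.55, 0.40))
  expect_equal(growth_rate(edge)$n_points, 3)
  # a curve never entering the window is an error
  high <- growth_curve(0:5, seq(2.0, 1.5, length.out = 6))
  expect_error(growth_rate(high), "inside the OD window")
  # over noisy repetitions the estimator stays close to the truth; window
  # selection on noisy OD readings leaves only a small truncation bias
  rates <- vapply(1:200, function(s)
    growth_rate(gen_growth_curve(0.05, od_start = 0.8, noise_sd = 0.02,
                                 seed = s))$rate, numeric(1))
  expect_lt(abs(mean(rates) - 0.05) / 0.05, 0.05)
})

test_that("lysed fraction normalizes each sample to its own anchors", {
  # F0 = 100, F100 = 500, F80 = 300 -> 0.5
  plate <- lysis_plate(data.frame(
    sample = "s1", buffer_pct = c(0, 20, 40, 60, 80, 100),
    fluorescence = c(100, 150, 200, 250, 300, 500)))
  expect_equal(lysed_fraction(plate)$fraction, 0.5)
  # anchor recovery: true 0 -> signal f0 -> fraction 0; true 1 -> 1
  expect_equal(lysed_fraction(gen_lysis_plate(0))$fraction, 0)
  expect_equal(lysed_fraction(gen_lysis_plate(1))$fraction, 1)
  # affine invariance: a*F + b leaves fractions unchanged
  p2 <- plate; p2$data$fluorescence <- 3.7 * p2$data$fluorescence + 42
  expect_equal(lysed_fraction(p2)$fraction, 0.5)
  # out-of-range fractions are reported, not clamped, and flagged
  p3 <- lysis_plate(data.frame(sample = "s1", buffer_pct = c(0, 80, 100),
                               fluorescence = c(100, 620, 500)))
  lf <- lysed_fraction(p3)
  expect_equal(lf$fraction, 1.3)
  expect_true(lf$flagged)
  # equal anchors are an error, as is a missing anchor well
  p4 <- lysis_plate(data.frame(sample = "s1", buffer_pct = c(0, 80, 100),
                               fluorescence = c(100, 300, 100)))
  expect_error(lysed_fraction(p4), "anchors are equal")
  expect_error(lysis_plate(data.frame(sample = "s1", buffer_pct = c(0, 80),
                                      fluorescence = c(1, 2))),
               "anchor wells")
  expect_error(gen_lysis_plate(0.5, f0 = 10, f100 = 10), "f100 must exceed")
})

test_that("group comparison runs one-way ANOVA with Tukey HSD", {
  set.seed(123)
  v <- c(rnorm(5, 0), rnorm(5, 0), rnorm(5, 5))
  g <- rep(c("a", "b", "c"), each = 5)
  res <- group_compare(v, g)
  expect_lt(res$p, 0.05)
  expect_equal(nrow(res$tukey), 3)           # all pairwise contrasts
  expect_true(all(c("diff", "p.adj") %in% names(res$tukey)))
  # the separated pair is significant, the null pair is not
  expect_lt(res$tukey$p.adj[res$tukey$pair == "c-a"], 0.05)
  expect_gt(res$tukey$p.adj[res$tukey$pair == "b-a"], 0.05)
  # identical groups -> F = 0
  res0 <- group_compare(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(res0$F, 0)
  # degenerate groups are errors
  expect_error(group_compare(1:3, c("a", "a", "b")), ">= 2 replicates")
  expect_error(group_compare(1:3, rep("a", 3)), ">= 2 groups")
})

test_that("assay CSV readers reconstruct curves and plates", {
  f <- tempfile(fileext = ".csv")
  gc <- gen_growth_curve(0.04, od_start = 0.85, noise_sd = 0.01, seed = 6)
  write.csv(data.frame(sample = "a", time_h = gc$time_h, od562 = gc$od562,
                       diet = "d9"), f, row.names = FALSE)
  back <- read_growth_curves(f)
  expect_equal(back$a$od562, gc$od562)
  expect_equal(back$a$diet, "d9")
  expect_error(read_growth_curves(tempfile()), "not found")

  f2 <- tempfile(fileext = ".csv")
  lp <- gen_lysis_plate(c(0.3, 0.6), noise_sd = 2, seed = 9)
  write.csv(lp$data, f2, row.names = FALSE)
  expect_equal(lysed_fraction(read_lysis_plate(f2))$fraction,
               lysed_fraction(lp)$fraction)
})
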