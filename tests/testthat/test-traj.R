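test_that("centering puts the midplane at z = 0 and is translation-invariant", {
  sp <- synthetic_bilayer_spec(10, n_frames = 2, seed = 5)
  fr <- gen_bilayer_frames(sp)
  # shift the whole bilayer to be built around z = 30
  sh <- fr; sh$coords[, 3, ] <- sh$coords[, 3, ] + 30
  frc <- center_and_assign_leaflets(fr)
  shc <- center_and_assign_leaflets(sh)
  expect_identical(frc$atoms$leaflet, shc$atoms$leaflet)
  expect_equal(shc$coords, frc$coords, tolerance = 1e-10)
  # symmetric build: half the molecules per leaflet
  mol <- frc$atoms[!duplicated(frc$atoms$resid), ]
  expect_equal(sum(mol$leaflet == 1), sum(mol$leaflet == -1))
})

test_that("a single-leaflet input is accepted with a warning", {
  sp <- synthetic_bilayer_spec(6, n_frames = 1, seed = 2, composition = 0)
  fr <- gen_bilayer_frames(sp)
  keep <- fr$atoms$leaflet_built == 1
  fr$atoms <- fr$atoms[keep, ]
  fr$coords <- fr$coords[keep, , , drop = FALSE]
  expect_warning(out <- center_and_assign_leaflets(fr), "single leaflet")
  expect_equal(length(unique(out$atoms$leaflet)), 1L)
})

test_that("S_CD hits its analytic limits and bounds", {
  mk <- function(cos2) center_and_assign_leaflets(gen_bilayer_frames(
    synthetic_bilayer_spec(10, composition = 0, target_cos2 = cos2,
                           n_frames = 4, seed = 13)))
  # all bonds parallel to the normal -> +1; all in-plane -> -0.5
  expect_equal(scd_profile(mk(1), chain = "sn2")$scd,
               rep(1, 17), tolerance = 1e-12)
  expect_equal(scd_profile(mk(0), chain = "sn1")$scd,
               rep(-0.5, 17), tolerance = 1e-12)
  # isotropic bonds: |S_CD| < 3 SE
  prof <- scd_profile(mk(1/3), chain = "sn2")
  expect_true(all(abs(prof$scd) < 3 * prof$se | prof$se == 0))
  # bounds hold everywhere, per-carbon sample counts recorded
  expect_true(all(prof$scd >= -0.5 & prof$scd <= 1))
  expect_true(all(prof$n_samples > 0))
})

test_that("S_CD is invariant to rigid z-translation and xy-rotation", {
  fr <- center_and_assign_leaflets(gen_bilayer_frames(
    synthetic_bilayer_spec(8, target_cos2 = 0.6, n_frames = 3, seed = 17)))
  base <- scd_profile(fr, chain = "sn2")$scd
  th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rot <- fr
  for (f in 1:3) rot$coords[, , f] <- fr$coords[, , f] %*% R
  expect_equal(scd_profile(rot, chain = "sn2")$scd, base, tolerance = 1e-12)
})

test_that("depth histograms conserve mass and honour folding", {
  fr <- center_and_assign_leaflets(gen_bilayer_frames(
    synthetic_bilayer_spec(24, n_frames = 10, seed = 31)))
  zh <- group_z_distribution(fr)
  expect_true(all(abs(colSums(zh$density) * zh$bin_width - 1) < 1e-9))
  # folded histogram equals the |z| histogram of the unfolded samples
  zh2 <- group_z_distribution(fr, fold = FALSE)
  expect_true(all(abs(colSums(zh2$density) * zh2$bin_width - 1) < 1e-9))
  # generator mean 9.5 sd 1 for M2: histogram mean within 3 SE
  m2 <- sum(zh$mids * zh$density[, "M2"]) * zh$bin_width
  n <- sum(zh$counts[, "M2"])
  expect_lt(abs(m2 - 9.5), 3 * (1 / sqrt(n)) + zh$bin_width / 2)
  # empty selection errors
  expect_error(group_z_distribution(fr, groups = "NOPE"), "matches no atoms")
  # uncentered frames are refused
  expect_error(group_z_distribution(gen_bilayer_frames(
    synthetic_bilayer_spec(6, n_frames = 1, seed = 1))), "not centered")
})

test_that("a delta-placed group puts all mass in its bin", {
  gd <- list(M1 = c(12, 0), M2 = c(9, 0), M3 = c(7, 0), M4 = c(5, 0),
             double_bond = c(9, 0))
  fr <- center_and_assign_leaflets(gen_bilayer_frames(
    synthetic_bilayer_spec(12, composition = 1, group_depths = gd,
                           n_frames = 3, seed = 7)))
  zh <- group_z_distribution(fr, groups = "M2")
  hit <- which(zh$edges[-length(zh$edges)] <= 9 & zh$edges[-1] > 9)
  expect_equal(unname(zh$density[hit, "M2"]) * zh$bin_width, 1)
})

test_that("overlap coefficient behaves as a bounded symmetric measure", {
  e <- seq(0, 4, by = 1)
  a <- manual_zhist(e, c(0.5, 0.5, 0, 0))
  b <- manual_zhist(e, c(0, 0, 0.5, 0.5))
  half <- manual_zhist(e, c(0, 0.5, 0.5, 0))
  expect_equal(overlap_coefficient(a, "V1", "V1"), 1)        # identical
  expect_equal(overlap_coefficient(a, "V1", "V1", h2 = b), 0) # disjoint
  expect_equal(overlap_coefficient(a, "V1", "V1", h2 = half), 0.5)
  expect_equal(overlap_coefficient(half, "V1", "V1", h2 = a), 0.5) # symmetric
  bad <- manual_zhist(seq(0, 8, by = 2), c(0.25, 0.25, 0, 0))
  expect_error(overlap_coefficient(a, "V1", "V1", h2 = bad),
               "mismatched bin edges")
  expect_error(overlap_coefficient(a, "V9", "V1"), "not present")
})

test_that("tilt angles follow the C24 -> O3 vector, folded to [0, 90]", {
  fr <- manual_terp_frames(list(c(0, 0, 8),        # along +z
                                c(8, 0, 0),        # in-plane
                                c(0, 0, -8),       # along -z
                                c(0, 8 / sqrt(3), 8)))  # 30 degrees
  td <- tilt_distribution(fr)
  expect_equal(td$angles, c(0, 90, 0, 30), tolerance = 1e-9)
  # missing orientation atom errors
  broken <- fr
  keep <- !(broken$atoms$resid == 2 & broken$atoms$name == "C24")
  broken$atoms <- broken$atoms[keep, ]
  broken$coords <- broken$coords[keep, , , drop = FALSE]
  expect_error(tilt_distribution(broken), "C24")
})
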