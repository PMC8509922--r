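test_that("molecule/concentration conversions follow the published correspondence", {
  conv <- cell_conversion()
  expect_equal(nM_to_molecules(1, conv), 360)
  expect_equal(nM_to_molecules(50, conv), 18000)
  expect_equal(molecules_to_nM(360, conv), 1)
  expect_equal(molecules_to_nM(18000, conv), 50)
  expect_equal(molecules_to_nM(0, conv), 0)
  expect_error(molecules_to_nM(-1, conv), ">= 0")
  expect_error(nM_to_molecules(-1, conv), ">= 0")
  expect_error(cell_conversion(0))
})

test_that("dynamic range inverts an analytic saturating curve", {
  # C(L) = 3600 L / (L + 0.1) molecules = 10 L / (L + 0.1) nM at 360/nM;
  # one complex per cell at L = 0.1/3599, 95% of the 10 nM plateau at 1.9
  f <- function(L) 10 * L / (L + 0.1)
  rc <- response_curve_from_function(f, 10^seq(-6, 4, length.out = 141))
  dr <- dynamic_range(rc, ligand_floor = FALSE)
  expect_true(dr$formable)
  expect_equal(dr$lower, 0.1 / 3599, tolerance = 1e-3)
  expect_equal(dr$upper, 1.9, tolerance = 1e-2)
  expect_equal(dr$fold, dr$upper / dr$lower)
  # the ligand-molecule floor lifts the lower bound when it binds later
  dr2 <- dynamic_range(rc, ligand_floor = TRUE)
  expect_equal(dr2$lower, 1 / 360, tolerance = 1e-6)
  # interpolation (no refinement) agrees with bisection to within a percent
  dr3 <- dynamic_range(rc, ligand_floor = FALSE, refine = FALSE)
  expect_equal(dr3$lower, dr$lower, tolerance = 0.01)
  expect_equal(dr3$upper, dr$upper, tolerance = 0.01)
})

test_that("an all-zero curve is reported as not formable", {
  rc <- response_curve_from_function(function(L) 0, 10^seq(-3, 1, length.out = 21))
  dr <- dynamic_range(rc)
  expect_false(dr$formable)
  expect_true(is.na(dr$fold))
})

test_that("formable dynamic ranges satisfy lower <= upper and fold >= 1", {
  rc <- ligand_response_curve(default_net, c(BmpR1 = 5, Acvr1 = 20, TypeII = 10),
                              ligand_grid = 10^seq(-4, 1, length.out = 41),
                              gamma = 10)
  dr <- dynamic_range(rc, refine = FALSE)
  ok <- dr[dr$formable, ]
  expect_gt(nrow(ok), 0)
  expect_true(all(ok$lower <= ok$upper))
  expect_true(all(ok$fold >= 1))
})

test_that("BmpR1 titration is biphasic for the Bmp2/7-(BmpR1)2 complex", {
  tc <- receptor_titration_curve(default_net, "BmpR1",
                                 values = 10^seq(0, log10(50), length.out = 15),
                                 receptors = c(Acvr1 = 10, TypeII = 10))
  x <- tc$concentration[tc$class == "Bmp2/7-(BmpR1)2-(TypeII)2"]
  pk <- which.max(x)
  expect_gt(pk, 1)
  expect_lt(pk, length(x))
  # and the heterodimer-heterotetramer is attenuated by high BmpR1
  xa <- tc$concentration[tc$class == HH]
  expect_lt(xa[length(xa)], max(xa))
})

test_that("type-II titration raises the Bmp2/7-(BmpR1)2 curve pointwise", {
  tc <- receptor_titration_curve(default_net, "TypeII",
                                 values = c(1, 2, 5, 10, 15),
                                 receptors = c(Acvr1 = 10, BmpR1 = 10))
  y <- tc$concentration[tc$class == "Bmp2/7-(BmpR1)2-(TypeII)2"]
  expect_true(all(diff(y) > 0))
})

test_that("dynamic-range bounds are stable under grid refinement", {
  rec <- c(BmpR1 = 5, Acvr1 = 20, TypeII = 10)
  coarse <- ligand_response_curve(default_net, rec,
                                  ligand_grid = 10^seq(-4, 1, length.out = 61),
                                  gamma = 10)
  fine <- ligand_response_curve(default_net, rec,
                                ligand_grid = 10^seq(-4, 1, length.out = 121),
                                gamma = 10)
  d1 <- dynamic_range(coarse, classes = HH, refine = FALSE)
  d2 <- dynamic_range(fine, classes = HH, refine = FALSE)
  expect_lt(abs(d1$lower / d2$lower - 1), 0.01)
  expect_lt(abs(d1$upper / d2$upper - 1), 0.01)
})

test_that("dynamic-range screen winners match a point-wise oracle", {
  vals <- c(1, 7, 50)
  scan <- 10^seq(-4, 1, length.out = 41)
  drs <- dynamic_range_screen(default_net, receptor_values = vals,
                              ligand_scan = scan)
  expect_equal(attr(drs, "n_points"), 27)
  ws <- dr_winner_summary(drs)
  expect_lte(sum(ws$fraction), 1 + 1e-12)
  # recompute a sample of points directly from fresh response curves
  pts <- unique(drs[, c("BmpR1", "Acvr1", "TypeII")])
  sel <- pts[c(1, 9, 14, 22, 27), ]
  for (i in seq_len(nrow(sel))) {
    rec <- c(BmpR1 = sel$BmpR1[i], Acvr1 = sel$Acvr1[i], TypeII = sel$TypeII[i])
    rc <- ligand_response_curve(default_net, rec, ligand_grid = scan, gamma = 10)
    dr <- dynamic_range(rc, refine = FALSE)
    want <- dr$class[dr$formable][which.max(dr$fold[dr$formable])]
    got <- drs[drs$BmpR1 == rec["BmpR1"] & drs$Acvr1 == rec["Acvr1"] &
                 drs$TypeII == rec["TypeII"] & drs$winner, ]$class
    expect_equal(got, want)
  }
  # pairwise summary structure
  pw <- dr_pairwise_summary(drs)
  expect_equal(nrow(pw$pairwise), 3)
  expect_gte(pw$saturation_highest, 0)
  expect_lte(pw$vs_best_bmpr1$fraction, 1)
})
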