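toy_grid <- grid_spec(ligand = c(0.1, 1), bmpr1 = c(2, 20), acvr1 = c(2, 20),
                      typeii = 10, gamma = 100)

test_that("grid specification expands to the advertised Cartesian product", {
  expect_equal(nrow(grid_points(grid_spec())), 84375)
  expect_equal(nrow(grid_points(toy_grid)), 8)
  # default Table-style values
  gs <- grid_spec()
  expect_equal(gs$ligand, 10^seq(-2, 0, length.out = 5))
  expect_equal(gs$bmpr1, seq(1, 50, length.out = 15))
  expect_equal(gs$gamma, c(10, 50, 100, 500, 1000))
})

test_that("a one-point grid reproduces solve_equilibrium", {
  g1 <- grid_spec(ligand = 0.1, bmpr1 = 10, acvr1 = 10, typeii = 10, gamma = 100)
  sc <- run_grid_screen(g1, default_net)
  expect_equal(nrow(sc), 1)
  st <- solve_equilibrium(mid_params, default_net)
  for (cl in tetramer_classes(default_net)) {
    sp <- default_net$species$id[which(default_net$species$tetramer_class == cl)]
    expect_equal(sc[[cl]], sum(unlist(st[, sp])), tolerance = 1e-12)
  }
})

test_that("screen rows match point-wise recomputation and argmax oracle", {
  sc <- run_grid_screen(toy_grid, default_net)
  expect_equal(nrow(sc), 8)
  classes <- tetramer_classes(default_net)
  pts <- grid_points(toy_grid)
  for (i in seq_len(nrow(pts))) {
    ps <- tibble::tibble(
      "Bmp2/2" = pts$ligand[i], "Bmp7/7" = pts$ligand[i], "Bmp2/7" = pts$ligand[i],
      BmpR1 = pts$BmpR1[i], Acvr1 = pts$Acvr1[i], TypeII = pts$TypeII[i],
      gamma = pts$gamma[i]
    )
    st <- solve_equilibrium(ps, default_net)
    conc <- vapply(classes, function(cl) {
      sp <- default_net$species$id[which(default_net$species$tetramer_class == cl)]
      sum(unlist(st[, sp]))
    }, 0)
    expect_equal(unlist(sc[i, classes]), conc, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(sc$most_abundant[i], classes[which.max(conc)])
  }
})

test_that("prevalence fractions cover all classes and sum to one", {
  sc <- run_grid_screen(toy_grid, default_net)
  prev <- prevalence_summary(sc)
  expect_equal(nrow(prev), 9)
  expect_equal(sum(prev$fraction), 1)
  expect_equal(sum(prev$n_wins), nrow(sc))
  expect_gte(attr(prev, "n_ties"), 0)
})

test_that("a Bmp2/2-only model with Acvr1 disabled always elects Bmp2-(BmpR1)2", {
  aff <- bmp_affinities()
  aff$enabled[aff$receptor == "Acvr1"] <- FALSE
  net <- build_network(bmp_ligands("Bmp2/2"), affinities = aff)
  sc <- run_grid_screen(grid_spec(ligand = c(0.1, 1), bmpr1 = c(5, 40),
                                  acvr1 = 10, typeii = c(5, 40), gamma = 100), net)
  prev <- prevalence_summary(sc)
  expect_equal(prev$fraction[prev$class == "Bmp2/2-(BmpR1)2-(TypeII)2"], 1)
})

test_that("predominance applies the strict summed-competitor definition", {
  sc <- run_grid_screen(toy_grid, default_net)
  # hand-built rows exercising the boundary
  classes <- tetramer_classes(default_net)
  fake <- sc[c(1, 1), ]
  fake[, classes] <- 0
  fake[1, HH] <- 1            # no homodimer competition: predominant
  fake[2, HH] <- 1            # equals the competitor sum: NOT predominant
  fake[2, "Bmp2/2-(BmpR1)2-(TypeII)2"] <- 0.5
  fake[2, "Bmp7/7-(BmpR1)2-(TypeII)2"] <- 0.5
  p <- predominance_summary(fake)
  expect_equal(p$n_predominant, 1)
  # alternative definition counts homomeric type-I receptor pairs instead
  p2 <- predominance_summary(fake, definition = "homomeric-receptor")
  expect_equal(p2$n_predominant, 1)
  # predominance is strictly stronger than most-abundant for the het-het
  full_prev <- prevalence_summary(sc)
  expect_lte(predominance_summary(sc)$fraction,
             full_prev$fraction[full_prev$class == HH] + 1e-12)
})

test_that("kinase discounting re-ranks over the remaining classes", {
  sc <- run_grid_screen(toy_grid, default_net)
  classes <- tetramer_classes(default_net)
  # empty inactive set reproduces plain prevalence
  d0 <- kinase_discounted_prevalence(sc, inactive = character())
  p0 <- prevalence_summary(sc)
  expect_equal(d0$fraction, p0$fraction)
  # all but one inactive: the survivor takes every point
  d1 <- kinase_discounted_prevalence(sc, inactive = setdiff(classes, HH))
  expect_equal(d1$fraction, 1)
  expect_error(kinase_discounted_prevalence(sc, inactive = classes), "inactive")
  expect_error(kinase_discounted_prevalence(sc, inactive = "NoSuchClass"),
               "unknown class")
  # default discounts exactly the three (BmpR1)2 complexes
  expect_length(bmpr1_homomeric_classes(sc), 3)
})

test_that("screens are identical across re-runs and checkpoint/resume", {
  a <- run_grid_screen(toy_grid, default_net)
  b <- run_grid_screen(toy_grid, default_net)
  expect_identical(as.data.frame(a), as.data.frame(b))
  ck <- withr::local_tempdir()
  c1 <- run_grid_screen(toy_grid, default_net, chunk_size = 3, checkpoint_dir = ck)
  expect_equal(length(list.files(ck)), 3)
  # resume: chunks are reused, results identical
  c2 <- run_grid_screen(toy_grid, default_net, chunk_size = 3, checkpoint_dir = ck)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_equal(c1$most_abundant, a$most_abundant)
})

test_that("scenario sweeps support ligand subsets and shipped configurations", {
  expect_named(bmp_scenarios(),
               c("equimolar", "excess-acvr1", "het-only",
                 "sensor-equimolar", "sensor-bmpr1-limited"))
  sw <- scenario_sweep(default_net, scenario = "het-only",
                       ligand_grid = c(0.05, 0.5))
  expect_equal(sort(unique(sw$class)), tetramer_classes(default_net))
  # homodimer-ligand classes cannot form when their dimers are quelled
  homo <- grepl("^Bmp2/2|^Bmp7/7", sw$class)
  expect_true(all(sw$concentration[homo] == 0))
  expect_true(all(sw$concentration[!homo] >= 0))
  expect_error(scenario_sweep(default_net, scenario = "no-such"), "unknown scenario")
})

test_that("equimolar ranking puts the three (BmpR1)2 classes on top", {
  # face-resolved affinities reproduce the published order exactly
  sw <- scenario_sweep(perface_net, scenario = "equimolar", ligand_grid = 0.3)
  ord <- dplyr::arrange(sw, -concentration)$class
  expect_equal(ord[1:3], c("Bmp2/2-(BmpR1)2-(TypeII)2",
                           "Bmp2/7-(BmpR1)2-(TypeII)2",
                           "Bmp7/7-(BmpR1)2-(TypeII)2"))
  # under the shipped shared type-II convention the heterodimer-
  # heterotetramer sits within the top five
  sw2 <- scenario_sweep(default_net, scenario = "equimolar", ligand_grid = 0.3)
  ord2 <- dplyr::arrange(sw2, -concentration)$class
  expect_true(HH %in% ord2[1:5])
})

test_that("critical affinity search brackets the prevalence threshold", {
  rec <- c(BmpR1 = 2, Acvr1 = 40, TypeII = 10)
  kd <- critical_affinity_search(default_net, rec, gamma = 10, ligand = 0.1,
                                 kd_range = c(10, 500), tol = 2)
  expect_true(is.na(kd) || is.numeric(kd))
  # without Acvr1 the heterotetramer cannot form at all
  expect_true(is.na(critical_affinity_search(default_net,
                                             c(BmpR1 = 5, TypeII = 10))))
  if (!is.na(kd) && is.null(attr(kd, "censored"))) {
    hh_at <- function(k) {
      net2 <- bmpassembly:::set_het_acvr1(default_net, k)
      sw <- scenario_sweep(net2, rec, ligand_grid = 0.1, gamma = 10)
      sw$class[which.max(sw$concentration)] == HH
    }
    expect_true(hh_at(kd))            # winning at the returned threshold
    expect_false(hh_at(1.1 * kd + 2)) # and losing just above it
    # strengthening the affinity below the threshold preserves the win
    for (k in seq(max(kd / 4, 10), kd, length.out = 4)) expect_true(hh_at(k))
  }
})
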