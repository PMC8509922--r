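test_that("default enumeration yields 51 oligomer species and 90 reactions", {
  expect_equal(nrow(default_net$species), 51)
  expect_equal(nrow(default_net$reactions), 90)
  # per dimer: 6 type-I pair states x 3 type-II counts minus the empty state
  expect_equal(unname(table(default_net$species$ligand)), rep(17L, 3) ,
               ignore_attr = TRUE)
})

test_that("convention search is exhaustive and finds exactly one match", {
  res <- convention_search(quiet = TRUE)
  expect_equal(nrow(res), 6)  # 3 lumping rules x 2 Acvr1/Bmp2 settings
  expect_equal(sum(res$match), 1)
  expect_equal(res$merge_sites[res$match], "class")
  expect_true(res$acvr1_bmp2[res$match])
})

test_that("single homodimer without Acvr1 gives the 8 bound occupancy states", {
  aff <- bmp_affinities()
  aff$enabled[aff$receptor == "Acvr1"] <- FALSE
  net <- build_network(bmp_ligands("Bmp2/2"), affinities = aff)
  expect_equal(nrow(net$species), 8)  # 3 type-I x 3 type-II states - empty
  expect_equal(nrow(net$reactions), 12)
})

test_that("empty ligand list gives a network with no species or reactions", {
  net <- build_network(bmp_ligands()[0, ])
  expect_equal(nrow(net$species), 0)
  expect_equal(nrow(net$reactions), 0)
  expect_equal(net$free_names, sort(bmp_receptors()$name))
})

test_that("exactly nine tetramer classes are distinguishable", {
  cls <- tetramer_classes(default_net)
  expect_length(cls, 9)
  expect_true(HH %in% cls)
  # 3 ligands x 3 type-I pair compositions
  expect_equal(sum(grepl("\\(BmpR1\\)2", cls)), 3)
  expect_equal(sum(grepl("\\(Acvr1\\)2", cls)), 3)
  expect_equal(sum(grepl("Acvr1-BmpR1", cls)), 3)
  # partially assembled species carry no class
  part <- default_net$species$id[default_net$species$bonds < 4]
  expect_true(all(is.na(classify_tetramer(default_net, part))))
  full <- default_net$species$id[default_net$species$bonds == 4]
  expect_false(any(is.na(classify_tetramer(default_net, full))))
})

test_that("species and reaction counts are invariant to declaration order", {
  lig <- bmp_ligands(c("Bmp2/7", "Bmp2/2", "Bmp7/7"))
  rec <- bmp_receptors()[c(3, 1, 2), ]
  aff <- bmp_affinities()[sample(seq_len(nrow(bmp_affinities()))), ]
  net <- build_network(lig, rec, aff)
  expect_equal(nrow(net$species), 51)
  expect_equal(nrow(net$reactions), 90)
  expect_equal(net$species$id, default_net$species$id)
  expect_equal(net$species$weight, default_net$species$weight)
})

test_that("class lumping preserves total microstate weight", {
  # the lumped weight of each class equals the sum over its face-resolved
  # microstates, so the two conventions describe the same equilibrium
  fine <- build_network(options = network_options(merge_sites = "none"))
  # map each microstate to its class key by receptor multiset
  key_of <- function(id, lig, occ) {
    paste(lig, paste(sort(occ), collapse = "+"))
  }
  agg <- tapply(
    fine$species$weight,
    paste(fine$species$ligand,
          vapply(fine$species$occupancy, function(o) paste(sort(o), collapse = "+"), "")),
    sum
  )
  coarse_keys <- paste(default_net$species$ligand,
                       vapply(default_net$species$occupancy,
                              function(o) paste(sort(o), collapse = "+"), ""))
  expect_equal(as.vector(agg[coarse_keys]), default_net$species$weight,
               tolerance = 1e-12)
  expect_equal(sum(fine$species$n_micro), sum(default_net$species$n_micro))
})

test_that("homodimer symmetry never splits equivalent occupancies", {
  # property over all microstates: swapping the two faces of a homodimer
  # maps every species id onto itself under class merging
  net <- build_network(bmp_ligands("Bmp7/7"))
  swapped <- function(occ) paste(sort(occ), collapse = "+")
  ids <- vapply(net$species$occupancy, swapped, "")
  expect_equal(length(unique(paste(net$species$id))), nrow(net$species))
  expect_equal(length(unique(ids)), length(unique(paste(net$species$bonds, ids))))
})

test_that("disabling a ligand-receptor pair removes exactly the species with that bond", {
  on <- build_network()
  aff_off <- bmp_affinities(acvr1_bmp2 = FALSE)
  off <- build_network(affinities = aff_off)
  gone <- setdiff(on$species$id, off$species$id)
  # every removed species contains an Acvr1 on a Bmp2-faced ligand; every
  # kept species is unchanged in weight unless it had a Bmp2-face Acvr1
  # microstate contribution
  expect_true(all(grepl("Acvr1", gone)))
  expect_true(all(grepl("^Bmp2/", gone)))  # Bmp2/2 or Bmp2/7 ligands only
  shared <- intersect(on$species$id, off$species$id)
  no_acv <- shared[!grepl("Acvr1", shared)]
  expect_equal(off$species$weight[match(no_acv, off$species$id)],
               on$species$weight[match(no_acv, on$species$id)])
})

test_that("rates_from_affinity implements K_D and gamma scaling", {
  k <- kinetics_config(kon_ref = 1e-3)
  r <- rates_from_affinity(0.8, k, surface = FALSE, multiplicity = 1)
  expect_equal(r$koff / r$kon, 0.8)
  r100 <- rates_from_affinity(0.8, k, surface = TRUE, gamma = 100)
  expect_equal(r100$kon, 100 * r$kon)
  expect_equal(r100$koff, r$koff)   # gamma boosts association only
  r1 <- rates_from_affinity(0.8, k, surface = TRUE, gamma = 1)
  expect_equal(r1$kon, r$kon)
  expect_error(rates_from_affinity(-1, k), "positive")
  expect_error(rates_from_affinity(0, k), "positive")
})

test_that("every reaction satisfies detailed balance against species weights", {
  # koff/kon == W_from / (gamma^surface * W_to) for each reaction closes
  # every thermodynamic cycle identically
  net <- default_net
  gam <- 100
  wt <- function(ids) {
    w <- net$species$weight[match(ids, net$species$id)]
    w[is.na(w)] <- 1
    w
  }
  rx <- net$reactions
  kon <- rx$m_assoc * ifelse(rx$surface, gam, 1)
  koff <- rx$m_diss * rx$kd_eff
  keq <- kon / koff
  expected <- ifelse(rx$surface, gam, 1) * wt(rx$product) / wt(rx$reactant)
  expect_lt(max(abs(keq / expected - 1)), 1e-12)
})

test_that("assembly-order cycles close exactly", {
  # type-I-first vs type-II-first assembly of the Bmp2/2 double complex
  net <- default_net
  keq <- function(reactant, receptor, product) {
    i <- which(net$reactions$reactant == reactant &
                 net$reactions$receptor == receptor &
                 net$reactions$product == product)
    expect_length(i, 1)
    kon <- net$reactions$m_assoc[i] * ifelse(net$reactions$surface[i], 100, 1)
    kon / (net$reactions$m_diss[i] * net$reactions$kd_eff[i])
  }
  a <- keq("Bmp2/2", "BmpR1", "Bmp2/2(BmpR1,-)(-,-)") *
    keq("Bmp2/2(BmpR1,-)(-,-)", "TypeII", "Bmp2/2(BmpR1,-)(TypeII,-)")
  b <- keq("Bmp2/2", "TypeII", "Bmp2/2(-,-)(TypeII,-)") *
    keq("Bmp2/2(-,-)(TypeII,-)", "BmpR1", "Bmp2/2(BmpR1,-)(TypeII,-)")
  expect_lt(abs(a / b - 1), 1e-12)
})

test_that("configuration errors are reported", {
  # enabled pair without a K_D entry
  aff <- bmp_affinities()
  expect_error(
    build_network(bmp_ligands(), affinities = aff[aff$receptor != "TypeII", ]),
    "no affinity entry"
  )
  expect_error(
    build_network(affinities = dplyr::mutate(bmp_affinities(), kd = -kd)),
    "K_D"
  )
  bad <- rbind(bmp_affinities(),
               tibble::tibble(face = "Bmp2", receptor = "NoSuch",
                              kd = 1, enabled = TRUE))
  expect_error(build_network(affinities = bad), "unknown receptor")
})
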