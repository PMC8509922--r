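test_that("both solvers reproduce the Langmuir closed form", {
  fx <- langmuir_fixture(1, 1, 1)
  alg <- solve_equilibrium(fx$params, fx$network)
  expect_equal(alg[["L(R)"]], fx$analytic$complex, tolerance = 1e-12)
  expect_equal(alg$free_L, fx$analytic$free_ligand, tolerance = 1e-10)
  ode <- integrate_to_steady_state(fx$params, fx$network)
  expect_true(ode$.converged)
  expect_equal(ode[["L(R)"]], fx$analytic$complex, tolerance = 1e-8)
})

test_that("zero ligand totals leave only free receptors", {
  ps <- mid_params
  ps[, c("Bmp2/2", "Bmp7/7", "Bmp2/7")] <- 0
  st <- solve_equilibrium(ps, default_net)
  expect_true(st$.converged)
  sp <- default_net$species$id
  expect_true(all(unlist(st[, sp]) == 0))
  expect_equal(st$free_BmpR1, 10)
  expect_equal(st$free_Acvr1, 10)
  expect_equal(st$free_TypeII, 10)
})

test_that("ODE endpoint matches the algebraic equilibrium on random parameter sets", {
  ps <- random_params(10, seed = 42)
  alg <- solve_equilibrium(ps, default_net)
  ode <- integrate_to_steady_state(ps, default_net)
  expect_true(all(ode$.converged))
  sp <- default_net$species$id
  for (i in seq_len(nrow(ps))) {
    d <- rel_diff(unlist(ode[i, sp]), unlist(alg[i, sp]))
    expect_lt(max(d), 1e-6)
  }
})

test_that("equilibrium is invariant under kon_ref rescaling", {
  net_fast <- build_network(kinetics = kinetics_config(kon_ref = 0.1))
  ps <- random_params(5, seed = 7)
  a <- solve_equilibrium(ps, default_net)
  b <- solve_equilibrium(ps, net_fast)
  sp <- default_net$species$id
  expect_lt(max(rel_diff(as.matrix(b[, sp]), as.matrix(a[, sp]))), 1e-9)
})

test_that("conservation holds to 1e-8 nM across random parameter sets", {
  ps <- random_params(200, seed = 11)
  st <- solve_equilibrium(ps, default_net)
  expect_true(all(st$.converged))
  mb <- mass_balance(st)
  expect_lt(max(mb$violation), 1e-8)
})

test_that("bound ligand increases weakly with the surface enhancement factor", {
  ps <- random_params(20, seed = 3)
  lig_cols <- paste0("free_", c("Bmp2/2", "Bmp7/7", "Bmp2/7"))
  bound_at <- function(g) {
    p <- dplyr::mutate(ps, gamma = g)
    st <- solve_equilibrium(p, default_net)
    rowSums(ps[, c("Bmp2/2", "Bmp7/7", "Bmp2/7")]) -
      rowSums(st[, lig_cols])
  }
  b1 <- bound_at(10); b2 <- bound_at(20); b3 <- bound_at(200)
  expect_true(all(b2 >= b1 - 1e-12))
  expect_true(all(b3 >= b2 - 1e-12))
})

test_that("mass_balance localizes deliberate perturbations", {
  st <- solve_equilibrium(mid_params, default_net)
  # perturb one tetramer (1 ligand + 2 BmpR1 + 2 TypeII) by +1 nM
  target <- "Bmp2/2(BmpR1,BmpR1)(TypeII,TypeII)"
  st2 <- st
  st2[[target]] <- st2[[target]] + 1
  mb <- mass_balance(st2, default_net)
  viol <- stats::setNames(mb$violation, mb$species)
  expect_equal(unname(viol["Bmp2/2"]), 1, tolerance = 1e-9)
  expect_equal(unname(viol["BmpR1"]), 2, tolerance = 1e-9)
  expect_equal(unname(viol["TypeII"]), 2, tolerance = 1e-9)
  expect_equal(unname(viol["Acvr1"]), 0, tolerance = 1e-9)
  # an all-zero state violates each total by exactly the total
  st3 <- st
  st3[, c(default_net$species$id, paste0("free_", default_net$free_names))] <- 0
  mb3 <- mass_balance(st3, default_net)
  expect_equal(mb3$violation, mb3$total)
})

test_that("clamped ligand mode holds free ligand fixed and conserves receptors", {
  sw <- scenario_sweep(default_net, receptors = c(BmpR1 = 5, Acvr1 = 5, TypeII = 5),
                       ligand_grid = c(0.1, 1), gamma = 50,
                       ligand_mode = "clamped")
  expect_true(attr(sw, "converged"))
  # under a reservoir the summed tetramer output can exceed what closed
  # 0.1 nM totals could supply at high demand; just check positivity and
  # that concentrations respond to the clamped level
  tot <- tapply(sw$concentration, sw$ligand, sum)
  expect_true(all(tot > 0))
  expect_gt(tot["1"], tot["0.1"] / 50)
})

test_that("non-convergence is flagged honestly rather than silently returned", {
  # an absurd tolerance cannot be met: the solver must say so
  expect_warning(
    st <- solve_equilibrium(mid_params, default_net, tol = 1e-30, maxit = 3),
    "did not converge"
  )
  expect_false(all(st$.converged))
})
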