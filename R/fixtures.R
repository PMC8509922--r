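#' Langmuir fixture: one ligand, one site, closed-form equilibrium
#'
#' Builds the minimal reversible-binding network (a single-site ligand L
#' and one receptor R) together with its quadratic closed-form solution
#' `C = ((R + L + K) - sqrt((R + L + K)^2 - 4 R L)) / 2`, which serves as
#' an independent oracle for both steady-state solvers.
#'
#' @param kd Dissociation constant (nM), > 0.
#' @param rtot,ltot Total receptor and ligand (nM); `ltot` may be 0.
#' @return A list: `network`, `params` (one-row tibble with `gamma = 1`),
#'   and `analytic` (tibble with `complex`, `free_ligand`,
#'   `free_receptor` in nM).
#' @export
#' @examples
#' fx <- langmuir_fixture(1, 1, 1)
#' fx$analytic$complex  # 0.381966...
langmuir_fixture <- function(kd = 1, rtot = 1, ltot = 1) {
  stopifnot(kd > 0, rtot > 0, ltot >= 0)
  lig <- toy_ligand("L", tibble::tibble(site = "s1", class = "type-I", face = "L"))
  rec <- tibble::tibble(name = "R", class = "type-I")
  aff <- tibble::tibble(face = "L", receptor = "R", kd = kd, enabled = TRUE)
  net <- build_network(lig, rec, aff)
  s <- rtot + ltot + kd
  # rationalized quadratic root: stable when kd dominates the totals
  cplx <- 2 * rtot * ltot / (s + sqrt(s^2 - 4 * rtot * ltot))
  list(
    network = net,
    params = tibble::tibble(L = ltot, R = rtot, gamma = 1),
    analytic = tibble::tibble(complex = cplx, free_ligand = ltot - cplx,
                              free_receptor = rtot - cplx)
  )
}

#' Two-independent-site fixture with a brute-force oracle
#'
#' A single ligand with two independent binding sites (dissociation
#' constants `kd1`, `kd2`) for one receptor type, solved by an exhaustive
#' grid search over the free receptor concentration with successive local
#' refinement -- sharing no code with the package's Newton solver. The
#' fixture exercises statistical factors and site independence: with
#' `kd1 = kd2` the singly/doubly bound species follow binomial weights.
#'
#' @param kd1,kd2 Site dissociation constants (nM), > 0.
#' @param rtot,ltot Totals (nM), > 0.
#' @param n_grid Points per grid-search pass.
#' @return A list: `network`, `params`, and `oracle` (tibble with free
#'   concentrations and every bound-species concentration, tolerance
#'   about 1e-6 relative after refinement).
#' @export
#' @examples
#' fx <- two_site_fixture(1, 5, 2, 1)
#' fx$oracle
two_site_fixture <- function(kd1 = 1, kd2 = 5, rtot = 2, ltot = 1,
                             n_grid = 600) {
  stopifnot(kd1 > 0, kd2 > 0, rtot > 0, ltot > 0)
  lig <- toy_ligand("L", tibble::tibble(site = c("s1", "s2"),
                                        class = "type-I", face = c("f1", "f2")))
  rec <- tibble::tibble(name = "R", class = "type-I")
  aff <- tibble::tibble(face = c("f1", "f2"), receptor = "R",
                        kd = c(kd1, kd2), enabled = TRUE)
  net <- build_network(lig, rec, aff)

  # receptor bound as a function of trial free receptor r (gamma = 1):
  # L_free = ltot / ((1 + r/kd1)(1 + r/kd2)); occupancy from independence
  bound_r <- function(r) {
    lf <- ltot / ((1 + r / kd1) * (1 + r / kd2))
    lf * (r / kd1 + r / kd2 + 2 * r^2 / (kd1 * kd2))
  }
  resid <- function(r) r + bound_r(r) - rtot
  lo <- rtot * 1e-12
  hi <- rtot
  for (pass in 1:6) {
    grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
    vals <- vapply(grid, resid, 0)
    i <- which(vals >= 0)[1]           # resid is increasing in r
    if (is.na(i)) i <- n_grid
    lo <- grid[max(i - 1, 1)]
    hi <- grid[i]
  }
  r <- (lo + hi) / 2
  lf <- ltot / ((1 + r / kd1) * (1 + r / kd2))
  oracle <- tibble::tibble(
    free_receptor = r,
    free_ligand = lf,
    bound_s1 = lf * r / kd1,
    bound_s2 = lf * r / kd2,
    bound_both = lf * r^2 / (kd1 * kd2)
  )
  list(network = net,
       params = tibble::tibble(L = ltot, R = rtot, gamma = 1),
       oracle = oracle)
}

#' Reproducible random parameter sets
#'
#' Draws parameter sets log-uniformly within the screened ranges (ligand
#' 0.01-1 nM per dimer, receptors 1-50 nM, gamma 10-1000 by default),
#' seeded for reproducibility. Used by the solver cross-validation tests.
#'
#' @param n Number of parameter sets.
#' @param seed Integer seed; the same seed always yields the same draws.
#' @param ligand_range,receptor_range,gamma_range Sampling ranges.
#' @param coupled If `TRUE` the three dimers share one total, as in the
#'   published screen; otherwise each dimer is drawn independently.
#' @return A tibble with columns `Bmp2/2`, `Bmp7/7`, `Bmp2/7`, `BmpR1`,
#'   `Acvr1`, `TypeII`, `gamma`.
#' @export
#' @examples
#' random_params(3, seed = 1)
random_params <- function(n, seed = 1, ligand_range = c(0.01, 1),
                          receptor_range = c(1, 50), gamma_range = c(10, 1000),
                          coupled = FALSE) {
  stopifnot(n >= 1, all(ligand_range > 0), all(receptor_range > 0),
            all(gamma_range >= 1))
  runif_log <- function(n, rng) exp(stats::runif(n, log(rng[1]), log(rng[2])))
  withr::with_seed(seed, {
    l1 <- runif_log(n, ligand_range)
    l2 <- if (coupled) l1 else runif_log(n, ligand_range)
    l3 <- if (coupled) l1 else runif_log(n, ligand_range)
    tibble::tibble(
      "Bmp2/2" = l1, "Bmp7/7" = l2, "Bmp2/7" = l3,
      BmpR1 = runif_log(n, receptor_range),
      Acvr1 = runif_log(n, receptor_range),
      TypeII = runif_log(n, receptor_range),
      gamma = runif_log(n, gamma_range)
    )
  })
}
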