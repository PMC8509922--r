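#' Receptor/cell-count conversion
#'
#' Converts between bulk concentration (nM) and molecules per cell. At the
#' published correspondence, 1-50 nM receptor is roughly 360-18,000
#' receptors per cell, i.e. 360 molecules per nM.
#'
#' @param molecules_per_nM Molecules per cell corresponding to 1 nM.
#' @return A list of class `"bmp_cell_conversion"`.
#' @export
#' @examples
#' conv <- cell_conversion()
#' nM_to_molecules(50, conv)   # 18000
cell_conversion <- function(molecules_per_nM = 360) {
  stopifnot(is.numeric(molecules_per_nM), molecules_per_nM > 0)
  structure(list(molecules_per_nM = molecules_per_nM),
            class = "bmp_cell_conversion")
}

#' @rdname cell_conversion
#' @param count Molecule count (>= 0).
#' @param conv A [cell_conversion()].
#' @export
molecules_to_nM <- function(count, conv = cell_conversion()) {
  if (any(count < 0)) stop("molecule counts must be >= 0", call. = FALSE)
  count / conv$molecules_per_nM
}

#' @rdname cell_conversion
#' @param conc Concentration in nM (>= 0).
#' @export
nM_to_molecules <- function(conc, conv = cell_conversion()) {
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  conc * conv$molecules_per_nM
}

#' Ligand dose-response curve
#'
#' Steady-state tetramer concentrations over a ligand scan at fixed
#' receptor totals: a thin wrapper around [scenario_sweep()] with the
#' dense logarithmic default grid used by the dynamic-range analysis.
#'
#' @inheritParams scenario_sweep
#' @param ligand_grid Strictly increasing ligand totals (nM).
#' @return A `"bmp_response_curve"` tibble (`ligand`, `class`,
#'   `concentration`).
#' @export
#' @examples
#' net <- build_network()
#' rc <- ligand_response_curve(net, c(BmpR1 = 10, Acvr1 = 10, TypeII = 10),
#'                             ligand_grid = 10^seq(-3, 0, length.out = 7))
ligand_response_curve <- function(network, receptors,
                                  ligand_grid = 10^seq(-4, 1, length.out = 61),
                                  gamma = 10, ligands = NULL,
                                  ligand_mode = c("clamped", "conserved")) {
  ligand_mode <- match.arg(ligand_mode)
  scenario_sweep(network, receptors = receptors, ligand_grid = ligand_grid,
                 gamma = gamma, ligands = ligands, ligand_mode = ligand_mode)
}

#' Receptor titration curve
#'
#' Varies one receptor total while the others (and the ligand totals) are
#' held fixed, and returns the tetramer-class concentrations at each
#' level -- the receptor-sensitivity analysis. With the default ligand
#' level of 0.3 nM per dimer and 10 nM of the non-varied accessory
#' receptor, titrating BmpR1 produces the characteristic biphasic
#' Bmp2/7-(BmpR1)2 response, while titrating the type-II receptor raises
#' it monotonically.
#'
#' @param network A `"bmp_network"`.
#' @param vary Receptor to titrate (`"BmpR1"`, `"Acvr1"`, `"TypeII"`).
#' @param values Totals (nM) for the varied receptor.
#' @param receptors Named totals for the non-varied receptors.
#' @param ligand Shared ligand total per dimer (nM).
#' @param gamma Surface enhancement factor.
#' @param ligands Dimers included (`NULL` = all).
#' @return A tibble of class `"bmp_titration_curve"`: `receptor`, `value`,
#'   `class`, `concentration`.
#' @export
#' @examples
#' net <- build_network()
#' tc <- receptor_titration_curve(net, "BmpR1", c(1, 5, 20),
#'                                receptors = c(Acvr1 = 10, TypeII = 10))
receptor_titration_curve <- function(network, vary = c("BmpR1", "Acvr1", "TypeII"),
                                     values = 10^seq(0, log10(50), length.out = 25),
                                     receptors = c(Acvr1 = 10, TypeII = 10),
                                     ligand = 0.3, gamma = 10, ligands = NULL,
                                     ligand_mode = c("clamped", "conserved")) {
  stopifnot(inherits(network, "bmp_network"))
  vary <- match.arg(vary)
  ligand_mode <- match.arg(ligand_mode)
  stopifnot(all(values >= 0), !(vary %in% names(receptors)))
  ligands <- ligands %||% network$ligand_names
  fn <- network$free_names
  totals <- matrix(0, length(values), length(fn), dimnames = list(NULL, fn))
  for (lg in ligands) totals[, lg] <- ligand
  for (r in names(receptors)) totals[, r] <- receptors[[r]]
  totals[, vary] <- values
  sol <- eq_solve_batch(network, totals, rep(gamma, length(values)),
                        clamped = if (ligand_mode == "clamped") ligands)
  tet <- !is.na(network$species$tetramer_class)
  TC <- t(rowsum(t(sol$conc[, tet, drop = FALSE]),
                 network$species$tetramer_class[tet]))
  out <- tibble::as_tibble(as.data.frame(TC, check.names = FALSE))
  out$value <- values
  out <- tidyr::pivot_longer(out, -"value", names_to = "class",
                             values_to = "concentration")
  out$receptor <- vary
  out <- dplyr::arrange(out[, c("receptor", "value", "class", "concentration")],
                        .data$class, .data$value)
  structure(out, class = c("bmp_titration_curve", class(out)),
            network = network, receptors = receptors, ligand = ligand,
            gamma = gamma, ligands = ligands)
}

#' Build a response curve from an analytic function
#'
#' Wraps a closed-form dose-response function into the
#' `"bmp_response_curve"` container, for validating the dynamic-range
#' metric against analytic inversions.
#'
#' @param f Function mapping ligand concentration (nM) to complex
#'   concentration (nM).
#' @param ligand_grid Scan grid (nM).
#' @param class Label for the curve.
#' @return A `"bmp_response_curve"` tibble with the function attached for
#'   bisection refinement.
#' @export
#' @examples
#' rc <- response_curve_from_function(function(L) 10 * L / (L + 0.1),
#'                                    10^seq(-6, 3, length.out = 91))
response_curve_from_function <- function(f, ligand_grid, class = "analytic") {
  stopifnot(is.function(f), !is.unsorted(ligand_grid, strictly = TRUE))
  out <- tibble::tibble(ligand = ligand_grid, class = class,
                        concentration = vapply(ligand_grid, f, 0))
  structure(out, class = c("bmp_response_curve", class(out)), solver_fun = f)
}

#' Dynamic range of a tetramer's ligand response
#'
#' The sensor metric: for each tetramer class, `lower` is the ligand
#' concentration at the detection floor -- the larger of the level
#' producing one complex per cell and (optionally) one ligand molecule
#' per cell -- and `upper` is the smallest ligand concentration reaching
#' `saturation_fraction` of the curve's maximum on its rising limb. The
#' fold range `upper/lower` measures how many multiples of ligand
#' concentration the complex can discriminate. A class that never reaches
#' one complex per cell over the scan is reported as not formable.
#'
#' Crossings are bracketed on the scan grid and refined: by bisection with
#' fresh steady-state evaluations when the curve carries its generating
#' model (`refine = TRUE`), otherwise by log-log interpolation.
#'
#' @param curve A `"bmp_response_curve"`.
#' @param classes Classes to evaluate (`NULL` = all in the curve).
#' @param conv A [cell_conversion()].
#' @param saturation_fraction Fraction of the curve maximum defining
#'   saturation.
#' @param floor_molecules Complexes per cell defining detection.
#' @param ligand_floor Also require at least one ligand molecule per cell
#'   (the published red-point rule).
#' @param refine Use bisection against the generating model where
#'   available.
#' @param tol Relative bisection tolerance on the ligand concentration.
#' @return A tibble of class `"bmp_dynamic_range"`: `class`, `lower`,
#'   `upper`, `fold`, `formable`.
#' @export
#' @examples
#' rc <- response_curve_from_function(function(L) 10 * L / (L + 0.1),
#'                                    10^seq(-6, 3, length.out = 91))
#' dynamic_range(rc, ligand_floor = FALSE)
dynamic_range <- function(curve, classes = NULL, conv = cell_conversion(),
                          saturation_fraction = 0.95, floor_molecules = 1,
                          ligand_floor = TRUE, refine = TRUE, tol = 1e-4) {
  stopifnot(inherits(curve, "bmp_response_curve"), nrow(curve) > 0,
            saturation_fraction > 0, saturation_fraction <= 1)
  classes <- classes %||% sort_c(unique(curve$class))
  floor_conc <- floor_molecules / conv$molecules_per_nM
  lig_floor <- if (ligand_floor) floor_molecules / conv$molecules_per_nM else 0

  solver <- curve_point_solver(curve, refine)

  rows <- purrr::map(classes, function(cl) {
    cc <- curve[curve$class == cl, , drop = FALSE]
    if (nrow(cc) == 0) stop("curve does not cover class ", cl, call. = FALSE)
    dr_one(cc$ligand, cc$concentration, cl, floor_conc, lig_floor,
           saturation_fraction, solver, tol)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bmp_dynamic_range", class(out))
  out
}

# Returns f(L, class) -> concentration, or NULL when the curve carries no
# generating model.
curve_point_solver <- function(curve, refine) {
  if (!refine) return(NULL)
  f <- attr(curve, "solver_fun")
  if (!is.null(f)) return(function(L, cl) f(L))
  net <- attr(curve, "network")
  if (is.null(net)) return(NULL)
  receptors <- attr(curve, "receptors")
  gamma <- attr(curve, "gamma")
  ligands <- attr(curve, "ligands")
  mode <- attr(curve, "ligand_mode") %||% "conserved"
  function(L, cl) {
    sw <- scenario_sweep(net, receptors = receptors, ligand_grid = L,
                         gamma = gamma, ligands = ligands, ligand_mode = mode)
    sw$concentration[sw$class == cl]
  }
}

dr_one <- function(L, C, cl, floor_conc, lig_floor, sat_frac, solver, tol) {
  none <- tibble::tibble(class = cl, lower = NA_real_, upper = NA_real_,
                         fold = NA_real_, formable = FALSE)
  i_max <- which.max(C)
  cmax <- C[i_max]
  if (!is.finite(cmax) || cmax < floor_conc) return(none)

  # crossings are searched on the rising limb only
  cross_up <- function(target) {
    ris <- seq_len(i_max)
    idx <- which(C[ris] >= target)[1]
    if (is.na(idx)) return(NA_real_)
    if (idx == 1) return(L[1])
    lo <- L[idx - 1]; hi <- L[idx]
    if (!is.null(solver)) {
      while (hi / lo - 1 > tol) {
        mid <- sqrt(lo * hi)
        if (solver(mid, cl) >= target) hi <- mid else lo <- mid
      }
      hi
    } else {
      # monotone log-log interpolation between the bracketing grid points
      c0 <- max(C[idx - 1], .Machine$double.xmin)
      exp(log(lo) + (log(target) - log(c0)) / (log(C[idx]) - log(c0)) *
            (log(hi) - log(lo)))
    }
  }

  lower <- max(cross_up(floor_conc), lig_floor)
  upper <- cross_up(sat_frac * cmax)
  # a complex saturating below the detection floor has no usable range
  if (is.finite(lower) && is.finite(upper) && upper < lower) upper <- lower
  tibble::tibble(class = cl, lower = lower, upper = upper,
                 fold = upper / lower, formable = TRUE)
}

#' Dynamic-range screen over receptor concentrations
#'
#' Evaluates the dynamic range of every tetramer class at each point of a
#' receptor-concentration grid (7 log-spaced levels per receptor over
#' 1-50 nM by default, 343 points) and identifies the class with the
#' largest fold range at each point. Classes that cannot produce one
#' complex per cell at a point are not formable there and cannot win.
#'
#' @param network A `"bmp_network"`.
#' @param receptor_values Levels (nM) applied to each receptor axis.
#' @param gamma Surface enhancement factor.
#' @param conv A [cell_conversion()].
#' @param saturation_fraction Saturation definition, as [dynamic_range()].
#' @param ligand_scan Log scan of the shared ligand level (nM).
#' @param ligands Dimers co-varied over the scan (`NULL` = all).
#' @param ligand_mode Ambient-reservoir (`"clamped"`, default) or closed
#'   totals (`"conserved"`) ligand semantics; see [scenario_sweep()].
#' @param quiet Suppress progress messages.
#' @return A tibble of class `"bmp_dr_screen"`, one row per (grid point,
#'   class): receptor totals, `class`, `lower`, `upper`, `fold`,
#'   `formable`, `winner` (logical).
#' @seealso [dr_winner_summary()], [dr_pairwise_summary()]
#' @export
dynamic_range_screen <- function(network,
                                 receptor_values = 10^seq(0, log10(50), length.out = 7),
                                 gamma = 10, conv = cell_conversion(),
                                 saturation_fraction = 0.95,
                                 ligand_scan = 10^seq(-4, 1, length.out = 61),
                                 ligands = NULL, quiet = TRUE,
                                 ligand_mode = c("clamped", "conserved")) {
  stopifnot(inherits(network, "bmp_network"))
  ligand_mode <- match.arg(ligand_mode)
  ligands <- ligands %||% network$ligand_names
  classes <- tetramer_classes(network)
  grid <- expand.grid(BmpR1 = receptor_values, Acvr1 = receptor_values,
                      TypeII = receptor_values, KEEP.OUT.ATTRS = FALSE)
  nL <- length(ligand_scan)
  nG <- nrow(grid)

  fn <- network$free_names
  totals <- matrix(0, nG * nL, length(fn), dimnames = list(NULL, fn))
  for (lg in ligands) totals[, lg] <- rep(ligand_scan, times = nG)
  totals[, "BmpR1"] <- rep(grid$BmpR1, each = nL)
  totals[, "Acvr1"] <- rep(grid$Acvr1, each = nL)
  totals[, "TypeII"] <- rep(grid$TypeII, each = nL)
  sol <- eq_solve_batch(network, totals, rep(gamma, nG * nL),
                        clamped = if (ligand_mode == "clamped") ligands)
  tet <- !is.na(network$species$tetramer_class)
  TC <- t(rowsum(t(sol$conc[, tet, drop = FALSE]),
                 network$species$tetramer_class[tet]))
  TC <- TC[, classes, drop = FALSE]

  floor_conc <- 1 / conv$molecules_per_nM
  rows <- purrr::map(seq_len(nG), function(gi) {
    sel <- (gi - 1) * nL + seq_len(nL)
    drs <- purrr::map(classes, function(cl) {
      dr_one(ligand_scan, TC[sel, cl], cl, floor_conc, floor_conc,
             saturation_fraction, solver = NULL, tol = 1e-4)
    })
    drs <- dplyr::bind_rows(drs)
    drs$BmpR1 <- grid$BmpR1[gi]
    drs$Acvr1 <- grid$Acvr1[gi]
    drs$TypeII <- grid$TypeII[gi]
    best <- which(drs$formable & drs$fold == max(drs$fold[drs$formable], -Inf))
    drs$winner <- FALSE
    if (length(best) > 0) drs$winner[best[1]] <- TRUE
    if (!quiet && gi %% 50 == 0) message("dynamic-range screen: ", gi, "/", nG)
    drs
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("BmpR1", "Acvr1", "TypeII", "class", "lower", "upper",
                 "fold", "formable", "winner")]
  structure(out, class = c("bmp_dr_screen", class(out)),
            classes = classes, n_points = nG, gamma = gamma,
            saturation_fraction = saturation_fraction)
}

#' Winner fractions of a dynamic-range screen
#'
#' @param drs A `"bmp_dr_screen"`.
#' @return A tibble per class: `class`, `n_wins`, `fraction`, `percent`
#'   (fractions sum to at most 1; points where no class is formable have
#'   no winner).
#' @export
dr_winner_summary <- function(drs) {
  stopifnot(inherits(drs, "bmp_dr_screen"))
  n <- attr(drs, "n_points")
  wins <- table(factor(drs$class[drs$winner], levels = attr(drs, "classes")))
  out <- tibble::tibble(class = attr(drs, "classes"), n_wins = as.integer(wins),
                        fraction = as.integer(wins) / n)
  out$percent <- 100 * out$fraction
  out
}

#' Heterodimer-heterotetramer vs BmpR1-homomeric dynamic range
#'
#' Fraction of screen points where the heterodimer-heterotetramer's fold
#' range exceeds that of every (BmpR1)2 tetramer class (a class that is
#' not formable at a point loses there), plus per-class pairwise
#' fractions and the fraction of points where the heterodimer-
#' heterotetramer has the largest saturation concentration.
#'
#' @param drs A `"bmp_dr_screen"`.
#' @return A list: `vs_best_bmpr1` (one-row tibble), `pairwise` (per
#'   (BmpR1)2 class), `saturation_highest` (fraction of points where the
#'   het-het upper bound is the maximum across all classes).
#' @export
dr_pairwise_summary <- function(drs) {
  stopifnot(inherits(drs, "bmp_dr_screen"))
  classes <- attr(drs, "classes")
  hh <- grep("^Bmp2/7-Acvr1-BmpR1", classes, value = TRUE)
  bb <- bmpr1_homomeric_classes(classes)
  wide_fold <- tidyr::pivot_wider(
    drs[, c("BmpR1", "Acvr1", "TypeII", "class", "fold")],
    names_from = "class", values_from = "fold")
  wide_up <- tidyr::pivot_wider(
    drs[, c("BmpR1", "Acvr1", "TypeII", "class", "upper")],
    names_from = "class", values_from = "upper")
  fold <- function(cl) {
    x <- wide_fold[[cl]]
    ifelse(is.na(x), -Inf, x)
  }
  hhf <- fold(hh)
  pair <- purrr::map(bb, function(cl) {
    tibble::tibble(class = cl, fraction = mean(hhf > fold(cl)))
  })
  pair <- dplyr::bind_rows(pair)
  pair$percent <- 100 * pair$fraction
  best_bb <- do.call(pmax, purrr::map(bb, fold))
  up <- as.matrix(wide_up[, classes])
  up[is.na(up)] <- -Inf
  sat_high <- mean(up[, hh] >= apply(up, 1, max))
  list(
    vs_best_bmpr1 = tibble::tibble(fraction = mean(hhf > best_bb),
                                   percent = 100 * mean(hhf > best_bb)),
    pairwise = pair,
    saturation_highest = sat_high
  )
}
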