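#' Parameter grid specification
#'
#' Describes the Cartesian parameter grid of the prevalence screen: a
#' shared total for the three ligand dimers (they are co-varied), the
#' three receptor totals, and the surface enhancement factor gamma. The
#' defaults reproduce the published 84,375-point design: 5 log-spaced
#' ligand levels over 0.01-1 nM, 15 levels per receptor over 1-50 nM
#' (linear by default; log-spacing available), and gamma in
#' \{10, 50, 100, 500, 1000\}.
#'
#' @param ligand Ligand totals (nM) applied to every dimer, or `NULL` for
#'   the default spacing.
#' @param bmpr1,acvr1,typeii Receptor totals (nM), or `NULL` for defaults.
#' @param gamma Surface enhancement factors.
#' @param ligand_spacing,receptor_spacing Spacing used when values are not
#'   given explicitly.
#' @param n_ligand,n_receptor Grid sizes for the default ranges.
#' @param ligand_range,receptor_range Ranges (nM) for the default grids.
#' @return A list of class `"bmp_grid_spec"`.
#' @seealso [grid_points()], [run_grid_screen()]
#' @export
#' @examples
#' grid_spec()                       # the 84,375-point screen
#' grid_spec(receptor_spacing = "log")
grid_spec <- function(ligand = NULL, bmpr1 = NULL, acvr1 = NULL, typeii = NULL,
                      gamma = c(10, 50, 100, 500, 1000),
                      ligand_spacing = c("log", "linear"),
                      receptor_spacing = c("linear", "log"),
                      n_ligand = 5, n_receptor = 15,
                      ligand_range = c(0.01, 1), receptor_range = c(1, 50)) {
  ligand_spacing <- match.arg(ligand_spacing)
  receptor_spacing <- match.arg(receptor_spacing)
  seq_by <- function(rng, n, spacing) {
    if (spacing == "log") 10^seq(log10(rng[1]), log10(rng[2]), length.out = n)
    else seq(rng[1], rng[2], length.out = n)
  }
  lig <- ligand %||% seq_by(ligand_range, n_ligand, ligand_spacing)
  rec <- function(x) x %||% seq_by(receptor_range, n_receptor, receptor_spacing)
  stopifnot(all(lig >= 0), all(gamma >= 1))
  structure(list(ligand = lig, bmpr1 = rec(bmpr1), acvr1 = rec(acvr1),
                 typeii = rec(typeii), gamma = gamma,
                 ligand_spacing = ligand_spacing,
                 receptor_spacing = receptor_spacing),
            class = "bmp_grid_spec")
}

#' @export
print.bmp_grid_spec <- function(x, ...) {
  n <- prod(lengths(x[c("ligand", "bmpr1", "acvr1", "typeii", "gamma")]))
  cat("<bmp_grid_spec> ", format(n, big.mark = ","), " points (",
      length(x$ligand), " ligand x ", length(x$bmpr1), "x", length(x$acvr1),
      "x", length(x$typeii), " receptor x ", length(x$gamma), " gamma)\n", sep = "")
  invisible(x)
}

#' Expand a grid specification into parameter points
#'
#' @param spec A [grid_spec()].
#' @return A tibble with columns `ligand`, `BmpR1`, `Acvr1`, `TypeII`,
#'   `gamma`, one row per grid point, in deterministic order (ligand
#'   varying fastest, gamma slowest).
#' @export
#' @examples
#' nrow(grid_points(grid_spec()))  # 84375
grid_points <- function(spec) {
  stopifnot(inherits(spec, "bmp_grid_spec"))
  g <- expand.grid(ligand = spec$ligand, BmpR1 = spec$bmpr1, Acvr1 = spec$acvr1,
                   TypeII = spec$typeii, gamma = spec$gamma,
                   KEEP.OUT.ATTRS = FALSE)
  tibble::as_tibble(g)
}

#' Run the tetramer prevalence screen over a parameter grid
#'
#' Solves every grid point to steady state with the algebraic equilibrium
#' solver and records the concentration of each fully assembled tetramer
#' class, the most abundant class, and tie/convergence diagnostics.
#' Long runs can be chunked and checkpointed: finished chunks are written
#' to `checkpoint_dir` and re-used when the screen is re-run.
#'
#' @param grid A [grid_spec()] or a tibble of grid points from
#'   [grid_points()].
#' @param network A `"bmp_network"`.
#' @param chunk_size Points per solver batch.
#' @param checkpoint_dir Directory for chunk checkpoints (`NULL` = none).
#' @param quiet Suppress progress messages (one per 10 chunks).
#' @return A tibble of class `"bmp_screen"`: grid columns, one
#'   concentration column (nM) per tetramer class, `most_abundant`,
#'   `tie`, `.converged`, `.residual`. Non-converged points are kept and
#'   flagged, and excluded from summaries with a warning there.
#' @export
#' @examples
#' net <- build_network()
#' toy <- grid_spec(ligand = 0.1, bmpr1 = c(2, 20), acvr1 = c(2, 20),
#'                  typeii = 10, gamma = 100)
#' run_grid_screen(toy, net)
run_grid_screen <- function(grid, network, chunk_size = 5000,
                            checkpoint_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(network, "bmp_network"))
  pts <- if (inherits(grid, "bmp_grid_spec")) grid_points(grid) else tibble::as_tibble(grid)
  need <- c("ligand", "BmpR1", "Acvr1", "TypeII", "gamma")
  stopifnot(all(need %in% names(pts)), nrow(pts) > 0)
  classes <- tetramer_classes(network)

  chunks <- split(seq_len(nrow(pts)), ceiling(seq_len(nrow(pts)) / chunk_size))
  use_ckpt <- !is.null(checkpoint_dir)
  if (use_ckpt && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }

  out <- purrr::map(seq_along(chunks), function(ci) {
    ck_file <- if (use_ckpt) {
      file.path(checkpoint_dir, sprintf("chunk_%05d.csv", ci))
    }
    if (use_ckpt && file.exists(ck_file)) {
      res <- utils::read.csv(ck_file, check.names = FALSE)
      return(tibble::as_tibble(res))
    }
    res <- screen_chunk(pts[chunks[[ci]], , drop = FALSE], network, classes)
    if (use_ckpt) {
      utils::write.csv(res, ck_file, row.names = FALSE)
      # re-read so checkpointed and fresh runs are bit-identical
      res <- tibble::as_tibble(utils::read.csv(ck_file, check.names = FALSE))
    }
    if (!quiet && ci %% 10 == 0) {
      message("screen: ", ci, "/", length(chunks), " chunks done")
    }
    res
  })
  out <- dplyr::bind_rows(out)
  if (any(!out$.converged)) {
    warning(sum(!out$.converged), " grid point(s) did not converge; ",
            "they are flagged and excluded from summaries", call. = FALSE)
  }
  class(out) <- c("bmp_screen", class(out))
  attr(out, "classes") <- classes
  attr(out, "network") <- network
  out
}

screen_chunk <- function(pts, network, classes) {
  fn <- network$free_names
  totals <- matrix(0, nrow(pts), length(fn), dimnames = list(NULL, fn))
  for (lg in network$ligand_names) totals[, lg] <- pts$ligand
  for (r in intersect(c("BmpR1", "Acvr1", "TypeII"), fn)) totals[, r] <- pts[[r]]
  sol <- eq_solve_batch(network, totals, pts$gamma)
  tet <- !is.na(network$species$tetramer_class)
  TC <- t(rowsum(t(sol$conc[, tet, drop = FALSE]),
                 network$species$tetramer_class[tet]))
  TC <- TC[, classes, drop = FALSE]
  top <- max.col(TC, ties.method = "first")
  sorted <- apply(TC, 1, function(z) sort(z, decreasing = TRUE)[1:2])
  res <- dplyr::bind_cols(
    pts,
    tibble::as_tibble(as.data.frame(TC, check.names = FALSE))
  )
  res$most_abundant <- classes[top]
  res$tie <- if (ncol(TC) >= 2) sorted[1, ] == sorted[2, ] else FALSE
  res$.converged <- sol$converged
  res$.residual <- sol$residual
  res
}

screen_classes <- function(screen) {
  attr(screen, "classes") %||%
    sort_c(grep("-\\(TypeII\\)2$", names(screen), value = TRUE))
}

screen_ok <- function(screen) {
  if (".converged" %in% names(screen)) screen$.converged else
    rep(TRUE, nrow(screen))
}

#' Prevalence summary: how often is each tetramer class the most abundant?
#'
#' @param screen A `"bmp_screen"` from [run_grid_screen()].
#' @return A tibble with one row per tetramer class: `class`, `n_wins`,
#'   `fraction`, `percent` (fractions over converged points sum to 1;
#'   ties are broken toward the lexicographically first class and their
#'   count is reported in attribute `"n_ties"`).
#' @export
#' @examples
#' net <- build_network()
#' sc <- run_grid_screen(grid_spec(ligand = 0.1, bmpr1 = c(2, 20),
#'                                 acvr1 = c(2, 20), typeii = 10, gamma = 100), net)
#' prevalence_summary(sc)
prevalence_summary <- function(screen) {
  classes <- screen_classes(screen)
  ok <- screen_ok(screen)
  wins <- table(factor(screen$most_abundant[ok], levels = classes))
  out <- tibble::tibble(
    class = classes,
    n_wins = as.integer(wins),
    fraction = as.integer(wins) / sum(ok)
  )
  out$percent <- 100 * out$fraction
  attr(out, "n_ties") <- sum(screen$tie[ok])
  attr(out, "n_points") <- sum(ok)
  out
}

#' Predominance of the heterodimer-heterotetramer
#'
#' A point is predominant when the Bmp2/7-Acvr1-BmpR1-(TypeII)2
#' concentration strictly exceeds the summed concentration of the
#' competing complexes: under the default `"homodimer-ligand"` definition
#' the sum of every tetramer whose ligand is a homodimer; under the
#' alternative `"homomeric-receptor"` definition the sum of every
#' tetramer carrying an identical type-I receptor pair.
#'
#' @param screen A `"bmp_screen"`.
#' @param definition Which competing-complex sum to use.
#' @return A one-row tibble: `definition`, `n_points`, `n_predominant`,
#'   `fraction`, `percent`.
#' @export
predominance_summary <- function(screen,
                                 definition = c("homodimer-ligand",
                                                "homomeric-receptor")) {
  definition <- match.arg(definition)
  classes <- screen_classes(screen)
  hh <- grep("^Bmp2/7-Acvr1-BmpR1", classes, value = TRUE)
  if (length(hh) != 1) stop("screen lacks the heterodimer-heterotetramer class", call. = FALSE)
  rivals <- if (definition == "homodimer-ligand") {
    classes[!grepl("^Bmp2/7-", classes)]
  } else {
    grep("\\((BmpR1|Acvr1)\\)2", classes, value = TRUE)
  }
  ok <- screen_ok(screen)
  x <- as.matrix(screen[ok, rivals, drop = FALSE])
  pre <- screen[[hh]][ok] > rowSums(x)
  tibble::tibble(definition = definition, n_points = sum(ok),
                 n_predominant = sum(pre), fraction = mean(pre),
                 percent = 100 * mean(pre))
}

#' The three tetramer classes carrying two BmpR1 receptors
#'
#' @param screen A `"bmp_screen"` (or a character vector of class names).
#' @return Character vector of (BmpR1)2 class labels.
#' @export
bmpr1_homomeric_classes <- function(screen) {
  classes <- if (is.character(screen)) screen else screen_classes(screen)
  grep("\\(BmpR1\\)2", classes, value = TRUE)
}

#' Prevalence after discounting catalytically inactive classes
#'
#' Re-ranks tetramer abundance after removing classes assumed to have no
#' signaling output -- by default the three complexes with two BmpR1
#' receptors, the scenario in which BmpR1 carries little kinase activity
#' relative to Acvr1.
#'
#' @param screen A `"bmp_screen"`.
#' @param inactive Character vector of class labels to discount.
#' @return A tibble as [prevalence_summary()], over the active classes.
#' @export
kinase_discounted_prevalence <- function(screen,
                                         inactive = bmpr1_homomeric_classes(screen)) {
  classes <- screen_classes(screen)
  bad <- setdiff(inactive, classes)
  if (length(bad) > 0) {
    stop("unknown class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  active <- setdiff(classes, inactive)
  if (length(active) == 0) stop("all tetramer classes are inactive", call. = FALSE)
  ok <- screen_ok(screen)
  x <- as.matrix(screen[ok, active, drop = FALSE])
  top <- max.col(x, ties.method = "first")
  wins <- table(factor(active[top], levels = active))
  out <- tibble::tibble(class = active, n_wins = as.integer(wins),
                        fraction = as.integer(wins) / sum(ok))
  out$percent <- 100 * out$fraction
  attr(out, "n_points") <- sum(ok)
  attr(out, "inactive") <- inactive
  out
}

#' Shipped scenario configurations
#'
#' Named receptor/ligand configurations used across the scenario analyses:
#' `equimolar` (all receptors 10 nM), `excess-acvr1` (8-fold Acvr1 excess
#' over BmpR1: 5/40/10 nM), `het-only` (Bmp2/7 alone, 9-fold Acvr1 excess,
#' 10 nM type II), and two sensor settings used for dynamic-range
#' examples (`sensor-equimolar`, `sensor-bmpr1-limited`).
#'
#' @return A named list; each element has `receptors` (named nM vector),
#'   `gamma`, and `ligands` (`NULL` = all three dimers).
#' @export
#' @examples
#' names(bmp_scenarios())
bmp_scenarios <- function() {
  list(
    "equimolar" = list(
      receptors = c(BmpR1 = 10, Acvr1 = 10, TypeII = 10),
      gamma = 100, ligands = NULL),
    "excess-acvr1" = list(
      receptors = c(BmpR1 = 1, Acvr1 = 8, TypeII = 10),
      gamma = 50, ligands = NULL),
    "het-only" = list(
      receptors = c(BmpR1 = 5, Acvr1 = 45, TypeII = 10),
      gamma = 100, ligands = "Bmp2/7"),
    "sensor-equimolar" = list(
      receptors = c(BmpR1 = 10, Acvr1 = 10, TypeII = 10),
      gamma = 100, ligands = NULL),
    "sensor-bmpr1-limited" = list(
      receptors = c(BmpR1 = 2, Acvr1 = 40, TypeII = 10),
      gamma = 100, ligands = NULL)
  )
}

#' Tetramer abundance as a function of ligand concentration
#'
#' Sweeps a shared ligand-dimer total over a grid at fixed receptor
#' totals and returns the steady-state concentration of every tetramer
#' class at each level. Used for the scenario analyses (excess type-I
#' receptor, antagonist-quelled homodimers) and as the input to the
#' dynamic-range sensor metric.
#'
#' @param network A `"bmp_network"`.
#' @param receptors Named vector of receptor totals (nM).
#' @param ligand_grid Increasing vector of ligand totals (nM) applied to
#'   each included dimer.
#' @param gamma Surface enhancement factor.
#' @param ligands Dimers to include (`NULL` = all in the network); the
#'   rest are held at zero, emulating homodimers quelled by antagonists.
#' @param scenario Alternatively, the name of a [bmp_scenarios()] entry
#'   supplying `receptors`, `gamma`, and `ligands`.
#' @param ligand_mode `"conserved"` treats the ligand values as closed
#'   totals shared with the bound pool; `"clamped"` holds the *free*
#'   ligand concentration fixed at each grid value (an open morphogen
#'   reservoir), which is the regime of the receptor-sensitivity and
#'   sensor analyses.
#' @return A tibble of class `"bmp_response_curve"`, long format:
#'   `ligand`, `class`, `concentration` (nM).
#' @export
#' @examples
#' net <- build_network()
#' sw <- scenario_sweep(net, scenario = "excess-acvr1",
#'                      ligand_grid = c(0.1, 0.5, 1))
#' head(sw)
scenario_sweep <- function(network, receptors = NULL,
                           ligand_grid = 10^seq(-3, 0, length.out = 31),
                           gamma = 100, ligands = NULL, scenario = NULL,
                           ligand_mode = c("conserved", "clamped")) {
  ligand_mode <- match.arg(ligand_mode)
  stopifnot(inherits(network, "bmp_network"))
  if (!is.null(scenario)) {
    cfg <- bmp_scenarios()[[scenario]]
    if (is.null(cfg)) stop("unknown scenario: ", scenario, call. = FALSE)
    receptors <- receptors %||% cfg$receptors
    gamma <- cfg$gamma
    ligands <- cfg$ligands
  }
  stopifnot(!is.null(receptors), all(ligand_grid >= 0),
            !is.unsorted(ligand_grid, strictly = TRUE))
  ligands <- ligands %||% network$ligand_names
  stopifnot(all(ligands %in% network$ligand_names))

  fn <- network$free_names
  totals <- matrix(0, length(ligand_grid), length(fn), dimnames = list(NULL, fn))
  for (lg in ligands) totals[, lg] <- ligand_grid
  for (r in names(receptors)) totals[, r] <- receptors[[r]]
  sol <- eq_solve_batch(network, totals, rep(gamma, length(ligand_grid)),
                        clamped = if (ligand_mode == "clamped") ligands)
  tet <- !is.na(network$species$tetramer_class)
  TC <- t(rowsum(t(sol$conc[, tet, drop = FALSE]),
                 network$species$tetramer_class[tet]))
  out <- tibble::as_tibble(as.data.frame(TC, check.names = FALSE))
  out$ligand <- ligand_grid
  out <- tidyr::pivot_longer(out, -"ligand", names_to = "class",
                             values_to = "concentration")
  out <- dplyr::arrange(out, .data$class, .data$ligand)
  structure(out,
            class = c("bmp_response_curve", class(out)),
            network = network, receptors = receptors, gamma = gamma,
            ligands = ligands, ligand_mode = ligand_mode,
            converged = all(sol$converged))
}

#' Weakest Acvr1 affinity preserving heterodimer-heterotetramer prevalence
#'
#' Rebuilds the network with the heterodimer-Acvr1 dissociation constant
#' set to `kd` on the Bmp7 face and `kd_ratio * kd` on the Bmp2 face
#' (preserving the published 2:1 face ratio) and asks whether the
#' heterodimer-heterotetramer is the most abundant tetramer class at the
#' given ligand level. Bisects for the weakest (largest) `kd` in
#' `kd_range` that still satisfies the criterion.
#'
#' @param network A `"bmp_network"` built from the default declarations.
#' @param receptors Named receptor totals (nM).
#' @param gamma Surface enhancement factor.
#' @param ligand Shared ligand-dimer total (nM); the published scan uses
#'   0.1 nM.
#' @param kd_range Search interval for the Bmp7-face K_D (nM).
#' @param kd_ratio Bmp2-face K_D as a multiple of the Bmp7-face value.
#' @param tol Bisection tolerance (nM).
#' @return The weakest qualifying K_D (nM), `NA` if none in range
#'   qualifies, or the upper range end (with attribute `censored = TRUE`)
#'   if even that qualifies.
#' @export
#' @examples
#' net <- build_network()
#' critical_affinity_search(net, c(BmpR1 = 2, Acvr1 = 40, TypeII = 10),
#'                          gamma = 10)
critical_affinity_search <- function(network, receptors, gamma = 100,
                                     ligand = 0.1, kd_range = c(10, 500),
                                     kd_ratio = 2, tol = 0.5) {
  stopifnot(inherits(network, "bmp_network"), length(kd_range) == 2,
            kd_range[1] > 0, kd_range[2] > kd_range[1])
  if (!("Acvr1" %in% names(receptors)) || receptors[["Acvr1"]] <= 0) {
    return(NA_real_)  # the heterotetramer cannot form without Acvr1
  }
  hh_wins <- function(kd) {
    net2 <- set_het_acvr1(network, kd, kd_ratio)
    sw <- scenario_sweep(net2, receptors, ligand_grid = ligand, gamma = gamma)
    top <- sw$class[which.max(sw$concentration)]
    max(sw$concentration) > 0 && grepl("^Bmp2/7-Acvr1-BmpR1", top)
  }
  if (!hh_wins(kd_range[1])) return(NA_real_)
  if (hh_wins(kd_range[2])) {
    return(structure(kd_range[2], censored = TRUE))
  }
  lo <- kd_range[1]; hi <- kd_range[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (hh_wins(mid)) lo <- mid else hi <- mid
  }
  lo
}

# Rebuild a default-model network with heterodimer-specific Acvr1 K_Ds.
set_het_acvr1 <- function(network, kd, kd_ratio = 2) {
  aff <- network$affinities
  aff <- aff[!(aff$face %in% c("Bmp2/7:Bmp2", "Bmp2/7:Bmp7") &
                 aff$receptor == "Acvr1"), , drop = FALSE]
  aff <- dplyr::bind_rows(aff, tibble::tibble(
    face = c("Bmp2/7:Bmp7", "Bmp2/7:Bmp2"), receptor = "Acvr1",
    kd = c(kd, kd_ratio * kd),
    enabled = c(TRUE, any(aff$enabled[aff$face == "Bmp2" & aff$receptor == "Acvr1"]))
  ))
  build_network(network$ligands, network$receptors, aff,
                network$kinetics, network$options)
}
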