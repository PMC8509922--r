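#' Export network species and reaction tables
#'
#' Writes `species.csv` (one row per oligomer: id, ligand, bonds,
#' microstate count, statistical weight, receptor counts, tetramer class)
#' and `reactions.csv` (one row per bidirectional reaction with
#' multiplicities and the effective single-bond K_D) into `dir`.
#'
#' @param network A `"bmp_network"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_network_tables <- function(network, dir) {
  stopifnot(inherits(network, "bmp_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- network$species
  tab <- dplyr::bind_cols(
    sp[, c("id", "ligand", "bonds", "n_micro", "weight", "tetramer_class")],
    tibble::as_tibble(as.data.frame(network$stoich[, network$receptor_names,
                                                   drop = FALSE],
                                    check.names = FALSE))
  )
  p1 <- file.path(dir, "species.csv")
  p2 <- file.path(dir, "reactions.csv")
  utils::write.csv(tab, p1, row.names = FALSE)
  utils::write.csv(network$reactions, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Export the network as SBML
#'
#' Writes an SBML Level 3 Version 1 document: every free and bound
#' species, and every reversible mass-action reaction with its `kon`
#' (including the gamma surface enhancement where applicable) and `koff`
#' as local parameters and a `kon*A*B - koff*C` kinetic law.
#'
#' @param network A `"bmp_network"`.
#' @param path Output file.
#' @param gamma Surface enhancement factor baked into the surface
#'   association rates.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(network, path, gamma = network$kinetics$gamma) {
  stopifnot(inherits(network, "bmp_network"), gamma >= 1)
  kon_ref <- network$kinetics$kon_ref
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1"
  )
  model <- xml2::xml_add_child(doc, "model", id = "bmp_oligomerization",
                               substanceUnits = "nanomole")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "membrane", size = "1",
                      constant = "true")
  sid <- function(x) {
    x <- gsub("[^A-Za-z0-9]", "_", x)
    paste0("s_", x)
  }
  species <- xml2::xml_add_child(model, "listOfSpecies")
  for (nm in c(network$free_names, network$species$id)) {
    xml2::xml_add_child(species, "species", id = sid(nm), name = nm,
                        compartment = "membrane", initialConcentration = "0",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  rxns <- xml2::xml_add_child(model, "listOfReactions")
  rx <- network$reactions
  for (i in seq_len(nrow(rx))) {
    kon <- rx$m_assoc[i] * kon_ref * if (rx$surface[i]) gamma else 1
    koff <- rx$m_diss[i] * kon_ref * rx$kd_eff[i]
    r <- xml2::xml_add_child(rxns, "reaction", id = sprintf("r_%03d", i),
                             reversible = "true", fast = "false")
    lr <- xml2::xml_add_child(r, "listOfReactants")
    xml2::xml_add_child(lr, "speciesReference", species = sid(rx$reactant[i]),
                        stoichiometry = "1", constant = "true")
    xml2::xml_add_child(lr, "speciesReference", species = sid(rx$receptor[i]),
                        stoichiometry = "1", constant = "true")
    lp <- xml2::xml_add_child(r, "listOfProducts")
    xml2::xml_add_child(lp, "speciesReference", species = sid(rx$product[i]),
                        stoichiometry = "1", constant = "true")
    kl <- xml2::xml_add_child(r, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "minus")
    t1 <- xml2::xml_add_child(ap, "apply")
    xml2::xml_add_child(t1, "times")
    xml2::xml_add_child(t1, "ci", "kon")
    xml2::xml_add_child(t1, "ci", sid(rx$reactant[i]))
    xml2::xml_add_child(t1, "ci", sid(rx$receptor[i]))
    t2 <- xml2::xml_add_child(ap, "apply")
    xml2::xml_add_child(t2, "times")
    xml2::xml_add_child(t2, "ci", "koff")
    xml2::xml_add_child(t2, "ci", sid(rx$product[i]))
    lpars <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lpars, "localParameter", id = "kon",
                        value = format(kon, digits = 15))
    xml2::xml_add_child(lpars, "localParameter", id = "koff",
                        value = format(koff, digits = 15))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write screen results and summary
#'
#' `write_screen_csv()` stores the full per-point table at full double
#' precision; `write_screen_summary()` writes a JSON report with
#' prevalence, both predominance definitions, and the kinase-discounted
#' prevalence, percentages rounded to two decimals.
#'
#' @param screen A `"bmp_screen"`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_screen_csv <- function(screen, path) {
  utils::write.csv(as.data.frame(screen), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_csv
#' @export
write_screen_summary <- function(screen, path) {
  prev <- prevalence_summary(screen)
  disc <- kinase_discounted_prevalence(screen)
  hh_prev <- prev$percent[grepl("^Bmp2/7-Acvr1-BmpR1", prev$class)]
  summary <- list(
    n_points = attr(prev, "n_points"),
    n_ties = attr(prev, "n_ties"),
    prevalence_percent = stats::setNames(as.list(round(prev$percent, 2)),
                                         prev$class),
    predominance_percent = list(
      "homodimer-ligand" = round(predominance_summary(
        screen, "homodimer-ligand")$percent, 2),
      "homomeric-receptor" = round(predominance_summary(
        screen, "homomeric-receptor")$percent, 2)
    ),
    kinase_discounted_percent = stats::setNames(as.list(round(disc$percent, 2)),
                                                disc$class),
    heterodimer_heterotetramer_percent = round(hh_prev, 2)
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read and write run configurations
#'
#' A run configuration is a YAML file capturing everything needed to
#' rebuild a network and re-run a screen or scenario: affinity convention
#' switches, kinetics, grid specification, scenario name and output
#' settings. Writing the configuration next to a run's outputs makes the
#' run reproducible; `read_run_config(write_run_config(cfg, f))`
#' round-trips exactly.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: the configuration as a named list with
#'   class `"bmp_run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "bmp_run_config")
}

#' @rdname read_run_config
#' @param config A named list (coerced to class `"bmp_run_config"`).
#' @return `write_run_config()`: invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Default run configuration
#'
#' @param ... Overrides merged over the defaults.
#' @return A `"bmp_run_config"` list.
#' @export
#' @examples
#' default_run_config(gamma = c(10, 100))
default_run_config <- function(...) {
  cfg <- list(
    het_typeii = "shared",
    acvr1_bmp2 = TRUE,
    acvr1_bmp2_kd = 1024,
    merge_sites = "class",
    site_kinetics = "microstate",
    kon_ref = 1e-3,
    ligand = 10^seq(-2, 0, length.out = 5),
    bmpr1 = seq(1, 50, length.out = 15),
    acvr1 = seq(1, 50, length.out = 15),
    typeii = seq(1, 50, length.out = 15),
    gamma = c(10, 50, 100, 500, 1000),
    seed = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "bmp_run_config")
}

#' Build a network from a run configuration
#'
#' @param config A `"bmp_run_config"` (or plain list with the same keys).
#' @return A `"bmp_network"`.
#' @export
network_from_config <- function(config) {
  build_network(
    affinities = bmp_affinities(
      acvr1_bmp2 = config$acvr1_bmp2 %||% TRUE,
      acvr1_bmp2_kd = config$acvr1_bmp2_kd %||% 1024,
      het_typeii = config$het_typeii %||% "shared"
    ),
    kinetics = kinetics_config(kon_ref = config$kon_ref %||% 1e-3),
    options = network_options(
      merge_sites = config$merge_sites %||% "class",
      site_kinetics = config$site_kinetics %||% "microstate"
    )
  )
}

#' Grid specification from a run configuration
#'
#' @param config A `"bmp_run_config"`.
#' @return A [grid_spec()].
#' @export
grid_from_config <- function(config) {
  grid_spec(ligand = config$ligand, bmpr1 = config$bmpr1,
            acvr1 = config$acvr1, typeii = config$typeii,
            gamma = config$gamma %||% c(10, 50, 100, 500, 1000))
}

#' Write a steady state in long CSV form
#'
#' One row per (parameter set, species) with the totals, gamma and the
#' species concentration -- the exchange format for downstream analysis.
#'
#' @param state A `"bmp_steady_state"`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_steady_state <- function(state, path) {
  long <- generics::tidy(state)
  utils::write.csv(as.data.frame(long), path, row.names = FALSE)
  invisible(path)
}
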