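#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a reaction network
#'
#' @param x A `"bmp_network"`.
#' @param what `"species"` for the oligomer table or `"reactions"` for
#'   the reaction table.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bmp_network
#' @export
tidy.bmp_network <- function(x, what = c("species", "reactions"), ...) {
  what <- match.arg(what)
  if (what == "reactions") return(tibble::as_tibble(x$reactions))
  sp <- x$species[, c("id", "ligand", "bonds", "n_micro", "weight",
                      "tetramer_class")]
  dplyr::bind_cols(sp, tibble::as_tibble(as.data.frame(
    x$stoich[, x$receptor_names, drop = FALSE], check.names = FALSE)))
}

#' @rdname tidy.bmp_network
#' @method glance bmp_network
#' @export
glance.bmp_network <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$species),
    n_reactions = nrow(x$reactions),
    n_tetramer_classes = length(tetramer_classes(x)),
    n_ligands = length(x$ligand_names),
    n_receptors = length(x$receptor_names),
    merge_sites = x$options$merge_sites,
    site_kinetics = x$options$site_kinetics
  )
}

#' Tidy a steady state into long format
#'
#' @param x A `"bmp_steady_state"`.
#' @param ... Unused.
#' @return A tibble with one row per (parameter set, species):
#'   `.row`, `species`, `type` (`"free"` or `"complex"`),
#'   `concentration` (nM).
#' @method tidy bmp_steady_state
#' @export
tidy.bmp_steady_state <- function(x, ...) {
  net <- attr(x, "network")
  free_cols <- grep("^free_", names(x), value = TRUE)
  sp_cols <- if (!is.null(net)) intersect(net$species$id, names(x)) else
    setdiff(names(x), c(grep("^total_|^free_|^\\.", names(x), value = TRUE), "gamma"))
  df <- tibble::as_tibble(x)
  df$.row <- seq_len(nrow(df))
  long_free <- tidyr::pivot_longer(df[, c(".row", free_cols)], -".row",
                                   names_to = "species",
                                   values_to = "concentration")
  long_free$species <- sub("^free_", "", long_free$species)
  long_free$type <- "free"
  long_sp <- tidyr::pivot_longer(df[, c(".row", sp_cols)], -".row",
                                 names_to = "species",
                                 values_to = "concentration")
  long_sp$type <- "complex"
  out <- dplyr::bind_rows(long_free, long_sp)
  out[, c(".row", "species", "type", "concentration")]
}

#' @rdname tidy.bmp_steady_state
#' @method glance bmp_steady_state
#' @export
glance.bmp_steady_state <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    n_converged = sum(x$.converged),
    max_residual = max(x$.residual)
  )
}

#' Tidy a prevalence screen into long format
#'
#' @param x A `"bmp_screen"`.
#' @param ... Unused.
#' @return A tibble with one row per (grid point, tetramer class).
#' @method tidy bmp_screen
#' @export
tidy.bmp_screen <- function(x, ...) {
  classes <- screen_classes(x)
  df <- tibble::as_tibble(x)
  df$.point <- seq_len(nrow(df))
  tidyr::pivot_longer(
    df[, c(".point", "ligand", "BmpR1", "Acvr1", "TypeII", "gamma", classes)],
    dplyr::all_of(classes), names_to = "class", values_to = "concentration"
  )
}

#' @rdname tidy.bmp_screen
#' @method glance bmp_screen
#' @export
glance.bmp_screen <- function(x, ...) {
  prev <- prevalence_summary(x)
  hh <- grepl("^Bmp2/7-Acvr1-BmpR1", prev$class)
  tibble::tibble(
    n_points = nrow(x),
    n_converged = sum(screen_ok(x)),
    n_ties = attr(prev, "n_ties"),
    top_class = prev$class[which.max(prev$fraction)],
    top_percent = max(prev$percent),
    het_het_percent = prev$percent[hh],
    predominance_percent = predominance_summary(x)$percent
  )
}

#' @rdname dr_winner_summary
#' @param x A `"bmp_dr_screen"`.
#' @param ... Unused.
#' @method glance bmp_dr_screen
#' @export
glance.bmp_dr_screen <- function(x, ...) {
  ws <- dr_winner_summary(x)
  pw <- dr_pairwise_summary(x)
  hh <- grepl("^Bmp2/7-Acvr1-BmpR1", ws$class)
  tibble::tibble(
    n_points = attr(x, "n_points"),
    het_het_winner_percent = ws$percent[hh],
    het_het_vs_bmpr1_percent = pw$vs_best_bmpr1$percent,
    saturation_highest_fraction = pw$saturation_highest
  )
}
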