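#' Build a BMP ligand-receptor oligomerization network
#'
#' Enumerates every reachable partially- and fully-occupied ligand-receptor
#' complex and every single-bond reversible association reaction between
#' them, from a declarative site model: each ligand dimer exposes binding
#' sites of a class (type-I or type-II) on a monomer face, each receptor
#' belongs to a class, and the affinity table assigns a per-site
#' dissociation constant to every enabled (face, receptor) pair.
#'
#' Species are lumped according to the enumeration convention in `options`
#' (see [network_options()]). Under the default class-multiset convention
#' with all six face/receptor pairs enabled, the three-dimer model contains
#' 51 ligand-receptor oligomer species connected by 90 bidirectional
#' reactions. Each lumped species carries a statistical weight `W` such
#' that its equilibrium concentration is
#' `W * gamma^(bonds-1) * [L] * prod([R]_i)`; the weight aggregates its
#' constituent face-resolved microstates, so detailed balance holds by
#' construction and every thermodynamic cycle closes exactly.
#'
#' @param ligands Ligand table from [bmp_ligands()] or [toy_ligand()].
#' @param receptors Receptor table, as [bmp_receptors()].
#' @param affinities Affinity table, as [bmp_affinities()].
#' @param kinetics Kinetic configuration from [kinetics_config()].
#' @param options Enumeration convention from [network_options()].
#' @return An object of class `"bmp_network"`: a list with the input
#'   declarations plus `species` (one row per bound oligomer: `id`,
#'   `ligand`, `bonds`, `n_micro`, `log_weight`, receptor-count columns,
#'   `tetramer_class`), `reactions` (one row per bidirectional reaction:
#'   `reactant`, `receptor`, `product`, multiplicities, effective site
#'   `kd_eff`, `surface` flag), and a species-by-free-species
#'   stoichiometry matrix.
#' @export
#' @examples
#' net <- build_network()
#' nrow(net$species)    # 51 oligomers
#' nrow(net$reactions)  # 90 reversible reactions
build_network <- function(ligands = bmp_ligands(), receptors = bmp_receptors(),
                          affinities = bmp_affinities(),
                          kinetics = kinetics_config(),
                          options = network_options()) {
  stopifnot(is.data.frame(receptors), is.data.frame(affinities))
  if (!inherits(kinetics, "bmp_kinetics")) stop("`kinetics` must come from kinetics_config()", call. = FALSE)
  if (!inherits(options, "bmp_network_options")) stop("`options` must come from network_options()", call. = FALSE)
  if (is.null(ligands)) ligands <- bmp_ligands()[0, ]
  if (nrow(receptors) > 0 && anyDuplicated(receptors$name)) {
    stop("duplicate receptor names", call. = FALSE)
  }
  validate_affinities(ligands, receptors, affinities)

  per_ligand <- purrr::map(seq_len(nrow(ligands)), function(i) {
    enumerate_ligand(ligands$name[i], ligands$sites[[i]], receptors, affinities, options)
  })

  species <- dplyr::bind_rows(purrr::map(per_ligand, "species"))
  edges <- dplyr::bind_rows(purrr::map(per_ligand, "edges"))

  rec_names <- sort_c(receptors$name)
  lig_names <- sort_c(ligands$name)
  free_names <- c(lig_names, rec_names)

  if (nrow(species) > 0) {
    species <- species[order_c(species$id), , drop = FALSE]
    # receptor count columns, zero-filled for receptors a ligand never binds
    counts <- matrix(0L, nrow(species), length(rec_names),
                     dimnames = list(species$id, rec_names))
    for (r in rec_names) {
      counts[, r] <- purrr::map_int(species$occupancy, ~ sum(.x == r))
    }
    stoich <- cbind(
      matrix(as.integer(outer(species$ligand, lig_names, "==")),
             nrow(species), dimnames = list(species$id, lig_names)),
      counts
    )
  } else {
    stoich <- matrix(0L, 0, length(free_names), dimnames = list(NULL, free_names))
  }

  if (nrow(edges) > 0) {
    edges <- edges[order_c(paste(edges$reactant, edges$receptor, edges$product)), , drop = FALSE]
    edges <- finalize_reactions(edges, species)
  }

  structure(
    list(
      ligands = ligands, receptors = receptors, affinities = affinities,
      kinetics = kinetics, options = options,
      species = species, reactions = edges, stoich = stoich,
      free_names = free_names, ligand_names = lig_names, receptor_names = rec_names
    ),
    class = "bmp_network"
  )
}

validate_affinities <- function(ligands, receptors, affinities) {
  need <- c("face", "receptor", "kd", "enabled")
  if (!all(need %in% names(affinities))) {
    stop("affinity table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  en <- affinities[affinities$enabled, , drop = FALSE]
  if (any(!is.finite(en$kd)) || any(en$kd <= 0)) {
    stop("every enabled affinity needs a finite K_D > 0", call. = FALSE)
  }
  if (nrow(en) > 0 && nrow(receptors) > 0) {
    unknown <- setdiff(en$receptor, receptors$name)
    if (length(unknown) > 0) {
      stop("affinity table references unknown receptor(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  # every (face, class-compatible receptor) pair that could bind must be declared
  for (i in seq_len(nrow(ligands))) {
    sites <- ligands$sites[[i]]
    for (j in seq_len(nrow(sites))) {
      compat <- receptors$name[receptors$class == sites$class[j]]
      for (r in compat) {
        hit <- (affinities$face == sites$face[j] |
                  affinities$face == paste0(ligands$name[i], ":", sites$face[j])) &
          affinities$receptor == r
        if (!any(hit)) {
          stop("no affinity entry for face '", sites$face[j], "' and receptor '",
               r, "'; add a row (enabled = FALSE to forbid binding)", call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}

# Enumerate the face-resolved occupancy microstates of one ligand and lump
# them into species under the chosen convention.
enumerate_ligand <- function(lig, sites, receptors, affinities, options) {
  n_sites <- nrow(sites)
  # ligand-qualified affinity rows ("<ligand>:<face>") shadow plain entries
  aff_row <- function(face, r) {
    hit <- which(affinities$face == paste0(lig, ":", face) & affinities$receptor == r)
    if (length(hit) == 0) hit <- which(affinities$face == face & affinities$receptor == r)
    hit[1]
  }
  allowed <- purrr::map(seq_len(n_sites), function(j) {
    ok <- receptors$name[receptors$class == sites$class[j]]
    keep <- purrr::map_lgl(ok, function(r) {
      i <- aff_row(sites$face[j], r)
      !is.na(i) && affinities$enabled[i]
    })
    sort_c(ok[keep])
  })
  kd_of <- function(face, r) affinities$kd[aff_row(face, r)]

  occ <- expand.grid(purrr::map(allowed, ~ c("-", .x)),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(occ) <- sites$site
  occ <- as.matrix(occ)
  n_micro <- nrow(occ)

  w_micro <- vapply(seq_len(n_micro), function(m) {
    b <- occ[m, ] != "-"
    if (!any(b)) return(1)
    prod(1 / vapply(which(b), function(j) kd_of(sites$face[j], occ[m, j]), 0))
  }, 0)

  keys <- species_keys(lig, occ, sites, options)

  grp <- split(seq_len(n_micro), keys$key)
  sp <- purrr::map(names(grp), function(k) {
    rows <- grp[[k]]
    first <- rows[1]
    filled <- occ[first, ] != "-"
    occupants <- occ[first, ][filled]
    by_class <- split(unname(occ[first, ][filled]), sites$class[filled])
    tibble::tibble(
      id = keys$id[first], ligand = lig,
      bonds = sum(filled),
      n_micro = length(rows),
      weight = sum(w_micro[rows]),
      occupancy = list(unname(occupants)),
      occ_by_class = list(by_class),
      tetramer_class = tetramer_label(lig, occ[first, ], sites)
    )
  })
  sp <- dplyr::bind_rows(sp)

  if (options$merge_sites == "class" && options$site_kinetics == "ordered") {
    sp$weight <- ordered_weights(sp, sites, kd_of)
  }

  # microstate transitions -> lumped reaction classes
  edges <- list()
  for (m in seq_len(n_micro)) {
    for (j in seq_len(n_sites)) {
      if (occ[m, j] != "-") next
      for (r in allowed[[j]]) {
        to <- occ[m, ]
        to[j] <- r
        key_to <- species_keys(lig, matrix(to, 1, dimnames = list(NULL, sites$site)),
                               sites, options)
        edges[[length(edges) + 1]] <- tibble::tibble(
          from_key = keys$key[m], from_id = keys$id[m],
          receptor = r, to_key = key_to$key, to_id = key_to$id,
          from_bonds = sum(occ[m, ] != "-")
        )
      }
    }
  }
  edges <- dplyr::bind_rows(edges)
  if (nrow(edges) > 0) {
    edges <- dplyr::summarise(
      dplyr::group_by(edges, .data$from_id, .data$receptor, .data$to_id),
      n_trans = dplyr::n(), surface = .data$from_bonds[1] >= 1L, .groups = "drop"
    )
    edges <- dplyr::rename(edges, reactant = "from_id", product = "to_id")
  }

  # the empty state is the free ligand, not an oligomer species
  empty_id <- sp$id[sp$bonds == 0]
  sp_bound <- sp[sp$bonds > 0, , drop = FALSE]
  sp_bound$log_weight <- log(sp_bound$weight)
  list(
    species = sp_bound,
    edges = edges,
    lookup = sp[, c("id", "n_micro", "weight", "bonds")],
    empty_id = empty_id
  )
}

# Species identity under the enumeration convention. Returns, per
# microstate, the lumping key and a printable canonical id.
species_keys <- function(lig, occ, sites, options) {
  n <- nrow(occ)
  mode <- options$merge_sites
  if (mode == "class") {
    classes <- sort_c(unique(sites$class))
    parts <- vapply(seq_len(n), function(m) {
      paste(vapply(classes, function(cl) {
        slots <- occ[m, sites$class == cl]
        filled <- sort_c(slots[slots != "-"])
        paste(c(filled, rep("-", sum(slots == "-"))), collapse = ",")
      }, ""), collapse = ")(")
    }, "")
    id <- ifelse(rowSums(occ != "-") == 0, lig, paste0(lig, "(", parts, ")"))
    return(list(key = id, id = id))
  }
  if (mode == "symmetry") {
    occ_c <- occ
    if (symmetric_dimer(sites)) {
      rot <- rotation_perm(sites)
      for (m in seq_len(n)) {
        a <- paste(occ[m, ], collapse = ",")
        b <- paste(occ[m, rot], collapse = ",")
        if (b < a) occ_c[m, ] <- occ[m, rot]
      }
    }
    occ <- occ_c
  }
  strs <- apply(occ, 1, paste, collapse = ",")
  id <- ifelse(rowSums(occ != "-") == 0, lig, paste0(lig, "[", strs, "]"))
  list(key = id, id = id)
}

symmetric_dimer <- function(sites) {
  nrow(sites) == 4 && all(sites$site == c("I1", "I2", "II1", "II2")) &&
    sites$face[1] == sites$face[2] && sites$face[3] == sites$face[4]
}

rotation_perm <- function(sites) c(2L, 1L, 4L, 3L)

# Ordered-binding weights: each receptor type occupies its strongest
# available face first, with the full equivalent-pair microstate count.
ordered_weights <- function(sp, sites, kd_of) {
  classes <- sort_c(unique(sites$class))
  vapply(seq_len(nrow(sp)), function(i) {
    if (sp$bonds[i] == 0) return(1)
    w <- sp$n_micro[i]
    for (cl in classes) {
      faces <- sites$face[sites$class == cl]
      occ_cl <- sp$occ_by_class[[i]][[cl]]
      if (is.null(occ_cl) || length(occ_cl) == 0) next
      for (r in unique(occ_cl)) {
        k <- sum(occ_cl == r)
        kds <- sort(vapply(faces, function(f) kd_of(f, r), 0))
        w <- w / prod(kds[seq_len(k)])
      }
    }
    w
  }, 0)
}

tetramer_label <- function(lig, occ_row, sites) {
  if (nrow(sites) != 4 || any(occ_row == "-")) return(NA_character_)
  if (!identical(sort_c(unique(sites$class)), c("type-I", "type-II"))) return(NA_character_)
  part <- function(cl) {
    x <- sort_c(occ_row[sites$class == cl])
    if (x[1] == x[2]) paste0("(", x[1], ")2") else paste(x, collapse = "-")
  }
  paste(lig, part("type-I"), part("type-II"), sep = "-")
}

# Attach multiplicities and the effective single-bond K_D to each lumped
# reaction, using microstate counts and lumped weights so that detailed
# balance holds exactly: kon/koff = gamma^surface * W_to / W_from.
finalize_reactions <- function(edges, species) {
  look <- tibble::tibble(id = species$id, n_micro = species$n_micro,
                         weight = species$weight)
  wt <- function(ids) {
    w <- look$weight[match(ids, look$id)]
    w[is.na(w)] <- 1  # free ligand reference state
    w
  }
  nm <- function(ids) {
    n <- look$n_micro[match(ids, look$id)]
    n[is.na(n)] <- 1L
    n
  }
  edges$m_assoc <- edges$n_trans / nm(edges$reactant)
  edges$m_diss <- edges$n_trans / nm(edges$product)
  edges$kd_eff <- (edges$m_assoc / edges$m_diss) * wt(edges$reactant) / wt(edges$product)
  edges[, c("reactant", "receptor", "product", "n_trans", "m_assoc",
            "m_diss", "kd_eff", "surface")]
}

#' Mass-action rates from a dissociation constant
#'
#' Converts a per-site dissociation constant into forward and reverse
#' mass-action rate constants: `koff = kd * kon_ref` and
#' `kon = multiplicity * kon_ref * gamma^surface`, so that the effective
#' per-site K_D of a surface recruitment step is `kd / gamma`.
#'
#' @param kd Dissociation constant in nM; must be > 0.
#' @param kinetics Kinetic configuration from [kinetics_config()].
#' @param surface Logical; is this association confined to the membrane
#'   surface (every recruitment step after initial ligand capture)?
#' @param multiplicity Statistical factor: number of equivalent empty
#'   sites the receptor can associate to.
#' @param gamma Surface enhancement factor; defaults to the value stored
#'   in `kinetics`.
#' @return A named list with `kon` (/nM/s) and `koff` (/s).
#' @export
#' @examples
#' rates_from_affinity(0.8, kinetics_config())
#' rates_from_affinity(0.8, kinetics_config(), surface = TRUE, gamma = 100)
rates_from_affinity <- function(kd, kinetics = kinetics_config(), surface = FALSE,
                                multiplicity = 1, gamma = kinetics$gamma) {
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd <= 0)) {
    stop("`kd` must be a positive finite dissociation constant (nM)", call. = FALSE)
  }
  stopifnot(gamma >= 1, multiplicity >= 1)
  list(kon = multiplicity * kinetics$kon_ref * ifelse(surface, gamma, 1),
       koff = kd * kinetics$kon_ref)
}

#' Classify fully assembled tetramer species
#'
#' Maps species ids to one of the nine tetramer classes
#' (ligand dimer x type-I receptor pair, with two type-II receptors), or
#' `NA` for partially assembled complexes.
#'
#' @param network A `"bmp_network"`.
#' @param ids Character vector of species ids; defaults to all species.
#' @return Character vector of class labels (`NA` where not a tetramer).
#' @export
#' @examples
#' net <- build_network()
#' table(classify_tetramer(net))
classify_tetramer <- function(network, ids = network$species$id) {
  stopifnot(inherits(network, "bmp_network"))
  network$species$tetramer_class[match(ids, network$species$id)]
}

#' The tetramer classes of a network
#'
#' @param network A `"bmp_network"`.
#' @return Sorted character vector of distinct fully-assembled tetramer
#'   class labels (nine for the default model).
#' @export
tetramer_classes <- function(network) {
  stopifnot(inherits(network, "bmp_network"))
  sort_c(unique(stats::na.omit(network$species$tetramer_class)))
}

#' Exhaustive search over enumeration conventions
#'
#' Rebuilds the default network under every combination of site-lumping
#' rule and Bmp2-face Acvr1 enablement, reporting species and reaction
#' counts for each. The convention reproducing the target counts (51
#' oligomer species, 90 bidirectional reactions for the full model) is
#' flagged; with the default targets that is class-multiset lumping with
#' Acvr1/Bmp2-face binding enabled.
#'
#' @param target_species,target_reactions Counts a convention must
#'   reproduce to be flagged as a match.
#' @param quiet Suppress the per-convention log.
#' @return A tibble with one row per convention (`merge_sites`,
#'   `acvr1_bmp2`, `n_species`, `n_reactions`, `match`), with the matching
#'   convention(s) first.
#' @export
#' @examples
#' convention_search(quiet = TRUE)
convention_search <- function(target_species = 51, target_reactions = 90,
                              quiet = FALSE) {
  grid <- expand.grid(merge_sites = c("class", "symmetry", "none"),
                      acvr1_bmp2 = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  res <- purrr::map(seq_len(nrow(grid)), function(i) {
    net <- build_network(
      affinities = bmp_affinities(acvr1_bmp2 = grid$acvr1_bmp2[i]),
      options = network_options(merge_sites = grid$merge_sites[i])
    )
    tibble::tibble(
      merge_sites = grid$merge_sites[i], acvr1_bmp2 = grid$acvr1_bmp2[i],
      n_species = nrow(net$species), n_reactions = nrow(net$reactions)
    )
  })
  res <- dplyr::bind_rows(res)
  res$match <- res$n_species == target_species & res$n_reactions == target_reactions
  res <- res[order(!res$match), , drop = FALSE]
  if (!quiet) {
    for (i in seq_len(nrow(res))) {
      message(sprintf("convention merge_sites=%-8s acvr1_bmp2=%-5s -> %3d species / %3d reactions%s",
                      res$merge_sites[i], res$acvr1_bmp2[i], res$n_species[i],
                      res$n_reactions[i], if (res$match[i]) "  [match]" else ""))
    }
  }
  res
}

#' @export
print.bmp_network <- function(x, ...) {
  cat("<bmp_network> ", nrow(x$species), " oligomer species, ",
      nrow(x$reactions), " reversible reactions\n", sep = "")
  cat("  ligands:   ", paste(x$ligand_names, collapse = ", "), "\n", sep = "")
  cat("  receptors: ", paste(x$receptor_names, collapse = ", "), "\n", sep = "")
  cat("  convention: merge_sites=", x$options$merge_sites,
      ", site_kinetics=", x$options$site_kinetics, "\n", sep = "")
  invisible(x)
}

# locale-independent ordering helpers
sort_c <- function(x) x[order_c(x)]
order_c <- function(x) order(x, method = "radix")
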