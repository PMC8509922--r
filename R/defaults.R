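#' Default BMP ligand dimers
#'
#' The three zebrafish dorsoventral-patterning ligand dimers: the Bmp2 and
#' Bmp7 homodimers and the Bmp2/7 heterodimer. Every dimer carries four
#' receptor binding sites -- two type-I and two type-II -- one of each class
#' contributed by each monomer subunit ("face"). Homodimers therefore have
#' two equivalent sites per class, while the heterodimer has a Bmp2-derived
#' and a Bmp7-derived site in each class.
#'
#' @param names Character vector of dimers to include (subset of
#'   `"Bmp2/2"`, `"Bmp7/7"`, `"Bmp2/7"`).
#' @return A tibble with columns `name`, `face1`, `face2` and a `sites`
#'   list-column (one tibble of binding sites per dimer).
#' @seealso [bmp_receptors()], [bmp_affinities()], [build_network()]
#' @export
#' @examples
#' bmp_ligands()
#' bmp_ligands("Bmp2/7")
bmp_ligands <- function(names = c("Bmp2/2", "Bmp7/7", "Bmp2/7")) {
  all <- tibble::tibble(
    name  = c("Bmp2/2", "Bmp7/7", "Bmp2/7"),
    face1 = c("Bmp2", "Bmp7", "Bmp2"),
    face2 = c("Bmp2", "Bmp7", "Bmp7")
  )
  bad <- setdiff(names, all$name)
  if (length(bad) > 0) {
    stop("unknown ligand dimer(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- all[match(names, all$name), , drop = FALSE]
  out$sites <- purrr::map2(out$face1, out$face2, dimer_sites)
  out
}

# The canonical four-site layout of a BMP dimer: one type-I and one type-II
# binding epitope per monomer face.
dimer_sites <- function(face1, face2) {
  tibble::tibble(
    site  = c("I1", "I2", "II1", "II2"),
    class = c("type-I", "type-I", "type-II", "type-II"),
    face  = c(face1, face2, face1, face2)
  )
}

#' Construct a custom ligand table
#'
#' Builds a one-ligand table with an arbitrary site layout, for reduced or
#' toy models (e.g. a single-site Langmuir ligand). Sites must declare a
#' `class` (matched against receptor classes) and a `face` (matched against
#' affinity-table rows).
#'
#' @param name Ligand identifier.
#' @param sites A data frame with columns `site`, `class`, `face`.
#' @return A one-row ligand tibble compatible with [build_network()].
#' @export
#' @examples
#' toy_ligand("L", tibble::tibble(site = "s1", class = "type-I", face = "L"))
toy_ligand <- function(name, sites) {
  stopifnot(is.data.frame(sites), all(c("site", "class", "face") %in% names(sites)))
  if (anyDuplicated(sites$site)) stop("site ids must be unique", call. = FALSE)
  tibble::tibble(
    name = name,
    face1 = sites$face[1],
    face2 = sites$face[min(2L, nrow(sites))],
    sites = list(tibble::as_tibble(sites))
  )
}

#' Default BMP receptor types
#'
#' BmpR1 (Alk3/6) and Acvr1 (Alk2/8) are the two type-I receptors; the
#' type-II receptors are pooled into a single species.
#'
#' @return A tibble with columns `name` and `class`.
#' @export
#' @examples
#' bmp_receptors()
bmp_receptors <- function() {
  tibble::tibble(
    name  = c("BmpR1", "Acvr1", "TypeII"),
    class = c("type-I", "type-I", "type-II")
  )
}

#' Default per-site dissociation constants
#'
#' Surface-plasmon-resonance-supported affinities of each monomer face for
#' each receptor, in nM. Bmp2 binds BmpR1 with high affinity (0.8 nM) and
#' type-II receptors with low affinity (47 nM); Bmp7 shows the mirrored
#' pattern (56 nM for BmpR1, 6.4 nM for type-II) and binds Acvr1 very weakly
#' (512 nM). Acvr1 binding through a Bmp2 face is weaker still; it is
#' modeled at 1024 nM and can be disabled outright with
#' `acvr1_bmp2 = FALSE`, in which case tetramers that need an Acvr1 on a
#' Bmp2 face cannot form. The heterodimer is assumed to bind receptors with
#' the same per-face rates as the corresponding homodimers.
#'
#' Rows may also be qualified to a single ligand context by prefixing the
#' face with the ligand name (`"Bmp2/7:Bmp2"`); qualified rows take
#' precedence over the plain face entry when that ligand's sites are
#' resolved. The `het_typeii` argument uses this mechanism: the structural
#' reading (`"per-face"`) gives the heterodimer one 47 nM and one 6.4 nM
#' type-II site, while the shipped default (`"shared"`) assigns the high
#' 6.4 nM affinity to both of its type-II sites, treating them as a shared
#' effective site pair.
#'
#' @param acvr1_bmp2 Logical; allow Acvr1 to bind Bmp2 faces (default TRUE).
#' @param acvr1_bmp2_kd Dissociation constant (nM) for the Bmp2-face/Acvr1
#'   interaction when enabled.
#' @param het_typeii `"shared"` (both heterodimer type-II sites at 6.4 nM,
#'   the default) or `"per-face"` (6.4 and 47 nM following the monomer
#'   composition of each site).
#' @return A tibble with columns `face`, `receptor`, `kd` (nM), `enabled`.
#' @export
#' @examples
#' bmp_affinities()
#' bmp_affinities(acvr1_bmp2 = FALSE, het_typeii = "per-face")
bmp_affinities <- function(acvr1_bmp2 = TRUE, acvr1_bmp2_kd = 1024,
                           het_typeii = c("shared", "per-face")) {
  stopifnot(is.numeric(acvr1_bmp2_kd), acvr1_bmp2_kd > 0)
  het_typeii <- match.arg(het_typeii)
  out <- tibble::tibble(
    face     = c("Bmp2", "Bmp2", "Bmp2", "Bmp7", "Bmp7", "Bmp7"),
    receptor = c("BmpR1", "TypeII", "Acvr1", "BmpR1", "TypeII", "Acvr1"),
    kd       = c(0.8, 47, acvr1_bmp2_kd, 56, 6.4, 512),
    enabled  = c(TRUE, TRUE, isTRUE(acvr1_bmp2), TRUE, TRUE, TRUE)
  )
  if (het_typeii == "shared") {
    out <- dplyr::bind_rows(out, tibble::tibble(
      face     = c("Bmp2/7:Bmp2", "Bmp2/7:Bmp7"),
      receptor = "TypeII",
      kd       = 6.4,
      enabled  = TRUE
    ))
  }
  out
}

#' Kinetic configuration
#'
#' Holds the reference association rate and the surface enhancement factor
#' gamma. The model's steady states are true equilibria of a closed,
#' detailed-balanced network, so they depend only on the dissociation
#' constants and gamma; `kon_ref` sets the overall time scale and cancels
#' from every equilibrium concentration (asserted by a regression test).
#' The default 1e-3 /nM/s (1e6 /M/s) is a typical protein-protein
#' association rate.
#'
#' Gamma implements a reduction-of-dimensionality correction: the first
#' ligand-capture step (a solution molecule finding a surface receptor)
#' proceeds at the solution-phase rate, while every subsequent
#' receptor-recruitment step is confined to the membrane and its
#' association rate is multiplied by gamma.
#'
#' @param kon_ref Reference association rate, /nM/s; must be > 0.
#' @param gamma Default surface enhancement factor (dimensionless, >= 1),
#'   used where a parameter set does not supply its own.
#' @param gamma_policy Which associations gamma multiplies. Only
#'   `"after-first-bond"` (all recruitment steps after initial ligand
#'   capture) is implemented.
#' @return A list of class `"bmp_kinetics"`.
#' @export
#' @examples
#' kinetics_config(gamma = 50)
kinetics_config <- function(kon_ref = 1e-3, gamma = 100,
                            gamma_policy = "after-first-bond") {
  stopifnot(is.numeric(kon_ref), length(kon_ref) == 1, kon_ref > 0,
            is.numeric(gamma), length(gamma) == 1, gamma >= 1)
  gamma_policy <- match.arg(gamma_policy)
  structure(list(kon_ref = kon_ref, gamma = gamma, gamma_policy = gamma_policy),
            class = "bmp_kinetics")
}

#' Network enumeration convention
#'
#' The bookkeeping convention used to lump microscopic site-occupancy
#' states into model species:
#'
#' * `merge_sites = "class"`: species are identified by the multiset of
#'   receptors bound within each site class ("one BmpR1 and two type-II"),
#'   regardless of which monomer face carries them. This is the shipped
#'   default; with Acvr1/Bmp2-face binding enabled it enumerates 51
#'   ligand-receptor oligomer species and 90 bidirectional reactions.
#' * `merge_sites = "symmetry"`: states are lumped only when related by the
#'   physical two-fold rotation of a homodimer; heterodimer faces stay
#'   distinguishable.
#' * `merge_sites = "none"`: fully face-resolved microstates.
#'
#' Under `"class"` merging the lumped statistical weight of a species is
#' the sum over its constituent microstates (`site_kinetics =
#' "microstate"`, exact lumping of the face-resolved equilibrium), or
#' alternatively an ordered-binding approximation in which each receptor
#' type fills its strongest available face first with full pair
#' multiplicity (`site_kinetics = "ordered"`).
#'
#' @param merge_sites Site lumping rule; see Details.
#' @param site_kinetics Weighting of lumped species under `"class"`
#'   merging.
#' @return A list of class `"bmp_network_options"`.
#' @export
#' @examples
#' network_options()
#' network_options(merge_sites = "none")
network_options <- function(merge_sites = c("class", "symmetry", "none"),
                            site_kinetics = c("microstate", "ordered")) {
  structure(list(merge_sites = match.arg(merge_sites),
                 site_kinetics = match.arg(site_kinetics)),
            class = "bmp_network_options")
}
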