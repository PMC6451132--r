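#' Interaction-energy table for a compound
#'
#' Holds per-component intermolecular interaction energies (kcal/mol) of a
#' ligand with parts of its binding pocket -- e.g. the eL42 Pro-Val-Phe
#' peptide (`PVF`), the cytosine (`Cyto`) and the guanine pair (`Gua`) of
#' the lissoclimide E-site pocket -- together with the net energy of the
#' full assembly.  The net energy is not constrained to equal the component
#' sum; the difference is the many-body (non-additivity) gap.
#'
#' @param compound Compound label.
#' @param components Named numeric vector of component energies, kcal/mol.
#' @param net Net interaction energy of the full assembly, kcal/mol.  When
#'   omitted it is derived as the component sum (and flagged as derived).
#'
#' @return A tibble of class `energy_table` with columns `compound`,
#'   `component`, `energy` and `role` (`"component"`/`"net"`); attribute
#'   `net_derived` records whether the net row was derived.
#' @examples
#' energy_table("CL", c(PVF = -18.07, Cyto = -5.17, Gua = -8.68), net = -31.49)
#' @export
energy_table <- function(compound, components, net = NULL) {
  stopifnot(is.numeric(components), !is.null(names(components)),
            all(is.finite(components)))
  derived <- is.null(net)
  if (derived) net <- sum(components)
  stopifnot(is.finite(net))
  out <- tibble::tibble(
    compound = compound,
    component = c(names(components), paste(names(components), collapse = "-")),
    energy = c(unname(components), net),
    role = c(rep("component", length(components)), "net")
  )
  attr(out, "net_derived") <- derived
  class(out) <- c("energy_table", class(out))
  out
}

#' Read an interaction-energy table from a delimited file
#'
#' Expects columns `compound`, `component`, `energy_kcal_mol`, `role`
#' (`component` or `net`), one or more compounds per file.
#'
#' @param path CSV file path.
#' @return A named list of `energy_table` objects, one per compound.
#' @examples
#' path <- system.file("extdata", "lissoclimide_interaction_energies.csv",
#'                     package = "lissofret")
#' names(read_energy_tables(path))
#' @export
read_energy_tables <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("compound", "component", "energy_kcal_mol", "role") %in% names(df)))
  split(df, df$compound) |>
    lapply(function(d) {
      comp <- d[d$role == "component", ]
      net <- d[d$role == "net", ]
      energy_table(
        compound = d$compound[1],
        components = setNames(comp$energy_kcal_mol, comp$component),
        net = if (nrow(net) == 1) net$energy_kcal_mol else NULL
      )
    })
}

#' Packaged BLYP-D3 interaction energies for the lissoclimide E-site pocket
#'
#' The per-component and net interaction energies (kcal/mol) of the reduced
#' C45 and CL pocket models: the eL42 Pro-Val-Phe peptide (`PVF`), cytosine
#' 2764 (`Cyto`) and the guanine pair 2793/2794 (`Gua`).  Values are
#' electronic interaction energies at dispersion-corrected DFT geometries
#' and exclude deformation and desolvation contributions.
#'
#' @return A named list with `energy_table` objects `C45` and `CL`.
#' @examples
#' lissoclimide_energies()$CL
#' @export
lissoclimide_energies <- function() {
  read_energy_tables(system.file("extdata",
                                 "lissoclimide_interaction_energies.csv",
                                 package = "lissofret"))
}

net_energy <- function(tab) tab$energy[tab$role == "net"][1]
component_energies <- function(tab) {
  comp <- tab[tab$role == "component", ]
  setNames(comp$energy, comp$component)
}

#' Compare two interaction-energy tables
#'
#' Component-wise differences, signed net difference, and each table's
#' additivity gap (net minus component sum, capturing many-body effects).
#' The net difference is reported as `a` minus `b` (so swapping the
#' arguments negates all signed differences).
#'
#' @param a,b `energy_table` objects with identical component keys.
#'
#' @return A list with `per_component` (tibble: `component`, `energy_a`,
#'   `energy_b`, `difference`), `net_difference` (signed, kcal/mol),
#'   `net_abs_difference`, `additivity_gap_a`, `additivity_gap_b`.
#' @examples
#' e <- lissoclimide_energies()
#' compare_energy_tables(e$CL, e$C45)$net_abs_difference
#' @export
compare_energy_tables <- function(a, b) {
  stopifnot(inherits(a, "energy_table"), inherits(b, "energy_table"))
  ca <- component_energies(a)
  cb <- component_energies(b)
  if (!setequal(names(ca), names(cb))) {
    stop("component keys differ: ",
         paste(union(setdiff(names(ca), names(cb)),
                     setdiff(names(cb), names(ca))), collapse = ", "),
         call. = FALSE)
  }
  cb <- cb[names(ca)]
  na <- net_energy(a)
  nb <- net_energy(b)
  list(
    per_component = tibble::tibble(
      component = names(ca),
      energy_a = unname(ca),
      energy_b = unname(cb),
      difference = unname(ca - cb)
    ),
    net_difference = na - nb,
    net_abs_difference = abs(na - nb),
    additivity_gap_a = na - sum(ca),
    additivity_gap_b = nb - sum(cb)
  )
}
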