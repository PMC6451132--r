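two_letter_elements <- c("CL", "BR", "MG", "MN", "FE", "ZN", "SE")

infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", atom_name)))
  two <- substr(nm, 1, 2)
  ifelse(two %in% two_letter_elements, two, substr(nm, 1, 1))
}

nucleobase_residues <- c("A", "G", "C", "U", "T", "DA", "DG", "DC", "DT",
                         "ADE", "GUA", "CYT", "URA", "THY")
purine_residues <- c("A", "G", "DA", "DG", "ADE", "GUA")

ring_atom_names <- function(residue_name, ring = c("six", "five", "fused")) {
  ring <- match.arg(ring)
  if (toupper(residue_name) %in% purine_residues) {
    switch(ring,
      six = c("N1", "C2", "N3", "C4", "C5", "C6"),
      five = c("C4", "C5", "N7", "C8", "N9"),
      fused = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"))
  } else if (toupper(residue_name) %in% nucleobase_residues) {
    c("N1", "C2", "N3", "C4", "C5", "C6")
  } else if (toupper(residue_name) %in% c("PHE", "TYR")) {
    c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  } else if (toupper(residue_name) == "TRP") {
    c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  } else if (toupper(residue_name) == "HIS") {
    c("CG", "ND1", "CD2", "CE1", "NE2")
  } else {
    NULL
  }
}

#' Load a macromolecular structure as an atom table
#'
#' Reads PDB or mmCIF coordinates (first model only) into a tidy atom
#' table.  Alternate locations are resolved to the highest-occupancy
#' conformer; missing element symbols are inferred from atom names
#' (two-letter halogens and common metals recognized).  Unrecognized
#' residue or atom naming is kept as-is.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#'
#' @return A tibble of class `structure_atoms` with columns `chain`,
#'   `residue_name`, `resno`, `atom_name`, `element`, `x`, `y`, `z`,
#'   `occupancy`.
#' @examples
#' pocket <- synthetic_esite_pocket()
#' f <- tempfile(fileext = ".pdb")
#' write_structure(pocket, f)
#' nrow(read_structure(f))
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- if (format == "cif") {
    bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
  } else {
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE, rm.alt = FALSE)
  }
  at <- pdb$atom
  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  element[missing_el] <- infer_element(at$elety[missing_el])
  out <- tibble::tibble(
    chain = at$chain,
    residue_name = at$resid,
    resno = at$resno,
    atom_name = at$elety,
    element = toupper(element),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt)
  )
  out <- out |>
    dplyr::group_by(.data$chain, .data$resno, .data$residue_name,
                    .data$atom_name) |>
    dplyr::slice_max(.data$occupancy, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"altloc") |>
    dplyr::arrange(.data$chain, .data$resno)
  attr(out, "source") <- path
  class(out) <- c("structure_atoms", class(out))
  out
}

#' Write an atom table to a PDB file
#'
#' @param atoms A `structure_atoms` tibble (or any tibble with the same
#'   columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = atoms$resno, resid = atoms$residue_name,
    chain = ifelse(is.na(atoms$chain), " ", atoms$chain),
    elety = atoms$atom_name, o = atoms$occupancy,
    elesy = atoms$element
  )
  invisible(path)
}

select_residue <- function(atoms, selector) {
  if (is.list(selector) && !is.data.frame(selector)) {
    out <- atoms
    if (!is.null(selector$chain)) out <- dplyr::filter(out, .data$chain == selector$chain)
    if (!is.null(selector$resno)) out <- dplyr::filter(out, .data$resno %in% selector$resno)
    if (!is.null(selector$residue_name)) {
      out <- dplyr::filter(out, .data$residue_name == selector$residue_name)
    }
    out
  } else {
    dplyr::filter(atoms, .data$residue_name == selector)
  }
}

#' Centroid and normal of an aromatic ring
#'
#' The centroid is the mean of the ring-atom coordinates; the normal is the
#' unit eigenvector of the smallest principal moment of the centered ring
#' atoms (the least-squares plane normal).  Sign convention: the normal is
#' flipped so that its largest-magnitude component is positive.
#'
#' @param atoms A `structure_atoms` tibble.
#' @param chain,resno Residue identifying the ring.
#' @param ring `"six"` (default: the six-membered ring, for purines),
#'   `"five"`, or `"fused"` (all fused-ring atoms).
#'
#' @return A list with `centroid` (length-3) and `normal` (unit length-3).
#' @examples
#' pocket <- synthetic_esite_pocket()
#' ring_centroid_normal(pocket, chain = "A", resno = 2794)
#' @export
ring_centroid_normal <- function(atoms, chain, resno,
                                 ring = c("six", "five", "fused")) {
  ring <- match.arg(ring)
  res <- dplyr::filter(atoms, .data$chain == !!chain, .data$resno == !!resno)
  if (nrow(res) == 0) stop("no atoms for ", chain, ":", resno, call. = FALSE)
  names_needed <- ring_atom_names(res$residue_name[1], ring)
  if (is.null(names_needed)) {
    stop("residue ", res$residue_name[1], " has no defined aromatic ring", call. = FALSE)
  }
  sel <- res[match(names_needed, res$atom_name), ]
  if (anyNA(sel$atom_name)) {
    missing <- names_needed[is.na(match(names_needed, res$atom_name))]
    stop("missing ring atom(s) ", paste(missing, collapse = ", "),
         " in ", chain, ":", resno, call. = FALSE)
  }
  xyz <- as.matrix(sel[, c("x", "y", "z")])
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  normal <- svd(centered)$v[, 3]
  i <- which.max(abs(normal))
  if (normal[i] < 0) normal <- -normal
  list(centroid = centroid, normal = normal)
}

#' Detect halogen-pi contacts between a ligand and aromatic rings
#'
#' Screens every (ligand halogen, aromatic ring) pair; a contact is
#' reported when the halogen-to-ring-centroid distance is at most
#' `max_distance`.  The face angle is the angle between the
#' halogen-centroid vector and the ring normal (0 = directly above the
#' ring face); contacts with face angle at most `max_face_angle` are
#' labelled face-on.  Rings are the nucleobases by default; aromatic
#' protein side chains can be included.
#'
#' @param atoms A `structure_atoms` tibble.
#' @param ligand Ligand selector: a residue name, or
#'   `list(chain =, resno =)`.
#' @param halogens Element symbols treated as halogens.
#' @param max_distance Centroid distance cutoff, Angstrom (default 4.5).
#' @param max_face_angle Face-on angle threshold, degrees (default 40).
#' @param ring Ring choice passed to [ring_centroid_normal()].
#' @param include_protein Also scan PHE/TYR/TRP/HIS side-chain rings.
#'
#' @return A tibble sorted by distance with the halogen and ring
#'   identities, `distance` (Angstrom), `angle` (degrees, in `[0, 90]`) and
#'   `face_on`.
#' @examples
#' pocket <- synthetic_esite_pocket()
#' find_halogen_pi(pocket, ligand = "C45")
#' @export
find_halogen_pi <- function(atoms, ligand, halogens = c("CL", "BR", "I", "F"),
                            max_distance = 4.5, max_face_angle = 40,
                            ring = c("six", "five", "fused"),
                            include_protein = FALSE) {
  ring <- match.arg(ring)
  lig <- select_residue(atoms, ligand)
  hal <- dplyr::filter(lig, .data$element %in% toupper(halogens))
  empty <- tibble::tibble(
    halogen_atom = character(), halogen_resno = integer(),
    ring_chain = character(), ring_residue = character(),
    ring_resno = integer(), ring = character(),
    distance = numeric(), angle = numeric(), face_on = logical()
  )
  if (nrow(hal) == 0) {
    warning("ligand contains no halogen atoms", call. = FALSE)
    return(empty)
  }
  aromatic_set <- nucleobase_residues
  if (include_protein) aromatic_set <- c(aromatic_set, "PHE", "TYR", "TRP", "HIS")
  lig_key <- paste(lig$chain, lig$resno)
  rings <- atoms |>
    dplyr::filter(toupper(.data$residue_name) %in% aromatic_set,
                  !(paste(.data$chain, .data$resno) %in% lig_key)) |>
    dplyr::distinct(.data$chain, .data$residue_name, .data$resno)
  out <- purrr::pmap_dfr(rings, function(chain, residue_name, resno) {
    use_ring <- if (!(toupper(residue_name) %in% purine_residues) &&
                    !(toupper(residue_name) %in% c("TRP"))) "six" else ring
    cn <- tryCatch(ring_centroid_normal(atoms, chain, resno, use_ring),
                   error = function(e) NULL)
    if (is.null(cn)) return(NULL)
    v <- as.matrix(hal[, c("x", "y", "z")]) -
      matrix(cn$centroid, nrow(hal), 3, byrow = TRUE)
    d <- sqrt(rowSums(v^2))
    cosang <- abs(v %*% cn$normal) / pmax(d, 1e-12)
    ang <- acos(pmin(pmax(cosang, 0), 1)) * 180 / pi
    tibble::tibble(
      halogen_atom = hal$atom_name, halogen_resno = hal$resno,
      ring_chain = chain, ring_residue = residue_name,
      ring_resno = resno, ring = use_ring,
      distance = d, angle = as.numeric(ang),
      face_on = as.numeric(ang) <= max_face_angle
    )
  })
  if (is.null(out) || nrow(out) == 0) return(empty)
  out |>
    dplyr::filter(.data$distance <= max_distance) |>
    dplyr::arrange(.data$distance)
}

#' Detect polar (hydrogen-bond-like) contacts of a ligand
#'
#' Heavy-atom distance screen between ligand halogens/oxygens and N/O
#' partner atoms of other residues; hydrogens are not required.  Contact
#' classes: `Cl...base` (ligand halogen to a nucleobase atom), `O...H-N`
#' (ligand oxygen to nitrogen) and `O...H-O` (ligand oxygen to oxygen).
#'
#' @inheritParams find_halogen_pi
#' @param max_distance Heavy-atom distance cutoff, Angstrom (default 3.6).
#'
#' @return A tibble sorted by distance with ligand and partner atom
#'   identities, `distance` and `class`.
#' @examples
#' pocket <- synthetic_esite_pocket()
#' find_polar_contacts(pocket, ligand = "C45")
#' @export
find_polar_contacts <- function(atoms, ligand, max_distance = 3.6,
                                halogens = c("CL", "BR", "I", "F")) {
  lig <- select_residue(atoms, ligand)
  donors <- dplyr::filter(lig, .data$element %in% c(toupper(halogens), "O"))
  lig_key <- paste(lig$chain, lig$resno)
  partners <- atoms |>
    dplyr::filter(.data$element %in% c("N", "O"),
                  !(paste(.data$chain, .data$resno) %in% lig_key))
  if (nrow(donors) == 0 || nrow(partners) == 0) {
    return(tibble::tibble(
      ligand_atom = character(), partner_chain = character(),
      partner_residue = character(), partner_resno = integer(),
      partner_atom = character(), distance = numeric(), class = character()
    ))
  }
  dm <- as.matrix(donors[, c("x", "y", "z")])
  pm <- as.matrix(partners[, c("x", "y", "z")])
  dist2 <- outer(rowSums(dm^2), rowSums(pm^2), "+") - 2 * dm %*% t(pm)
  hits <- which(dist2 <= max_distance^2, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      ligand_atom = character(), partner_chain = character(),
      partner_residue = character(), partner_resno = integer(),
      partner_atom = character(), distance = numeric(), class = character()
    ))
  }
  i <- hits[, 1]; j <- hits[, 2]
  halogen_donor <- donors$element[i] %in% toupper(halogens)
  base_partner <- toupper(partners$residue_name[j]) %in% nucleobase_residues
  cls <- dplyr::case_when(
    halogen_donor & base_partner ~ "Cl...base",
    halogen_donor ~ "Cl...X",
    partners$element[j] == "N" ~ "O...H-N",
    TRUE ~ "O...H-O"
  )
  tibble::tibble(
    ligand_atom = donors$atom_name[i],
    partner_chain = partners$chain[j],
    partner_residue = partners$residue_name[j],
    partner_resno = partners$resno[j],
    partner_atom = partners$atom_name[j],
    distance = sqrt(pmax(dist2[hits], 0)),
    class = cls
  ) |>
    dplyr::arrange(.data$distance)
}

#' Least-squares rigid superposition (Kabsch) and RMSD
#'
#' Optimal rotation via the SVD of the covariance of the paired, centered
#' coordinate sets, with the reflection guard on the determinant; returns
#' the minimized RMSD and the rigid transform mapping `coords_a` onto
#' `coords_b` (`a %*% t(rotation) + translation`).
#'
#' @param coords_a,coords_b Paired n x 3 coordinate matrices (or tibbles
#'   with `x`, `y`, `z`), n >= 3, not collinear.
#'
#' @return A list of class `superposition` with `rmsd` (Angstrom),
#'   `rotation` (3 x 3) and `translation` (length 3).
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' superpose_rmsd(a, a)$rmsd
#' @export
superpose_rmsd <- function(coords_a, coords_b) {
  a <- if (is.data.frame(coords_a)) as.matrix(coords_a[, c("x", "y", "z")]) else as.matrix(coords_a)
  b <- if (is.data.frame(coords_b)) as.matrix(coords_b[, c("x", "y", "z")]) else as.matrix(coords_b)
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3, ncol(b) == 3)
  if (nrow(a) < 3) stop("at least 3 paired points are required", call. = FALSE)
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  if (qr(ac)$rank < 2) stop("degenerate (collinear) coordinate set", call. = FALSE)
  h <- t(ac) %*% bc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- ac %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - bc)^2)))
  translation <- cb - as.numeric(rot %*% ca)
  structure(list(rmsd = rmsd, rotation = rot, translation = translation),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD = %.4f Angstrom\n", x$rmsd))
  invisible(x)
}

#' E-site contact report for a bound ligand
#'
#' Convenience wrapper measuring, in one call, the halogen-pi contacts of
#' the ligand's chlorines to nucleobase ring centroids and its polar
#' contacts, as used to characterize lissoclimide binding in the large
#' subunit E-site.  Works on any loaded structure; point it at a deposited
#' ribosome-inhibitor model (e.g. the 6HHQ mmCIF) to measure the published
#' pocket, or at [synthetic_esite_pocket()] for a self-contained example.
#'
#' @param structure A `structure_atoms` tibble or a path to a PDB/mmCIF
#'   file.
#' @param ligand Ligand selector (see [find_halogen_pi()]).
#' @param ... Passed to [find_halogen_pi()].
#'
#' @return A list with tibbles `halogen_pi` and `polar`.
#' @examples
#' measure_esite_contacts(synthetic_esite_pocket(), ligand = "C45")
#' @export
measure_esite_contacts <- function(structure, ligand, ...) {
  atoms <- if (is.character(structure)) read_structure(structure) else structure
  list(
    halogen_pi = find_halogen_pi(atoms, ligand, ...),
    polar = find_polar_contacts(atoms, ligand)
  )
}
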