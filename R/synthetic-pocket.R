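# Idealized planar ring coordinates, used to build the synthetic pocket.
# Hexagon vertices in ring order, bond length 1.39 A, in the xy-plane.
hexagon_ring <- function(atom_names, radius = 1.39) {
  ang <- seq(0, by = pi / 3, length.out = 6)
  tibble::tibble(
    atom_name = atom_names,
    x = radius * cos(ang), y = radius * sin(ang), z = 0
  )
}

# Regular pentagon sharing the edge (p1, p2), built on the far side from
# the hexagon center; returns the three new vertices in ring order.
pentagon_completion <- function(p1, p2, new_names) {
  s <- sqrt(sum((p2 - p1)^2))
  rp <- s / (2 * sin(pi / 5))          # circumradius
  ap <- rp * cos(pi / 5)               # apothem
  mid <- (p1 + p2) / 2
  u <- mid / sqrt(sum(mid^2))          # outward from hexagon center (origin)
  center <- mid + ap * u
  th1 <- atan2(p2[2] - center[2], p2[1] - center[1])
  th2 <- atan2(p1[2] - center[2], p1[1] - center[1])
  # step direction that walks from p2 around to p1 the long way
  step <- 2 * pi / 5 * sign(sin(th2 - th1))
  purrr::map_dfr(seq_along(new_names), function(k) {
    th <- th1 + step * k
    tibble::tibble(atom_name = new_names[k],
                   x = center[1] + rp * cos(th),
                   y = center[2] + rp * sin(th), z = 0)
  })
}

rigid_place <- function(df, rotation = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rotation)
  df$x <- xyz[, 1] + shift[1]
  df$y <- xyz[, 2] + shift[2]
  df$z <- xyz[, 3] + shift[3]
  df
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

rot_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
}

guanine_atoms <- function(chain, resno, rotation = diag(3), shift = c(0, 0, 0)) {
  hex <- hexagon_ring(c("C4", "C5", "C6", "N1", "C2", "N3"))
  p1 <- unlist(hex[hex$atom_name == "C4", c("x", "y", "z")])
  p2 <- unlist(hex[hex$atom_name == "C5", c("x", "y", "z")])
  five <- pentagon_completion(p1[1:2], p2[1:2], c("N7", "C8", "N9"))
  five$z <- 0
  atoms <- dplyr::bind_rows(hex, five)
  atoms <- rigid_place(atoms, rotation, shift)
  tibble::tibble(
    chain = chain, residue_name = "G", resno = as.integer(resno),
    atom_name = atoms$atom_name,
    element = substr(atoms$atom_name, 1, 1),
    x = atoms$x, y = atoms$y, z = atoms$z, occupancy = 1
  )
}

cytosine_atoms <- function(chain, resno, rotation = diag(3), shift = c(0, 0, 0)) {
  hex <- hexagon_ring(c("N1", "C2", "N3", "C4", "C5", "C6"))
  # exocyclic amine N4 bonded to C4, radially outward at 1.34 A
  c4 <- unlist(hex[hex$atom_name == "C4", c("x", "y")])
  n4_dir <- c4 / sqrt(sum(c4^2))
  hex <- dplyr::bind_rows(hex, tibble::tibble(
    atom_name = "N4", x = c4[1] + 1.34 * n4_dir[1],
    y = c4[2] + 1.34 * n4_dir[2], z = 0
  ))
  atoms <- rigid_place(hex, rotation, shift)
  tibble::tibble(
    chain = chain, residue_name = "C", resno = as.integer(resno),
    atom_name = atoms$atom_name,
    element = substr(atoms$atom_name, 1, 1),
    x = atoms$x, y = atoms$y, z = atoms$z, occupancy = 1
  )
}

#' Synthetic E-site pocket with a dichlorinated ligand
#'
#' Constructs, entirely in code, a minimal synthetic stand-in for the
#' lissoclimide binding pocket: two stacked guanines (numbered 2793 and
#' 2794 after their 25S rRNA counterparts), a cytosine (2764), and a
#' reduced two-chlorine ligand (residue name `C45`).  Each chlorine sits
#' 3.4 Angstrom from a guanine six-membered-ring centroid along the ring
#' normal (ideal face-on halogen-pi geometry) and the C2-chlorine is
#' additionally placed 3.2 Angstrom from the cytosine N4.  This object is
#' synthetic -- built from idealized ring geometry, not from any deposited
#' model -- and exists so the contact-detection machinery can be exercised
#' and demonstrated without coordinate downloads.
#'
#' @return A `structure_atoms` tibble.
#' @examples
#' pocket <- synthetic_esite_pocket()
#' find_halogen_pi(pocket, ligand = "C45")
#' @export
synthetic_esite_pocket <- function() {
  g2794 <- guanine_atoms("A", 2794)
  # neighbouring guanine: 35 degree helical twist, 3.4 A rise, lateral slide
  # large enough that each chlorine contacts only its own ring
  # shifted away from the G2794 imidazole ring so each chlorine sees one ring
  g2793 <- guanine_atoms("A", 2793, rotation = rot_z(35), shift = c(-4.5, -2.0, -3.4))

  cn94 <- ring_centroid_normal(g2794, "A", 2794, "six")
  cn93 <- ring_centroid_normal(g2793, "A", 2793, "six")
  # normals point along +z (sign convention); chlorines sit on the ligand side
  cl2 <- unname(cn94$centroid + 3.4 * cn94$normal)
  cl3 <- unname(cn93$centroid + 3.4 * cn93$normal)

  # cytosine placed so its N4 lies 3.2 A from the C2 chlorine, amine
  # pointing at the chlorine so the ring body stays clear of the pocket
  n4_target <- unname(cl2 + 3.2 * c(1, 0, 1) / sqrt(2))
  cyt0 <- cytosine_atoms("A", 2764, rotation = rot_y(-45))
  n4_now <- unlist(cyt0[cyt0$atom_name == "N4", c("x", "y", "z")])
  cyt <- cytosine_atoms("A", 2764, rotation = rot_y(-45),
                        shift = unname(n4_target - n4_now))

  ligand <- tibble::tibble(
    chain = "L", residue_name = "C45", resno = 1L,
    atom_name = c("CL2", "CL3", "C2", "C3", "C1", "O7"),
    element = c("CL", "CL", "C", "C", "C", "O"),
    x = c(cl2[1], cl3[1], cl2[1] + 1.2, cl3[1] + 1.2, cl2[1] + 1.9, cl2[1] - 2.6),
    y = c(cl2[2], cl3[2], cl2[2] + 1.2, cl3[2] + 1.2, cl2[2] + 2.2, cl2[2] - 3.4),
    z = c(cl2[3], cl3[3], cl2[3] + 0.4, cl3[3] - 0.4, cl2[3] + 0.9, cl2[3] + 1.4),
    occupancy = 1
  )

  out <- dplyr::bind_rows(g2793, g2794, cyt, ligand)
  attr(out, "source") <- "synthetic (idealized ring geometry; not a deposited model)"
  class(out) <- c("structure_atoms", class(out))
  out
}
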