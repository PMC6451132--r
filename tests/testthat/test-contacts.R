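hexagon_atoms <- function(radius = 1, chain = "A", resno = 1L) {
  ang <- seq(0, by = pi / 3, length.out = 6)
  tibble::tibble(
    chain = chain, residue_name = "C", resno = resno,
    atom_name = c("N1", "C2", "N3", "C4", "C5", "C6"),
    element = c("N", "C", "N", "C", "C", "C"),
    x = radius * cos(ang), y = radius * sin(ang), z = 0, occupancy = 1
  )
}

test_that("a planar hexagon has its centroid at the center and a z normal", {
  hx <- hexagon_atoms()
  cn <- ring_centroid_normal(hx, "A", 1)
  expect_equal(cn$centroid, c(x = 0, y = 0, z = 0), tolerance = 1e-12)
  expect_equal(abs(cn$normal[3]), 1, tolerance = 1e-12)
})

test_that("centroid and normal are rigid-motion equivariant", {
  set.seed(101)
  hx <- hexagon_atoms()
  for (i in 1:5) {
    rot <- random_rotation()
    shift <- rnorm(3, 0, 10)
    cn0 <- ring_centroid_normal(hx, "A", 1)
    cn1 <- ring_centroid_normal(rotate_atoms(hx, rot, shift), "A", 1)
    expect_equal(unname(cn1$centroid),
                 as.numeric(rot %*% cn0$centroid + shift), tolerance = 1e-9)
    expect_equal(abs(sum(cn1$normal * (rot %*% cn0$normal))), 1,
                 tolerance = 1e-9)
  }
})

test_that("the normal of a puckered ring stays near the mean plane", {
  set.seed(202)
  tilts <- numeric(10)
  for (i in 1:10) {
    hx <- hexagon_atoms(radius = 1.39)
    hx$z <- rnorm(6, 0, 0.1)
    cn <- ring_centroid_normal(hx, "A", 1)
    tilts[i] <- acos(abs(cn$normal[3])) * 180 / pi
    # least-squares plane oracle via linear regression z ~ x + y
    fit <- lm(z ~ x + y, data = hx)
    n_lm <- c(-coef(fit)[2], -coef(fit)[3], 1)
    n_lm <- n_lm / sqrt(sum(n_lm^2))
    ang_lm <- acos(min(1, abs(sum(cn$normal * n_lm)))) * 180 / pi
    expect_lt(ang_lm, 0.5)
  }
  # 0.1 A of out-of-plane noise on a 1.39 A ring tilts the fitted plane by
  # a few degrees; individual draws can exceed this, the typical one not
  expect_lt(median(tilts), 5)
})

test_that("missing ring atoms are reported by name", {
  hx <- hexagon_atoms()[-2, ]
  expect_error(ring_centroid_normal(hx, "A", 1), "C2")
})

test_that("constructed face-on and edge-on chlorines are classified", {
  pocket <- synthetic_esite_pocket()
  hits <- find_halogen_pi(pocket, ligand = "C45")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$distance, c(3.4, 3.4), tolerance = 1e-9)
  expect_equal(hits$angle, c(0, 0), tolerance = 1e-6)
  expect_true(all(hits$face_on))
  expect_setequal(hits$ring_resno, c(2793, 2794))

  # an in-plane chlorine at the same distance is edge-on, not face-on
  hx <- hexagon_atoms(radius = 1.39, resno = 10L)
  hx$residue_name <- "G"
  hx$atom_name <- c("C4", "C5", "C6", "N1", "C2", "N3")
  lig <- tibble::tibble(chain = "L", residue_name = "LIG", resno = 1L,
                        atom_name = "CL1", element = "CL",
                        x = 3.4, y = 0, z = 0, occupancy = 1)
  got <- find_halogen_pi(dplyr::bind_rows(hx, lig), ligand = "LIG")
  expect_equal(got$angle, 90, tolerance = 1e-6)
  expect_false(got$face_on)
})

test_that("halogen-pi detection agrees with an all-pairs brute-force scan", {
  set.seed(303)
  for (rep in 1:5) {
    pocket <- synthetic_esite_pocket()
    pocket$x <- pocket$x + rnorm(nrow(pocket), 0, 0.05)
    pocket$y <- pocket$y + rnorm(nrow(pocket), 0, 0.05)
    pocket$z <- pocket$z + rnorm(nrow(pocket), 0, 0.05)
    got <- find_halogen_pi(pocket, ligand = "C45")
    oracle <- brute_halogen_pi(pocket, "C45")
    expect_equal(nrow(got), nrow(oracle))
    expect_equal(got$distance, oracle$distance, tolerance = 1e-9)
    expect_equal(got$angle, oracle$angle, tolerance = 1e-6)
    expect_equal(got$ring_resno, oracle$ring_resno)
  }
})

test_that("polar contacts respect the distance cutoff and classes", {
  pocket <- synthetic_esite_pocket()
  pc <- find_polar_contacts(pocket, ligand = "C45")
  cl_base <- pc[pc$class == "Cl...base", ]
  expect_equal(nrow(cl_base), 1)
  expect_equal(cl_base$distance, 3.2, tolerance = 1e-9)
  expect_equal(cl_base$partner_resno, 2764)
  expect_equal(cl_base$partner_atom, "N4")

  # boundary: a partner at 3.7 A is excluded at the default 3.6 A cutoff
  base <- hexagon_atoms(resno = 5L)
  lig <- tibble::tibble(chain = "L", residue_name = "LIG", resno = 1L,
                        atom_name = "CL1", element = "CL",
                        x = 1 + 3.7, y = 0, z = 0, occupancy = 1)
  got <- find_polar_contacts(dplyr::bind_rows(base, lig), ligand = "LIG")
  expect_false(any(got$partner_atom == "N1" & got$partner_resno == 5))
})

test_that("polar contact detection matches the brute-force scan", {
  set.seed(404)
  for (rep in 1:5) {
    pocket <- synthetic_esite_pocket()
    pocket$x <- pocket$x + rnorm(nrow(pocket), 0, 0.1)
    pocket$y <- pocket$y + rnorm(nrow(pocket), 0, 0.1)
    pocket$z <- pocket$z + rnorm(nrow(pocket), 0, 0.1)
    got <- find_polar_contacts(pocket, ligand = "C45")
    oracle <- brute_polar(pocket, "C45")
    n_oracle <- if (is.null(oracle)) 0 else nrow(oracle)
    expect_equal(nrow(got), n_oracle)
    if (n_oracle > 0) {
      expect_equal(got$distance, oracle$distance, tolerance = 1e-9)
    }
  }
})

test_that("superposition of identical and rigidly moved sets is exact", {
  set.seed(505)
  a <- matrix(rnorm(30), 10, 3)
  s0 <- superpose_rmsd(a, a)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-8)
  for (i in 1:5) {
    rot <- random_rotation()
    shift <- rnorm(3, 0, 5)
    b <- a %*% t(rot) + matrix(shift, 10, 3, byrow = TRUE)
    s <- superpose_rmsd(a, b)
    expect_equal(s$rmsd, 0, tolerance = 1e-9)
    expect_equal(s$rotation, rot, tolerance = 1e-7)
  }
})

test_that("noisy-copy RMSD matches its analytic expectation", {
  set.seed(606)
  n <- 10
  sigma <- 0.1
  a <- matrix(rnorm(3 * n), n, 3)
  rms <- replicate(200, {
    b <- a + matrix(rnorm(3 * n, 0, sigma), n, 3)
    superpose_rmsd(a, b)$rmsd
  })
  # rigid superposition absorbs 6 degrees of freedom:
  # E[RMSD^2] ~ sigma^2 (3n - 6) / n
  expected <- sigma * sqrt((3 * n - 6) / n)
  expect_lt(abs(mean(rms) - expected) / expected, 0.1)
})

test_that("superposition RMSD agrees with the bio3d reference fit", {
  set.seed(707)
  a <- matrix(rnorm(36), 12, 3)
  b <- a %*% t(random_rotation()) + matrix(rnorm(36, 0, 0.2), 12, 3)
  ours <- superpose_rmsd(a, b)$rmsd
  xyz_a <- as.numeric(t(a))
  xyz_b <- as.numeric(t(b))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_b, mobile = xyz_a,
                                            fixed.inds = 1:36,
                                            mobile.inds = 1:36))
  ref <- sqrt(mean(colSums(matrix((fitted - xyz_b)^2, 3))))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("degenerate coordinate sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose_rmsd(line, line), "collinear")
  expect_error(superpose_rmsd(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "3 paired points")
})

test_that("contact geometry is invariant under global rigid motion", {
  set.seed(808)
  pocket <- synthetic_esite_pocket()
  g0 <- find_halogen_pi(pocket, "C45")
  p0 <- find_polar_contacts(pocket, "C45")
  for (i in 1:3) {
    moved <- rotate_atoms(pocket, random_rotation(), rnorm(3, 0, 20))
    g1 <- find_halogen_pi(moved, "C45")
    p1 <- find_polar_contacts(moved, "C45")
    expect_equal(g1$distance, g0$distance, tolerance = 1e-9)
    expect_equal(g1$angle, g0$angle, tolerance = 1e-6)
    expect_equal(p1$distance, p0$distance, tolerance = 1e-9)
  }
})

test_that("PDB round trips preserve coordinates to file precision", {
  pocket <- synthetic_esite_pocket()
  f <- tempfile(fileext = ".pdb")
  write_structure(pocket, f)
  back <- read_structure(f)
  expect_equal(nrow(back), nrow(pocket))
  m <- match(paste(pocket$chain, pocket$resno, pocket$atom_name),
             paste(back$chain, back$resno, back$atom_name))
  expect_false(anyNA(m))
  expect_equal(back$x[m], pocket$x, tolerance = 1e-3)
  expect_equal(back$y[m], pocket$y, tolerance = 1e-3)
  expect_equal(back$z[m], pocket$z, tolerance = 1e-3)
  unlink(f)
})

test_that("minimal hand-written PDB records parse, altlocs resolve", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N1    G A 101       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  C2    G A 101       2.500   2.000   3.000  1.00 10.00           C",
    "ATOM      3 CL1 ALIG L   1       0.000   0.000   3.400  0.40 10.00          CL",
    "ATOM      4 CL1 BLIG L   1       0.100   0.000   3.500  0.60 10.00          CL",
    "END"), f)
  atoms <- read_structure(f)
  expect_equal(nrow(atoms), 3)
  cl <- atoms[atoms$atom_name == "CL1", ]
  expect_equal(nrow(cl), 1)          # highest-occupancy altloc kept
  expect_equal(cl$z, 3.5)
  expect_equal(cl$element, "CL")
  n1 <- atoms[atoms$atom_name == "N1", ]
  expect_equal(c(n1$x, n1$y, n1$z), c(1, 2, 3))
  unlink(f)
})
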