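# Structure model: PDB round trips, hydrogen stripping, torsion geometry.

test_that("PDB round trip preserves altlocs, coordinates, occupancies and B", {
  ts <- make_toy_system(8, 0.4, occupancies = c(0.6, 0.4), seed = 2)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ts, f1)
  st <- read_pdb(f1)
  write_pdb(st, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_length(st$residues, 8L)
  multi <- Filter(function(r) length(r$conformers) > 1L, st$residues)
  expect_true(length(multi) >= 1L)
  expect_equal(vapply(multi[[1L]]$conformers, `[[`, "", "altloc"),
               c("A", "B"))
  expect_equal(vapply(multi[[1L]]$conformers, `[[`, 0, "occ"), c(0.6, 0.4))

  # coordinates survive at 3 decimals
  a0 <- ts$residues[[1L]]$conformers[[1L]]$atoms
  a1 <- st$residues[[1L]]$conformers[[1L]]$atoms
  expect_equal(atom_coords(a1), atom_coords(a0), tolerance = 1e-3)
})

test_that("ANISOU tensors round trip through PDB files", {
  st <- new_structure(list(toy_residue("ALA", aniso = TRUE)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st, f)
  expect_true(any(startsWith(readLines(f), "ANISOU")))
  st2 <- read_pdb(f)
  at <- st2$residues[[1L]]$conformers[[1L]]$atoms
  i <- match("CB", at$name)
  expect_equal(unlist(at[i, c("u11", "u22", "u33", "u12", "u13", "u23")]),
               c(u11 = 0.06, u22 = 0.04, u33 = 0.03,
                 u12 = 0.005, u13 = -0.004, u23 = 0.003))
})

test_that("malformed ATOM records raise an error naming the line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 12.00           N",
             "ATOM      2  CA  ALA A   1       x.xxx   0.000   0.000  1.00 12.00           C")
  writeLines(lines, f)
  expect_error(read_pdb(f), "line 2")
})

test_that("strip_hydrogens removes H, keeps heavy atoms, and is idempotent", {
  at <- new_atoms(c("N", "CA", "C", "O", "CB", "H", "HA", "HB1", "HB2", "HB3"),
                  c("N", "C", "C", "O", "C", "H", "H", "H", "H", "H"),
                  matrix(rnorm(30), 10L, 3L))
  st <- new_structure(list(new_residue("A", 1L, "ALA",
                                       list(new_conformer(at, "", 1)))))
  s1 <- strip_hydrogens(st)
  a1 <- s1$residues[[1L]]$conformers[[1L]]$atoms
  expect_equal(a1$name, c("N", "CA", "C", "O", "CB"))
  expect_equal(atom_coords(a1), atom_coords(at)[1:5, ])
  expect_identical(strip_hydrogens(s1), s1)
  # no hydrogens present: unchanged
  expect_identical(strip_hydrogens(strip_hydrogens(st)), s1)
})

test_that("dihedral_angle matches an independent vector-algebra oracle", {
  # planar reference cases
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  # random quadruples vs a separate projection-based formula
  oracle <- function(a, b, c_, d) {
    u <- c_ - b
    u <- u / sqrt(sum(u^2))
    p <- (a - b) - sum((a - b) * u) * u
    q <- (d - c_) - sum((d - c_) * u) * u
    s <- -sign(sum(u * c(p[2] * q[3] - p[3] * q[2],
                         p[3] * q[1] - p[1] * q[3],
                         p[1] * q[2] - p[2] * q[1])))
    ang <- acos(max(-1, min(1, sum(p * q) / sqrt(sum(p^2) * sum(q^2))))) * 180 / pi
    if (s < 0) -ang else ang
  }
  set.seed(42)
  for (k in 1:25) {
    pts <- matrix(rnorm(12), 4L, 3L)
    a <- pts[1, ]; b <- pts[2, ]; c_ <- pts[3, ]; d <- pts[4, ]
    expect_equal(dihedral_angle(a, b, c_, d), oracle(a, b, c_, d),
                 tolerance = 1e-9)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("conformer_rmsd equals the direct per-atom sum", {
  cf <- toy_residue("SER")$conformers[[1L]]
  expect_equal(conformer_rmsd(cf, cf), 0)
  shifted <- cf
  shifted$atoms$x <- shifted$atoms$x + 0.5
  expect_equal(conformer_rmsd(cf, shifted), 0.5)
  set.seed(7)
  other <- cf
  other$atoms[, c("x", "y", "z")] <-
    other$atoms[, c("x", "y", "z")] + matrix(rnorm(nrow(cf$atoms) * 3), ncol = 3)
  direct <- sqrt(sum((atom_coords(cf$atoms) - atom_coords(other$atoms))^2) /
                   nrow(cf$atoms))
  expect_equal(conformer_rmsd(cf, other), direct, tolerance = 1e-12)
  expect_error(conformer_rmsd(cf, other, character(0)), "empty")
})

test_that("set_chi is an exact rigid rotation", {
  cf <- toy_residue("TYR")$conformers[[1L]]
  cur <- multiconf:::get_chi(cf, "TYR", 1L)
  # identity rotation leaves coordinates untouched
  same <- set_chi(cf, "TYR", 1L, cur)
  expect_equal(atom_coords(same$atoms), atom_coords(cf$atoms),
               tolerance = 1e-9)
  # read-back of the requested angle
  for (target in c(-170, -65, 30, 120)) {
    rot <- set_chi(cf, "TYR", 2L, target)
    expect_equal(multiconf:::get_chi(rot, "TYR", 2L), target,
                 tolerance = 1e-6)
  }
  # +theta then -theta composes to the identity
  fwd <- set_chi(cf, "TYR", 1L, cur + 40)
  back <- set_chi(fwd, "TYR", 1L, cur)
  expect_equal(atom_coords(back$atoms), atom_coords(cf$atoms),
               tolerance = 1e-9)
  # rigid: all pairwise distances among moved atoms preserved
  moved <- which(cf$atoms$name %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"))
  d0 <- dist(atom_coords(cf$atoms)[moved, ])
  d1 <- dist(atom_coords(fwd$atoms)[moved, ])
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  expect_error(set_chi(cf, "TYR", 3L, 0), "chi3")
})
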