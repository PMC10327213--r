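# Candidate enumeration: closed-form counts, pruning, determinism.

test_that("backbone sampling yields 9 isotropic / 81 anisotropic candidates", {
  iso <- sample_backbone(toy_residue("ALA"))
  expect_length(iso$conformers, 9L)
  # the unperturbed conformer is among them
  in0 <- toy_residue("ALA")$conformers[[1L]]
  d0 <- vapply(iso$conformers, conformer_rmsd, 0, b = in0)
  expect_equal(min(d0), 0)
  # every candidate is a rigid translation bounded by the extent
  for (cf in iso$conformers) {
    delta <- atom_coords(cf$atoms) - atom_coords(in0$atoms)
    expect_lt(max(sqrt(rowSums(delta^2))), 0.3 + 1e-9)
    expect_lt(max(apply(delta, 2L, function(col) diff(range(col)))), 1e-12)
  }

  ani <- sample_backbone(toy_residue("ALA", aniso = TRUE))
  expect_length(ani$conformers, 81L)
  da <- vapply(ani$conformers, conformer_rmsd, 0, b = in0)
  expect_equal(min(da), 0)
  # all candidates distinct
  expect_equal(length(unique(round(da + vapply(ani$conformers, function(cf)
    cf$atoms$x[1L] * 1e3, 0), 9))), 81L)

  # glycine works through the pseudo-Cb fallback
  expect_length(sample_backbone(toy_residue("GLY"))$conformers, 9L)

  incomplete <- toy_residue("ALA")
  incomplete$conformers[[1L]]$atoms <-
    incomplete$conformers[[1L]]$atoms[-1L, ]
  expect_error(sample_backbone(incomplete), "skip-residue")
})

test_that("aromatic angle sampling gives 5 bends per conformer, pass-through otherwise", {
  bb <- sample_backbone(toy_residue("TYR"))
  ar <- sample_aromatic_angle(bb)
  expect_length(ar$conformers, 5L * length(bb$conformers))
  # offset 0 reproduces the parent exactly
  parent <- bb$conformers[[1L]]
  five <- ar$conformers[1:5]
  rmsds <- vapply(five, conformer_rmsd, 0, b = parent)
  expect_equal(min(rmsds), 0)
  # bend angles hit the requested offsets
  angs <- vapply(five, function(cf) {
    at <- cf$atoms
    bond_angle(multiconf:::.atom_xyz(at, "CA"), multiconf:::.atom_xyz(at, "CB"),
               multiconf:::.atom_xyz(at, "CG"))
  }, 0)
  base <- angs[rmsds == 0][1L]
  expect_setequal(round(angs - base, 4), c(-7.5, -3.75, 0, 3.75, 7.5))

  leu <- sample_backbone(toy_residue("LEU"))
  expect_identical(sample_aromatic_angle(leu), leu)
})

test_that("chi sampling enumerates means x offsets with exact torsion read-back", {
  ser <- toy_residue("SER")
  cs <- multiconf:::.new_candidate_set(ser, ser$conformers, "input")
  out <- sample_chi(cs, 1L)
  expect_length(out$conformers, 3L * 9L)       # 3 chi1 means x 9 offsets
  chis <- vapply(out$conformers, function(cf)
    multiconf:::get_chi(cf, "SER", 1L), 0)
  means <- sort(unique(rotamer_library()$SER[, 1L]))
  expected <- sort(((rep(means, each = 9L) + seq(-24, 24, 6) + 180) %% 360) - 180)
  expect_equal(sort(chis), expected, tolerance = 1e-6)

  pro <- toy_residue("PRO")
  pc <- sample_chi(multiconf:::.new_candidate_set(pro, pro$conformers, "input"), 1L)
  expect_length(pc$conformers, 2L * 9L)        # two puckers x 9 offsets

  expect_error(sample_chi(cs, 2L), "chi2")
})

test_that("pruning removes duplicates and matches a brute-force greedy filter", {
  ser <- toy_residue("SER")
  cs <- multiconf:::.new_candidate_set(ser, ser$conformers, "input")
  dup <- cs
  dup$conformers <- rep(cs$conformers, 4L)
  expect_length(prune_candidates(dup)$conformers, 1L)

  # pair at RMSD 0.005 collapses to one survivor
  near <- cs
  shifted <- cs$conformers[[1L]]
  shifted$atoms$x <- shifted$atoms$x + 0.005
  near$conformers <- list(cs$conformers[[1L]], shifted)
  expect_length(prune_candidates(near)$conformers, 1L)

  # survivors equal an O(n^2) greedy oracle on the same ordering
  many <- sample_chi(cs, 1L, params = sampling_params(chi_step = 1, chi_extent = 3))
  pruned <- prune_candidates(many)
  oracle_keep <- integer(0L)
  for (i in seq_along(many$conformers)) {
    if (all(vapply(oracle_keep, function(j)
      conformer_rmsd(many$conformers[[i]], many$conformers[[j]]) >= 0.01,
      TRUE))) oracle_keep <- c(oracle_keep, i)
  }
  survivors <- vapply(pruned$conformers, function(cf)
    multiconf:::get_chi(cf, "SER", 1L), 0)
  oracle_chis <- vapply(many$conformers[oracle_keep], function(cf)
    multiconf:::get_chi(cf, "SER", 1L), 0)
  expect_equal(survivors, oracle_chis, tolerance = 1e-9)

  # idempotent
  expect_identical(prune_candidates(pruned), pruned)
})

test_that("clashing candidates are eliminated by the hard-sphere test", {
  # fold OG onto the backbone nitrogen (a nonbonded 1-4 pair): hard clash
  ser <- toy_residue("SER")
  good <- ser$conformers[[1L]]
  bad <- good
  n_xyz <- multiconf:::.atom_xyz(bad$atoms, "N")
  i <- match("OG", bad$atoms$name)
  bad$atoms[i, c("x", "y", "z")] <- n_xyz + c(1.0, 0, 0)
  cs <- multiconf:::.new_candidate_set(ser, list(good, bad), "x")
  kept <- prune_candidates(cs)
  expect_length(kept$conformers, 1L)
  expect_equal(conformer_rmsd(kept$conformers[[1L]], good), 0)
  # bonded 1-2/1-3 pairs are exempt: the ideal conformer itself survives
  expect_length(prune_candidates(
    multiconf:::.new_candidate_set(ser, list(good), "x"))$conformers, 1L)
})

test_that("B-factor sampling expands by the stated multipliers only", {
  ser <- toy_residue("SER", b = 10)
  cs <- multiconf:::.new_candidate_set(ser, rep(ser$conformers, 5L), "qp")
  out <- sample_bfactors(cs)
  expect_length(out$conformers, 30L)
  bs <- sort(unique(vapply(out$conformers, function(cf) cf$atoms$b[1L], 0)))
  expect_equal(bs, 10 * c(0.5, 0.7, 0.9, 1.1, 1.3, 1.5))
  # the unscaled conformer is deliberately not reproduced
  expect_false(any(abs(bs - 10) < 1e-9))
  # coordinates untouched
  expect_equal(atom_coords(out$conformers[[1L]]$atoms),
               atom_coords(ser$conformers[[1L]]$atoms))
})

test_that("sampling is deterministic: identical inputs, identical output order", {
  ty <- toy_residue("TYR", aniso = TRUE)
  run <- function() {
    cs <- sample_backbone(ty)
    cs <- sample_aromatic_angle(cs)
    cs <- sample_chi(cs, 1L)
    prune_candidates(cs)
  }
  expect_identical(run(), run())
})
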