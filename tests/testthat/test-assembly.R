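# Segment identification/optimization, relabeling, segment-only repair,
# culling, restraint output.

# three consecutive residues with paired double backbones inside a 5-residue
# chain; truth pairs A(dz=+0.4, occ .6) with A, B(dz=-0.4, occ .4) with B
segment_fixture <- function() {
  base <- make_toy_system(5, 0, seed = 1)
  shift <- function(cf, dz, al, occ) {
    cf$atoms$z <- cf$atoms$z + dz
    cf$altloc <- al; cf$occ <- occ; cf$atoms$occ <- occ
    cf
  }
  truth <- base
  for (i in 2:4) {
    cf <- base$residues[[i]]$conformers[[1L]]
    truth$residues[[i]]$conformers <- list(shift(cf, 0.4, "A", 0.6),
                                           shift(cf, -0.4, "B", 0.4))
  }
  truth
}

test_that("segments are maximal runs of multi-backbone residues", {
  single <- make_toy_system(6, 0, seed = 1)
  expect_length(identify_segments(single), 0L)

  truth <- segment_fixture()
  segs <- identify_segments(truth)
  expect_length(segs, 1L)
  expect_equal(segs[[1L]], 2:4)

  # side-chain-only heterogeneity does not create a segment
  toy <- make_toy_system(6, 0.5, seed = 2)   # second rotamer, same backbone
  expect_length(identify_segments(toy), 0L)

  # segments plus singles partition the chain
  covered <- c(unlist(segs),
               setdiff(seq_along(truth$residues), unlist(segs)))
  expect_setequal(covered, seq_along(truth$residues))
  expect_equal(anyDuplicated(covered), 0L)
})

test_that("fragment optimization pairs truth conformers and shares occupancies", {
  truth <- segment_fixture()
  g <- synthesize_map(truth, 1.0, spacing = 0.35, background = 0.3)
  cfg <- build_config(1.0)
  scrambled <- truth
  for (i in 2:4) for (k in 1:2) {
    scrambled$residues[[i]]$conformers[[k]]$occ <- 0.5
    scrambled$residues[[i]]$conformers[[k]]$atoms$occ <- 0.5
  }
  opt <- optimize_segment(scrambled, 2:4, g, cfg)
  # 2^3 combinations enumerable in the first window
  expect_equal(attr(opt, "n_enumerated"), 8L)
  for (i in 2:4) {
    confs <- opt$residues[[i]]$conformers
    expect_length(confs, 2L)
    occs <- vapply(confs, `[[`, 0, "occ")
    # ground-truth pairing recovered with harmonized weights
    dz <- vapply(confs, function(cf)
      cf$atoms$z[1L] - segment_fixture()$residues[[i]]$conformers[[1L]]$atoms$z[1L], 0)
    expect_equal(occs[order(-occs)], c(0.6, 0.4), tolerance = 0.05)
    expect_equal(sort(dz), c(-0.8, 0))       # one +0.4 and one -0.4 shift
  }
  # neighbouring paired conformers share one occupancy
  o2 <- vapply(opt$residues[[2L]]$conformers, `[[`, 0, "occ")
  o3 <- vapply(opt$residues[[3L]]$conformers, `[[`, 0, "occ")
  expect_equal(o2, o3)
  # single-residue segments pass through unchanged
  expect_identical(optimize_segment(truth, 3L, g, cfg), truth)
})

test_that("relabeling swaps clashing labels and never raises the energy", {
  mkc <- function(xoff, z, al) {
    at <- new_atoms(c("N", "CA", "C", "O", "CB"), c("N", "C", "C", "O", "C"),
                    rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0),
                          c(1.7, 2.3, 0), c(2, -1, 0)) +
                      matrix(rep(c(xoff, 0, z), each = 5L), 5L), b = 12)
    new_conformer(at, al, 0.5)
  }
  # residue pair with same-label clashes that a swap fixes
  r1 <- new_residue("A", 1L, "ALA", list(mkc(0, 0, "A"), mkc(0, 2, "B")))
  r2 <- new_residue("A", 3L, "ALA", list(mkc(2.5, 0.1, "A"), mkc(2.5, 2.1, "B")))
  m <- new_structure(list(r1, r2))
  out <- relabel_altlocs(m, seed = 0L)
  expect_lt(attr(out, "energy_final"), attr(out, "energy_initial"))
  # the B-ward conformer of residue 2 now carries label A or vice versa
  z_a <- out$residues[[2L]]$conformers[[1L]]$atoms$z[1L]
  expect_gt(z_a, 1)

  # reproducible under a fixed seed
  out2 <- relabel_altlocs(m, seed = 0L)
  expect_identical(out, out2)

  # isolated residues keep their labels
  far <- new_residue("A", 9L, "ALA", list(mkc(50, 0, "A"), mkc(50, 2, "B")))
  m2 <- new_structure(list(r1, far))
  out3 <- relabel_altlocs(m2, seed = 1L)
  expect_identical(vapply(out3$residues[[2L]]$conformers, function(cf)
    cf$atoms$z[1L], 0), c(0, 2))

  # energy never increases across seeds
  for (s in 1:5) {
    o <- relabel_altlocs(m, seed = s)
    expect_lte(attr(o, "energy_final"), attr(o, "energy_initial") + 1e-9)
  }
})

test_that("segment-only repair duplicates conformers and conserves occupancy", {
  truth <- segment_fixture()
  # give residue 3 four conformers, leave 2 and 4 with two
  r3 <- truth$residues[[3L]]
  extra <- lapply(c(0.9, -0.9), function(dz) {
    cf <- truth$residues[[3L]]$conformers[[1L]]
    cf$atoms$z <- cf$atoms$z + dz
    cf
  })
  r3$conformers <- c(r3$conformers, extra)
  for (k in 1:4) {
    r3$conformers[[k]]$altloc <- LETTERS[k]
    r3$conformers[[k]]$occ <- 0.25
    r3$conformers[[k]]$atoms$occ <- 0.25
  }
  truth$residues[[3L]] <- r3
  pre_totals <- vapply(truth$residues, function(r)
    sum(vapply(r$conformers, `[[`, 0, "occ")), 0)

  rep_ <- segment_only(truth)          # no map: counts + labels only
  for (i in 2:4)
    expect_length(rep_$residues[[i]]$conformers, 4L)
  # residue 2's C and D duplicate its A and B
  r2 <- rep_$residues[[2L]]
  expect_equal(atom_coords(r2$conformers[[3L]]$atoms),
               atom_coords(r2$conformers[[1L]]$atoms))
  expect_equal(atom_coords(r2$conformers[[4L]]$atoms),
               atom_coords(r2$conformers[[2L]]$atoms))
  # parents split occupancy equally with their duplicates
  expect_equal(r2$conformers[[1L]]$occ, 0.3)
  expect_equal(r2$conformers[[3L]]$occ, 0.3)
  post_totals <- vapply(rep_$residues, function(r)
    sum(vapply(r$conformers, `[[`, 0, "occ")), 0)
  expect_equal(post_totals, pre_totals, tolerance = 1e-6)

  # an already-uniform segment keeps its conformer counts
  uni <- segment_fixture()
  rep2 <- segment_only(uni)
  for (i in 2:4) expect_length(rep2$residues[[i]]$conformers, 2L)
})

test_that("low-occupancy culling renormalizes exactly and is idempotent", {
  mk <- function(occs) {
    confs <- lapply(seq_along(occs), function(k) {
      cf <- bb_conformer(dz = (k - 1) * 1.5, altloc = LETTERS[k], occ = occs[k])
      cf
    })
    new_structure(list(new_residue("A", 1L, "ALA", confs)))
  }
  # (0.95, 0.05): one survivor at full occupancy with a blank altloc
  c1 <- cull_low_occupancy(mk(c(0.95, 0.05)))
  expect_length(c1$residues[[1L]]$conformers, 1L)
  expect_equal(c1$residues[[1L]]$conformers[[1L]]$occ, 1)
  expect_equal(c1$residues[[1L]]$conformers[[1L]]$altloc, "")
  # (0.6, 0.4): untouched
  c2 <- cull_low_occupancy(mk(c(0.6, 0.4)))
  expect_equal(vapply(c2$residues[[1L]]$conformers, `[[`, 0, "occ"),
               c(0.6, 0.4))
  # (0.50, 0.42, 0.08) -> renormalized two survivors
  c3 <- cull_low_occupancy(mk(c(0.50, 0.42, 0.08)))
  expect_equal(vapply(c3$residues[[1L]]$conformers, `[[`, 0, "occ"),
               c(0.50, 0.42) / 0.92, tolerance = 1e-9)
  # everything below the cutoff: the best conformer survives at 1.0
  c4 <- cull_low_occupancy(mk(c(0.06, 0.04)))
  expect_length(c4$residues[[1L]]$conformers, 1L)
  expect_equal(c4$residues[[1L]]$conformers[[1L]]$occ, 1)
  # idempotent
  expect_identical(cull_low_occupancy(c3), c3)
})

test_that("occupancy restraint groups cover each segment-altloc pair", {
  f <- withr::local_tempfile(fileext = ".txt")
  # no segments: header-only file
  write_occupancy_restraints(make_toy_system(4, 0, seed = 1), f)
  lines <- readLines(f)
  expect_true(all(startsWith(lines, "#")))

  truth <- segment_fixture()
  write_occupancy_restraints(truth, f)
  lines <- readLines(f)
  groups <- grep("^group", lines, value = TRUE)
  expect_length(groups, 2L)
  expect_true(any(grepl("altloc=A", groups)) && any(grepl("altloc=B", groups)))
  expect_true(all(grepl("resseq 2:4", groups)))
})
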