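# Candidate enumeration: backbone translations, aromatic-angle perturbations,
# chi-angle rotamer grids, proline puckers, B-factor multipliers; clash and
# redundancy pruning.  Everything here is deterministic -- no RNG.

#' Sampling parameters
#'
#' Defaults: backbone translations in 0.1-angstrom steps out to 0.3;
#' aromatic Ca-Cb-Cg angle offsets of +/-3.75 degrees out to +/-7.5;
#' chi offsets every 6 degrees out to +/-24 around each idealized rotamer
#' mean; redundancy threshold 0.01 angstrom all-atom RMSD; B-factor
#' multipliers 0.5-1.5 in increments of 0.2; hard-sphere clash radii scaled
#' by 0.75.
#'
#' @param backbone_step,backbone_extent backbone translation grid, angstroms.
#' @param aromatic_step,aromatic_extent aromatic angle grid, degrees.
#' @param chi_step,chi_extent chi-angle grid, degrees.
#' @param redundancy_rmsd all-atom RMSD below which candidates are redundant.
#' @param bfactor_multipliers multipliers applied to every atom B-factor.
#' @param clash_scale van der Waals radius scale for the hard-sphere test.
#' @return A `sampling_params` list.
#' @export
sampling_params <- function(backbone_step = 0.1, backbone_extent = 0.3,
                            aromatic_step = 3.75, aromatic_extent = 7.5,
                            chi_step = 6, chi_extent = 24,
                            redundancy_rmsd = 0.01,
                            bfactor_multipliers = c(0.5, 0.7, 0.9, 1.1, 1.3, 1.5),
                            clash_scale = 0.75) {
  stopifnot(backbone_extent %% backbone_step < 1e-9 ||
              abs(backbone_extent %% backbone_step - backbone_step) < 1e-9,
            chi_extent %% chi_step == 0)
  structure(list(backbone_step = backbone_step,
                 backbone_extent = backbone_extent,
                 aromatic_step = aromatic_step,
                 aromatic_extent = aromatic_extent,
                 chi_step = chi_step, chi_extent = chi_extent,
                 redundancy_rmsd = redundancy_rmsd,
                 bfactor_multipliers = bfactor_multipliers,
                 clash_scale = clash_scale),
            class = "sampling_params")
}

.new_candidate_set <- function(residue, conformers, stage) {
  structure(list(chain = residue$chain, resno = residue$resno,
                 icode = residue$icode, resn = residue$resn,
                 conformers = conformers, stage = stage),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate set (%s %s%d): %d conformers, stage '%s'\n",
              x$resn, x$chain, x$resno, length(x$conformers), x$stage))
  invisible(x)
}

# translate every atom of a conformer (side chain rides with the backbone)
.translate_conformer <- function(cf, t) {
  cf$atoms$x <- cf$atoms$x + t[1L]
  cf$atoms$y <- cf$atoms$y + t[2L]
  cf$atoms$z <- cf$atoms$z + t[3L]
  cf
}

# pseudo-Cb direction for glycine, built from backbone geometry
.pseudo_cb_dir <- function(at) {
  n <- .atom_xyz(at, "N"); ca <- .atom_xyz(at, "CA"); c <- .atom_xyz(at, "C")
  b1 <- .vunit(ca - n); b2 <- .vunit(ca - c)
  .vunit(.vunit(b1 + b2) * sin(.deg2rad(54.75)) +
           .vunit(.vcross(b2, b1)) * cos(.deg2rad(54.75)))
}

#' Backbone translation sampling
#'
#' Collective rigid translations of the residue.  With isotropic B-factors:
#' 9 candidates (the input plus translations of 0.1-0.3 angstroms along the
#' Ca-Cb, C-N and Cb-Ca x C-N directions; glycine uses a pseudo-Cb built
#' from backbone geometry).  With an anisotropic tensor on Cb (or Ca): 81
#' candidates on a grid over the displacement-tensor principal axes (9
#' offsets along the dominant axis, 3 along each minor axis), including the
#' input.
#'
#' @param residue a residue with complete backbone (N, CA, C, O).
#' @param params a [sampling_params()].
#' @return A `candidate_set` (stage `"backbone"`).
#' @export
sample_backbone <- function(residue, params = sampling_params()) {
  cf <- residue$conformers[[1L]]
  at <- cf$atoms
  if (!all(.backbone_atoms %in% at$name))
    stop("skip-residue: missing backbone atom in ", .residue_label(residue))

  anchor <- if ("CB" %in% at$name) "CB" else "CA"
  ai <- match(anchor, at$name)
  has_aniso <- !is.na(at$u11[ai])

  if (!has_aniso) {
    ca <- .atom_xyz(at, "CA"); cc <- .atom_xyz(at, "C"); nn <- .atom_xyz(at, "N")
    u1 <- if ("CB" %in% at$name) .vunit(.atom_xyz(at, "CB") - ca)
          else .pseudo_cb_dir(at)
    u2 <- .vunit(nn - cc)
    u3 <- .vunit(.vcross(u1, u2))
    mags <- seq(params$backbone_step, params$backbone_extent,
                by = params$backbone_step)
    shifts <- list(c(0, 0, 0))
    for (k in 1:3) for (m in mags) {
      if (k == 1L && m == mags[1L]) next  # null translation takes this slot
      shifts[[length(shifts) + 1L]] <- switch(k, u1, u2, u3) * m
    }
  } else {
    U <- matrix(c(at$u11[ai], at$u12[ai], at$u13[ai],
                  at$u12[ai], at$u22[ai], at$u23[ai],
                  at$u13[ai], at$u23[ai], at$u33[ai]), 3L, 3L)
    ev <- eigen(U, symmetric = TRUE)
    e1 <- ev$vectors[, 1L]; e2 <- ev$vectors[, 2L]; e3 <- ev$vectors[, 3L]
    ext <- params$backbone_extent
    g1 <- seq(-ext, ext, length.out = 9L)
    g2 <- c(-ext / 2, 0, ext / 2)
    shifts <- list()
    for (c3 in g2) for (c2 in g2) for (c1 in g1)
      shifts[[length(shifts) + 1L]] <- c1 * e1 + c2 * e2 + c3 * e3
  }
  confs <- lapply(shifts, function(t) .translate_conformer(cf, t))
  .new_candidate_set(residue, confs, "backbone")
}

#' Aromatic Ca-Cb-Cg angle sampling
#'
#' For His, Tyr, Phe and Trp, bends the side chain about Cb in the
#' Ca-Cb-Cg plane by offsets of 0, +/-3.75 and +/-7.5 degrees, yielding 5
#' partial conformers per input conformer.  Non-aromatic residues pass
#' through unchanged.
#'
#' @param candidates a `candidate_set`.
#' @param params a [sampling_params()].
#' @return A `candidate_set` (stage `"aromatic"`).
#' @export
sample_aromatic_angle <- function(candidates, params = sampling_params()) {
  if (!(candidates$resn %in% .aromatic_residues)) return(candidates)
  offsets <- sort(unique(c(
    seq(-params$aromatic_extent, params$aromatic_extent,
        by = params$aromatic_step))))
  movers <- .chi_moving[[candidates$resn]][[1L]]  # CG and beyond
  out <- list()
  for (cf in candidates$conformers) {
    at <- cf$atoms
    ca <- .atom_xyz(at, "CA"); cb <- .atom_xyz(at, "CB")
    cg <- .atom_xyz(at, "CG")
    if (is.null(cg)) stop("aromatic residue lacks CG")
    axis <- .vcross(ca - cb, cg - cb)   # normal of the Ca-Cb-Cg plane
    idx <- which(at$name %in% c(movers))
    for (off in offsets) {
      nf <- cf
      if (abs(off) > 0) {
        xyz <- atom_coords(at)[idx, , drop = FALSE]
        nf$atoms[idx, c("x", "y", "z")] <-
          .rotate_about_axis(xyz, cb, axis, off)
      }
      out[[length(out) + 1L]] <- nf
    }
  }
  res <- candidates
  res$conformers <- out
  res$stage <- "aromatic"
  res
}

#' Chi-angle sampling around idealized rotamer means
#'
#' For each input conformer and each distinct idealized mean of the
#' requested chi, enumerates torsions every `chi_step` degrees out to
#' +/-`chi_extent` (9 offsets by default).  Proline samples its exo and
#' endo ring puckers the same way (2 x 9 per input conformer).
#'
#' @param candidates a `candidate_set`.
#' @param chi_index 1-based chi index.
#' @param library rotamer library (see [rotamer_library()]).
#' @param params a [sampling_params()].
#' @return A `candidate_set` (stage `"chi_<k>"`).
#' @export
sample_chi <- function(candidates, chi_index, library = rotamer_library(),
                       params = sampling_params()) {
  resn <- candidates$resn
  if (chi_index > .n_chi(resn))
    stop("residue type ", resn, " has no chi", chi_index)
  means <- .chi_means(resn, chi_index, library)
  offsets <- seq(-params$chi_extent, params$chi_extent, by = params$chi_step)
  out <- list()
  for (cf in candidates$conformers)
    for (mu in means)
      for (off in offsets)
        out[[length(out) + 1L]] <- set_chi(cf, resn, chi_index, mu + off)
  res <- candidates
  res$conformers <- out
  res$stage <- paste0("chi_", chi_index)
  res
}

# ---------------------------------------------------------------------------
# Pruning

# 1-2/1-3 exclusion mask.  For standard residues, bonds come from the known
# covalent topology (robust to distorted input geometry); otherwise from a
# distance heuristic on the reference conformer.
.bond_exclusions <- function(atoms, resn = NULL) {
  n <- nrow(atoms)
  bonded <- matrix(FALSE, n, n)
  if (!is.null(resn) && !is.null(.sc_bonds[[resn]])) {
    for (bd in c(.bb_bonds, .sc_bonds[[resn]])) {
      i <- match(bd[1L], atoms$name); j <- match(bd[2L], atoms$name)
      if (!is.na(i) && !is.na(j)) bonded[i, j] <- bonded[j, i] <- TRUE
    }
  } else {
    xyz <- atom_coords(atoms)
    d <- as.matrix(stats::dist(xyz))
    cut <- matrix(1.85, n, n)
    heavy2 <- outer(atoms$element %in% c("S", "P", "SE"),
                    atoms$element %in% c("S", "P", "SE"), `|`)
    cut[heavy2] <- 2.1
    bonded <- d < cut & d > 1e-6
  }
  excl <- bonded
  # 1-3: share a bonded neighbor
  excl <- excl | ((bonded %*% bonded) > 0)
  diag(excl) <- TRUE
  excl
}

.has_internal_clash <- function(atoms, excl, clash_scale) {
  xyz <- atom_coords(atoms)
  r <- .vdw_radius(atoms$element) * clash_scale
  d <- as.matrix(stats::dist(xyz))
  lim <- outer(r, r, `+`)
  any(d < lim & !excl)
}

#' Prune clashing and redundant candidates
#'
#' Removes conformers with an internal heavy-atom hard-sphere overlap
#' (van der Waals radii scaled by `params$clash_scale`, 1-2/1-3 bonded pairs
#' excluded) and conformers within `params$redundancy_rmsd` all-atom RMSD of
#' an earlier survivor (first seen wins).  Idempotent.
#'
#' @param candidates a `candidate_set`.
#' @param params a [sampling_params()].
#' @return The pruned `candidate_set`; zero survivors signal the caller to
#'   fall back to the input conformer.
#' @export
prune_candidates <- function(candidates, params = sampling_params()) {
  confs <- candidates$conformers
  if (!length(confs)) return(candidates)
  heavy <- confs[[1L]]$atoms$element != "H"
  ref <- confs[[1L]]$atoms[heavy, , drop = FALSE]
  excl <- .bond_exclusions(ref, candidates$resn)
  ok <- vapply(confs, function(cf) {
    !.has_internal_clash(cf$atoms[cf$atoms$element != "H", , drop = FALSE],
                         excl, params$clash_scale)
  }, TRUE)
  confs <- confs[ok]
  if (length(confs) > 1L) {
    # all-atom RMSD = euclidean distance of flattened coordinates / sqrt(n)
    flat <- t(vapply(confs, function(cf) as.vector(atom_coords(cf$atoms)),
                     numeric(3L * nrow(confs[[1L]]$atoms))))
    natoms <- nrow(confs[[1L]]$atoms)
    dmat <- as.matrix(stats::dist(flat)) / sqrt(natoms)
    keep <- logical(length(confs))
    for (i in seq_along(confs)) {
      kept <- which(keep)
      keep[i] <- !length(kept) || all(dmat[i, kept] >= params$redundancy_rmsd)
    }
    confs <- confs[keep]
  }
  res <- candidates
  res$conformers <- confs
  res
}

#' B-factor multiplier sampling
#'
#' Expands every conformer into one copy per multiplier, scaling each atom's
#' B-factor; coordinates are unchanged.  With the default multiplier set
#' {0.5, 0.7, 0.9, 1.1, 1.3, 1.5} the unscaled conformer is not reproduced
#' exactly.
#'
#' @param candidates a `candidate_set`.
#' @param params a [sampling_params()].
#' @return A `candidate_set` (stage `"bfactor"`) with
#'   `length(multipliers) * n` conformers.
#' @export
sample_bfactors <- function(candidates, params = sampling_params()) {
  out <- list()
  for (cf in candidates$conformers)
    for (m in params$bfactor_multipliers) {
      nf <- cf
      nf$atoms$b <- cf$atoms$b * m
      out[[length(out) + 1L]] <- nf
    }
  res <- candidates
  res$conformers <- out
  res$stage <- "bfactor"
  res
}
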