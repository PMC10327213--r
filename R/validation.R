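# Model-assessment metrics: occupancy-weighted B-factor, multiconformer
# classification against a ground truth, per-atom Q-score, rotamer
# agreement categories.

#' Occupancy-weighted B-factor of a residue
#'
#' Per heavy atom: `occupancy * (4 * pi / B)^1.5`; the residue value is the
#' mean over its heavy atoms (all conformers).  The formula is applied as
#' printed in the field's convention for this metric.
#'
#' @param residue a residue.
#' @return Numeric scalar.
#' @export
weighted_bfactor <- function(residue) {
  vals <- unlist(lapply(residue$conformers, function(cf) {
    at <- cf$atoms[cf$atoms$element != "H", , drop = FALSE]
    if (any(at$b <= 0)) stop("non-positive B-factor in weighted_bfactor")
    at$occ * (4 * pi / at$b)^1.5
  }))
  mean(vals)
}

#' Is a residue a genuine multiconformer?
#'
#' TRUE iff some pair of its conformers differs by more than `cutoff` in
#' side-chain heavy-atom RMSD (residues without side-chain atoms beyond the
#' backbone are compared over all heavy atoms).  Near-overlapping altlocs
#' therefore do not count.
#'
#' @param residue a residue.
#' @param cutoff RMSD cutoff, angstroms (default 0.5).
#' @return Logical.
#' @export
is_multiconformer <- function(residue, cutoff = 0.5) {
  confs <- residue$conformers
  if (length(confs) < 2L) return(FALSE)
  for (i in 1:(length(confs) - 1L))
    for (j in (i + 1L):length(confs))
      if (conformer_rmsd(confs[[i]], confs[[j]], "sidechain") > cutoff)
        return(TRUE)
  FALSE
}

# greedy one-to-one pairing of test conformers to truth conformers by
# ascending side-chain RMSD; returns max paired RMSD or Inf if injective
# pairing is impossible
.pair_conformers <- function(test, truth) {
  nt <- length(test); ng <- length(truth)
  if (nt > ng) return(Inf)
  rm <- matrix(Inf, nt, ng)
  for (i in seq_len(nt)) for (j in seq_len(ng))
    rm[i, j] <- conformer_rmsd(test[[i]], truth[[j]], "sidechain")
  worst <- 0
  for (rep in seq_len(nt)) {
    ij <- which(rm == min(rm), arr.ind = TRUE)[1L, ]
    worst <- max(worst, rm[ij[1L], ij[2L]])
    rm[ij[1L], ] <- Inf
    rm[, ij[2L]] <- Inf
  }
  worst
}

#' Classify a built residue against its ground truth
#'
#' Four exhaustive categories: the built residue's multiconformer status
#' picks the axis (`multiconformer_*` vs `single_*`); a match requires
#' every built conformer to pair one-to-one with a ground-truth conformer
#' within `cutoff` side-chain heavy-atom RMSD, with matching multiconformer
#' status.
#'
#' @param truth,test residues with the same identity.
#' @param cutoff RMSD cutoff, angstroms (default 0.5).
#' @return One of `"multiconformer_match"`, `"multiconformer_no_match"`,
#'   `"single_match"`, `"single_no_match"`.
#' @export
classify_match <- function(truth, test, cutoff = 0.5) {
  tmulti <- is_multiconformer(test, cutoff)
  gmulti <- is_multiconformer(truth, cutoff)
  if (tmulti) {
    ok <- gmulti &&
      .pair_conformers(test$conformers, truth$conformers) <= cutoff
    if (ok) "multiconformer_match" else "multiconformer_no_match"
  } else {
    # all built conformers (possibly near-duplicates) must sit within
    # cutoff of some truth conformer, and the truth must be single too
    worst <- max(vapply(test$conformers, function(tc)
      min(vapply(truth$conformers, function(gc)
        conformer_rmsd(tc, gc, "sidechain"), 0)), 0))
    if (!gmulti && worst <= cutoff) "single_match" else "single_no_match"
  }
}

#' Match classification report for a whole model
#'
#' @param truth,test `mc_structure`s sharing residue numbering.
#' @param cutoff RMSD cutoff, angstroms.
#' @return data.frame with one row per residue: chain, resno, resn,
#'   category.
#' @export
match_report <- function(truth, test, cutoff = 0.5) {
  stopifnot(length(truth$residues) == length(test$residues))
  do.call(rbind, lapply(seq_along(truth$residues), function(i) {
    tr <- truth$residues[[i]]; te <- test$residues[[i]]
    data.frame(chain = tr$chain, resno = tr$resno, resn = tr$resn,
               category = classify_match(tr, te, cutoff),
               stringsAsFactors = FALSE)
  }))
}

# trilinear interpolation of grid values at Cartesian points (n x 3)
.interp_grid <- function(grid, xyz) {
  d <- dim(grid$values)
  f <- sweep(sweep(xyz, 2L, grid$origin), 2L, grid$spacing, `/`)
  f <- pmin(pmax(f, 0), matrix(rep(d - 1L, each = nrow(f)), ncol = 3L) - 1e-9)
  i0 <- floor(f)
  t <- f - i0
  out <- numeric(nrow(f))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx) t[, 1L] else 1 - t[, 1L]
    wy <- if (dy) t[, 2L] else 1 - t[, 2L]
    wz <- if (dz) t[, 3L] else 1 - t[, 3L]
    ix <- pmin(i0[, 1L] + dx, d[1L] - 1L)
    iy <- pmin(i0[, 2L] + dy, d[2L] - 1L)
    iz <- pmin(i0[, 3L] + dz, d[3L] - 1L)
    out <- out + wx * wy * wz *
      grid$values[cbind(ix + 1L, iy + 1L, iz + 1L)]
  }
  out
}

# fixed radial sampling directions (8 normalized cube corners)
.qscore_dirs <- {
  d <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  dimnames(d) <- NULL
  d
}

#' Per-atom Q-score
#'
#' Correlation between the map profile sampled on radial shells around an
#' atom and the ideal Gaussian profile the atom would produce if it
#' perfectly fit the density.  1 indicates an ideal fit; a flat
#' (zero-variance) local map returns 0 with attribute `"flat"`.
#'
#' @param atom one-row atom table (or list with `x`, `y`, `z`, `b`).
#' @param grid a [density_grid()].
#' @param resolution map resolution, angstroms.
#' @param radii shell radii, angstroms.
#' @param blur resolution-blur constant matching the density model.
#' @return Q-score in [-1, 1].
#' @export
qscore <- function(atom, grid, resolution, radii = seq(0.1, 2.0, length.out = 8L),
                   blur = 0.225) {
  ctr <- c(atom$x[1L], atom$y[1L], atom$z[1L])
  v <- .atom_variance(atom$b[1L], resolution, blur)
  pts <- ctr
  ref <- 1
  for (r in radii) {
    pts <- rbind(pts, sweep(.qscore_dirs * r, 2L, ctr, `+`))
    ref <- c(ref, rep(exp(-r^2 / (2 * v)), nrow(.qscore_dirs)))
  }
  obs <- .interp_grid(grid, pts)
  if (stats::sd(obs) < 1e-12) {
    out <- 0
    attr(out, "flat") <- TRUE
    return(out)
  }
  stats::cor(obs, ref)
}

# nearest rotamer bin over the first two chi angles (circular distance)
.rotamer_bin <- function(conformer, resn, library = rotamer_library()) {
  lib <- library[[resn]]
  nchi <- .n_chi(resn)
  if (is.null(lib) || nchi == 0L) return(NA_integer_)
  k <- min(2L, nchi, ncol(lib))
  obs <- vapply(seq_len(k), function(ci)
    tryCatch(get_chi(conformer, resn, ci), error = function(e) NA_real_), 0)
  if (any(is.na(obs))) return(NA_integer_)
  dist <- apply(lib[, seq_len(k), drop = FALSE], 1L, function(mu) {
    dd <- abs(((obs - mu + 180) %% 360) - 180)
    sqrt(sum(dd^2))
  })
  which.min(dist)
}

#' Rotamer agreement between two models
#'
#' Names each conformer's rotamer as the nearest library bin over the first
#' two chi angles only, then compares the per-residue rotamer sets:
#' `consistent` (same sets), `additional_in_model2` / `additional_in_model1`
#' (one set strictly contains the other), `consistent_and_different`
#' (overlapping sets, extras on both sides) and `different` (disjoint).
#'
#' @param model1,model2 `mc_structure`s sharing residue numbering.
#' @param library rotamer library.
#' @return data.frame with one row per residue: chain, resno, resn,
#'   category.
#' @export
rotamer_agreement <- function(model1, model2, library = rotamer_library()) {
  stopifnot(length(model1$residues) == length(model2$residues))
  rows <- lapply(seq_along(model1$residues), function(i) {
    r1 <- model1$residues[[i]]; r2 <- model2$residues[[i]]
    b1 <- unique(stats::na.omit(vapply(r1$conformers, .rotamer_bin,
                                       0L, resn = r1$resn, library = library)))
    b2 <- unique(stats::na.omit(vapply(r2$conformers, .rotamer_bin,
                                       0L, resn = r2$resn, library = library)))
    cat_ <- if (!length(b1) && !length(b2)) "consistent"
    else if (setequal(b1, b2)) "consistent"
    else if (all(b1 %in% b2)) "additional_in_model2"
    else if (all(b2 %in% b1)) "additional_in_model1"
    else if (length(intersect(b1, b2))) "consistent_and_different"
    else "different"
    data.frame(chain = r1$chain, resno = r1$resno, resn = r1$resn,
               category = cat_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
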