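# Reconnecting residues: segment identification, fragment optimization with
# the segment BIC, Monte Carlo altloc relabeling, segment-only repair,
# occupancy culling/renormalization and the occupancy-restraint writer.

# number of distinct backbone conformations among a residue's conformers
.n_backbone_confs <- function(res, tol = 1e-4) {
  if (length(res$conformers) <= 1L) return(length(res$conformers))
  bb <- lapply(res$conformers, function(cf) {
    at <- cf$atoms[cf$atoms$name %in% .backbone_atoms, , drop = FALSE]
    at <- at[order(at$name), , drop = FALSE]
    as.vector(atom_coords(at))
  })
  n <- 1L
  for (i in 2:length(bb)) {
    dup <- FALSE
    for (j in 1:(i - 1L)) {
      if (length(bb[[i]]) == length(bb[[j]]) &&
          sqrt(mean((bb[[i]] - bb[[j]])^2)) < tol) { dup <- TRUE; break }
    }
    if (!dup) n <- n + 1L
  }
  n
}

#' Identify multiconformer backbone segments
#'
#' Maximal runs of sequence-contiguous residues with multiple backbone
#' conformations, delimited on each end by a residue with a single backbone
#' conformation (or a chain break).
#'
#' @param model an `mc_structure`.
#' @return List of integer vectors of residue indices into `model$residues`.
#' @export
identify_segments <- function(model) {
  rs <- model$residues
  multi <- vapply(rs, function(r) .n_backbone_confs(r) >= 2L, TRUE)
  segs <- list()
  cur <- integer(0L)
  for (i in seq_along(rs)) {
    contiguous <- length(cur) &&
      identical(rs[[i]]$chain, rs[[cur[length(cur)]]]$chain) &&
      rs[[i]]$resno == rs[[cur[length(cur)]]]$resno + 1L
    if (multi[i] && (!length(cur) || contiguous)) {
      cur <- c(cur, i)
    } else {
      if (length(cur)) segs[[length(segs) + 1L]] <- cur
      cur <- if (multi[i]) i else integer(0L)
    }
  }
  if (length(cur)) segs[[length(segs) + 1L]] <- cur
  segs
}

# combined conformer spanning several residues (atoms concatenated), used
# only for fragment density synthesis
.fragment_conformer <- function(model, seg_idx, pick) {
  at <- do.call(rbind, lapply(seq_along(seg_idx), function(k) {
    model$residues[[seg_idx[k]]]$conformers[[pick[k]]]$atoms
  }))
  list(altloc = "", occ = 1, atoms = at)
}

#' Harmonize occupancies along a segment
#'
#' Enumerates combinations of member-residue conformations as connected
#' fragments -- the first window spans up to three residues, then one
#' residue is appended at a time -- and selects at most five fragments per
#' step by MIQP with the segment-mode BIC (`k` = number of conformations).
#' After the pass, every residue in the segment carries the selected
#' fragments' conformers with shared fragment occupancies, so paired
#' neighboring backbones have equal occupancy.
#'
#' Fragments whose inter-residue peptide bond (C of residue i to N of
#' residue i+1) deviates from the ideal 1.329 angstroms by more than
#' `bond_tol` are chemically disconnected and are discarded before scoring
#' (same-altloc atoms of adjacent residues must bond); if every combination
#' fails the filter it is skipped.
#'
#' @param model an `mc_structure`.
#' @param seg_idx integer vector of residue indices (one segment).
#' @param grid a [density_grid()].
#' @param config a [build_config()].
#' @param bond_tol peptide-bond continuity tolerance, angstroms.
#' @return The model with that segment's conformers and occupancies
#'   replaced; attribute `"n_enumerated"` reports the fragment count of the
#'   first window.
#' @export
optimize_segment <- function(model, seg_idx, grid, config, bond_tol = 0.1) {
  if (length(seg_idx) <= 1L) return(model)
  nconfs <- vapply(seg_idx, function(i)
    length(model$residues[[i]]$conformers), 0L)

  # fragment state: matrix of conformer picks (rows = fragments) + weights
  picks <- matrix(seq_len(nconfs[1L]), ncol = 1L)
  first_window <- min(3L, length(seg_idx))
  n_enumerated <- NA_integer_

  select_fragments <- function(picks, upto) {
    confs <- lapply(seq_len(nrow(picks)), function(r)
      .fragment_conformer(model, seg_idx[seq_len(upto)], picks[r, ]))
    cs <- structure(list(conformers = confs), class = "candidate_set")
    fp <- extract_footprint(cs, grid, config$rmask)
    D <- .candidate_densities(confs, grid, fp, config$scatter,
                              config$resolution, config$blur)
    y <- target_vector(grid, fp, config$scatter)
    sol <- select_by_bic(as.matrix(D), y, config$miqp,
                         k_mode = "segment",
                         scaling_factor = config$bic_scaling)
    list(picks = picks[sol$selected, , drop = FALSE], w = sol$weights)
  }

  extend <- function(picks, j) {
    nc <- nconfs[j]
    out <- do.call(rbind, lapply(seq_len(nc), function(c2)
      cbind(picks, c2)))
    out[order(apply(out, 1L, paste, collapse = ".")), , drop = FALSE]
  }

  # junction peptide-bond length between conformer ci of residue j-1 and
  # conformer cj of residue j
  junction_ok <- function(j, ci, cj) {
    c_xyz <- .atom_xyz(model$residues[[seg_idx[j - 1L]]]$conformers[[ci]]$atoms, "C")
    n_xyz <- .atom_xyz(model$residues[[seg_idx[j]]]$conformers[[cj]]$atoms, "N")
    if (is.null(c_xyz) || is.null(n_xyz)) return(TRUE)
    abs(.vnorm(n_xyz - c_xyz) - 1.329) <= bond_tol
  }

  n_enumerated <- prod(nconfs[seq_len(first_window)])
  for (j in 2:length(seg_idx)) {
    picks <- extend(picks, j)
    ok <- vapply(seq_len(nrow(picks)), function(r)
      junction_ok(j, picks[r, j - 1L], picks[r, j]), TRUE)
    if (any(ok)) picks <- picks[ok, , drop = FALSE]
    if (j >= first_window || nrow(picks) > 5L) {
      sel <- select_fragments(picks, j)
      picks <- sel$picks
      w <- sel$w
    }
  }
  if (!exists("w", inherits = FALSE)) {
    sel <- select_fragments(picks, length(seg_idx))
    picks <- sel$picks
    w <- sel$w
  }

  ord <- order(-w)
  picks <- picks[ord, , drop = FALSE]
  w <- w[ord]
  for (k in seq_along(seg_idx)) {
    res <- model$residues[[seg_idx[k]]]
    confs <- lapply(seq_len(nrow(picks)), function(r) {
      cf <- res$conformers[[picks[r, k]]]
      cf$altloc <- if (nrow(picks) == 1L) "" else LETTERS[r]
      cf$occ <- w[r]
      cf$atoms$occ <- w[r]
      cf
    })
    res$conformers <- confs
    model$residues[[seg_idx[k]]] <- res
  }
  attr(model, "n_enumerated") <- n_enumerated
  model
}

# ---------------------------------------------------------------------------
# Relabeling

# soft steric overlap energy between two conformers' heavy atoms; backbone-
# backbone pairs of sequence-adjacent residues are covalently linked through
# the peptide bond and are excluded
.pair_energy <- function(a, b, cutoff = 4, adjacent = FALSE) {
  keep_a <- a$atoms$element != "H"
  keep_b <- b$atoms$element != "H"
  xa <- atom_coords(a$atoms[keep_a, , drop = FALSE])
  xb <- atom_coords(b$atoms[keep_b, , drop = FALSE])
  ra <- .vdw_radius(a$atoms$element[keep_a])
  rb <- .vdw_radius(b$atoms$element[keep_b])
  bb_a <- a$atoms$name[keep_a] %in% .backbone_atoms
  bb_b <- b$atoms$name[keep_b] %in% .backbone_atoms
  e <- 0
  for (i in seq_len(nrow(xa))) {
    d <- sqrt((xb[, 1L] - xa[i, 1L])^2 + (xb[, 2L] - xa[i, 2L])^2 +
                (xb[, 3L] - xa[i, 3L])^2)
    near <- d < cutoff
    if (adjacent && bb_a[i]) near <- near & !bb_b
    if (any(near)) {
      ov <- pmax(0, ra[i] + rb[near] - d[near])
      e <- e + sum(ov^2)
    }
  }
  e
}

# precomputed clash-energy tables: for each close residue pair (i, j), a
# matrix e[[ci, cj]] of conformer-conformer energies
.contact_tables <- function(model, cutoff = 4) {
  rs <- model$residues
  centers <- t(vapply(rs, function(r)
    colMeans(atom_coords(r$conformers[[1L]]$atoms)), numeric(3L)))
  radii <- vapply(rs, function(r)
    max(sqrt(rowSums(sweep(atom_coords(r$conformers[[1L]]$atoms), 2L,
                           colMeans(atom_coords(r$conformers[[1L]]$atoms)))^2))),
    0)
  tabs <- list()
  for (i in seq_along(rs)) for (j in seq_along(rs)) {
    if (j <= i) next
    if (.vnorm(centers[i, ] - centers[j, ]) >
        radii[i] + radii[j] + cutoff + 1) next
    ni <- length(rs[[i]]$conformers); nj <- length(rs[[j]]$conformers)
    adj <- identical(rs[[i]]$chain, rs[[j]]$chain) &&
      abs(rs[[i]]$resno - rs[[j]]$resno) == 1L
    m <- matrix(0, ni, nj)
    for (ci in seq_len(ni)) for (cj in seq_len(nj))
      m[ci, cj] <- .pair_energy(rs[[i]]$conformers[[ci]],
                                rs[[j]]$conformers[[cj]], cutoff, adj)
    if (any(m > 0)) tabs[[length(tabs) + 1L]] <- list(i = i, j = j, e = m)
  }
  tabs
}

# total same-altloc steric energy of a labeling state.  perms[[i]] maps
# altloc slot k -> conformer index of residue i; single-conformer residues
# interact with every slot.
.state_energy <- function(tabs, perms, nconf) {
  e <- 0
  for (tb in tabs) {
    i <- tb$i; j <- tb$j
    ks <- seq_len(max(nconf[i], nconf[j]))
    for (k in ks) {
      ci <- if (nconf[i] == 1L) 1L else if (k <= nconf[i]) perms[[i]][k] else NA
      cj <- if (nconf[j] == 1L) 1L else if (k <= nconf[j]) perms[[j]][k] else NA
      if (!is.na(ci) && !is.na(cj)) e <- e + tb$e[ci, cj]
    }
  }
  e
}

#' Monte Carlo altloc relabeling
#'
#' Permutes altloc letters within residues to minimize a soft steric
#' overlap energy summed over same-altloc heavy-atom pairs of different
#' residues (atoms with different altlocs cannot interact).  Simulated
#' annealing with label-swap proposals; the best state seen is returned, so
#' the final energy never exceeds the initial one.  Reproducible for a
#' fixed seed.
#'
#' @param model an `mc_structure`.
#' @param seed RNG seed.
#' @param contact_cutoff interaction distance cutoff, angstroms.
#' @return The relabeled model; attributes `"energy_initial"` and
#'   `"energy_final"` report the steric energies.
#' @export
relabel_altlocs <- function(model, seed = 0L, contact_cutoff = 4) {
  rs <- model$residues
  nconf <- vapply(rs, function(r) length(r$conformers), 0L)
  multi <- which(nconf > 1L)
  tabs <- .contact_tables(model, contact_cutoff)
  perms <- lapply(nconf, seq_len)
  e0 <- .state_energy(tabs, perms, nconf)
  if (length(multi) && length(tabs)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    best <- perms; ebest <- e0; ecur <- e0
    nprop <- 10L * length(multi)^2 + 20L
    temps <- seq(max(e0, 1) * 0.5, 1e-6, length.out = nprop)
    for (t in seq_len(nprop)) {
      ri <- multi[sample.int(length(multi), 1L)]
      ks <- sample.int(nconf[ri], 2L)
      cand <- perms
      cand[[ri]][ks] <- cand[[ri]][rev(ks)]
      enew <- .state_energy(tabs, cand, nconf)
      if (enew <= ecur || stats::runif(1L) < exp((ecur - enew) / temps[t])) {
        perms <- cand; ecur <- enew
        if (enew < ebest) { best <- perms; ebest <- enew }
      }
    }
    perms <- best
  }
  for (i in multi) {
    res <- rs[[i]]
    res$conformers <- res$conformers[perms[[i]]]
    for (k in seq_along(res$conformers))
      res$conformers[[k]]$altloc <- LETTERS[k]
    rs[[i]] <- res
  }
  model$residues <- rs
  attr(model, "energy_initial") <- e0
  attr(model, "energy_final") <- .state_energy(tabs, perms, nconf)
  model
}

#' Segment-only repair of a hand-edited multiconformer model
#'
#' Within each segment, residues with fewer conformers than the segment
#' maximum gain duplicates of their existing conformers (each parent's
#' occupancy split equally among itself and its duplicates) so all
#' backbones pair up; occupancies are then re-harmonized (when a map is
#' supplied) and altlocs relabeled.  Per-residue occupancy totals are
#' preserved.
#'
#' @param model an `mc_structure`.
#' @param grid optional [density_grid()] for re-optimization; without it
#'   only counts and labels are repaired.
#' @param config a [build_config()] (required with `grid`).
#' @param seed relabeling seed.
#' @return The repaired model.
#' @export
segment_only <- function(model, grid = NULL, config = NULL, seed = 0L) {
  segs <- identify_segments(model)
  for (seg in segs) {
    mx <- max(vapply(seg, function(i) length(model$residues[[i]]$conformers), 0L))
    for (i in seg) {
      res <- model$residues[[i]]
      nc <- length(res$conformers)
      if (nc < mx) {
        pre_total <- sum(vapply(res$conformers, `[[`, 0, "occ"))
        reps <- ceiling(mx / nc)
        confs <- rep(res$conformers, reps)[seq_len(mx)]
        copies <- tabulate(rep(seq_len(nc), reps)[seq_len(mx)], nc)
        for (k in seq_len(mx)) {
          parent <- ((k - 1L) %% nc) + 1L
          confs[[k]]$occ <- res$conformers[[parent]]$occ / copies[parent]
          confs[[k]]$atoms$occ <- confs[[k]]$occ
          confs[[k]]$altloc <- LETTERS[k]
        }
        res$conformers <- confs
        model$residues[[i]] <- res
      }
    }
    if (!is.null(grid)) {
      pre <- mean(vapply(seg, function(i)
        sum(vapply(model$residues[[i]]$conformers, `[[`, 0, "occ")), 0))
      model <- optimize_segment(model, seg, grid, config)
      post <- sum(vapply(model$residues[[seg[1L]]]$conformers, `[[`, 0, "occ"))
      if (post > 1e-9) {
        scale <- pre / post
        for (i in seg) {
          res <- model$residues[[i]]
          for (k in seq_along(res$conformers)) {
            res$conformers[[k]]$occ <- res$conformers[[k]]$occ * scale
            res$conformers[[k]]$atoms$occ <- res$conformers[[k]]$occ
          }
          model$residues[[i]] <- res
        }
      }
    }
  }
  relabel_altlocs(model, seed = seed)
}

#' Cull low-occupancy conformers and renormalize
#'
#' Drops conformers with occupancy below `cutoff` (if all fall below, the
#' highest-occupancy one survives at 1.0) and renormalizes each residue's
#' occupancies to sum to exactly 1.  Single survivors get a blank altloc.
#' Idempotent.
#'
#' @param model an `mc_structure`.
#' @param cutoff occupancy cutoff (default 0.10).
#' @return The culled model.
#' @export
cull_low_occupancy <- function(model, cutoff = 0.10) {
  model$residues <- lapply(model$residues, function(res) {
    occ <- vapply(res$conformers, `[[`, 0, "occ")
    keep <- occ >= cutoff
    if (!any(keep)) keep <- seq_along(occ) == which.max(occ)
    confs <- res$conformers[keep]
    w <- occ[keep] / sum(occ[keep])
    for (k in seq_along(confs)) {
      confs[[k]]$occ <- w[k]
      confs[[k]]$atoms$occ <- w[k]
      confs[[k]]$altloc <- if (length(confs) == 1L) "" else LETTERS[k]
    }
    res$conformers <- confs
    res
  })
  model
}

#' Write group-occupancy refinement restraints
#'
#' One group per (segment, altloc): atoms of that altloc across the
#' segment's residues are constrained to refine to a single occupancy
#' (Phenix-compatible selection strings).
#'
#' @param model an `mc_structure`.
#' @param path output text file.
#' @return Invisibly, the path.
#' @export
write_occupancy_restraints <- function(model, path) {
  segs <- identify_segments(model)
  out <- c("# occupancy restraint groups for constrained group refinement",
           "# one group per (segment, altloc); selections are Phenix syntax")
  gi <- 0L
  for (s in seq_along(segs)) {
    seg <- segs[[s]]
    rs <- model$residues[seg]
    alts <- sort(unique(unlist(lapply(rs, function(r)
      vapply(r$conformers, `[[`, "", "altloc")))))
    alts <- alts[nzchar(alts)]
    chain <- rs[[1L]]$chain
    lo <- min(vapply(rs, `[[`, 0L, "resno"))
    hi <- max(vapply(rs, `[[`, 0L, "resno"))
    for (al in alts) {
      gi <- gi + 1L
      out <- c(out, sprintf(
        'group id=%d segment=%d altloc=%s selection="chain %s and resseq %d:%d and altloc %s"',
        gi, s, al, chain, lo, hi, al))
    }
  }
  writeLines(out, path)
  invisible(path)
}
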