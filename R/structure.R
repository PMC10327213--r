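# Hierarchical protein model: structure -> residues -> conformers -> atoms.
#
# A structure is a list of residues; each residue holds one conformer per
# altloc (blank altloc => a single conformer).  Atoms live in a plain
# data.frame with columns name, element, x, y, z, occ, b and the six
# anisotropic displacement components u11..u23 (angstrom^2, NA when absent).

.atom_cols <- c("name", "element", "x", "y", "z", "occ", "b",
                "u11", "u22", "u33", "u12", "u13", "u23")

#' Construct an atom table
#'
#' @param name atom names (PDB convention, e.g. `"CA"`, `"OG"`).
#' @param element chemical element symbols.
#' @param xyz numeric matrix (n x 3) of coordinates, angstroms.
#' @param occ occupancies in (0, 1].
#' @param b isotropic B-factors, angstrom^2 (> 0).
#' @param aniso optional n x 6 matrix of anisotropic displacement components
#'   (u11, u22, u33, u12, u13, u23), angstrom^2.
#' @return data.frame of atoms.
#' @export
new_atoms <- function(name, element, xyz, occ = 1, b = 10, aniso = NULL) {
  xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  df <- data.frame(name = as.character(name),
                   element = toupper(as.character(element)),
                   x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                   occ = rep_len(occ, n), b = rep_len(b, n),
                   u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
                   u12 = NA_real_, u13 = NA_real_, u23 = NA_real_,
                   stringsAsFactors = FALSE)
  if (!is.null(aniso)) {
    aniso <- matrix(aniso, ncol = 6L)
    df[, c("u11", "u22", "u33", "u12", "u13", "u23")] <- aniso
  }
  df
}

#' @rdname new_atoms
#' @param atoms an atom table.
#' @return `atom_coords()`: n x 3 numeric matrix.
#' @export
atom_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

.set_coords <- function(atoms, xyz) {
  atoms[, c("x", "y", "z")] <- xyz
  atoms
}

# Coordinates of one named atom (first match), or NULL.
.atom_xyz <- function(atoms, name) {
  i <- match(name, atoms$name)
  if (is.na(i)) return(NULL)
  c(atoms$x[i], atoms$y[i], atoms$z[i])
}

#' Construct conformers, residues and structures
#'
#' @param atoms atom table (see [new_atoms()]).
#' @param altloc single altloc letter, or `""` for an unlabelled conformer.
#' @param occ conformer occupancy shared by its atoms.
#' @return A conformer, residue or structure list object.
#' @export
new_conformer <- function(atoms, altloc = "", occ = 1) {
  atoms$occ <- occ
  list(altloc = altloc, occ = occ, atoms = atoms)
}

#' @rdname new_conformer
#' @param chain chain identifier (single character).
#' @param resno residue sequence number.
#' @param resn three-letter residue name.
#' @param conformers list of conformers.
#' @param icode insertion code (`""` when absent).
#' @export
new_residue <- function(chain, resno, resn, conformers, icode = "") {
  list(chain = chain, resno = as.integer(resno), icode = icode,
       resn = resn, conformers = conformers)
}

#' @rdname new_conformer
#' @param residues list of residues in sequence order.
#' @export
new_structure <- function(residues) {
  structure(list(residues = residues), class = "mc_structure")
}

#' @export
print.mc_structure <- function(x, ...) {
  nres <- length(x$residues)
  nconf <- sum(vapply(x$residues, function(r) length(r$conformers), 0L))
  nmulti <- sum(vapply(x$residues, function(r) length(r$conformers) > 1L, TRUE))
  cat(sprintf("multiconformer structure: %d residues, %d conformers (%d multiconformer residues)\n",
              nres, nconf, nmulti))
  invisible(x)
}

.residue_label <- function(res) {
  sprintf("%s%d%s %s", res$chain, res$resno, res$icode, res$resn)
}

# ---------------------------------------------------------------------------
# PDB I/O.  Fixed-column ATOM/ANISOU/TER records; altloc in column 17,
# occupancy in columns 55-60.  Output uses strictly standard altloc layout so
# downstream model-building tools can read it.

.parse_num <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v)))
    stop(sprintf("malformed ATOM record at line %d: bad %s field '%s'",
                 lineno, what, s))
  v
}

#' Read a PDB file into a structure
#'
#' Conformers are grouped by altloc within each residue; atoms with a blank
#' altloc in a residue that also carries lettered altlocs (shared backbone)
#' are replicated into every conformer.  ANISOU records populate the u11..u23
#' columns.  Hydrogens are retained (see [strip_hydrogens()]).
#'
#' @param path path to a PDB-format text file.
#' @return An `mc_structure`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  keep <- which(rec %in% c("ATOM  ", "HETATM", "ANISOU"))
  if (!length(keep)) stop("no ATOM records found in ", path)

  fields <- lapply(keep, function(i) {
    ln <- lines[[i]]
    ln <- formatC(ln, width = 80L, flag = "-")
    list(lineno = i,
         rec = substr(ln, 1L, 6L),
         name = trimws(substr(ln, 13L, 16L)),
         altloc = trimws(substr(ln, 17L, 17L)),
         resn = trimws(substr(ln, 18L, 20L)),
         chain = substr(ln, 22L, 22L),
         resno = substr(ln, 23L, 26L),
         icode = trimws(substr(ln, 27L, 27L)),
         body = ln)
  })

  # residue key in file order
  keys <- vapply(fields, function(f)
    paste(f$chain, trimws(f$resno), f$icode, sep = "|"), "")
  ukeys <- unique(keys)

  residues <- vector("list", length(ukeys))
  for (ri in seq_along(ukeys)) {
    fs <- fields[keys == ukeys[[ri]]]
    atom_fs <- Filter(function(f) f$rec != "ANISOU", fs)
    aniso_fs <- Filter(function(f) f$rec == "ANISOU", fs)

    parse_atom <- function(f) {
      ln <- f$body
      xyz <- c(.parse_num(substr(ln, 31L, 38L), f$lineno, "x"),
               .parse_num(substr(ln, 39L, 46L), f$lineno, "y"),
               .parse_num(substr(ln, 47L, 54L), f$lineno, "z"))
      occ <- .parse_num(substr(ln, 55L, 60L), f$lineno, "occupancy")
      b <- .parse_num(substr(ln, 61L, 66L), f$lineno, "B-factor")
      el <- trimws(substr(ln, 77L, 78L))
      if (!nzchar(el)) el <- gsub("[0-9]", "", substr(f$name, 1L, 1L))
      list(name = f$name, altloc = f$altloc, element = toupper(el),
           xyz = xyz, occ = occ, b = b)
    }
    parsed <- lapply(atom_fs, parse_atom)

    aniso_map <- list()
    for (f in aniso_fs) {
      u <- vapply(seq(0L, 5L), function(k)
        .parse_num(substr(f$body, 29L + 7L * k, 35L + 7L * k),
                   f$lineno, "ANISOU"), 0) / 1e4
      aniso_map[[paste(f$name, f$altloc)]] <- u
    }

    alts <- unique(vapply(parsed, `[[`, "", "altloc"))
    lettered <- setdiff(alts, "")
    confs <- if (length(lettered)) lettered else ""

    make_conf <- function(al) {
      sel <- Filter(function(p) p$altloc == al | p$altloc == "", parsed)
      nm <- vapply(sel, `[[`, "", "name")
      xyz <- t(vapply(sel, `[[`, numeric(3L), "xyz"))
      at <- new_atoms(nm, vapply(sel, `[[`, "", "element"), xyz,
                      occ = vapply(sel, `[[`, 0, "occ"),
                      b = vapply(sel, `[[`, 0, "b"))
      for (j in seq_along(sel)) {
        u <- aniso_map[[paste(sel[[j]]$name, sel[[j]]$altloc)]]
        if (!is.null(u))
          at[j, c("u11", "u22", "u33", "u12", "u13", "u23")] <- u
      }
      # conformer occupancy: occupancy of its lettered atoms (fall back to
      # the shared atoms for blank-only residues)
      own <- vapply(sel, function(p) p$altloc == al, TRUE)
      occ <- if (any(own)) sel[[which(own)[1L]]]$occ else sel[[1L]]$occ
      cf <- new_conformer(at, altloc = al, occ = occ)
      cf$atoms$occ <- vapply(sel, `[[`, 0, "occ")
      cf
    }
    conformers <- lapply(confs, make_conf)

    f1 <- atom_fs[[1L]]
    residues[[ri]] <- new_residue(chain = f1$chain,
                                  resno = as.integer(trimws(f1$resno)),
                                  resn = f1$resn,
                                  conformers = conformers,
                                  icode = f1$icode)
  }
  new_structure(residues)
}

.format_atom_name <- function(name, element) {
  # element symbols of one character start in column 14
  if (nchar(name) >= 4L) return(substr(name, 1L, 4L))
  if (nchar(element) == 2L) formatC(name, width = -4L)
  else paste0(" ", formatC(name, width = -3L))
}

#' Write a structure to a PDB file
#'
#' Multiconformer residues are written with one full copy of the residue per
#' conformer, each carrying its altloc letter and occupancy; single blank
#' conformers are written plainly.  ANISOU records are emitted for atoms with
#' anisotropic components.
#'
#' @param structure an `mc_structure`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_pdb <- function(structure, path) {
  out <- character(0L)
  serial <- 0L
  last_chain <- NULL
  for (res in structure$residues) {
    if (!is.null(last_chain) && !identical(last_chain, res$chain))
      out <- c(out, "TER")
    last_chain <- res$chain
    for (cf in res$conformers) {
      al <- if (nzchar(cf$altloc)) cf$altloc else " "
      at <- cf$atoms
      for (j in seq_len(nrow(at))) {
        serial <- serial + 1L
        out <- c(out, sprintf(
          "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, .format_atom_name(at$name[j], at$element[j]), al,
          res$resn, res$chain, res$resno, ifelse(nzchar(res$icode), res$icode, " "),
          at$x[j], at$y[j], at$z[j], at$occ[j], at$b[j],
          formatC(at$element[j], width = 2L)))
        if (!is.na(at$u11[j])) {
          u <- round(unlist(at[j, c("u11", "u22", "u33", "u12", "u13", "u23")]) * 1e4)
          out <- c(out, sprintf(
            "ANISOU%5d %s%1s%3s %1s%4d%1s %7d%7d%7d%7d%7d%7d      %2s",
            serial %% 100000L, .format_atom_name(at$name[j], at$element[j]), al,
            res$resn, res$chain, res$resno,
            ifelse(nzchar(res$icode), res$icode, " "),
            u[1L], u[2L], u[3L], u[4L], u[5L], u[6L],
            formatC(at$element[j], width = 2L)))
        }
      }
    }
  }
  out <- c(out, "TER", "END")
  writeLines(out, path)
  invisible(path)
}

#' Remove hydrogen atoms
#'
#' Drops every atom whose element is H (or D) from all conformers; heavy
#' atoms are untouched.  Idempotent.
#'
#' @param structure an `mc_structure` (or a single residue / conformer).
#' @return Object of the same shape without hydrogens.
#' @export
strip_hydrogens <- function(structure) {
  strip_conf <- function(cf) {
    cf$atoms <- cf$atoms[!(cf$atoms$element %in% c("H", "D")), , drop = FALSE]
    rownames(cf$atoms) <- NULL
    cf
  }
  if (inherits(structure, "mc_structure")) {
    structure$residues <- lapply(structure$residues, function(res) {
      res$conformers <- lapply(res$conformers, strip_conf)
      res
    })
    structure
  } else if (!is.null(structure$conformers)) {
    structure$conformers <- lapply(structure$conformers, strip_conf)
    structure
  } else {
    strip_conf(structure)
  }
}

#' Unsuperposed RMSD between two conformers
#'
#' Root-mean-square deviation over a named atom subset, with no fitting:
#' used for redundancy pruning (all atoms) and match classification
#' (side-chain heavy atoms).
#'
#' @param a,b conformers with matching atom names over the subset.
#' @param subset one of `"all"`, `"heavy"`, `"sidechain"` (heavy atoms
#'   excluding N, CA, C, O; falls back to all heavy atoms when the residue
#'   has no side chain), or a character vector of atom names.
#' @return RMSD in angstroms.
#' @export
conformer_rmsd <- function(a, b, subset = "all") {
  sel_names <- function(at) {
    if (identical(subset, "all")) at$name
    else if (identical(subset, "heavy")) at$name[at$element != "H"]
    else if (identical(subset, "sidechain")) {
      sc <- at$name[at$element != "H" & !(at$name %in% .backbone_atoms)]
      if (length(sc)) sc else at$name[at$element != "H"]
    } else intersect(subset, at$name)
  }
  nms <- intersect(sel_names(a$atoms), sel_names(b$atoms))
  if (!length(nms)) stop("empty atom subset in conformer_rmsd")
  ia <- match(nms, a$atoms$name)
  ib <- match(nms, b$atoms$name)
  da <- atom_coords(a$atoms)[ia, , drop = FALSE]
  db <- atom_coords(b$atoms)[ib, , drop = FALSE]
  sqrt(sum((da - db)^2) / length(nms))
}

#' Set a side-chain chi angle
#'
#' Rigidly rotates all atoms distal to the chi bond so the torsion equals
#' `angle`; bond lengths and angles are unchanged.
#'
#' @param conformer a conformer.
#' @param resn residue type (three-letter code).
#' @param chi_index 1-based chi index.
#' @param angle target torsion, degrees.
#' @return The modified conformer.
#' @export
set_chi <- function(conformer, resn, chi_index, angle) {
  defs <- .chi_atoms[[resn]]
  if (is.null(defs) || chi_index > length(defs))
    stop("residue type ", resn, " has no chi", chi_index)
  quad <- defs[[chi_index]]
  at <- conformer$atoms
  pts <- lapply(quad, function(nm) .atom_xyz(at, nm))
  if (any(vapply(pts, is.null, TRUE)))
    stop("missing atoms for chi", chi_index, " of ", resn)
  cur <- dihedral_angle(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]])
  delta <- angle - cur
  movers <- intersect(.chi_moving[[resn]][[chi_index]], at$name)
  idx <- which(at$name %in% movers)
  if (length(idx)) {
    xyz <- atom_coords(at)[idx, , drop = FALSE]
    xyz <- .rotate_about_axis(xyz, pts[[2L]], pts[[3L]] - pts[[2L]], delta)
    at[idx, c("x", "y", "z")] <- xyz
  }
  conformer$atoms <- at
  conformer
}

# Read one chi angle from a conformer (degrees).
get_chi <- function(conformer, resn, chi_index) {
  quad <- .chi_atoms[[resn]][[chi_index]]
  pts <- lapply(quad, function(nm) .atom_xyz(conformer$atoms, nm))
  dihedral_angle(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]])
}
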