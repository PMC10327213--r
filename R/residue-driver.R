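# Per-residue orchestration of the build: backbone -> (aromatic) -> chi loop
# with QP reduction, B-factor sampling and MIQP capping -> terminal BIC
# selection.  Residues are independent units of work (no shared mutable
# state, no RNG), so any execution order yields identical output.

#' Build configuration
#'
#' Bundles everything the per-residue pipeline needs: experiment mode,
#' resolution, MIQP constraints, footprint radius and sampling parameters.
#'
#' @param resolution map resolution, angstroms.
#' @param mode `"xray"` or `"em"`.
#' @param cardinality,threshold MIQP constraints; `NULL` picks the mode
#'   defaults (5 and 0.2 for X-ray, 3 and 0.3 for EM).
#' @param rmask footprint mask radius; default `0.5 + resolution / 3`.
#' @param solvent_level flat solvent background subtracted in X-ray mode.
#' @param blur resolution-blur constant of the density model.
#' @param sampling a [sampling_params()].
#' @param bic_scaling BIC penalty discount.
#' @param qscores optional named per-residue Q-score vector or data.frame
#'   (see [read_qscores()]).
#' @param qscore_cutoff residues scoring below this are not built as
#'   multiconformers (feature off unless `qscores` given).
#' @return A `build_config` list.
#' @export
build_config <- function(resolution, mode = c("xray", "em"),
                         cardinality = NULL, threshold = NULL,
                         rmask = NULL, solvent_level = NULL, blur = 0.225,
                         sampling = sampling_params(), bic_scaling = 0.95,
                         qscores = NULL, qscore_cutoff = 0.7) {
  mode <- match.arg(mode)
  if (resolution <= 0) stop("resolution must be positive")
  if (is.null(rmask)) rmask <- 0.5 + resolution / 3
  structure(list(resolution = resolution,
                 scatter = scattering_mode(mode, solvent_level),
                 miqp = miqp_config(mode, cardinality, threshold),
                 rmask = rmask, blur = blur, sampling = sampling,
                 bic_scaling = bic_scaling,
                 qscores = qscores, qscore_cutoff = qscore_cutoff),
            class = "build_config")
}

# score a candidate set: shared footprint, density matrix, target vector
.score_candidates <- function(cands, grid, config) {
  fp <- extract_footprint(cands, grid, config$rmask)
  D <- .candidate_densities(cands$conformers, grid, fp, config$scatter,
                            config$resolution, config$blur)
  y <- target_vector(grid, fp, config$scatter)
  list(fp = fp, D = as.matrix(D), y = y)
}

.subset_candidates <- function(cands, idx) {
  cands$conformers <- cands$conformers[idx]
  cands
}

# merge selected conformers with (near-)identical coordinates, summing
# weights; keeps the heavier-weighted variant's B-factors
.merge_identical <- function(confs, weights, tol = 0.01) {
  if (length(confs) <= 1L) return(list(confs = confs, weights = weights))
  keep <- rep(TRUE, length(confs))
  for (i in seq_along(confs)) {
    if (!keep[i]) next
    for (j in seq_along(confs)) {
      if (j <= i || !keep[j]) next
      r <- conformer_rmsd(confs[[i]], confs[[j]], "all")
      if (r < tol) {
        if (weights[j] > weights[i]) confs[[i]] <- confs[[j]]
        weights[i] <- weights[i] + weights[j]
        keep[j] <- FALSE
      }
    }
  }
  list(confs = confs[keep], weights = weights[keep])
}

#' Q-score gate
#'
#' Residues whose Q-score falls below the cutoff are not built as
#' multiconformers (they still participate in segment assembly).  Residues
#' missing from the table pass (logged via attribute).
#'
#' @param residue a residue.
#' @param qscores named numeric vector (`"chain.resno"`) or data.frame with
#'   columns chain, resno, qscore.
#' @param cutoff minimum Q-score to build (default 0.7).
#' @return `TRUE` if the residue may be built as a multiconformer.
#' @export
qscore_gate <- function(residue, qscores = NULL, cutoff = 0.7) {
  if (is.null(qscores)) return(TRUE)
  if (is.data.frame(qscores)) {
    q <- qscores$qscore[qscores$chain == residue$chain &
                          qscores$resno == residue$resno]
  } else {
    q <- qscores[paste(residue$chain, residue$resno, sep = ".")]
  }
  if (!length(q) || is.na(q[1L])) {
    out <- TRUE
    attr(out, "missing") <- TRUE
    return(out)
  }
  q[1L] >= cutoff
}

#' Read a per-residue Q-score file
#'
#' Whitespace-delimited lines of `chain resno qscore` (comment lines
#' starting with `#` are skipped).
#'
#' @param path text file path.
#' @return data.frame with columns `chain`, `resno`, `qscore`.
#' @export
read_qscores <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  parts <- strsplit(ln, "\\s+")
  data.frame(chain = vapply(parts, `[[`, "", 1L),
             resno = as.integer(vapply(parts, `[[`, "", 2L)),
             qscore = as.numeric(vapply(parts, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Build a multiconformer residue against a density map
#'
#' The full per-residue pipeline: strip hydrogens, enumerate backbone
#' translations (9 isotropic / 81 anisotropic), aromatic-angle bending for
#' His/Tyr/Phe/Trp, then for each chi angle sample the idealized-rotamer
#' grid, prune clashes/redundancy, reduce by QP, expand by B-factor
#' multipliers and cap at 5 conformers by MIQP; at the terminal chi the
#' MIQP is run at every cardinality and the lowest-BIC set wins.  Gly/Ala
#' stop after backbone scoring.
#'
#' @param residue a residue (the first conformer is the build seed).
#' @param grid a [density_grid()].
#' @param config a [build_config()].
#' @return The residue with 1-5 weighted conformers (altlocs `A`..`E`, or
#'   blank for a single conformer).  On skip (missing atoms, out of map,
#'   gated by Q-score) the input residue is returned with attribute
#'   `"skipped"` naming the reason.
#' @export
build_residue <- function(residue, grid, config) {
  skip <- function(reason) {
    attr(residue, "skipped") <- reason
    residue
  }
  if (!(residue$resn %in% .standard_aa)) return(skip("non-standard residue"))
  if (!isTRUE(as.logical(qscore_gate(residue, config$qscores,
                                     config$qscore_cutoff))))
    return(skip("q-score below cutoff"))

  res <- strip_hydrogens(residue)
  res$conformers <- res$conformers[1L]
  res$conformers[[1L]]$occ <- 1
  res$conformers[[1L]]$atoms$occ <- 1

  cands <- tryCatch(sample_backbone(res, config$sampling),
                    error = function(e) NULL)
  if (is.null(cands)) return(skip("missing backbone atoms"))
  cands <- sample_aromatic_angle(cands, config$sampling)

  nchi <- .n_chi(res$resn)
  input_set <- .new_candidate_set(res, res$conformers, "input")

  run_stage <- function(cands, terminal) {
    pruned <- prune_candidates(cands, config$sampling)
    if (!length(pruned$conformers)) pruned <- input_set
    sc <- tryCatch(.score_candidates(pruned, grid, config),
                   error = function(e) e)
    if (inherits(sc, "error")) return(sc)
    qp <- qp_solve(sc$D, sc$y)
    if (!length(qp$selected)) qp$selected <- 1L  # featureless density
    reduced <- .subset_candidates(pruned, qp$selected)
    expanded <- sample_bfactors(reduced, config$sampling)
    sc2 <- .score_candidates(expanded, grid, config)
    if (terminal) {
      sol <- select_by_bic(sc2$D, sc2$y, config$miqp,
                           n_atoms = nrow(expanded$conformers[[1L]]$atoms),
                           k_mode = "residue",
                           scaling_factor = config$bic_scaling)
    } else {
      sol <- nonconvex_fallback(sc2$D, sc2$y, config$miqp,
                                conformers = expanded$conformers)
    }
    list(cands = .subset_candidates(expanded, sol$selected), sol = sol)
  }

  if (nchi == 0L) {
    st <- run_stage(cands, terminal = TRUE)
  } else {
    for (ci in seq_len(nchi)) {
      cands <- sample_chi(cands, ci, params = config$sampling)
      st <- run_stage(cands, terminal = (ci == nchi))
      if (inherits(st, "error")) break
      cands <- st$cands
    }
  }
  if (inherits(st, "error")) return(skip(conditionMessage(st)))

  mg <- .merge_identical(st$cands$conformers, st$sol$weights)
  ord <- order(-mg$weights)
  confs <- mg$confs[ord]
  w <- mg$weights[ord]
  for (i in seq_along(confs)) {
    confs[[i]]$altloc <- if (length(confs) == 1L) "" else LETTERS[i]
    confs[[i]]$occ <- w[i]
    confs[[i]]$atoms$occ <- w[i]
  }
  res$conformers <- confs
  attr(res, "log") <- data.frame(
    chain = res$chain, resno = res$resno, resn = res$resn,
    n_conformers = length(confs),
    rss = st$sol$rss, bic = st$sol$bic,
    occ_sum = sum(w))
  res
}
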