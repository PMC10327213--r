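# Occupancy fitting: quadratic programming over candidate densities, exact
# deterministic MIQP via subset enumeration, the non-convex fallback, and
# BIC-based parsimony selection.
#
# All solvers minimize ||target - D w||^2 subject to w >= 0 and sum(w) <= 1;
# the occupancy deficit (1 - sum w) absorbs unmodeled density.  The MIQP adds
# a cardinality bound and a per-conformer minimum weight.  Subproblems are
# solved exactly with quadprog's dual active-set method; the combinatorial
# part is an exhaustive enumeration over a QP-preselected pool, which keeps
# the solver deterministic and dependency-light.

.qp_ridge <- 1e-9

# least squares with w >= lower and sum(w) <= 1, via quadprog
.qp_box_sum <- function(G, d, lower = 0) {
  n <- length(d)
  lower <- rep_len(lower, n)
  Dmat <- G + diag(.qp_ridge * max(mean(diag(G)), 1e-12), n)
  Amat <- cbind(rep(-1, n), diag(n))
  bvec <- c(-1, lower)
  sol <- quadprog::solve.QP(Dmat, d, Amat, bvec)
  w <- sol$solution
  pmax(w, lower)
}

.new_solution <- function(selected, weights, rss, cardinality_used,
                          bic = NA_real_) {
  structure(list(selected = selected, weights = weights, rss = rss,
                 cardinality_used = cardinality_used, bic = bic),
            class = "occupancy_solution")
}

#' @export
print.occupancy_solution <- function(x, ...) {
  cat(sprintf("occupancy solution: %d conformer(s), weights [%s], rss %.4g%s\n",
              length(x$selected), paste(sprintf("%.3f", x$weights),
                                        collapse = ", "),
              x$rss, if (is.finite(x$bic)) sprintf(", BIC %.2f", x$bic) else ""))
  invisible(x)
}

#' Quadratic-programming occupancy fit
#'
#' Minimizes `||target - sum_i w_i density_i||^2` subject to `w >= 0` and
#' `sum(w) <= 1`.  Candidates with weight below `weight_tol` are dropped
#' from the selection.
#'
#' @param densities numeric matrix, voxels x candidates (a shared footprint).
#' @param target observed density vector over the same footprint.
#' @param weight_tol weights below this are treated as zero.
#' @return An `occupancy_solution` with fields `selected` (candidate
#'   indices), `weights`, `rss` and `cardinality_used`.
#' @export
qp_solve <- function(densities, target, weight_tol = 1e-4) {
  densities <- as.matrix(densities)
  n <- ncol(densities)
  if (n < 1L) stop("need at least one candidate")
  G <- crossprod(densities)
  d <- crossprod(densities, target)[, 1L]
  w <- tryCatch(.qp_box_sum(G, d, lower = 0),
                error = function(e) stop("QP solver failure: ",
                                         conditionMessage(e)))
  w[w < weight_tol] <- 0
  sel <- which(w > 0)
  rss <- sum((target - densities %*% w)^2)
  .new_solution(sel, w[sel], rss, length(sel))
}

#' MIQP configuration
#'
#' @param mode `"xray"` or `"em"`; sets the defaults (cardinality 5 and
#'   threshold 0.2 for X-ray; cardinality 3 and threshold 0.3 for EM).
#' @param cardinality maximum number of selected conformers (1-5).
#' @param threshold minimum occupancy weight of any selected conformer.
#' @param pool_size candidates kept (by QP weight) for the exact subset
#'   enumeration; sets of at most `pool_size` candidates are solved
#'   exhaustively.
#' @return An `miqp_config` list.
#' @export
miqp_config <- function(mode = c("xray", "em"), cardinality = NULL,
                        threshold = NULL, pool_size = 12L) {
  mode <- match.arg(mode)
  if (is.null(cardinality)) cardinality <- if (mode == "em") 3L else 5L
  if (is.null(threshold)) threshold <- if (mode == "em") 0.3 else 0.2
  stopifnot(cardinality >= 1L, cardinality <= 5L,
            threshold > 0, threshold < 1)
  structure(list(mode = mode, cardinality = as.integer(cardinality),
                 threshold = threshold, pool_size = as.integer(pool_size)),
            class = "miqp_config")
}

# Exhaustive best subset per size 1..maxcard over a preselected pool.
# Returns list of per-size solutions (possibly NULL when infeasible).
.miqp_enumerate <- function(densities, target, config) {
  n <- ncol(densities)
  G <- crossprod(densities)
  d <- crossprod(densities, target)[, 1L]
  yty <- sum(target^2)

  pool <- seq_len(n)
  if (n > config$pool_size) {
    w0 <- .qp_box_sum(G, d, lower = 0)
    ord <- order(-w0, seq_len(n))
    pool <- sort(ord[seq_len(config$pool_size)])
  }
  best <- vector("list", config$cardinality)
  for (s in seq_len(min(config$cardinality, length(pool)))) {
    if (s * config$threshold > 1 + 1e-9) break  # infeasible size
    subsets <- utils::combn(pool, s)
    brss <- Inf; bidx <- NULL; bw <- NULL
    for (j in seq_len(ncol(subsets))) {
      idx <- subsets[, j]
      w <- tryCatch(
        .qp_box_sum(G[idx, idx, drop = FALSE], d[idx],
                    lower = config$threshold),
        error = function(e) NULL)
      if (is.null(w)) next
      rss <- yty - 2 * sum(w * d[idx]) +
        sum(w * (G[idx, idx, drop = FALSE] %*% w))
      if (rss < brss - 1e-12) {
        brss <- rss; bidx <- idx; bw <- w
      }
    }
    if (!is.null(bidx))
      best[[s]] <- .new_solution(bidx, bw, max(brss, 0), s)
  }
  best
}

#' Mixed-integer quadratic-programming occupancy fit
#'
#' Same objective and constraints as [qp_solve()] plus a cardinality bound
#' and a minimum weight for every selected conformer.  Solved exactly and
#' deterministically: subsets of a QP-weight-preselected pool (all subsets
#' when there are at most `config$pool_size` candidates) are enumerated and
#' each subset's constrained QP solved; ties prefer fewer conformers.
#'
#' @inheritParams qp_solve
#' @param config an [miqp_config()].
#' @return An `occupancy_solution`.
#' @export
miqp_solve <- function(densities, target, config = miqp_config()) {
  densities <- as.matrix(densities)
  best <- .miqp_enumerate(densities, target, config)
  sols <- Filter(Negate(is.null), best)
  if (!length(sols)) {
    cond <- structure(class = c("miqp_failure", "error", "condition"),
                      list(message = "MIQP found no feasible solution",
                           call = sys.call()))
    stop(cond)
  }
  rsss <- vapply(sols, `[[`, 0, "rss")
  sols[[which.min(rsss + 1e-12 * seq_along(rsss))]]
}

#' Iterative fallback for non-convex MIQP failures
#'
#' When the MIQP signals failure, repeatedly removes one member of the
#' candidate pair with the smallest inter-conformer RMSD (the later-indexed
#' one) and retries, terminating with a solution or a single-candidate QP
#' fit.
#'
#' @inheritParams miqp_solve
#' @param conformers optional list of candidate conformers (for the RMSD
#'   tie-break); without it, Euclidean distance between density columns is
#'   used as the similarity measure.
#' @param solver the MIQP routine to retry (injectable for testing).
#' @return An `occupancy_solution`; `selected` indexes the original
#'   candidate list.
#' @export
nonconvex_fallback <- function(densities, target, config = miqp_config(),
                               conformers = NULL, solver = miqp_solve) {
  densities <- as.matrix(densities)
  live <- seq_len(ncol(densities))
  repeat {
    res <- tryCatch(solver(densities[, live, drop = FALSE], target, config),
                    miqp_failure = function(e) e)
    if (!inherits(res, "miqp_failure")) {
      res$selected <- live[res$selected]
      return(res)
    }
    if (length(live) == 1L) {
      res <- qp_solve(densities[, live, drop = FALSE], target)
      res$selected <- live[res$selected]
      return(res)
    }
    # drop the later-indexed member of the closest pair
    if (!is.null(conformers)) {
      flat <- t(vapply(conformers[live],
                       function(cf) as.vector(atom_coords(cf$atoms)),
                       numeric(3L * nrow(conformers[[1L]]$atoms))))
      dd <- as.matrix(stats::dist(flat))
    } else {
      dd <- as.matrix(stats::dist(t(densities[, live, drop = FALSE])))
    }
    diag(dd) <- Inf
    ij <- which(dd == min(dd), arr.ind = TRUE)[1L, ]
    live <- live[-max(ij)]
  }
}

#' Bayesian information criterion for a density fit
#'
#' `BIC = n * ln(rss / n) + k * ln(n) * scaling_factor` with the heuristic
#' scaling factor (default 0.95) discounting the penalty because sampled
#' coordinate parameters are not independent.
#'
#' @param rss residual sum of squares over the footprint.
#' @param n number of voxels in the footprint.
#' @param k parameter count (see [parameter_count()]).
#' @param scaling_factor penalty discount in (0, 1].
#' @return BIC value; if `rss <= 0` it is clamped to machine epsilon times
#'   `n` and the result carries attribute `clamped = TRUE`.
#' @export
compute_bic <- function(rss, n, k, scaling_factor = 0.95) {
  stopifnot(n > 1, k >= 1)
  clamped <- FALSE
  if (rss <= 0) {
    rss <- .Machine$double.eps * n
    clamped <- TRUE
  }
  out <- n * log(rss / n) + k * log(n) * scaling_factor
  if (clamped) attr(out, "clamped") <- TRUE
  out
}

#' Parameter count for BIC
#'
#' Residue mode counts x, y, z and B for every atom of every conformer
#' (`4 * conformers * atoms`); segment mode counts one parameter per
#' conformation.
#'
#' @param n_conformers number of conformers in the solution.
#' @param n_atoms atoms per conformer (ignored in segment mode).
#' @param mode `"residue"` or `"segment"`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(n_conformers, n_atoms = NULL,
                            mode = c("residue", "segment")) {
  mode <- match.arg(mode)
  stopifnot(n_conformers >= 1)
  if (mode == "segment") return(as.integer(n_conformers))
  stopifnot(!is.null(n_atoms), n_atoms >= 1)
  as.integer(4L * n_conformers * n_atoms)
}

#' BIC-guided cardinality selection
#'
#' Runs the MIQP at cardinalities 1 through `config$cardinality`, scores
#' each solution with [compute_bic()] (`n` = footprint voxels, `k` from
#' [parameter_count()]) and returns the lowest-BIC solution; ties go to the
#' smaller cardinality.
#'
#' @inheritParams miqp_solve
#' @param n_atoms atoms per conformer (residue mode `k`).
#' @param k_mode `"residue"` or `"segment"`.
#' @param scaling_factor BIC penalty discount.
#' @return An `occupancy_solution` with its `bic` field set; attribute
#'   `"bic_by_cardinality"` records the score of every cardinality tried.
#' @export
select_by_bic <- function(densities, target, config = miqp_config(),
                          n_atoms = NULL, k_mode = c("residue", "segment"),
                          scaling_factor = 0.95) {
  k_mode <- match.arg(k_mode)
  densities <- as.matrix(densities)
  n_vox <- nrow(densities)
  best <- .miqp_enumerate(densities, target, config)

  bics <- rep(NA_real_, config$cardinality)
  sols <- vector("list", config$cardinality)
  for (card in seq_len(config$cardinality)) {
    avail <- Filter(Negate(is.null), best[seq_len(card)])
    if (!length(avail)) next
    rsss <- vapply(avail, `[[`, 0, "rss")
    sol <- avail[[which.min(rsss + 1e-12 * seq_along(rsss))]]
    k <- parameter_count(length(sol$selected), n_atoms, k_mode)
    bics[card] <- as.numeric(compute_bic(sol$rss, n_vox, k, scaling_factor))
    sols[[card]] <- sol
  }
  if (all(is.na(bics))) {
    # every cardinality infeasible: best single-candidate QP fit
    fits <- apply(densities, 2L, function(col) {
      s <- qp_solve(matrix(col, ncol = 1L), target)
      s$rss
    })
    j <- which.min(fits)
    sol <- qp_solve(densities[, j, drop = FALSE], target)
    sol$selected <- j
    return(sol)
  }
  pick <- which.min(bics + 1e-9 * seq_along(bics))  # ties: smaller cardinality
  sol <- sols[[pick]]
  sol$bic <- bics[pick]
  attr(sol, "bic_by_cardinality") <- bics
  sol
}
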