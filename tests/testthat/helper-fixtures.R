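# Shared fixtures and independent mini-oracles for the test suite.
# Everything is generated in code; no stored data.

# a small backbone+CB conformer at an offset, for hand-built residues
bb_conformer <- function(xoff = 0, dz = 0, altloc = "", occ = 1, b = 12) {
  at <- new_atoms(c("N", "CA", "C", "O", "CB"), c("N", "C", "C", "O", "C"),
                  rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0),
                        c(1.7, 2.3, 0), c(2, -1, 0)) +
                    matrix(rep(c(xoff, 0, dz), each = 5L), 5L),
                  occ = occ, b = b)
  new_conformer(at, altloc, occ)
}

# random synthetic candidate densities on a shared footprint: columns are
# Gaussian bumps at random centers over a 1-D pseudo-footprint
random_densities <- function(n_vox, n_cand, seed) {
  set.seed(seed)
  x <- seq(0, 10, length.out = n_vox)
  sapply(seq_len(n_cand), function(i) {
    ctr <- runif(1, 0, 10)
    w <- runif(1, 0.3, 1.2)
    exp(-(x - ctr)^2 / (2 * w^2))
  })
}

# Independent constrained-QP mini solver: exact KKT active-set enumeration
# for minimize ||y - D w||^2 s.t. w >= lower, sum(w) <= 1, for <= 6
# variables.  Enumerates every combination of active constraints and keeps
# the feasible KKT point with the lowest objective.  Algorithmically
# unrelated to quadprog's dual method.
kkt_qp_oracle <- function(D, y, lower = 0) {
  n <- ncol(D)
  G <- crossprod(D)
  b <- crossprod(D, y)[, 1]
  lower <- rep_len(lower, n)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^n - 1)) {          # bit k set => w_k fixed at lower
    fixed <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    for (sum_active in c(FALSE, TRUE)) {
      free <- which(!fixed)
      w <- lower
      if (length(free)) {
        if (sum_active) {
          A <- rbind(cbind(G[free, free, drop = FALSE], 1),
                     c(rep(1, length(free)), 0))
          rhs <- c(b[free] - G[free, fixed, drop = FALSE] %*% lower[fixed],
                   1 - sum(lower[fixed]))
          sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
          if (is.null(sol)) next
          w[free] <- sol[seq_along(free)]
        } else {
          rhs <- b[free] - G[free, fixed, drop = FALSE] %*% lower[fixed]
          sol <- tryCatch(solve(G[free, free, drop = FALSE], rhs),
                          error = function(e) NULL)
          if (is.null(sol)) next
          w[free] <- sol
        }
      } else if (sum_active && abs(sum(lower) - 1) > 1e-9) next
      if (any(w < lower - 1e-8) || sum(w) > 1 + 1e-8) next
      obj <- sum((y - D %*% w)^2)
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best <- w
      }
    }
  }
  list(weights = best, rss = best_obj)
}

# exhaustive MIQP oracle for small candidate sets: subset enumeration +
# KKT mini solver per subset
miqp_oracle <- function(D, y, cardinality, threshold) {
  n <- ncol(D)
  best <- NULL
  best_rss <- Inf
  for (s in seq_len(min(cardinality, n))) {
    if (s * threshold > 1 + 1e-9) break
    for (cols in utils::combn(n, s, simplify = FALSE)) {
      sol <- kkt_qp_oracle(D[, cols, drop = FALSE], y, lower = threshold)
      if (is.null(sol$weights)) next
      if (sol$rss < best_rss - 1e-9) {
        best_rss <- sol$rss
        best <- list(selected = cols, weights = sol$weights, rss = sol$rss)
      }
    }
  }
  best
}

# single toy residue wrapped as a one-residue structure with a map
# synthesized from a given set of conformers
residue_with_map <- function(conformers, resn = "SER", resolution = 1.2,
                             spacing = resolution / 3, background = 0.3) {
  res <- new_residue("A", 1L, resn, conformers)
  st <- new_structure(list(res))
  grid <- synthesize_map(st, resolution, spacing = spacing,
                         background = background)
  list(residue = res, structure = st, grid = grid)
}
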