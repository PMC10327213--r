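# QP/MIQP occupancy fitting, the non-convex fallback and BIC selection.

test_that("QP fitting recovers exact mixtures and obeys its constraints", {
  D <- random_densities(200, 12, seed = 3)
  # one candidate, target equals its density
  s1 <- qp_solve(D[, 1, drop = FALSE], D[, 1])
  expect_equal(s1$weights, 1, tolerance = 1e-5)
  expect_lt(s1$rss, 1e-8)
  # zero target: empty selection, zero rss
  s0 <- qp_solve(D, rep(0, 200))
  expect_length(s0$selected, 0L)
  expect_equal(s0$rss, 0)
  # disjoint-support candidates against the normal-equations oracle
  a <- c(rep(1, 50), rep(0, 150))
  b <- c(rep(0, 150), rep(1, 50))
  y <- 0.6 * a + 0.4 * b
  sd <- qp_solve(cbind(a, b), y)
  expect_equal(sort(sd$weights, decreasing = TRUE), c(0.6, 0.4),
               tolerance = 1e-4)
  # general mixture
  y2 <- 0.5 * D[, 2] + 0.3 * D[, 7]
  s2 <- qp_solve(D, y2)
  w <- numeric(12); w[s2$selected] <- s2$weights
  expect_equal(sum((y2 - D %*% w)^2), s2$rss, tolerance = 1e-8)
  expect_true(all(s2$weights > 0))
  expect_lte(sum(s2$weights), 1 + 1e-6)
})

test_that("QP rss never increases as candidates are added", {
  D <- random_densities(150, 10, seed = 9)
  set.seed(11)
  y <- D %*% runif(10, 0, 0.15) + abs(rnorm(150, 0, 0.05))
  rss <- vapply(1:10, function(k) qp_solve(D[, 1:k, drop = FALSE], y)$rss, 0)
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("MIQP respects cardinality and minimum-weight constraints", {
  D <- random_densities(300, 100, seed = 5)
  y <- 0.45 * D[, 3] + 0.35 * D[, 50] + 0.2 * D[, 80]
  sx <- miqp_solve(D, y, miqp_config("xray"))
  expect_lte(length(sx$selected), 5L)
  expect_gte(min(sx$weights), 0.2 - 1e-6)
  se <- miqp_solve(D, y, miqp_config("em"))
  expect_lte(length(se$selected), 3L)
  expect_gte(min(se$weights), 0.3 - 1e-6)
  # cardinality 1 with the target equal to one candidate picks it
  s1 <- miqp_solve(D[, 1:2], D[, 1], miqp_config("xray", cardinality = 1))
  expect_equal(s1$selected, 1L)
  expect_equal(s1$weights, 1, tolerance = 1e-4)
  # MIQP is feasible for QP and never beats it
  q <- qp_solve(D, y)
  expect_gte(sx$rss, q$rss - 1e-8)
})

test_that("MIQP equals an independent exhaustive KKT oracle on small sets", {
  for (seed in c(2, 4, 6, 8)) {
    D <- random_densities(80, 3, seed = seed)
    set.seed(seed + 100)
    y <- D %*% runif(3, 0, 0.5) + abs(rnorm(80, 0, 0.02))
    cfg <- miqp_config("xray")
    got <- miqp_solve(D, y, cfg)
    want <- miqp_oracle(D, y, cfg$cardinality, cfg$threshold)
    expect_equal(got$rss, want$rss, tolerance = 1e-4)
    wg <- numeric(3); wg[got$selected] <- got$weights
    ww <- numeric(3); ww[want$selected] <- want$weights[want$weights > 0]
    expect_equal(wg, ww, tolerance = 1e-3)
  }
})

test_that("the iterative fallback removes near-duplicates until MIQP succeeds", {
  D <- random_densities(100, 4, seed = 12)
  y <- 0.7 * D[, 1] + 0.3 * D[, 4]
  cfg <- miqp_config("xray")
  # no failure: identical to plain MIQP
  direct <- miqp_solve(D, y, cfg)
  same <- nonconvex_fallback(D, y, cfg)
  expect_equal(same$rss, direct$rss)
  expect_equal(same$selected, direct$selected)
  # forced failures: solver refuses until <= 2 candidates remain
  calls <- 0L
  stubborn <- function(dd, tt, cc) {
    calls <<- calls + 1L
    if (ncol(dd) > 2L)
      stop(structure(class = c("miqp_failure", "error", "condition"),
                     list(message = "nonconvex", call = NULL)))
    miqp_solve(dd, tt, cc)
  }
  fb <- nonconvex_fallback(D, y, cfg, solver = stubborn)
  expect_lte(calls, ncol(D))          # terminates in <= n-1 removals
  expect_true(all(fb$selected %in% 1:4))
  expect_s3_class(fb, "occupancy_solution")
})

test_that("BIC matches its closed form and penalizes complexity", {
  expect_equal(compute_bic(rss = 500, n = 500, k = 12), 0.95 * 12 * log(500))
  expect_equal(compute_bic(1000 * 0.5, 1000, 10),
               1000 * log(0.5) + 10 * log(1000) * 0.95, tolerance = 1e-9)
  expect_equal(compute_bic(317.2, 850, 48),
               850 * log(317.2 / 850) + 48 * log(850) * 0.95, tolerance = 1e-9)
  expect_gt(compute_bic(500, 1000, 20), compute_bic(500, 1000, 10))
  clamped <- compute_bic(0, 100, 4)
  expect_true(isTRUE(attr(clamped, "clamped")))
  expect_true(is.finite(clamped))
})

test_that("parameter counts follow the residue and segment definitions", {
  expect_identical(parameter_count(2L, 8L, "residue"), 64L)
  expect_identical(parameter_count(1L, 1L, "residue"), 4L)
  expect_identical(parameter_count(3L, mode = "segment"), 3L)
  expect_identical(parameter_count(5L, 100L, "segment"), 5L)
})

test_that("BIC selection recovers the true cardinality and is an argmin", {
  D <- random_densities(400, 8, seed = 21)
  # target from exactly one candidate: cardinality 1 wins
  s1 <- select_by_bic(D, D[, 4], miqp_config("xray"), n_atoms = 6)
  expect_length(s1$selected, 1L)
  expect_equal(s1$selected, 4L)
  # clean half/half mixture of two well-separated candidates
  y <- 0.5 * D[, 1] + 0.5 * D[, 6]
  s2 <- select_by_bic(D, y, miqp_config("xray"), n_atoms = 6)
  expect_setequal(s2$selected, c(1L, 6L))
  expect_equal(sort(s2$weights), c(0.5, 0.5), tolerance = 1e-3)
  # the returned BIC is the minimum over every cardinality tried
  bics <- attr(s2, "bic_by_cardinality")
  expect_equal(s2$bic, min(bics, na.rm = TRUE))
})
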