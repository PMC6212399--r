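test_that("the finite-difference GRC has its stated algebraic properties", {
  expect_identical(grc_from_pair(1, 1), 0)
  expect_identical(grc_from_pair(1, 3), 1)
  # invariance to a common (blot-proportionality) factor
  for (c0 in c(0.5, 2, 7)) {
    expect_equal(grc_from_pair(3 * c0, 3 * c0 * 1.7), grc_from_pair(1, 1.7))
  }
  # bounded in (-2, 2) for positive measurement pairs
  set.seed(1)
  z0 <- rexp(1000) + 1e-6; z1 <- rexp(1000) + 1e-6
  g <- grc_from_pair(z0, z1)
  expect_true(all(g > -2 & g < 2))
  expect_error(grc_from_pair(1, -1), "denominator")
})

test_that("grc_matrix applies T1 entrywise with the configured control", {
  prof <- make_profile(c(1, 2, 3), matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3, 3))
  expect_equal(grc_matrix(prof), matrix(0, 3, 3))

  g <- grc_matrix(perturbation_response(mapk_model(), rep(0.2, 3)))
  expect_true(all(abs(g) > 1e-4))  # the feedback loop makes every response global
  expect_true(all(abs(g) < 2))
})

test_that("assemble_system encodes the block-diagonal MRA relations", {
  set.seed(2)
  R <- matrix(rnorm(9), 3, 3)
  sys <- assemble_system(R)
  expect_equal(dim(sys$A), c(6, 6))
  expect_equal(length(sys$y), 6)
  # three independent 2x2 blocks
  blocks <- kronecker(diag(3), matrix(1, 2, 2))
  expect_true(all(sys$A[blocks == 0] == 0))
  # row for (i, k): sum_j r_ij R[j, k] = R[i, k]; check one row explicitly
  expect_equal(sys$A[1, 1:2], c(R[2, 2], R[3, 2]))
  expect_equal(sys$y[1], R[1, 2])
  # diagonal GRC matrix gives a zero response vector
  expect_equal(assemble_system(diag(c(1, 2, 3)))$y, rep(0, 6))
})

test_that("rescaling a GRC column leaves the exact LRC solution unchanged", {
  # the perturbation increment cancels from both sides of each relation
  set.seed(3)
  r <- matrix(rnorm(9), 3, 3); diag(r) <- -1
  R <- forward_grc(r, c(2, 0.5, 1.3))
  for (k in 1:3) {
    Rs <- R; Rs[, k] <- 3.7 * Rs[, k]
    expect_equal(solve_lrc_ols(Rs), solve_lrc_ols(R), tolerance = 1e-8)
  }
})

test_that("OLS recovers forward-constructed LRCs and equals the normal equations", {
  set.seed(4)
  for (rep in 1:5) {
    r <- matrix(rnorm(9), 3, 3); diag(r) <- -1
    R <- forward_grc(r, runif(3, 0.5, 2))
    expect_lt(max(abs(solve_lrc_ols(R) - r)), 1e-8)
  }
  # overdetermined noisy stack: QR solution equals (A^T A)^{-1} A^T y per block
  r <- matrix(rnorm(9), 3, 3); diag(r) <- -1
  stack <- lapply(1:3, function(k)
    forward_grc(r) + matrix(rnorm(9, 0, 0.1), 3, 3))
  fit <- solve_lrc_ols(stack)
  for (i in 1:3) {
    b <- mranoise:::stacked_block(stack, i)
    xne <- solve(t(b$A) %*% b$A, t(b$A) %*% b$y)
    expect_equal(fit[i, b$j], as.numeric(xne), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_equal(solve_lrc_ols(diag(c(1, 2, 3))),
               matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3))
})

test_that("TLS equals OLS on consistent systems and a direct-minimization oracle on noisy ones", {
  set.seed(5)
  r <- matrix(rnorm(9), 3, 3); diag(r) <- -1
  R <- forward_grc(r, c(1.5, 0.7, 1.1))
  expect_lt(max(abs(solve_lrc_tls(R) - r)), 1e-8)
  expect_lt(max(abs(solve_lrc_tls(R) - solve_lrc_ols(R))), 1e-8)

  # replicate stack of identical matrices: duplication invariance
  expect_equal(solve_lrc_tls(list(R, R, R)), solve_lrc_tls(R),
               tolerance = 1e-8)

  # noisy overdetermined blocks against the optimization oracle
  stack <- lapply(1:4, function(k) R + matrix(rnorm(9, 0, 0.08), 3, 3))
  fit <- solve_lrc_tls(stack)
  for (i in 1:3) {
    b <- mranoise:::stacked_block(stack, i)
    expect_equal(fit[i, b$j], as.numeric(brute_tls(b$A, b$y)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("the mean estimator averages replicate GRCs before one OLS solve", {
  set.seed(6)
  r <- matrix(rnorm(9), 3, 3); diag(r) <- -1
  M <- forward_grc(r)
  expect_equal(solve_lrc_mean(M), solve_lrc_ols(M))
  expect_equal(solve_lrc_mean(list(M, M, M)), solve_lrc_ols(M))
  D <- matrix(rnorm(9, 0, 0.2), 3, 3)
  expect_equal(solve_lrc_mean(list(M + D, M - D)), solve_lrc_ols(M),
               tolerance = 1e-10)
})

test_that("mra() dispatches the three estimators and exposes model-style methods", {
  prof <- perturbation_response(mapk_model(), rep(0.2, 3))
  ms <- sample_measurements(prof, noise_spec(0.05, 0.1, seed = 8),
                            replicates = 3, strategy = "cs1")
  stack <- grc_replicates(ms)
  for (est in c("mean", "ols", "tls")) {
    fit <- mra(ms, estimator = est)
    expect_s3_class(fit, "mra_fit")
    expect_equal(coef(fit), switch(est,
                                   mean = solve_lrc_mean(stack),
                                   ols = solve_lrc_ols(stack),
                                   tls = solve_lrc_tls(stack)))
    expect_equal(diag(coef(fit)), rep(-1, 3))
  }
  fit <- mra(ms, "ols")
  res <- residuals(fit)
  expect_length(res, 3)
  # fitted + residual reconstructs each off-diagonal GRC relation response
  recon <- mapply(function(f, r) f + r, fitted(fit), res, SIMPLIFY = FALSE)
  for (k in 1:3) {
    off <- !diag(3)
    expect_equal(recon[[k]][off], stack[[k]][off], tolerance = 1e-10)
  }
  expect_output(print(summary(fit)), "Estimator: ols")
})

test_that("noise-free estimates converge to the Jacobian truth as perturbations vanish", {
  for (nm in c("mapk", "p53")) {
    m <- mra_model(nm)
    b99 <- max(intrinsic_bias(m, rep(0.99, 3)))
    b999 <- max(intrinsic_bias(m, rep(0.999, 3)))
    expect_lt(b999, b99)
    expect_lt(b999, 2e-3)
  }
})

test_that("a linear response model has zero intrinsic bias at any strength", {
  toy <- linear_toy_model()
  expect_lt(max(intrinsic_bias(toy, c(0.5, 0.5))), 1e-7)
  expect_lt(max(intrinsic_bias(toy, c(1.4, 0.3))), 1e-7)
})

test_that("noise-free edge signs match the reference at all studied strengths", {
  for (nm in c("mapk", "p53")) {
    m <- mra_model(nm)
    edges <- m$reference_structure != 0
    for (s in c(0.2, 0.5, 0.75, 1.5)) {
      rh <- lrc_noise_free(m, rep(s, 3))
      expect_identical(sign(rh[edges]), m$reference_structure[edges] + 0)
    }
  }
})
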