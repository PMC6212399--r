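test_that("steady_state solves closed-form linear systems", {
  ref1 <- matrix(0, 1, 1)
  m1 <- ode_model("decay", 1, function(x, p) p[1] - x[1], ref1)
  expect_equal(as.numeric(steady_state(m1, 1)), 1, tolerance = 1e-8)

  toy <- linear_toy_model()
  # x = (p1 - 1 + p2, p2)
  expect_equal(as.numeric(steady_state(toy, c(1.3, 0.7))), c(1.0, 0.7),
               tolerance = 1e-8)
  expect_error(steady_state(toy, c(-1, 1)), "positive")
})

test_that("both test-bed models are well-posed at nominal parameters", {
  for (nm in c("mapk", "p53")) {
    m <- mra_model(nm)
    x <- steady_state(m, m$nominal_params)
    expect_true(all(x > 0))
    expect_lt(attr(x, "residual"), 1e-10)
  }
})

test_that("true LRC sign patterns match the reference structures", {
  # MAPK: Raf -> MEK -> ERK with negative ERK->Raf feedback;
  # p53: ATM -> p53 -> MDM2 with negative MDM2 -| p53 feedback.
  for (nm in c("mapk", "p53")) {
    m <- mra_model(nm)
    off <- !diag(m$n_nodes)
    for (pj in c(0.2, 0.5, 1.0, 1.5)) {
      r <- true_lrc(m, c(pj, 1, 1))
      edges <- off & m$reference_structure != 0
      expect_identical(sign(r[edges]), m$reference_structure[edges] + 0)
      expect_lt(max(abs(r[off & m$reference_structure == 0])), 1e-7)
    }
  }
})

test_that("true_lrc matches the closed-form normalized Jacobian on a linear system", {
  # dx1 = -x1 + x2, dx2 = -x2 + p2: at p2 = 1, x = (1, 1) and r12 = x2/x1 = 1
  ref <- matrix(0, 2, 2); ref[1, 2] <- 1
  m <- ode_model("lin", 2, function(x, p) c(-x[1] + x[2], -x[2] + p[2]), ref)
  r <- true_lrc(m, c(1, 1))
  expect_equal(r[1, 2], 1, tolerance = 1e-8)
  expect_equal(r[2, 1], 0, tolerance = 1e-8)
  expect_equal(unname(diag(r)), rep(-1, 2))
})

test_that("steady states are stable and positive over the studied perturbation range", {
  for (nm in c("mapk", "p53")) {
    m <- mra_model(nm)
    for (pj in c(0.2, 0.5, 0.75, 1.0, 1.5)) for (j in 1:3) {
      p <- m$nominal_params; p[j] <- pj
      x <- steady_state(m, p)
      expect_true(all(x > 0))
      J <- mranoise:::num_jacobian(function(z) m$rhs(z, p), as.numeric(x))
      expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
    }
  }
})

test_that("steady-state responses are continuous over the perturbation range", {
  # no bifurcation: neighbouring evaluations on a grid stay close
  m <- mapk_model()
  grid <- seq(0.2, 1.5, by = 0.01)
  xs <- sapply(grid, function(s) as.numeric(steady_state(m, c(s, 1, 1))))
  rel_step <- abs(xs[, -1] - xs[, -ncol(xs)]) / xs[, -ncol(xs)]
  expect_lt(max(rel_step), 0.10)
})

test_that("perturbation_response has the single-parameter experiment layout", {
  m <- mapk_model()
  prof1 <- perturbation_response(m, rep(1, 3))
  expect_equal(prof1$perturbed_states,
               matrix(prof1$control_states, 3, 3,
                      dimnames = dimnames(prof1$perturbed_states)),
               tolerance = 1e-7)

  prof <- perturbation_response(m, rep(0.2, 3))
  expect_true(all(prof$perturbed_states > 0))
  # a 50% knockdown of node 2 changes every node: the response is global
  prof50 <- perturbation_response(m, rep(0.5, 3))
  expect_true(all(abs(prof50$perturbed_states[, 2] -
                        prof50$control_states) > 1e-3))

  toy <- linear_toy_model()
  pr <- perturbation_response(toy, c(0.5, 0.5))
  expect_equal(pr$control_states, c(x1 = 1, x2 = 1), tolerance = 1e-8)
  expect_equal(unname(pr$perturbed_states[, 1]), c(0.5, 1), tolerance = 1e-8)
  expect_equal(unname(pr$perturbed_states[, 2]), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("the p53 model is the strongly non-linear counterpart of the MAPK model", {
  b_mapk <- intrinsic_bias(mapk_model(), rep(0.2, 3))
  b_p53 <- intrinsic_bias(p53_model(), rep(0.2, 3))
  expect_true(any(b_p53 > max(b_mapk)))
})
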