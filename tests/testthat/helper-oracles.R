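# Independent oracles used to pin down expected values.

# Literal double-loop medcouple: median of the kernel over all admissible
# pairs x_i <= m <= x_j, x_i != x_j. Kept deliberately naive and separate
# from the package implementation.
brute_medcouple <- function(x) {
  m <- median(x)
  lower <- x[x <= m]
  upper <- x[x >= m]
  vals <- c()
  for (a in lower) for (b in upper) {
    if (a != b) vals <- c(vals, ((b - m) - (m - a)) / (b - a))
  }
  median(vals)
}

# Direct-minimization total least squares: minimize the Frobenius norm of
# the correction, equivalently ||Ax - y||^2 / (1 + ||x||^2), by generic
# numerical optimization from the OLS start.
brute_tls <- function(A, y) {
  obj <- function(x) sum((A %*% x - y)^2) / (1 + sum(x^2))
  grad <- function(x) {
    f <- sum((A %*% x - y)^2); g <- 1 + sum(x^2)
    as.numeric(2 * t(A) %*% (A %*% x - y)) / g - f * 2 * x / g^2
  }
  x0 <- qr.coef(qr(A), y)
  optim(x0, obj, grad, method = "BFGS",
        control = list(reltol = 1e-15, maxit = 5000))$par
}

# Minimal two-node linear toy system: dx1 = (p1 - 1) - x1 + x2,
# dx2 = -x2 + p2. Steady state x = (p1 - 1 + p2, p2); responses are linear
# in the perturbations, so the finite-difference MRA workflow is exact.
linear_toy_model <- function() {
  ref <- matrix(0, 2, 2); ref[1, 2] <- 1
  ode_model("toy2", 2,
            rhs = function(x, p) c((p[1] - 1) - x[1] + x[2], -x[2] + p[2]),
            reference_structure = ref,
            x_guess = function(p) c(1, 1))
}

# Hand-built perturbation profile (bypasses the ODE solver) for noise tests.
make_profile <- function(control, perturbed) {
  structure(list(control_states = control, perturbed_states = perturbed,
                 perturbation_strengths = rep(NA_real_, length(control)),
                 model_name = "synthetic"),
            class = "perturbation_profile")
}

# Forward-construct a GRC matrix whose exact MRA solution is a chosen LRC
# matrix r (diagonal -1): the MRA relations hold exactly iff r %*% R is
# diagonal, so R = r^{-1} %*% D has solution r for any nonzero diagonal D.
forward_grc <- function(r, d = rep(1, nrow(r))) {
  solve(r) %*% diag(d, nrow(r))
}
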