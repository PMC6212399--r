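#' ODE test-bed model constructor
#'
#' Bundles the right-hand side of an ODE system \eqn{\dot x = f(x, p)} with
#' the metadata needed for perturbation experiments: the number of nodes, the
#' signed reference structure of the true network, and the nominal parameter
#' vector (all ones, the unperturbed control condition). Each parameter
#' \eqn{p_j} enters the dynamics of node \eqn{j} only, typically scaling a
#' total protein amount or production rate, so that setting \eqn{p_j = 0.2}
#' emulates an 80% knockdown of node \eqn{j} and \eqn{p_j = 1.5} a 150%
#' overexpression.
#'
#' @param name model label, e.g. `"mapk"`.
#' @param n_nodes number of network nodes \eqn{N}.
#' @param rhs function `(x, p)` returning \eqn{dx/dt} (numeric length-N).
#' @param reference_structure N x N matrix with entries in \{-1, 0, 1\};
#'   off-diagonal signs of the true direct interactions (diagonal ignored).
#' @param node_names optional character vector of node labels.
#' @param x_guess optional function `(p)` giving an initial state for the
#'   steady-state solver; defaults to a small positive constant state.
#' @return An object of class `"ode_model"`.
#' @seealso [mapk_model()], [p53_model()], [steady_state()], [true_lrc()]
#' @export
ode_model <- function(name, n_nodes, rhs, reference_structure,
                      node_names = NULL, x_guess = NULL) {
  stopifnot(is.function(rhs), n_nodes >= 1)
  reference_structure <- as.matrix(reference_structure)
  stopifnot(nrow(reference_structure) == n_nodes,
            ncol(reference_structure) == n_nodes,
            all(reference_structure %in% c(-1, 0, 1)))
  if (is.null(node_names)) node_names <- paste0("x", seq_len(n_nodes))
  if (is.null(x_guess)) x_guess <- function(p) rep(0.1, n_nodes)
  structure(list(name = name, n_nodes = n_nodes, rhs = rhs,
                 reference_structure = reference_structure,
                 nominal_params = rep(1, n_nodes),
                 node_names = node_names, x_guess = x_guess),
            class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat("ODE test-bed model '", x$name, "' with ", x$n_nodes, " nodes (",
      paste(x$node_names, collapse = ", "), ")\n", sep = "")
  ne <- sum(x$reference_structure != 0 & !diag(x$n_nodes))
  cat("Reference structure:", ne, "signed edges\n")
  invisible(x)
}

#' MAPK cascade test-bed model
#'
#' Three-tiered phosphorylation-dephosphorylation cascade: active Raf
#' (node 1) phosphorylates and activates MEK (node 2), active MEK activates
#' ERK (node 3), and active ERK feeds back negatively on Raf activation.
#' All reactions follow Michaelis-Menten kinetics; \eqn{p_j} scales the
#' total protein amount of node \eqn{j}. The resulting steady-state response
#' curves over \eqn{p_j \in [0.2, 1.5]} are only moderately non-linear,
#' making this the "mild" counterpart to the strongly sigmoidal
#' [p53_model()].
#'
#' The true network therefore has exactly three edges: \eqn{r_{21} > 0},
#' \eqn{r_{32} > 0} and the feedback \eqn{r_{13} < 0}.
#'
#' @return An `"ode_model"` with 3 nodes.
#' @examples
#' m <- mapk_model()
#' steady_state(m, c(1, 1, 1))
#' @export
mapk_model <- function() {
  # x_i: active protein of tier i; p_i scales the tier's total protein S*p_i.
  # S sets the concentration unit so control steady states sit at typical
  # normalized blot-signal levels (a few units above background).
  S <- 8
  V1 <- 1.0 * S; K1 <- 0.5 * S; KI <- 0.3 * S; V2 <- 0.4 * S; K2 <- 0.3 * S
  V3 <- 2.0; K3 <- 0.5 * S; V4 <- 1.0 * S; K4 <- 0.3 * S
  V5 <- 2.0; K5 <- 0.5 * S; V6 <- 1.0 * S; K6 <- 0.3 * S
  rhs <- function(x, p) {
    c(V1 * (S * p[1] - x[1]) / (K1 + S * p[1] - x[1]) * KI / (KI + x[3]) -
        V2 * x[1] / (K2 + x[1]),
      V3 * x[1] * (S * p[2] - x[2]) / (K3 + S * p[2] - x[2]) -
        V4 * x[2] / (K4 + x[2]),
      V5 * x[2] * (S * p[3] - x[3]) / (K5 + S * p[3] - x[3]) -
        V6 * x[3] / (K6 + x[3]))
  }
  ref <- matrix(0, 3, 3)
  ref[2, 1] <- 1   # Raf -> MEK
  ref[3, 2] <- 1   # MEK -> ERK
  ref[1, 3] <- -1  # ERK -| Raf
  ode_model("mapk", 3, rhs, ref,
            node_names = c("pRaf", "ppMEK", "ppERK"),
            x_guess = function(p) 0.2 * S * p)
}

#' p53-MDM2-ATM test-bed model
#'
#' Core DNA-damage response circuit: active ATM (node 1) stabilises and
#' activates p53 (node 2), p53 induces MDM2 expression (node 3), and MDM2
#' promotes p53 degradation, closing a negative feedback loop. The three
#' regulatory interactions are modelled with ultra-sensitive Hill terms
#' (Hill coefficient 4), so steady-state responses over
#' \eqn{p_j \in [0.2, 1.5]} are visibly sigmoidal — the strongly non-linear
#' counterpart to [mapk_model()]. Consequently the finite-difference
#' approximation of response coefficients carries a much larger intrinsic
#' bias at strong perturbations.
#'
#' True edges: \eqn{r_{21} > 0}, \eqn{r_{32} > 0}, \eqn{r_{23} < 0}.
#'
#' @return An `"ode_model"` with 3 nodes.
#' @export
p53_model <- function() {
  hill <- function(x, K, n) x^n / (K^n + x^n)
  # S sets the concentration unit (control steady states a few units).
  S <- 5
  a1 <- 1.0 * S; d1 <- 1.0
  a2 <- 1.0 * S; Ka <- 0.6 * S; d2 <- 0.2; k3 <- 1.5; Kb <- 0.5 * S
  a3 <- 1.0 * S; Kc <- 0.4 * S; d3 <- 1.0
  rhs <- function(x, p) {
    c(a1 * p[1] - d1 * x[1],
      a2 * p[2] * hill(x[1], Ka, 4) - d2 * x[2] -
        k3 * x[2] * hill(x[3], Kb, 4),
      a3 * p[3] * hill(x[2], Kc, 4) - d3 * x[3])
  }
  ref <- matrix(0, 3, 3)
  ref[2, 1] <- 1   # ATM -> p53
  ref[3, 2] <- 1   # p53 -> MDM2
  ref[2, 3] <- -1  # MDM2 -| p53
  ode_model("p53", 3, rhs, ref,
            node_names = c("ATM", "p53", "MDM2"),
            x_guess = function(p) S * c(p[1], 0.5 * p[2], 0.3 * p[3]))
}

#' Look up a built-in test-bed model by name
#'
#' @param name `"mapk"` or `"p53"`.
#' @return An `"ode_model"`.
#' @export
mra_model <- function(name) {
  switch(match.arg(name, c("mapk", "p53")),
         mapk = mapk_model(),
         p53 = p53_model())
}

# Central-difference Jacobian with step scaled to the argument magnitude.
num_jacobian <- function(f, x, rel_step = 1e-6) {
  n <- length(x)
  fx <- f(x)
  J <- matrix(0, length(fx), n)
  for (j in seq_len(n)) {
    h <- rel_step * max(abs(x[j]), 1e-3)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Steady state of a test-bed model
#'
#' Integrates the ODE system to near-equilibrium and then polishes the root
#' of \eqn{f(x, p) = 0} with damped Newton iterations, so the returned state
#' satisfies \eqn{\|f(\bar x, p)\|_\infty} below `tol`. Deterministic for
#' fixed inputs.
#'
#' @param model an `"ode_model"`.
#' @param p strictly positive parameter vector (length `n_nodes`).
#' @param tol residual infinity-norm tolerance (default `1e-10`).
#' @param t_chunk,max_chunks integration is run in chunks of this length
#'   until the residual falls below `1e-9` or the chunk budget is exhausted.
#' @return Steady-state vector \eqn{\bar x}, with attribute `"residual"`.
#' @export
steady_state <- function(model, p, tol = 1e-10, t_chunk = 200,
                         max_chunks = 50) {
  stopifnot(inherits(model, "ode_model"), length(p) == model$n_nodes)
  if (any(p <= 0)) stop("perturbation parameters must be strictly positive")
  f <- function(x) model$rhs(x, p)
  x <- model$x_guess(p)
  deriv <- function(t, y, parms) list(f(y))
  for (chunk in seq_len(max_chunks)) {
    sol <- deSolve::lsoda(y = x, times = c(0, t_chunk), func = deriv,
                          parms = NULL, rtol = 1e-10, atol = 1e-12,
                          maxsteps = 1e5)
    x <- as.numeric(sol[nrow(sol), -1])
    if (max(abs(f(x))) < 1e-9) break
  }
  # Newton polish
  for (it in 1:50) {
    fx <- f(x)
    if (max(abs(fx)) < tol * 1e-2) break
    J <- num_jacobian(f, x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      if (all(xn > 0) && max(abs(f(xn))) < max(abs(fx))) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { xn <- x; break }
    }
    if (identical(xn, x)) break
    x <- xn
  }
  res <- max(abs(f(x)))
  if (!is.finite(res) || res > tol)
    stop(sprintf(
      "steady-state solver did not converge for model '%s': residual %.3e",
      model$name, res))
  names(x) <- model$node_names
  attr(x, "residual") <- res
  x
}

#' True local response coefficients from the Jacobian
#'
#' Computes the ground-truth local response coefficient (LRC) matrix from
#' the normalized Jacobian of the system at steady state:
#' \deqn{r_{ij}^{true} = -\frac{\partial f_i/\partial x_j}
#'   {\partial f_i/\partial x_i} \cdot \frac{\bar x_j}{\bar x_i}, \quad
#'   i \ne j,}
#' with the conventional diagonal \eqn{r_{ii} = -1}. The Jacobian is
#' evaluated by central finite differences with a relative step of `1e-6`
#' scaled to the state magnitude.
#'
#' @param model an `"ode_model"`.
#' @param p parameter vector at which to evaluate (default nominal, all 1).
#' @return N x N LRC matrix, diagonal -1.
#' @export
true_lrc <- function(model, p = model$nominal_params) {
  x <- steady_state(model, p)
  J <- num_jacobian(function(z) model$rhs(z, p), as.numeric(x))
  n <- model$n_nodes
  if (any(abs(diag(J)) < 1e-12))
    stop("degenerate system: a diagonal Jacobian entry vanishes at steady state")
  r <- matrix(-1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    r[i, j] <- -(J[i, j] / J[i, i]) * (x[j] / x[i])
  dimnames(r) <- list(model$node_names, model$node_names)
  r
}

#' Noise-free perturbation experiment
#'
#' Simulates the full single-node perturbation design: one control
#' experiment at nominal parameters (all ones) plus one experiment per node
#' \eqn{j} in which only \eqn{p_j} is set to `strengths[j]`.
#'
#' @param model an `"ode_model"`.
#' @param strengths strictly positive vector of perturbed \eqn{p_j} values,
#'   one per node (e.g. `rep(0.2, 3)` for 80% knockdown of every node).
#' @return Object of class `"perturbation_profile"` with fields
#'   `control_states` (length N), `perturbed_states` (N x N; column j is the
#'   steady state under perturbation of node j) and `perturbation_strengths`.
#' @export
perturbation_response <- function(model, strengths) {
  n <- model$n_nodes
  stopifnot(length(strengths) == n)
  if (any(strengths <= 0)) stop("perturbation strengths must be positive")
  control <- as.numeric(steady_state(model, model$nominal_params))
  pert <- matrix(0, n, n)
  for (j in seq_len(n)) {
    p <- model$nominal_params
    p[j] <- strengths[j]
    pert[, j] <- tryCatch(as.numeric(steady_state(model, p)),
                          error = function(e) stop(sprintf(
                            "perturbation %d failed: %s", j,
                            conditionMessage(e)), call. = FALSE))
  }
  dimnames(pert) <- list(model$node_names, model$node_names)
  names(control) <- model$node_names
  structure(list(control_states = control, perturbed_states = pert,
                 perturbation_strengths = strengths, model_name = model$name),
            class = "perturbation_profile")
}

#' @export
print.perturbation_profile <- function(x, ...) {
  cat("Perturbation profile (model '", x$model_name, "', strengths ",
      paste(signif(x$perturbation_strengths, 3), collapse = ", "), ")\n",
      sep = "")
  cat("Control steady state:\n")
  print(signif(x$control_states, 4))
  invisible(x)
}
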