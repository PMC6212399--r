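#' Measurement noise specification
#'
#' The error model applied to every noise-free steady state \eqn{\bar x}:
#' \deqn{\bar z = \bar x \cdot \eta + \varepsilon, \qquad
#'   \eta \sim \log N(0, \sigma_\eta^2), \quad
#'   \varepsilon \sim N(0, \sigma_\varepsilon^2),}
#' a multiplicative lognormal component (proportional error, typical of
#' densitometry-quantified Western blots) plus an independent additive
#' Gaussian component (background). Blot-specific proportionality factors
#' are not simulated: the finite-difference response coefficients are
#' invariant to them.
#'
#' @param sigma_eta standard deviation of \eqn{\log\eta} (dimensionless).
#' @param sigma_eps standard deviation of \eqn{\varepsilon} (concentration
#'   units).
#' @param seed integer RNG seed.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(sigma_eta = 0.1, sigma_eps = 0.2, seed = 1L) {
  stopifnot(sigma_eta >= 0, sigma_eps >= 0)
  structure(list(sigma_eta = sigma_eta, sigma_eps = sigma_eps,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Draw noisy replicate measurements of a perturbation experiment
#'
#' Applies the error model of [noise_spec()] to every steady state of a
#' noise-free [perturbation_response()] profile, for a chosen number of
#' replicates and control strategy:
#' \describe{
#'   \item{CS1}{one control realization per (node, replicate), shared across
#'     all perturbation experiments — the cheap design actually used in most
#'     blotting studies. Sharing induces block-wise positive correlations
#'     between the global response coefficients of one node.}
#'   \item{CS2}{an independent control realization per (node, replicate,
#'     perturbation).}
#' }
#' All draws are mutually independent apart from the CS1 sharing, and the
#' draw order is fixed, so a given seed yields a bit-identical result.
#' Negative or zero realizations (possible when `sigma_eps` is large
#' relative to the steady state) are retained untruncated; the downstream
#' finite-difference transformation guards its own domain.
#'
#' @param profile a `"perturbation_profile"`.
#' @param noise a `"noise_spec"`.
#' @param replicates number of replicates (>= 1).
#' @param strategy `"cs1"` (shared control) or `"cs2"` (control per
#'   perturbation).
#' @return Object of class `"measurement_set"`: `control` is an N x R matrix
#'   under CS1 or an N x N x R array under CS2 (node x perturbation x
#'   replicate); `perturbed` is an N x N x R array with entry (i, j, r) the
#'   r-th noisy measurement of node i under perturbation of node j.
#' @export
sample_measurements <- function(profile, noise, replicates = 1L,
                                strategy = c("cs1", "cs2")) {
  stopifnot(inherits(profile, "perturbation_profile"),
            inherits(noise, "noise_spec"), replicates >= 1)
  strategy <- match.arg(strategy)
  n <- length(profile$control_states)
  R <- as.integer(replicates)
  x0 <- profile$control_states
  xp <- profile$perturbed_states

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)

  noisy <- function(xbar, k) {
    eta <- exp(stats::rnorm(k, 0, noise$sigma_eta))
    eps <- stats::rnorm(k, 0, noise$sigma_eps)
    xbar * eta + eps
  }
  # fixed draw order: control block first, then perturbed block
  if (strategy == "cs1") {
    control <- matrix(noisy(rep(x0, R), n * R), n, R)
  } else {
    control <- array(noisy(rep(x0, n * R), n * n * R), dim = c(n, n, R))
  }
  perturbed <- array(noisy(rep(as.numeric(xp), R), n * n * R),
                     dim = c(n, n, R))
  structure(list(control = control, perturbed = perturbed,
                 control_strategy = strategy, replicate_count = R,
                 noise = noise, profile = profile),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("Measurement set:", dim(x$perturbed)[1], "nodes x",
      dim(x$perturbed)[2], "perturbations x", x$replicate_count,
      "replicates;", toupper(x$control_strategy), "controls;",
      sprintf("sigma_eta = %g, sigma_eps = %g", x$noise$sigma_eta,
              x$noise$sigma_eps), "\n")
  invisible(x)
}
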