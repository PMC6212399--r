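#' Scenario configuration for a Monte Carlo noise-propagation run
#'
#' Collects every knob of one simulated MRA study: the test-bed model, the
#' perturbation design, the noise level, the replicate structure, the
#' control strategy, the replicate-handling estimator, the number of Monte
#' Carlo runs and the root seed.
#'
#' Designs: `"kd80"`, `"kd50"`, `"kd25"` are 80/50/25% knockdowns
#' (\eqn{p_j} = 0.2, 0.5, 0.75) of every node, `"oe150"` is 150%
#' overexpression (\eqn{p_j = 1.5}), and `"mixture"` combines one
#' realization each of the 80, 50 and 25% knockdowns as a replicate stack.
#'
#' @param model `"mapk"` or `"p53"`.
#' @param design one of `"kd80"`, `"kd50"`, `"kd25"`, `"oe150"`,
#'   `"mixture"`.
#' @param sigma_eta,sigma_eps noise standard deviations (see
#'   [noise_spec()]); the study grid uses \eqn{\sigma_\eta \in \{0.05, 0.1,
#'   0.2\}} and \eqn{\sigma_\varepsilon \in \{0.1, 0.2, 0.5\}}.
#' @param replicates replicates per perturbation experiment (1, 3 or 6 in
#'   the study; any >= 1 accepted). Under `"mixture"` this is the number of
#'   replicates per knockdown strength.
#' @param control_strategy `"cs1"` (shared control) or `"cs2"`.
#' @param estimator `"mean"`, `"ols"` or `"tls"` (see [mra()]).
#' @param runs number of Monte Carlo runs.
#' @param seed root RNG seed; together with the configuration it fully
#'   determines every numeric output.
#' @return Object of class `"mra_scenario"`.
#' @export
mra_scenario <- function(model = c("mapk", "p53"),
                         design = c("kd80", "kd50", "kd25", "oe150",
                                    "mixture"),
                         sigma_eta = 0.1, sigma_eps = 0.2,
                         replicates = 1L,
                         control_strategy = c("cs1", "cs2"),
                         estimator = c("mean", "ols", "tls"),
                         runs = 1000L, seed = 1L) {
  structure(list(model = match.arg(model), design = match.arg(design),
                 sigma_eta = sigma_eta, sigma_eps = sigma_eps,
                 replicates = as.integer(replicates),
                 control_strategy = match.arg(control_strategy),
                 estimator = match.arg(estimator),
                 runs = as.integer(runs), seed = as.integer(seed)),
            class = "mra_scenario")
}

#' @export
print.mra_scenario <- function(x, ...) {
  cat(sprintf(paste0("MRA scenario: model %s, design %s, sigma_eta %g, ",
                     "sigma_eps %g, %d replicate(s), %s, estimator %s, ",
                     "%d runs, seed %d\n"),
              x$model, x$design, x$sigma_eta, x$sigma_eps, x$replicates,
              toupper(x$control_strategy), x$estimator, x$runs, x$seed))
  invisible(x)
}

design_strengths <- function(design) {
  switch(design,
         kd80 = list(0.2), kd50 = list(0.5), kd25 = list(0.75),
         oe150 = list(1.5), mixture = list(0.2, 0.5, 0.75))
}

# Off-diagonal coefficient bookkeeping (row-major over i, skipping i = j).
offdiag_index <- function(n) {
  i <- rep(seq_len(n), each = n - 1)
  j <- unlist(lapply(seq_len(n), function(k) setdiff(seq_len(n), k)))
  data.frame(i = i, j = j, label = paste0("r", i, j))
}

#' Run one Monte Carlo noise-propagation scenario
#'
#' Computes the noise-free perturbation profile(s) of the scenario once,
#' then for each Monte Carlo run draws a noisy measurement set, applies
#' transformation T1 per replicate and the configured estimator (T2), and
#' stores the resulting LRC estimate together with the replicate-mean GRC
#' matrix and the sign-aware fit quality of the run. Runs that hit a
#' numerical domain failure (zero denominator in T1, rank-deficient or
#' degenerate T2 system) are dropped and counted by reason, never imputed.
#'
#' Per-coefficient robust summaries (bias of median relative to the true
#' Jacobian-derived LRC, IQR, LMC, RMC) are computed on the valid runs;
#' the intrinsic bias of the design is reported alongside.
#'
#' @param scenario an `"mra_scenario"`.
#' @param keep_runs keep the per-run estimate matrices (default `TRUE`;
#'   required for the internal-consistency audit and custom summaries).
#' @return Object of class `"mra_mc"`; see `summary()`, `plot()`,
#'   [grc_tail_summary()] and [sign_correct_rate()].
#' @export
mra_montecarlo <- function(scenario, keep_runs = TRUE) {
  stopifnot(inherits(scenario, "mra_scenario"), scenario$runs >= 1)
  model <- mra_model(scenario$model)
  n <- model$n_nodes
  idx <- offdiag_index(n)
  profiles <- lapply(design_strengths(scenario$design),
                     function(s) perturbation_response(model, rep(s, n)))
  truth <- true_lrc(model)
  nf_stack <- lapply(profiles, grc_matrix)
  r_nf <- solve_lrc_ols(nf_stack)
  intrinsic <- abs(r_nf - truth); diag(intrinsic) <- 0
  grc_nf <- Reduce(`+`, nf_stack) / length(nf_stack)

  set.seed(scenario$seed)
  run_seeds <- sample.int(2147483646L, scenario$runs)

  lrc_runs <- matrix(NA_real_, scenario$runs, nrow(idx),
                     dimnames = list(NULL, idx$label))
  grc_runs <- matrix(NA_real_, scenario$runs, n * n)
  fitq <- rep(NA_real_, scenario$runs)
  drop_reasons <- character(0)
  for (t in seq_len(scenario$runs)) {
    est <- tryCatch({
      stack <- list()
      for (k in seq_along(profiles)) {
        sub_seed <- (run_seeds[t] + 7919L * (k - 1L)) %% 2147483646L + 1L
        ms <- sample_measurements(profiles[[k]],
                                  noise_spec(scenario$sigma_eta,
                                             scenario$sigma_eps, sub_seed),
                                  replicates = scenario$replicates,
                                  strategy = scenario$control_strategy)
        stack <- c(stack, grc_replicates(ms))
      }
      list(lrc = mra(stack, scenario$estimator)$lrc,
           grc = Reduce(`+`, stack) / length(stack))
    }, error = function(e) e)
    if (inherits(est, "error")) {
      drop_reasons <- c(drop_reasons, conditionMessage(est))
      next
    }
    lrc_runs[t, ] <- est$lrc[cbind(idx$i, idx$j)]
    grc_runs[t, ] <- as.numeric(est$grc)
    fitq[t] <- fit_quality(est$lrc, model$reference_structure)$auc
  }
  valid <- !is.na(lrc_runs[, 1])
  n_dropped <- sum(!valid)

  summaries <- do.call(rbind, lapply(seq_len(nrow(idx)), function(k) {
    # robust summaries need a minimal sample; smoke-sized runs skip them
    s <- if (sum(valid) >= 10) {
      as.data.frame(summarize_sample(lrc_runs[valid, k],
                                     reference = truth[idx$i[k], idx$j[k]],
                                     n_dropped = n_dropped))
    } else {
      data.frame(median = NA_real_, bias_of_median = NA_real_,
                 iqr = NA_real_, lmc = NA_real_, rmc = NA_real_,
                 n_valid = sum(valid), n_dropped = n_dropped)
    }
    cbind(data.frame(coefficient = idx$label[k],
                     true = truth[idx$i[k], idx$j[k]],
                     noise_free = r_nf[idx$i[k], idx$j[k]],
                     intrinsic_bias = intrinsic[idx$i[k], idx$j[k]]),
          s)
  }))

  out <- list(scenario = scenario, true_lrc = truth, lrc_noise_free = r_nf,
              intrinsic_bias = intrinsic, grc_noise_free = grc_nf,
              reference_structure = model$reference_structure,
              summaries = summaries, fit_quality = fitq[valid],
              n_valid = sum(valid), n_dropped = n_dropped,
              drop_reasons = drop_reasons, coef_index = idx)
  if (keep_runs) {
    out$lrc_runs <- lrc_runs[valid, , drop = FALSE]
    out$grc_runs <- grc_runs[valid, , drop = FALSE]
  }
  structure(out, class = "mra_mc")
}

#' @export
print.mra_mc <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("%d valid runs, %d dropped; mean fit quality %.3f\n",
              x$n_valid, x$n_dropped, mean(x$fit_quality)))
  invisible(x)
}

#' @export
summary.mra_mc <- function(object, ...) object$summaries

#' @export
plot.mra_mc <- function(x, ...) {
  if (is.null(x$lrc_runs))
    stop("per-run estimates were not kept (keep_runs = FALSE)")
  graphics::boxplot(as.data.frame(x$lrc_runs),
                    ylab = "estimated LRC", ...)
  graphics::points(seq_len(ncol(x$lrc_runs)),
                   x$true_lrc[cbind(x$coef_index$i, x$coef_index$j)],
                   pch = 4, col = 2)
  invisible(x)
}

#' Robust tail summary of the GRC entries of a Monte Carlo result
#'
#' Summarizes each entry of the (replicate-mean) global response
#' coefficient matrix across Monte Carlo runs, relative to its noise-free
#' value — the input-side counterpart of `summary()` on the LRCs, used to
#' show where the heavy tails enter the workflow.
#'
#' @param mc an `"mra_mc"` result with kept runs.
#' @return Data frame with one row per GRC entry.
#' @export
grc_tail_summary <- function(mc) {
  stopifnot(inherits(mc, "mra_mc"))
  if (is.null(mc$grc_runs)) stop("per-run GRCs were not kept")
  n <- nrow(mc$grc_noise_free)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  do.call(rbind, lapply(seq_len(nrow(ij)), function(k) {
    s <- summarize_sample(mc$grc_runs[, k],
                          reference = mc$grc_noise_free[ij$i[k], ij$j[k]],
                          n_dropped = mc$n_dropped)
    cbind(data.frame(entry = paste0("R", ij$i[k], ij$j[k])),
          as.data.frame(s))
  }))
}

#' Fraction of runs with a fully sign-correct edge set
#'
#' The share of valid Monte Carlo runs in which every true edge of the
#' reference structure was estimated with the correct sign — a simple
#' qualitative-recovery rate.
#'
#' @param mc an `"mra_mc"` result with kept runs.
#' @return Numeric scalar in [0, 1].
#' @export
sign_correct_rate <- function(mc) {
  stopifnot(inherits(mc, "mra_mc"))
  if (is.null(mc$lrc_runs)) stop("per-run estimates were not kept")
  idx <- mc$coef_index
  ref <- mc$reference_structure[cbind(idx$i, idx$j)]
  edges <- which(ref != 0)
  ok <- vapply(seq_len(nrow(mc$lrc_runs)), function(t)
    all(sign(mc$lrc_runs[t, edges]) == sign(ref[edges])), TRUE)
  mean(ok)
}

#' Run a grid of Monte Carlo scenarios
#'
#' Executes each scenario with an independent sub-seed derived from `seed`
#' and combines the per-coefficient summaries into one tidy data frame
#' keyed by the scenario settings, suitable for comparison plots across
#' noise levels, designs, control strategies and estimators.
#'
#' @param scenarios list of `"mra_scenario"` objects (their own seeds are
#'   overridden by derived sub-seeds).
#' @param seed root seed for the whole grid.
#' @param keep_results also return the full `"mra_mc"` objects.
#' @return Object of class `"mra_grid"`: list with `table` (tidy summary
#'   data frame) and, optionally, `results`.
#' @export
run_scenario_grid <- function(scenarios, seed = 1L, keep_results = FALSE) {
  stopifnot(length(scenarios) >= 1)
  rows <- list()
  results <- list()
  for (k in seq_along(scenarios)) {
    sc <- scenarios[[k]]
    sc$seed <- (as.integer(seed) + 104729L * k) %% 2147483646L + 1L
    mc <- mra_montecarlo(sc, keep_runs = keep_results)
    key <- data.frame(model = sc$model, design = sc$design,
                      sigma_eta = sc$sigma_eta, sigma_eps = sc$sigma_eps,
                      replicates = sc$replicates,
                      control_strategy = sc$control_strategy,
                      estimator = sc$estimator, runs = sc$runs)
    rows[[k]] <- cbind(key, mc$summaries,
                       mean_fit_quality = mean(mc$fit_quality))
    if (keep_results) results[[k]] <- mc
  }
  structure(list(table = do.call(rbind, rows),
                 results = if (keep_results) results),
            class = "mra_grid")
}

#' @export
print.mra_grid <- function(x, ...) {
  cat("MRA scenario grid:", length(unique(interaction(
    x$table$model, x$table$design, x$table$sigma_eta, x$table$sigma_eps,
    x$table$replicates, x$table$control_strategy, x$table$estimator))),
    "scenarios,", nrow(x$table), "summary rows\n")
  invisible(x)
}

#' Persist a Monte Carlo result to plain-text files
#'
#' Writes `estimates.csv` (per-run LRC estimates and fit quality),
#' `summaries.csv` (per-coefficient robust summaries) and `config.yaml`
#' (the scenario, for provenance) into a directory.
#'
#' @param mc an `"mra_mc"` result with kept runs.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(mc, dir) {
  stopifnot(inherits(mc, "mra_mc"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(mc$lrc_runs))
    utils::write.csv(cbind(as.data.frame(mc$lrc_runs),
                           fit_quality = mc$fit_quality),
                     file.path(dir, "estimates.csv"), row.names = FALSE)
  utils::write.csv(mc$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  cfg <- unclass(mc$scenario)
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  } else {
    dput(cfg, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
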