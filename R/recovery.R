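# Parameter-recovery simulation: the pipeline's own validation loop.
# Simulate at a known truth, fit, and score bias and interval coverage.

#' Run a parameter-recovery study
#'
#' For each replicate: simulate a dataset at the given ground truth and
#' study design, fit the model with the matching candidate (precursor
#' and recruitment mode), and score the posterior against the truth.
#' Reports, per replicate and parameter, the posterior median, relative
#' bias, and whether the central 95% credible interval covers the true
#' value.
#'
#' @param truth A [trm_truth()] or preset name (see [default_truths()]).
#' @param design A [study_design()].
#' @param n_replicates Number of simulate-fit replicates (0 allowed:
#'   returns an empty report).
#' @param seed Integer seed; replicate r uses `seed + r` for simulation
#'   and fitting.
#' @param chains,warmup,iter MCMC settings passed to [trm_config()].
#' @param parameters Which parameters to score.
#' @return A tibble of class `trm_recovery`: one row per
#'   replicate x parameter with `truth`, `median`, `rel_bias`,
#'   `covered`, plus the replicate's convergence flag.
#' @export
run_recovery_study <- function(truth, design = study_design(),
                               n_replicates = 5, seed,
                               chains = 2, warmup = 500, iter = 500,
                               parameters = c("mu", "rho", "beta")) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.character(truth)) truth <- default_truths()[[truth]]
  stopifnot(inherits(truth, "trm_truth"))
  truth_vals <- c(mu = truth$params$mu, rho = truth$params$rho,
                  beta = truth$params$beta)
  if (n_replicates == 0) {
    out <- tibble::tibble(replicate = integer(), term = character(),
                          truth = numeric(), median = numeric(),
                          rel_bias = numeric(), covered = logical(),
                          converged = logical())
    class(out) <- c("trm_recovery", class(out))
    return(out)
  }
  rows <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    s <- as.integer(seed) + r
    d <- simulate_reporter_data(truth, design, seed = s)
    cfg <- trm_config(
      target_tissue = truth$target_tissue,
      target_subset = truth$target_subset,
      precursor = truth$precursor, mode = truth$params$mode,
      precursor_ki67 = truth$precursor_ki67, t0 = truth$t0,
      chains = chains, warmup = warmup, iter = iter, seed = s)
    fit <- suppressWarnings(fit_trm_model(d, cfg))
    sm <- summarize_posterior(fit, check_convergence = FALSE)
    sm <- sm[sm$term %in% parameters, ]
    tibble::tibble(
      replicate = r, term = sm$term,
      truth = unname(truth_vals[sm$term]),
      median = sm$median,
      rel_bias = sm$median / unname(truth_vals[sm$term]) - 1,
      covered = sm$lo95 <= unname(truth_vals[sm$term]) &
        unname(truth_vals[sm$term]) <= sm$hi95,
      converged = fit$converged)
  })
  class(rows) <- c("trm_recovery", class(rows))
  rows
}

#' Summarize a recovery study
#'
#' @param object A `trm_recovery` report.
#' @param ... Unused.
#' @return One row per parameter: mean relative bias, coverage of the
#'   95% intervals, and number of replicates.
#' @method glance trm_recovery
#' @export
glance.trm_recovery <- function(object, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), term),
    mean_rel_bias = mean(rel_bias),
    coverage = mean(covered),
    n_replicates = dplyr::n(),
    .groups = "drop")
}
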