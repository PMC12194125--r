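# Synthetic dual-reporter datasets. The generator reproduces the
# statistical structure of the study design: a single tamoxifen pulse at
# day 0, analysis from day 5, a 9-week chase in Ki67-DIVN mice (YFP and
# Ki67 readouts) and a 57-week chase in Cd4-FR mice (mTom readout),
# cross-sectional sampling (each mouse contributes one timepoint), and
# binomial counting noise on the labelled fractions.

#' Study design for a synthetic fate-reporter experiment
#'
#' Defaults mirror the dual-strain design: 31 Ki67-DIVN mice sampled
#' over days 5-63 and 36 Cd4-FR mice over days 5-399, 2-4 mice per
#' timepoint, with per-channel sampled-cell counts drawn log-normally
#' (log-mean log(2000), log-sd 0.5, floored at 20 cells) so binomial
#' noise is at tissue-realistic levels.
#'
#' @param n_ki67divn,n_cd4fr Number of mice per reporter strain.
#' @param window_ki67divn,window_cd4fr Chase window (days) per strain.
#' @param mice_per_timepoint Target number of mice sharing a timepoint.
#' @param log_mean_cells,log_sd_cells Log-normal parameters of the
#'   per-mouse, per-channel sampled-cell count.
#' @param min_cells Floor on sampled cells per channel.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_ki67divn = 31, n_cd4fr = 36,
                         window_ki67divn = c(5, 63),
                         window_cd4fr = c(5, 399),
                         mice_per_timepoint = 3,
                         log_mean_cells = log(2000),
                         log_sd_cells = 0.5,
                         min_cells = 20) {
  stopifnot(n_ki67divn >= 0, n_cd4fr >= 0,
            length(window_ki67divn) == 2L, length(window_cd4fr) == 2L,
            mice_per_timepoint >= 1, log_sd_cells >= 0, min_cells >= 1)
  structure(
    list(n_ki67divn = as.integer(n_ki67divn),
         n_cd4fr = as.integer(n_cd4fr),
         window_ki67divn = window_ki67divn,
         window_cd4fr = window_cd4fr,
         mice_per_timepoint = mice_per_timepoint,
         log_mean_cells = log_mean_cells,
         log_sd_cells = log_sd_cells,
         min_cells = min_cells),
    class = "study_design"
  )
}

# Quasi-uniform timepoint schedule over a chase window: whole days,
# round-robin assignment of mice to timepoints.
schedule_times <- function(n_mice, window, mice_per_timepoint) {
  if (n_mice == 0L) return(numeric(0))
  n_t <- max(1L, ceiling(n_mice / mice_per_timepoint))
  tp <- round(seq(window[1L], window[2L], length.out = n_t))
  tp[((seq_len(n_mice) - 1L) %% n_t) + 1L]
}

# Map a precursor population name to its (tissue, subset) location.
precursor_location <- function(precursor, target_tissue) {
  switch(precursor,
    naive = list(tissue = "LN", subset = "naive"),
    CM = list(tissue = "LN", subset = "CM"),
    EM = , TEM = list(tissue = "LN", subset = "TEM"),
    CD69neg = list(tissue = target_tissue, subset = "CD69neg"),
    stop("unknown precursor: ", precursor, call. = FALSE)
  )
}

#' Ground-truth record for synthetic data generation
#'
#' Bundles everything needed to simulate (and later score recovery of)
#' one target population: its kinetic parameters, the initial label
#' state at day 5, the precursor's YFP and mTom descriptor curves, and
#' the identities of target and precursor.
#'
#' @param params A [kinetic_params()] object.
#' @param initial Named vector/list: `yfp_ki67hi`, `yfp_ki67lo`,
#'   `yneg_ki67hi`, `yneg_ki67lo` (sum 1) and `mtom`, the state at t0.
#' @param precursor_yfp,precursor_mtom [precursor_descriptor()] objects.
#' @param precursor_ki67 Constant precursor Ki67-high fraction.
#' @param target_tissue,target_subset Target population identity.
#' @param precursor One of `"naive"`, `"CM"`, `"TEM"`, `"CD69neg"`.
#' @param t0 Analysis start, days post-treatment.
#' @return An object of class `trm_truth`.
#' @export
trm_truth <- function(params, initial, precursor_yfp, precursor_mtom,
                      precursor_ki67 = 0.05,
                      target_tissue = "skin", target_subset = "Trm69pos",
                      precursor = "CD69neg", t0 = 5) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(precursor_yfp, "precursor_descriptor"),
            inherits(precursor_mtom, "precursor_descriptor"))
  precursor_location(precursor, target_tissue)  # validates the name
  structure(
    list(params = params, initial = unlist(initial),
         precursor_yfp = precursor_yfp, precursor_mtom = precursor_mtom,
         precursor_ki67 = precursor_ki67,
         target_tissue = target_tissue, target_subset = target_subset,
         precursor = precursor, t0 = t0),
    class = "trm_truth"
  )
}

#' Built-in ground-truth presets
#'
#' Two presets encode the favoured models for each site:
#' \describe{
#'   \item{`skin_trm`}{CD69+ TRM in skin: replacement mu = 0.02/day,
#'     division rate rho = 1/49/day (7-week interdivision time),
#'     beta = 1/3/day, division-linked recruitment from the local
#'     CD69- population. Implied residence time 1/(mu+rho) ~ 24.5 d.}
#'   \item{`lp_trm`}{CD69+ TRM in gut lamina propria: mu = 0.055/day,
#'     rho = 1/63/day (9-week interdivision), beta = 1/3/day, quiescent
#'     recruitment from lymph-node effector-memory T cells. Implied
#'     residence ~ 14.1 d.}
#' }
#' Precursor curves are flat in YFP and decline roughly eight-fold in
#' mTom over a year, matching the qualitative trajectories of the
#' circulating subsets.
#'
#' @return A named list of [trm_truth()] objects.
#' @examples
#' tr <- default_truths()$skin_trm
#' 1 / (tr$params$mu + tr$params$rho)  # residence time, days
#' @export
default_truths <- function() {
  yfp_flat <- function(level, pop) {
    precursor_descriptor(a = qlogis(level), b = 0, c = 0.01,
                         label = "YFP", population = pop)
  }
  mtom_declining <- function(from, to, pop) {
    precursor_descriptor(a = qlogis(to), b = qlogis(from) - qlogis(to),
                         c = 0.01, label = "mTom", population = pop)
  }
  skin_initial <- c(yfp_ki67hi = 0.16, yfp_ki67lo = 0.04,
                    yneg_ki67hi = 0.12, yneg_ki67lo = 0.68, mtom = 0.40)
  lp_initial <- c(yfp_ki67hi = 0.07, yfp_ki67lo = 0.03,
                  yneg_ki67hi = 0.06, yneg_ki67lo = 0.84, mtom = 0.40)
  list(
    skin_trm = trm_truth(
      params = kinetic_params(mu = 0.02, rho = 1 / 49, beta = 1 / 3,
                              mode = "division_linked"),
      initial = skin_initial,
      precursor_yfp = yfp_flat(0.45, "CD69neg"),
      precursor_mtom = mtom_declining(0.40, 0.05, "CD69neg"),
      precursor_ki67 = 0.05,
      target_tissue = "skin", target_subset = "Trm69pos",
      precursor = "CD69neg"
    ),
    lp_trm = trm_truth(
      params = kinetic_params(mu = 0.055, rho = 1 / 63, beta = 1 / 3,
                              mode = "quiescent"),
      initial = lp_initial,
      precursor_yfp = yfp_flat(0.45, "TEM"),
      precursor_mtom = mtom_declining(0.40, 0.05, "TEM"),
      precursor_ki67 = 0.05,
      target_tissue = "LP", target_subset = "Trm69pos",
      precursor = "TEM"
    )
  )
}

# Deterministic channel predictions for a truth at given times.
truth_predictions <- function(truth, times) {
  times <- sort(unique(c(truth$t0, times)))
  tr <- solve_label_trajectories(
    truth$params,
    precursor_yfp = truth$precursor_yfp,
    precursor_mtom = truth$precursor_mtom,
    precursor_ki67 = truth$precursor_ki67,
    initial = truth$initial,
    times = times
  )
  tr$prec_yfp <- eval_precursor(truth$precursor_yfp, tr$time, t0 = truth$t0)
  tr$prec_mtom <- eval_precursor(truth$precursor_mtom, tr$time,
                                 t0 = truth$t0)
  tr
}

#' Simulate a dual-reporter dataset from a ground truth
#'
#' For every mouse and its scheduled timepoint, the deterministic model
#' trajectory gives each channel's labelled fraction; the observed count
#' is then binomial in the (log-normally drawn) number of sampled cells.
#' Ki67-DIVN mice contribute the target's YFP+ fraction, Ki67-high
#' fractions among YFP+ and YFP- target cells, and the precursor's YFP+
#' fraction; Cd4-FR mice contribute the target's and precursor's mTom+
#' fractions. The same (truth, design, seed) always yields the same
#' table.
#'
#' @param truth A [trm_truth()] object (or preset name, see
#'   [default_truths()]).
#' @param design A [study_design()].
#' @param seed Integer RNG seed (required).
#' @return A validated observation tibble; the generating truth is
#'   attached as attribute `"truth"`.
#' @examples
#' d <- simulate_reporter_data("skin_trm",
#'                             study_design(n_ki67divn = 4, n_cd4fr = 4),
#'                             seed = 7)
#' dplyr::count(d, strain, channel)
#' @export
simulate_reporter_data <- function(truth, design = study_design(), seed) {
  if (is.character(truth)) {
    presets <- default_truths()
    if (!truth %in% names(presets)) {
      stop("unknown truth preset: ", truth, call. = FALSE)
    }
    truth <- presets[[truth]]
  }
  stopifnot(inherits(truth, "trm_truth"), inherits(design, "study_design"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(as.integer(seed))

  prec_loc <- precursor_location(truth$precursor, truth$target_tissue)
  t_ki <- schedule_times(design$n_ki67divn, design$window_ki67divn,
                         design$mice_per_timepoint)
  t_cd <- schedule_times(design$n_cd4fr, design$window_cd4fr,
                         design$mice_per_timepoint)

  all_times <- c(t_ki, t_cd)
  if (length(all_times) == 0L) {
    out <- tibble::tibble(
      mouse_id = character(), strain = character(), t_days = numeric(),
      tissue = character(), subset = character(), channel = character(),
      n_pos = integer(), n_total = integer())
    attr(out, "truth") <- truth
    return(out)
  }

  pred <- truth_predictions(truth, all_times)
  at <- function(col, t) pred[[col]][match(t, pred$time)]

  draw_row <- function(mouse, strain, t, tissue, subset, channel, p) {
    n_tot <- max(design$min_cells,
                 round(rlnorm(1, design$log_mean_cells, design$log_sd_cells)))
    tibble::tibble(mouse_id = mouse, strain = strain, t_days = t,
                   tissue = tissue, subset = subset, channel = channel,
                   n_pos = rbinom(1L, n_tot, p), n_total = as.integer(n_tot))
  }

  rows <- list()
  for (i in seq_along(t_ki)) {
    m <- sprintf("KD%02d", i); t <- t_ki[i]
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(
      draw_row(m, "Ki67DIVN", t, truth$target_tissue, truth$target_subset,
               "yfp_pos", at("yfp", t)),
      draw_row(m, "Ki67DIVN", t, truth$target_tissue, truth$target_subset,
               "ki67hi_given_yfp_pos", at("ki67hi_yfp_pos", t)),
      draw_row(m, "Ki67DIVN", t, truth$target_tissue, truth$target_subset,
               "ki67hi_given_yfp_neg", at("ki67hi_yfp_neg", t)),
      draw_row(m, "Ki67DIVN", t, prec_loc$tissue, prec_loc$subset,
               "yfp_pos", at("prec_yfp", t))
    )
  }
  for (i in seq_along(t_cd)) {
    m <- sprintf("CF%02d", i); t <- t_cd[i]
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(
      draw_row(m, "Cd4FR", t, truth$target_tissue, truth$target_subset,
               "mtom_pos", at("frac_mtom", t)),
      draw_row(m, "Cd4FR", t, prec_loc$tissue, prec_loc$subset,
               "mtom_pos", at("prec_mtom", t))
    )
  }
  out <- dplyr::bind_rows(rows)
  validate_observations(out)
  attr(out, "truth") <- truth
  out
}

#' Serialize / restore a ground-truth record as JSON
#'
#' @param truth A [trm_truth()] object.
#' @param path File path for the JSON representation.
#' @return `write_truth()` returns `path` invisibly; `read_truth()`
#'   returns the restored `trm_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "trm_truth"))
  x <- list(
    params = list(mu = truth$params$mu, rho = truth$params$rho,
                  beta = truth$params$beta, mode = truth$params$mode,
                  precursor_ki67 = truth$params$precursor_ki67),
    initial = as.list(truth$initial),
    precursor_yfp = unclass(truth$precursor_yfp),
    precursor_mtom = unclass(truth$precursor_mtom),
    precursor_ki67 = truth$precursor_ki67,
    target_tissue = truth$target_tissue,
    target_subset = truth$target_subset,
    precursor = truth$precursor,
    t0 = truth$t0
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  desc <- function(d) {
    precursor_descriptor(a = d$a, b = d$b, c = d$c, b2 = d$b2, c2 = d$c2,
                         label = d$label, population = d$population)
  }
  trm_truth(
    params = kinetic_params(mu = x$params$mu, rho = x$params$rho,
                            beta = x$params$beta, mode = x$params$mode,
                            precursor_ki67 = x$params$precursor_ki67),
    initial = unlist(x$initial),
    precursor_yfp = desc(x$precursor_yfp),
    precursor_mtom = desc(x$precursor_mtom),
    precursor_ki67 = x$precursor_ki67,
    target_tissue = x$target_tissue, target_subset = x$target_subset,
    precursor = x$precursor, t0 = x$t0
  )
}
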