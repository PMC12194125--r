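# Observation schema and likelihood. One row = one mouse x channel
# count: n_pos label-positive cells among n_total sampled. Channels are
# strain-specific: mTom is read out in Cd4-FR mice, YFP and Ki67-by-YFP
# in Ki67-DIVN mice.

OBS_COLUMNS <- c("mouse_id", "strain", "t_days", "tissue", "subset",
                 "channel", "n_pos", "n_total")
OBS_STRAINS <- c("Cd4FR", "Ki67DIVN")
OBS_TISSUES <- c("skin", "LP", "LN")
OBS_SUBSETS <- c("EM", "Trm69pos", "CD69neg", "naive", "CM", "TEM")
OBS_CHANNELS <- c("mtom_pos", "yfp_pos", "ki67hi_given_yfp_pos",
                  "ki67hi_given_yfp_neg")
STRAIN_CHANNELS <- list(
  Cd4FR = "mtom_pos",
  Ki67DIVN = c("yfp_pos", "ki67hi_given_yfp_pos", "ki67hi_given_yfp_neg")
)

#' Validate a table of fate-reporter observations
#'
#' Checks an observation table against the package schema: required
#' columns; known strain / tissue / subset / channel levels; integer
#' counts with `0 <= n_pos <= n_total`, `n_total > 0`; non-negative
#' times; and channel-strain consistency (mTom only in Cd4-FR mice,
#' YFP/Ki67 channels only in Ki67-DIVN mice).
#'
#' @param data A data frame of observations (one row per
#'   mouse x channel count).
#' @param collect If `TRUE`, return a tibble of violations (columns
#'   `row`, `problem`) instead of erroring; an empty tibble means the
#'   table is valid.
#' @return The validated data as a tibble (invisibly), or the violations
#'   tibble when `collect = TRUE`.
#' @examples
#' d <- simulate_reporter_data(default_truths()$skin_trm,
#'                             study_design(n_ki67divn = 2, n_cd4fr = 2),
#'                             seed = 1)
#' validate_observations(d)
#' @export
validate_observations <- function(data, collect = FALSE) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(OBS_COLUMNS, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- tibble::as_tibble(data)
  probs <- list()
  note <- function(rows, what) {
    if (length(rows)) {
      probs[[length(probs) + 1L]] <<- tibble::tibble(row = rows,
                                                     problem = what)
    }
  }
  note(which(!d$strain %in% OBS_STRAINS), "unknown strain")
  note(which(!d$tissue %in% OBS_TISSUES), "unknown tissue")
  note(which(!d$subset %in% OBS_SUBSETS), "unknown subset")
  note(which(!d$channel %in% OBS_CHANNELS), "unknown channel")
  note(which(!is.finite(d$t_days) | d$t_days < 0), "t_days must be >= 0")
  note(which(!is.finite(d$n_total) | d$n_total <= 0 |
               d$n_total != round(d$n_total)),
       "n_total must be a positive integer")
  note(which(!is.finite(d$n_pos) | d$n_pos < 0 |
               d$n_pos != round(d$n_pos)),
       "n_pos must be a non-negative integer")
  note(which(is.finite(d$n_pos) & is.finite(d$n_total) &
               d$n_pos > d$n_total), "n_pos exceeds n_total")
  bad_chan <- which(
    (d$strain == "Cd4FR" & !d$channel %in% STRAIN_CHANNELS$Cd4FR) |
    (d$strain == "Ki67DIVN" & !d$channel %in% STRAIN_CHANNELS$Ki67DIVN)
  )
  note(bad_chan, "channel not available in this strain")

  violations <- if (length(probs)) {
    dplyr::arrange(dplyr::bind_rows(probs), row)
  } else {
    tibble::tibble(row = integer(), problem = character())
  }
  if (collect) return(violations)
  if (nrow(violations)) {
    msg <- utils::head(
      sprintf("  row %d: %s", violations$row, violations$problem), 20L)
    stop("invalid observation table (", nrow(violations), " problem(s)):\n",
         paste(msg, collapse = "\n"), call. = FALSE)
  }
  invisible(d)
}

#' Drop observations taken before the analysis window opens
#'
#' Reporter expression is still being induced during the first days
#' after tamoxifen treatment, so label frequencies before day `t0` do
#' not reflect cellular dynamics and are excluded from fitting.
#'
#' @param data Observation data frame.
#' @param t0 Start of the fit window in days post-treatment (default 5).
#' @param quiet Suppress the message reporting how many rows were
#'   removed.
#' @return The filtered tibble, original row order preserved.
#' @export
filter_fit_window <- function(data, t0 = 5, quiet = FALSE) {
  d <- tibble::as_tibble(data)
  keep <- d$t_days >= t0
  if (!quiet) {
    message("filter_fit_window: removed ", sum(!keep), " of ", nrow(d),
            " records before day ", t0)
  }
  d[keep, , drop = FALSE]
}

#' Binomial log-likelihood of one labelled-count observation
#'
#' The count of label-positive cells among the cells sampled from a
#' mouse is modelled as binomial at the model-predicted fraction,
#' clamped to `[eps, 1 - eps]` so the log-likelihood is finite even when
#' the model predicts a fraction of exactly 0 or 1.
#'
#' @param n_pos,n_total Observed positive and total counts (vectors
#'   recycle).
#' @param predicted Model-predicted labelled fraction(s), in \[0, 1\].
#' @param eps Clamp width (default 1e-6).
#' @return Log-likelihood value(s); the sum over rows of a dataset is
#'   its total log-likelihood (mice and channels are independent).
#' @examples
#' pointwise_loglik(5, 10, 0.5)  # log C(10,5) - 10 log 2
#' @export
pointwise_loglik <- function(n_pos, n_total, predicted, eps = 1e-6) {
  if (any(n_total <= 0)) stop("`n_total` must be positive", call. = FALSE)
  if (any(n_pos < 0 | n_pos > n_total)) {
    stop("`n_pos` must lie in [0, n_total]", call. = FALSE)
  }
  if (any(!is.finite(predicted) | predicted < 0 | predicted > 1)) {
    stop("`predicted` must lie in [0, 1]", call. = FALSE)
  }
  p <- pmin(pmax(predicted, eps), 1 - eps)
  dbinom(n_pos, n_total, p, log = TRUE)
}

#' Read / write observation tables
#'
#' Plain-CSV round-tripping of the observation schema (UTF-8, header,
#' '.' decimal). `read_observations()` validates on read.
#'
#' @param path File path.
#' @param data Observation data frame.
#' @return `read_observations()` returns a validated tibble;
#'   `write_observations()` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  d <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_observations(d)
  d
}

#' @rdname read_observations
#' @export
write_observations <- function(data, path) {
  validate_observations(data)
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}
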