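# ggplot2 visualizations of data, fits and comparisons.

CHANNEL_LABELS <- c(
  mtom_pos = "mTom+ fraction",
  yfp_pos = "YFP+ fraction",
  ki67hi_given_yfp_pos = "Ki67hi | YFP+",
  ki67hi_given_yfp_neg = "Ki67hi | YFP-"
)

#' Plot an observation table
#'
#' Observed labelled fractions per mouse against time, faceted by
#' channel and population.
#'
#' @param data An observation table (see [validate_observations()]).
#' @return A ggplot object.
#' @export
plot_observations <- function(data) {
  d <- validate_observations(data)
  d$frac <- d$n_pos / d$n_total
  d$panel <- paste(d$tissue, d$subset, CHANNEL_LABELS[d$channel],
                   sep = " / ")
  ggplot2::ggplot(d, ggplot2::aes(t_days, frac)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "days post-treatment", y = "labelled fraction") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' @rdname autoplot-trmkin
#' @method autoplot trm_fit
#' @export
autoplot.trm_fit <- function(object, ...) {
  fit <- object
  tr <- fit_trajectories(fit)
  rec <- fit$records
  rec$frac <- rec$n_pos / rec$n_total
  rec$panel <- ifelse(rec$kind == "target",
                      paste("target:", CHANNEL_LABELS[rec$channel]),
                      paste("precursor:", CHANNEL_LABELS[rec$channel]))
  curve_map <- c("target: YFP+ fraction" = "yfp",
                 "target: mTom+ fraction" = "frac_mtom",
                 "target: Ki67hi | YFP+" = "ki67hi_yfp_pos",
                 "target: Ki67hi | YFP-" = "ki67hi_yfp_neg",
                 "precursor: YFP+ fraction" = "prec_yfp",
                 "precursor: mTom+ fraction" = "prec_mtom")
  curves <- purrr::map_dfr(names(curve_map), function(p) {
    tibble::tibble(panel = p, time = tr$time, pred = tr[[curve_map[p]]])
  })
  curves <- curves[curves$panel %in% unique(rec$panel), ]
  ggplot2::ggplot(rec, ggplot2::aes(t_days, frac)) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(time, pred), colour = "black") +
    ggplot2::geom_point(alpha = 0.6, size = 1.4, colour = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = "days post-treatment", y = "fraction",
                  title = sprintf("%s %s <- %s (%s), MAP trajectory",
                                  fit$config$target_tissue,
                                  fit$config$target_subset,
                                  fit$config$precursor,
                                  fit$config$mode)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' Autoplot methods
#'
#' `autoplot(<trm_fit>)` overlays the MAP trajectory on the fitted
#' per-mouse fractions, one facet per timecourse;
#' `autoplot(<trm_comparison>)` shows candidate model weights.
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-trmkin
NULL

#' @rdname autoplot-trmkin
#' @method autoplot trm_comparison
#' @export
autoplot.trm_comparison <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$candidate <- factor(d$candidate, levels = rev(d$candidate))
  ggplot2::ggplot(d, ggplot2::aes(weight, candidate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "model weight", y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_bw()
}
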