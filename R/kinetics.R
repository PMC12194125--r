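# Core label-kinetics model: a steady-state target population that
# self-renews at rate rho, is lost at total rate delta = rho + mu, and is
# topped up by immigrants arriving at fractional rate mu = theta/N whose
# label content follows the precursor population.

RECRUITMENT_MODES <- c("quiescent", "neutral", "division_linked")

#' Kinetic parameters of a steady-state resident population
#'
#' Bundles the per-day rate constants of the label-kinetics model:
#' fractional replacement by immigration `mu` (= theta / N for influx
#' theta cells/day into a population of constant size N), per-cell
#' division rate `rho` (mean interdivision time 1/rho), and the rate
#' `beta` at which cells revert from Ki67-high to Ki67-low (Ki67 is
#' expressed during division and for roughly 3-4 days afterwards, so
#' beta is about 1/3.5 per day). The total loss rate delta = rho + mu is
#' implied by the steady-state balance (influx + division = loss) and is
#' never stored separately.
#'
#' The recruitment `mode` fixes the Ki67-high fraction h among immigrant
#' cells: `"quiescent"` (h = 0), `"division_linked"` (h = 1), or
#' `"neutral"` (h equals the precursor's Ki67-high frequency, supplied
#' via `precursor_ki67`).
#'
#' @param mu Fractional replacement rate, per day (>= 0).
#' @param rho Per-cell division rate, per day (>= 0).
#' @param beta Ki67-high to Ki67-low transition rate, per day (> 0).
#' @param mode One of `"quiescent"`, `"neutral"`, `"division_linked"`.
#' @param precursor_ki67 Ki67-high fraction of the precursor, in \[0, 1\];
#'   required when `mode = "neutral"`, ignored otherwise.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(mu = 0.02, rho = 1 / 49, beta = 1 / 3,
#'                mode = "division_linked")
#' @export
kinetic_params <- function(mu, rho, beta, mode = "quiescent",
                           precursor_ki67 = NULL) {
  mode <- match.arg(mode, RECRUITMENT_MODES)
  for (nm in c("mu", "rho", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (mu < 0 || rho < 0) stop("`mu` and `rho` must be >= 0", call. = FALSE)
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  if (mode == "neutral") {
    if (is.null(precursor_ki67)) {
      stop("`precursor_ki67` is required when mode = \"neutral\"",
           call. = FALSE)
    }
    if (!is.numeric(precursor_ki67) || any(!is.finite(precursor_ki67)) ||
        any(precursor_ki67 < 0) || any(precursor_ki67 > 1)) {
      stop("`precursor_ki67` must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(mu = mu, rho = rho, beta = beta, mode = mode,
         precursor_ki67 = precursor_ki67),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  mu   = %.4g /day  (replacement %.2g%%/day)\n",
              x$mu, 100 * x$mu))
  cat(sprintf("  rho  = %.4g /day  (interdivision %.3g d)\n",
              x$rho, 1 / x$rho))
  cat(sprintf("  beta = %.4g /day  (Ki67-high duration %.3g d)\n",
              x$beta, 1 / x$beta))
  cat(sprintf("  delta = mu + rho = %.4g /day  (residence %.3g d)\n",
              x$mu + x$rho, 1 / (x$mu + x$rho)))
  cat("  recruitment mode:", x$mode, "\n")
  invisible(x)
}

# Coerce a precursor specification (constant, function of time, or
# precursor_descriptor) to a function of time returning a fraction.
as_precursor_fn <- function(x, t0 = 5, what = "precursor") {
  if (inherits(x, "precursor_descriptor")) {
    force(x)
    return(function(t) eval_precursor(x, t, t0 = t0))
  }
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1) {
    force(x)
    return(function(t) rep(x, length(t)))
  }
  stop("`", what, "` must be a fraction, a function of time, ",
       "or a precursor_descriptor", call. = FALSE)
}

# Ki67-high fraction among immigrants as a function of time.
immigrant_ki67_fn <- function(params, precursor_ki67_fn = NULL, t0 = 5) {
  switch(params$mode,
    quiescent = function(t) rep(0, length(t)),
    division_linked = function(t) rep(1, length(t)),
    neutral = {
      if (!is.null(precursor_ki67_fn)) {
        precursor_ki67_fn
      } else if (!is.null(params$precursor_ki67)) {
        as_precursor_fn(params$precursor_ki67, t0 = t0)
      } else {
        stop("neutral recruitment needs a precursor Ki67 frequency",
             call. = FALSE)
      }
    }
  )
}

#' Solve the label-kinetics trajectories of a target population
#'
#' Integrates the linear ODE system for the fractions of the target
#' population in the four YFP x Ki67 states, plus the mTom-positive
#' fraction (tracked in a separate reporter strain but governed by the
#' same turnover). With a = YFP+Ki67hi, b = YFP+Ki67lo, c = YFP-Ki67hi,
#' d = YFP-Ki67lo, precursor YFP frequency gY(t), immigrant Ki67-high
#' fraction h(t), and delta = rho + mu:
#' \deqn{da/dt = \mu g_Y h + \rho a + 2\rho b - (\beta+\delta) a}
#' \deqn{db/dt = \mu g_Y (1-h) + \beta a - (\rho+\delta) b}
#' \deqn{dc/dt = \mu (1-g_Y) h + \rho c + 2\rho d - (\beta+\delta) c}
#' \deqn{dd/dt = \mu (1-g_Y)(1-h) + \beta c - (\rho+\delta) d}
#' \deqn{dm/dt = \mu (g_m(t) - m)}
#' A dividing Ki67-low cell yields two Ki67-high daughters (the 2 rho
#' term); a dividing Ki67-high cell adds one net Ki67-high cell.
#'
#' @param params A [kinetic_params()] object.
#' @param precursor_yfp,precursor_mtom Precursor YFP+ / mTom+ frequency:
#'   a constant in \[0,1\], a function of time, or a
#'   [precursor_descriptor()].
#' @param initial Named list or vector with entries `yfp_ki67hi`,
#'   `yfp_ki67lo`, `yneg_ki67hi`, `yneg_ki67lo` (summing to 1) and
#'   `mtom` — the state at the first requested time.
#' @param times Increasing vector of times (days); the first entry is
#'   the time origin t0 at which `initial` applies (day 5 by default in
#'   this study design: earlier times fall in the reporter-induction
#'   window and are never modelled).
#' @param precursor_ki67 Optional precursor Ki67-high frequency
#'   (constant or function) used when `params$mode == "neutral"`.
#' @param rtol,atol Integrator tolerances (adaptive LSODA).
#' @return A tibble with one row per time: the five state fractions and
#'   the three observable ratios `yfp` (= a + b), `ki67hi_yfp_pos`
#'   (= a / (a+b), `NA` when the YFP+ fraction is below 1e-12) and
#'   `ki67hi_yfp_neg` (= c / (c+d)).
#' @examples
#' p <- kinetic_params(0.03, 0.02, 0.3, mode = "division_linked")
#' solve_label_trajectories(p, precursor_yfp = 0.4, precursor_mtom = 0.3,
#'   initial = c(yfp_ki67hi = 0.1, yfp_ki67lo = 0.1,
#'               yneg_ki67hi = 0.1, yneg_ki67lo = 0.7, mtom = 0.4),
#'   times = c(5, 20, 60))
#' @export
solve_label_trajectories <- function(params, precursor_yfp, precursor_mtom,
                                     initial, times,
                                     precursor_ki67 = NULL,
                                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(times) < 1L || any(!is.finite(times))) {
    stop("`times` must be finite", call. = FALSE)
  }
  if (is.unsorted(times, strictly = FALSE)) {
    stop("`times` must be sorted increasing", call. = FALSE)
  }
  t0 <- times[1L]
  ini <- unlist(initial)
  needed <- c("yfp_ki67hi", "yfp_ki67lo", "yneg_ki67hi", "yneg_ki67lo",
              "mtom")
  if (!all(needed %in% names(ini))) {
    stop("`initial` must name ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  y0 <- ini[needed]
  if (any(!is.finite(y0)) || any(y0 < -1e-12) || any(y0 > 1 + 1e-12)) {
    stop("initial fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(y0[1:4]) - 1) > 1e-9) {
    stop("initial YFP x Ki67 fractions must sum to 1", call. = FALSE)
  }

  gY <- as_precursor_fn(precursor_yfp, t0 = t0, what = "precursor_yfp")
  gM <- as_precursor_fn(precursor_mtom, t0 = t0, what = "precursor_mtom")
  hK <- immigrant_ki67_fn(
    params,
    precursor_ki67_fn = if (!is.null(precursor_ki67)) {
      as_precursor_fn(precursor_ki67, t0 = t0, what = "precursor_ki67")
    },
    t0 = t0
  )

  mu <- params$mu; rho <- params$rho; beta <- params$beta
  delta <- mu + rho

  rhs <- function(t, y, parms) {
    g <- gY(t); m_in <- gM(t); h <- hK(t)
    a <- y[1L]; b <- y[2L]; cc <- y[3L]; d <- y[4L]; m <- y[5L]
    list(c(
      mu * g * h + rho * a + 2 * rho * b - (beta + delta) * a,
      mu * g * (1 - h) + beta * a - (rho + delta) * b,
      mu * (1 - g) * h + rho * cc + 2 * rho * d - (beta + delta) * cc,
      mu * (1 - g) * (1 - h) + beta * cc - (rho + delta) * d,
      mu * (m_in - m)
    ))
  }

  if (length(times) == 1L) {
    sol <- matrix(c(times, y0), nrow = 1L)
  } else {
    sol <- deSolve::lsoda(y = unname(y0), times = times, func = rhs,
                          parms = NULL, rtol = rtol, atol = atol)
  }
  a <- sol[, 2L]; b <- sol[, 3L]; cc <- sol[, 4L]; d <- sol[, 5L]
  m <- sol[, 6L]
  ypos <- a + b
  tibble::tibble(
    time = sol[, 1L],
    frac_yfp_ki67hi = a,
    frac_yfp_ki67lo = b,
    frac_yneg_ki67hi = cc,
    frac_yneg_ki67lo = d,
    frac_mtom = m,
    yfp = ypos,
    ki67hi_yfp_pos = ifelse(ypos < 1e-12, NA_real_, a / ypos),
    ki67hi_yfp_neg = ifelse((cc + d) < 1e-12, NA_real_, cc / (cc + d))
  )
}

#' Equilibrium Ki67-high fraction of the target population
#'
#' Closed-form steady state of the kinetics model: the total Ki67-high
#' fraction converges to
#' \deqn{k = (\mu h + 2\rho) / (\beta + \delta + \rho)}
#' with delta = rho + mu and h the immigrant Ki67-high fraction fixed by
#' the recruitment mode (0 quiescent, 1 division-linked, the precursor's
#' constant Ki67 frequency for neutral). This is the quantity measured
#' directly by Ki67 staining of the population in bulk and is the basis
#' of the Ki67-only residence-time bounds in [ki67_residence_bounds()].
#'
#' @param params A [kinetic_params()] object.
#' @return The equilibrium Ki67-high fraction, in \[0, 1\].
#' @examples
#' # skin TRM, division-linked recruitment, 7-week interdivision time
#' steady_state_ki67_fraction(
#'   kinetic_params(0.02, 1 / 49, 1 / 3, mode = "division_linked"))
#' @export
steady_state_ki67_fraction <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  h <- switch(params$mode,
    quiescent = 0,
    division_linked = 1,
    neutral = {
      if (is.null(params$precursor_ki67)) {
        stop("neutral recruitment needs `precursor_ki67`", call. = FALSE)
      }
      params$precursor_ki67[[1L]]
    }
  )
  mu <- params$mu; rho <- params$rho; beta <- params$beta
  if (mu + rho == 0) return(0)
  delta <- mu + rho
  k <- (mu * h + 2 * rho) / (beta + delta + rho)
  min(max(k, 0), 1)
}
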