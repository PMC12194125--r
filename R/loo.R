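# Leave-one-out model comparison. PSIS-LOO approximates each record's
# out-of-sample log predictive density by importance sampling over the
# posterior draws, stabilizing the importance weights by fitting a
# generalized Pareto distribution to their upper tail (Pareto-smoothed
# importance sampling). Candidate models are then combined into
# normalized weights by stacking of predictive distributions (default)
# or pseudo-BMA+ with a Bayesian bootstrap.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Empirical-Bayes fit of a generalized Pareto distribution to sorted
# exceedances (Zhang & Stephens 2009), with the usual weak prior
# shrinking the shape toward 0.5. Returns shape k and scale sigma.
gpd_fit <- function(x) {
  n <- length(x)
  prior_bs <- 3
  prior_k <- 10
  m_est <- 30L + floor(sqrt(n))
  b <- 1 - sqrt(m_est / (seq_len(m_est) - 0.5))
  b <- b / (prior_bs * x[floor(n / 4 + 0.5)])
  b <- b + 1 / x[n]
  k_ary <- vapply(b, function(bj) mean(log1p(-bj * x)), numeric(1))
  len_scale <- n * (log(-(b / k_ary)) - k_ary - 1)
  w <- 1 / vapply(seq_along(b), function(j) {
    sum(exp(len_scale - len_scale[j]))
  }, numeric(1))
  keep <- w >= 10 * .Machine$double.eps
  w <- w[keep] / sum(w[keep])
  b_post <- sum(b[keep] * w)
  k_post <- mean(log1p(-b_post * x))
  sigma <- -k_post / b_post
  k_post <- (n * k_post + prior_k * 0.5) / (n + prior_k)
  list(k = k_post, sigma = sigma)
}

# Inverse generalized Pareto distribution function.
gpd_quantile <- function(p, k, sigma) {
  if (sigma <= 0) return(rep(NaN, length(p)))
  if (abs(k) < .Machine$double.eps) {
    sigma * (-log1p(-p))
  } else {
    sigma * expm1(-k * log1p(-p)) / k
  }
}

# Pareto-smooth one vector of log importance ratios. Returns the
# smoothed (unnormalized, max-shifted) log weights and the tail shape.
psis_smooth <- function(lw) {
  s <- length(lw)
  lw <- lw - max(lw)
  ord <- order(lw)
  cutoff_ind <- s - as.integer(ceiling(min(s / 5, 3 * sqrt(s))))
  if (cutoff_ind < 1L) {
    return(list(log_weights = lw, khat = Inf))
  }
  xcutoff <- max(lw[ord[cutoff_ind]], log(.Machine$double.xmin))
  tailinds <- which(lw > xcutoff)
  if (length(tailinds) <= 4L) {
    return(list(log_weights = lw, khat = Inf))
  }
  tail_si <- order(lw[tailinds])
  exceed <- exp(lw[tailinds][tail_si]) - exp(xcutoff)
  fit <- gpd_fit(exceed)
  if (is.finite(fit$k)) {
    m <- length(tailinds)
    sti <- (seq_len(m) - 0.5) / m
    smoothed <- log(gpd_quantile(sti, fit$k, fit$sigma) + exp(xcutoff))
    lw[tailinds[tail_si]] <- smoothed
    lw[lw > 0] <- 0
  }
  list(log_weights = lw, khat = fit$k)
}

#' PSIS-LOO expected log predictive density of a fit
#'
#' Computes the Pareto-smoothed importance-sampling estimate of
#' leave-one-out expected log predictive density (elpd) from a fit's
#' pointwise log-likelihood matrix. By default only the target
#' population's channels enter: candidate models share the precursor
#' data unequally, so precursor-descriptor terms are excluded from
#' comparison.
#'
#' @param fit A `trm_fit`, or a draws x records pointwise
#'   log-likelihood matrix.
#' @param records Which records to include when `fit` is a `trm_fit`:
#'   `"target"` (default), `"all"`, or an integer index vector.
#' @return A list of class `trm_loo`: `elpd`, `se`, `pointwise` (per
#'   record elpd), `pareto_k`, and `n_high_k` (count of k > 0.7).
#' @export
compute_loo <- function(fit, records = "target") {
  if (inherits(fit, "trm_fit")) {
    idx <- if (identical(records, "target")) {
      which(fit$records$kind == "target")
    } else if (identical(records, "all")) {
      seq_len(ncol(fit$pointwise))
    } else {
      as.integer(records)
    }
    ll <- fit$pointwise[, idx, drop = FALSE]
  } else {
    ll <- as.matrix(fit)
    idx <- seq_len(ncol(ll))
  }
  if (ncol(ll) < 2L) {
    stop("need at least 2 pointwise records for LOO", call. = FALSE)
  }
  s <- nrow(ll)
  elpd_i <- numeric(ncol(ll))
  khat <- numeric(ncol(ll))
  for (i in seq_len(ncol(ll))) {
    sm <- psis_smooth(-ll[, i])
    lw <- sm$log_weights
    elpd_i[i] <- logsumexp(lw + ll[, i]) - logsumexp(lw)
    khat[i] <- sm$khat
  }
  n <- length(elpd_i)
  structure(
    list(elpd = sum(elpd_i),
         se = sqrt(n * var(elpd_i)),
         pointwise = elpd_i,
         pareto_k = khat,
         n_high_k = sum(is.finite(khat) & khat > 0.7) +
           sum(is.infinite(khat)),
         record_index = idx),
    class = "trm_loo"
  )
}

#' @export
print.trm_loo <- function(x, ...) {
  cat(sprintf("<trm_loo> elpd = %.2f (se %.2f), %d records, %d with k > 0.7\n",
              x$elpd, x$se, length(x$pointwise), x$n_high_k))
  invisible(x)
}

# Stacking: maximize sum_i log sum_k w_k exp(lpd_ik) over the simplex,
# via a softmax parametrization and BFGS.
stacking_weights <- function(lpd) {
  n <- nrow(lpd); k <- ncol(lpd)
  shift <- apply(lpd, 1L, max)
  p <- exp(lpd - shift)  # n x k, each row scaled so max = 1
  obj <- function(eta) {
    w <- exp(c(eta, 0)); w <- w / sum(w)
    -sum(log(p %*% w))
  }
  grad <- function(eta) {
    w <- exp(c(eta, 0)); w <- w / sum(w)
    denom <- drop(p %*% w)
    dw <- -colSums(p / denom)          # d(-obj)/dw
    # chain rule through softmax
    J <- -outer(w, w); diag(J) <- w * (1 - w)
    drop(dw %*% J)[seq_len(k - 1L)]
  }
  opt <- optim(rep(0, k - 1L), obj, gr = grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  w <- exp(c(opt$par, 0)); w / sum(w)
}

# Pseudo-BMA+ weights with Bayesian-bootstrap regularization of the
# elpd differences.
pseudobma_weights <- function(lpd, n_boot = 1000L, seed = 1L) {
  n <- nrow(lpd); k <- ncol(lpd)
  set.seed(seed)
  w_acc <- matrix(0, n_boot, k)
  for (b in seq_len(n_boot)) {
    alpha <- rgamma(n, 1)
    alpha <- alpha / sum(alpha)
    z <- n * colSums(lpd * alpha)
    w_acc[b, ] <- exp(z - max(z))
    w_acc[b, ] <- w_acc[b, ] / sum(w_acc[b, ])
  }
  colMeans(w_acc)
}

#' Normalized model weights over candidate fits
#'
#' Combines the per-record LOO predictive densities of two or more
#' candidate models into weights on the simplex, by stacking of
#' predictive distributions (default) or pseudo-BMA+ with a Bayesian
#' bootstrap. All candidates must be evaluated on the same records.
#'
#' @param lpd_list A list of pointwise LOO elpd vectors (one per
#'   candidate, equal lengths; e.g. the `pointwise` element of
#'   [compute_loo()] results).
#' @param method `"stacking"` or `"pseudobma"`.
#' @param n_boot,seed Bayesian-bootstrap settings for pseudo-BMA+.
#' @return A numeric vector of non-negative weights summing to 1.
#' @export
model_weights <- function(lpd_list, method = c("stacking", "pseudobma"),
                          n_boot = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (length(lpd_list) < 2L) {
    stop("need at least 2 candidates to weight", call. = FALSE)
  }
  lens <- lengths(lpd_list)
  if (length(unique(lens)) != 1L) {
    stop("candidates were evaluated on different record sets",
         call. = FALSE)
  }
  lpd <- do.call(cbind, lpd_list)
  w <- switch(method,
              stacking = stacking_weights(lpd),
              pseudobma = pseudobma_weights(lpd, n_boot, seed))
  w <- pmax(w, 0)
  w <- w / sum(w)
  names(w) <- names(lpd_list)
  w
}

#' Compare candidate precursor / recruitment-mode models
#'
#' Runs [compute_loo()] on each fitted candidate (restricted to the
#' target population's channels) and reports elpd, its standard error,
#' Pareto-k diagnostics and the normalized weight of every candidate
#' for one target population.
#'
#' @param fits A named list of `trm_fit` objects for the same target
#'   population and the same records.
#' @param method Weighting scheme, see [model_weights()].
#' @return A tibble of class `trm_comparison`: `candidate`,
#'   `precursor`, `mode`, `elpd`, `se`, `n_high_pareto_k`, `weight`,
#'   ordered by decreasing weight.
#' @export
compare_models <- function(fits, method = c("stacking", "pseudobma")) {
  method <- match.arg(method)
  stopifnot(is.list(fits), length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "trm_fit")))
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) {
      paste(f$config$precursor, f$config$mode, sep = "_")
    }, character(1))
  }
  loos <- lapply(fits, compute_loo)
  w <- model_weights(lapply(loos, `[[`, "pointwise"), method = method)
  out <- tibble::tibble(
    candidate = names(fits),
    precursor = vapply(fits, function(f) f$config$precursor, character(1)),
    mode = vapply(fits, function(f) f$config$mode, character(1)),
    elpd = vapply(loos, `[[`, numeric(1), "elpd"),
    se = vapply(loos, `[[`, numeric(1), "se"),
    n_high_pareto_k = vapply(loos, `[[`, numeric(1), "n_high_k"),
    weight = unname(w)
  )
  out <- out[order(-out$weight), ]
  class(out) <- c("trm_comparison", class(out))
  out
}
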