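# MCMC sampler on an unconstrained parameter space: a mixture kernel of
# (i) adaptive random-walk Metropolis whose proposal covariance tracks
# the running posterior covariance during warmup (Haario-style), with
# the global scale tuned toward the optimal random-walk acceptance rate
# of ~0.234 by Robbins-Monro updates, and (ii) an independence
# Metropolis move proposing from a multivariate-t approximation of the
# posterior (centred on the numerically located mode with the Laplace
# covariance). When the posterior is close to Gaussian the independence
# moves give near-uncorrelated draws; the random-walk component keeps
# the chain valid when it is not. After warmup the kernel is frozen so
# the retained draws form a time-homogeneous Markov chain.

# Multivariate-t proposal helper: Sigma = t(chol_up) %*% chol_up.
mvt_proposal <- function(mean, sigma, df = 4) {
  d <- length(mean)
  chol_up <- chol(sigma + diag(1e-10, d))
  log_det <- 2 * sum(log(diag(chol_up)))
  const <- lgamma((df + d) / 2) - lgamma(df / 2) -
    (d / 2) * log(df * pi) - log_det / 2
  list(
    draw = function() {
      z <- rnorm(d)
      u <- stats::rchisq(1, df)
      mean + drop(crossprod(chol_up, z)) * sqrt(df / u)
    },
    logd = function(x) {
      y <- backsolve(chol_up, x - mean, transpose = TRUE)
      const - (df + d) / 2 * log1p(sum(y^2) / df)
    }
  )
}

# log_post(theta) must return list(lp = scalar, ll = pointwise vector).
run_chain <- function(log_post, init, n_warmup, n_iter, seed,
                      sigma0 = NULL, ind_prop = NULL,
                      p_independent = 0.5, target_accept = 0.234) {
  set.seed(seed)
  d <- length(init)
  theta <- init
  cur <- log_post(theta)
  if (!is.finite(cur$lp)) stop("initial point has non-finite posterior")
  n_ll <- length(cur$ll)
  if (is.null(ind_prop)) p_independent <- 0

  Sigma <- if (is.null(sigma0)) diag(0.05, d) else sigma0
  log_lambda <- log(2.38^2 / d)
  chol_prop <- chol(Sigma * exp(log_lambda) + diag(1e-12, d))
  run_mean <- theta
  run_cov <- Sigma
  n_seen <- 1
  cur_logq <- if (p_independent > 0) ind_prop$logd(theta) else NA_real_

  total <- n_warmup + n_iter
  draws <- matrix(NA_real_, n_iter, d)
  lp <- numeric(n_iter)
  ll <- matrix(NA_real_, n_iter, n_ll)
  n_acc <- 0L

  for (i in seq_len(total)) {
    use_ind <- p_independent > 0 && runif(1) < p_independent
    if (use_ind) {
      prop <- ind_prop$draw()
      cand <- log_post(prop)
      prop_logq <- ind_prop$logd(prop)
      log_alpha <- if (is.finite(cand$lp)) {
        (cand$lp - prop_logq) - (cur$lp - cur_logq)
      } else -Inf
    } else {
      prop <- theta + drop(rnorm(d) %*% chol_prop)
      cand <- log_post(prop)
      log_alpha <- if (is.finite(cand$lp)) cand$lp - cur$lp else -Inf
    }
    alpha <- min(1, exp(log_alpha))
    if (runif(1) < alpha) {
      theta <- prop
      cur <- cand
      if (p_independent > 0) {
        cur_logq <- if (use_ind) prop_logq else ind_prop$logd(theta)
      }
      if (i > n_warmup) n_acc <- n_acc + 1L
    }
    if (i <= n_warmup) {
      # running mean / covariance of the warmup trajectory
      n_seen <- n_seen + 1
      dlt <- theta - run_mean
      run_mean <- run_mean + dlt / n_seen
      run_cov <- run_cov * ((n_seen - 2) / (n_seen - 1)) +
        tcrossprod(dlt) / n_seen
      if (!use_ind) {
        log_lambda <- log_lambda +
          min(1, 5 / i^0.6) * (alpha - target_accept)
      }
      if (i %% 25 == 0 || i == n_warmup) {
        S <- run_cov + diag(1e-8, d)
        ch <- tryCatch(chol(S * exp(log_lambda)), error = function(e) NULL)
        if (!is.null(ch)) chol_prop <- ch
      }
    } else {
      j <- i - n_warmup
      draws[j, ] <- theta
      lp[j] <- cur$lp
      ll[j, ] <- cur$ll
    }
  }
  list(draws = draws, lp = lp, ll = ll,
       accept_rate = n_acc / max(1L, n_iter))
}

# Split-Rhat (Gelman-Rubin on half-chains) for one parameter.
# draws: iterations x chains matrix.
split_rhat <- function(draws) {
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  grp <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(grp)
  means <- colMeans(grp)
  vars <- apply(grp, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Effective sample size via the initial monotone positive sequence of
# autocorrelations, pooled across chains.
ess_basic <- function(draws) {
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4L) return(NA_real_)
  max_lag <- min(n - 1L, 200L)
  acfs <- sapply(seq_len(m), function(j) {
    stats::acf(draws[, j], lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  })
  rho <- rowMeans(acfs)[-1L]  # drop lag 0
  # sum paired autocorrelations while the pair sums stay positive
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  ess <- n * m / (1 + 2 * s)
  min(ess, n * m)
}
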