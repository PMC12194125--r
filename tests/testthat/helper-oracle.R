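# Independent oracles used by the tests. These never call the solver
# code paths they check.

# Matrix-exponential solution of the label-kinetics system over one
# interval with CONSTANT precursor inputs g (YFP), gm (mTom) and
# immigrant Ki67-high fraction h. State x = (a, b, c, d, m); the affine
# system dx/dt = A x + f is solved exactly via the exponential of the
# augmented matrix [[A, f], [0, 0]].
expm_segment <- function(x0, dt, mu, rho, beta, g, gm, h) {
  delta <- mu + rho
  A <- matrix(0, 5, 5)
  A[1, 1] <- rho - (beta + delta); A[1, 2] <- 2 * rho
  A[2, 1] <- beta; A[2, 2] <- -(rho + delta)
  A[3, 3] <- rho - (beta + delta); A[3, 4] <- 2 * rho
  A[4, 3] <- beta; A[4, 4] <- -(rho + delta)
  A[5, 5] <- -mu
  f <- c(mu * g * h, mu * g * (1 - h),
         mu * (1 - g) * h, mu * (1 - g) * (1 - h),
         mu * gm)
  Aug <- rbind(cbind(A, f), 0)
  E <- as.matrix(Matrix::expm(Aug * dt))
  drop(E[1:5, ] %*% c(x0, 1))
}

# Full piecewise-constant trajectory: breaks partition [times[1],
# max(times)]; g_vals etc. give the constant level on each piece.
expm_trajectory <- function(x0, times, breaks, g_vals, gm_vals, h_vals,
                            mu, rho, beta) {
  edges <- c(breaks, max(times) + 1)
  out <- matrix(NA_real_, length(times), 5)
  out[1, ] <- x0
  x <- x0
  t_cur <- times[1]
  for (j in seq_along(times)[-1]) {
    t_next <- times[j]
    # advance piece by piece from t_cur to t_next
    while (t_cur < t_next - 1e-12) {
      piece <- findInterval(t_cur + 1e-12, edges)
      t_end <- min(t_next, edges[piece + 1])
      x <- expm_segment(x, t_end - t_cur, mu, rho, beta,
                        g_vals[piece], gm_vals[piece], h_vals[piece])
      t_cur <- t_end
    }
    out[j, ] <- x
  }
  out
}

# Chain the package solver across constant pieces (constant precursor
# levels are plain inputs), so it can be compared to the oracle on the
# same piecewise-constant forcing.
solver_piecewise <- function(params, x0, times, breaks, g_vals, gm_vals,
                             prec_ki67_vals = NULL) {
  edges <- c(breaks, max(times) + 1)
  state <- c(yfp_ki67hi = x0[1], yfp_ki67lo = x0[2],
             yneg_ki67hi = x0[3], yneg_ki67lo = x0[4], mtom = x0[5])
  out <- matrix(NA_real_, length(times), 5)
  out[1, ] <- x0
  t_cur <- times[1]
  for (j in seq_along(times)[-1]) {
    t_next <- times[j]
    while (t_cur < t_next - 1e-12) {
      piece <- findInterval(t_cur + 1e-12, edges)
      t_end <- min(t_next, edges[piece + 1])
      tr <- solve_label_trajectories(
        params,
        precursor_yfp = g_vals[piece], precursor_mtom = gm_vals[piece],
        precursor_ki67 = if (!is.null(prec_ki67_vals))
          prec_ki67_vals[piece],
        initial = state, times = c(t_cur, t_end))
      last <- tr[nrow(tr), ]
      state <- c(yfp_ki67hi = last$frac_yfp_ki67hi,
                 yfp_ki67lo = last$frac_yfp_ki67lo,
                 yneg_ki67hi = last$frac_yneg_ki67hi,
                 yneg_ki67lo = last$frac_yneg_ki67lo,
                 mtom = last$frac_mtom)
      t_cur <- t_end
    }
    out[j, ] <- unname(state)
  }
  out
}

# Exact (unsmoothed) importance-sampling LOO for tiny draw counts:
# elpd_i = log( sum_s w_s p_is / sum_s w_s ) with w_s = 1 / p_is.
brute_force_loo <- function(ll) {
  sapply(seq_len(ncol(ll)), function(i) {
    w <- exp(-ll[, i])
    log(sum(w * exp(ll[, i])) / sum(w))
  })
}

# Small deterministic fit fixture shared across inference tests.
tiny_fit_fixture <- function(seed = 11, chains = 1, warmup = 100,
                             iter = 60) {
  design <- study_design(n_ki67divn = 8, n_cd4fr = 8)
  d <- simulate_reporter_data("skin_trm", design, seed = seed)
  suppressWarnings(fit_trm_model(
    d, trm_config(chains = chains, warmup = warmup, iter = iter,
                  seed = seed)))
}
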