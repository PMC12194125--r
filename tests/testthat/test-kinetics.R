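# The label-kinetics ODE model and its closed-form steady state.

test_that("a closed population keeps its mTom frequency constant", {
  p <- kinetic_params(mu = 0, rho = 0.03, beta = 0.25,
                      mode = "quiescent")
  tr <- solve_label_trajectories(
    p, precursor_yfp = 0.5, precursor_mtom = 0.1,
    initial = c(yfp_ki67hi = 0.1, yfp_ki67lo = 0.2, yneg_ki67hi = 0.1,
                yneg_ki67lo = 0.6, mtom = 0.37),
    times = c(5, 30, 120, 400))
  expect_equal(tr$frac_mtom, rep(0.37, 4), tolerance = 1e-8)
  # and with no influx the YFP+ fraction is constant too
  expect_equal(tr$yfp, rep(0.3, 4), tolerance = 1e-8)
})

test_that("mTom relaxes exponentially toward a constant precursor level", {
  mu <- 0.04; g <- 0.25; m0 <- 0.6
  p <- kinetic_params(mu = mu, rho = 0.01, beta = 0.3,
                      mode = "quiescent")
  times <- c(5, 10, 50, 200)
  tr <- solve_label_trajectories(
    p, precursor_yfp = 0.5, precursor_mtom = g,
    initial = c(yfp_ki67hi = 0.05, yfp_ki67lo = 0.15, yneg_ki67hi = 0.1,
                yneg_ki67lo = 0.7, mtom = m0),
    times = times)
  expect_equal(tr$frac_mtom, g + (m0 - g) * exp(-mu * (times - 5)),
               tolerance = 1e-7)
})

test_that("solver matches the matrix-exponential oracle (fixed case)", {
  p <- kinetic_params(mu = 0.03, rho = 0.02, beta = 0.3,
                      mode = "division_linked")
  x0 <- c(0.08, 0.12, 0.1, 0.7, 0.45)
  times <- c(5, 12, 30, 55, 90)
  breaks <- c(5, 20, 60)
  g <- c(0.5, 0.35, 0.3); gm <- c(0.4, 0.25, 0.1)
  ours <- solver_piecewise(p, x0, times, breaks, g, gm)
  oracle <- expm_trajectory(x0, times, breaks, g, gm,
                            h_vals = c(1, 1, 1),
                            mu = 0.03, rho = 0.02, beta = 0.3)
  expect_lt(max(abs(ours - oracle)), 1e-8)
})

test_that("solver matches the oracle on random parameter draws", {
  set.seed(20240917)
  for (i in 1:20) {
    mu <- runif(1, 0, 0.1)
    rho <- runif(1, 0, 0.05)
    beta <- runif(1, 0.1, 0.5)
    mode <- sample(c("quiescent", "neutral", "division_linked"), 1)
    hk <- runif(3)
    h <- switch(mode, quiescent = rep(0, 3),
                division_linked = rep(1, 3), neutral = hk)
    x4 <- runif(4); x4 <- x4 / sum(x4)
    x0 <- c(x4, runif(1))
    breaks <- c(5, 25, 70)
    times <- c(5, 15, 40, 100)
    g <- runif(3); gm <- runif(3)
    p <- kinetic_params(mu, rho, beta, mode = mode,
                        precursor_ki67 = if (mode == "neutral") hk[1])
    ours <- solver_piecewise(p, x0, times, breaks, g, gm,
                             prec_ki67_vals = if (mode == "neutral") hk)
    oracle <- expm_trajectory(x0, times, breaks, g, gm, h,
                              mu = mu, rho = rho, beta = beta)
    expect_lt(max(abs(ours - oracle)), 1e-8)
  }
})

test_that("the four YFP x Ki67 fractions always sum to 1", {
  set.seed(7)
  for (i in 1:10) {
    p <- kinetic_params(runif(1, 0, 0.1), runif(1, 0, 0.05),
                        runif(1, 0.1, 0.5), mode = "division_linked")
    x4 <- runif(4); x4 <- x4 / sum(x4)
    tr <- solve_label_trajectories(
      p, precursor_yfp = function(t) plogis(0.5 - 0.01 * t),
      precursor_mtom = function(t) plogis(-1 - 0.005 * t),
      initial = c(yfp_ki67hi = x4[1], yfp_ki67lo = x4[2],
                  yneg_ki67hi = x4[3], yneg_ki67lo = x4[4], mtom = 0.3),
      times = seq(5, 400, by = 20))
    sums <- tr$frac_yfp_ki67hi + tr$frac_yfp_ki67lo +
      tr$frac_yneg_ki67hi + tr$frac_yneg_ki67lo
    expect_lt(max(abs(sums - 1)), 1e-9)
    expect_true(all(tr$yfp >= -1e-9 & tr$yfp <= 1 + 1e-9))
  }
})

test_that("long-run Ki67 fraction converges to the closed form", {
  set.seed(99)
  for (i in 1:5) {
    mu <- runif(1, 0.005, 0.08)
    rho <- runif(1, 0.005, 0.04)
    beta <- runif(1, 0.2, 0.4)
    mode <- sample(c("quiescent", "neutral", "division_linked"), 1)
    pk <- runif(1)
    p <- kinetic_params(mu, rho, beta, mode = mode,
                        precursor_ki67 = if (mode == "neutral") pk)
    t_end <- 5 + 20 / min(mu + rho, beta)
    tr <- solve_label_trajectories(
      p, precursor_yfp = 0.4, precursor_mtom = 0.2,
      initial = c(yfp_ki67hi = 0.25, yfp_ki67lo = 0.25,
                  yneg_ki67hi = 0.25, yneg_ki67lo = 0.25, mtom = 0.5),
      times = c(5, t_end))
    k_num <- tr$frac_yfp_ki67hi[2] + tr$frac_yneg_ki67hi[2]
    expect_equal(k_num, steady_state_ki67_fraction(p), tolerance = 1e-6)
  }
})

test_that("larger replacement accelerates mTom convergence", {
  g <- 0.15; m0 <- 0.7
  gaps <- sapply(c(0.01, 0.03, 0.09), function(mu) {
    p <- kinetic_params(mu, 0.02, 0.3, mode = "quiescent")
    tr <- solve_label_trajectories(
      p, precursor_yfp = 0.4, precursor_mtom = g,
      initial = c(yfp_ki67hi = 0.1, yfp_ki67lo = 0.1, yneg_ki67hi = 0.1,
                  yneg_ki67lo = 0.7, mtom = m0),
      times = c(5, 60))
    abs(tr$frac_mtom[2] - g)
  })
  expect_true(all(diff(gaps) < 0))
})

test_that("steady-state Ki67 fraction reproduces the site estimates", {
  # skin: 2%/day replacement, 7-week interdivision, division-linked
  k_skin <- steady_state_ki67_fraction(
    kinetic_params(0.02, 1 / 49, 1 / 3, mode = "division_linked"))
  expect_equal(round(k_skin, 2), 0.15)
  # LP: 5.5%/day replacement, 9-week interdivision, quiescent
  k_lp <- steady_state_ki67_fraction(
    kinetic_params(0.055, 1 / 63, 1 / 3, mode = "quiescent"))
  expect_equal(k_lp, 0.076, tolerance = 0.01)
  # no division, quiescent immigrants: no Ki67-high source at all
  expect_equal(steady_state_ki67_fraction(
    kinetic_params(0.02, 0, 1 / 3, mode = "quiescent")), 0)
})

test_that("parameter and input validation catches bad values", {
  expect_error(kinetic_params(NA, 0.1, 0.3), "finite")
  expect_error(kinetic_params(-0.01, 0.1, 0.3), ">= 0")
  expect_error(kinetic_params(0.01, 0.1, 0), "> 0")
  expect_error(kinetic_params(0.01, 0.1, 0.3, mode = "neutral"),
               "precursor_ki67")
  p <- kinetic_params(0.01, 0.01, 0.3, mode = "quiescent")
  ini <- c(yfp_ki67hi = 0.25, yfp_ki67lo = 0.25, yneg_ki67hi = 0.25,
           yneg_ki67lo = 0.25, mtom = 0.5)
  expect_error(
    solve_label_trajectories(p, 0.5, 0.5, ini, times = c(10, 5)),
    "sorted")
  bad <- ini; bad["yfp_ki67hi"] <- 0.5
  expect_error(solve_label_trajectories(p, 0.5, 0.5, bad, times = c(5, 9)),
               "sum to 1")
})
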