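# Derived quantities: clonal half-lives and Ki67-only residence bounds.

test_that("clonal half-life reproduces the site estimates", {
  # skin: ~24-day residence, 7-week interdivision -> ~5 weeks
  expect_equal(clonal_half_life(rho = 1 / 49, delta = 1 / 24), 32.6,
               tolerance = 0.01)
  # LP: ~14-day residence, 8-week interdivision -> ~2 weeks
  expect_equal(clonal_half_life(rho = 1 / 56, delta = 1 / 14), 12.9,
               tolerance = 0.01)
  # no self-renewal: plain exponential decay of the cohort
  expect_equal(clonal_half_life(rho = 0, delta = 0.05), log(2) / 0.05)
  # self-renewal balancing loss: non-decaying
  expect_equal(clonal_half_life(rho = 0.05, delta = 0.05), Inf)
})

test_that("Ki67 bounds match a root-finding oracle and bracket 1/delta", {
  # numerically invert the steady-state Ki67 balance for rho at h fixed
  solve_rho <- function(k, mu, beta, h) {
    f <- function(rho) {
      (mu * h + 2 * rho) / (beta + (mu + rho) + rho) - k
    }
    out <- try(stats::uniroot(f, c(0, 10), tol = 1e-12)$root,
               silent = TRUE)
    if (inherits(out, "try-error")) 0 else out
  }
  b <- ki67_residence_bounds(k = 0.15, mu = 0.02, beta = 1 / 3.5)
  rho_q <- solve_rho(0.15, 0.02, 1 / 3.5, h = 0)
  rho_d <- solve_rho(0.15, 0.02, 1 / 3.5, h = 1)
  expect_equal(b$lower_days, 1 / (rho_q + 0.02), tolerance = 1e-9)
  expect_equal(b$upper_days, 1 / (rho_d + 0.02), tolerance = 1e-9)
  expect_equal(b$lower_days, 21.3, tolerance = 0.01)
  expect_equal(b$upper_days, 28.4, tolerance = 0.01)

  # LP: the division-linked balance is infeasible, rho floored at 0
  b2 <- ki67_residence_bounds(k = 0.07, mu = 0.055, beta = 1 / 3)
  expect_equal(b2$lower_days, 14.5, tolerance = 0.01)
  expect_equal(b2$upper_days, 1 / 0.055, tolerance = 1e-9)
})

test_that("bounds bracket the truth, equal at the matching mode", {
  set.seed(42)
  for (i in 1:20) {
    mu <- runif(1, 0.005, 0.08)
    rho <- runif(1, 0.002, 0.05)
    beta <- runif(1, 0.2, 0.4)
    mode <- sample(c("quiescent", "division_linked"), 1)
    k <- steady_state_ki67_fraction(
      kinetic_params(mu, rho, beta, mode = mode))
    b <- ki67_residence_bounds(k, mu, beta)
    res <- 1 / (mu + rho)
    expect_lte(b$lower_days, b$upper_days)
    expect_lte(b$lower_days, res + 1e-6)
    expect_gte(b$upper_days, res - 1e-6)
    matching <- if (mode == "quiescent") b$lower_days else b$upper_days
    expect_equal(matching, res, tolerance = 1e-6)
  }
})

test_that("vanishing Ki67 drives both bounds to the replacement limit", {
  b <- ki67_residence_bounds(k = 1e-9, mu = 0.03, beta = 1 / 3.5)
  expect_equal(b$lower_days, 1 / 0.03, tolerance = 1e-5)
  expect_equal(b$upper_days, 1 / 0.03, tolerance = 1e-5)
  expect_error(ki67_residence_bounds(0, 0.03), "inside")
  expect_error(ki67_residence_bounds(1, 0.03), "inside")
})

test_that("derive_estimates maps draws to all reported scales", {
  d <- derive_estimates(tibble::tibble(mu = c(0.02, 0), rho = c(1 / 49, 0.01),
                                       beta = c(1 / 3, 0.25)))
  expect_equal(d$residence_days[1], 1 / (0.02 + 1 / 49), tolerance = 1e-12)
  # the printed skin residence time is ~24 days
  expect_equal(d$residence_days[1], 24, tolerance = 0.05)
  expect_equal(d$replacement_pct_per_day[1], 2)
  expect_equal(d$clonal_half_life_days[1], log(2) / 0.02)
  # half-life always exceeds residence * ln 2 (delta - rho = mu <= delta)
  expect_true(all(d$clonal_half_life_days >=
                    d$residence_days * log(2) - 1e-12))
  # mu = 0: cohort does not decay
  expect_true(d$non_decaying[2])
  expect_equal(d$clonal_half_life_days[2], Inf)
})
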