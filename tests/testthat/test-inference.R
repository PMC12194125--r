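# Bayesian fitting: self-consistency, reproducibility, summaries.

fit_small <- tiny_fit_fixture(seed = 11, chains = 1, warmup = 150,
                              iter = 80)

test_that("near-noiseless synthetic data recovers the generating rates", {
  # huge per-mouse cell counts and one mouse per timepoint: binomial
  # noise is negligible, so posterior medians must sit near the truth
  truth <- default_truths()$skin_trm
  des <- study_design(n_ki67divn = 10, n_cd4fr = 10,
                      mice_per_timepoint = 1,
                      log_mean_cells = log(1e5), log_sd_cells = 0.01)
  d <- simulate_reporter_data(truth, des, seed = 21)
  fit <- suppressWarnings(fit_trm_model(
    d, trm_config(chains = 2, warmup = 300, iter = 250, seed = 21)))
  s <- summarize_posterior(fit, check_convergence = FALSE)
  med <- setNames(s$median, s$term)
  expect_equal(med[["mu"]], truth$params$mu, tolerance = 0.1)
  expect_equal(med[["rho"]], truth$params$rho, tolerance = 0.1)
  expect_equal(med[["beta"]], truth$params$beta, tolerance = 0.1)
})

test_that("identical seed and config give identical results", {
  f1 <- tiny_fit_fixture(seed = 33, chains = 1, warmup = 100, iter = 40)
  f2 <- tiny_fit_fixture(seed = 33, chains = 1, warmup = 100, iter = 40)
  expect_identical(f1$draws, f2$draws)
  expect_identical(summarize_posterior(f1, check_convergence = FALSE),
                   summarize_posterior(f2, check_convergence = FALSE))
})

test_that("posterior draws respect parameter domains", {
  dr <- fit_small$draws
  expect_true(all(dr$mu > 0 & dr$rho > 0 & dr$beta > 0))
  for (p in c("yfp0", "ki67_yfp0", "ki67_yneg0", "mtom0")) {
    expect_true(all(dr[[p]] > 0 & dr[[p]] < 1))
  }
  expect_true(all(dr$prec_yfp_c > 0 & dr$prec_mtom_c > 0))
  expect_true(all(is.finite(dr$lp__)))
})

test_that("summaries equal independent recomputation from raw draws", {
  s <- summarize_posterior(fit_small, check_convergence = FALSE)
  dr <- fit_small$draws
  # median and central interval recomputed directly
  expect_equal(s$median[s$term == "mu"],
               unname(quantile(dr$mu, 0.5)), tolerance = 1e-12)
  expect_equal(s$lo95[s$term == "rho"],
               unname(quantile(dr$rho, 0.025)), tolerance = 1e-12)
  res <- 1 / (dr$mu + dr$rho)
  expect_equal(s$median[s$term == "residence_days"],
               unname(quantile(res, 0.5)), tolerance = 1e-12)
  expect_equal(s$hi95[s$term == "clonal_half_life_days"],
               unname(quantile(log(2) / dr$mu, 0.975)), tolerance = 1e-12)
  # MAP is the draw with the highest joint log posterior
  i <- which.max(dr$lp__)
  expect_equal(s$map[s$term == "mu"], dr$mu[i])
  # interval ordering
  expect_true(all(s$lo95 <= s$median & s$median <= s$hi95))
})

test_that("pointwise matrix dimensions match draws x records", {
  expect_equal(dim(fit_small$pointwise),
               c(nrow(fit_small$draws), nrow(fit_small$records)))
  expect_true(all(is.finite(fit_small$pointwise)))
})

test_that("tidy and glance expose the fit in broom style", {
  td <- tidy(fit_small)
  expect_true(all(c("term", "estimate", "lo95", "hi95", "rhat", "ess")
                  %in% names(td)))
  expect_equal(nrow(td), 13)
  g <- glance(fit_small)
  expect_equal(g$n_records, nrow(fit_small$records))
  expect_equal(g$n_draws, 80)
  expect_true(is.logical(g$converged))
})

test_that("missing required channels raise a configuration error", {
  d <- simulate_reporter_data("skin_trm",
                              study_design(n_ki67divn = 4, n_cd4fr = 4),
                              seed = 9)
  no_mtom <- d[!(d$subset == "Trm69pos" & d$channel == "mtom_pos"), ]
  expect_error(
    fit_trm_model(no_mtom, trm_config(chains = 1, warmup = 100,
                                      iter = 20, seed = 1)),
    "mtom_pos")
  no_prec <- d[d$subset != "CD69neg", ]
  expect_error(
    fit_trm_model(no_prec, trm_config(chains = 1, warmup = 100,
                                      iter = 20, seed = 1)),
    "precursor")
})

test_that("trajectories at the MAP draw stay inside [0, 1]", {
  tr <- trmkin:::fit_trajectories(fit_small)
  for (col in c("yfp", "frac_mtom", "ki67hi_yfp_pos", "ki67hi_yfp_neg",
                "prec_yfp", "prec_mtom")) {
    expect_true(all(tr[[col]] >= -1e-9 & tr[[col]] <= 1 + 1e-9))
  }
})

test_that("fit configurations round-trip through JSON", {
  cfg <- trm_config(target_tissue = "LP", precursor = "TEM",
                    mode = "neutral", precursor_ki67 = 0.08,
                    chains = 2, warmup = 200, iter = 100, seed = 5,
                    priors = trm_priors(mu_meanlog = log(0.05)))
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$mode, "neutral")
  expect_equal(back$precursor_ki67, 0.08)
  expect_equal(back$priors$mu_meanlog, log(0.05))
  expect_equal(back$seed, 5L)
})
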