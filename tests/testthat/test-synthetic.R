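# Synthetic dataset generation.

test_that("presets imply the reported residence and Ki67 levels", {
  tr <- default_truths()
  res_skin <- 1 / (tr$skin_trm$params$mu + tr$skin_trm$params$rho)
  res_lp <- 1 / (tr$lp_trm$params$mu + tr$lp_trm$params$rho)
  expect_equal(res_skin, 1 / (0.02 + 1 / 49), tolerance = 1e-12)
  expect_equal(res_skin, 24, tolerance = 0.05)   # printed: ~24 d
  expect_equal(res_lp, 14.1, tolerance = 0.01)   # printed: ~14 d
  for (t in tr) {
    k <- steady_state_ki67_fraction(t$params)
    expect_true(is.finite(k) && k > 0 && k < 1)
  }
})

test_that("generation is deterministic given (truth, design, seed)", {
  des <- study_design(n_ki67divn = 5, n_cd4fr = 5)
  d1 <- simulate_reporter_data("skin_trm", des, seed = 31)
  d2 <- simulate_reporter_data("skin_trm", des, seed = 31)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_reporter_data("skin_trm", des, seed = 32)
  expect_false(identical(d1$n_pos, d3$n_pos))
})

test_that("an empty design yields an empty, well-formed table", {
  d <- simulate_reporter_data("skin_trm",
                              study_design(n_ki67divn = 0, n_cd4fr = 0),
                              seed = 1)
  expect_equal(nrow(d), 0)
  expect_named(d, c("mouse_id", "strain", "t_days", "tissue", "subset",
                    "channel", "n_pos", "n_total"))
})

test_that("default design matches the dual-strain study layout", {
  d <- simulate_reporter_data("skin_trm", study_design(), seed = 8)
  kd <- d[d$strain == "Ki67DIVN", ]
  cf <- d[d$strain == "Cd4FR", ]
  expect_equal(length(unique(kd$mouse_id)), 31)
  expect_equal(length(unique(cf$mouse_id)), 36)
  expect_true(all(kd$t_days >= 5 & kd$t_days <= 63))
  expect_true(all(cf$t_days >= 5 & cf$t_days <= 399))
  # each Ki67-DIVN mouse: 3 target channels + 1 precursor channel
  expect_equal(nrow(kd), 31 * 4)
  expect_equal(nrow(cf), 36 * 2)
  expect_true(all(d$n_total >= 20))
})

test_that("empirical frequencies converge to the model trajectory", {
  # many mice at a single timepoint: per-channel mean within 3 MC SEs
  truth <- default_truths()$skin_trm
  des <- study_design(n_ki67divn = 500, n_cd4fr = 500,
                      window_ki67divn = c(21, 21),
                      window_cd4fr = c(150, 150))
  d <- simulate_reporter_data(truth, des, seed = 12)
  pred <- trmkin:::truth_predictions(truth, c(21, 150))
  expected <- list(
    list(ch = "yfp_pos", sub = "Trm69pos", t = 21, col = "yfp"),
    list(ch = "ki67hi_given_yfp_pos", sub = "Trm69pos", t = 21,
         col = "ki67hi_yfp_pos"),
    list(ch = "ki67hi_given_yfp_neg", sub = "Trm69pos", t = 21,
         col = "ki67hi_yfp_neg"),
    list(ch = "mtom_pos", sub = "Trm69pos", t = 150, col = "frac_mtom"),
    list(ch = "yfp_pos", sub = "CD69neg", t = 21, col = "prec_yfp"),
    list(ch = "mtom_pos", sub = "CD69neg", t = 150, col = "prec_mtom"))
  for (e in expected) {
    rows <- d[d$channel == e$ch & d$subset == e$sub, ]
    frac <- rows$n_pos / rows$n_total
    target <- pred[[e$col]][match(e$t, pred$time)]
    se <- sd(frac) / sqrt(nrow(rows))
    expect_lt(abs(mean(frac) - target), 3 * se + 1e-12)
  }
})

test_that("mTom in Cd4-FR mice declines over the long chase", {
  d <- simulate_reporter_data("skin_trm", study_design(), seed = 5)
  m <- d[d$strain == "Cd4FR" & d$subset == "Trm69pos", ]
  early <- m[m$t_days <= 60, ]
  late <- m[m$t_days >= 300, ]
  expect_gt(mean(early$n_pos / early$n_total),
            3 * mean(late$n_pos / late$n_total))
})

test_that("truth records round-trip through JSON", {
  truth <- default_truths()$lp_trm
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(back$params$mu, truth$params$mu)
  expect_equal(back$params$mode, truth$params$mode)
  expect_equal(back$initial, truth$initial)
  expect_equal(back$precursor_mtom$b, truth$precursor_mtom$b)
  expect_equal(back$precursor, truth$precursor)
})
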