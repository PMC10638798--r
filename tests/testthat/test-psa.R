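test_that("sampled parameters match their published moments", {
  p <- base_params()
  set.seed(99)
  draws <- replicate(2000, sample_draw(p), simplify = FALSE)

  uam <- vapply(draws, function(d) d$utilities$uam, numeric(1))
  expect_equal(mean(uam), 0.84, tolerance = 0.01)
  expect_true(all(uam >= 0 & uam <= 1))

  cam <- vapply(draws, function(d) d$costs$cam, numeric(1))
  expect_equal(mean(cam) / 87670, 1, tolerance = 0.01)
  expect_true(all(cam > 0))

  ages <- vapply(draws, function(d) d$entry_age, numeric(1))
  expect_true(all(ages >= 18 & ages <= 100))
  expect_equal(ages, round(ages))
  expect_equal(mean(ages), 58, tolerance = 1)

  mult <- vapply(draws, function(d) d$transitions$tpA2B_multiplier, numeric(1))
  expect_equal(mean(mult), 1, tolerance = 0.02)
  # multiplier scales all windows jointly and keeps probabilities in [0,1]
  d1 <- draws[[1]]
  for (s in strategies()) {
    p9 <- vapply(c(0, 5, 10), function(cy) tpA2B_at(s, cy, d1), numeric(1))
    base9 <- vapply(c(0, 5, 10), function(cy) tpA2B_at(s, cy, p), numeric(1))
    expect_equal(p9, pmin(base9 * d1$transitions$tpA2B_multiplier, 1))
  }

  # feasibility maintained in every draw
  for (d in draws[1:200]) {
    expect_lte(d$transitions$tpB2C + d$transitions$tpB2F, 1)
    expect_lte(d$transitions$tpD2E + d$transitions$tpD2F, 1)
  }
})

test_that("PSA draw stream is reproducible for a fixed seed", {
  p <- base_params()
  lt <- base_lifetable()
  a <- suppressWarnings(run_psa(p, lt, n_iter = 5, seed = 123))
  b <- suppressWarnings(run_psa(p, lt, n_iter = 5, seed = 123))
  expect_identical(a$draws, b$draws)
  c <- suppressWarnings(run_psa(p, lt, n_iter = 5, seed = 124))
  expect_false(identical(a$draws$qaly, c$draws$qaly))
  expect_error(run_psa(p, lt, n_iter = 0), "n_iter")
})

test_that("degenerate distributions reproduce the deterministic results", {
  p <- base_params()
  p$psa <- point_mass_psa(p)
  lt <- base_lifetable()
  psa <- run_psa(p, lt, n_iter = 3, seed = 5)
  det <- run_strategies(p, lt)
  for (s in strategies()) {
    d <- psa$draws[psa$draws$strategy == s, ]
    expect_equal(d$qaly, rep(det[[s]]$qaly, 3))
    expect_equal(d$cost_healthcare, rep(det[[s]]$cost_healthcare, 3))
    expect_equal(d$cost_societal, rep(det[[s]]$cost_societal, 3))
  }
  expect_equal(psa$summary$mean_qaly,
               vapply(det, `[[`, numeric(1), "qaly")[psa$summary$strategy],
               ignore_attr = TRUE)
})

test_that("summary percentiles agree with a direct sort of the draws", {
  p <- base_params()
  lt <- base_lifetable()
  psa <- suppressWarnings(run_psa(p, lt, n_iter = 60, seed = 11))
  d <- psa$draws[psa$draws$strategy == "mastectomy", ]
  s <- psa$summary[psa$summary$strategy == "mastectomy", ]
  expect_equal(s$qaly_lo, as.numeric(quantile(d$qaly, 0.025, names = FALSE)))
  expect_equal(s$cost_healthcare_hi,
               as.numeric(quantile(d$cost_healthcare, 0.975, names = FALSE)))
  expect_true(s$qaly_lo <= s$mean_qaly && s$mean_qaly <= s$qaly_hi)
})

test_that("CEAC probabilities are well-behaved in the WTP limits", {
  p <- base_params()
  lt <- base_lifetable()
  psa <- suppressWarnings(run_psa(p, lt, n_iter = 100, seed = 21))
  cmp <- c("lumpectomy_rt", "lumpectomy_no_rt")
  curve <- ceac(psa, cmp, wtp_grid = c(0, 5e5, 1e6, 5e7))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))

  inc <- ce_plane(psa, cmp, "healthcare")
  # lambda = 0: NMB reduces to -cost
  expect_equal(curve$probability[1], mean(inc$d_cost < 0))
  # irradiation always gains QALYs here, so probability -> 1 as lambda grows
  expect_equal(curve$probability[nrow(curve)], 1)

  expect_error(ceac(psa, cmp, wtp_grid = numeric(0)), "empty")
  expect_error(ceac(psa, cmp, wtp_grid = c(2, 1)), "increasing")
})

test_that("age sampling pulls PSA mean QALYs below the deterministic value", {
  p <- base_params()
  lt <- base_lifetable()
  psa <- suppressWarnings(run_psa(p, lt, n_iter = 150, seed = 31))
  det <- run_strategies(p, lt)
  for (s in strategies()) {
    expect_lt(psa$summary$mean_qaly[psa$summary$strategy == s],
              det[[s]]$qaly)
  }
})
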