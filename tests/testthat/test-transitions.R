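test_that("rate and cumulative-incidence conversions match the exponential model", {
  expect_equal(round(prob_from_rate(71.70), 3), 0.069)
  expect_equal(round(prob_from_rate(36.90), 3), 0.036)
  expect_equal(prob_from_rate(0), 0)
  expect_error(prob_from_rate(-1), ">= 0")

  expect_equal(round(prob_from_cumulative_incidence(0.143, 20), 3), 0.008)
  expect_equal(round(prob_from_cumulative_incidence(0.609, 2), 3), 0.375)
  expect_equal(prob_from_cumulative_incidence(0, 7), 0)
  expect_error(prob_from_cumulative_incidence(1, 5), "\\[0, 1\\)")
  expect_error(prob_from_cumulative_incidence(0.3, 0), "> 0")
})

test_that("cumulative-incidence conversion is monotone and self-consistent", {
  cis <- seq(0.05, 0.9, by = 0.05)
  p_inc <- prob_from_cumulative_incidence(cis, 10)
  expect_true(all(diff(p_inc) > 0))               # increasing in CI
  years <- c(1, 2, 5, 10, 20, 40)
  p_dec <- prob_from_cumulative_incidence(0.5, years)
  expect_true(all(diff(p_dec) < 0))               # decreasing in T
  # reconstructing CI over T years recovers the input
  for (ci in cis) {
    for (T in years) {
      p <- prob_from_cumulative_incidence(ci, T)
      expect_equal(1 - (1 - p)^T, ci, tolerance = 1e-9)
    }
  }
})

test_that("IRR transfer rescales the recurrence schedule", {
  sched <- recurrence_schedule(c(71.70, 34.00, 9.00))
  m <- mastectomy_schedule_from_irr(sched, 1.27)
  expect_equal(round(m$rate, 2), c(56.46, 26.77, 7.09))
  expect_equal(mastectomy_schedule_from_irr(sched, 1), sched)
  expect_error(mastectomy_schedule_from_irr(sched, 0), "> 0")
})

test_that("time-dependent recurrence probability uses half-open windows", {
  p <- base_params()
  expect_equal(round(tpA2B_at("mastectomy", 0, p), 3), 0.055)
  expect_equal(round(tpA2B_at("lumpectomy_no_rt", 12, p), 3), 0.009)
  expect_equal(round(tpA2B_at("lumpectomy_rt", 7, p), 3), 0.024)
  # boundary cycles fall into the later window
  expect_equal(tpA2B_at("lumpectomy_no_rt", 5, p), prob_from_rate(34.00))
  expect_equal(tpA2B_at("lumpectomy_no_rt", 10, p), prob_from_rate(9.00))
  expect_equal(tpA2B_at("lumpectomy_no_rt", 4, p), prob_from_rate(71.70))
  expect_error(tpA2B_at("lumpectomy_rt", 30, p), "horizon")
  expect_error(tpA2B_at("lobectomy", 0, p), "unknown strategy")
})

test_that("all nine published annual recurrence probabilities reproduce to 3 dp", {
  p <- base_params()
  printed <- rbind(
    mastectomy       = c(0.055, 0.026, 0.007),
    lumpectomy_no_rt = c(0.069, 0.033, 0.009),
    lumpectomy_rt    = c(0.036, 0.024, 0.008)
  )
  for (s in rownames(printed)) {
    got <- vapply(c(0, 5, 10), function(cy) tpA2B_at(s, cy, p), numeric(1))
    expect_equal(round(got, 3), unname(printed[s, ]))
  }
})

test_that("transition matrix rows carry the published complements", {
  p <- base_params()
  lt0 <- zero_mortality_lifetable()
  M <- build_transition_matrix("mastectomy", 20, 78, p, lt0)
  expect_equal(unname(M["B", ]), c(0, 0.770, 0.165, 0, 0, 0.065))
  expect_equal(unname(M["D", "D"]), 0.447)
  expect_equal(unname(M["F", ]), c(0, 0, 0, 0, 0, 1))

  # certain background death: every non-F row collapses to death
  lt1 <- zero_mortality_lifetable()
  lt1$q[] <- 1
  M1 <- suppressWarnings(build_transition_matrix("mastectomy", 0, 58, p, lt1))
  expect_true(all(M1[, "F"] == 1))
  # a single infeasible row (here D: 0.375 + 0.178 + 0.5 > 1) warns
  lt5 <- zero_mortality_lifetable()
  lt5$q[] <- 0.5
  expect_warning(M5 <- build_transition_matrix("mastectomy", 0, 58, p, lt5),
                 "row D.*capped")
  expect_equal(unname(M5["D", ]), c(0, 0, 0, 0, 0, 1))
  expect_equal(unname(rowSums(M5)), rep(1, 6), tolerance = 1e-12)
})

test_that("matrices are row-stochastic with the fixed arc structure everywhere", {
  p <- base_params()
  lt <- base_lifetable()
  allowed <- matrix(FALSE, 6, 6,
                    dimnames = list(c("A", "B", "C", "D", "E", "F"),
                                    c("A", "B", "C", "D", "E", "F")))
  allowed["A", c("A", "B", "D", "F")] <- TRUE
  allowed["B", c("B", "C", "F")] <- TRUE
  allowed["C", c("C", "D", "F")] <- TRUE
  allowed["D", c("D", "E", "F")] <- TRUE
  allowed["E", c("E", "F")] <- TRUE
  allowed["F", "F"] <- TRUE
  for (s in strategies()) {
    for (cy in c(0, 3, 5, 9, 10, 29)) {
      for (age in c(58, 70, 88, 105)) {
        # extreme old age exercises the documented death-capping, whose
        # warning is asserted separately
        M <- suppressWarnings(build_transition_matrix(s, cy, age, p, lt))
        expect_equal(unname(rowSums(M)), rep(1, 6), tolerance = 1e-12)
        expect_true(all(M >= 0 & M <= 1))
        expect_true(all(M[!allowed] == 0))
      }
    }
  }
})
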