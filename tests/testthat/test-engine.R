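test_that("degenerate one-cycle cohort accrues one discounted year in state A", {
  lt0 <- zero_mortality_lifetable()

  p <- frozen_params(horizon = 1L, oDR = 0)
  r <- run_cohort("lumpectomy_rt", p, lt0)
  expect_equal(r$qaly, 0.87)

  p3 <- frozen_params(horizon = 1L, oDR = 0.03)
  r3 <- run_cohort("lumpectomy_rt", p3, lt0)
  expect_equal(r3$qaly, 0.87 / 1.03)

  # with cycle-0 valuation the initial year is also counted, undiscounted
  p0 <- frozen_params(horizon = 1L, oDR = 0.03)
  p0$options$count_cycle0 <- TRUE
  expect_equal(run_cohort("lumpectomy_rt", p0, lt0)$qaly, 0.87 + 0.87 / 1.03)
})

test_that("occupancy is conserved and death is absorbing", {
  p <- base_params()
  lt <- base_lifetable()
  for (s in strategies()) {
    tr <- run_cohort(s, p, lt)$trace
    expect_equal(unname(rowSums(tr)), rep(1, p$horizon + 1), tolerance = 1e-10)
    expect_true(all(diff(tr[, "F"]) >= 0))
    expect_true(all(tr >= 0 & tr <= 1))
    expect_equal(unname(tr[1, ]), c(1, 0, 0, 0, 0, 0))
  }
})

test_that("expected time in state sums trace occupancy", {
  # cohort that dies immediately: all mass in F after cycle 1
  dead <- matrix(0, 3, 6, dimnames = list(NULL, c("A", "B", "C", "D", "E", "F")))
  dead[1, "A"] <- 1; dead[2:3, "F"] <- 1
  expect_equal(expected_time_in_state(dead, "A"), 1)
  expect_equal(expected_time_in_state(dead, "A", count_cycle0 = FALSE), 0)
  expect_equal(expected_time_in_state(dead, "F"), 2)

  p <- base_params()
  lt <- base_lifetable()
  t_rt <- expected_time_in_state(run_cohort("lumpectomy_rt", p, lt), "A")
  t_no <- expected_time_in_state(run_cohort("lumpectomy_no_rt", p, lt), "A")
  expect_gt(t_rt, t_no)  # lower recurrence keeps patients cancer-free longer
})

test_that("discounting is monotone and zero-value limits hold", {
  lt <- base_lifetable()
  qalys <- costs <- numeric(0)
  for (rate in c(0, 0.03, 0.08)) {
    p <- base_params()
    p$discount$oDR <- rate
    p$discount$cDR <- rate
    r <- run_cohort("lumpectomy_no_rt", p, lt)
    qalys <- c(qalys, r$qaly)
    costs <- c(costs, r$cost_healthcare)
  }
  expect_true(all(diff(qalys) < 0))
  expect_true(all(diff(costs) < 0))

  p0 <- base_params()
  p0$utilities[c("uam", "ual", "ub", "uc", "ud", "ue", "uf")] <- 0
  expect_equal(run_cohort("mastectomy", p0, lt)$qaly, 0)

  pc <- base_params()
  pc$costs[c("cam", "cal_wo", "cal_w", "cbm", "cbl", "cd", "infocare",
             "infocare_lump_no_rt", "prod")] <- 0
  rc <- run_cohort("mastectomy", pc, lt)
  expect_equal(rc$cost_healthcare, 0)
  expect_equal(rc$cost_societal, 0)
})

test_that("time-homogeneous trace equals the matrix-power closed form", {
  p <- base_params()
  # freeze recurrence at one window's rate for all cycles
  for (s in strategies()) {
    p$transitions$recurrence[[s]]$rate <-
      rep(p$transitions$recurrence[[s]]$rate[1], 3)
  }
  lt_const <- zero_mortality_lifetable()
  lt_const$q[] <- 0.01
  M <- build_transition_matrix("lumpectomy_rt", 0, 58, p, lt_const)
  tr <- run_cohort("lumpectomy_rt", p, lt_const)$trace
  v <- c(1, 0, 0, 0, 0, 0)
  Mt <- diag(6)
  for (t in 0:p$horizon) {
    expect_equal(unname(tr[t + 1, ]), as.numeric(v %*% Mt), tolerance = 1e-10)
    Mt <- Mt %*% M
  }
})

test_that("base-case QALY ordering matches the published dominance pattern", {
  p <- base_params()
  lt <- base_lifetable()
  res <- run_strategies(p, lt)
  q <- vapply(res, `[[`, numeric(1), "qaly")
  expect_gte(q["lumpectomy_rt"], q["lumpectomy_no_rt"])
  expect_equal(names(which.min(q)), "mastectomy")
  expect_true(all(q > 0 & q <= p$horizon + 1))
  ch <- vapply(res, `[[`, numeric(1), "cost_healthcare")
  expect_true(all(ch >= 0))
})

test_that("societal perspective adds informal care and deducts productivity", {
  p <- base_params()
  lt <- base_lifetable()
  r_m <- run_cohort("mastectomy", p, lt)
  r_wo <- run_cohort("lumpectomy_no_rt", p, lt)
  r_rt <- run_cohort("lumpectomy_rt", p, lt)

  annuity <- 4104 * sum((1 + 0.03)^-(1:10))
  # mastectomy: informal care only, at the full rate
  expect_equal(r_m$cost_societal - r_m$cost_healthcare,
               10003 * r_m$alive_years_undiscounted)
  # lumpectomy arms: informal care minus the 10-year productivity annuity
  expect_equal(r_wo$cost_societal - r_wo$cost_healthcare,
               5002 * r_wo$alive_years_undiscounted - annuity)
  expect_equal(r_rt$cost_societal - r_rt$cost_healthcare,
               10003 * r_rt$alive_years_undiscounted - annuity)

  # state-D scope switch confines informal care to metastasis occupancy
  pD <- base_params()
  pD$options$informal_care_scope <- "state_D"
  rD <- run_cohort("mastectomy", pD, lt)
  expect_equal(rD$cost_societal - rD$cost_healthcare,
               10003 * expected_time_in_state(rD, "D"))
  expect_lt(rD$cost_societal, r_m$cost_societal)
})

test_that("trace export is tidy and consistent with the result", {
  p <- base_params()
  r <- run_cohort("mastectomy", p, base_lifetable())
  df <- trace_df(r, p)
  expect_equal(nrow(df), p$horizon + 1)
  expect_equal(df$age, 58:88)
  expect_equal(sum(df$qaly_disc), r$qaly)
})
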