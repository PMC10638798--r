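# Shared fixtures built in code.

base_params <- function() default_parameters()

base_lifetable <- function() generate_lifetable()

# parameters for degenerate engine checks: no background mortality, no
# disease transitions, configurable horizon; uses the end-of-cycle valuation
# convention (count_cycle0 = FALSE) so a 1-cycle run accrues exactly one
# discounted year
frozen_params <- function(horizon = 1L, oDR = 0.03) {
  p <- default_parameters()
  p$horizon <- as.integer(horizon)
  p$transitions$tpA2D <- 0
  for (s in strategies()) {
    p$transitions$recurrence[[s]] <- recurrence_schedule(c(0, 0, 0))
  }
  p$discount$oDR <- oDR
  p$options$count_cycle0 <- FALSE
  p
}

# PSA spec table with every distribution degenerate at its base-case value
point_mass_psa <- function(params) {
  specs <- params$psa
  det <- c(tpA2D = params$transitions$tpA2D, tpB2C = params$transitions$tpB2C,
           tpB2F = params$transitions$tpB2F, tpC2D = params$transitions$tpC2D,
           tpD2E = params$transitions$tpD2E, tpD2F = params$transitions$tpD2F,
           cam = params$costs$cam, cal_wo = params$costs$cal_wo,
           cal_w = params$costs$cal_w, cbm = params$costs$cbm,
           cbl = params$costs$cbl, cd = params$costs$cd,
           uam = params$utilities$uam, ual = params$utilities$ual,
           ub = params$utilities$ub, uc = params$utilities$uc,
           ud = params$utilities$ud, ue = params$utilities$ue,
           age = params$entry_age, tpA2B = 1)
  specs$family <- "fixed"
  specs$alpha <- as.numeric(det[specs$parameter])
  # tpA2B fixed spec: multiplier reference becomes 1, so alpha = 1 keeps the
  # base-case schedule
  specs
}

# geometric (independent, brute-force) frontier oracle for 3-strategy
# instances: a strategy is excluded iff some single alternative weakly
# dominates it, or a convex combination of two alternatives attains its
# QALY at strictly lower cost
oracle_frontier <- function(df) {
  n <- nrow(df)
  on_frontier <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && df$qaly[j] >= df$qaly[i] && df$cost[j] <= df$cost[i] &&
          (df$qaly[j] > df$qaly[i] || df$cost[j] < df$cost[i])) {
        on_frontier[i] <- FALSE
      }
    }
    if (!on_frontier[i]) next
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (j == i || k == i || j == k) next
        if (df$qaly[j] < df$qaly[i] && df$qaly[i] < df$qaly[k]) {
          lambda <- (df$qaly[i] - df$qaly[j]) / (df$qaly[k] - df$qaly[j])
          mix_cost <- df$cost[j] + lambda * (df$cost[k] - df$cost[j])
          if (mix_cost < df$cost[i]) on_frontier[i] <- FALSE
        }
      }
    }
  }
  sort(df$strategy[on_frontier])
}
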