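# Deterministic cohort engine: propagate state occupancy over the horizon
# and accumulate discounted costs (both perspectives) and QALYs.
#
# Valuation conventions (all switchable via params$options, defaults chosen
# to reproduce the published deterministic results; see the methods
# vignette):
#   * start-of-cycle valuation: occupancy rows t = 0..horizon are valued
#     with discount factor (1+r)^-t, so the initial all-in-A row carries the
#     undiscounted baseline surgery cost and one undiscounted year at the
#     State A utility;
#   * State A accrues the arm's baseline cost in every cycle of occupancy
#     (costs accumulate in states A, B and D only);
#   * societal perspective adds the arm's informal-care rate times
#     *undiscounted* expected alive-years, and subtracts, for the lumpectomy
#     arms, the annual productivity gain as a 10-year annuity discounted at
#     the cost rate (not survival-weighted).

#' Run the deterministic cohort simulation for one strategy
#'
#' Propagates a cohort that starts entirely in the cancer-free state through
#' `params$horizon` one-year cycles by left-multiplication with the
#' per-cycle transition matrix ([build_transition_matrix()]), with attained
#' age `entry_age + cycle`, then accumulates discounted QALYs and discounted
#' total cost under both the healthcare and the societal perspective.
#'
#' @param strategy One of [strategies()].
#' @param params `cea_parameters` object.
#' @param lifetable Background-mortality life table.
#' @return Object of class `strategy_result`: a list with elements
#'   `strategy`, `qaly`, `cost_healthcare`, `cost_societal`,
#'   `alive_years_undiscounted`, and `trace` (a `(horizon+1) x 6` occupancy
#'   matrix, row 0 = all in state A).
#' @export
#' @examples
#' res <- run_cohort("lumpectomy_rt", default_parameters(), generate_lifetable())
#' res$qaly
run_cohort <- function(strategy, params, lifetable) {
  assert_strategy(strategy)
  H <- params$horizon
  occ <- matrix(0, H + 1, 6, dimnames = list(0:H, state_codes()))
  occ[1, "A"] <- 1
  for (t in seq_len(H)) {
    M <- build_transition_matrix(strategy, t - 1L,
                                 params$entry_age + t - 1L,
                                 params, lifetable)
    occ[t + 1, ] <- occ[t, ] %*% M
  }

  u <- state_utilities(strategy, params)
  cs <- state_costs(strategy, params)
  opt <- params$options

  rows <- if (isTRUE(opt$count_cycle0)) 0:H else 1:H
  odf <- (1 + params$discount$oDR)^-rows
  cdf <- (1 + params$discount$cDR)^-rows
  occ_v <- occ[rows + 1, , drop = FALSE]

  qaly <- sum(odf * (occ_v %*% u))
  cycle_cost <- occ_v %*% cs
  cost_hc <- sum(cdf * cycle_cost)
  if (identical(opt$state_a_cost, "baseline_once")) {
    cost_hc <- cost_hc + baseline_cost(strategy, params)
  }

  alive <- 1 - occ_v[, "F"]
  alive_undisc <- sum(alive)

  # societal add-ons
  info_rate <- if (strategy == "lumpectomy_no_rt") {
    params$costs$infocare_lump_no_rt
  } else {
    params$costs$infocare
  }
  info_weight <- if (identical(opt$informal_care_scope, "state_D")) {
    occ_v[, "D"]
  } else {
    alive
  }
  info_df <- if (isTRUE(opt$informal_care_discounted)) cdf else rep(1, length(rows))
  informal <- info_rate * sum(info_df * info_weight)

  prod_total <- 0
  if (strategy != "mastectomy") {
    py <- seq_len(min(params$costs$prod_years, H))
    pdf <- (1 + params$discount$cDR)^-py
    w <- if (isTRUE(opt$productivity_survival_weighted)) {
      1 - occ[py + 1, "F"]
    } else {
      rep(1, length(py))
    }
    prod_total <- params$costs$prod * sum(pdf * w)
  }
  cost_soc <- cost_hc + informal - prod_total

  structure(list(
    strategy = strategy,
    qaly = qaly,
    cost_healthcare = cost_hc,
    cost_societal = cost_soc,
    alive_years_undiscounted = alive_undisc,
    trace = occ
  ), class = "strategy_result")
}

baseline_cost <- function(strategy, params) {
  switch(strategy,
         mastectomy = params$costs$cam,
         lumpectomy_no_rt = params$costs$cal_wo,
         lumpectomy_rt = params$costs$cal_w)
}

# per-state annual healthcare cost vector (A..F); remission and death states
# accrue nothing
state_costs <- function(strategy, params) {
  cA <- if (identical(params$options$state_a_cost, "per_cycle")) {
    baseline_cost(strategy, params)
  } else {
    0
  }
  cB <- if (strategy == "mastectomy") params$costs$cbm else params$costs$cbl
  c(A = cA, B = cB, C = 0, D = params$costs$cd, E = 0, F = 0)
}

state_utilities <- function(strategy, params) {
  ut <- params$utilities
  uA <- if (strategy == "mastectomy") ut$uam else ut$ual
  c(A = uA, B = ut$ub, C = ut$uc, D = ut$ud, E = ut$ue, F = ut$uf)
}

#' Run all three strategies
#'
#' @param params `cea_parameters` object.
#' @param lifetable Life table.
#' @return Named list of `strategy_result`, one per strategy.
#' @export
run_strategies <- function(params, lifetable) {
  stats::setNames(lapply(strategies(), run_cohort, params = params,
                         lifetable = lifetable), strategies())
}

#' Undiscounted expected years spent in a state
#'
#' Sums occupancy across the valued cycles of a trace (person-years).
#'
#' @param result `strategy_result` from [run_cohort()], or a bare occupancy
#'   matrix with columns `A`..`F`.
#' @param state State letter, one of `"A"`..`"F"`.
#' @param count_cycle0 Include the initial row (default `TRUE`, matching the
#'   engine's default valuation).
#' @return Expected undiscounted person-years in `state`.
#' @export
expected_time_in_state <- function(result, state, count_cycle0 = TRUE) {
  occ <- if (inherits(result, "strategy_result")) result$trace else result
  if (!state %in% colnames(occ)) stop("unknown state: ", state, call. = FALSE)
  rows <- if (count_cycle0) seq_len(nrow(occ)) else seq_len(nrow(occ))[-1]
  sum(occ[rows, state])
}

#' Tidy per-cycle trace table
#'
#' @param result `strategy_result`.
#' @param params The parameters the result was produced with (for entry age
#'   and discount rates).
#' @return `data.frame` with cycle, age, occupancy of each state, and the
#'   per-cycle discounted QALY contribution.
#' @export
trace_df <- function(result, params) {
  occ <- result$trace
  H <- nrow(occ) - 1L
  u <- state_utilities(result$strategy, params)
  data.frame(
    cycle = 0:H,
    age = params$entry_age + 0:H,
    as.data.frame(occ, row.names = FALSE),
    qaly_disc = as.numeric((occ %*% u) * (1 + params$discount$oDR)^-(0:H))
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s: %.3f QALYs, %s SEK (healthcare), %s SEK (societal)\n",
              x$strategy, x$qaly,
              format(round(x$cost_healthcare), big.mark = ","),
              format(round(x$cost_societal), big.mark = ",")))
  invisible(x)
}
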