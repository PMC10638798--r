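# Conversion of published incidences / cumulative incidences into annual
# transition probabilities, and assembly of the per-cycle 6x6 transition
# matrix with the background-mortality overlay.

#' Convert an incidence rate to an annual transition probability
#'
#' Uses the exponential relation `p = 1 - exp(-r t)` with `t = 1` year and
#' `r` the incidence divided by 1000 (rates are quoted per 1000
#' person-years).
#'
#' @param rate_per_1000py Incidence per 1000 person-years (>= 0).
#' @return Annual probability in \[0, 1).
#' @export
#' @examples
#' prob_from_rate(71.70)  # ~0.069
prob_from_rate <- function(rate_per_1000py) {
  if (any(rate_per_1000py < 0)) stop("incidence rate must be >= 0", call. = FALSE)
  1 - exp(-rate_per_1000py / 1000)
}

#' Convert a cumulative incidence to an annual transition probability
#'
#' A cumulative incidence `CI` observed over `T` years of follow-up implies
#' a constant event rate `r = -log(1 - CI) / T`; the annual probability is
#' then `p = 1 - exp(-r)`.
#'
#' @param ci Cumulative incidence, in \[0, 1).
#' @param years Follow-up period in years (> 0).
#' @return Annual probability in \[0, 1).
#' @export
#' @examples
#' prob_from_cumulative_incidence(0.143, 20)  # ~0.008
prob_from_cumulative_incidence <- function(ci, years) {
  if (any(ci < 0) || any(ci >= 1)) {
    stop("cumulative incidence must be in [0, 1)", call. = FALSE)
  }
  if (any(years <= 0)) stop("follow-up years must be > 0", call. = FALSE)
  r <- -log(1 - ci) / years
  1 - exp(-r)
}

#' Derive the mastectomy recurrence schedule via an incidence rate ratio
#'
#' No Swedish incidence of loco-regional recurrence after mastectomy is
#' available, so it is transferred from the lumpectomy-without-irradiation
#' schedule using the mastectomy vs lumpectomy-without-irradiation incidence
#' rate ratio observed in a US trial (base case 1.27, with the Swedish
#' without-irradiation incidence as numerator): each window's incidence is
#' divided by the ratio.
#'
#' @param lump_no_rt_schedule Recurrence schedule
#'   (see [recurrence_schedule()]) of lumpectomy without irradiation.
#' @param irr Incidence rate ratio (> 0), default 1.27.
#' @return Recurrence schedule for mastectomy.
#' @export
#' @examples
#' mastectomy_schedule_from_irr(recurrence_schedule(c(71.70, 34.00, 9.00)))
mastectomy_schedule_from_irr <- function(lump_no_rt_schedule, irr = 1.27) {
  if (irr <= 0) stop("incidence rate ratio must be > 0", call. = FALSE)
  out <- lump_no_rt_schedule
  out$rate <- out$rate / irr
  out
}

#' Time-dependent recurrence probability tpA2B
#'
#' Selects the follow-up window containing model cycle `cycle` (0-based;
#' cycles 0-4 use the first window, 5-9 the second, 10-29 the third) and
#' converts that window's incidence with [prob_from_rate()]. A multiplicative
#' uncertainty factor (`transitions$tpA2B_multiplier`, used by the PSA) is
#' applied afterwards and the result clipped to \[0, 1\].
#'
#' @param strategy One of [strategies()].
#' @param cycle 0-based cycle index within the model horizon.
#' @param params `cea_parameters` object.
#' @return Annual probability of moving from cancer-free to loco-regional
#'   recurrence.
#' @export
tpA2B_at <- function(strategy, cycle, params) {
  assert_strategy(strategy)
  sched <- params$transitions$recurrence[[strategy]]
  if (any(cycle < 0) || any(cycle >= params$horizon)) {
    stop("cycle outside model horizon [0, ", params$horizon, ")", call. = FALSE)
  }
  idx <- findInterval(cycle, sched$start)  # half-open windows [start, end)
  p <- prob_from_rate(sched$rate[idx]) * params$transitions$tpA2B_multiplier
  pmin(pmax(p, 0), 1)
}

#' Build the per-cycle transition matrix for one strategy
#'
#' Assembles the 6x6 row-stochastic transition matrix at a given cycle and
#' attained age. Age-specific background mortality `mor_gp(age)` enters as
#' the death probability from states A, C and E and, by default, is added to
#' the disease-specific death probabilities from B and D; stay-probabilities
#' are the row complements. If a complement would be negative, the death
#' probability is capped at 1, the other exits are set to 0 and a warning is
#' emitted (base-case inputs never reach this regime).
#'
#' @param strategy One of [strategies()].
#' @param cycle 0-based cycle index.
#' @param age Attained age (years) at the start of the cycle.
#' @param params `cea_parameters` object.
#' @param lifetable Life table (see [generate_lifetable()]).
#' @return 6x6 matrix with dimnames `A`..`F`, rows summing to 1.
#' @export
#' @examples
#' lt0 <- zero_mortality_lifetable()
#' build_transition_matrix("mastectomy", 20, 78, default_parameters(), lt0)["B", ]
build_transition_matrix <- function(strategy, cycle, age, params, lifetable) {
  assert_strategy(strategy)
  tr <- params$transitions
  m <- mortality_at(lifetable, age)
  M <- matrix(0, 6, 6, dimnames = list(state_codes(), state_codes()))

  a2b <- tpA2B_at(strategy, cycle, params)
  M["A", "B"] <- a2b
  M["A", "D"] <- tr$tpA2D
  M["A", "F"] <- m
  M["B", "C"] <- tr$tpB2C
  M["B", "F"] <- tr$tpB2F + if (params$options$bg_mortality_additive) m else 0
  M["C", "D"] <- tr$tpC2D
  M["C", "F"] <- m
  M["D", "E"] <- tr$tpD2E
  M["D", "F"] <- tr$tpD2F + if (params$options$bg_mortality_additive) m else 0
  M["E", "F"] <- m
  M["F", "F"] <- 1

  for (s in c("A", "B", "C", "D", "E")) {
    stay <- 1 - sum(M[s, ])
    if (stay < 0) {
      # infeasible row: certain death dominates, drop the other exits
      warning("transition row ", s, " infeasible at age ", age,
              "; death capped at 1", call. = FALSE)
      M[s, ] <- 0
      M[s, "F"] <- 1
    } else {
      M[s, s] <- stay
    }
  }
  M
}
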