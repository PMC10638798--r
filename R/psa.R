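# Probabilistic sensitivity analysis: joint parameter sampling, Monte Carlo
# re-evaluation of the cohort model, CE-plane and CEAC summaries.

#' Sample one parameter draw for the probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter from its published distribution:
#' probabilities and utilities from Beta(alpha, beta), costs from
#' Gamma(shape, scale), entry age from Normal(58, 11.8) truncated to
#' \[18, 100\] (inverse-CDF truncation) and rounded to whole years.
#' Parameters marked not-applicable in the published table (discount rates,
#' background mortality, informal care, productivity, complements) are held
#' fixed, and complements are recomputed per draw inside the transition
#' matrix.
#'
#' The time-dependent recurrence probability has a single published Beta
#' whose mean equals the mastectomy first-window annual probability; the
#' draw is converted into a multiplicative shift `p*/mean` applied to all
#' nine window probabilities (clipped to \[0,1\]) so the windows co-vary.
#'
#' Draws implying a negative stay-probability (`tpB2C + tpB2F > 1` or
#' `tpD2E + tpD2F > 1`) are rejected and resampled, up to 1000 consecutive
#' rejections.
#'
#' @param params Base `cea_parameters`; sampled values overwrite its
#'   transition, cost and utility fields.
#' @return A `cea_parameters` object with sampled values and the sampled
#'   `entry_age`.
#' @export
sample_draw <- function(params) {
  specs <- params$psa
  for (attempt in seq_len(1000)) {
    draw <- params
    for (i in seq_len(nrow(specs))) {
      row <- specs[i, ]
      value <- switch(row$family,
        beta   = stats::rbeta(1, row$alpha, row$beta),
        gamma  = stats::rgamma(1, shape = row$alpha, scale = row$beta),
        normal = stats::rnorm(1, row$alpha, row$beta),
        fixed  = row$alpha,
        stop("unknown distribution family '", row$family, "' for ",
             row$parameter, call. = FALSE)
      )
      draw <- assign_sampled(draw, row$parameter, value, row)
    }
    tr <- draw$transitions
    if (tr$tpB2C + tr$tpB2F <= 1 && tr$tpD2E + tr$tpD2F <= 1) {
      return(draw)
    }
  }
  stop("PSA: 1000 consecutive draws rejected as infeasible", call. = FALSE)
}

assign_sampled <- function(params, parameter, value, row) {
  if (parameter == "age") {
    if (row$family == "normal") {
      # re-map the normal draw through inverse-CDF truncation to [18, 100]
      p <- stats::pnorm(value, row$alpha, row$beta)
      lo <- stats::pnorm(18, row$alpha, row$beta)
      hi <- stats::pnorm(100, row$alpha, row$beta)
      value <- stats::qnorm(lo + p * (hi - lo), row$alpha, row$beta)
    }
    params$entry_age <- round(min(max(value, 18), 100))
  } else if (parameter == "tpA2B") {
    reference <- if (row$family == "beta") {
      row$alpha / (row$alpha + row$beta)
    } else {
      1
    }
    params$transitions$tpA2B_multiplier <- value / reference
  } else if (parameter %in% c("tpA2D", "tpB2C", "tpB2F", "tpC2D",
                              "tpD2E", "tpD2F")) {
    params$transitions[[parameter]] <- value
  } else if (parameter %in% c("cam", "cal_wo", "cal_w", "cbm", "cbl", "cd")) {
    params$costs[[parameter]] <- value
  } else if (parameter %in% c("uam", "ual", "ub", "uc", "ud", "ue")) {
    params$utilities[[parameter]] <- value
  } else {
    stop("PSA specification for unknown parameter '", parameter, "'",
         call. = FALSE)
  }
  params
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo simulation: `n_iter` joint parameter draws, one cohort run
#' per strategy per draw with common sampled parameters across strategies,
#' summarised as per-strategy means and empirical 2.5/97.5 percentile
#' intervals, plus the raw draw-level results for CE-plane and CEAC
#' construction.
#'
#' @param params Base `cea_parameters`.
#' @param lifetable Life table; attained ages beyond its coverage use its
#'   oldest rate.
#' @param n_iter Number of iterations (default 1000).
#' @param seed Integer seed for reproducibility.
#' @return Object of class `psa_result`: list with `draws` (one row per
#'   iteration x strategy: `iter`, `strategy`, `entry_age`, `qaly`,
#'   `cost_healthcare`, `cost_societal`), `summary` (per-strategy means and
#'   95% percentile intervals) and `n_iter`.
#' @export
run_psa <- function(params, lifetable, n_iter = 1000, seed = NULL) {
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    draw <- sample_draw(params)
    res <- run_strategies(draw, lifetable)
    out[[it]] <- data.frame(
      iter = it,
      strategy = strategies(),
      entry_age = draw$entry_age,
      qaly = vapply(res, `[[`, numeric(1), "qaly"),
      cost_healthcare = vapply(res, `[[`, numeric(1), "cost_healthcare"),
      cost_societal = vapply(res, `[[`, numeric(1), "cost_societal")
    )
  }
  draws <- do.call(rbind, out)
  rownames(draws) <- NULL

  pct <- function(x, p) as.numeric(stats::quantile(x, p, names = FALSE))
  summary <- do.call(rbind, lapply(strategies(), function(s) {
    d <- draws[draws$strategy == s, ]
    data.frame(
      strategy = s,
      mean_qaly = mean(d$qaly),
      qaly_lo = pct(d$qaly, 0.025), qaly_hi = pct(d$qaly, 0.975),
      mean_cost_healthcare = mean(d$cost_healthcare),
      cost_healthcare_lo = pct(d$cost_healthcare, 0.025),
      cost_healthcare_hi = pct(d$cost_healthcare, 0.975),
      mean_cost_societal = mean(d$cost_societal),
      cost_societal_lo = pct(d$cost_societal, 0.025),
      cost_societal_hi = pct(d$cost_societal, 0.975)
    )
  }))
  rownames(summary) <- NULL
  structure(list(draws = draws, summary = summary, n_iter = n_iter),
            class = "psa_result")
}

#' Incremental analysis on PSA means
#'
#' @param psa `psa_result`.
#' @param perspective `"healthcare"` or `"societal"`.
#' @return `cea_result` computed from the PSA mean costs and QALYs.
#' @export
psa_incremental <- function(psa, perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  costcol <- paste0("mean_cost_", perspective)
  incremental_analysis(
    data.frame(strategy = psa$summary$strategy,
               cost = psa$summary[[costcol]],
               qaly = psa$summary$mean_qaly),
    perspective)
}

# draw-level incremental (alternative minus comparator) cost/QALY pairs
pairwise_increments <- function(psa, comparison, perspective) {
  costcol <- paste0("cost_", perspective)
  a <- psa$draws[psa$draws$strategy == comparison[1], ]
  b <- psa$draws[psa$draws$strategy == comparison[2], ]
  a <- a[order(a$iter), ]; b <- b[order(b$iter), ]
  data.frame(iter = a$iter,
             d_qaly = a$qaly - b$qaly,
             d_cost = a[[costcol]] - b[[costcol]])
}

#' Cost-effectiveness plane points
#'
#' Per-draw incremental (QALY, cost) pairs for one ordered comparison
#' (alternative minus comparator).
#'
#' @param psa `psa_result`.
#' @param comparison Character vector `c(alternative, comparator)`.
#' @param perspective `"healthcare"` or `"societal"`.
#' @return `data.frame` with `iter`, `d_qaly`, `d_cost`.
#' @export
ce_plane <- function(psa, comparison,
                     perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  vapply(comparison, assert_strategy, character(1))
  pairwise_increments(psa, comparison, perspective)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold `lambda`, the probability that the
#' alternative is cost-effective against the comparator: the fraction of
#' draws with positive incremental net monetary benefit,
#' `NMB = lambda x QALY - cost`.
#'
#' @param psa `psa_result`.
#' @param comparison Character vector `c(alternative, comparator)`.
#' @param wtp_grid Thresholds in SEK/QALY (default 0 to 2,000,000 in
#'   100,000-SEK steps).
#' @param perspective `"healthcare"` or `"societal"`.
#' @return Object of class `ceac_curve`: `data.frame` with `wtp` and
#'   `probability`.
#' @export
#' @examples
#' \donttest{
#' psa <- run_psa(default_parameters(), generate_lifetable(),
#'                n_iter = 100, seed = 1)
#' ceac(psa, c("lumpectomy_rt", "lumpectomy_no_rt"))
#' }
ceac <- function(psa, comparison, wtp_grid = seq(0, 2e6, by = 1e5),
                 perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  if (!length(wtp_grid)) stop("empty WTP grid", call. = FALSE)
  if (is.unsorted(wtp_grid, strictly = TRUE)) {
    stop("WTP grid must be strictly increasing", call. = FALSE)
  }
  inc <- pairwise_increments(psa, comparison, perspective)
  if (!nrow(inc)) stop("no PSA draws", call. = FALSE)
  probability <- vapply(wtp_grid, function(lambda) {
    mean(lambda * inc$d_qaly - inc$d_cost > 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = probability),
            class = c("ceac_curve", "data.frame"),
            comparison = comparison, perspective = perspective)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis, %d iterations\n", x$n_iter))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-17s QALY %5.2f (%.2f-%.2f)  cost(hc) %s (%s-%s) SEK\n",
                s$strategy[i], s$mean_qaly[i], s$qaly_lo[i], s$qaly_hi[i],
                format(round(s$mean_cost_healthcare[i]), big.mark = ","),
                format(round(s$cost_healthcare_lo[i]), big.mark = ","),
                format(round(s$cost_healthcare_hi[i]), big.mark = ",")))
  }
  invisible(x)
}
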