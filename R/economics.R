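# Incremental cost-effectiveness analysis: ICERs, strong and extended
# dominance elimination, Swedish willingness-to-pay categories.

#' Incremental cost-effectiveness ratio
#'
#' `(cost_a - cost_b) / (qaly_a - qaly_b)`, in SEK per QALY gained.
#'
#' @param cost_a,qaly_a Cost and effect of the first alternative.
#' @param cost_b,qaly_b Cost and effect of the comparator.
#' @return SEK per QALY.
#' @export
icer <- function(cost_a, qaly_a, cost_b, qaly_b) {
  if (isTRUE(all.equal(qaly_a, qaly_b))) {
    stop("ICER undefined: equal QALYs", call. = FALSE)
  }
  (cost_a - cost_b) / (qaly_a - qaly_b)
}

#' Swedish cost-per-QALY category of an ICER
#'
#' Below 100,000 SEK/QALY gained: `low`; 100,000 to just under 500,000:
#' `moderate`; 500,000 up to and including 1 million: `high`; exceeding 1
#' million: `very_high`.
#'
#' @param icer_value Non-negative ICER in SEK per QALY.
#' @return One of `"low"`, `"moderate"`, `"high"`, `"very_high"`.
#' @export
#' @examples
#' categorize_icer(402994)  # "moderate"
categorize_icer <- function(icer_value) {
  if (any(icer_value < 0)) {
    stop("negative ICER: resolve dominance before categorising", call. = FALSE)
  }
  out <- as.character(cut(icer_value, breaks = c(-Inf, 1e5, 5e5, 1e6, Inf),
                          labels = c("low", "moderate", "high", "very_high"),
                          right = FALSE, include.lowest = TRUE))
  out[icer_value == 1e6] <- "high"  # "exceeding 1 million" is strict
  out
}

#' Incremental analysis with dominance elimination
#'
#' Orders strategies by effectiveness, marks strong dominance (weakly: a
#' strategy is dominated if some alternative has no higher cost and no lower
#' QALY, with at least one strict — ties resolved in favour of the cheaper
#' strategy), then iteratively removes extended dominance (a strategy whose
#' incremental ICER exceeds that of the next move up the frontier), and
#' computes ICERs between adjacent frontier strategies together with their
#' Swedish cost-per-QALY category.
#'
#' @param results Either a named list of `strategy_result` objects (from
#'   [run_strategies()]) or a `data.frame` with columns `strategy`, `cost`,
#'   `qaly`.
#' @param perspective `"healthcare"` or `"societal"`; used only when
#'   `results` is a list of `strategy_result`s.
#' @return Object of class `cea_result`: a list with `table` (one row per
#'   strategy: cost, qaly, average CE ratio, dominance label, frontier flag,
#'   ICER vs previous frontier strategy, category) and `frontier` (ordered
#'   frontier strategy names).
#' @export
incremental_analysis <- function(results,
                                 perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  if (!is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r) {
      data.frame(strategy = r$strategy,
                 cost = if (perspective == "healthcare") r$cost_healthcare
                        else r$cost_societal,
                 qaly = r$qaly)
    }))
  }
  if (nrow(results) < 2) {
    stop("incremental analysis needs at least 2 strategies", call. = FALSE)
  }

  df <- results[order(results$qaly, results$cost), ]
  df$acer <- df$cost / df$qaly
  df$dominance <- "none"

  # strong (incl. weak tie-breaking) dominance
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j) next
      if (df$qaly[j] >= df$qaly[i] && df$cost[j] <= df$cost[i] &&
          (df$qaly[j] > df$qaly[i] || df$cost[j] < df$cost[i])) {
        df$dominance[i] <- "strongly_dominated"
        break
      }
    }
  }

  # extended dominance: drop strategies producing a non-increasing ICER
  # sequence along the candidate frontier
  frontier <- df$strategy[df$dominance == "none"]
  repeat {
    sub <- df[match(frontier, df$strategy), ]
    if (nrow(sub) < 3) break
    icers <- diff(sub$cost) / diff(sub$qaly)
    bad <- which(diff(icers) < 0)
    if (!length(bad)) break
    drop <- sub$strategy[bad[1] + 1]
    df$dominance[df$strategy == drop] <- "extendedly_dominated"
    frontier <- setdiff(frontier, drop)
  }

  df$frontier <- df$strategy %in% frontier
  df$icer <- NA_real_
  df$category <- NA_character_
  idx <- match(frontier, df$strategy)
  if (length(idx) >= 2) {
    for (k in 2:length(idx)) {
      v <- icer(df$cost[idx[k]], df$qaly[idx[k]],
                df$cost[idx[k - 1]], df$qaly[idx[k - 1]])
      df$icer[idx[k]] <- v
      df$category[idx[k]] <- if (v >= 0) categorize_icer(v) else NA_character_
    }
  }
  rownames(df) <- NULL
  structure(list(table = df, frontier = frontier, perspective = perspective),
            class = "cea_result")
}

#' Table-style summary of a deterministic analysis
#'
#' Runs all three strategies and lays out QALYs, costs under both
#' perspectives, pairwise increments and frontier ICERs — the deterministic
#' results table of the analysis.
#'
#' @param params `cea_parameters` object.
#' @param lifetable Life table.
#' @return A list with `strategies` (per-strategy QALY/costs), `incremental`
#'   (pairwise differences), and `cea` (a `cea_result` per perspective).
#' @export
cea_table <- function(params, lifetable) {
  res <- run_strategies(params, lifetable)
  per_strategy <- do.call(rbind, lapply(res, function(r) {
    data.frame(strategy = r$strategy, qaly = r$qaly,
               cost_healthcare = r$cost_healthcare,
               cost_societal = r$cost_societal)
  }))
  rownames(per_strategy) <- NULL
  pairs <- list(c("mastectomy", "lumpectomy_no_rt"),
                c("lumpectomy_no_rt", "lumpectomy_rt"),
                c("mastectomy", "lumpectomy_rt"))
  incremental <- do.call(rbind, lapply(pairs, function(p) {
    a <- res[[p[1]]]; b <- res[[p[2]]]
    data.frame(comparison = paste(p[1], "vs", p[2]),
               d_qaly = a$qaly - b$qaly,
               d_cost_healthcare = a$cost_healthcare - b$cost_healthcare,
               d_cost_societal = a$cost_societal - b$cost_societal)
  }))
  list(strategies = per_strategy,
       incremental = incremental,
       cea = list(healthcare = incremental_analysis(res, "healthcare"),
                  societal = incremental_analysis(res, "societal")))
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Incremental cost-effectiveness analysis (", x$perspective,
      " perspective)\n", sep = "")
  df <- x$table
  df$cost <- format(round(df$cost), big.mark = ",")
  df$qaly <- round(df$qaly, 3)
  df$acer <- format(round(df$acer), big.mark = ",")
  df$icer <- ifelse(is.na(df$icer), "-",
                    format(round(df$icer), big.mark = ","))
  print(df, row.names = FALSE)
  invisible(x)
}
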