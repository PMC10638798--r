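# Fixed six-state topology and the three surgical comparators.

#' Health states of the Markov model
#'
#' The model distinguishes six health states: cancer-free after successful
#' primary surgery (`A`), loco-regional recurrence (`B`), remission after
#' recurrence (`C`), distant metastasis (`D`), remission after metastasis
#' (`E`) and death (`F`, absorbing). Transitions are restricted to the arcs
#' A->{A,B,D,F}, B->{B,C,F}, C->{C,D,F}, D->{D,E,F}, E->{E,F}, F->F.
#'
#' @return Named character vector of the six state codes.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c(A = "cancer_free",
    B = "locoregional_recurrence",
    C = "remission_after_recurrence",
    D = "metastasis",
    E = "remission_after_metastasis",
    F = "death")
}

#' Surgical strategies compared by the model
#'
#' @return Character vector of the three strategy codes: `mastectomy`,
#'   `lumpectomy_no_rt` (breast-conserving surgery without follow-up
#'   irradiation) and `lumpectomy_rt` (with irradiation).
#' @export
strategies <- function() {
  c("mastectomy", "lumpectomy_no_rt", "lumpectomy_rt")
}

# internal: state letter codes in matrix order
state_codes <- function() c("A", "B", "C", "D", "E", "F")

assert_strategy <- function(strategy) {
  if (!is.character(strategy) || length(strategy) != 1L ||
      !strategy %in% strategies()) {
    stop("unknown strategy: ", paste(strategy, collapse = ", "),
         " (expected one of ", paste(strategies(), collapse = ", "), ")",
         call. = FALSE)
  }
  strategy
}
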