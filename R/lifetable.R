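# Age-indexed background mortality: synthetic Gompertz-Makeham generator
# and CSV reader for externally supplied national tables.

#' Generate a synthetic annual mortality life table
#'
#' Stand-in for a national all-cause mortality schedule. Annual death
#' probability follows a Gompertz-Makeham hazard,
#' `q(age) = 1 - exp(-(a + b * c^age))`: a small age-independent term `a`
#' plus exponential senescent growth. The default parameters are calibrated
#' so that `q(58)` is about 0.004 and `q(85)` about 0.08 — the order of
#' magnitude of contemporary Swedish female mortality.
#'
#' The table is deterministic given its parameters; `seed` is reserved for
#' optional jitter and currently unused.
#'
#' @param makeham_a Age-independent hazard component (default 2e-4).
#' @param gompertz_b Senescent hazard scale (default 5.3e-6).
#' @param gompertz_c Per-year hazard growth factor (default 1.12).
#' @param ages Integer ages covered (default 0:110).
#' @param seed Unused; kept for interface stability.
#' @return Object of class `lifetable`: a `data.frame` with columns `age`
#'   and `q` (annual death probability).
#' @export
#' @examples
#' lt <- generate_lifetable()
#' mortality_at(lt, 58)
generate_lifetable <- function(makeham_a = 2e-4, gompertz_b = 5.3e-6,
                               gompertz_c = 1.12, ages = 0:110,
                               seed = NULL) {
  hazard <- makeham_a + gompertz_b * gompertz_c^ages
  q <- 1 - exp(-hazard)
  if (any(q < 0) || any(q > 1) || any(!is.finite(q))) {
    stop("life-table parameters produce probabilities outside [0,1]",
         call. = FALSE)
  }
  new_lifetable(data.frame(age = as.integer(ages), q = q))
}

#' All-zero mortality life table (testing/diagnostic helper)
#'
#' @param ages Integer ages covered.
#' @return `lifetable` with `q = 0` everywhere.
#' @export
zero_mortality_lifetable <- function(ages = 0:110) {
  new_lifetable(data.frame(age = as.integer(ages), q = 0))
}

new_lifetable <- function(df) {
  structure(df, class = c("lifetable", "data.frame"))
}

validate_lifetable <- function(df) {
  if (!all(c("age", "q") %in% names(df))) {
    stop("life table needs columns 'age' and 'q'", call. = FALSE)
  }
  bad <- which(df$q < 0 | df$q > 1 | !is.finite(df$q))
  if (length(bad)) {
    stop("life table q outside [0,1] at age ", df$age[bad[1]],
         " (row ", bad[1], ")", call. = FALSE)
  }
  d <- diff(df$age)
  if (any(d != 1)) {
    i <- which(d != 1)[1]
    stop("life table ages must be contiguous; gap after age ", df$age[i],
         " (row ", i, ")", call. = FALSE)
  }
  new_lifetable(df)
}

#' Read a life table from CSV
#'
#' Expects a header `age,q` with one row per single year of age. Use this to
#' supply a real national mortality table (e.g. the WHO Swedish schedule)
#' in place of the synthetic Gompertz-Makeham default; ages must be
#' contiguous and probabilities in \[0,1\].
#'
#' @param path CSV file path.
#' @return `lifetable` object.
#' @export
read_lifetable <- function(path) {
  df <- utils::read.csv(path)
  validate_lifetable(df[, c("age", "q")])
}

#' Write a life table to CSV
#'
#' @param lifetable `lifetable` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(lifetable, path) {
  utils::write.csv(as.data.frame(lifetable), path, row.names = FALSE)
  invisible(path)
}

#' Annual background death probability at a given age
#'
#' Looks up the integer age (no interpolation). Ages outside the table's
#' coverage are clamped to its boundary rows; the probabilistic sensitivity
#' analysis samples entry ages whose attained age can exceed any finite
#' table, and the oldest available rate is then carried forward.
#'
#' @param lifetable `lifetable` object.
#' @param age Age in years (vectorised).
#' @return Annual death probability.
#' @export
mortality_at <- function(lifetable, age) {
  age <- floor(age)
  age <- pmin(pmax(age, lifetable$age[1]), lifetable$age[nrow(lifetable)])
  lifetable$q[match(age, lifetable$age)]
}
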