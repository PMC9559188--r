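# DR staging: combine bilateral feature scores with interval weights and bin
# the weighted totals into DR stages.

#' Combine bilateral scores with interval weights
#'
#' Weighted total `score_p * w_p + score_c * w_c` (the comprehensive index
#' `T_CI = w_p(t) T_p + w_c(t) T_c` applied to integer feature scores).
#'
#' @param score_p,score_c Integer scores of the PBC and CBC feature levels.
#' @param w_p,w_c Weights with `w_p + w_c = 1`.
#' @return Numeric total score(s).
#' @export
#' @examples
#' combine_scores(3, 1, 0.37731, 0.62269)  # 1.75462
combine_scores <- function(score_p, score_c, w_p, w_c) {
  if (any(abs(w_p + w_c - 1) > 1e-8)) stop("w_p + w_c must equal 1")
  score_p * w_p + score_c * w_c
}

#' Bin a weighted total score into a DR stage
#'
#' The total is rounded to 2 decimals and placed in half-open intervals
#' `(lower, upper]` with boundaries from the score table (1.50/2.00/2.50 for
#' T and N, 1.50 for grade and ER); a total of exactly 1.00 maps to stage 1.
#'
#' @param total Weighted total score(s).
#' @param variable One of `"t"`, `"n"`, `"grade"`, `"er"`.
#' @param table A [default_score_table()].
#' @return Integer DR stage(s).
#' @export
#' @examples
#' bin_total_score(1.75462, "t")  # stage 2
bin_total_score <- function(total, variable, table = default_score_table()) {
  breaks <- table$breaks[[variable]]
  if (is.null(breaks)) stop("unknown variable: ", variable)
  r <- round(total, 2)
  if (any(r < breaks[1] - 1e-6 | r > breaks[length(breaks)] + 1e-6))
    stop("total score outside [", breaks[1], ", ", breaks[length(breaks)],
         "] for variable ", variable)
  r <- pmin(pmax(r, breaks[1]), breaks[length(breaks)])
  stage <- findInterval(r, breaks, left.open = TRUE)
  as.integer(pmax(stage, 1L))  # exactly 1.00 falls before the first break
}

#' DR-stage a single patient
#'
#' Evaluates each variable's fitted weight curve at the patient's interval
#' time, combines the bilateral scores and bins the totals.
#'
#' @param record One-row `dr_cohort` slice (or list) with non-missing
#'   bilateral T, N, grade and ER and an `interval_time`.
#' @param fits Named list of `dr_weight_fit` for `t`, `n`, `grade`, `er`.
#' @param table A [default_score_table()].
#' @return `dr_stage_result`: list with `dr_stage`, `total_score`,
#'   `weights_used` (each named by variable) and `interval_time`.
#' @export
stage_patient <- function(record, fits, table = default_score_table()) {
  t_int <- record$interval_time
  stages <- totals <- numeric(0)
  wts <- list()
  for (v in .dr_variables) {
    lp <- record[[.side_col(v, "pbc")]]
    lc <- record[[.side_col(v, "cbc")]]
    if (is.null(lp) || is.na(lp) || is.null(lc) || is.na(lc))
      stop("missing required feature: ", v)
    w <- evaluate_weights(fits[[v]], t_int)
    tot <- combine_scores(table$scores[[v]][[lp]], table$scores[[v]][[lc]],
                          w$w_p, w$w_c)
    totals[v] <- tot
    stages[v] <- bin_total_score(tot, v, table)
    wts[[v]] <- c(w_p = w$w_p, w_c = w$w_c)
  }
  structure(list(dr_stage = stages, total_score = totals,
                 weights_used = wts, interval_time = t_int),
            class = "dr_stage_result")
}

#' DR-stage a whole cohort
#'
#' Vectorized staging; patients missing any required bilateral feature get
#' `NA` stages (reported in the `n_unstaged` attribute).
#'
#' @param cohort A `dr_cohort`.
#' @param fits Named list of `dr_weight_fit` for `t`, `n`, `grade`, `er`.
#' @param table A [default_score_table()].
#' @return The cohort with added numeric columns `<v>_total` and integer
#'   columns `<v>_dr` for v in t, n, grade, er.
#' @export
stage_cohort <- function(cohort, fits, table = default_score_table()) {
  out <- cohort
  for (v in .dr_variables) {
    lp <- as.character(cohort[[.side_col(v, "pbc")]])
    lc <- as.character(cohort[[.side_col(v, "cbc")]])
    ok <- !is.na(lp) & !is.na(lc)
    w <- evaluate_weights(fits[[v]], cohort$interval_time)
    tot <- rep(NA_real_, nrow(cohort))
    tot[ok] <- combine_scores(unname(table$scores[[v]][lp[ok]]),
                              unname(table$scores[[v]][lc[ok]]),
                              w$w_p[ok], w$w_c[ok])
    stg <- rep(NA_integer_, nrow(cohort))
    stg[ok] <- bin_total_score(tot[ok], v, table)
    out[[paste0(v, "_total")]] <- tot
    out[[paste0(v, "_dr")]] <- stg
  }
  attr(out, "n_unstaged") <- sum(!complete.cases(
    out[, paste0(.dr_variables, "_dr")]))
  out
}
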