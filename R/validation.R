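# Model assessment: 2:1 splitting, competing-risk concordance, bootstrap
# calibration.

#' Random 2:1 cohort split
#'
#' Simple random split without stratification.  The training set holds
#' `round(n * ratio[1] / sum(ratio))` patients (for the default 2:1 split of
#' n = 13,304 that is 8,869 / 4,435); the two parts are disjoint and
#' exhaustive.
#'
#' @param cohort A `dr_cohort` (n >= 3).
#' @param seed Integer seed recorded on the result.
#' @param ratio Two positive numbers, default `c(2, 1)`.
#' @return List with `training` and `validation` cohorts and `split_seed`.
#' @export
split_cohort <- function(cohort, seed = 1L, ratio = c(2, 1)) {
  n <- nrow(cohort)
  if (n < 3) stop("need at least 3 records to split")
  n_train <- round(n * ratio[1] / sum(ratio))
  set.seed(seed)
  idx <- sample.int(n, n_train)
  prov <- attr(cohort, "provenance")
  df <- as.data.frame(cohort)
  list(training = .new_cohort(df[idx, , drop = FALSE],
                              paste0(prov, " [training]")),
       validation = .new_cohort(df[-idx, , drop = FALSE],
                                paste0(prov, " [validation]")),
       split_seed = as.integer(seed))
}

# core truncated concordance; variant "wolbers" keeps competing-cause
# patients comparable after their event, "harrell" censors them
.cindex_core <- function(predictions, times, events, horizon, variant) {
  idx1 <- which(events == 1 & times <= horizon)
  if (length(idx1) == 0) stop("no comparable pairs: no cause-1 events before horizon")
  num <- 0; den <- 0
  for (i in idx1) {
    comp <- if (variant == "wolbers") (times > times[i]) | (events == 2)
            else times > times[i]
    comp[i] <- FALSE
    m <- sum(comp)
    if (m == 0) next
    pj <- predictions[comp]
    num <- num + sum(pj < predictions[i]) + 0.5 * sum(pj == predictions[i])
    den <- den + m
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

#' Competing-risk concordance index
#'
#' Truncated concordance for predicted cause-1 risk under competing risks.
#' In the default Wolbers-type variant a pair (i, j) is comparable if i has a
#' cause-1 event at `T_i <= horizon` and either `T_j > T_i` or j's event is
#' the competing cause; the pair is concordant when `risk_i > risk_j`, ties
#' count 1/2.  The Harrell-style variant (competing deaths treated as
#' censored) is also exposed.  The confidence interval is a percentile
#' bootstrap over patients.
#'
#' @param predictions Per-patient predicted risk (higher = worse) at
#'   `horizon`.
#' @param times,events Follow-up years and event codes 0/1/2.
#' @param horizon Truncation horizon in years.
#' @param variant `"wolbers"` (default) or `"harrell"`.
#' @param n_boot Bootstrap resamples for the CI (default 200; 0 skips).
#' @param conf_level Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return List with `c_index`, `ci_low`, `ci_upp`, `variant`, `horizon`,
#'   `n_boot`.
#' @export
concordance_index <- function(predictions, times, events, horizon,
                              variant = c("wolbers", "harrell"),
                              n_boot = 200, conf_level = 0.95, seed = NULL) {
  variant <- match.arg(variant)
  if (horizon <= 0) stop("horizon must be > 0")
  stopifnot(length(predictions) == length(times),
            length(times) == length(events))
  ci <- .cindex_core(predictions, times, events, horizon, variant)
  lo <- up <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(times)
    reps <- vapply(seq_len(n_boot), function(b) {
      s <- sample.int(n, n, replace = TRUE)
      tryCatch(.cindex_core(predictions[s], times[s], events[s], horizon,
                            variant),
               error = function(e) NA_real_)
    }, 0)
    qs <- quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                   na.rm = TRUE, names = FALSE)
    lo <- qs[1]; up <- qs[2]
  }
  list(c_index = ci, ci_low = lo, ci_upp = up, variant = variant,
       horizon = horizon, n_boot = n_boot)
}

#' Calibration table for arbitrary risk predictions
#'
#' Bins patients into (near) equal-size groups by predicted cumulative
#' incidence and contrasts each group's mean prediction with the observed
#' Aalen-Johansen CIF at the horizon, with percentile bootstrap intervals on
#' the observed value.  Constant predictions collapse to a single
#' informative group; groups without cause-1 events carry a sparse flag.
#'
#' @param predictions Predicted cause-1 cumulative incidence at `horizon`.
#' @param times,events Follow-up years and event codes 0/1/2.
#' @param horizon Horizon in years.
#' @param groups Number of risk groups (default 3, tertiles).
#' @param n_boot Bootstrap resamples (default 1000; 0 skips the CI).
#' @param conf_level Confidence level.
#' @param seed Optional bootstrap seed.
#' @return data.frame with one row per group: `group`, `n`,
#'   `mean_predicted`, `observed`, `ci_low`, `ci_upp`, `sparse`, `collapsed`.
#' @export
calibration_table <- function(predictions, times, events, horizon,
                              groups = 3, n_boot = 1000, conf_level = 0.95,
                              seed = NULL) {
  if (groups < 2) stop("groups must be >= 2")
  breaks <- unique(quantile(predictions, probs = seq(0, 1, length.out = groups + 1)))
  collapsed <- length(breaks) < groups + 1
  if (length(breaks) < 2) {
    grp <- factor(rep(1L, length(predictions)))
  } else {
    grp <- cut(predictions, breaks = breaks, include.lowest = TRUE,
               labels = FALSE)
    grp <- factor(grp)
  }
  if (!is.null(seed)) set.seed(seed)
  obs_at <- function(tt, ee) .cif_at(estimate_cif(tt, ee, 1L), horizon)
  out <- lapply(levels(grp), function(g) {
    sel <- grp == g
    tt <- times[sel]; ee <- events[sel]
    obs <- obs_at(tt, ee)
    lo <- up <- NA_real_
    if (n_boot > 0 && sum(sel) > 1) {
      reps <- vapply(seq_len(n_boot), function(b) {
        s <- sample.int(length(tt), length(tt), replace = TRUE)
        obs_at(tt[s], ee[s])
      }, 0)
      qs <- quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                     names = FALSE)
      lo <- qs[1]; up <- qs[2]
    }
    data.frame(group = as.integer(g), n = sum(sel),
               mean_predicted = mean(predictions[sel]),
               observed = obs, ci_low = lo, ci_upp = up,
               sparse = sum(ee == 1 & tt <= horizon) == 0,
               collapsed = collapsed)
  })
  do.call(rbind, out)
}

#' Calibration curve of a DR nomogram on a staged cohort
#'
#' Predicts per-patient BCCM from the nomogram's Fine-Gray fit and calls
#' [calibration_table()].
#'
#' @param model A `dr_nomogram`.
#' @param staged A staged cohort (see [stage_cohort()]).
#' @param horizon Horizon in years.
#' @inheritParams calibration_table
#' @return A calibration data.frame (see [calibration_table()]) with
#'   attribute `horizon`.
#' @export
calibration_curve <- function(model, staged, horizon, groups = 3,
                              n_boot = 1000, conf_level = 0.95, seed = NULL) {
  vars <- paste0(.dr_variables, "_dr")
  keep <- complete.cases(staged[, vars])
  dat <- as.data.frame(staged)[keep, , drop = FALSE]
  preds <- predict_cif(model$fit, dat[, vars], horizon)
  out <- calibration_table(preds, dat$followup_time, dat$event, horizon,
                           groups, n_boot, conf_level, seed)
  attr(out, "horizon") <- horizon
  out
}

#' End-to-end validation report
#'
#' Computes the concordance index (10-year horizon on predicted 10-year
#' BCCM by default) and per-horizon calibration tables for a staged cohort
#' under a fitted nomogram.
#'
#' @param model A `dr_nomogram`.
#' @param staged A staged cohort.
#' @param horizons Calibration horizons (default 3/5/10 years).
#' @param c_horizon Concordance truncation horizon (default 10).
#' @param groups Calibration risk groups.
#' @param n_boot_c,n_boot_cal Bootstrap resamples for the two statistics.
#' @param seed Bootstrap seed.
#' @return `dr_validation`: list with `c_index` (from
#'   [concordance_index()]) and `calibration` (named list per horizon).
#' @export
validate_nomogram <- function(model, staged, horizons = c(3, 5, 10),
                              c_horizon = 10, groups = 3, n_boot_c = 200,
                              n_boot_cal = 1000, seed = 1L) {
  vars <- paste0(.dr_variables, "_dr")
  keep <- complete.cases(staged[, vars])
  dat <- as.data.frame(staged)[keep, , drop = FALSE]
  preds <- predict_cif(model$fit, dat[, vars], c_horizon)
  cidx <- concordance_index(preds, dat$followup_time, dat$event, c_horizon,
                            n_boot = n_boot_c, seed = seed)
  calib <- lapply(horizons, function(h)
    calibration_curve(model, staged, h, groups, n_boot_cal, seed = seed))
  names(calib) <- sprintf("%gy", horizons)
  structure(list(c_index = cidx, calibration = calib, split_seed = seed),
            class = "dr_validation")
}

#' @export
print.dr_validation <- function(x, ...) {
  cat(sprintf("C-index (%s, %g-year): %.3f (95%% CI %.3f-%.3f)\n",
              x$c_index$variant, x$c_index$horizon, x$c_index$c_index,
              x$c_index$ci_low, x$c_index$ci_upp))
  for (h in names(x$calibration)) {
    cat("calibration @", h, "\n")
    print(x$calibration[[h]], row.names = FALSE)
  }
  invisible(x)
}
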