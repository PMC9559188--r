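# Variable screening: univariate and multivariate Fine-Gray analysis of the
# recoded bilateral variables, selecting the nomogram's inputs.

# Build the encoded design column(s) for one screening variable.
# Paired categorical variables become a single factor "PBC/CBC" with the
# concordant-lowest pair as reference; age is binned on the CBC side;
# interval_time stays continuous.
.screen_encode <- function(cohort, variable) {
  paired <- c("t", "n", "grade", "er", "pr", "her2", "pathology", "surgery")
  if (variable %in% paired) {
    lev <- .dr_levels[[variable]]
    p <- factor(cohort[[.side_col(variable, "pbc")]], levels = lev)
    c <- factor(cohort[[.side_col(variable, "cbc")]], levels = lev)
    combo <- factor(paste(as.character(p), as.character(c), sep = "/"),
                    levels = as.vector(outer(lev, lev,
                                             function(a, b) paste(a, b, sep = "/"))))
    combo[is.na(p) | is.na(c)] <- NA
    out <- data.frame(x = combo)
  } else if (variable == "age") {
    out <- data.frame(x = cut(cohort$age_cbc, breaks = c(-Inf, 40, 50, 60, Inf),
                              labels = c("<=40", "41-50", "51-60", ">60")))
  } else if (variable == "interval_time") {
    out <- data.frame(x = cohort$interval_time)
  } else if (variable %in% c("race", "marital_pair")) {
    out <- data.frame(x = factor(cohort[[variable]],
                                 levels = .dr_levels[[variable]]))
  } else {
    stop("unknown screening variable: ", variable)
  }
  names(out) <- variable
  out
}

# joint Wald chi-square over all coefficients of one variable
.joint_wald_p <- function(fit, variable) {
  idx <- grep(paste0("^`?", variable), names(fit$coefficients))
  b <- fit$coefficients[idx]
  V <- fit$covariance[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  pchisq(stat, df = length(b), lower.tail = FALSE)
}

#' Screen bilateral variables by Fine-Gray regression
#'
#' Reproduces the two-step screening flow: each recoded variable is fitted
#' univariately against breast-cancer death (competing: other-cause death);
#' variables significant at `alpha` (joint Wald test across the variable's
#' dummy coefficients) enter one joint multivariate fit; the selected set
#' holds the variables whose multivariate joint Wald p-value is below
#' `alpha`.  Per-level SHRs, Wald confidence intervals and p-values are
#' reported for both steps.  Variables with a single observed level are
#' skipped with a degeneracy note.
#'
#' @param cohort A `dr_cohort`.
#' @param variables Variables to screen; defaults to age, interval time,
#'   race, marital status and the paired T/N/grade/ER/pathology/surgery/PR/
#'   HER2 variables.
#' @param alpha Selection threshold (default 0.05).
#' @param multivariate_exclude Variables reported univariately but never
#'   entered into the multivariate fit (default PR and HER2, which lack
#'   multivariate entries in the source screening design).
#' @return `dr_screening`: list with `table` (per variable/level counts,
#'   percentages, univariate and multivariate SHR/CI/p), `variable_p`
#'   (joint Wald p per variable and step), `selected`, `skipped`, `alpha`.
#' @export
screen_variables <- function(cohort,
                             variables = c("age", "interval_time", "race",
                                           "marital_pair", "t", "n", "grade",
                                           "er", "pathology", "surgery",
                                           "pr", "her2"),
                             alpha = 0.05,
                             multivariate_exclude = c("pr", "her2")) {
  fu <- cohort$followup_time
  ev <- cohort$event
  rows <- list()
  uni_p <- setNames(rep(NA_real_, length(variables)), variables)
  skipped <- character()

  enc <- lapply(setNames(variables, variables),
                function(v) .screen_encode(cohort, v))

  for (v in variables) {
    x <- enc[[v]][[1]]
    if (is.factor(x)) x <- droplevels(x)
    n_lev <- if (is.factor(x)) nlevels(x) else Inf
    if (n_lev < 2 || (is.numeric(x) && length(unique(x[!is.na(x)])) < 2)) {
      skipped <- c(skipped, v)
      next
    }
    design <- setNames(data.frame(x), v)
    fit <- tryCatch(fit_fine_gray(design, fu, ev),
                    error = function(e) stop("screening fit failed for '", v,
                                             "': ", conditionMessage(e)))
    uni_p[v] <- .joint_wald_p(fit, v)
    rows[[v]] <- .screen_rows(v, x, fit, step = "uni")
  }

  screened <- setdiff(variables, skipped)
  uni_sig <- screened[!is.na(uni_p[screened]) & uni_p[screened] < alpha]
  multi_vars <- setdiff(uni_sig, multivariate_exclude)
  multi_p <- setNames(rep(NA_real_, length(variables)), variables)
  if (length(multi_vars) >= 1) {
    design <- do.call(cbind, enc[multi_vars])
    names(design) <- multi_vars
    keep <- complete.cases(design)
    mfit <- fit_fine_gray(design[keep, , drop = FALSE], fu[keep], ev[keep])
    for (v in multi_vars) {
      multi_p[v] <- .joint_wald_p(mfit, v)
      rows[[v]] <- .merge_multi(rows[[v]], .screen_rows(v, enc[[v]][[1]],
                                                        mfit, step = "multi"))
    }
  }
  selected <- multi_vars[!is.na(multi_p[multi_vars]) & multi_p[multi_vars] < alpha]
  if (alpha >= 1) selected <- screened

  for (v in names(rows))  # variables outside the multivariate fit: NA columns
    for (col in c("multi_shr", "multi_ci_low", "multi_ci_upp", "multi_p"))
      if (!col %in% names(rows[[v]])) rows[[v]][[col]] <- NA_real_
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 variable_p = data.frame(variable = variables,
                                         uni_p = unname(uni_p[variables]),
                                         multi_p = unname(multi_p[variables])),
                 selected = selected, skipped = skipped, alpha = alpha),
            class = "dr_screening")
}

# per-level report rows for one variable from one fit
.screen_rows <- function(v, x, fit, step) {
  if (is.numeric(x)) {
    nm <- v
    lev <- "continuous"
    n <- sum(!is.na(x)); pct <- rep(NA_real_, 1)
  } else {
    x <- droplevels(x)
    lev <- levels(x)
    nm <- paste0(v, lev)
    tabx <- table(x)
    n <- as.integer(tabx)
    pct <- 100 * n / sum(n)
  }
  idx <- match(nm, names(fit$coefficients))
  out <- data.frame(variable = v, level = lev, n = n, percent = pct,
                    stringsAsFactors = FALSE)
  out[[paste0(step, "_shr")]] <- ifelse(is.na(idx), NA, fit$shr[idx])
  out[[paste0(step, "_ci_low")]] <- ifelse(is.na(idx), NA, fit$ci_low[idx])
  out[[paste0(step, "_ci_upp")]] <- ifelse(is.na(idx), NA, fit$ci_upp[idx])
  out[[paste0(step, "_p")]] <- ifelse(is.na(idx), NA, fit$p_values[idx])
  out
}

.merge_multi <- function(uni_rows, multi_rows) {
  cbind(uni_rows, multi_rows[, grep("^multi_", names(multi_rows)),
                             drop = FALSE])
}

#' @export
print.dr_screening <- function(x, ...) {
  cat(sprintf("Fine-Gray variable screening (alpha = %g)\n", x$alpha))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  if (length(x$skipped))
    cat("skipped (degenerate):", paste(x$skipped, collapse = ", "), "\n")
  print(x$variable_p, row.names = FALSE)
  invisible(x)
}
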