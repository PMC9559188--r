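# DR competing-risk nomogram: Fine-Gray on the four DR stages (treated as
# ordinal scores), conventional 0-100 point normalization, and 3/5/10-year
# BCCM predictions.

#' Fit the DR nomogram
#'
#' Multivariable Fine-Gray fit of breast-cancer-specific cumulative
#' mortality on the four DR stages entered as ordinal integer scores.
#' Points for variable `v` at stage `s` are
#' `100 * beta_v * (s - s_min_v) / max_u(beta_u * range_u)`, so the variable
#' with the largest coefficient-times-range spans exactly 100 points.
#'
#' @param staged A cohort from [stage_cohort()] (columns `t_dr`, `n_dr`,
#'   `grade_dr`, `er_dr`); rows with missing stages are dropped.
#' @param horizons Prediction horizons in years for the lookup table.
#' @param grid_size Number of total-point rows in the lookup table.
#' @return `dr_nomogram`: list with the Fine-Gray `fit`, `points` (per
#'   variable data.frame stage/points), `horizon_table` (total points ->
#'   predicted BCCM per horizon), `reference` stages, and the affine map
#'   (`eta_min`, `scale`) from total points to the linear predictor.
#' @export
fit_dr_nomogram <- function(staged, horizons = c(3, 5, 10), grid_size = 21) {
  vars <- paste0(.dr_variables, "_dr")
  if (!all(vars %in% names(staged)))
    stop("staged cohort must carry the four DR-stage columns (run stage_cohort)")
  keep <- complete.cases(staged[, vars]) & !is.na(staged$followup_time) &
    !is.na(staged$event)
  dat <- as.data.frame(staged)[keep, , drop = FALSE]
  design <- dat[, vars]
  fit <- fit_fine_gray(design, dat$followup_time, dat$event)
  beta <- fit$coefficients[vars]
  if (any(beta < 0))
    warning("negative DR-stage coefficient(s): ",
            paste(vars[beta < 0], collapse = ", "),
            "; point scores for these variables decrease with stage")
  s_min <- vapply(design, min, 0)
  s_max <- vapply(design, max, 0)
  scale_m <- max(beta * (s_max - s_min))
  points <- lapply(seq_along(vars), function(k) {
    st <- seq(s_min[k], s_max[k])
    data.frame(stage = st,
               points = 100 * beta[k] * (st - s_min[k]) / scale_m)
  })
  names(points) <- vars
  eta_min <- sum(beta * s_min)
  max_total <- sum(vapply(points, function(p) max(p$points), 0))
  grid <- seq(0, max_total, length.out = grid_size)
  ht <- data.frame(total_points = grid)
  for (h in horizons) {
    eta <- eta_min + grid * scale_m / 100
    cif0 <- .cif_at(fit$baseline_cif, h)
    ht[[sprintf("bccm_%gy", h)]] <- 1 - (1 - cif0)^exp(eta)
  }
  structure(list(fit = fit, points = points, horizon_table = ht,
                 reference = s_min, eta_min = eta_min, scale = scale_m,
                 horizons = horizons, n_used = nrow(dat)),
            class = "dr_nomogram")
}

#' @export
print.dr_nomogram <- function(x, ...) {
  cat(sprintf("DR competing-risk nomogram (n = %d)\n", x$n_used))
  for (v in names(x$points)) {
    p <- x$points[[v]]
    cat(sprintf("  %-9s stages %s -> points %s\n", v,
                paste(p$stage, collapse = "/"),
                paste(sprintf("%.1f", p$points), collapse = "/")))
  }
  cat("total points -> BCCM lookup (head):\n")
  print(head(x$horizon_table, 4), row.names = FALSE)
  invisible(x)
}

#' Predict BCCM and total points for one staged patient
#'
#' @param model A `dr_nomogram`.
#' @param staged A `dr_stage_result` from [stage_patient()], or a named
#'   vector/list of stages (`t_dr`, `n_dr`, `grade_dr`, `er_dr`), or a
#'   one-row staged cohort slice.
#' @param horizon Horizon in years.
#' @return List with `total_points` and `probability` (predicted BCCM from
#'   the underlying fit; the horizon table is presentation only).
#' @export
predict_patient <- function(model, staged, horizon) {
  vars <- paste0(.dr_variables, "_dr")
  if (inherits(staged, "dr_stage_result")) {
    stages <- setNames(as.numeric(staged$dr_stage[.dr_variables]), vars)
  } else {
    st <- unlist(staged[intersect(names(staged), vars)])
    if (length(st) != 4 || anyNA(st))
      stop("unstaged input: need non-missing ", paste(vars, collapse = ", "))
    stages <- setNames(as.numeric(st[vars]), vars)
  }
  pts <- sum(vapply(vars, function(v) {
    p <- model$points[[v]]
    i <- match(stages[[v]], p$stage)
    if (is.na(i)) stop("stage ", stages[[v]], " outside the fitted range of ", v)
    p$points[i]
  }, 0))
  prob <- predict_cif(model$fit, as.data.frame(as.list(stages)), horizon)
  list(total_points = pts, probability = unname(prob))
}

#' Serialize a nomogram to JSON
#'
#' @param model A `dr_nomogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
nomogram_to_json <- function(model, path) {
  obj <- list(points = model$points, horizon_table = model$horizon_table,
              reference = as.list(model$reference),
              coefficients = as.list(model$fit$coefficients),
              eta_min = model$eta_min, scale = model$scale,
              baseline_cif = list(times = model$fit$baseline_cif$times,
                                  values = model$fit$baseline_cif$values),
              n_used = model$n_used)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
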