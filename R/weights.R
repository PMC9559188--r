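# Interval-time-dependent bilateral weights.
#
# For one clinical variable and one interval-time window, patients are
# cross-classified by (PBC level i, CBC level j).  Each cell gets the area
# S_ij under its cause-1 CIF on [0, R].  The across-row spread
#   D_p = sum_j max_{i1 != i2} |S_{i1 j} - S_{i2 j}|
# measures how much the PBC level moves prognosis at that interval; D_c is
# the symmetric column-wise construction for the CBC level.  The normalized
# PBC weight is w_p = D_p / (D_p + D_c), and an arctan curve
# w_p(t) = a * (pi/2 - atan(b t + c)) is fitted across interval bins.

#' CIF-area matrix of one bilateral variable in an interval-time window
#'
#' @param cohort A `dr_cohort`.
#' @param variable One of `"t"`, `"n"`, `"grade"`, `"er"`.
#' @param bin Interval-time window `c(lower, upper)`; patients with
#'   `lower <= interval_time < upper` enter.
#' @param upper_r Integration horizon `R` in years post-CBC (default 10).
#' @param min_subgroup Minimum patients per (i, j) cell; sparser cells are
#'   marked missing.
#' @return Matrix `S` with PBC levels as rows and CBC levels as columns;
#'   missing/sparse cells are `NA`.  Errors if every cell is missing.
#' @export
compute_area_matrix <- function(cohort, variable, bin, upper_r = 10,
                                min_subgroup = 20) {
  if (!variable %in% .dr_variables)
    stop("variable must be one of: ", paste(.dr_variables, collapse = ", "))
  lev <- .dr_levels[[variable]]
  pcol <- cohort[[.side_col(variable, "pbc")]]
  ccol <- cohort[[.side_col(variable, "cbc")]]
  sel <- !is.na(pcol) & !is.na(ccol) &
    cohort$interval_time >= bin[1] & cohort$interval_time < bin[2]
  if (!any(sel)) stop("bin unusable: no patients in window [",
                      bin[1], ", ", bin[2], ")")
  S <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  fu <- cohort$followup_time; ev <- cohort$event
  for (i in lev) for (j in lev) {
    cell <- sel & pcol == i & ccol == j
    if (sum(cell) >= min_subgroup) {
      cif <- estimate_cif(fu[cell], ev[cell], cause = 1L)
      S[i, j] <- cif_area(cif, upper_r)
    }
  }
  if (all(is.na(S))) stop("bin unusable: every (i, j) cell below min_subgroup")
  S
}

# shared worker: spread over `margin` (1 = across PBC rows -> D_p,
# 2 = across CBC columns -> D_c); missing cells skipped pairwise
.d_norm <- function(S, margin) {
  spread_one <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    max(v) - min(v)  # equals max over pairs of |S_i1 - S_i2|
  }
  spreads <- apply(S, 3 - margin, spread_one)
  if (all(is.na(spreads)))
    return(structure(0, degenerate = TRUE))
  structure(sum(spreads, na.rm = TRUE), degenerate = FALSE)
}

#' Across-PBC-level spread of CIF areas
#'
#' `D_p` sums, over each CBC column, the maximal absolute spread of `S_ij`
#' across PBC rows.  Fewer than 2 comparable levels everywhere yields 0 with
#' attribute `degenerate = TRUE`.
#'
#' @param S Area matrix from [compute_area_matrix()] (rows = PBC levels).
#' @return Numeric `D_p` with attribute `degenerate`.
#' @export
#' @examples
#' dp_from_areas(matrix(c(1, 3, 2, 5), 2))  # 5
dp_from_areas <- function(S) .d_norm(S, margin = 1)

#' Across-CBC-level spread of CIF areas
#'
#' Symmetric construction to [dp_from_areas()] over CBC columns.
#'
#' @inheritParams dp_from_areas
#' @return Numeric `D_c` with attribute `degenerate`.
#' @export
dc_from_areas <- function(S) .d_norm(S, margin = 2)

#' Normalized raw PBC weight
#'
#' @param d_p,d_c Non-negative spreads from [dp_from_areas()] /
#'   [dc_from_areas()].
#' @return `d_p / (d_p + d_c)`; 0.5 when both are zero.
#' @export
raw_weight <- function(d_p, d_c) {
  stopifnot(d_p >= 0, d_c >= 0)
  if (d_p + d_c == 0) return(0.5)
  as.numeric(d_p) / (as.numeric(d_p) + as.numeric(d_c))
}

#' Per-bin raw weight series of one variable
#'
#' Slides overlapping interval-time windows across the cohort and computes
#' the normalized PBC weight in each.  Bins with fewer than `min_bin`
#' patients, an unusable area matrix, or degenerate spreads in both
#' directions are flagged sparse and skipped by the curve fit.
#'
#' @inheritParams compute_area_matrix
#' @param centers Window centers in years (default 1..15).
#' @param half_width Window half-width; each bin is
#'   `[center - half_width, center + half_width)`.
#' @param min_bin Minimum patients per usable bin.
#' @return `dr_weight_series`: data.frame with `center`, `count`, `raw_wp`,
#'   `sparse`, plus attributes `variable` and `area_matrices`.
#' @export
compute_weight_series <- function(cohort, variable, centers = 1:15,
                                  half_width = 1, upper_r = 10,
                                  min_subgroup = 20, min_bin = 100) {
  pcol <- cohort[[.side_col(variable, "pbc")]]
  ccol <- cohort[[.side_col(variable, "cbc")]]
  ok <- !is.na(pcol) & !is.na(ccol)
  mats <- vector("list", length(centers))
  names(mats) <- as.character(centers)
  out <- data.frame(center = centers, count = NA_integer_,
                    raw_wp = NA_real_, sparse = TRUE)
  for (k in seq_along(centers)) {
    bin <- c(centers[k] - half_width, centers[k] + half_width)
    out$count[k] <- sum(ok & cohort$interval_time >= bin[1] &
                          cohort$interval_time < bin[2])
    S <- tryCatch(compute_area_matrix(cohort, variable, bin, upper_r,
                                      min_subgroup),
                  error = function(e) NULL)
    if (is.null(S)) next
    mats[[k]] <- S
    dp <- dp_from_areas(S); dc <- dc_from_areas(S)
    out$raw_wp[k] <- raw_weight(dp, dc)
    degen <- attr(dp, "degenerate") && attr(dc, "degenerate")
    out$sparse[k] <- out$count[k] < min_bin || degen
  }
  structure(out, class = c("dr_weight_series", "data.frame"),
            variable = variable, area_matrices = mats, upper_r = upper_r)
}

#' Fit the arctan interval-weight function
#'
#' Weighted nonlinear least squares of the raw per-bin PBC weights on the
#' bin centers, model `w_p(t) = a * (pi/2 - atan(b t + c))`, weights equal
#' to bin patient counts.  Fitting is tried from a grid of starting values
#' (port algorithm, bounds `0 < a <= 3/pi`, `b >= 0`); a flat series or a
#' complete fitting failure falls back to the constant fit
#' `w_p == mean(raw_wp)` encoded as `a = mean/(pi/2), b = 0, c = 0`.
#'
#' @param series A `dr_weight_series` (needs >= 3 usable bins).
#' @return `dr_weight_fit`: list with `variable`, `a`, `b`, `c`,
#'   `residual_rms`, `fallback` flag and the fitted `series`.
#' @export
fit_weight_function <- function(series) {
  use <- !series$sparse & !is.na(series$raw_wp)
  if (sum(use) < 3) stop("fewer than 3 usable bins for variable ",
                         attr(series, "variable"))
  t <- series$center[use]
  y <- series$raw_wp[use]
  w <- series$count[use]

  const_fit <- function() {
    m <- sum(w * y) / sum(w)
    list(a = m / (pi / 2), b = 0, c = 0,
         rms = sqrt(sum(w * (y - m)^2) / sum(w)), fallback = TRUE)
  }
  if (max(y) - min(y) < 1e-9) {
    best <- const_fit()
  } else {
    dat <- data.frame(t = t, y = y)
    starts <- expand.grid(a = c(0.2, 0.4, 0.6, 2 / pi),
                          b = c(0.05, 0.2, 0.5, 1.5),
                          c = c(-2, -1, 0, 1))
    best <- NULL
    for (r in seq_len(nrow(starts))) {
      fit <- tryCatch(
        nls(y ~ a * (pi / 2 - atan(b * t + c)), data = dat,
            weights = w, start = as.list(starts[r, ]),
            algorithm = "port",
            lower = c(a = 1e-6, b = 0, c = -50),
            upper = c(a = 3 / pi, b = 50, c = 50),
            control = list(maxiter = 200, warnOnly = FALSE)),
        error = function(e) NULL)
      if (is.null(fit)) next
      co <- coef(fit)
      rms <- sqrt(sum(w * resid(fit)^2) / sum(w))
      if (is.null(best) || rms < best$rms)
        best <- list(a = co[["a"]], b = co[["b"]], c = co[["c"]],
                     rms = rms, fallback = FALSE)
    }
    if (is.null(best)) best <- const_fit()
  }
  structure(list(variable = attr(series, "variable"),
                 a = best$a, b = best$b, c = best$c,
                 residual_rms = best$rms, fallback = best$fallback,
                 series = series),
            class = "dr_weight_fit")
}

#' @export
print.dr_weight_fit <- function(x, ...) {
  cat(sprintf("Interval weight fit [%s]: w_p(t) = %.4f*(pi/2 - atan(%.4f*t + %.4f)); RMS %.4f%s\n",
              x$variable, x$a, x$b, x$c, x$residual_rms,
              if (x$fallback) " (constant fallback)" else ""))
  invisible(x)
}

#' Evaluate the fitted bilateral weights at an interval time
#'
#' The fitted curve is clipped to `[0.01, 0.99]` before use so neither
#' side's feature is ever fully discarded; `w_c = 1 - w_p` exactly.
#'
#' @param fit A `dr_weight_fit`, or a plain list with `a`, `b`, `c`.
#' @param t Interval time(s) in years, >= 0.
#' @return List with numeric vectors `w_p` and `w_c`.
#' @export
evaluate_weights <- function(fit, t) {
  stopifnot(all(t >= 0))
  wp <- .arctan_wp(t, fit$a, fit$b, fit$c)
  wp <- pmin(pmax(wp, 0.01), 0.99)
  list(w_p = wp, w_c = 1 - wp)
}

#' Fit interval-weight curves for all DR variables
#'
#' Convenience wrapper running [compute_weight_series()] and
#' [fit_weight_function()] for T, N, grade and ER.
#'
#' @inheritParams compute_weight_series
#' @param variables Variables to fit (default all four DR variables).
#' @return Named list of `dr_weight_fit` objects.
#' @export
fit_all_weights <- function(cohort, variables = .dr_variables, centers = 1:15,
                            half_width = 1, upper_r = 10, min_subgroup = 20,
                            min_bin = 100) {
  fits <- lapply(variables, function(v) {
    s <- compute_weight_series(cohort, v, centers, half_width, upper_r,
                               min_subgroup, min_bin)
    fit_weight_function(s)
  })
  setNames(fits, variables)
}

#' Serialize weight fits to JSON
#'
#' @param fits Named list of `dr_weight_fit` (or a single fit).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
weights_to_json <- function(fits, path) {
  if (inherits(fits, "dr_weight_fit")) fits <- setNames(list(fits), fits$variable)
  obj <- lapply(fits, function(f) {
    list(variable = f$variable, a = f$a, b = f$b, c = f$c,
         residual_rms = f$residual_rms, fallback = f$fallback,
         series = as.data.frame(f$series[, c("center", "count", "raw_wp",
                                             "sparse")]))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read weight fits back from JSON
#'
#' @param path JSON file written by [weights_to_json()].
#' @return Named list of `dr_weight_fit` objects (series retained as data).
#' @export
weights_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fits <- lapply(obj, function(f) {
    structure(list(variable = f$variable, a = f$a, b = f$b, c = f$c,
                   residual_rms = f$residual_rms, fallback = f$fallback,
                   series = f$series),
              class = "dr_weight_fit")
  })
  setNames(fits, vapply(fits, function(f) f$variable, ""))
}
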