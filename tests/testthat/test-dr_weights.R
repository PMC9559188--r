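# CIF-area contrasts, D_p/D_c spreads, raw weights and arctan curve fitting

test_that("dp/dc evaluate the spread formula on hand examples", {
  S1 <- matrix(c(1, 1, 2, 2), 2)            # rows PBC: [[1,2],[1,2]]
  expect_equal(as.numeric(dp_from_areas(S1)), 0)
  expect_equal(as.numeric(dc_from_areas(S1)), 2)

  S2 <- matrix(c(1, 2, 1, 2), 2)            # [[1,1],[2,2]]
  expect_equal(as.numeric(dp_from_areas(S2)), 2)
  expect_equal(as.numeric(dc_from_areas(S2)), 0)

  S3 <- matrix(c(1, 3, 2, 5), 2)            # [[1,2],[3,5]]
  expect_equal(as.numeric(dp_from_areas(S3)), 5)
  expect_equal(as.numeric(dc_from_areas(S3)), 3)
  expect_equal(raw_weight(dp_from_areas(S3), dc_from_areas(S3)), 0.625)
})

test_that("spreads skip missing cells pairwise and flag degeneracy", {
  S <- matrix(c(1, NA, 2, NA), 2)           # one usable row
  dp <- dp_from_areas(S)
  expect_equal(as.numeric(dp), 0)
  expect_true(attr(dp, "degenerate"))
  dc <- dc_from_areas(S)                     # row 1 has both columns
  expect_equal(as.numeric(dc), 1)
  expect_false(attr(dc, "degenerate"))
  # invariance to adding a constant to every entry
  S3 <- matrix(c(1, 3, 2, 5), 2)
  expect_equal(as.numeric(dp_from_areas(S3 + 7)),
               as.numeric(dp_from_areas(S3)))
  expect_equal(as.numeric(dc_from_areas(S3 + 7)),
               as.numeric(dc_from_areas(S3)))
})

test_that("raw_weight normalizes pairwise with a symmetric fallback", {
  expect_equal(raw_weight(5, 3), 0.625)
  expect_equal(raw_weight(0, 2), 0)
  expect_equal(raw_weight(0, 0), 0.5)
  expect_error(raw_weight(-1, 2))
})

test_that("compute_area_matrix matches hand-computed step integrals", {
  # construct a bin whose subgroups have closed-form CIFs:
  # (T1,T1): events at t=1 of 4 -> CIF 1/4 from 1 on; area on [0,10] = 9/4
  # (T2,T1): events at t=2, 2 of 4 -> CIF 1/2 from 2 on; area = 4
  mk <- function(id0, tp, tc, fu, ev) {
    df <- tiny_cohort_df()[rep(1, length(fu)), ]
    df$patient_id <- paste0(id0, seq_along(fu))
    df$t_pbc <- tp; df$t_cbc <- tc
    df$interval_time <- 5
    df$followup_time <- fu; df$event <- ev
    df
  }
  g1 <- mk("a", "T1", "T1", c(1, 3, 6, 9), c(1L, 0L, 0L, 0L))
  g2 <- mk("b", "T2", "T1", c(2, 2, 7, 8), c(1L, 1L, 0L, 0L))
  co <- drbilat:::.new_cohort(rbind(g1, g2))
  S <- compute_area_matrix(co, "t", bin = c(4, 6), upper_r = 10,
                           min_subgroup = 4)
  expect_equal(S["T1", "T1"], (10 - 1) * 1/4)
  expect_equal(S["T2", "T1"], (10 - 2) * 1/2)
  expect_true(is.na(S["T3-4", "T1"]))

  # identical event patterns give equal entries
  g3 <- mk("c", "T1", "T2", c(1, 3, 6, 9), c(1L, 0L, 0L, 0L))
  co2 <- drbilat:::.new_cohort(rbind(g1, g3))
  S2 <- compute_area_matrix(co2, "t", c(4, 6), 10, min_subgroup = 4)
  expect_equal(S2["T1", "T1"], S2["T1", "T2"])

  expect_error(compute_area_matrix(co, "t", bin = c(20, 22)), "bin unusable")
  expect_error(compute_area_matrix(co, "age", c(4, 6)), "variable must be")
})

test_that("fit_weight_function recovers a noiseless generator exactly", {
  a <- 0.4; b <- 0.5; cc <- -2
  t <- 1:10
  s <- make_series(t, a * (pi / 2 - atan(b * t + cc)))
  fit <- fit_weight_function(s)
  expect_lt(abs(fit$a - a), 1e-6)
  expect_lt(abs(fit$b - b), 1e-6)
  expect_lt(abs(fit$c - cc), 1e-6)
  expect_false(fit$fallback)
})

test_that("flat series fall back to the constant fit", {
  s <- make_series(1:8, rep(0.5, 8))
  fit <- fit_weight_function(s)
  expect_true(fit$fallback)
  w <- evaluate_weights(fit, c(0.5, 3, 17))
  expect_equal(w$w_p, rep(0.5, 3))
  expect_error(fit_weight_function(make_series(1:2, c(.4, .5))), "3 usable")
})

test_that("noisy series recover the truth within RMS 0.05", {
  set.seed(77)
  a <- 0.4; b <- 0.5; cc <- -2
  t <- 1:15
  truth <- a * (pi / 2 - atan(b * t + cc))
  s <- make_series(t, truth + rnorm(15, 0, 0.03))
  fit <- fit_weight_function(s)
  fitted <- evaluate_weights(fit, t)$w_p
  expect_lt(sqrt(mean((fitted - truth)^2)), 0.05)
})

test_that("evaluate_weights is complementary, clipped and monotone", {
  fit <- make_weight_fit(0.4, 0.5, -2)
  t <- seq(0, 20, by = 0.5)
  w <- evaluate_weights(fit, t)
  expect_equal(w$w_p + w$w_c, rep(1, length(t)))
  expect_true(all(diff(w$w_p) <= 0))          # b > 0 -> non-increasing
  big <- evaluate_weights(make_weight_fit(2 / pi, 5, -100), c(0, 1))
  expect_true(all(big$w_p <= 0.99))
  expect_error(evaluate_weights(fit, -1))
})

test_that("swapping PBC and CBC columns maps w_p to 1 - w_p", {
  co <- simulate_cohort(simulation_config(n = 8000, seed = 19))
  sw <- co
  for (v in c("t", "n", "grade", "er")) {
    p <- paste0(v, "_pbc"); c <- paste0(v, "_cbc")
    sw[[p]] <- co[[c]]; sw[[c]] <- co[[p]]
  }
  s1 <- compute_weight_series(co, "t", centers = 3:6)
  s2 <- compute_weight_series(sw, "t", centers = 3:6)
  ok <- !is.na(s1$raw_wp) & !is.na(s2$raw_wp)
  expect_true(any(ok))
  expect_equal(s2$raw_wp[ok], 1 - s1$raw_wp[ok], tolerance = 1e-12)
})

test_that("weight fits round-trip through JSON", {
  fits <- flat_weight_fits(0.4)
  fits$t$series <- make_series(1:5, rep(0.4, 5))
  path <- tempfile(fileext = ".json")
  weights_to_json(fits, path)
  back <- weights_from_json(path)
  expect_equal(back$t$a, fits$t$a)
  expect_equal(evaluate_weights(back$grade, 4), evaluate_weights(fits$grade, 4))
})
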