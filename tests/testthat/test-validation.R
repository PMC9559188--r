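# splitting, concordance, calibration

test_that("split_cohort reproduces the 2:1 arithmetic and is seeded", {
  co <- simulate_cohort(simulation_config(n = 999, seed = 1))
  sp <- split_cohort(co, seed = 4)
  expect_equal(nrow(sp$training), 666)
  expect_equal(nrow(sp$validation), 333)
  expect_length(intersect(sp$training$patient_id, sp$validation$patient_id), 0)
  expect_setequal(c(sp$training$patient_id, sp$validation$patient_id),
                  co$patient_id)
  sp2 <- split_cohort(co, seed = 4)
  expect_identical(sp$training$patient_id, sp2$training$patient_id)
  co3 <- simulate_cohort(simulation_config(n = 3, seed = 2))
  sp3 <- split_cohort(co3, seed = 1)
  expect_equal(c(nrow(sp3$training), nrow(sp3$validation)), c(2, 1))
  expect_error(split_cohort(co3[1:2, ], seed = 1), "at least 3")
})

test_that("concordance is 1 for a perfect predictor and 0 for its flip", {
  set.seed(71)
  t <- rexp(300); e <- rep(1L, 300)
  expect_equal(concordance_index(-t, t, e, horizon = 10, n_boot = 0)$c_index, 1)
  expect_equal(concordance_index(t, t, e, horizon = 10, n_boot = 0)$c_index, 0)
  expect_error(concordance_index(-t, t, rep(0L, 300), 10, n_boot = 0),
               "no comparable pairs")
  expect_error(concordance_index(-t, t, e, horizon = -1), "horizon")
})

test_that("concordance is invariant to strictly increasing transforms", {
  set.seed(72); n <- 600
  x <- rnorm(n)
  d <- simulate_finegray(0.8 * x, p = 0.3, lambda = 0.2, other_rate = 0.05,
                         censor_rate = 0.04)
  a <- concordance_index(x, d$time, d$event, 10, n_boot = 0)$c_index
  b <- concordance_index(exp(3 * x) + 5, d$time, d$event, 10,
                         n_boot = 0)$c_index
  expect_equal(a, b)
  # harrell variant is exposed and differs in its comparable set
  h <- concordance_index(x, d$time, d$event, 10, variant = "harrell",
                         n_boot = 0)$c_index
  expect_true(is.finite(h))
})

test_that("bootstrap CI brackets the point estimate", {
  set.seed(73); n <- 400
  x <- rnorm(n)
  d <- simulate_finegray(0.8 * x, p = 0.3, lambda = 0.2, other_rate = 0.05)
  ci <- concordance_index(x, d$time, d$event, 10, n_boot = 60, seed = 1)
  expect_true(ci$ci_low <= ci$c_index && ci$c_index <= ci$ci_upp)
})

test_that("calibration groups recover a constructed miscalibration", {
  set.seed(74); n <- 20000
  eta <- rnorm(n, 0, 0.8)
  p <- 0.3; lam <- 0.15; h <- 10
  d <- simulate_finegray(eta, p, lam, other_rate = 0.04)
  truth <- 1 - (1 - p * (1 - exp(-lam * h)))^exp(eta)
  shifted <- pmin(truth + 0.1, 1)
  ct <- calibration_table(shifted, d$time, d$event, h, groups = 3, n_boot = 0)
  expect_lt(max(abs((ct$mean_predicted - ct$observed) - 0.1)), 0.02)
})

test_that("pooled group observations equal the whole-cohort CIF (no censoring)", {
  set.seed(75); n <- 5000
  eta <- rnorm(n, 0, 0.5)
  d <- simulate_finegray(eta, 0.3, 0.15, other_rate = 0.04)  # no censoring
  preds <- runif(n)
  h <- 8
  ct <- calibration_table(preds, d$time, d$event, h, groups = 4, n_boot = 0)
  pooled <- sum(ct$n * ct$observed) / sum(ct$n)
  overall <- drbilat:::.cif_at(estimate_cif(d$time, d$event, 1), h)
  expect_equal(pooled, overall, tolerance = 1e-3)
})

test_that("constant predictions collapse to a single flagged group", {
  set.seed(76)
  d <- simulate_finegray(rep(0, 200), 0.3, 0.2, other_rate = 0.05)
  ct <- calibration_table(rep(0.25, 200), d$time, d$event, 5, groups = 3,
                          n_boot = 0)
  expect_equal(nrow(ct), 1)
  expect_true(all(ct$collapsed))
})

test_that("event-free groups carry a sparse flag", {
  times <- c(rexp(50) + 20, rexp(50))       # low-risk group has no early events
  events <- c(rep(0L, 50), rep(1L, 50))
  preds <- c(runif(50, 0, 0.1), runif(50, 0.5, 1))
  ct <- calibration_table(preds, times, events, horizon = 5, groups = 2,
                          n_boot = 0)
  expect_true(ct$sparse[1])
  expect_equal(ct$observed[1], 0)
  expect_false(ct$sparse[2])
})

test_that("validate_nomogram assembles a coherent report", {
  co <- simulate_cohort(simulation_config(n = 3000, seed = 77))
  st <- stage_cohort(co, flat_weight_fits(0.5))
  model <- fit_dr_nomogram(st)
  val <- validate_nomogram(model, st, n_boot_c = 30, n_boot_cal = 30, seed = 2)
  expect_true(val$c_index$c_index > 0.5 && val$c_index$c_index < 1)
  expect_named(val$calibration, c("3y", "5y", "10y"))
  expect_equal(sum(val$calibration$`10y`$n), sum(complete.cases(
    st[, c("t_dr", "n_dr", "grade_dr", "er_dr")])))
})
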