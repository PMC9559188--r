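# Aalen-Johansen estimation, CIF areas, Fine-Gray regression

test_that("estimate_cif reproduces the hand-computed 3-record example", {
  cif <- estimate_cif(c(1, 2, 3), c(1, 2, 0), cause = 1)
  expect_equal(drbilat:::.cif_at(cif, c(0.5, 1, 2.5, 10)), c(0, 1/3, 1/3, 1/3))
  expect_equal(cif_area(cif, 3), 2/3)
})

test_that("estimate_cif handles degenerate inputs", {
  cif0 <- estimate_cif(c(1, 2), c(0, 0), cause = 1)   # all censored
  expect_length(cif0$times, 0)
  expect_equal(drbilat:::.cif_at(cif0, 5), 0)
  cifn <- estimate_cif(c(1, 2, 3), c(2, 2, 0), cause = 1)  # no cause-1 events
  expect_true(all(cifn$values == 0))
  expect_error(estimate_cif(c(-1, 2), c(1, 0)), "negative")
  expect_error(estimate_cif(numeric(), integer()), "at least one")
  expect_error(estimate_cif(c(1, 2), c(1, 0, 0)), "lengths differ")
})

test_that("with a single event type the CIF equals 1 - Kaplan-Meier", {
  set.seed(21)
  t <- rexp(400); e <- rbinom(400, 1, 0.6)
  cif <- estimate_cif(t, e, 1)
  km <- survival::survfit(survival::Surv(t, e) ~ 1)
  expect_lt(max(abs(cif$values - (1 - km$surv[km$n.event > 0]))), 1e-12)
})

test_that("cause-specific CIFs and event-free survival sum to one", {
  set.seed(22)
  t <- round(rexp(500), 2)  # force ties
  e <- sample(0:2, 500, TRUE, prob = c(0.3, 0.4, 0.3))
  c1 <- estimate_cif(t, e, 1); c2 <- estimate_cif(t, e, 2)
  km <- survival::survfit(survival::Surv(t, e != 0) ~ 1)
  s <- km$surv[km$n.event > 0]
  expect_equal(c1$times, c2$times)
  expect_lt(max(abs(c1$values + c2$values + s - 1)), 1e-10)
})

test_that("cif_area integrates step functions exactly and is linear/monotone", {
  cif0 <- estimate_cif(c(1, 2), c(0, 0), 1)
  expect_equal(cif_area(cif0, 5), 0)

  step <- structure(list(times = 2, values = 0.5, cause = 1L, at_risk = 1L),
                    class = "dr_cif")
  expect_equal(cif_area(step, 4), 1.0)
  expect_error(cif_area(step, 0), "must be > 0")

  set.seed(23)
  t <- rexp(100); e <- sample(0:2, 100, TRUE)
  cif <- estimate_cif(t, e, 1)
  # monotone in R
  areas <- vapply(c(1, 2, 5, 10), function(r) cif_area(cif, r), 0)
  expect_true(all(diff(areas) >= 0))
  # linear in the curve: scaling values scales the area
  half <- cif; half$values <- cif$values / 2
  expect_equal(cif_area(half, 8), cif_area(cif, 8) / 2)
})

test_that("fit_fine_gray matches the survival::finegray + coxph oracle", {
  set.seed(11); n <- 400
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  d <- simulate_finegray(0.5 * x1 - 0.3 * x2, p = 0.35, lambda = 0.2,
                         other_rate = 0.08, censor_rate = 0.06,
                         admin_horizon = 18)
  fit <- fit_fine_gray(data.frame(x1 = x1, x2 = x2), d$time, d$event)
  dd <- data.frame(.ftime = d$time,
                   .fstatus = factor(d$event, 0:2, c("cens", "c1", "c2")),
                   .id = seq_len(n), x1 = x1, x2 = x2)
  fg <- survival::finegray(survival::Surv(.ftime, .fstatus) ~ . - .id,
                           data = dd, etype = "c1", id = .id)
  cph <- survival::coxph(
    survival::Surv(fgstart, fgstop, fgstatus) ~ x1 + x2, data = fg,
    weights = fg$fgwt, ties = "breslow", cluster = fg$.id)
  expect_equal(unname(fit$coefficients), unname(coef(cph)), tolerance = 1e-9)
  expect_equal(unname(sqrt(diag(fit$covariance))),
               unname(sqrt(diag(vcov(cph)))), tolerance = 1e-7)
  bh <- survival::basehaz(cph, centered = FALSE)
  theirs <- 1 - exp(-bh$hazard[match(fit$baseline_cif$times, bh$time)])
  expect_equal(fit$baseline_cif$values, theirs, tolerance = 1e-10)
})

test_that("without competing events or censoring, Fine-Gray equals Cox", {
  set.seed(3); n <- 300
  x <- rnorm(n); t <- rexp(n, exp(0.5 * x)); e <- rep(1L, n)
  fg <- fit_fine_gray(data.frame(x = x), t, e)
  cx <- survival::coxph(survival::Surv(t, e) ~ x, ties = "breslow")
  expect_lt(abs(unname(fg$coefficients) - unname(coef(cx))), 1e-6)
})

test_that("fit is invariant to record order and equivariant to affine recoding", {
  set.seed(12); n <- 250
  x <- rnorm(n)
  d <- simulate_finegray(0.6 * x, p = 0.3, lambda = 0.2, other_rate = 0.06,
                         censor_rate = 0.04)
  f1 <- fit_fine_gray(data.frame(x = x), d$time, d$event)
  perm <- sample(n)
  f2 <- fit_fine_gray(data.frame(x = x[perm]), d$time[perm], d$event[perm])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  # affine recoding x -> (x - 3) / 2 rescales beta by 2 exactly
  f3 <- fit_fine_gray(data.frame(x = (x - 3) / 2), d$time, d$event)
  expect_equal(unname(f3$coefficients), 2 * unname(f1$coefficients),
               tolerance = 1e-8)
})

test_that("fit_fine_gray guards degenerate inputs and separation", {
  expect_error(fit_fine_gray(data.frame(x = c(1, 2)), c(1, 2), c(0, 0)),
               "no cause-1 events")
  expect_error(fit_fine_gray(data.frame(x = c(1, 1)), c(1, 2), c(1, 1)),
               "distinct covariate patterns")
  # perfectly separating covariate: only x = 1 patients ever die of cause 1
  set.seed(13); n <- 80
  x <- rep(0:1, each = n / 2)
  t <- rexp(n)
  e <- ifelse(x == 1, 1L, 0L)
  expect_error(fit_fine_gray(data.frame(x = x), t, e),
               "separation|converge")
})

test_that("Wald interval covers a null coefficient at about the nominal rate", {
  set.seed(14)
  reps <- 60
  cover <- logical(reps)
  for (r in seq_len(reps)) {
    n <- 800
    x <- rnorm(n)
    d <- simulate_finegray(rep(0, n), p = 0.3, lambda = 0.2,
                           other_rate = 0.06, censor_rate = 0.04)
    f <- fit_fine_gray(data.frame(x = x), d$time, d$event)
    se <- sqrt(diag(f$covariance))
    cover[r] <- abs(f$coefficients / se) < qnorm(0.975)
  }
  expect_gt(mean(cover), 0.85)   # 3 SE below 0.95 at 60 replicates
})

test_that("predict_cif is baseline at the reference and monotone in horizon", {
  set.seed(15); n <- 300
  x <- rbinom(n, 1, 0.5)
  d <- simulate_finegray(0.5 * x, p = 0.3, lambda = 0.2, other_rate = 0.05)
  fit <- fit_fine_gray(data.frame(x = x), d$time, d$event)
  expect_equal(predict_cif(fit, data.frame(x = 0), 5),
               drbilat:::.cif_at(fit$baseline_cif, 5))
  ps <- vapply(c(2, 5, 10, 15), function(h)
    predict_cif(fit, data.frame(x = 1), h), 0)
  expect_true(all(diff(ps) >= 0))
  # eta -> -Inf limit gives 0
  fit2 <- fit
  fit2$coefficients[] <- -50
  expect_equal(predict_cif(fit2, data.frame(x = 1), 10), 0, tolerance = 1e-12)
  expect_error(predict_cif(fit, data.frame(z = 1), 5), "unknown covariate")
})

test_that("Fine-Gray fits serialize to JSON", {
  set.seed(16)
  x <- rnorm(200)
  d <- simulate_finegray(0.4 * x, p = 0.3, lambda = 0.2, other_rate = 0.05)
  fit <- fit_fine_gray(data.frame(x = x), d$time, d$event)
  path <- tempfile(fileext = ".json")
  finegray_to_json(fit, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$coefficients$x, unname(fit$coefficients["x"]))
  expect_equal(got$baseline_cif$values, fit$baseline_cif$values)
})
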