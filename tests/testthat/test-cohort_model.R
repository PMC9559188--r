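# cohort ingestion, eligibility filtering, summaries

test_that("read_cohort ingests a well-formed table and enforces invariants", {
  path <- write_tiny_cohort()
  co <- read_cohort(path)
  rep <- attr(co, "ingest_report")
  expect_s3_class(co, "dr_cohort")
  expect_equal(nrow(co), 3)
  expect_equal(rep$n_rejected, 0)

  # bad event code -> that row rejected with a reason
  df <- tiny_cohort_df()
  df$event[2] <- 7L
  co2 <- read_cohort(write_tiny_cohort(df))
  rep2 <- attr(co2, "ingest_report")
  expect_equal(nrow(co2), 2)
  expect_equal(rep2$n_rejected, 1)
  expect_match(rep2$rejects$reason, "event code")

  # unmapped category level -> per-row rejection
  df <- tiny_cohort_df()
  df$t_pbc[1] <- "T9"
  co3 <- read_cohort(write_tiny_cohort(df))
  expect_equal(nrow(co3), 2)
  expect_match(attr(co3, "ingest_report")$rejects$reason, "unmapped level in t_pbc")

  # header-only file -> empty cohort
  df0 <- tiny_cohort_df()[0, ]
  co4 <- read_cohort(write_tiny_cohort(df0))
  expect_equal(nrow(co4), 0)

  # duplicate ids and invariant violations rejected
  df <- tiny_cohort_df()
  df$patient_id[2] <- "P1"
  df$age_cbc[3] <- 30
  co5 <- read_cohort(write_tiny_cohort(df))
  expect_equal(nrow(co5), 1)
})

test_that("read_cohort errors on a missing mandatory column, naming it", {
  df <- tiny_cohort_df()
  df$followup_time <- NULL
  expect_error(read_cohort(write_tiny_cohort(df)), "followup_time")
  expect_error(read_cohort(tempfile()), "not found")
})

test_that("dialect maps source columns and codes; months convert to years", {
  df <- tiny_cohort_df()
  names(df)[names(df) == "event"] <- "COD_RECODE"
  df$COD_RECODE <- c("alive", "bc_death", "other_death")
  df$interval_time <- df$interval_time * 12
  df$followup_time <- df$followup_time * 12
  path <- write_tiny_cohort(df)
  dialect <- list(
    columns = list(event = "COD_RECODE"),
    codes = list(event = list(alive = "0", bc_death = "1", other_death = "2")),
    time_unit = "months")
  co <- read_cohort(path, dialect)
  expect_equal(co$event, c(0L, 1L, 2L))
  expect_equal(co$interval_time, c(5, 7, 2.5))
  expect_equal(co$followup_time, c(4, 2, 8))
})

test_that("write then read round-trips values", {
  co <- read_cohort(write_tiny_cohort())
  path2 <- tempfile(fileext = ".tsv")
  write_cohort(co, path2)
  co2 <- read_cohort(path2)
  expect_cohort_equal(co, co2)
})

test_that("eligibility filters apply the 6-month, 3-month, age and metastasis rules", {
  df <- tiny_cohort_df()
  extra <- df[c(1, 1, 1, 1), ]
  extra$patient_id <- c("X1", "X2", "X3", "X4")
  extra$interval_time[1] <- 0.3    # excluded: 6-month rule
  extra$followup_time[2] <- 0.1    # excluded: 3-month rule
  extra$age_pbc[3] <- 17           # excluded: age range
  extra$distant_met[4] <- "true"   # excluded: metastasis flag
  co <- read_cohort(write_tiny_cohort(rbind(df, extra)))
  out <- apply_eligibility_filters(co)
  rep <- attr(out, "exclusion_report")
  expect_equal(nrow(out), 3)       # the original three survive
  expect_equal(rep$interval_lt_6mo, 1)
  expect_equal(rep$followup_lt_3mo, 1)
  expect_equal(rep$age_out_of_range, 1)
  expect_equal(rep$distant_met, 1)
  expect_true(all(out$interval_time >= 0.5))

  # retained example: interval 5 y, follow-up 2 y, age 58
  df2 <- tiny_cohort_df()[1, ]
  df2$interval_time <- 5; df2$followup_time <- 2; df2$age_pbc <- 58
  df2$age_cbc <- 63
  co2 <- apply_eligibility_filters(read_cohort(write_tiny_cohort(df2)))
  expect_equal(nrow(co2), 1)

  # idempotence
  out2 <- apply_eligibility_filters(out)
  expect_cohort_equal(out, out2)
  expect_equal(attr(out2, "exclusion_report")$n_excluded, 0)
})

test_that("summarize_cohort computes per-variable percentages", {
  co <- simulate_cohort(simulation_config(n = 400, seed = 3))
  s <- summarize_cohort(co, "t_pbc")
  expect_equal(sum(s$count), 400)
  expect_equal(sum(s$percent), 100, tolerance = 1e-10)

  # numeric grouping partitions and percentages sum to 100 +- rounding slack
  s2 <- summarize_cohort(co, "interval_time",
                         grouping = list(breaks = c(0, 7, Inf),
                                         labels = c("<=7", ">7")))
  expect_equal(sum(round(s2$percent, 2)), 100, tolerance = 0.05)

  # single group -> 100.00
  s3 <- summarize_cohort(co, "interval_time",
                         grouping = list(breaks = c(0, Inf), labels = "all"))
  expect_equal(s3$percent, 100)

  # denominator excludes missing values (her2 has simulated missingness)
  s4 <- summarize_cohort(co, "her2_pbc")
  expect_equal(attr(s4, "denominator"), sum(!is.na(co$her2_pbc)))
  expect_equal(sum(s4$percent), 100, tolerance = 1e-10)

  expect_error(summarize_cohort(co, "not_a_column"), "unknown variable")
})
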