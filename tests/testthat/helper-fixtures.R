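# Shared fixtures: a tiny hand-written cohort and builders for synthetic
# objects used across test files.

# deterministic 3-patient cohort covering all mandatory fields
tiny_cohort_df <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P3"),
    age_pbc = c(50, 61, 44), age_cbc = c(55, 68, 46.5),
    interval_time = c(5, 7, 2.5),
    t_pbc = c("T1", "T2", "T3-4"), t_cbc = c("T1", "T1", "T2"),
    n_pbc = c("N0", "N1", "N2-3"), n_cbc = c("N0", "N0", "N1"),
    grade_pbc = c("I-II", "III-IV", "I-II"),
    grade_cbc = c("I-II", "I-II", "III-IV"),
    er_pbc = c("+", "-", "+"), er_cbc = c("+", "+", "-"),
    followup_time = c(4, 2, 8), event = c(0L, 1L, 2L),
    race = c("white", "black", "other"),
    marital_pair = c("NonP/NonP", "WithP/WithP", "WithP/NonP"),
    pathology_pbc = c("IDC", "ILC", "IDC"),
    pathology_cbc = c("IDC", "IDC", "other"),
    surgery_pbc = c("BCM", "SM", "RM"), surgery_cbc = c("BCM", "RM", "RM"),
    pr_pbc = c("+", "-", "+"), pr_cbc = c("+", "-", "-"),
    her2_pbc = c("-", NA, "+"), her2_cbc = c("-", NA, "-"),
    distant_met = c("false", "false", "false"),
    stringsAsFactors = FALSE)
}

write_tiny_cohort <- function(df = tiny_cohort_df(), path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  path
}

# synthetic weight series (for fitting tests that bypass cohort machinery)
make_series <- function(centers, raw_wp, counts = rep(1000, length(centers)),
                        variable = "t", sparse = rep(FALSE, length(centers))) {
  structure(data.frame(center = centers, count = counts, raw_wp = raw_wp,
                       sparse = sparse),
            class = c("dr_weight_series", "data.frame"),
            variable = variable, area_matrices = NULL, upper_r = 10)
}

# weight fit with exact coefficients (bypasses fitting)
make_weight_fit <- function(a, b, c, variable = "t") {
  structure(list(variable = variable, a = a, b = b, c = c,
                 residual_rms = 0, fallback = FALSE, series = NULL),
            class = "dr_weight_fit")
}

# weight fits whose w_p at a given interval equals a prescribed value
# (b = 0, c = 0 so the curve is flat: a = wp / (pi/2))
flat_weight_fits <- function(wp) {
  fits <- lapply(c("t", "n", "grade", "er"), function(v)
    make_weight_fit(wp / (pi / 2), 0, 0, variable = v))
  names(fits) <- c("t", "n", "grade", "er")
  fits
}

expect_cohort_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
}
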