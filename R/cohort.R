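# Cohort container, SEER-style table ingestion, eligibility filtering and
# descriptive summaries.

# Columns every cohort table must provide (before dialect renaming).
.mandatory_cols <- c(
  "patient_id", "age_pbc", "age_cbc", "interval_time",
  "t_pbc", "t_cbc", "n_pbc", "n_cbc", "grade_pbc", "grade_cbc",
  "er_pbc", "er_cbc", "followup_time", "event"
)

.optional_cols <- c(
  "race", "marital_pair", "pr_pbc", "pr_cbc", "her2_pbc", "her2_cbc",
  "pathology_pbc", "pathology_cbc", "surgery_pbc", "surgery_cbc",
  "distant_met"
)

.numeric_cols <- c("age_pbc", "age_cbc", "interval_time", "followup_time")

# level vocabulary for a patient-record column, or NULL if free/numeric
.col_levels <- function(col) {
  base <- sub("_(pbc|cbc)$", "", col)
  .dr_levels[[base]]
}

.new_cohort <- function(df, provenance = "unspecified") {
  rownames(df) <- NULL
  structure(df, class = c("dr_cohort", "data.frame"), provenance = provenance)
}

#' @export
print.dr_cohort <- function(x, ...) {
  cat(sprintf("MBBC cohort: %d patients (provenance: %s)\n",
              nrow(x), attr(x, "provenance")))
  ev <- table(factor(x$event, levels = 0:2))
  cat(sprintf("  events: %d censored, %d breast-cancer deaths, %d other-cause deaths\n",
              ev[["0"]], ev[["1"]], ev[["2"]]))
  invisible(x)
}

# Validate one ingested data.frame row-wise.  Returns list(keep, reasons):
# `reasons` is a character vector, NA for valid rows.
.validate_rows <- function(df) {
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  flag <- function(bad, msg) {
    bad <- bad & is.na(reason)
    reason[bad] <<- msg
  }
  flag(is.na(df$patient_id) | df$patient_id == "", "missing patient_id")
  for (col in intersect(.numeric_cols, names(df)))
    flag(is.na(df[[col]]), paste("non-numeric", col))
  flag(!(df$event %in% c(0L, 1L, 2L)) | is.na(df$event),
       "event code outside {0,1,2}")
  flag(df$followup_time <= 0, "followup_time <= 0")
  flag(df$interval_time < 0, "negative interval_time")
  flag(df$age_cbc < df$age_pbc, "age_cbc < age_pbc")
  for (col in names(df)) {
    lev <- .col_levels(col)
    if (!is.null(lev)) {
      val <- as.character(df[[col]])
      bad <- !is.na(val) & !(val %in% lev)
      flag(bad, paste("unmapped level in", col))
      if (col %in% .mandatory_cols) flag(is.na(val), paste("missing", col))
    }
  }
  dup <- duplicated(df$patient_id)
  flag(dup, "duplicate patient_id")
  list(keep = is.na(reason), reasons = reason)
}

#' Read a SEER-style MBBC case-listing table
#'
#' Reads a delimited text table (comma or tab, header required), applies an
#' optional dialect mapping from source column names and source codes to the
#' canonical patient-record fields and levels, coerces types, and drops rows
#' that violate the record invariants.  Dropped rows are counted, with
#' reasons, in the attached ingest report.
#'
#' @param path Path to a delimited text file.
#' @param dialect Optional column-mapping configuration: a list (or path to a
#'   JSON file) with elements `columns` (named list: canonical field ->
#'   source column name), `codes` (named list of named lists: canonical
#'   field -> source code -> canonical level) and `time_unit` (`"years"`,
#'   the default, or `"months"`; month-granular times are divided by 12).
#' @param provenance Free-text label stored on the cohort.
#' @return A `dr_cohort` (a data.frame of patient records) with attributes
#'   `provenance` and `ingest_report` (list: `n_read`, `n_kept`,
#'   `n_rejected`, `rejects` data.frame of row/reason).
#' @export
read_cohort <- function(path, dialect = NULL, provenance = basename(path)) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.character(dialect)) dialect <- jsonlite::read_json(dialect, simplifyVector = TRUE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  # rename source columns to canonical names
  if (!is.null(dialect$columns)) {
    for (canon in names(dialect$columns)) {
      src <- dialect$columns[[canon]]
      if (!src %in% names(raw))
        stop("mandatory column missing from input: ", src, " (mapped to ", canon, ")")
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(.mandatory_cols, names(raw))
  if (length(missing_cols) > 0)
    stop("mandatory column missing from input: ", paste(missing_cols, collapse = ", "))
  for (col in setdiff(.optional_cols, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[, c(.mandatory_cols, .optional_cols)]
  for (col in names(raw))  # blank cells are missing values
    if (is.character(raw[[col]])) raw[[col]][!is.na(raw[[col]]) &
                                               trimws(raw[[col]]) == ""] <- NA

  # translate source codes to canonical levels
  if (!is.null(dialect$codes)) {
    for (col in names(dialect$codes)) {
      map <- unlist(dialect$codes[[col]])
      val <- raw[[col]]
      hit <- val %in% names(map)
      raw[[col]][hit] <- unname(map[val[hit]])
    }
  }

  for (col in .numeric_cols) raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  raw$event <- suppressWarnings(as.integer(raw$event))
  if (identical(dialect$time_unit, "months")) {
    raw$interval_time <- raw$interval_time / 12
    raw$followup_time <- raw$followup_time / 12
  }
  raw$distant_met <- tolower(as.character(raw$distant_met)) %in%
    c("true", "t", "1", "yes", "y")

  chk <- .validate_rows(raw)
  kept <- raw[chk$keep, , drop = FALSE]
  rejects <- data.frame(row = which(!chk$keep),
                        reason = chk$reasons[!chk$keep],
                        stringsAsFactors = FALSE)
  out <- .new_cohort(kept, provenance)
  attr(out, "ingest_report") <- list(
    n_read = nrow(raw), n_kept = nrow(kept), n_rejected = nrow(rejects),
    rejects = rejects)
  out
}

#' Write a cohort back to delimited text
#'
#' @param cohort A `dr_cohort`.
#' @param path Output file path; tab-separated (`.csv` switches to commas).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as.data.frame(cohort)
  df$distant_met <- ifelse(is.na(df$distant_met), NA,
                           ifelse(df$distant_met, "true", "false"))
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Apply the MBBC eligibility filters
#'
#' Retains patients who survived at least 6 months between the two diagnoses
#' (interval_time >= 0.5 years), had at least 3 months of follow-up after
#' the contralateral diagnosis (followup_time >= 0.25 years), were aged
#' 18--97 at the primary diagnosis, and carried no distant-metastasis flag.
#' The operation is idempotent.
#'
#' @param cohort A `dr_cohort`.
#' @return The filtered `dr_cohort` with attribute `exclusion_report`, a list
#'   of per-criterion exclusion counts plus `n_before`, `n_after` and
#'   `n_excluded` (a record failing several criteria is counted under each).
#' @export
apply_eligibility_filters <- function(cohort) {
  crit <- list(
    interval_lt_6mo  = cohort$interval_time < 0.5,
    followup_lt_3mo  = cohort$followup_time < 0.25,
    age_out_of_range = cohort$age_pbc < 18 | cohort$age_pbc > 97,
    distant_met      = !is.na(cohort$distant_met) & cohort$distant_met
  )
  drop <- Reduce(`|`, crit)
  out <- .new_cohort(as.data.frame(cohort)[!drop, , drop = FALSE],
                     attr(cohort, "provenance"))
  attr(out, "exclusion_report") <- c(
    lapply(crit, sum),
    list(n_before = nrow(cohort), n_after = nrow(out), n_excluded = sum(drop)))
  out
}

#' Tabulate counts and percentages of a cohort variable
#'
#' Percentages use the count of records non-missing for the variable as the
#' denominator, mirroring per-variable denominators in descriptive cohort
#' tables.  Full precision is retained; the print method rounds to 2
#' decimals.
#'
#' @param cohort A `dr_cohort` (or plain data.frame with the column).
#' @param variable Column name to summarize.
#' @param grouping Optional level definition. For a categorical variable, a
#'   named list mapping group label -> character vector of levels; for a
#'   numeric variable, a list with `breaks` (cut points, intervals are
#'   `(lo, hi]`, the lowest closed) and optional `labels`. `NULL` uses each
#'   observed level as its own group.
#' @return A data.frame of class `dr_summary` with columns `group`, `count`,
#'   `percent` plus attributes `variable` and `denominator`.
#' @export
#' @examples
#' co <- simulate_cohort(simulation_config(n = 200, seed = 1))
#' summarize_cohort(co, "interval_time",
#'                  grouping = list(breaks = c(0, 7, Inf),
#'                                  labels = c("<=7", ">7")))
summarize_cohort <- function(cohort, variable, grouping = NULL) {
  if (!variable %in% names(cohort)) stop("unknown variable: ", variable)
  x <- cohort[[variable]]
  keep <- !is.na(x)
  x <- x[keep]
  if (is.numeric(x) && !is.null(grouping)) {
    labs <- grouping$labels
    g <- cut(x, breaks = grouping$breaks, labels = labs,
             include.lowest = TRUE, right = TRUE)
  } else if (!is.null(grouping) && is.null(grouping$breaks)) {
    g <- rep(NA_character_, length(x))
    for (lab in names(grouping)) g[x %in% grouping[[lab]]] <- lab
    if (anyNA(g)) stop("grouping does not partition the observed values of ",
                       variable)
    g <- factor(g, levels = names(grouping))
  } else {
    lev <- .col_levels(variable)
    g <- if (is.null(lev)) factor(x) else factor(x, levels = lev)
  }
  tab <- table(g)
  denom <- sum(tab)
  out <- data.frame(group = names(tab), count = as.integer(tab),
                    percent = 100 * as.integer(tab) / denom,
                    stringsAsFactors = FALSE)
  structure(out, class = c("dr_summary", "data.frame"),
            variable = variable, denominator = denom)
}

#' @export
print.dr_summary <- function(x, ...) {
  cat(sprintf("Variable: %s (n non-missing = %d)\n",
              attr(x, "variable"), attr(x, "denominator")))
  shown <- data.frame(group = x$group, count = x$count,
                      percent = sprintf("%.2f", x$percent))
  print(shown, row.names = FALSE)
  invisible(x)
}
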