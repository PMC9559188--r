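# Canonical level vocabularies and the prognostic score/cutoff tables.

# Ordered levels for every categorical field of a patient record.  Paired
# variables (one value per side) are stored as <name>_pbc / <name>_cbc.
.dr_levels <- list(
  t         = c("T1", "T2", "T3-4"),
  n         = c("N0", "N1", "N2-3"),
  grade     = c("I-II", "III-IV"),
  er        = c("+", "-"),
  pr        = c("+", "-"),
  her2      = c("+", "-"),
  race      = c("white", "black", "other"),
  pathology = c("IDC", "ILC", "other"),
  surgery   = c("BCM", "SM", "RM"),
  marital_pair = c("NonP/NonP", "NonP/WithP", "WithP/NonP", "WithP/WithP")
)

# Variables that receive DR treatment (bilateral score + interval weight).
.dr_variables <- c("t", "n", "grade", "er")

#' Prognostic score assignment and DR-stage cutoffs
#'
#' Returns the per-variable integer scores of each feature level and the
#' half-open total-score intervals that define the DR stages.  T and N are
#' scored 1--3 with stage cutoffs at 1.50/2.00/2.50 (four DR stages); grade
#' and ER are scored 1--2 with a single cutoff at 1.50 (two DR stages).
#' Totals are rounded to 2 decimals before binning, a total of exactly 1.00
#' maps to stage 1, and each interval is open on the left and closed on the
#' right, so 1.50 falls in stage 1 and 1.51 in stage 2.
#'
#' @return An object of class `dr_score_table`: a list with elements
#'   `scores` (named list: level -> integer score per variable) and
#'   `breaks` (named list: stage boundaries per variable).
#' @export
#' @examples
#' tab <- default_score_table()
#' tab$scores$t
default_score_table <- function() {
  structure(list(
    scores = list(
      t     = c("T1" = 1L, "T2" = 2L, "T3-4" = 3L),
      n     = c("N0" = 1L, "N1" = 2L, "N2-3" = 3L),
      grade = c("I-II" = 1L, "III-IV" = 2L),
      er    = c("+" = 1L, "-" = 2L)
    ),
    breaks = list(
      t     = c(1, 1.5, 2, 2.5, 3),
      n     = c(1, 1.5, 2, 2.5, 3),
      grade = c(1, 1.5, 2),
      er    = c(1, 1.5, 2)
    )
  ), class = "dr_score_table")
}

# internal: side-suffixed column name, e.g. .side_col("t", "pbc") -> "t_pbc"
.side_col <- function(variable, side) paste(variable, side, sep = "_")
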