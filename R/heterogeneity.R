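# Per-lesion tumor heterogeneity from variant-allele-fraction tables:
# MATH score, bilateral MATH ratio, trunk/branch fractions, and the
# MATH-ratio-vs-interval regression.

#' Read a per-lesion variant table
#'
#' Accepts either a minimal table with columns `variant_id` and `vaf`
#' (optionally `lesion_id`), or MAF-like columns from which the VAF is
#' derived as `t_alt_count / t_depth` and the variant identifier as
#' `gene:chrom:pos:ref:alt`.
#'
#' @param path Delimited text file (tab or comma).
#' @return data.frame with `variant_id` and `vaf` (plus `lesion_id` when
#'   present).
#' @export
read_variant_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (all(c("variant_id", "vaf") %in% names(df))) {
    out <- df
  } else if (all(c("gene", "chrom", "pos", "ref", "alt",
                   "t_alt_count", "t_depth") %in% names(df))) {
    out <- data.frame(
      variant_id = paste(df$gene, df$chrom, df$pos, df$ref, df$alt, sep = ":"),
      vaf = df$t_alt_count / df$t_depth, stringsAsFactors = FALSE)
    if ("lesion_id" %in% names(df)) out$lesion_id <- df$lesion_id
  } else {
    stop("variant table needs (variant_id, vaf) or MAF-like columns")
  }
  if (any(out$vaf < 0 | out$vaf > 1, na.rm = TRUE))
    stop("VAF outside [0, 1]")
  if (anyDuplicated(out$variant_id)) stop("duplicate variant_id in lesion")
  out
}

#' MATH score of one lesion
#'
#' Mutant-allele tumor heterogeneity: `100 * MAD(vaf) / median(vaf)`, with
#' the median absolute deviation scaled by the normal-consistency constant
#' 1.4826 (the convention of the original MATH definition).  Invariant to
#' uniform VAF rescaling and to variant order.
#'
#' @param table A variant table (data.frame with a `vaf` column) or a plain
#'   numeric vector of VAFs.
#' @return The MATH score.
#' @export
#' @examples
#' math_score(c(0.1, 0.2, 0.3, 0.4, 0.5))  # 49.42
math_score <- function(table) {
  vaf <- if (is.numeric(table)) table else table$vaf
  vaf <- vaf[!is.na(vaf) & vaf > 0]
  if (length(vaf) < 2) stop("need at least 2 variants with VAF > 0")
  100 * mad(vaf) / median(vaf)  # mad() applies the 1.4826 constant
}

#' Trunk and branch mutation fractions of a lesion pair
#'
#' Trunk (ubiquitous) mutations are shared by both lesions; branch
#' (heterogeneous) mutations are private to one side.
#'
#' @param pbc,cbc Variant tables (data.frames with `variant_id`).
#' @return Named numeric `c(trunk, branch)`; `trunk = |shared| / |union|`,
#'   `branch = 1 - trunk`.
#' @export
trunk_branch_fractions <- function(pbc, cbc) {
  ids_p <- unique(pbc$variant_id)
  ids_c <- unique(cbc$variant_id)
  u <- union(ids_p, ids_c)
  if (length(u) == 0) stop("both variant tables are empty")
  trunk <- length(intersect(ids_p, ids_c)) / length(u)
  c(trunk = trunk, branch = 1 - trunk)
}

#' Bilateral heterogeneity metrics for one patient
#'
#' @param pbc,cbc Variant tables of the two lesions.
#' @param interval_time Years between the two diagnoses.
#' @return One-row data.frame with `math_pbc`, `math_cbc`, `math_ratio`
#'   (CBC / PBC; see Details), `trunk_fraction`, `branch_fraction`,
#'   `interval_time`.
#' @details The MATH ratio is defined as `MATH_CBC / MATH_PBC`: the
#'   contralateral lesion's mutational diversity relative to the primary.
#'   Values above 1 mean the later tumor is the more heterogeneous one.
#' @export
heterogeneity_metrics <- function(pbc, cbc, interval_time) {
  tb <- trunk_branch_fractions(pbc, cbc)
  mp <- math_score(pbc)
  mc <- math_score(cbc)
  data.frame(math_pbc = mp, math_cbc = mc, math_ratio = mc / mp,
             trunk_fraction = tb[["trunk"]], branch_fraction = tb[["branch"]],
             interval_time = interval_time)
}

#' Regress the MATH ratio on interval time
#'
#' Ordinary least squares of `math_ratio` on `interval_time` across
#' patients.
#'
#' @param metrics data.frame with columns `math_ratio` and `interval_time`
#'   (>= 3 rows, non-degenerate interval times).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
regress_ratio_on_interval <- function(metrics) {
  if (nrow(metrics) < 3) stop("need at least 3 points")
  if (length(unique(metrics$interval_time)) < 2)
    stop("degenerate interval times (all equal)")
  fit <- lm(math_ratio ~ interval_time, data = metrics)
  # R^2 computed directly: summary.lm warns on noiseless inputs
  tss <- sum((metrics$math_ratio - mean(metrics$math_ratio))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - sum(resid(fit)^2) / tss
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = nrow(metrics))
}
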