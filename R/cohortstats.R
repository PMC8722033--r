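# Cohort-level diagnostic statistics: per-class yields, exact two-tailed
# Fisher tests, de novo fractions, and recurrence tables.

#' Diagnostic yield of cohort table rows
#'
#' Yield = 100 x (double + cnv_only + variant_only) / cases, rounded half-up
#' to two decimals. The three diagnosed columns count fetuses once: `double`
#' are fetuses with both a causative CNV and a causative variant, the other
#' two are single-diagnosis counts.
#'
#' @param tab data.frame with columns `cases`, `double`, `cnv_only`,
#'   `variant_only` (one row per phenotypic class).
#' @return numeric vector of yields in percent (2 dp).
#' @export
diagnostic_yield <- function(tab) {
  .check(all(c("cases", "double", "cnv_only", "variant_only") %in% names(tab)),
         "cohort table must have cases/double/cnv_only/variant_only columns")
  .check(all(tab$cases > 0), "zero cases in a cohort table row")
  diag <- tab$double + tab$cnv_only + tab$variant_only
  .check(all(diag <= tab$cases), "diagnosed counts exceed cases")
  round_half_up(100 * diag / tab$cases, 2)
}

#' Read a bundled or user cohort count table
#'
#' TSV with columns `class`, `cases`, `double`, `cnv_only`, `variant_only`.
#' The package ships an example table of published per-class counts at
#' `system.file("extdata", "table2_cohort_counts.tsv", package = "prenataldx")`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check(all(c("class", "cases", "double", "cnv_only", "variant_only") %in%
               names(tab)), "malformed cohort table: %s", path)
  tab
}

#' Exact two-tailed Fisher test for a 2x2 table
#'
#' Conditional on both margins, the count in the top-left cell follows a
#' hypergeometric distribution. The two-sided p-value is the total
#' probability of all tables with the same margins whose point probability
#' does not exceed that of the observed table (small relative tolerance for
#' floating-point ties).
#'
#' @param table 2x2 matrix of non-negative counts, or a length-4 vector
#'   (a, b, c, d) read row-wise.
#' @param tie_tol relative tolerance when comparing point probabilities
#'   (default 1e-7).
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_tailed <- function(table, tie_tol = 1e-7) {
  x <- as.vector(t(table))
  .check(length(x) == 4, "need a 2x2 table")
  .check(all(x >= 0) && all(x == floor(x)), "cells must be non-negative integers")
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  .check(m + n > 0, "table has no observations")
  support <- max(0, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs <- stats::dhyper(a, m, n, k, log = TRUE)
  p <- sum(exp(logp[logp <= obs + log1p(tie_tol)]))
  min(1, p)
}

#' Summarize finalized trio diagnoses over a cohort
#'
#' @param diagnoses data.frame with one row per diagnosed trio: `trio_id`,
#'   `double_diagnosis` (logical), `inheritance` (label of the single
#'   finding; ignored for double-diagnosis rows), `alteration_key`
#'   (recurrence key -- cytoband-interval label for CNVs or gene symbol for
#'   variants; comma-separated when a trio has several findings). May have
#'   zero rows.
#' @param cohort_size total trios tested.
#' @return list with `de_novo_fraction` (percent of diagnosed trios whose
#'   single-diagnosis finding is de novo, 2 dp; NULL when no trio is
#'   diagnosed), `double_count`, and `recurrence` (data.frame
#'   `alteration_key`, `count`, `percent` of cohort, sorted by count then
#'   key).
#' @export
cohort_summary <- function(diagnoses, cohort_size) {
  .check(cohort_size > 0, "cohort_size must be positive")
  n_diag <- nrow(diagnoses)
  if (n_diag == 0)
    return(list(de_novo_fraction = NULL, double_count = 0L,
                recurrence = data.frame(alteration_key = character(0),
                                        count = integer(0),
                                        percent = numeric(0),
                                        stringsAsFactors = FALSE)))
  single_dn <- !diagnoses$double_diagnosis &
    diagnoses$inheritance == "de_novo"
  keys <- unlist(strsplit(as.character(diagnoses$alteration_key), ",",
                          fixed = TRUE))
  keys <- keys[!is.na(keys) & keys != ""]
  counts <- sort(table(keys), decreasing = TRUE)
  rec <- data.frame(alteration_key = as.character(names(counts)),
                    count = as.integer(counts),
                    percent = round_half_up(100 * as.integer(counts) /
                                              cohort_size, 2),
                    stringsAsFactors = FALSE)
  rec <- rec[order(-rec$count, rec$alteration_key), , drop = FALSE]
  rownames(rec) <- NULL
  list(de_novo_fraction = round_half_up(100 * sum(single_dn) / n_diag, 2),
       double_count = sum(diagnoses$double_diagnosis),
       recurrence = rec)
}
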