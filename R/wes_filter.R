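#' Screen trio variant records on per-member quality
#'
#' Applies the variant-level quality screen to one trio member's fields: a
#' record passes iff Genotype Quality `GQ >= min_gq`, variant read depth
#' `DP >= min_dp`, and the fraction of low-quality bases at the site is
#' strictly below `max_lowq_frac`. Sites at or above the low-quality-base
#' boundary are excluded (a site dominated by low-quality bases is not
#' trustworthy), so `lowq_frac = max_lowq_frac` fails. Missing quality
#' fields fail closed with reason `missing_field`.
#'
#' @param records data.frame of variant records with per-member columns
#'   `<member>_gt`, `<member>_gq`, `<member>_dp`, `<member>_lqf`.
#' @param member one of `"father"`, `"mother"`, `"fetus"`.
#' @param min_gq minimum genotype quality (default 15).
#' @param min_dp minimum read depth (default 3).
#' @param max_lowq_frac exclusive upper bound on the low-quality base
#'   fraction (default 0.4).
#' @return list with `pass` (data.frame) and `fail` (data.frame with an
#'   added `reasons` column listing every violated criterion, separated by
#'   `;`). `pass` and `fail` partition the input.
#' @export
filter_variant_records <- function(records, member = "fetus",
                                   min_gq = 15, min_dp = 3,
                                   max_lowq_frac = 0.4) {
  .check(member %in% c("father", "mother", "fetus"),
         "unknown trio member '%s'", member)
  cols <- paste0(member, c("_gq", "_dp", "_lqf"))
  .check(all(cols %in% names(records)),
         "records lack quality columns for member '%s'", member)
  n <- nrow(records)
  if (n == 0) return(list(pass = records,
                          fail = cbind(records, reasons = character(0))))
  gq <- records[[cols[1]]]; dp <- records[[cols[2]]]; lqf <- records[[cols[3]]]
  .check(all(is.na(lqf) | (lqf >= 0 & lqf <= 1)),
         "lowq_frac outside [0,1]")
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    rs <- character(0)
    if (is.na(gq[i]) || is.na(dp[i]) || is.na(lqf[i])) rs <- "missing_field"
    if (!is.na(gq[i]) && gq[i] < min_gq) rs <- c(rs, "low_GQ")
    if (!is.na(dp[i]) && dp[i] < min_dp) rs <- c(rs, "low_DP")
    if (!is.na(lqf[i]) && lqf[i] >= max_lowq_frac) rs <- c(rs, "high_lowq_frac")
    reasons[[i]] <- rs
  }
  ok <- lengths(reasons) == 0
  fail <- records[!ok, , drop = FALSE]
  fail$reasons <- vapply(reasons[!ok], paste, "", collapse = ";")
  list(pass = records[ok, , drop = FALSE], fail = fail)
}
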