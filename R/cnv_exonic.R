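# Exonic CNV calling from a cohort exon-depth matrix: depth filtering,
# PCA removal of dominant systematic components, per-sample z-scoring, and
# a 3-state Viterbi decoding with a minimum of 3 contiguous exons per call.

#' Normalize a cohort exon-depth matrix
#'
#' (1) Drops exons and samples whose mean depth falls outside the given
#' bounds; (2) mean-centers each exon (column); (3) removes every principal
#' component of the centered samples x exons matrix whose variance exceeds
#' `pc_variance_factor` times the mean component variance (systematic
#' capture/batch structure); (4) z-scores each sample's residual row.
#' Rows with zero residual variance are returned as all-zero z.
#'
#' @param depths samples x exons numeric matrix (rownames = sample ids).
#' @param exons data.frame describing the columns, in genomic order:
#'   `chrom`, `start`, `end`, `gene_id`.
#' @param min_mean_exon,max_mean_exon exon mean-depth bounds (default 10,
#'   2000).
#' @param min_mean_sample,max_mean_sample sample mean-depth bounds (default
#'   25, 500).
#' @param pc_variance_factor PC-removal multiplier of the mean component
#'   variance (default 0.7).
#' @return object of class `exon_depth_matrix`: `z` (retained samples x
#'   exons), `exons` (retained, genomic order), `sample_ids`,
#'   `excluded_exons`, `excluded_samples`, `n_pc_removed`.
#' @export
normalize_exon_matrix <- function(depths, exons,
                                  min_mean_exon = 10, max_mean_exon = 2000,
                                  min_mean_sample = 25, max_mean_sample = 500,
                                  pc_variance_factor = 0.7) {
  .check(nrow(exons) == ncol(depths),
         "exons table (%d rows) does not match depth matrix (%d columns)",
         nrow(exons), ncol(depths))
  exon_mean <- colMeans(depths)
  keep_e <- exon_mean >= min_mean_exon & exon_mean <= max_mean_exon
  sample_mean <- rowMeans(depths[, keep_e, drop = FALSE])
  keep_s <- sample_mean >= min_mean_sample & sample_mean <= max_mean_sample
  x <- depths[keep_s, keep_e, drop = FALSE]
  .check(nrow(x) >= 10, "only %d samples pass depth filtering (need >= 10)",
         nrow(x))
  .check(ncol(x) >= 20, "only %d exons pass depth filtering (need >= 20)",
         ncol(x))

  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  compvar <- sv$d^2
  remove <- compvar > pc_variance_factor * mean(compvar)
  resid <- xc
  if (any(remove)) {
    ir <- which(remove)
    resid <- xc - sv$u[, ir, drop = FALSE] %*%
      diag(sv$d[ir], nrow = length(ir)) %*% t(sv$v[, ir, drop = FALSE])
  }
  z <- t(apply(resid, 1, function(r) {
    s <- stats::sd(r)
    if (!is.finite(s) || s < .Machine$double.eps^0.5) rep(0, length(r))
    else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(x)
  structure(list(z = z, exons = exons[keep_e, , drop = FALSE],
                 sample_ids = rownames(x),
                 excluded_exons = which(!keep_e),
                 excluded_samples = rownames(depths)[!keep_s],
                 n_pc_removed = sum(remove)),
            class = "exon_depth_matrix")
}

# 3-state HMM parameters in log space; states DEL(1) DIP(2) DUP(3)
.exon_hmm <- function(M, p_event, p_stay) {
  trans <- matrix(c(
    p_stay,        1 - p_stay,       0,
    p_event,       1 - 2 * p_event,  p_event,
    0,             1 - p_stay,       p_stay), 3, 3, byrow = TRUE)
  list(means = c(-M, 0, M), ltrans = log(trans),
       linit = log(c(p_event, 1 - 2 * p_event, p_event)))
}

#' Viterbi decoding of a z series (internal)
#'
#' Most probable DEL/DIP/DUP state path for one sample on one chromosome.
#' Ties (measure-zero for continuous z) resolve to the lower state index.
#' @keywords internal
viterbi_decode <- function(z, M = 3, p_event = 1e-4, p_stay = 0.9) {
  n <- length(z)
  hmm <- .exon_hmm(M, p_event, p_stay)
  emis <- vapply(1:3, function(s) stats::dnorm(z, hmm$means[s], 1, log = TRUE),
                 numeric(n))
  if (n == 1) emis <- matrix(emis, nrow = 1)
  delta <- matrix(-Inf, n, 3)
  psi <- matrix(0L, n, 3)
  delta[1, ] <- hmm$linit + emis[1, ]
  if (n > 1) for (t in 2:n) for (s in 1:3) {
    cand <- delta[t - 1, ] + hmm$ltrans[, s]
    psi[t, s] <- which.max(cand)
    delta[t, s] <- cand[psi[t, s]] + emis[t, s]
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Call exonic CNVs by Viterbi decoding
#'
#' Decodes each retained sample's z series per chromosome with a 3-state
#' HMM: DEL emits Normal(-M, 1), diploid Normal(0, 1), DUP emits
#' Normal(+M, 1); the diploid state transitions to DEL or DUP with
#' probability `p_event` each, non-diploid states persist with `p_stay` and
#' never jump directly between DEL and DUP. Contiguous non-diploid runs of
#' at least `min_exons` exons become calls; shorter runs are suppressed.
#'
#' @param edm an `exon_depth_matrix`.
#' @param M absolute emission mean of the CNV states (default 3).
#' @param p_event diploid-to-CNV transition probability (default 1e-4).
#' @param p_stay CNV self-transition probability (default 0.9).
#' @param min_exons minimum contiguous exons per call (default 3).
#' @return data.frame of calls: `sample_id`, `chrom`, `start`, `end`,
#'   `gene_ids` (comma-joined), `state` (`DEL`/`DUP`), `n_exons`, `mean_z`,
#'   `origin = "exonic"`.
#' @export
viterbi_call_exonic_cnvs <- function(edm, M = 3, p_event = 1e-4,
                                     p_stay = 0.9, min_exons = 3L) {
  calls <- list()
  ex <- edm$exons
  for (si in seq_along(edm$sample_ids)) {
    for (cn in unique(ex$chrom)) {
      cols <- which(ex$chrom == cn)
      if (length(cols) == 0) next
      z <- edm$z[si, cols]
      path <- viterbi_decode(z, M, p_event, p_stay)
      run <- rle(path)
      ends <- cumsum(run$lengths)
      starts <- ends - run$lengths + 1L
      for (ri in seq_along(run$values)) {
        if (run$values[ri] == 2L || run$lengths[ri] < min_exons) next
        lo <- cols[starts[ri]]; hi <- cols[ends[ri]]
        calls[[length(calls) + 1L]] <- data.frame(
          sample_id = edm$sample_ids[si], chrom = cn,
          start = ex$start[lo], end = ex$end[hi],
          gene_ids = paste(unique(ex$gene_id[lo:hi]), collapse = ","),
          state = if (run$values[ri] == 1L) "DEL" else "DUP",
          n_exons = run$lengths[ri],
          mean_z = mean(z[starts[ri]:ends[ri]]),
          origin = "exonic", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0)
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      gene_ids = character(0), state = character(0),
                      n_exons = integer(0), mean_z = numeric(0),
                      origin = character(0), stringsAsFactors = FALSE))
  do.call(rbind, calls)
}
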