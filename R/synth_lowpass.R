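#' Simulate shallow-WGS bin counts for a sample batch
#'
#' Draws per-sample, per-bin read counts from a Poisson model emulating
#' low-pass sequencing at roughly 5 million short reads per sample binned at
#' 20 kb. The Poisson mean for sample i and bin j is
#' \deqn{\lambda_{ij} = depth \times w_j / G \times bias_j \times batch_i
#'   \times copies_{ij} / 2}
#' where \eqn{w_j} is the bin width, \eqn{G} the genome size, `bias_j` a
#' log-normal bin-level bias (capturing mappability/GC and other locus
#' effects), `batch_i` a log-normal sample-level scaling, and `copies_ij`
#' the planted copy number (2 outside planted CNVs).
#'
#' Planted CNV coordinates are snapped outward to bin boundaries and the
#' snapped coordinates are recorded back into the returned truth table.
#'
#' @param model a `genome_model`.
#' @param cnv_truth data.frame of planted CNVs with columns `sample_id`,
#'   `chrom`, `start`, `end`, `copies` (in 0,1,3,4), `parental_origin`
#'   (`denovo`, `pat` or `mat`); may be empty or NULL.
#' @param samples character vector of sample ids in the batch.
#' @param depth expected reads per sample (default 5e6).
#' @param seed integer seed.
#' @param bias_sd standard deviation of log bin bias (default 0.1).
#' @param batch_sd standard deviation of log sample scaling (default 0.05).
#' @return list of class `lowpass_sim` with `counts` (bins x samples integer
#'   matrix), `bins` (data.frame chrom/start/end), `sample_ids`, `truth`
#'   (the snapped CNV table), and `bin_size`.
#' @export
simulate_lowpass_counts <- function(model, cnv_truth = NULL, samples,
                                    depth = 5e6, seed = 1L,
                                    bias_sd = 0.1, batch_sd = 0.05) {
  .check(length(samples) > 0, "at least one sample required")
  .check(depth >= 0, "depth must be non-negative")
  bins <- genome_bins(model)
  nb <- nrow(bins)
  genome_size <- sum(model$chromosomes$length)
  set.seed(seed)
  bias <- if (bias_sd > 0)
    stats::rlnorm(nb, meanlog = -bias_sd^2 / 2, sdlog = bias_sd) else rep(1, nb)
  batch <- if (batch_sd > 0)
    stats::rlnorm(length(samples), meanlog = -batch_sd^2 / 2, sdlog = batch_sd)
  else rep(1, length(samples))

  copies <- matrix(2, nrow = nb, ncol = length(samples),
                   dimnames = list(NULL, samples))
  truth <- cnv_truth
  if (!is.null(truth) && nrow(truth) > 0) {
    b <- model$bin_size
    for (k in seq_len(nrow(truth))) {
      ci <- match(truth$chrom[k], model$chromosomes$name)
      .check(!is.na(ci), "CNV on unknown chromosome '%s'", truth$chrom[k])
      clen <- model$chromosomes$length[ci]
      .check(truth$start[k] >= 0 && truth$end[k] <= clen &&
               truth$end[k] > truth$start[k],
             "CNV %d outside chromosome bounds", k)
      .check(truth$copies[k] %in% c(0, 1, 3, 4),
             "planted CNV copies must be in {0,1,3,4}")
      s <- floor(truth$start[k] / b) * b
      e <- min(ceiling(truth$end[k] / b) * b, clen)
      truth$start[k] <- s; truth$end[k] <- e
      sel <- bins$chrom == truth$chrom[k] & bins$start >= s & bins$start < e
      si <- match(truth$sample_id[k], samples)
      .check(!is.na(si), "CNV sample '%s' not in batch", truth$sample_id[k])
      copies[sel, si] <- truth$copies[k]
    }
  }

  width_frac <- (bins$end - bins$start) / genome_size
  counts <- matrix(0L, nrow = nb, ncol = length(samples),
                   dimnames = list(NULL, samples))
  for (i in seq_along(samples)) {
    lambda <- depth * width_frac * bias * batch[i] * copies[, i] / 2
    counts[, i] <- stats::rpois(nb, lambda)
  }
  structure(list(counts = counts, bins = bins, sample_ids = samples,
                 truth = truth, bin_size = model$bin_size),
            class = "lowpass_sim")
}
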