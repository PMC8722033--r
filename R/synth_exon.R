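#' Plant exonic CNV events for simulation
#'
#' Draws multi-exon deletion/duplication events whose genomic sizes span the
#' range seen for exonic CNVs in diagnostic practice (defaults 1.75 to
#' 74.35 kb). Each event covers at least one exon; the returned truth table
#' records both bp coordinates and the contiguous exon index range (row
#' indices into `model$exons`, genomic order).
#'
#' @param model a `genome_model`.
#' @param samples sample ids eligible to carry an event.
#' @param n_events number of events to plant (one carrier each, sampled with
#'   replacement from `samples`).
#' @param copies_choices copy numbers to sample from (default c(0, 1, 3)).
#' @param size_range_kb numeric length-2, event size range in kb.
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `copies`, `exon_lo`, `exon_hi`, `n_exons`.
#' @export
plant_exonic_events <- function(model, samples, n_events,
                                copies_choices = c(0, 1, 3),
                                size_range_kb = c(1.75, 74.35), seed = 1L) {
  set.seed(seed)
  ex <- model$exons
  out <- vector("list", n_events)
  for (k in seq_len(n_events)) {
    size <- stats::runif(1, size_range_kb[1], size_range_kb[2]) * 1000
    anchor <- sample.int(nrow(ex), 1L)
    chrom <- ex$chrom[anchor]
    lo <- anchor
    hi <- anchor
    while (hi < nrow(ex) && ex$chrom[hi + 1L] == chrom &&
           ex$end[hi + 1L] - ex$start[lo] <= size) hi <- hi + 1L
    out[[k]] <- data.frame(
      sample_id = sample(samples, 1L), chrom = chrom,
      start = ex$start[lo], end = ex$end[hi],
      copies = sample(copies_choices, 1L),
      exon_lo = lo, exon_hi = hi, n_exons = hi - lo + 1L,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a cohort exon-depth matrix
#'
#' Generates per-sample, per-exon mean read depths as
#' \deqn{depth_{ij} = base_i \times exoneff_j \times copies_{ij}/2
#'   \times \exp(latent_{ij}) \times noise_{ij}}
#' with log-normal multiplicative noise and `n_latent` low-rank latent
#' factors providing structured, PCA-removable variation (mimicking batch
#' and capture-efficiency structure in exome cohorts). With `noise_sd = 0`
#' and `n_latent = 0` and no planted events the matrix is exactly rank 1.
#'
#' @param model a `genome_model`.
#' @param exonic_truth data.frame as returned by [plant_exonic_events()]
#'   (columns `sample_id`, `exon_lo`, `exon_hi`, `copies`), or NULL.
#' @param n_samples number of samples (must be at least 10: downstream
#'   normalization needs a cohort).
#' @param seed integer seed.
#' @param base_depth median per-sample depth (default 100).
#' @param sample_sd sd of log sample effects (default 0.2).
#' @param exon_sd sd of log exon efficiencies (default 0.5).
#' @param n_latent number of latent factors (default 2).
#' @param latent_sd scale of latent factor effects on log depth (default 0.1).
#' @param noise_sd sd of log multiplicative noise (default 0.1).
#' @return list of class `exon_sim` with `depths` (samples x exons matrix,
#'   sample ids SMP0001... as rownames), `exons`, `truth`.
#' @export
simulate_exon_depths <- function(model, exonic_truth = NULL, n_samples,
                                 seed = 1L, base_depth = 100,
                                 sample_sd = 0.2, exon_sd = 0.5,
                                 n_latent = 2L, latent_sd = 0.1,
                                 noise_sd = 0.1) {
  .check(n_samples >= 10, "n_samples must be >= 10 (normalization needs a cohort)")
  set.seed(seed)
  ex <- model$exons
  ne <- nrow(ex)
  samples <- sprintf("SMP%04d", seq_len(n_samples))
  base <- base_depth * exp(stats::rnorm(n_samples, 0, sample_sd))
  exoneff <- exp(stats::rnorm(ne, 0, exon_sd))
  copies <- matrix(2, n_samples, ne, dimnames = list(samples, NULL))
  if (!is.null(exonic_truth) && nrow(exonic_truth) > 0) {
    for (k in seq_len(nrow(exonic_truth))) {
      si <- match(exonic_truth$sample_id[k], samples)
      .check(!is.na(si), "truth sample '%s' not in cohort",
             exonic_truth$sample_id[k])
      copies[si, exonic_truth$exon_lo[k]:exonic_truth$exon_hi[k]] <-
        exonic_truth$copies[k]
    }
  }
  logd <- log(base) %o% rep(1, ne) + rep(1, n_samples) %o% log(exoneff) +
    log(copies / 2)  # -Inf where copies == 0 gives exact zero depth
  if (n_latent > 0) {
    scores <- matrix(stats::rnorm(n_samples * n_latent, 0, latent_sd),
                     n_samples, n_latent)
    loadings <- matrix(stats::rnorm(n_latent * ne), n_latent, ne)
    logd <- logd + scores %*% loadings
  }
  if (noise_sd > 0)
    logd <- logd + matrix(stats::rnorm(n_samples * ne, 0, noise_sd),
                          n_samples, ne)
  depths <- exp(logd)
  dimnames(depths) <- list(samples, paste(ex$chrom, ex$start, sep = ":"))
  structure(list(depths = depths, exons = ex, truth = exonic_truth,
                 sample_ids = samples),
            class = "exon_sim")
}
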