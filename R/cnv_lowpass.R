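# Genome-wide CNV calling from shallow-WGS 20 kb bin counts:
# batch-median normalization -> local-linear smoothing -> first-order
# difference -> thresholded breakpoints -> paired-breakpoint segments.

#' Bin aligned read starts into fixed-width bins
#'
#' Counts read start positions per contiguous half-open bin
#' `[k*bin_size, (k+1)*bin_size)` along each chromosome. Total counts equal
#' the number of input reads.
#'
#' @param read_starts named list: chromosome name -> sorted integer vector
#'   of 0-based read start positions.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (default 20000).
#' @param sample_id sample label carried through.
#' @return object of class `bin_count_profile`: list with `sample_id`,
#'   `bins` (data.frame chrom/start/end/count), `bin_size`.
#' @export
bin_reads <- function(read_starts, chrom_lengths, bin_size = 20000L,
                      sample_id = "sample") {
  .check(bin_size > 0, "bin_size must be positive")
  .check(all(names(read_starts) %in% names(chrom_lengths)),
         "read chromosomes missing from chrom_lengths")
  out <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    starts <- seq(0, len - 1, by = bin_size)
    bins <- data.frame(chrom = cn, start = starts,
                       end = pmin(starts + bin_size, len),
                       stringsAsFactors = FALSE)
    pos <- read_starts[[cn]]
    if (is.null(pos) || length(pos) == 0) {
      bins$count <- 0L
      return(bins)
    }
    .check(!is.unsorted(pos), "read positions on %s are not sorted", cn)
    .check(pos[1] >= 0 && pos[length(pos)] < len,
           "read position out of range on %s", cn)
    idx <- pos %/% bin_size + 1L
    bins$count <- tabulate(idx, nbins = nrow(bins))
    bins
  })
  structure(list(sample_id = sample_id, bins = do.call(rbind, out),
                 bin_size = as.integer(bin_size)),
            class = "bin_count_profile")
}

#' Normalize a batch of bin-count profiles
#'
#' All samples sequenced in the same batch regularize one another: each
#' sample is scaled to a common total, the per-bin reference is the
#' across-batch median of scaled counts, and each sample's per-bin ratio is
#' its scaled count over that reference. Bins whose reference falls below
#' `min_ref` (unmappable or empty regions) are masked and excluded from all
#' downstream arithmetic. After the final scaling the per-bin batch median
#' of ratios is exactly 1 on unmasked bins.
#'
#' @param profiles list of `bin_count_profile` from one batch (>= 8), or an
#'   equivalent bins x samples count matrix plus `bins` attribute (see
#'   [as_batch_input()] helpers in the readers).
#' @param min_ref minimum per-bin median scaled count for a bin to stay
#'   usable (default 10).
#' @param min_batch minimum batch size (default 8).
#' @return object of class `batch_matrix`: `sample_ids`, `bins`, `counts`,
#'   `ratio` (linear, NA on masked bins), `log2_ratio`, `mask` (TRUE =
#'   usable).
#' @export
normalize_batch <- function(profiles, min_ref = 10, min_batch = 8L) {
  if (is.list(profiles) && !is.null(profiles$counts)) {
    counts <- profiles$counts
    bins <- profiles$bins
    sample_ids <- colnames(counts)
  } else {
    sample_ids <- vapply(profiles, function(p) p$sample_id, "")
    bins <- profiles[[1]]$bins[c("chrom", "start", "end")]
    counts <- vapply(profiles, function(p) {
      .check(nrow(p$bins) == nrow(bins), "profiles have differing bin grids")
      as.numeric(p$bins$count)
    }, numeric(nrow(bins)))
    colnames(counts) <- sample_ids
  }
  .check(ncol(counts) >= min_batch,
         "batch regularization needs at least %d samples, got %d",
         min_batch, ncol(counts))

  totals <- colSums(counts)
  .check(all(totals > 0), "sample(s) with zero total counts")
  target <- mean(totals)
  scaled <- sweep(counts, 2, target / totals, `*`)
  ref0 <- apply(scaled, 1, stats::median)
  mask <- ref0 >= min_ref

  # rescale over usable bins only, then take the final reference so that the
  # per-bin median ratio is exactly 1
  tot_u <- colSums(counts[mask, , drop = FALSE])
  .check(all(tot_u > 0), "sample(s) with zero counts on usable bins")
  scaled <- sweep(counts, 2, mean(tot_u) / tot_u, `*`)
  ref <- apply(scaled, 1, stats::median)
  ratio <- sweep(scaled, 1, ref, `/`)
  ratio[!mask, ] <- NA_real_
  structure(list(sample_ids = sample_ids, bins = bins, counts = counts,
                 ratio = ratio, log2_ratio = log2(ratio), mask = mask,
                 min_ref = min_ref),
            class = "batch_matrix")
}

# centered local linear regression smoother on an equally spaced series;
# edges use truncated windows (the fitted value at the evaluation point)
.loclin_smooth <- function(y, window) {
  n <- length(y)
  if (window <= 1 || n < 3) return(y)
  h <- (window - 1) %/% 2
  s <- numeric(n)
  x <- seq_len(n)
  cs_y <- cumsum(y); cs_xy <- cumsum(x * y)
  cs_x <- cumsum(x); cs_x2 <- cumsum(x^2)
  rsum <- function(cs, a, b) cs[b] - if (a > 1) cs[a - 1] else 0
  for (j in x) {
    a <- max(1L, j - h); b <- min(n, j + h)
    m <- b - a + 1L
    sx <- rsum(cs_x, a, b); sy <- rsum(cs_y, a, b)
    sxy <- rsum(cs_xy, a, b); sx2 <- rsum(cs_x2, a, b)
    den <- m * sx2 - sx^2
    if (den <= 0) { s[j] <- sy / m; next }
    beta <- (m * sxy - sx * sy) / den
    alpha <- (sy - beta * sx) / m
    s[j] <- alpha + beta * j
  }
  s
}

#' Detect CNV breakpoints in one sample of a normalized batch
#'
#' Per chromosome: (1) smooth the log2-ratio series over usable bins with a
#' centered local linear regression of `window` bins (truncated at edges;
#' chromosomes shorter than the window use the full series); (2) take the
#' first-order difference `d[j] = s[j] - s[j-1]`; (3) set the breakpoint
#' threshold `tau = max(k * 1.4826 * MAD(d), tau_floor)`; (4) within each
#' contiguous same-sign run of bins with `|d| > tau`, place one breakpoint,
#' refined to the cut position that maximizes the contrast between the mean
#' raw log2 ratio of the `window` bins on either side. Deterministic.
#'
#' @param batch a `batch_matrix`.
#' @param sample_id sample to analyze.
#' @param window smoothing window in bins (default 15).
#' @param k MAD multiplier for the threshold (default 5).
#' @param tau_floor absolute lower bound on `tau` in log2 units
#'   (default 0.02), so that noise-free series still yield a finite
#'   threshold.
#' @return data.frame of class columns: `chrom`, `bin` (row index into
#'   `batch$bins`), `start` (bp of that bin), `magnitude` (the thresholded
#'   difference value), `direction` (`"up"`/`"down"`).
#' @export
detect_breakpoints <- function(batch, sample_id, window = 15L, k = 5,
                               tau_floor = 0.02) {
  si <- match(sample_id, batch$sample_ids)
  .check(!is.na(si), "sample '%s' not in batch", sample_id)
  out <- list()
  for (cn in unique(batch$bins$chrom)) {
    rows <- which(batch$bins$chrom == cn & batch$mask)
    if (length(rows) < 2) {
      warning(sprintf("chromosome %s: fewer than 2 usable bins, skipped", cn))
      next
    }
    y <- batch$log2_ratio[rows, si]
    w <- if (length(y) < window) length(y) else window
    s <- .loclin_smooth(y, w)
    d <- diff(s)                      # d[j] = s[j+1] - s[j], breakpoint at j+1
    tau <- max(k * stats::mad(d), tau_floor)
    cand <- which(abs(d) > tau)
    if (length(cand) == 0) next
    sgn <- sign(d[cand])
    grp <- cumsum(c(TRUE, diff(cand) != 1L | diff(sgn) != 0))
    cw <- max(2L, ceiling(w / 2))     # contrast half-window; shorter than the
    for (g in unique(grp)) {          # smoothing window so nearby flanks of
      run <- cand[grp == g]           # short events do not dilute the contrast
      bp_bins <- run + 1L
      # refine: pick the cut c (series index of first right-side bin)
      # maximizing |mean(y[right window]) - mean(y[left window])|
      contrast <- vapply(bp_bins, function(cc) {
        l <- y[max(1L, cc - cw):(cc - 1L)]
        rgt <- y[cc:min(length(y), cc + cw - 1L)]
        abs(mean(rgt) - mean(l))
      }, 0)
      best <- bp_bins[which.max(contrast)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, bin = rows[best], start = batch$bins$start[rows[best]],
        magnitude = d[best - 1L],
        direction = if (sign(d[best - 1L]) < 0) "down" else "up",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), bin = integer(0),
                      start = numeric(0), magnitude = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(.chrom_order(res$chrom, unique(batch$bins$chrom)), res$bin), ,
      drop = FALSE]
}

#' Assemble CNV calls from paired breakpoints
#'
#' Consecutive breakpoints bracket candidate segments: a `down` breakpoint
#' opens a loss segment that an `up` breakpoint closes, and vice versa for
#' gains. Chromosome ends and masked-bin gaps act as implicit (wildcard)
#' boundaries so terminal events are callable. A segment becomes a call iff
#' it spans at least `min_bins` usable bins and its mean linear ratio lies
#' outside `[loss_ratio, gain_ratio]`.
#'
#' @param breakpoints data.frame from [detect_breakpoints()].
#' @param batch a `batch_matrix`.
#' @param sample_id sample the breakpoints belong to.
#' @param min_bins minimum segment length in usable bins (default 3).
#' @param loss_ratio mean-ratio upper bound for a loss (default 0.75).
#' @param gain_ratio mean-ratio lower bound for a gain (default 1.25).
#' @return data.frame of CNV calls: `sample_id`, `chrom`, `start`, `end`
#'   (bp, bin-aligned half-open), `mean_ratio`, `copy_number` (round of
#'   2 x mean ratio, clipped to [0, 6]), `state` (`loss`/`gain`), `n_bins`,
#'   `origin = "lowpass"`.
#' @export
assemble_cnv_calls <- function(breakpoints, batch, sample_id,
                               min_bins = 3L, loss_ratio = 0.75,
                               gain_ratio = 1.25) {
  si <- match(sample_id, batch$sample_ids)
  .check(!is.na(si), "sample '%s' not in batch", sample_id)
  calls <- list()
  for (cn in unique(batch$bins$chrom)) {
    rows <- which(batch$bins$chrom == cn & batch$mask)
    if (length(rows) < min_bins) next
    # contiguous usable runs (masked gaps split them)
    run_id <- cumsum(c(TRUE, diff(rows) != 1L))
    bp <- breakpoints[breakpoints$chrom == cn, , drop = FALSE]
    for (rg in unique(run_id)) {
      rr <- rows[run_id == rg]
      inbp <- bp[bp$bin %in% rr, , drop = FALSE]
      # cuts: positions (global row index of first bin right of the cut)
      cuts <- data.frame(bin = c(rr[1], inbp$bin, rr[length(rr)] + 1L),
                         type = c("boundary", inbp$direction, "boundary"),
                         stringsAsFactors = FALSE)
      cuts <- cuts[order(cuts$bin), , drop = FALSE]
      for (q in seq_len(nrow(cuts) - 1L)) {
        b1 <- cuts[q, ]; b2 <- cuts[q + 1L, ]
        seg <- rr[rr >= b1$bin & rr < b2$bin]
        if (length(seg) < min_bins) next
        mr <- mean(batch$ratio[seg, si])
        is_loss <- mr <= loss_ratio &&
          b1$type %in% c("down", "boundary") &&
          b2$type %in% c("up", "boundary")
        is_gain <- mr >= gain_ratio &&
          b1$type %in% c("up", "boundary") &&
          b2$type %in% c("down", "boundary")
        if (!is_loss && !is_gain) next
        calls[[length(calls) + 1L]] <- data.frame(
          sample_id = sample_id, chrom = cn,
          start = batch$bins$start[seg[1]],
          end = batch$bins$end[seg[length(seg)]],
          mean_ratio = mr,
          copy_number = max(0, min(6, floor(2 * mr + 0.5))),
          state = if (is_loss) "loss" else "gain",
          n_bins = length(seg), origin = "lowpass",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0)
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      mean_ratio = numeric(0), copy_number = numeric(0),
                      state = character(0), n_bins = integer(0),
                      origin = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, calls)
  res[order(.chrom_order(res$chrom, unique(batch$bins$chrom)), res$start), ,
      drop = FALSE]
}

#' Call low-pass CNVs for one sample (convenience wrapper)
#'
#' Runs [detect_breakpoints()] then [assemble_cnv_calls()] with shared
#' parameters.
#'
#' @inheritParams detect_breakpoints
#' @inheritParams assemble_cnv_calls
#' @return data.frame of CNV calls (see [assemble_cnv_calls()]).
#' @export
call_cnvs_lowpass <- function(batch, sample_id, window = 15L, k = 5,
                              tau_floor = 0.02, min_bins = 3L,
                              loss_ratio = 0.75, gain_ratio = 1.25) {
  bps <- detect_breakpoints(batch, sample_id, window = window, k = k,
                            tau_floor = tau_floor)
  assemble_cnv_calls(bps, batch, sample_id, min_bins = min_bins,
                     loss_ratio = loss_ratio, gain_ratio = gain_ratio)
}
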