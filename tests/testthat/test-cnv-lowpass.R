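test_that("bin_reads honors the half-open convention and conserves reads", {
  prof <- bin_reads(list(`1` = c(0, 19999, 20000)),
                    c(`1` = 100000), bin_size = 20000, sample_id = "S")
  expect_equal(prof$bins$count, c(2, 1, 0, 0, 0))

  empty <- bin_reads(list(), c(`1` = 100000), 20000)
  expect_true(all(empty$bins$count == 0))

  set.seed(1)
  pos <- sort(sample.int(10e6, 10000) - 1L)
  prof2 <- bin_reads(list(`1` = pos), c(`1` = 10e6), 20000)
  expect_equal(sum(prof2$bins$count), 10000)   # conservation
  expect_equal(nrow(prof2$bins), 500)
  expect_equal(mean(prof2$bins$count), 20)

  expect_error(bin_reads(list(`1` = c(5, 1)), c(`1` = 100), 20), "sorted")
  expect_error(bin_reads(list(`1` = c(1, 200)), c(`1` = 100), 20), "range")
})

make_flat_batch <- function(n_samples = 10, n_bins = 200, level = 1000,
                            tweak = NULL) {
  counts <- matrix(level, n_bins, n_samples,
                   dimnames = list(NULL, sprintf("S%02d", 1:n_samples)))
  if (!is.null(tweak)) counts <- tweak(counts)
  bins <- data.frame(chrom = "1", start = (seq_len(n_bins) - 1) * 20000,
                     end = seq_len(n_bins) * 20000)
  normalize_batch(list(counts = counts, bins = bins))
}

test_that("batch normalization zeroes identical and rescaled samples", {
  b <- make_flat_batch()
  expect_true(all(abs(b$log2_ratio[b$mask, ]) < 1e-12))

  b2 <- make_flat_batch(tweak = function(cnt) { cnt[, 1] <- cnt[, 1] * 2; cnt })
  expect_true(all(abs(b2$log2_ratio[b2$mask, "S01"]) < 1e-12))

  # per-bin median of ratios is exactly 1 on usable bins
  med <- apply(b2$ratio[b2$mask, ], 1, median)
  expect_true(all(abs(med - 1) < 1e-12))
})

test_that("zero-median bins are masked and small batches rejected", {
  b <- make_flat_batch(tweak = function(cnt) { cnt[7, ] <- 0; cnt })
  expect_false(b$mask[7])
  expect_true(all(is.na(b$ratio[7, ])))
  expect_true(all(b$mask[-7]))

  counts <- matrix(10, 5, 5, dimnames = list(NULL, letters[1:5]))
  bins <- data.frame(chrom = "1", start = 0:4 * 20, end = 1:5 * 20)
  expect_error(normalize_batch(list(counts = counts, bins = bins)),
               "at least 8")
})

test_that("breakpoint detection finds a noiseless step exactly once", {
  # bins 1..50 at full level, 51..200 halved: one down breakpoint at the
  # 0-based bin 50 boundary (bp 1,000,000)
  b <- make_flat_batch(tweak = function(cnt) {
    cnt[51:200, 1] <- cnt[51:200, 1] / 2; cnt })
  bp <- detect_breakpoints(b, "S01", window = 1, k = 0)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$direction, "down")
  expect_equal(bp$start, 1e6)

  # constant series: no breakpoints at any window
  flat <- make_flat_batch()
  expect_equal(nrow(detect_breakpoints(flat, "S01", window = 1, k = 0)), 0)
  expect_equal(nrow(detect_breakpoints(flat, "S01")), 0)
})

test_that("paired breakpoints assemble into the expected loss call", {
  # 1000 bins so the 50-bin event barely perturbs the sample total
  b <- make_flat_batch(n_bins = 1000, tweak = function(cnt) {
    cnt[51:100, 1] <- cnt[51:100, 1] / 2; cnt })
  bp <- detect_breakpoints(b, "S01", window = 1, k = 0)
  expect_equal(bp$direction, c("down", "up"))
  calls <- assemble_cnv_calls(bp, b, "S01")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$state, "loss")
  expect_equal(calls$copy_number, 1)
  expect_equal(calls$n_bins, 50)
  expect_equal(calls$start, 1e6)
  expect_equal(calls$end, 2e6)
  expect_equal(calls$mean_ratio, 0.5, tolerance = 0.03)

  # no breakpoints -> no calls
  expect_equal(nrow(assemble_cnv_calls(detect_breakpoints(
    make_flat_batch(), "S01"), make_flat_batch(), "S01")), 0)
})

test_that("segments inside the copy-neutral band are not called", {
  b <- make_flat_batch(tweak = function(cnt) {
    cnt[51:100, 1] <- round(cnt[51:100, 1] * 1.02); cnt })
  bp <- detect_breakpoints(b, "S01", window = 1, k = 0)
  expect_gt(nrow(bp), 0)           # breakpoints exist...
  calls <- assemble_cnv_calls(bp, b, "S01")
  expect_equal(nrow(calls), 0)     # ...but mean ratio 1.02 is not a CNV
})

test_that("calls respect min_bins and bin alignment", {
  b <- make_flat_batch(tweak = function(cnt) {
    cnt[51:52, 1] <- cnt[51:52, 1] / 2; cnt })
  calls <- assemble_cnv_calls(detect_breakpoints(b, "S01", window = 1, k = 0),
                              b, "S01", min_bins = 3)
  expect_equal(nrow(calls), 0)     # 2-bin event suppressed

  model <- small_model()
  tr <- data.frame(sample_id = "S1", chrom = "1", start = 2e6, end = 2.4e6,
                   copies = 1, parental_origin = "denovo")
  sim <- simulate_lowpass_counts(model, tr, sprintf("S%d", 1:8),
                                 depth = 7e5, seed = 9)
  batch <- normalize_batch(sim)
  calls <- call_cnvs_lowpass(batch, "S1")
  expect_true(all(calls$start %% model$bin_size == 0))
  expect_true(all(calls$n_bins >= 3))
})

test_that("calls are scale invariant and deterministic", {
  model <- small_model()
  tr <- data.frame(sample_id = "S1", chrom = "1", start = 3e6, end = 3.5e6,
                   copies = 3, parental_origin = "denovo")
  sim <- simulate_lowpass_counts(model, tr, sprintf("S%d", 1:8),
                                 depth = 7e5, seed = 10)
  batch <- normalize_batch(sim)
  calls1 <- call_cnvs_lowpass(batch, "S1")

  sim$counts[, "S1"] <- sim$counts[, "S1"] * 7L
  batch2 <- normalize_batch(sim)
  calls2 <- call_cnvs_lowpass(batch2, "S1")
  expect_equal(calls1[c("chrom", "start", "end", "state", "n_bins")],
               calls2[c("chrom", "start", "end", "state", "n_bins")])

  calls3 <- call_cnvs_lowpass(batch, "S1")
  expect_identical(calls1, calls3)
})

test_that("planted events are recovered with accurate boundaries", {
  rec <- run_lowpass_recovery(n_batches = 4, seed = 99)
  expect_equal(rec$n_events, 32)
  expect_gte(rec$sensitivity, 0.95)
  expect_gte(rec$frac_within2, 0.95)
  expect_lte(rec$false_per_free_sample, 0.1)
})
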