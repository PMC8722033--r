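# End-to-end pipeline runners shared by module tests and the acceptance
# suite. Study conditions: planted low-pass CNVs of 10-40 bins (copies 1 or
# 3) at >= 1000 expected reads per bin, batches of 8 carriers + 2 CNV-free
# samples.

run_lowpass_recovery <- function(n_batches, seed = 1) {
  model <- small_model(seed = 1)
  n_bins_total <- sum(ceiling(model$chromosomes$length / model$bin_size))
  depth <- 1000 * n_bins_total
  hits <- 0L; tot <- 0L; errs <- numeric(0)
  false_calls <- 0L; n_free <- 0L
  set.seed(seed)
  for (rep in seq_len(n_batches)) {
    samples <- sprintf("B%03dS%02d", rep, 1:10)
    carriers <- samples[1:8]
    len_bins <- sample(10:40, 8, replace = TRUE)
    st <- sample(20:500, 8) * model$bin_size
    tr <- data.frame(sample_id = carriers, chrom = "1", start = st,
                     end = st + len_bins * model$bin_size,
                     copies = rep(c(1, 3), 4), parental_origin = "denovo",
                     stringsAsFactors = FALSE)
    sim <- simulate_lowpass_counts(model, tr, samples, depth = depth,
                                   seed = seed * 10000 + rep)
    batch <- normalize_batch(sim)
    for (i in 1:8) {
      calls <- call_cnvs_lowpass(batch, carriers[i])
      tot <- tot + 1L
      want <- if (tr$copies[i] < 2) "loss" else "gain"
      ov <- calls[calls$state == want &
                    pmin(calls$end, tr$end[i]) - pmax(calls$start, tr$start[i]) >=
                    0.5 * pmax(calls$end - calls$start,
                               tr$end[i] - tr$start[i]), , drop = FALSE]
      if (nrow(ov) > 0) {
        hits <- hits + 1L
        errs <- c(errs, abs(ov$start[1] - tr$start[i]) / model$bin_size,
                  abs(ov$end[1] - tr$end[i]) / model$bin_size)
      }
    }
    for (s in samples[9:10]) {
      false_calls <- false_calls + nrow(call_cnvs_lowpass(batch, s))
      n_free <- n_free + 1L
    }
  }
  list(sensitivity = hits / tot, frac_within2 = mean(errs <= 2),
       false_per_free_sample = false_calls / n_free, n_events = tot)
}

# build per-member CNV call tables from a cohort's planted CNVs
cohort_cnv_calls <- function(cohort, trio_id) {
  cn <- cohort$cnvs
  mk <- function(mb) {
    if (is.null(cn)) return(NULL)
    x <- cn[cn$trio_id == trio_id & cn$member == mb, , drop = FALSE]
    if (nrow(x) == 0) return(NULL)
    data.frame(sample_id = x$sample_id, chrom = x$chrom, start = x$start,
               end = x$end, state = x$state, copy_number = x$copies,
               gene_ids = x$gene_id, stringsAsFactors = FALSE)
  }
  list(fetus = mk("fetus"), father = mk("father"), mother = mk("mother"))
}

# run integrate -> classify -> comphet for one cohort trio
analyze_cohort_trio <- function(cohort, i, filter = TRUE) {
  tr <- cohort$trios[i, ]
  trio <- make_trio(tr$trio_id, tr$father_id, tr$mother_id, tr$fetus_id,
                    tr$fetal_sex)
  v <- cohort$variants[cohort$variants$trio_id == tr$trio_id, , drop = FALSE]
  if (filter) v <- filter_variant_records(v, "fetus")$pass
  cand <- integrate_trio_candidates(v, cohort_cnv_calls(cohort, tr$trio_id),
                                    trio)
  cand <- classify_inheritance(cand, trio)
  ch <- detect_compound_het(cand, trio)
  list(trio = trio, candidates = ch$candidates, pairs = ch$pairs)
}

# fraction of trios whose planted mechanism is recovered with the exact
# expected label / compound-het pair, on noise-free genotypes
run_mechanism_recovery <- function(n_trios, seed = 1) {
  model <- small_model(seed = 2, genes_per_chrom = 6)
  cohort <- simulate_trio_cohort(
    model, n_trios,
    rates = list(denovo_rate = 0, causal_fraction = 1, xl_fraction = 0.25,
                 ar_fraction = 0.5, comphet_snv_fraction = 0.33,
                 comphet_cnv_snv_fraction = 0.34),
    seed = seed, lowqual_fraction = 0)
  mech <- cohort$truth$mechanisms
  ok <- logical(n_trios)
  for (i in seq_len(n_trios)) {
    res <- analyze_cohort_trio(cohort, i, filter = FALSE)
    cand <- res$candidates
    g <- mech$gene_id[i]
    in_gene <- vapply(cand$gene_ids, function(x)
      g %in% strsplit(x, ",", fixed = TRUE)[[1]], FALSE)
    ok[i] <- switch(
      mech$mechanism[i],
      ad_denovo = any(in_gene & cand$inheritance == "de_novo" &
                        cand$kind == "variant"),
      xl_maternal = any(in_gene & cand$inheritance == "x_linked_maternal"),
      ar_homozygous = any(in_gene &
                            cand$inheritance == "biparental_homozygous"),
      ar_comphet_snv = ,
      ar_comphet_cnv_snv = {
        p <- res$pairs
        p <- p[p$gene_id == g & p$phase_confidence == "certain", ,
               drop = FALSE]
        found <- FALSE
        for (r in seq_len(nrow(p))) {
          kinds <- cand$kind[c(p$first[r], p$second[r])]
          want_cnv <- mech$mechanism[i] == "ar_comphet_cnv_snv"
          if (want_cnv && setequal(kinds, c("cnv", "variant"))) found <- TRUE
          if (!want_cnv && all(kinds == "variant")) found <- TRUE
        }
        found
      },
      FALSE)
  }
  mean(ok)
}

# fraction of phenotype-matched causal trios whose causal gene tops the
# ranking, at default phenotype noise
run_rank_first <- function(n_trios, seed = 1) {
  model <- small_model(seed = 2, genes_per_chrom = 6)
  cohort <- simulate_trio_cohort(
    model, n_trios,
    rates = list(causal_fraction = 1, xl_fraction = 0.2, ar_fraction = 0.3),
    seed = seed)
  mech <- cohort$truth$mechanisms
  top_ok <- logical(n_trios)
  for (i in seq_len(n_trios)) {
    res <- analyze_cohort_trio(cohort, i)
    pri <- prioritize_candidates(res$candidates,
                                 cohort$phenotypes[[mech$trio_id[i]]],
                                 model$ontology)
    top <- pri$ranked$gene_ids[1]
    top_ok[i] <- !is.na(top) &&
      mech$gene_id[i] %in% strsplit(top, ",", fixed = TRUE)[[1]]
  }
  mean(top_ok)
}
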