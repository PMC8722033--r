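test_that("genome model respects configured sizes and is deterministic", {
  cfg <- list(chromosomes = data.frame(name = c("1", "2", "X"),
                                       length = c(10e6, 10e6, 5e6)))
  model <- build_genome_model(cfg, seed = 1)
  bins <- genome_bins(model)
  expect_equal(as.vector(table(factor(bins$chrom, c("1", "2", "X")))),
               c(500, 500, 250))
  expect_true(all(bins$end - bins$start == 20000))

  model2 <- build_genome_model(cfg, seed = 1)
  expect_identical(serialize(model, NULL), serialize(model2, NULL))
  model3 <- build_genome_model(cfg, seed = 2)
  expect_false(identical(serialize(model, NULL), serialize(model3, NULL)))
})

test_that("tree ontology has the forced term count and reaches the root", {
  model <- build_genome_model(list(ontology_depth = 2, ontology_branching = 3),
                              seed = 1)
  onto <- model$ontology
  expect_length(onto$terms, 13)  # 1 + 3 + 9
  for (t in onto$terms) expect_true(onto$root %in% term_closure(t, onto))
  expect_silent(validate_ontology(onto))
})

test_that("invalid genome configs error out", {
  expect_error(build_genome_model(list(bin_size = 0)), "bin_size")
  expect_error(build_genome_model(
    list(chromosomes = data.frame(name = character(0), length = numeric(0)))),
    "chromosomes")
  expect_error(build_genome_model(
    list(chromosomes = data.frame(name = "1", length = 1e6))), "X")
})

test_that("low-pass counts match the Poisson expectation", {
  model <- build_genome_model(
    list(chromosomes = data.frame(name = c("1", "X"),
                                  length = c(30e6, 30e6))), seed = 1)
  sim <- simulate_lowpass_counts(model, NULL, samples = c("A", "B"),
                                 depth = 5e6, seed = 2,
                                 bias_sd = 0, batch_sd = 0)
  # expectation 5e6 * 20e3 / 60e6 = 1666.7 per bin; 3000 bins per sample
  expect_equal(nrow(sim$counts), 3000)
  expect_equal(mean(sim$counts[, "A"]), 5e6 * 20e3 / 60e6, tolerance = 0.01)
  expect_equal(mean(sim$counts[, "B"]), 5e6 * 20e3 / 60e6, tolerance = 0.01)
})

test_that("planted deletion halves the mean count and snaps to bins", {
  model <- small_model()
  tr <- data.frame(sample_id = "A", chrom = "1", start = 2e6 + 1234,
                   end = 4e6 + 9999, copies = 1, parental_origin = "denovo")
  sim <- simulate_lowpass_counts(model, tr, samples = c("A", "B"),
                                 depth = 2e6, seed = 3,
                                 bias_sd = 0, batch_sd = 0)
  expect_equal(sim$truth$start, 2e6)       # snapped outward
  expect_equal(sim$truth$end, 4.02e6)
  ev <- sim$bins$chrom == "1" & sim$bins$start >= 2e6 & sim$bins$start < 4.02e6
  flank <- sim$bins$chrom == "1" & !ev
  expect_equal(mean(sim$counts[ev, "A"]) / mean(sim$counts[flank, "A"]),
               0.5, tolerance = 0.05)
})

test_that("planted bins track copies/2 within Monte-Carlo error", {
  model <- small_model()
  depth <- 1000 * 700  # >= 1000 expected reads per bin over 700 bins
  baseline <- depth * model$bin_size / sum(model$chromosomes$length)
  for (cp in c(0, 1, 3, 4)) {
    tr <- data.frame(sample_id = "S1", chrom = "1", start = 2e6, end = 3e6,
                     copies = cp, parental_origin = "denovo")
    sim <- simulate_lowpass_counts(model, tr, samples = sprintf("S%d", 1:8),
                                   depth = depth, seed = 10 + cp,
                                   bias_sd = 0, batch_sd = 0)
    ev <- sim$bins$chrom == "1" & sim$bins$start >= 2e6 &
      sim$bins$start < 3e6
    r <- sim$counts[ev, "S1"] / baseline
    se <- stats::sd(r) / sqrt(length(r))
    expect_lt(abs(mean(r) - cp / 2), 3 * max(se, 1e-3))
  }
})

test_that("zero depth gives an all-zero matrix and bad CNVs error", {
  model <- small_model()
  sim <- simulate_lowpass_counts(model, NULL, samples = "A", depth = 0,
                                 seed = 1)
  expect_true(all(sim$counts == 0))
  bad <- data.frame(sample_id = "A", chrom = "1", start = 11e6, end = 13e6,
                    copies = 1, parental_origin = "denovo")
  expect_error(simulate_lowpass_counts(model, bad, samples = "A",
                                       depth = 1e5, seed = 1), "bounds")
})

test_that("exon depths are rank 1 without noise and zero under hom deletion", {
  model <- small_model()
  sim <- simulate_exon_depths(model, NULL, n_samples = 12, seed = 4,
                              n_latent = 0, noise_sd = 0)
  expect_equal(qr(sim$depths)$rank, 1)

  tr <- data.frame(sample_id = "SMP0001", chrom = model$exons$chrom[1],
                   exon_lo = 1, exon_hi = 5, copies = 0)
  sim2 <- simulate_exon_depths(model, tr, n_samples = 12, seed = 4)
  expect_true(all(sim2$depths["SMP0001", 1:5] == 0))
  expect_true(all(sim2$depths["SMP0002", 1:5] > 0))
})

test_that("het deletion halves exon depth relative to the cohort", {
  model <- small_model()
  tr <- data.frame(sample_id = "SMP0001", chrom = model$exons$chrom[11],
                   exon_lo = 11, exon_hi = 15, copies = 1)
  sim <- simulate_exon_depths(model, tr, n_samples = 50, seed = 5,
                              sample_sd = 0, noise_sd = 0.1)
  ratio <- mean(sim$depths["SMP0001", 11:15]) /
    mean(colMeans(sim$depths[-1, 11:15]))
  expect_equal(ratio, 0.5, tolerance = 0.1)
  expect_error(simulate_exon_depths(model, NULL, n_samples = 5, seed = 1),
               ">= 10")
})

test_that("trio cohort is Mendelian-consistent when nothing is planted", {
  model <- small_model(seed = 2)
  cohort <- simulate_trio_cohort(
    model, 25, rates = list(denovo_rate = 0, causal_fraction = 0), seed = 6)
  v <- cohort$variants
  sex <- cohort$trios$fetal_sex[match(v$trio_id, cohort$trios$trio_id)]
  consistent <- vapply(seq_len(nrow(v)), function(i)
    mendelian_consistent(v$fetus_gt[i], v$father_gt[i], v$mother_gt[i],
                         chrom = v$chrom[i], fetal_sex = sex[i]), FALSE)
  expect_true(all(consistent))
  expect_true(all(cohort$truth$mechanisms$mechanism == "none"))
})

test_that("planted mechanisms have the promised genotype structure", {
  model <- small_model(seed = 2, genes_per_chrom = 6)
  cohort <- simulate_trio_cohort(
    model, 60,
    rates = list(denovo_rate = 0, causal_fraction = 1, xl_fraction = 0.3,
                 ar_fraction = 0.5, comphet_cnv_snv_fraction = 0.5,
                 comphet_snv_fraction = 0.25),
    seed = 7, lowqual_fraction = 0)
  mech <- cohort$truth$mechanisms
  expect_true(all(c("xl_maternal", "ar_comphet_cnv_snv") %in% mech$mechanism))

  for (i in which(mech$mechanism == "xl_maternal")) {
    expect_equal(cohort$trios$fetal_sex[i], "male")
    f <- cohort$truth$causal_findings[[mech$trio_id[i]]]
    v <- cohort$variants[cohort$variants$trio_id == mech$trio_id[i] &
                           cohort$variants$site_id %in% f$site_id, ]
    expect_equal(v$fetus_gt, "1")
    expect_equal(v$mother_gt, "0/1")
    expect_equal(v$father_gt, "0")
  }
  for (i in which(mech$mechanism == "ar_comphet_cnv_snv")) {
    tid <- mech$trio_id[i]
    cnv <- cohort$cnvs[cohort$cnvs$trio_id == tid, ]
    expect_true("fetus" %in% cnv$member)
    parent <- setdiff(unique(cnv$member), "fetus")
    expect_length(parent, 1)   # CNV inherited from exactly one parent
    f <- cohort$truth$causal_findings[[tid]]
    snv <- cohort$variants[cohort$variants$trio_id == tid &
                             cohort$variants$site_id %in% f$site_id, ]
    expect_equal(snv$gene_id, unique(cnv$gene_id))  # same gene
    # SNV comes from the opposite parent
    if (parent == "father") expect_equal(snv$mother_gt, "0/1")
    else expect_equal(snv$father_gt, "0/1")
  }
})

test_that("cohort generation is deterministic and rejects bad rates", {
  model <- small_model(seed = 2)
  c1 <- simulate_trio_cohort(model, 5, seed = 8)
  c2 <- simulate_trio_cohort(model, 5, seed = 8)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  expect_error(simulate_trio_cohort(model, 5,
                                    rates = list(denovo_rate = 1.5),
                                    seed = 1), "denovo_rate")
})
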