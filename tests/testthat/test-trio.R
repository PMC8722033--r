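cnv_row <- function(sample_id, start, end, chrom = "1", state = "loss",
                    copy_number = 1, gene_ids = "G1") {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             state = state, copy_number = copy_number, gene_ids = gene_ids,
             stringsAsFactors = FALSE)
}

test_that("candidate integration records parental presence correctly", {
  trio <- test_trio()
  v <- variant_row(fetus_gt = "0/1", father_gt = "0/0", mother_gt = "0/0")
  cand <- integrate_trio_candidates(v, list(), trio)
  expect_equal(nrow(cand), 1)
  expect_false(cand$father_presence)
  expect_false(cand$mother_presence)

  # 50% reciprocal overlap: fetal loss 1.0-2.0 Mb vs father loss 1.1-2.1 Mb
  cnvs <- list(fetus = cnv_row("FE1", 1.0e6, 2.0e6),
               father = cnv_row("FA1", 1.1e6, 2.1e6))
  cand2 <- integrate_trio_candidates(NULL, cnvs, trio)
  expect_true(cand2$father_presence)
  expect_false(cand2$mother_presence)

  # overlapping but different state does not count as parental presence
  cnvs$father$state <- "gain"
  cand3 <- integrate_trio_candidates(NULL, cnvs, trio)
  expect_false(cand3$father_presence)

  # below-threshold reciprocal overlap
  cnvs2 <- list(fetus = cnv_row("FE1", 1.0e6, 2.0e6),
                father = cnv_row("FA1", 1.9e6, 4.5e6))
  expect_false(integrate_trio_candidates(NULL, cnvs2, trio)$father_presence)

  empty <- integrate_trio_candidates(NULL, list(), trio)
  expect_equal(nrow(empty), 0)
})

test_that("non-carrier fetal records never become candidates", {
  trio <- test_trio()
  v <- rbind(variant_row(fetus_gt = "0/0", father_gt = "0/1"),
             variant_row(fetus_gt = "0/1", pos = 600L))
  cand <- integrate_trio_candidates(v, list(), trio)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 600)
})

test_that("inheritance rules are applied in order", {
  trio <- test_trio("male")
  cases <- list(
    list(v = variant_row(fetus_gt = "0/1"), lab = "de_novo"),
    list(v = variant_row(chrom = "X", fetus_gt = "1", mother_gt = "0/1",
                         father_gt = "0"), lab = "x_linked_maternal"),
    list(v = variant_row(fetus_gt = "1/1", father_gt = "0/1",
                         mother_gt = "0/1"), lab = "biparental_homozygous"),
    list(v = variant_row(fetus_gt = "0/1", father_gt = "0/1"),
         lab = "paternal"),
    list(v = variant_row(fetus_gt = "0/1", mother_gt = "0/1"),
         lab = "maternal"),
    list(v = variant_row(fetus_gt = "0/1", father_gt = "0/1",
                         mother_gt = "0/1"), lab = "unclassified"))
  for (cs in cases) {
    cand <- classify_inheritance(
      integrate_trio_candidates(cs$v, list(), trio), trio)
    expect_equal(cand$inheritance, cs$lab)
  }
  # an X de novo in a male fetus is still de novo (rule 1 precedes XL)
  x_dn <- variant_row(chrom = "X", fetus_gt = "1", father_gt = "0",
                      mother_gt = "0/0")
  cand <- classify_inheritance(
    integrate_trio_candidates(x_dn, list(), trio), trio)
  expect_equal(cand$inheritance, "de_novo")
})

comphet_candidates <- function(trio, v_list, cnvs = list()) {
  cand <- integrate_trio_candidates(
    if (length(v_list)) do.call(rbind, v_list) else NULL, cnvs, trio)
  classify_inheritance(cand, trio)
}

test_that("CNV+SNV in trans yields a certain compound het pair", {
  trio <- test_trio()
  cnvs <- list(fetus = cnv_row("FE1", 1e6, 2e6, gene_ids = "G1"),
               father = cnv_row("FA1", 1e6, 2e6, gene_ids = "G1"))
  v <- variant_row(fetus_gt = "0/1", mother_gt = "0/1", pos = 1.5e6)
  cand <- comphet_candidates(trio, list(v), cnvs)
  res <- detect_compound_het(cand, trio)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$phase_confidence, "certain")
  expect_setequal(res$candidates$inheritance, "compound_heterozygous")
  expect_setequal(res$candidates$kind[c(res$pairs$first, res$pairs$second)],
                  c("cnv", "variant"))
})

test_that("same-origin and de novo pairings follow the phase rules", {
  trio <- test_trio()
  # two maternal hets in one gene: cis by origin, no pair
  v1 <- variant_row(fetus_gt = "0/1", mother_gt = "0/1", pos = 100L,
                    site_id = "a")
  v2 <- variant_row(fetus_gt = "0/1", mother_gt = "0/1", pos = 200L,
                    site_id = "b")
  res <- detect_compound_het(comphet_candidates(trio, list(v1, v2)), trio)
  expect_equal(nrow(res$pairs), 0)

  # de novo + paternal: possible
  v3 <- variant_row(fetus_gt = "0/1", pos = 100L, site_id = "a")
  v4 <- variant_row(fetus_gt = "0/1", father_gt = "0/1", pos = 200L,
                    site_id = "b")
  res2 <- detect_compound_het(comphet_candidates(trio, list(v3, v4)), trio)
  expect_equal(res2$pairs$phase_confidence, "possible")
  # possible pairs keep their original labels
  expect_setequal(res2$candidates$inheritance, c("de_novo", "paternal"))

  # homozygous fetus genotypes are not comphet-eligible
  v5 <- variant_row(fetus_gt = "1/1", father_gt = "0/1", mother_gt = "0/1",
                    pos = 100L, site_id = "a")
  v6 <- variant_row(fetus_gt = "0/1", father_gt = "0/1", pos = 200L,
                    site_id = "b")
  res3 <- detect_compound_het(comphet_candidates(trio, list(v5, v6)), trio)
  expect_equal(nrow(res3$pairs), 0)
})

test_that("pair detection is symmetric in input order", {
  trio <- test_trio()
  v1 <- variant_row(fetus_gt = "0/1", father_gt = "0/1", pos = 100L,
                    site_id = "a")
  v2 <- variant_row(fetus_gt = "0/1", mother_gt = "0/1", pos = 200L,
                    site_id = "b")
  r12 <- detect_compound_het(comphet_candidates(trio, list(v1, v2)), trio)
  r21 <- detect_compound_het(comphet_candidates(trio, list(v2, v1)), trio)
  expect_equal(r12$pairs, r21$pairs)
})

test_that("double diagnosis requires both a CNV and a variant", {
  trio <- test_trio()
  cnv <- integrate_trio_candidates(NULL,
                                   list(fetus = cnv_row("FE1", 1e6, 2e6)),
                                   trio)
  v <- integrate_trio_candidates(variant_row(), list(), trio)
  both <- rbind(cnv, v)
  expect_true(summarize_diagnosis(both, trio)$double_diagnosis)
  expect_false(summarize_diagnosis(cnv, trio)$double_diagnosis)
  undiag <- summarize_diagnosis(both[0, ], trio)
  expect_false(undiag$diagnosed)
  expect_false(undiag$double_diagnosis)
})

test_that("bundled double-diagnosis findings behave as double diagnoses", {
  tab <- read.delim(system.file("extdata", "double_diagnosis_findings.tsv",
                                package = "prenataldx"),
                    stringsAsFactors = FALSE)
  expect_equal(length(unique(tab$fetus_id)), 10)
  for (fid in unique(tab$fetus_id)) {
    fnd <- tab[tab$fetus_id == fid, ]
    trio <- make_trio(fid, paste0(fid, "_F"), paste0(fid, "_M"),
                      paste0(fid, "_C"), "male")
    d <- summarize_diagnosis(fnd, trio)
    expect_true(d$double_diagnosis, info = fid)
  }
  # the two compound-het fetuses pair a CNV with a variant in one gene
  ch <- tab[tab$inheritance == "compound_heterozygous", ]
  expect_setequal(unique(ch$fetus_id), c("FetalC0862", "FetalC1595"))
  for (fid in unique(ch$fetus_id)) {
    fnd <- ch[ch$fetus_id == fid, ]
    expect_setequal(fnd$kind, c("cnv", "variant"))
    expect_equal(length(unique(fnd$genes)), 1)
  }
})

test_that("Mendelian-only cohorts produce zero de novo labels", {
  model <- small_model(seed = 2)
  cohort <- simulate_trio_cohort(
    model, 20, rates = list(denovo_rate = 0, causal_fraction = 0),
    seed = 13, lowqual_fraction = 0)
  labs <- unlist(lapply(seq_len(20), function(i)
    analyze_cohort_trio(cohort, i, filter = FALSE)$candidates$inheritance))
  expect_false("de_novo" %in% labs)
})

test_that("planted mechanisms are recovered with exact labels", {
  expect_equal(run_mechanism_recovery(30, seed = 21), 1.0)
})
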