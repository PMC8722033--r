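# Trio cohort simulator: parental genotypes from population allele
# frequencies, fetal genotypes by Mendelian transmission, plus designated
# causal mechanisms (AD de novo, AR homozygous, AR compound het SNV+SNV or
# CNV+SNV, X-linked maternal) with matching phenotype profiles.

.GT_HET <- "0/1"; .GT_REF <- "0/0"; .GT_HOM <- "1/1"

# draw one transmitted allele from a diploid genotype string
.transmit <- function(gt) {
  al <- strsplit(gt, "/", fixed = TRUE)[[1]]
  al[sample.int(length(al), 1L)]
}

.hwe_genotype <- function(af) {
  a1 <- stats::rbinom(1, 1, af); a2 <- stats::rbinom(1, 1, af)
  paste(sort(c(a1, a2)), collapse = "/")
}

#' Check Mendelian consistency of a fetal genotype
#'
#' @param fetus,father,mother genotype strings (`0/0`, `0/1`, `1/1`, or
#'   hemizygous `0`/`1` for male X).
#' @param chrom chromosome name; `"X"` triggers hemizygous logic.
#' @param fetal_sex `"male"` or `"female"`.
#' @return TRUE iff the fetal genotype can arise by transmission.
#' @export
mendelian_consistent <- function(fetus, father, mother, chrom = "1",
                                 fetal_sex = "female") {
  alleles <- function(gt) strsplit(gt, "/", fixed = TRUE)[[1]]
  m <- alleles(mother)
  if (chrom == "X" && fetal_sex == "male") {
    return(alleles(fetus) %in% m)  # single maternal allele
  }
  f <- alleles(father)  # on X a hemizygous father contributes his one allele
  fe <- alleles(fetus)
  if (length(fe) != 2) return(FALSE)
  any(outer(f, m, function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "/")
  }) == paste(sort(fe), collapse = "/"))
}

# clean per-member quality triple (GQ, DP, lowq_frac)
.clean_quality <- function(n) {
  data.frame(gq = sample(40:99, n, replace = TRUE),
             dp = stats::rpois(n, 40) + 10L,
             lqf = round(stats::runif(n, 0, 0.2), 3))
}

.bad_quality <- function(n) {
  mode <- sample(1:3, n, replace = TRUE)
  data.frame(gq = ifelse(mode == 1, sample(0:14, n, replace = TRUE),
                         sample(40:99, n, replace = TRUE)),
             dp = ifelse(mode == 2, sample(0:2, n, replace = TRUE),
                         stats::rpois(n, 40) + 10L),
             lqf = round(ifelse(mode == 3, stats::runif(n, 0.4, 1),
                                stats::runif(n, 0, 0.2)), 3))
}

#' Simulate a trio cohort with planted diagnostic mechanisms
#'
#' Generates `n_trios` father-mother-fetus trios. Each trio receives
#' background variants at shared panel sites (parental genotypes in
#' Hardy-Weinberg proportions, fetal genotypes by transmission), background
#' de novo alleles at `rates$denovo_rate` per site, and -- for a
#' `rates$causal_fraction` of trios -- one designated causal mechanism:
#' autosomal-dominant de novo, autosomal-recessive homozygous, AR compound
#' heterozygous (SNV+SNV), AR compound heterozygous combining an inherited
#' gene-overlapping CNV with a het variant from the other parent, or
#' X-linked maternal in a male fetus. Fetal phenotype profiles are the
#' causal gene's ontology terms with per-term dropout plus decoy terms.
#'
#' @param model a `genome_model`.
#' @param n_trios number of trios.
#' @param rates list; recognized elements (defaults in parentheses):
#'   `denovo_rate` (0.001, per background site), `causal_fraction` (0.25),
#'   `xl_fraction` (0.05), `ar_fraction` (0.1) as fractions of causal trios,
#'   `comphet_snv_fraction` (0.25) and `comphet_cnv_snv_fraction` (0.25) as
#'   fractions of AR trios (the remainder are homozygous).
#' @param seed integer seed.
#' @param n_background_sites shared panel size (default 30).
#' @param male_prob probability a fetus is male (default 0.58).
#' @param term_dropout per-term dropout probability for causal phenotype
#'   terms (default 0.2).
#' @param n_decoy_terms decoy terms added per profile (default 2).
#' @param lowqual_fraction fraction of background records given failing
#'   quality fields (default 0.05).
#' @return list of class `trio_cohort` with `trios` (trio_id, member ids,
#'   fetal_sex), `variants` (one row per trio x site with per-member
#'   GT/GQ/DP/lowq_frac), `cnvs` (per-member planted CNVs), `phenotypes`
#'   (named list of term vectors), and `truth` (mechanisms, planted
#'   variants/CNVs, causal findings incl. compound-het pairs).
#' @export
simulate_trio_cohort <- function(model, n_trios,
                                 rates = list(), seed = 1L,
                                 n_background_sites = 30L,
                                 male_prob = 0.58,
                                 term_dropout = 0.2, n_decoy_terms = 2L,
                                 lowqual_fraction = 0.05) {
  r <- utils::modifyList(list(
    denovo_rate = 0.001, causal_fraction = 0.25, xl_fraction = 0.05,
    ar_fraction = 0.1, comphet_snv_fraction = 0.25,
    comphet_cnv_snv_fraction = 0.25), rates)
  for (nm in names(r))
    .check(r[[nm]] >= 0 && r[[nm]] <= 1, "rate '%s' must be in [0,1]", nm)
  set.seed(seed)

  genes <- model$genes
  onto <- model$ontology
  bases <- c("A", "C", "G", "T")
  ad_genes <- genes$gene_id[genes$inheritance_mode == "AD"]
  ar_genes <- genes$gene_id[genes$inheritance_mode == "AR"]
  xl_genes <- genes$gene_id[genes$inheritance_mode == "XL"]

  # shared background site panel (autosomal + X), common-ish benign alleles
  panel_rows <- sample.int(nrow(genes), n_background_sites, replace = TRUE)
  panel <- data.frame(
    site_id = sprintf("BG%04d", seq_len(n_background_sites)),
    chrom = genes$chrom[panel_rows],
    pos = genes$start[panel_rows] +
      sample.int(1000L, n_background_sites, replace = TRUE),
    gene_id = genes$gene_id[panel_rows],
    af = round(stats::runif(n_background_sites, 0.02, 0.3), 4),
    consequence = sample(c("synonymous", "intronic", "missense", "other"),
                         n_background_sites, replace = TRUE,
                         prob = c(0.4, 0.3, 0.25, 0.05)),
    stringsAsFactors = FALSE)
  panel$ref <- sample(bases, n_background_sites, replace = TRUE)
  panel$alt <- vapply(panel$ref, function(x) sample(setdiff(bases, x), 1L), "")

  trios <- data.frame(
    trio_id = sprintf("TRIO%04d", seq_len(n_trios)),
    father_id = sprintf("FA%04d", seq_len(n_trios)),
    mother_id = sprintf("MO%04d", seq_len(n_trios)),
    fetus_id = sprintf("FE%04d", seq_len(n_trios)),
    fetal_sex = ifelse(stats::runif(n_trios) < male_prob, "male", "female"),
    stringsAsFactors = FALSE)

  # designate mechanisms
  mech <- rep("none", n_trios)
  causal <- stats::runif(n_trios) < r$causal_fraction
  for (i in which(causal)) {
    u <- stats::runif(1)
    if (u < r$xl_fraction) {
      mech[i] <- "xl_maternal"
      trios$fetal_sex[i] <- "male"  # mechanism requires a male fetus
    } else if (u < r$xl_fraction + r$ar_fraction) {
      v <- stats::runif(1)
      mech[i] <- if (v < r$comphet_cnv_snv_fraction) "ar_comphet_cnv_snv"
      else if (v < r$comphet_cnv_snv_fraction + r$comphet_snv_fraction)
        "ar_comphet_snv" else "ar_homozygous"
    } else mech[i] <- "ad_denovo"
  }

  variants <- list(); cnvs <- list(); phen <- list()
  truth_var <- list(); truth_cnv <- list(); findings <- list()
  causal_gene <- rep(NA_character_, n_trios)
  vrow <- 0L

  add_variant <- function(trio, site, f_gt, m_gt, fe_gt, quality = NULL) {
    vrow <<- vrow + 1L
    q <- if (is.null(quality)) .clean_quality(3L) else quality
    variants[[vrow]] <<- data.frame(
      trio_id = trio$trio_id, site_id = site$site_id, chrom = site$chrom,
      pos = site$pos, ref = site$ref, alt = site$alt,
      gene_id = site$gene_id, consequence = site$consequence,
      population_af = site$af,
      father_gt = f_gt, father_gq = q$gq[1], father_dp = q$dp[1],
      father_lqf = q$lqf[1],
      mother_gt = m_gt, mother_gq = q$gq[2], mother_dp = q$dp[2],
      mother_lqf = q$lqf[2],
      fetus_gt = fe_gt, fetus_gq = q$gq[3], fetus_dp = q$dp[3],
      fetus_lqf = q$lqf[3],
      stringsAsFactors = FALSE)
    vrow
  }

  new_site <- function(id, gene_id, consequence, af) {
    g <- genes[genes$gene_id == gene_id, ]
    ref <- sample(bases, 1L)
    list(site_id = id, chrom = g$chrom,
         pos = g$start + sample.int(g$end - g$start, 1L),
         gene_id = gene_id, consequence = consequence, af = af,
         ref = ref, alt = sample(setdiff(bases, ref), 1L))
  }

  for (i in seq_len(n_trios)) {
    trio <- trios[i, ]
    male <- trio$fetal_sex == "male"

    # background sites
    for (s in seq_len(nrow(panel))) {
      site <- as.list(panel[s, ])
      on_x <- site$chrom == "X"
      f_gt <- if (on_x) as.character(stats::rbinom(1, 1, site$af))
      else .hwe_genotype(site$af)
      m_gt <- .hwe_genotype(site$af)
      if (on_x && male) {
        fe_gt <- .transmit(m_gt)
      } else {
        fe_al <- sort(c(if (on_x) f_gt else .transmit(f_gt), .transmit(m_gt)))
        fe_gt <- paste(fe_al, collapse = "/")
      }
      # background de novo injection
      if (stats::runif(1) < r$denovo_rate) {
        if (on_x && male) fe_gt <- "1"
        else if (fe_gt == .GT_REF) fe_gt <- .GT_HET
        else if (fe_gt == .GT_HET) fe_gt <- .GT_HOM
        truth_var[[length(truth_var) + 1L]] <- data.frame(
          trio_id = trio$trio_id, site_id = site$site_id, origin = "denovo",
          role = "background", stringsAsFactors = FALSE)
      }
      # skip rows where nobody carries and nothing was planted
      if (all(c(f_gt, m_gt, fe_gt) %in% c(.GT_REF, "0"))) next
      q <- if (stats::runif(1) < lowqual_fraction) .bad_quality(3L) else NULL
      add_variant(trio, site, f_gt, m_gt, fe_gt, q)
    }

    # causal mechanism
    mk <- mech[i]
    tf <- list()
    if (mk == "ad_denovo") {
      g <- sample(ad_genes, 1L); causal_gene[i] <- g
      site <- new_site(sprintf("CAU%04da", i), g,
                       sample(c("truncating", "missense"), 1L, prob = c(.5, .5)),
                       0)
      idx <- add_variant(trio, site, .GT_REF, .GT_REF, .GT_HET)
      tf <- list(data.frame(kind = "variant", site_id = site$site_id,
                            gene_id = g, origin = "denovo",
                            stringsAsFactors = FALSE))
    } else if (mk == "ar_homozygous") {
      g <- sample(ar_genes, 1L); causal_gene[i] <- g
      site <- new_site(sprintf("CAU%04da", i), g, "missense",
                       round(stats::runif(1, 5e-4, 5e-3), 5))
      add_variant(trio, site, .GT_HET, .GT_HET, .GT_HOM)
      tf <- list(data.frame(kind = "variant", site_id = site$site_id,
                            gene_id = g, origin = "biparental",
                            stringsAsFactors = FALSE))
    } else if (mk == "ar_comphet_snv") {
      g <- sample(ar_genes, 1L); causal_gene[i] <- g
      s1 <- new_site(sprintf("CAU%04da", i), g, "truncating",
                     round(stats::runif(1, 5e-4, 5e-3), 5))
      s2 <- new_site(sprintf("CAU%04db", i), g, "missense",
                     round(stats::runif(1, 5e-4, 5e-3), 5))
      add_variant(trio, s1, .GT_HET, .GT_REF, .GT_HET)   # paternal
      add_variant(trio, s2, .GT_REF, .GT_HET, .GT_HET)   # maternal
      tf <- list(data.frame(kind = "variant",
                            site_id = c(s1$site_id, s2$site_id),
                            gene_id = g, origin = c("pat", "mat"),
                            stringsAsFactors = FALSE))
    } else if (mk == "ar_comphet_cnv_snv") {
      g <- sample(ar_genes, 1L); causal_gene[i] <- g
      grow <- genes[genes$gene_id == g, ]
      cnv_parent <- sample(c("pat", "mat"), 1L)
      carrier <- if (cnv_parent == "pat") trio$father_id else trio$mother_id
      member <- if (cnv_parent == "pat") "father" else "mother"
      for (who in list(c(trio$fetus_id, "fetus"), c(carrier, member))) {
        truth_cnv[[length(truth_cnv) + 1L]] <- data.frame(
          trio_id = trio$trio_id, sample_id = who[1], member = who[2],
          chrom = grow$chrom, start = grow$start, end = grow$end,
          copies = 1, state = "loss", parental_origin = cnv_parent,
          gene_id = g, stringsAsFactors = FALSE)
      }
      site <- new_site(sprintf("CAU%04da", i), g, "missense",
                       round(stats::runif(1, 5e-4, 5e-3), 5))
      if (cnv_parent == "pat") add_variant(trio, site, .GT_REF, .GT_HET, .GT_HET)
      else add_variant(trio, site, .GT_HET, .GT_REF, .GT_HET)
      tf <- list(
        data.frame(kind = "cnv", site_id = NA_character_, gene_id = g,
                   origin = cnv_parent, stringsAsFactors = FALSE),
        data.frame(kind = "variant", site_id = site$site_id, gene_id = g,
                   origin = if (cnv_parent == "pat") "mat" else "pat",
                   stringsAsFactors = FALSE))
    } else if (mk == "xl_maternal") {
      g <- sample(xl_genes, 1L); causal_gene[i] <- g
      site <- new_site(sprintf("CAU%04da", i), g,
                       sample(c("truncating", "missense"), 1L), 0)
      add_variant(trio, site, "0", .GT_HET, "1")
      tf <- list(data.frame(kind = "variant", site_id = site$site_id,
                            gene_id = g, origin = "mat",
                            stringsAsFactors = FALSE))
    }
    if (length(tf) > 0)
      findings[[trio$trio_id]] <- do.call(rbind, tf)

    # phenotype profile
    if (!is.na(causal_gene[i])) {
      terms <- onto$gene_annotations[[causal_gene[i]]]
      keep <- terms[stats::runif(length(terms)) >= term_dropout]
      if (length(keep) == 0) keep <- sample(terms, 1L)
      decoys <- sample(setdiff(onto$terms, c(term_closure(keep, onto))),
                       n_decoy_terms)
      phen[[trio$trio_id]] <- unique(c(keep, decoys))
    } else {
      phen[[trio$trio_id]] <- sample(setdiff(onto$terms, onto$root),
                                     n_decoy_terms + 1L)
    }
  }

  variants <- if (vrow > 0) do.call(rbind, variants) else
    utils::head(data.frame(), 0)
  rownames(variants) <- NULL
  truth <- list(
    mechanisms = data.frame(trio_id = trios$trio_id, mechanism = mech,
                            gene_id = causal_gene, stringsAsFactors = FALSE),
    planted_variants = if (length(truth_var)) do.call(rbind, truth_var) else NULL,
    planted_cnvs = if (length(truth_cnv)) do.call(rbind, truth_cnv) else NULL,
    causal_findings = findings)
  structure(list(trios = trios, variants = variants,
                 cnvs = truth$planted_cnvs, phenotypes = phen, truth = truth,
                 panel = panel),
            class = "trio_cohort")
}
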