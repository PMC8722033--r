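# Plain-text fixture I/O: VCF (v4.2, GT:GQ:DP:LQF), BED, TSV count
# matrices, JSON ontology/phenotypes/truth, 6-column PED. Writing then
# reading reproduces the in-memory objects exactly.

#' Write a trio cohort VCF
#'
#' VCF v4.2 with one column per cohort sample and FORMAT `GT:GQ:DP:LQF`
#' (`LQF` = fraction of low-quality bases at the site, this toolkit's
#' dialect). Site-level `INFO` carries `SID` (site id), `GENE`, `CSQ`
#' (consequence) and `AF` (population allele frequency). Samples without a
#' record at a site are written as `0/0` with missing quality fields.
#'
#' @param cohort a `trio_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(cohort, path) {
  v <- cohort$variants
  trios <- cohort$trios
  samples <- as.vector(t(as.matrix(trios[c("father_id", "mother_id",
                                           "fetus_id")])))
  key <- paste(v$chrom, v$pos, v$ref, v$alt, v$site_id, sep = "\r")
  sites <- v[!duplicated(key), c("site_id", "chrom", "pos", "ref", "alt",
                                 "gene_id", "consequence", "population_af")]
  ord <- order(sites$chrom, sites$pos, sites$site_id)
  sites <- sites[ord, , drop = FALSE]

  gt <- matrix("0/0:.:.:.", nrow(sites), length(samples),
               dimnames = list(sites$site_id, samples))
  member_ids <- list(father = trios$father_id, mother = trios$mother_id,
                     fetus = trios$fetus_id)
  for (r in seq_len(nrow(v))) {
    ti <- match(v$trio_id[r], trios$trio_id)
    for (mb in names(member_ids)) {
      gt[v$site_id[r], member_ids[[mb]][ti]] <- sprintf(
        "%s:%d:%d:%s", v[[paste0(mb, "_gt")]][r],
        v[[paste0(mb, "_gq")]][r], v[[paste0(mb, "_dp")]][r],
        format(v[[paste0(mb, "_lqf")]][r], trim = TRUE))
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SID,Number=1,Type=String,Description="Site id">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene id">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Population allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=LQF,Number=1,Type=Float,Description="Fraction of low-quality bases at the site">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    info <- sprintf("SID=%s;GENE=%s;CSQ=%s;AF=%s", sites$site_id[i],
                    sites$gene_id[i], sites$consequence[i],
                    format(sites$population_af[i], trim = TRUE,
                           scientific = FALSE))
    paste(c(sites$chrom[i], sites$pos[i], sites$site_id[i], sites$ref[i],
            sites$alt[i], ".", "PASS", info, "GT:GQ:DP:LQF",
            gt[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a trio cohort VCF back into a variants table
#'
#' Inverse of [write_trio_vcf()]: a (trio, site) row is reconstructed
#' whenever all three members carry non-missing quality fields.
#'
#' @param path VCF file.
#' @param trios trio table (`trio_id`, `father_id`, `mother_id`,
#'   `fetus_id`).
#' @return variants data.frame in [simulate_trio_cohort()] layout.
#' @export
read_trio_vcf <- function(path, trios) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  lqf <- vcfR::extract.gt(vcf, element = "LQF", as.numeric = TRUE)
  info1 <- function(key) vcfR::extract.info(vcf, element = key)
  sid <- info1("SID"); gene <- info1("GENE"); csq <- info1("CSQ")
  af <- as.numeric(info1("AF"))
  out <- list()
  for (ti in seq_len(nrow(trios))) {
    f <- trios$father_id[ti]; m <- trios$mother_id[ti]
    fe <- trios$fetus_id[ti]
    have <- !is.na(gq[, f]) & !is.na(gq[, m]) & !is.na(gq[, fe])
    if (!any(have)) next
    idx <- which(have)
    out[[length(out) + 1L]] <- data.frame(
      trio_id = trios$trio_id[ti], site_id = sid[idx],
      chrom = fix$CHROM[idx], pos = as.numeric(fix$POS[idx]),
      ref = fix$REF[idx], alt = fix$ALT[idx], gene_id = gene[idx],
      consequence = csq[idx], population_af = af[idx],
      father_gt = unname(gt[idx, f]), father_gq = as.integer(gq[idx, f]),
      father_dp = as.integer(dp[idx, f]), father_lqf = lqf[idx, f],
      mother_gt = unname(gt[idx, m]), mother_gq = as.integer(gq[idx, m]),
      mother_dp = as.integer(dp[idx, m]), mother_lqf = lqf[idx, m],
      fetus_gt = unname(gt[idx, fe]), fetus_gq = as.integer(gq[idx, fe]),
      fetus_dp = as.integer(dp[idx, fe]), fetus_lqf = lqf[idx, fe],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write CNV intervals as BED
#'
#' 0-based half-open BED6+ rows: name = sample id, score = copies, then any
#' remaining columns.
#'
#' @param cnvs data.frame with `chrom`, `start`, `end`, `sample_id`,
#'   `copies`, and optional extra columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cnv_bed <- function(cnvs, path) {
  extra <- setdiff(names(cnvs), c("chrom", "start", "end", "sample_id",
                                  "copies"))
  bed <- data.frame(chrom = cnvs$chrom, start = cnvs$start, end = cnvs$end,
                    name = cnvs$sample_id, score = cnvs$copies,
                    strand = rep(".", nrow(cnvs)), stringsAsFactors = FALSE)
  if (length(extra) > 0) bed <- cbind(bed, cnvs[extra])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a CNV BED written by [write_cnv_bed()]
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `sample_id`, `copies`
#'   plus extra columns.
#' @export
read_cnv_bed <- function(path) {
  bed <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(bed)[names(bed) == "name"] <- "sample_id"
  names(bed)[names(bed) == "score"] <- "copies"
  bed$strand <- NULL
  bed
}

#' Write / read a bin-count matrix TSV
#'
#' Columns: `chrom`, `start`, `end`, then one column per sample.
#' @param sim a `lowpass_sim` (or any list with `bins` and `counts`).
#' @param path file path.
#' @return `path` invisibly; the reader returns a list with `bins`,
#'   `counts`, `sample_ids` accepted by [normalize_batch()].
#' @export
write_bincounts_tsv <- function(sim, path) {
  utils::write.table(cbind(sim$bins, sim$counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bincounts_tsv
#' @export
read_bincounts_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  bins <- tab[c("chrom", "start", "end")]
  counts <- as.matrix(tab[setdiff(names(tab), names(bins))])
  bins$chrom <- as.character(bins$chrom)
  list(bins = bins, counts = counts, sample_ids = colnames(counts))
}

#' Write / read an exon-depth matrix TSV
#'
#' Columns: `chrom`, `start`, `end`, `gene_id`, then one column per sample
#' (exons as rows; the in-memory orientation is samples x exons).
#' @param sim an `exon_sim` (or list with `exons` and `depths`).
#' @param path file path.
#' @return `path` invisibly; the reader returns a list with `depths`
#'   (samples x exons) and `exons`.
#' @export
write_exondepth_tsv <- function(sim, path) {
  utils::write.table(cbind(sim$exons, t(sim$depths)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exondepth_tsv
#' @export
read_exondepth_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- c("chrom", "start", "end", "gene_id")
  exons <- tab[meta]
  exons$chrom <- as.character(exons$chrom)
  depths <- t(as.matrix(tab[setdiff(names(tab), meta)]))
  colnames(depths) <- paste(exons$chrom, exons$start, sep = ":")
  list(depths = depths, exons = exons)
}

#' Serialize / deserialize a toy ontology as JSON
#' @param onto a `toy_ontology`.
#' @param path file path.
#' @return `path` invisibly; the reader returns a `toy_ontology`.
#' @export
write_ontology_json <- function(onto, path) {
  jsonlite::write_json(list(root = onto$root, terms = onto$terms,
                            parents = onto$parents,
                            gene_annotations = onto$gene_annotations),
                       path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ontology_json
#' @export
read_ontology_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  toy_ontology(x$terms, as.list(x$parents), as.list(x$gene_annotations),
               x$root)
}

#' Write cohort fixture files
#'
#' Writes whatever artifacts are supplied into `out_dir`: `trios.vcf`,
#' `trios.ped`, `truth_cnv.bed`, `bincounts.tsv`, `exondepth.tsv`,
#' `ontology.json`, `phenotypes.json`, `truth.json`. Reading the files back
#' with the paired readers reproduces the objects.
#'
#' @param out_dir output directory (created if needed).
#' @param model optional `genome_model` (provides the ontology).
#' @param lowpass optional `lowpass_sim`.
#' @param exonsim optional `exon_sim`.
#' @param cohort optional `trio_cohort`.
#' @return named character vector of written paths.
#' @export
write_fixtures <- function(out_dir, model = NULL, lowpass = NULL,
                           exonsim = NULL, cohort = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .check(dir.exists(out_dir), "cannot create output directory '%s'", out_dir)
  paths <- character(0)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(cohort)) {
    paths["vcf"] <- write_trio_vcf(cohort, p("trios.vcf"))
    ped <- data.frame(fam = cohort$trios$trio_id,
                      id = cohort$trios$fetus_id,
                      father = cohort$trios$father_id,
                      mother = cohort$trios$mother_id,
                      sex = ifelse(cohort$trios$fetal_sex == "male", 1L, 2L),
                      phenotype = 2L)
    parents <- data.frame(
      fam = rep(cohort$trios$trio_id, 2),
      id = c(cohort$trios$father_id, cohort$trios$mother_id),
      father = "0", mother = "0",
      sex = rep(c(1L, 2L), each = nrow(cohort$trios)), phenotype = 1L)
    utils::write.table(rbind(parents, ped), p("trios.ped"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths["ped"] <- p("trios.ped")
    jsonlite::write_json(cohort$phenotypes, p("phenotypes.json"),
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
    paths["phenotypes"] <- p("phenotypes.json")
    jsonlite::write_json(cohort$truth, p("truth.json"), auto_unbox = FALSE,
                         digits = NA, pretty = TRUE, null = "null")
    paths["truth"] <- p("truth.json")
    if (!is.null(cohort$cnvs))
      paths["truth_cnv"] <- write_cnv_bed(cohort$cnvs, p("truth_cnv.bed"))
  }
  if (!is.null(lowpass)) {
    paths["bincounts"] <- write_bincounts_tsv(lowpass, p("bincounts.tsv"))
    if (!is.null(lowpass$truth) && is.null(paths["truth_cnv"]))
      paths["truth_cnv"] <- write_cnv_bed(lowpass$truth, p("truth_cnv.bed"))
  }
  if (!is.null(exonsim))
    paths["exondepth"] <- write_exondepth_tsv(exonsim, p("exondepth.tsv"))
  if (!is.null(model))
    paths["ontology"] <- write_ontology_json(model$ontology,
                                             p("ontology.json"))
  paths
}

#' Read a phenotypes JSON (trio id -> term vector)
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_phenotypes_json <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.character)
}

#' Read a 6-column PED file into a trio table
#' @param path PED file (fam, id, father, mother, sex, phenotype; no header).
#' @return data.frame `trio_id`, `father_id`, `mother_id`, `fetus_id`,
#'   `fetal_sex` (one row per offspring line).
#' @export
read_ped <- function(path) {
  ped <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fam", "id", "father", "mother",
                                         "sex", "phenotype"))
  off <- ped[ped$father != "0" & ped$mother != "0", , drop = FALSE]
  data.frame(trio_id = off$fam, father_id = off$father,
             mother_id = off$mother, fetus_id = off$id,
             fetal_sex = ifelse(off$sex == 1, "male", "female"),
             stringsAsFactors = FALSE)
}
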