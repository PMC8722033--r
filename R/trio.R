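# Trio-level integration: unify fetal variants and CNVs into candidates,
# classify inheritance, detect compound-heterozygous configurations
# (including CNV+SNV in trans), and flag double diagnoses.

#' Construct a trio descriptor
#'
#' @param trio_id label.
#' @param father_id,mother_id,fetus_id distinct sample ids.
#' @param fetal_sex `"male"` or `"female"`.
#' @return list of class `trio`.
#' @export
make_trio <- function(trio_id, father_id, mother_id, fetus_id, fetal_sex) {
  ids <- c(father_id, mother_id, fetus_id)
  .check(length(unique(ids)) == 3, "trio members must be distinct")
  .check(fetal_sex %in% c("male", "female"), "fetal_sex must be male/female")
  structure(list(trio_id = trio_id, father_id = father_id,
                 mother_id = mother_id, fetus_id = fetus_id,
                 fetal_sex = fetal_sex), class = "trio")
}

# fraction of the smaller of the two reciprocal overlaps
.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

#' Annotate CNV calls with overlapped gene ids
#'
#' @param calls CNV call data.frame (`chrom`, `start`, `end`).
#' @param genes gene table (`chrom`, `start`, `end`, `gene_id`).
#' @return `calls` with a `gene_ids` column (comma-joined, possibly empty).
#' @export
annotate_cnv_genes <- function(calls, genes) {
  calls$gene_ids <- vapply(seq_len(nrow(calls)), function(i) {
    hit <- genes$chrom == calls$chrom[i] & genes$start < calls$end[i] &
      genes$end > calls$start[i]
    paste(genes$gene_id[hit], collapse = ",")
  }, "")
  calls
}

.gt_carries <- function(gt) !is.na(gt) & grepl("1", gt, fixed = TRUE)

#' Integrate variants and CNVs into trio candidates
#'
#' Builds one candidate per fetal alteration. Variant candidates keep the
#' trio genotypes; parental presence is carrier status of the genotype. CNV
#' candidates are the fetal calls; a parent is flagged present when it
#' carries a same-state call with at least `min_recip` reciprocal overlap.
#' Output is sorted by (chrom, start) and deterministic.
#'
#' @param variants data.frame of quality-passing variant records for this
#'   trio (columns as produced by [simulate_trio_cohort()]); only records
#'   where the fetus carries the alternate allele become candidates.
#' @param cnvs named list with elements `fetus`, `father`, `mother`, each a
#'   CNV call data.frame (may be empty/NULL); fetal calls need a `gene_ids`
#'   column (see [annotate_cnv_genes()]).
#' @param trio a `trio`.
#' @param min_recip reciprocal-overlap threshold for parental CNV matching
#'   (default 0.5).
#' @return data.frame of candidates: `trio_id`, `kind` (`variant`/`cnv`),
#'   `chrom`, `start`, `end`, `gene_ids`, `consequence`, `population_af`,
#'   genotypes, `copy_number`, `cnv_state`, `father_presence`,
#'   `mother_presence`, `inheritance` (NA, see [classify_inheritance()]),
#'   `phase_confidence`.
#' @export
integrate_trio_candidates <- function(variants, cnvs, trio, min_recip = 0.5) {
  empty <- data.frame(
    trio_id = character(0), kind = character(0), chrom = character(0),
    start = numeric(0), end = numeric(0), gene_ids = character(0),
    consequence = character(0), population_af = numeric(0),
    fetus_gt = character(0), father_gt = character(0),
    mother_gt = character(0), copy_number = numeric(0),
    cnv_state = character(0), father_presence = logical(0),
    mother_presence = logical(0), inheritance = character(0),
    phase_confidence = character(0), stringsAsFactors = FALSE)
  out <- list(empty)

  if (!is.null(variants) && nrow(variants) > 0) {
    v <- variants[.gt_carries(variants$fetus_gt), , drop = FALSE]
    if (nrow(v) > 0)
      out[[length(out) + 1L]] <- data.frame(
        trio_id = trio$trio_id, kind = "variant", chrom = v$chrom,
        start = v$pos, end = v$pos + 1, gene_ids = v$gene_id,
        consequence = v$consequence, population_af = v$population_af,
        fetus_gt = v$fetus_gt, father_gt = v$father_gt,
        mother_gt = v$mother_gt, copy_number = NA_real_,
        cnv_state = NA_character_,
        father_presence = .gt_carries(v$father_gt),
        mother_presence = .gt_carries(v$mother_gt),
        inheritance = NA_character_, phase_confidence = NA_character_,
        stringsAsFactors = FALSE)
  }

  fe <- cnvs$fetus
  if (!is.null(fe) && nrow(fe) > 0) {
    .check(!is.null(fe$gene_ids), "fetal CNV calls need a gene_ids column")
    present_in <- function(parent) {
      p <- cnvs[[parent]]
      vapply(seq_len(nrow(fe)), function(i) {
        if (is.null(p) || nrow(p) == 0) return(FALSE)
        same <- p$chrom == fe$chrom[i] & p$state == fe$state[i]
        any(same & .reciprocal_overlap(fe$start[i], fe$end[i],
                                       p$start, p$end) >= min_recip)
      }, FALSE)
    }
    out[[length(out) + 1L]] <- data.frame(
      trio_id = trio$trio_id, kind = "cnv", chrom = fe$chrom,
      start = fe$start, end = fe$end, gene_ids = fe$gene_ids,
      consequence = NA_character_, population_af = NA_real_,
      fetus_gt = NA_character_, father_gt = NA_character_,
      mother_gt = NA_character_,
      copy_number = if (!is.null(fe$copy_number)) fe$copy_number else
        ifelse(fe$state %in% c("loss", "DEL"), 1, 3),
      cnv_state = fe$state,
      father_presence = present_in("father"),
      mother_presence = present_in("mother"),
      inheritance = NA_character_, phase_confidence = NA_character_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  chrom_lv <- unique(res$chrom)
  res <- res[order(match(res$chrom, chrom_lv), res$start, res$kind), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify inheritance of trio candidates
#'
#' Rules, applied in order per candidate: (1) neither parent carries ->
#' `de_novo`; (2) variant on chrX in a hemizygous male fetus with a
#' heterozygous carrier mother and a non-carrier father ->
#' `x_linked_maternal`; (3) fetus homozygous alternate with both parents
#' carriers -> `biparental_homozygous`; (4) exactly one parent carries ->
#' `paternal` / `maternal`; (5) both carry otherwise -> `unclassified`.
#' `compound_heterozygous` is assigned only by [detect_compound_het()].
#'
#' @param candidates data.frame from [integrate_trio_candidates()].
#' @param trio a `trio`.
#' @param x_chrom name of the X chromosome (default `"X"`).
#' @return `candidates` with the `inheritance` column filled.
#' @export
classify_inheritance <- function(candidates, trio, x_chrom = "X") {
  lab <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cc <- candidates[i, ]
    fp <- isTRUE(cc$father_presence); mp <- isTRUE(cc$mother_presence)
    if (!fp && !mp) { lab[i] <- "de_novo"; next }
    if (cc$kind == "variant" && cc$chrom == x_chrom &&
        trio$fetal_sex == "male" && identical(cc$fetus_gt, "1") &&
        mp && identical(cc$mother_gt, "0/1") && !fp) {
      lab[i] <- "x_linked_maternal"; next
    }
    if (cc$kind == "variant" && identical(cc$fetus_gt, "1/1") && fp && mp) {
      lab[i] <- "biparental_homozygous"; next
    }
    if (fp && !mp) { lab[i] <- "paternal"; next }
    if (mp && !fp) { lab[i] <- "maternal"; next }
    lab[i] <- "unclassified"
  }
  candidates$inheritance <- lab
  candidates
}

# heterozygous carrier status usable for compound-het pairing
.comphet_eligible <- function(cand) {
  if (cand$kind == "variant")
    identical(cand$fetus_gt, "0/1")
  else
    cand$copy_number %in% c(1, 3)
}

#' Detect compound-heterozygous pairs within genes
#'
#' Within each gene, pairs heterozygous carrier candidates (variants or
#' gene-overlapping CNVs) whose parental origins are opposite (one
#' `paternal`, one `maternal`): phase is certain (in trans by origin). A
#' `de_novo` candidate paired with one inherited candidate yields phase
#' confidence `possible` (true phase unknowable from trio genotypes).
#' Same-origin pairs are rejected as cis-by-origin. Members of certain
#' pairs are relabeled `compound_heterozygous`.
#'
#' @param candidates data.frame with `inheritance` filled
#'   (see [classify_inheritance()]).
#' @param trio a `trio`.
#' @return list with `pairs` (data.frame `gene_id`, `first`, `second` row
#'   indices into `candidates`, `phase_confidence`) and `candidates`
#'   (relabeled, `phase_confidence` filled on pair members).
#' @export
detect_compound_het <- function(candidates, trio) {
  pairs <- list()
  genes <- unique(unlist(strsplit(candidates$gene_ids[
    !is.na(candidates$gene_ids)], ",", fixed = TRUE)))
  genes <- sort(setdiff(genes, ""))
  for (g in genes) {
    in_gene <- which(vapply(seq_len(nrow(candidates)), function(i) {
      gl <- strsplit(candidates$gene_ids[i], ",", fixed = TRUE)[[1]]
      g %in% gl
    }, FALSE))
    elig <- in_gene[vapply(in_gene, function(i)
      .comphet_eligible(candidates[i, ]), FALSE)]
    if (length(elig) < 2) next
    for (a in seq_along(elig)) for (b in seq_along(elig)) {
      if (a >= b) next
      i <- elig[a]; j <- elig[b]
      oi <- candidates$inheritance[i]; oj <- candidates$inheritance[j]
      conf <- NULL
      if ((oi == "paternal" && oj == "maternal") ||
          (oi == "maternal" && oj == "paternal")) conf <- "certain"
      else if ((oi == "de_novo" && oj %in% c("paternal", "maternal")) ||
               (oj == "de_novo" && oi %in% c("paternal", "maternal")))
        conf <- "possible"
      if (is.null(conf)) next
      ord <- order(candidates$start[c(i, j)])
      ij <- c(i, j)[ord]
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_id = g, first = ij[1], second = ij[2],
        phase_confidence = conf, stringsAsFactors = FALSE)
      candidates$phase_confidence[ij] <- conf
      if (conf == "certain")
        candidates$inheritance[ij] <- "compound_heterozygous"
    }
  }
  pairs <- if (length(pairs)) unique(do.call(rbind, pairs)) else
    data.frame(gene_id = character(0), first = integer(0),
               second = integer(0), phase_confidence = character(0),
               stringsAsFactors = FALSE)
  list(pairs = pairs, candidates = candidates)
}

#' Summarize a trio's reported findings into a diagnosis
#'
#' @param reported data.frame of candidates with report tier P or LP
#'   (possibly empty).
#' @param trio a `trio`.
#' @param comphet_pairs optional pair table from [detect_compound_het()].
#' @return list of class `diagnosis`: `trio_id`, `findings`, `diagnosed`,
#'   `double_diagnosis` (at least one reported CNV and one reported
#'   variant), `comphet_pairs`.
#' @export
summarize_diagnosis <- function(reported, trio, comphet_pairs = NULL) {
  diagnosed <- !is.null(reported) && nrow(reported) > 0
  dd <- diagnosed && any(reported$kind == "cnv") &&
    any(reported$kind == "variant")
  structure(list(trio_id = trio$trio_id, findings = reported,
                 diagnosed = diagnosed, double_diagnosis = dd,
                 comphet_pairs = comphet_pairs),
            class = "diagnosis")
}
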