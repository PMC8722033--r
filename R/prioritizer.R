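# Phenotype-driven prioritization: information-content match of candidate
# genes against the fetal phenotype profile, allele-frequency and
# consequence filters, and a simplified ("ACMG-lite") report tier.

#' Information-content phenotype match score for one gene
#'
#' Gene-centric Phrank-style score. With `n(t)` the number of genes whose
#' annotation closure contains term `t`, and `n_pa(t)` the number of genes
#' whose closure contains all parents of `t` (for the root, the total number
#' of annotated genes), the marginal information of `t` is
#' \deqn{\Phi(t) = -\log_2(n(t) / n_{pa}(t))}
#' and the score is the sum of \eqn{\Phi(t)} over the intersection of the
#' profile's ancestor closure with the gene's annotation closure. Profiles
#' sharing only the root with a gene score 0 bits.
#'
#' @param profile_terms character vector of phenotype term ids.
#' @param gene_id gene to score (must be annotated in the ontology).
#' @param onto a `toy_ontology`.
#' @return score in bits (non-negative).
#' @export
phrank_score <- function(profile_terms, gene_id, onto) {
  ann <- onto$gene_annotations[[gene_id]]
  .check(!is.null(ann) && length(ann) > 0, "gene '%s' is not annotated",
         gene_id)
  shared <- intersect(term_closure(profile_terms, onto),
                      term_closure(ann, onto))
  if (length(shared) == 0) return(0)
  info <- term_information(onto)
  sum(info[shared])
}

#' Marginal information content of every ontology term
#'
#' @param onto a `toy_ontology`.
#' @return named numeric vector: term -> Phi(t) in bits.
#' @export
term_information <- function(onto) {
  closures <- lapply(onto$gene_annotations, term_closure, onto = onto)
  n_genes <- length(closures)
  n_t <- vapply(onto$terms, function(t)
    sum(vapply(closures, function(cl) t %in% cl, FALSE)), 0)
  phi <- vapply(onto$terms, function(t) {
    pa <- onto$parents[[t]]
    n_pa <- if (is.null(pa) || length(pa) == 0) n_genes
    else sum(vapply(closures, function(cl) all(pa %in% cl), FALSE))
    -log2(n_t[[t]] / n_pa)
  }, 0)
  names(phi) <- onto$terms
  phi
}

#' Score all candidate genes of a trio against its phenotype profile
#'
#' Each candidate's score is the maximum [phrank_score()] over the genes it
#' touches (a CNV may span several genes). Candidates touching no annotated
#' gene score 0.
#'
#' @param candidates candidate data.frame (with `gene_ids`).
#' @param profile_terms phenotype term ids for the trio.
#' @param onto a `toy_ontology`.
#' @return `candidates` with a `phrank_score` column.
#' @export
score_candidates <- function(candidates, profile_terms, onto) {
  candidates$phrank_score <- vapply(seq_len(nrow(candidates)), function(i) {
    gl <- strsplit(candidates$gene_ids[i], ",", fixed = TRUE)[[1]]
    gl <- intersect(gl, names(onto$gene_annotations))
    if (length(gl) == 0) return(0)
    max(vapply(gl, phrank_score, 0, profile_terms = profile_terms,
               onto = onto))
  }, 0)
  candidates
}

.severity_rank <- function(consequence, kind) {
  ifelse(kind == "cnv", 4L,
         c(truncating = 4L, splice_region = 3L, missense = 2L,
           synonymous = 1L, intronic = 1L, other = 1L)[consequence])
}

#' Frequency-filter and rank scored candidates
#'
#' Drops variant candidates whose population allele frequency exceeds the
#' threshold matching their inheritance context: recessive contexts
#' (`biparental_homozygous`, `compound_heterozygous`) use
#' `max_af_recessive`, all others (de novo / dominant) use
#' `max_af_dominant`. Missing AF (and CNVs) are retained. The survivors are
#' ranked by phenotype score (descending), then consequence severity
#' (truncating > splice_region > missense > other; CNVs rank with
#' truncating), then genomic position -- a deterministic total order.
#'
#' @param candidates data.frame with `phrank_score` and `inheritance`.
#' @param max_af_dominant AF cutoff for dominant/de novo context
#'   (default 0.001).
#' @param max_af_recessive AF cutoff for recessive context (default 0.01).
#' @return filtered, ranked data.frame with `rank` and `af_pass` columns
#'   (rows failing the AF filter are dropped).
#' @export
filter_and_rank <- function(candidates, max_af_dominant = 0.001,
                            max_af_recessive = 0.01) {
  if (nrow(candidates) == 0) {
    candidates$rank <- integer(0)
    return(candidates)
  }
  recessive <- candidates$inheritance %in%
    c("biparental_homozygous", "compound_heterozygous")
  cutoff <- ifelse(recessive, max_af_recessive, max_af_dominant)
  keep <- candidates$kind == "cnv" | is.na(candidates$population_af) |
    candidates$population_af <= cutoff
  out <- candidates[keep, , drop = FALSE]
  if (nrow(out) == 0) { out$rank <- integer(0); return(out) }
  sev <- .severity_rank(out$consequence, out$kind)
  chrom_lv <- unique(out$chrom)
  ord <- order(-out$phrank_score, -sev, match(out$chrom, chrom_lv), out$start)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Assign simplified report tiers (ACMG-lite)
#'
#' A deliberately reduced stand-in for full ACMG classification, applied to
#' ranked, filter-passing candidates. Evidence flags per candidate:
#' `de_novo` (inheritance label), `lof` (truncating/splice consequence, or
#' any CNV), `phenotype_match` (positive phenotype score and rank within the
#' top `k`). Tiers: P when lof + de novo + phenotype match, or a CNV
#' overlapping a configured known-syndrome region; LP for any two of the
#' three flags, or a recessive genotype (compound heterozygous or
#' biparental homozygous) in a phenotype-matched gene; VUS otherwise. Only
#' P/LP are reported.
#'
#' @param ranked data.frame from [filter_and_rank()].
#' @param mms_regions optional data.frame of known microdeletion/
#'   microduplication syndrome regions (`chrom`, `start`, `end`); a CNV
#'   overlapping one is tier P.
#' @param top_k rank cutoff for the phenotype-match flag (default 3).
#' @return `ranked` with logical evidence columns and a `tier` column in
#'   `c("P", "LP", "VUS")`.
#' @export
assign_report_tier <- function(ranked, mms_regions = NULL, top_k = 3L) {
  n <- nrow(ranked)
  if (n == 0) { ranked$tier <- character(0); return(ranked) }
  de_novo <- ranked$inheritance == "de_novo"
  lof <- ranked$kind == "cnv" |
    ranked$consequence %in% c("truncating", "splice_region")
  pheno <- ranked$phrank_score > 0 & ranked$rank <= top_k
  in_mms <- rep(FALSE, n)
  if (!is.null(mms_regions) && nrow(mms_regions) > 0) {
    for (i in which(ranked$kind == "cnv")) {
      in_mms[i] <- any(mms_regions$chrom == ranked$chrom[i] &
                         mms_regions$start < ranked$end[i] &
                         mms_regions$end > ranked$start[i])
    }
  }
  recessive <- ranked$inheritance %in%
    c("compound_heterozygous", "biparental_homozygous") & pheno
  tier <- rep("VUS", n)
  tier[(de_novo + lof + pheno) >= 2 | recessive] <- "LP"
  tier[(lof & de_novo & pheno) | in_mms] <- "P"
  ranked$evidence_de_novo <- de_novo
  ranked$evidence_lof <- lof
  ranked$evidence_phenotype_match <- pheno
  ranked$evidence_mms <- in_mms
  ranked$tier <- tier
  ranked
}

#' Prioritize a trio's candidates end to end
#'
#' Convenience wrapper: phenotype scoring, AF filtering and ranking, tier
#' assignment; returns the ranked table and the reported (P/LP) subset.
#'
#' @param candidates labeled candidates (after [classify_inheritance()] and
#'   [detect_compound_het()]).
#' @param profile_terms phenotype terms of the trio.
#' @param onto a `toy_ontology`.
#' @param mms_regions see [assign_report_tier()].
#' @param ... passed to [filter_and_rank()].
#' @return list with `ranked` and `reported`.
#' @export
prioritize_candidates <- function(candidates, profile_terms, onto,
                                  mms_regions = NULL, ...) {
  scored <- score_candidates(candidates, profile_terms, onto)
  ranked <- filter_and_rank(scored, ...)
  ranked <- assign_report_tier(ranked, mms_regions = mms_regions)
  list(ranked = ranked,
       reported = ranked[ranked$tier %in% c("P", "LP"), , drop = FALSE])
}
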