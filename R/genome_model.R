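#' Build a synthetic genome model
#'
#' Constructs the fixed scaffold every simulator draws from: chromosome
#' lengths, a 20 kb binning grid, genes with inheritance modes (autosomal
#' dominant/recessive on autosomes, X-linked on the designated X), exon
#' structures, and a toy phenotype ontology with gene annotations. All
#' coordinates are 0-based half-open.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{chromosomes}{data.frame with columns `name`, `length` (bp); must
#'       include a chromosome named `"X"`.}
#'     \item{bin_size}{bin width in bp (default 20000).}
#'     \item{genes_per_chrom}{genes placed per chromosome (default 8).}
#'     \item{exons_per_gene}{exons per gene (default 10).}
#'     \item{exon_size}{exon width in bp (default 150).}
#'     \item{ontology_depth, ontology_branching}{tree ontology shape
#'       (defaults 3 and 3).}
#'   }
#' @param seed integer seed; the model is a deterministic function of
#'   (config, seed).
#' @return an object of class `genome_model` with elements `chromosomes`,
#'   `bin_size`, `genes`, `exons`, `ontology`.
#' @export
build_genome_model <- function(config = list(), seed = 1L) {
  chrom_default <- data.frame(name = c("1", "2", "X"),
                              length = c(10e6, 10e6, 5e6))
  chrom_user <- config$chromosomes
  config$chromosomes <- NULL
  cfg <- utils::modifyList(list(
    bin_size = 20000L,
    genes_per_chrom = 8L,
    exons_per_gene = 10L,
    exon_size = 150L,
    ontology_depth = 3L,
    ontology_branching = 3L
  ), config)
  cfg$chromosomes <- if (is.null(chrom_user)) chrom_default else chrom_user
  .check(is.data.frame(cfg$chromosomes) && nrow(cfg$chromosomes) > 0,
         "config$chromosomes must be a non-empty data.frame")
  .check(cfg$bin_size > 0, "bin_size must be positive")
  .check("X" %in% cfg$chromosomes$name,
         "chromosome set must include one chromosome named 'X'")
  .check(all(cfg$chromosomes$length > 0), "chromosome lengths must be positive")

  set.seed(seed)
  chroms <- cfg$chromosomes
  chroms$name <- as.character(chroms$name)

  genes <- list(); exons <- list(); gid <- 0L
  for (ci in seq_len(nrow(chroms))) {
    cname <- chroms$name[ci]; clen <- chroms$length[ci]
    n_genes <- cfg$genes_per_chrom
    # gene body: exons + introns; lay genes on an even grid with jitter so
    # spans never overlap
    gene_span <- cfg$exons_per_gene * cfg$exon_size * 20
    slot <- floor(clen / n_genes)
    .check(slot > gene_span, "chromosome %s too short for %d genes",
           cname, n_genes)
    for (g in seq_len(n_genes)) {
      gid <- gid + 1L
      id <- sprintf("GENE%04d", gid)
      start <- (g - 1L) * slot +
        sample.int(max(1L, slot - gene_span), 1L) - 1L
      mode <- if (cname == "X") "XL" else sample(c("AD", "AR"), 1L)
      intron <- floor((gene_span - cfg$exons_per_gene * cfg$exon_size) /
                        max(1L, cfg$exons_per_gene - 1L))
      ex_start <- start + (seq_len(cfg$exons_per_gene) - 1L) *
        (cfg$exon_size + intron)
      exons[[gid]] <- data.frame(
        chrom = cname, start = ex_start, end = ex_start + cfg$exon_size,
        gene_id = id, stringsAsFactors = FALSE)
      genes[[gid]] <- data.frame(
        chrom = cname, start = start, end = start + gene_span,
        gene_id = id, inheritance_mode = mode, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  onto <- build_tree_ontology(cfg$ontology_depth, cfg$ontology_branching,
                              genes$gene_id)
  structure(list(
    chromosomes = chroms,
    bin_size = as.integer(cfg$bin_size),
    genes = genes,
    exons = exons,
    ontology = onto,
    config = cfg,
    seed = as.integer(seed)
  ), class = "genome_model")
}

#' Binning grid of a genome model
#'
#' @param model a `genome_model`.
#' @return data.frame with columns `chrom`, `start`, `end`; contiguous
#'   half-open bins of `bin_size` bp, the terminal bin of each chromosome
#'   possibly shorter.
#' @export
genome_bins <- function(model) {
  b <- model$bin_size
  out <- lapply(seq_len(nrow(model$chromosomes)), function(i) {
    len <- model$chromosomes$length[i]
    starts <- seq(0, len - 1, by = b)
    data.frame(chrom = model$chromosomes$name[i], start = starts,
               end = pmin(starts + b, len), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "genome_model: %d chromosome(s), %.1f Mb, bin %d bp, %d genes, %d exons, %d ontology terms\n",
    nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6, x$bin_size,
    nrow(x$genes), nrow(x$exons), length(x$ontology$terms)))
  invisible(x)
}
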