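# Shared fixture builders for the test suite. Everything is generated in
# code; no binary data.

# small two-chromosome genome (12 Mb autosome + 2 Mb X)
small_model <- function(seed = 1, genes_per_chrom = 4) {
  build_genome_model(list(
    chromosomes = data.frame(name = c("1", "X"), length = c(12e6, 2e6)),
    genes_per_chrom = genes_per_chrom), seed = seed)
}

# hand-built 4-gene ontology matching the worked information-content
# example: root -> A -> {B, C}; root -> D.
# gene annotations: g1 {B}, g2 {C}, g3 {D}, g4 {D}
example_ontology <- function() {
  toy_ontology(
    terms = c("root", "A", "B", "C", "D"),
    parents = list(A = "root", B = "A", C = "A", D = "root"),
    gene_annotations = list(g1 = "B", g2 = "C", g3 = "D", g4 = "D"),
    root = "root")
}

# a default trio descriptor
test_trio <- function(sex = "male") {
  make_trio("T1", "FA1", "MO1", "FE1", sex)
}

# one variant record row with clean quality, overridable fields
variant_row <- function(chrom = "1", pos = 500L, gene_id = "G1",
                        consequence = "missense", population_af = 0,
                        father_gt = "0/0", mother_gt = "0/0",
                        fetus_gt = "0/1", gq = 60L, dp = 40L, lqf = 0.05,
                        trio_id = "T1", site_id = "S1") {
  data.frame(trio_id = trio_id, site_id = site_id, chrom = chrom, pos = pos,
             ref = "A", alt = "T", gene_id = gene_id,
             consequence = consequence, population_af = population_af,
             father_gt = father_gt, father_gq = gq, father_dp = dp,
             father_lqf = lqf,
             mother_gt = mother_gt, mother_gq = gq, mother_dp = dp,
             mother_lqf = lqf,
             fetus_gt = fetus_gt, fetus_gq = gq, fetus_dp = dp,
             fetus_lqf = lqf, stringsAsFactors = FALSE)
}

# wrap a z matrix into a minimal exon_depth_matrix
make_edm <- function(z, chrom = rep("1", ncol(z))) {
  structure(list(
    z = z,
    exons = data.frame(chrom = chrom, start = seq_len(ncol(z)) * 100,
                       end = seq_len(ncol(z)) * 100 + 50,
                       gene_id = paste0("G", cumsum(!duplicated(chrom)))),
    sample_ids = rownames(z)), class = "exon_depth_matrix")
}

# brute-force Viterbi oracle: enumerate all 3^n state paths
viterbi_bruteforce <- function(z, M = 3, p_event = 1e-4, p_stay = 0.9) {
  n <- length(z)
  trans <- matrix(c(p_stay, 1 - p_stay, 0,
                    p_event, 1 - 2 * p_event, p_event,
                    0, 1 - p_stay, p_stay), 3, 3, byrow = TRUE)
  init <- c(p_event, 1 - 2 * p_event, p_event)
  means <- c(-M, 0, M)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  lp <- apply(paths, 1, function(pth) {
    v <- log(init[pth[1]]) + dnorm(z[1], means[pth[1]], 1, log = TRUE)
    if (n > 1) for (t in 2:n)
      v <- v + log(trans[pth[t - 1], pth[t]]) +
        dnorm(z[t], means[pth[t]], 1, log = TRUE)
    v
  })
  as.integer(paths[which.max(lp), ])
}

# enumeration oracle for the exact two-sided Fisher test, written with
# explicit binomial-coefficient arithmetic (no dhyper)
fisher_bruteforce <- function(a, b, c_, d, tie_tol = 1e-7) {
  m <- a + b; n <- c_ + d; k <- a + c_
  tot <- choose(m + n, k)
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / tot, 0)
  obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= obs * (1 + tie_tol)]))
}
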