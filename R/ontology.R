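#' Toy phenotype ontology
#'
#' A minimal HPO-like structure: a rooted directed acyclic graph of phenotype
#' terms plus gene-to-term annotations. It carries just enough structure for
#' information-content phenotype matching: term identity, parent edges, and
#' which genes are annotated with which terms.
#'
#' @param terms character vector of term ids (must include the root).
#' @param parents named list mapping each non-root term id to a character
#'   vector of parent term ids; the root has no entry (or an empty one).
#' @param gene_annotations named list mapping gene ids to character vectors
#'   of term ids (direct annotations).
#' @param root id of the root term.
#' @return an object of class `toy_ontology`.
#' @export
toy_ontology <- function(terms, parents, gene_annotations, root) {
  terms <- unique(as.character(terms))
  .check(root %in% terms, "root term '%s' not in term set", root)
  parents <- parents[intersect(names(parents), terms)]
  bad <- setdiff(unlist(parents, use.names = FALSE), terms)
  .check(length(bad) == 0, "parent edge to unknown term(s): %s",
         paste(bad, collapse = ", "))
  onto <- structure(
    list(terms = terms, parents = parents,
         gene_annotations = gene_annotations, root = root),
    class = "toy_ontology")
  validate_ontology(onto)
  onto
}

#' Validate a toy ontology
#'
#' Checks acyclicity, that every term reaches the root, and that every term
#' is annotated (directly or through a descendant) to at least one gene.
#'
#' @param onto a `toy_ontology`.
#' @return the ontology, invisibly; errors on violation.
#' @export
validate_ontology <- function(onto) {
  for (t in onto$terms) {
    cl <- term_closure(t, onto)
    .check(onto$root %in% cl, "term '%s' does not reach the root", t)
  }
  covered <- unique(unlist(lapply(onto$gene_annotations, term_closure, onto = onto),
                           use.names = FALSE))
  uncov <- setdiff(onto$terms, covered)
  .check(length(uncov) == 0,
         "terms with no annotated gene in their subtree: %s",
         paste(uncov, collapse = ", "))
  invisible(onto)
}

#' Ancestor closure of a term set
#'
#' Union of the given terms with all of their ancestors up to the ontology
#' root. Idempotent; the closure of the empty set is empty.
#'
#' @param terms character vector of term ids.
#' @param onto a `toy_ontology`.
#' @return character vector of term ids (sorted, unique).
#' @export
term_closure <- function(terms, onto) {
  terms <- unique(as.character(terms))
  if (length(terms) == 0) return(character(0))
  unknown <- setdiff(terms, onto$terms)
  .check(length(unknown) == 0, "unknown term id(s): %s",
         paste(unknown, collapse = ", "))
  seen <- character(0)
  frontier <- terms
  # ontology is a DAG with a finite term set, so this terminates; a cycle
  # would stall the frontier without growing `seen`, which we guard against
  while (length(frontier) > 0) {
    new <- setdiff(frontier, seen)
    if (length(new) == 0) break
    seen <- c(seen, new)
    frontier <- unique(unlist(onto$parents[new], use.names = FALSE))
    .check(length(seen) <= length(onto$terms) + 1L,
           "cycle detected in ontology parent edges")
  }
  sort(seen)
}

#' Build a balanced tree ontology
#'
#' Constructs a complete `branching`-ary tree of the given depth (depth 0 is
#' the root alone) and annotates genes with leaf terms such that every leaf
#' is annotated to at least one gene (leaves are dealt round-robin across
#' genes, then each gene receives extra random leaves).
#'
#' @param depth tree depth below the root.
#' @param branching children per internal node.
#' @param gene_ids character vector of gene ids to annotate.
#' @param terms_per_gene target number of direct leaf annotations per gene.
#' @return a `toy_ontology`.
#' @keywords internal
build_tree_ontology <- function(depth, branching, gene_ids, terms_per_gene = 3) {
  .check(depth >= 1, "ontology depth must be >= 1")
  .check(branching >= 1, "ontology branching must be >= 1")
  root <- "HP:0000001"
  terms <- root
  parents <- list()
  level <- root
  idx <- 1L
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) {
      for (b in seq_len(branching)) {
        id <- sprintf("HP:%07d", idx + 1L); idx <- idx + 1L
        parents[[id]] <- p
        nxt <- c(nxt, id)
      }
    }
    terms <- c(terms, nxt)
    level <- nxt
  }
  leaves <- level
  ng <- length(gene_ids)
  ann <- vector("list", ng)
  names(ann) <- gene_ids
  # round-robin so every leaf is covered even when ng > or < #leaves
  owner <- rep(seq_len(ng), length.out = length(leaves))
  for (i in seq_len(ng)) ann[[i]] <- leaves[owner == i]
  for (i in seq_len(ng)) {
    extra <- max(0L, terms_per_gene - length(ann[[i]]))
    if (extra > 0)
      ann[[i]] <- unique(c(ann[[i]], sample(leaves, min(extra, length(leaves)))))
  }
  toy_ontology(terms, parents, ann, root)
}
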