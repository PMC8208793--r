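#' Load a scored protein-protein interaction edge list
#'
#' Reads a STRING-style TSV (first three columns: protein a, protein b,
#' combined score), keeps edges at or above `min_score`, canonicalizes
#' undirected pairs, and drops self-loops and duplicates (keeping the
#' highest score). The score scale is auto-detected: any score above 1
#' implies the 0-1000 STRING convention, and a `min_score` given on the
#' 0-1 scale is mapped accordingly (0.9 -> 900).
#'
#' @param path path to the TSV file.
#' @param min_score minimum confidence score (boundary inclusive; default
#'   0.9 on the unit scale).
#' @return `data.frame` with columns `protein_a`, `protein_b`, `score`
#'   (scores on the scale found in the file).
#' @export
load_ppi_edges <- function(path, min_score = 0.9) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 3)
    stop("PPI file needs at least 3 columns (protein_a, protein_b, score)")
  edges <- data.frame(protein_a = as.character(tab[[1]]),
                      protein_b = as.character(tab[[2]]),
                      score = as.numeric(tab[[3]]),
                      stringsAsFactors = FALSE)
  if (anyNA(edges$score)) stop("non-numeric scores in ", path)
  string_scale <- any(edges$score > 1)
  thr <- if (string_scale && min_score <= 1) min_score * 1000 else min_score
  if (!string_scale && min_score > 1)
    stop("min_score ", min_score, " exceeds the file's 0-1 score scale")
  n0 <- nrow(edges)
  edges <- edges[edges$score >= thr, , drop = FALSE]
  n_low <- n0 - nrow(edges)
  self <- edges$protein_a == edges$protein_b
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  edges$protein_a <- a
  edges$protein_b <- b
  o <- order(a, b, -edges$score)
  edges <- edges[o, , drop = FALSE]
  dup <- duplicated(edges[, c("protein_a", "protein_b")])
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  message("load_ppi_edges: kept ", nrow(edges), " edges (dropped ", n_low,
          " below score threshold, ", n_self, " self-loops, ", n_dup,
          " duplicates)")
  rownames(edges) <- NULL
  edges
}

#' Extract the subnetwork induced by a node set
#'
#' Keeps exactly the edges with both endpoints in `node_set`. Members of
#' `node_set` with no surviving edge remain in the subnetwork with degree
#' 0 (see [node_degrees]).
#'
#' @param edges edge `data.frame` as from [load_ppi_edges].
#' @param node_set character vector of node identifiers (non-empty).
#' @return the induced edge `data.frame`.
#' @export
extract_subnetwork <- function(edges, node_set) {
  if (!length(node_set)) stop("node_set must be non-empty")
  keep <- edges$protein_a %in% node_set & edges$protein_b %in% node_set
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node degrees within a subnetwork
#'
#' @param edges induced edge `data.frame` (see [extract_subnetwork]).
#' @param node_set the node universe; nodes without edges get degree 0.
#' @return `data.frame` with columns `gene_id`, `degree`.
#' @export
node_degrees <- function(edges, node_set) {
  node_set <- unique(as.character(node_set))
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b"), drop = FALSE],
    directed = FALSE, vertices = node_set)
  deg <- igraph::degree(g)
  data.frame(gene_id = names(deg), degree = as.integer(deg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare node-degree distributions between two gene groups
#'
#' Two-tailed Wilcoxon rank-sum test on subnetwork degrees of two gene
#' groups (e.g. up- vs downregulated DEGs, or near-end vs elsewhere).
#' Genes absent from the degree table (not represented in the interaction
#' universe) are excluded by default — they are not proteins "in the
#' subnetwork" — or scored as degree 0 with `absent = "zero"`.
#'
#' @param degrees `data.frame` from [node_degrees].
#' @param groups named character vector or factor mapping `gene_id` to one
#'   of exactly two group labels.
#' @param absent `"exclude"` (default) or `"zero"`.
#' @return list with `p` (two-tailed rank-sum p), `medians` (named, per
#'   group), `n` (group sizes) and `n_absent` (genes with no degree
#'   record).
#' @export
degree_comparison <- function(degrees, groups, absent = c("exclude", "zero")) {
  absent <- match.arg(absent)
  groups <- stats::setNames(as.character(groups), names(groups))
  labs <- unique(groups)
  if (length(labs) != 2) stop("groups must have exactly two labels")
  idx <- match(names(groups), degrees$gene_id)
  n_absent <- sum(is.na(idx))
  deg <- degrees$degree[idx]
  if (absent == "zero") deg[is.na(idx)] <- 0L
  keep <- !is.na(deg)
  deg <- deg[keep]
  grp <- groups[keep]
  a <- deg[grp == labs[1]]
  b <- deg[grp == labs[2]]
  if (!length(a) || !length(b))
    stop("a group is empty after matching degrees")
  list(
    p = ranksum_compare(a, b),
    medians = stats::setNames(c(stats::median(a), stats::median(b)), labs),
    n = stats::setNames(c(length(a), length(b)), labs),
    n_absent = n_absent
  )
}

#' Map gene identifiers to protein identifiers
#'
#' Applies a two-column mapping table; genes without a mapping are dropped
#' and counted in a message (no identifier system is hard-coded).
#'
#' @param gene_ids character vector of gene identifiers.
#' @param mapping `data.frame` with columns `gene_id`, `protein_id`.
#' @return named character vector protein ids, named by gene id.
#' @export
map_genes_to_proteins <- function(gene_ids, mapping) {
  if (!all(c("gene_id", "protein_id") %in% names(mapping)))
    stop("mapping needs 'gene_id' and 'protein_id' columns")
  idx <- match(gene_ids, mapping$gene_id)
  if (anyNA(idx))
    message("map_genes_to_proteins: ", sum(is.na(idx)),
            " gene(s) without a protein mapping excluded")
  stats::setNames(mapping$protein_id[idx[!is.na(idx)]], gene_ids[!is.na(idx)])
}

#' Write a PPI edge list as TSV
#' @param edges edge `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
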