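#' Representative gene coordinate
#'
#' Distances are measured from a single point per gene. The default is the
#' transcription start site (gene start on the plus strand, gene end on the
#' minus strand, gene start when the strand is unknown), because position
#' effects from telomeres act on promoters and a point avoids genes
#' straddling bin boundaries; the gene midpoint is available as an
#' alternative.
#'
#' @param genes gene `data.frame` (see [read_gene_annotation]).
#' @param coordinate `"tss"` (default) or `"midpoint"`.
#' @return numeric vector of positions, one per gene.
#' @export
gene_position <- function(genes, coordinate = c("tss", "midpoint")) {
  coordinate <- match.arg(coordinate)
  if (coordinate == "midpoint")
    return((genes$start + genes$end) / 2)
  ifelse(genes$strand == "-", genes$end, genes$start)
}

#' Distance from genes to the nearest chromosome end
#'
#' For a representative coordinate `p` on a chromosome of length `L`, the
#' distance to the p-terminus is `p - 1` (a gene starting at base 1 touches
#' the end) and to the q-terminus `L - p`; the minimum of the two is
#' returned, so the result never exceeds `floor(L / 2)`.
#'
#' @inheritParams gene_position
#' @param chrom_map a [chrom_map] covering every chromosome in `genes`.
#' @return numeric vector of distances in base pairs (>= 0).
#' @export
distance_to_chromosome_end <- function(genes, chrom_map,
                                       coordinate = c("tss", "midpoint")) {
  pos <- gene_position(genes, coordinate)
  idx <- chrom_lookup(chrom_map, genes$chrom)
  len <- chrom_map$length[idx]
  pmin(pos - 1, len - pos)
}

#' Distance from genes to the nearest centromere boundary
#'
#' Zero when the representative coordinate falls inside the annotated
#' centromere interval. Chromosomes without an annotated centromere raise an
#' error rather than silently returning 0: the centromere control analysis
#' must not mix in unanchored genes.
#'
#' @inheritParams distance_to_chromosome_end
#' @return numeric vector of distances in base pairs (>= 0).
#' @export
distance_to_centromere <- function(genes, chrom_map,
                                   coordinate = c("tss", "midpoint")) {
  pos <- gene_position(genes, coordinate)
  idx <- chrom_lookup(chrom_map, genes$chrom)
  cs <- chrom_map$centromere_start[idx]
  ce <- chrom_map$centromere_end[idx]
  if (anyNA(cs))
    stop("no centromere annotated for chromosome(s): ",
         paste(unique(genes$chrom[is.na(cs)]), collapse = ", "))
  pmax(0, pmax(cs - pos, pos - ce))
}

#' Assign genes to distance bins
#'
#' Genes are grouped into non-overlapping windows of `bin_width` base pairs
#' of distance from the chosen anchor. Bin 1 covers distances
#' `[0, bin_width)`, bin 2 `[bin_width, 2 * bin_width)`, and so on; both
#' chromosome arms contribute (each end has its own "first bin") and the
#' per-bin counts downstream pool all arms of all chromosomes.
#'
#' With `anchor = "centromere"`, genes on chromosomes without an annotated
#' centromere are excluded and their count reported via a message.
#'
#' @inheritParams distance_to_chromosome_end
#' @param bin_width bin width in base pairs (default 1 Mb).
#' @param anchor `"chromosome_end"` (default) or `"centromere"`.
#' @return `data.frame` with columns `gene_id`, `distance_bp`, `bin_index`
#'   (1-based) and `anchor`.
#' @examples
#' cm <- chrom_map("chr1", 5e7, 2e7, 3e7)
#' g <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
#'                 start = c(5e5, 4.25e6), end = c(6e5, 4.3e6),
#'                 strand = "+", biotype = "protein_coding")
#' assign_bins(g, cm)
#' @export
assign_bins <- function(genes, chrom_map, bin_width = 1e6,
                        anchor = c("chromosome_end", "centromere"),
                        coordinate = c("tss", "midpoint")) {
  anchor <- match.arg(anchor)
  coordinate <- match.arg(coordinate)
  stopifnot(bin_width > 0)
  if (anchor == "centromere") {
    idx <- chrom_lookup(chrom_map, genes$chrom)
    has_cen <- !is.na(chrom_map$centromere_start[idx])
    if (!any(has_cen))
      stop("no chromosome carrying these genes has an annotated centromere")
    if (any(!has_cen))
      message("assign_bins: excluded ", sum(!has_cen),
              " gene(s) on chromosomes without an annotated centromere")
    genes <- genes[has_cen, , drop = FALSE]
    d <- distance_to_centromere(genes, chrom_map, coordinate)
  } else {
    d <- distance_to_chromosome_end(genes, chrom_map, coordinate)
  }
  data.frame(
    gene_id = genes$gene_id,
    distance_bp = d,
    bin_index = floor(d / bin_width) + 1L,
    anchor = anchor,
    stringsAsFactors = FALSE
  )
}
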