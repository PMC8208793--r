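#' Read a gene annotation (GTF or BED)
#'
#' Parses gene records from a GTF (9-column, `gene_id` / `gene_type`
#' attributes, as in GENCODE) or a BED4+ file into the package's internal
#' 1-based inclusive coordinate convention. GTF files contribute only their
#' `gene` features; BED intervals are taken as one gene each (rtracklayer
#' performs the 0-based half-open to 1-based inclusive conversion).
#'
#' Non-protein-coding genes are retained but carry their `biotype` so that
#' downstream steps can filter on it (see [filter_genes]).
#'
#' @param path path to the annotation file.
#' @param format `"gtf"` or `"bed"`; defaults to the file extension.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`, `"-"` or `"unknown"`) and `biotype`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff")) "gtf"
    else if (ext == "bed") "bed"
    else stop("cannot infer annotation format from extension '", ext,
              "'; pass format = \"gtf\" or \"bed\"")
  }
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gtf") {
    md <- S4Vectors::mcols(gr)
    is_gene <- !is.null(md$type) & as.character(md$type) == "gene"
    if (!any(is_gene)) {
      warning("no 'gene' features found in ", path, "; returning 0 genes")
      gr <- gr[0]
    } else {
      gr <- gr[is_gene]
    }
    md <- S4Vectors::mcols(gr)
    biotype <- if (!is.null(md$gene_type)) as.character(md$gene_type)
    else if (!is.null(md$gene_biotype)) as.character(md$gene_biotype)
    else rep(NA_character_, length(gr))
    gene_id <- if (!is.null(md$gene_id)) as.character(md$gene_id)
    else stop("GTF gene features lack a gene_id attribute")
  } else {
    md <- S4Vectors::mcols(gr)
    gene_id <- if (!is.null(md$name)) as.character(md$name)
    else sprintf("bed_%d", seq_along(gr))
    biotype <- rep("unknown", length(gr))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "unknown"
  genes <- data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(utils::head(unique(genes$gene_id[duplicated(genes$gene_id)])),
               collapse = ", "))
  genes
}

#' Restrict a gene table to the analysis universe
#'
#' The default universe is protein-coding genes on autosomes 1-22 plus X
#' (chromosome names matched with or without a `"chr"` prefix). Genes on
#' chromosomes outside the universe, or with other biotypes, are dropped
#' with a message giving the counts.
#'
#' @param genes a gene `data.frame` as from [read_gene_annotation].
#' @param chroms chromosome names to keep, or `NULL` for 1-22 + X.
#' @param protein_coding_only drop genes whose biotype is not
#'   `"protein_coding"`? Genes with unknown (`NA`) biotype are kept.
#' @return The filtered gene `data.frame`.
#' @export
filter_genes <- function(genes, chroms = NULL, protein_coding_only = TRUE) {
  strip <- function(x) sub("^chr", "", x)
  if (is.null(chroms)) chroms <- c(as.character(1:22), "X")
  keep_chr <- strip(genes$chrom) %in% strip(chroms)
  keep_bio <- if (protein_coding_only)
    is.na(genes$biotype) | genes$biotype == "protein_coding"
  else rep(TRUE, nrow(genes))
  dropped_chr <- sum(!keep_chr)
  dropped_bio <- sum(keep_chr & !keep_bio)
  if (dropped_chr + dropped_bio > 0)
    message("filter_genes: dropped ", dropped_chr,
            " gene(s) outside the chromosome universe and ", dropped_bio,
            " non-protein-coding gene(s); ", sum(keep_chr & keep_bio),
            " retained")
  genes[keep_chr & keep_bio, , drop = FALSE]
}

#' Write gene records as GTF
#'
#' Inverse of [read_gene_annotation] for the synthetic-data module: one
#' `gene` feature per record with `gene_id` and `gene_type` attributes.
#'
#' @param genes a gene `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  strand <- genes$strand
  strand[!strand %in% c("+", "-")] <- "."
  lines <- sprintf(
    '%s\tsubtelomeR\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_type "%s";',
    genes$chrom, as.integer(genes$start), as.integer(genes$end), strand,
    genes$gene_id,
    ifelse(is.na(genes$biotype), "unknown", genes$biotype))
  writeLines(lines, path)
  invisible(path)
}
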