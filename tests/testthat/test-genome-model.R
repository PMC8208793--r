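test_that("GTF and BED annotations parse into 1-based gene records", {
  gtf <- write_tmp_gtf(c(
    gtf_gene_line("chr1", 1000, 2000, "+", "G1"),
    gtf_gene_line("chr1", 5000, 9000, "-", "G2"),
    gtf_gene_line("chr2", 100, 500, "+", "G3"),
    'chr1\tsrc\texon\t1000\t1500\t.\t+\t.\tgene_id "G1"; gene_type "protein_coding";'
  ))
  g <- read_gene_annotation(gtf, "gtf")
  expect_equal(nrow(g), 3)
  expect_equal(g$gene_id, c("G1", "G2", "G3"))
  expect_true(all(g$biotype == "protein_coding"))
  expect_equal(g$strand, c("+", "-", "+"))

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tGENE1", bed)
  b <- read_gene_annotation(bed, "bed")
  expect_equal(b$start, 1000)
  expect_equal(b$end, 2000)
  expect_equal(b$gene_id, "GENE1")

  exon_only <- write_tmp_gtf(
    'chr1\tsrc\texon\t1000\t1500\t.\t+\t.\tgene_id "G1"; gene_type "protein_coding";')
  expect_warning(e <- read_gene_annotation(exon_only, "gtf"), "no 'gene'")
  expect_equal(nrow(e), 0)
})

test_that("the gene universe filter keeps protein-coding genes on 1-22 + X", {
  genes <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    chrom = c("chr1", "chrX", "chrY", "chr2"),
    start = 1, end = 10, strand = "+",
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "lincRNA"))
  expect_message(out <- filter_genes(genes), "dropped 1 gene")
  expect_equal(out$gene_id, c("a", "b"))
  # prefix-free chromosome names match the same universe
  genes$chrom <- sub("chr", "", genes$chrom)
  expect_equal(suppressMessages(filter_genes(genes))$gene_id, c("a", "b"))
})

test_that("distance to the nearest chromosome end follows the TSS convention", {
  cm <- chrom_map("chr1", 1e7)
  g <- function(start, end, strand)
    data.frame(gene_id = "g", chrom = "chr1", start = start, end = end,
               strand = strand, biotype = "protein_coding")
  expect_equal(distance_to_chromosome_end(g(1, 100, "+"), cm), 0)
  expect_equal(distance_to_chromosome_end(g(1234567, 1240000, "+"), cm),
               1234566)
  # minus strand: TSS is the gene end; equals brute-force min over both ends
  gm <- g(9500000, 9600000, "-")
  tss <- 9600000
  expect_equal(distance_to_chromosome_end(gm, cm),
               min(tss - 1, 1e7 - tss))
  expect_equal(distance_to_chromosome_end(gm, cm), 400000)
  expect_error(distance_to_chromosome_end(
    data.frame(gene_id = "g", chrom = "chrZ", start = 1, end = 2,
               strand = "+", biotype = "x"), cm), "unknown")
})

test_that("distance to the centromere boundary is zero inside the interval", {
  cm <- chrom_map("chr1", 1e7, 4e6, 5e6)
  g <- function(tss) data.frame(gene_id = "g", chrom = "chr1", start = tss,
                                end = tss + 10, strand = "+", biotype = "x")
  expect_equal(distance_to_centromere(g(3900000), cm), 100000)
  expect_equal(distance_to_centromere(g(4500000), cm), 0)
  expect_equal(distance_to_centromere(g(5000001), cm), 1)
  cm_none <- chrom_map("chr1", 1e7)
  expect_error(distance_to_centromere(g(100), cm_none), "no centromere")
})

test_that("bin assignment partitions genes with half-open 1 Mb bins", {
  cm <- chrom_map("chr1", 4e7)
  tss <- c(1, 1e6, 1e6 + 1, 2e6 + 1)           # distances 0, 999999, 1e6, 2e6
  genes <- data.frame(gene_id = paste0("g", seq_along(tss)), chrom = "chr1",
                      start = tss, end = tss + 10, strand = "+",
                      biotype = "x")
  b <- assign_bins(genes, cm, bin_width = 1e6)
  expect_equal(b$bin_index, c(1L, 1L, 2L, 3L))
  expect_equal(b$bin_index, floor(b$distance_bp / 1e6) + 1L)

  # ten genes at 0.5, 1.5, ..., 9.5 Mb -> bins 1..10, one each
  tss10 <- (seq(0.5, 9.5) * 1e6) + 1
  g10 <- data.frame(gene_id = paste0("u", 1:10), chrom = "chr1",
                    start = tss10, end = tss10 + 1, strand = "+",
                    biotype = "x")
  b10 <- assign_bins(g10, cm, 1e6)
  expect_equal(sort(b10$bin_index), 1:10)

  # partition: every mapped gene appears exactly once
  expect_equal(nrow(b10), nrow(g10))
  expect_equal(sum(table(b10$bin_index)), nrow(g10))
})

test_that("centromere-anchored binning excludes unannotated chromosomes", {
  cm <- chrom_map(c("chr1", "chr2"), c(4e7, 4e7),
                  c(1.5e7, NA), c(2e7, NA))
  genes <- data.frame(gene_id = c("a", "b"), chrom = c("chr1", "chr2"),
                      start = c(1e6, 1e6), end = c(1e6, 1e6) + 10,
                      strand = "+", biotype = "x")
  expect_message(b <- assign_bins(genes, cm, anchor = "centromere"),
                 "excluded 1")
  expect_equal(b$gene_id, "a")
  cm_none <- chrom_map(c("chr1", "chr2"), c(4e7, 4e7))
  expect_error(assign_bins(genes, cm_none, anchor = "centromere"),
               "centromere")
})

test_that("end distance is symmetric under reflection through the midpoint", {
  set.seed(11)
  L <- 5e7
  cm <- chrom_map("chr1", L)
  n <- 200
  start <- sample.int(L - 1e5, n)
  genes <- data.frame(gene_id = paste0("g", 1:n), chrom = "chr1",
                      start = start, end = start + sample.int(1e5, n),
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      biotype = "x")
  refl <- data.frame(gene_id = genes$gene_id, chrom = "chr1",
                     start = L - genes$end + 1, end = L - genes$start + 1,
                     strand = ifelse(genes$strand == "+", "-", "+"),
                     biotype = "x")
  d1 <- distance_to_chromosome_end(genes, cm)
  d2 <- distance_to_chromosome_end(refl, cm)
  expect_equal(d1, d2)
  expect_true(all(d1 <= floor(L / 2)))
})
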