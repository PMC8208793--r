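#' GRCh38 chromosome map
#'
#' Chromosome lengths for the human GRCh38 assembly (autosomes 1-22 plus
#' X) with approximate centromere intervals (rounded to 0.1 Mb from the
#' UCSC hg38 centromere annotation). This is the default coordinate frame
#' for classifying real Hi-C loop calls by distance to chromosome ends.
#'
#' @return a [chrom_map] with 23 chromosomes.
#' @examples
#' grch38_chrom_map()
#' @export
grch38_chrom_map <- function() {
  chrom_map(
    chrom = paste0("chr", c(1:22, "X")),
    length = c(248956422, 242193529, 198295559, 190214555, 181538259,
               170805979, 159345973, 145138636, 138394717, 133797422,
               135086622, 133275309, 114364328, 107043718, 101991189,
               90338345, 83257441, 80373285, 58617616, 64444167,
               46709983, 50818468, 156040895),
    centromere_start = 1e6 * c(121.7, 91.8, 87.8, 48.2, 46.1, 58.5, 58.1,
                               43.2, 42.2, 38.0, 51.0, 34.7, 16.5, 16.1,
                               17.5, 35.3, 22.7, 15.4, 24.4, 25.7, 10.9,
                               13.7, 58.1),
    centromere_end = 1e6 * c(125.1, 96.0, 94.0, 51.8, 50.1, 62.6, 62.4,
                             47.2, 45.5, 41.6, 55.8, 37.2, 18.9, 18.2,
                             20.5, 38.3, 27.4, 21.0, 28.1, 30.2, 13.0,
                             17.4, 63.8)
  )
}
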