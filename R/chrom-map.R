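#' Chromosome map
#'
#' A chromosome map holds, for every chromosome in the analysis universe, its
#' total length in base pairs and (optionally) the centromere interval. All
#' distance and binning computations in the package are anchored on it.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer-valued vector of chromosome lengths in base pairs.
#' @param centromere_start,centromere_end optional centromere interval bounds
#'   (1-based, inclusive); use `NA` where no centromere is annotated.
#' @return A `data.frame` of class `"chrom_map"` with columns `chrom`,
#'   `length`, `centromere_start`, `centromere_end`.
#' @examples
#' cm <- chrom_map(c("chr1", "chr2"), c(5e7, 4e7),
#'                 centromere_start = c(2e7, NA), centromere_end = c(3e7, NA))
#' cm
#' @export
chrom_map <- function(chrom, length,
                      centromere_start = NA_real_,
                      centromere_end = NA_real_) {
  n <- base::length(chrom)
  cm <- data.frame(
    chrom = as.character(chrom),
    length = as.numeric(length),
    centromere_start = rep_len(as.numeric(centromere_start), n),
    centromere_end = rep_len(as.numeric(centromere_end), n),
    stringsAsFactors = FALSE
  )
  validate_chrom_map(cm)
  class(cm) <- c("chrom_map", "data.frame")
  cm
}

validate_chrom_map <- function(cm) {
  if (anyDuplicated(cm$chrom))
    stop("chromosome names must be unique: ",
         paste(unique(cm$chrom[duplicated(cm$chrom)]), collapse = ", "))
  if (any(!is.finite(cm$length)) || any(cm$length <= 0))
    stop("chromosome lengths must be positive")
  has_cen <- !is.na(cm$centromere_start) | !is.na(cm$centromere_end)
  if (any(has_cen & (is.na(cm$centromere_start) | is.na(cm$centromere_end))))
    stop("centromere interval must give both start and end, or neither")
  ok <- !has_cen |
    (cm$centromere_start >= 1 &
       cm$centromere_start < cm$centromere_end &
       cm$centromere_end <= cm$length)
  if (!all(ok))
    stop("invalid centromere interval on: ",
         paste(cm$chrom[!ok], collapse = ", "))
  invisible(cm)
}

#' Read a chromosome map from TSV
#'
#' Expects a tab-separated file with header columns `chrom`, `length`,
#' `centromere_start`, `centromere_end`; empty centromere fields mean the
#' centromere is not annotated for that chromosome.
#'
#' @param path path to the TSV file.
#' @return A [chrom_map] object.
#' @export
read_chrom_map <- function(path) {
  if (!file.exists(path)) stop("chromosome map file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "length")
  if (!all(need %in% names(tab)))
    stop("chromosome map must have columns 'chrom' and 'length'")
  cs <- if ("centromere_start" %in% names(tab))
    as.numeric(tab$centromere_start) else NA_real_
  ce <- if ("centromere_end" %in% names(tab))
    as.numeric(tab$centromere_end) else NA_real_
  chrom_map(tab$chrom, tab$length, cs, ce)
}

#' Write a chromosome map to TSV
#' @param cm a [chrom_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_map <- function(cm, path) {
  utils::write.table(as.data.frame(cm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.chrom_map <- function(x, ...) {
  cat("Chromosome map:", nrow(x), "chromosomes,",
      format(sum(x$length), big.mark = ","), "bp total;",
      sum(!is.na(x$centromere_start)), "with annotated centromere\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

chrom_lookup <- function(cm, chroms, what = "chromosome") {
  idx <- match(chroms, cm$chrom)
  if (anyNA(idx)) {
    missing <- unique(chroms[is.na(idx)])
    stop("unknown ", what, " not in chromosome map: ",
         paste(missing, collapse = ", "))
  }
  idx
}
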