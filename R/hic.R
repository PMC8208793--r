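#' Read chromatin loop calls from BEDPE
#'
#' One loop per line; the two anchors are converted from BEDPE's 0-based
#' half-open coordinates to the internal 1-based inclusive convention
#' (via rtracklayer). Lines starting with `#` are skipped.
#' Inter-chromosomal records are retained but flagged.
#'
#' @param path path to the BEDPE file.
#' @param source dataset identifier recorded with every loop (default: the
#'   file name).
#' @return `data.frame` with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `inter_chromosomal`, `source`.
#' @export
read_loops <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("loop file not found: ", path)
  pairs <- rtracklayer::import(path, format = "bedpe")
  f <- S4Vectors::first(pairs)
  s <- S4Vectors::second(pairs)
  loops <- data.frame(
    chrom1 = as.character(GenomicRanges::seqnames(f)),
    start1 = GenomicRanges::start(f),
    end1 = GenomicRanges::end(f),
    chrom2 = as.character(GenomicRanges::seqnames(s)),
    start2 = GenomicRanges::start(s),
    end2 = GenomicRanges::end(s),
    stringsAsFactors = FALSE
  )
  bad <- loops$start1 > loops$end1 | loops$start2 > loops$end2
  if (any(bad))
    stop("malformed anchor (start >= end) at loop record(s): ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  loops$inter_chromosomal <- loops$chrom1 != loops$chrom2
  loops$source <- source
  loops
}

#' Write loops as BEDPE (0-based half-open)
#' @param loops loop `data.frame` (internal 1-based convention).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t.",
                   loops$chrom1, as.integer(loops$start1) - 1L,
                   as.integer(loops$end1),
                   loops$chrom2, as.integer(loops$start2) - 1L,
                   as.integer(loops$end2),
                   if (is.null(loops$source)) "." else loops$source)
  writeLines(lines, path)
  invisible(path)
}

#' Classify loops by anchor distance to chromosome ends
#'
#' Each anchor's distance is measured from its representative point
#' (anchor-interval midpoint by default; loop calls are resolution-sized
#' bins, so the midpoint is robust to resolution) to the nearer end of its
#' own chromosome. `d_near` is the smaller of the two anchor distances and
#' `d_far` the larger. A loop is `telomeric` when `d_near < first_bin`
#' (strictly — mirroring bin 1's half-open interval) and `contained` when
#' additionally `d_far <= window`. Loops whose anchors sit nearer to
#' opposite chromosome ends are classified by the nearer-end anchor and
#' flagged `opposite_arms` for audit. Inter-chromosomal loops are skipped
#' with a message, not an error.
#'
#' @param loops loop `data.frame` from [read_loops] or [simulate_loops].
#' @param chrom_map a [chrom_map].
#' @param first_bin width of the terminal bin defining "telomeric"
#'   (default 1 Mb).
#' @param window subtelomeric containment window (default 2 Mb).
#' @param point `"midpoint"` (default) or `"edge"` (distance of the anchor
#'   edge closest to the end).
#' @return `data.frame`: the intra-chromosomal loops with added columns
#'   `d_near`, `d_far`, `telomeric`, `contained`, `opposite_arms`.
#' @export
classify_loops <- function(loops, chrom_map, first_bin = 1e6, window = 2e6,
                           point = c("midpoint", "edge")) {
  point <- match.arg(point)
  inter <- if (is.null(loops$inter_chromosomal))
    loops$chrom1 != loops$chrom2 else loops$inter_chromosomal
  if (any(inter))
    message("classify_loops: skipped ", sum(inter),
            " inter-chromosomal loop(s)")
  loops <- loops[!inter, , drop = FALSE]
  idx <- chrom_lookup(chrom_map, loops$chrom1)
  len <- chrom_map$length[idx]
  anchor_dist <- function(s, e) {
    if (point == "midpoint") {
      mid <- (s + e) / 2
      list(d = pmin(mid - 1, len - mid), arm = ifelse(mid - 1 <= len - mid,
                                                      "p", "q"))
    } else {
      dp <- s - 1
      dq <- len - e
      list(d = pmin(dp, dq), arm = ifelse(dp <= dq, "p", "q"))
    }
  }
  a1 <- anchor_dist(loops$start1, loops$end1)
  a2 <- anchor_dist(loops$start2, loops$end2)
  if (any(a1$d < 0 | a2$d < 0))
    stop("anchor beyond chromosome length at record(s): ",
         paste(utils::head(which(a1$d < 0 | a2$d < 0), 10), collapse = ", "))
  out <- loops
  out$d_near <- pmin(a1$d, a2$d)
  out$d_far <- pmax(a1$d, a2$d)
  out$arm <- ifelse(a1$d <= a2$d, a1$arm, a2$arm)
  out$telomeric <- out$d_near < first_bin
  out$contained <- out$telomeric & out$d_far <= window
  out$opposite_arms <- a1$arm != a2$arm
  rownames(out) <- NULL
  out
}

#' Fraction of telomeric loops contained in the subtelomeric window
#'
#' `100 * contained / telomeric`, as a percentage. With `by_source = TRUE`
#' the fraction is also computed per dataset.
#'
#' @param classifications output of [classify_loops].
#' @param by_source also return per-source breakdown?
#' @return the pooled percentage, or (with `by_source`) a list with
#'   `pooled` and a per-source `data.frame`.
#' @export
subtelomeric_fraction <- function(classifications, by_source = FALSE) {
  n_tel <- sum(classifications$telomeric)
  if (n_tel == 0)
    stop("no telomeric loops: subtelomeric fraction undefined")
  pooled <- 100 * sum(classifications$contained) / n_tel
  if (!by_source) return(pooled)
  src <- split(classifications, classifications$source)
  per <- do.call(rbind, lapply(names(src), function(s) {
    x <- src[[s]]
    data.frame(source = s,
               telomeric = sum(x$telomeric),
               contained = sum(x$contained),
               pct = if (sum(x$telomeric))
                 100 * sum(x$contained) / sum(x$telomeric) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(pooled = pooled, per_source = per)
}

#' Report long-range telomere-anchored loops
#'
#' Telomeric loops whose far anchor lies beyond the subtelomeric window but
#' within `max_far` of a chromosome end, sorted by decreasing reach.
#'
#' @param classifications output of [classify_loops].
#' @param min_far lower bound on `d_far`, exclusive (default 2 Mb).
#' @param max_far upper bound on `d_far`, inclusive (default 11 Mb).
#' @return the selected rows, sorted by `d_far` descending, with the
#'   chromosome arm of the telomeric anchor.
#' @export
long_range_report <- function(classifications, min_far = 2e6,
                              max_far = 11e6) {
  keep <- classifications$telomeric &
    classifications$d_far > min_far & classifications$d_far <= max_far
  out <- classifications[keep, , drop = FALSE]
  out[order(-out$d_far), , drop = FALSE]
}
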