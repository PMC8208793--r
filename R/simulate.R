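#' Ground-truth parameters for synthetic data
#'
#' Bundles the planted parameters against which pipeline recovery is
#' tested. `theta` is the planted odds ratio of up- versus downregulation
#' among true DEGs in the first two 1 Mb bins from chromosome ends,
#' relative to the genome-wide (elsewhere) up:down odds of 1 — the bias
#' acts on the direction mix, not on DEG density, so it isolates exactly
#' the per-bin odds-ratio statistic. Every generator derives its random
#' stream deterministically from `seed`.
#'
#' @param theta planted subtelomeric up:down odds ratio (> 0; 1 = null).
#' @param deg_fraction fraction of genes that are true DEGs (in (0, 1)).
#' @param beta_mean,beta_sd mean and sd of the absolute per-year log2
#'   expression effect of true DEGs.
#' @param dispersion negative-binomial dispersion (constant across genes).
#' @param loop_containment probability that a telomere-anchored loop has
#'   its far anchor within the 2 Mb subtelomeric window.
#' @param seed integer seed.
#' @return an object of class `"synthetic_truth"` (a validated list).
#' @export
synthetic_truth <- function(theta = 1, deg_fraction = 0.25,
                            beta_mean = 0.02, beta_sd = 0.005,
                            dispersion = 0.1, loop_containment = 0.863,
                            seed = 1) {
  stopifnot(theta > 0, deg_fraction > 0, deg_fraction < 1,
            dispersion > 0, loop_containment >= 0, loop_containment <= 1,
            beta_mean >= 0, beta_sd >= 0)
  structure(list(theta = theta, deg_fraction = deg_fraction,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 dispersion = dispersion,
                 loop_containment = loop_containment,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth: theta =", x$theta,
      "| DEG fraction =", x$deg_fraction,
      "| |beta| ~ N(", x$beta_mean, ",", x$beta_sd,
      ") | dispersion =", x$dispersion,
      "| loop containment =", x$loop_containment,
      "| seed =", x$seed, "\n")
  invisible(x)
}

#' Simulate a genome annotation
#'
#' Chromosomes of equal length with a centromere planted across the middle
#' fifth; gene transcription start sites placed uniformly at random outside
#' the centromere, without collisions. Deterministic given the truth seed.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in base pairs (>= 20 Mb so at
#'   least 10 one-Mb bins exist per arm).
#' @param n_genes total number of genes (>= `n_chrom`).
#' @param truth a [synthetic_truth].
#' @return list with `chrom_map` (a [chrom_map]) and `genes` (gene
#'   `data.frame`).
#' @export
simulate_genome <- function(n_chrom = 4, chrom_length = 6e7, n_genes = 5000,
                            truth = synthetic_truth()) {
  if (n_genes < n_chrom || n_genes < 1)
    stop("need at least one gene per chromosome")
  if (chrom_length < 2e7)
    stop("chrom_length must be >= 20 Mb (10 bins per arm)")
  set.seed(truth$seed)
  cen_start <- floor(0.4 * chrom_length)
  cen_end <- floor(0.6 * chrom_length)
  cm <- chrom_map(paste0("chr", seq_len(n_chrom)), rep(chrom_length, n_chrom),
                  rep(cen_start, n_chrom), rep(cen_end, n_chrom))
  chrom <- sample(cm$chrom, n_genes, replace = TRUE)
  n_per <- table(factor(chrom, levels = cm$chrom))
  avail <- chrom_length - (cen_end - cen_start + 1)
  if (any(n_per > avail / 10))
    stop("gene density infeasible on at least one chromosome")
  tss <- unlist(lapply(cm$chrom, function(ch) {
    n <- n_per[[ch]]
    pos <- sample.int(avail, n)             # uniform outside the centromere
    ifelse(pos >= cen_start, pos + (cen_end - cen_start + 1), pos)
  }))
  chrom <- rep(cm$chrom, n_per)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  glen <- sample.int(9e4, n_genes) + 1e3
  start <- ifelse(strand == "+", tss, pmax(1, tss - glen))
  end <- ifelse(strand == "+", pmin(chrom_length, tss + glen), tss)
  genes <- data.frame(
    gene_id = sprintf("G%05d", seq_len(n_genes)),
    chrom = chrom, start = start, end = end, strand = strand,
    biotype = "protein_coding", stringsAsFactors = FALSE)
  list(chrom_map = cm, genes = genes)
}

#' Simulate an RNA-seq count matrix with planted age effects
#'
#' Sample ages are uniform on [20, 79] with balanced sexes (one sample per
#' subject). A `deg_fraction` subset of genes are true DEGs whose log2
#' mean expression changes linearly with age; within the first two 1 Mb
#' bins from chromosome ends the probability that a true DEG is
#' upregulated is `theta / (1 + theta)` (so the planted up:down odds are
#' `theta` times the elsewhere odds of 1), and elsewhere it is 1/2. Counts
#' are negative binomial with per-sample sequencing-depth factors uniform
#' on [0.7, 1.3]; a tenth of genes additionally carry a sex effect so the
#' covariate is exercised. Deterministic given the truth seed.
#'
#' @param genes,chrom_map output of [simulate_genome].
#' @param n_samples number of samples (>= 20).
#' @param truth a [synthetic_truth].
#' @return list with `counts` (gene x sample integer matrix), `meta`
#'   (sample metadata `data.frame`) and `labels` (per-gene truth:
#'   `gene_id`, `is_deg`, `direction`, `beta`, `bin_index`).
#' @export
simulate_expression <- function(genes, chrom_map, n_samples = 200,
                                truth = synthetic_truth()) {
  if (n_samples < 20) stop("need at least 20 samples")
  set.seed(truth$seed + 1L)
  G <- nrow(genes)
  bins <- assign_bins(genes, chrom_map, 1e6)
  meta <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    subject_id = sprintf("SUBJ%04d", seq_len(n_samples)),
    tissue = "simulated",
    sex = rep_len(c("male", "female"), n_samples),
    age = stats::runif(n_samples, 20, 79),
    stringsAsFactors = FALSE)
  is_deg <- stats::rbinom(G, 1, truth$deg_fraction) == 1
  p_up <- ifelse(bins$bin_index <= 2, truth$theta / (1 + truth$theta), 0.5)
  up <- stats::rbinom(G, 1, p_up) == 1
  direction <- ifelse(!is_deg, "none", ifelse(up, "up", "down"))
  beta <- ifelse(is_deg,
                 ifelse(up, 1, -1) *
                   abs(stats::rnorm(G, truth$beta_mean, truth$beta_sd)),
                 0)
  b0 <- stats::runif(G, 3, 8)
  sex_beta <- ifelse(stats::runif(G) < 0.1, stats::rnorm(G, 0, 0.3), 0)
  depth <- stats::runif(n_samples, 0.7, 1.3)
  female <- as.numeric(meta$sex == "female")
  log2mu <- outer(b0, rep(1, n_samples)) +
    outer(beta, meta$age - 50) +
    outer(sex_beta, female)
  mu <- sweep(2^log2mu, 2, depth, `*`)
  counts <- matrix(stats::rnbinom(G * n_samples, mu = mu,
                                  size = 1 / truth$dispersion),
                   nrow = G,
                   dimnames = list(genes$gene_id, meta$sample_id))
  labels <- data.frame(gene_id = genes$gene_id, is_deg = is_deg,
                       direction = direction, beta = beta,
                       bin_index = bins$bin_index,
                       stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, labels = labels)
}

#' Simulate telomere-anchored chromatin loops
#'
#' One anchor of every loop falls in the first 1 Mb from a random
#' chromosome end; the other anchor lands within the 2 Mb subtelomeric
#' window of the same end with probability `loop_containment`, and
#' otherwise uniformly between 2 and 11 Mb from that end (the long-range
#' regime). Anchors are 10 kb wide; anchor order within each record is
#' randomized. Deterministic given the truth seed.
#'
#' @param chrom_map a [chrom_map] (chromosomes must exceed 22 Mb).
#' @param n_loops number of loops (>= 1).
#' @param truth a [synthetic_truth].
#' @param source dataset identifier stored with every loop.
#' @return loop `data.frame` in the [read_loops] layout.
#' @export
simulate_loops <- function(chrom_map, n_loops = 5000,
                           truth = synthetic_truth(),
                           source = "synthetic") {
  if (n_loops < 1) stop("n_loops must be >= 1")
  if (any(chrom_map$length < 2.3e7))
    stop("chromosomes must be > 23 Mb for the 11 Mb long-range regime")
  set.seed(truth$seed + 2L)
  half <- 5000L
  chrom <- sample(chrom_map$chrom, n_loops, replace = TRUE)
  L <- chrom_map$length[match(chrom, chrom_map$chrom)]
  arm <- sample(c("p", "q"), n_loops, replace = TRUE)
  d1 <- stats::runif(n_loops, half + 1, 1e6 - 2)
  contained <- stats::runif(n_loops) < truth$loop_containment
  d2 <- ifelse(contained,
               stats::runif(n_loops, half + 1, 2e6 - 2),
               stats::runif(n_loops, 2e6 + 10, 11e6 - 10))
  to_anchor <- function(d) {
    mid <- ifelse(arm == "p", round(d) + 1, L - round(d))
    start <- as.integer(mid) - half
    data.frame(start = start, end = start + 2L * half - 1L)
  }
  a1 <- to_anchor(d1)
  a2 <- to_anchor(d2)
  swap <- stats::runif(n_loops) < 0.5
  loops <- data.frame(
    chrom1 = chrom,
    start1 = ifelse(swap, a2$start, a1$start),
    end1 = ifelse(swap, a2$end, a1$end),
    chrom2 = chrom,
    start2 = ifelse(swap, a1$start, a2$start),
    end2 = ifelse(swap, a1$end, a2$end),
    inter_chromosomal = FALSE,
    source = source,
    stringsAsFactors = FALSE)
  loops
}

#' Simulate a scored PPI edge list with group-dependent connectivity
#'
#' A fitness (Chung-Lu style) random graph over the gene universe in which
#' the expected degree of genes labelled `down` is `degree_ratio_down_vs_up`
#' times that of other genes; edge confidence scores are uniform on
#' [0.9, 1]. Deterministic given the truth seed.
#'
#' @param gene_ids character vector of node identifiers.
#' @param mean_degree expected degree of a baseline (up/none) gene (>= 0).
#' @param degree_ratio_down_vs_up connectivity multiplier for `down` genes.
#' @param labels optional character vector (same length as `gene_ids`) of
#'   directions; only `"down"` entries are boosted.
#' @param truth a [synthetic_truth].
#' @return edge `data.frame` with columns `protein_a`, `protein_b`,
#'   `score`.
#' @export
simulate_ppi <- function(gene_ids, mean_degree = 4,
                         degree_ratio_down_vs_up = 1, labels = NULL,
                         truth = synthetic_truth()) {
  stopifnot(mean_degree >= 0, degree_ratio_down_vs_up > 0)
  set.seed(truth$seed + 3L)
  n <- length(gene_ids)
  empty <- data.frame(protein_a = character(), protein_b = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (mean_degree == 0 || n < 2) return(empty)
  w <- rep(mean_degree, n)
  if (!is.null(labels)) w[labels == "down"] <- mean_degree *
      degree_ratio_down_vs_up
  g <- igraph::sample_fitness(no.of.edges = round(sum(w) / 2),
                              fitness.out = w, loops = FALSE,
                              multiple = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (!nrow(el)) return(empty)
  data.frame(protein_a = gene_ids[el[, 1]],
             protein_b = gene_ids[el[, 2]],
             score = stats::runif(nrow(el), 0.9, 1),
             stringsAsFactors = FALSE)
}
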