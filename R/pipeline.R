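#' Default pipeline configuration
#'
#' A nested list with one section per stage; all analysis defaults mirror
#' the package's core constants (1 Mb bins, 2 Mb subtelomeric window,
#' Bonferroni alpha 0.001, PPI score threshold 0.9). Stage input paths
#' default to the files the `simulate` stage writes under `outdir`, so
#' `stage = "all"` is self-contained.
#'
#' @param outdir output directory.
#' @param seed integer seed recorded in the manifest and used by the
#'   simulate stage.
#' @return the configuration list.
#' @export
default_config <- function(outdir = "tpe_run", seed = 1) {
  p <- function(f) file.path(outdir, f)
  list(
    outdir = outdir,
    seed = as.integer(seed),
    truth = list(theta = 1, deg_fraction = 0.25, beta_mean = 0.02,
                 beta_sd = 0.005, dispersion = 0.1,
                 loop_containment = 0.863),
    simulate = list(n_chrom = 4, chrom_length = 6e7, n_genes = 2000,
                    n_samples = 100, n_loops = 2000, mean_degree = 4,
                    degree_ratio = 1),
    deg = list(counts = p("counts.tsv"), meta = p("metadata.tsv"),
               covariates = "sex", min_mean = 1, alpha = 0.001),
    enrich = list(annotation = p("annotation.gtf"),
                  chrom_map = p("chrom_map.tsv"), degs = p("degs.tsv"),
                  bin_width = 1e6, n_bins = 10),
    network = list(ppi = p("ppi.tsv"), degs = p("degs.tsv"),
                   min_score = 0.9),
    hic = list(loops = p("loops.bedpe"), chrom_map = p("chrom_map.tsv"),
               first_bin = 1e6, window = 2e6)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the analysis pipeline
#'
#' Executes the requested stage (or all stages in dependency order) and
#' writes every stage's outputs plus a JSON run manifest recording the
#' seed, input checksums, filter counts and timings. Stage outputs are
#' pure functions of (inputs, config, seed): re-running with an identical
#' configuration reproduces byte-identical TSVs.
#'
#' Stages: `simulate` (synthetic annotation, counts, metadata, PPI, loops,
#' truth JSON), `deg` (DEG table), `enrich` (telomere and centromere
#' enrichment profiles), `network` (subnetwork degrees and up/down degree
#' comparison), `hic` (loop classification and per-source containment
#' summary), `all`.
#'
#' On a stage failure a `<stage>.partial` marker is left in `outdir` and
#' the error is re-raised naming the stage.
#'
#' @param stage one of `"simulate"`, `"deg"`, `"enrich"`, `"network"`,
#'   `"hic"`, `"all"`.
#' @param config a configuration list (see [default_config]), a path to a
#'   YAML file with the same structure, or `NULL` for the defaults.
#' @param outdir,seed convenience overrides of the config fields.
#' @return the run manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(stage = "all", config = NULL, outdir = NULL,
                         seed = NULL) {
  stage <- match.arg(stage, c("all", "simulate", "deg", "enrich",
                              "network", "hic"))
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  cfg <- default_config(
    outdir = if (!is.null(outdir)) outdir
    else if (!is.null(config$outdir)) config$outdir else "tpe_run",
    seed = if (!is.null(seed)) seed
    else if (!is.null(config$seed)) config$seed else 1)
  if (!is.null(config)) {
    config$outdir <- NULL; config$seed <- NULL
    cfg <- merge_config(cfg, config)
  }
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  stages <- if (stage == "all")
    c("simulate", "deg", "enrich", "network", "hic") else stage
  manifest <- list(seed = cfg$seed, outdir = cfg$outdir, stages = list())
  for (st in stages) {
    marker <- file.path(cfg$outdir, paste0(st, ".partial"))
    file.create(marker)
    t0 <- proc.time()[["elapsed"]]
    rec <- tryCatch(
      switch(st,
             simulate = stage_simulate(cfg),
             deg = stage_deg(cfg),
             enrich = stage_enrich(cfg),
             network = stage_network(cfg),
             hic = stage_hic(cfg)),
      error = function(e)
        stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
             call. = FALSE))
    file.remove(marker)
    rec$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    rec$input_md5 <- as.list(tools::md5sum(
      Filter(file.exists, unlist(rec$inputs %||% character()))))
    manifest$stages[[st]] <- rec
  }
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_simulate <- function(cfg) {
  s <- cfg$simulate
  truth <- do.call(synthetic_truth, c(cfg$truth, list(seed = cfg$seed)))
  genome <- simulate_genome(s$n_chrom, s$chrom_length, s$n_genes, truth)
  expr <- simulate_expression(genome$genes, genome$chrom_map, s$n_samples,
                              truth)
  loops <- simulate_loops(genome$chrom_map, s$n_loops, truth)
  ppi <- simulate_ppi(genome$genes$gene_id, s$mean_degree, s$degree_ratio,
                      labels = expr$labels$direction, truth = truth)
  p <- function(f) file.path(cfg$outdir, f)
  write_gene_annotation(genome$genes, p("annotation.gtf"))
  write_chrom_map(genome$chrom_map, p("chrom_map.tsv"))
  write_counts(expr$counts, p("counts.tsv"))
  utils::write.table(expr$meta, p("metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_ppi_edges(ppi, p("ppi.tsv"))
  write_loops(loops, p("loops.bedpe"))
  utils::write.table(expr$labels, p("truth_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(truth), p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  list(counts = list(genes = nrow(genome$genes),
                     samples = s$n_samples,
                     true_degs = sum(expr$labels$is_deg),
                     loops = nrow(loops), ppi_edges = nrow(ppi)),
       outputs = c("annotation.gtf", "chrom_map.tsv", "counts.tsv",
                   "metadata.tsv", "ppi.tsv", "loops.bedpe",
                   "truth_labels.tsv", "truth.json"))
}

stage_deg <- function(cfg) {
  d <- cfg$deg
  if (!file.exists(d$counts)) stop("counts file not found: ", d$counts)
  if (!file.exists(d$meta)) stop("metadata file not found: ", d$meta)
  counts <- read_counts(d$counts)
  meta <- read_sample_meta(d$meta)
  fit <- fit_age_degs(counts, meta, covariates = d$covariates,
                      min_mean = d$min_mean, alpha = d$alpha)
  out <- file.path(cfg$outdir, "degs.tsv")
  utils::write.table(fit$table, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(inputs = c(d$counts, d$meta),
       counts = list(genes_in = fit$n_genes_in,
                     genes_tested = fit$n_genes_tested,
                     degs_up = sum(fit$table$direction == "up"),
                     degs_down = sum(fit$table$direction == "down")),
       outputs = "degs.tsv")
}

stage_enrich <- function(cfg) {
  e <- cfg$enrich
  for (f in c(e$annotation, e$chrom_map, e$degs))
    if (!file.exists(f)) stop("input not found: ", f)
  genes <- filter_genes(read_gene_annotation(e$annotation))
  cm <- read_chrom_map(e$chrom_map)
  degs <- utils::read.delim(e$degs, stringsAsFactors = FALSE)
  if (!any(degs$direction %in% c("up", "down")))
    warning("no DEGs upstream: enrichment profile is empty-table null")
  bins <- assign_bins(genes, cm, e$bin_width)
  prof <- enrichment_profile(degs, bins, n_bins = e$n_bins)
  write_enrichment(prof, file.path(cfg$outdir, "enrichment.tsv"))
  outputs <- "enrichment.tsv"
  if (any(!is.na(cm$centromere_start))) {
    cen <- centromere_control(degs, genes, cm, e$bin_width, e$n_bins)
    write_enrichment(cen, file.path(cfg$outdir, "centromere_enrichment.tsv"))
    outputs <- c(outputs, "centromere_enrichment.tsv")
  }
  list(inputs = c(e$annotation, e$chrom_map, e$degs),
       counts = list(genes_binned = nrow(bins),
                     degs = sum(degs$direction != "none")),
       outputs = outputs)
}

stage_network <- function(cfg) {
  nw <- cfg$network
  for (f in c(nw$ppi, nw$degs))
    if (!file.exists(f)) stop("input not found: ", f)
  degs <- utils::read.delim(nw$degs, stringsAsFactors = FALSE)
  degs <- degs[degs$direction %in% c("up", "down"), , drop = FALSE]
  edges <- load_ppi_edges(nw$ppi, nw$min_score)
  if (!is.null(nw$mapping)) {
    mapping <- utils::read.delim(nw$mapping, stringsAsFactors = FALSE)
    prot <- map_genes_to_proteins(degs$gene_id, mapping)
    degs <- degs[degs$gene_id %in% names(prot), , drop = FALSE]
    degs$node_id <- unname(prot[degs$gene_id])
  } else degs$node_id <- degs$gene_id
  sub <- extract_subnetwork(edges, degs$node_id)
  deg_tab <- node_degrees(sub, degs$node_id)
  out <- file.path(cfg$outdir, "degrees.tsv")
  utils::write.table(deg_tab, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cmp <- if (length(unique(degs$direction)) == 2)
    degree_comparison(deg_tab,
                      stats::setNames(degs$direction, degs$node_id))
  else NULL
  if (!is.null(cmp)) {
    summ <- data.frame(group = names(cmp$medians),
                       n = as.integer(cmp$n),
                       median_degree = as.numeric(cmp$medians),
                       ranksum_p = cmp$p)
    utils::write.table(summ, file.path(cfg$outdir, "degree_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(inputs = c(nw$ppi, nw$degs),
       counts = list(deg_nodes = nrow(deg_tab),
                     subnetwork_edges = nrow(sub)),
       outputs = c("degrees.tsv",
                   if (!is.null(cmp)) "degree_comparison.tsv"))
}

stage_hic <- function(cfg) {
  h <- cfg$hic
  for (f in c(h$loops, h$chrom_map))
    if (!file.exists(f)) stop("input not found: ", f)
  loops <- read_loops(h$loops)
  cm <- read_chrom_map(h$chrom_map)
  cls <- classify_loops(loops, cm, h$first_bin, h$window)
  utils::write.table(cls, file.path(cfg$outdir, "loop_classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  frac <- subtelomeric_fraction(cls, by_source = TRUE)
  summ <- frac$per_source
  summ <- rbind(summ, data.frame(source = "pooled",
                                 telomeric = sum(cls$telomeric),
                                 contained = sum(cls$contained),
                                 pct = frac$pooled))
  utils::write.table(summ, file.path(cfg$outdir, "loop_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(inputs = c(h$loops, h$chrom_map),
       counts = list(loops = nrow(loops),
                     telomeric = sum(cls$telomeric),
                     contained = sum(cls$contained)),
       outputs = c("loop_classification.tsv", "loop_summary.tsv"))
}
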