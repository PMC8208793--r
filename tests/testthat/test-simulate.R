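test_that("generators are byte-deterministic given the same truth", {
  truth <- synthetic_truth(theta = 2, seed = 99)
  g1 <- simulate_genome(2, 3e7, 500, truth)
  g2 <- simulate_genome(2, 3e7, 500, truth)
  expect_identical(g1, g2)
  e1 <- simulate_expression(g1$genes, g1$chrom_map, 30, truth)
  e2 <- simulate_expression(g1$genes, g1$chrom_map, 30, truth)
  expect_identical(e1, e2)
  l1 <- simulate_loops(g1$chrom_map, 200, truth)
  expect_identical(l1, simulate_loops(g1$chrom_map, 200, truth))
  p1 <- simulate_ppi(g1$genes$gene_id, 4, 2, e1$labels$direction, truth)
  expect_identical(p1, simulate_ppi(g1$genes$gene_id, 4, 2,
                                    e1$labels$direction, truth))
})

test_that("simulated genomes respect chromosome geometry", {
  truth <- synthetic_truth(seed = 1)
  sim <- simulate_genome(2, 5e7, 1000, truth)
  expect_equal(nrow(sim$genes), 1000)
  d <- distance_to_chromosome_end(sim$genes, sim$chrom_map)
  expect_true(all(d <= 2.5e7))
  # TSS are unique within each chromosome and outside the centromere
  tss <- gene_position(sim$genes)
  expect_false(any(duplicated(paste(sim$genes$chrom, tss))))
  cs <- sim$chrom_map$centromere_start[1]
  ce <- sim$chrom_map$centromere_end[1]
  expect_false(any(tss >= cs & tss <= ce))
  expect_error(simulate_genome(2, 5e7, 0, truth), "at least one gene")
  expect_error(simulate_genome(2, 1e7, 100, truth), "20 Mb")
})

test_that("expression truth labels are internally consistent", {
  truth <- synthetic_truth(theta = 4, seed = 5)
  sim <- simulate_genome(2, 3e7, 800, truth)
  expr <- simulate_expression(sim$genes, sim$chrom_map, 40, truth)
  lab <- expr$labels
  expect_setequal(unique(lab$direction), c("up", "down", "none"))
  expect_true(all((lab$direction == "none") == !lab$is_deg))
  expect_true(all(sign(lab$beta[lab$direction == "up"]) == 1))
  expect_true(all(sign(lab$beta[lab$direction == "down"]) == -1))
  expect_true(all(lab$beta[!lab$is_deg] == 0))
  expect_equal(dim(expr$counts), c(800, 40))
  expect_true(all(expr$counts >= 0))
  expect_true(all(expr$meta$age >= 20 & expr$meta$age <= 79))
  expect_equal(sum(expr$meta$sex == "male"), 20)
  expect_error(simulate_expression(sim$genes, sim$chrom_map, 10, truth),
               "at least 20")
})

test_that("a null truth plants no direction bias near chromosome ends", {
  truth <- synthetic_truth(theta = 1, seed = 6)
  sim <- simulate_genome(4, 6e7, 5000, truth)
  expr <- simulate_expression(sim$genes, sim$chrom_map, 20, truth)
  lab <- expr$labels[expr$labels$is_deg, ]
  inbin <- lab$bin_index <= 2
  p <- stats::prop.test(
    c(sum(lab$direction[inbin] == "up"), sum(lab$direction[!inbin] == "up")),
    c(sum(inbin), sum(!inbin)))$p.value
  expect_gt(p, 0.01)
})

test_that("DEG recall is high at generous signal strength", {
  truth <- synthetic_truth(theta = 1, deg_fraction = 0.25,
                           beta_mean = 0.04, beta_sd = 0.005,
                           dispersion = 0.05, seed = 7)
  sim <- simulate_genome(2, 3e7, 1000, truth)
  expr <- simulate_expression(sim$genes, sim$chrom_map, 200, truth)
  fit <- fit_age_degs(expr$counts, expr$meta)
  merged <- merge(fit$table, expr$labels, by = "gene_id")
  recall <- mean(merged$direction.x[merged$is_deg] != "none")
  expect_gte(recall, 0.9)
  called <- merged$is_deg & merged$direction.x != "none"
  expect_true(all(merged$direction.x[called] == merged$direction.y[called]))
})

test_that("loop containment extremes behave exactly", {
  cm <- chrom_map(c("chr1", "chr2"), c(5e7, 5e7))
  all_in <- simulate_loops(cm, 300, synthetic_truth(loop_containment = 1,
                                                    seed = 8))
  cls <- classify_loops(all_in, cm)
  expect_equal(subtelomeric_fraction(cls), 100)
  none_in <- simulate_loops(cm, 300, synthetic_truth(loop_containment = 0,
                                                     seed = 9))
  cls0 <- classify_loops(none_in, cm)
  expect_equal(subtelomeric_fraction(cls0), 0)
  expect_equal(nrow(long_range_report(cls0)), 300)
  expect_true(all(cls0$d_far <= 11e6))
})

test_that("PPI simulation scales connectivity by group", {
  truth <- synthetic_truth(seed = 10)
  ids <- paste0("g", 1:400)
  labels <- rep(c("up", "down"), each = 200)
  expect_equal(nrow(simulate_ppi(ids, 0, 3, labels, truth)), 0)
  edges <- simulate_ppi(ids, 4, 3, labels, truth)
  deg <- node_degrees(edges, ids)
  m_up <- mean(deg$degree[match(ids[labels == "up"], deg$gene_id)])
  m_down <- mean(deg$degree[match(ids[labels == "down"], deg$gene_id)])
  expect_gt(m_down / m_up, 2)
  expect_true(all(edges$score >= 0.9 & edges$score <= 1))
})
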