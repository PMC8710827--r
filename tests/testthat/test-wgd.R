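test_that("majority-rank block classification follows the dotplot rule", {
  ga <- toy_genome("a", n_genes = 30)
  gb <- toy_genome("b", n_genes = 30)
  mk <- function(ranks) {
    h <- toy_hits(ga, gb, x = seq_along(ranks), y = seq_along(ranks),
                  rank = ranks)
    classify_blocks(chain_anchors(h, ga, gb, min_block_pairs = 2))
  }
  expect_equal(mk(c(1, 1, 1, 2, 1))$blocks$class, "orthologous")
  expect_equal(mk(c(2, 2, 3, 2))$blocks$class, "outparalogous")

  h <- toy_hits(ga, gb, x = 1:4, y = 1:4, rank = 1L)
  b <- chain_anchors(h, ga, gb, min_block_pairs = 2)
  b$pairs$rank <- NA_integer_
  expect_error(classify_blocks(b), "rank")
})

test_that("an exact 50% rank-1 tie is resolved against competing blocks", {
  ga <- toy_genome("a", n_genes = 40)
  gb <- toy_genome("b", n_chrom = 2, n_genes = 40)
  # two blocks over the same reference span: ranks (1,2,1,2) vs (3,4,3,4)
  h <- data.frame(query_gene = rep(sprintf("a_g%03d", 1:4), 2),
                  subject_gene = c(sprintf("b_g%03d", 1:4),
                                   sprintf("b_g%03d", 41:44)),
                  score = 100, evalue = 0, match_fraction = 1,
                  rank = c(1, 2, 1, 2, 3, 4, 3, 4),
                  stringsAsFactors = FALSE)
  b <- classify_blocks(chain_anchors(h, ga, gb, min_block_pairs = 2))
  expect_equal(nrow(b$blocks), 2)
  cls <- setNames(b$blocks$class, b$blocks$chrom_b)
  expect_equal(unname(cls["chr1"]), "orthologous")   # tie, lower mean rank
  expect_equal(unname(cls["chr2"]), "outparalogous")
})

test_that("an identical genome maps with multiplicity 1", {
  set.seed(15)
  cds <- setNames(vapply(1:40, function(i) grasswgd:::random_cds(80), ""),
                  sprintf("a_g%03d", 1:40))
  ga <- toy_genome("a", n_genes = 40)
  ga$cds <- cds; ga$proteins <- grasswgd:::translate_cds(cds)
  gb <- toy_genome("b", n_genes = 40)
  gb$cds <- setNames(cds, sprintf("b_g%03d", 1:40))
  gb$proteins <- grasswgd:::translate_cds(gb$cds)
  hits <- find_homologs(ga$proteins, gb$proteins)
  mr <- infer_multiplicity(classify_blocks(chain_anchors(hits, ga, gb)),
                           ga)
  expect_equal(mr$modal_multiplicity, 1)
  expect_equal(mr$inferred_extra_wgd_count, 0L)
})

test_that("one lineage-specific WGD doubles the syntenic multiplicity", {
  for (seed in c(101, 202)) {
    sc <- wgd_scenario(n_chromosomes = 2, genes_per_chromosome = 80,
                       specific_wgd_ds = 0.15, ortholog_ds = 0.45,
                       retention_prob = 0.7, cds_length_codons = 150,
                       seed = seed)
    sim <- simulate_wgd_genome(sc)
    hits <- find_homologs(sim$reference$proteins, sim$focal$proteins)
    blocks <- classify_blocks(chain_anchors(hits, sim$reference,
                                            sim$focal))
    mr <- infer_multiplicity(blocks, sim$reference)
    expect_equal(mr$modal_multiplicity, 2, label = paste("seed", seed))
  }
})

test_that("two stacked WGDs quadruple the count of collinear regions", {
  sc <- wgd_scenario(n_chromosomes = 2, genes_per_chromosome = 60,
                     specific_wgd_ds = c(0.3, 0.15), ortholog_ds = 0.45,
                     retention_prob = 0.9, cds_length_codons = 150,
                     seed = 77)
  sim <- simulate_wgd_genome(sc)
  hits <- find_homologs(sim$reference$proteins, sim$focal$proteins)
  blocks <- chain_anchors(hits, sim$reference, sim$focal)
  # no duplication predates the split here, so there is no outparalogous
  # tier: every collinear region is orthologous correspondence
  mr <- infer_multiplicity(blocks, sim$reference, classes = NULL)
  expect_equal(mr$modal_multiplicity, 4)
  expect_equal(mr$inferred_extra_wgd_count, 2L)
})

test_that("proportional calibration is linear and anchored", {
  cal <- list(ks_cal = 0.6, age_cal = 96)
  expect_equal(date_event(0.6, cal), 96)
  expect_equal(date_event(0.3, cal), 48)
  expect_equal(date_event(0.15, cal), 24)
  expect_equal(date_event(2 * 0.21, cal), 2 * date_event(0.21, cal))
  expect_error(date_event(-1, cal), "positive")
})

test_that("mixture peak detection recovers planted block-mean structures", {
  set.seed(55)
  one <- rlnorm(150, log(0.5), 0.12)
  p1 <- detect_ks_peaks(one)
  expect_lt(abs(p1$mode[which.max(p1$weight)] - 0.5), 0.05)

  two <- c(rlnorm(150, log(0.15), 0.12), rlnorm(150, log(0.5), 0.1))
  p2 <- detect_ks_peaks(two)
  expect_gte(attr(p2, "n_components"), 2)
  expect_lt(abs(min(p2$mode) - 0.15), 0.03)
  expect_lt(abs(max(p2$mode) - 0.5), 0.05)
  expect_false(attr(p2, "kde_flag"))

  degenerate <- rep(0.4, 60)
  pd <- detect_ks_peaks(degenerate)
  expect_equal(nrow(pd), 1)
  expect_equal(pd$mode, 0.4, tolerance = 1e-8)
  expect_error(detect_ks_peaks(rlnorm(10, log(0.3), 0.1)), "at least 50")
})

test_that("block-average Ks respects the window and the minimum pair count", {
  ga <- toy_genome("a", n_genes = 30)
  gb <- toy_genome("b", n_genes = 30)
  h <- toy_hits(ga, gb, x = 1:6, y = 1:6)
  b <- chain_anchors(h, ga, gb, min_block_pairs = 2)
  b$pairs$ks <- c(0.1, 0.2, 0.3, 2.5, NA, 0.4)  # 2.5 out of window, NA dropped
  expect_equal(unname(block_ks_distribution(b, min_pairs_for_mean = 3)),
               mean(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(length(block_ks_distribution(b, min_pairs_for_mean = 5)), 0)
  b$pairs$ks <- rep(NA_real_, 6)
  expect_warning(res <- block_ks_distribution(b), "saturated")
  expect_equal(length(res), 0)
})

test_that("karyotype painting recovers planted fusion counts exactly", {
  # single-origin chromosome: one segment, no fusion
  ga <- toy_genome("a", n_genes = 30)
  map1 <- setNames(rep("AGK1", 30), ga$genes$gene_id)
  kp1 <- paint_karyotype(ga, map1)
  expect_equal(nrow(kp1$segments), 1)
  expect_false(any(kp1$fusions$fusion_flag))

  # hand-built fusion: two origin labels on one chromosome
  map2 <- setNames(rep(c("AGK1", "AGK2"), each = 15), ga$genes$gene_id)
  kp2 <- paint_karyotype(ga, map2)
  expect_true(kp2$fusions$fusion_flag)
  expect_equal(nrow(kp2$segments), 2)

  # simulated genome with three planted fusions
  sc <- wgd_scenario(n_chromosomes = 6, genes_per_chromosome = 40,
                     specific_wgd_ds = 0.15, ortholog_ds = 0.45,
                     retention_prob = 0.8, n_fusions = 3,
                     cds_length_codons = 51, seed = 21)
  sim <- simulate_wgd_genome(sc)
  agk <- setNames(sim$truth$genes$proto_chromosome,
                  sim$truth$genes$gene_id)
  kp <- paint_karyotype(sim$focal, agk[sim$focal$genes$gene_id])
  expect_equal(sum(kp$fusions$fusion_flag), 3)
  expect_setequal(kp$fusions$chromosome[kp$fusions$fusion_flag],
                  sim$truth$fused_chromosomes)

  # chromosome with no mapped genes is labelled unassigned
  kp0 <- paint_karyotype(ga, setNames(rep(NA_character_, 30),
                                      ga$genes$gene_id))
  expect_equal(kp0$segments$label, "unassigned")
})
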