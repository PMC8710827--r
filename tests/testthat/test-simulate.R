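test_that("scenario constructors validate their parameter spaces", {
  expect_error(wgd_scenario(retention_prob = 0), "retention_prob")
  expect_error(wgd_scenario(specific_wgd_ds = 0.5, ortholog_ds = 0.45),
               "specific_wgd_ds")
  expect_error(wgd_scenario(shared_wgd_ds = 0.4, ortholog_ds = 0.45),
               "ortholog_ds")
  expect_error(expression_scenario(de_fraction = 1.5), "de_fraction")
  expect_error(expression_scenario(pattern_mix = c(I = 0.5, II = 0.5,
                                                   III = 0.5, IV = 0.5)),
               "pattern_mix")
  expect_error(kmer_scenario(coverage = 0), "coverage")
  expect_error(kmer_scenario(k = 16), "odd")
})

test_that("the same seed reproduces byte-identical simulations", {
  sc <- wgd_scenario(n_chromosomes = 2, genes_per_chromosome = 20,
                     cds_length_codons = 60, seed = 99)
  s1 <- simulate_wgd_genome(sc)
  s2 <- simulate_wgd_genome(sc)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  es <- expression_scenario(n_genes = 200, seed = 42)
  expect_identical(serialize(simulate_counts(es), NULL),
                   serialize(simulate_counts(es), NULL))

  ks <- kmer_scenario(genome_size_bp = 1e5, seed = 7)
  expect_identical(serialize(simulate_kmer_histogram(ks), NULL),
                   serialize(simulate_kmer_histogram(ks), NULL))
})

test_that("lossless duplication yields exactly two focal orthologs per reference gene", {
  sc <- wgd_scenario(n_chromosomes = 2, genes_per_chromosome = 25,
                     retention_prob = 1, n_fusions = 0, inversion_rate = 0,
                     cds_length_codons = 60, seed = 13)
  sim <- simulate_wgd_genome(sc)
  tr <- sim$truth$relations
  orth <- tr[tr$relation == "ortholog", ]
  per_ref <- table(orth$gene_1)
  expect_true(all(per_ref == 2))
  spec <- tr[tr$relation == "specific_paralog", ]
  per_focal <- table(c(spec$gene_1, spec$gene_2))
  expect_true(all(per_focal == 1))        # exactly one surviving partner
  expect_equal(nrow(sim$focal$genes), 2 * nrow(sim$reference$genes))
})

test_that("specific-only scenarios put all paralog pairs at the specific target ds", {
  sc <- wgd_scenario(n_chromosomes = 2, genes_per_chromosome = 15,
                     shared_wgd_ds = NA, specific_wgd_ds = 0.15,
                     retention_prob = 1, cds_length_codons = 60, seed = 3)
  sim <- simulate_wgd_genome(sc)
  spec <- sim$truth$relations[
    sim$truth$relations$relation == "specific_paralog", ]
  expect_true(all(spec$target_ds == 0.15))
  expect_false(any(sim$truth$relations$relation == "shared_paralog"))
})

test_that("fractionation survival tracks the retention probability", {
  sc <- wgd_scenario(n_chromosomes = 4, genes_per_chromosome = 250,
                     retention_prob = 0.7, cds_length_codons = 51, seed = 8)
  sim <- simulate_wgd_genome(sc)
  tg <- sim$truth$genes
  n_copies <- 2 * sc$n_chromosomes * sc$genes_per_chromosome
  surv <- nrow(tg[tg$genome == "focal", ]) / n_copies
  se <- sqrt(0.7 * 0.3 / n_copies)
  expect_lt(abs(surv - 0.7), 3 * se)
})

test_that("planted expression truth matches the requested design", {
  es0 <- expression_scenario(n_genes = 300, de_fraction = 0, seed = 1)
  sim0 <- simulate_counts(es0)
  expect_equal(nrow(sim0$truth$effects), 0)

  pairs <- data.frame(copy_1 = sprintf("L%03d", 1:200),
                      copy_2 = sprintf("R%03d", 1:200))
  es <- expression_scenario(n_genes = 600, seed = 2)
  sim <- simulate_counts(es, pairs)
  tt <- sim$truth$pairs
  expect_equal(nrow(tt), 200)
  # planted pattern III pairs regulate the same tissue in opposite ways
  for (i in which(tt$pattern == "III")) {
    e1 <- sim$truth$effects[sim$truth$effects$gene_id == tt$copy_1[i], ]
    e2 <- sim$truth$effects[sim$truth$effects$gene_id == tt$copy_2[i], ]
    expect_equal(unique(e1$tissue), unique(e2$tissue))
    expect_true(all(sign(e1$log2fc) == -sign(e2$log2fc)))
  }
  # category allocation is deterministic given the mix
  alloc <- grasswgd:::apportion(200, es$category_mix)
  expect_equal(unname(table(tt$category)[c("neither_deg", "one_deg",
                                           "both_deg")]),
               unname(alloc), ignore_attr = TRUE)
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  es <- expression_scenario(n_genes = 1000, nb_dispersion = 0,
                            de_fraction = 0, baseline_log_mean = log(500),
                            baseline_log_sd = 0.2, seed = 6)
  sim <- simulate_counts(es)
  grp <- sim$design$sample_id[sim$design$tissue == "root" &
                                sim$design$time_h == 0]
  sub <- sim$counts[, grp]
  ratio <- apply(sub, 1, var) / rowMeans(sub)
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("pattern mixes that cannot be realized raise an error", {
  pairs <- data.frame(copy_1 = c("a1", "a2"), copy_2 = c("b1", "b2"))
  es <- expression_scenario(n_genes = 100,
                            category_mix = c(neither = 0, one = 0,
                                             both = 1),
                            seed = 3)
  # 2 both-DE pairs cannot carry 4 positive pattern proportions
  expect_error(simulate_counts(es, pairs), "pattern_mix incompatible")
})
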