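test_that("TPM matches its closed form and normalises every sample to 1e6", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- compute_tpm(counts, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  one <- matrix(7, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(unname(compute_tpm(one, c(g1 = 123))[1, 1]), 1e6)

  set.seed(4)
  for (i in 1:20) {
    n <- sample(5:40, 1); m <- sample(2:6, 1)
    cm <- matrix(rpois(n * m, 50), n, m,
                 dimnames = list(sprintf("g%d", 1:n), sprintf("s%d", 1:m)))
    lens <- setNames(sample(200:5000, n), rownames(cm))
    expect_equal(unname(colSums(compute_tpm(cm, lens))), rep(1e6, m),
                 tolerance = 1e-6)
  }
  zero <- matrix(0L, 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_warning(tz <- compute_tpm(zero, c(g1 = 100, g2 = 100)),
                 "all-zero")
  expect_equal(unname(tz[, 1]), c(0, 0))
})

test_that("the NB Wald test controls type-I error on null simulations", {
  for (seed in 1:3) {
    es <- expression_scenario(n_genes = 2000, de_fraction = 0, seed = seed)
    sim <- simulate_counts(es)
    degs <- call_degs(sim$counts, sim$design, "root", 6)
    frac <- mean(degs$is_deg)
    tol <- 3 * sqrt(0.05 * 0.95 / nrow(degs))
    expect_lte(frac, 0.05 + tol)
  }
})

test_that("strong planted effects are detected with high power", {
  set.seed(9)
  n <- 500
  design <- salt_design(replicates = 4)
  mu <- matrix(100, n, nrow(design),
               dimnames = list(sprintf("g%d", 1:n), design$sample_id))
  trt <- design$sample_id[design$tissue == "root" & design$time_h == 6]
  planted <- sprintf("g%d", 1:50)
  mu[planted, trt] <- 400               # planted 4-fold change
  counts <- matrix(rnbinom(length(mu), size = 10, mu = mu), n,
                   dimnames = dimnames(mu))
  degs <- call_degs(counts, design, "root", 6)
  hit <- degs$is_deg & !is.na(degs$direction) & degs$direction == "up"
  expect_gte(mean(hit[match(planted, degs$gene_id)]), 0.8)
  expect_lte(mean(degs$is_deg[!degs$gene_id %in% planted]), 0.02)

  # identical groups give log2fc exactly 0
  flat <- matrix(rep(rpois(n, 50), nrow(design)), n,
                 dimnames = dimnames(mu))
  d0 <- call_degs(flat, design, "root", 6)
  expect_true(all(d0$log2fc == 0))
  expect_false(any(d0$is_deg))
})

test_that("DEG calls agree with an independent NB implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  n <- 400
  design <- salt_design(replicates = 4)
  mu <- matrix(exp(rnorm(n, log(150), 0.7)), n, nrow(design),
               dimnames = list(sprintf("g%d", 1:n), design$sample_id))
  trt <- design$sample_id[design$tissue == "root" & design$time_h == 6]
  de_idx <- sample(n, 80)
  mu[de_idx, trt] <- mu[de_idx, trt] * rep(c(8, 1 / 8), 40)
  counts <- matrix(rnbinom(length(mu), size = 10, mu = mu), n,
                   dimnames = dimnames(mu))
  mine <- call_degs(counts, design, "root", 6)

  sel <- design$tissue == "root" & design$time_h %in% c(0, 6)
  cd <- data.frame(condition = factor(design$time_h[sel],
                                      levels = c(0, 6)))
  dds <- DESeq2::DESeqDataSetFromMatrix(counts[, design$sample_id[sel]],
                                        cd, ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds)
  theirs <- rownames(res)[!is.na(res$padj) & res$padj < 0.05 &
                            abs(res$log2FoldChange) >= 1]
  ours <- mine$gene_id[mine$is_deg]
  jac <- length(intersect(ours, theirs)) / length(union(ours, theirs))
  expect_gt(jac, 0.7)
  # planted genes dominate both call sets
  expect_gt(mean(ours %in% rownames(counts)[de_idx]), 0.9)
})

test_that("fate signatures classify the four canonical patterns", {
  mk_degs <- function(...) {
    sig <- list(...)
    base <- expand.grid(gene_id = names(sig), tissue = c("root", "shoot"),
                        time_h = c(6, 24), stringsAsFactors = FALSE)
    base$log2fc <- 0; base$pvalue <- 1; base$fdr <- 1
    base$is_deg <- FALSE; base$direction <- NA_character_
    for (g in names(sig)) {
      for (s in sig[[g]]) {
        parts <- strsplit(s, ":")[[1]]
        i <- base$gene_id == g & base$tissue == parts[1]
        base$is_deg[i] <- TRUE
        base$direction[i] <- parts[2]
        base$log2fc[i] <- if (parts[2] == "up") 2 else -2
        base$fdr[i] <- 0.001
      }
    }
    base
  }
  pair <- data.frame(copy_1 = "c1", copy_2 = "c2")
  cls <- function(s1, s2) {
    degs <- mk_degs(c1 = s1, c2 = s2)
    classify_fate(pair, degs)
  }
  expect_equal(cls("root:up", "root:up")$pattern, "I")
  expect_equal(cls("root:up", "shoot:up")$pattern, "II")
  expect_equal(cls("root:up", "root:down")$pattern, "III")
  expect_equal(cls("root:up", "shoot:down")$pattern, "IV")
  one <- cls("root:up", character(0))
  expect_equal(one$category, "one_deg")
  expect_true(is.na(one$pattern))
  neither <- cls(character(0), character(0))
  expect_equal(neither$category, "neither_deg")
})

test_that("fate summaries partition pairs and reproduce printed-ratio arithmetic", {
  pairs <- data.frame(
    copy_1 = sprintf("x%04d", 1:6796), copy_2 = sprintf("y%04d", 1:6796),
    category = rep(c("neither_deg", "one_deg", "both_deg"),
                   c(5347, 1047, 402)),
    pattern = c(rep(NA, 6394), rep(c("I", "II", "III", "IV"),
                                   c(258, 108, 10, 26))),
    stringsAsFactors = FALSE)
  s <- summarize_fate(pairs)
  expect_equal(sum(s$categories$n), 6796)
  expect_equal(sum(s$patterns$n), 402)
  # 402/6796 = 5.91524..% rounds half-up to 5.92
  expect_equal(s$categories$pct, c(78.68, 15.41, 5.92))
  expect_equal(s$patterns$pct, c(64.18, 26.87, 2.49, 6.47))

  empty <- summarize_fate(pairs[0, ])
  expect_equal(nrow(empty$categories), 0)
})

test_that("planted pattern mixes are recovered end to end within 5 points", {
  pairs <- data.frame(copy_1 = sprintf("A%04d", 1:800),
                      copy_2 = sprintf("B%04d", 1:800))
  es <- expression_scenario(n_genes = 2500, de_log2fc = 3,
                            baseline_log_mean = log(300),
                            baseline_log_sd = 0.5, seed = 12)
  sim <- simulate_counts(es, pairs)
  degs <- call_all_degs(sim$counts, sim$design)
  got <- summarize_fate(classify_fate(pairs, degs))
  planted_cat <- grasswgd:::apportion(800, es$category_mix)
  expect_true(all(abs(got$categories$pct -
                        100 * planted_cat / 800) <= 5))
  planted_pat <- grasswgd:::apportion(planted_cat[["both"]],
                                      es$pattern_mix)
  expect_true(all(abs(got$patterns$pct -
                        100 * planted_pat / sum(planted_pat)) <= 5))
  # partition property holds
  expect_equal(sum(got$categories$n), 800)
  expect_equal(sum(got$patterns$n),
               got$categories$n[got$categories$category == "both_deg"])
})

test_that("fold regulation uses pseudo-counted group means", {
  design <- salt_design(replicates = 2)
  tpm <- matrix(10, 3, nrow(design),
                dimnames = list(c("g1", "g2", "g3"), design$sample_id))
  trt <- design$sample_id[design$tissue == "root" & design$time_h == 6]
  tpm["g2", trt] <- 20
  tpm["g3", ] <- 0
  tpm["g3", trt] <- 10
  fr <- fold_regulation(tpm, design, "root", 6)
  expect_equal(unname(fr["g1"]), 1)
  expect_equal(unname(fr["g2"]), 20.5 / 10.5)
  expect_equal(unname(fr["g3"]), 10.5 / 0.5)  # finite despite zero control
})
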