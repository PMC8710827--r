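#' Default salt-stress RNA-seq design
#'
#' Root and shoot tissue, sampled at 0, 6 and 24 h after salt treatment,
#' with four biological replicates per group.
#'
#' @param replicates Replicates per (tissue, time) group.
#' @param drop_shoot24_rep If `TRUE`, one shoot 24 h replicate is dropped
#'   (mirroring a discarded library in typical designs).
#' @return A design data.frame (`sample_id`, `tissue`, `time_h`,
#'   `replicate`).
#' @export
salt_design <- function(replicates = 4L, drop_shoot24_rep = FALSE) {
  design <- expand.grid(replicate = seq_len(replicates),
                        time_h = c(0, 6, 24),
                        tissue = c("root", "shoot"),
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%dh_r%d", design$tissue, design$time_h,
                              design$replicate)
  design <- design[, c("sample_id", "tissue", "time_h", "replicate")]
  if (drop_shoot24_rep)
    design <- design[!(design$tissue == "shoot" & design$time_h == 24 &
                         design$replicate == replicates), ]
  rownames(design) <- NULL
  design
}

#' Expression simulation scenario
#'
#' Negative-binomial RNA-seq counts with log-normal baselines and planted
#' (tissue, time)-specific fold changes.  When paralog pairs are supplied
#' to [simulate_counts()], pairs are planted to realize `category_mix`
#' (no copy DE / one copy DE / both copies DE) and, among both-DE pairs,
#' `pattern_mix` over the four expression-fate patterns.  The default
#' mixes follow the proportions typically reported for duplicate pairs
#' under salt stress (roughly 79/15/6 across categories and 64/27/2/7
#' across patterns I-IV).
#'
#' @param n_genes Total number of genes in the matrix.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   per-gene baseline mean (natural-log scale).
#' @param nb_dispersion NB dispersion `alpha` (variance `mu + alpha*mu^2`).
#' @param de_fraction Fraction of background genes with planted effects.
#' @param de_log2fc Planted |log2 fold change|.
#' @param design Design table, see [salt_design()].
#' @param pattern_mix Named proportions for patterns `I`-`IV`; must sum
#'   to 1.
#' @param category_mix Named proportions for `neither`/`one`/`both`.
#' @param seed Integer seed.
#' @return A list of class `expression_scenario`.
#' @export
expression_scenario <- function(n_genes = 2000,
                                baseline_log_mean = log(150),
                                baseline_log_sd = 1,
                                nb_dispersion = 0.1,
                                de_fraction = 0.15,
                                de_log2fc = 2,
                                design = salt_design(),
                                pattern_mix = c(I = 0.6418, II = 0.2686,
                                                III = 0.0249, IV = 0.0647),
                                category_mix = c(neither = 0.7868,
                                                 one = 0.1541,
                                                 both = 0.0591),
                                seed = 1L) {
  if (de_fraction < 0 || de_fraction > 1)
    gw_stop("expression_scenario(): de_fraction must be in [0, 1]")
  if (abs(sum(pattern_mix) - 1) > 1e-8)
    gw_stop("expression_scenario(): pattern_mix must sum to 1")
  if (abs(sum(category_mix) - 1) > 1e-8)
    gw_stop("expression_scenario(): category_mix must sum to 1")
  design <- validate_design(design)
  structure(list(n_genes = n_genes, baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 nb_dispersion = nb_dispersion, de_fraction = de_fraction,
                 de_log2fc = de_log2fc, design = design,
                 pattern_mix = pattern_mix, category_mix = category_mix,
                 seed = as.integer(seed)),
            class = "expression_scenario")
}

## deterministic apportionment of n into round(mix*n) with remainder
## assigned by largest fractional part (keeps planted proportions exact)
apportion <- function(n, mix) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

#' Simulate an RNA-seq count matrix with planted differential expression
#'
#' Draws NB counts around log-normal baselines and plants
#' (tissue, time)-specific fold changes.  If `paralog_pairs` is given
#' (a data.frame with `copy_1`, `copy_2`), pairs are allocated across
#' DE categories and patterns I-IV deterministically according to the
#' scenario mixes; planted signatures apply at both 6 and 24 h in the
#' chosen tissue(s).
#'
#' @param scenario An [expression_scenario].
#' @param paralog_pairs Optional data.frame of focal duplicate pairs.
#' @return `list(counts, design, truth)`; `truth$effects` lists every
#'   planted (gene, tissue, time, log2fc) and `truth$pairs` the planted
#'   category/pattern per pair.
#' @export
simulate_counts <- function(scenario, paralog_pairs = NULL) {
  stopifnot(inherits(scenario, "expression_scenario"))
  set.seed(scenario$seed)
  design <- scenario$design
  pair_genes <- character(0)
  if (!is.null(paralog_pairs) && nrow(paralog_pairs)) {
    pair_genes <- unique(c(paralog_pairs$copy_1, paralog_pairs$copy_2))
    if (anyDuplicated(c(paralog_pairs$copy_1, paralog_pairs$copy_2)))
      gw_stop("simulate_counts(): a gene appears in more than one pair")
  }
  n_bg <- max(0L, scenario$n_genes - length(pair_genes))
  gene_ids <- c(pair_genes, sprintf("bg%05d", seq_len(n_bg)))
  n <- length(gene_ids)
  baseline <- rlnorm(n, scenario$baseline_log_mean, scenario$baseline_log_sd)
  names(baseline) <- gene_ids

  effects <- list()
  add_effect <- function(gene, tissue, dir) {
    for (t in c(6, 24))
      effects[[length(effects) + 1L]] <<- data.frame(
        gene_id = gene, tissue = tissue, time_h = t,
        log2fc = dir * scenario$de_log2fc, stringsAsFactors = FALSE)
  }

  pair_truth <- NULL
  if (length(pair_genes)) {
    np <- nrow(paralog_pairs)
    cat_n <- apportion(np, scenario$category_mix)
    if (cat_n[["both"]] > 0) {
      if (cat_n[["both"]] < sum(scenario$pattern_mix > 0))
        gw_stop("simulate_counts(): pattern_mix incompatible with the ",
                "available both-DE pair count (", cat_n[["both"]], ")")
      pat_n <- apportion(cat_n[["both"]], scenario$pattern_mix)
    } else pat_n <- stats::setNames(integer(4), names(scenario$pattern_mix))
    category <- sample(rep(names(cat_n), cat_n))
    pattern <- rep(NA_character_, np)
    pattern[category == "both"] <- sample(rep(names(pat_n), pat_n))
    for (i in seq_len(np)) {
      g1 <- paralog_pairs$copy_1[i]; g2 <- paralog_pairs$copy_2[i]
      tis <- sample(c("root", "shoot"), 1)
      oth <- setdiff(c("root", "shoot"), tis)
      dir <- sample(c(-1, 1), 1)
      if (category[i] == "one") {
        add_effect(sample(c(g1, g2), 1), tis, dir)
      } else if (category[i] == "both") {
        switch(pattern[i],
               I = { add_effect(g1, tis, dir); add_effect(g2, tis, dir) },
               II = { add_effect(g1, tis, dir); add_effect(g2, oth, dir) },
               III = { add_effect(g1, tis, dir); add_effect(g2, tis, -dir) },
               IV = { add_effect(g1, tis, dir); add_effect(g2, oth, -dir) })
      }
    }
    pair_truth <- data.frame(copy_1 = paralog_pairs$copy_1,
                             copy_2 = paralog_pairs$copy_2,
                             category = ifelse(category == "neither",
                                               "neither_deg",
                                               ifelse(category == "one",
                                                      "one_deg", "both_deg")),
                             pattern = pattern, stringsAsFactors = FALSE)
  }
  if (n_bg > 0 && scenario$de_fraction > 0) {
    bg <- gene_ids[seq.int(length(pair_genes) + 1L, n)]
    de <- bg[runif(n_bg) <= scenario$de_fraction]
    for (g in de)
      add_effect(g, sample(c("root", "shoot"), 1), sample(c(-1, 1), 1))
  }
  effects <- if (length(effects)) do.call(rbind, effects) else
    data.frame(gene_id = character(), tissue = character(),
               time_h = numeric(), log2fc = numeric())

  lfc <- matrix(0, n, nrow(design),
                dimnames = list(gene_ids, design$sample_id))
  for (i in seq_len(nrow(effects))) {
    sel <- design$tissue == effects$tissue[i] &
      design$time_h == effects$time_h[i]
    lfc[effects$gene_id[i], sel] <- lfc[effects$gene_id[i], sel] +
      effects$log2fc[i]
  }
  mu <- baseline * 2^lfc
  alpha <- scenario$nb_dispersion
  counts <- if (alpha <= 1e-12) {
    matrix(rpois(length(mu), lambda = mu), nrow = n)
  } else {
    matrix(rnbinom(length(mu), size = 1 / alpha, mu = mu), nrow = n)
  }
  dimnames(counts) <- dimnames(lfc)
  list(counts = counts, design = design,
       truth = list(effects = effects, pairs = pair_truth,
                    baseline = baseline))
}

#' K-mer histogram simulation scenario
#'
#' Parameters of the read set whose k-mer spectrum is emulated: a main
#' coverage peak, a heterozygous peak at half depth scaled by the
#' heterozygosity, and error k-mers concentrated at depth 1-2.
#'
#' @param genome_size_bp Haploid genome size in bp.
#' @param coverage Mean sequencing depth.
#' @param error_rate Per-base sequencing error probability.
#' @param heterozygosity Fraction of sites heterozygous.
#' @param k Odd k-mer length (>= 11 for real data; default 17).
#' @param read_length Read length used for the k-mers-per-read geometry.
#' @param seed Integer seed.
#' @return A list of class `kmer_scenario`.
#' @export
kmer_scenario <- function(genome_size_bp = 5e6, coverage = 52,
                          error_rate = 0.002, heterozygosity = 0.005,
                          k = 17L, read_length = 150L, seed = 1L) {
  if (coverage <= 0) gw_stop("kmer_scenario(): coverage must be > 0")
  if (k %% 2L == 0L) gw_stop("kmer_scenario(): k must be odd")
  if (heterozygosity * k >= 1)
    gw_stop("kmer_scenario(): heterozygosity too high for this k")
  structure(list(genome_size_bp = genome_size_bp, coverage = coverage,
                 error_rate = error_rate, heterozygosity = heterozygosity,
                 k = as.integer(k), read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "kmer_scenario")
}

#' Simulate a k-mer depth histogram
#'
#' `mode = "mixture"` composes the histogram directly: homozygous k-mers
#' at Poisson depths around the effective k-mer coverage
#' `c = coverage * (1 - error_rate)^k * (read_length - k + 1) /
#' read_length`, heterozygous k-mers (two allelic versions of the k
#' k-mers overlapping each heterozygous site) at depth `c / 2`, and error
#' k-mers at depth 1-2.  `mode = "reads"` synthesises reads from a random
#' diploid genome and counts canonical k-mers with [count_kmers()]
#' (practical only for small genomes).
#'
#' @param scenario A [kmer_scenario].
#' @param mode `"mixture"` or `"reads"`.
#' @return A [kmer_histogram].
#' @export
simulate_kmer_histogram <- function(scenario, mode = c("mixture", "reads")) {
  stopifnot(inherits(scenario, "kmer_scenario"))
  mode <- match.arg(mode)
  set.seed(scenario$seed)
  if (scenario$coverage < 5)
    warning("simulate_kmer_histogram(): coverage < 5 - error and ",
            "coverage peaks may merge")
  if (mode == "reads") return(simulate_kmer_reads(scenario))
  G <- scenario$genome_size_bp
  k <- scenario$k
  c_eff <- scenario$coverage * (1 - scenario$error_rate)^k *
    (scenario$read_length - k + 1) / scenario$read_length
  n_het_sites <- round(G * scenario$heterozygosity)
  n_het_kmers <- 2 * n_het_sites * k
  n_hom <- G - n_het_sites * k
  depths <- c(rpois(n_hom, c_eff), rpois(n_het_kmers, c_eff / 2))
  n_err <- round(G * scenario$coverage * scenario$error_rate * k /
                   (1 - scenario$error_rate))
  if (n_err > 0)
    depths <- c(depths, 1L + rbinom(n_err, 1L, 0.05))
  depths <- depths[depths > 0]
  tab <- table(depths)
  kmer_histogram(k, stats::setNames(as.numeric(tab), names(tab)))
}

simulate_kmer_reads <- function(sc) {
  if (sc$genome_size_bp > 2e6)
    gw_stop("simulate_kmer_histogram(mode = 'reads'): genome too large ",
            "for read-level simulation; use mode = 'mixture'")
  hap1 <- paste(sample(BASES, sc$genome_size_bp, replace = TRUE),
                collapse = "")
  hap2 <- hap1
  n_het <- round(sc$genome_size_bp * sc$heterozygosity)
  if (n_het > 0) {
    pos <- sample.int(sc$genome_size_bp, n_het)
    for (p in pos) {
      cur <- substr(hap2, p, p)
      substr(hap2, p, p) <- sample(setdiff(BASES, cur), 1)
    }
  }
  L <- sc$read_length
  n_reads <- round(sc$genome_size_bp * sc$coverage / L)
  starts <- sample.int(sc$genome_size_bp - L + 1L, n_reads, replace = TRUE)
  hap <- sample(1:2, n_reads, replace = TRUE)
  reads <- ifelse(hap == 1L, substring(hap1, starts, starts + L - 1L),
                  substring(hap2, starts, starts + L - 1L))
  if (sc$error_rate > 0) {
    n_err <- rbinom(n_reads, L, sc$error_rate)
    for (i in which(n_err > 0)) {
      for (p in sample.int(L, n_err[i])) {
        cur <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(BASES, cur), 1)
      }
    }
  }
  count_kmers(reads, sc$k)
}
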