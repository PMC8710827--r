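# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the package code.

# --- exhaustive codon-pathway oracle for NG86 counting -----------------
# Enumerates every ordering of the differing codon positions by explicit
# recursion (not the permutation-list approach used in the package),
# drops orderings that pass through stop codons, and averages the
# synonymous / nonsynonymous step counts.
oracle_codon_diff <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  walk <- function(cur, remaining, allow_stop) {
    if (!length(remaining)) return(list(c(s = 0, n = 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && gc[[nxt]] == "*") next
      step <- if (gc[[nxt]] == gc[[cur]]) c(s = 1, n = 0) else c(s = 0, n = 1)
      for (tail in walk(nxt, setdiff(remaining, p), allow_stop))
        out[[length(out) + 1L]] <- step + tail
    }
    out
  }
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(s = 0, n = 0))
  paths <- walk(c1, pos, allow_stop = FALSE)
  if (!length(paths)) paths <- walk(c1, pos, allow_stop = TRUE)
  Reduce(`+`, paths) / length(paths)
}

oracle_syn_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  s <- 0
  for (p in 1:3) {
    ref <- substr(codon, p, p)
    for (b in setdiff(c("A", "C", "G", "T"), ref)) {
      alt <- codon
      substr(alt, p, p) <- b
      if (gc[[alt]] == gc[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

# --- brute-force chain oracle ------------------------------------------
# Longest orientation-consistent chain by exhaustive depth-first search
# over all anchor subsets ordered on axis a (feasible for <= 12 anchors).
oracle_best_chain_size <- function(x, y, max_gap) {
  n <- length(x)
  best <- 0L
  extend <- function(last, count, sign_y) {
    best <<- max(best, count)
    for (i in seq_len(n)) {
      dx <- x[i] - x[last]
      dy <- sign_y * (y[i] - y[last])
      if (dx > 0 && dx <= max_gap && dy > 0 && dy <= max_gap)
        extend(i, count + 1L, sign_y)
    }
  }
  for (s in c(1L, -1L)) for (i in seq_len(n)) extend(i, 1L, s)
  best
}

# --- small helpers to build fixtures in code ---------------------------
toy_genome <- function(name, n_chrom = 1, n_genes = 10) {
  genes <- data.frame(
    gene_id = sprintf("%s_g%03d", name, seq_len(n_chrom * n_genes)),
    chromosome = rep(sprintf("chr%d", seq_len(n_chrom)), each = n_genes),
    start = rep(seq(1, by = 1000, length.out = n_genes), n_chrom),
    end = rep(seq(900, by = 1000, length.out = n_genes), n_chrom),
    strand = "+", stringsAsFactors = FALSE)
  genome(name, genes)
}

# anchors -> hits data.frame usable by chain_anchors on toy genomes
toy_hits <- function(genome_a, genome_b, x, y, rank = 1L) {
  ga <- genome_a$genes; gb <- genome_b$genes
  data.frame(query_gene = ga$gene_id[match(x, ga$order_index)],
             subject_gene = gb$gene_id[match(y, gb$order_index)],
             score = 100, evalue = 0, match_fraction = 1,
             rank = rep_len(rank, length(x)), stringsAsFactors = FALSE)
}
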