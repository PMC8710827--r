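## Homolog detection and collinear block chaining.

## Karlin-Altschul parameters for gapped BLOSUM62 (gap open 11, extend 1)
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Find homologous protein pairs between two proteomes
#'
#' All-vs-all protein comparison: candidate pairs sharing at least one
#' exact `word_size`-residue word are aligned locally (BLOSUM62, affine
#' gaps), scored in bits via the Karlin-Altschul formula with the subject
#' proteome as the database, and filtered at `evalue <= max_evalue` and
#' `match_fraction >= min_match_fraction` (aligned length over the
#' shorter protein).  Ranks are assigned per query by descending score,
#' ties broken by subject id.
#'
#' @param proteins_a,proteins_b Named character vectors of protein
#'   sequences; queries are `proteins_a`.  For an intra-genome search
#'   pass the same vector twice and set `self = TRUE`.
#' @param max_evalue,min_match_fraction Retention thresholds (defaults
#'   1e-5 and 0.5).
#' @param word_size Exact-word prefilter length (default 5).
#' @param self Intra-genome mode: self-hits are excluded and each
#'   unordered pair is aligned once.
#' @return data.frame `query_gene, subject_gene, score, evalue,
#'   match_fraction, rank` (score in bits).
#' @export
find_homologs <- function(proteins_a, proteins_b,
                          max_evalue = 1e-5, min_match_fraction = 0.5,
                          word_size = 5L, self = FALSE) {
  if (!length(proteins_a) || !length(proteins_b))
    gw_stop("find_homologs(): empty proteome")
  check_aa <- function(x, lab) {
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", x)
    if (any(bad))
      gw_stop("find_homologs(): non-amino-acid characters in ", lab,
              " sequence ", names(x)[bad][1])
  }
  check_aa(proteins_a, "query"); check_aa(proteins_b, "subject")
  cand <- word_candidates(proteins_a, proteins_b, word_size, self)
  if (!nrow(cand))
    return(empty_hits())
  db_size <- sum(nchar(proteins_b))
  mat <- blosum62()
  rows <- vector("list", length(unique(cand$subject)))
  ri <- 0L
  for (sb in unique(cand$subject)) {
    qs <- cand$query[cand$subject == sb]
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(proteins_a[qs]),
      Biostrings::AAString(proteins_b[[sb]]),
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = FALSE)
    raw <- Biostrings::score(pa)
    aln_len <- nchar(gsub("-", "", as.character(Biostrings::pattern(pa))))
    bits <- (KA_LAMBDA * raw - log(KA_K)) / log(2)
    evalue <- nchar(proteins_a[qs]) * db_size * 2^(-bits)
    mf <- aln_len / pmin(nchar(proteins_a[qs]), nchar(proteins_b[[sb]]))
    ri <- ri + 1L
    rows[[ri]] <- data.frame(query_gene = qs, subject_gene = sb,
                             score = bits, evalue = evalue,
                             match_fraction = mf, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue <= max_evalue &
                 hits$match_fraction >= min_match_fraction, , drop = FALSE]
  if (self && nrow(hits)) {
    ## symmetrise: each retained unordered pair is reported both ways
    rev <- hits
    rev$query_gene <- hits$subject_gene
    rev$subject_gene <- hits$query_gene
    hits <- rbind(hits, rev)
  }
  if (!nrow(hits)) return(empty_hits())
  hits <- hits[order(hits$query_gene, -hits$score, hits$subject_gene), ,
               drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query_gene,
                          FUN = seq_along)
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query_gene = character(), subject_gene = character(),
             score = numeric(), evalue = numeric(),
             match_fraction = numeric(), rank = integer())
}

word_candidates <- function(pa, pb, w, self) {
  words_of <- function(s) {
    n <- nchar(s)
    if (n < w) return(character(0))
    unique(substring(s, 1:(n - w + 1L), w:n))
  }
  idx_b <- new.env(parent = emptyenv(), size = 4L * length(pb))
  for (nm in names(pb)) {
    for (wd in words_of(pb[[nm]])) {
      assign(wd, c(get0(wd, envir = idx_b, ifnotfound = character(0)), nm),
             envir = idx_b)
    }
  }
  qs <- character(0); sbs <- character(0)
  for (nm in names(pa)) {
    hits <- unique(unlist(lapply(words_of(pa[[nm]]), get0, envir = idx_b,
                                 ifnotfound = NULL), use.names = FALSE))
    if (self) hits <- hits[hits > nm]  # each unordered pair once, no self
    if (length(hits)) {
      qs <- c(qs, rep(nm, length(hits)))
      sbs <- c(sbs, hits)
    }
  }
  data.frame(query = qs, subject = sbs, stringsAsFactors = FALSE)
}

#' Chain homologous anchors into collinear synteny blocks
#'
#' For every chromosome pair, anchors (homologous gene pairs placed at
#' their gene-order coordinates) are chained by dynamic programming: an
#' anchor extends a chain iff the gene-order gap on both axes is at most
#' `max_gap` and the direction on axis b matches the chain's orientation.
#' Both orientations are searched; maximal chains are extracted greedily
#' (longest first), each anchor belongs to at most one block, and chains
#' shorter than `min_block_pairs` are discarded.
#'
#' @param hits Homology hits from [find_homologs()] (`query_gene` must
#'   belong to `genome_a`).
#' @param genome_a,genome_b [genome] objects supplying gene order.
#' @param max_gap Maximum order-index gap between consecutive collinear
#'   genes (default 50).
#' @param min_block_pairs Minimum anchors per reported block (default 5).
#' @param min_diagonal_offset In intra-genome mode (`genome_a` and
#'   `genome_b` the same genome), anchors closer than this to the
#'   self-diagonal are dropped (default 5).
#' @return A `synteny_blocks` object: `$blocks` (one row per block) and
#'   `$pairs` (one row per anchor with its block id and hit rank).
#' @export
chain_anchors <- function(hits, genome_a, genome_b, max_gap = 50L,
                          min_block_pairs = 5L, min_diagonal_offset = 5L) {
  if (max_gap < 1) gw_stop("chain_anchors(): max_gap must be >= 1")
  ga <- genome_a$genes; gb <- genome_b$genes
  ia <- match(hits$query_gene, ga$gene_id)
  ib <- match(hits$subject_gene, gb$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  anc <- data.frame(gene_a = hits$query_gene[keep],
                    gene_b = hits$subject_gene[keep],
                    chrom_a = ga$chromosome[ia[keep]],
                    chrom_b = gb$chromosome[ib[keep]],
                    x = ga$order_index[ia[keep]],
                    y = gb$order_index[ib[keep]],
                    rank = hits$rank[keep], stringsAsFactors = FALSE)
  intra <- identical(genome_a$name, genome_b$name)
  if (intra) {
    anc <- anc[!(anc$chrom_a == anc$chrom_b &
                   abs(anc$x - anc$y) < min_diagonal_offset), , drop = FALSE]
  }
  blocks <- list(); pair_rows <- list(); bid <- 0L
  for (key in unique(paste(anc$chrom_a, anc$chrom_b, sep = "\r"))) {
    sub <- anc[paste(anc$chrom_a, anc$chrom_b, sep = "\r") == key, ,
               drop = FALSE]
    repeat {
      ch <- best_chain(sub$x, sub$y, max_gap)
      if (length(ch$idx) < min_block_pairs) break
      bid <- bid + 1L
      sel <- sub[ch$idx, , drop = FALSE]
      blocks[[bid]] <- data.frame(
        block_id = sprintf("blk%04d", bid),
        genome_a = genome_a$name, chrom_a = sel$chrom_a[1],
        genome_b = genome_b$name, chrom_b = sel$chrom_b[1],
        n_pairs = nrow(sel), orientation = ch$orientation,
        mean_ks = NA_real_, stringsAsFactors = FALSE)
      sel$block_id <- sprintf("blk%04d", bid)
      pair_rows[[bid]] <- sel
      sub <- sub[-ch$idx, , drop = FALSE]
      if (!nrow(sub)) break
    }
  }
  if (!bid) {
    return(structure(list(
      blocks = data.frame(block_id = character(), genome_a = character(),
                          chrom_a = character(), genome_b = character(),
                          chrom_b = character(), n_pairs = integer(),
                          orientation = character(), mean_ks = numeric()),
      pairs = data.frame(block_id = character(), gene_a = character(),
                         gene_b = character(), chrom_a = character(),
                         chrom_b = character(), x = integer(),
                         y = integer(), rank = integer())),
      class = "synteny_blocks"))
  }
  structure(list(blocks = do.call(rbind, blocks),
                 pairs = do.call(rbind, pair_rows)),
            class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("synteny_blocks: ", nrow(x$blocks), " blocks, ",
      nrow(x$pairs), " anchor pairs\n", sep = "")
  invisible(x)
}

## longest orientation-consistent chain under the gap bound, by O(n^2)
## dynamic programming; returns indices into (x, y) and the orientation
best_chain <- function(x, y, max_gap) {
  n <- length(x)
  if (!n) return(list(idx = integer(0), orientation = "same"))
  run <- function(sign_y) {
    o <- order(x, if (sign_y > 0) y else -y)
    xs <- x[o]; ys <- y[o]
    f <- rep(1L, n); pred <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        dx <- xs[i] - xs[j]
        dy <- sign_y * (ys[i] - ys[j])
        if (dx > 0L && dx <= max_gap && dy > 0L && dy <= max_gap &&
            f[j] + 1L > f[i]) {
          f[i] <- f[j] + 1L
          pred[i] <- j
        }
      }
    }
    best <- which.max(f)
    idx <- integer(0)
    while (!is.na(best)) {
      idx <- c(best, idx)
      best <- pred[best]
    }
    list(idx = o[idx], len = f[which.max(f)])
  }
  fwd <- run(+1L)
  rev <- run(-1L)
  if (rev$len > fwd$len) list(idx = rev$idx, orientation = "inverted")
  else list(idx = fwd$idx, orientation = "same")
}

#' Summarise synteny blocks per chromosome pair
#'
#' @param blocks A `synteny_blocks` object.
#' @return data.frame with one row per (chrom_a, chrom_b): number of
#'   blocks, total anchor pairs, and the largest block (ties broken by
#'   block id).
#' @export
block_summary <- function(blocks) {
  df <- blocks$blocks
  if (!nrow(df))
    return(data.frame(chrom_a = character(), chrom_b = character(),
                      n_blocks = integer(), n_pairs = integer(),
                      largest_block = character(),
                      largest_n_pairs = integer()))
  key <- paste(df$chrom_a, df$chrom_b, sep = "\r")
  out <- lapply(split(df, key), function(d) {
    d <- d[order(-d$n_pairs, d$block_id), , drop = FALSE]
    data.frame(chrom_a = d$chrom_a[1], chrom_b = d$chrom_b[1],
               n_blocks = nrow(d), n_pairs = sum(d$n_pairs),
               largest_block = d$block_id[1],
               largest_n_pairs = d$n_pairs[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom_a, out$chrom_b), , drop = FALSE]
}
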