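## Codon bookkeeping for the NG86 Ka/Ks estimator and the codon simulator.
## Site fractions, pathway-averaged difference counts and the 64x64 lookup
## tables are built once per session from the standard genetic code.

BASES <- c("A", "C", "G", "T")

codon_tables <- function() {
  if (!is.null(.gw$codons)) return(.gw$codons)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  sense <- codons[aa != "*"]
  ## per-codon synonymous site count: each position contributes the
  ## fraction of its 3 possible changes that are synonymous; changes to
  ## stop codons count as nonsynonymous
  syn_sites <- vapply(codons, function(cd) {
    if (gc[[cd]] == "*") return(NA_real_)
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(BASES, substr(cd, p, p))) {
        alt <- cd
        substr(alt, p, p) <- b
        if (gc[[alt]] == gc[[cd]]) s <- s + 1 / 3
      }
    }
    s
  }, 1)
  .gw$codons <- list(gc = gc, codons = codons, sense = sense,
                     syn_sites = syn_sites)
  .gw$codons
}

## pathway-averaged (syn, nonsyn) difference counts for one codon pair:
## all orderings of the differing positions are enumerated, pathways
## passing through stop codons are discarded, and step classifications
## are averaged over the remaining pathways (plain average if none remain)
codon_pair_diff <- function(c1, c2, gc) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(pos) else
    if (nd == 2L) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
  score_path <- function(ord, allow_stop) {
    cur <- c1
    s <- 0; n <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && gc[[nxt]] == "*") return(NULL)
      if (gc[[nxt]] == gc[[cur]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- Filter(Negate(is.null), lapply(perms, score_path, allow_stop = FALSE))
  if (!length(res)) res <- lapply(perms, score_path, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

## 64x64 lookup matrices of pathway-averaged syn / nonsyn differences
pair_diff_tables <- function() {
  if (!is.null(.gw$pair_diff)) return(.gw$pair_diff)
  ct <- codon_tables()
  n <- length(ct$codons)
  sd_m <- matrix(0, n, n, dimnames = list(ct$codons, ct$codons))
  nd_m <- sd_m
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- codon_pair_diff(ct$codons[i], ct$codons[j], ct$gc)
      sd_m[i, j] <- d["sd"]; nd_m[i, j] <- d["nd"]
    }
  }
  .gw$pair_diff <- list(sd = sd_m, nd = nd_m)
  .gw$pair_diff
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) gw_stop("sequence length not a multiple of 3")
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

jc_correction <- function(p) {
  arg <- 1 - 4 / 3 * p
  ifelse(arg <= 0, NA_real_, -3 / 4 * log(arg))
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Maps each aligned amino-acid column onto its source codon; gap columns
#' expand to 3-nucleotide gaps.  The proteins must be exact translations
#' of their coding sequences (terminal stop codons on the CDS are
#' tolerated and dropped).
#'
#' @param aln_a,aln_b Aligned protein strings (equal length, `-` for gaps).
#' @param cds_a,cds_b Ungapped coding sequences.
#' @return `list(codon_a =, codon_b =)` of gapped codon-aligned strings.
#' @export
backtranslate_alignment <- function(aln_a, aln_b, cds_a, cds_b) {
  if (nchar(aln_a) != nchar(aln_b))
    gw_stop("backtranslate_alignment(): aligned lengths differ")
  expand <- function(aln, cds, label) {
    if (nchar(cds) %% 3L != 0L)
      gw_stop("backtranslate_alignment(): CDS length of ", label,
              " is not a multiple of 3")
    codons <- split_codons(cds)
    gc <- codon_tables()$gc
    if (gc[[codons[length(codons)]]] == "*")
      codons <- codons[-length(codons)]
    aa_aln <- strsplit(aln, "")[[1]]
    aa_res <- aa_aln[aa_aln != "-"]
    if (length(aa_res) != length(codons))
      gw_stop("backtranslate_alignment(): ", label,
              " protein length does not match its CDS")
    trans <- unname(gc[codons])
    bad <- which(trans != aa_res)
    if (length(bad))
      gw_stop("backtranslate_alignment(): translation mismatch in ", label,
              " at codon ", bad[1], " (", codons[bad[1]], " -> ",
              trans[bad[1]], ", alignment has ", aa_res[bad[1]], ")")
    out <- character(length(aa_aln))
    out[aa_aln == "-"] <- "---"
    out[aa_aln != "-"] <- codons
    paste(out, collapse = "")
  }
  list(codon_a = expand(aln_a, cds_a, "sequence a"),
       codon_b = expand(aln_b, cds_b, "sequence b"))
}

#' Estimate Ka and Ks for a codon alignment (NG86)
#'
#' Implements the Nei-Gojobori (1986) counting method: per-codon
#' synonymous site fractions from the standard genetic code, differences
#' averaged over all minimal substitution pathways (pathways through stop
#' codons excluded), and Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)` of the raw proportions.  Columns holding a
#' gap in either sequence are dropped before counting.
#'
#' @param codon_a,codon_b Codon-aligned sequences (equal length, gaps as
#'   `---`), e.g. from [backtranslate_alignment()].
#' @param method Currently `"NG86"`.
#' @param min_codons Minimum number of ungapped codons required
#'   (default 30; lower it only for toy examples).
#' @return A one-row data.frame with `ka`, `ks`, `n_sites`, `s_sites`,
#'   `sd_count`, `nd_count`, `saturated` and `method`.
#' @export
estimate_ks <- function(codon_a, codon_b, method = "NG86",
                        min_codons = 30L) {
  method <- match.arg(method, "NG86")
  ca <- split_codons(codon_a)
  cb <- split_codons(codon_b)
  if (length(ca) != length(cb))
    gw_stop("estimate_ks(): aligned codon counts differ")
  keep <- !grepl("-", ca) & !grepl("-", cb)
  ca <- ca[keep]; cb <- cb[keep]
  ct <- codon_tables()
  if (any(ct$gc[ca] == "*") || any(ct$gc[cb] == "*"))
    gw_stop("estimate_ks(): internal stop codon in alignment")
  if (length(ca) < min_codons)
    gw_stop("estimate_ks(): fewer than ", min_codons, " ungapped codons")
  s_a <- sum(ct$syn_sites[ca])
  s_b <- sum(ct$syn_sites[cb])
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  pd <- pair_diff_tables()
  idx <- cbind(match(ca, ct$codons), match(cb, ct$codons))
  Sd <- sum(pd$sd[idx])
  Nd <- sum(pd$nd[idx])
  ks <- jc_correction(Sd / S)
  ka <- jc_correction(Nd / N)
  data.frame(ka = ka, ks = ks, n_sites = N, s_sites = S,
             sd_count = Sd, nd_count = Nd,
             saturated = is.na(ks) || is.na(ka), method = method,
             stringsAsFactors = FALSE)
}

#' Estimate Ka/Ks for every gene pair of a set of synteny blocks
#'
#' For each block pair the two coding sequences are aligned at the protein
#' level (Needleman-Wunsch global alignment when lengths differ; direct
#' pairing otherwise), back-translated to codons and passed to
#' [estimate_ks()].
#'
#' @param blocks A `synteny_blocks` object.
#' @param cds_a,cds_b Named CDS vectors for the two genomes.
#' @param min_codons Passed to [estimate_ks()].
#' @return The blocks object with a `ks` column added to `$pairs`.
#' @export
block_ks <- function(blocks, cds_a, cds_b, min_codons = 30L) {
  pairs <- blocks$pairs
  ks <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sa <- cds_a[[pairs$gene_a[i]]]
    sb <- cds_b[[pairs$gene_b[i]]]
    if (is.null(sa) || is.null(sb)) next
    est <- tryCatch(pair_kaks(sa, sb, min_codons = min_codons),
                    error = function(e) NULL)
    if (!is.null(est) && !est$saturated) ks[i] <- est$ks
  }
  blocks$pairs$ks <- ks
  blocks
}

#' Ka/Ks for one pair of coding sequences
#'
#' Convenience wrapper: translate, align the proteins globally if their
#' lengths differ, back-translate and run [estimate_ks()].
#'
#' @inheritParams block_ks
#' @param cds1,cds2 Coding sequences.
#' @return See [estimate_ks()].
#' @export
pair_kaks <- function(cds1, cds2, min_codons = 30L) {
  p1 <- translate_cds(c(x = cds1))[[1]]
  p2 <- translate_cds(c(x = cds2))[[1]]
  if (nchar(p1) == nchar(p2)) {
    aln <- list(a = p1, b = p2)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(p1), Biostrings::AAString(p2),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "global")
    aln <- list(a = as.character(Biostrings::alignedPattern(pa)),
                b = as.character(Biostrings::alignedSubject(pa)))
  }
  cod <- backtranslate_alignment(aln$a, aln$b, cds1, cds2)
  estimate_ks(cod$codon_a, cod$codon_b, min_codons = min_codons)
}

blosum62 <- function() {
  if (is.null(.gw$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .gw$blosum62 <- e$BLOSUM62
  }
  .gw$blosum62
}
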