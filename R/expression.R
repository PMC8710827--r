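## Expression quantification, NB differential expression, and
## duplicate-pair expression-fate classification.

#' Transcripts per million
#'
#' Length-normalised within-sample expression: per sample,
#' `rate_g = count_g / length_g(kb)` and `tpm_g = 1e6 * rate_g /
#' sum(rates)`.  Columns sum to 1e6 (all-zero samples return a zero
#' column with a warning).
#'
#' @param counts Genes x samples count matrix (row names are gene ids).
#' @param gene_lengths Named vector of effective lengths in bp.
#' @return TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  len <- gene_lengths[rownames(counts)]
  if (anyNA(len)) gw_stop("compute_tpm(): missing gene lengths")
  if (any(len <= 0)) gw_stop("compute_tpm(): lengths must be positive")
  rate <- counts / (len / 1000)
  totals <- colSums(rate)
  if (any(totals == 0)) {
    warning("compute_tpm(): all-zero sample(s): ",
            paste(colnames(counts)[totals == 0], collapse = ", "))
    totals[totals == 0] <- 1
  }
  sweep(rate, 2, totals, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' The classical NB normalisation: per sample, the median ratio of counts
#' to the per-gene geometric mean across samples (genes with a zero
#' anywhere are excluded from the reference).
#'
#' @param counts Genes x samples count matrix.
#' @return Named numeric vector of size factors.
#' @export
estimate_size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use))
    gw_stop("estimate_size_factors(): no gene has all-positive counts")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt)
    exp(median(log(cnt) - log_gm[use], na.rm = TRUE)))
  sf
}

#' Call differentially expressed genes for one (tissue, time) contrast
#'
#' A negative-binomial Wald test in the DESeq mould, self-contained so
#' every step is inspectable: median-of-ratios size factors, per-gene
#' method-of-moments dispersion on normalised counts shrunk toward a
#' `a0 + a1/mean` mean-dispersion trend, a Wald z-test on the log2 fold
#' change (treatment vs the 0 h control of the same tissue), and BH
#' correction over all genes tested in the contrast.  A gene is a DEG iff
#' `|log2fc| >= lfc_threshold` and `fdr < fdr_threshold`.
#'
#' @param counts Genes x samples count matrix.
#' @param design Design table ([salt_design()] layout).
#' @param tissue `"root"` or `"shoot"`.
#' @param time_h 6 or 24.
#' @param lfc_threshold Minimum |log2fc| (default 1, i.e. twofold).
#' @param fdr_threshold BH FDR cut-off (default 0.05).
#' @param size_factors Optional precomputed size factors for all samples.
#' @return data.frame `gene_id, tissue, time_h, base_mean, log2fc,
#'   pvalue, fdr, is_deg, direction` (genes with all-zero counts in the
#'   contrast are excluded from testing and from the BH family).
#' @export
call_degs <- function(counts, design, tissue, time_h,
                      lfc_threshold = 1, fdr_threshold = 0.05,
                      size_factors = NULL) {
  design <- validate_design(design)
  if (!time_h %in% c(6, 24))
    gw_stop("call_degs(): time_h must be 6 or 24")
  trt <- design$sample_id[design$tissue == tissue & design$time_h == time_h]
  ctl <- design$sample_id[design$tissue == tissue & design$time_h == 0]
  if (length(ctl) < 2)
    gw_stop("call_degs(): missing or underpowered 0 h control group")
  if (length(trt) < 2)
    gw_stop("call_degs(): fewer than 2 treatment replicates")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  nc <- sweep(counts[, c(ctl, trt), drop = FALSE], 2,
              size_factors[c(ctl, trt)], "/")
  tested <- rowSums(nc) > 0
  nc <- nc[tested, , drop = FALSE]
  ic <- seq_along(ctl); it <- length(ctl) + seq_along(trt)
  mc <- rowMeans(nc[, ic, drop = FALSE])
  mt <- rowMeans(nc[, it, drop = FALSE])
  ## pooled within-group method-of-moments dispersion
  vc <- apply(nc[, ic, drop = FALSE], 1, var)
  vt <- apply(nc[, it, drop = FALSE], 1, var)
  df_c <- length(ic) - 1L; df_t <- length(it) - 1L
  vp <- (vc * df_c + vt * df_t) / (df_c + df_t)
  mm <- (mc + mt) / 2
  alpha_raw <- pmax((vp - mm) / mm^2, 1e-8)
  ## parametric trend alpha(mu) = a0 + a1 / mu, fitted on informative genes
  pos <- alpha_raw > 1e-8 & mm > 1
  alpha_trend <- rep(median(alpha_raw[pos]) %||% 0.1, length(mm))
  if (sum(pos) >= 50) {
    fit <- lm(alpha_raw[pos] ~ I(1 / mm[pos]))
    a0 <- max(coef(fit)[1], 1e-4); a1 <- max(coef(fit)[2], 0)
    alpha_trend <- a0 + a1 / mm
  }
  w <- (df_c + df_t) / (df_c + df_t + 4)
  alpha <- exp(w * log(alpha_raw) + (1 - w) * log(pmax(alpha_trend, 1e-8)))
  alpha <- pmin(pmax(alpha, 1e-8), 10)
  ## Wald test on the log fold change (delta-method SE)
  pc <- 0.5
  lfc <- log2((mt + pc) / (mc + pc))
  v_ln <- function(mu, k) (1 / (mu + pc) + alpha) / k
  se_lfc <- sqrt(v_ln(mc, length(ic)) + v_ln(mt, length(it))) / log(2)
  z <- lfc / se_lfc
  pval <- 2 * pnorm(-abs(z))
  fdr <- p.adjust(pval, method = "BH")
  is_deg <- abs(lfc) >= lfc_threshold & fdr < fdr_threshold
  data.frame(gene_id = rownames(nc), tissue = tissue, time_h = time_h,
             base_mean = mm, log2fc = lfc, pvalue = pval, fdr = fdr,
             is_deg = is_deg,
             direction = ifelse(is_deg, ifelse(lfc > 0, "up", "down"),
                                NA_character_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call DEGs for every (tissue, time) contrast in a design
#'
#' @inheritParams call_degs
#' @return Row-bound [call_degs()] results for all four contrasts
#'   (root/shoot x 6/24 h vs 0 h).
#' @export
call_all_degs <- function(counts, design, lfc_threshold = 1,
                          fdr_threshold = 0.05) {
  sf <- estimate_size_factors(counts)
  out <- list()
  for (tis in c("root", "shoot")) for (t in c(6, 24))
    out[[paste(tis, t)]] <- call_degs(counts, design, tis, t,
                                      lfc_threshold, fdr_threshold,
                                      size_factors = sf)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Pair duplicate genes descending from the young WGD
#'
#' Emits pairs `(copy_1, copy_2, reference_gene)` in which the two focal
#' genes are collinear partners in an intra-focal block attributed to the
#' lineage-specific WGD (block-mean Ks below the midpoint of the two
#' youngest focal Ks peaks) and both are rank-1 (orthologous-block)
#' matches of the same reference gene.  Reference genes with three or
#' more focal copies are excluded; pairs are deduplicated.
#'
#' @param intra_blocks Intra-focal `synteny_blocks` with block-mean Ks
#'   attached (a `mean_ks` column on `$blocks`, e.g. from
#'   [block_ks()] + [block_ks_distribution()]).
#' @param inter_blocks Reference-vs-focal classified `synteny_blocks`
#'   (reference on axis a).
#' @param ks_peaks Focal paralog `ks_peaks` (needs >= 2 peaks, else all
#'   intra blocks are taken as young with a warning).
#' @return data.frame `copy_1, copy_2, reference_gene`.
#' @export
pair_paralogs <- function(intra_blocks, inter_blocks, ks_peaks) {
  if (is.null(ks_peaks))
    gw_stop("pair_paralogs(): Ks peaks unavailable; run detect_ks_peaks()",
            " first")
  if (is.null(intra_blocks$blocks$mean_ks) ||
      all(is.na(intra_blocks$blocks$mean_ks)))
    gw_stop("pair_paralogs(): intra-focal blocks carry no mean_ks")
  if (nrow(ks_peaks) >= 2) {
    young_cut <- mean(sort(ks_peaks$mode)[1:2])
  } else {
    warning("pair_paralogs(): single Ks peak; taking all intra blocks ",
            "as young")
    young_cut <- Inf
  }
  yb <- intra_blocks$blocks$block_id[
    !is.na(intra_blocks$blocks$mean_ks) &
      intra_blocks$blocks$mean_ks < young_cut]
  dup <- intra_blocks$pairs[intra_blocks$pairs$block_id %in% yb, ,
                            drop = FALSE]
  if (is.null(inter_blocks$blocks$class))
    gw_stop("pair_paralogs(): inter-genome blocks are unclassified")
  orth_ids <- inter_blocks$blocks$block_id[
    inter_blocks$blocks$class == "orthologous"]
  op <- inter_blocks$pairs[inter_blocks$pairs$block_id %in% orth_ids, ,
                           drop = FALSE]
  ## focal gene -> reference gene via its best-ranked anchor inside an
  ## orthologous block (each focal copy sits in its own orthologous
  ## block; the two co-orthologs of one reference gene anchor to it from
  ## different blocks)
  op <- op[order(op$gene_b, op$rank, op$gene_a), , drop = FALSE]
  ref_of <- vapply(split(op$gene_a, op$gene_b), `[`, "", 1)
  overcopied <- names(which(vapply(split(op$gene_b, op$gene_a),
                                   function(x) length(unique(x)),
                                   1L) > 2))
  out <- list()
  for (i in seq_len(nrow(dup))) {
    g1 <- dup$gene_a[i]; g2 <- dup$gene_b[i]
    r1 <- unname(ref_of[g1])
    r2 <- unname(ref_of[g2])
    if (is.na(r1) || is.na(r2) || r1 != r2) next
    if (r1 %in% overcopied) next
    key <- paste(sort(c(g1, g2)), collapse = "\r")
    out[[key]] <- data.frame(copy_1 = sort(c(g1, g2))[1],
                             copy_2 = sort(c(g1, g2))[2],
                             reference_gene = r1, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(copy_1 = character(), copy_2 = character(),
                      reference_gene = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## (tissue, direction) signature of one gene over its DEG calls,
## collapsing time points by union
deg_signature <- function(gene, degs) {
  d <- degs[degs$gene_id == gene & degs$is_deg, , drop = FALSE]
  if (!nrow(d)) return(character(0))
  sort(unique(paste(d$tissue, d$direction, sep = ":")))
}

#' Classify the expression fate of duplicate pairs
#'
#' Builds, per copy, the set of (tissue, direction) values across its DEG
#' calls (time points collapsed by union) and assigns: category
#' `neither_deg` / `one_deg` / `both_deg`, and for both-DEG pairs the
#' pattern -- `I` identical signatures (redundancy), `II` disjoint tissue
#' sets with compatible directions, `III` a shared tissue with opposite
#' directions and no other difference, `IV` both a tissue difference and
#' an opposite-direction co-occurrence.  A copy that is up at one time
#' and down at another in the same tissue carries both directions.
#'
#' @param pairs data.frame from [pair_paralogs()] (or any `copy_1`,
#'   `copy_2` table).
#' @param degs DEG calls from [call_all_degs()] covering both tissues
#'   and both non-zero time points.
#' @return `pairs` with `category` and `pattern` columns added.
#' @export
classify_fate <- function(pairs, degs) {
  need <- expand.grid(tissue = c("root", "shoot"), time_h = c(6, 24))
  have <- unique(degs[, c("tissue", "time_h")])
  if (nrow(merge(need, have)) < 4)
    gw_stop("classify_fate(): DEG calls must cover root/shoot x 6/24 h")
  category <- character(nrow(pairs))
  pattern <- rep(NA_character_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    s1 <- deg_signature(pairs$copy_1[i], degs)
    s2 <- deg_signature(pairs$copy_2[i], degs)
    if (!length(s1) && !length(s2)) { category[i] <- "neither_deg"; next }
    if (!length(s1) || !length(s2)) { category[i] <- "one_deg"; next }
    category[i] <- "both_deg"
    pattern[i] <- fate_pattern(s1, s2)
  }
  pairs$category <- category
  pairs$pattern <- pattern
  pairs
}

fate_pattern <- function(s1, s2) {
  split_sig <- function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)
    data.frame(tissue = vapply(parts, `[`, "", 1),
               direction = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  }
  a <- split_sig(s1); b <- split_sig(s2)
  if (identical(s1, s2)) return("I")
  shared <- intersect(a$tissue, b$tissue)
  ## direction conflict: a shared tissue regulated in opposite ways, or
  ## the two copies' overall direction repertoires differ (so e.g.
  ## root-up vs shoot-down counts as opposite-direction co-occurrence)
  opp_shared <- any(vapply(shared, function(t)
    !setequal(a$direction[a$tissue == t],
              b$direction[b$tissue == t]), logical(1)))
  conflict <- opp_shared || !setequal(a$direction, b$direction)
  tissue_diff <- !setequal(a$tissue, b$tissue)
  if (conflict && !tissue_diff) return("III")
  if (!conflict && tissue_diff) return("II")
  if (conflict && tissue_diff) return("IV")
  ## equal tissue sets, no direction conflict, not identical: unreachable
  ## for well-formed signatures, but keep a defined answer
  "I"
}

#' Summarise duplicate-pair fate categories and patterns
#'
#' Counts and percentages per category and, within both-DEG pairs, per
#' pattern.  Percentages use two-decimal round-half-up ([percent()]).
#'
#' @param pairs Classified pairs from [classify_fate()].
#' @return `list(categories, patterns)` data.frames; empty input yields
#'   empty tables.
#' @export
summarize_fate <- function(pairs) {
  if (!nrow(pairs))
    return(list(categories = data.frame(category = character(),
                                        n = integer(), pct = numeric()),
                patterns = data.frame(pattern = character(),
                                      n = integer(), pct = numeric())))
  total <- nrow(pairs)
  cats <- c("neither_deg", "one_deg", "both_deg")
  cat_n <- vapply(cats, function(cl) sum(pairs$category == cl), 1L)
  categories <- data.frame(category = cats, n = cat_n,
                           pct = percent(cat_n, total), row.names = NULL)
  n_both <- cat_n[["both_deg"]]
  pats <- c("I", "II", "III", "IV")
  if (n_both > 0) {
    pat_n <- vapply(pats, function(p)
      sum(pairs$pattern == p, na.rm = TRUE), 1L)
    patterns <- data.frame(pattern = pats, n = pat_n,
                           pct = percent(pat_n, n_both), row.names = NULL)
  } else {
    patterns <- data.frame(pattern = pats, n = 0L, pct = NA_real_)
  }
  stopifnot(sum(categories$n) == total)
  list(categories = categories, patterns = patterns)
}

#' Per-gene regulation ratio of group-mean TPM
#'
#' `TPM_treatment / TPM_control` with a pseudo-count of 0.5 added to both
#' group means (keeps zero-control genes finite).
#'
#' @param tpm TPM matrix.
#' @param design Design table.
#' @param tissue,time_h Treatment group (control is 0 h, same tissue).
#' @return Named numeric vector of ratios.
#' @export
fold_regulation <- function(tpm, design, tissue, time_h) {
  design <- validate_design(design)
  trt <- design$sample_id[design$tissue == tissue & design$time_h == time_h]
  ctl <- design$sample_id[design$tissue == tissue & design$time_h == 0]
  if (!length(trt) || !length(ctl))
    gw_stop("fold_regulation(): both groups must be present")
  mt <- rowMeans(tpm[, trt, drop = FALSE])
  mc <- rowMeans(tpm[, ctl, drop = FALSE])
  (mt + 0.5) / (mc + 0.5)
}
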