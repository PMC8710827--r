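## Dotplot classification, syntenic multiplicity, Ks peak detection,
## proportional age calibration, and ancestral-karyotype painting.

#' Classify synteny blocks as orthologous or outparalogous
#'
#' Mirrors the dotplot reading in which best (rank 1) hits mark
#' orthologous correspondence and secondary hits mark outparalogous
#' (pre-speciation) correspondence: a block is orthologous iff more than
#' half of its anchor pairs are rank-1 hits for the reference-side
#' (axis a) gene.  An exact 50% tie is resolved in favour of orthologous
#' iff the block's mean rank is below the mean rank of all blocks whose
#' reference span overlaps its own.
#'
#' @param blocks A `synteny_blocks` object whose pairs carry hit ranks
#'   (see [find_homologs()] and [chain_anchors()]).
#' @return The same object with a `class` column
#'   (`"orthologous"`/`"outparalogous"`) added to `$blocks`.
#' @export
classify_blocks <- function(blocks) {
  if (!nrow(blocks$blocks))
    return(blocks)
  if (is.null(blocks$pairs$rank) || anyNA(blocks$pairs$rank))
    gw_stop("classify_blocks(): blocks carry no hit ranks; re-run ",
            "find_homologs() and chain_anchors() with rank data")
  pr <- blocks$pairs
  frac1 <- tapply(pr$rank == 1L, pr$block_id, mean)
  meanrk <- tapply(pr$rank, pr$block_id, mean)
  span <- do.call(rbind, lapply(split(pr, pr$block_id), function(d)
    data.frame(block_id = d$block_id[1], chrom_a = d$chrom_a[1],
               lo = min(d$x), hi = max(d$x), stringsAsFactors = FALSE)))
  cls <- character(nrow(blocks$blocks))
  for (i in seq_len(nrow(blocks$blocks))) {
    b <- blocks$blocks$block_id[i]
    f <- frac1[[b]]
    if (f > 0.5) cls[i] <- "orthologous"
    else if (f < 0.5) cls[i] <- "outparalogous"
    else {
      me <- span[span$block_id == b, ]
      others <- span[span$chrom_a == me$chrom_a & span$block_id != b &
                       span$lo <= me$hi & span$hi >= me$lo, ]
      ref_mean <- if (nrow(others)) mean(meanrk[others$block_id]) else Inf
      cls[i] <- if (meanrk[[b]] < ref_mean) "orthologous" else
        "outparalogous"
    }
  }
  blocks$blocks$class <- cls
  blocks
}

#' Infer syntenic multiplicity per reference chromosome
#'
#' Projects orthologous blocks onto reference gene-order coordinates and
#' counts, per reference chromosome, the distinct focal locations covered
#' by at least `min_region_pairs` anchor pairs.  Blocks landing on the
#' same focal chromosome with overlapping or near-adjacent focal spans are
#' merged into one region first.  A genome that underwent n extra WGDs
#' relative to the reference shows modal multiplicity `2^n` (the 1:2
#' dotplot signature for a single lineage-specific event).
#'
#' @param blocks A classified `synteny_blocks` object ([classify_blocks()]).
#' @param reference A [genome]; its chromosomes index the report.
#' @param min_region_pairs Minimum anchor support per counted region
#'   (default 10).
#' @param merge_gap Focal-span gap (gene-order units) below which blocks
#'   on the same focal chromosome are merged (default 50).
#' @param classes Block classes to count (default `"orthologous"`, the
#'   dotplot best-match tier).  Pass `NULL` to count every collinear
#'   region - appropriate when no pre-speciation duplication exists and
#'   hence no outparalogous tier (e.g. scoring stacked lineage-specific
#'   WGDs against a reference that shares no WGD with the focal genome).
#' @return `list(per_chromosome, modal_multiplicity,
#'   inferred_extra_wgd_count, power_of_two)`, class
#'   `multiplicity_report`.
#' @export
infer_multiplicity <- function(blocks, reference, min_region_pairs = 10L,
                               merge_gap = 50L, classes = "orthologous") {
  if (is.null(classes)) {
    orth <- blocks$blocks
  } else {
    if (is.null(blocks$blocks$class))
      gw_stop("infer_multiplicity(): run classify_blocks() first")
    orth <- blocks$blocks[blocks$blocks$class %in% classes, , drop = FALSE]
    if (!nrow(orth)) gw_stop("infer_multiplicity(): no orthologous blocks")
  }
  if (!nrow(orth)) gw_stop("infer_multiplicity(): no blocks to count")
  pr <- blocks$pairs[blocks$pairs$block_id %in% orth$block_id, ,
                     drop = FALSE]
  chroms <- unique(reference$genes$chromosome)
  counts <- integer(length(chroms))
  names(counts) <- chroms
  for (ci in seq_along(chroms)) {
    sub <- pr[pr$chrom_a == chroms[ci], , drop = FALSE]
    if (!nrow(sub)) { counts[ci] <- 0L; next }
    n_regions <- 0L
    for (fc in unique(sub$chrom_b)) {
      d <- sub[sub$chrom_b == fc, , drop = FALSE]
      spans <- do.call(rbind, lapply(split(d, d$block_id), function(s)
        c(lo = min(s$y), hi = max(s$y), n = nrow(s))))
      spans <- spans[order(spans[, "lo"]), , drop = FALSE]
      ## merge near-adjacent focal spans into regions
      reg_hi <- -Inf; reg_n <- 0L
      for (ri in seq_len(nrow(spans))) {
        if (spans[ri, "lo"] > reg_hi + merge_gap) {
          if (reg_n >= min_region_pairs) n_regions <- n_regions + 1L
          reg_n <- 0L
        }
        reg_hi <- max(reg_hi, spans[ri, "hi"])
        reg_n <- reg_n + spans[ri, "n"]
      }
      if (reg_n >= min_region_pairs) n_regions <- n_regions + 1L
    }
    counts[ci] <- n_regions
  }
  covered <- counts[counts > 0]
  if (!length(covered))
    gw_stop("infer_multiplicity(): no chromosome reaches min_region_pairs")
  tab <- table(covered)
  modal <- max(as.integer(names(tab)[tab == max(tab)]))
  p2 <- log2(modal) %% 1 == 0
  structure(list(per_chromosome = data.frame(chromosome = chroms,
                                             n_ortholog_regions = counts,
                                             row.names = NULL),
                 modal_multiplicity = modal,
                 inferred_extra_wgd_count = if (p2) as.integer(log2(modal))
                 else NA_integer_,
                 power_of_two = p2),
            class = "multiplicity_report")
}

#' @export
print.multiplicity_report <- function(x, ...) {
  cat("modal syntenic multiplicity:", x$modal_multiplicity,
      if (x$power_of_two)
        paste0("(", x$inferred_extra_wgd_count, " extra WGD",
               if (x$inferred_extra_wgd_count != 1) "s", ")")
      else "(not a power of two - flagged)", "\n")
  invisible(x)
}

#' Block-average Ks distribution
#'
#' Per-block arithmetic mean of unsaturated pair Ks values inside the
#' analysis window `(0, ks_max]`; blocks with fewer than
#' `min_pairs_for_mean` usable values are excluded.  Block averages, not
#' per-pair values, are the unit of the peak analysis.
#'
#' @param blocks A `synteny_blocks` object whose `$pairs` carry a `ks`
#'   column (see [block_ks()]).
#' @param min_pairs_for_mean Minimum usable pairs per block (default 3).
#' @param ks_max Upper end of the Ks window (default 2; beyond that
#'   synonymous sites saturate).
#' @return Named numeric vector of block-mean Ks (names are block ids).
#' @export
block_ks_distribution <- function(blocks, min_pairs_for_mean = 3L,
                                  ks_max = 2) {
  pr <- blocks$pairs
  if (is.null(pr$ks))
    gw_stop("block_ks_distribution(): pairs carry no ks column; ",
            "run block_ks() first")
  ok <- !is.na(pr$ks) & pr$ks > 0 & pr$ks <= ks_max
  if (!any(ok)) {
    warning("block_ks_distribution(): all pairs saturated or outside ",
            "the Ks window")
    return(stats::setNames(numeric(0), character(0)))
  }
  pr <- pr[ok, , drop = FALSE]
  n <- tapply(pr$ks, pr$block_id, length)
  m <- tapply(pr$ks, pr$block_id, mean)
  m[n >= min_pairs_for_mean]
}

#' Detect peaks in a block-average Ks distribution
#'
#' Fits Gaussian mixtures with 1..`max_components` components to
#' `log(Ks)` (Ks is right-skewed and multiplicative), selects the
#' component count by BIC, and back-transforms component means to modes
#' on the Ks scale.  A kernel-density mode finder (Gaussian kernel,
#' Silverman bandwidth) is run as a cross-check; a relative disagreement
#' above 25% on any matched mode is flagged in the `kde_flag` attribute.
#'
#' @param block_ks Numeric vector of block-mean Ks values (>= 50).
#' @param max_components Largest mixture size considered (default 4).
#' @param min_values Minimum number of values required (default 50).
#' @return data.frame of class `ks_peaks` with columns `mode`, `weight`,
#'   `component_sd` (log scale), sorted by mode; attributes
#'   `n_components`, `kde_modes`, `kde_flag`.
#' @export
detect_ks_peaks <- function(block_ks, max_components = 4L,
                            min_values = 50L) {
  x <- block_ks[is.finite(block_ks) & block_ks > 0]
  if (length(x) < min_values)
    gw_stop("detect_ks_peaks(): need at least ", min_values,
            " block-mean Ks values, got ", length(x))
  lx <- log(x)
  if (stats::sd(lx) < 1e-8) {
    out <- data.frame(mode = exp(mean(lx)), weight = 1,
                      component_sd = 1e-3)
    class(out) <- c("ks_peaks", class(out))
    attr(out, "n_components") <- 1L
    attr(out, "kde_modes") <- out$mode
    attr(out, "kde_flag") <- FALSE
    return(out)
  }
  fit <- mclust::Mclust(lx, G = seq_len(max_components),
                        modelNames = "V", verbose = FALSE)
  if (is.null(fit)) gw_stop("detect_ks_peaks(): mixture fit failed")
  mu <- as.numeric(fit$parameters$mean)
  sdv <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sdv) == 1L) sdv <- rep(sdv, length(mu))
  w <- as.numeric(fit$parameters$pro)
  o <- order(mu)
  out <- data.frame(mode = exp(mu[o]), weight = w[o],
                    component_sd = pmax(sdv[o], 1e-3))
  kde <- stats::density(lx, bw = "nrd0")
  km <- kde$x[local_maxima(kde$y)]
  kde_modes <- exp(km)
  flag <- FALSE
  for (m in out$mode) {
    if (!length(kde_modes)) { flag <- TRUE; break }
    rel <- min(abs(kde_modes - m) / m)
    if (rel > 0.25) flag <- TRUE
  }
  class(out) <- c("ks_peaks", class(out))
  attr(out, "n_components") <- length(mu)
  attr(out, "kde_modes") <- kde_modes
  attr(out, "kde_flag") <- flag
  out
}

local_maxima <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

#' Date a WGD event by proportional Ks calibration
#'
#' Converts a Ks peak mode into an age by linear scaling against a
#' calibrating event: `age = age_cal * mode / ks_cal`.  The default
#' anchor is the grass-wide duplication at Ks 0.6 and 96 Ma.
#'
#' @param mode Ks mode of the event to date (> 0).
#' @param calibration `list(ks_cal =, age_cal =)`.
#' @return Age in Ma.
#' @export
date_event <- function(mode, calibration = list(ks_cal = 0.6,
                                                age_cal = 96)) {
  if (mode <= 0 || calibration$ks_cal <= 0 || calibration$age_cal <= 0)
    gw_stop("date_event(): mode and calibration must be positive")
  calibration$age_cal * mode / calibration$ks_cal
}

#' Paint chromosomes by ancestral-karyotype origin
#'
#' Assigns each gene the dominant ancestral label of its sliding
#' gene-order window (majority vote, ties broken lexicographically),
#' merges consecutive same-label runs into segments, absorbs segments
#' supported by fewer than `min_segment_genes` genes into their larger
#' neighbour, and flags a chromosome as fused iff at least two distinct
#' labels survive.
#'
#' @param target A [genome].
#' @param agk_map Named character vector: gene id -> ancestral
#'   (proto)chromosome label.
#' @param window_genes Sliding window width in genes (default 10).
#' @param min_segment_genes Minimum surviving segment support (default 5).
#' @return `list(segments, fusions)`, class `karyotype_painting`:
#'   `segments` has one row per segment (`chromosome, start_order_index,
#'   end_order_index, label, n_genes`), `fusions` one row per chromosome
#'   with its `fusion_flag`.
#' @export
paint_karyotype <- function(target, agk_map, window_genes = 10L,
                            min_segment_genes = 5L) {
  genes <- target$genes
  seg_rows <- list(); fus_rows <- list()
  half <- max(1L, window_genes %/% 2L)
  for (ch in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == ch, , drop = FALSE]
    g <- g[order(g$order_index), , drop = FALSE]
    lab <- unname(agk_map[g$gene_id])
    if (all(is.na(lab))) {
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        chromosome = ch, start_order_index = min(g$order_index),
        end_order_index = max(g$order_index), label = "unassigned",
        n_genes = nrow(g), stringsAsFactors = FALSE)
      fus_rows[[length(fus_rows) + 1L]] <- data.frame(
        chromosome = ch, fusion_flag = FALSE, stringsAsFactors = FALSE)
      next
    }
    n <- nrow(g)
    voted <- character(n)
    for (i in seq_len(n)) {
      win <- lab[max(1L, i - half):min(n, i + half)]
      win <- win[!is.na(win)]
      voted[i] <- if (!length(win)) NA_character_ else {
        tb <- table(win)
        sort(names(tb)[tb == max(tb)])[1]
      }
    }
    ## carry forward over unmapped stretches
    for (i in seq_len(n))
      if (is.na(voted[i])) voted[i] <- if (i > 1) voted[i - 1] else
        voted[which(!is.na(voted))[1]]
    r <- rle(voted)
    ## absorb short segments into their larger neighbour, iteratively
    repeat {
      if (length(r$lengths) <= 1L) break
      small <- which(r$lengths < min_segment_genes)
      if (!length(small)) break
      i <- small[which.min(r$lengths[small])]
      nb <- if (i == 1L) 2L else if (i == length(r$lengths)) i - 1L else
        if (r$lengths[i - 1L] >= r$lengths[i + 1L]) i - 1L else i + 1L
      r$values[i] <- r$values[nb]
      r <- rle(inverse.rle(r))
    }
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (si in seq_along(r$lengths))
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        chromosome = ch, start_order_index = g$order_index[starts[si]],
        end_order_index = g$order_index[ends[si]], label = r$values[si],
        n_genes = r$lengths[si], stringsAsFactors = FALSE)
    fus_rows[[length(fus_rows) + 1L]] <- data.frame(
      chromosome = ch,
      fusion_flag = length(unique(r$values)) >= 2L,
      stringsAsFactors = FALSE)
  }
  structure(list(segments = do.call(rbind, seg_rows),
                 fusions = do.call(rbind, fus_rows)),
            class = "karyotype_painting")
}

#' @export
print.karyotype_painting <- function(x, ...) {
  cat("karyotype_painting: ", nrow(x$fusions), " chromosomes, ",
      sum(x$fusions$fusion_flag), " fused\n", sep = "")
  invisible(x)
}
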