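#' Construct a k-mer depth histogram
#'
#' Holds the number of distinct canonical k-mers observed at each depth,
#' together with the total number of k-mer instances
#' (`sum(depth * count)`), which is the numerator of the genome-size
#' formula `size = total_instances / peak_depth`.
#'
#' @param k K-mer length (odd).
#' @param counts Named numeric vector: names are depths (>= 1), values are
#'   the number of distinct k-mers at that depth.
#' @return An object of class `kmer_histogram` with fields `k`, `counts`
#'   and `total_instances`.
#' @export
kmer_histogram <- function(k, counts) {
  depths <- as.numeric(names(counts))
  if (anyNA(depths) || any(depths < 1))
    gw_stop("kmer_histogram(): depths must be integers >= 1")
  if (any(counts < 0)) gw_stop("kmer_histogram(): negative counts")
  counts <- counts[counts > 0]
  depths <- as.numeric(names(counts))
  o <- order(depths)
  counts <- counts[o]
  structure(list(k = as.integer(k), counts = counts,
                 total_instances = sum(as.numeric(names(counts)) * counts)),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat("kmer_histogram: k=", x$k, ", ", length(x$counts),
      " depth bins, ", format(x$total_instances, big.mark = ","),
      " instances\n", sep = "")
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Count canonical k-mers
#'
#' A k-mer and its reverse complement are collapsed to one canonical key
#' (the lexicographically smaller of the two); k must therefore be odd so
#' no k-mer is its own reverse complement.  K-mers containing `N` are
#' skipped.
#'
#' @param sequences Character vector of nucleotide sequences (ACGTN).
#' @param k Odd k-mer length.
#' @return A [kmer_histogram].
#' @export
count_kmers <- function(sequences, k = 17L) {
  k <- as.integer(k)
  if (k %% 2L == 0L)
    gw_stop("count_kmers(): k must be odd (canonical ambiguity for even k)")
  if (k < 1L) gw_stop("count_kmers(): k must be positive")
  kmers <- unlist(lapply(toupper(sequences), function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (!length(kmers))
    return(kmer_histogram(k, stats::setNames(numeric(0), character(0))))
  rc <- revcomp(kmers)
  canon <- ifelse(kmers <= rc, kmers, rc)
  depth_per_kmer <- table(canon)
  hist <- table(as.integer(depth_per_kmer))
  kmer_histogram(k, stats::setNames(as.numeric(hist), names(hist)))
}

#' Call coverage peaks in a k-mer histogram
#'
#' After moving-average smoothing, the first local minimum after depth 1
#' is taken as the trough separating sequencing-error k-mers from genuine
#' coverage; the main peak is the argmax of the smoothed counts beyond
#' that trough.  A secondary (heterozygous) peak is reported when the
#' largest local maximum in `[0.4, 0.6] * main_peak_depth` reaches a
#' prominence fraction of the main peak height.
#'
#' @param histogram A [kmer_histogram].
#' @param smoothing_window Moving-average window (odd, default 3).
#' @param het_prominence Minimum height of the heterozygous peak as a
#'   fraction of the main peak height (default 0.1).
#' @return `list(main_peak_depth, het_peak_depth, error_trough_depth)`,
#'   class `peak_call`; `het_peak_depth` is `NA` when absent.
#' @export
call_peaks <- function(histogram, smoothing_window = 3L,
                       het_prominence = 0.1) {
  stopifnot(inherits(histogram, "kmer_histogram"))
  depths <- as.numeric(names(histogram$counts))
  if (!length(depths)) gw_stop("call_peaks(): empty histogram")
  max_d <- max(depths)
  if (max_d < 4L)
    gw_stop("call_peaks(): histogram is monotone at low depth - no ",
            "coverage peak; higher coverage needed")
  dense <- numeric(max_d)
  dense[depths] <- histogram$counts
  w <- max(1L, as.integer(smoothing_window))
  sm <- stats::filter(dense, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- dense[is.na(sm)]
  sm <- as.numeric(sm)
  trough <- NA_integer_
  for (d in 2:max(2L, max_d - 1L)) {
    if (d + 1L > max_d) break
    if (sm[d] <= sm[d - 1L] && sm[d] <= sm[d + 1L]) { trough <- d; break }
  }
  if (is.na(trough))
    gw_stop("call_peaks(): no error trough found; histogram is monotone - ",
            "coverage may be too low to separate a peak")
  cand <- seq_len(max_d) > trough
  if (!any(cand) || all(sm[cand] <= 0))
    gw_stop("call_peaks(): no coverage peak beyond the error trough; ",
            "higher coverage needed")
  main <- which(cand)[which.max(sm[cand])]
  if (sm[main] <= min(sm[(trough):main]))
    gw_stop("call_peaks(): no coverage peak beyond the error trough")
  lo <- max(2L, floor(0.4 * main)); hi <- ceiling(0.6 * main)
  het <- NA_integer_
  if (hi > lo) {
    win <- lo:hi
    is_max <- vapply(win, function(d) {
      d > 1L && d < max_d && sm[d] >= sm[d - 1L] && sm[d] >= sm[d + 1L]
    }, logical(1))
    win <- win[is_max & sm[win] >= het_prominence * sm[main]]
    if (length(win)) het <- win[which.max(sm[win])]
  }
  structure(list(main_peak_depth = as.integer(main),
                 het_peak_depth = as.integer(het),
                 error_trough_depth = as.integer(trough)),
            class = "peak_call")
}

#' Estimate genome size from a k-mer histogram
#'
#' Applies the classical formula `genome size = k-mer instances / peak
#' depth`.  In `"raw"` mode the full instance total is used; in
#' `"error_filtered"` mode instances at depths below the error trough are
#' subtracted first (unfiltered totals inflate the estimate when the error
#' rate is high).
#'
#' @param histogram A [kmer_histogram].
#' @param peaks A `peak_call` from [call_peaks()].
#' @param mode `"raw"` (default) or `"error_filtered"`.
#' @return `list(size_bp, size_mb, mode)`, class `genome_size_estimate`.
#' @export
estimate_genome_size <- function(histogram, peaks,
                                 mode = c("raw", "error_filtered")) {
  mode <- match.arg(mode)
  stopifnot(inherits(histogram, "kmer_histogram"))
  peak <- peaks$main_peak_depth
  if (is.null(peak) || is.na(peak) || peak < 2)
    gw_stop("estimate_genome_size(): main peak depth must be >= 2")
  total <- histogram$total_instances
  if (mode == "error_filtered") {
    depths <- as.numeric(names(histogram$counts))
    low <- depths < peaks$error_trough_depth
    total <- total - sum(depths[low] * histogram$counts[low])
  }
  size_bp <- total / peak
  structure(list(size_bp = size_bp, size_mb = size_bp / 1e6, mode = mode),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("genome size estimate (%s): %.0f bp (%.0f Mb)\n",
              x$mode, x$size_bp, x$size_mb))
  invisible(x)
}
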