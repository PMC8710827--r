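#' Construct a genome object
#'
#' A genome is the substrate of all synteny operations: an ordered table of
#' gene models on named chromosomes, optionally carrying coding and protein
#' sequences.  Coordinates are 1-based inclusive throughout the package;
#' BED-like input is converted at the read boundary.
#'
#' @param name Genome name.
#' @param genes data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` (`+`/`-`).  `order_index` (0-based rank of each gene
#'   along its chromosome by start) is computed if absent.
#' @param cds Optional named character vector of coding sequences
#'   (names are gene ids; lengths must be positive multiples of 3).
#' @param proteins Optional named character vector of protein sequences.
#'   If `cds` is given and `proteins` is `NULL`, proteins are derived by
#'   translation.
#' @return An object of class `genome`.
#' @export
genome <- function(name, genes, cds = NULL, proteins = NULL) {
  required <- c("gene_id", "chromosome", "start", "end", "strand")
  miss <- setdiff(required, names(genes))
  if (length(miss))
    gw_stop("genome(): missing gene columns: ", paste(miss, collapse = ", "))
  genes$gene_id    <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  if (anyDuplicated(genes$gene_id))
    gw_stop("genome(): duplicate gene_id: ",
            genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(genes$start > genes$end))
    gw_stop("genome(): start > end for gene ",
            genes$gene_id[which(genes$start > genes$end)[1]])
  if (!all(genes$strand %in% c("+", "-")))
    gw_stop("genome(): strand must be '+' or '-'")
  if (nrow(genes) == 0L) gw_stop("genome(): no genes")
  genes <- genes[order(genes$chromosome, genes$start), , drop = FALSE]
  genes$order_index <- stats::ave(genes$start, genes$chromosome,
                                  FUN = function(x) seq_along(x) - 1L)
  rownames(genes) <- NULL
  if (!is.null(cds)) {
    bad <- nchar(cds) == 0L | nchar(cds) %% 3L != 0L
    if (any(bad))
      gw_stop("genome(): CDS length not a positive multiple of 3: ",
              names(cds)[bad][1])
    if (is.null(proteins)) proteins <- translate_cds(cds)
  }
  structure(list(name = name, genes = genes, cds = cds,
                 proteins = proteins),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome '", x$name, "': ", nrow(x$genes), " genes on ",
      length(unique(x$genes$chromosome)), " chromosomes",
      if (!is.null(x$cds)) " (+CDS)", "\n", sep = "")
  invisible(x)
}

translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds), no.init.codon = TRUE))
  names(aa) <- names(cds)
  sub("\\*$", "", aa)
}

#' Read a gene-position table
#'
#' Supports a BED-like 5-column layout (`chrom start end gene_id strand`,
#' 0-based half-open) and a GFF-like 9-column layout (coordinates 1-based
#' inclusive, gene id taken from an `ID=` attribute).  BED-like coordinates
#' are converted to the internal 1-based inclusive convention.
#'
#' @param path Path to a whitespace/tab separated file.
#' @param dialect `"bed"` or `"gff"`.
#' @param name Genome name (defaults to the file base name).
#' @return A [genome] object with `order_index` assigned.
#' @export
read_gene_table <- function(path, dialect = c("bed", "gff"),
                            name = sub("\\.[^.]*$", "", basename(path))) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) gw_stop("read_gene_table(): no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- if (dialect == "bed") 5L else 9L
  bad <- which(vapply(fields, length, 1L) < ncols)
  if (length(bad))
    gw_stop("read_gene_table(): malformed row at line ", bad[1],
            " (expected ", ncols, " columns)")
  m <- do.call(rbind, fields)
  if (dialect == "bed") {
    genes <- data.frame(gene_id = m[, 4], chromosome = m[, 1],
                        start = as.integer(m[, 2]) + 1L,
                        end = as.integer(m[, 3]),
                        strand = m[, 5], stringsAsFactors = FALSE)
  } else {
    ids <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
    if (any(!grepl("ID=", m[, 9])))
      gw_stop("read_gene_table(): GFF row without ID attribute at line ",
              which(!grepl("ID=", m[, 9]))[1])
    genes <- data.frame(gene_id = ids, chromosome = m[, 1],
                        start = as.integer(m[, 4]),
                        end = as.integer(m[, 5]),
                        strand = m[, 7], stringsAsFactors = FALSE)
  }
  if (anyNA(genes$start) || anyNA(genes$end))
    gw_stop("read_gene_table(): non-numeric coordinate")
  genome(name, genes)
}

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings I/O returning plain named character
#' vectors.  `write_fasta()` then `read_fasta()` is the identity on records
#' (order and sequence preserved; line wrapping normalised).
#'
#' @param path File path.
#' @param x Named character vector of sequences.
#' @param width Line width used when writing.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) gw_stop("read_fasta(): no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(set) == 0L))
    gw_stop("read_fasta(): empty record: ",
            names(set)[Biostrings::width(set) == 0L][1])
  stats::setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    gw_stop("write_fasta(): sequences must be named")
  if (any(nchar(x) == 0L)) gw_stop("write_fasta(): empty sequence")
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a count matrix and its design table
#'
#' The count file is TSV with gene ids in the first column and one column
#' per sample; the design file is TSV with columns `sample_id`, `tissue`
#' (`root`/`shoot`), `time_h` (0/6/24) and `replicate`.  Sample columns are
#' reordered to match the design.
#'
#' @param path Count matrix TSV.
#' @param design_path Design TSV.
#' @return `list(counts = <integer matrix>, design = <data.frame>)`.
#' @export
read_counts <- function(path, design_path) {
  tab <- read_tsv_prov(path, check.names = FALSE)
  design <- read_tsv_prov(design_path)
  design <- validate_design(design)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  if (any(counts < 0) || any(counts != round(counts)))
    gw_stop("read_counts(): counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  missing <- setdiff(colnames(counts), design$sample_id)
  if (length(missing))
    gw_stop("read_counts(): samples absent from design: ",
            paste(missing, collapse = ", "))
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  design <- design[!is.na(design$sample_id), , drop = FALSE]
  list(counts = counts[, design$sample_id, drop = FALSE], design = design)
}

validate_design <- function(design) {
  req <- c("sample_id", "tissue", "time_h", "replicate")
  miss <- setdiff(req, names(design))
  if (length(miss))
    gw_stop("design: missing columns: ", paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  if (!all(design$tissue %in% c("root", "shoot")))
    gw_stop("design: tissue must be 'root' or 'shoot'")
  if (!all(design$time_h %in% c(0, 6, 24)))
    gw_stop("design: time_h must be 0, 6 or 24")
  key <- paste(design$tissue, design$time_h, design$replicate)
  if (anyDuplicated(key))
    gw_stop("design: duplicated (tissue, time_h, replicate)")
  grp <- table(paste(design$tissue, design$time_h))
  if (any(grp < 2))
    gw_stop("design: every (tissue, time_h) group needs >= 2 replicates")
  design
}

#' Write synteny blocks as TSV
#'
#' Emits one row per block with the columns
#' `block_id, genome_a, chrom_a, genome_b, chrom_b, n_pairs, orientation,
#' mean_ks, class`, preceded by a commented provenance header.
#'
#' @param blocks A `synteny_blocks` object (see [chain_anchors()]).
#' @param path Output path.
#' @param params Named list recorded in the header.
#' @export
write_blocks_tsv <- function(blocks, path, params = list()) {
  df <- blocks$blocks
  if (is.null(df$mean_ks)) df$mean_ks <- NA_real_
  if (is.null(df$class)) df$class <- NA_character_
  keep <- c("block_id", "genome_a", "chrom_a", "genome_b", "chrom_b",
            "n_pairs", "orientation", "mean_ks", "class")
  write_tsv_prov(df[, keep], path, params)
}
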