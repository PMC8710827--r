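## Synthetic-data generators.  These produce every input the pipeline
## consumes -- gene-order genomes with planted WGDs, codon pairs at
## controlled synonymous divergence, NB RNA-seq counts with planted
## effects, and k-mer depth histograms -- together with truth tables
## sufficient to score every downstream inference.

#' WGD simulation scenario
#'
#' Describes a focal genome that shares an ancient WGD with a reference
#' lineage and additionally underwent one (or more, if
#' `specific_wgd_ds` has several elements, oldest first) lineage-specific
#' WGDs, followed by fractionation, chromosome fusions and segmental
#' inversions.
#'
#' @param n_chromosomes Number of ancestral (proto) chromosomes.
#' @param genes_per_chromosome Genes per proto chromosome.
#' @param shared_wgd_ds Synonymous divergence (Ks) target of the ancient
#'   WGD shared by both lineages; `NA` skips the shared event, in which
#'   case the reference genome equals the proto genome.
#' @param specific_wgd_ds Ks target(s) of the focal-lineage WGD event(s);
#'   each must be younger than `ortholog_ds`.
#' @param ortholog_ds Ks target of the reference/focal speciation.
#' @param retention_prob Probability that each copy created by a WGD
#'   survives fractionation, applied independently per copy and per event.
#' @param n_fusions Number of end-to-end chromosome fusions in the focal
#'   genome (each joins two chromosomes of distinct proto origin).
#' @param inversion_rate Expected segmental inversions per focal
#'   chromosome (Poisson).
#' @param omega Ka/Ks ratio used when evolving coding sequences.
#' @param cds_length_codons Length of every simulated CDS, in codons.
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return A list of class `wgd_scenario`.
#' @export
wgd_scenario <- function(n_chromosomes = 5, genes_per_chromosome = 200,
                         shared_wgd_ds = NA, specific_wgd_ds = 0.15,
                         ortholog_ds = 0.45, retention_prob = 0.7,
                         n_fusions = 0, inversion_rate = 0,
                         omega = 0.2, cds_length_codons = 150,
                         seed = 1L) {
  if (retention_prob <= 0 || retention_prob > 1)
    gw_stop("wgd_scenario(): retention_prob must be in (0, 1]")
  if (any(specific_wgd_ds >= ortholog_ds))
    gw_stop("wgd_scenario(): specific_wgd_ds must be < ortholog_ds")
  if (!is.na(shared_wgd_ds) && ortholog_ds >= shared_wgd_ds)
    gw_stop("wgd_scenario(): ortholog_ds must be < shared_wgd_ds")
  structure(list(n_chromosomes = n_chromosomes,
                 genes_per_chromosome = genes_per_chromosome,
                 shared_wgd_ds = shared_wgd_ds,
                 specific_wgd_ds = sort(specific_wgd_ds, decreasing = TRUE),
                 ortholog_ds = ortholog_ds,
                 retention_prob = retention_prob,
                 n_fusions = n_fusions, inversion_rate = inversion_rate,
                 omega = omega, cds_length_codons = cds_length_codons,
                 seed = as.integer(seed)),
            class = "wgd_scenario")
}

random_cds <- function(length_codons) {
  ct <- codon_tables()
  start <- "ATG"
  body <- sample(ct$sense, length_codons - 1L, replace = TRUE)
  paste(c(start, body), collapse = "")
}

## Evolve a CDS along one branch of length ds_branch (expected synonymous
## substitutions per synonymous site).  Mutation events hit uniform
## nucleotide positions; synonymous changes are always accepted,
## nonsynonymous changes with probability omega, stop-creating changes
## never.  This makes the accepted-event densities ds and omega*ds on the
## NG86 site scale while multiple hits accumulate naturally.
mutate_cds <- function(cds, ds_branch, omega) {
  if (ds_branch <= 0) return(cds)
  gc <- codon_tables()$gc
  codons <- split_codons(cds)
  L <- length(codons)
  n_events <- rpois(1L, 3 * L * ds_branch)
  if (n_events == 0L) return(cds)
  pos <- sample.int(3L * L, n_events, replace = TRUE)
  alt_draw <- sample.int(3L, n_events, replace = TRUE)
  acc_draw <- runif(n_events)
  for (i in seq_len(n_events)) {
    ci <- (pos[i] - 1L) %/% 3L + 1L
    wp <- (pos[i] - 1L) %% 3L + 1L
    cur <- codons[ci]
    base <- substr(cur, wp, wp)
    alt <- setdiff(BASES, base)[alt_draw[i]]
    new <- cur
    substr(new, wp, wp) <- alt
    if (gc[[new]] == "*") next
    if (gc[[new]] == gc[[cur]] || acc_draw[i] <= omega)
      codons[ci] <- new
  }
  paste(codons, collapse = "")
}

#' Evolve a pair of coding sequences to a target synonymous divergence
#'
#' Generates a random ancestral CDS (no internal stops) and evolves two
#' independent copies, each along a branch of `target_ds / 2`, by Poisson
#' placement of point substitutions so that the expected pairwise
#' synonymous divergence is `target_ds` and the nonsynonymous divergence
#' is `omega * target_ds`.
#'
#' @param length_codons CDS length in codons (>= 50 recommended).
#' @param target_ds Target pairwise Ks in `[0, 2]`.
#' @param omega Ka/Ks ratio.
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @return `list(cds1, cds2, realized_events)` where `realized_events`
#'   gives the accepted synonymous/nonsynonymous substitution counts.
#' @export
evolve_cds_pair <- function(length_codons, target_ds, omega = 0.2,
                            seed = NULL) {
  if (target_ds > 2)
    gw_stop("evolve_cds_pair(): target_ds > 2 is saturated; Ks is not ",
            "recoverable at that depth")
  if (target_ds < 0) gw_stop("evolve_cds_pair(): target_ds must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  anc <- random_cds(length_codons)
  cds1 <- mutate_cds(anc, target_ds / 2, omega)
  cds2 <- mutate_cds(anc, target_ds / 2, omega)
  diff1 <- count_sub_types(anc, cds1)
  diff2 <- count_sub_types(anc, cds2)
  list(cds1 = cds1, cds2 = cds2,
       realized_events = diff1 + diff2)
}

count_sub_types <- function(cds_a, cds_b) {
  ct <- codon_tables()
  pd <- pair_diff_tables()
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  idx <- cbind(match(ca, ct$codons), match(cb, ct$codons))
  c(syn = sum(pd$sd[idx]), nonsyn = sum(pd$nd[idx]))
}

#' Simulate a reference/focal genome pair with planted WGDs
#'
#' Builds a proto genome, optionally applies the shared ancient WGD to
#' both lineages, then the focal-specific WGD(s), with independent
#' per-copy fractionation at `retention_prob`, end-to-end chromosome
#' fusions and Poisson segmental inversions in the focal genome.  Coding
#' sequences are evolved along the implied gene trees so that paralog and
#' ortholog pairs hit their target Ks depths in expectation.
#'
#' @param scenario A [wgd_scenario].
#' @param max_retries Number of regeneration attempts if fractionation
#'   empties a focal chromosome.
#' @return `list(focal, reference, truth)`: two [genome] objects plus a
#'   truth list with `$genes` (origin of every gene) and `$relations`
#'   (every ortholog/paralog pair with its relation and target Ks).
#' @export
simulate_wgd_genome <- function(scenario, max_retries = 5L) {
  stopifnot(inherits(scenario, "wgd_scenario"))
  set.seed(scenario$seed)
  for (attempt in seq_len(max_retries)) {
    res <- try(build_wgd_genomes(scenario), silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
    if (!grepl("empty chromosome", as.character(res)))
      stop(attr(res, "condition"))
    warning("simulate_wgd_genome(): fractionation emptied a chromosome; ",
            "regenerating (attempt ", attempt, ")")
  }
  gw_stop("simulate_wgd_genome(): retention too low - a chromosome ",
          "emptied in every attempt")
}

build_wgd_genomes <- function(sc) {
  n_genes <- sc$n_chromosomes * sc$genes_per_chromosome
  proto <- data.frame(
    proto_gene = sprintf("g%05d", seq_len(n_genes)),
    proto_chromosome = rep(sprintf("pc%02d", seq_len(sc$n_chromosomes)),
                           each = sc$genes_per_chromosome),
    proto_pos = rep(seq_len(sc$genes_per_chromosome), sc$n_chromosomes),
    stringsAsFactors = FALSE)
  anc_cds <- vapply(seq_len(n_genes),
                    function(i) random_cds(sc$cds_length_codons), "")
  shared <- !is.na(sc$shared_wgd_ds)
  copies <- if (shared) c("U", "V") else "U"
  r <- sc$retention_prob

  ## sequence at the speciation node, per proto gene x shared copy
  spec_seq <- list()
  for (cp in copies) {
    stem <- if (shared) (sc$shared_wgd_ds - sc$ortholog_ds) / 2 else 0
    spec_seq[[cp]] <- vapply(anc_cds, mutate_cds, "",
                             ds_branch = stem, omega = sc$omega,
                             USE.NAMES = FALSE)
  }

  ## ---- reference lineage: shared copies fractionate independently ----
  ref_rows <- list(); ref_cds <- character(0)
  for (cp in copies) {
    keep <- if (shared) runif(n_genes) <= r else rep(TRUE, n_genes)
    idx <- which(keep)
    if (!length(idx)) gw_stop("empty chromosome in reference")
    ids <- paste0("R_", proto$proto_gene[idx], "_", cp)
    seqs <- vapply(spec_seq[[cp]][idx], mutate_cds, "",
                   ds_branch = sc$ortholog_ds / 2, omega = sc$omega,
                   USE.NAMES = FALSE)
    ref_cds <- c(ref_cds, stats::setNames(seqs, ids))
    ref_rows[[cp]] <- data.frame(
      gene_id = ids,
      chromosome = paste0("r", proto$proto_chromosome[idx],
                          if (shared) cp else ""),
      proto_idx = idx, copy = cp, stringsAsFactors = FALSE)
  }
  ref_tab <- do.call(rbind, ref_rows)

  ## ---- focal lineage: shared fractionation, then the specific WGD(s) ----
  events <- sc$specific_wgd_ds
  foc_rows <- list(); foc_cds <- character(0)
  for (cp in copies) {
    keep <- if (shared) runif(n_genes) <= r else rep(TRUE, n_genes)
    base_idx <- which(keep)
    if (!length(base_idx)) gw_stop("empty chromosome in focal")
    depth0 <- sc$ortholog_ds / 2
    seq0 <- spec_seq[[cp]][base_idx]
    leaves <- evolve_subtree(seq0, depth0, events, sc$omega, r)
    for (path in names(leaves)) {
      lf <- leaves[[path]]
      idx <- base_idx[lf$alive]
      if (!length(idx)) gw_stop("empty chromosome in focal")
      ids <- paste0("F_", proto$proto_gene[idx], "_", cp, path)
      foc_cds <- c(foc_cds, stats::setNames(lf$seq[lf$alive], ids))
      foc_rows[[paste0(cp, path)]] <- data.frame(
        gene_id = ids,
        chromosome = paste0("f", proto$proto_chromosome[idx], cp, path),
        proto_idx = idx, copy = paste0(cp, path), stringsAsFactors = FALSE)
    }
  }
  foc_tab <- do.call(rbind, foc_rows)

  ## positions along each chromosome follow proto gene order
  mk_genes <- function(tab) {
    tab <- tab[order(tab$chromosome, tab$proto_idx), , drop = FALSE]
    pos <- stats::ave(tab$proto_idx, tab$chromosome,
                      FUN = function(x) seq_along(x))
    data.frame(gene_id = tab$gene_id, chromosome = tab$chromosome,
               start = (pos - 1L) * 1000L + 1L,
               end = (pos - 1L) * 1000L + 900L,
               strand = "+", stringsAsFactors = FALSE)
  }
  ref_genes <- mk_genes(ref_tab)
  foc_genes <- mk_genes(foc_tab)

  ## segmental inversions (focal)
  if (sc$inversion_rate > 0)
    foc_genes <- apply_inversions(foc_genes, sc$inversion_rate)
  ## chromosome fusions (focal)
  fused <- character(0)
  if (sc$n_fusions > 0) {
    fus <- apply_fusions(foc_genes, foc_tab, sc$n_fusions)
    foc_genes <- fus$genes
    fused <- fus$fused
  }

  reference <- genome("reference", ref_genes, cds = ref_cds)
  focal <- genome("focal", foc_genes, cds = foc_cds)

  truth_genes <- rbind(
    data.frame(gene_id = ref_tab$gene_id, genome = "reference",
               proto_gene = proto$proto_gene[ref_tab$proto_idx],
               proto_chromosome = proto$proto_chromosome[ref_tab$proto_idx],
               copy = ref_tab$copy, stringsAsFactors = FALSE),
    data.frame(gene_id = foc_tab$gene_id, genome = "focal",
               proto_gene = proto$proto_gene[foc_tab$proto_idx],
               proto_chromosome = proto$proto_chromosome[foc_tab$proto_idx],
               copy = foc_tab$copy, stringsAsFactors = FALSE))
  relations <- truth_relations(truth_genes, sc)
  list(focal = focal, reference = reference,
       truth = list(genes = truth_genes, relations = relations,
                    fused_chromosomes = fused, scenario = sc))
}

## recursively evolve a vector of sequences down the focal event tree;
## returns one entry per leaf path with per-gene survival flags
evolve_subtree <- function(seqs, depth, events, omega, retention) {
  if (!length(events)) {
    out <- vapply(seqs, mutate_cds, "", ds_branch = depth, omega = omega,
                  USE.NAMES = FALSE)
    return(stats::setNames(list(list(seq = out,
                                     alive = rep(TRUE, length(out)))), ""))
  }
  e <- events[1]
  node <- vapply(seqs, mutate_cds, "", ds_branch = depth - e / 2,
                 omega = omega, USE.NAMES = FALSE)
  res <- list()
  for (child in c("a", "b")) {
    alive <- runif(length(node)) <= retention
    sub <- evolve_subtree(node, e / 2, events[-1], omega, retention)
    for (pi in seq_along(sub)) {
      entry <- sub[[pi]]
      entry$alive <- entry$alive & alive
      res[[paste0(child, names(sub)[pi])]] <- entry
    }
  }
  res
}

apply_inversions <- function(genes, rate) {
  for (ch in unique(genes$chromosome)) {
    sel <- which(genes$chromosome == ch)
    sel <- sel[order(genes$start[sel])]
    n_inv <- rpois(1L, rate)
    for (i in seq_len(n_inv)) {
      n <- length(sel)
      if (n < 2) break
      ends <- sort(sample.int(n, 2L))
      span <- sel[ends[1]:ends[2]]
      genes$gene_id[span] <- rev(genes$gene_id[span])
      genes$strand[span] <- rev(ifelse(genes$strand[span] == "+", "-", "+"))
    }
  }
  genes
}

apply_fusions <- function(genes, tab, n_fusions) {
  origin <- tapply(tab$proto_idx, tab$chromosome, function(i) i[1])
  proto_of <- sub("^f(pc[0-9]+).*$", "\\1", names(origin))
  avail <- names(origin)
  fused <- character(0)
  for (i in seq_len(n_fusions)) {
    if (length(avail) < 2)
      gw_stop("apply_fusions(): not enough chromosomes left to fuse")
    c1 <- sample(avail, 1)
    other <- avail[proto_of[match(avail, names(origin))] !=
                     proto_of[match(c1, names(origin))]]
    if (!length(other))
      gw_stop("apply_fusions(): no fusion partner of distinct origin")
    c2 <- sample(other, 1)
    new_name <- paste0(c1, "_", c2)
    off <- max(genes$end[genes$chromosome == c1]) + 1000L
    sel2 <- genes$chromosome == c2
    genes$start[sel2] <- genes$start[sel2] + off
    genes$end[sel2] <- genes$end[sel2] + off
    genes$chromosome[genes$chromosome %in% c(c1, c2)] <- new_name
    fused <- c(fused, new_name)
    avail <- setdiff(avail, c(c1, c2))
  }
  list(genes = genes, fused = fused)
}

truth_relations <- function(truth_genes, sc) {
  shared <- !is.na(sc$shared_wgd_ds)
  rel <- list()
  for (pg in split(truth_genes, truth_genes$proto_gene)) {
    refs <- pg[pg$genome == "reference", ]
    focs <- pg[pg$genome == "focal", ]
    ## reference vs focal
    if (nrow(refs) && nrow(focs)) {
      for (i in seq_len(nrow(refs))) for (j in seq_len(nrow(focs))) {
        same_copy <- substr(refs$copy[i], 1, 1) == substr(focs$copy[j], 1, 1)
        rel[[length(rel) + 1L]] <- data.frame(
          gene_1 = refs$gene_id[i], gene_2 = focs$gene_id[j],
          relation = if (same_copy) "ortholog" else "outparalog",
          target_ds = if (same_copy) sc$ortholog_ds else sc$shared_wgd_ds,
          stringsAsFactors = FALSE)
      }
    }
    ## focal vs focal
    if (nrow(focs) > 1) {
      for (i in seq_len(nrow(focs) - 1L)) for (j in (i + 1L):nrow(focs)) {
        ci <- focs$copy[i]; cj <- focs$copy[j]
        if (substr(ci, 1, 1) != substr(cj, 1, 1)) {
          rel[[length(rel) + 1L]] <- data.frame(
            gene_1 = focs$gene_id[i], gene_2 = focs$gene_id[j],
            relation = "shared_paralog", target_ds = sc$shared_wgd_ds,
            stringsAsFactors = FALSE)
        } else {
          ## divergence event = first path position where the copies differ
          pi <- substring(ci, 2); pj <- substring(cj, 2)
          k <- which(strsplit(pi, "")[[1]] != strsplit(pj, "")[[1]])[1]
          rel[[length(rel) + 1L]] <- data.frame(
            gene_1 = focs$gene_id[i], gene_2 = focs$gene_id[j],
            relation = "specific_paralog",
            target_ds = sc$specific_wgd_ds[k], stringsAsFactors = FALSE)
        }
      }
    }
    ## reference vs reference shared pairs
    if (shared && nrow(refs) > 1) {
      rel[[length(rel) + 1L]] <- data.frame(
        gene_1 = refs$gene_id[1], gene_2 = refs$gene_id[2],
        relation = "shared_paralog", target_ds = sc$shared_wgd_ds,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rel))
    return(data.frame(gene_1 = character(), gene_2 = character(),
                      relation = character(), target_ds = numeric()))
  do.call(rbind, rel)
}
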