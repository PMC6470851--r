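# Synthetic inputs with recoverable ground truth: gene orders with planted
# tandem arrays and collinear segments, codon pairs diverged under a
# controlled dN/dS, and replicated Ct tables with planted fold changes.

#' Simulate a genome's gene order with planted duplicate structure
#'
#' Lays out `genes_per_chrom` filler genes per chromosome, then plants (a)
#' tandem arrays: runs of adjacent genes whose consecutive members form true
#' tandem pairs, and (b) duplicated collinear segments: rank-parallel anchor
#' runs across two chromosomes. Noise homolog pairs connect random unrelated
#' genes. Truth labels score any downstream detector.
#'
#' @param n_chrom Chromosome count.
#' @param genes_per_chrom Genes per chromosome (filler included).
#' @param n_tandem_arrays,tandem_array_len Number and length (genes) of
#'   planted tandem arrays.
#' @param n_segments,segment_anchors Number and anchor count of planted
#'   duplicated segments.
#' @param n_noise_pairs Random homolog pairs with no planted structure.
#' @param seed Integer seed fixing all draws.
#' @return list: `registry` (ranked `gene_registry`), `pairs` (homolog pairs
#'   with scores), `truth` (data.frame `gene_a`, `gene_b`, `true_type` in
#'   tandem/segmental/noise).
#' @export
simulate_genome <- function(n_chrom = 3, genes_per_chrom = 200,
                            n_tandem_arrays = 2, tandem_array_len = 3,
                            n_segments = 1, segment_anchors = 8,
                            n_noise_pairs = 0, seed = 1L) {
  stopifnot(n_chrom >= 1, genes_per_chrom >= 2)
  set.seed(as.integer(seed))
  gid <- function(chr, idx) sprintf("g%02d_%04d", chr, idx)
  genes <- do.call(rbind, lapply(seq_len(n_chrom), function(chr) {
    data.frame(gene_id = gid(chr, seq_len(genes_per_chrom)),
               chromosome = chr,
               start = seq_len(genes_per_chrom) * 1000,
               stringsAsFactors = FALSE)
  }))
  used <- lapply(seq_len(n_chrom), function(i) integer(0))
  claim <- function(chr, len) {
    for (try in 1:200) {
      s <- sample.int(genes_per_chrom - len + 1L, 1L)
      span <- s:(s + len - 1L)
      if (!any(span %in% used[[chr]])) {
        used[[chr]] <<- c(used[[chr]], span)
        return(span)
      }
    }
    stop("infeasible placement: chromosome ", chr, " cannot fit a run of ", len)
  }
  truth <- data.frame(gene_a = character(0), gene_b = character(0),
                      true_type = character(0), stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (n_tandem_arrays > 0) {
    stopifnot(tandem_array_len >= 2)
    for (t in seq_len(n_tandem_arrays)) {
      chr <- sample.int(n_chrom, 1L)
      span <- claim(chr, tandem_array_len)
      ids <- gid(chr, span)
      for (i in seq_len(tandem_array_len - 1L)) {
        truth <- rbind(truth, data.frame(gene_a = ids[i], gene_b = ids[i + 1L],
                                         true_type = "tandem"))
        pairs <- rbind(pairs, data.frame(gene_a = ids[i], gene_b = ids[i + 1L],
                                         score = stats::runif(1, 80, 100)))
      }
    }
  }
  if (n_segments > 0) {
    stopifnot(segment_anchors >= 2, n_chrom >= 2 || segment_anchors * 2 <= genes_per_chrom)
    for (s in seq_len(n_segments)) {
      chrs <- if (n_chrom >= 2) sample.int(n_chrom, 2L) else c(1L, 1L)
      span_a <- claim(chrs[1], segment_anchors)
      span_b <- claim(chrs[2], segment_anchors)
      for (i in seq_len(segment_anchors)) {
        pa <- gid(chrs[1], span_a[i]); pb <- gid(chrs[2], span_b[i])
        truth <- rbind(truth, data.frame(gene_a = pa, gene_b = pb,
                                         true_type = "segmental"))
        pairs <- rbind(pairs, data.frame(gene_a = pa, gene_b = pb,
                                         score = stats::runif(1, 80, 100)))
      }
    }
  }
  if (n_noise_pairs > 0) {
    key <- paste(pmin(pairs$gene_a, pairs$gene_b),
                 pmax(pairs$gene_a, pairs$gene_b))
    added <- 0
    while (added < n_noise_pairs) {
      cand <- sample(genes$gene_id, 2L)
      k <- paste(min(cand), max(cand))
      if (k %in% key) next
      key <- c(key, k)
      pairs <- rbind(pairs, data.frame(gene_a = cand[1], gene_b = cand[2],
                                       score = stats::runif(1, 30, 70)))
      truth <- rbind(truth, data.frame(gene_a = cand[1], gene_b = cand[2],
                                       true_type = "noise"))
      added <- added + 1
    }
  }
  reg <- gene_registry(genes$gene_id, locus_tag = genes$gene_id,
                       chromosome = genes$chromosome,
                       start = genes$start, end = genes$start + 500)
  reg <- assign_ranks(reg)
  list(registry = reg, pairs = canonical_pairs(pairs),
       truth = truth)
}

#' Simulate a codon-sequence pair diverged under a controlled dN/dS
#'
#' A random ancestor of sense codons evolves along two independent lineages:
#' single-base changes are proposed uniformly over sites and alternative
#' bases; synonymous proposals are always accepted, nonsynonymous ones with
#' probability `omega`, and stop-creating ones rejected. Evolution stops once
#' the realized synonymous divergence (accepted synonymous changes per
#' ancestral synonymous site, both lineages pooled) reaches `ks_target`. Under
#' this kernel the realized dN/dS approaches `omega` at low divergence.
#'
#' @param n_codons Sequence length in codons.
#' @param omega Target nonsynonymous/synonymous rate ratio (> 0).
#' @param ks_target Expected synonymous divergence (>= 0).
#' @param seed Integer seed.
#' @return list: `a`, `b` (CDS strings), `alignment` (`codon_alignment`),
#'   `truth` (list with `omega`, `ks_target`, realized `syn_subs` and
#'   `nonsyn_subs`).
#' @export
simulate_codon_pair <- function(n_codons = 300, omega = 0.2, ks_target = 0.3,
                                seed = 1L) {
  if (omega <= 0) stop("omega must be > 0")
  if (ks_target < 0) stop("ks_target must be >= 0")
  set.seed(as.integer(seed))
  sense <- sense_codons()
  anc <- sample(sense, n_codons, replace = TRUE)
  S_anc <- sum(vapply(anc, syn_sites, 0))
  target_subs <- ks_target * S_anc
  gc <- codon_table()
  bases <- c("A", "C", "G", "T")
  lineages <- list(anc, anc)
  syn_done <- 0; nonsyn_done <- 0
  while (syn_done < target_subs) {
    l <- sample.int(2L, 1L)
    ci <- sample.int(n_codons, 1L)
    pos <- sample.int(3L, 1L)
    cod <- strsplit(lineages[[l]][ci], "")[[1]]
    alt <- sample(setdiff(bases, cod[pos]), 1L)
    new <- cod; new[pos] <- alt
    newc <- paste(new, collapse = "")
    if (gc[[newc]] == "*") next
    syn <- gc[[newc]] == gc[[lineages[[l]][ci]]]
    if (syn || stats::runif(1) < omega) {
      lineages[[l]][ci] <- newc
      if (syn) syn_done <- syn_done + 1 else nonsyn_done <- nonsyn_done + 1
    }
  }
  a <- paste(lineages[[1]], collapse = "")
  b <- paste(lineages[[2]], collapse = "")
  list(a = a, b = b,
       alignment = structure(list(a = a, b = b), class = "codon_alignment"),
       truth = list(omega = omega, ks_target = ks_target,
                    syn_subs = syn_done, nonsyn_subs = nonsyn_done))
}

#' Simulate a replicated Ct table with planted fold changes
#'
#' `Ct(g, s, rep) = baseline(g) - planted_log2fold(g, s) + noise`; the
#' reference gene is flat at `ref_ct` plus noise. The first condition column
#' is the calibrator and its planted folds must all be zero. Noise is Gaussian
#' per technical well, in cycles.
#'
#' @param log2fold Genes x conditions matrix of planted log2 fold changes
#'   (dimnames required; calibrator column = first column, all zero).
#' @param baseline_ct Per-gene baseline Ct (recycled; default 24).
#' @param ref_gene,ref_ct Reference gene id and its Ct level.
#' @param n_bio,n_tech Biological and technical replicate counts.
#' @param noise_sd Gaussian noise sd in cycles (>= 0).
#' @param seed Integer seed.
#' @return list: `table` (a `ct_table`), `truth` (the planted `log2fold`
#'   matrix).
#' @export
simulate_ct_table <- function(log2fold, baseline_ct = 24, ref_gene = "ACT",
                              ref_ct = 18, n_bio = 3, n_tech = 3,
                              noise_sd = 0.2, seed = 1L) {
  if (noise_sd < 0) stop("noise sd must be >= 0")
  stopifnot(!is.null(rownames(log2fold)), !is.null(colnames(log2fold)))
  if (any(log2fold[, 1] != 0)) {
    stop("calibrator (first) column of planted log2 folds must be zero")
  }
  set.seed(as.integer(seed))
  genes <- rownames(log2fold)
  conds <- colnames(log2fold)
  base <- rep_len(baseline_ct, length(genes))
  rows <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                      gene_id = c(genes, ref_gene), sample_id = conds,
                      stringsAsFactors = FALSE)
  mu <- ifelse(rows$gene_id == ref_gene, ref_ct,
               base[match(rows$gene_id, genes)] -
                 log2fold[cbind(match(rows$gene_id, genes),
                                match(rows$sample_id, conds))])
  rows$ct <- mu + stats::rnorm(nrow(rows), 0, noise_sd)
  list(table = ct_table(rows, ref_gene, conds[1]), truth = log2fold)
}
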