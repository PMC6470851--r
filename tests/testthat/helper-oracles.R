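# Independent oracles and fixture builders shared across test files.

table1_path <- function() system.file("extdata", "table1.tsv", package = "paralogdiv")
table2_path <- function() system.file("extdata", "table2.tsv", package = "paralogdiv")

read_table2 <- function() utils::read.delim(table2_path(), stringsAsFactors = FALSE)

# --- Nei-Gojobori oracle -----------------------------------------------------
# Independent of the package's implementation: per-codon synonymous fractions
# recomputed from the genetic code, and differing codons decomposed by
# recursive enumeration of complete mutational paths (the package enumerates
# orderings of differing positions instead).
oracle_ng <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(a); cb <- split3(b)
  bases <- c("A", "C", "G", "T")
  syn_frac <- function(cod) {
    aa <- gc[[cod]]; s <- 0
    v0 <- strsplit(cod, "")[[1]]
    for (pos in 1:3) for (bs in setdiff(bases, v0[pos])) {
      v <- v0; v[pos] <- bs
      if (gc[[paste(v, collapse = "")]] == aa) s <- s + 1 / 3
    }
    s
  }
  paths <- function(c1, c2) {
    if (c1 == c2) return(list(c(0, 0)))
    v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
    out <- list()
    for (pos in which(v1 != v2)) {
      nv <- v1; nv[pos] <- v2[pos]
      nc <- paste(nv, collapse = "")
      if (gc[[nc]] == "*") next
      step <- if (gc[[nc]] == gc[[c1]]) c(1, 0) else c(0, 1)
      for (rest in paths(nc, c2)) out[[length(out) + 1L]] <- step + rest
    }
    out
  }
  S1 <- S2 <- Sd <- Nd <- 0; used <- 0
  sense <- names(gc)[gc != "*"]
  for (i in seq_along(ca)) {
    if (!(ca[i] %in% sense) || !(cb[i] %in% sense)) next
    pp <- paths(ca[i], cb[i])
    if (length(pp) == 0) next
    m <- do.call(rbind, pp)
    S1 <- S1 + syn_frac(ca[i]); S2 <- S2 + syn_frac(cb[i])
    Sd <- Sd + mean(m[, 1]); Nd <- Nd + mean(m[, 2])
    used <- used + 1
  }
  S_sites <- (S1 + S2) / 2
  N_sites <- 3 * used - S_sites
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  pS <- if (S_sites > 0) Sd / S_sites else NA_real_
  pN <- if (N_sites > 0) Nd / N_sites else NA_real_
  list(S_sites = S_sites, N_sites = N_sites, Sd = Sd, Nd = Nd,
       Ks = jc(pS), Ka = jc(pN), codons_used = used)
}

# Fixed codon set for the oracle-equivalence sweep: includes codons one step
# from stops so stop-crossing pathway exclusion is exercised.
NG_CODON_SET <- c("TTT", "TTA", "TAC", "TGC", "AGA", "GGG", "ATG", "AAA")

random_codon_seq <- function(len, set = NG_CODON_SET) {
  paste(sample(set, len, replace = TRUE), collapse = "")
}

# --- trees -------------------------------------------------------------------
# Random additive distance matrix: path lengths of a random tree.
random_additive_dm <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
  dm <- stats::cophenetic(tr)
  dm <- dm[order(rownames(dm)), order(colnames(dm))]
  list(tree = ape::unroot(tr), dm = dm)
}

# Four-taxon protein alignment with a strong AB|CD split: shared columns
# separate the pairs, a few private columns give within-pair divergence.
strong_split_msa <- function(n_split = 60, n_priv = 10) {
  col <- function(a, b, c, d) c(A = a, B = b, C = c, D = d)
  cols <- c(replicate(n_split, col("A", "A", "S", "S"), simplify = FALSE),
            replicate(n_priv, col("K", "R", "K", "K"), simplify = FALSE),
            replicate(n_priv, col("L", "L", "I", "L"), simplify = FALSE))
  m <- do.call(cbind, cols)
  apply(m, 1, paste, collapse = "")
}

# --- Table 2 duplication evidence -------------------------------------------
# Table 1 plus synthetic filler genes and synthetic collinear anchors planted
# so that the two segmentally duplicated pairs fall inside real chained
# blocks, while every tandem pair keeps its locus adjacency. The paper's
# collinearity output is not deposited, so this evidence is synthetic by
# construction.
table2_evidence <- function() {
  t1 <- utils::read.delim(table1_path(), stringsAsFactors = FALSE)
  filler <- data.frame(
    gene_id = c(sprintf("FIL2_%d", 1:4), sprintf("FIL4_%d", 1:4),
                sprintf("FIL5a_%d", 1:4), sprintf("FIL5b_%d", 1:4)),
    locus_tag = c(sprintf("LOC_Os02g%05d.1", 36400 + 4 * (0:3)),
                  sprintf("LOC_Os04g%05d.1", 38200 + 5 * (0:3)),
                  sprintf("LOC_Os05g%05d.1", 49200 + 10 * (0:3)),
                  sprintf("LOC_Os05g%05d.1", 50240 + 10 * (0:3))),
    subfamily = NA_character_, stringsAsFactors = FALSE)
  all <- rbind(t1[c("gene_id", "locus_tag", "subfamily")], filler)
  reg <- gene_registry(all$gene_id, locus_tag = all$locus_tag,
                       subfamily = all$subfamily)
  reg <- suppressWarnings(assign_ranks(reg, use_locus_order = TRUE))
  anchors <- data.frame(
    gene_a = c(sprintf("FIL2_%d", 1:4), "OsSTP10",
               sprintf("FIL5a_%d", 1:4), "OsERD3"),
    gene_b = c(sprintf("FIL4_%d", 1:4), "OsSTP18",
               sprintf("FIL5b_%d", 1:4), "OsERD5"),
    score = 100, stringsAsFactors = FALSE)
  list(registry = reg, anchors = anchors)
}
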