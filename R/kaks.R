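# Codon bookkeeping for the Nei-Gojobori counting method. All tables derive
# from the standard genetic code shipped with Biostrings; pathway
# decompositions are memoized per codon pair.
.codon_cache <- new.env(parent = emptyenv())

codon_table <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  gc <- codon_table()
  names(gc)[gc != "*"]
}

translate_codons <- function(codons) {
  gc <- codon_table()
  aa <- gc[codons]
  if (anyNA(aa)) stop("untranslatable codon: ", codons[is.na(aa)][1])
  unname(aa)
}

#' Translate a CDS to protein
#'
#' @param cds In-frame coding sequence (no gaps); length divisible by 3.
#' @return Amino-acid string (stops as `*`).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(translate_codons(codons), collapse = "")
}

# Fraction of the three possible single-base changes at each codon position
# that preserve the amino acid; changes to stop codons count as nonsynonymous.
# Returns the codon's total synonymous site count (sum over positions of n/3).
syn_sites <- function(codon) {
  key <- paste0("S:", codon)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- codon_table()
  aa <- gc[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  cvec <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (b in setdiff(bases, cvec[pos])) {
      mut <- cvec; mut[pos] <- b
      if (gc[[paste(mut, collapse = "")]] == aa) s <- s + 1 / 3
    }
  }
  assign(key, s, envir = .codon_cache)
  s
}

# Pathway-averaged (syn, nonsyn) difference counts between two sense codons:
# all orderings of the differing positions are enumerated with equal weight,
# orderings passing through a stop codon are excluded. Returns c(sd, nd), or
# NULL when every pathway crosses a stop.
codon_path_counts <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  key <- paste0("P:", c1, c2)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) return(if (all(is.na(hit))) NULL else hit)
  gc <- codon_table()
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  diffpos <- which(v1 != v2)
  orders <- .permutations(diffpos)
  sd <- nd <- 0; valid <- 0
  for (ord in orders) {
    cur <- v1; s <- n <- 0; ok <- TRUE
    for (pos in ord) {
      aa_from <- gc[[paste(cur, collapse = "")]]
      cur[pos] <- v2[pos]
      aa_to <- gc[[paste(cur, collapse = "")]]
      if (aa_to == "*") { ok <- FALSE; break }
      if (aa_to == aa_from) s <- s + 1 else n <- n + 1
    }
    if (ok) { sd <- sd + s; nd <- nd + n; valid <- valid + 1 }
  }
  out <- if (valid == 0) NULL else c(sd / valid, nd / valid)
  assign(key, if (is.null(out)) c(NA_real_, NA_real_) else out,
         envir = .codon_cache)
  out
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Build a codon alignment pair from an aligned protein pair and raw CDSs
#'
#' Expands each aligned amino acid to its source codon and each protein gap to
#' `---`, preserving frame. A terminal stop codon on either CDS is trimmed.
#'
#' @param protein_a,protein_b Gap-aligned protein strings of equal length.
#' @param cds_a,cds_b Ungapped in-frame CDS for each protein.
#' @return list of class `codon_alignment` with elements `a` and `b` (aligned
#'   CDS strings of equal length divisible by 3).
#' @export
back_translate_alignment <- function(protein_a, protein_b, cds_a, cds_b) {
  if (nchar(protein_a) != nchar(protein_b)) {
    stop("ragged protein alignment: lengths ",
         nchar(protein_a), " vs ", nchar(protein_b))
  }
  expand <- function(prot, cds, who) {
    cds <- toupper(cds)
    bare <- gsub("-", "", prot)
    if (nchar(cds) == 3 * (nchar(bare) + 1)) {
      last <- substring(cds, nchar(cds) - 2, nchar(cds))
      if (codon_table()[[last]] == "*") cds <- substring(cds, 1, nchar(cds) - 3)
    }
    if (nchar(cds) != 3 * nchar(bare)) {
      stop("CDS length mismatch for sequence ", who, ": ", nchar(cds),
           " nt vs ", nchar(bare), " aa")
    }
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- translate_codons(codons)
    bare_vec <- strsplit(bare, "")[[1]]
    mism <- which(aa != bare_vec & bare_vec != "X")
    if (length(mism)) {
      stop("translation mismatch for sequence ", who, " at codon ", mism[1],
           ": ", codons[mism[1]], " -> ", aa[mism[1]], " vs ", bare_vec[mism[1]])
    }
    out <- character(nchar(prot)); k <- 0
    pv <- strsplit(prot, "")[[1]]
    for (i in seq_along(pv)) {
      if (pv[i] == "-") out[i] <- "---" else { k <- k + 1; out[i] <- codons[k] }
    }
    paste(out, collapse = "")
  }
  structure(list(a = expand(protein_a, cds_a, "a"),
                 b = expand(protein_b, cds_b, "b")),
            class = "codon_alignment")
}

#' Ka and Ks by the Nei-Gojobori (1986) counting method
#'
#' Synonymous site counts average the per-position fraction of single-base
#' changes preserving the amino acid (denominator 3, changes to stops counted
#' nonsynonymous), averaged between the two sequences. Differing codons are
#' decomposed over all minimal mutational pathways with equal weight,
#' stop-crossing pathways excluded; codon pairs whose every pathway crosses a
#' stop are excluded from both sites and differences. Proportions are
#' Jukes-Cantor corrected, `d = -(3/4) ln(1 - (4/3) p)`; `p >= 3/4` flags the
#' rate as saturated (`NA`).
#'
#' @param a,b Aligned in-frame CDS strings of equal length (gaps `-`), or a
#'   single `codon_alignment` as `a`. Codon columns with a gap, an ambiguity
#'   code, or a stop in either sequence are excluded pairwise.
#' @return list of class `kaks_result`: `N_sites`, `S_sites`, `Nd`, `Sd`,
#'   `pN`, `pS`, `Ka`, `Ks`, `ratio`, `saturated` (named logical), `codons_used`,
#'   `codons_excluded`.
#' @export
nei_gojobori <- function(a, b = NULL) {
  if (inherits(a, "codon_alignment")) { b <- a$b; a <- a$a }
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  if (nchar(a) %% 3 != 0) stop("alignment length not divisible by 3")
  starts <- seq(1, nchar(a), 3)
  ca <- substring(a, starts, starts + 2)
  cb <- substring(b, starts, starts + 2)
  sense <- sense_codons()
  comparable <- ca %in% sense & cb %in% sense
  S1 <- S2 <- Sd <- Nd <- 0; used <- 0; excluded <- sum(!comparable)
  for (i in which(comparable)) {
    counts <- codon_path_counts(ca[i], cb[i])
    if (is.null(counts)) { excluded <- excluded + 1; next }
    S1 <- S1 + syn_sites(ca[i]); S2 <- S2 + syn_sites(cb[i])
    Sd <- Sd + counts[1]; Nd <- Nd + counts[2]
    used <- used + 1
  }
  if (used == 0) stop("zero comparable codon columns")
  S_sites <- (S1 + S2) / 2
  N_sites <- 3 * used - S_sites
  pS <- if (S_sites > 0) Sd / S_sites else NA_real_
  pN <- if (N_sites > 0) Nd / N_sites else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  sat <- c(ka = !is.na(pN) && pN >= 3 / 4, ks = !is.na(pS) && pS >= 3 / 4)
  res <- list(N_sites = N_sites, S_sites = S_sites, Nd = Nd, Sd = Sd,
              pN = pN, pS = pS, Ka = Ka, Ks = Ks,
              ratio = kaks_ratio(Ka, Ks), saturated = sat,
              codons_used = used, codons_excluded = excluded)
  class(res) <- "kaks_result"
  res
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> Ka = %s  Ks = %s  Ka/Ks = %s  (%d codons)\n",
              format(x$Ka), format(x$Ks), format(x$ratio), x$codons_used))
  invisible(x)
}

#' Ka/Ks ratio
#'
#' Vectorized over `ka`/`ks`, or applied to a single [nei_gojobori()] result.
#' `Ks = 0` or an undefined rate yields `NA` (flagged, not an error).
#'
#' @param ka Nonsynonymous rate(s), or a `kaks_result`.
#' @param ks Synonymous rate(s) (ignored when `ka` is a `kaks_result`).
#' @return Numeric ratio(s); `NA` where undefined.
#' @export
kaks_ratio <- function(ka, ks = NULL) {
  if (inherits(ka, "kaks_result")) { ks <- ka$Ks; ka <- ka$Ka }
  ifelse(is.na(ka) | is.na(ks) | ks <= 0, NA_real_, ka / ks)
}

#' Molecular-clock date of a duplication event
#'
#' `T = K / (2 * clock_rate) * 1e-6` million years, the standard paralog-dating
#' formula with `clock_rate` substitutions per site per year (rice default
#' 9.1e-9).
#'
#' @param K Substitution rate(s) per site (usually Ks; see `rate_column` in
#'   [date_duplicates()]).
#' @param clock_rate Substitutions/site/year.
#' @return Time(s) in Mya.
#' @export
divergence_time <- function(K, clock_rate = 9.1e-9) {
  stopifnot(clock_rate > 0)
  if (any(!is.na(K) & K < 0)) stop("negative substitution rate")
  K / (2 * clock_rate) * 1e-6
}

#' Date a table of duplicate pairs
#'
#' @param kaks_table data.frame with `ka` and `ks` columns.
#' @param rate_column `"ks"` (the stated clock substrate) or `"ka"`.
#' @param clock_rate Substitutions/site/year.
#' @return The table with added `date_mya`, plus attributes `rate_column` and
#'   `clock_rate`.
#' @export
date_duplicates <- function(kaks_table, rate_column = c("ks", "ka"),
                            clock_rate = 9.1e-9) {
  rate_column <- match.arg(rate_column)
  stopifnot(rate_column %in% names(kaks_table))
  kaks_table$date_mya <- divergence_time(kaks_table[[rate_column]], clock_rate)
  attr(kaks_table, "rate_column") <- rate_column
  attr(kaks_table, "clock_rate") <- clock_rate
  kaks_table
}

#' Selection regime from a Ka/Ks ratio
#'
#' @param ratio Numeric ratio(s).
#' @param tol Equality tolerance around 1 (default 1e-9).
#' @return `"positive"`, `"negative"` or `"neutral"` per element (`NA` in,
#'   `NA` out).
#' @export
selection_class <- function(ratio, tol = 1e-9) {
  ifelse(is.na(ratio), NA_character_,
         ifelse(abs(ratio - 1) <= tol, "neutral",
                ifelse(ratio > 1, "positive", "negative")))
}
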