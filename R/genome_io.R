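# Allowed subfamily vocabulary for monosaccharide-transporter-style families.
MST_SUBFAMILIES <- c("STP", "PLT", "AZT", "ERD", "pGlcT", "INT", "XTPH")

.ALPHABETS <- list(
  protein = c(LETTERS[!LETTERS %in% c("B", "J", "O", "U", "Z")], "X", "*", "-"),
  dna     = c("A", "C", "G", "T", "N", "-")
)

#' Read a FASTA file into a validated sequence set
#'
#' Parses FASTA with Biostrings, uppercases sequences, strips whitespace, and
#' validates every character against the declared alphabet. Protein sequences
#' may contain the 20 standard residues plus `X`, `*` and `-`; DNA sequences
#' `ACGTN-`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return A named character vector of sequences (class `seq_set`), one element
#'   per record in file order, with an `alphabet` attribute.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT"), tf)
#' read_fasta(tf, "dna")
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  names(seqs) <- sub("\\s.*$", "", names(set))
  ok <- .ALPHABETS[[alphabet]]
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!chars %in% ok)
    if (length(bad)) {
      stop(sprintf("illegal %s character '%s' in record '%s' at position %d",
                   alphabet, chars[bad[1]], names(seqs)[i], bad[1]))
    }
    if (!nzchar(seqs[[i]])) stop("empty sequence in record '", names(seqs)[i], "'")
  }
  structure(seqs, alphabet = alphabet, class = "seq_set")
}

#' Write a sequence set to FASTA
#'
#' @param seqs Named character vector of sequences (e.g. from [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse the chromosome number out of a TIGR-style locus tag
#'
#' Locus tags of the form `LOC_Os<NN>g<digits>[.<isoform>]` encode the
#' chromosome in the two digits after `Os`; the isoform suffix is ignored.
#'
#' @param locus_tag Character vector of locus tags.
#' @return Integer vector of chromosome numbers.
#' @examples
#' locus_to_chromosome("LOC_Os02g13560.1") # 2
#' @export
locus_to_chromosome <- function(locus_tag) {
  m <- regmatches(locus_tag,
                  regexec("^LOC_Os([0-9]{2})g([0-9]+)(\\.[0-9]+)?$", locus_tag))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) stop("unparseable locus tag: ", locus_tag[which(bad)[1]])
  as.integer(vapply(m, `[`, "", 2L))
}

# Numeric gene index along the chromosome (the digits after 'g'); used as a
# surrogate start coordinate for registries that carry no coordinates.
locus_gene_number <- function(locus_tag) {
  m <- regmatches(locus_tag,
                  regexec("^LOC_Os([0-9]{2})g([0-9]+)(\\.[0-9]+)?$", locus_tag))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) stop("unparseable locus tag: ", locus_tag[which(bad)[1]])
  as.integer(vapply(m, `[`, "", 3L))
}

#' Construct a gene registry
#'
#' A gene registry is an ordered `data.frame` (class `gene_registry`) with one
#' row per gene: `gene_id`, `locus_tag`, `chromosome`, `start`, `end`,
#' `strand` (`+`, `-` or `*` for unknown), `rank` (0-based order among genes of
#' the same chromosome, `NA` until assigned), and `subfamily`.
#'
#' @param gene_id,locus_tag Character vectors; `gene_id` must be unique.
#' @param chromosome Integer; inferred from `locus_tag` where `NA`.
#' @param start,end 1-based inclusive coordinates (optional).
#' @param strand `+`, `-` or `*`.
#' @param subfamily Optional label from the family vocabulary
#'   (STP, PLT, AZT, ERD, pGlcT, INT, XTPH), or `NA`.
#' @return A `gene_registry` data.frame.
#' @export
gene_registry <- function(gene_id, locus_tag = gene_id,
                          chromosome = NA_integer_,
                          start = NA_real_, end = NA_real_, strand = "*",
                          subfamily = NA_character_) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1])
  }
  reg <- data.frame(
    gene_id = as.character(gene_id),
    locus_tag = as.character(rep_len(locus_tag, n)),
    chromosome = as.integer(rep_len(chromosome, n)),
    start = as.numeric(rep_len(start, n)),
    end = as.numeric(rep_len(end, n)),
    strand = as.character(rep_len(strand, n)),
    rank = NA_integer_,
    subfamily = as.character(rep_len(subfamily, n)),
    stringsAsFactors = FALSE
  )
  infer <- is.na(reg$chromosome) & grepl("^LOC_Os", reg$locus_tag)
  if (any(infer)) reg$chromosome[infer] <- locus_to_chromosome(reg$locus_tag[infer])
  known <- !is.na(reg$chromosome) & grepl("^LOC_Os", reg$locus_tag)
  if (any(known)) {
    parsed <- locus_to_chromosome(reg$locus_tag[known])
    if (any(parsed != reg$chromosome[known])) {
      i <- which(parsed != reg$chromosome[known])[1]
      stop("chromosome field disagrees with locus tag for gene ",
           reg$gene_id[known][i])
    }
  }
  bad <- !is.na(reg$start) & !is.na(reg$end) & reg$start > reg$end
  if (any(bad)) stop("start > end for gene ", reg$gene_id[bad][1])
  ok_sub <- is.na(reg$subfamily) | reg$subfamily %in% MST_SUBFAMILIES
  if (!all(ok_sub)) {
    stop("unknown subfamily label '", reg$subfamily[!ok_sub][1],
         "'; allowed: ", paste(MST_SUBFAMILIES, collapse = ", "))
  }
  class(reg) <- c("gene_registry", "data.frame")
  reg
}

#' Read a gene-registry TSV
#'
#' Expects a tab-separated file with at least `gene_id`, `locus_tag` and
#' `subfamily` columns; `chromosome`, `start`, `end`, `strand` are optional.
#' Chromosomes are inferred from locus tags when absent; ranks are assigned
#' when coordinates are present.
#'
#' @param path Path to the TSV.
#' @return A `gene_registry`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "locus_tag", "subfamily")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing columns: ", paste(miss, collapse = ", "))
  get <- function(col, default) if (col %in% names(df)) df[[col]] else default
  reg <- gene_registry(
    gene_id = df$gene_id, locus_tag = df$locus_tag,
    chromosome = get("chromosome", NA_integer_),
    start = get("start", NA_real_), end = get("end", NA_real_),
    strand = get("strand", "*"), subfamily = df$subfamily
  )
  if (all(!is.na(reg$start))) reg <- assign_ranks(reg)
  reg
}

#' Write a gene registry to TSV
#'
#' Round-trips with [read_gene_table()] field-for-field.
#'
#' @param registry A `gene_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(registry, path) {
  utils::write.table(as.data.frame(registry), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign per-chromosome gene ranks
#'
#' Sorts genes within each chromosome by start coordinate (ties broken by end,
#' then `gene_id`) and assigns 0-based ranks. Registries without coordinates
#' (e.g. built from a printed family table) can rank by the locus-tag gene
#' number instead with `use_locus_order = TRUE`; a warning then notes that rank
#' gaps are measured in family-gene units, not genome-annotation units.
#'
#' @param registry A `gene_registry`.
#' @param use_locus_order Rank by the numeric locus-tag index when coordinates
#'   are missing.
#' @return The registry with the `rank` column filled.
#' @export
assign_ranks <- function(registry, use_locus_order = FALSE) {
  stopifnot(inherits(registry, "gene_registry"))
  pos <- registry$start
  if (use_locus_order && anyNA(pos)) {
    pos <- locus_gene_number(registry$locus_tag)
    warning("ranking by locus-tag order: rank gaps are in family-gene units, ",
            "not full-annotation gene units")
  }
  if (anyNA(pos)) {
    stop("missing coordinates for gene ",
         registry$gene_id[is.na(pos)][1],
         " (supply start/end or use_locus_order = TRUE)")
  }
  if (anyNA(registry$chromosome)) {
    stop("missing chromosome for gene ",
         registry$gene_id[is.na(registry$chromosome)][1])
  }
  ends <- ifelse(is.na(registry$end), pos, registry$end)
  registry$rank <- NA_integer_
  for (chr in unique(registry$chromosome)) {
    i <- which(registry$chromosome == chr)
    o <- order(pos[i], ends[i], registry$gene_id[i])
    registry$rank[i[o]] <- seq_along(i) - 1L
  }
  registry
}

#' @export
print.gene_registry <- function(x, ...) {
  cat("<gene_registry> ", nrow(x), " genes on ",
      length(unique(x$chromosome)), " chromosomes\n", sep = "")
  NextMethod()
}

# Lookup helper: rows by gene_id, error when absent.
registry_rows <- function(registry, gene_ids) {
  i <- match(gene_ids, registry$gene_id)
  if (anyNA(i)) stop("gene absent from registry: ", gene_ids[is.na(i)][1])
  registry[i, , drop = FALSE]
}
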