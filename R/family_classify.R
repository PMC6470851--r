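#' Pairwise protein distance from a global alignment
#'
#' Globally aligns two protein sequences (BLOSUM62, affine gaps: open 10,
#' extend 0.5) and returns the proportion of mismatches among aligned non-gap
#' columns (`correction = "p"`), or its Poisson correction `-ln(1 - p)`.
#'
#' @param a,b Protein sequences (character scalars).
#' @param correction `"p"` or `"poisson"`.
#' @return Distance (numeric scalar). A `saturated` attribute is set when
#'   p >= 1, where the Poisson correction is undefined (`Inf`).
#' @export
pairwise_protein_distance <- function(a, b, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- pa != "-" & pb != "-"
  if (!any(keep)) stop("no overlap: zero aligned non-gap columns")
  p <- sum(pa[keep] != pb[keep]) / sum(keep)
  sat <- p >= 1
  d <- if (correction == "p") p else if (sat) Inf else -log(1 - p)
  structure(d, saturated = sat)
}

#' Distance matrix over a set of protein sequences
#'
#' @param seqs Named character vector of protein sequences.
#' @param correction Passed to [pairwise_protein_distance()].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = sequence ids.
#' @export
protein_distance_matrix <- function(seqs, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- as.numeric(
        pairwise_protein_distance(seqs[[i]], seqs[[j]], correction))
    }
  }
  d
}

# p / Poisson distances between rows of an aligned matrix of characters,
# skipping columns gapped in either row. Used by the bootstrap path.
.aln_dist <- function(rows, correction = "p") {
  n <- nrow(rows)
  d <- matrix(0, n, n, dimnames = list(rownames(rows), rownames(rows)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- rows[i, ] != "-" & rows[j, ] != "-"
      if (!any(keep)) stop("no overlap between ", rownames(rows)[i],
                           " and ", rownames(rows)[j])
      p <- sum(rows[i, keep] != rows[j, keep]) / sum(keep)
      d[i, j] <- d[j, i] <- if (correction == "p") p else -log(max(1 - p, 1e-12))
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step joins the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch lengths
#' from the usual rate-corrected split formulas. Q ties are broken by the
#' lexicographically smallest pair of representative taxon ids, so the result
#' is deterministic for a given matrix. Negative branch-length estimates are
#' clamped to zero with the deficit moved to the sibling edge.
#'
#' @param dm Symmetric numeric matrix with taxon dimnames (>= 2 taxa).
#' @return An unrooted `phylo` tree (package \pkg{ape}).
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), nrow(dm) >= 2,
            !is.null(rownames(dm)))
  if (anyNA(dm) || any(!is.finite(dm))) stop("distance matrix has NA/non-finite entries")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  taxa <- rownames(dm)
  if (length(taxa) == 2) {
    nwk <- sprintf("(%s:%.10g,%s:%.10g);", taxa[1], dm[1, 2] / 2,
                   taxa[2], dm[1, 2] / 2)
    return(ape::read.tree(text = nwk))
  }
  # Active nodes: Newick fragments plus a representative (smallest leaf label).
  frag <- taxa
  rep_ <- taxa
  d <- dm
  clamp2 <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    c(li, lj)
  }
  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    keypair <- apply(best, 1, function(ij) {
      paste(sort(c(rep_[ij[1]], rep_[ij[2]])), collapse = "\r")
    })
    pick <- best[order(keypair)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    ll <- clamp2(li, lj)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], ll[1], frag[j], ll[2])
    newrep <- min(rep_[i], rep_[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_ <- c(rep_[keep], newrep)
  }
  # Final three nodes joined at the central (unrooted) vertex.
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  c3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ln <- pmax(c(a, b, c3), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], ln[1], frag[2], ln[2], frag[3], ln[3])
  ape::read.tree(text = nwk)
}

# Nontrivial bipartitions of a phylo as canonical keys: each internal edge's
# leaf set, complemented if needed so the key never contains the first taxon
# (alphabetically) -- orientation-free split identity.
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  anchor <- min(tips)
  ntip <- length(tips)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tips[i]
  # edges in postorder so children are resolved before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    desc[[eo[k, 1]]] <- c(desc[[eo[k, 1]]], desc[[eo[k, 2]]])
  }
  keys <- character(0)
  root <- ntip + 1L
  for (node in setdiff(unique(tree$edge[, 2]), seq_len(ntip))) {
    if (node == root) next
    set <- desc[[node]]
    if (length(set) <= 1 || length(set) >= ntip - 1) next  # trivial split
    if (anchor %in% set) set <- setdiff(tips, set)
    keys <- c(keys, paste(sort(set), collapse = "|"))
  }
  keys
}

#' Bootstrap supports for a neighbor-joining protein tree
#'
#' Builds the NJ tree from the full alignment, then resamples alignment columns
#' with replacement `n_reps` times, rebuilds NJ per replicate, and scores each
#' internal edge of the full-data tree by the percentage of replicates whose
#' tree contains the same bipartition.
#'
#' @param msa Named character vector of aligned sequences, all the same length
#'   (gaps as `-`).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; fixes the column resampling stream.
#' @param correction Distance used on alignment columns: `"p"` or `"poisson"`.
#' @return A `phylo` with `node.label` carrying supports in \[0, 100\] on
#'   internal nodes (`NA` on the outermost/root node).
#' @export
bootstrap_support <- function(msa, n_reps, seed = 1L, correction = "p") {
  stopifnot(length(msa) >= 3, !is.null(names(msa)))
  if (n_reps < 1) stop("n_reps must be >= 1")
  lens <- nchar(msa)
  if (length(unique(lens)) != 1) stop("ragged alignment: unequal row lengths")
  rows <- do.call(rbind, strsplit(toupper(as.character(msa)), ""))
  rownames(rows) <- names(msa)
  ncol_aln <- ncol(rows)
  tree <- neighbor_joining(.aln_dist(rows, correction))
  keys <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(keys)), keys)
  set.seed(as.integer(seed))
  for (b in seq_len(n_reps)) {
    idx <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    bt <- neighbor_joining(.aln_dist(rows[, idx, drop = FALSE], correction))
    hit <- intersect(keys, tree_bipartitions(bt))
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps
  # map supports onto node labels of the main tree
  ntip <- length(tree$tip.label)
  labels <- rep(NA_character_, tree$Nnode)
  tips <- tree$tip.label
  anchor <- min(tips)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tips[i]
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) desc[[eo[k, 1]]] <- c(desc[[eo[k, 1]]], desc[[eo[k, 2]]])
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    set <- desc[[node]]
    if (length(set) <= 1 || length(set) >= ntip - 1) next
    if (anchor %in% set) set <- setdiff(tips, set)
    key <- paste(sort(set), collapse = "|")
    if (key %in% names(support)) {
      labels[node - ntip] <- format(support[[key]], trim = TRUE)
    }
  }
  tree$node.label <- labels
  attr(tree, "supports") <- support
  tree
}

#' Assign subfamily labels to unlabelled leaves by clade membership
#'
#' Each unlabelled leaf receives the label of the smallest clade containing it
#' whose labelled leaves are unanimous (method `"clade"`). When every enclosing
#' clade short of the root mixes labels, the leaf falls back to the label of
#' the nearest labelled leaf by patristic path length (method
#' `"nearest-leaf"`).
#'
#' @param tree A `phylo`.
#' @param labels Named character vector: reference gene id -> subfamily label.
#' @return A data.frame with columns `gene_id`, `subfamily`, `method`.
#' @export
assign_subfamily <- function(tree, labels) {
  tips <- tree$tip.label
  labels <- labels[names(labels) %in% tips]
  if (length(labels) == 0) stop("no labelled leaves present in the tree")
  ntip <- length(tips)
  root <- ntip + 1L
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tips[i]
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) desc[[eo[k, 1]]] <- c(desc[[eo[k, 1]]], desc[[eo[k, 2]]])
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  patristic <- NULL
  out <- data.frame(gene_id = character(0), subfamily = character(0),
                    method = character(0), stringsAsFactors = FALSE)
  for (tip in setdiff(tips, names(labels))) {
    node <- parent[match(tip, tips)]
    assigned <- NA_character_; method <- NA_character_
    while (node != 0L && node != root) {
      inlab <- labels[intersect(names(labels), desc[[node]])]
      if (length(inlab) > 0) {
        if (length(unique(inlab)) == 1) {
          assigned <- unique(inlab); method <- "clade"
        }
        break  # smallest clade with labels decides or forces fallback
      }
      node <- parent[node]
    }
    if (is.na(assigned)) {
      if (is.null(patristic)) patristic <- stats::cophenetic(tree)
      dd <- patristic[tip, names(labels)]
      assigned <- labels[[names(which.min(dd))]]
      method <- "nearest-leaf"
    }
    out <- rbind(out, data.frame(gene_id = tip, subfamily = assigned,
                                 method = method, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
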