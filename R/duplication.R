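#' Canonicalize homolog pairs
#'
#' Stores each unordered pair with `gene_a < gene_b` lexicographically and
#' drops self-pairs and duplicates (highest score kept).
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` and optionally
#'   `score`.
#' @return data.frame `gene_a`, `gene_b`, `score`.
#' @export
canonical_pairs <- function(pairs) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  a <- pmin(pairs$gene_a, pairs$gene_b)
  b <- pmax(pairs$gene_a, pairs$gene_b)
  score <- if ("score" %in% names(pairs)) pairs$score else rep(1, nrow(pairs))
  keep <- a != b
  out <- data.frame(gene_a = a[keep], gene_b = b[keep], score = score[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, -out$score), ]
  out <- out[!duplicated(out[c("gene_a", "gene_b")]), ]
  rownames(out) <- NULL
  out
}

#' Detect tandem and proximal duplicate pairs from gene ranks
#'
#' A pair is *tandem* when both genes lie on the same chromosome with at most
#' `max_gap` genes between them (rank gap minus one); *proximal* when not
#' tandem but within `proximal_window` intervening genes; otherwise
#' *dispersed*.
#'
#' @param registry A ranked `gene_registry` (see [assign_ranks()]).
#' @param pairs Homolog pairs (data.frame `gene_a`, `gene_b`).
#' @param max_gap Maximum intervening genes for a tandem call (default 1).
#' @param proximal_window Maximum intervening genes for a proximal call
#'   (default 20, the MCScanX convention).
#' @return data.frame `gene_a`, `gene_b`, `dup_type`, `evidence` (intervening
#'   gene count, `NA` for cross-chromosome pairs).
#' @export
detect_tandem <- function(registry, pairs, max_gap = 1L, proximal_window = 20L) {
  stopifnot(max_gap >= 0)
  pairs <- canonical_pairs(pairs)
  ra <- registry_rows(registry, pairs$gene_a)
  rb <- registry_rows(registry, pairs$gene_b)
  if (anyNA(ra$rank) || anyNA(rb$rank)) stop("registry has unranked genes; run assign_ranks()")
  same <- ra$chromosome == rb$chromosome
  intervening <- ifelse(same, abs(ra$rank - rb$rank) - 1L, NA_integer_)
  type <- ifelse(same & intervening <= max_gap, "tandem",
          ifelse(same & intervening <= proximal_window, "proximal", "dispersed"))
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             dup_type = type, evidence = intervening, stringsAsFactors = FALSE)
}

#' Chain homolog anchors into collinear (segmental) blocks
#'
#' Dynamic-programming chaining of anchors per chromosome pair: anchor j may
#' extend a chain ending at anchor i iff `0 < rank_a(j) - rank_a(i) <=
#' max_anchor_gap` and the rank-b step is within `max_anchor_gap` in a
#' direction consistent with the chain (same or inverted orientation). Chains
#' with at least `min_block_size` anchors are emitted greedily by chain score,
#' each anchor consumed at most once.
#'
#' @param registry A ranked `gene_registry`.
#' @param anchors Homolog pairs (data.frame `gene_a`, `gene_b`, optional
#'   `score`).
#' @param min_block_size Minimum anchors per block (default 5).
#' @param max_anchor_gap Maximum rank gap between consecutive anchors
#'   (default 25).
#' @return list with `blocks` (data.frame: `block_id`, `chr_a`, `chr_b`,
#'   `orientation`, `n_anchors`, `score`) and `anchors` (data.frame of member
#'   anchors with `block_id`).
#' @export
chain_collinear_blocks <- function(registry, anchors, min_block_size = 5L,
                                   max_anchor_gap = 25L) {
  stopifnot(min_block_size >= 2)
  anchors <- canonical_pairs(anchors)
  ga <- registry_rows(registry, anchors$gene_a)
  gb <- registry_rows(registry, anchors$gene_b)
  if (anyNA(ga$rank) || anyNA(gb$rank)) stop("registry has unranked genes; run assign_ranks()")
  # orient each anchor so (chr_a, rank_a) is the lower side
  flip <- (gb$chromosome < ga$chromosome) |
    (gb$chromosome == ga$chromosome & gb$rank < ga$rank)
  df <- data.frame(
    gene_a = ifelse(flip, anchors$gene_b, anchors$gene_a),
    gene_b = ifelse(flip, anchors$gene_a, anchors$gene_b),
    chr_a = ifelse(flip, gb$chromosome, ga$chromosome),
    chr_b = ifelse(flip, ga$chromosome, gb$chromosome),
    rank_a = ifelse(flip, gb$rank, ga$rank),
    rank_b = ifelse(flip, ga$rank, gb$rank),
    score = anchors$score, stringsAsFactors = FALSE)
  blocks <- data.frame(block_id = integer(0), chr_a = integer(0),
                       chr_b = integer(0), orientation = character(0),
                       n_anchors = integer(0), score = numeric(0))
  members <- df[0, ]
  members$block_id <- integer(0)
  next_id <- 1L
  for (grp in split(seq_len(nrow(df)), paste(df$chr_a, df$chr_b))) {
    sub <- df[grp, , drop = FALSE]
    sub <- sub[order(sub$rank_a, sub$rank_b), , drop = FALSE]
    used <- rep(FALSE, nrow(sub))
    repeat {
      best <- .best_chain(sub, used, max_anchor_gap)
      if (is.null(best) || length(best$idx) < min_block_size) break
      chain <- sub[best$idx, , drop = FALSE]
      chain$block_id <- next_id
      members <- rbind(members, chain)
      blocks <- rbind(blocks, data.frame(
        block_id = next_id, chr_a = chain$chr_a[1], chr_b = chain$chr_b[1],
        orientation = best$orientation, n_anchors = nrow(chain),
        score = sum(chain$score)))
      next_id <- next_id + 1L
      used[best$idx] <- TRUE
    }
  }
  rownames(members) <- NULL
  list(blocks = blocks, anchors = members)
}

# Best remaining chain (by summed score, ties to more anchors) among unused
# anchors of one chromosome-pair group, for each orientation.
.best_chain <- function(sub, used, max_gap) {
  idx <- which(!used)
  if (length(idx) < 2) {
    if (length(idx) == 1) return(list(idx = idx, orientation = "same"))
    return(NULL)
  }
  best <- NULL
  for (dir in c(1, -1)) {
    m <- length(idx)
    score <- sub$score[idx]
    prev <- rep(NA_integer_, m)
    tot <- score
    for (jj in seq_len(m)) {
      for (ii in seq_len(jj - 1)) {
        da <- sub$rank_a[idx[jj]] - sub$rank_a[idx[ii]]
        db <- dir * (sub$rank_b[idx[jj]] - sub$rank_b[idx[ii]])
        if (da > 0 && da <= max_gap && db > 0 && db <= max_gap) {
          cand <- tot[ii] + score[jj]
          if (cand > tot[jj]) { tot[jj] <- cand; prev[jj] <- ii }
        }
      }
    }
    end <- which.max(tot)
    chain <- end
    while (!is.na(prev[chain[1]])) chain <- c(prev[chain[1]], chain)
    cand <- list(idx = idx[chain], score = tot[end],
                 orientation = if (dir == 1) "same" else "inverted")
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && length(cand$idx) > length(best$idx))) {
      best <- cand
    }
  }
  best
}

#' Classify duplicate pairs with segmental > tandem > proximal > dispersed priority
#'
#' A pair appearing as an anchor of any collinear block is *segmental*
#' regardless of rank adjacency; otherwise the tandem/proximal/dispersed call
#' from [detect_tandem()] stands. Every input pair receives exactly one type.
#'
#' @param pairs Homolog pairs to classify.
#' @param blocks Result of [chain_collinear_blocks()] (or `NULL` for none).
#' @param tandem Result of [detect_tandem()] over the same pairs.
#' @return data.frame `gene_a`, `gene_b`, `dup_type`, `evidence` (block id or
#'   intervening count).
#' @export
classify_duplicates <- function(pairs, blocks, tandem) {
  pairs <- canonical_pairs(pairs)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  out <- merge(pairs[c("gene_a", "gene_b")],
               tandem[c("gene_a", "gene_b", "dup_type", "evidence")],
               by = c("gene_a", "gene_b"), all.x = TRUE)
  out$evidence <- as.character(out$evidence)
  if (anyNA(out$dup_type)) stop("pair missing from tandem calls: ",
                                out$gene_a[is.na(out$dup_type)][1])
  if (!is.null(blocks) && nrow(blocks$anchors) > 0) {
    bkey <- key(blocks$anchors$gene_a, blocks$anchors$gene_b)
    hit <- match(key(out$gene_a, out$gene_b), bkey)
    seg <- !is.na(hit)
    out$dup_type[seg] <- "segmental"
    out$evidence[seg] <- paste0("block:", blocks$anchors$block_id[hit[seg]])
  }
  out[order(out$gene_a, out$gene_b), ]
}
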