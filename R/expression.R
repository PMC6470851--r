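#' Construct a Ct table
#'
#' Container for replicated qRT-PCR threshold cycles: one observation per
#' (sample, gene, biological replicate, technical replicate), with a designated
#' reference (housekeeping) gene and calibrator sample. The reference gene must
#' be measured in every sample and the calibrator sample must be present.
#'
#' @param observations data.frame with columns `sample_id`, `gene_id`,
#'   `bio_rep`, `tech_rep`, `ct` (cycles, finite).
#' @param reference_gene Gene id of the internal control (e.g. Actin).
#' @param calibrator_sample Sample id of the baseline condition (fold = 1).
#' @return list of class `ct_table`.
#' @export
ct_table <- function(observations, reference_gene, calibrator_sample) {
  need <- c("sample_id", "gene_id", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(observations))
  if (length(miss)) stop("Ct observations missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(observations$ct))) stop("non-finite Ct value")
  samples <- unique(observations$sample_id)
  if (!calibrator_sample %in% samples) {
    stop("calibrator sample '", calibrator_sample, "' not present")
  }
  has_ref <- vapply(samples, function(s) {
    any(observations$sample_id == s & observations$gene_id == reference_gene)
  }, TRUE)
  if (!all(has_ref)) {
    stop("reference gene '", reference_gene, "' missing in sample '",
         samples[!has_ref][1], "'")
  }
  structure(list(data = observations, reference_gene = reference_gene,
                 calibrator_sample = calibrator_sample),
            class = "ct_table")
}

#' Two-stage replicate averaging of a Ct table
#'
#' Technical replicates are averaged within each biological replicate first,
#' then biological-replicate means are averaged; pooling all technical wells
#' directly would overweight samples with more technical replicates. The
#' standard deviation across biological-replicate means is retained as
#' `sd_ct`.
#'
#' @param table A `ct_table`.
#' @return A `ct_table` whose data has one row per (sample, gene) with columns
#'   `ct`, `sd_ct`, `n_bio`.
#' @export
aggregate_replicates <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  df <- table$data
  bio <- stats::aggregate(ct ~ sample_id + gene_id + bio_rep, df, mean)
  agg <- stats::aggregate(ct ~ sample_id + gene_id, bio, mean)
  sds <- stats::aggregate(ct ~ sample_id + gene_id, bio,
                          function(x) if (length(x) > 1) stats::sd(x) else NA_real_)
  ns <- stats::aggregate(ct ~ sample_id + gene_id, bio, length)
  agg$sd_ct <- sds$ct[match(paste(agg$sample_id, agg$gene_id),
                            paste(sds$sample_id, sds$gene_id))]
  agg$n_bio <- ns$ct[match(paste(agg$sample_id, agg$gene_id),
                           paste(ns$sample_id, ns$gene_id))]
  agg$bio_rep <- NA_integer_; agg$tech_rep <- NA_integer_
  ct_table(agg, table$reference_gene, table$calibrator_sample)
}

#' Relative expression by the 2^-ddCt (Livak) method
#'
#' `dCt(g, s) = Ct(g, s) - Ct(ref, s)` normalizes each target to the reference
#' gene within a sample; `ddCt(g, s) = dCt(g, s) - dCt(g, calibrator)`
#' normalizes to the calibrator sample; the fold change is `2^-ddCt`. The
#' calibrator column is identically 1.
#'
#' @param table A `ct_table` (aggregated automatically if it still carries
#'   replicates).
#' @return Numeric genes x samples matrix of fold changes, with attribute
#'   `calibrator`.
#' @export
delta_delta_ct <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  if (anyDuplicated(paste(table$data$sample_id, table$data$gene_id))) {
    table <- aggregate_replicates(table)
  }
  df <- table$data
  samples <- unique(df$sample_id)
  genes <- setdiff(unique(df$gene_id), table$reference_gene)
  ctm <- matrix(NA_real_, length(genes) + 1, length(samples),
                dimnames = list(c(genes, table$reference_gene), samples))
  ctm[cbind(df$gene_id, df$sample_id)] <- df$ct
  ref <- ctm[table$reference_gene, ]
  if (anyNA(ref)) stop("reference gene missing in sample ",
                       samples[is.na(ref)][1])
  dct <- sweep(ctm[genes, , drop = FALSE], 2, ref, `-`)
  cal <- dct[, table$calibrator_sample]
  if (anyNA(cal)) {
    stop("gene absent in calibrator sample: ", genes[is.na(cal)][1])
  }
  if (anyNA(dct)) {
    i <- which(is.na(dct), arr.ind = TRUE)[1, ]
    stop("gene '", genes[i[1]], "' not measured in sample '", samples[i[2]], "'")
  }
  ddct <- sweep(dct, 1, cal, `-`)
  folds <- 2^(-ddct)
  attr(folds, "calibrator") <- table$calibrator_sample
  folds
}

#' Up/down regulation calls at a fold-change threshold
#'
#' A gene is called `up` in a condition when fold > `threshold`, `down` when
#' fold < `1/threshold` (the threshold is symmetric on the log scale), and
#' `ns` otherwise. The conventional cutoff for this kind of qRT-PCR screen is
#' 1.5.
#'
#' @param folds Genes x conditions fold-change matrix from [delta_delta_ct()].
#' @param threshold Fold threshold, > 1.
#' @return data.frame `gene`, `condition`, `fold`, `call`.
#' @export
call_regulation <- function(folds, threshold = 1.5) {
  if (threshold <= 1) stop("threshold must be > 1")
  out <- data.frame(
    gene = rep(rownames(folds), times = ncol(folds)),
    condition = rep(colnames(folds), each = nrow(folds)),
    fold = as.vector(folds), stringsAsFactors = FALSE)
  out$call <- ifelse(out$fold > threshold, "up",
                     ifelse(out$fold < 1 / threshold, "down", "ns"))
  out
}

#' Pearson correlation between two expression profiles
#'
#' @param profile_a,profile_b Equal-length numeric vectors (length >= 3),
#'   typically the concatenated condition-wise fold changes of a duplicate
#'   pair.
#' @return Pearson r, or `NA` (with a warning) when either profile has zero
#'   variance.
#' @export
pair_expression_correlation <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b)) stop("profiles differ in length")
  if (length(profile_a) < 3) stop("profiles shorter than 3 conditions")
  if (stats::var(profile_a) == 0 || stats::var(profile_b) == 0) {
    warning("zero-variance profile: correlation undefined")
    return(NA_real_)
  }
  stats::cor(profile_a, profile_b, method = "pearson")
}

#' Expression-divergence class of a duplicate pair
#'
#' `r < 0.3` is divergent, `0.3 <= r < 0.5` ongoing divergence, `r >= 0.5`
#' non-divergent. Boundary values go to the higher class (the defining open
#' intervals leave them unassigned).
#'
#' @param r Pearson correlation(s).
#' @return `"divergent"`, `"ongoing"` or `"non-divergent"` per element.
#' @export
classify_divergence <- function(r) {
  ifelse(is.na(r), NA_character_,
         ifelse(r < 0.3, "divergent",
                ifelse(r < 0.5, "ongoing", "non-divergent")))
}

#' Per-gene z-scores of log2 fold changes (heatmap export)
#'
#' Each row is log2-transformed, centred, and scaled by its population
#' standard deviation (denominator n). Constant rows become all zeros and are
#' listed in the `constant_rows` attribute.
#'
#' @param folds Genes x conditions fold-change matrix (entries > 0).
#' @return Matrix of z-scores with attribute `constant_rows`.
#' @export
row_scale <- function(folds) {
  stopifnot(ncol(folds) >= 2, all(folds > 0))
  lg <- log2(folds)
  mu <- rowMeans(lg)
  sdv <- sqrt(rowMeans(sweep(lg, 1, mu, `-`)^2))
  const <- sdv == 0
  sdv[const] <- 1
  z <- sweep(sweep(lg, 1, mu, `-`), 1, sdv, `/`)
  attr(z, "constant_rows") <- rownames(folds)[const]
  z
}
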