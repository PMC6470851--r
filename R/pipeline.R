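#' Run the gene-family evolution / expression pipeline end to end
#'
#' Orchestrates registry bookkeeping, duplicate classification, Ka/Ks dating,
#' and (optionally) expression analysis, and returns a report bundle shaped
#' like the classic gene-family survey table: one row per duplicate pair with
#' Ka, Ks, Ka/Ks, date, and duplication type, plus subfamily counts and the
#' chromosome distribution.
#'
#' Stages are skippable: with no `kaks_table` the duplication/dating sections
#' are marked skipped; likewise for expression without a `ct` input.
#'
#' @param gene_table Path to a gene-registry TSV (see [read_gene_table()]).
#' @param kaks_table Optional path to a duplicate-pair TSV with columns
#'   `seq1`, `seq2`, `ka`, `ks` (extra columns kept). When it carries a
#'   `dup_type` column with `"segmental"` entries and no `anchors` input is
#'   given, those rows are treated as externally supplied collinearity
#'   evidence (e.g. from an MCScanX-style run upstream).
#' @param anchors Optional data.frame of homolog anchors (`gene_a`, `gene_b`,
#'   `score`) chained into collinear blocks for segmental evidence.
#' @param ct Optional `ct_table` for the expression stage.
#' @param clock_rate Molecular-clock rate, substitutions/site/year.
#' @param rate_column `"ks"` or `"ka"`: which rate feeds the dating formula.
#' @param max_gap Tandem threshold: maximum intervening genes (default 1).
#' @param min_block_size Minimum anchors per collinear block.
#' @param fold_threshold Fold-change cutoff for regulation calls.
#' @param out_dir Optional directory for TSV + markdown outputs.
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(gene_table, kaks_table = NULL, anchors = NULL,
                         ct = NULL, clock_rate = 9.1e-9,
                         rate_column = c("ks", "ka"), max_gap = 1L,
                         min_block_size = 5L, fold_threshold = 1.5,
                         out_dir = NULL) {
  rate_column <- match.arg(rate_column)
  params <- list(clock_rate = clock_rate, rate_column = rate_column,
                 max_gap = max_gap, min_block_size = min_block_size,
                 fold_threshold = fold_threshold)
  registry <- read_gene_table(gene_table)
  if (anyNA(registry$rank)) {
    registry <- suppressWarnings(assign_ranks(registry, use_locus_order = TRUE))
  }
  report <- list(params = params)
  report$genes <- list(
    n = nrow(registry),
    subfamily_counts = table(registry$subfamily),
    chromosome_counts = table(registry$chromosome))
  report$registry <- registry

  if (!is.null(kaks_table)) {
    kk <- utils::read.delim(kaks_table, stringsAsFactors = FALSE)
    need <- c("seq1", "seq2", "ka", "ks")
    miss <- setdiff(need, names(kk))
    if (length(miss)) stop("kaks stage failed: table missing columns ",
                           paste(miss, collapse = ", "))
    pairs <- data.frame(gene_a = kk$seq1, gene_b = kk$seq2,
                        stringsAsFactors = FALSE)
    tand <- detect_tandem(registry, pairs, max_gap = max_gap)
    blocks <- NULL
    if (!is.null(anchors)) {
      blocks <- chain_collinear_blocks(registry, anchors,
                                       min_block_size = min_block_size)
    } else if ("dup_type" %in% names(kk)) {
      seg <- kk$dup_type == "segmental"
      if (any(seg)) {
        blocks <- list(
          blocks = data.frame(block_id = seq_len(sum(seg))),
          anchors = data.frame(
            gene_a = pmin(kk$seq1[seg], kk$seq2[seg]),
            gene_b = pmax(kk$seq1[seg], kk$seq2[seg]),
            block_id = seq_len(sum(seg)), stringsAsFactors = FALSE))
      }
    }
    calls <- classify_duplicates(pairs, blocks, tand)
    merged <- kk
    mk <- paste(pmin(kk$seq1, kk$seq2), pmax(kk$seq1, kk$seq2))
    ck <- paste(calls$gene_a, calls$gene_b)
    merged$dup_type <- calls$dup_type[match(mk, ck)]
    merged$kaks <- kaks_ratio(merged$ka, merged$ks)
    merged$selection <- selection_class(merged$kaks)
    merged$date_mya <- divergence_time(merged[[rate_column]], clock_rate)
    alt <- setdiff(c("ks", "ka"), rate_column)
    merged[[paste0("date_mya_", alt)]] <- divergence_time(merged[[alt]], clock_rate)
    report$duplicates <- merged
    report$duplication_counts <- table(merged$dup_type)
  } else {
    report$duplicates <- "skipped"
  }

  if (!is.null(ct)) {
    folds <- delta_delta_ct(ct)
    report$expression <- list(
      folds = folds,
      calls = call_regulation(folds, fold_threshold),
      zscores = row_scale(folds))
    if (!is.null(kaks_table) && is.data.frame(report$duplicates)) {
      dd <- report$duplicates
      have <- dd$seq1 %in% rownames(folds) & dd$seq2 %in% rownames(folds)
      if (any(have)) {
        r <- vapply(which(have), function(i) {
          pair_expression_correlation(folds[dd$seq1[i], ], folds[dd$seq2[i], ])
        }, 0)
        report$pair_divergence <- data.frame(
          gene_a = dd$seq1[have], gene_b = dd$seq2[have], r = r,
          class = classify_divergence(r), stringsAsFactors = FALSE)
      }
    }
  } else {
    report$expression <- "skipped"
  }

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== gene-family pipeline report ==\n")
  cat("genes:", x$genes$n, "in", length(x$genes$subfamily_counts),
      "subfamilies over", length(x$genes$chromosome_counts), "chromosomes\n")
  cat("subfamilies:",
      paste(names(x$genes$subfamily_counts), x$genes$subfamily_counts,
            sep = "=", collapse = " "), "\n")
  if (is.data.frame(x$duplicates)) {
    cat("duplicate pairs:", nrow(x$duplicates), "(",
        paste(names(x$duplication_counts), x$duplication_counts,
              sep = "=", collapse = ", "), ")\n")
    cat("Ka/Ks range:", format(min(x$duplicates$kaks, na.rm = TRUE)), "-",
        format(max(x$duplicates$kaks, na.rm = TRUE)),
        "; dates", format(round(min(x$duplicates$date_mya), 2)), "-",
        format(round(max(x$duplicates$date_mya), 2)), "Mya (",
        x$params$rate_column, "clock )\n")
  } else cat("duplication/kaks: skipped\n")
  if (is.list(x$expression)) {
    cat("expression:", nrow(x$expression$folds), "genes x",
        ncol(x$expression$folds), "conditions\n")
  } else cat("expression: skipped\n")
  invisible(x)
}

#' Write a pipeline report to TSV + markdown
#'
#' Deterministic for a fixed report: reruns produce byte-identical files.
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(report$registry, file.path(out_dir, "registry.tsv"))
  if (is.data.frame(report$duplicates)) {
    utils::write.table(report$duplicates, file.path(out_dir, "duplicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (is.list(report$expression)) {
    utils::write.table(as.data.frame(report$expression$folds),
                       file.path(out_dir, "folds.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(report$expression$calls, file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$pair_divergence)) {
    utils::write.table(report$pair_divergence,
                       file.path(out_dir, "pair_divergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  md <- c("# Gene-family pipeline report", "",
          "## Parameters",
          paste0("- ", names(report$params), ": ",
                 vapply(report$params, format, "")), "",
          "## Genes",
          paste0("- total: ", report$genes$n),
          paste0("- ", names(report$genes$subfamily_counts), ": ",
                 as.integer(report$genes$subfamily_counts)), "",
          "## Chromosome distribution",
          paste0("- chr", names(report$genes$chromosome_counts), ": ",
                 as.integer(report$genes$chromosome_counts)))
  if (is.data.frame(report$duplicates)) {
    md <- c(md, "", "## Duplication events",
            paste0("- ", names(report$duplication_counts), ": ",
                   as.integer(report$duplication_counts)))
  } else md <- c(md, "", "## Duplication events", "- skipped")
  if (!is.list(report$expression)) md <- c(md, "", "## Expression", "- skipped")
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
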