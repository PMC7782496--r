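# Assembly of the per-gene feature table and the correlation/comparison
# report: Spearman correlations of features with piRNA abundance
# (Benjamini-Hochberg adjusted) and Wilcoxon group comparisons.

#' Assemble a per-gene feature table
#'
#' Full-joins any number of per-gene tables (each with a `gene_id` column)
#' onto a base set of gene ids. Missing values stay `NA` (undefined
#' methylation, for example, is never silently zero).
#'
#' @param gene_ids Character vector of gene ids (one row each).
#' @param ... Named `data.table`s/data.frames keyed by `gene_id`.
#' @return `data.table`, one row per gene.
#' @export
build_feature_table <- function(gene_ids, ...) {
  out <- data.table(gene_id = gene_ids)
  for (tbl in list(...)) {
    if (is.null(tbl)) next
    tbl <- as.data.table(tbl)
    stopifnot("gene_id" %in% names(tbl))
    out <- merge(out, tbl, by = "gene_id", all.x = TRUE, sort = FALSE)
  }
  out
}

#' Correlate features with piRNA abundance
#'
#' Spearman rank correlation (average ranks for ties) of each feature
#' column against the abundance column, two-sided p values, and
#' Benjamini-Hochberg adjustment across the feature set. Significant iff
#' adjusted p < `alpha`.
#'
#' @param table Feature table (one row per gene).
#' @param features Character vector of numeric feature columns.
#' @param abundance_col Name of the abundance column (default
#'   `"abundance_rpm"`).
#' @param alpha Significance level on adjusted p values (default 0.05).
#' @return `data.table` with `feature`, `rho`, `p`, `p_adj`, `significant`,
#'   `n` (complete pairs used).
#' @export
correlate_with_abundance <- function(table, features,
                                     abundance_col = "abundance_rpm",
                                     alpha = 0.05) {
  tbl <- as.data.table(table)
  stopifnot(abundance_col %in% names(tbl), all(features %in% names(tbl)))
  res <- lapply(features, function(f) {
    x <- as.numeric(tbl[[abundance_col]])
    y <- as.numeric(tbl[[f]])
    keep_rows <- stats::complete.cases(x, y)
    ct <- suppressWarnings(
      cor.test(x[keep_rows], y[keep_rows], method = "spearman",
               alternative = "two.sided", exact = FALSE))
    data.table(feature = f, rho = unname(ct$estimate), p = ct$p.value,
               n = sum(keep_rows))
  })
  out <- rbindlist(res)
  out[, p_adj := p.adjust(p, method = "BH")]
  out[, significant := p_adj < alpha]
  out[]
}

#' Compare a quantity between two groups
#'
#' Two-sided Wilcoxon test: rank-sum for independent groups, signed-rank
#' for paired measurements. A degenerate paired comparison (all
#' differences zero) is flagged rather than tested.
#'
#' @param values Numeric vector.
#' @param group_labels Vector with exactly two distinct labels.
#' @param paired Whether observations are paired across groups (pairing by
#'   order within group).
#' @return List with `statistic`, `p`, `method`, and `degenerate` flag.
#' @export
compare_groups <- function(values, group_labels, paired = FALSE) {
  g <- factor(group_labels)
  stopifnot(nlevels(g) == 2L)
  a <- values[g == levels(g)[1L]]
  b <- values[g == levels(g)[2L]]
  if (paired) {
    stopifnot(length(a) == length(b))
    if (all(a - b == 0))
      return(list(statistic = NA_real_, p = NA_real_,
                  method = "wilcoxon_signed_rank", degenerate = TRUE))
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                       alternative = "two.sided"))
    return(list(statistic = unname(wt$statistic), p = wt$p.value,
                method = "wilcoxon_signed_rank", degenerate = FALSE))
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = "wilcoxon_rank_sum", degenerate = FALSE)
}

#' Format a p value for reporting
#'
#' Three significant figures; values at or below the double-precision
#' floor are reported as the floor with a flag, never truncated to 0.
#'
#' @param p Numeric p values.
#' @return `data.table` with `p_text` and `floored`.
#' @export
format_p <- function(p) {
  floor_p <- 2.2e-16
  floored <- !is.na(p) & p < floor_p
  txt <- ifelse(floored, paste0("< ", format(floor_p)),
                signif(p, 3))
  data.table(p_text = as.character(txt), floored = floored)
}

#' Write the feature/correlation report
#'
#' Emits `features.tsv`, `correlations.tsv` and a `run_log.txt` recording
#' package version, seed and thresholds; deterministic given its inputs.
#'
#' @param table Feature table.
#' @param correlations Output of [correlate_with_abundance()].
#' @param dir Output directory (created if needed).
#' @param config Optional named list logged verbatim.
#' @return Invisibly, the directory path.
#' @export
emit_report <- function(table, correlations, dir, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(as.data.table(table), file.path(dir, "features.tsv"),
                     sep = "\t")
  data.table::fwrite(as.data.table(correlations),
                     file.path(dir, "correlations.tsv"), sep = "\t")
  log_lines <- c(
    paste0("pachyscan version: ",
           as.character(utils::packageVersion("pachyscan"))),
    vapply(names(config), function(k)
      paste0(k, ": ", paste(format(config[[k]]), collapse = ",")),
      character(1)))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
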