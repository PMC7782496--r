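# Control-gene signal normalization, promoter/gene-body aggregation,
# strand-oriented binning, metagene profiles, and the extension-index
# statistic for broad signal domains.

#' Select expression-stable control genes
#'
#' A gene qualifies as a control iff its expression is similar across the
#' three germ-cell types (every pairwise ratio strictly inside
#' `(lower, upper)`) and its maximal expression exceeds `min_expr` RPKM.
#' The control set anchors cross-sample normalization of ChIP/ATAC levels.
#'
#' @param expr Numeric matrix or data.frame, genes x 3 cell types, with
#'   rownames.
#' @param lower,upper Pairwise fold-change band (defaults 0.66 and 1.5,
#'   both exclusive).
#' @param min_expr Maximal-expression floor (default 0.1 RPKM, exclusive).
#' @return Character vector of qualifying gene ids.
#' @export
select_control_genes <- function(expr, lower = 0.66, upper = 1.5,
                                 min_expr = 0.1) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == 3L, !is.null(rownames(expr)))
  ok <- apply(expr, 1L, function(v) {
    if (max(v) <= min_expr) return(FALSE)
    if (any(v <= 0)) return(FALSE)
    r <- max(v) / min(v)
    r < upper && 1 / r > lower
  })
  rownames(expr)[ok]
}

#' Normalize signal levels by control-gene medians
#'
#' Divides each sample's per-gene levels by that sample's median level over
#' the control genes, so the control median becomes 1 in every sample and
#' levels are comparable across antibodies/batches/tissues.
#'
#' @param levels Numeric matrix, genes x samples, with rownames.
#' @param control_genes Character vector of control gene ids (must intersect
#'   the rownames; the per-sample control median must be positive).
#' @return Matrix of the same shape, scaled.
#' @export
normalize_by_controls <- function(levels, control_genes) {
  levels <- as.matrix(levels)
  ctrl <- intersect(control_genes, rownames(levels))
  if (length(ctrl) == 0L) stop("empty control gene set")
  med <- apply(levels[ctrl, , drop = FALSE], 2L, median)
  if (any(!is.finite(med)) || any(med <= 0))
    stop("control median must be positive in every sample")
  sweep(levels, 2L, med, "/")
}

#' Mean signal over a gene region
#'
#' Length-weighted mean of track values across a region with bedGraph
#' zero-fill: uncovered bases contribute 0.
#'
#' @param track Signal track `GRanges`.
#' @param regions `GRanges` of regions (vectorized).
#' @return Numeric vector of means, parallel to `regions`.
#' @export
aggregate_signal <- function(track, regions) {
  out <- numeric(length(regions))
  if (length(track) == 0L || length(regions) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(track, regions, ignore.strand = TRUE)
  if (length(hits)) {
    seg <- pintersect(granges(track)[S4Vectors::queryHits(hits)],
                      granges(regions)[S4Vectors::subjectHits(hits)],
                      ignore.strand = TRUE)
    agg <- data.table(i = S4Vectors::subjectHits(hits),
                      v = width(seg) * track$score[S4Vectors::queryHits(hits)])[
                        , .(s = sum(v)), by = i]
    out[agg$i] <- agg$s
  }
  out / width(regions)
}

#' Canonical aggregation regions of a gene
#'
#' `promoter`: TSS +/- 2 kb; `gene_body`: TSS + 2 kb to the 3' end (empty
#' for genes shorter than 2 kb, returned zero-width and flagged `NA`
#' downstream); `tss500`: TSS +/- 500 bp (the 5hmC window). All regions are
#' strand-aware.
#'
#' @param genes Gene models.
#' @param region One of `"promoter"`, `"gene_body"`, `"tss500"`.
#' @return `GRanges` with `gene_id` (zero-width where undefined).
#' @export
gene_regions <- function(genes, region = c("promoter", "gene_body", "tss500")) {
  region <- match.arg(region)
  tss <- gene_tss(genes)
  minus <- as.character(strand(genes)) == "-"
  if (region == "promoter") {
    s <- tss - 2000L; e <- tss + 2000L
  } else if (region == "tss500") {
    s <- tss - 500L; e <- tss + 500L
  } else {
    s <- ifelse(minus, start(genes), tss + 2000L)
    e <- ifelse(minus, tss - 2000L, end(genes))
    bad <- s > e
    s[bad] <- tss[bad]; e[bad] <- tss[bad]   # degenerate: zero-length body
  }
  GRanges(seqnames(genes), IRanges(pmax(1L, s), pmax(1L, e)),
          strand = strand(genes), gene_id = genes$gene_id)
}

#' Mean signal per gene at promoter, gene body or TSS windows
#'
#' @param track Signal track.
#' @param genes Gene models.
#' @param region See [gene_regions()].
#' @return Named numeric vector (by `gene_id`).
#' @export
gene_signal <- function(track, genes, region = "promoter") {
  r <- gene_regions(genes, region)
  setNames(aggregate_signal(track, r), genes$gene_id)
}

#' Strand-oriented binned signal around a TSS
#'
#' Cuts the window `[TSS + span[1], TSS + span[2])` (offsets in
#' transcription direction) into `bin`-bp bins and reports each bin's mean
#' track value (zero-fill). For minus-strand genes the window maps to
#' decreasing genomic coordinates, so "downstream" is always transcription
#' direction. Bins extending beyond the chromosome are `NA` when `sizes`
#' is supplied.
#'
#' @param track Signal track.
#' @param gene Single gene model.
#' @param bin Bin width in bp (default 200).
#' @param span Offset range relative to TSS (default `c(-10000, 100000)`).
#' @param sizes Optional named chromosome sizes.
#' @return `data.table` with `offset` (bp, bin start relative to TSS) and
#'   `value`.
#' @export
bin_signal <- function(track, gene, bin = 200L, span = c(-10000L, 100000L),
                       sizes = NULL) {
  stopifnot(length(gene) == 1L)
  offsets <- seq.int(span[1L], span[2L] - bin, by = bin)
  tss <- unname(gene_tss(gene))
  chr <- as.character(seqnames(gene))
  if (as.character(strand(gene)) == "+") {
    gstart <- tss + offsets
    gend <- gstart + bin - 1L
  } else {
    gend <- tss - offsets
    gstart <- gend - bin + 1L
  }
  L <- if (!is.null(sizes)) sizes[[chr]] else NA_integer_
  outside <- if (is.na(L)) gend < 1L else (gend < 1L | gstart > L)
  qs <- pmax(1L, gstart)
  qe <- if (is.na(L)) gend else pmin(gend, L)
  vals <- rep(NA_real_, length(offsets))
  inb <- !outside & qs <= qe
  if (any(inb)) {
    # bins partially clipped at a chromosome edge average over the clipped part
    vals[inb] <- aggregate_signal(track, GRanges(chr, IRanges(qs[inb], qe[inb])))
  }
  data.table(offset = offsets, value = vals)
}

#' Extension index of a binned signal
#'
#' Quantifies how far a signal domain extends downstream of the TSS. Bins
#' at `[TSS + 80 kb, TSS + 100 kb)` are background; bins whose value
#' strictly exceeds the 95 percent quantile of the gene's own background
#' bins are signal-enriched. Walking downstream from the TSS, runs of up
#' to `max_gap_bins` (19, i.e. 3800 bp) consecutive sub-threshold bins may
#' be bridged (transposon insertions inside clusters commonly interrupt
#' the signal); a run of 20 or more ends the walk. The extension index is
#' the distance from the TSS to the far edge of the furthest enriched bin
#' reached (0 when the first 20 bins are all sub-threshold). The relative
#' extension index divides by the first-exon length (gene length for
#' intronless genes), capped at 1.
#'
#' @param binned Binned signal from [bin_signal()] (must span through the
#'   background range; `NA` bins count as sub-threshold).
#' @param first_unit_length First-exon length (spliced) or gene length
#'   (intronless), bp.
#' @param background_range Offset range of background bins (default
#'   `c(80000, 100000)`).
#' @param bg_quantile Background quantile defining the threshold
#'   (default 0.95).
#' @param max_gap_bins Largest bridgeable run of sub-threshold bins
#'   (default 19).
#' @param min_background Minimum number of defined background bins
#'   (default 25).
#' @return List with `extension_index` (bp), `relative_extension`,
#'   `threshold`, `n_background`.
#' @export
extension_index <- function(binned, first_unit_length,
                            background_range = c(80000L, 100000L),
                            bg_quantile = 0.95, max_gap_bins = 19L,
                            min_background = 25L) {
  stopifnot(first_unit_length > 0)
  bin <- binned$offset[2L] - binned$offset[1L]
  bg <- binned$value[binned$offset >= background_range[1L] &
                       binned$offset < background_range[2L]]
  bg <- bg[!is.na(bg)]
  if (length(bg) < min_background)
    stop("fewer than ", min_background, " background bins")
  thr <- as.numeric(quantile(bg, bg_quantile, names = FALSE))
  down <- binned[binned$offset >= 0L]
  enriched <- !is.na(down$value) & down$value > thr
  last <- 0L     # far edge (bins) of furthest reached enriched bin; 0 = none
  i <- 1L
  n <- length(enriched)
  while (i <= n) {
    if (enriched[i]) {
      last <- i
      i <- i + 1L
    } else {
      # allow a run of up to max_gap_bins sub-threshold bins after a reached bin
      run_end <- i
      while (run_end <= n && !enriched[run_end]) run_end <- run_end + 1L
      if (run_end > n || (run_end - i) > max_gap_bins) break
      i <- run_end
    }
  }
  ext <- last * bin
  list(extension_index = as.numeric(ext),
       relative_extension = min(1, ext / first_unit_length),
       threshold = thr,
       n_background = length(bg))
}

#' Extension indices for a set of genes
#'
#' Convenience wrapper: bins `track` around each gene's TSS and computes
#' the extension index against the gene's first-exon (or intronless gene)
#' length.
#'
#' @param track Signal track.
#' @param genes Gene models.
#' @param sizes Optional chromosome sizes.
#' @param ... Passed to [extension_index()].
#' @return `data.table` with `gene_id`, `extension_index`,
#'   `relative_extension`, `threshold`.
#' @export
gene_extension_index <- function(track, genes, sizes = NULL, ...) {
  fu <- first_exon_metrics(genes)
  res <- lapply(seq_along(genes), function(i) {
    b <- bin_signal(track, genes[i], sizes = sizes)
    extension_index(b, fu$first_unit_length[i], ...)
  })
  data.table(gene_id = genes$gene_id,
             extension_index = vapply(res, `[[`, numeric(1), "extension_index"),
             relative_extension = vapply(res, `[[`, numeric(1),
                                         "relative_extension"),
             threshold = vapply(res, `[[`, numeric(1), "threshold"))
}

#' Metagene profile
#'
#' Per-bin mean across genes of strand-oriented binned signal around the
#' TSS (default: +/- 2 kb in 10-bp bins).
#'
#' @param track Signal track.
#' @param genes Gene models.
#' @param span Offset range (default `c(-2000, 2000)`).
#' @param bin Bin width (default 10 bp).
#' @param sizes Optional chromosome sizes.
#' @return `data.table` with `offset`, `mean`, `n` (genes contributing).
#' @export
metagene_profile <- function(track, genes, span = c(-2000L, 2000L), bin = 10L,
                             sizes = NULL) {
  mats <- lapply(seq_along(genes), function(i)
    bin_signal(track, genes[i], bin = bin, span = span, sizes = sizes)$value)
  m <- do.call(cbind, mats)
  offsets <- seq.int(span[1L], span[2L] - bin, by = bin)
  data.table(offset = offsets,
             mean = rowMeans(m, na.rm = TRUE),
             n = rowSums(!is.na(m)))
}
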