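# De novo annotation of piRNA-producing loci from mapped small-RNA reads:
# 20-kb sliding windows -> abundance/complexity/1U-10A filters -> merge ->
# 100-bp boundary trimming -> strand assignment -> intron inference ->
# genic/intergenic classification.

#' Sliding-window small-RNA statistics
#'
#' Computes, for 20-kb windows advanced in 1-kb steps across each
#' chromosome, the apportioned piRNA abundance (reads per million uniquely
#' mapped reads), the number of distinct read species, and the fraction of
#' read weight carrying the piRNA sequence signature (1U or 10A). A read
#' overlapping several windows is counted once per window; multi-mapping
#' reads contribute `1/n_map_locations`. Distinct species are distinct
#' `(start, end, strand)` tuples.
#'
#' @param reads Read table as from [read_small_rna()].
#' @param sizes Named integer vector of chromosome lengths (bp).
#' @param window Window width in bp (default 20000).
#' @param step Step in bp (default 1000).
#' @param unique_total Number of uniquely mapping reads genome-wide; by
#'   default computed from `reads`. Must be positive.
#' @return `data.table` with `chrom, start, end` (0-based half-open),
#'   `rpm`, `n_distinct`, `frac_1u10a`; one row per window position.
#' @export
compute_window_stats <- function(reads, sizes, window = 20000L, step = 1000L,
                                 unique_total = NULL) {
  if (is.null(unique_total)) unique_total <- unique_mapper_count(reads)
  if (unique_total <= 0L) stop("no uniquely mapped reads")
  wins <- .tile_windows(sizes, window, step)
  rd <- data.table::copy(data.table::as.data.table(reads))
  rd[, read_key := .GRP, by = .(chrom, start, end, strand)]
  hits <- GenomicRanges::findOverlaps(
    reads_as_granges(rd),
    GRanges(wins$chrom, IRanges(wins$start + 1L, wins$end)))
  h <- data.table(win = S4Vectors::subjectHits(hits),
                  weight = rd$weight[S4Vectors::queryHits(hits)],
                  sig = (rd$nt1 %chin% c("T", "U") |
                           rd$nt10 == "A")[S4Vectors::queryHits(hits)],
                  read_key = rd$read_key[S4Vectors::queryHits(hits)])
  agg <- h[, .(w = sum(weight), nd = uniqueN(read_key),
               ws = sum(weight[sig])), by = win]
  wins[, `:=`(rpm = 0, n_distinct = 0L, frac_1u10a = NA_real_)]
  wins[agg$win, `:=`(rpm = agg$w / unique_total * 1e6,
                     n_distinct = agg$nd,
                     frac_1u10a = agg$ws / agg$w)]
  wins[]
}

`%chin%` <- data.table::`%chin%`

.tile_windows <- function(sizes, window, step) {
  out <- lapply(names(sizes), function(chr) {
    L <- sizes[[chr]]
    starts <- if (L <= window) 0L else seq.int(0L, L - window, by = step)
    data.table(chrom = chr, start = as.integer(starts),
               end = as.integer(pmin(starts + window, L)))
  })
  rbindlist(out)
}

#' Filter candidate windows
#'
#' A window is retained iff its abundance exceeds `min_rpm` piRNAs per
#' million uniquely mapped reads, it holds at least `min_distinct` distinct
#' read species (guards against unannotated miRNA/rRNA/tRNA fragments,
#' which produce many identical reads), and at least `min_frac` of its read
#' weight carries a 1U or 10A.
#'
#' @param stats Window table from [compute_window_stats()].
#' @param min_rpm Abundance threshold, exclusive (default 100).
#' @param min_distinct Distinct-species threshold, inclusive (default 200).
#' @param min_frac 1U/10A fraction threshold, inclusive (default 0.5).
#' @return The passing rows of `stats`.
#' @export
call_windows <- function(stats, min_rpm = 100, min_distinct = 200L,
                         min_frac = 0.5) {
  stats[rpm > min_rpm & n_distinct >= min_distinct &
          !is.na(frac_1u10a) & frac_1u10a >= min_frac]
}

#' Merge passing windows into candidate clusters
#'
#' Overlapping or bookended passing windows on one chromosome are merged
#' into a single candidate spanning their union (with a 1-kb step, adjacent
#' passing 20-kb windows overlap by construction).
#'
#' @param passing Passing windows from [call_windows()].
#' @return `GRanges` of candidate clusters.
#' @export
merge_windows <- function(passing) {
  if (nrow(passing) == 0L) return(GRanges())
  GenomicRanges::reduce(
    GRanges(passing$chrom, IRanges(passing$start + 1L, passing$end)))
}

#' Trim candidate boundaries on a 100-bp grid
#'
#' Scanning 100-bp windows inward from each end of the candidate, the
#' boundary is placed at the outer edge of the first window `w` such that
#' `w` and the next qualifying window inward are separated by a gap smaller
#' than `max_gap` bp and both exceed `min_rpm` piRNAs per million uniquely
#' mapped reads. A candidate in which no such pair exists is discarded with
#' a reason (reported, never silently dropped).
#'
#' @param candidate Single-range `GRanges` from [merge_windows()].
#' @param reads Read table.
#' @param unique_total Uniquely mapping read count genome-wide.
#' @param window Grid window width (default 100 bp).
#' @param min_rpm Per-window abundance threshold, exclusive (default 2).
#' @param max_gap Maximum gap between the paired qualifying windows
#'   (default 1000 bp, exclusive).
#' @return List with `interval` (`GRanges` or `NULL`) and `reason`
#'   (`"ok"`, `"no_qualifying_pair"`, or `"too_short"`).
#' @export
trim_boundaries <- function(candidate, reads, unique_total, window = 100L,
                            min_rpm = 2, max_gap = 1000L) {
  stopifnot(is(candidate, "GRanges"), length(candidate) == 1L)
  if (width(candidate) < window)
    return(list(interval = NULL, reason = "too_short"))
  chr <- as.character(seqnames(candidate))
  gstart <- start(candidate)
  starts <- seq.int(gstart, end(candidate) - window + 1L, by = window)
  grid <- GRanges(chr, IRanges(starts, width = window))
  rd <- reads[chrom == chr]
  w <- numeric(length(grid))
  if (nrow(rd)) {
    hits <- GenomicRanges::findOverlaps(reads_as_granges(rd), grid)
    agg <- data.table(win = S4Vectors::subjectHits(hits),
                      weight = rd$weight[S4Vectors::queryHits(hits)])[
                        , .(w = sum(weight)), by = win]
    w[agg$win] <- agg$w
  }
  rpm <- w / unique_total * 1e6
  q <- which(rpm > min_rpm)
  if (length(q) < 2L)
    return(list(interval = NULL, reason = "no_qualifying_pair"))
  gaps <- (diff(q) - 1L) * window          # bp between consecutive qualifiers
  ok <- which(gaps < max_gap)
  if (length(ok) == 0L)
    return(list(interval = NULL, reason = "no_qualifying_pair"))
  i5 <- q[min(ok)]                          # outer window of first inward pair
  i3 <- q[max(ok) + 1L]                     # outer window of last inward pair
  out <- GRanges(chr, IRanges(starts[i5], starts[i3] + window - 1L))
  list(interval = out, reason = "ok")
}

#' Assign transcriptional direction from stranded RNA coverage
#'
#' The strand with the larger summed long-RNA coverage over the interval
#' wins; a tie (including zero coverage on both strands) yields `"."` with
#' a warning, flagging the locus for manual review.
#'
#' @param candidate Single-range `GRanges`.
#' @param cov_plus,cov_minus Signal tracks of plus- and minus-strand RNA-seq
#'   coverage.
#' @return `"+"`, `"-"`, or `"."`.
#' @export
assign_strand <- function(candidate, cov_plus, cov_minus) {
  p <- .signal_sum(cov_plus, candidate)
  m <- .signal_sum(cov_minus, candidate)
  if (p > m) "+" else if (m > p) "-" else {
    warning("ambiguous strand (plus = ", p, ", minus = ", m, ") for ",
            as.character(seqnames(candidate)), ":", start(candidate), "-",
            end(candidate))
    "."
  }
}

.signal_sum <- function(track, region) {
  hits <- GenomicRanges::findOverlaps(track, region)
  if (length(hits) == 0L) return(0)
  seg <- pintersect(track[S4Vectors::queryHits(hits)],
                    rep(region, length(hits)))
  sum(width(seg) * track$score[S4Vectors::queryHits(hits)])
}

#' Infer exon blocks from RNA-seq splice junctions
#'
#' Junctions wholly inside the interval on its strand with read support at
#' least `min_support` are assembled greedily in order of descending
#' support into a non-overlapping intron chain; the exons are the
#' complementary blocks. Without junctions the locus is intronless (one
#' exon spanning the interval).
#'
#' @param candidate Single-range `GRanges` (trimmed cluster interval).
#' @param junctions `data.table` with `chrom, start, end` (0-based
#'   half-open intron coordinates), `strand`, `support`.
#' @param cluster_strand `"+"`, `"-"`, or `"."` (`"."` accepts either
#'   junction strand).
#' @param min_support Minimum junction read support (default 2).
#' @return `IRanges` of exon blocks (absolute 1-based coordinates).
#' @export
infer_introns <- function(candidate, junctions, cluster_strand = ".",
                          min_support = 2L) {
  stopifnot(is(candidate, "GRanges"), length(candidate) == 1L)
  span <- IRanges(start(candidate), end(candidate))
  if (is.null(junctions) || nrow(junctions) == 0L) return(span)
  j <- junctions[chrom == as.character(seqnames(candidate)) &
                   support >= min_support &
                   start + 1L > start(candidate) & end < end(candidate)]
  if (cluster_strand %in% c("+", "-")) j <- j[strand == cluster_strand]
  if (nrow(j) == 0L) return(span)
  setorder(j, -support, start)
  introns <- IRanges()
  for (k in seq_len(nrow(j))) {
    cand <- IRanges(j$start[k] + 1L, j$end[k])
    if (length(introns) == 0L ||
        !any(IRanges::overlapsAny(cand, introns)))
      introns <- c(introns, cand)
  }
  sort(IRanges::setdiff(span, introns))
}

#' Classify a cluster as genic or intergenic
#'
#' Genic iff more than half of the cluster's base pairs overlap
#' protein-coding gene spans (strand-agnostic; exactly 50 percent is
#' intergenic).
#'
#' @param cluster `GRanges` (one or more clusters).
#' @param coding_genes Gene models of protein-coding genes (spans used).
#' @return Character vector, `"genic"` or `"intergenic"`.
#' @export
classify_genic <- function(cluster, coding_genes) {
  if (length(coding_genes) == 0L)
    return(rep("intergenic", length(cluster)))
  cov <- GenomicRanges::reduce(granges(coding_genes), ignore.strand = TRUE)
  frac <- vapply(seq_along(cluster), function(i) {
    ov <- GenomicRanges::intersect(granges(cluster[i]), cov,
                                   ignore.strand = TRUE)
    sum(width(ov)) / width(cluster)[i]
  }, numeric(1))
  ifelse(frac > 0.5, "genic", "intergenic")
}

#' Discover piRNA clusters de novo
#'
#' Runs the full annotation chain: window statistics, threshold filters,
#' merging, boundary trimming, strand assignment from stranded RNA
#' coverage, intron inference from splice junctions, genic classification,
#' and apportioned abundance.
#'
#' @param reads Read table as from [read_small_rna()].
#' @param sizes Named chromosome lengths (bp).
#' @param junctions Optional junction table (see [infer_introns()]).
#' @param cov_plus,cov_minus Optional stranded RNA coverage tracks.
#' @param coding_genes Optional protein-coding gene models.
#' @param window,step,min_rpm,min_distinct,min_frac Window-calling
#'   parameters (see [compute_window_stats()] and [call_windows()]).
#' @param trim_window,trim_min_rpm,trim_max_gap Boundary-trimming
#'   parameters (see [trim_boundaries()]).
#' @param min_support Junction support threshold.
#' @return List with `clusters` (gene models: `gene_id`, `biotype =
#'   "piRNA_cluster"`, `blocks`, plus `genic_type` and `abundance_rpm`
#'   metadata) and `provenance` (`data.table` of every candidate with its
#'   outcome).
#' @export
discover_clusters <- function(reads, sizes, junctions = NULL,
                              cov_plus = NULL, cov_minus = NULL,
                              coding_genes = NULL,
                              window = 20000L, step = 1000L,
                              min_rpm = 100, min_distinct = 200L,
                              min_frac = 0.5,
                              trim_window = 100L, trim_min_rpm = 2,
                              trim_max_gap = 1000L, min_support = 2L) {
  U <- unique_mapper_count(reads)
  stats <- compute_window_stats(reads, sizes, window, step, unique_total = U)
  cands <- merge_windows(call_windows(stats, min_rpm, min_distinct, min_frac))
  prov <- data.table(chrom = character(), cand_start0 = integer(),
                     cand_end = integer(), outcome = character(),
                     start0 = integer(), end = integer(), strand = character())
  keep <- list()
  for (i in seq_along(cands)) {
    tr <- trim_boundaries(cands[i], reads, U, trim_window, trim_min_rpm,
                          trim_max_gap)
    row <- data.table(chrom = as.character(seqnames(cands[i])),
                      cand_start0 = start(cands[i]) - 1L,
                      cand_end = end(cands[i]),
                      outcome = tr$reason, start0 = NA_integer_,
                      end = NA_integer_, strand = NA_character_)
    if (tr$reason == "ok") {
      itv <- tr$interval
      str <- if (!is.null(cov_plus) && !is.null(cov_minus))
        assign_strand(itv, cov_plus, cov_minus) else "."
      blocks <- infer_introns(itv, junctions, str, min_support)
      row[, `:=`(start0 = start(itv) - 1L, end = end(itv), strand = str)]
      keep[[length(keep) + 1L]] <- list(interval = itv, strand = str,
                                        blocks = blocks)
    }
    prov <- rbind(prov, row)
  }
  if (length(keep) == 0L) {
    return(list(clusters = gene_models(GRanges(), character(0)),
                provenance = prov))
  }
  gr <- GRanges(
    vapply(keep, function(x) as.character(seqnames(x$interval)), character(1)),
    IRanges(vapply(keep, function(x) start(x$interval), integer(1)),
            vapply(keep, function(x) end(x$interval), integer(1))),
    strand = vapply(keep, function(x)
      if (x$strand == ".") "+" else x$strand, character(1)))
  ids <- paste0("cl_", as.character(seqnames(gr)), "_", start(gr) - 1L)
  cl <- gene_models(gr, gene_id = ids,
                    blocks = IRangesList(lapply(keep, `[[`, "blocks")),
                    biotype = "piRNA_cluster")
  cl$strand_flagged <- vapply(keep, function(x) x$strand == ".", logical(1))
  cl$genic_type <- if (!is.null(coding_genes))
    classify_genic(cl, coding_genes) else NA_character_
  cl$abundance_rpm <- pirna_abundance(reads, cl, unique_total = U)
  list(clusters = cl, provenance = prov)
}
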