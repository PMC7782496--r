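# RPKM/RPM computation, apportioned piRNA abundance, tissue-specificity
# score, testis-specificity calls, and first-exon-length classification.

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param count Read count(s) assigned to the gene.
#' @param transcript_length_bp Total transcript (exonic) length in bp.
#' @param total_mapped Total mapped reads in the library.
#' @return Numeric RPKM.
#' @examples
#' compute_rpkm(10, 1000, 1e6)  # 10
#' @export
compute_rpkm <- function(count, transcript_length_bp, total_mapped) {
  stopifnot(all(transcript_length_bp > 0), all(total_mapped > 0))
  count / (transcript_length_bp / 1000) / (total_mapped / 1e6)
}

#' Apportioned piRNA abundance of clusters
#'
#' Sums `1/n_map_locations` over reads overlapping each cluster interval
#' and scales per million uniquely mapped reads (RPM). A read overlapping
#' two clusters is counted in each with unchanged weight. With
#' `per_kb = TRUE`, additionally divides by the cluster's exonic length in
#' kb (RPKM variant).
#'
#' @param reads Read table as from [read_small_rna()].
#' @param clusters `GRanges` of clusters (gene models or plain ranges).
#' @param unique_total Uniquely mapping read count; computed from `reads`
#'   by default.
#' @param per_kb Return RPKM instead of RPM.
#' @return Numeric vector parallel to `clusters`.
#' @export
pirna_abundance <- function(reads, clusters, unique_total = NULL,
                            per_kb = FALSE) {
  if (is.null(unique_total)) unique_total <- unique_mapper_count(reads)
  if (unique_total <= 0L) stop("no uniquely mapped reads")
  out <- numeric(length(clusters))
  if (length(clusters) && nrow(reads)) {
    hits <- GenomicRanges::findOverlaps(reads_as_granges(reads),
                                        granges(clusters),
                                        ignore.strand = TRUE)
    agg <- data.table(cl = S4Vectors::subjectHits(hits),
                      weight = reads$weight[S4Vectors::queryHits(hits)])[
                        , .(w = sum(weight)), by = cl]
    out[agg$cl] <- agg$w / unique_total * 1e6
  }
  if (per_kb) {
    len <- if (!is.null(clusters$blocks))
      vapply(clusters$blocks, function(b) sum(width(b)), numeric(1))
    else width(clusters)
    out <- out / (len / 1000)
  }
  out
}

#' Tissue-specificity score
#'
#' With \eqn{Exp_{ts}} the testis expression level and \eqn{n} the total
#' number of tissues (testis included),
#' \deqn{ts = \frac{\sum_{i=1}^{n}(1 - Exp_i/Exp_{ts})}{n - 1}.}
#' The score is clamped to 0 whenever any tissue exceeds the testis level,
#' and to 0 when the gene is not expressed in testis (\eqn{Exp_{ts} = 0}).
#' It equals 1 iff all non-testis levels are 0 and \eqn{Exp_{ts} > 0}.
#'
#' @param expr Named numeric vector of expression levels (RPKM), one entry
#'   per tissue, including the testis sample.
#' @param testis_sample Name of the testis entry (default `"testis"`).
#' @return Score in `[0, 1]`.
#' @examples
#' ts_score(c(testis = 10, brain = 0, liver = 5, heart = 0,
#'            kidney = 0, lung = 0, spleen = 0, colon = 0, muscle = 0))
#' @export
ts_score <- function(expr, testis_sample = "testis") {
  stopifnot(testis_sample %in% names(expr), all(expr >= 0), length(expr) >= 2L)
  ts <- expr[[testis_sample]]
  if (ts == 0) return(0)
  if (any(expr > ts)) return(0)
  sum(1 - expr / ts) / (length(expr) - 1L)
}

#' Classify testis specificity of a gene
#'
#' A gene is `exclusive` when its transcripts are essentially undetectable
#' outside the testis (maximal somatic level `< exclusive_max` RPKM),
#' `testis_specific` when the testis level is at least `fold` times the
#' maximal somatic level (protein-coding genes additionally require a
#' testis level of at least `coding_floor` RPKM), and `broad` otherwise.
#'
#' @param expr Named numeric vector of RPKM across tissues (testis
#'   included; every non-testis entry is treated as somatic).
#' @param kind `"piRNA"` or `"coding"`.
#' @param testis_sample Name of the testis entry.
#' @param exclusive_max Somatic detection ceiling (default 0.1 RPKM).
#' @param fold Testis/somatic fold requirement (default 4).
#' @param coding_floor Minimum testis RPKM for coding genes (default 10).
#' @return List with `ts_score`, `category` (factor: `exclusive`,
#'   `testis_specific`, `broad`), and `fold_over_somatic`.
#' @export
classify_specificity <- function(expr, kind = c("piRNA", "coding"),
                                 testis_sample = "testis",
                                 exclusive_max = 0.1, fold = 4,
                                 coding_floor = 10) {
  kind <- match.arg(kind)
  ts <- expr[[testis_sample]]
  som <- expr[setdiff(names(expr), testis_sample)]
  max_som <- max(som)
  category <- if (max_som < exclusive_max) {
    "exclusive"
  } else if (ts >= fold * max_som && (kind != "coding" || ts >= coding_floor)) {
    "testis_specific"
  } else {
    "broad"
  }
  list(ts_score = ts_score(expr, testis_sample),
       category = factor(category,
                         levels = c("exclusive", "testis_specific", "broad")),
       fold_over_somatic = if (max_som > 0) ts / max_som else Inf)
}

#' First-exon length and structural type
#'
#' For spliced genes, the length of the 5'-most exon in transcription
#' direction; for intronless genes, the full transcript length. `long`
#' means at least `long_cut` bp (default 10 kb; inclusive). Structural
#' types: `long_intronless`, `long_first_exon`, `short`.
#'
#' @param genes Gene models.
#' @param long_cut Long/short boundary in bp; `inclusive = FALSE` switches
#'   to a strict `>` rule.
#' @param inclusive Whether `long_cut` itself counts as long (default TRUE).
#' @return `data.table` with `gene_id`, `first_unit_length`, `long_flag`,
#'   `structural_type`, `spliced`.
#' @export
first_exon_metrics <- function(genes, long_cut = 10000L, inclusive = TRUE) {
  spliced <- is_spliced(genes)
  fe_len <- width(first_exon(genes))
  tx_len <- vapply(genes$blocks, function(b) sum(width(b)), numeric(1))
  len <- ifelse(spliced, fe_len, tx_len)
  long_flag <- if (inclusive) len >= long_cut else len > long_cut
  type <- ifelse(!long_flag, "short",
                 ifelse(spliced, "long_first_exon", "long_intronless"))
  data.table(gene_id = genes$gene_id,
             first_unit_length = as.numeric(len),
             long_flag = long_flag,
             structural_type = factor(type, levels = c("long_intronless",
                                                       "long_first_exon",
                                                       "short")),
             spliced = spliced)
}
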