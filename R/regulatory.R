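# Rule-based regulatory calls: A-MYB-regulated genes and BTBD18-dependent
# pachytene piRNA clusters. Calls are pure functions of their evidence.

#' Distance from gene TSSs to the nearest ChIP peak
#'
#' Measured from the TSS to the nearest peak edge; 0 when the TSS lies
#' inside a peak. Genes on chromosomes without any peak get `Inf`.
#'
#' @param genes Gene models.
#' @param peaks `GRanges` of ChIP-seq peaks.
#' @return Numeric vector of distances (bp), named by `gene_id`.
#' @export
amyb_peak_distance <- function(genes, peaks) {
  tss <- gene_tss(genes)
  tss_gr <- GRanges(seqnames(genes), IRanges(tss, tss))
  d <- rep(Inf, length(genes))
  if (length(peaks)) {
    hit <- GenomicRanges::distanceToNearest(tss_gr, peaks, ignore.strand = TRUE)
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  }
  setNames(d, genes$gene_id)
}

#' Call A-MYB-regulated genes
#'
#' A gene is A-MYB regulated iff (1) its TSS lies within `max_distance` bp
#' of an A-MYB ChIP-seq peak, (2) the A-MYB ChIP enrichment over input in
#' the TSS +/- 500 bp window is at least `min_enrichment`-fold, and (3)
#' expression drops more than `1/max_ratio`-fold in the A-Myb mutant
#' relative to heterozygous littermates at both 14.5 and 17.5 days
#' post partum.
#'
#' @param peak_distance TSS-to-peak distance(s), bp.
#' @param promoter_enrichment A-MYB ChIP IP/input enrichment at the
#'   promoter.
#' @param mut_het_ratio_14,mut_het_ratio_17 Mutant/heterozygote expression
#'   ratios at 14.5 and 17.5 dpp. `NA` (e.g. a zero heterozygote
#'   denominator) makes the gene not assessable (`NA` call).
#' @param max_distance Peak distance ceiling (default 500 bp, inclusive).
#' @param min_enrichment Promoter enrichment floor (default 3, inclusive).
#' @param max_ratio Mutant/het ratio ceiling (default 0.5, exclusive: the
#'   decrease must exceed 2-fold).
#' @return Logical vector (NA where not assessable).
#' @export
call_amyb <- function(peak_distance, promoter_enrichment,
                      mut_het_ratio_14, mut_het_ratio_17,
                      max_distance = 500, min_enrichment = 3,
                      max_ratio = 0.5) {
  peak_distance <= max_distance &
    promoter_enrichment >= min_enrichment &
    mut_het_ratio_14 < max_ratio &
    mut_het_ratio_17 < max_ratio
}

#' Call BTBD18-dependent piRNA clusters
#'
#' Dependent iff both the precursor expression level and the piRNA
#' abundance are at least 2-fold lower in the Btbd18 mutant than in
#' heterozygous littermates (ratios `<= max_ratio`; the boundary, exactly
#' 2-fold lower, counts as dependent).
#'
#' @param expr_mut_over_het Mutant/het precursor expression ratio.
#' @param pirna_mut_over_het Mutant/het piRNA abundance ratio.
#' @param max_ratio Ratio ceiling (default 0.5, inclusive).
#' @return Logical vector (NA where a ratio is NA, i.e. not assessable).
#' @export
call_btbd18 <- function(expr_mut_over_het, pirna_mut_over_het,
                        max_ratio = 0.5) {
  expr_mut_over_het <= max_ratio & pirna_mut_over_het <= max_ratio
}

#' Mutant/heterozygote expression ratio
#'
#' Plain RPKM ratio with a guard for unexpressed heterozygotes: a zero
#' denominator yields `NA` ("not assessable") rather than `Inf`.
#'
#' @param mut,het Expression levels (RPKM).
#' @return Numeric ratio vector.
#' @export
mut_het_ratio <- function(mut, het) {
  ifelse(het > 0, mut / het, NA_real_)
}
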