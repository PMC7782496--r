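# Promoter CG-content statistic, CG-class assignment, and DNA-methylation
# aggregation.

#' Observed/expected CG dinucleotide ratio
#'
#' The normalized CpG content of a sequence:
#' \deqn{O/E\,CG = \frac{f_{CpG}}{[(f_C + f_G)/2]^2}}
#' where \eqn{f_C = \#C/L}, \eqn{f_G = \#G/L} and \eqn{f_{CpG}} is the count
#' of CG dinucleotides divided by the number of dinucleotide positions
#' (\eqn{L-1}; set `cpg_denominator = "L"` to divide by \eqn{L} instead).
#' `N` bases count toward \eqn{L} but never toward C, G or CG counts. A
#' sequence without any C or G returns 0.
#'
#' @param sequence A character string, `DNAString`, or a `DNAStringSet`
#'   (vectorized).
#' @param cpg_denominator `"L-1"` (default) or `"L"`.
#' @return Numeric O/E CG ratio(s), `>= 0`.
#' @examples
#' compute_oe_cg("CGCGCGCG")  # (4/7) / 0.25
#' compute_oe_cg("ATATATAT")  # 0
#' @export
compute_oe_cg <- function(sequence, cpg_denominator = c("L-1", "L")) {
  cpg_denominator <- match.arg(cpg_denominator)
  if (is.character(sequence) && length(sequence) > 1L)
    sequence <- Biostrings::DNAStringSet(sequence)
  if (is(sequence, "DNAStringSet")) {
    return(vapply(seq_along(sequence),
                  function(i) compute_oe_cg(sequence[[i]], cpg_denominator),
                  numeric(1)))
  }
  s <- if (is(sequence, "DNAString")) sequence else Biostrings::DNAString(sequence)
  L <- length(s)
  if (L < 2L) stop("sequence must have length >= 2")
  cg <- Biostrings::letterFrequency(s, c("C", "G"))
  fC <- cg[["C"]] / L
  fG <- cg[["G"]] / L
  if (fC + fG == 0) return(0)
  denom_len <- if (cpg_denominator == "L-1") L - 1L else L
  fCpG <- Biostrings::countPattern("CG", s) / denom_len
  fCpG / (((fC + fG) / 2)^2)
}

#' Classify a promoter by its O/E CG ratio
#'
#' Bands: low (`< low_cut`), high (`> high_cut`), intermediate otherwise.
#' Values exactly at a cutoff fall in the intermediate band (the band
#' definitions use strict inequalities on both sides, so the conservative
#' middle bin takes the boundaries).
#'
#' @param oe_cg Numeric O/E CG ratio(s).
#' @param low_cut,high_cut Band boundaries (defaults 0.25 and 0.5).
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
classify_cg <- function(oe_cg, low_cut = 0.25, high_cut = 0.5) {
  stopifnot(low_cut < high_cut)
  out <- ifelse(oe_cg < low_cut, "low",
                ifelse(oe_cg > high_cut, "high", "intermediate"))
  factor(out, levels = c("low", "intermediate", "high"))
}

#' Promoter windows around gene TSSs
#'
#' The genomic window `[TSS - window, TSS + window - 1]` (width `2 * window`),
#' clipped to the chromosome. O/E CG is strand-symmetric (the reverse
#' complement of CG is CG), so windows are reported on the forward strand.
#'
#' @param genes Gene models.
#' @param window Half-width in bp (default 500).
#' @param sizes Optional named chromosome sizes for clipping.
#' @return `GRanges` of promoter windows with `gene_id`.
#' @export
promoter_windows <- function(genes, window = 500L, sizes = NULL) {
  tss <- gene_tss(genes)
  s <- pmax(1L, tss - as.integer(window))
  e <- tss + as.integer(window) - 1L
  if (!is.null(sizes))
    e <- pmin(e, sizes[as.character(seqnames(genes))])
  GRanges(seqnames(genes), IRanges(s, e), strand = "*", gene_id = genes$gene_id)
}

#' Per-gene promoter O/E CG and CG class
#'
#' @param genome `DNAStringSet` genome.
#' @param genes Gene models.
#' @param window Promoter half-width in bp around the TSS (default 500).
#' @param ... Passed to [compute_oe_cg()] and [classify_cg()].
#' @return `data.table` with `gene_id`, `oe_cg`, `cg_class`.
#' @export
promoter_oe_cg <- function(genome, genes, window = 500L, ...) {
  win <- promoter_windows(genes, window, chrom_sizes(genome))
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(win), function(i) {
    Biostrings::subseq(genome[[as.character(seqnames(win))[i]]],
                       start(win)[i], end(win)[i])
  }))
  oe <- compute_oe_cg(seqs, ...)
  data.table(gene_id = genes$gene_id, oe_cg = oe, cg_class = classify_cg(oe))
}

#' Read per-CG-site methylation calls
#'
#' TSV with columns `chrom, pos0, meth, total, replicate` (0-based position
#' of the C of the CG site; counts of methylated and total calls).
#'
#' @param path Path to the TSV.
#' @return `data.table` of calls.
#' @export
read_methylation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "pos0", "meth", "total", "replicate")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("methylation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(dt$total < 1L)) stop("total call count must be >= 1")
  if (any(dt$meth > dt$total)) stop("meth cannot exceed total")
  dt[]
}

#' Methylation level of a region
#'
#' Per replicate, the unweighted mean over detected CG sites of
#' `meth / total`; the final level is the mean of the replicate means.
#' Regions without any detected site are flagged undefined (`NA` level)
#' rather than reported as 0.
#'
#' @param sites Methylation calls as from [read_methylation()].
#' @param region A single-range `GRanges` (1-based closed).
#' @return List with `level` (in `[0,1]` or `NA`), `n_sites`,
#'   `replicate_levels` (named numeric), and `defined` flag.
#' @export
promoter_methylation <- function(sites, region) {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  sel <- sites[chrom == as.character(seqnames(region)) &
                 pos0 + 1L >= start(region) & pos0 + 1L <= end(region)]
  if (nrow(sel) == 0L)
    return(list(level = NA_real_, n_sites = 0L,
                replicate_levels = numeric(0), defined = FALSE))
  rep_means <- sel[, .(level = mean(meth / total)), by = replicate]
  list(level = mean(rep_means$level),
       n_sites = length(unique(sel$pos0)),
       replicate_levels = setNames(rep_means$level, rep_means$replicate),
       defined = TRUE)
}

#' Per-gene promoter methylation levels
#'
#' Applies [promoter_methylation()] to each gene's promoter window.
#'
#' @param sites Methylation calls.
#' @param genes Gene models.
#' @param window Promoter half-width in bp (default 500).
#' @return `data.table` with `gene_id`, `meth_level`, `n_sites`.
#' @export
gene_methylation <- function(sites, genes, window = 500L) {
  win <- promoter_windows(genes, window)
  res <- lapply(seq_along(win), function(i) promoter_methylation(sites, win[i]))
  data.table(gene_id = genes$gene_id,
             meth_level = vapply(res, `[[`, numeric(1), "level"),
             n_sites = vapply(res, `[[`, integer(1), "n_sites"))
}
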