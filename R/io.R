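# Readers and writers for the on-disk formats the pipeline touches.
# Internal representation is Bioconductor-standard (GRanges, 1-based closed);
# BED-like formats are converted from 0-based half-open at this boundary.

#' Read a genome from FASTA
#'
#' Loads all records of a FASTA file into a `DNAStringSet`, uppercasing
#' lowercase (soft-masked) bases. Record names are truncated at the first
#' whitespace. Only the alphabet `{A, C, G, T, N}` is accepted; `N` bases are
#' retained (downstream they count toward sequence length but never toward C,
#' G or CG counts).
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtACGT"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate record name(s) in FASTA: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(Biostrings::width(x) < 1L))
    stop("empty sequence record(s) in FASTA: ",
         paste(names(x)[Biostrings::width(x) < 1L], collapse = ", "))
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  af <- Biostrings::alphabetFrequency(x)
  bad <- rowSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"),
                    drop = FALSE])
  if (any(bad > 0))
    stop("sequence(s) contain letters outside {A,C,G,T,N}: ",
         paste(names(x)[bad > 0], collapse = ", "))
  x
}

#' Chromosome sizes of a genome
#'
#' @param genome A `DNAStringSet` as returned by [read_genome()].
#' @return Named integer vector of chromosome lengths in bp.
#' @export
chrom_sizes <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

# ---- gene models -----------------------------------------------------------

#' Construct a set of gene models
#'
#' A gene model is a transcript on a strand with ordered, non-overlapping
#' exon blocks. Models are stored as a `GRanges` (one range per transcript)
#' with metadata columns `gene_id`, `biotype`, `class_label` and `blocks`, an
#' `IRangesList` of exon blocks in absolute genomic coordinates.
#'
#' @param gr `GRanges` of transcript spans with strand `+` or `-`.
#' @param gene_id Character vector of unique identifiers.
#' @param blocks `IRangesList` of exon blocks (absolute coordinates, sorted,
#'   non-overlapping, contained in the span). Default: one exon per model
#'   covering the whole span (intronless).
#' @param biotype Optional character vector
#'   (`protein_coding`/`lncRNA`/`piRNA_cluster`).
#' @param class_label Optional character vector
#'   (`pachytene`/`hybrid`/`prepachytene`/`none`).
#' @return `GRanges` of validated gene models.
#' @export
gene_models <- function(gr, gene_id, blocks = NULL, biotype = NA_character_,
                        class_label = NA_character_) {
  stopifnot(is(gr, "GRanges"))
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (any(!as.character(strand(gr)) %in% c("+", "-")))
    stop("gene models require strand '+' or '-'")
  if (is.null(blocks))
    blocks <- as(IRanges::IRanges(start(gr), end(gr)), "IRangesList")
  blocks <- as(blocks, "IRangesList")
  stopifnot(length(blocks) == length(gr))
  ok <- vapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    length(b) >= 1L &&
      all(start(b) >= start(gr)[i]) && all(end(b) <= end(gr)[i]) &&
      !is.unsorted(start(b)) &&
      (length(b) == 1L || all(start(b)[-1L] > end(b)[-length(b)]))
  }, logical(1))
  if (!all(ok))
    stop("invalid exon blocks for gene_id: ",
         paste(gene_id[!ok], collapse = ", "))
  mcols(gr) <- S4Vectors::DataFrame(
    gene_id = as.character(gene_id),
    biotype = rep_len(biotype, length(gr)),
    class_label = rep_len(class_label, length(gr)),
    blocks = blocks
  )
  names(gr) <- gene_id
  gr
}

#' Transcription start sites of gene models
#'
#' TSS is the 5'-most transcribed base: the leftmost coordinate on `+` and
#' the rightmost on `-`.
#'
#' @param genes Gene models from [gene_models()].
#' @return Integer vector of 1-based TSS positions, named by `gene_id`.
#' @export
gene_tss <- function(genes) {
  setNames(ifelse(as.character(strand(genes)) == "+", start(genes), end(genes)),
           genes$gene_id)
}

#' First exon (5'-most block in transcription direction)
#'
#' @param genes Gene models.
#' @return `GRanges` of first exons, parallel to `genes`.
#' @export
first_exon <- function(genes) {
  b <- genes$blocks
  fe <- vapply(seq_along(genes), function(i) {
    x <- b[[i]]
    if (as.character(strand(genes))[i] == "+") c(start(x)[1L], end(x)[1L])
    else c(start(x)[length(x)], end(x)[length(x)])
  }, integer(2))
  GRanges(seqnames(genes), IRanges(fe[1L, ], fe[2L, ]), strand = strand(genes),
          gene_id = genes$gene_id)
}

#' Whether each gene model is spliced
#' @param genes Gene models.
#' @return Logical vector.
#' @export
is_spliced <- function(genes) lengths(genes$blocks) > 1L

#' Read gene models from BED12 or GTF
#'
#' BED12 is parsed as 0-based half-open; GTF as 1-based closed. Both are
#' converted to the in-memory 1-based closed representation, with exon
#' blocks reconstructed per transcript (GTF `exon` features grouped by
#' `transcript_id`).
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed12"` or `"gtf"`.
#' @return Gene models as from [gene_models()].
#' @export
read_gene_models <- function(path, dialect = c("bed12", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed12") {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$blocks))
      gr$blocks <- as(IRanges(rep(1L, length(gr)), width(gr)), "IRangesList")
    bad <- vapply(seq_along(gr), function(i) {
      b <- gr$blocks[[i]]
      start(b)[1L] != 1L || end(b)[length(b)] != width(gr)[i]
    }, logical(1))
    if (any(bad))
      stop("BED12 blocks inconsistent with record span for: ",
           paste(gr$name[bad], collapse = ", "))
    abs_blocks <- IRanges::shift(gr$blocks, start(gr) - 1L)
    gene_models(granges(gr), gene_id = gr$name, blocks = abs_blocks)
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0L) stop("GTF contains no exon features")
    tid <- ex$transcript_id
    if (is.null(tid) || anyNA(tid)) stop("GTF exons lack transcript_id")
    sp <- split(ex, tid)
    span <- unlist(range(sp))
    blocks <- IRangesList(lapply(sp, function(g) sort(ranges(g))))
    bt <- vapply(sp, function(g) {
      b <- g$gene_biotype
      if (is.null(b)) NA_character_ else as.character(b[1L])
    }, character(1))
    gene_models(span, gene_id = names(sp), blocks = blocks, biotype = bt)
  }
}

#' Write gene models as BED12
#'
#' @param genes Gene models.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(genes, path) {
  out <- granges(genes)
  out$name <- genes$gene_id
  out$blocks <- IRanges::shift(genes$blocks, -(start(genes) - 1L))
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

# ---- small RNA reads -------------------------------------------------------

.small_rna_cols <- c("chrom", "start", "end", "strand", "length",
                     "nt1", "nt10", "n_map_locations")

#' Read mapped small-RNA reads from a BED-like TSV
#'
#' The table must carry columns `chrom, start, end, strand, length, nt1,
#' nt10, n_map_locations` (tab-separated, header row, `#` comments allowed;
#' coordinates 0-based half-open). Reads shorter than `min_len` or longer
#' than `max_len` nt are dropped (piRNA-sized reads are 24-32 nt) and the
#' number dropped is reported via `message()` and the `"n_filtered"`
#' attribute. Each read receives an apportioning weight
#' `1 / n_map_locations` so that multi-mapping reads contribute
#' fractionally.
#'
#' @param path Path to the TSV.
#' @param min_len,max_len Retained read-length range (nt).
#' @return A `data.table` of reads with an added `weight` column.
#' @export
read_small_rna <- function(path, min_len = 24L, max_len = 32L) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  missing_cols <- setdiff(.small_rna_cols, names(dt))
  if (length(missing_cols))
    stop("small RNA table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(dt$n_map_locations < 1L))
    stop("n_map_locations must be >= 1 for every read")
  n0 <- nrow(dt)
  dt <- dt[length >= min_len & length <= max_len]
  n_filtered <- n0 - nrow(dt)
  if (n_filtered > 0L)
    message("read_small_rna: dropped ", n_filtered, " read(s) outside ",
            min_len, "-", max_len, " nt")
  dt[, weight := 1 / n_map_locations]
  data.table::setattr(dt, "n_filtered", n_filtered)
  dt[]
}

#' Write small-RNA reads to TSV
#' @param reads Read table as from [read_small_rna()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_small_rna <- function(reads, path) {
  data.table::fwrite(reads[, .small_rna_cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Convert a read table to GRanges (1-based closed)
#' @param reads Read table (0-based half-open `start`/`end`).
#' @return `GRanges` parallel to the rows of `reads`.
#' @export
reads_as_granges <- function(reads) {
  GRanges(reads$chrom, IRanges(reads$start + 1L, reads$end),
          strand = reads$strand)
}

#' Number of uniquely mapping reads
#'
#' The normalization denominator for all per-million quantities: reads with
#' a single genomic mapping location.
#'
#' @param reads Read table.
#' @return Integer count.
#' @export
unique_mapper_count <- function(reads) sum(reads$n_map_locations == 1L)

# ---- signal tracks ---------------------------------------------------------

#' Read a bedGraph signal track
#'
#' A signal track is a `GRanges` with a numeric `score`: per-interval
#' enrichment (or depth-normalized density) with bedGraph semantics, i.e.
#' positions not covered by any interval have value 0. Overlapping intervals
#' on one chromosome are rejected.
#'
#' @param path Path to a 4-column bedGraph.
#' @return `GRanges` with a `score` column, sorted.
#' @export
read_signal_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  strand(gr) <- "*"
  gr <- sort(gr)
  if (!isDisjoint(gr))
    stop("overlapping intervals in bedGraph: ", path)
  if (any(!is.finite(gr$score)))
    stop("non-finite score values in bedGraph: ", path)
  gr
}

#' Canonicalize a signal track
#'
#' Sorts intervals and merges adjacent intervals carrying an identical value,
#' the canonical form used by the write/read round-trip contract.
#'
#' @param track Signal track `GRanges`.
#' @return Canonicalized `GRanges`.
#' @export
canonicalize_track <- function(track) {
  stopifnot(is(track, "GRanges"))
  track <- sort(track)
  if (length(track) < 2L) return(track)
  prev_adjacent <- c(FALSE,
                     as.character(seqnames(track))[-1L] ==
                       as.character(seqnames(track))[-length(track)] &
                       start(track)[-1L] == end(track)[-length(track)] + 1L &
                       track$score[-1L] == track$score[-length(track)])
  grp <- cumsum(!prev_adjacent)
  s <- tapply(start(track), grp, min)
  e <- tapply(end(track), grp, max)
  v <- track$score[!duplicated(grp)]
  chr <- as.character(seqnames(track))[!duplicated(grp)]
  GRanges(chr, IRanges(as.integer(s), as.integer(e)), score = v)
}

#' Write a signal track as bedGraph
#' @param track Signal track `GRanges` (any order; canonicalized on write).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signal_track <- function(track, path) {
  rtracklayer::export(canonicalize_track(track), path, format = "bedGraph")
  invisible(path)
}

#' Signal value at a single position
#'
#' @param track Signal track.
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @return Numeric value; 0 if the position is uncovered.
#' @export
signal_at <- function(track, chrom, pos) {
  hit <- track[seqnames(track) == chrom & start(track) <= pos & end(track) >= pos]
  if (length(hit) == 0L) 0 else hit$score[1L]
}
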