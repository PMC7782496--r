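# Cross-species conservation classification of mouse piRNA clusters from
# syntenic piRNA abundances.

.eutherian_panel <- c("human", "rhesus", "marmoset", "rat", "cow")

#' Syntenic piRNA abundance in another species
#'
#' If the lifted-over (syntenic) interval overlaps an annotated same-strand
#' piRNA cluster of that species, the coordinates snap to that cluster and
#' its abundance is used. Otherwise the syntenic interval is extended by
#' `extend` bp on both ends (to be inclusive of piRNAs mapping at its
#' boundaries) and apportioned abundance is computed from that species'
#' reads.
#'
#' @param synteny Single-range `GRanges` (the syntenic interval, with
#'   strand) in the target species' genome; `NULL`/empty means the region
#'   did not lift over, yielding abundance 0 with an `unmapped` flag.
#' @param species_clusters `GRanges` of that species' annotated piRNA
#'   clusters carrying an `abundance_rpm` column (may be empty).
#' @param species_reads Read table of that species (used when no cluster
#'   overlaps).
#' @param unique_total Uniquely mapping read count in that species.
#' @param extend Extension in bp (default 10000).
#' @return List with `rpm`, `snapped` (logical), `unmapped` (logical),
#'   and `interval` (the interval actually quantified, or `NULL`).
#' @export
syntenic_abundance <- function(synteny, species_clusters = GRanges(),
                               species_reads = NULL, unique_total = NULL,
                               extend = 10000L) {
  if (is.null(synteny) || length(synteny) == 0L)
    return(list(rpm = 0, snapped = FALSE, unmapped = TRUE, interval = NULL))
  stopifnot(length(synteny) == 1L)
  if (length(species_clusters)) {
    hit <- GenomicRanges::findOverlaps(synteny, species_clusters,
                                       ignore.strand = FALSE)
    if (length(hit)) {
      j <- S4Vectors::subjectHits(hit)[1L]
      return(list(rpm = species_clusters$abundance_rpm[j], snapped = TRUE,
                  unmapped = FALSE, interval = granges(species_clusters[j])))
    }
  }
  ext <- GRanges(seqnames(synteny),
                 IRanges(pmax(1L, start(synteny) - extend),
                         end(synteny) + extend),
                 strand = strand(synteny))
  rpm <- if (is.null(species_reads)) 0 else
    pirna_abundance(species_reads, ext, unique_total = unique_total)
  list(rpm = rpm, snapped = FALSE, unmapped = FALSE, interval = ext)
}

#' Fold-similarity of piRNA output between two loci
#'
#' Symmetric: similar iff both abundances are positive and the fold change
#' in either direction is strictly below `max_fold`. Invariant to scaling
#' both values by a common factor.
#'
#' @param rpm_a,rpm_b Abundances (RPM).
#' @param max_fold Fold-change bound (default 5, strict).
#' @return Logical vector.
#' @export
similar_abundance <- function(rpm_a, rpm_b, max_fold = 5) {
  rpm_a > 0 & rpm_b > 0 & pmax(rpm_a / rpm_b, rpm_b / rpm_a) < max_fold
}

#' Conservation class of a mouse piRNA cluster
#'
#' `eutherian_conserved` iff at least `min_similar` of the five eutherian
#' reference species (human, rhesus, marmoset, rat, cow) produce a similar
#' amount of piRNAs from the syntenic locus (fold change below `max_fold`
#' in either direction); otherwise `murine_conserved` iff the rat locus is
#' similar; otherwise `mouse_specific`. Abundances for species outside the
#' eutherian panel (e.g. opossum, platypus) may be present and are ignored
#' by the rules.
#'
#' @param mouse_rpm Mouse abundance (RPM), must be positive (clusters are
#'   annotated with positive abundance).
#' @param species_rpm Named numeric vector of syntenic abundances; names
#'   must include the eutherian panel (0 = no piRNAs / unmapped).
#' @param max_fold Similarity bound (default 5, strict).
#' @param min_similar Species count for the eutherian call (default 3).
#' @return List with `class` (factor: `eutherian_conserved`,
#'   `murine_conserved`, `mouse_specific`) and `similar` (named logical
#'   over the eutherian panel).
#' @export
classify_conservation <- function(mouse_rpm, species_rpm, max_fold = 5,
                                  min_similar = 3L) {
  if (mouse_rpm <= 0) stop("mouse abundance must be positive")
  missing_sp <- setdiff(.eutherian_panel, names(species_rpm))
  if (length(missing_sp))
    stop("species_rpm lacks: ", paste(missing_sp, collapse = ", "))
  sim <- vapply(.eutherian_panel, function(sp)
    similar_abundance(mouse_rpm, species_rpm[[sp]], max_fold), logical(1))
  cls <- if (sum(sim) >= min_similar) "eutherian_conserved"
  else if (sim[["rat"]]) "murine_conserved"
  else "mouse_specific"
  list(class = factor(cls, levels = c("eutherian_conserved",
                                      "murine_conserved", "mouse_specific")),
       similar = sim)
}

#' Conservation classes for a table of clusters
#'
#' @param abundance `data.table`/data.frame with columns `gene_id`,
#'   `species`, `rpm` (syntenic abundances; long format).
#' @param mouse_rpm Named numeric vector of mouse abundances by `gene_id`.
#' @param ... Passed to [classify_conservation()].
#' @return `data.table` with `gene_id`, `class`, and `n_similar`.
#' @export
conservation_table <- function(abundance, mouse_rpm, ...) {
  ab <- as.data.table(abundance)
  ids <- names(mouse_rpm)
  res <- lapply(ids, function(g) {
    sp <- ab[gene_id == g]
    v <- setNames(rep(0, length(.eutherian_panel)), .eutherian_panel)
    present <- intersect(sp$species, .eutherian_panel)
    v[present] <- sp$rpm[match(present, sp$species)]
    cc <- classify_conservation(mouse_rpm[[g]], v, ...)
    data.table(gene_id = g, class = cc$class, n_similar = sum(cc$similar))
  })
  rbindlist(res)
}
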