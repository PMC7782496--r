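# End-to-end analysis of a (synthetic or real) study: discover clusters,
# match them to an annotation, assemble per-gene features, and run the
# correlation report and rule-based classifications.

#' Match discovered clusters to a reference annotation
#'
#' For each reference cluster, finds the discovered cluster with the
#' largest overlap and reports the boundary error (the larger of the
#' absolute start and end differences).
#'
#' @param discovered `GRanges` of discovered clusters (with `gene_id`).
#' @param reference `GRanges` of reference cluster models (with `gene_id`).
#' @return `data.table` with `gene_id` (reference), `disc_id`, `disc_idx`,
#'   `boundary_error_bp` (`NA` if unrecovered), `recovered`.
#' @export
match_clusters <- function(discovered, reference) {
  out <- data.table(gene_id = reference$gene_id,
                    disc_id = NA_character_, disc_idx = NA_integer_,
                    boundary_error_bp = NA_real_, recovered = FALSE)
  if (length(discovered) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(reference, discovered,
                                      ignore.strand = TRUE)
  if (length(hits)) {
    ov <- width(pintersect(granges(reference)[S4Vectors::queryHits(hits)],
                           granges(discovered)[S4Vectors::subjectHits(hits)],
                           ignore.strand = TRUE))
    h <- data.table(q = S4Vectors::queryHits(hits),
                    s = S4Vectors::subjectHits(hits), ov = ov)
    best <- h[order(-ov)][!duplicated(q)]
    err <- pmax(abs(start(reference)[best$q] - start(discovered)[best$s]),
                abs(end(reference)[best$q] - end(discovered)[best$s]))
    out[best$q, `:=`(disc_id = discovered$gene_id[best$s],
                     disc_idx = best$s,
                     boundary_error_bp = as.numeric(err),
                     recovered = TRUE)]
  }
  out
}

#' Analyze a simulated study end to end
#'
#' Runs de novo cluster discovery on the simulated reads, matches the
#' calls to the planted clusters, assembles the per-cluster feature table
#' (abundance, first-exon metrics, promoter O/E CG, extension index,
#' promoter methylation, tissue specificity), computes the Spearman
#' correlation report, and applies the A-MYB, BTBD18 and conservation
#' rules to the simulated evidence tables.
#'
#' @param sim Output of [simulate_dataset()].
#' @param ... Passed to [discover_clusters()].
#' @return List with `discovery`, `matches`, `features`, `correlations`,
#'   `extension`, `amyb`, `btbd18`, `conservation`, `background_calls`
#'   (discovered clusters overlapping neither planted clusters nor
#'   decoys), and `decoy_calls`.
#' @export
analyze_simulation <- function(sim, ...) {
  truth <- sim$truth
  disc <- discover_clusters(
    sim$reads, truth$sizes, junctions = sim$junctions,
    cov_plus = sim$tracks$rna_plus, cov_minus = sim$tracks$rna_minus,
    coding_genes = truth$coding_models, ...)
  matches <- match_clusters(disc$clusters, truth$clusters)

  called <- disc$clusters
  in_truth <- IRanges::overlapsAny(called, truth$clusters,
                                   ignore.strand = TRUE)
  in_decoy <- IRanges::overlapsAny(called, truth$decoys,
                                   ignore.strand = TRUE)
  background_calls <- called[!in_truth & !in_decoy]
  decoy_calls <- called[in_decoy]

  rec <- matches[matches$recovered == TRUE]
  models <- disc$clusters[rec$disc_idx]
  # key recovered models by their planted identity for table joins
  models <- gene_models(granges(models), gene_id = rec$gene_id,
                        blocks = models$blocks, biotype = "piRNA_cluster")
  abundance <- data.table(gene_id = rec$gene_id,
                          abundance_rpm =
                            disc$clusters$abundance_rpm[rec$disc_idx])
  fe <- first_exon_metrics(models)
  oe <- promoter_oe_cg(sim$genome, models)
  ext <- gene_extension_index(sim$tracks$kac, models, truth$sizes)
  meth <- gene_methylation(sim$tables$methylation, models)
  spec <- rbindlist(lapply(rec$gene_id, function(g) {
    s <- classify_specificity(sim$tables$expression[g, ], kind = "piRNA")
    data.table(gene_id = g, ts_score = s$ts_score,
               specificity = as.character(s$category))
  }))
  features <- build_feature_table(rec$gene_id, abundance, fe, oe,
                                  ext[, .(gene_id, relative_extension,
                                          extension_index)],
                                  meth, spec)
  correlations <- correlate_with_abundance(
    features, c("first_unit_length", "oe_cg"))

  # regulatory calls over planted clusters and coding genes
  all_genes <- c(truth$clusters, truth$coding_models)
  dist <- amyb_peak_distance(all_genes, sim$tables$amyb_peaks)
  ae <- merge(sim$tables$amyb_enrichment, sim$tables$amyb_expr,
              by = "gene_id", sort = FALSE)
  amyb <- data.table(
    gene_id = ae$gene_id,
    amyb_regulated = call_amyb(
      dist[ae$gene_id], ae$promoter_enrichment,
      mut_het_ratio(ae$mut_14, ae$het_14),
      mut_het_ratio(ae$mut_17, ae$het_17)))
  bt <- sim$tables$btbd18
  btbd18 <- data.table(
    gene_id = bt$gene_id,
    btbd18_dependent = call_btbd18(
      mut_het_ratio(bt$expr_mut, bt$expr_het),
      mut_het_ratio(bt$pirna_mut, bt$pirna_het)))
  mouse_rpm <- setNames(abundance$abundance_rpm, abundance$gene_id)
  conservation <- conservation_table(sim$tables$species_abundance,
                                     mouse_rpm)

  list(discovery = disc, matches = matches, features = features,
       correlations = correlations, extension = ext, amyb = amyb,
       btbd18 = btbd18, conservation = conservation,
       background_calls = background_calls, decoy_calls = decoy_calls)
}
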