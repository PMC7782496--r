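# Synthetic-data generator: a toy genome with planted piRNA clusters of the
# three structural types (long intronless, long first exon, short), decoy
# loci that each violate exactly one discovery filter, piRNA-sized reads
# with 1U/10A composition and multimappers, signal tracks with broad or
# narrow domains, and the downstream evidence tables (tissue expression,
# mutant/heterozygote pairs, methylation calls, multi-species abundances).
# Every generator is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defaults define the package's reference synthetic study: a 2 x 2-Mb
#' genome carrying 8 planted piRNA clusters (3 long intronless, 2 with a
#' long first exon, 3 short), 3 decoy loci each violating one discovery
#' filter, 20 protein-coding genes, and ~1 M small-RNA read equivalents.
#' Planted cluster abundances increase with first-unit length and decrease
#' with promoter O/E CG, the joint pattern the feature report is expected
#' to recover.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_chromosomes,chrom_length Genome shape (default 2 x 2 Mb).
#' @param total_reads Total simulated small-RNA reads (default 1e6).
#' @param frac_1u,frac_10a Fractions of cluster reads with U at position 1
#'   / A at position 10 (defaults 0.7 / 0.3).
#' @param frac_multimap Fraction of reads mapping to 2 genomic locations
#'   (default 0.1; the rest map uniquely).
#' @param background_rpm Diffuse background abundance, weighted reads per
#'   million unique mappers per 20-kb window (default 2, the density a real
#'   library's few-percent diffuse read fraction yields per 20 kb of a
#'   mammalian genome; far below the 100-RPM calling threshold).
#' @param clusters,decoys,coding `data.frame`s describing planted loci; the
#'   defaults are the reference study (see Details in the package
#'   vignette).
#' @param kac_enrich,peak_enrich,hmc_enrich,baseline Signal-track levels
#'   (enrichment units over input; baseline is the uniform nonspecific
#'   level).
#' @param peak_up,peak_down Narrow promoter peak extent (bp upstream /
#'   downstream of the TSS).
#' @param signal_noise_sd Gaussian noise added to signal tracks per 200-bp
#'   cell (default 0: domains and background are exact, making domain
#'   recovery deterministic).
#' @param somatic_tissues Names of the somatic tissue panel (8 tissues).
#' @param meth_depth,meth_replicates WGBS-like call depth and replicate
#'   count (defaults 20 and 4).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 2e6L,
                       total_reads = 1e6L,
                       frac_1u = 0.7,
                       frac_10a = 0.3,
                       frac_multimap = 0.1,
                       background_rpm = 2,
                       clusters = NULL,
                       decoys = NULL,
                       coding = NULL,
                       kac_enrich = 4,
                       peak_enrich = 5,
                       hmc_enrich = 3,
                       baseline = 0.1,
                       peak_up = 1000L,
                       peak_down = 600L,
                       signal_noise_sd = 0,
                       somatic_tissues = c("brain", "colon", "heart",
                                           "kidney", "liver", "lung",
                                           "muscle", "spleen"),
                       meth_depth = 20L,
                       meth_replicates = 4L) {
  if (is.null(clusters)) clusters <- .default_clusters()
  if (is.null(decoys)) decoys <- .default_decoys()
  if (is.null(coding)) coding <- .default_coding(n_chromosomes, chrom_length)
  stopifnot(frac_1u >= 0, frac_1u <= 1, frac_multimap >= 0, frac_multimap < 1,
            all(clusters$rpm > 0))
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    total_reads = as.integer(total_reads),
    frac_1u = frac_1u, frac_10a = frac_10a, frac_multimap = frac_multimap,
    background_rpm = background_rpm, clusters = clusters, decoys = decoys,
    coding = coding, kac_enrich = kac_enrich, peak_enrich = peak_enrich,
    hmc_enrich = hmc_enrich, baseline = baseline,
    peak_up = as.integer(peak_up), peak_down = as.integer(peak_down),
    signal_noise_sd = signal_noise_sd, somatic_tissues = somatic_tissues,
    meth_depth = as.integer(meth_depth),
    meth_replicates = as.integer(meth_replicates)),
    class = "sim_config")
}

# Reference planted clusters. Abundance targets (RPM, relative to the
# realized unique-mapper count) rise monotonically with first-unit length;
# promoter O/E CG targets fall monotonically with abundance. Short spliced
# clusters keep first exons of several kb so that a promoter-confined peak
# occupies a small fraction of the first exon at 200-bp bin resolution.
.default_clusters <- function() {
  data.frame(
    gene_id = paste0("pi", 1:8),
    chrom = rep(c("chr1", "chr2"), each = 4L),
    slot = rep(c(150e3, 400e3, 650e3, 900e3), 2L),
    strand = rep(c("+", "-"), 4L),
    type = c("long_intronless", "long_intronless", "long_intronless",
             "long_first_exon", "long_first_exon", "short", "short", "short"),
    first_unit = c(30000L, 25000L, 20000L, 40000L, 15000L, 9000L, 7500L,
                   6000L),
    intron = c(0L, 0L, 0L, 5000L, 4000L, 3000L, 2000L, 2000L),
    exon2 = c(0L, 0L, 0L, 3000L, 2000L, 2000L, 1500L, 1000L),
    rpm = c(215000, 180000, 145000, 240000, 120000, 72000, 48000, 24000),
    target_oe = c(0.10, 0.13, 0.16, 0.08, 0.20, 0.30, 0.42, 0.65),
    specificity = c(rep("exclusive", 6L), "testis_specific",
                    "testis_specific"),
    amyb_regulated = TRUE,
    btbd18_dependent = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    conservation = c("eutherian_conserved", "eutherian_conserved",
                     "murine_conserved", "eutherian_conserved",
                     "murine_conserved", "mouse_specific", "mouse_specific",
                     "mouse_specific"),
    stringsAsFactors = FALSE)
}

# Decoys each violate exactly one discovery filter.
.default_decoys <- function() {
  data.frame(
    gene_id = c("decoy_low_rpm", "decoy_low_complexity", "decoy_low_1u"),
    chrom = "chr2",
    slot = c(1.15e6, 1.40e6, 1.65e6),
    span = 20000L,
    type = c("low_rpm", "low_complexity", "low_1u"),
    rpm = c(50, 500, 500),
    stringsAsFactors = FALSE)
}

.default_coding <- function(n_chrom, chrom_length) {
  n <- 20L
  data.frame(
    gene_id = sprintf("cg%02d", seq_len(n)),
    chrom = "chr1",
    slot = 1.15e6 + (seq_len(n) - 1L) * 35e3,
    strand = rep(c("+", "-"), length.out = n),
    testis_specific = c(rep(TRUE, 5L), rep(FALSE, n - 5L)),
    amyb_regulated = c(rep(TRUE, 5L), rep(FALSE, n - 5L)),
    stringsAsFactors = FALSE)
}

# Common RPM scale factor: with targets t_i, multimapper fraction f and
# N total reads, counts n_i = N t_i / sum(t) yield measured RPM of
# lambda * t_i where lambda = 1e6 (1 - f/2) / (1 - f) / sum(t).
.rpm_scale <- function(config) {
  tot <- sum(config$clusters$rpm) + sum(config$decoys$rpm) +
    config$background_rpm * config$n_chromosomes * config$chrom_length / 20000
  1e6 * (1 - config$frac_multimap / 2) / (1 - config$frac_multimap) / tot
}

.oe_band <- function(target) {
  if (target < 0.25) c(0, 0.25) else if (target < 0.5) c(0.25, 0.5)
  else c(0.5, Inf)
}

# Rejection-sample a promoter-sized sequence hitting a target O/E CG, both
# over the full window and over the central subwindow the pipeline scores.
.sample_oe_seq <- function(len, target, center = NULL, tol = 0.05,
                           max_try = 400L) {
  gc <- if (target > 0.5) 0.55 else 0.45
  bases <- c("A", "C", "G", "T")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  rho <- min(1, target)
  band <- .oe_band(target)
  for (i in seq_len(max_try)) {
    s <- sample(bases, len, replace = TRUE, prob = prob)
    cg <- which(s[-len] == "C" & s[-1L] == "G")
    drop <- cg[runif(length(cg)) > rho]
    if (length(drop)) s[drop + 1L] <- sample(c("A", "T"), length(drop),
                                             replace = TRUE)
    seqstr <- paste(s, collapse = "")
    oe_full <- compute_oe_cg(seqstr)
    ok_mid <- TRUE
    if (!is.null(center)) {
      oe_mid <- compute_oe_cg(substr(seqstr, center[1L], center[2L]))
      ok_mid <- oe_mid >= band[1L] && oe_mid < band[2L] &&
        (band[2L] == Inf || oe_mid < band[2L] - 0.02) &&
        (band[1L] == 0 || oe_mid > band[1L] + 0.02)
    }
    if (abs(oe_full - target) <= tol &&
        oe_full >= band[1L] && oe_full < band[2L] && ok_mid)
      return(seqstr)
    rho <- max(0.01, min(1.5, rho * target / max(oe_full, 1e-6)))
  }
  stop("could not sample promoter sequence at target O/E CG ", target)
}

#' Simulate a genome with planted piRNA clusters
#'
#' Builds random chromosomes, embeds a CG-composition-controlled promoter
#' sequence (TSS +/- 2 kb) at each planted locus so its O/E CG lands in the
#' configured band, and constructs gene models for clusters, decoys and
#' protein-coding genes.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`DNAStringSet`), `genes` (gene models for
#'   clusters and coding genes), and `truth` (planted ground truth: cluster
#'   models with structural type, abundance targets and expected measured
#'   values, promoter O/E targets and realized measurements, regulatory and
#'   conservation flags, decoy loci, chromosome sizes).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cl <- config$clusters
  span <- ifelse(cl$type == "long_intronless", cl$first_unit,
                 cl$first_unit + cl$intron + cl$exon2)
  if (any(cl$slot + span + 110e3 > config$chrom_length) ||
      any(cl$slot - 110e3 < 1))
    stop("chromosome too small to host requested loci")
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  sizes <- setNames(rep(config$chrom_length, length(chroms)), chroms)

  seqs <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE,
           prob = c(0.29, 0.21, 0.21, 0.29)))
  names(seqs) <- chroms

  # cluster gene models
  block_list <- lapply(seq_len(nrow(cl)), function(i) {
    s <- as.integer(cl$slot[i])
    if (cl$type[i] == "long_intronless") {
      IRanges(s, s + cl$first_unit[i] - 1L)
    } else if (cl$strand[i] == "+") {
      IRanges(c(s, s + cl$first_unit[i] + cl$intron[i]),
              width = c(cl$first_unit[i], cl$exon2[i]))
    } else {
      IRanges(c(s, s + cl$exon2[i] + cl$intron[i]),
              width = c(cl$exon2[i], cl$first_unit[i]))
    }
  })
  spans <- IRanges(vapply(block_list, function(b) min(start(b)), integer(1)),
                   vapply(block_list, function(b) max(end(b)), integer(1)))
  clusters <- gene_models(GRanges(cl$chrom, spans, strand = cl$strand,
                                  seqlengths = sizes),
                          gene_id = cl$gene_id,
                          blocks = IRangesList(block_list),
                          biotype = "piRNA_cluster",
                          class_label = "pachytene")

  # coding gene models: 3 short exons over a 3-kb span
  cod <- config$coding
  cod_blocks <- IRangesList(lapply(seq_len(nrow(cod)), function(i) {
    s <- as.integer(cod$slot[i])
    IRanges(c(s, s + 1000L, s + 2350L), width = c(200L, 150L, 650L))
  }))
  coding <- gene_models(
    GRanges(cod$chrom, IRanges(as.integer(cod$slot),
                               as.integer(cod$slot) + 2999L),
            strand = cod$strand, seqlengths = sizes),
    gene_id = cod$gene_id, blocks = cod_blocks, biotype = "protein_coding")

  genes <- c(clusters, coding)

  # embed CG-controlled promoters (TSS +/- 2 kb) for clusters; coding genes
  # get CpG-island-like promoters (O/E ~ 0.65)
  oe_measured <- numeric(length(genes))
  targets <- c(cl$target_oe, rep(0.65, nrow(cod)))
  tss_all <- gene_tss(genes)
  for (i in seq_along(genes)) {
    tss <- unname(tss_all[i])
    p <- .sample_oe_seq(4001L, targets[i], center = c(1501L, 2500L))
    ch <- as.character(seqnames(genes))[i]
    seqs[[ch]][(tss - 2000L):(tss + 2000L)] <- strsplit(p, "")[[1L]]
    oe_measured[i] <- compute_oe_cg(
      paste(seqs[[ch]][(tss - 500L):(tss + 499L)], collapse = ""))
  }

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- chroms

  dec <- config$decoys
  decoy_gr <- GRanges(dec$chrom, IRanges(as.integer(dec$slot),
                                         as.integer(dec$slot) + dec$span - 1L),
                      strand = "+", gene_id = dec$gene_id, type = dec$type,
                      rpm = dec$rpm)
  lambda <- .rpm_scale(config)
  fe <- first_exon_metrics(clusters)
  truth <- list(
    clusters = clusters,
    coding_models = coding,
    cluster_info = data.table(
      gene_id = cl$gene_id, type = cl$type,
      first_unit_length = fe$first_unit_length,
      target_rpm = cl$rpm, expected_rpm = lambda * cl$rpm,
      target_oe = cl$target_oe,
      oe_cg = oe_measured[seq_len(nrow(cl))],
      cg_class = classify_cg(oe_measured[seq_len(nrow(cl))]),
      specificity = cl$specificity,
      amyb_regulated = cl$amyb_regulated,
      btbd18_dependent = cl$btbd18_dependent,
      conservation = cl$conservation,
      meth_level = c(low = 0.85, intermediate = 0.16, high = 0.05)[
        as.character(classify_cg(oe_measured[seq_len(nrow(cl))]))]),
    coding_info = data.table(
      gene_id = cod$gene_id, testis_specific = cod$testis_specific,
      amyb_regulated = cod$amyb_regulated,
      oe_cg = oe_measured[nrow(cl) + seq_len(nrow(cod))]),
    decoys = decoy_gr,
    sizes = sizes,
    rpm_scale = lambda)
  list(genome = genome, genes = genes, truth = truth)
}

.sample_read_lengths <- function(n) {
  sample(24:32, n, replace = TRUE,
         prob = c(0.02, 0.03, 0.05, 0.10, 0.20, 0.25, 0.20, 0.10, 0.05))
}

.read_table <- function(chrom, start0, len, strand, nt1, nt10, n_map) {
  data.table(chrom = chrom, start = as.integer(start0),
             end = as.integer(start0 + len), strand = strand,
             length = as.integer(len), nt1 = nt1, nt10 = nt10,
             n_map_locations = as.integer(n_map),
             weight = 1 / as.integer(n_map))
}

.sample_nt <- function(n, hit, hit_base, alt) {
  ifelse(runif(n) < hit, hit_base, sample(alt, n, replace = TRUE))
}

# sample read start positions confined to exon blocks
.sample_block_starts <- function(blocks, len) {
  w <- width(blocks)
  idx <- sample.int(length(blocks), length(len), replace = TRUE,
                    prob = w / sum(w))
  lo <- start(blocks)[idx]
  hi <- pmax(lo, end(blocks)[idx] - len + 1L)
  (lo + floor(runif(length(len)) * (hi - lo + 1L))) - 1L   # 0-based
}

#' Simulate mapped small-RNA reads
#'
#' Draws piRNA-sized (24-32 nt) reads uniformly over the exons of every
#' planted cluster at its configured abundance, plus diffuse background
#' reads and the decoy loci (a low-abundance locus, a low-complexity locus
#' producing few distinct species, and a locus without 1U/10A bias). The
#' configured multimapper fraction receives `n_map_locations = 2`.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_genome()].
#' @return `data.table` of reads (BED-like, 0-based half-open) with
#'   apportioning weights.
#' @export
simulate_small_rna <- function(config, truth) {
  set.seed(config$seed + 1L)
  tot <- sum(config$clusters$rpm) + sum(config$decoys$rpm) +
    config$background_rpm * sum(truth$sizes) / 20000
  parts <- list()

  for (i in seq_len(nrow(config$clusters))) {
    n <- round(config$total_reads * config$clusters$rpm[i] / tot)
    len <- .sample_read_lengths(n)
    blocks <- truth$clusters$blocks[[i]]
    start0 <- .sample_block_starts(blocks, len)
    parts[[length(parts) + 1L]] <- .read_table(
      config$clusters$chrom[i], start0, len,
      as.character(strand(truth$clusters))[i],
      .sample_nt(n, config$frac_1u, "U", c("A", "C", "G")),
      .sample_nt(n, config$frac_10a, "A", c("C", "G", "U")),
      ifelse(runif(n) < config$frac_multimap, 2L, 1L))
  }

  for (i in seq_len(nrow(config$decoys))) {
    d <- config$decoys[i, ]
    n <- round(config$total_reads * d$rpm / tot)
    if (d$type == "low_complexity") {
      sp_len <- .sample_read_lengths(50L)
      sp_start <- d$slot - 1L + floor(runif(50L) * (d$span - 32L))
      pick <- sample.int(50L, n, replace = TRUE)
      len <- sp_len[pick]; start0 <- sp_start[pick]
      nt1 <- .sample_nt(n, config$frac_1u, "U", c("A", "C", "G"))
      nt10 <- .sample_nt(n, config$frac_10a, "A", c("C", "G", "U"))
    } else {
      len <- .sample_read_lengths(n)
      start0 <- d$slot - 1L + floor(runif(n) * (d$span - len))
      if (d$type == "low_1u") {
        nt1 <- .sample_nt(n, 0.1, "U", c("A", "C", "G"))
        nt10 <- .sample_nt(n, 0.05, "A", c("C", "G", "U"))
      } else {
        nt1 <- .sample_nt(n, config$frac_1u, "U", c("A", "C", "G"))
        nt10 <- .sample_nt(n, config$frac_10a, "A", c("C", "G", "U"))
      }
    }
    parts[[length(parts) + 1L]] <- .read_table(
      d$chrom, start0, len, "+", nt1, nt10,
      ifelse(runif(n) < config$frac_multimap, 2L, 1L))
  }

  n_bg <- round(config$total_reads *
                  config$background_rpm * sum(truth$sizes) / 20000 / tot)
  chrom <- sample(names(truth$sizes), n_bg, replace = TRUE,
                  prob = truth$sizes / sum(truth$sizes))
  len <- .sample_read_lengths(n_bg)
  start0 <- floor(runif(n_bg) * (truth$sizes[chrom] - len))
  parts[[length(parts) + 1L]] <- .read_table(
    chrom, start0, len, sample(c("+", "-"), n_bg, replace = TRUE),
    .sample_nt(n_bg, 0.5, "U", c("A", "C", "G")),
    .sample_nt(n_bg, 0.25, "A", c("C", "G", "U")),
    ifelse(runif(n_bg) < config$frac_multimap, 2L, 1L))

  rbindlist(parts)
}

#' Simulate RNA-seq splice junctions
#'
#' One well-supported junction per planted intron, plus a single
#' low-support spurious junction that the default support filter removes.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_genome()].
#' @return `data.table` with `chrom, start, end` (0-based half-open intron
#'   coordinates), `strand`, `support`.
#' @export
simulate_junctions <- function(config, truth) {
  rows <- list()
  for (i in seq_along(truth$clusters)) {
    b <- truth$clusters$blocks[[i]]
    if (length(b) < 2L) next
    for (k in seq_len(length(b) - 1L)) {
      rows[[length(rows) + 1L]] <- data.table(
        chrom = as.character(seqnames(truth$clusters))[i],
        start = end(b)[k], end = start(b)[k + 1L] - 1L,
        strand = as.character(strand(truth$clusters))[i], support = 50L)
    }
  }
  # spurious junction inside the first long-first-exon cluster, support 1
  lfe <- which(truth$cluster_info$type == "long_first_exon")[1L]
  if (!is.na(lfe)) {
    fe <- first_exon(truth$clusters[lfe])
    rows[[length(rows) + 1L]] <- data.table(
      chrom = as.character(seqnames(fe)),
      start = start(fe) + 499L, end = start(fe) + 1499L,
      strand = as.character(strand(fe)), support = 1L)
  }
  rbindlist(rows)
}

# assemble a bedGraph-style track from baseline + additive segments
.track_from_segments <- function(sizes, segments, baseline = 0,
                                 noise_sd = 0, noise_bin = 200L, seed = NULL) {
  cov <- lapply(names(sizes), function(ch) {
    r <- S4Vectors::Rle(baseline, sizes[[ch]])
    if (!is.null(segments) && nrow(segments)) {
      seg <- segments[chrom == ch]
      for (k in seq_len(nrow(seg))) {
        lo <- max(1L, seg$start[k]); hi <- min(sizes[[ch]], seg$end[k])
        if (lo <= hi) r[lo:hi] <- r[lo:hi] + seg$value[k]
      }
    }
    if (noise_sd > 0) {
      n_cells <- ceiling(sizes[[ch]] / noise_bin)
      noise <- rep(rnorm(n_cells, 0, noise_sd), each = noise_bin)
      r <- r + S4Vectors::Rle(noise[seq_len(sizes[[ch]])])
      r[r < 0] <- 0
    }
    r
  })
  names(cov) <- names(sizes)
  gr <- as(methods::as(cov, "SimpleRleList"), "GRanges")
  strand(gr) <- "*"
  gr
}

#' Simulate epigenomic signal tracks
#'
#' Builds enrichment tracks over a uniform nonspecific baseline: a histone
#' acylation track (`kac`) with a broad domain spanning the first exon or
#' intronless gene body of long planted loci and only a narrow promoter
#' peak at short loci; narrow promoter peaks for `h3k4me3` and `atac`
#' everywhere; `h3k27me3` elevated at broadly expressed coding genes;
#' `hmc5` (5hmC) high at low-CG cluster promoters; and stranded long-RNA
#' coverage (`rna_plus`, `rna_minus`) over exons for strand assignment.
#' Far-downstream windows (TSS + 80-100 kb) of every planted locus stay at
#' baseline.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_genome()].
#' @return Named list of signal-track `GRanges`.
#' @export
simulate_signal_tracks <- function(config, truth) {
  set.seed(config$seed + 2L)
  cl <- truth$clusters
  info <- truth$cluster_info
  tss <- gene_tss(cl)
  minus <- as.character(strand(cl)) == "-"
  chrom <- as.character(seqnames(cl))
  up <- config$peak_up; down <- config$peak_down

  peak_seg <- function(genes_gr) {
    t <- gene_tss(genes_gr); m <- as.character(strand(genes_gr)) == "-"
    data.table(chrom = as.character(seqnames(genes_gr)),
               start = as.integer(ifelse(m, t - down + 1L, t - up)),
               end = as.integer(ifelse(m, t + up, t + down - 1L)))
  }

  # kac: broad domain across first unit for long loci, narrow peak for short
  long_idx <- info$type != "short"
  kac_seg <- rbind(
    data.table(chrom = chrom[long_idx],
               start = as.integer(ifelse(minus[long_idx],
                                         tss[long_idx] -
                                           info$first_unit_length[long_idx] + 1L,
                                         tss[long_idx])),
               end = as.integer(ifelse(minus[long_idx], tss[long_idx],
                                       tss[long_idx] +
                                         info$first_unit_length[long_idx] - 1L)),
               value = config$kac_enrich + log10(info$target_rpm[long_idx])),
    cbind(peak_seg(cl[!long_idx]),
          value = config$kac_enrich + log10(info$target_rpm[!long_idx])))

  coding <- truth_coding_models(truth)
  all_genes <- suppressWarnings(c(cl, coding))
  h3k4_seg <- cbind(peak_seg(all_genes), value = config$peak_enrich)
  atac_seg <- cbind(peak_seg(all_genes), value = 0.6 * config$peak_enrich)

  broad_cod <- coding[!truth$coding_info$testis_specific]
  k27_seg <- cbind(peak_seg(broad_cod), value = 2)

  low_cg <- info$cg_class == "low"
  hmc_seg <- data.table(
    chrom = chrom, start = as.integer(tss - 500L), end = as.integer(tss + 499L),
    value = ifelse(low_cg, config$hmc_enrich, 0.3))

  # stranded RNA coverage over exons, proportional to testis expression
  rna_rows <- function(genes_gr, level) {
    rbindlist(lapply(seq_along(genes_gr), function(i) {
      b <- genes_gr$blocks[[i]]
      data.table(chrom = as.character(seqnames(genes_gr))[i],
                 start = start(b), end = end(b), value = level[i],
                 strand = as.character(strand(genes_gr))[i])
    }))
  }
  rna <- rbind(rna_rows(cl, info$target_rpm / 5000),
               rna_rows(coding, rep(10, length(coding))))

  ns <- config$signal_noise_sd
  list(
    kac = .track_from_segments(truth$sizes, kac_seg, config$baseline, ns),
    h3k4me3 = .track_from_segments(truth$sizes, h3k4_seg, config$baseline, ns),
    atac = .track_from_segments(truth$sizes, atac_seg, config$baseline, ns),
    h3k27me3 = .track_from_segments(truth$sizes, k27_seg, config$baseline, ns),
    hmc5 = .track_from_segments(truth$sizes, hmc_seg, config$baseline, ns),
    rna_plus = .track_from_segments(truth$sizes, rna[strand == "+"], 0),
    rna_minus = .track_from_segments(truth$sizes, rna[strand == "-"], 0))
}

# coding gene models are carried inside truth so downstream generators can
# run standalone
truth_coding_models <- function(truth) {
  truth$coding_models
}

#' Simulate downstream evidence tables
#'
#' Emits the tables the classification stages consume: a gene x tissue
#' RPKM matrix (testis plus eight somatic tissues), a three-cell-type
#' expression matrix for control-gene selection, A-MYB ChIP peaks with
#' promoter enrichments and A-Myb mutant/heterozygote expression at 14.5
#' and 17.5 dpp, Btbd18 mutant/heterozygote expression and piRNA
#' abundance, per-CG-site methylation calls across replicates, and
#' multi-species syntenic piRNA abundances with a synteny map.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_genome()].
#' @param genome The simulated genome (for locating CG sites).
#' @return Named list of tables (see vignette).
#' @export
simulate_tables <- function(config, truth, genome) {
  set.seed(config$seed + 3L)
  info <- truth$cluster_info
  cod <- truth$coding_info
  coding <- truth_coding_models(truth)
  cl <- truth$clusters
  tissues <- config$somatic_tissues

  # --- tissue expression matrix (RPKM) ---
  n_cl <- nrow(info); n_cod <- nrow(cod)
  testis_cl <- info$target_rpm / 5000
  expr <- matrix(0, n_cl + n_cod, 1L + length(tissues),
                 dimnames = list(c(info$gene_id, cod$gene_id),
                                 c("testis", tissues)))
  expr[seq_len(n_cl), "testis"] <- testis_cl
  for (i in seq_len(n_cl)) {
    som <- runif(length(tissues), 0, 0.05)
    if (info$specificity[i] == "testis_specific")
      som[1L] <- testis_cl[i] / 6          # detectable but >= 4-fold below
    expr[i, tissues] <- som
  }
  for (j in seq_len(n_cod)) {
    i <- n_cl + j
    if (cod$testis_specific[j]) {
      expr[i, "testis"] <- runif(1, 15, 40)
      som <- runif(length(tissues), 0, 0.08)
      som[1L] <- expr[i, "testis"] / 8
      expr[i, tissues] <- som
    } else {
      expr[i, ] <- runif(1L + length(tissues), 2, 10)
    }
  }

  # --- three germ-cell types for control selection ---
  ct <- matrix(0, n_cl + n_cod, 3L,
               dimnames = list(rownames(expr),
                               c("spermatogonia", "spermatocyte",
                                 "spermatid")))
  for (i in seq_len(n_cl)) ct[i, ] <- c(0.5, 5, 10) * testis_cl[i] / 5
  for (j in seq_len(n_cod)) {
    i <- n_cl + j
    if (j <= 5L) ct[i, ] <- c(1, 3, 9)             # variable: excluded
    else ct[i, ] <- 5 * runif(3, 0.85, 1.15)       # stable controls
  }

  # --- A-MYB evidence ---
  all_ids <- c(info$gene_id, cod$gene_id)
  regulated <- c(info$amyb_regulated, cod$amyb_regulated)
  genes_all <- suppressWarnings(c(cl, coding))
  tss_all <- gene_tss(genes_all)
  peak_rows <- which(regulated)
  peaks <- GRanges(as.character(seqnames(genes_all))[peak_rows],
                   IRanges(tss_all[peak_rows] - 100L,
                           tss_all[peak_rows] + 100L))
  # far-away decoy peak in background
  peaks <- c(peaks, GRanges("chr2", IRanges(1.9e6, 1.9e6 + 200L)))
  amyb_enrichment <- data.table(
    gene_id = all_ids,
    promoter_enrichment = ifelse(regulated, runif(length(all_ids), 4, 8),
                                 runif(length(all_ids), 0.8, 1.6)))
  amyb_expr <- data.table(
    gene_id = all_ids, het_14 = runif(length(all_ids), 10, 30),
    het_17 = runif(length(all_ids), 10, 30))
  amyb_expr[, `:=`(
    mut_14 = het_14 * ifelse(regulated, runif(.N, 0.2, 0.45),
                             runif(.N, 0.8, 1.2)),
    mut_17 = het_17 * ifelse(regulated, runif(.N, 0.2, 0.45),
                             runif(.N, 0.8, 1.2)))]

  # --- BTBD18 evidence (clusters only) ---
  dep <- info$btbd18_dependent
  btbd18 <- data.table(
    gene_id = info$gene_id,
    expr_het = testis_cl, pirna_het = info$target_rpm)
  btbd18[, `:=`(
    expr_mut = expr_het * ifelse(dep, runif(.N, 0.2, 0.45),
                                 runif(.N, 0.75, 1.2)),
    pirna_mut = pirna_het * ifelse(dep, runif(.N, 0.2, 0.45),
                                   runif(.N, 0.75, 1.2)))]

  # --- methylation calls: CG sites in promoter, 4 replicates ---
  meth_rows <- list()
  lev_all <- c(info$meth_level, ifelse(cod$testis_specific, 0.6, 0.05))
  for (i in seq_along(genes_all)) {
    ch <- as.character(seqnames(genes_all))[i]
    tss <- tss_all[[i]]
    win <- Biostrings::subseq(genome[[ch]], tss - 500L, tss + 499L)
    pos <- Biostrings::start(Biostrings::matchPattern("CG", win))
    if (length(pos) == 0L) next
    pos0 <- tss - 500L + pos - 1L - 1L       # 0-based C position
    for (r in seq_len(config$meth_replicates)) {
      meth_rows[[length(meth_rows) + 1L]] <- data.table(
        chrom = ch, pos0 = as.integer(pos0),
        meth = rbinom(length(pos0), config$meth_depth, lev_all[i]),
        total = config$meth_depth, replicate = r)
    }
  }
  methylation <- rbindlist(meth_rows)

  # --- conservation: synteny map and per-species syntenic abundance ---
  species <- c("human", "rhesus", "marmoset", "rat", "cow", "opossum",
               "platypus")
  similar_sets <- list(
    eutherian_conserved = c("human", "rhesus", "rat"),
    murine_conserved = "rat",
    mouse_specific = character(0))
  cons_rows <- list(); syn_rows <- list()
  for (i in seq_len(n_cl)) {
    sim_sp <- similar_sets[[info$conservation[i]]]
    if (info$conservation[i] == "eutherian_conserved" && i %% 2L == 0L)
      sim_sp <- c(sim_sp, "cow")             # vary which panel members match
    for (sp in species) {
      lifted <- runif(1) < 0.9 || sp %in% sim_sp
      syn_rows[[length(syn_rows) + 1L]] <- data.table(
        gene_id = info$gene_id[i], species = sp,
        chrom = ifelse(lifted, "chrA", NA_character_),
        start = ifelse(lifted, as.integer(2e5 * i), NA_integer_),
        end = ifelse(lifted, as.integer(2e5 * i + 5e4), NA_integer_),
        strand = "+")
      rpm <- if (sp %in% sim_sp) {
        info$target_rpm[i] * runif(1, 0.45, 2.0)
      } else if (lifted && runif(1) < 0.5) {
        info$target_rpm[i] / runif(1, 8, 40)
      } else 0
      cons_rows[[length(cons_rows) + 1L]] <- data.table(
        gene_id = info$gene_id[i], species = sp, rpm = rpm)
    }
  }

  list(expression = expr, celltype_expression = ct,
       amyb_peaks = peaks, amyb_enrichment = amyb_enrichment,
       amyb_expr = amyb_expr, btbd18 = btbd18, methylation = methylation,
       synteny = rbindlist(syn_rows),
       species_abundance = rbindlist(cons_rows))
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_genome()], [simulate_small_rna()],
#' [simulate_junctions()], [simulate_signal_tracks()] and
#' [simulate_tables()] under one configuration.
#'
#' @param config A [sim_config()] (default: the reference study).
#' @return List with `config`, `genome`, `genes`, `truth`, `reads`,
#'   `junctions`, `tracks`, `tables`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  g <- simulate_genome(config)
  reads <- simulate_small_rna(config, g$truth)
  junctions <- simulate_junctions(config, g$truth)
  tracks <- simulate_signal_tracks(config, g$truth)
  tables <- simulate_tables(config, g$truth, g$genome)
  list(config = config, genome = g$genome, genes = g$genes, truth = g$truth,
       reads = reads, junctions = junctions, tracks = tracks,
       tables = tables)
}

#' Write a simulated study to disk
#'
#' Emits the on-disk forms of every component: FASTA genome, BED12 gene
#' models, read and junction TSVs, bedGraph tracks, evidence tables, and a
#' `truth/` directory of TSV manifests.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gene_models(sim$genes, file.path(dir, "genes.bed12"))
  write_small_rna(sim$reads, file.path(dir, "reads.tsv"))
  data.table::fwrite(sim$junctions, file.path(dir, "junctions.tsv"),
                     sep = "\t")
  tdir <- file.path(dir, "tracks")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in names(sim$tracks))
    write_signal_track(sim$tracks[[nm]], file.path(tdir, paste0(nm,
                                                                ".bedGraph")))
  xdir <- file.path(dir, "tables")
  dir.create(xdir, showWarnings = FALSE)
  for (nm in setdiff(names(sim$tables), "amyb_peaks")) {
    x <- sim$tables[[nm]]
    if (is.matrix(x))
      x <- data.table(gene_id = rownames(x), as.data.table(x))
    data.table::fwrite(x, file.path(xdir, paste0(nm, ".tsv")), sep = "\t")
  }
  pk <- as.data.table(sim$tables$amyb_peaks)[, .(chrom = seqnames,
                                                 start = start - 1L, end)]
  data.table::fwrite(pk, file.path(xdir, "amyb_peaks.bed"), sep = "\t",
                     col.names = FALSE)
  udir <- file.path(dir, "truth")
  dir.create(udir, showWarnings = FALSE)
  data.table::fwrite(sim$truth$cluster_info,
                     file.path(udir, "clusters.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$coding_info,
                     file.path(udir, "coding.tsv"), sep = "\t")
  invisible(dir)
}
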