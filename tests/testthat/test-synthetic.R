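# The generators are pure functions of (config, seed); the planted
# structure must be realizable by the module's own measurement code.

test_that("generators are deterministic in the seed", {
  cfg <- sim_config(seed = 3, total_reads = 5e4)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$cluster_info, b$truth$cluster_info)
  ra <- simulate_small_rna(cfg, a$truth)
  rb <- simulate_small_rna(cfg, b$truth)
  expect_identical(ra, rb)
  cfg2 <- sim_config(seed = 4, total_reads = 5e4)
  c <- simulate_genome(cfg2)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("planted loci counts and structural types are conserved", {
  sim <- small_sim()
  info <- sim$truth$cluster_info
  expect_equal(nrow(info), 8L)
  expect_equal(sum(info$type == "long_intronless"), 3L)
  expect_equal(sum(info$type == "long_first_exon"), 2L)
  expect_equal(sum(info$type == "short"), 3L)
  fe <- first_exon_metrics(sim$truth$clusters)
  expect_true(all(fe$first_unit_length[fe$structural_type != "short"] >=
                    10000))
  expect_true(all(fe$first_unit_length[fe$structural_type == "short"] <
                    10000))
  # every planted cluster appears in every truth table
  expect_setequal(sim$truth$cluster_info$gene_id,
                  sim$truth$clusters$gene_id)
  expect_true(all(info$gene_id %in% sim$tables$btbd18$gene_id))
  expect_true(all(info$gene_id %in% rownames(sim$tables$expression)))
})

test_that("planted promoters reach their O/E CG band", {
  sim <- small_sim()
  info <- sim$truth$cluster_info
  # verified with the package's own O/E computation on the emitted genome
  oe <- promoter_oe_cg(sim$genome, sim$truth$clusters)
  expect_equal(as.character(classify_cg(info$target_oe)),
               as.character(oe$cg_class))
  # wider promoter window (TSS +/- 2 kb) also lands in the band
  oe2k <- promoter_oe_cg(sim$genome, sim$truth$clusters, window = 2000L)
  expect_equal(as.character(classify_cg(info$target_oe)),
               as.character(oe2k$cg_class))
})

test_that("read simulation realizes the planted abundances and signatures", {
  sim <- small_sim()
  info <- sim$truth$cluster_info
  ab <- pirna_abundance(sim$reads, sim$truth$clusters)
  expect_true(all(abs(ab / info$expected_rpm - 1) < 0.05))
  # 1U/10A weighted fraction of in-cluster reads clears the filter
  st <- compute_window_stats(sim$reads, sim$truth$sizes)
  hot <- st[st$rpm > 100]
  expect_true(all(hot$frac_1u10a >= 0.5 | hot$n_distinct < 200L))
  # abundant clusters produce well over 200 distinct species
  expect_true(all(hot[hot$rpm > 1000]$n_distinct > 200L))
  # pure-background windows stay far below the calling threshold
  bg <- st[st$chrom == "chr2" & st$start >= 1.75e6]
  expect_true(all(bg$rpm < 100))
  # multimappers carry apportioned weight
  expect_setequal(unique(sim$reads$n_map_locations), c(1L, 2L))
  expect_equal(sim$reads$weight, 1 / sim$reads$n_map_locations)
})

test_that("degenerate 1U fraction puts U on every cluster read", {
  cfg <- sim_config(seed = 9, total_reads = 5e4, frac_1u = 1,
                    background_rpm = 0)
  g <- simulate_genome(cfg)
  rd <- simulate_small_rna(cfg, g$truth)
  in_cluster <- IRanges::overlapsAny(reads_as_granges(rd), g$truth$clusters)
  expect_true(all(rd$nt1[in_cluster] == "U"))
})

test_that("decoys violate exactly their designated filter", {
  sim <- small_sim()
  st <- compute_window_stats(sim$reads, sim$truth$sizes)
  st_gr <- GenomicRanges::GRanges(st$chrom, IRanges::IRanges(st$start + 1L,
                                                             st$end))
  dec <- sim$truth$decoys
  for (i in seq_along(dec)) {
    w <- st[IRanges::overlapsAny(st_gr, dec[i])]
    w <- w[w$rpm > 0]
    if (dec$type[i] == "low_rpm") {
      expect_true(all(w$rpm <= 100))
    } else if (dec$type[i] == "low_complexity") {
      expect_true(any(w$rpm > 100))            # abundant enough to tempt
      expect_true(all(w[w$rpm > 100]$n_distinct < 200L))
    } else {                                    # low_1u
      expect_true(any(w$rpm > 100))
      expect_true(all(w[w$rpm > 100]$frac_1u10a < 0.5))
    }
  }
})

test_that("evidence tables realize the planted flags", {
  sim <- small_sim()
  info <- sim$truth$cluster_info
  expr <- sim$tables$expression
  tissues <- sim$config$somatic_tissues
  excl <- info$gene_id[info$specificity == "exclusive"]
  expect_true(all(apply(expr[excl, tissues, drop = FALSE], 1L, max) < 0.1))
  bt <- sim$tables$btbd18
  dep <- merge(bt, info[, c("gene_id", "btbd18_dependent")], by = "gene_id")
  expect_true(all((dep$expr_mut / dep$expr_het <= 0.5 &
                     dep$pirna_mut / dep$pirna_het <= 0.5) ==
                    dep$btbd18_dependent))
  # eutherian-conserved clusters have >= 3 eutherian species within 5-fold
  sp <- sim$tables$species_abundance
  for (g in info$gene_id[info$conservation == "eutherian_conserved"]) {
    v <- sp[sp$gene_id == g & sp$species %in%
              c("human", "rhesus", "marmoset", "rat", "cow")]
    mouse <- info$target_rpm[info$gene_id == g]
    n_sim <- sum(v$rpm > 0 & pmax(v$rpm / mouse, mouse / v$rpm) < 5)
    expect_gte(n_sim, 3L)
  }
  # four methylation replicates per site
  reps <- sim$tables$methylation[, .(n = data.table::uniqueN(replicate))]
  expect_equal(reps$n, 4L)
})

test_that("signal tracks are at baseline in the far-downstream window", {
  sim <- small_sim()
  base <- sim$config$baseline
  for (i in seq_along(sim$truth$clusters)) {
    b <- bin_signal(sim$tracks$kac, sim$truth$clusters[i],
                    sizes = sim$truth$sizes)
    bg <- b$value[b$offset >= 80000L & b$offset < 100000L]
    expect_equal(bg, rep(base, length(bg)))
  }
})

test_that("simulation round-trips through its on-disk formats", {
  cfg <- sim_config(seed = 13, total_reads = 2e4)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(sim$genome))
  rd <- read_small_rna(file.path(dir, "reads.tsv"))
  expect_equal(nrow(rd), nrow(sim$reads))
  expect_equal(sum(rd$weight), sum(sim$reads$weight))
  genes <- read_gene_models(file.path(dir, "genes.bed12"), "bed12")
  expect_equal(length(genes), length(sim$genes))
  i <- match(sim$genes$gene_id, genes$gene_id)
  expect_equal(start(genes)[i], start(sim$genes))
  expect_equal(as.list(genes$blocks[i]), as.list(sim$genes$blocks))
  kac <- read_signal_track(file.path(dir, "tracks", "kac.bedGraph"))
  expect_equal(aggregate_signal(kac, sim$truth$clusters[1L]),
               aggregate_signal(sim$tracks$kac, sim$truth$clusters[1L]))
})
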