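mk_track <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         score = df$value)
}

test_that("control-gene selection enforces the fold band and floor", {
  expr <- rbind(a = c(1.0, 1.2, 0.9),    # max/min 1.33: control
                b = c(1.0, 2.0, 1.0),    # 2-fold: excluded
                c = c(0.05, 0.05, 0.05), # below expression floor
                d = c(5, 5, 5))
  expect_equal(select_control_genes(expr), c("a", "d"))
  # exactly 1.5-fold is excluded (strict bound)
  expect_equal(select_control_genes(rbind(x = c(1, 1.5, 1))), character(0))
})

test_that("control normalization scales each sample to control median 1", {
  lv <- cbind(s1 = c(g1 = 2, g2 = 4, g3 = 2), s2 = c(1, 8, 1))
  out <- normalize_by_controls(lv, c("g1", "g3"))
  expect_equal(out[, "s1"], c(g1 = 1, g2 = 2, g3 = 1))
  expect_equal(out[, "s2"], c(g1 = 1, g2 = 8, g3 = 1))
  expect_equal(unname(apply(out[c("g1", "g3"), ], 2, median)), c(1, 1))
  same <- cbind(s1 = c(g1 = 3, g2 = 3))
  expect_equal(unname(normalize_by_controls(same, c("g1", "g2"))[, 1L]),
               c(1, 1))
  expect_error(normalize_by_controls(lv, "nope"), "empty control")
})

test_that("signal aggregation is a zero-filled length-weighted mean", {
  tr <- mk_track(data.frame(chrom = "c1", start = 1, end = 1000, value = 3))
  r <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 1000))
  expect_equal(aggregate_signal(tr, r), 3)
  # half covered at 4, half uncovered
  tr2 <- mk_track(data.frame(chrom = "c1", start = 1, end = 500, value = 4))
  expect_equal(aggregate_signal(tr2, r), 2)
  # disjoint pieces
  tr3 <- mk_track(data.frame(chrom = "c1", start = c(1, 901), end = c(100, 1000),
                             value = c(10, 5)))
  expect_equal(aggregate_signal(tr3, r), (100 * 10 + 100 * 5) / 1000)
})

test_that("gene regions are strand-aware", {
  gp <- gene_models(GenomicRanges::GRanges("c1", IRanges::IRanges(10000, 30000),
                                           strand = "+"), "gp")
  gm <- gene_models(GenomicRanges::GRanges("c1", IRanges::IRanges(10000, 30000),
                                           strand = "-"), "gm")
  pp <- gene_regions(gp, "promoter")
  pm <- gene_regions(gm, "promoter")
  expect_equal(c(start(pp), end(pp)), c(8000L, 12000L))
  expect_equal(c(start(pm), end(pm)), c(28000L, 32000L))   # TSS at right end
  bp <- gene_regions(gp, "gene_body")
  bm <- gene_regions(gm, "gene_body")
  expect_equal(c(start(bp), end(bp)), c(12000L, 30000L))
  expect_equal(c(start(bm), end(bm)), c(10000L, 28000L))
  t5 <- gene_regions(gm, "tss500")
  expect_equal(c(start(t5), end(t5)), c(29500L, 30500L))

  # minus-strand aggregation sees the promoter at the right end
  tr <- mk_track(data.frame(chrom = "c1", start = 28000, end = 32000,
                            value = 6))
  expect_equal(unname(gene_signal(tr, gm, "promoter")), 6)
  expect_equal(unname(gene_signal(tr, gp, "promoter")), 0)
})

test_that("binned signal is oriented along transcription", {
  # enrichment on [TSS, TSS+999] of a minus-strand gene (TSS at 150000)
  g <- gene_models(GenomicRanges::GRanges("c1",
                                          IRanges::IRanges(130000, 150000),
                                          strand = "-"), "g")
  tr <- mk_track(data.frame(chrom = "c1", start = 149001, end = 150000,
                            value = 5))
  b <- bin_signal(tr, g)
  expect_equal(b$value[b$offset %in% c(0L, 800L)], c(5, 5))
  expect_equal(b$value[b$offset == 1000L], 0)
  expect_equal(b$value[b$offset == -200L], 0)
  expect_equal(nrow(b), 550L)
})

test_that("extension index applies threshold, gap rule and cap", {
  offsets <- seq.int(-10000L, 99800L, by = 200L)
  base <- data.table::data.table(offset = offsets, value = 1)
  enrich <- function(b, from, to, v = 5) {
    b <- data.table::copy(b)
    b[offset >= from & offset < to, value := v]
    b[]
  }
  # enriched 0-20 kb, background constant: index is 20 kb
  b1 <- enrich(base, 0L, 20000L)
  r1 <- extension_index(b1, first_unit_length = 40000)
  expect_equal(r1$extension_index, 20000)
  expect_equal(r1$relative_extension, 0.5)
  # no enriched bins
  r0 <- extension_index(base, 10000)
  expect_equal(r0$extension_index, 0)
  expect_equal(r0$relative_extension, 0)
  # a 19-bin (3800 bp) gap is bridged
  b19 <- enrich(enrich(base, 0L, 5000L), 8800L, 10000L)
  expect_equal(extension_index(b19, 1e5)$extension_index, 10000)
  # a 20-bin (4000 bp) gap is not
  b20 <- enrich(enrich(base, 0L, 5000L), 9000L, 10000L)
  expect_equal(extension_index(b20, 1e5)$extension_index, 5000)
  # cap at 1: extension beyond the first unit
  b2 <- enrich(base, 0L, 50000L)
  expect_equal(extension_index(b2, 40000)$relative_extension, 1)
  # leading sub-threshold run of 20 bins kills the walk
  b3 <- enrich(base, 4000L, 10000L)
  expect_equal(extension_index(b3, 1e5)$extension_index, 0)
  b4 <- enrich(base, 3800L, 10000L)
  expect_equal(extension_index(b4, 1e5)$extension_index, 10000)
  # background bins are required
  short <- base[offset < 50000L]
  expect_error(extension_index(short, 1000), "background")
})

test_that("extension index matches the exhaustive oracle and is monotone", {
  offsets <- seq.int(-10000L, 99800L, by = 200L)
  set.seed(61)
  for (i in 1:60) {
    v <- exp(rnorm(length(offsets), 0, 1))
    if (i %% 3L == 0L)   # sometimes plant a real domain
      v[offsets >= 0L & offsets < sample(c(1e4, 4e4), 1L)] <- 10
    b <- data.table::data.table(offset = offsets, value = v)
    got <- extension_index(b, 1e5)
    expect_equal(got$extension_index, extension_oracle(b))
    # raising one non-background bin never decreases the index
    j <- sample(which(offsets >= 0L & offsets < 80000L), 1L)
    v2 <- v; v2[j] <- v2[j] + 5
    b2 <- data.table::data.table(offset = offsets, value = v2)
    expect_gte(extension_index(b2, 1e5)$extension_index, got$extension_index)
  }
})

test_that("metagene profile averages strand-oriented bins", {
  gp <- gene_models(GenomicRanges::GRanges("c1", IRanges::IRanges(5000, 9000),
                                           strand = "+"), "gp")
  gm <- gene_models(GenomicRanges::GRanges("c1", IRanges::IRanges(20000, 25000),
                                           strand = "-"), "gm")
  # signal downstream of each TSS (strand-aware)
  tr <- mk_track(data.frame(chrom = "c1", start = c(5000, 24001),
                            end = c(5999, 25000), value = 4))
  single <- metagene_profile(tr, gp)
  expect_equal(single$mean[single$offset == 0L], 4)
  expect_equal(single$mean[single$offset == -100L], 0)
  both <- metagene_profile(tr, suppressWarnings(c(gp, gm)))
  # mirrored genes give the same oriented profile, so the mean is unchanged
  expect_equal(both$mean, single$mean)
  expect_equal(unique(both$n), 2)
  # constant track gives a constant profile
  flat <- mk_track(data.frame(chrom = "c1", start = 1, end = 50000, value = 2))
  expect_equal(unique(metagene_profile(flat, gp)$mean), 2)
})
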