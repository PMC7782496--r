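# hand-built read table helper
mk_reads <- function(start0, n_map = 1L, chrom = "c1", strand = "+",
                     len = 30L, nt1 = "U", nt10 = "A") {
  data.table::data.table(
    chrom = chrom, start = as.integer(start0),
    end = as.integer(start0 + len), strand = strand, length = len,
    nt1 = nt1, nt10 = nt10, n_map_locations = as.integer(n_map),
    weight = 1 / as.integer(n_map))
}

test_that("window statistics count apportioned weights per window", {
  sizes <- c(c1 = 40000L)
  # 150 unique reads inside the first window
  rd <- mk_reads(seq(100L, by = 50L, length.out = 150L))
  st <- compute_window_stats(rd, sizes, unique_total = 1e6)
  expect_equal(st$rpm[1L], 150)
  expect_equal(st$n_distinct[1L], 150L)
  expect_equal(st$frac_1u10a[1L], 1)
  # empty window
  far <- st[st$start == 20000L]
  expect_equal(far$rpm, 0)
  expect_equal(far$n_distinct, 0L)

  # 100 unique + 10 double-mappers: 100 + 10 * 0.5 = 105
  rd2 <- rbind(mk_reads(seq(100L, by = 50L, length.out = 100L)),
               mk_reads(seq(10000L, by = 50L, length.out = 10L), n_map = 2L))
  st2 <- compute_window_stats(rd2, sizes, unique_total = 1e6)
  expect_equal(st2$rpm[1L], 105)

  expect_error(compute_window_stats(rd[0L], sizes), "no uniquely mapped")
})

test_that("read mass is conserved across a non-overlapping tiling", {
  sizes <- c(c1 = 60000L)
  set.seed(11)
  # reads placed away from tile boundaries so each falls in one tile
  start0 <- as.vector(sapply(seq(0L, 40000L, by = 20000L), function(o)
    o + sample(100:19800, 50)))
  rd <- mk_reads(sort(start0), n_map = sample(c(1L, 2L), 150L, TRUE))
  st <- compute_window_stats(rd, sizes, step = 20000L, unique_total = 1e6)
  expect_equal(sum(st$rpm) / 1e6 * 1e6, sum(rd$weight) / 1e6 * 1e6)
  expect_equal(sum(st$n_distinct), nrow(unique(rd[, .(start, end)])))
})

test_that("window filters apply the three thresholds conjunctively", {
  st <- data.table::data.table(
    chrom = "c1", start = c(0L, 1000L, 2000L, 3000L),
    end = c(20000L, 21000L, 22000L, 23000L),
    rpm = c(150, 150, 150, 100),
    n_distinct = c(250L, 150L, 250L, 250L),
    frac_1u10a = c(0.6, 0.6, 0.45, 0.6))
  pass <- call_windows(st)
  expect_equal(pass$start, 0L)          # others fail distinct / 1U10A / rpm
  # rpm threshold is strict: exactly 100 fails
  expect_equal(nrow(call_windows(st[4L])), 0L)
  # distinct and frac thresholds are inclusive
  st2 <- data.table::data.table(chrom = "c1", start = 0L, end = 20000L,
                                rpm = 101, n_distinct = 200L,
                                frac_1u10a = 0.5)
  expect_equal(nrow(call_windows(st2)), 1L)
})

test_that("passing windows merge when overlapping or bookended", {
  w <- data.table::data.table(chrom = "c1", start = c(0L, 1000L),
                              end = c(20000L, 21000L))
  m <- merge_windows(w)
  expect_equal(length(m), 1L)
  expect_equal(c(start(m) - 1L, end(m)), c(0L, 21000L))

  w2 <- data.table::data.table(chrom = "c1", start = c(0L, 50000L),
                               end = c(20000L, 70000L))
  expect_equal(length(merge_windows(w2)), 2L)
  w3 <- w2[1L]
  m3 <- merge_windows(w3)
  expect_equal(c(start(m3) - 1L, end(m3)), c(0L, 20000L))
})

test_that("boundary trimming matches a brute-force scan oracle", {
  U <- 1e6
  cand <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 21000))
  # dense region [5000, 15000) inside a wide candidate
  rd <- mk_reads(seq(5000L, 14950L, by = 10L))
  tr <- trim_boundaries(cand, rd, U)
  expect_equal(tr$reason, "ok")
  expect_lt(abs(start(tr$interval) - 5001L), 101L)
  expect_lt(abs(end(tr$interval) - 14980L), 101L)

  # uniform dense reads: trimmed interval stays the candidate (within grid)
  rd2 <- mk_reads(seq(1L, 20950L, by = 10L))
  tr2 <- trim_boundaries(cand, rd2, U)
  expect_lte(start(tr2$interval) - start(cand), 100L)
  expect_lte(end(cand) - end(tr2$interval), 200L)

  # sparse candidate is discarded with a reason
  tr3 <- trim_boundaries(cand, mk_reads(c(100L, 9000L)), U)
  expect_null(tr3$interval)
  expect_equal(tr3$reason, "no_qualifying_pair")

  # two qualifying windows 1500 bp apart do not pair; boundary moves inward
  rd4 <- rbind(mk_reads(c(1000L, 1010L, 1020L)),
               mk_reads(c(2500L, 2510L, 2520L)),
               mk_reads(seq(8000L, 12000L, by = 10L)))
  tr4 <- trim_boundaries(cand, rd4, U)
  expect_gte(start(tr4$interval), 8001L - 100L)

  set.seed(21)
  for (i in 1:20) {
    n <- sample(20:200, 1L)
    rd <- mk_reads(sort(sample.int(20500L, n)),
                   n_map = sample(c(1L, 2L), n, TRUE))
    tr <- trim_boundaries(cand, rd, U)
    orc <- trim_oracle(start(cand), end(cand), rd$start, rd$end, rd$weight, U)
    if (is.null(orc)) {
      expect_null(tr$interval)
    } else {
      expect_equal(c(start(tr$interval), end(tr$interval)), orc)
    }
  }
})

test_that("strand assignment follows dominant RNA coverage", {
  cand <- GenomicRanges::GRanges("c1", IRanges::IRanges(1000, 2000))
  mk_track <- function(v) GenomicRanges::GRanges("c1",
                                                 IRanges::IRanges(1000, 2000),
                                                 score = v)
  expect_equal(assign_strand(cand, mk_track(0.9), mk_track(0.1)), "+")
  expect_equal(assign_strand(cand, mk_track(0.1), mk_track(0.9)), "-")
  expect_warning(s <- assign_strand(cand, mk_track(0), mk_track(0)),
                 "ambiguous")
  expect_equal(s, ".")
})

test_that("intron inference assembles a maximal-support chain", {
  cand <- GenomicRanges::GRanges("c1", IRanges::IRanges(1001, 10000))
  expect_equal(infer_introns(cand, NULL), IRanges::IRanges(1001, 10000))

  j1 <- data.table::data.table(chrom = "c1", start = 3000L, end = 5000L,
                               strand = "+", support = 10L)
  ex <- infer_introns(cand, j1, "+")
  expect_equal(start(ex), c(1001L, 5001L))
  expect_equal(end(ex), c(3000L, 10000L))

  # overlapping junctions: higher support wins
  j2 <- rbind(j1, data.table::data.table(chrom = "c1", start = 4000L,
                                         end = 6000L, strand = "+",
                                         support = 3L))
  expect_equal(infer_introns(cand, j2, "+"), ex)

  # below support threshold and wrong strand junctions are ignored
  j3 <- data.table::data.table(chrom = "c1", start = c(3000L, 6000L),
                               end = c(5000L, 7000L), strand = c("+", "-"),
                               support = c(1L, 10L))
  expect_equal(infer_introns(cand, j3, "+"), IRanges::IRanges(1001, 10000))

  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:8, 1L)
    s <- sample(1500:8000, n)
    j <- data.table::data.table(chrom = "c1", start = s,
                                end = s + sample(100:1500, n, TRUE),
                                strand = "+", support = sample(2:30, n, TRUE))
    j <- j[end < 9800L]
    if (nrow(j) == 0L) next
    got <- infer_introns(cand, j, "+")
    want <- intron_chain_oracle(as.data.frame(
      j[, .(start = start + 1L, end, support)]))
    introns <- IRanges::IRanges(want$start, want$end)
    expected <- sort(IRanges::setdiff(IRanges::IRanges(1001, 10000), introns))
    expect_equal(got, expected)
  }
})

test_that("genic classification uses a strict majority-overlap rule", {
  genes <- gene_models(GenomicRanges::GRanges("c1",
                                              IRanges::IRanges(1, 600),
                                              strand = "+"), "pc1",
                       biotype = "protein_coding")
  cl60 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 1000))
  expect_equal(classify_genic(cl60, genes), "genic")      # 60%
  cl50 <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 1100))
  expect_equal(classify_genic(cl50, genes), "intergenic") # exactly 50%
  cl0 <- GenomicRanges::GRanges("c1", IRanges::IRanges(2000, 3000))
  expect_equal(classify_genic(cl0, genes), "intergenic")
  expect_equal(classify_genic(cl0, genes[0L]), "intergenic")
})

test_that("raising the abundance threshold never yields more clusters", {
  sim <- small_sim()
  st <- compute_window_stats(sim$reads, sim$truth$sizes)
  n_called <- vapply(c(50, 100, 500, 5000, 5e4, 5e5), function(thr)
    length(merge_windows(call_windows(st, min_rpm = thr))), numeric(1))
  expect_true(all(diff(n_called) <= 0))
})
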