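# Independent reference implementations used to cross-check the package's
# statistics, plus lazily cached synthetic runs shared across test files.

# O/E CG by a plain character-vector scan
oe_cg_brute <- function(s, denom = c("L-1", "L")) {
  denom <- match.arg(denom)
  v <- strsplit(toupper(s), "")[[1L]]
  L <- length(v)
  stopifnot(L >= 2L)
  fC <- sum(v == "C") / L
  fG <- sum(v == "G") / L
  if (fC + fG == 0) return(0)
  n_cg <- sum(v[-L] == "C" & v[-1L] == "G")
  fCpG <- n_cg / if (denom == "L-1") L - 1L else L
  fCpG / (((fC + fG) / 2)^2)
}

# extension index by exhaustive set expansion over reachable enriched bins
extension_oracle <- function(binned, bin = 200L, bg_range = c(80000L, 100000L),
                             q = 0.95, max_gap = 19L) {
  bg <- binned$value[binned$offset >= bg_range[1L] &
                       binned$offset < bg_range[2L]]
  bg <- bg[!is.na(bg)]
  thr <- as.numeric(quantile(bg, q, names = FALSE))
  down <- binned$value[binned$offset >= 0L]
  enr <- which(!is.na(down) & down > thr)
  reach <- integer(0)
  repeat {
    frontier <- if (length(reach) == 0L) 0L else max(reach)
    nxt <- enr[enr > frontier & enr <= frontier + max_gap + 1L]
    if (length(nxt) == 0L) break
    reach <- union(reach, nxt)
  }
  if (length(reach) == 0L) 0 else max(reach) * as.numeric(bin)
}

# candidate trimming by a naive per-window scan
trim_oracle <- function(cand_start, cand_end, starts0, ends, weights, U,
                        window = 100L, min_rpm = 2, max_gap = 1000L) {
  gstarts <- seq.int(cand_start, cand_end - window + 1L, by = window)
  rpm <- vapply(gstarts, function(s)
    sum(weights[ends >= s & starts0 + 1L <= s + window - 1L]) / U * 1e6,
    numeric(1))
  q <- which(rpm > min_rpm)
  if (length(q) < 2L) return(NULL)
  ok <- which((diff(q) - 1L) * window < max_gap)
  if (length(ok) == 0L) return(NULL)
  c(gstarts[q[min(ok)]], gstarts[q[max(ok) + 1L]] + window - 1L)
}

# recursive maximal-support non-overlapping intron chain
intron_chain_oracle <- function(j) {
  if (nrow(j) == 0L) return(j)
  j <- j[order(-j$support, j$start), , drop = FALSE]
  pick <- j[1L, , drop = FALSE]
  rest <- j[!(j$start <= pick$end & j$end >= pick$start), , drop = FALSE]
  out <- rbind(pick, intron_chain_oracle(rest))
  out[order(out$start), , drop = FALSE]
}

# random canonical signal track for round-trip tests
random_track <- function(n = 20L, chroms = c("c1", "c2")) {
  rows <- lapply(chroms, function(ch) {
    bounds <- sort(sample.int(10000L, 2L * n))
    s <- bounds[seq(1L, length(bounds), 2L)]
    e <- bounds[seq(2L, length(bounds), 2L)]
    data.frame(ch, s, e, v = round(stats::runif(n, 0, 10), 3))
  })
  df <- do.call(rbind, rows)
  canonicalize_track(GenomicRanges::GRanges(df$ch,
                                            IRanges::IRanges(df$s, df$e),
                                            score = df$v))
}

# shared synthetic runs (built once per test session)
.ps_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.ps_cache$small_sim))
    .ps_cache$small_sim <- simulate_dataset(sim_config(seed = 7,
                                                       total_reads = 2e5))
  .ps_cache$small_sim
}

reference_sim <- function() {
  if (is.null(.ps_cache$ref_sim))
    .ps_cache$ref_sim <- simulate_dataset(sim_config(seed = 1))
  .ps_cache$ref_sim
}

reference_analysis <- function() {
  if (is.null(.ps_cache$ref_res))
    .ps_cache$ref_res <- analyze_simulation(reference_sim())
  .ps_cache$ref_res
}
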