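---
title: "Methods: annotating and characterizing pachytene piRNA clusters"
author: "pachyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and characterizing pachytene piRNA clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pachyscan)
```

## Background

Pachytene piRNA clusters are roughly one hundred autosomal loci that, in
pachytene spermatocytes, produce the bulk of mammalian PIWI-interacting
RNAs. They behave like ordinary RNA polymerase II genes — capped, spliced,
polyadenylated — yet their transcripts are routed into piRNA biogenesis
rather than translation, and their expression is confined almost entirely
to the male germline. Two genic features distinguish them from ordinary
protein-coding and lncRNA genes: an unusually long first exon (or a long,
entirely unspliced transcript) and a promoter with a low or intermediate
density of CG dinucleotides that is nonetheless heavily methylated and
still actively transcribed in the germline. `pachyscan` implements the
computational pipeline around these observations: de novo cluster
annotation from mapped small-RNA reads, promoter CpG classification,
tissue-specificity scoring, normalized epigenomic signal aggregation, a
broad-domain "extension index", and rule-based regulatory and
cross-species conservation classification — together with a synthetic-data
generator that plants all of this structure in a toy genome so every stage
can be validated without external downloads.

## Cluster discovery

Input reads are pre-aligned 24–32-nt small RNAs given as intervals with
their first and tenth nucleotide and their number of genomic mapping
locations. Reads mapping to $k$ locations contribute weight $1/k$
(apportioning); all per-million quantities are normalized to the count of
uniquely mapping reads.

Discovery proceeds in five steps, each exposed as its own function:

1. **Window statistics** (`compute_window_stats`): 20-kb windows advanced
   in 1-kb steps; per window the apportioned abundance (RPM), the number
   of distinct read species, and the weighted fraction of reads with a
   5'-uridine or an adenine at position 10 (the ping-pong signature).
2. **Filters** (`call_windows`): a window survives iff RPM > 100 (strict),
   distinct species ≥ 200 (guards against unannotated miRNA/rRNA/tRNA
   fragments, which yield many copies of few sequences), and 1U/10A
   weighted fraction ≥ 0.5.
3. **Merging** (`merge_windows`): overlapping or bookended surviving
   windows merge into candidates; at a 1-kb step adjacent survivors
   overlap by construction.
4. **Trimming** (`trim_boundaries`): scanning 100-bp windows inward from
   each candidate end, the boundary is the outer edge of the first window
   that (a) exceeds 2 reads per million unique mappers and (b) is followed
   by another such window with a gap below 1000 bp. Requiring a *pair* of
   nearby qualifying windows, rather than a single one, guards against
   isolated stray reads in the up-to-19-kb flanks that merging
   necessarily attaches to every candidate; the trimmed coordinates and
   the outcome of every candidate are recorded in a provenance table.
   Candidates with no qualifying pair are discarded with a recorded
   reason, never silently.
5. **Annotation**: transcription direction comes from the dominant strand
   of long-RNA coverage over the interval (ties are flagged `.`), introns
   from splice junctions wholly inside the interval with support ≥ 2,
   assembled greedily by descending support into a non-overlapping chain,
   and a cluster is *genic* iff more than half its base pairs overlap
   protein-coding gene spans.

Abundance thresholds are applied to apportioned (weighted) counts; a flag
is not provided to switch to unique-only counting because the gene-level
abundance used everywhere downstream is also apportioned, and mixing the
two conventions inside one pipeline invites silent inconsistencies.

## Promoter CG content

The observed/expected CpG statistic of a sequence of length $L$ is

$$\mathrm{O/E\,CG} \;=\; \frac{f_{CpG}}{\left[(f_C + f_G)/2\right]^2},
\qquad f_C = \frac{\#C}{L},\; f_G = \frac{\#G}{L},\;
f_{CpG} = \frac{\#CG}{L-1}.$$

`N` bases count toward $L$ only. Three numerical choices were open and are
settable:

* the promoter window is TSS ± 500 bp by default (the statistic itself
  does not fix a window; the default matches the 5hmC aggregation window
  so that both promoter measures describe the same stretch of DNA, and
  `window` is an argument);
* $f_{CpG}$ divides by the number of dinucleotide positions $L-1$
  (`cpg_denominator = "L"` selects $L$);
* classes are low (< 0.25), intermediate, high (> 0.5); the defining
  inequalities are strict on both sides, so values exactly at a cutoff
  fall in the intermediate band.

O/E CG is strand-symmetric (the reverse complement of CG is CG), so
promoter windows are scored on the forward strand.

## Expression metrics

RPKM is `count / (length/1000) / (total/1e6)`. The tissue-specificity
score over $n$ tissues with testis expression $E_{ts}$ is

$$ts = \frac{\sum_{i=1}^{n} (1 - E_i/E_{ts})}{n-1},$$

clamped to 0 when any tissue exceeds the testis level and when
$E_{ts}=0$ (an unexpressed gene is not testis-specific; returning 0 rather
than NaN keeps rankings total). Formulations of this score differ in
whether the denominator carries the testis level or the overall maximum;
the clamp makes the two coincide whenever the score is nonzero, so the
testis level is used. All non-testis columns present in the matrix enter
$n$.

Specificity classes: *exclusive* when every somatic tissue is below
0.1 RPKM; *testis-specific* when testis is ≥ 4-fold above the somatic
maximum (protein-coding genes additionally need ≥ 10 RPKM in testis);
*broad* otherwise. First exons are *long* at ≥ 10 kb — the definition is
inclusive; `inclusive = FALSE` selects a strict boundary instead. Intronless genes are measured by their full transcript
length.

## Signal aggregation and the extension index

ChIP/ATAC tracks arrive as bedGraph enrichment over input. Cross-sample
comparability uses a control-gene set: genes whose expression across
spermatogonia, spermatocytes and round spermatids stays within
(0.66, 1.5)-fold pairwise with maximal expression > 0.1 RPKM; each
sample's levels are divided by its median over the controls
(`normalize_by_controls`), making the control median 1 everywhere.

Aggregation regions are the promoter (TSS ± 2 kb), the gene body
(TSS + 2 kb to the 3' end) and the 5hmC window (TSS ± 500 bp), all
strand-aware, with bedGraph zero-fill (uncovered bases contribute 0).

The extension index quantifies how far a signal domain reaches into the
gene body. The window [TSS − 10 kb, TSS + 100 kb] is cut into 200-bp bins
oriented along transcription; bins at [TSS + 80 kb, TSS + 100 kb) are the
gene's own background, and a bin is *enriched* when it strictly exceeds
the 95 % quantile of those background bins. Walking downstream from the
TSS, runs of up to 19 consecutive sub-threshold bins (3800 bp) are
bridged — transposon copies inside clusters commonly punch holes in the
signal — while a run of 20 ends the walk. The index is the distance from
the TSS to the far edge of the furthest bin reached; the relative index
divides by the first-exon length (gene length for intronless genes) and
caps at 1. Numerical conventions chosen here: the background quantile is
per gene (the phrasing ties background bins to each gene's downstream
region; a shared global background can be emulated by passing a common
threshold through the binned values); exactly 19 sub-threshold bins are
bridgeable and 20 are not; spans truncated by a chromosome end drop the
missing bins and at least 25 defined background bins are required;
enrichment values are used on the linear scale — a strictly monotone
transform such as log2 applied to all bins leaves the quantile threshold
comparisons, and hence the index, unchanged, so log-scaling is left to
display code.

## Regulatory and conservation rules

*A-MYB-regulated*: TSS within 500 bp of an A-MYB ChIP peak (distance to
the nearest peak edge, 0 inside a peak), promoter (TSS ± 500 bp) IP/input
enrichment ≥ 3, and mutant/heterozygote expression ratio < 0.5 at both
14.5 and 17.5 dpp. *BTBD18-dependent*: both precursor expression and
piRNA abundance at most half of the heterozygote level (the boundary,
exactly 2-fold, counts as dependent). Ratios are computed on RPKM; a zero heterozygote denominator
yields NA ("not assessable") rather than an infinite ratio.

*Conservation*: for each mouse cluster, the lifted-over locus in another
species is snapped to that species' annotated same-strand cluster when
they overlap, otherwise extended by 10 kb on both ends before abundance
is computed. A species is *similar* when the fold change in either
direction is strictly below 5 (similarity is symmetric and scale-free;
an absent locus is never similar). A cluster is eutherian-conserved with
≥ 3 similar species among human, rhesus, marmoset, rat and cow;
otherwise murine-conserved if rat is similar; otherwise mouse-specific.
Opossum and platypus abundances may ride along in tables but never enter
the rules.

## The synthetic study

`sim_config()` defines the reference study: two 2-Mb chromosomes, eight
planted clusters — three long intronless (30/25/20 kb), two with long
first exons (40/15 kb), three short spliced (first exons 9/7.5/6 kb) —
twenty protein-coding genes, three decoy loci, and one million read
equivalents with a 0.7 fraction of 1U reads, 0.3 of 10A, and 10 %
two-location multimappers.

Choices worth explaining:

* **Abundances are compositional.** Because the pipeline normalizes to
  the unique-mapper count *of the emitted table*, planted RPM targets
  must sum (with background and decoys) to
  $10^6 (1-f/2)/(1-f)$ for multimapper fraction $f$; the defaults do, so
  measured abundances land on their targets (the residual common factor
  is stored as `rpm_scale` in the truth object). The eight targets rise
  monotonically with first-unit length while the promoter O/E CG targets
  fall — the joint pattern the correlation report is expected to recover
  at the sign level. Per-locus abundances of 2–24 % of the library are
  realistic for dominant pachytene clusters, which individually capture
  up to ~10 % of all piRNAs in adult testis.
* **Background density.** Diffuse background is 2 weighted reads per
  million per 20-kb window: scaling a real library's few-percent diffuse
  fraction over a ~2.5-Gb genome to a 20-kb window gives about 1 RPM, so
  2 is already generous. Denser backgrounds are unrealistic and
  eventually produce chance 3-read clumps in candidate flanks that the
  two-nearby-windows trimming rule was never designed to reject.
* **Short first exons of several kb.** At 200-bp bin resolution a
  promoter-confined peak (1 kb upstream to 600 bp downstream of the TSS)
  spans three downstream bins; short planted exons of 6–9 kb keep the
  relative extension of narrow-peak loci well below the 0.2 mark while
  remaining short by the 10-kb definition. Real clusters with few-hundred-bp
  first exons would saturate the relative index at any peak width — a
  limitation of the statistic itself at that scale, not of the
  implementation.
* **Deterministic signal tracks.** Tracks are a uniform nonspecific
  baseline plus additive enrichment domains; the default per-bin noise is
  zero, so background bins are *exactly* baseline and domain calls are
  deterministic. This is a deliberate idealization: with any i.i.d. noise
  shared between background and gene body, 5 % of gene-body bins exceed a
  95 % background quantile by construction, and the 19-bin gap bridging
  then chains spurious enrichment for kilobases. Passing tests on the
  default tracks therefore demonstrate correctness of the walk, the
  threshold and the cap — not robustness of the extension index to
  realistic noise, which should be assessed per dataset
  (`signal_noise_sd` turns noise on).
* **Promoter composition.** Promoter sequences (TSS ± 2 kb) are
  rejection-sampled from a CG-suppressed (or CpG-island-like) base
  composition until both the full window and the central ± 500-bp window
  the pipeline scores land in the planted O/E CG band.
* **Decoys.** One locus violates exactly one filter each: 50 RPM (below
  the abundance threshold), 500 RPM from only 50 distinct species
  (complexity filter), and 500 RPM without 1U/10A bias (signature
  filter).
* **Read identity.** Distinctness of read species is simulated as
  distinct `(start, end, strand)` tuples; no nucleotide strings are
  generated because the complexity filter needs only distinctness.

What the generator does **not** emulate: transposon content and
mappability structure, sequencing errors, fragment-level RNA-seq (splice
junctions are emitted directly with supports), pre-pachytene/hybrid
class labels (these are input metadata in real analyses), and realistic
noise correlation in signal tracks. Results on synthetic data validate
the machinery, not biological effect sizes.

Default problem sizes — 2 × 2 Mb, one million reads, eight clusters —
were chosen so that a complete simulate-and-analyze cycle is an
interactive-scale computation on a single core while every stage still
operates far from trivial regimes (thousands of windows, ~10^6-row
overlap joins).

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_config(seed = 1))
res <- analyze_simulation(sim)
res$matches            # recovery of the 8 planted clusters
res$features           # per-cluster feature table
res$correlations       # Spearman report with BH adjustment
```

## Coordinate conventions and I/O

In memory everything is Bioconductor-standard: `GRanges`, 1-based closed
intervals, `DNAStringSet` genomes. On disk, BED6/BED12, bedGraph and the
read/methylation TSVs are 0-based half-open and GTF is 1-based closed;
conversion happens only inside the readers/writers (via `rtracklayer`)
and is covered by round-trip tests in both directions. Mapped reads are
consumed as interval tables, not BAM: alignment is upstream of this
package's scope.

## Known limitations

* The two-nearby-windows trimming criterion admits alternative
  formalizations (e.g. measuring the 1000-bp closeness start-to-start
  rather than as the gap); they would shift boundaries by at most one
  100-bp window plus one gap.
* The extension index is fragile for genes whose first unit is smaller
  than a few bins, and its gap-bridging makes it sensitive to isolated
  super-threshold noise bins (see above).
* Manual curation of cluster models — merging fragmented calls, fixing
  TSSs against ChIP evidence — is intentionally out of scope; the
  provenance table exists to make such curation auditable.
* Pachytene/pre-pachytene/hybrid class labels are accepted as input
  metadata; inferring them would require a developmental time course.
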