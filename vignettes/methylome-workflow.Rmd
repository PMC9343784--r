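---
title: "Sliding-window differential methylation analysis with methslide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window differential methylation analysis with methslide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methslide)
```

## The analysis problem

methslide implements the downstream half of a whole-genome bisulfite
sequencing (WGBS) study of a factorial exposure design: four groups
(`SAL_SAL`, `METH_SAL`, `SAL_METH`, `METH_METH`, i.e. prenatal x postnatal
exposure, three biological replicates each), with methylation measured as
per-cytosine methylated/unmethylated read counts (Bismark-style cytosine
reports). The pipeline starts at those count tables — read QC, alignment and
methylation calling are upstream and out of scope — and produces:

* differentially methylated cytosines (**DMCs**) per two-group contrast;
* differentially methylated regions (**DMRs**) from 1-kb sliding windows,
  refined to significant 200-bp tiles;
* genomic-feature summaries (promoter / exon / intron / intergenic with a
  CpG-island overlay);
* cross-contrast comparisons: Venn partitions with hypergeometric overlap
  tests, Pearson correlation of methylation differences, z-scored
  clustering matrices, and GMT-based gene-set enrichment;
* meta-gene methylation profiles (5 kb upstream of the TSS, scaled gene
  body, 5 kb downstream of the TTS).

Because the study's raw sequencing data are not needed to exercise any of
this machinery, the package ships a synthetic methylome generator whose
spiked truth regions make every stage testable end to end.

## Statistical model

### DMC calling

Replicates are pooled within each group before testing, following the
study's combine-then-test strategy. For each CpG the pooled counts form a
2x2 table

|          | methylated | unmethylated |
|----------|-----------:|-------------:|
| group A  | $m_A$      | $u_A$        |
| group B  | $m_B$      | $u_B$        |

tested with a **two-sided Fisher exact test** (the source analysis names no
test; Fisher on pooled tables is the standard choice for replicate-pooled
WGBS and is exactly verifiable against enumeration). The two-sided p-value
sums all hypergeometric table probabilities not exceeding the observed one,
with the conventional $1 + 10^{-7}$ relative tolerance — identical to
`stats::fisher.test`, but vectorised. Only CpG-context sites with pooled
coverage **strictly greater than 10** in *both* groups are tested, matching
the stated ">10x depth" criterion literally. Benjamini–Hochberg adjustment
over the tested sites gives q-values; the significance flag defaults to
$q \le 0.05$. Differences are reported in percentage points as
$\Delta = 100\,(m_B/c_B - m_A/c_A)$ with B the treatment (second-listed)
group, so hypermethylation means "higher in treatment".

Two significance thresholds appear in the source analysis — $q \le 0.05$
for DMC counting and FDR < 0.01 for the CpG inside a DMR — and both are
kept as separate parameters (`q_max` in `call_dmcs()`, `sig_q` in
`call_dmrs()`) rather than reconciled.

Strands are never merged: cytosine reports are per-cytosine, and a + and a
− strand CpG at adjacent positions are distinct records throughout.

### DMR calling

Windows of 1,000 bp slide in 200-bp steps (the window size is stated by the
study; the step is a package choice, set to 200 bp so window phase aligns
with the 200-bp refinement tiles). Each window is evaluated against four
criteria *in order*, and the rejection log records the first failure:

1. at least 3 tested CpGs;
2. at least one CpG with $q < 0.01$;
3. mean methylation difference of at least 20 percentage points ("20%"
   difference is read as 20 points, the standard WGBS usage), with every
   qualifying ($q<0.01$) CpG concordant in sign with the window mean;
4. a combined window p-value, recorded for multiplicity control.

The combined p uses **Stouffer's signed-Z method** with weights
$\sqrt{\text{pooled coverage}}$: each CpG's two-sided p becomes
$z_i = \mathrm{sign}(\Delta_i)\,\Phi^{-1}(1 - p_i/2)$ and
$Z = \sum w_i z_i / \sqrt{\sum w_i^2}$. The study requires a region-level
p-value but names no combination method; Stouffer respects direction
concordance, which the criteria demand anyway.

Candidate windows are BH-adjusted genome-wide and kept at
$q_{\text{region}} \le 0.05$ (the looser raw $p < 0.05$ reading is
available via `multiplicity = "raw"`). Overlapping kept windows of the
*same* direction merge into maximal runs; opposite directions may abut but
never merge. Statistics of a merged region are recomputed over the union
of member CpGs. One deliberate refinement: when null CpGs lying between
strong windows dilute the union below the 20-point criterion, the run is
represented by its strongest member window (smallest combined p) instead of
being dropped — every member window satisfies all four criteria by
construction, so every *called* DMR re-checks cleanly, and spike-in
sensitivity is not sacrificed to a bookkeeping artifact of merging. The
merged region's $q_{\text{region}}$ is the minimum over member windows.

`refine_subregions()` intersects a DMR with genome-aligned 200-bp tiles and
keeps tiles retaining at least one $q \le 0.05$ CpG; those CpGs define the
DMR's DMC membership.

### Genomic annotation

Each region gets exactly one primary label with precedence
**Promoter > Exons > Introns > Intergenic**, decided by the region
*midpoint* (a 1-kb window can straddle features; the midpoint rule is
deterministic and order-independent; any-overlap is available as
`rule = "any"`). Promoters are `[TSS - 2000, TSS + 200)` on the gene's
strand — the study never defines "promoter", so the extent is a documented
convention and configurable. CpG islands are an *overlay flag* (>= 1 bp
overlap), not a fifth category: in the published distribution table the
four primary categories already sum to the DMR total, which forces this
reading. Percentages mirror the published rounding: percent-of-total to 2
decimals, hyper/hypo percent of the row count to 4 decimals.

Gene assignment prefers an overlapping gene, otherwise the nearest TSS
within 10 kb; ties break by distance, then lexicographic gene id, and are
flagged.

### Cross-contrast comparisons

DMC sets from two contrasts are keyed by (chrom, position, strand). The
overlap p-value is upper-tail hypergeometric,
$P[X \ge n_{\text{common}}]$ with $X \sim \mathrm{Hyp}(N, |A|, |B|)$, where
the universe $N$ counts sites *tested in both contrasts* — the most
conservative defensible universe, since the source never states one; it is
a parameter. Correlations of per-site differences are computed on two
scopes and both are reported: `union` (DMC in either contrast; the literal
reading of "all CpG sites that were differentially methylated in" either
condition) and `common` (DMC in both). The p-value uses the t transform
$t = r\sqrt{(n-2)/(1-r^2)}$.

Clustering matrices are per-sample methylation levels at the chosen sites,
row z-scored (constant rows dropped with a warning), and clustered with
Euclidean distance and **complete linkage** — the pheatmap default, since
the study clustered with pheatmap without stating a linkage.

Gene-set enrichment is upper-tail hypergeometric per GMT set against a
user-supplied universe with BH adjustment — a generic framework; no GO/KEGG
database content is shipped.

### Meta-gene profiles

The axis is 50 upstream flank bins (100 bp each, 5 kb total), 60 equal
bins across the gene body, and 50 downstream bins. Minus-strand genes use
the exact mirror of the plus-strand bin boundaries with the axis reversed,
so bin 0 is always biological upstream; flipping every gene's strand
therefore reverses the profile exactly, which the tests assert. Bin means
are coverage-weighted by default (unweighted means are one parameter away);
a site overlapping several genes contributes to each; genes with bodies
shorter than the bin count are skipped with a warning. The bin counts are
package choices — the study states only the 5-kb flank extent — and whether
its profiles were coverage-weighted is unknown.

## The synthetic methylome generator

`sim_config()` fixes the study conditions: 2 chromosomes x 1 Mb, 60 genes,
4 groups x 3 replicates, mean coverage 30x (negative binomial, size 10 —
moderate depth overdispersion typical of WGBS), beta-binomial methylated
counts with correlation parameter 0.05, island CpG density 10x background
with ~15% of CpGs in islands, baselines 0.60 (background CpG), 0.30
(island CpG) and 0.005 (CHG/CHH — non-CpG methylation is low in adult
brain, and these sites exist mainly to exercise the context summary).
Baselines sit far enough from 0 and 1 that the default 30-pp spike fits in
either direction; the config validates this.

Spiked truth regions are 1-kb spans with at least three background CpGs
(island CpGs are avoided so shifted means stay in range), disjoint, with
at least two window-widths of separation so distinct truth regions can
never be merged into one call. Directions are balanced 50/50 per factor.
Factors map to group-mean shifts:

| factor        | shifted groups                          |
|---------------|-----------------------------------------|
| `pre`         | METH_SAL, METH_METH                     |
| `post`        | SAL_METH, METH_METH                     |
| `interaction` | METH_METH only                          |
| `exposure`    | METH_SAL, SAL_METH, METH_METH           |
| `reversal`    | SAL_METH (+), METH_METH (−)             |

`pre`/`post`/`interaction` are the factorial design. `exposure` and
`reversal` generate the *structured cross-contrast scenarios*: `exposure`
shifts every METH-exposed group together, so the prenatal and postnatal
contrasts see the same effects with the same sign (strongly positive
union- and common-scope correlations); `reversal` encodes a postnatal
response that prenatal exposure inverts, giving the postnatal vs
pre-and-postnatal pair strongly negative correlations. These mirror, at
the level of sign, the positive and negative cross-contrast correlations
the source study reports.

A second, purely structural source of correlation is worth knowing about:
the two published contrast pairs each share one group (the first pair
shares the SAL_SAL control; the second shares SAL_METH, entering the two
deltas with opposite signs). Shared-group sampling noise alone therefore
pushes the first pair's correlation positive and the second's negative
even for disjoint factorial spikes — the default fixture shows r around
+0.6 / −0.6 on the union scope from this effect plus the interaction
spikes. The `exposure`/`reversal` scenarios add genuinely shared biology
on top and are what the acceptance checks use.

What the generator does *not* emulate: read-level data (no FASTQ, no
bisulfite-conversion error), alignment artifacts, spatial correlation of
methylation along the genome beyond the spiked regions, missing sites
(unless `dropout > 0`), and replicate-specific global shifts. Passing
tests therefore demonstrate the correctness of the statistics and
plumbing under a clean factorial signal, not robustness to alignment or
batch pathologies of real WGBS.

## Numerical and operating choices

* **Coordinates.** Internally 0-based half-open everywhere; cytosine
  reports are 1-based and converted only at I/O. This removes the
  off-by-one ambiguity that region definitions otherwise invite.
* **Determinism.** The generator derives all randomness from the config
  seed (each operation re-seeds with a fixed offset, so results do not
  depend on call order); everything downstream of the counts is
  deterministic, and `run_pipeline()` reruns byte-identically.
* **Degenerate inputs.** Fisher tables with a zero margin return p = 1;
  an all-zero 2x2 likewise; empty DMC tables give empty DMR sets; a DMR
  left without any significant CpG after merging is flagged by
  `refine_subregions()`; constant rows are dropped before clustering;
  zero-coverage contexts report a missing level.
* **Type-I calibration.** The null calibration check runs on binomial
  counts (dispersion 0), where "no difference" is exactly true and the
  nominal level of the pooled Fisher test is defined; the observed
  q<=0.05 call rate is ~0 over >10^4 CpGs. With the default replicate
  overdispersion (rho = 0.05) the pooled test flags ~5% of null sites at
  q<=0.05: those are *real* pooled differences created by replicate-level
  random effects, the known cost of the pool-then-test strategy (which
  the source study also uses). Replicate-aware dispersion modelling
  (beta-binomial regression, smoothing-based callers) is deliberately out
  of scope.
* **Problem sizes.** The test and acceptance runs use 1–2 chromosomes of
  1 Mb (~10–23k CpGs, 12 samples), 20 truth regions per factor for
  benchmarks and 10 x 3 small replicates for the effect-size monotonicity
  check — sizes chosen so the full suite exercises every stage in a few
  minutes while keeping Monte-Carlo tolerances (3 SE bands) meaningful.

## Worked example

```{r example, eval = FALSE}
library(methslide)

cfg <- sim_config(seed = 1)
fx  <- make_fixture("fixture", cfg)         # 12 cytosine reports + truth
res <- run_pipeline(fx$config_path)          # full analysis, TSV outputs

res$dmr[["SAL_SAL-vs-METH_SAL"]]             # called DMRs, pre contrast
dmr_benchmark(res$dmr[["SAL_SAL-vs-METH_SAL"]],
              fx$truth[fx$truth$factor_id == "pre"])
```

On the default fixture the prenatal contrast recovers 20/20 spiked
regions with no false calls (bp-level Jaccard ~0.7 — called spans extend
up to one window beyond the 1-kb truth span, which bounds the Jaccard
below 1 by construction).

## Known limitations

* Pooling discards replicate-level variance; effect sizes at marginally
  covered sites are noisy and the q-values are calibrated only under the
  binomial model (see above).
* DMR boundaries are window-quantised (200-bp phase); true region edges
  are recovered only to within a step.
* The hypergeometric overlap universe and the correlation site scope are
  both choices the source leaves open; both are parameters and both
  readings are reported where they matter.
* The enrichment framework ships no pathway databases; results are only
  as meaningful as the supplied GMT and universe.
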