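---
title: "Detecting and dating ancient gene duplications from transcriptome Ks distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating ancient gene duplications from transcriptome Ks distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksdup)
```

## The model

Whole-genome duplications (WGD, paleopolyploidy) and bursts of single-gene
duplication leave a statistical footprint in any transcriptome: pairs of
paralogous transcripts whose synonymous divergence Ks — substitutions per
synonymous site — clusters around the age of the event. Because synonymous
changes are largely invisible to selection, Ks accumulates roughly
clock-like, so the distribution of pairwise Ks over all paralog pairs is a
paralog *age* distribution: a large excess near Ks = 0 from ongoing
duplication and recent retention, a diffuse background from the birth–death
of small families, and — when WGDs occurred — distinct peaks at the Ks depth
of each event.

`ksdup` implements this analysis end to end for an assembled transcriptome
(CDS/transcript FASTA):

1. **Homology.** All-vs-all nucleotide similarity search (seed-and-extend,
   exact affine-gap local alignment on triggered candidates) and
   reciprocal-hit pairing at an e-value ceiling of 1e-20. All reciprocal
   hits are retained, not only best hits: a gene retained through several
   WGD rounds has several genuine paralogs, and restricting to best hits
   would erase the older peaks.
2. **Ks estimation.** Per pair: six-frame longest-ORF selection,
   protein-guided codon alignment, Nei–Gojobori site counting and
   Jukes–Cantor correction, with explicit rejection reasons
   (`saturated`, `too_few_sites`, `antisense`, `no_orf`).
3. **Peak detection.** Univariate Gaussian mixtures with unequal variances
   fitted by EM for every component count k in 1–10; the model with the
   lowest BIC, `-2 logLik + (3k - 1) log n`, is selected and component
   means are reported as duplication peaks, partitioned into *recent*
   (mean ≤ 0.1) and *ancient* (mean > 0.1).
4. **Significance.** A SiZer map — SIgnificant ZERo crossings of
   derivatives — classifies the smoothed density's slope at every
   (location, bandwidth) cell as significantly increasing, decreasing, or
   flat at level alpha = 0.05; a peak is *significant* when an increase run
   is followed (possibly across flat cells) by a decrease run.
5. **Dating.** Peak ages under a constant synonymous substitution rate,
   by default the classic dicot background rate of 1.5e-8 substitutions
   per synonymous site per year.

## The Ks estimator

For a codon alignment, every gap-free, N-free, stop-free codon column
contributes to four totals. Each codon position contributes a fraction
`f = (synonymous one-step changes at that position) / 3` of a synonymous
site, averaged over the two sequences' codons, so `S + N = 3 ×` (number of
counted columns) exactly. Differences between codons differing at `d`
positions are classified by averaging over all `d!` orderings of the single
steps, discarding orderings that pass through a stop codon (if all
orderings are blocked, all are used). This is pathway-averaged, unweighted
counting: no transition/transversion or codon-usage weighting, which keeps
the estimator transparent and exactly testable against brute-force pathway
enumeration over all 61 × 61 sense-codon pairs.

The observed synonymous difference proportion `p_s = Sd / S` is corrected
for multiple hits with the Jukes–Cantor formula

    Ks = -(3/4) ln(1 - (4/3) p_s)

which is undefined at `p_s >= 3/4`: such pairs are *saturated* — too
divergent for the substitution model — and are rejected rather than
extrapolated. There is no additional Ks ceiling below saturation. Pairs
with fewer than `min_sites = 10` synonymous sites are rejected as
uninformative (tiny alignment overlaps otherwise produce wild Ks values);
the floor is exposed as a parameter.

### Reading frame and alignment

Transcriptome assemblies are unoriented and often partial, so each sequence
is trimmed to the longest stop-free codon run over all six frames (ties:
forward strand, lowest frame), requiring at least 30 codons. The two
translations are aligned globally under BLOSUM62 with affine gaps (open 10,
extend 0.5 per residue) and the alignment is back-mapped so each residue
gap becomes one 3-nt gap — codon structure is preserved by construction.
Pairs whose only similarity is on opposite strands are flagged antisense
and excluded from Ks: a codon alignment of an antisense artifact would be
meaningless.

## The similarity search

The built-in search indexes all exact 11-mers (both strands of the subject
set), probes each candidate pair with an ungapped X-drop extension
(x_drop = 20) from one seed per diagonal, and computes a full affine-gap
local alignment with traceback once the ungapped score reaches a trigger
of 25. Scoring is match +1, mismatch −2, gap of length L costing 5 + 2L;
raw scores are converted to e-values with the Karlin–Altschul formula
`E = K m n exp(-lambda S)` using the published parameters for this scheme
(lambda = 1.28, K = 0.46) and the total residue count of the set as the
database size. The trigger score is far below the score needed to reach
the 1e-20 ceiling at realistic set sizes (roughly 50), so the pre-filter
does not remove reportable hits unless an alignment is extremely
gap-dense; the gapped stage is banded over the pair's seed diagonals plus
64 on each side, with out-of-band cells treated as fresh zero-score local
starts, so the reported score never exceeds the exact optimum and equals
it whenever the optimal path stays inside the band (always, in practice,
for the substitution-dominated divergence this pipeline targets).
Word size, scores, trigger, band and e-value parameters are all exposed.
For interoperability, hits can also be read from and written to the
standard 12-column tabular format.

## Mixture fitting and model selection

EM uses unequal per-component variances (peak width grows with age), a
quantile-spread initialisation (k means at evenly spread quantiles,
standard deviations `sd(x)/k`, uniform weights) plus 9 jittered restarts,
iterates to a relative log-likelihood change below 1e-8 (at most 500
iterations), and floors component standard deviations at 1e-4 so duplicated
values cannot collapse a component. Log-likelihood is monotone across
iterations — asserted per iteration in the tests. BIC uses `p = 3k - 1`
free parameters; ties within 1e-6 go to the smaller k. Fitting is on raw
Ks values: the sample is non-negative, but no truncation correction is
applied — a plain normal-mixture reading. The 0.1 recent/ancient cutoff is
exposed rather than hard-coded, because the boundary between "ongoing
duplication" and the youngest discrete event is a biological judgement:
a mixture can legitimately place a component just above the cutoff (e.g. a
mean of 0.12) that is neither clearly recent nor one of the well-separated
ancient peaks, and the package reports the partition without guessing.

## The SiZer map

For each grid location x and bandwidth h, the Gaussian-kernel density
derivative estimate is the sample mean of `-(x - X_i)/h^2 · phi((x - X_i)/h) / h`,
and its standard error is the sample standard deviation of those
evaluations divided by sqrt(n). Simultaneous inference across each row
uses the independent-blocks quantile with `m(h) = range / (2h)` blocks:
`q = Phi^{-1}((1 + (1 - alpha)^{1/m}) / 2)`. Cells where fewer than 5
observations fall within ±2h are coded SPARSE rather than classified. The
default grids are 201 equal steps over `[0, max(Ks)]` and 21 log-spaced
bandwidths spanning `[range/100, range/2]`. Peaks are reported at the
smallest bandwidth exhibiting the increase-then-decrease pattern, and
overlapping intervals across bandwidths are merged. Raising alpha can only
promote FLAT cells to significant, never the reverse — a monotonicity the
tests exercise directly.

## Dating convention

Ages are computed as `age = Ks / rate`. Under this convention the
canonical peaks at Ks 0.27, 0.51 and 0.91 date to 18, 34 and 60.7 Myr at
rate 1.5e-8. The alternative per-lineage convention `Ks / (2 rate)` —
appropriate when the rate is calibrated per lineage rather than per
diverging pair — halves every age and is available via `per_lineage = TRUE`.
The package reports unrounded ages and a two-significant-figure display
column.

## The simulator

`simulate_duplicated_transcriptome()` provides ground truth the real data
cannot: for every (family, depth) combination an independent ancestral
stop-free CDS (starting ATG) is duplicated, and the copy is separated from
the ancestor by planting substitutions until the pairwise synonymous
difference proportion matches the Jukes–Cantor inversion of the target
depth, `p_s = (3/4)(1 - e^{-4d/3})`. Synonymous changes are placed only at
positions where a single-base change is synonymous — so Nei–Gojobori
counting sees exactly the planted signal — and nonsynonymous changes are
added at relative rate `omega = 0.2`, enough contamination to exercise the
protein-guided alignment without degrading it. Divergence is planted
pairwise (not per lineage), consistent with the `Ks / rate` dating
convention. Defaults are 150 families per depth, depths {0.27, 0.51,
0.91}, 500-codon genes.

Ancestors are drawn independently per (family, depth), so the only
detectable paralogy is the planted one and the truth table is exact. This
is a deliberate simplification: the simulator emulates the *statistical
structure* the analysis assumes — Ks concentrated at known depths over a
clean background — not the full biology of real transcriptomes. It has no
indel evolution, no gene-family birth–death, no transcript isoforms or
assembly chimeras, no codon-usage bias, and no among-site rate variation.
Passing recovery tests therefore demonstrate that the pipeline's inference
machinery is correct and unbiased on data satisfying its own model; they do
not certify performance on real assemblies, where alignment error,
fractionation and rate heterogeneity blur peaks.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_duplicated_transcriptome(seed = 1)
report <- run_duplication_scan(sim$records, out_dir = "dupscan_out", seed = 1)
report$summary$ancient_peaks   # mixture means above the 0.1 cutoff
report$peaks_dated             # ages under the 1.5e-8 clock
significant_peaks(report$sizer)
```

## Numerical choices and degenerate inputs

* Alignment tie-breaks are deterministic (diagonal preferred over gaps in
  traceback; consensus ties resolved A < C < G < T < gap), so every output
  is byte-reproducible for a fixed seed.
* Columns containing N or a gap are wholly excluded from site counting;
  codons containing N translate to X.
* An all-identical sample fits k = 1 with the floored standard deviation
  and a finite log-likelihood.
* Zero viable pairs produce a structured report with empty downstream
  sections (and a nonzero exit code from the command-line wrapper) rather
  than an error cascade.
* Fewer than 5 viable pairs skip the mixture stage; fewer than 50 skip the
  SiZer stage, which needs a meaningful density estimate.

## Test problem sizes

The test suite validates each stage against independent oracles:
brute-force pathway enumeration over all 61 × 61 sense-codon pairs;
`Biostrings::pairwiseAlignment` as the exact alignment oracle (local DNA
on sequences up to 400 bp, global protein); a quadratic mutual-edge scan
for reciprocal pairs; `mclust` as an independent EM implementation; and
closed forms for N50, Jukes–Cantor and the clock. Parameter recovery runs
the full pipeline on 20 seeded replicates of the default simulation (150
families per depth at {0.27, 0.51, 0.91}, 500-codon genes, 900 transcripts
per replicate) and requires every detected ancient peak within ±0.07 of a
planted depth in at least 18 of 20, with a significant SiZer interval
covering the densest planted peak. Mixture model selection is checked on
1500-point unimodal and well-separated bimodal samples over 20 seeds
(k_max = 6, 4 restarts) with the same 18/20 bar.

## Limitations

* The Ks estimator is Nei–Gojobori + Jukes–Cantor by design: simple,
  exactly testable, and adequate for locating peaks. It ignores
  transition/transversion bias and codon usage, which shift absolute Ks
  values on real data; maximum-likelihood codon models are out of scope.
* Mixture components are Gaussian on raw Ks; strongly skewed old peaks can
  absorb background or split.
* The constant-rate clock inherits all caveats of its calibration; ages
  should be read as orders of magnitude anchored to the chosen rate.
* The similarity search is designed for transcriptome-scale inputs
  (thousands of sequences), not genome-scale databases.
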