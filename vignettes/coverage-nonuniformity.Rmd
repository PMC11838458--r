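---
title: "Diagnosing coverage non-uniformity in RNA-Seq: methods and design"
author: "covvalley authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing coverage non-uniformity in RNA-Seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covvalley)
```

## The problem

Fragment coverage along a transcript in bulk (and single-cell) short-read
RNA-Seq is far from uniform: even libraries built from intact, full-length
transcripts show broad, reproducible hills and valleys, overlaid with
base-scale wiggles. These artifacts degrade isoform-level quantification and
complicate any analysis that treats per-base coverage as a signal.
`covvalley` provides the statistics used to *diagnose* the candidate
mechanisms — fragmentation position bias, random-hexamer end preference,
GC-dependent PCR amplification, 3' degradation under polyA selection, and
alignment ambiguity — together with a ground-truthed simulator of the library
preparation chain, so that every diagnostic can be validated against planted
biases before being pointed at real data.

The package deliberately works on **single-isoform genes in transcript
coordinates**: with one isoform there are no junctions in the transcriptome,
the region between the outer ends of a read pair is guaranteed covered, and
coverage non-uniformity cannot be an isoform-mixture effect. Throughout the
package coordinates are **0-based, half-open**; GTF input (1-based, closed)
is converted once, inside `load_annotation()`.

## Gene selection

`load_annotation()` keeps only genes with exactly one annotated transcript;
`select_genes()` then applies the analysis filter: transcript length between
600 and 7000 bases (both bounds inclusive), biotype `protein_coding` or
`lncRNA`, ranked by deduplicated fragment count with ties broken
lexicographically by gene id, keeping the top `n` (default 100). Ranking by
raw deduplicated count rather than a length-normalized measure is a
deliberate, configurable choice: the quantity that matters for these
diagnostics is the per-gene fragment depth actually available.

## Coverage tracks

`fragment_coverage()` increments every position between the start and end of
each (deduplicated) fragment. Derived variants:

* `smooth_track(track, sigma = 30)` — discrete Gaussian convolution with the
  kernel truncated at ±4σ (mass lost < 1e-4). At the transcript edges the
  truncated kernel is **renormalized over the in-bounds support** rather than
  reflected or zero-padded. This preserves constants exactly — zero-padding
  would carve artificial valleys at the transcript ends that the valley
  detector would then report. Internally the mean-centered signal is
  convolved so constant tracks survive FFT round-off bit-exactly.
* `normalize_track()` — per-gene, per-sample scaling to [0, 1] by the
  maximum.
* `residual_track()` — raw minus smoothed; isolates the base-scale wiggles.
  `residual + smoothed = raw` holds to 1e-9 relative.
* `pairwise_correlation()` / `local_correlation()` — replicate concordance of
  full or residual coverage. Read-depth normalization divides each gene's
  track by its own mean, making the statistic gene-local. Genes are
  concatenated by default; a per-gene-average variant is provided because the
  choice is not forced by anything in the method. Zero-variance inputs give
  `NA`, never a silent 0.

## Valleys and the global valley score

Valley detection operates on the smoothed track. All local maxima are
located (plateaus contribute their leftmost index, for determinism; the track
endpoints are eligible as bounding maxima, since otherwise valleys adjacent
to the transcript ends would be invisible). For each pair of **adjacent**
maxima, the minimum between them is a valley iff the drop from minimum to
*both* maxima is at least 10% of the gene's mean smoothed coverage — one
consistent mean, used again for normalization below.

The *local valley score* is the water the valley could hold:

$$ w = \sum_{i \,\text{between peaks}} \max\bigl(0,\ \min(\text{left},
\text{right}) - \mathrm{cov}_i\bigr) $$

and the *global valley score* (gvs) of a gene is the total water over all its
valleys, normalized by mean smoothed coverage × transcript length. The gvs
is invariant under positive scaling of coverage and is 0 for constant or
monotone tracks.

Two consequences of the adjacent-maxima rule are worth knowing. First, no
merging is performed across sub-threshold intermediate maxima, so a broad
valley whose floor contains noise-level micro-maxima can be fragmented into
sub-threshold pieces and missed entirely; flat-floored, step-edged valleys
under Poisson noise are the degenerate case. Smooth-walled valleys — the
shape the smoothing bandwidth produces from real fragment data — are
detected reliably. Second, the per-base `max(0, ·)` in the water sum is
mathematically a no-op between bounding maxima and exists purely as a
numerical guard.

`classify_regions()` divides the smoothed value range of a gene into thirds:
*low* regions are the portions of valleys in the bottom third; *high* regions
are neighborhoods (±50 bp, a documented constant — nothing in the method
fixes it) of the valleys' bounding maxima in the top third.

## 3' bias fit and correction

PolyA selection of degraded RNA inflates coverage toward the 3' end. Against
a low-bias reference sample (an unselected library, or the highest-integrity
sample available), the natural-log coverage ratio is regressed by OLS,
pooling all genes with one shared coefficient set:

$$ \log\frac{\mathrm{cov}_s(i)}{\mathrm{cov}_{ref}(i)} =
\beta_0 + \beta_d\, d + \beta_r\, r + \beta_{dr}\, d r $$

with \(d\) the distance from the 3' end in bases and \(r = i/L\) the relative
position from the 5' end. Positions with zero coverage in either track are
excluded. `correct_3prime_bias()` divides coverage by the fitted factor;
valley scores of polyA/degraded samples should be computed on the corrected
track.

Two practical constraints on the *design* of a recovery experiment (enforced
with an informative error where detectable):

* **Length variation is required.** Within a single gene of length \(L\),
  \(d = (L-1) - rL\) is an exact linear function of \(r\), so with all genes
  the same length the design matrix is aliased and the decay cannot be
  attributed. The fit refuses aliased designs.
* **Depth must keep the faintest positions observable.** The zero-exclusion
  rule truncates the log-ratio distribution wherever expected coverage drops
  toward ~1 read, biasing the slope toward zero. At the desk-scale depth used
  in the tests (2000 fragments/gene), transcripts are drawn from 600–3000
  bases with equal expression so that \(\delta d \le 3\) at
  \(\delta = 0.001\)/base and expected coverage stays well above the
  truncation regime; lengths up to 7000 at this depth visibly flatten the
  recovered slope.

## Fragment-end sequence preference (hexamer-priming bias)

Random-hexamer priming leaves a base-composition signature at fragment ends.
`build_pwms()` tallies the first and last 12 bases of every fragment (in
transcript orientation) into start/end position-frequency matrices, with a
pseudocount of 1 per cell; 12 and the pseudocount are documented constants.
Frequencies (not log-odds against background) are used, with scores in log
base 2.

The composite score at a boundary is the log2-likelihood of the next 12
bases under the start PWM minus that of the previous 12 bases under the end
PWM — the net propensity for coverage to rise across the boundary. It is
correlated (Pearson) with the coverage delta across the same boundary after
removing the smoothed trend, gene by gene.

Significance uses a column-permutation test: each of `n_perm = 100`
permutations shuffles the 12 position columns of both PWMs (contents intact)
and recomputes every gene's correlation against the *same* shuffled pair —
the permutation acts on the PWM, not per-gene data, so the null preserves
both the matrices' base composition and the autocorrelation of coverage.
One-sided add-one p-values, \(p = (1 + \#\{r_{perm} \ge r_{obs}\}) /
(1 + n_{perm})\), never return exactly 0; an undefined observed correlation
reports \(p = 1\). Because the PWMs are estimated from the same library they
are tested on, the null is mildly anti-conservative at very low per-gene
depth; the calibration check in the test suite quantifies this.

## PCR duplicates

`dedup_fragments()` collapses raw copies by the exact key (transcript,
start, end, UMI). This is simpler than directional UMI-network methods: the
simulator emits error-free UMIs, so an edit-distance network would never
fire; on real data with sequencing errors it will slightly over-count
distinct molecules, which is documented rather than hidden.

* `positional_dupe_rate()` — at each position, the fraction of overlapping
  deduplicated fragments seen in ≥2 copies; undefined (`NA`) where nothing
  overlaps.
* `gc_binned_dupe_rate()` — duplicate rate in 5%-wide bins of first-read GC
  (left-closed, final bin closed). For trend statistics, bins with fewer
  than ~20 fragments carry no stable rate estimate and are excluded from
  the occupied-bin set.
* `dupe_coverage_association()` — both tracks are smoothed (σ = 30),
  adjacent-differenced, and rank-correlated (Spearman) where the rate was
  originally defined. Undefined gaps are linearly interpolated before
  smoothing (Gaussian smoothing needs contiguous input) and re-masked after.
  Whether the duplicate-rate track should itself be smoothed is genuinely
  ambiguous; both are smoothed by default and a toggle is provided. Across
  genes, per-gene correlations are tested against zero with a **two-sided**
  one-sample Wilcoxon signed-rank test (the direction is an empirical
  finding, not an assumption).

## Mappability of peaks versus valleys

`extract_probes()` samples 100-bp windows uniformly from classified low/high
regions (intervals shorter than the probe are skipped; overlaps are allowed
— nothing in the procedure forbids them). `count_placements()` counts exact
full-length placements of the probe or its reverse complement across the
reference (palindromes counted once); unique ⇔ count = 1. Exact matching
replaces an external spliced aligner: for the peak-versus-valley contingency
logic on a transcriptome reference, mismatch tolerance adds nothing but an
external dependency, and the divergence is documented.

`fisher_exact()` is a direct hypergeometric enumeration. The two-sided
p-value follows the probability-ordering convention (all tables with
probability ≤ observed, with 1e-7 relative slack for floating-point ties);
the odds ratio is the sample odds ratio \(ad/bc\), `Inf` when \(bc = 0\).
One-sided tails are available: for the canonical published peak/valley table
(805/29 unique/multi in peaks vs 493/32 in valleys) the upper-tail test is
what reproduces the reported p = 0.017, while the two-sided convention gives
0.031 — users comparing against reported values should mind the sidedness.

## The synthetic library generator

`bias_config()` + `make_transcriptome()` + `simulate_library()` emulate the
preparation chain per molecule, with every bias planted and recorded in a
`TruthBundle`:

1. **Transcriptome** — single-exon, single-isoform genes, i.i.d. bases at a
   per-gene target GC (optionally a sinusoidal within-gene GC wave, which
   turns GC-dependent amplification into a positional driver), lengths
   uniform in range. Defaults follow the study conditions: lengths within
   600–7000, top-100-style gene counts, 13 PCR cycles, 5% GC bins, σ = 30,
   PWM width 12, probe width 100, 100 permutations.
2. **Expression** — gene drawn ∝ lognormal weights (meanlog 0, sdlog 1 by
   default; recovery experiments use equal expression to isolate positional
   effects).
3. **3' degradation** — each molecule survives as a 3'-side suffix of length
   `Exponential(δ)` capped at `L`, so the chance that the position at
   distance `d` from the 3' end is retained is exactly `exp(-δd)` — the
   functional form the correction regression assumes. Candidate fragments
   are drawn over the full transcript and *discarded* when they leave the
   surviving suffix: degradation therefore reduces a molecule's fragment
   yield proportionally. (Renormalizing the start distribution onto the
   surviving interval instead would make yield independent of degradation
   and destroy the exponential coverage profile.)
4. **Fragmentation and size selection** — uniform starts, Normal(200, 40)
   lengths rounded and clipped at the 3' end, kept if within the 100–400
   size-selection window. These are field-typical values; nothing in the
   method fixes them.
5. **Positional propensity** — a trough profile
   \(1 - a \sum_j e^{-(p - c_j)^2 / 2w^2}\) evaluated at the fragment
   **midpoint** acts as a retention probability. Midpoint (rather than
   start) anchoring makes the planted trough center coincide with the
   resulting coverage-valley center; start-anchored weighting would displace
   the valley by about half a fragment length, decoupling the planted truth
   from what the detector is asked to find.
6. **End preference** — fragments are accepted by rejection sampling with
   probability ∝ the PWM likelihood of their first and last 12 bases
   (normalized by the maximal column product so probabilities are ≤ 1). A
   persistent acceptance rate below 1e-3 aborts with advice to weaken the
   PWM. With a uniform background the accepted fragments' end composition
   equals the planted PWM exactly, which is what makes PWM recovery a sharp
   test.
7. **UMI** — an i.i.d. random 8-mer per molecule (error-free by design).
8. **PCR** — `E` cycles of a Galton–Watson branching process: each existing
   copy duplicates per cycle with probability `e(GC)`, a logistic function
   of fragment GC. `e ≡ 1` doubles deterministically; expected pool size per
   molecule is \((1+e)^E\).
9. **Sequencing** — `depth` copies drawn *without replacement* from the
   amplified pool, so duplicates arise only through amplification, matching
   UMI semantics. Molecules are generated until the pool holds
   `oversample × depth` copies (default 3), so sequencing samples about a
   third of the library; sequencing an entire pool would mechanically
   inflate duplicate rates.

What the simulator does **not** emulate: base-call errors and quality
scores, UMI errors, multi-isoform genes, rRNA contamination and depletion
chemistry, real hexamer-priming chemistry beyond the end-PWM acceptance, and
— because sequences are i.i.d. — the repeat structure that drives real
multi-mapping. Consequently, passing recovery tests demonstrates that the
*statistics* correctly invert the *modeled* mechanisms at realistic depth
and noise; they do not certify behavior on real libraries where several
mechanisms act at once and the sequence composition is structured.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each recovery is statistically
comfortable: decay recovery at 50 genes × 2000 fragments/gene; PWM recovery
at 10,000 fragments; permutation power at 20 genes and calibration at 200
genes × 100 permutations; GC-trend recovery at 50,000 fragments over 40
genes spanning GC 0.35–0.65; valley-score separation over 20 independent
seeds per condition at 12 genes × 5000 fragments/gene. Every stochastic
step takes an explicit seed and the whole pipeline — simulation, export,
analysis — is bit-for-bit reproducible given one.

## Known limitations

* The exact-key deduplication over-splits duplicate groups under real UMI
  sequencing errors.
* The valley detector's no-merging rule can fragment broad noisy valleys
  (see above); a persistence-based merger is a possible extension, not
  implemented to keep the statistic exactly as defined.
* The 3'-bias fit shares coefficients across genes by construction; per-gene
  decay heterogeneity is averaged, not modeled.
* Exact-match mappability is blind to near-exact repeats that a mismatch-
  tolerant aligner would report as multi-mapping.
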