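---
title: "Models and methods behind mejamir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mejamir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mejamir` analyses small-RNA sequencing of a four-timepoint
methyl-jasmonate elicitation design (CK/T1/T2/T3, two replicates each).
This vignette documents the statistical models, the tunable parameters
and their defaults, the synthetic-data generator's design, and the
numerical and design choices a maintainer should know about.

## Read cleaning

Cleaning applies seven rules in a fixed order (low quality → N →
missing 3′ adapter → 5′ adapter present → empty insert → polyA →
length), each read stopping at the first rule it violates, so the
per-library filter report partitions the raw reads exactly. Parameters:

* **Quality rule** — more than one base with Phred score ≤ 20 rejects
  the read. The threshold is inclusive and the count threshold is one
  base, i.e. a single low-quality base is tolerated.
* **Adapter location** — exact match of the leading 8-mer of the 3′
  adapter, first occurrence. Allowing a mismatched seed would rescue a
  small fraction of reads at the cost of non-deterministic trimming;
  exactness keeps the preprocessing byte-reproducible, which the
  pipeline's determinism contract relies on.
* **polyA** — an insert is polyA when ≥ 80 % of its bases are A *or* it
  ends in a run of ≥ 10 A's. The rule is applied to the insert (after
  adapter trimming), since an untrimmed read always carries non-A
  adapter sequence.
* **Length** — retained inserts are 18–30 nt, matching the size range
  a small-RNA library preparation purifies; shorter and longer inserts
  get their own rejection bins.

Only Phred+33 qualities are accepted; a quality character above `]`
(score 60) aborts parsing with an explicit message rather than guessing
a Phred+64 dialect.

## Tag classification

The removal cascade mirrors standard small-RNA annotation practice:
non-coding RNA first, then transcriptome-derived material, then the
mature-miRNA search, then the novel screen. Two choices deserve note:

* The mature search tolerates ≤ 2 mismatches without indels, with both
  tag ends within ± 2 nt of the reference ends — the common tolerance
  for mature-miRNA matching; the multi-hit tie goes to the
  alphabetically first reference id, deterministically.
* The spec-level ordering places mRNA-degradation removal *before* the
  mature search but defines degradation fragments as transcriptome
  matches "without hairpin acceptance", which is only decidable by
  running the hairpin screen. We therefore evaluate the hairpin screen
  once for every transcriptome-mapped tag: > 10 loci ⇒ repeat-excluded,
  mapped and hairpin-rejected ⇒ mRNA fragment, mapped and
  hairpin-accepted ⇒ survives to the mature search and, failing that,
  becomes a novel candidate.

### The fold model

The hairpin screen folds two windows around the mapped tag (tag ± 20 nt
on one side and 150 nt on the other) with a maximum-weight
nested-pairing dynamic program: pair weights GC = 3, AU = 2, G:U = 1,
minimum hairpin loop 3 nt; the score is the negated total weight. This
is a deliberately simple surrogate for a thermodynamic folder — it
ranks stems by paired mass, which is all the acceptance thresholds
need. The thresholds (≥ 14 tag bases paired to the opposite arm, ≤ 4
unpaired, window score ≤ −18) are fixture-calibrated constants of this
package, not estimates of any external tool's behaviour. Traceback is
deterministic: the left end of an interval pairs whenever pairing
attains the optimum, to the outermost equal-scoring partner, so equal
seeds give identical structures.

## Quantification

TPM is tag count over the library's **total clean-tag count** × 10⁶ —
the total over all categories, not just miRNA-mapped tags, which is the
literal reading of the normalisation the pipeline targets. Two
invariants are tested: Σ TPM = 10⁶ when every clean tag is counted, and
scale invariance in (count, total).

## Differential expression

The exact two-library statistic treats the pair of counts (x, y) at
library sizes (N₁, N₂): conditional on x, y follows the negative
binomial p(y|x) = (N₂/N₁)ʸ (x+y)!/(x! y!) (1+N₂/N₁)^−(x+y+1), which
sums to one over y. Replicates are summed within group before applying
the statistic (it is defined for library pairs), and the two-sided
p-value is 2·min(C, D) capped at 1, with C and D the lower and upper
tail sums including the observed point.

Numerical notes: masses are computed in log space via log-gamma; the
upper tail is summed directly out to
max(y, mode) + 20√(mode+y+1) + 60(1+N₂/N₁) + 100 terms — the far tail
decays geometrically with ratio r/(1+r), so the cutoff must scale with
(1+r). Computing D as 1 − C + p(y) instead cancels catastrophically for
extreme observations (it produced negative p-values in an early draft
and is avoided). The 2·min(C, D) combination is symmetric under
swapping (x, N₁) with (y, N₂) only up to the observed point mass; the
property suite asserts symmetry to that bound.

A DEM requires |log₂FC| ≥ 1 **and** p < 0.05, with fold change on
group-mean TPM plus a 0.01-TPM pseudocount on both sides. No
multiple-testing correction is applied at this stage (the enrichment
stage does correct); the joint fold-change + p rule is what keeps the
realized null call rate near 4 % in the validation runs even though the
raw exact-test p is anti-conservative under overdispersed counts.

## Temporal profiles

Candidate profiles over 4 timepoints start at 0 with integer steps in
[−c, c]; defaults c = 2 (125 candidates) and k = 20 representatives
chosen by greedy maximin Euclidean distance seeded at the flat profile.
Profile identity here is by shape, not by any external tool's
numbering. Expression enters as log₂(TPM_t / TPM_CK) with pseudocount,
so every vector starts at 0; assignment maximizes Pearson correlation
with ties to the smaller profile id, and zero-variance vectors go to
the flat profile by convention. Significance permutes each gene's four
timepoint values independently, re-references, re-assigns, and uses
p = (1 + #{count ≥ observed}) / (B + 1); profiles at p ≤ 0.02 are
flagged. B defaults to 1000 in the pipeline (10⁴ gives the same
decisions on the shipped problem sizes at 10× the cost); the
permutation seed comes from the run configuration, making the stage
bit-reproducible.

## Target prediction

The duplex model is ungapped and antiparallel: miRNA position i (1 =
5′ end) faces window position L−i+1 on the transcript's sense strand;
U ≡ T. Rules, in order: (1) mismatch score ≤ 4 with G:U = 0.5 and no
run of > 2 adjacent full mismatches; (2) in positions 2–12 no adjacent
position pair with combined weight > 1.0 — so G:U+G:U is tolerated,
anything involving a full mismatch is not — and positions 10–11 must be
strictly Watson–Crick (a wobble there counts as a violation under the
stringent reading of "no mismatches", since a wobble is half a
mismatch); (3) score ≤ 2.5 over positions 1–12; (4) |E_dup|/|E_perf| ≥
0.74. The first violated rule is reported, and the scan keeps one site
per (miRNA, gene): lowest score, then lowest E_dup, then leftmost.

The energy model is an explicit additive surrogate (GC −3, AU −2, G:U
−1, mismatch 0 with +1 per maximal mismatch run), not a
nearest-neighbour thermodynamic model. The ratio criterion only needs
monotone degradation — every weakened position strictly raises E_dup —
which the surrogate provides and the property suite verifies; the
`energy_fn`/`perfect_fn` hooks accept an external folding engine where
thermodynamic energies are wanted.

Anti-correlation uses Pearson r over the 8 samples with the exact
t-transform p-value (t = r√(n−2)/√(1−r²), df = 6, two-sided); a pair
qualifies at r < −0.50 and p ≤ 0.05. At n = 8 a sample r of exactly
−0.5 has p ≈ 0.207, so the p-condition is the binding one near the
threshold. Pearson (not Spearman) was chosen to match the linear
association displayed by expression heatmaps; with n = 8 the two mostly
agree, and rank correlation would make the planted-truth calibration of
the generator less direct.

## Enrichment

The hypergeometric upper tail is computed as 1 minus the partial lower
sum with log-binomials, clamped to [0, 1]; it matches both direct
upper-tail enumeration and `phyper` to round-off in the tested range.
The universe N is the annotated universe; selected genes lacking
annotation are excluded from n and logged. Q-values are
Benjamini–Hochberg — the standard default where the adjustment method
is not otherwise specified; both raw P (used for the 0.05 significance
flag) and Q are reported. Report cells render as "m (p%)" with the
percentage 100·m/n rounded half-even to two decimals and trailing zeros
trimmed ("5.6%", "12%", "0.63%"), and m = 0 as "0".

## qPCR

2^−ΔΔCt with ΔCt = mean Ct(target) − mean Ct(U6) per condition and the
control timepoint CK as calibrator. The replicate SD is computed on
per-replicate ΔCt values and expressed on the fold scale as the
2^−(ΔΔCt±SD) range. Concordance with the sequencing fold changes is
assessed on direction only: the scaling that would make the two
magnitudes commensurate is not defined, so magnitude agreement is not
claimed.

## The synthetic-data generator

`simulate_bundle()` emulates the study's data-generating structure with
a fully recoverable truth set: 500 planted mature miRNAs (lognormal
baseline abundance, σ_log = 0.7), 10 % up- and 10 % down-regulated
4-fold at T1–T3, hairpin precursors as perfect inverted repeats for
novel candidates, ncRNA fragments, mRNA-degradation fragments,
contaminant reads injected at fixed per-class rates (low quality, N, no
3′ adapter, 5′ adapter, no insert, polyA, too short, too long), planted
complementary target sites with controlled edits (perfect, one G:U at a
legal position, a position-10 mismatch, three adjacent mismatches at
18–20), mRNA partners generated to a target correlation of −0.9, and
pathway tables with three terms concentrated on the targets of
regulated miRNAs.

Two design points matter for interpreting validation results:

* **Classes are planted on the TPM scale.** The pipeline measures
  relative abundance, so expected counts are defined as fixed fractions
  of the library depth (miRNAs 60 % at CK, ncRNA fragments 3 %, novel
  1.5 %, degradation fragments 1.2 %) and an *uncharacterized filler*
  class absorbs the mass difference across timepoints, keeping every
  library's expected depth constant. Without the filler, the asymmetric
  planted up-mass would shift every null miRNA's TPM (a real
  compositional artefact of TPM normalisation) and "null" would not
  mean null on the measured scale. Real libraries do contain a large
  uncharacterized bulk, so the filler also improves realism; the
  compositional fragility of TPM itself remains a genuine limitation of
  the method (see below).
* **Counts are negative binomial with dispersion 0.1** — deliberately
  harsher than the Poisson-like sampling the exact test assumes. The
  raw exact-test p-values are therefore anti-conservative on this data;
  the DEM rule's fold-change condition is what controls the realized
  null rate. Validation thresholds (recall ≥ 0.9, type-I ≤ 0.07) are
  met under this stress, which is the point of choosing it.

Problem sizes used by the validation suite: the full-scale run uses
depth 10⁵ per library and 500 miRNAs (≈ 1 minute end-to-end); module
tests use a 4 000-read, 40-miRNA configuration. What the generator does
**not** emulate: per-base sequencing error outside the injected
contaminant classes, isomiR variation, multi-site additive repression,
GO DAG topology (terms are flat), and genome-scale repeat structure.
Passing tests therefore demonstrate correctness of the implemented
rules and statistics under controlled truth, not performance on real
tissue libraries.

## Coordinates, determinism, degenerate inputs

All tabular outputs use 1-based closed coordinates, the R/Bioconductor
convention. Every stochastic stage draws from a seed in the run
configuration; equal seeds give byte-identical stage outputs, which the
manifest (md5 per output file) makes checkable. Degenerate inputs have
defined behaviour: empty FASTQ parses to an empty stream, an empty
annotation table is an error at enrichment (N = 0), zero-variance
expression vectors are dropped from correlation pairing with a logged
reason and sent to the flat profile in clustering, and `ac_pvalue` at
the symmetric point returns exactly 1.

## Known limitations

TPM normalisation is compositional: strongly asymmetric regulation
shifts all relative abundances, and neither the exact test nor the fold
change corrects for it (no TMM/quantile step is provided, by design
scope). The exact test ignores biological replicate variance by summing
replicates. The duplex energy is a surrogate; sites near the 0.74 ratio
boundary may be classified differently by a thermodynamic model. The
hairpin screen is transcriptome-based and will miss precursors whose
arms span contig boundaries.
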