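---
title: "Discriminating paralogous miRNA precursors: models and design choices"
author: "paralomiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating paralogous miRNA precursors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralomiR)
```

# The problem and the data model

A paralogous miRNA family is a set of hairpin precursors at different
genomic loci that are processed into an identical major mature miRNA.
Reads from that mature form are ambiguous between family members, so the
family's tissue expression cannot be attributed to a member from major
counts alone. The discriminating signal used here is the **minor
(passenger) form**: it derives from the opposite hairpin arm, is poorly
conserved, and typically differs between paralogs — sometimes by a single
nucleotide. A member that truly drives expression in a tissue should show
joint enrichment of the shared major and its own minor form there.

Everything downstream derives from a long-form read-mapping table with one
record per (precursor, read start position within the hairpin, tissue),
mirroring miRBase's per-experiment read reports. Coordinates are 1-based
and inclusive, the miRBase convention, both within hairpins and for
genomic loci read from GFF3. Reads are assumed pre-filtered to perfect
matches; no alignment is performed. Duplicate records are summed on
loading, which also makes loading insensitive to row order. Tissue labels
are matched exactly after whitespace trimming; multi-mapping reads are
counted once per hairpin record as given in the input (the table states
per-precursor pileups; no fractional reassignment is attempted).

# Arm assignment and quantification

Per precursor, the start position with the highest read count summed over
tissues is the major mature form and defines the guide-strand arm; the
highest-count start on the opposite arm is the minor form. A start belongs
to the 5p arm when it lies at or before the hairpin midpoint. Two
numerical conventions matter:

* **argmax ties** break toward the 5'-most position, making assignment
  deterministic;
* precursors with zero reads, or reads on one arm only, are flagged
  rather than dropped, and carry all-zero count vectors.

Expression is quantified at three levels — precursor (all starts summed),
major and minor (the designated starts) — and normalised to reads per
million, dividing by the tissue's total reads in the source table
(overridable when external library totals are known). Normalisation is
scale-equivariant per tissue and conserves the constant: when the
quantified entities partition all reads, each tissue column sums to 1e6.
Arm-usage ratios (major/minor totals over tissues) are reported for pairs
whose major total strictly exceeds 50 reads; the filter can instead be
applied to combined major+minor reads — the two readings select slightly
different pair universes, so both are supported and the choice is
explicit. A minor with zero reads yields an infinite ratio,
kept as `Inf` rather than dropped. Tissues where the minor out-reads the
major are reported as arm-switch tissues.

# The coexpression score

With `M_ij` reads of entity *i* in tissue *j*, `T_i` its cross-tissue
total and `Q_j` the per-tissue read fraction of the scoring universe, the
tissue-specificity statistic is the binomial standardised excess

$$Z_{ij} = \frac{M_{ij} - T_i Q_j}{\sqrt{T_i Q_j (1-Q_j)}}$$

clamped at zero, with $Z_{ij}=0$ when $M_{ij}=0$ or the denominator
degenerates ($T_i=0$, or $Q_j \in \{0,1\}$ — with a single tissue no
specificity is definable). The clamp encodes that *depletion* is not
specificity, and makes the pair score

$$S_j = Z^{major}_{j} \cdot Z^{minor}_{j}$$

non-negative and exactly zero whenever the minor form has no reads — the
documented zero-read rule. The forms above are the standard binomial-null
specificity z-score and its product score for pairs; they satisfy every
property the scoring framework requires (non-negativity, the zero-read
rule) and produce score magnitudes up to ~1e6 on deep libraries, i.e.
products of z-values of order $\sqrt{T}$.
Each formula is isolated in a single function
(`tissueSpecificityZ`, `coexpressionScore`) so an alternative
transcription is a one-line swap, and a spreadsheet-arithmetic oracle in
the tests pins the implemented algebra.

**Read filter.** Entities enter the pair universe when the *major* form
has more than 50 reads across tissues. The filter is deliberately not
applied to minors: sub-50 and even zero-read minors must stay in the
report (scored low or zero) because a zero score for one member *is* the
discriminating evidence for its sibling.

**Selection.** The top 10 % of all member-by-tissue scores are flagged
globally (per-family or per-tissue alternatives were considered but the
global pool matches the single ranked score list the method describes).
`ceiling(0.1 N)` highest scores are taken; ties at the cutoff are all
included; zero scores are never flagged. Rank percentiles use minimum-rank
counting so that tied scores share the best rank.

**Fisher screen.** Differential expression of sibling minors in tissue
*j* uses the 2×2 table [minor A in *j*, A elsewhere; minor B in *j*, B
elsewhere] — this tissue-versus-elsewhere construction is the package's
documented choice of contingency layout. The two-sided p sums the probabilities of all tables at the
observed margins whose hypergeometric probability does not exceed the
observed one (point-probability method, with a 1e-7 relative tie
tolerance), implemented directly over `dhyper` for speed; an all-zero
margin is degenerate and returns p = 1. The screen is uncorrected by
default (raw p < 0.05); a Benjamini–Hochberg option is exposed upstream via
`p.adjust`. In families with more than two members a member must beat
*every* sibling (p < 0.05 and directionally enriched in the tissue).

A member passing both filters is the called contributor (highest score
wins if several pass); families whose members share identical minors are
flagged indistinguishable and always reported unresolved — no statistic
can separate them. A Pearson pre-screen of major-vs-minor association is
available (`corPrefilter`) but off by default: the correlation screen is
provided as its own module, and the contributor call is defined by the
decile and Fisher filters.

# Correlation, tissue patterns, qPCR

**Pearson screens** (major/minor pairs, clustered pairs at inter-locus
distance < 5000 bp on the same chromosome and strand, miRNA/host-gene
pairs) use the exact t-transform p with n−2 degrees of freedom; default
alpha 0.01 for pair screens and 0.05 for host-gene checks. Correlations
are computed on RPM values by default, consistent with the normalised
matrices used everywhere else in the pipeline; a raw-count option is
exposed. Constant vectors give an
undefined R: flagged, excluded from tallies. Cluster gaps are measured
between nearest ends of precursor genomic intervals, strictly below the
threshold; host-gene links are supplied annotations, not inferred from
transcript overlap (inferring them would require transcript models, out
of scope here).

**SPM/CTM.** The thresholds (specific: SPM > 0.9; selective: at least two
tissues with SPM > 0.5 and joint CTM > 0.9) are only meaningful with the
metric of the pattern-gene framework they come from, so the cosine form is
adopted: $SPM_j = x_j/\lVert x\rVert$ (squared values sum to 1) and
$CTM_S = \sqrt{\sum_{j\in S} SPM_j^2}$, computed on RPM vectors.
Specific takes priority over selective, so calls are mutually exclusive;
all-zero vectors are flagged undefined. Both formulas live in one
function each (`spmScores`, `ctmScore`) in case the served
implementation's algebra ever proves to differ.

**qPCR.** Comparative-CT: ΔCt = Ct(target) − Ct(reference) per tissue,
ΔΔCt against a calibrator, fold = 2^(−ΔΔCt). No calibrator is named in
the protocols this mirrors, so the default is the tissue with the lowest
mean ΔCt (highest expression), making the calibrator fold exactly 1 and
all folds ≤ 1-ish scale-free quantities; it is configurable. Preferential
tissues come from a one-way ANOVA on replicate-level log2 relative
expression — each target replicate paired with its own reference
replicate, which keeps replicate errors independent and the ANOVA gate at
its nominal size (subtracting a tissue-mean reference instead shares
reference noise within groups and inflates the type-I rate) — gated at
p < 0.05, followed by Tukey HSD: the largest top-mean group whose members
each significantly exceed every non-flagged tissue is flagged, so
co-preferential tissues need not separate from each other. Fewer than two
replicates anywhere refuses the ANOVA. Amplification-efficiency
correction and standard curves are out of scope.

# The synthetic study generator

`simulateReads` emulates the statistical structure the pipeline targets:
six two-member paralogous families, each member the sole contributor in
one member-specific tissue (expected 2000 major reads, minor:major ratio
0.1); singletons with planted one-tissue and two-tissue patterns
(expected 1500 reads per pattern tissue over a background of 2);
clusters of sizes 2 and 3 placed with 2 kb intra-cluster gaps on a
deterministic pseudo-genome; a satellite read start adjacent to each
major (1 % of its level) to exercise the argmax; and filler precursors
bringing each tissue's expected library to 3e5 reads so that RPM
denominators and `Q_j` are realistic. Counts are negative-binomial with
size 50 — mild overdispersion beyond Poisson, appropriate for one pooled
sequencing library per tissue as in per-experiment read reports (between-
animal biological variance, which would be far larger, is not the
sampling unit here). Size 50 was fixed a priori by a power argument: at
the selective-pattern boundary the two pattern tissues must stay within a
ratio of √3, and cv ≈ 1/√50 keeps the probability of crossing that
boundary, and hence pattern misclassification, at the percent level.
Dispersion, levels and ratios are configurable, including a `noiseFree`
exact-mean limit used by the degenerate-input tests.

The generator does **not** model sequence-content or ligation biases,
isomiR 3'-end heterogeneity, cross-mapping between family members, or
between-animal variability. Passing recovery tests therefore show the
statistical machinery is correct under the stated noise model, not that
real libraries meet its assumptions.

`simulateCt` plants preferential tissues as a Ct depression (default 2
cycles = 4-fold) with Gaussian replicate noise (σ = 0.25 cycles, n = 3
triplicates, the field's default) over a flat reference gene.

# Problem sizes and tolerances

The test suite and the acceptance script run the recovery battery at 50
and 20 seeds respectively of the default configuration (12 planted
contributors and 14 planted patterns per seed), sizes at which the
binomial proportions of interest are estimated to a few percent; the
Fisher implementation is checked against exhaustive hypergeometric
enumeration over all 2×2 tables with row margins ≤ 40 (741,320 tables);
Pearson null uniformity uses 10,000 simulated n = 15 pairs; the ANOVA
null uses 2,000 replicates of an 8-tissue, 3-replicate design. Numerical
comparisons use 1e-9 absolute tolerance for exact quantities (Fisher
enumeration, spreadsheet oracles) and the documented 1e-7 relative tie
tolerance inside the exact test; `Q_j` must sum to 1 within 1e-9 and
normalised columns to the scale constant within 1e-6 relative.

# Known limitations

* Families whose members share both major and minor sequences are
  intrinsically unresolvable and are only reported as such.
* The score attributes expression, it does not quantify mixture
  proportions; no model-based deconvolution or EM read reassignment is
  attempted.
* The adopted Z/score and SPM/CTM algebra are the standard forms of
  their frameworks; validating them bit-exactly against large external
  datasets (e.g. the miRBase release-19 mouse read reports) is left to
  integration studies, and the isolation of each formula in one function
  keeps any swap cheap.
* With very uneven library sizes, `Q_j` is dominated by the deep tissues
  and specificity in shallow tissues needs proportionally larger excesses
  — a property of the binomial null, not a bug, but worth knowing when
  interpreting scores across tissues.
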