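---
title: "Methods: detecting bacterial transfer between sexual partners from paired ASV tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting bacterial transfer between sexual partners from paired ASV tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexome)
```

## The problem

When a couple has penetrative intercourse, each partner leaves bacterial
traces on the other. With full-length 16S rRNA amplicon sequencing those
traces are visible as amplicon sequence variants (ASVs) that appear in a
partner's genital sample *after* intercourse while having been absent
*before* — and present in the other partner beforehand. This package turns
that idea into a reproducible pipeline over a couple-paired before/after
design: per couple, four specimens (female/male x before/after), plus
extraction blanks, no-template controls (NTCs) and a mock community.

The unit of analysis is the ASV count table (ASVs x samples, integer
reads). Everything upstream — sequencing, denoising, taxonomy assignment —
is out of scope; the pipeline starts at the validated triplet of counts,
taxonomy and sample metadata.

## Pipeline stages and their definitions

**Contaminant identification (prevalence method).** Reagent contaminants
are over-represented in negative controls relative to specimens. For each
ASV we form the 2x2 presence table (present/absent x specimen/control) and
score the one-sided tail probability that control prevalence is at least
as extreme as observed. With well-filled tables this is half of the
chi-squared tail on the 2x2 statistic, direction-adjusted; whenever any
expected cell falls below 5 — which is the normal situation with 3–6
negative controls — we use the exact hypergeometric tail instead, because
the chi-squared approximation is unreliable there. An ASV never seen in a
control scores 1 by convention. ASVs scoring below the threshold (default
0.05) are removed before any analysis. Extraction blanks and NTCs are
pooled as "negative controls" by default; the pooling is a configuration
switch (`control_classes`) because protocols differ on whether NTCs, which
carry almost no reads, should count. Presence is `count >= 1 read`; no
minimum-read floor is imposed by default.

**Alpha diversity.** Shannon index in natural-log units (nats), the
convention of the R ecology stack, computed on the decontaminated but
otherwise unfiltered table: rare ASVs are real signal for richness.
Whether the 0.1% relative-abundance filter should also precede alpha
diversity is genuinely ambiguous; it is exposed as the `alpha_filtered`
switch and off by default. Group contrasts use the two-sided Wilcoxon
rank-sum test — exact by enumeration when both groups have at most ten
tie-free observations, the normal approximation with tie and continuity
correction otherwise. Pairing by couple is *not* exploited (unpaired
test); a paired variant would be a straightforward extension but the
unpaired contrast is what the grouped comparisons report.

**Beta diversity.** Bray–Curtis dissimilarity
\(BC(x,y)=\sum_i|x_i-y_i| / \sum_i(x_i+y_i)\) on counts, with no prior
transformation. Before ordination, ASVs whose relative abundance never
strictly exceeds 0.1% in any sample are removed; this filter is scoped to
the ordination inputs only — the transfer stage runs on the unfiltered
decontaminated table, because presence/absence of rare ASVs is exactly
what transfer detection needs. Principal coordinates analysis applies
Gower double-centering to \(-\tfrac12 D^2\) and an eigendecomposition;
coordinates are eigenvectors scaled by \(\sqrt{\lambda}\). Bray–Curtis is
non-Euclidean, so negative eigenvalues occur: they are reported but
excluded from coordinates and from the proportion-explained denominator,
and no Cailliez/Lingoes correction is applied. Axis signs are fixed by
making the largest-magnitude loading positive, so ordinations are
reproducible across runs.

**PERMANOVA.** One-factor only, matching the two separate tests the
pipeline reports (sex; couple). With \(N\) samples in \(a\) groups,
\(SS_T=\sum_{i<j}d_{ij}^2/N\), \(SS_W=\sum_g\sum_{i<j\in g}d_{ij}^2/n_g\),
pseudo-\(F=\frac{(SS_T-SS_W)/(a-1)}{SS_W/(N-a)}\),
\(R^2=1-SS_W/SS_T\). The p-value uses free (unrestricted) label
permutations with a stated seed: \(p=(1+\#\{F^\pi\ge F\})/(1+n_{perm})\),
999 permutations by default, so p has granularity 1/1000 and is
reproducible bit-for-bit. On small two-group designs an exact mode
enumerates every distinct label assignment instead. A degenerate
\(SS_W=0\) is reported as the smallest attainable p with a warning.

**Community state types.** Female before-intercourse samples are assigned
one of the five canonical vaginal community state types from species-level
composition: CST I/II/III/V when *L. crispatus* / *L. gasseri* /
*L. iners* / *L. jensenii* respectively is the single most abundant
species *and* reaches the dominance threshold; otherwise the diverse,
Lactobacillus-poor CST IV. The five-CST framework does not come with a
universal threshold; 0.30 relative abundance is the default here, it is
recorded in the output (`threshold_used`), and raising it can only move
samples toward CST IV (a monotonicity the tests assert). Ties at the top
resolve to CST IV: "dominated by one specific species" requires a unique
argmax.

**Transfer classification.** For each participant, the *baseline
community* is the set of ASVs present in both of their timepoints
(before ∩ after support). An ASV is *cohort-unique* to a participant when
it occurs in that participant's baseline and in no other baseline in the
cohort. For each couple's after samples, every detected ASV is assigned
exactly one category: *retained* (in the recipient's own before sample),
*transferred* (absent from own before, present in the partner's before) or
*introduced* (absent from both before samples — environmental or
other-body-site origin); ASVs present before but not after are reported
separately as *lost*. Two definitional choices deserve note:

* Transfer detection works on raw before/after supports, not baselines —
  a taxon can transfer and simultaneously fail to persist in the donor.
* Uniqueness of a transferred ASV is assessed with respect to the donor
  against all participants' baselines excluding the recipient (the
  recipient's after sample contains the transfer itself and must not veto
  uniqueness). A switch (`unique_on = "before_support"`) evaluates
  uniqueness on raw before supports instead, for sensitivity analysis.

The per-couple summary reports, for each partner, baseline total/unique
counts and their percentage, and for each direction transfer total/unique
counts and percentage. Percentages are 100·unique/total rounded half away
from zero to one decimal (the printed-table convention); a zero total
yields `NA`, distinct from a zero numerator which yields `0.0`.

**Contributor genera.** At genus level, a genus is a *male contributor*
when its relative abundance decreases in the male across intercourse and
increases in the female (net movement male → female); mirrored for female
contributors. Both changes must exceed a tolerance δ, default 0.5
percentage points, which suppresses multinomial counting noise at typical
read depths; δ = 0 recovers the strict rule. The cohort-level call uses
the group means underlying the sex-by-timepoint heatmap.

## The synthetic cohort

No sequencing data ships with the package; a simulator generates
cohorts with full ground truth so every stage is testable end-to-end.

* **Design**: 12 couples x 2 partners x 2 timepoints, 3 extraction
  blanks, 2 NTCs, one mock community — the paired design the pipeline
  targets. Mean specimen depth 8,292 reads, drawn negative-binomially
  (size 30) to mimic overdispersed real depths; sample totals equal the
  drawn depth exactly by multinomial sampling.
* **Communities**: log-normal relative abundances over niche pools
  renormalised to the simplex — the simplest model with realistic
  rank-abundance curves. The vaginal pool holds the four CST-defining
  *Lactobacillus* species plus common anaerobes; the penile pool is
  deliberately richer (24 vs 14 taxa, 15–22 drawn vs 5–12), which makes
  penile communities both richer and higher-Shannon, the direction real
  cohorts show. For CSTs I/II/III/V the designated species is drawn to
  70–95% relative abundance; CST IV excludes the four CST species
  entirely so the planted label is always recoverable under the 0.30
  dominance rule. Each participant additionally receives 2–6 *personal*
  ASVs (participant-specific sequence variants of niche-appropriate
  species, 5–15% of the community) — without them a small shared taxon
  pool would make cohort-unique ASVs, and hence unique transfer,
  impossible; real ASV tables get this individuality from strain-level
  sequence variation.
* **Transfer**: the after composition is the convex mixture
  \((1-m)\cdot\text{own before} + m\cdot\text{partner before}\), with the
  mixing proportion \(m\) drawn uniformly in [0.05, 0.2] per direction by
  default. No quantitative transfer proportion is established in the
  literature; these are free parameters surfaced in `couple_config()` and
  never hard-coded in analysis stages. A condom flag scales \(m\) by 0.3
  (female→male) and 0.05 (male→female), encoding the observation that
  barrier-protected transfer is predominantly female-to-male; no couple
  uses a condom by default. 0–3 *introduced* environmental/oral taxa per
  couple are added to both after samples at 0.2–0.8% each.
* **Contamination**: five "kitome" taxa appear in each extraction blank
  with probability 0.9 and carry over into each specimen with
  probability 0.15 at 0.5% relative abundance; NTCs hold near-zero reads
  (Poisson mean 2). Contamination is on by default and switchable off
  for clean validation runs.
* **Mock**: the mock sample is drawn at 27,993 reads from the observed
  eight-species profile of the reference protocol (20.0/18.1/17.3/13.9/
  13.6/9.7/4.9/2.3%), i.e. it emulates the *recovered* composition,
  protocol bias included, not the nominal even mixture.
* **Ground truth** records planted transfers with a closed-form detection
  probability — the probability that the donor's before sample shows the
  taxon and the recipient's after sample captures at least one read,
  \(\bigl(1-(1-p_d)^{D_b}\bigr)\bigl(1-(1-p_a)^{D_a}\bigr)\) at the
  realized depths — plus the contaminant list, planted CSTs, effective
  mixing proportions and the true (pre-sampling) before supports.
  Recovery is scored over transfers with detection probability ≥ 0.99;
  transfer calls not planted are *explainable* when the taxon truly lived
  in the recipient's before community but dropped out of that finite-depth
  sample, or is a planted contaminant — anything else counts as an
  unexplained false positive.
* **Determinism**: one RNG stream seeded once; draws are ordered by
  (couple, sex, timepoint), so identical configurations reproduce
  bit-identical integer tables; the caller's RNG state is restored.

What the simulator does **not** emulate: sequencing error and chimeras,
16S copy-number variation, menstrual-cycle dynamics, replicate-swab
selection, and within-species strain structure beyond the personal-ASV
device. Passing tests therefore demonstrate the *logic* of the pipeline
under a plausible compositional model, not performance on real sequencing
artifacts.

## Numerical and testing choices

* Degenerate inputs: all-zero samples are rejected where proportions are
  required and skipped by the abundance filter's screen; an empty
  post-filter ASV set is returned (with a warning) rather than an error.
* The 0.1% filter uses strict inequality: retained iff relative
  abundance > threshold in at least one sample.
* Rounding of printed percentages is half away from zero, one decimal.
* The test suite sizes simulations to run on one CPU in a few minutes:
  transfer recovery over 20 seeds of the full 12-couple, depth-8,292
  design; PERMANOVA calibration over 1,000 null datasets of 12 samples
  with 199 permutations each (granularity 1/200 suffices at α = 0.05);
  contaminant operating characteristics over 100 seeds at depth 3,000 —
  prevalence scores depend on presence patterns, not depth, once
  contaminants are comfortably above the detection floor. The
  contaminant criterion uses six extraction blanks as its control panel:
  the stated condition (control prevalence ≥ 0.8) is a property of
  blanks; near-empty NTCs cannot carry it.
* External oracles: Shannon, Bray–Curtis, PCoA and PERMANOVA are
  implemented in the package and cross-checked in the tests against
  vegan and ape on shared inputs, alongside closed-form and brute-force
  oracles coded independently in the test files.

## Known limitations

* Uniqueness within a 24-participant cohort is weak evidence of global
  uniqueness; the package reports cohort-uniqueness only.
* One-factor PERMANOVA cannot separate sex from couple effects; the two
  reported tests are marginal, not adjusted.
* The prevalence score follows the 2x2-table construction described
  above; it is not guaranteed to reproduce any particular external
  implementation bit-for-bit, especially where those rely on the
  chi-squared approximation in sparse tables.
* Strain/serovar identity of transferred taxa is beyond 16S resolution;
  identical ASVs in two people are compatible with, not proof of,
  transfer.
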