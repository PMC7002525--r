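---
title: "Inferring cancer cell fractions of structural variant breakpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cancer cell fractions of structural variant breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svccf)
```

## The problem

A tumour is a mixture of normal cells and one or more tumour cell
populations. For a somatic variant, the *cancer cell fraction* (CCF) is
the fraction of tumour cells that carry it; clonal variants (CCF 1) are
in every tumour cell, subclonal ones in a subset. For SNVs, CCF
estimation from read counts is well established. Structural variants
(SVs) are harder: the evidence for an SV is split between two breakends
`(l, u)`, supporting reads are split or discordantly mapped rather than
simple mismatches, and the two breakends can sit on different background
copy-number states. `svccf` estimates SV breakpoint allele frequencies
from aligned reads, converts them to CCFs with purity, ploidy and
copy-number information, and clusters SVs into clonal and subclonal
populations with a Bayesian mixture model that uses *both* breakends of
every SV.

## Breakend annotation

Each breakend has a direction: `+` when the breakpoint is on the right
side of the locus (the joined sequence continues to the left of the
position; soft-clipped read tails fall to the right), `-` for the mirror
case. When the caller does not provide directions they are inferred from
which side of the locus the soft-clips fall; a minority side holding at
least 10% of clips marks the locus *mixed*, and mixed events are
resolved against the rest of the input (lone events are duplicated as
`(-,-)`/`(+,+)`; matched pairs are split by file order; the positional
rank pattern `(1,2),(2,3),(1,3)` is recognised as a reciprocal
translocation; more than two partners marks the event complex, and
complex events are discarded before counting). The clip-side-to-sign
mapping (clips to the right of the locus mean `+`) is this package's
convention; the sign semantics (which side connects to the partner) fix
only the relationship between the two, and the convention is used
consistently by the generator and the counter. Classification follows a
small decision tree over the direction pair and nearby partner
breakpoints: `DEL` for `(+,-)`, `DUP` for `(-,+)`, `INV` for matching
signs, `INTRX` whenever the chromosomes differ, `INTDUP` for a
`(-,+)`/`(+,-)` pair whose lower ends agree within 100 bp, and `TRX`
when a third deletion-signature breakpoint spans the mobile element
within 6 bp at both ends. Caller-provided directions and classes always
take precedence over inference.

## Read counting and allele frequency

Reads near a breakend are classified as:

* **split** — soft-clip boundary within 6 bp of the breakend, clip
  longer than `round(0.1 * read_len)` (10 for 100 bp reads), clip side
  matching the direction;
* **spanning** — mates flanking the breakpoint, both oriented toward the
  break, with *adjusted insert* (the sum of each mate's distance to its
  breakend) below `insert_mean + 3 * insert_sd`;
* **normal** — the read or its insert crosses the locus with at least
  10 bp on each side and soft-clips of at most 6 bp;
* **anomalous** — crosses the locus but fits no category (oversized
  insert, mates not facing the break, double clips, sub-threshold clips,
  opposite-direction support). Anomalous reads contribute to nothing.

Supporting reads are only counted when they match the breakend
direction, which prevents double-counting for events with reads on both
sides (inversions, translocations). The 6 bp positional window also
absorbs micro-homologies up to that length; SVs with longer
micro-homology should be filtered upstream. The total support is
`b = s_l + s_u + c` and the per-end depth is `d_i = b + o_i`; by default
the total support is shared by both ends' binomial trials (the per-side
alternative `b_i = s_i + c` is available via
`count_params(support_mode = "per-side")` — the field's notation is
genuinely ambiguous here, and sharing the total uses all evidence at
both ends). Loci whose depth exceeds `expected_depth * max_cn` are
flagged as high-depth (likely collapsed repeats) and removed.

Duplication-class SVs (`DUP`, `INTDUP`) gain DNA without displacing the
reference allele, so their normal read counts are inflated and the raw
VAF `b / (b + o)` is biased low. Their normal counts are rescaled by
`1 - purity / ploidy` before the VAF is formed; the correction is exact
for the heterozygous diploid case (a clonal heterozygous duplication at
purity *t* recovers the expected VAF *t*/2) and the adjusted counts are
carried as reals until reporting.

## Filtering and background copy number

Filtering is deliberately conservative because SV counts per sample are
small (dozens to low hundreds): germline-supported events (both ends
matching a germline breakpoint within 6 bp with matching directions and
any support), intra-chromosomal events no larger than the fragment size,
events lacking one split or one spanning read, events with per-end depth
of 2 or less, events without a valid copy-number state (major + minor
of at least 1) at either end, blacklist overlaps and high-depth loci are
removed, each with a machine-readable reason. Optional filters restrict
to copy-number neutral or clonal-copy-number backgrounds.

The *background* copy number of a breakend is the state that existed
before the rearrangement: upstream of the lower and downstream of the
upper breakend for intra-chromosomal SVs, and opposite the breakend
direction for inter-chromosomal ones — never the rearranged interval
itself. Battenberg-style subclonal segmentations contribute up to two
states with fractions `rho` and `1 - rho`; the weighted total
`n_tot = sum(rho_r * (major_r + minor_r))` enters the model. Without
copy-number input the tumour total is assumed equal to the normal total
with no subclonality. An SV with exactly one invalid end keeps the valid
end's annotation and takes the default at the other, flagged in the
output (`cn_fallback`) rather than discarded.

## The dual-breakend mixture model

Supporting counts at the two breakends of SV `j` are modelled as
conditionally independent binomials sharing one CCF:
`b_ij ~ Binomial(d_ij, f_ij)` with success probability
`f = w * phi_k + eps`, where

```
w = t * (m * (1 - eps) - n_tot_t * eps) / ((1 - t) * n_tot_n + t * n_tot_t)
```

links the cluster CCF `phi_k` to the expected VAF through purity `t`,
multiplicity `m` and the total tumour and normal copy numbers. The
multiplicity candidate set is `{1..major}` for clonal backgrounds and
all weighted sums `rho_1 x_1 + rho_2 x_2` over per-clone integer states
for subclonal ones; under subclonal background the weighted-average
total replaces `n_tot_t`.

Cluster CCFs get a Gaussian prior (mean 1, variance 1 — centred on
clonality, weakly informative), mixing weights a sparse symmetric
Dirichlet prior (concentration 0.01 per component, letting unused
components empty out so quality control can prune them), and
assignments a categorical prior. Inference is coordinate-ascent
variational inference with factorised `q(Z) q(phi) q(pi)`. To keep every
update conjugate (and the evidence lower bound exactly computable and
provably non-decreasing — the suite asserts this on every fit at 1e-8),
the binomial observation enters the coordinate updates through its
Gaussian approximation at the observed depth: the empirical VAF
`y = b/d` is treated as Gaussian around `w * phi + eps` with plug-in
precision `d / (f~ (1 - f~))`, `f~ = (b + 0.5)/(d + 1)`. At the depths
where subclonal inference is feasible at all this approximation is
excellent, and the uncertainty in `phi` is integrated out when forming
responsibilities, which mitigates overdispersion in the same way a
beta-binomial would while remaining fully tractable.

Multiplicities are point-estimated. Inside the coordinate ascent each
end's multiplicity maximises the same variational objective over its
candidate set (so the update is true coordinate ascent and cannot
decrease the bound); the final reported multiplicities maximise the
responsibility-weighted *expected binomial* log-likelihood, the
expectation over `q(phi_k)` taken by 11-point Gauss–Hermite quadrature
(`estimate_multiplicity()`; the suite checks it against exhaustive
enumeration with adaptive quadrature). Ties break toward the smallest
multiplicity, the conservative choice. Multiplicity 0 (possible in the
subclonal candidate enumeration) gives a non-positive weight and is
treated as infeasible for a variant-carrying locus.

The model is fitted for every cluster number in `1..6` with 5 restarts
each; restart seeds derive deterministically from `(seed, K, repeat)`,
initial means are K-quantiles of the empirical per-variant CCFs
(multiplicity 1), and the best evidence lower bound wins. Convergence is
a relative ELBO change below 1e-6 or 1000 iterations. Quality control
then (1) removes empty clusters, (2) removes clusters holding under 1%
of the data, (3) merges clusters whose posterior means are within 0.10
CCF, re-running the variational refinement after each step.

Per-variant CCFs invert the linear model at the estimated multiplicity:
`CCF = min(2, (VAF - eps)/w)`, floored at 0; the representative SV CCF
is the mean of the two ends. The cap at 2 acknowledges that the linear
relationship has no natural upper bound under copy-number
misspecification. The error constant defaults to `eps = 1e-3`
(configurable; the model is insensitive to it at realistic depths).

## Post-assignment

When a sample has too few filtered SVs to cluster reliably (roughly ten
or fewer), or when initially-filtered variants should still receive a
CCF, `post_assign()` takes an existing fit — SV- or SNV-derived — as a
frozen reference: `q(phi)` is held bit-identical while the assignment
and mixing-weight posteriors are iterated to convergence on the new
data, so the post-assignment proportions reflect the new variants
rather than the reference cohort. Multiplicities are re-estimated
against the frozen posterior. Quality control during post-assignment
merges *assignment labels* only (frozen means are never altered — the
alternative would contradict the freeze); per-label means are
recomputed from members for reporting, and merges are recorded in the
returned object.

## Clonality statistics

A variant is subclonal when its CCF is strictly below 0.7 (a CCF at the
cutoff is clonal — the test is for being *below* the cutoff). The
subclonal copy-number-neutral rearrangement (SCNR) pattern is tested by
hypergeometric upper tail: population all SVs, successes the balanced
classes (`INV`, `INTRX`), draws the subclonal SVs. The dispersion test
compares, per variant, a binomial with success probability `t/2` against
a beta-binomial whose `beta` is a moment-style plug-in from the cohort
(`mu = mean(d) * t/2`, `sigma` the standard deviation of the observed
supporting counts) with `alpha` matched so the mean is preserved, via a
likelihood-ratio statistic against chi-square with one degree of
freedom. Two properties matter in practice: under binomial data the
plug-in denominator sits at the degeneracy point of the beta-binomial
family, so non-overdispersed cohorts yield an infeasible (non-positive)
`beta` — the statistic is then 0 by convention — and the test is
strongly conservative under the null (empirically near-zero type-I
error) while retaining clear power against genuine overdispersion. It
is a model-adequacy screen, not a calibrated hypothesis test. A
per-variant-depth variant of `mu` is available behind a flag.

## Benchmarking

`evaluate_fit()` reproduces the standard metric panel against a known
truth: cluster number error (true minus inferred), signed mean cluster
CCF error over pairs matched by alternating extremes (highest-to-
highest, lowest-to-lowest, second-highest, and so on until either side
is exhausted; with even counts the highest-first convention claims the
middle — the parity rule is otherwise ambiguous), signed mean variant
CCF error, signed mean multiplicity error against the multiplicity
implied by the true cluster mean (`optimal_multiplicity_ccf()`, which is
by construction the brute-force likelihood argmax), and subclonal
sensitivity/specificity at the 0.7 cutoff. Signed (not absolute) errors
preserve the direction of bias.

## The synthetic generator

`simulate_counts()` draws datasets from the model's own forward process:
per SV a background state, a multiplicity from the candidate set, then
Poisson depths and binomial supporting counts at both ends sharing one
CCF. Default conditions mirror the validation design for the VAF
estimator: heterozygous SVs on a copy-number neutral diploid background
at 100 kb spacing, Poisson depth around the target coverage, error
constant 1e-3; subclonal and amplified backgrounds are opt-in. DNA-gain
classes are generated with undisplaced reference reads so the emitted
table carries both the biased raw VAF and the corrected one.
`make_mixture()` builds count-level analogues of two-sample in-silico
mixtures (shared variants clonal, private variants at the mixing
proportions, counts re-drawn at the new CCFs), and
`simulate_cn_perturbation()` implements the systematic copy-number
perturbations (major minus/plus one with the 1-0 guard, subclonal
fraction plus/minus 0.3 with the 0.9 cap). `generate_alignments()`
writes small sorted indexed BAMs realising exact split/spanning/normal/
anomalous tallies, so the read counter is testable without external read
simulation; its geometry is the exact inverse of the classification
rules.

What passing tests on these data do and do not show: the generator
draws from the fitted model's own family with independent Poisson
depths, clean category geometry and correct copy-number annotations. It
does not emulate mapping artefacts, GC and mappability waves,
micro-homology beyond the positional window, overdispersed depth, or
copy-number calls that are simply wrong (the perturbation module probes
the last point deliberately). Recovery results here therefore bound
what real data can give from above.

## Problem sizes and determinism

The shipped tests use 40–100 SVs per fit at 60–200x simulated depth
(1000x for the quality-control threshold checks, where statistical and
rule-based merging must be separable), 20 seeded replicates for the
two-clone recovery study, 1000 randomised cases for the multiplicity
oracle, and 50 randomised alignment fixtures for the counting loop —
sizes at which every property is stable across seeds. All randomness
flows from explicit integer seeds; identical seeds give bit-identical
datasets, fits and output files.

## Known limitations

SVs are treated as independent events even when they belong to one
complex rearrangement; complex events are discarded, not typed. The
Gaussian-approximate likelihood slightly underweights depth-zero and
near-zero-support ends (they are excluded or variance-stabilised). No
phylogeny is reconstructed — cluster CCFs are population summaries, not
a clone tree. Directionality inference uses soft-clip sides only, with
no local realignment, and is intended as a fallback when the caller
provides none.
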