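---
title: "Testing clonal relatedness of tumor pairs from copy number and mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing clonal relatedness of tumor pairs from copy number and mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalpair)
```

## The question

When two tumor lesions are found in the same patient — say a focus of
lobular carcinoma in situ (LCIS) and an invasive lobular carcinoma in the
same breast — did they descend from one ancestral neoplastic clone, or did
they arise independently? The distinction matters clinically (a precursor
lesion is not the same risk object as an independent primary) and cannot
be settled by histology. It can be settled molecularly: two clonally
related lesions inherit the somatic events of their common ancestor, so
they share exact mutations and matching copy-number changes far beyond
what coincidence produces.

`clonalpair` implements the statistical machinery for this decision from
two independent data types:

1. **Copy-number concordance.** Arm-level gain/loss calls from segmented
   log-ratio profiles are compared between the two lesions; concordant
   events are scored by how closely their boundaries match and how rare
   the event is, and the total is benchmarked against pairs of lesions
   from *different* patients.
2. **Shared-mutation likelihood ratio.** Exact mutational matches
   (chromosome, position, ref, alt) between the two exomes are weighed by
   each mutation's marginal frequency in a reference cohort, via a
   likelihood-ratio test of independence against partial clonality.

A pair is called **clonal** when either test rejects independence at
p < 0.01 (a "believe the positive" rule with a strict level), and
**equivocal** when the smaller p-value lies in [0.01, 0.05). When
mutation data exist but the lesions share *no* mutation, the pair is
called **independent** even if the copy-number p-value is suggestive: a
clonal pair cannot lose every trunk mutation, so zero exact matches is
strong evidence of independence.

## Copy-number processing

### From probes to arm calls

Probe-level log2 ratios are averaged in non-overlapping groups of 12
adjacent probes per chromosome arm (`average_adjacent()`), which reduces
array noise by √12 while keeping focal events several markers wide. A
trailing remainder group is kept as its own marker when it has at least
half a group's probes and is otherwise merged into the previous group;
marker position is the median probe position. Grouping is per arm, so no
marker straddles a centromere.

Segmentation (`segment_genome()`) is recursive binary splitting in the
circular-binary-segmentation style: for a marker series the candidate
split is the sub-interval maximizing

$$T(s,e) = \frac{|\bar{x}_{in} - \bar{x}_{out}|}{s_p\sqrt{1/n_{in} + 1/n_{out}}},$$

with $s_p$ the pooled within-group SD. The split is accepted when its
within-arm permutation p-value is below 0.01 (1000 shuffles by default),
and the algorithm recurses on the three resulting pieces. Ties in the
maximization are broken toward the shorter interval, then the leftmost —
a determinism requirement, and the convention the test-suite oracle
reproduces independently.

Calling (`call_segments()`) is relative to the genome-wide median log
ratio with the noise scale taken as the **unscaled** median absolute
deviation of the marker residuals (no 1.4826 normal-consistency factor —
stated once here, used everywhere). A segment is a gain when its height
*strictly exceeds* median + 1 MAD, a loss when strictly below
median − 1 MAD. A residual MAD of exactly zero (noiseless input)
degenerates to calling any segment off the median, with a message.

The clonality comparison uses a **one-step** variant
(`one_step_arm_calls()`): at most one gain or loss region per arm. The
best interior sub-interval is retained only when its split passes the
same permutation test — without that gate the maximization would hand
every flat arm a selection-biased noise interval — otherwise the whole
arm is the candidate, scored implicitly against the genome median. When
the best split touches an arm boundary, the two resulting pieces share
the same $T$; the piece deviating more from the genome median is taken
as the aberrant region. The retained candidate is then called under the
same 1-MAD rule.

### Array quality gate

Noisy or flat profiles would poison both the index comparisons and the
cross-patient reference, so lesions enter the copy-number test only if
(1) more than 10% of markers lie in called segments, or (2) the 75th
percentile of called-segment heights at least 10 markers long — measured
as |height − median|, making the gate shift-invariant — exceeds 1.75
MAD (`qc_gate()`). Mutation testing is unaffected by the gate.

### The concordance statistic and its null

For arms where both lesions carry the same event type,

$$S = \sum_{a\ \text{concordant}} c_a \cdot (-\log \hat\pi_a),$$

where $c_a$ is the Jaccard overlap of the two called marker intervals
(marker indices, not base pairs: the marker grid is the resolution of
the calls) and $\hat\pi_a$ is the cohort frequency of that arm event,
estimated with pseudo-counts, $(x + 0.5)/(n + 1)$, and leaving out the
index pair's patient to avoid self-influence. Discordant arms contribute
zero. Sharing a ubiquitous event (a 1q gain or 16q loss, frequency near
0.8 in LCIS-like cohorts) contributes $-\log 0.8 \approx 0.22$ per arm,
while one rare matching event at frequency 0.05 contributes
$\approx 3$ — the statistic discounts what co-occurs by chance.

$S$ has no usable closed-form null, because lesions share technical
noise, event-frequency structure, and segmentation artifacts. The null
is therefore *empirical*: $S$ is computed for every cross-patient lesion
pair in the cohort (both lesions QC-passing, frequencies re-estimated
leaving out both patients), and

$$p = \frac{1 + \#\{S_{ref} \ge S_{obs}\}}{1 + N_{ref}},$$

which is never zero and is reported together with $N_{ref}$ — with few
patients the resolution of this p-value is limited, and a pipeline run
on a single patient reports no copy-number p-value at all.

## The mutation likelihood-ratio test

Conditioning is on the smaller profile (ties broken by lexicographically
first lesion id) after germline filtering: variants with population
minor-allele frequency above 5% are disregarded (a frequency exactly at
the threshold is kept; absent frequencies count as rare). For each
conditioning mutation $i$ with reference marginal $p_i$, the match
indicator in the other tumor is Bernoulli($p_i$) under independence and
Bernoulli($\xi + (1-\xi)p_i$) under clonality with clonality fraction
$\xi$ — the trunk fraction of the conditioning tumor's burden. The
likelihood ratio is

$$LR(\xi) = \prod_{i\ \text{shared}} \frac{\xi + (1-\xi)p_i}{p_i}
\cdot (1-\xi)^{\,n-m},$$

maximized over $\xi \in [0, 1)$; $\Lambda = \max_\xi LR(\xi) \ge 1$,
with $\Lambda = 1$ (and $\hat\xi = 0$, p = 1) whenever $m = 0$. A match
at a mutation with $p_i \to 1$ contributes nothing — a ubiquitous
hotspot match carries no evidence.

Marginals come from a reference table via
$p_i = (x_i + \alpha)/(N + 2\alpha)$ with $\alpha = 0.5$: the
locus-level count when available, otherwise the gene-level count
apportioned over a nominal 100 distinct sites per gene (a configurable
stand-in for the sparsity of locus-level counts in public references),
otherwise the pseudo-count floor.

**Null distribution.** For conditioning sets up to 20 mutations the
p-value is computed by exact enumeration of all $2^n$ match
configurations (tail probability of $\Lambda$, ties included); beyond
that, by Monte Carlo with the +1-corrected rank formula, so p is never
0. Numerically, $\log LR$ is evaluated on a fixed grid of ~250 $\xi$
values (denser near 1, where $\log(1-\xi)$ is steep) for the observed
statistic and every enumerated or simulated configuration alike, keeping
the tail comparisons internally consistent; the *reported* $\hat\xi$ and
$\Lambda$ are refined around the grid argmax with `stats::optimize`
(tolerance 1e-8). Tail comparisons use an absolute tolerance of 1e-9 on
the log scale. The test suite checks the enumeration path bit-for-bit
against an independent per-configuration `optimize` oracle.

Indels and SNVs are treated as uniform mutation keys; protein-level
matching is deliberately not used (exact genomic matches are the
evidential basis of the test).

## Exome-derived copy number

Where array profiles are unavailable (or as cross-validation), copy
number is derived from tumor/normal exome coverage: loci on the capture
targets are selected greedily left-to-right with ≥250 bp spacing
(resetting at region boundaries) and ≥25× depth in every normal
(`select_loci()`); the per-locus signal is the library-size-scaled log2
tumor/normal depth ratio (log base 2 is a package convention, stated in
the output headers); GC bias is removed by taking residuals of a LOESS
fit of the log ratio on the GC fraction of a 1-kb window centered at
each locus (span 0.3, degree 2, symmetric family; skipped with a
warning below 30 loci; median-centering when GC is constant). The
corrected series then enters `average_adjacent()` and the identical
segmentation and clonality machinery as the array path. Published
processing of this kind reduced ~227,000 loci to 14,603 markers — a
ratio nearer 15.5 than 12 — so the grouping factor is a parameter with
default 12 and the discrepancy is documented rather than resolved.

## The synthetic cohort

No raw data accompany the study design this package addresses, so every
stage is validated on generated cohorts (`simulate_cohort()`) whose
defaults describe a multifocal-LCIS mastectomy series: 20 patients with
2–3 lesions each; negative-binomial mutation burdens (mean 33,
dispersion 5, matching the published median burdens of ~29–38 per
histology); a 6% rate of hypermutated lesions (~500 mutations); a
2000-locus mutation catalog with two dominant hotspots standing in for
*CDH1* and *PIK3CA* (reference counts 300 and 250 out of N = 1000) over
a power-law tail; arm-event priors with two ubiquitous events (gain on
the first q arm, loss on the second — the 1q-gain/16q-loss stand-ins, at
frequency 0.7) and 0.1 elsewhere; probe noise SD 0.15 on 200–600-probe
arms of a toy 8-arm genome; trunk copy-number events copied between
related lesions with ±24-probe boundary jitter; exome depth 192 (the
published median) with an optional planted GC bias.

Two generator properties matter for honest validation:

* **Consistency with the reference.** Each lesion carries every catalog
  mutation independently with exactly its reference marginal
  probability; the rest of the burden is filled with never-recurrent
  novel loci (unique keys, floor marginals). The frequency table the LR
  test consumes is therefore *true* for the generated data — so
  calibration failures are failures of the test, not of the fixture.
* **Exact trunk semantics.** A related pair's trunk is fraction $\xi$ of
  the smaller lesion's burden, present in full in every related lesion,
  so $\hat\xi$ recovery can be scored against a known truth.

What the generator does **not** emulate: wave artifacts, probe-specific
biases, mappability and purity effects, subclonal structure beyond the
two-compartment trunk/private model, caller-specific false positives,
and germline leakage (population frequencies are clean). Passing tests
therefore demonstrate the statistics behave as designed under their own
assumptions — not that those assumptions absorb every artifact of real
arrays and exomes.

## Validation experiments and problem sizes

The test suite runs, at sizes chosen to keep the whole suite in a few
minutes while leaving the conclusions stable:

* exact-path type-I error: 1000 simulated conditioning sets of 12
  mutations with moderate marginals; each pair's *exact* rejection
  probability is computed by full enumeration (`lr_exact_null()`) and
  averaged, eliminating single-draw binomial noise from the comparison
  with the nominal level;
* enumeration vs. oracle equality up to $n = 12$; Monte Carlo vs.
  enumeration within binomial error;
* copy-number null calibration: 10 independent 20-patient cohorts, the
  200 within-patient pairs benchmarked against each cohort's
  cross-patient reference and tested for uniformity (Kolmogorov–Smirnov;
  a residual atom at p = 1 from pairs with no concordant arm is part of
  the statistic's discrete behavior and stays small when lesions carry
  events on most arms);
* frequency discounting: clonal pairs sharing only marginal-0.8 events
  are detected no more often than the nominal level, while the same
  clonal signal on a rare catalog is detected with high power;
* one-step bounds vs. an exhaustive max-T search on arms of 20–50
  markers; planted-GC-bias removal to <10% of its magnitude; $\hat\xi$
  recovery within ±0.1 at burden 40 for $\xi \in \{0.3, 0.5, 0.8\}$.

The `analysis/` scripts re-run these experiments in narrative form and
write their tables under `results/`.

## Known limitations

* The concordance statistic is a concrete implementation of the three
  ingredients the field's copy-number clonality tests share —
  concordance, boundary closeness, frequency discounting, benchmarked
  on cross-patient pairs — not a line-by-line reproduction of any one
  published measure; whether discordant arms should *penalize* (they
  contribute zero here) is an open modeling choice.
* Which tumor the LR test conditions on is a convention (the smaller
  profile); published variants differ, and the choice is conservative
  but not canonical.
* The empirical copy-number p-value is bounded below by
  $1/(1+N_{ref})$: small cohorts cannot reach p < 0.01 on copy number
  alone.
* Mutation matching trusts the caller: recurrent artifacts or germline
  leak-through shared between lesions would inflate evidence for
  clonality, a caveat that applies doubly to pairs with a single shared
  mutation.
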