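---
title: "Methods: time-of-day resolved pooled CRISPR screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-of-day resolved pooled CRISPR screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoscreen)
```

## The problem

A pooled knockout screen infects a cell population with a genome-wide
sgRNA library, applies a selective pressure, and reads out guide
abundances by amplicon sequencing. In a chronochemotherapy screen the
pressure is applied at two circadian phases (zeitgeber times ZT16 and
ZT28 after serum-shock synchronization), each with a drug and a vehicle
arm, plus a pre-treatment baseline — five samples in all. The question is
not just *which* knockouts change drug fitness, but *at which time of
day* they do: a gene whose loss confers resistance only when the drug is
given at ZT16 is a candidate effector of time-dependent efficacy.

This vignette documents the model and procedure choices behind each stage
of the package, the parameters that matter, and what the synthetic
validation does and does not establish.

## Guide quantification

Reads are assigned by **exact spacer matching** (zero mismatches). The
default *scan* mode slides a spacer-length window across the read and
accepts a unique dictionary hit; *fixed-offset* mode looks only at a
declared position and is faster when the amplicon layout is known. A read
containing spacers of two or more distinct guides is counted as
*ambiguous* and assigned to neither — fractional assignment would break
the integer count model downstream. Matching is forward-strand by default
(amplicon protocols read the spacer in a fixed orientation); a
reverse-complement pass is opt-in. No mismatch-tolerant mode is offered:
with unique 20-mers and deep coverage, exact matching trades a small loss
of reads for unambiguous assignment, and the per-sample mapping rate is
reported so that loss is visible. The QC convention adopted here flags
samples under 75% mapped and reports mean coverage against a 100–300×
representation window.

## Normalization

"Median normalization" is implemented literally as **median scaling**:
sample *j*'s size factor is its median guide count divided by the global
reference median (the median of per-sample medians), so every sample's
post-normalization median equals the reference. A **median-ratio**
(DESeq-style) alternative is provided for matrices where medians are
fragile — e.g. very sparse samples, for which median scaling refuses to
run (a zero median gives an undefined factor). Nontargeting guides are
*included* in size-factor computation: they are sequenced library members
and are removed only later, at the hit-calling step, which is also why
the full library rather than a post-filter subset feeds the size factors.

## The hit-calling algebra

The caller is deliberately rule-based rather than statistical: with three
guides per gene and one sample per condition there is no within-condition
replication to estimate a variance from, so calls rest on fold-change
gates plus gene-level concordance.

Parameters (all exposed in `hitcall_params()`):

| parameter | default | meaning |
|---|---|---|
| `up_threshold` | 2 (inclusive) | enrichment gate on drug/vehicle ratio |
| `down_threshold` | 0.5 (strict) | depletion gate |
| `strong_up` | 5 (inclusive) | single-guide rescue, enrichment side |
| `strong_down` | 0.2 (strict) | single-guide rescue, depletion side |
| `min_concordant_guides` | 2 | distinct gated guides for a concordance call |
| `pseudocount` | 1 | added after filtering, before ratios |
| `zero_filter_scope` | `any_sample` | zero-count guide removal rule |

Choices that were genuinely open, and how they were resolved:

- **"Genes supported by the same sgRNA set"** is read as *at least 2
  distinct guides inside the gate*. With 3 guides per gene this is the
  only operational middle ground between "any guide" (no concordance at
  all) and "all guides" (defeated by a single inactive guide); it is a
  parameter, not a constant.
- **Zero filtering** defaults to dropping a guide with a zero in *any* of
  the four screen samples. The set algebra implicitly requires all four
  datasets to share one guide index — a guide present in B1 but absent
  from A1 has no defined ratio — and the any-sample rule is the only
  scope that guarantees this. The all-samples reading is offered for
  completeness.
- **Order of operations** is normalize → filter → pseudocount → ratio.
  Normalization must precede filtering because "zero" is judged on the
  library-size-adjusted scale of the shared index; the pseudocount then
  guarantees positive denominators.
- **Threshold inclusivity** follows the printed inequalities exactly
  (≥ 2, ≥ 5 inclusive; < 0.5, < 0.2 strict). To keep gate membership
  platform-stable for guides sitting exactly on a threshold, ratios are
  quotients of values rounded to 12 decimal places — well below any
  biologically meaningful difference, but enough to absorb
  double-rounding noise from normalization.
- **The baseline sample takes no part in hit calling.** Only the four
  timepoint × treatment cells enter the algebra; the baseline serves
  mapping/representation QC.

Every intermediate (per-guide ratios, gate flags, primed/double-primed
provenance, shared intersections) is retained in the returned ledger and
written to the output TSVs, so a call can always be traced to the rule
that admitted it.

## Pathway enrichment

Over-representation is the hypergeometric upper tail P(X ≥ k) with
BH adjustment across the collection. The **universe defaults to the
screened targeting genes**, not the whole genome: hits can only arise
from genes the library targets, and a genome-wide background would
overstate significance. Raw p-values are retained alongside q-values.
No gene-set data ships with the package beyond a toy fixture; collections
are user-supplied GMT files. Enriched-list intersection
(`intersect_enrichments()`) requires both tables to come from the same
collection and returns the Venn partition at a q cutoff.

## The synthetic screen generator

`simulate_counts()` draws guide counts as negative binomial around
(guide abundance × coverage × treatment multiplier):

- per-guide baseline abundances are log-normal with mean 1 and
  `baseline_abundance_sdlog = 0.5` — a moderate post-cloning
  representation spread;
- `dispersion = 0.01` — the tight count-level reproducibility of a
  well-covered amplicon screen; most realised noise then comes from
  low-abundance guides through the Poisson term, so the difficulty of
  recovery varies across guides as it does in real data;
- `mean_coverage = 300` reads per guide, the upper end of the 100–300×
  representation band such screens target;
- planted effects: 20 ZT16-specific, 20 ZT28-specific and 10 shared genes
  receive a multiplicative fold (`effect_multiplier = 8`) on the mean of
  *drugged* samples only; vehicle and baseline are effect-free. A fold of
  8 models a strong fitness gene under a 36-h drug pulse — clearly
  callable, but still subject to gate failures on low-abundance guides;
- `effective_guide_fraction` (default 1) lets a fraction of an affected
  gene's guides stay inert, stressing the concordance rule the way
  inactive guides do in real libraries.

`simulate_fastq()` embeds each guide's spacer at a fixed offset
(default 11) inside constant vector flanks in 50-nt reads with constant
quality, and adds a configurable fraction of random off-library reads, so
total reads per sample are `round(on_library / (1 - contaminant_fraction))`
and the expected mapping rate is `100 × (1 - contaminant_fraction)`.

The library preset `gecko_b_profile()` reproduces the composition of the
screened GeCKO-B-style sub-library: 58,028 guides with 1,000 nontargeting
controls. Since 57,028 targeting guides are not a multiple of three, the
preset assigns 3 guides to each of 19,009 synthetic genes and a fourth
guide to one designated gene — the one layout that honours all the stated
counts at once; the real library's gene count is not public.

**What the generator does not emulate:** infection MOI and selection
dynamics, cell-cycle or synchronization decay effects, sequencing base
errors (beyond whole-read contaminants), guide-specific cutting
efficiency beyond the binary effective/inert split, and correlated
off-target effects. Passing recovery tests therefore demonstrates the
*procedure's* correctness and its behaviour under overdispersed counting
noise — not robustness to every failure mode of a wet screen.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles:

- the full algebra against a naive straight-line loop re-implementation
  on 1,000+ random small screens (exact equality of every set, including
  under non-default parameters);
- a hand-traced three-gene worked example covering every rule
  (concordance, strong-guide rescue, shared-set subtraction);
- hypergeometric p against the brute-force combinatorial sum to 1e-12;
- generator-level Monte-Carlo checks (planted fold recovered within
  sampling bounds, null screens free of systematic shift, false-call
  totals matching an independent Monte-Carlo estimate);
- end-to-end recovery on a scaled screen — 2,000 genes × 3 guides +
  1,000 nontargeting controls, 50 replicate screens — requiring ≥ 90% of
  planted timepoint-specific genes in the correct time-specific set and
  no nontargeting label in any gene-level output;
- FASTQ-level checks at ≥ 10^5 reads per sample with a 20% contaminant
  fraction, requiring every sample's mapping rate above the 75% QC bar;
- bit-identical pipeline reruns under a fixed seed.

The scaled 2,000-gene library is used wherever the full 19,009-gene
preset would only add runtime without exercising different code paths;
the preset itself is validated directly for composition.

## Known limitations

- One sample per condition is an assumption of the design, not a
  recommendation; with replicates, a count-model framework (e.g.
  negative-binomial GLMs) would be preferable to fold-change gates.
- The gates are sensitive to the pseudocount at very low coverage;
  coverage below ~50× per guide makes the 0.5/2 gates noisy, which is
  visible in the simulator.
- Exact matching discards reads with any sequencing error inside the
  spacer; the mapping-rate report makes the cost visible but nothing
  recovers those reads.
- Enrichment p-values depend strongly on the chosen universe; results
  against different universes are not comparable.
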