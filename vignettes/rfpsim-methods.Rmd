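---
title: "Simulating and cataloguing recurrent false positive variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and cataloguing recurrent false positive variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfpsim)
```

## The phenomenon

Short-read resequencing calls variants by aligning reads to a reference and
looking for systematic mismatches. Mammalian genomes contain recently
duplicated regions — paralogous genes, their untranslated flanks, and
processed pseudogenes — whose copies differ by only a fraction of a percent.
When the divergence between copies approaches the sequencing error rate, an
aligner can no longer tell the copies apart for many reads: the best-scoring
placements tie, mapping quality drops to zero, and the read must be assigned
at random. Reads that truly belong to copy A then land on copy B carrying
copy-A alleles, and the caller sees a low-to-intermediate-frequency
"variant" at copy B. Because the underlying sequence differences are fixed,
these miscalls recur at the *same sites* whenever the same genome is
resequenced or reanalysed — yet, because tie-breaking and sequencing error
are stochastic, they appear only *intermittently*. We call them recurrent
false positive (RFP) variants.

rfpsim reproduces this entire causal chain with fully synthetic data, so
every link can be checked against ground truth: the difference sites between
copies are recorded in a ledger at genome construction time, and the reads'
true origins are retained through simulation.

## The procedure

One *round* is resample → realign → recall: draw an error-bearing read set
from the individual's genome, align it to the reference, call SNVs. Running
`run_rounds()` for $N$ rounds (independently seeded per round) yields a
boolean call matrix of variant keys × rounds. Per-key call frequency
$f$ classifies each key (`classify_calls()`):

* $f \ge 0.95$ — **consistent**: predominantly true variation (plus any
  miscall strong enough to fire every round); retained but flagged so it
  can be discarded or cross-checked downstream;
* $0.05 < f < 0.95$ — **RFP**: recurrent yet intermittent, the class this
  package exists to catalogue;
* $f \le 0.05$ — **sporadic**: one-off noise.

Both thresholds are strict inequalities. The same rule applied across
individuals of a cohort rather than across rounds (`popfreq_classify()`)
separates fixed strain variation (near 100% population frequency), rare
pedigree variation, and cohort-level RFPs; when a "cohort" is assembled
from the rounds of a single individual the two classifications coincide
exactly, which the test suite asserts.

## Models and default parameters

**Genome forge.** A single contig carries exon-like target regions: unique
targets and paralog family copies laid out in random order with randomised
spacing (minimum gap 400 bp, exceeding the pad). Each family is realised
from a template; every copy beyond the first receives difference sites drawn
binomially at rate $1-\mathrm{identity}$, placed uniformly, with the
alternative base uniform over the three non-template bases (divergence
between real paralogs is not characterised beyond "generally > 98%
identity", so uniform placement is this package's own choice). The ledger
records every pairwise difference site by direct comparison of the emitted
copies, so it is definitionally complete. A family can contribute a
*pseudogene*: a copy present in the genome but absent from the target
annotation, attracting reads without contributing any.

**Individuals.** `derive_individual()` plants homozygous (default) or
heterozygous SNVs into the target regions — about one per kilobase in the
standard scenarios, strain-like density — with a controllable fraction
inside paralog copies (default proportional to the paralog share of the
target space). Variants are confined to targets rather than the padded
sampling space: in exome designs the 325 bp pad exists to keep exon
coverage flat, while depth in the pad itself ramps toward the capture
edge; planting there would produce depth-driven call flicker unrelated to
paralogy. SNVs only (no indels), so individual and reference coordinates
coincide.

**Read sampler.** wgsim-style: fragments uniform with replacement over the
padded target space, insert length Normal(500, 50) truncated to
[2×read length, 2000], 120 bp mates (mate 2 reverse-complemented, the
physical end that becomes mate 1 randomised), each base substituted
independently at 1% to a uniform different base, constant Q25 base quality.
Coverage 30× in the standard scenarios; `coverage` converts to a pair count
over the sampling space. These follow the error rate, read length and
paired-end layout of the source workflow; insert geometry and quality
constant are this package's own defaults where the workflow left them
unstated.

**Aligner.** Seed-and-extend with three non-overlapping k-mer seeds
(k = 20) at read offsets {0, L/3, 2L/3}, querying both orientations of an
exact k-mer index; candidates are scored by Hamming distance (N counts as a
mismatch) and the minimum wins, with `max_mismatch` defaulting to
⌈3 + 4·error·L⌉ so true placements survive 1% error at 120 bp. Ties are
broken uniformly at random with a counter-based generator keyed on
(master seed, round, read index) — rounds are order-independent and
byte-reproducible — and tied placements get MAPQ 0. Otherwise MAPQ is
min(60, 10·(second−best)+20), a monotone function of the score gap chosen
for simplicity; 60 when no competitor exists. Paired mode prefers proper
pairs (opposite strands, leftmost forward, implied insert within ±4 SD)
scored jointly, and a jointly tied pair moves between copies as a unit with
a single draw. We claim the same qualitative random-assignment contract as
production BWA-style aligners, not placement-probability equivalence.

**Callers.** The pileup collapses duplicate pairs first (rmdup semantics)
and by default *includes* MAPQ-0 reads — tied reads entering the pileup is
the causal pathway of the phenomenon, and `min_mapq = 1` is provided
precisely to demonstrate suppression. Two independent rules emulate a
dual-caller comparison: rule A thresholds depth ≥ 5, alt count ≥ 3, alt
fraction ≥ 0.2; rule B compares binomial genotype likelihoods (RR/RA/AA at
ε = 0.01) and calls at likelihood ratio ≥ 10. Rule A is the pipeline
default. A consequence of these fixed parameters worth knowing: rule B's
minimal calling count is at or below rule A's at every depth, so A's calls
are essentially a subset of B's on the same pileup; the callers therefore
agree on clear sites (asserted ≥ 99% in tests) but their intersection
cannot emulate the partial overlap seen between production callers with
genuinely different error models. Rule B also admits more near-threshold
error-driven keys at 30×, which is why the standard catalogues use rule A.

## Why the mechanism needs individual variation

Under exhaustive Hamming scoring, an error-free read overlapping a
reference difference site always scores strictly better on its own copy —
reference difference sites alone are *not* miscalled at realistic
thresholds (the error-conversion route that flips the score order has
per-site rates orders of magnitude below the alt-count gates at 30×). What
is miscalled is the individual's own variation inside a duplicated region:
a read carrying a private SNV mismatches *both* copies equally once its
span covers no reference difference site, ties, and exports the allele to
the homologous position of the sister copy — the "echo" that recurs
intermittently. The mechanism oracle `mechanism_check()` therefore defines
inter-copy differences as the reference ledger sites *plus* planted
in-paralog variants, and verifies that an RFP's alternate allele equals the
sister copy's base at the homologous offset in the individual's realised
haplotypes. In the standard scenario every RFP key satisfies this check,
and excluding MAPQ-0 reads removes the class entirely — ties are the causal
pathway.

## Alignability

`alignability_track()` scores position $i$ as $1/$(number of exact
genome-wide occurrences of the k-mer starting at $i$, both strands);
k defaults to the read length under analysis. Occurrence counting is
exact-match — simpler than mismatch-tolerant mappability tracks, and
sufficient for synthetic genomes. For site-level comparisons the default
summary is the mean score over the k windows *covering* the site, i.e. the
uniqueness of the reads that pile up there, which is the quantity the
miscall mechanism acts through; the single start-window convention is
available as an option. RFP sites concentrate where covering windows are
shared between copies (score 0.5), and a one-sided Welch test against an
equal number of random target sites shows significantly lower alignability
(validated in the tests against a direct t-distribution computation).

## Study scenarios and problem sizes

All validation runs use fixed scenario builders:

* `null_scenario()` — 200 kb, no duplications, eight 5 kb unique targets,
  100 planted hom SNVs. Thirty rounds at 30× produce zero RFP-class keys
  and recover ≥ 99% of planted variants as consistent.
* `paralog_scenario()` — adds three 2-copy 10 kb families at 0.99 identity,
  one family's second copy a non-target pseudogene. Sized so the RFP class
  holds on the order of ten sites per 30-round run: enough for stable
  class fractions and a powered alignability test, in line with the
  RFP-rich non-reference strains that motivated the method.
* `sweep_scenario()` — a compact 120 kb variant (two families, three unique
  targets) used where many complete runs are required: the
  80/100/120/140 bp read-length sweep at matched base coverage (constant
  coverage, so fewer, longer pairs; five master seeds × 30 rounds each) and
  the individual-specificity study (three private-divergence levels ×
  three seeds × two individuals).

These sizes are desk-scale by design; the genome-scale phenomena they
reproduce are directional (monotone read-length effect, length-specific
catalogue membership, similarity decreasing with genetic distance), not the
absolute counts of any real genome.

## What the synthetic data does and does not emulate

The generator reproduces the ingredients the mechanism needs: near-identical
duplications with known difference sites, pseudogene-like untargeted
copies, strain-like variant density inside duplications, uniform redundant
sampling, substitution error, and random tie-breaking. It does not emulate
GC-dependent coverage bias, indels or structural variation, base-quality
variation, context-dependent error, capture efficiency differences, or the
seeding heuristics of production aligners (which add further, heuristic
miscall routes). Passing tests therefore demonstrate the causal chain and
the behaviour of the classification machinery, not calibrated error rates
for real exomes.

## Numerical choices and degenerate inputs

Tie-breaking, read sampling and per-round seeds all derive from a
splitmix-style counter generator, so results are independent of execution
order and of R's global RNG state (R-side draws are wrapped in
seed-restoring scopes). Strict threshold comparisons are exact because call
frequencies are small-integer ratios. Degenerate cases are signalled
explicitly: empty similarity comparisons return 1 with a warning, an empty
candidate universe makes `fraction_discovered()` error rather than return
NaN, zero-variance alignability comparisons error, and sampling intervals
shorter than twice the read length are skipped with a warning. The
accumulation curve takes its candidate universe from the *final* matrix
(keys with intermediate final frequency), making the curve reproducible;
its rate is summarised by the mean per-round increment with round 1
excluded as burn-in, plus a variance/mean dispersion statistic for
comparison with a Poisson increment model.

## Known limitations

* Single-contig genomes in the standard scenarios (the machinery supports
  multiple contigs; layouts beyond one contig are untested territory).
* The caller pair is deliberately simple; its nested thresholds cannot
  reproduce the partial-overlap behaviour of production caller pairs.
* Exact-match alignability underestimates the redundancy a
  mismatch-tolerant aligner experiences at diverged copies.
* Heterozygous support exists throughout (per-fragment haplotype sampling)
  but the validation scenarios are homozygous, matching the inbred-strain
  setting.
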