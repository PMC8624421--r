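---
title: "Methods: paired-tissue somatic mosaicism analysis for Hirschsprung disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-tissue somatic mosaicism analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enccmosaic)
```

This vignette is the package's own account of its models, parameters and
design choices. Hirschsprung disease (HSCR) is the congenital absence of
enteric ganglia in the distal gut; its cellular cause is the failure of
enteric neural crest cells (ENCCs) to complete rostro-caudal colonization of
the gut tube. When no germline mutation is found, a somatic mutation confined
to the ENCC lineage is a candidate explanation. The package implements the
full analytical chain for testing that hypothesis on paired-tissue data, and
a simulator for reasoning about when such a mutation could be sampled at all.

## 1. Cell-type-exclusive calling from amplicon counts

The unit of calling is a genomic site with per-amplicon ref/alt read counts
in two tissues of one individual (ENCC vs blood or fibroblast). Amplicon
capture groups reads by amplicon, so independent support can be counted per
amplicon. The rule set is deterministic:

* **presence** in a tissue: at least `min_alt_reads_per_amplicon` (5) alt
  reads in each of at least `min_supporting_amplicons` (2) amplicons, *and*
  pooled VAF at least `min_vaf` (10%). The 5-read rule is applied per
  amplicon and the 10% rule to the pooled reads: the former is phrased per
  amplicon, the latter over "reads" as a single pool;
* **absence** in the other tissue: pooled VAF at most `absence_max_vaf` (2%)
  and at most `absence_max_alt_reads` (2) alt reads in total. Literal zero is
  unattainable under sequencing noise, so "absent" must be an explicit
  threshold; 2% sits well below the 10% presence floor, and both knobs are
  configurable;
* **coverage mask**: both tissues need `min_coverage_both` (20×) pooled
  reads, otherwise the site is `masked_low_coverage` and never classified. A
  VAF with a zero-depth denominator is undefined, and such sites are always
  masked rather than called.

A site is `encc_only` (or `germline_only`) when presence holds in exactly one
tissue and absence in the other, `shared` when presence holds in both, and
`no_variant` otherwise. Every rule outcome is recorded in a `rationale`
string. Protein-altering candidates additionally pass a rarity filter:
population frequency strictly below `max_popfreq` (0.001) in *both* GnomAD
exome and genome sets — failing either set fails the variant, the
conservative reading of an "and/or" phrasing.

Multi-allelic sites are represented as separate bi-allelic records (chrom,
pos, ref, alt); nothing in the pipeline assumes one record per position.

### Concordance

Cross-tissue genotype concordance restricts to sites with ≥ 20× in both
tissues, genotypes each tissue by VAF bands and reports the fraction of
agreeing sites. The het band is `[0.20, 0.80]`: the lower bound follows the
conventional normal range for germline hets (20–70%); the upper bound is
symmetrized at 0.80 rather than 0.70 because an asymmetric band would misread
ordinary hom-alt noise (a het band ending at 0.70 classifies a 75%-VAF het as
hom-alt). True paired tissues concord at roughly 98.6–99.6% at this depth;
the synthetic generator, whose noise model is simpler than real
whole-exome chemistry, concords at ~100%.

## 2. Prioritization

Three disjunct deleteriousness criteria, any one sufficient (the source
phrasing is "and/or", and the study's own candidate list retains variants
lacking expression support, confirming OR semantics):

1. putative loss of function (frameshift, premature stop) or predicted splice
   effect, in an intolerant gene;
2. CADD (v1.4 scale) ≥ 15; a missing CADD never satisfies the criterion;
3. a deleterious majority in each of three prediction-tool clusters. The
   eleven underlying tools are not reimplemented; votes arrive as annotation
   input (or from the synthetic generator), with cluster sizes (4, 4, 3) and
   a strict per-cluster majority by default.

"Intolerant" has no published cutoff in this context; the default derivation
is pLI ≥ 0.9 **or** missense-Z ≥ 3, and callers may instead supply an
`intolerant_gene` column. Expression in the developing ENS (human fetal
intestine EW12–16; mouse ENS E11–15.5) *ranks* candidates but does not gate
them. The validation ranking is fully deterministic: passing verdicts, then
criteria count, then expression support, then supporting alt reads, then
CADD, then genomic order.

### The fixture replica configuration

The packaged per-variant study table prints constraint (MisZ, pLI) and
expression flags but neither CADD scores nor per-tool votes. Several printed
rows cannot re-derive a passing verdict from printed columns alone (e.g. a
premature stop in a gene with pLI 0.00). `table2_replica()` therefore credits
every fixture row with cluster consensus — the unprinted evidence behind its
inclusion — so the fixture cross-check verifies the package's *bookkeeping*:
grouping the listing by patient must reproduce the printed per-patient
prioritized counts (5, 1, 0, 15, 2). It is not a re-derivation of
deleteriousness, and the configuration is shipped precisely so that this
assumption is explicit and inspectable.

## 3. Detection power and Sanger validation

Alt reads in amplicon $i$ are $X_i \sim \mathrm{Bin}(C, p_\mathrm{eff})$ with
$p_\mathrm{eff} = v(1-e) + (1-v)e$ for true VAF $v$ and per-read error $e$.
The presence rule is an event over $(X_1,\dots,X_n)$; the analytic method
computes it exactly by dynamic programming over amplicons, tracking the
supporting-amplicon count and the pooled alt total (cost
$n(n{+}1)(nC{+}1)(C{+}1)$; above a configurable state bound the method
refuses and directs to Monte Carlo). Monte Carlo estimates the same
probability from seeded replicates; the two agree within 3 Monte-Carlo
standard errors across a VAF × coverage grid, and in the fully permissive
limit (1 read, 1 amplicon, no VAF floor) the dynamic programme equals
$1-(1-P(X \ge 1))^n$ exactly.

Power is monotone in true VAF. In coverage it is monotone only **above** the
10% pooled-VAF floor: below the floor, deeper sequencing concentrates the
observed VAF under the cutoff and the detection probability goes to zero.
This is a genuine property of threshold-based calling, documented and tested
rather than "fixed".

Sanger validation is modelled as a deterministic VAF threshold (default 10%),
matching the single sensitivity figure available for the assay: candidates
with true VAF at or above the floor confirm; sequencing artifacts (true VAF
0) never confirm. A logistic sensitivity curve was considered and rejected:
there is no data to fit its slope, and the threshold model already reproduces
the qualitative outcome pattern. Detection power concerns the affected tissue
only by default; a joint two-tissue option multiplies in the probability that
the other tissue passes the absence rule.

## 4. Mosaic copy number from paired array profiles

The study inspected paired array profiles visually. Visual inspection is not
testable, so this module substitutes an explicit, documented algorithm — a
deliberate replacement, not a reimplementation:

* **Segmentation**: binary segmentation of the LRR track per chromosome. A
  split is accepted when its SSE reduction exceeds
  `penalty_mult · σ² · log n` (default multiplier 3), with σ estimated
  robustly from successive LRR differences (MAD/√2). The penalty has a small
  absolute floor so that noise-free profiles are not split on rounding error.
  Minimum segment size is `min_probes` (25).
* **State**: from segment mean LRR against cutoffs (±0.03 by default;
  a mosaic loss in 10% of cells shifts LRR by log₂(1.95/2) ≈ −0.037, so the
  cutoffs sit just inside the platform's stated 10% detection limit).
* **Mosaic fraction**: from BAF, not LRR, because allele-frequency shift is
  the quantity of interest in the paired comparison. For a het locus with one
  allele lost in fraction $f$ of cells the BAF bands are $(1-f)/(2-f)$ and
  its mirror; for a single-copy gain, $1/(2+f)$ and $(1+f)/(2+f)$. The
  half-band-width $d$ is estimated noise-corrected as
  $\hat d = \sqrt{\max(\overline{(b-0.5)^2} - \hat\sigma^2_\mathrm{BAF},\,0)}$
  with $\hat\sigma^2_\mathrm{BAF}$ from homozygous probes, then inverted
  ($f = 4d/(1+2d)$ for losses, $4d/(1-2d)$ for gains). All statistics use
  $|b - 0.5|$, so reflecting BAF about 0.5 changes nothing (mirror symmetry).
* **Paired comparison**: ENCC-only events (germline interval copy-neutral)
  are flagged at estimated fraction ≥ 0.10; allele-specific differences on
  shared events at paired fraction difference ≥ 0.20 — the two thresholds
  transcribe the platform's stated detection limits. Each candidate is backed
  by a Wilcoxon rank-sum test on per-probe het BAF deviations with
  Benjamini–Hochberg correction at 0.05 across tested segments (the source
  procedure is silent on multiplicity; BH at 0.05 is the field default).

The synthetic profile generator places evenly spaced probes, draws
heterozygosity at 35% (typical informative-probe rate), puts het BAF on the
expected bands with the band side shared between tissues (the same physical
allele is affected), and adds Gaussian noise (BAF SD 0.03, LRR SD 0.15 —
representative of Illumina bead arrays). It does not model GC waves,
B-allele-frequency asymmetry, or probe-specific bias; passing tests therefore
demonstrate correctness of the statistics, not robustness to every real-array
artifact.

## 5. The clonal colonization simulator

No rates or update rules exist for the three verbal selection models, so the
simulator is an explicit formalization with all mechanics documented as
package choices. The gut is a chain of `n_segments` (50) segments with
carrying capacity 40 cells each. `n_founders` (10) cells start rostrally.
Per step, cells act in randomized order (avoiding positional bias):

* survive with probability `p_survive` (0.98);
* divide with probability `p_divide` (0.3), offspring placed locally if the
  segment has room;
* migrate one segment caudally with probability
  `p_advance · occupancy/capacity` (`p_advance` 0.5) if the target has room.

Migration is crowding-driven: sparsely populated segments retain their cells,
so the rostral gut stays colonized and the front advances by proliferation
pressure — the standard frontal-expansion picture of ENCC colonization. An
unconditional migration rule was tried and rejected: it drains the rostral
segments, leaving the proximal gut aganglionic even in healthy runs.

One uniformly chosen living cell mutates at the end of step `t_mut`
(`t_mut = 0` mutates a founder). Selection multiplies the mutant's
probabilities by `1 + s` (advantage) or `1 − s` (disadvantage) on any subset
of {division, migration, survival}, clipped to [0, 1] — the disadvantage
model names both migration and viability, so all three are selectable.
Superstar mode draws founder division multipliers from a Pareto law (tail
index 1.2), reproducing dominance of the final ENS by few clones, measured as
the Gini coefficient of final clone sizes.

Defaults were calibrated once so that wild-type colonization succeeds in well
over 95% of seeds within `n_steps` (120), leaving selection — not baseline
failure — as the driver of aganglionosis. Scenario sweeps in the analysis
scripts use 2 founders, mutation at step 0 and a 100-step window: the
early-mutation worst case with a deliberately tight colonization margin, the
regime where selection visibly shortens colonization. Sacral neural crest,
trans-mesenteric migration and ganglion differentiation are not modelled.

The biopsy readout converts a segment's mutant cell fraction into the allele
fraction bulk sequencing would see:
`expected_vaf = mutant_fraction × encc_tissue_fraction / 2` for a
heterozygous variant, with `encc_tissue_fraction` defaulting to 0.05 (ENCCs
are a small minority of a full-thickness biopsy) and 1 for a sorted/purified
ENCC sample. This is why even a surviving clone is near-invisible in a bulk
proximal biopsy: a 50% mutant fraction reads as ~1.2% VAF at 5% ENCC content,
far below both the caller's 10% floor and Sanger sensitivity.

## 6. The synthetic count generator

Per site and amplicon, coverage is negative-binomial (mean 50, dispersion 10;
dispersion → ∞ recovers Poisson) — no coverage distribution is published for
this assay, and moderate overdispersion mimics capture variability. Alt reads
are binomial with success probability `v(1−e) + (1−v)e` (symmetric per-read
miscall, default e = 0.001). Germline het sites sit at v = 0.5 in both
tissues; planted somatic variants have v > 0 in exactly one tissue. Optional
*systematic artifact* sites carry an elevated error rate (default 5%) in
**both** tissues — the mechanism that produces unvalidatable candidates: an
artifact can pass the presence rule in one tissue by chance while passing the
absence rule in the other, yet has true somatic VAF 0 and never confirms.
Both tissues share one amplicon panel (two staggered amplicons per site; two
is the minimum the calling rule can satisfy). A single integer seed fixes the
entire output.

The generator emulates count-level statistics only: no read-level errors, no
alignment artifacts, no strand bias, no DNA-quality gradients between
samples. Tests passing on this generator validate the pipeline's logic and
its operating characteristics under the stated noise model, not performance
on real Haloplex exomes.

## 7. Problem sizes and numerical choices

The shipped tests and scripts use: 500 single-site replicates for recovery
rates; a 5 × 5 VAF × coverage grid at 10⁴ Monte-Carlo replicates for power
agreement; CNV events holding ~500 het probes on 2000-probe chromosomes with
50–100 seeds per fraction; 200–500 colonization runs for drift checks and
80–100 seeds per sweep scenario. These sizes give Monte-Carlo standard errors
comfortably below the effect sizes being checked. Ties in the validation
ranking resolve by genomic order; degenerate inputs (zero-depth VAFs, empty
segments, empty gene lists) return masked/NA/warning results rather than
errors wherever the input is plausible in practice.

## 8. Known limitations

* The calling rule is the study's deterministic filter; it is not a
  probabilistic somatic genotyper and performs no error modelling beyond the
  thresholds.
* The rarity and deleteriousness annotations are inputs; no live GnomAD/CADD
  queries, no reimplementation of the cited prediction tools, and no ACMG
  classification (the fixture's "VUS" column is pass-through).
* The CNV module deliberately replaces the platform software + visual
  inspection with a documented algorithm; it does not reproduce the study's
  twelve germline CNVs, whose underlying data are not shareable.
* The colonization model is one-dimensional with local carrying capacity;
  continuous-space and reaction–diffusion formulations are out of scope.
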