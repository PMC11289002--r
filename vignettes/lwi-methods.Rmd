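---
title: "Methods: lipid-water-interface composition and conservation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid-water-interface composition and conservation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lwiscan)
```

## The problem

Polytopic membrane proteins such as sperm Ca^2+^ channels sit in the bilayer
with their transmembrane (TM) helices buried in the acyl core and a narrow
belt of residues on either membrane face exposed to the lipid-water interface
(LWI) — the headgroup layer where water is scarce but present and where
amphipathic ligands (steroids such as progesterone, prostaglandins) partition
preferentially. Whether a channel family shows molecular selection at this
belt — enrichment of aromatic "anchor" residues, exclusion of oxidation-prone
cysteines, a conserved balance of charge and hydrophobicity — is informative
about how it is regulated and how strongly each structural layer has been
constrained across evolution.

`lwiscan` implements this comparative analysis for a multi-species alignment
of a channel family: it anchors a TM topology on one reference sequence,
derives the LWI flank regions, and computes region-wise composition,
background comparisons, Kullback-Leibler enrichment/depletion logos, and
pairwise p-distance conservation, all stratified by vertebrate phylum
(mammal, bird, reptile, amphibian, fish). A star-phylogeny simulator with
planted ground truth closes the loop: every statistic the package reports is
validated against data whose true rates and compositions are known.

## Region model

The topology is given in 1-based inclusive *ungapped* reference coordinates
(the residue numbering a biologist would use, e.g. "Ser579") and transferred
to the alignment through the reference row's gap structure. The LWI is
operationalized as a residue rule, not an Angstrom rule: the `flank_width = 5`
residues on the N-terminal side (`N-TMi`) and the C-terminal side (`C-TMi`)
of each TM helix. A 6-TM topology therefore yields twelve flanks.

Three geometric conventions matter:

* **Membrane sides.** The side (inner = cytoplasmic, outer = extracellular)
  alternates at every TM crossing, starting from the annotated side of the
  N-terminus. With six TMs and an inner N-terminus the inner flanks are
  N-TM1, C-TM2, N-TM3, C-TM4, N-TM5, C-TM6.
* **Short loops.** When the loop between two TMs is shorter than
  `2 * flank_width`, the facing flanks overlap; the shared residues belong to
  *both* flanks. Per-flank statistics keep this double assignment, while the
  pooled selectors (`LWI_total`, `LWI_inner`, `LWI_outer`) deduplicate
  columns so that short loops are not double-weighted in aggregate
  frequencies. For a loop of length $L$ the overlap is
  $\min(L, \max(0, 2w - L))$ with $w$ the flank width: flanks are clipped so
  they never enter a TM segment, so a loop shorter than $w$ cannot share more
  than its own $L$ residues. A zero-length loop yields empty, truncated
  flanks rather than an error.
* **Reference anchoring.** Regions are defined on the reference and read in
  all species through alignment columns. Insertions private to non-reference
  species are invisible to the region statistics — the price of a single
  consistent coordinate system, and the same convention used when regions are
  selected from an alignment by hand.

## Composition statistics

Counts pool every non-gap, non-`X` character at the region columns over the
sequences of a stratum (`X` is never counted as an amino acid and never
enters a denominator). Pooling by residues (each residue one observation) is
the default; per-sequence averaging is available because reasonable software
differs on this point, and the two modes disagree exactly when sequences
contribute unequal residue numbers.

Group totals use a fixed seven-member hydrophobic set (Tyr, Ile, Leu, Met,
Phe, Cys, Trp) and the complementary thirteen-member hydrophilic set
(including Val), with positive = Arg, His, Lys and negative = Asp, Glu. Two
deliberate quirks are preserved because the analyses are defined on them:
Val sits in the hydrophilic set, and His belongs to both the hydrophilic and
the positive set, so the charge totals are not a sub-partition of the
hydrophilic total (the only invariants asserted are hydrophobic +
hydrophilic = 1 and positive + negative <= 1). A `conventional = TRUE`
switch in `aa_scales()` substitutes the Kyte-Doolittle-sign partition for
sensitivity analyses. Hydropathy is the frequency-weighted mean of the
published 20-value Kyte-Doolittle index; the Wimley-White interfacial
ordering is shipped for display ordering only; snorkeling-capable residues
(Lys, Arg, Trp, Tyr by default) are an annotation layer, not a statistic.

The "natural abundance" background is an explicit input. The packaged
default is the UniProtKB/Swiss-Prot proteome-average composition, chosen
because it is a standard, stable published baseline (Phe 0.0386, Cys 0.0138);
any two-column TSV can replace it. Ratios with a zero denominator are
flagged `Inf`, and `0/0` is `NaN`; enrichment calls are `absent` whenever the
observed frequency is exactly zero, which makes the Cys-exclusion phenotype a
deterministic, binary read-out.

## Conservation scoring

Conservation uses the p-distance — the proportion of differing residues over
compared sites, uniform rates across sites, 0 = identical, 1 = fully
diverged — because it is the least model-committed distance and the one the
boxplot comparisons are defined on. Data treatment happens per analyzed
region, in two steps: a sequence whose region is more than 50% gaps/`X` is
dropped from that region (the threshold is configurable and every drop is
recorded with its reason), and under complete deletion every remaining
column containing any gap/`X` is removed before distances are computed.
Pairwise deletion is available for full-length comparisons where complete
deletion would be too aggressive.

Bootstrap variances resample the retained columns with replacement
(independently across replicates, multinomially over columns) and record the
per-pair variance of replicate distances; 1000 replicates is the default. A
single integer seed drives all resampling, and a fixed seed reproduces the
variances bit for bit. Degenerate pairs (no comparable sites) carry `NA`
flags rather than raising errors, so one bad sequence cannot abort a family
run; fewer than two retained sequences is an error.

## Enrichment/depletion logos

Logo heights are the signed per-letter Kullback-Leibler contributions
$h_a = p_a \log_2(p_a / q_a)$ against the background $q$: positive for
enriched letters, negative for depleted ones, zero at $p_a = q_a$, and
summing (with signs) to the position's KL divergence, which is non-negative
whenever $p$ is a proper distribution. Column distributions use
background-weighted pseudocounts, $p_a = (n_a + w q_a)/(n + w)$ with
$w = 1$ by default: this keeps unobserved letters off the $\log 0$
singularity while shrinking all heights toward zero as $w \to \infty$.
$w = 0$ is permitted — unobserved letters then contribute height 0 by the
$p \log p \to 0$ limit — and is what the exact closed-form checks in the test
suite use. The background must be strictly positive; a zero entry is a
configuration error, not a silent infinity. The tested surface is the height
table; the stacked-letter graphic is a best-effort rendering.

## Chi-square reporting

Independence tests use the Pearson statistic without continuity correction
and $(r-1)(c-1)$ degrees of freedom. The default table construction is
letters x regions within a stratum (TM vs inner LWI vs outer LWI), the most
direct reading of "independence of the group" across region categories; the
mode is recorded in the run manifest because other constructions are
defensible. All-zero rows (e.g. Cys absent everywhere) can be dropped before
testing, and a zero margin is a degeneracy error. No multiple-testing
correction is applied by default — the reports carry raw statistics — and a
Bonferroni option is deliberately left to the caller's judgment.

## The synthetic-data generator

The simulator is first-class, tested code, because it is the ground truth
everything else is validated against. Its model:

* **Star phylogeny.** Every species descends independently from a common
  ancestor. This is deliberately unrealistic (no nested clades) but makes the
  expected pairwise distance analytically checkable: two branches with
  substitution probability $r$ at a site class with stationary composition
  $p$ differ with probability $(1-(1-r)^2)\,(1-\sum_a p_a^2)$.
* **Substitution to stationarity.** A substituting site redraws its residue
  from the class stationary distribution (possibly the same letter), so the
  planted compositions are exact stationary targets while distances grow
  with the rate — the property the composition-recovery tests need.
* **Architecture.** Six 21-residue TMs, loop lengths 12, 8, 16, 10, 24: one
  loop shorter than $2w$ (overlapping flanks) and one exactly $2w$ (abutting
  flanks), so the overlap bookkeeping is exercised by the default dataset.
  Tails are length-jittered per species (uniform +/- 15) and gap-padded
  outward; the core is gapless, since downstream statistics only read
  reference-anchored columns and simulating an aligner is out of scope.
* **Rates.** TM 0.05 < LWI 0.20 < loop 0.30 plant the conservation ordering
  TM < full-length < LWI. Terminal tails evolve at 0.10: the full-length
  distance is a site mixture dominated by the long tails, and a moderate
  tail rate places that mixture strictly between the TM and LWI medians — a
  long, moderately conserved tail, consistent with a tail that carries
  functional content (the His-rich pH-sensor-like mammalian N-terminus)
  while still being the least structurally constrained part of the protein.
* **Compositions.** The inner-LWI stationary pins Phe at 0.20 (against a
  background of 0.039) with Trp/Tyr elevated, both LWI classes carry zero
  Cys weight (the planted exclusion), the TM stationary is
  hydrophobic-dominated, and loops/tails follow the Swiss-Prot background.
  Tails are lineage-specific expansions, so each phylum draws its own tail
  ancestor; the mammal override pins His at 0.17 in mammalian tails
  (N-tails 350 residues vs 120 in fish).

### What a passing test does and does not show

The generator emulates the *statistical* structure of a real multi-species
retrieval: phylum strata, region-specific constraint, planted compositional
signals, length-variable tails. It does not emulate indel evolution inside
the core, alignment error, annotation error in the TM intervals, nested
phylogenetic structure, or site-to-site rate variation within a class.
Passing tests therefore demonstrate that the *pipeline* recovers planted
structure correctly — not that any particular biological family has that
structure.

### Correlation-aware validation intervals

One statistical point is easy to get wrong and is handled explicitly
throughout the test suite. Under the star model the residues of different
species at one site are *correlated* (they share an ancestor with
probability $(1-r)^2$), so the pooled frequency of a letter over $S$ sites
and $N$ species has variance

$$\mathrm{Var}(\hat f) \;=\; \frac{p(1-p)\,\bigl[1 + (N-1)(1-r)^2\bigr]}{S\,N},$$

not the binomial $p(1-p)/(SN)$. At the default LWI rate ($r = 0.2$,
$N = 50$) the inflation factor is about 32: the effective sample size is set
by ancestor *sites*, not residues. Recovery tests for planted frequencies
therefore use 99% intervals from this exact variance (pooling several
independently seeded families to grow $S$), and the chi-square calibration
check runs at near-saturation rates ($r = 0.95$), where the correlation term
vanishes and Pearson's test is actually calibrated — at low rates the shared
ancestry overdisperses the counts and no implementation would produce
uniform p-values. For the same reason the noise floor of a null logo is set
by ancestral dominance of each column, not by multinomial sampling, so the
null-logo check compares the fixture against a bound derived by simulating
the same null process rather than against a fixed constant.

## Numerical choices and degenerate inputs

* Background tables must cover all 20 letters, be strictly inside $(0,1)$,
  and sum to 1 within $10^{-3}$ (then renormalized exactly); anything else
  is an error, not a warning.
* Frequencies of a non-degenerate profile sum to 1 within floating-point
  error; empty regions produce flagged degenerate profiles rather than NaN
  arithmetic downstream.
* Ties in median orderings are reported as ties (`=`), never broken
  arbitrarily.
* All user-facing coordinates are 1-based inclusive; the single conversion
  to alignment columns happens in `map_reference_to_columns()`.
* Every stochastic step (generator, bootstrap) is governed by one integer
  seed and restores the caller's RNG state, so pipeline outputs are
  byte-identical across runs with the same inputs and seed.

## Problem sizes

The bundled study conditions use 50 sequences (5 phyla x 10 species) of
aligned width ~725, giving 1225 pairwise distances per pooled region, 1400+
pooled inner-LWI residues per family, and 28/30 inner/outer interface
columns. Validation runs pool up to six independently seeded families for
composition recovery, use 200 generated families for the chi-square null
calibration, 200 random topologies for the geometry oracle, and 1000
replicates for bootstrap variances. These sizes keep every sampling check
inside comfortable Monte-Carlo error while the full suite runs in under a
minute on one core.

## Limitations

* Regions are reference-anchored: species-private insertions never enter
  any region statistic.
* The 50% gap-fraction drop rule is a declared stand-in for the informal
  "improper sequence" removal a human analyst performs; it is configurable
  and logged, but any fixed threshold is somewhat arbitrary.
* p-distance ignores substitution-model corrections by design; at high
  divergence it saturates and differences between highly diverged regions
  compress.
* The chi-square construction on pooled residue counts inherits the
  phylogenetic-correlation caveat above whenever species are few and slowly
  evolving; its raw statistics are comparative descriptors, not calibrated
  hypothesis tests, on such data.
* The logo module implements the standard KL construction only — no
  sequence weighting or redundancy reduction.
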