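---
title: "Variant effect maps from multiplexed assays: models and methods"
author: "mavemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant effect maps from multiplexed assays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mavemap)
```

# Overview

`mavemap` implements the computational side of a multiplexed assay of
variant effect (MAVE) built on TileSeq-style variant counting: a
saturation-mutagenised library of protein variants is subjected to a
selection (for example, competitive yeast growth reporting enzymatic
activity, or FACS gating on a GFP fusion reporting steady-state protein
abundance), short amplicon tiles are sequenced deeply before and after
selection, and per-variant read frequencies are turned into functional
scores. The package covers five analysis layers:

1. **Synthetic data** with known ground truth (`simulateTruth()`,
   `simulateCountTables()`), so that every downstream stage is testable
   without any external download.
2. **Scoring** (`scoreTileseq()` and its stage functions): filtering,
   wild-type error correction, enrichment ratios, error regularisation,
   replicate combination, and rescaling.
3. **Map assembly** (`buildEffectMap()` and map-level statistics).
4. **Clinical calibration** (`balancedPrcCurve()`, `kdeLlr()`,
   `evidenceStrength()`).
5. **Structure and trajectory annotation** (`computeRsa()`,
   `interfaceResidues()`, `msf()`, `hbondOccupancy()`, ...).

# The selection and sequencing model behind the generator

The generator emulates the experiment at the level where the scoring
pipeline meets the data: marginal variant frequencies in read counts.

**Variant space.** `enumerateVariantSpace()` enumerates every amino-acid
outcome reachable by replacing each codon with an NNK degenerate codon
(N = A/C/G/T, K = G/T); NNK reaches all 20 residues plus the TAG stop, so
a protein of L residues yields 21 outcomes per position: one synonymous,
one nonsense, 19 missense. The default reference ORF is a seeded random
synthetic sequence (`randomOrf()`); any real ORF can be substituted and
nothing downstream depends on the particular codons beyond the NNK
reachability pattern.

**True effects.** Missense effects are drawn from a two-mode Gaussian
mixture: a damaged mode centred at 0 and a tolerated mode centred at 1
(`modeSd = 0.08` each), with the damaged-mode weight
`deleteriousFraction` defaulting to 0.15 (the scenario presets use 0.14
for the activity flavour and 0.18 for abundance, matching the fractions
of missense variants observed in the deleterious peaks of real maps).
Synonymous variants are fixed at exactly 1 and nonsense at exactly 0.
Real score distributions say nothing about the *within-mode* shape of
true effects; the Gaussian modes are a declared stand-in, and tests that
depend only on the bimodal structure are insensitive to it.

**Clone pool and selection.** Substitutions per clone are Poisson with
mean `cloneLambda` (0.64 activity / 0.83 abundance) over a pool of
`poolSize` clones, variants assigned uniformly; only marginal carriage
frequencies are tracked, because amplicon tiles cannot observe distal
co-occurring variants, so linkage is deliberately not modelled.
Selection multiplies each variant's frequency by

$$ s(e) = f + (1 - f)\,\mathrm{clamp}(e, 0, 1), $$

with `selectionFloor` $f = 0.05$ the residual survival of a null
variant, then renormalises over the pool (mean pool fitness
$\bar Z$). A consequence worth knowing when testing: the expected
corrected post/pre ratio of a nonsense variant is $f / \bar Z$, which
approaches $f$ only as the selected fraction of the pool vanishes.

**Replicate noise.** At a depth of 1.3 million reads per tile,
multinomial counting noise alone would give replicate-to-replicate score
correlations near 0.99 — far tighter than real biological replicates,
which agree at about $R \approx 0.8$ in this assay family. The generator
therefore applies a log-normal factor (sd `replicateNoiseSd`, natural
log) to each variant's selection weight independently per replicate,
emulating growth and sorting stochasticity. The default 0.5 was fixed
once by matching the replicate agreement regime (it yields
$R \approx 0.78$–$0.79$ across seeds; 0.4 gave $\approx 0.85$); it was
not revisited afterwards.

**Errors and controls.** Each variant carries a gamma-distributed
sequencing-error frequency (shape 2, scale $2.5\times10^{-6}$; mean 5
reads per million, the ballpark of duplex-sequencing residual error).
The same per-variant error rate enters the library conditions and is the
*only* signal in the wild-type control samples, so WT subtraction is
exactly unbiased in expectation — a deliberate idealisation: real error
processes drift between samples.

Counts per tile, condition and replicate are multinomial at the
configured depth, with the per-tile wild-type remainder absorbing the
unassigned mass, so counts conserve depth exactly.

# Scoring

Given counts for `pre`, `post`, `wt_pre` and `wt_post`:

* **Filters** (per replicate; a variant is excluded only if flagged in
  every replicate): pre-selection raw count < 10 reads; pre-selection
  frequency < 10 counts per million (inclusive at 10); pre-selection
  frequency not exceeding the 90th percentile of the wild-type-control
  frequency distribution *within the same tile*. The percentile is taken
  across variants within a tile — the wording of this filter is
  ambiguous in the field, and per-tile-across-variants is the reading
  that makes the control distribution estimable from one sample.
* **Correction and enrichment**: corrected frequencies
  $f' = f_{\mathrm{lib}} - f_{\mathrm{WT}}$ in both conditions;
  $\phi = f'_{post}/f'_{pre}$, worked on the log2 scale (log ratios
  symmetrise noise; the lineage of TileSeq scoring tools does the same).
  A non-positive corrected pre frequency is unscorable; a non-positive
  corrected post frequency is floored at one pseudo-read ($1/\text{depth}$)
  so fully depleted (typically nonsense) variants stay scoreable.
* **Error regularisation**: the empirical replicate sd of $\log_2\phi$
  is shrunk toward a trend fitted by linear regression of
  $\log(\mathrm{sd})$ on $\log(\text{pre-selection cpm})$ over all
  variants, with pseudo-observation weight $m = 2$:
  $se_{reg}^2 = (m\,\sigma^2_{model} + (n-1)\,\sigma^2_{emp})/(m+n-1)$,
  $df = m+n-1$. $m = 2$ balances a two-replicate design; $m = 0$
  recovers the raw empirical sd.
* **Replicate combination**: inverse-variance weighted mean, combined
  $se = (\sum w)^{-1/2}$, Welch–Satterthwaite df. Single-replicate
  variants pass through flagged.
* **Rescaling**: scores are linear-rescaled on the combined log2 scale
  so the nonsense median is exactly 0 and the synonymous median exactly
  1; standard errors scale by the same factor. This makes the two anchor
  medians exact by construction — a property the acceptance checks
  verify on every synthetic run.

# Map assembly and tolerance classes

`buildEffectMap()` arranges scores into an L × 21 matrix. Cells are
*damaging* below the map threshold (0.5 for activity-style maps, −0.4
for abundance-style maps — both taken from the minimum between the
bimodal score modes in the real maps), *hyper* above $1 + 2\,se$ (the
published maps colour an above-WT class without stating a rule; two
standard errors above the WT anchor is this package's choice), *wt* on
the wild-type residue, *tolerated* otherwise.

`findBimodalThreshold()` re-derives a threshold from data: a
kernel-density estimate (Sheather–Jones bandwidth — Silverman's rule
oversmooths mixtures) whose most *prominent* interior valley (maximum
ratio of the lower flanking peak to the valley density, at least 1.5)
gives the cut point; the centre of the minimal-density plateau is
reported so the result is stable when the inter-mode density underflows
to a flat zero. Unimodal inputs fall back to the configured default with
a warning.

Map-level statistics use standard machinery: two-sided Mann–Whitney
contrasts over substitution-property groups (exact enumeration for small
groups — the base distribution functions cannot produce exact two-sided
p-values under ties), Benjamini–Hochberg adjustment within each contrast
family, Fisher's exact test with the sample log-odds ratio for
counter-selection against observed cohorts, sample-size-weighted
collapsing for multi-study phenotype values, and Spearman correlations
throughout (reported as "undefined" rather than NaN for constant
vectors). The stability-discordance report flags positions whose median
score falls below the damaging threshold while the median predicted
ΔΔG sits at or above the destabilisation cutoff; both the −0.5 and the
−0.1 cutoff conventions circulate for ΔΔG and the parameter is exposed
rather than asserted.

# Clinical calibration

**Balanced precision–recall.** With reference sets of unequal size,
precision depends on the set-size ratio; balanced precision re-weights
positives and negatives 50/50 via Bayes' rule:
$bp = \mathrm{recall}/(\mathrm{recall} + \mathrm{FPR})$. Thresholds
sweep the observed scores, lower score meaning more pathogenic by
default, with ties called pathogenic-side. AUBPRC is the trapezoid area
over recall after keeping the best balanced precision per distinct
recall; R90BP is the largest recall at $bp \ge 0.9$, 0 if never
reached.

**LLRp.** Densities of the positive and negative reference scores are
fitted with an Epanechnikov kernel and per-set Sheather–Jones bandwidth;
$LLR_p(s) = \ln f_P(s) - \ln f_B(s)$. Queries outside the joint support
are clamped to its edge and each density is floored at $10^{-6}$ of its
maximum, so extreme scores give large but finite evidence. Confidence
intervals are percentile bootstrap (case resampling within each
reference set independently, both densities refitted per resample;
degenerate resamples dropped and counted) — the interval method is this
package's choice, as the published maps ship intervals without stating
one.

**Evidence strengths** follow the odds-of-pathogenicity ladder: with
very-strong odds `opVst = 350`, pathogenic cutoffs sit at
$\ln 350^{1/8}, \ln 350^{1/4}, \ln 350^{1/2}, \ln 350$
(supporting/moderate/strong/very strong), mirrored on the benign side.
By default a category is assigned only when the bootstrap interval
excludes the opposite side of zero; this conservative gate is not part
of the published ladder and can be disabled (`gateCI = FALSE`).

# Structure and trajectory annotation

Solvent accessibility is computed by the Shrake–Rupley point-sampling
algorithm over heavy atoms (crystal structures typically lack
hydrogens), 960 deterministic golden-spiral points per atom and a 1.4 Å
water probe, normalised by the theoretical Gly-X-Gly maxima (Tien et
al. 2013) to a relative accessibility that may exceed 1 in extended
conformations. Residues are *core* below 20% and *surface* above 35%
relative accessibility; both monomer and complex contexts can be
computed by selecting chains, and the caller chooses which to classify
on. Interfaces are residues with any heavy atom within 5.0 Å of the
partner chain. Positional map summaries can be painted into the
B-factor column for structure viewers, with a sentinel for unscored
residues.

Trajectory statistics operate on multi-model PDB input (keeping the
package dependency-light): mean-square fluctuation relative to the first
frame, with optional Kabsch superposition over Cα atoms (on by default;
the atom selection is caller-specified since conventions differ between
backbone and Cα-only reporting); Cα pair-distance mean and *population*
sd; and hydrogen-bond occupancy with inclusive thresholds of 3.4 Å on
the donor–acceptor distance and 120° on the donor–hydrogen···acceptor
angle (180° = linear). Explicit hydrogens are required — no implicit
hydrogen geometry is inferred.

# Numerical choices and degenerate inputs

* All randomness flows from one root seed through fixed per-stage
  substreams (`mavemap:::stageSeed`), so identical configurations
  reproduce byte-identical outputs.
* Tie handling: scores exactly at a PRC threshold are pathogenic-side;
  Mann–Whitney ties count one half; evidence-ladder boundaries are
  inclusive on their own side.
* Degenerate inputs error early and name the offender: zero depth,
  duplicate count rows, missing wild-type controls, constant reference
  sets (zero bandwidth), inverted selection (synonymous median at or
  below nonsense median), residue types without a tabulated maximum
  ASA, unknown chains, unresolvable atoms.
* `regularizeErrors()` refuses to fit its trend on fewer than 30
  replicate pairs rather than silently extrapolating.

# Problem sizes used by the tests

The test and acceptance runs use the default study conditions — 153
residues, five tiles, 1.3 million reads per tile, two replicates (3213
variants) — for the end-to-end properties, and 25–60-residue variants of
the same configuration for distributional unit tests. Bootstrap
intervals use 200 resamples in tests (1000 by default in the pipeline).

# What passing tests do and do not show

The generator reproduces the statistical structure the scoring pipeline
assumes: marginal frequencies, shared error rates between library and
control, independent replicate noise, depth-conserving counts. It does
not model PCR jackpotting, base-caller artefacts, linkage between
co-occurring variants, fluorescence gating, or drifting error profiles —
so green tests certify the pipeline's arithmetic and its behaviour under
the declared model, not robustness to every real-data pathology. The
calibration layer is exercised against synthetic reference sets with
known contamination (`labelNoise`); real reference sets carry
label noise of unknown structure, and performance numbers on them should
be read accordingly.

# Known limitations

* Scores for multi-variant clones are marginal by construction; a
  variant sharing clones with a deleterious passenger is not modelled.
* The KDE threshold finder assumes at most two meaningful modes.
* Bootstrap LLRp intervals understate uncertainty when a reference set
  is very small, because bandwidth selection is re-estimated per
  resample and can stabilise artificially.
* The Shrake–Rupley implementation is O(atoms × neighbours × points) in
  plain R: comfortably fast for single proteins and complexes, not for
  large trajectories of accessibility calculations.
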