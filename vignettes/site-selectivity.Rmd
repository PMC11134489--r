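---
title: "Predicting C-H borylation regioselectivity site by site"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting C-H borylation regioselectivity site by site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borysite)
```

## The problem

Iridium-catalyzed C–H borylation installs a pinacol boronate (Bpin) group at
an aromatic C–H position of a substrate. Because most substrates expose
several chemically similar C–H bonds, the practical question is
*regioselectivity*: which position reacts, and does the reaction happen at
all. borysite treats this as a per-site binary classification (and,
secondarily, per-site yield regression) problem:

1. every symmetry-distinct aromatic C–H position of a substrate becomes one
   *site reaction* `substrate>>site-product`, generated by formally replacing
   one H by Bpin;
2. each site reaction is featurized with a differential reaction fingerprint
   (DRFP);
3. a random forest predicts whether the site reacts (class 1) or not
   (class 0), or its percent yield;
4. per-site predictions are aggregated to a molecule-level call: the set of
   reactive sites, the major site, or "no reaction" when every site is
   predicted unreactive.

## Site identity and enumeration

All structural reasoning happens on OpenBabel canonical SMILES; a site is an
atom index into the canonical atom ordering, so site identities survive
re-serialization. Two positions of a molecule give the same monoborylation
product exactly when they are exchanged by an automorphism of the molecular
graph, so enumeration works per symmetry class: classes are the orbits of
the vertex- and bond-colored automorphism group (computed exactly with
BLISS via igraph; atoms are colored by element, aromaticity, charge,
isotope and hydrogen count). The class representative is the lowest
canonical atom id, and each class contributes one candidate site. The
equivalence between "one site per symmetry class" and "one site per unique
canonical product" is enforced by a test that brute-forces the product set
over every raw position.

Two eligibility modes exist: `aromatic_CH` (the default; aromatic carbons
bearing hydrogen) and `nonquaternary_C` (any carbon bearing hydrogen, for
datasets labeled over all non-quaternary carbons). Heteroatom N–H/O–H
positions are never enumerated.

```{r}
enumerate_sites("c1ccncc1")[, c("site_atom", "n_equivalent", "site_product")]
```

## Curation of raw reaction data

Raw reaction SMILES collections mix genuine C–H borylations with Miyaura
borylations (C–X → C–B), other boron chemistry, and noise. The curation
funnel applies, in order:

1. **naive screen** — substrate has a C–H bond and some product a C–B bond;
2. **fragment matching** — every product C–B bond is cut in turn, the boron
   fragment discarded, the carbon capped with one hydrogen and
   re-canonicalized; the reaction is kept if some cleavage reproduces the
   substrate exactly. This pinpoints the borylated carbon and rejects
   Miyaura-type reactions, whose capped fragment lacks the halide. The
   boron-containing fragment is discarded whole whatever its identity
   (Bpin, Bneop, catecholboronate), and capping restores exactly one
   hydrogen, preserving charges and isotopes — C–H borylation replaces H by
   B, so its reversal must restore H;
3. **validity** — records whose SMILES do not parse are dropped here (the
   external structure-resolution step used with proprietary registries is
   replaced by parseability checking, so the pipeline has no service
   dependency);
4. **yield presence** (optional) and the **iridium + aromatic-site** filter;
5. deduplication by canonical (substrate, product) pair, ignoring agents,
   since commercial databases multiply report the same transformation under
   different conditions.

Stage counts are reported as a funnel (`autoplot()` draws it). Retained
records carry the matched site atom id, which `build_site_dataset()` uses
to label every enumerated candidate site 0 or 1 by canonical product
comparison. Multi-product records are kept as mixtures and simply label
several sites reactive; unmatched experimental products are surfaced as
warnings rather than silently dropped.

## Differential reaction fingerprints

The DRFP of a site reaction is built from scratch:

- **shingles**: for every atom and radius 0–3, the circular environment
  (all atoms within that bond distance) is extracted as a canonical
  fragment string; every smallest ring contributes a shingle too.
  Fragment strings are written by the package's own deterministic writer
  over a Weisfeiler–Lehman canonical atom ordering, so the same abstract
  substructure yields the same string in any molecule and any input
  serialization (environments that straddle partial aromatic rings are not
  valid standalone SMILES, which is why molecule-level canonicalization
  cannot be reused here; shingles are hash keys and are never re-parsed).
  Hydrogen counts are omitted from shingle atom tokens.
- **symmetric difference**: shingles present on exactly one side of the
  reaction survive; shared context cancels. Agents are ignored and the
  fingerprint is invariant to reaction direction.
- **hashing**: each surviving shingle sets bit `fnv1a32(shingle) mod n_bits`.
  FNV-1a (offset basis 2166136261, prime 16777619) is fixed, documented and
  platform-independent, so fingerprints are bit-exact across machines and
  processes — a per-process randomized hash would silently break model
  reuse.

Defaults are 256 bits and radius 3 with ring shingles, the construction of
the original DRFP literature; both are arguments everywhere. 256 bits is
deliberately small: collisions occur but the classifier tolerates them.

```{r}
f <- drfp("c1ccccc1>>CC1(C)OB(OC1(C)C)c1ccccc1")
sum(f)   # set bits out of 256
```

## Models

`fit_site_model()` trains a ranger random forest on the fingerprints of
labeled site reactions. The "default hyperparameters" of the baseline are
pinned numerically in the model object so they cannot drift with library
versions: 500 trees; Gini splitting with `mtry = floor(sqrt(p))` for
classification; variance splitting with `mtry = p` (all features, the
convention of the toolkit family the fingerprint baseline originates from)
for regression; one thread; an explicit seed. The classifier's decision
threshold is a 0.5 class probability (majority vote).

For the yield task, unreactive sites train with yield 0. Reactive sites
with unreported yields are *excluded* rather than imputed: reported yields
in the literature are biased upward, and imputing a mid value would teach
the regressor that unmeasured successes look like failures. A reaction is
called successful when its (predicted) yield reaches the 5% threshold,
which is also where the regressor is compared with the classifier.

`predict_molecule()` aggregates per-site predictions; the major site is the
argmax of probability or predicted yield, with ties broken toward the
lowest canonical atom id for determinism. Candidate products can be
screened with `substructure_postfilter()`: in C–H functionalization the
substrate must be a subgraph of any true product, so candidates failing an
element-, aromaticity- and bond-type-aware monomorphism test are discarded.

## Evaluation

Reactive and unreactive sites are imbalanced (roughly 1:2 under the
synthetic conditions below, more skewed in real data), so the headline
site-level metric is the Matthews correlation coefficient, with accuracy,
PPV, recall and F1 reported alongside. The molecule-level metric is strict:
a substrate counts as correct only when *all* its sites are classified
correctly. For regression, R², MAE and RMSE are complemented by the
outcome-MCC at the 5% success threshold and by major-product accuracy
(argmax predicted yield versus the experimentally highest-yielding site;
experimental ties count any tied site as correct).

Splits are always by unique substrate — splitting by reaction record would
leak the same molecule into train and test. Besides the seeded random
split (10% held out by default, matching a ~100-molecule validation set
for a ~1000-reaction corpus), two chemistry-aware partitions stress
generalization: heterocycle- versus carbocycle-reacting substrates
(decided by the reactive site's smallest aromatic rings; substrates
reacting at both kinds go to the heterocycle side with a warning, and
substrates with no reactive site default to the carbocycle side) and
single- versus multi-ring substrates.

## The synthetic data generator

Real borylation corpora are built from licensed registry records and
cannot be redistributed, so the package ships a seeded generator whose
*selectivity structure* follows the field's qualitative guidelines:
borylation avoids positions flanked by substituents (sterics) and
positions adjacent to basic pyridine-type nitrogens; electron-poor
N-heteroarenes react preferentially to plain arenes; five-membered
heteroarenes are the most reactive. Substrates are drawn from the ring
systems that dominate real borylation data (benzene, thiophene, furan,
pyridine, pyrazole, indole, quinoline, benzothiophene, benzofuran,
benzene-weighted), optionally biaryl-linked, and decorated with 0–3
substituents from {Me, OMe, F, Cl, CF3, CN, CO2Me}.

Each candidate site receives an additive score: base 2.0 on five-membered
heteroaromatic rings, 1.5 on six-membered N-heteroaromatic rings, 1.0 on
carbocycles; −1.5 per flanking ring atom carrying a substituent or ring
fusion; −2.0 per adjacent pyridine-type nitrogen. The constants are
deliberately arbitrary — the guidelines are ordinal — and were chosen once
so that each guideline is decisive in isolation (each is verified by a
dedicated test). Score maxima react; ties react as mixtures. Major-site
yields are drawn from N(70, 15) clipped to [5, 99], minor mixture
components from N(30, 10) clipped to [5, 60]; only yields ≥ 5 are ever
reported, emulating the reporting bias of the literature. An optional
noise fraction reassigns the reactive site uniformly at random. Agents
include B2pin2 and an iridium species (the placeholder `[Ir]` — the
catalyst's identity is irrelevant to every downstream step, which only
tests for the element).

What the generator does *not* emulate: real ring-frequency proportions,
chelation- or catalyst-directed selectivity, solvent/temperature effects,
and systematically missing yields. Passing the recovery experiment below
therefore shows that the pipeline can learn a consistent steric/electronic
selectivity rule from ~1000 reactions — not that it reproduces real-data
accuracy.

## The reference experiment

The package's standard end-to-end experiment generates 1000 substrates
(seed 7, no label noise), curates them (the full set survives the funnel
by construction, which is itself a round-trip test of enumeration against
fragmentation), builds ~3800 labeled sites, splits 800/200 substrates, and
trains both models on the training sites. Typical held-out results:
site-level MCC ≈ 0.67 with accuracy ≈ 0.84, molecule-level all-sites
accuracy ≈ 0.59, yield R² ≈ 0.43 with outcome-MCC ≈ 0.50 at the 5%
threshold, and major-product accuracy ≈ 0.82. This mirrors the ordering
seen with the real-data baselines this design follows (strong site-level
classification, a weaker thresholded regressor, strict molecule-level
accuracy well below site accuracy). `scripts/acceptance.R` reruns exactly
this experiment from scratch and writes the numbers as JSON.

These problem sizes keep a full run in the ten-minute range on one core;
the same experiment at a few hundred substrates runs in about a minute and
is what most tests use.

## Numerical and degenerate-input choices

- MCC is defined as 0 whenever a denominator factor vanishes; PPV, recall
  and F1 fall back to 0 in their degenerate cases; R² on a constant target
  is NaN with a warning. MCC is computed in double precision (the
  denominator product overflows 32-bit integers at realistic sizes).
- Enumeration of a substrate with no eligible carbon returns zero rows, and
  molecule-level prediction then reports `no_reaction` with an empty site
  list rather than erroring.
- Unparseable records in curation are counted as validity-stage drops and
  logged by id; the funnel counts are non-increasing by construction.
- Aromaticity is OpenBabel's default perception model, used consistently on
  canonical SMILES everywhere (the aromaticity convention assumed by
  upstream registry exports is unknowable from the data itself; one model
  applied uniformly keeps site identities and matches self-consistent).
- All randomness (generator, splits, forests) flows through explicit integer
  seeds; reruns are bit-identical.

## Known limitations

- Stereochemistry is ignored: stereo marks parse but do not contribute to
  site identity or shingles.
- The Bpin group is fixed for generated products; experimental products
  carrying other boron groups are matched only through fragment cleavage
  during curation, not during site labeling.
- The Weisfeiler–Lehman ordering behind shingle strings is not a complete
  graph canonicalization; on highly regular fragments two non-equivalent
  atoms could in principle tie, perturbing single fingerprint bits. Site
  identity never relies on it (orbits come from BLISS automorphisms).
- Molecule-level symmetry means per-class enumeration weights each unique
  product once; datasets that count raw positions can use
  `collapse_symmetry = FALSE`.
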