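---
title: "Karyotype and oligo-FISH signal analysis: models and methods"
author: "karyofish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype and oligo-FISH signal analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyofish)
```

## Scope

`karyofish` implements a complete karyotype and FISH-signal analysis
pipeline for five Fabaceae taxa — *Robinia pseudoacacia*, its cultivar
'idaho', *R. pseudoacacia* f. *decaisneana*, *Styphnolobium japonicum*, and
*Amorpha fruticosa* — whose diploid karyotypes were characterized with a
telomeric oligonucleotide probe, (AG~3~T~3~)~3~ labelled with FAM, and a 5S
rDNA probe labelled with TAMRA, over a DAPI counterstain. No raw
micrographs are publicly deposited for these species, so the pipeline is
organized around ground-truth fixtures: each species' published descriptors
are encoded as a `karyotype_fixture`, and every downstream stage (synthetic
spread rendering, segmentation, medial-axis measurement, signal detection,
karyotype analytics, signal-profile clustering) is validated by round-trip
recovery of those descriptors.

## The karyotype model

A diploid complement of `2n` chromosomes is modelled as `n = 2n/2` homolog
pairs. Three descriptor families are computed, all standard in plant
cytogenetics:

* **Levan centromere classes.** Each chromosome's arm ratio `r = long/short`
  maps to metacentric (`r <= 1.70`), submetacentric (`1.70 < r <= 3.00`),
  subtelocentric (`3.00 < r <= 7.00`) or telocentric (`r > 7.00`). The
  class-count vector yields the karyotype formula, e.g.
  `2n = 2x = 14m + 12sm + 2st`. Band boundaries are inclusive toward the
  more symmetric class; the classifier is monotone in `r` by construction.
* **Interchromosomal (longest/shortest) ratio.** The ratio of the longest
  to the shortest chromosome's total length. In the source table this
  pipeline mirrors, the column headed "Arm Ratio" is interpreted as this
  interchromosomal ratio, not a within-chromosome arm ratio: printed values
  such as 3.4821 exceed the maximum within-chromosome ratio (3.00) possible
  for a complement of 20 metacentrics and 2 submetacentrics, while all five
  printed values are consistent with the printed Stebbins letters under the
  standard column rule. This reading is the package's central interpretive
  decision; it is the only one consistent with the printed formulas.
* **Stebbins cytotype.** The column letter comes from the longest/shortest
  ratio (`A < 2`, `B` in `[2, 4]`, `C > 4`); the row from the proportion
  `p` of chromosomes with arm ratio above 2 (`1: p = 0`; `2: 0 < p <= 0.5`;
  `3: 0.5 < p < 1`; `4: p = 1`). Boundary policy: `p` exactly one half
  stays in row 2 and a length ratio of exactly 2 stays in column B — this
  keeps the *S. japonicum* complement (14 of 28 chromosomes above ratio 2)
  at its published "2B".

Relative chromosome length is expressed as a percentage of the whole
diploid complement (all `2n` bars of an ideogram), so the values sum to
100.

## The synthetic-data generator

The generator defines the study conditions; its defaults are the encoded
conditions of the five-species study and are not tuned per run.

**Measurement tables.** Haploid total lengths follow a geometric decay from
the longest chromosome (4.0 µm for the 2n = 22/28 taxa, 3.6 µm for
*A. fruticosa*, metaphase-typical sizes) down to the shortest, with the
decay rate fixed so the longest/shortest ratio equals the species value
exactly. The two homologs of a pair are identical at zero noise. Each pair
carries a representative within-class arm ratio: metacentrics 1.3,
subtelocentrics 4.0, and submetacentrics 2.2 where the species' published
Stebbins row is 2 (so that the sm chromosomes push `p` above zero) or 1.9
where it is 1 (so that they do not) — the minimal assignment consistent
with every published formula, ratio and cytotype simultaneously.
Measurement noise is an independent multiplicative Gaussian per arm with
coefficient of variation `noise_cv`, truncated at ±3 SD so lengths stay
positive.

**5S signal assignments.** The verbal position vocabulary is encoded as arm
fractions measured from the centromere: centromere 0.05, proximal 0.30,
proximal telomere 0.80, telomere 0.95. Per species: the type carries four
TAMRA pairs (one centromeric, three telomeric/proximal-telomeric; the
centromeric count is stated ambiguously in the source text and is taken as
one pair so that eight chromosomes bear signal, matching the summary
count); f. *decaisneana* four pairs (two centromeric, two
telomeric/proximal-telomeric); 'idaho' three pairs, one of them
heteromorphic (one strong and one weak homolog — encoded as two one-homolog
assignments of differing intensity; its positions are not stated in the
source and the fixture's two-telomeric-plus-one-centromeric placement is an
assumption); *S. japonicum* one proximal-telomeric pair (the summary count
of two signal-bearing chromosomes is followed where the running text is
garbled); *A. fruticosa* two centromeric pairs.

**Spread rendering.** Each chromosome is a smoothly bent capsule: an
arc-length-parametrized sinusoidal centerline (random bow up to 8% of
length), half-width 0.20 µm, with a Gaussian width constriction (depth 0.6,
σ 0.15 µm) at the centromere implied by its arm lengths. The neck is floored
at two pixels so the mask cannot pinch apart. FAM spots sit at both capsule
tips of every chromosome, TAMRA spots at the assigned arm fractions, both
as Gaussian intensity spots (σ 0.08 µm, weak spots at 0.4 of strong
amplitude); channels get a constant background offset (0.05) plus Gaussian
noise (SD 0.02) on a [0, 1] intensity scale, written as 16-bit TIFF. The
default resolution is 0.04 µm/pixel, placing the shortest chromosomes near
30 px and the longest near 100 px. With the default automatic canvas,
chromosomes are placed on a shuffled, jittered grid with random
orientation, which guarantees pairwise-disjoint footprints under the
"forbid" overlap policy; with a user-fixed canvas, rejection sampling is
used and a placement error is raised after bounded retries. All randomness
flows through explicit seed arguments; no global RNG state leaks.

What the generator does *not* emulate: chromatid-level substructure
(sister-chromatid doublets), satellites and secondary constrictions (none
were reported in these taxa), intensity vignetting, optical blur beyond the
Gaussian spot model, and genuinely touching or overlapping chromosomes in
the default spreads. Passing round-trip tests therefore demonstrate the
internal consistency and accuracy of the measurement algorithms under
clean, well-spread conditions, not performance on difficult real
micrographs.

## Image measurement

**Segmentation** thresholds the DAPI channel with Otsu's method (after a
contrast pre-check so pure background is never split), labels connected
components, drops components below 60 px², and attempts a
distance-transform watershed split of components above 8000 px²;
unsplittable clusters are returned whole and flagged rather than
force-split. Masks are ordered stably by centroid.

**Medial-axis measurement** thins each mask (Zhang–Suen), takes the longest
geodesic path through the skeleton graph (bridging any components the
thinning disconnected at a deep constriction), and reads half-widths from
the Euclidean distance transform. Digital arc length uses the
Kulpa-corrected step weights (0.948 orthogonal, 1.340 diagonal), which
removes the few-percent overestimate of naive 1/√2 weighting. The
centromere is the arc-midpoint of the constriction plateau of the width
profile smoothed over a 10%-of-length window, with a 10% margin excluded at
each end to avoid the telomeric taper; a profile with no interior minimum
is flagged `metacentric-by-default` with a midpoint centromere. Because
thinning erodes the rounded telomeric caps, each arm is extended by the
projection of the mask onto the outward tangent at the skeleton tip. On a
seeded batch of 50 rendered chromosomes of true arm ratio 2.2 at default
resolution, the mean absolute arm-ratio error is about 3% (every
chromosome within about 8%). Accuracy degrades on the stubbiest
chromosomes whose constriction sits inside the excluded end margin; their
counts and lengths remain reliable, but their arm split is ill-posed at
this resolution — a genuine property of short submetacentric chromosomes,
not just of the simulation.

**Spot detection** takes connected components above a robust per-channel
threshold (median + 8 MAD, with the MAD floored for mostly-dark channels),
assigns each spot to the containing mask or the nearest mask within 6 px,
and reports unassignable spots separately instead of dropping them. A spot
is "weak" when its summed background-subtracted intensity falls below half
the channel's median spot intensity; this 0.5 cut is a free parameter (the
source study gives no threshold separating its one weak signal from the
strong ones) chosen to sit midway between the rendered weak/strong
amplitude ratio (0.4) and parity. Detected sites are projected onto the
measured medial axis to obtain arm, position fraction, and one of four
position categories: centromeric (≤ 0.15), interstitial (0.15–0.70),
proximal-telomeric (0.70–0.90), telomeric (≥ 0.90). These thresholds place
the fixture encodings one per category, with "proximal" (0.30) deliberately
falling in the interstitial band.

## Signal-profile clustering

Each species is summarized as a profile: the number of 5S-bearing homolog
pairs, the per-category 5S site counts, and the number of heteromorphic
pairs. The dissimilarity is a weighted L1 pseudometric,

d(p, q) = w_n |Δpairs| + w_c L1(category counts) + w_h |Δheteromorphic|,

with defaults w_n = 1.0, w_c = 0.5, w_h = 0.25, so pair-count differences
dominate — mirroring the reasoning that ranks the taxa by number of 5S
pairs. It is symmetric, zero exactly on identical profiles, and satisfies
the triangle inequality (it is a weighted L1 norm on concatenated count
vectors); these axioms are property-tested. Agglomerative clustering
(average linkage by default) produces a *similarity dendrogram over signal
patterns* — deliberately labelled phenetics, not a phylogeny estimate.

With the packaged profiles the dendrogram merges the type with
f. *decaisneana* first (d = 2), adds 'idaho' (height 3.25), and completes
with the final join of the *S. japonicum*–*A. fruticosa* group onto the
Robinia clade. One structural point deserves emphasis: under *any*
non-negative weighting of this pseudometric, *S. japonicum* (1 pair,
proximal-telomeric) is closer to *A. fruticosa* (2 pairs, centromeric) than
to any Robinia taxon, because the pair-count terms alone already exceed
their mutual distance — so the two signal-poor taxa necessarily merge with
each other before either joins the Robinia cluster. "*A. fruticosa* is the
most distant taxon" is therefore realized as: it never groups with any
Robinia taxon before the root, and no taxon enters the tree at a later
merge. A dendrogram in which *A. fruticosa* joins strictly last as a
singleton is not attainable from these profiles under this family of
dissimilarities.

## Numerical and design choices

* Zero-noise tables are exactly deterministic and seed-independent; the
  longest/shortest ratio is reproduced to 1e-9 and class counts exactly.
* Length ties in ordering are broken by ascending arm ratio, then
  chromosome id, making `order_by_length` deterministic and idempotent.
* Homolog pairing sorts by length and pairs adjacently; when signal data
  are attached, adjacent candidates within 5% relative length are locally
  re-paired to maximize within-pair signal agreement.
* The ideogram writer emits SVG text directly rather than through a
  graphics device, so identical input produces byte-identical files.
* Robustness under noise: at `noise_cv = 0.02`, formula and cytotype match
  the noise-free values in at least 8 of 10 seeded replicates per species
  (the borderline cases are the 'idaho'/f. *decaisneana* sm chromosomes at
  ratio 1.9 and f. *decaisneana*'s longest/shortest ratio 2.0787, both of
  which sit close to a Stebbins boundary by construction). The 8/10
  threshold is a test parameter of this package, not a published claim.

## Problem sizes

The validation suite renders one spread per species per check (2n = 22–40
chromosomes, canvases around 620–810 px), ten seeded spreads per species
for the chromosome-count check, and a 50-chromosome batch for arm-ratio
recovery; the property suites use 1000 random profile pairs and 250
triples. These sizes were chosen so the whole suite completes in a few
minutes on a single CPU while still exercising every published descriptor.

## Known limitations

* The pipeline measures simulated spreads; real micrographs bring touching
  chromosomes, uneven staining and chromatid substructure that the
  generator deliberately omits. The watershed split path is implemented and
  tested on synthetic fused clusters, but untested on real data.
* Arm-position categories for signals on chromosomes shorter than ~1.5 µm
  at default resolution are unreliable (see above); category-based
  profiles in the validation suite therefore come from the fixture route,
  with the image route cross-checked on pair counts and heteromorphism.
* The 'idaho' 5S positions and the ambiguous centromeric pair count of the
  type are documented fixture assumptions, not published facts; the
  clustering conclusions do not depend on them (pair counts dominate the
  dissimilarity).
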