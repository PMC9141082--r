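# karyofish

Karyotype analytics and oligo-FISH signal mapping for diploid plant
metaphase spreads.

Plant cytogenetics characterizes a species by its karyotype — the number,
sizes and centromere positions of its chromosomes — and by the positions of
fluorescence in situ hybridization (FISH) probe signals along those
chromosomes. `karyofish` implements that workflow end to end for a
five-taxon Fabaceae study system (*Robinia pseudoacacia*, the cultivar
'idaho', *R. pseudoacacia* f. *decaisneana*, *Styphnolobium japonicum*,
*Amorpha fruticosa*) characterized with two oligo probes: a telomeric
(AG₃T₃)₃ probe (FAM, green) marking both ends of every chromosome, and a 5S
rDNA probe (TAMRA, red) whose site number and arm position is
species-characteristic. Because no raw micrographs are deposited for these
taxa, the package ships ground-truth fixtures and a synthetic metaphase
spread renderer, and validates every stage by round-trip recovery of the
published descriptors.

The pipeline:

1. **Fixtures and simulation** — per-species karyotype fixtures
   (`load_species_fixture()`), measurement-table generation with controlled
   noise (`generate_measurement_table()`), and three-channel metaphase image
   rendering with full ground truth (`render_metaphase_image()`).
2. **Image measurement** — DAPI segmentation (`segment_chromosomes()`),
   medial-axis chromosome measurement with width-profile centromere
   detection (`measure_chromosome()`), and FISH spot detection with
   arm-position mapping (`detect_signals()`).
3. **Karyotype analytics** — Levan arm-ratio classes (`classify_levan()`:
   m ≤ 1.70 < sm ≤ 3.00 < st ≤ 7.00 < t), karyotype formula
   (`karyotype_formula()`), longest/shortest interchromosomal ratio
   (`interchromosomal_ratio()`), and Stebbins asymmetry cytotype
   (`stebbins_cytotype()`: columns A/B/C by longest/shortest < 2 / ≤ 4 / > 4;
   rows 1–4 by the proportion of chromosomes with arm ratio > 2).
4. **Signal phenetics** — species-level 5S signal profiles
   (`fixture_signal_profile()`, `encode_signal_profile()`), a weighted-L1
   profile pseudometric (`profile_dissimilarity()`), and agglomerative
   clustering with Newick export (`cluster_profiles()`).

## Worked example

```r
library(karyofish)

fx  <- load_species_fixture("styphnolobium_japonicum")
tab <- generate_measurement_table(fx, noise_cv = 0)
analyze_karyotype(tab)
#> <karyotype_result> styphnolobium_japonicum
#>   2n = 2x = 14m + 12sm + 2st   cytotype 2B   longest/shortest 2.6847
```

The formula says the 28-chromosome diploid complement has 14 metacentric,
12 submetacentric and 2 subtelocentric chromosomes; the longest chromosome
is 2.68 times the shortest (Stebbins column B), and half the complement has
an arm ratio above 2 (row 2), hence cytotype 2B.

Rendering a spread and measuring it back:

```r
img   <- render_metaphase_image(tab, fx$signal_pairs, seed = 1)
masks <- segment_chromosomes(img)
ms    <- measure_spread(masks, img$pixel_size)
sites <- detect_signals(img, masks, measurements = ms$measurements)
length(masks)                                             # 28
length(unique(sites$chromosome_id[sites$channel == "TAMRA"]))  # 2
analyze_karyotype(ms$table, species_id = "measured")$formula_string
#> "2n = 2x = 14m + 12sm + 2st"
```

Segmentation recovers all 28 chromosomes, the 5S probe is detected on the
single signal-bearing homolog pair (2 chromosomes), and the karyotype
formula measured from the image equals the generating formula.

Clustering the five species' 5S profiles:

```r
profs <- lapply(species_ids(), \(s) fixture_signal_profile(load_species_fixture(s)))
cluster_profiles(profs)
#> <signal_dendrogram> 5 taxa, average linkage
#>   merge 1 @ 2.000: {robinia_pseudoacacia, robinia_pseudoacacia_decaisneana}
#>   merge 2 @ 3.250: {robinia_pseudoacacia, robinia_pseudoacacia_decaisneana, robinia_pseudoacacia_idaho}
#>   merge 3 @ 4.000: {amorpha_fruticosa, styphnolobium_japonicum}
#>   merge 4 @ 5.417: {amorpha_fruticosa, robinia_pseudoacacia, robinia_pseudoacacia_decaisneana, robinia_pseudoacacia_idaho, styphnolobium_japonicum}
```

The two four-pair taxa merge first, the three *Robinia* taxa form a clade,
and *A. fruticosa* never joins the *Robinia* group before the root.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the whole study
and write tables, spreads, ideograms and the dendrogram under `results/`:

```sh
Rscript analysis/01_simulate.R    # fixtures -> tables + rendered spreads
Rscript analysis/02_measure.R     # spreads -> measured tables + signal sites
Rscript analysis/03_karyotype.R   # analytics -> karyotype table + ideograms
Rscript analysis/04_cluster.R     # 5S profiles -> dissimilarity + tree.nwk
Rscript analysis/05_report.R      # bundled report + run manifest
```

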