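# rarewoods

Rarity, protection status and commercial timber availability of woody
species from nested cluster-plot forest inventories.

## What it does and who it is for

Forest managers and conservation ecologists working with national or
regional woody-plant inventories need to answer a recurring set of
questions: which species are rare, and in what way? How much of each
species' distribution falls inside protected areas? How do habitats differ
in species richness and composition? And which commercial timber species
still carry legally and ecologically harvestable populations?

`rarewoods` answers these questions for inventories with a nested
cluster-plot design: square 1 ha clusters of four 0.1 ha plots in which
every stem with DBH ≥ 10 cm is measured over the whole plot, while small
stems (5 ≤ DBH < 10 cm) are recorded only in one 25 × 10 m subplot and must
be expanded by the design weight 1/0.25 = 4 when densities are computed.

The analytical core:

- **Rabinowitz rarity classification.** Three binary criteria — geographic
  distribution (wide: occupied fraction of sampling units > 10 %; narrow:
  ≤ 10 %), habitat specificity (various: > 1 habitat; single: 1) and local
  population size (large: abundance > 2; small: ≤ 2) — cross into eight
  categories: `Common` plus rarity forms 1–7, with Form 7 (narrow + single
  + small) the extreme form of rarity.
- **Continuous rarity indices** (`gri`, `hsi`, `psi` and their mean `ri`),
  each normalized to [0, 1] with higher = rarer.
- **Protection index** PI = occurrences inside protected areas / total
  occurrences, with status `highly` (PI = 1), `poorly` (PI = 0) or
  `partially` (0 < PI < 1).
- **Nonparametric richness**: bias-corrected Chao1,
  `S_obs + f1(f1−1)/(2(f2+1))` with its companion variance, and ACE with
  the conventional rare-species cutoff of 10.
- **β-diversity partitioning**: pairwise and multiple-site Sørensen
  dissimilarity split into turnover (Simpson) and nestedness-resultant
  components, `β_sor = β_sim + β_sne`.
- **Timber screen**: per species × habitat, the expansion-weighted density
  of stems at or above the minimum felling diameter outside protected
  areas, stem-form (SF1/SF2/SF3) profiles by DBH class, and a
  harvest-eligibility decision (timber ∧ fully common ∧ allowed habitat ∧
  density above the legal minimum) with complete machine-readable denial
  codes.

A synthetic inventory generator (`community_params()`,
`generate_census()`, `apply_measurement_protocol()`) produces whole
censuses with known ground truth — realized range, habitats, abundance and
the rarity form implied by them — so every stage of the pipeline can be
validated end to end without access to restricted inventory data.

## Worked example

```r
library(rarewoods)

cen <- generate_census(community_params(seed = 2025))
res <- run_pipeline(cen$records)
summary(res)
```

```
Woodland species assessment
  30075 records, 200 species, 75 clusters surveyed
  rare species: 141 of 200 (70%)
  multiple-site dissimilarity: 0.53 (turnover 0.46, nestedness 0.07)

Richness by habitat:
       site S_obs     N chao1 chao1_se    ace
1     humid   125 16389 137.4    7.953 138.89
2     rainy    89  4074  93.4    3.558  97.38
3 semi-arid   126  9612 147.4   13.151 142.00

Species per rarity form:
   level count proportion percent
1 Common    59      0.295      30
2  Form1     0      0.000       0
3  Form2    37      0.185      19
4  Form3     0      0.000       0
5  Form4    27      0.135      14
6  Form5     9      0.045       5
7  Form6    40      0.200      20
8  Form7    28      0.140      14

Species per protection status:
      level count proportion percent
1    highly     7      0.035       4
2 partially   162      0.810      81
3    poorly    31      0.155      16

Pairwise beta-diversity partition:
  site_i    site_j total turnover nestedness
1  humid     rainy 0.449    0.337     0.1115
2  humid semi-arid 0.450    0.448     0.0022
3  rainy semi-arid 0.470    0.360     0.1102
```

Reading this: 70 % of the 200 simulated species are rare in at least one
of Rabinowitz's senses, and only 4 % occur exclusively inside protected
areas. Chao1 and ACE estimate that a handful of species per habitat were
missed by the survey (e.g. 137 ± 8 against 125 observed in the humid
habitat). About half of the compositional dissimilarity across the three
habitats (0.53) is species turnover (0.46) rather than nestedness. The
classification of every species matches the generator's ground truth
exactly (`res$rarity$form` vs `cen$truth$true_rarity_form`), which is the
package's core end-to-end guarantee.

Real inventories enter through `read_inventory()` (delimited text, one
row per stem) and species metadata through `read_species_metadata()`;
`write_report(res, "outdir")` serializes all tables plus a JSON manifest.
A thin command-line wrapper with `run` and `generate` subcommands is
installed at `inst/scripts/assess.R`.

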