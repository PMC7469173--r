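# PAEzone

Parsimony analysis of endemicity (PAE) and faunistic zonation in R.

PAE asks a cladistic question about geography: which areas form natural
groups by virtue of the species they share?  It treats areas as taxa and
species as binary characters — a cell of the areas × species
presence-absence matrix is 1 when the species occurs in the area — and
builds a maximum-parsimony *area cladogram* rooted on a hypothetical area
with no species at all.  Clades supported by two or more *synapomorphic*
species (present in every member area and nowhere else) are areas of
endemism (AOEs), and nesting along the rooted cladogram yields a zone /
subzone scheme.  The approach is used to zone faunas — for example
pollinating butterflies across the 22 ecoregions of a mountainous province —
for conservation planning.

The package implements the whole pipeline as composable, seeded, tested
steps:

* **Matrix construction** — occurrence records → validated binary matrix,
  hypothetical root, richness summaries; NEXUS (`DATATYPE=STANDARD`) and CSV
  round-trip I/O.
* **Parsimony search** — Fitch scoring of binary characters (compiled
  kernel, exact on multifurcations), stepwise-addition starting trees,
  TBR/SPR/NNI branch swapping with random-addition replicates, and an
  exhaustive-search oracle up to 9 areas.
* **Uncertainty** — strict and majority-rule consensus, nonparametric
  bootstrap with fractional split weights, ensemble fit indices
  (CI = Σm/Σs, RI = (Σg−Σs)/(Σg−Σm), RC = CI·RI, HI = 1−CI) and the
  random-tree length-distribution skewness g1.
* **Zonation** — AOE detection from strict supporters, and a deterministic
  formalization of the branch-nesting rule turning the rooted,
  support-annotated cladogram into zones and cherry subzones.
* **Synthetic data** — a hierarchical-vicariance generator with planted
  endemics, widespread species, singletons and per-cell flip noise, so every
  stage is testable end to end with known truth.

## A worked example

```r
library(PAEzone)

sim <- simulateMatrix(simulationConfig(nAreas = 6, flipProbability = 0, seed = 11))
sim@pam
#> PresenceAbsenceMatrix: 7 areas x 35 species
#>   hypothetical root area: ROOT
#>   richness range: 15 - 22

res <- heuristicSearch(sim@pam, searchConfig(nReplicates = 3, seed = 1))
res
#> ParsimonyResult: 1 tree of length 35

ensembleIndices(res, sim@pam)
#> Ensemble indices over 35 characters:
#>   CI = 1.000  RI = 1.000  RC = 1.000  HI = 0.000
#>   sums: m = 35, s = 35, g = 60

cons   <- strictConsensus(res, ref = "ROOT")
rooted <- rootOn(cons, "ROOT", prune = TRUE)
extractZonation(rooted, sim@pam)
#> ZonationScheme: 2 zones, 2 subzones, 4 areas of endemism
#>   A: AR01, AR03, AR05, AR06  [subzones: AR03+AR05; AR01+AR06]
#>   B: AR02, AR04
```

The length 35 is exactly the number of variable characters (4 planted
clades × 5 endemics + 10 widespread + 5 singletons): in noiseless data every
character fits the true tree in one step, so CI = 1 and the planted topology,
AOEs and zone partition are recovered exactly.  With `flipProbability > 0`
the same pipeline quantifies how recovery and CI degrade.

A thin command-line front end ships in `inst/cli/pae.R` with subcommands
`simulate`, `build-matrix`, `search`, `bootstrap`, `zonate` and `run-all`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pae.R",package="PAEzone"))')" \
    run-all --matrix matrix.csv --root ROOT --seed 1 --out run/
```

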