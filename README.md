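# hopanotype

Genotype-to-chemotype inference for hopanoid production in
Alphaproteobacteria.

Hopanoids — and especially the C<sub>35</sub> bacteriohopanepolyol
derivatives (BHPDs) with their polyfunctionalized side chains — are
bacterial membrane lipids whose diagenetic products (hopanes) are read as
biomarkers throughout the geological record. Whether a bacterium can make
them is written in its genome: the MEP isoprenoid pathway
(*dxs*…*ispH*, *ispA*), squalene synthesis (*hpnC/D/E*), squalene–hopene
cyclase (*shc*), the committed C<sub>35</sub> steps (*hpnH*, *hpnG*), the
cyclitol-ether branch (*hpnI/K/J*), the amino branch (*hpnO*), the ring-A
methylases *hpnP* (C-2) and *hpnR* (C-3), and tetrahymanol synthase
(*ths*). `hopanotype` is for geobiologists and microbial lipidomicists who
want to confront that genetic capacity with measured lipid phenotypes.

The package implements, as tested R functions:

* **Gene detection** — Smith–Waterman local protein alignment (BLOSUM62,
  gap open 11 / extend 1) against a shipped gene-family catalog, with
  per-family percent-*similarity* thresholds (positives convention: the
  fraction of alignment columns scoring > 0), a query-coverage floor, and
  the special rule that squalene–hopene cyclase candidates under 40%
  similarity are the distantly related secondary Shc clade, not the pathway
  gene.
* **Cluster architecture** — grouping of accepted hits into candidate
  biosynthetic gene clusters by contig adjacency and locus-tag arithmetic
  (tags typically step by 5 per gene), with a Kendall-type concordance of
  observed vs canonical A–R gene order, strand-flip invariant.
* **A biosynthesis rule engine** — `predict_chemotype()` chains
  `shc ⇒ C30 hopanoids`, `+hpnH ⇒ BHPDs`, `+hpnG ⇒ BHT`,
  `+hpnO ⇒ aminotriol`, the `hpnI→hpnK→hpnJ` cyclitol-ether terminal stage,
  methylation capacities from `hpnP`/`hpnR`, and tetrahymanol from `ths`.
  Predictions are capacities, not guarantees — methylation genes without
  detectable product are an expected concordance outcome.
* **Measurement arithmetic** — internal-standard quantification
  (`(A/A_IS)·m_IS/m_biomass`), MRM degree of ring-A methylation
  (`100·M/(M+U)` from the m/z 205 and 191 channels), 22S/(22S+22R) epimer
  fractions, and normalized inventory summaries over the five BHPD
  structural groups.
* **In-silico Rohmer degradation** — maps each BHPD to its
  periodate/borohydride product (tetrol-based → C32 hopanol, pentol → C31,
  hexol → C30, nucleosides → none) to cross-check LC inventories against GC
  hopanol profiles.
* **Concordance & survey statistics** — per-feature gene-vs-product
  2×2 tables with predictive values, and survey fractions over gene-hit
  count tables.
* **A synthetic-data generator** — genomes with planted clusters, decoys
  and divergence-controlled genes; lipidomes with known methylation
  degrees, epimer fractions and lognormal peak noise — so every stage is
  testable against ground truth.

It also ships transcriptions of the reference tables for a 54-species
culture panel (strain roster, order-level genome survey, Rohmer
concentrations, MRM methylation degrees, narrated per-species gene calls),
with below-detection and not-determined as distinct states that are never
coerced to zero.

## Worked example

Simulate a genome with a planted, contiguous *hpn* cluster (plus one Shc
decoy), scan it, and predict its chemotype:

```r
library(hopanotype)

sc <- genotype_scenario(
  c("dxs","dxr","ispDF","ispE","ispG","ispH","ispA",
    "hpnC","hpnD","hpnE","shc","hpnG","hpnH","hpnI","hpnK","hpnN","hpnP"),
  fragments = 1, n_decoys = 1, n_background = 60)
sim  <- simulate_genome(sc, seed = 11)
hits <- scan_proteome(sim$proteome, genome_id = "demo")
arch <- classify_architecture(cluster_hits(hits, sim$features))
arch
#> hpn cluster architecture: contiguous (1 fragment(s)); order concordance 1.00

geno <- assemble_genotype(hits, arch)
geno
#> genotype of demo: 17 families present
#>   present: dxs dxr ispE ispDF ispG ispH ispA hpnC hpnD hpnE shc hpnG hpnH hpnI hpnK hpnN hpnP
#>   MEP pathway complete: TRUE  [ispD and ispF fused as ispDF]

predict_chemotype(geno)
#> predicted chemotype capacities:
#>    c30_hopanoids, bhpd_any, adenosylhopane, bht, ce_glucosamine_terminal, methyl_2
```

All 17 planted genes are recovered (the decoy is called
`rejected_decoy`), the cluster reads as one fragment in canonical order,
and the rule engine concludes: this genome can make C<sub>30</sub>
hopanoids and BHPDs through BHT, its cyclitol-ether branch stalls at BHT
glucosamine (no *hpnJ*), and it carries 2-methylation capacity (*hpnP*).

Panel statistics are recomputed from the shipped tables at call time:

```r
panel_counts()
#> panel summary over 54 species ( 52 measured by Rohmer degradation)
#>   without Rohmer products:       9
#>   without C30 hopanoids:         22
#>   without intact BHPDs:          6
#>   tetrahymanol producers:        3
#>   max 22S/(22S+22R):             0.79
#>   2-Me C32 hopanol: n=8 mean=1.03 max=5.10
```

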