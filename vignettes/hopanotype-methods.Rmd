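---
title: "From hpn genotype to BHPD chemotype: models and design choices"
author: "hopanotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From hpn genotype to BHPD chemotype: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopanotype)
```

## The scientific problem

Hopanoids are pentacyclic triterpenoid membrane lipids made by many
bacteria; their C~35~ representatives, the bacteriohopanepolyol derivatives
(BHPDs), carry a polyfunctionalized side chain (hydroxyls, amino groups,
sugars, nucleosides) and survive diagenesis as hopanes, making them widely
used biomarkers in microbial ecology and the geological record.
Alphaproteobacteria are prolific BHPD producers and — uncomfortably for the
fossil record — include species that methylate ring A at C-2, the position
long read as a cyanobacterial signature.

Whether a strain *can* make these lipids is encoded in a well-characterized
gene set: the MEP isoprenoid pathway (*dxs*…*ispH*, *ispA*), squalene
synthesis (*hpnC/D/E*), squalene–hopene cyclase (*shc*), the committed C~35~
steps (*hpnH*, *hpnG*), the cyclitol-ether branch (*hpnI/K/J*), the amino
branch (*hpnO*), ring-A methylases (*hpnP* for C-2, *hpnR* for C-3), and
tetrahymanol synthase (*ths*). This package turns that biology into a tested
pipeline: detect the genes in a proteome, read the cluster architecture,
predict the producible BHPD classes, and quantify the measurement side
(Rohmer degradation products, MRM methylation degrees, epimer fractions,
inventory summaries) so that genotype and phenotype can be confronted on a
common footing.

## Homology detection

Gene detection is protein-level local alignment of each family's query
against every protein of the genome: Smith–Waterman with BLOSUM62 and affine
gaps (open 11, extend 1), the standard scoring of protein database searches.
A hit is accepted when

* **percent similarity** — the fraction of alignment columns with a positive
  substitution score ("positives" convention; gap columns count as
  non-positive) — reaches the family threshold, and
* **query coverage** is at least 70% of the query length.

Thresholds are 50% similarity for all families except *hpnP* (55%), where
other B12-binding radical SAM proteins create a band of spurious similarity,
and squalene–hopene cyclase carries an extra rule: a second, distantly
related Shc clade (< 40% similarity) occurs in some genomes outside the
biosynthetic cluster and is flagged `rejected_decoy` rather than counted.

Two fidelity limits are deliberate. First, iterative profile search
(multiple search iterations against a large reference database) is *not*
re-implemented; a single-pass local alignment stands in, because everything
downstream consumes only percent similarity and presence calls. Second, the
shipped query sequences are frozen surrogates with realistic length and
composition, not database proteins: detection tests plant (mutated) copies
of the surrogates, so no conclusion about real proteomes rests on their
residues. The 70% coverage floor is our own choice — it is not part of the
source protocol — and is configurable via `threshold_policy()`.

## Cluster architecture

The *hpn* genes commonly co-localize as a biosynthetic gene cluster whose
locus tags step by 5 per gene. `cluster_hits()` joins two pathway genes into
one cluster when they share a contig and either at most `G = 5` non-pathway
genes intervene or their locus-tag numeric suffixes differ by at most
`L = 50` (ten genes at step 5). Both defaults are explicit, configurable
knobs: cluster diagrams of real genomes show small non-pathway insertions
inside clusters, but no universal gap rule is stated anywhere, so we chose
values that tolerate such insertions without bridging unrelated loci.
Raising `G` can only merge clusters (monotone coarsening, property-tested).

`classify_architecture()` reports `contiguous` (one fragment), `fragmented`
(several fragments, at least one of which still groups ≥ 2 cluster genes),
`dispersed` (only isolated genes) or `absent`, plus an order concordance:
the Kendall rank correlation between the observed genomic order and the
canonical A–R gene order, computed only over genes present and only over
canonical cluster members (*hpnO*, *hpnP*, *hpnR* typically live elsewhere
in the genome and are never order-scored). Each fragment is
orientation-normalized by its majority strand first, so a minus-strand
operon scores exactly like its forward image. With fewer than two scored
genes the concordance is `NA` rather than a fabricated 1.

## The rule engine: capacities, not guarantees

`predict_chemotype()` chains the pathway logic: *shc* ⇒ C~30~ hopanoids;
plus *hpnH* ⇒ BHPDs (adenosylhopane); plus *hpnG* ⇒ BHT; plus *hpnO* ⇒
aminotriol; the cyclitol-ether branch terminal stage follows *hpnI* →
*hpnK* → *hpnJ*; *hpnP*/*hpnR* ⇒ ring-A methylation capacity; *ths* ⇒
tetrahymanol. Three design points deserve emphasis:

* **Predictions are capacities.** Methylation genes in particular occur
  without detectable methylated product; the concordance module therefore
  treats gene-present/product-absent as a legitimate outcome cell, never a
  pipeline error.
* **No rule asserts BHpentol, BHhexol or unsaturation** — their genes are
  unknown. The sterol-desaturase-like gene only sets an advisory
  `unsaturation_suggested` flag.
* **Monotonicity is scoped.** Adding a gene never retracts a *cumulative*
  capacity (C~30~, BHPD, BHT, aminotriol, methylation, tetrahymanol) — a
  property we test over random genotypes. The three `ce_*` flags, in
  contrast, describe the *terminal* stage of the cyclitol-ether branch and
  legitimately move forward when *hpnK* or *hpnJ* arrive; they are tested
  for mutual exclusivity instead. Fixture-derived genotypes may carry
  `unknown` states; an unknown can never switch a flag to `TRUE` and is
  surfaced in `confidence_notes`.

## Measurement arithmetic

The measurement side is deliberately plain arithmetic with hard input
validation:

* `quantify_by_internal_standard()`: single-point semi-quantification
  against n-tricosan-1-ol (0.03075 mg per sample in the reference protocol),
  response factor 1. Semi-quantitative by design; we document rather than
  invent response factors.
* `methylation_degree()`: `100 · M/(M+U)` from the two MRM channels
  (transition to *m/z* 205 for the ring-A methylated skeleton, *m/z* 191
  for the unmethylated one). Because the channels are separate, coelution of
  2-methyl hopanols with their unmethylated counterparts does not bias the
  ratio — which is why the function takes areas, not retention windows.
  Undefined (error, not 0) when both areas are zero.
* `epimer_fraction()`: `100 · S/(S+R)`; same degenerate-input rule.
* `normalize_inventory()` / `summarize_inventory()`: relative abundances sum
  to 100 (tested to 1e-9 relative tolerance); the pentol-plus-hexol share
  includes the CE and carbamoyl derivatives of pentol/hexol bases.
* Report rendering (whole numbers ≥ 10, one decimal below, a
  below-detection marker under 0.01%) never touches stored values.

## In-silico Rohmer degradation

Periodate/borohydride treatment cleaves BHPD side chains at vicinal diols;
the resulting hopanol's carbon number fingerprints the parent class:
tetrol-based → C~32~, pentol-based → C~31~, hexol-based → C~30~, with
ring-A methylation, ring unsaturation and C-22 configuration carried
through. Nucleoside BHPDs yield nothing (no free vicinal diol pair) and form
the "invisible fraction" of `predict_gc_profile()` — a pure adenosylhopane
producer is invisible to the method. Two rules are assumptions we flag
rather than facts: CE-series and glucosamine side chains are treated as
cleavable at their polyol-base diols (consistent with species whose only
BHPD is a BHT cyclitol ether yet which give degradation products), and the
anhydro-pentol maps to *none* because its internal ether consumes the free
diol. `cross_platform_check()` compares LC and GC views (pentol+hexol
share, unsaturation, 22S fraction) with a default tolerance of 15
percentage points — generous by intent, since the two platforms differ in
detection limits and response.

## The packaged panel tables

The package ships transcriptions of the printed reference tables for a
54-species culture panel (strain roster, order-level genome survey counts,
Rohmer concentrations with 22S fractions and inventory summaries, MRM
methylation degrees), plus a per-species gene table restricted to facts the
survey narrative states explicitly — everything else is `unknown`, not
guessed from figure pixels. Below-detection (`BD`) and not-determined
(`NA`) cells are distinct states and are never coerced to zero; every
derived count (`panel_counts()`, `reproduce()`) is computed from these
tables at call time. Counts whose printed denominator covers only measured
species exclude the two not-determined species; counts over the intact-BHPD
columns cover all 54.

The 63-entry BHPD structure roster reconstructs the identified structures
from the narrative survey; five entries fill gaps where the text names a
group but not each compound and are marked `inferred`. Tests assert that
every entry constructs a legal structure and that the five structural groups
are covered — not the exact membership, which only the full supplementary
inventory would pin down.

## The synthetic-data generator

`simulate_genome()` and `simulate_lipidome()` exist so that every pipeline
stage can be tested against known truth without downloads.

* Planted genes are the surrogate queries mutated to a target similarity:
  substitutions draw from residues scoring non-positively against the
  original, and the substitution count is tuned by bisection against the
  measured similarity, landing within ±5 points of the target for
  references ≥ 150 aa (verified over many seeds). Decoys are planted at 35%
  similarity, below the secondary-Shc floor.
* Background proteomes are residue-shuffled copies of the references
  (default 300 genes, 2 contigs — enough to exercise clustering; genome
  realism is not the point). Locus tags step by 5; cluster fragments are
  separated by 12 background genes, which breaks both adjacency rules.
* Lipidomes draw abundances from a symmetric Dirichlet over the structure
  classes the chemotype permits and apply multiplicative lognormal noise
  (default CV 0.05, the standard model for chromatographic areas) to peak
  areas. Planted methylation degrees and epimer fractions are recovered
  exactly at zero noise — the round-trip is an identity by construction,
  which is precisely what makes it a useful regression test. Defaults plant
  a 2-methylation degree of 1% (the panel-average magnitude for extended
  hopanoids) and a 22S fraction of 0 (most species are pure 22R).

What passing these tests shows: the pipeline's bookkeeping, thresholds and
rule logic are internally consistent and recover planted truth. What it does
not show: performance on real proteomes (real paralogs share ancestry in a
way shuffled sequences do not), or biological variability of lipid
abundances (growth phase, medium and cultivation conditions all move them).

## Problem sizes and numerical choices

The test suite runs the alignment oracle exhaustively for all peptide pairs
up to length 3 over a 4-letter alphabet and on seeded random pairs up to
length 12 (the full enumeration to length 12 is combinatorially out of
reach), 200 random cluster layouts, 1000 random genotypes, and an
end-to-end recovery experiment of 50 simulated genomes with 40-gene
backgrounds at 85% planted similarity — sizes chosen so the suite documents
the properties without belabouring them. Ties between equally scoring best
hits break to the lexicographically smallest protein id; all hit tables are
ordered by (family, protein); every random draw flows from an explicit seed
argument, and `with_seed()` restores the caller's RNG state.

## Known limitations

* Single-pass alignment understates the sensitivity of iterative profile
  searches; borderline families in real genomes may be missed at the 50%
  cutoff that a profile search would recover.
* Surrogate queries mean absolute similarity values are not comparable to
  published search results; only the machinery is exercised.
* The genotype fixture encodes narrated facts only; features whose
  per-species states are unknown contribute `unknown` cells to concordance
  rather than counts.
* Response factors of 1 make all concentrations semi-quantitative, as in
  the source protocol.
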