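# trioCAPS

Tools for characterising a plant introgression line and the rhizobial
strains occupying its nodules. The package grew out of a concrete use case
— a pea line carrying the *Sym2^A^* nodulation-specificity segment from an
Afghan landrace in a European cultivar background, genotyped together with
both parents, plus a CAPS assay telling the rhizobial *nodX* alleles apart
in single nodules — but every stage is generic: any donor/recipient/line
trio VCF, any GFF3 gene models, any primer pair and restriction-enzyme
table, any per-nodule assay table.

## What it computes

**Trio introgression mapping.** For each biallelic variant with genotypes
of donor (D), recipient (R) and line (L), the site is donor-derived when
all three are homozygous and `L = D ≠ R`, recipient-derived when
`L = R ≠ D`; heterozygous/missing genotypes are uninformative and
`L ∉ {D, R}` is a conflict. After a `QUAL ≥ 20` filter, variants are
classified against gene models (5′ UTR / exon / 3′ UTR / intron /
upstream / downstream / intergenic, UTR > exon > intron precedence,
strand-aware 5 kb flanks) and only genic variants are kept. A gene is
donor-derived when it holds donor-assigned variants and no
recipient-assigned ones; the inheritance fraction is
`100 · d/(d + r)` over gene counts. Donor blocks are maximal runs of
donor sites tolerating ≤ 2 interior non-donor informative sites, with ≥ 5
supporting sites, summarised by span and overlapping gene count, exportable
as BED.

**CAPS marker design.** In-silico PCR (mismatch-counted primer sites with
a strict 3′ anchor), IUPAC-degenerate restriction-site scanning on both
strands, linear digest fragment prediction, and a search for enzymes whose
fragment-length multisets differ between two allelic amplicons.

**Nodule occupancy.** Per-nodule control/target/digest observations become
calls (`FAILED`, `NODX_MINUS`, `TOM_ONLY`, `NON_TOM_ONLY`, `MIXED`),
aggregated into per-group percentage tables (failures excluded from
denominators, half-up integer rounding), with Kruskal–Wallis and Welch
(on `ln`-transformed counts) tests for the accompanying count data.

**Synthetic data.** Seeded generators for trio VCFs with planted donor
blocks (plus FASTA/GFF3/truth files), allele-template pairs with a planted
discriminating restriction site, and assay tables with specified category
proportions — each with exact ground truth, used throughout the test
suite.

## Worked example

```r
library(trioCAPS)

## simulate a trio with two planted donor blocks and map them back
ds  <- generateTrioDataset(trioSimConfig(seed = 42))
res <- mapIntrogression(ds$variants, ds$models)
res$blocks[, c("nDonor", "span", "nGenes")]
#>       seqnames        ranges strand |    nDonor      span    nGenes
#>   [1]     chr2 300035-499796      * |       195    199762        17
#>   [2]     chr3  50057-148260      * |       104     98204         9
```

The two detected blocks match the planted segments (chr2:300001–500000,
chr3:50001–150000) to within the local spacing of informative variants;
`nDonor` counts the supporting donor-assigned sites and `nGenes` the genes
overlapping each block. Gene-level origin for the same run:

```r
table(res$geneOrigin)
#>           DONOR       RECIPIENT NON_POLYMORPHIC        CONFLICT
#>              13             143             112               0
round(res$inheritancePct, 1)
#> [1] 8.3
```

i.e. 13 of the 156 polymorphic genes (8.3%) trace to the donor — the two
planted blocks cover ~10% of this toy genome. Marker design on a
simulated allele pair differing at 24 of 1106 positions:

```r
mk <- generateMarkerTemplates(seed = 1)
pairwiseIdentity(mk$templates[["alleleA"]], mk$templates[["alleleB"]])
#> $length      [1] 1106
#> $differences [1] 24
#> $identity    [1] 97.83

designCapsMarker(as.character(mk$templates[[1]]),
                 as.character(mk$templates[[2]]), pair = mk$pair)$markers
#>   enzyme pattern cutsA cutsB        fragmentsA     fragmentsB minFragment
#> 1   RsaI    GTAC     4     3 207,26,694,40,109 233,694,40,109          26
```

Exactly one enzyme discriminates the alleles — RsaI, the one the generator
planted: allele A's amplicon gains one cut (207 + 26 = 233), so the two
digests separate cleanly on a gel. Occupancy aggregation:

```r
sim <- generateNoduleAssays(c(A33_TOM = 100),
                            c(TOM_ONLY = 0.64, MIXED = 0.32,
                              NON_TOM_ONLY = 0.04))
tab <- occupancyTable(sim$assays$group, callNodule(sim$assays))
tomContainingFraction(tab, "A33_TOM")
#> [1] 96
```

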