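---
title: "Methods: trio introgression mapping, CAPS markers and nodule occupancy"
author: "trioCAPS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio introgression mapping, CAPS markers and nodule occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioCAPS)
library(GenomicRanges)
```

# The problem

An introgression line carries a small chromosomal segment transferred from a
donor genotype (here, an Afghan pea landrace contributing the *Sym2^A^*
nodulation-specificity locus) into a recipient cultivar's genetic
background. Characterising such a line raises three computational
questions, each answered by one module of this package:

1. **Which parts of the genome come from the donor?** Given whole-genome
   variant calls for the trio — donor parent, recipient parent, derived
   line — assign each variant a parental origin and delineate contiguous
   donor-derived blocks.
2. **How can the two rhizobial *nodX* alleles be told apart cheaply?**
   Design and validate a CAPS (cleaved amplified polymorphic sequence)
   marker: a PCR product that one allele's restriction site splits in two
   while the other allele's product stays intact.
3. **Which strain occupies each nodule?** Turn per-nodule PCR/digest
   observations into occupancy calls, aggregate them per plant group, and
   test count differences.

A fourth module generates synthetic inputs with known ground truth for all
three, so every stage is testable without sequencing data.

# Trio-based introgression mapping

## Model and assumptions

The line is assumed inbred: informative sites are fixed differences. A
variant site contributes to origin assignment only when all three genotypes
are homozygous and the parents differ; the line's allele then names the
parent it came from. Heterozygous or missing genotypes make a site
`UNINFORMATIVE` — a deliberately conservative rule that avoids phasing and
absorbs residual heterozygosity and genotyping dropouts. A homozygous line
allele matching neither parent is a `CONFLICT` (possible genotyping error,
mutation, or multi-allelic artefact). Multi-allelic records are split into
biallelic sites on reading; a genotype homozygous for another record's
allele is carried as `other_alt` so conflicts remain visible.

Sites are first filtered on call quality (`QUAL >= 20` by default, boundary
inclusive — the conventional bcftools threshold). Each site is then placed
into one of seven region classes against single-transcript gene models:
5' UTR, exon, 3' UTR, intron, upstream, downstream, intergenic. Within a
gene body UTR takes precedence over exon and exon over intron, which keeps
the three genic classes disjoint in reports. Flank classes are
strand-aware, extend `flankWindow` bp (default 5000, the conventional
annotator default for up/downstream effects), and go to the nearest gene
when two genes' flanks overlap, with distance ties resolved toward the gene
with the smaller start coordinate — an arbitrary but deterministic
tie-break. Indels are located by their VCF anchor base. Only genic variants
(5' UTR, exon, 3' UTR) are retained for gene-level summaries: variants in
introns, flanks and intergenic space are judged least likely to affect
protein function or regulation, while UTR variants are kept as potentially
regulatory.

A gene's origin is `DONOR` when it contains at least one retained
donor-assigned variant and no recipient-assigned one, `RECIPIENT`
symmetrically, `NON_POLYMORPHIC` with no retained variant, and `CONFLICT`
with both — conflicted genes are counted separately rather than folded into
either parent's tally. The genome-wide inheritance fraction is
$100 \cdot d/(d+r)$ over donor- and recipient-assigned gene counts,
reported to one decimal.

## Block delineation

Donor-derived blocks are maximal runs of donor-assigned sites per
chromosome, scanned in position order over the informative (donor- or
recipient-assigned) sites only. Up to `maxGapSites` consecutive non-donor
informative sites (default 2) are tolerated inside a run, so isolated
opposite-direction calls do not fragment a block, while longer interruptions
close it; runs with fewer than `minSupportSites` donor sites (default 5)
are discarded as noise. A block extends from its first to its last
supporting variant — spans are therefore measured variant-to-variant, not
gene-boundary-to-gene-boundary, which slightly underestimates the true
segment. Gene content is counted by any (>= 1 bp) overlap between gene body
and block. For BED export the 1-based closed block becomes 0-based
half-open; all interval arithmetic elsewhere stays 1-based closed as in
VCF/GFF3.

```{r blocks-demo}
ds <- generateTrioDataset(trioSimConfig(seed = 42))
tv <- filterQuality(ds$variants, 20)
blocks <- detectBlocks(tv, assignParent(tv))
summarizeBlocks(blocks, ds$models)
ds$truth$blocks
```

# CAPS marker design

Primer binding uses mismatch counting with a strict 3' anchor: a site
qualifies when the primer matches with at most `maxMismatch` mismatches
(default 2) and its `anchor` 3'-terminal bases (default 3) match exactly,
reflecting the dominance of the 3' end in polymerase extension. There is no
melting-temperature model; the rule is transparent and sufficient to
reproduce "amplifies allele A and B but not more distant homologues"
behaviour. In-silico PCR enumerates every orientation-valid pairing of a
plus-strand forward site with a downstream minus-strand reverse site within
a product cap; zero or multiple products are reported as such.

Restriction-site scanning matches IUPAC-degenerate patterns on both
strands. A cut position $c$ means cleavage between bases $c$ and $c+1$.
Palindromic patterns are scanned on the given strand only, so one locus
yields one cut; for palindromic enzymes with asymmetric (sticky-end) cut
offsets this pins the predicted cut to the strand the sequence is supplied
on — a convention that cancels in any comparison of two alleles under the
same convention. Cuts at position 0 or at the sequence end produce no
fragment; a linear digest therefore yields one more fragment than interior
cuts, and fragment lengths always sum to the amplicon length. An enzyme
discriminates two alleles when its predicted fragment-length multisets
differ; fragments under a configurable gel floor (default 20 bp, about the
smallest band reliably visible on standard agarose) are flagged.

The enzyme table is data, not code: a small editable TSV ships with the
package (`inst/extdata/enzymes.tsv`). RsaI is listed with its canonical
blunt site GT^AC; GATC, sometimes quoted for it informally, is the
recognition site of MboI, which the table also carries — keeping the table
editable means no such discrepancy is ever hard-coded.

Percent identity of an aligned pair is $100 (L - d)/L$ with gap columns
counted as differences, reported to two decimals:

```{r identity}
mk <- generateMarkerTemplates(seed = 1, templateLength = 1106, k = 24)
pairwiseIdentity(mk$templates[["alleleA"]], mk$templates[["alleleB"]])
```

# Nodule occupancy genotyping

Each nodule assay has a control amplification (*nodE*, present in all
rhizobia), a target amplification (*nodX*, present only in some strains),
and a digest pattern of the target product. The call rule: no control band,
`FAILED`; control but no target, `NODX_MINUS`; target fully cut,
`TOM_ONLY`; fully uncut, `NON_TOM_ONLY`; both products, `MIXED`. A target
band with no digest pattern is malformed and rejected. `FAILED` nodules are
excluded from all denominators — failures are tracked, but percentages
describe genotyped nodules. Percentages are rounded half-up to integers
(so 2/64 reports as 3%), matching conventional reporting of such assays;
`.5` cases never round down. The TOM-containing fraction of a group is the
percentage of genotyped nodules called `TOM_ONLY` or `MIXED`.

```{r occupancy}
sim <- generateNoduleAssays(c(A33_TOM = 100),
                            c(TOM_ONLY = 0.64, MIXED = 0.32,
                              NON_TOM_ONLY = 0.04))
tab <- occupancyTable(sim$assays$group, callNodule(sim$assays))
tab
tomContainingFraction(tab, "A33_TOM")
```

Two count statistics accompany the tables. `kruskalWallisTest()` wraps the
rank-based Kruskal–Wallis test (tie-corrected H, chi-square p) for
comparing nodule counts across groups; all-identical input returns H = 0,
p = 1 rather than an error. `welchLnTest()` runs Welch's unequal-variance
t-test on `ln(x + offset)`-transformed counts with Welch–Satterthwaite
degrees of freedom. The offset defaults to 0 because the transform is meant
for strictly positive counts; `offset = 1` is the documented choice when
zero counts occur. Zero variance in both samples is signalled as undefined.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are the fixed
study conditions used throughout the package's own validation:

* **Genome**: 3 chromosomes of 1 Mb. Small enough to simulate in seconds,
  large enough for thousands of variants per run.
* **Donor blocks**: two planted segments on different chromosomes — chr2:
  300,001–500,000 and chr3: 50,001–150,000 — echoing the one-large-plus-
  one-smaller two-region structure typical of a characterised introgression
  line.
* **Variant density** 1/600 bp, giving roughly 5,000 variants genome-wide;
  **SNV:indel ratio** 29:1, the genome-wide ratio seen in such cultivar
  comparisons.
* **Genotype noise**: 2% heterozygous and 1% missing rewrites per
  genotype; **QUAL** from a normal(60, 20) truncated at 0, so a realistic
  tail falls below the threshold of 20.
* **Gene models**: 300 non-overlapping single-transcript genes (about 100
  per chromosome), each with explicit 5'/3' UTRs and 2–4 exons — the
  simplest structure that exercises all seven region classes.

At each variant site the ALT allele is carried by the donor only, the
recipient only, or both (equal probability), so about two-thirds of sites
are informative. The line's genotype equals the donor's inside planted
blocks and the recipient's outside, *before* noise; noise can only erase
information (heterozygous/missing rewrites make sites uninformative), never
create a false donor assignment, which is why recovered background is
essentially zero while block boundaries are limited by the local
informative-site spacing. One seeded stream drives reference, gene models,
variants, genotypes, noise and quality in that documented order, so a
configuration plus seed reproduces a dataset byte for byte.

The marker-template generator plants a concrete recognition-site instance
in allele A and destroys it in allele B with one substitution; the
remaining `k - 1` substitutions are rejection-sampled so that none changes
any table enzyme's local site content in either allele. The planted enzyme
is therefore the only discriminating one by construction — which is what
makes "end-to-end design recovers exactly the planted enzyme" a sharp test.
The assay generator emits, for each drawn category, exactly the observation
fields the call rule maps back to it; exact mode allocates `n * p` by the
largest-remainder method with ties broken in declaration order.

## What the simulations do not capture

The generator emulates data *structure*, not biology: uniform variant
placement (no mutation-rate heterogeneity, no linkage-informed spacing),
independent uniform genotype noise (no allele-specific dropout or mapping
bias near indels), clean biallelic records, ideal primers, and error-free
digests. Real chromosome sizes and gene content are deliberately out of
scope. Passing the recovery tests therefore shows the algorithms are
correct under their stated assumptions; it does not certify performance on
reads-derived call sets with structured artefacts.

# Numerical choices and degenerate inputs

* Reported percentages round half-up (`floor(x + 0.5)`), never banker's
  rounding; identity uses two decimals, inheritance one.
* `inheritanceFraction()` returns full precision by default so the
  complementarity identity $f(a,b) + f(b,a) = 100$ holds exactly;
  rounding is explicit via `digits`.
* Empty inputs propagate as empty results (quality filter, PCR, block
  detection); contradictory requests error early (`k = 0` with a planted
  site, both-zero gene counts, zero-variance Welch input, malformed assay
  records).
* Validation problem sizes — 20 trio seeds at 3 x 1 Mb, 100 random 1 kb
  scans against a position-by-position oracle, 100 marker seeds,
  brute-force block enumeration up to 200 sites — were chosen as the
  smallest sets that exercise every code path with stable stochastic
  margins.

# Known limitations

* Block spans are variant-bounded; a block's true edges lie within one
  inter-site gap of the reported ones.
* The 3'-anchor primer model ignores thermodynamics; primers with strong
  secondary structure would need external design tools.
* Circular templates and partial digests are unsupported; all digests are
  linear and complete.
* Genes with internally conflicting variant assignments are reported as
  `CONFLICT`, not resolved; downstream inheritance fractions use only the
  unambiguous counts.
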