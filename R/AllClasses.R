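#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand findOverlaps countOverlaps
#' @importFrom IRanges IRanges
NULL

## genotype codes used throughout: hom_ref, hom_alt, het, missing, other_alt
.GT_LEVELS <- c("hom_ref", "hom_alt", "het", "missing", "other_alt")

.REGION_LEVELS <- c("FIVE_UTR", "EXON", "THREE_UTR", "INTRON",
                    "UPSTREAM", "DOWNSTREAM", "INTERGENIC")

.PARENT_LEVELS <- c("DONOR", "RECIPIENT", "UNINFORMATIVE", "CONFLICT")

.CALL_LEVELS <- c("FAILED", "NODX_MINUS", "TOM_ONLY", "NON_TOM_ONLY", "MIXED")

.DIGEST_LEVELS <- c("CUT", "UNCUT", "BOTH")

#' TrioVariants: biallelic variant sites genotyped in a parent/parent/line trio
#'
#' Holds one record per biallelic variant with the genotypes of the donor
#' parent, the recipient parent and the derived line, plus the variant class
#' (SNV or indel) and a phred-like quality score. Positions follow the VCF
#' convention (1-based; indels anchored at the POS base).
#'
#' The underlying container is a [GenomicRanges::GRanges] of width-1 anchors
#' with metadata columns `ref`, `alt`, `varClass`, `qual`, `gtDonor`,
#' `gtRecipient`, `gtLine`. Genotypes are collapsed to the allelic states the
#' trio analysis needs: `"hom_ref"`, `"hom_alt"`, `"het"`, `"missing"`, and
#' `"other_alt"` (homozygous for an allele other than the record's ALT, as
#' arises when multi-allelic records are split).
#'
#' @slot ranges `GRanges` of variant anchors with the metadata columns above.
#' @slot samples named character vector with elements `donor`, `recipient`,
#'   `line` giving the VCF sample names.
#'
#' @seealso [TrioVariants()], [readTrioVcf()], [assignParent()]
#' @aliases TrioVariants-class
#' @exportClass TrioVariants
setClass("TrioVariants",
         representation(ranges = "GRanges", samples = "character"))

setValidity("TrioVariants", function(object) {
    msg <- character()
    need <- c("ref", "alt", "varClass", "qual",
              "gtDonor", "gtRecipient", "gtLine")
    have <- colnames(mcols(object@ranges))
    if (!all(need %in% have))
        msg <- c(msg, paste("missing metadata columns:",
                            paste(setdiff(need, have), collapse = ", ")))
    else {
        m <- mcols(object@ranges)
        if (any(!nzchar(m$ref)) || any(!nzchar(m$alt)))
            msg <- c(msg, "ref and alt alleles must be non-empty")
        isSnv <- m$varClass == "SNV"
        if (any(isSnv & (nchar(m$ref) != 1L | nchar(m$alt) != 1L)))
            msg <- c(msg, "SNV records must have 1-bp ref and alt")
        if (any(!isSnv & nchar(m$ref) == 1L & nchar(m$alt) == 1L))
            msg <- c(msg, "1-bp ref/alt records must be class SNV")
        if (!all(m$varClass %in% c("SNV", "indel")))
            msg <- c(msg, "varClass must be 'SNV' or 'indel'")
        for (g in c("gtDonor", "gtRecipient", "gtLine"))
            if (!all(m[[g]] %in% .GT_LEVELS))
                msg <- c(msg, paste(g, "contains values outside",
                                    paste(.GT_LEVELS, collapse = "/")))
        if (any(m$qual < 0, na.rm = TRUE))
            msg <- c(msg, "quality scores must be non-negative")
    }
    if (!all(c("donor", "recipient", "line") %in% names(object@samples)))
        msg <- c(msg, "samples must be named donor, recipient, line")
    if (length(msg)) msg else TRUE
})

#' GeneModels: single-transcript gene structures for region classification
#'
#' A minimal gene annotation: per-gene span plus exon and UTR intervals, the
#' structure needed to place a variant into one of the seven region classes
#' (5' UTR, exon, 3' UTR, intron, upstream, downstream, intergenic).
#' Coordinates are 1-based closed, as in GFF3.
#'
#' @slot genes `GRanges` of gene bodies; `mcols(genes)$gene_id` holds ids.
#' @slot exons `GRangesList` of exon intervals, named by gene id.
#' @slot utr5,utr3 `GRangesList` of 5'/3' UTR intervals, named by gene id
#'   (possibly empty per gene).
#'
#' @seealso [GeneModels()], [readGeneModels()], [classifyRegion()]
#' @aliases GeneModels-class
#' @exportClass GeneModels
setClass("GeneModels",
         representation(genes = "GRanges", exons = "GRangesList",
                        utr5 = "GRangesList", utr3 = "GRangesList"))

setValidity("GeneModels", function(object) {
    msg <- character()
    ids <- mcols(object@genes)$gene_id
    if (is.null(ids) || anyDuplicated(ids))
        return("genes must carry unique mcols gene_id")
    for (slotName in c("exons", "utr5", "utr3")) {
        grl <- slot(object, slotName)
        if (!all(names(grl) %in% ids))
            msg <- c(msg, paste(slotName, "names must be gene ids"))
        feat <- unlist(grl, use.names = FALSE)
        if (length(feat)) {
            gi <- rep(match(names(grl), ids), S4Vectors::elementNROWS(grl))
            bad <- is.na(gi) |
                start(feat) < start(object@genes)[gi] |
                end(feat) > end(object@genes)[gi]
            if (any(bad))
                msg <- c(msg, paste(slotName,
                                    "intervals must lie within their gene"))
        }
    }
    if (length(msg)) msg else TRUE
})

#' PrimerPair: a forward/reverse primer pair with matching stringency
#'
#' Primer sequences are written 5'->3'. Binding-site search allows up to
#' `maxMismatch` mismatches per primer but requires the `anchor` 3'-terminal
#' bases to match exactly (mimicking the dominance of the 3' end in PCR
#' extension); there is no melting-temperature model.
#'
#' @slot forward,reverse character, primer sequences 5'->3' over A/C/G/T.
#' @slot maxMismatch integer, maximum mismatches tolerated per primer.
#' @slot anchor integer, number of 3'-terminal bases that must match exactly.
#'
#' @seealso [primerPair()], [findBindingSites()], [inSilicoPcr()]
#' @aliases PrimerPair-class
#' @exportClass PrimerPair
setClass("PrimerPair",
         representation(forward = "character", reverse = "character",
                        maxMismatch = "integer", anchor = "integer"))

setValidity("PrimerPair", function(object) {
    msg <- character()
    for (p in c(object@forward, object@reverse)) {
        if (nchar(p) < 15L)
            msg <- c(msg, "primers must be at least 15 nt")
        if (grepl("[^ACGT]", p))
            msg <- c(msg, "primers must be over A/C/G/T")
    }
    if (object@maxMismatch < 0L) msg <- c(msg, "maxMismatch must be >= 0")
    if (object@anchor < 0L || object@anchor > min(nchar(object@forward),
                                                  nchar(object@reverse)))
        msg <- c(msg, "anchor must be between 0 and the primer length")
    if (length(msg)) msg else TRUE
})

#' TrioSimConfig: parameters of the synthetic trio dataset generator
#'
#' Describes the simulated genome (chromosome lengths), the variant landscape
#' (density, SNV:indel ratio, quality-score distribution), the genotype noise
#' (heterozygous and missing fractions), the planted donor-derived blocks,
#' and the gene-model geometry. One configuration plus one seed determines
#' the dataset byte-for-byte.
#'
#' @slot chromLengths named numeric, chromosome lengths in bp.
#' @slot variantDensity numeric, expected variants per bp.
#' @slot donorBlocks `GRanges`, planted donor-derived segments (1-based
#'   closed); must be non-overlapping per chromosome and lie inside their
#'   chromosome.
#' @slot hetFraction,missingFraction numeric in \[0,1\], per-genotype
#'   probabilities of being rewritten as heterozygous / missing.
#' @slot snvIndelRatio numeric, expected SNV:indel count ratio.
#' @slot qualMean,qualSd numeric, parameters of the (truncated-at-0) normal
#'   from which QUAL scores are drawn.
#' @slot geneCount integer, total number of genes to place.
#' @slot meanGeneLength,meanExonLength,meanUtrLength numeric, mean feature
#'   lengths in bp.
#' @slot seed integer, random seed.
#'
#' @seealso [trioSimConfig()], [generateTrioDataset()]
#' @aliases TrioSimConfig-class
#' @exportClass TrioSimConfig
setClass("TrioSimConfig",
         representation(chromLengths = "numeric", variantDensity = "numeric",
                        donorBlocks = "GRanges", hetFraction = "numeric",
                        missingFraction = "numeric", snvIndelRatio = "numeric",
                        qualMean = "numeric", qualSd = "numeric",
                        geneCount = "integer", meanGeneLength = "numeric",
                        meanExonLength = "numeric", meanUtrLength = "numeric",
                        seed = "integer"))

setValidity("TrioSimConfig", function(object) {
    msg <- character()
    cl <- object@chromLengths
    if (is.null(names(cl)) || any(!nzchar(names(cl))) || anyDuplicated(names(cl)))
        msg <- c(msg, "chromLengths must have unique non-empty names")
    if (any(cl < 1))
        msg <- c(msg, "chromosome lengths must be positive")
    if (object@variantDensity < 0 || object@variantDensity > 1)
        msg <- c(msg, "variantDensity must be in [0, 1]")
    for (f in c("hetFraction", "missingFraction")) {
        v <- slot(object, f)
        if (v < 0 || v > 1) msg <- c(msg, paste(f, "must be in [0, 1]"))
    }
    blocks <- object@donorBlocks
    if (length(blocks)) {
        chr <- as.character(seqnames(blocks))
        if (!all(chr %in% names(cl)))
            msg <- c(msg, "donor blocks on chromosomes absent from chromLengths")
        else if (any(start(blocks) < 1) || any(end(blocks) > cl[chr]))
            msg <- c(msg, "donor blocks must lie inside their chromosome")
        ov <- findOverlaps(blocks, drop.self = TRUE, drop.redundant = TRUE)
        if (length(ov))
            msg <- c(msg, "donor blocks must not overlap")
    }
    if (object@snvIndelRatio <= 0) msg <- c(msg, "snvIndelRatio must be > 0")
    if (object@qualSd < 0) msg <- c(msg, "qualSd must be >= 0")
    if (object@geneCount < 0L) msg <- c(msg, "geneCount must be >= 0")
    if (length(msg)) msg else TRUE
})
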