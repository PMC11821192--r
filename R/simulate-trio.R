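#' Configure the synthetic trio dataset generator
#'
#' The defaults describe the standard simulated study: a small three-
#' chromosome genome with two planted donor-derived blocks (one large, one
#' smaller, on different chromosomes), a variant density giving roughly
#' 5,000 variants genome-wide, an SNV:indel ratio of 29:1, low heterozygous
#' and missing genotype noise, and QUAL scores from a truncated normal whose
#' lower tail falls below the usual threshold of 20.
#'
#' @param chromLengths named numeric, chromosome lengths (bp).
#' @param variantDensity expected variants per bp.
#' @param donorBlocks `GRanges` (or `data.frame` with `chrom`, `start`,
#'   `end`) of planted donor segments, 1-based closed, non-overlapping and
#'   inside their chromosomes.
#' @param hetFraction,missingFraction per-genotype probabilities of being
#'   rewritten as heterozygous / missing after the trio is constructed.
#' @param snvIndelRatio expected SNV:indel ratio.
#' @param qualMean,qualSd QUAL distribution (normal truncated at 0).
#' @param geneCount number of genes to place (allocated across chromosomes
#'   proportionally to length).
#' @param meanGeneLength,meanExonLength,meanUtrLength mean feature lengths
#'   (bp).
#' @param seed integer random seed.
#' @return A validated [TrioSimConfig-class] object.
#' @export
trioSimConfig <- function(chromLengths = c(chr1 = 1e6, chr2 = 1e6,
                                           chr3 = 1e6),
                          variantDensity = 1 / 600,
                          donorBlocks = GRanges(
                              c("chr2", "chr3"),
                              IRanges(c(300001L, 50001L),
                                      c(500000L, 150000L))),
                          hetFraction = 0.02, missingFraction = 0.01,
                          snvIndelRatio = 29, qualMean = 60, qualSd = 20,
                          geneCount = 300L, meanGeneLength = 3000,
                          meanExonLength = 200, meanUtrLength = 150,
                          seed = 1L) {
    if (is.data.frame(donorBlocks))
        donorBlocks <- GRanges(donorBlocks$chrom,
                               IRanges(donorBlocks$start, donorBlocks$end))
    new("TrioSimConfig", chromLengths = chromLengths,
        variantDensity = variantDensity, donorBlocks = donorBlocks,
        hetFraction = hetFraction, missingFraction = missingFraction,
        snvIndelRatio = snvIndelRatio, qualMean = qualMean, qualSd = qualSd,
        geneCount = as.integer(geneCount), meanGeneLength = meanGeneLength,
        meanExonLength = meanExonLength, meanUtrLength = meanUtrLength,
        seed = as.integer(seed))
}

setMethod("show", "TrioSimConfig", function(object) {
    cat("TrioSimConfig:", length(object@chromLengths), "chromosome(s),",
        sum(object@chromLengths), "bp total;",
        length(object@donorBlocks), "donor block(s);",
        "density", signif(object@variantDensity, 3),
        "; het", object@hetFraction, "; missing", object@missingFraction,
        "; seed", object@seed, "\n")
})

## lay out non-overlapping single-transcript genes along one chromosome
.simGenes <- function(chrom, chromLen, nGenes, meanExon, meanUtr,
                      meanGene, idOffset) {
    genes <- list(); exons <- list(); utr5 <- list(); utr3 <- list()
    meanIntron <- max(100, (meanGene - 2 * meanUtr - 3 * meanExon) / 2)
    cursor <- 1L + stats::rpois(1, 3000)
    g <- 0L
    while (g < nGenes) {
        u5 <- 30L + stats::rpois(1, max(0, meanUtr - 30))
        u3 <- 30L + stats::rpois(1, max(0, meanUtr - 30))
        nEx <- sample(2:4, 1L)
        exLens <- 50L + stats::rpois(nEx, max(0, meanExon - 50))
        inLens <- 80L + stats::rpois(nEx - 1L, max(0, meanIntron - 80))
        segLens <- c(u5, as.vector(rbind(exLens,
                                         c(inLens, NA)))[-(2 * nEx)], u3)
        gLen <- sum(segLens)
        gEnd <- cursor + gLen - 1L
        if (gEnd > chromLen) break
        g <- g + 1L
        id <- sprintf("gene%04d", idOffset + g)
        std <- sample(c("+", "-"), 1L)
        bounds <- cursor + cumsum(c(0L, segLens))
        segStart <- bounds[-length(bounds)]
        segEnd <- bounds[-1] - 1L
        ## segments left to right: UTR, exon, (intron, exon)..., UTR;
        ## on '-' genes the left UTR is the 3' UTR
        nSeg <- length(segLens)
        exIdx <- seq(2L, nSeg - 1L, by = 2L)
        leftUtr <- IRanges(segStart[1], segEnd[1])
        rightUtr <- IRanges(segStart[nSeg], segEnd[nSeg])
        genes[[id]] <- data.frame(chrom = chrom, start = cursor, end = gEnd,
                                  strand = std, gene_id = id)
        exons[[id]] <- GRanges(chrom, IRanges(segStart[exIdx], segEnd[exIdx]),
                               strand = std)
        u5r <- if (std == "+") leftUtr else rightUtr
        u3r <- if (std == "+") rightUtr else leftUtr
        utr5[[id]] <- GRanges(chrom, u5r, strand = std)
        utr3[[id]] <- GRanges(chrom, u3r, strand = std)
        cursor <- gEnd + 1L + as.integer(round(stats::runif(1, 2000, 15000)))
    }
    list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3)
}

#' Generate a complete synthetic trio dataset
#'
#' Builds, from one seeded random stream, (1) a random reference sequence
#' per chromosome, (2) non-overlapping single-transcript gene models with
#' explicit UTRs, (3) trio variant records in which the line's genotype
#' equals the donor's inside the planted donor blocks and the recipient's
#' outside them, with heterozygous/missing noise and QUAL scores applied
#' afterwards, and (4) the ground truth (per-site origin, planted blocks,
#' per-gene origin). The stream is consumed in that order, so a fixed
#' configuration (including its seed) reproduces the dataset exactly.
#'
#' @param config a [TrioSimConfig-class] object.
#' @return list with elements `reference` (`DNAStringSet`), `models`
#'   ([GeneModels-class]), `variants` ([TrioVariants-class]), `truth`
#'   (list: `blocks` `GRanges`, `siteOrigin` character per variant,
#'   `geneOrigin` named character) and `config`.
#' @seealso [writeTrioDataset()], [mapIntrogression()]
#' @export
generateTrioDataset <- function(config) {
    stopifnot(is(config, "TrioSimConfig"))
    validObject(config)
    set.seed(config@seed)
    cl <- config@chromLengths
    chroms <- names(cl)

    ## 1. reference
    reference <- Biostrings::DNAStringSet(
        vapply(cl, function(n) .randomDna(n), character(1)))
    names(reference) <- chroms

    ## 2. gene models
    alloc <- round(config@geneCount * cl / sum(cl))
    parts <- list(); off <- 0L
    for (ch in chroms) {
        parts[[ch]] <- .simGenes(ch, cl[[ch]], alloc[[ch]],
                                 config@meanExonLength, config@meanUtrLength,
                                 config@meanGeneLength, off)
        off <- off + length(parts[[ch]]$genes)
    }
    geneDf <- do.call(rbind, unlist(lapply(parts, `[[`, "genes"),
                                    recursive = FALSE))
    geneGr <- GRanges(geneDf$chrom, IRanges(geneDf$start, geneDf$end),
                      strand = geneDf$strand)
    mcols(geneGr) <- DataFrame(gene_id = geneDf$gene_id)
    asGrl <- function(field) {
        lst <- unlist(lapply(parts, `[[`, field), recursive = FALSE)
        names(lst) <- vapply(strsplit(names(lst), ".", fixed = TRUE),
                             function(x) x[[2]], character(1))
        GRangesList(lst)
    }
    models <- GeneModels(geneGr, asGrl("exons"), asGrl("utr5"),
                         asGrl("utr3"))

    ## 3. variants
    pIndel <- 1 / (1 + config@snvIndelRatio)
    sites <- list()
    for (ch in chroms) {
        n <- stats::rpois(1, cl[[ch]] * config@variantDensity)
        n <- min(n, cl[[ch]] - 5L)
        pos <- sort(sample.int(cl[[ch]] - 5L, n))
        refSeq <- as.character(reference[[ch]])
        isIndel <- stats::runif(n) < pIndel
        refA <- substring(refSeq, pos, pos)
        altA <- character(n)
        bases <- c("A", "C", "G", "T")
        for (i in seq_len(n)) {
            if (!isIndel[i]) {
                altA[i] <- sample(setdiff(bases, refA[i]), 1L)
            } else if (stats::runif(1) < 0.5) {  # insertion
                ins <- paste(sample(bases, sample(1:4, 1L), replace = TRUE),
                             collapse = "")
                altA[i] <- paste0(refA[i], ins)
            } else {                              # deletion
                dl <- sample(1:4, 1L)
                refA[i] <- substring(refSeq, pos[i], pos[i] + dl)
                altA[i] <- substring(refSeq, pos[i], pos[i])
            }
        }
        sites[[ch]] <- data.frame(chrom = ch, pos = pos, ref = refA,
                                  alt = altA)
    }
    sites <- do.call(rbind, sites)
    n <- nrow(sites)

    ## 4. trio genotypes: each site carries ALT in the donor, the recipient
    ## or both (equal probability); the line copies the donor inside blocks
    conf <- sample(3L, n, replace = TRUE)  # 1 donor-only, 2 recip-only, 3 both
    gtD <- ifelse(conf == 2L, "hom_ref", "hom_alt")
    gtR <- ifelse(conf == 1L, "hom_ref", "hom_alt")
    siteGr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
    inBlock <- countOverlaps(siteGr, config@donorBlocks) > 0
    gtL <- ifelse(inBlock, gtD, gtR)

    ## 5. noise: one uniform per genotype; [0,het) -> het,
    ## [het, het+missing) -> missing
    noisify <- function(g) {
        u <- stats::runif(n)
        g[u < config@hetFraction] <- "het"
        g[u >= config@hetFraction &
          u < config@hetFraction + config@missingFraction] <- "missing"
        g
    }
    gtD <- noisify(gtD); gtR <- noisify(gtR); gtL <- noisify(gtL)

    ## 6. quality
    qual <- pmax(0, round(stats::rnorm(n, config@qualMean, config@qualSd), 1))

    ## align with the (chromosome, position) sort order of TrioVariants
    ord <- order(sites$chrom, sites$pos)
    sites <- sites[ord, ]; qual <- qual[ord]; inBlock <- inBlock[ord]
    gtD <- gtD[ord]; gtR <- gtR[ord]; gtL <- gtL[ord]

    variants <- TrioVariants(sites$chrom, sites$pos, sites$ref, sites$alt,
                             qual, gtD, gtR, gtL)
    geneOrigin <- ifelse(countOverlaps(geneGr, config@donorBlocks) > 0,
                         "DONOR", "RECIPIENT")
    names(geneOrigin) <- geneDf$gene_id
    list(reference = reference, models = models, variants = variants,
         truth = list(blocks = config@donorBlocks,
                      siteOrigin = ifelse(inBlock, "DONOR", "RECIPIENT"),
                      geneOrigin = geneOrigin),
         config = config)
}

#' Write a synthetic trio dataset to disk
#'
#' Writes `reference.fa`, `genes.gff3`, `trio.vcf` and `truth.json` into a
#' directory.
#'
#' @param dataset result of [generateTrioDataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeTrioDataset <- function(dataset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(dataset$reference,
                                file.path(dir, "reference.fa"))
    writeGeneModels(dataset$models, file.path(dir, "genes.gff3"))
    writeTrioVcf(dataset$variants, file.path(dir, "trio.vcf"),
                 contigLengths = dataset$config@chromLengths)
    truth <- dataset$truth
    gr <- variantRanges(dataset$variants)
    jsonlite::write_json(
        list(blocks = data.frame(
                 chrom = as.character(seqnames(truth$blocks)),
                 start = start(truth$blocks), end = end(truth$blocks)),
             siteOrigin = data.frame(
                 chrom = as.character(seqnames(gr)), pos = start(gr),
                 origin = truth$siteOrigin),
             geneOrigin = as.list(truth$geneOrigin)),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
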