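#' Filter variant sites on quality
#'
#' Keeps sites whose phred-like QUAL is greater than or equal to the
#' threshold (the boundary value itself is retained). Order is preserved.
#'
#' @param tv a [TrioVariants-class] object.
#' @param minQual numeric threshold, default 20.
#' @return The retained subset, a `TrioVariants` object.
#' @examples
#' tv <- TrioVariants("chr1", c(1, 2), c("A", "A"), c("G", "G"),
#'                    qual = c(20, 19.9),
#'                    gtDonor = "hom_alt", gtRecipient = "hom_ref",
#'                    gtLine = "hom_alt")
#' length(filterQuality(tv, 20))  # 1: the QUAL 20 site stays
#' @export
filterQuality <- function(tv, minQual = 20) {
    stopifnot(minQual >= 0)
    tv[which(mcols(variantRanges(tv))$qual >= minQual)]
}

#' Assign parental origin to each trio site
#'
#' Implements the trio allelic-state rule for an inbred derived line: a site
#' is informative only when all three genotypes are homozygous and the two
#' parents differ. The line's allele then identifies the parent it was
#' inherited from.
#'
#' \itemize{
#'   \item `DONOR`: parents differ, line matches the donor.
#'   \item `RECIPIENT`: parents differ, line matches the recipient.
#'   \item `UNINFORMATIVE`: parents agree, or any genotype is heterozygous
#'     or missing.
#'   \item `CONFLICT`: all homozygous, parents differ, but the line matches
#'     neither (e.g. it carries an allele absent from both parents).
#' }
#'
#' @param tv a [TrioVariants-class] object (normally quality-filtered).
#' @return factor of length `length(tv)` with levels
#'   `DONOR`, `RECIPIENT`, `UNINFORMATIVE`, `CONFLICT`.
#' @export
assignParent <- function(tv) {
    m <- mcols(variantRanges(tv))
    homStates <- c("hom_ref", "hom_alt", "other_alt")
    d <- m$gtDonor; r <- m$gtRecipient; l <- m$gtLine
    allHom <- d %in% homStates & r %in% homStates & l %in% homStates
    out <- rep("UNINFORMATIVE", length(d))
    informative <- allHom & d != r
    out[informative & l == d] <- "DONOR"
    out[informative & l == r] <- "RECIPIENT"
    out[informative & l != d & l != r] <- "CONFLICT"
    factor(out, levels = .PARENT_LEVELS)
}

#' Classify each variant site into a gene-region class
#'
#' Seven-way classification against single-transcript gene models with
#' precedence, within a gene body, 5'/3' UTR over exon over intron; outside
#' any gene body, `UPSTREAM`/`DOWNSTREAM` (strand-aware, within
#' `flankWindow` bp of the gene) and `INTERGENIC` otherwise. When the flanks
#' of two genes overlap a site, the nearer gene wins; distance ties go to
#' the gene with the smaller start coordinate. Indels are classified by
#' their VCF anchor base.
#'
#' @param tv a [TrioVariants-class] object.
#' @param models a [GeneModels-class] object.
#' @param flankWindow flank width in bp (default 5000).
#' @return A [S4Vectors::DataFrame] with columns `regionClass` (factor over
#'   the seven classes) and `geneId` (the gene attributed to the class;
#'   `NA` for `INTERGENIC`).
#' @export
classifyRegion <- function(tv, models, flankWindow = 5000) {
    stopifnot(flankWindow > 0)
    sites <- GRanges(seqnames(variantRanges(tv)),
                     IRanges(start(variantRanges(tv)), width = 1L))
    n <- length(sites)
    cls <- rep(NA_character_, n)
    gene <- rep(NA_character_, n)
    genes <- geneRanges(models)
    ids <- geneIds(models)

    known <- as.character(seqnames(sites)) %in%
        unique(as.character(seqnames(genes)))
    if (any(!known))
        warning(sum(!known), " site(s) on chromosomes absent from the ",
                "annotation; classified INTERGENIC")

    ## common seqlevels so overlap calls do not warn on partial annotations
    allLv <- union(GenomeInfoDb::seqlevels(sites),
                   GenomeInfoDb::seqlevels(genes))
    harmonize <- function(gr) {
        GenomeInfoDb::seqlevels(gr) <- allLv
        gr
    }
    sites <- harmonize(sites)
    genes <- harmonize(genes)

    hitFeature <- function(grl, label) {
        if (!length(grl)) return()
        feat <- harmonize(unlist(grl, use.names = FALSE))
        featGene <- rep(names(grl), S4Vectors::elementNROWS(grl))
        ov <- findOverlaps(sites, feat)
        take <- S4Vectors::queryHits(ov)[is.na(cls[S4Vectors::queryHits(ov)])]
        featIdx <- S4Vectors::subjectHits(ov)[is.na(cls[S4Vectors::queryHits(ov)])]
        if (length(take)) {
            first <- !duplicated(take)
            cls[take[first]] <<- label
            gene[take[first]] <<- featGene[featIdx[first]]
        }
    }
    hitFeature(models@utr5, "FIVE_UTR")
    hitFeature(models@utr3, "THREE_UTR")
    hitFeature(models@exons, "EXON")

    ## remaining sites inside a gene body are intronic
    ovGene <- findOverlaps(sites, genes)
    qh <- S4Vectors::queryHits(ovGene); sh <- S4Vectors::subjectHits(ovGene)
    open <- is.na(cls[qh])
    first <- open & !duplicated(qh)
    cls[qh[first]] <- "INTRON"
    gene[qh[first]] <- ids[sh[first]]

    ## flanks: strand-aware windows; nearest gene wins, tie -> smaller start
    minus <- as.character(strand(genes)) == "-"
    up <- GenomicRanges::flank(genes, flankWindow, start = TRUE)
    dn <- GenomicRanges::flank(genes, flankWindow, start = FALSE)
    up <- IRanges::restrict(up, start = 1L)
    dn <- IRanges::restrict(dn, start = 1L)
    flanks <- c(up, dn)
    flankClass <- rep(c("UPSTREAM", "DOWNSTREAM"), each = length(genes))
    flankGene <- rep(seq_along(genes), 2L)
    ovF <- findOverlaps(sites, flanks)
    if (length(ovF)) {
        qf <- S4Vectors::queryHits(ovF); sf <- S4Vectors::subjectHits(ovF)
        keep <- is.na(cls[qf])
        qf <- qf[keep]; sf <- sf[keep]
        if (length(qf)) {
            gi <- flankGene[sf]
            dist <- pmax(start(genes)[gi] - start(sites)[qf],
                         start(sites)[qf] - end(genes)[gi])
            ord <- order(qf, dist, start(genes)[gi])
            qf <- qf[ord]; sf <- sf[ord]
            first <- !duplicated(qf)
            cls[qf[first]] <- flankClass[sf[first]]
            gene[qf[first]] <- ids[flankGene[sf[first]]]
        }
    }
    cls[is.na(cls)] <- "INTERGENIC"
    DataFrame(regionClass = factor(cls, levels = .REGION_LEVELS),
              geneId = gene)
}

#' Retain only genic variant sites (5' UTR, exon, 3' UTR)
#'
#' Variants in introns, flanks and intergenic space are discarded; UTR
#' variants are kept as potentially regulatory.
#'
#' @param regionClass factor as returned by [classifyRegion()].
#' @return integer indices of the retained sites.
#' @export
applyRegionFilter <- function(regionClass) {
    which(regionClass %in% c("FIVE_UTR", "EXON", "THREE_UTR"))
}

#' Tabulate retained variants by region class and variant class
#'
#' @param regionClass factor over `FIVE_UTR`/`EXON`/`THREE_UTR` (values
#'   outside these are rejected — filter first).
#' @param varClass character, `"SNV"` or `"indel"` per site.
#' @return 3 x 2 integer matrix (rows `FIVE_UTR`, `EXON`, `THREE_UTR`;
#'   columns `SNV`, `indel`); its sum equals the number of input sites.
#' @examples
#' variantRegionTable(rep(c("EXON", "FIVE_UTR"), c(2, 1)),
#'                    c("SNV", "SNV", "indel"))
#' @export
variantRegionTable <- function(regionClass, varClass) {
    keepLevels <- c("FIVE_UTR", "EXON", "THREE_UTR")
    regionClass <- as.character(regionClass)
    if (!all(regionClass %in% keepLevels))
        stop("variantRegionTable expects region-filtered input ",
             "(FIVE_UTR/EXON/THREE_UTR only)")
    tab <- table(factor(regionClass, levels = keepLevels),
                 factor(varClass, levels = c("SNV", "indel")))
    m <- matrix(as.integer(tab), nrow = 3, dimnames = dimnames(tab))
    names(dimnames(m)) <- NULL
    m
}

#' Assign a parental origin to each gene
#'
#' A gene is `DONOR` when it contains at least one retained donor-assigned
#' variant and no recipient-assigned one; `RECIPIENT` symmetrically;
#' `NON_POLYMORPHIC` when it contains no retained variant;
#' `CONFLICT` when it contains both.
#'
#' @param models a [GeneModels-class] object.
#' @param geneId character, gene attribution of each retained site (from
#'   [classifyRegion()], subset to the retained sites).
#' @param assignment factor from [assignParent()] for the same sites.
#' @return named factor (one element per gene in `models`) with levels
#'   `DONOR`, `RECIPIENT`, `NON_POLYMORPHIC`, `CONFLICT`.
#' @export
assignGeneOrigin <- function(models, geneId, assignment) {
    stopifnot(length(geneId) == length(assignment))
    ids <- geneIds(models)
    donorHits <- table(factor(geneId[assignment == "DONOR"], levels = ids))
    recipHits <- table(factor(geneId[assignment == "RECIPIENT"], levels = ids))
    out <- ifelse(donorHits > 0 & recipHits > 0, "CONFLICT",
           ifelse(donorHits > 0, "DONOR",
           ifelse(recipHits > 0, "RECIPIENT", "NON_POLYMORPHIC")))
    factor(stats::setNames(out, ids),
           levels = c("DONOR", "RECIPIENT", "NON_POLYMORPHIC", "CONFLICT"))
}

#' Genome-wide inheritance fraction from gene counts
#'
#' The percentage of polymorphic genes inherited from the donor:
#' `100 * donor / (donor + recipient)`. The value is returned at full
#' precision; reports round it to one decimal (see `digits`).
#'
#' @param donorGenes,recipientGenes non-negative gene counts.
#' @param digits if non-`NULL`, round (half-up) to this many decimals.
#' @return numeric percentage.
#' @examples
#' inheritanceFraction(464, 14365, digits = 1)  # 3.1
#' @export
inheritanceFraction <- function(donorGenes, recipientGenes, digits = NULL) {
    if (donorGenes + recipientGenes <= 0)
        stop("inheritance fraction undefined: no assigned genes")
    pct <- 100 * donorGenes / (donorGenes + recipientGenes)
    if (!is.null(digits)) pct <- .roundHalfUp(pct, digits)
    pct
}

#' Delineate donor-derived introgression blocks
#'
#' Scans the informative (donor- or recipient-assigned) sites of each
#' chromosome in position order and reports maximal runs of donor sites. Up
#' to `maxGapSites` *consecutive* non-donor informative sites are tolerated
#' inside a run; a longer interruption closes it. Runs supported by fewer
#' than `minSupportSites` donor sites are dropped. A block extends from its
#' first to its last supporting donor site.
#'
#' @param sites `GRanges` of width-1 variant anchors (or a
#'   [TrioVariants-class] object, from which anchors are taken), sorted by
#'   (chromosome, position).
#' @param assignment factor from [assignParent()], parallel to `sites`.
#'   `UNINFORMATIVE`/`CONFLICT` sites are ignored.
#' @param maxGapSites maximum run of interior non-donor informative sites
#'   tolerated (default 2).
#' @param minSupportSites minimum donor sites per block (default 5).
#' @return `GRanges` of blocks with metadata columns `nDonor` (supporting
#'   donor sites), `nInterior` (interior non-donor informative sites) and
#'   `span` (end - start + 1).
#' @export
detectBlocks <- function(sites, assignment, maxGapSites = 2L,
                         minSupportSites = 5L) {
    if (is(sites, "TrioVariants")) sites <- variantRanges(sites)
    stopifnot(length(sites) == length(assignment),
              maxGapSites >= 0L, minSupportSites >= 1L)
    chrom <- as.character(seqnames(sites))
    pos <- start(sites)
    if (is.unsorted(order(chrom, pos)) &&
        any(unlist(tapply(pos, chrom, is.unsorted))))
        stop("sites must be sorted by (chromosome, position)")
    keep <- assignment %in% c("DONOR", "RECIPIENT")
    chrom <- chrom[keep]; pos <- pos[keep]
    isDonor <- assignment[keep] == "DONOR"
    res <- list()
    for (ch in unique(chrom)) {
        sel <- chrom == ch
        p <- pos[sel]; d <- isDonor[sel]
        i <- 1L; n <- length(p)
        while (i <= n) {
            if (!d[i]) { i <- i + 1L; next }
            ## open a run at donor site i
            j <- i; lastDonor <- i; gap <- 0L; nDonor <- 0L; nInterior <- 0L
            while (j <= n) {
                if (d[j]) {
                    nDonor <- nDonor + 1L
                    nInterior <- nInterior + gap
                    gap <- 0L; lastDonor <- j
                } else {
                    gap <- gap + 1L
                    if (gap > maxGapSites) break
                }
                j <- j + 1L
            }
            if (nDonor >= minSupportSites)
                res[[length(res) + 1L]] <-
                    data.frame(chrom = ch, start = p[i], end = p[lastDonor],
                               nDonor = nDonor, nInterior = nInterior)
            i <- lastDonor + 1L
            while (i <= n && !d[i]) i <- i + 1L
        }
    }
    if (!length(res))
        return(GRanges(nDonor = integer(), nInterior = integer(),
                       span = integer()))
    df <- do.call(rbind, res)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    mcols(gr) <- DataFrame(nDonor = df$nDonor, nInterior = df$nInterior,
                           span = df$end - df$start + 1L)
    gr
}

#' Summarise introgression blocks against the gene annotation
#'
#' A gene is counted for a block when its body overlaps the block interval
#' by at least one bp.
#'
#' @param blocks `GRanges` from [detectBlocks()].
#' @param models a [GeneModels-class] object.
#' @return The blocks with added metadata columns `nGenes` and `genes`
#'   (a `CharacterList` of overlapping gene ids).
#' @export
summarizeBlocks <- function(blocks, models) {
    genes <- geneRanges(models)
    ov <- findOverlaps(blocks, genes)
    hitIds <- split(geneIds(models)[S4Vectors::subjectHits(ov)],
                    factor(S4Vectors::queryHits(ov),
                           levels = seq_along(blocks)))
    mcols(blocks)$nGenes <- countOverlaps(blocks, genes)
    mcols(blocks)$genes <- IRanges::CharacterList(hitIds)
    blocks
}

#' Binned per-chromosome distribution of donor-assigned sites
#'
#' @param sites `GRanges` of width-1 anchors (or a [TrioVariants-class]).
#' @param assignment factor from [assignParent()].
#' @param binSize bin width in bp.
#' @param chromLengths optional named lengths; defaults to the last donor
#'   site position per chromosome (rounded up to a full bin).
#' @return `data.frame` with columns `chrom`, `binStart`, `binEnd`, `count`;
#'   counts sum to the number of donor-assigned sites.
#' @seealso [plotChromosomeDistribution()]
#' @export
chromosomeDistribution <- function(sites, assignment, binSize = 1e6,
                                   chromLengths = NULL) {
    stopifnot(binSize > 0)
    if (is(sites, "TrioVariants")) sites <- variantRanges(sites)
    chrom <- as.character(seqnames(sites))
    pos <- start(sites)
    donor <- assignment == "DONOR"
    chroms <- if (!is.null(chromLengths)) names(chromLengths) else
        sort(unique(chrom))
    out <- lapply(chroms, function(ch) {
        len <- if (!is.null(chromLengths)) chromLengths[[ch]] else
            max(pos[chrom == ch], binSize)
        nbin <- ceiling(len / binSize)
        p <- pos[donor & chrom == ch]
        cnt <- tabulate(pmin((p - 1) %/% binSize + 1, nbin), nbins = nbin)
        data.frame(chrom = ch,
                   binStart = (seq_len(nbin) - 1) * binSize + 1,
                   binEnd = pmin(seq_len(nbin) * binSize, len),
                   count = cnt)
    })
    do.call(rbind, out)
}

#' Plot the per-chromosome distribution of donor-derived variants
#'
#' One panel per chromosome, donor-site counts per bin along the
#' chromosome.
#'
#' @param dist `data.frame` from [chromosomeDistribution()].
#' @return A ggplot object.
#' @export
plotChromosomeDistribution <- function(dist) {
    mid <- count <- NULL  # data columns, for R CMD check
    dist$mid <- (dist$binStart + dist$binEnd) / 2
    ggplot2::ggplot(dist, ggplot2::aes(x = mid, y = count)) +
        ggplot2::geom_col(width = (dist$binEnd - dist$binStart)[1] * 0.9,
                          fill = "grey30") +
        ggplot2::facet_wrap(~chrom, ncol = 1) +
        ggplot2::labs(x = "position (bp)",
                      y = "donor-derived variants per bin") +
        ggplot2::theme_bw()
}

#' Map donor introgression blocks from a trio VCF and gene models
#'
#' End-to-end convenience wrapper: quality filter, parental assignment,
#' region classification and filter, Table-1-style region counts,
#' per-gene origin, inheritance fraction, and block delineation with
#' per-block span/gene summaries.
#'
#' @param tv a [TrioVariants-class] object.
#' @param models a [GeneModels-class] object.
#' @param minQual QUAL threshold (default 20).
#' @param flankWindow flank width for region classification (default 5000).
#' @param maxGapSites,minSupportSites block-detection parameters, see
#'   [detectBlocks()].
#' @return A list with elements `sites` (retained `GRanges` with
#'   `assignment`, `regionClass`, `geneId`), `regionTable` (donor sites by
#'   region x variant class), `geneOrigin` (factor per gene),
#'   `inheritancePct` (unrounded percent), `blocks` (summarised `GRanges`),
#'   and `distribution` (binned donor-site counts).
#' @export
mapIntrogression <- function(tv, models, minQual = 20, flankWindow = 5000,
                             maxGapSites = 2L, minSupportSites = 5L) {
    tv <- filterQuality(tv, minQual)
    assignment <- assignParent(tv)
    reg <- classifyRegion(tv, models, flankWindow)
    keep <- applyRegionFilter(reg$regionClass)
    gr <- variantRanges(tv)
    mcols(gr)$assignment <- assignment
    mcols(gr)$regionClass <- reg$regionClass
    mcols(gr)$geneId <- reg$geneId
    retained <- gr[keep]
    donorRetained <- retained[retained$assignment == "DONOR"]
    regionTable <- variantRegionTable(
        as.character(donorRetained$regionClass), donorRetained$varClass)
    geneOrigin <- assignGeneOrigin(models, retained$geneId,
                                   retained$assignment)
    counts <- table(geneOrigin)
    inhPct <- if (counts[["DONOR"]] + counts[["RECIPIENT"]] > 0)
        inheritanceFraction(counts[["DONOR"]], counts[["RECIPIENT"]])
    else NA_real_
    blocks <- detectBlocks(gr, assignment, maxGapSites, minSupportSites)
    blocks <- summarizeBlocks(blocks, models)
    list(sites = retained, regionTable = regionTable,
         geneOrigin = geneOrigin, inheritancePct = inhPct,
         blocks = blocks,
         distribution = chromosomeDistribution(gr, assignment))
}

#' Write introgression blocks as BED
#'
#' BED uses 0-based half-open coordinates; the 1-based closed block
#' \[start, end\] becomes \[start-1, end).
#'
#' @param blocks `GRanges` of blocks.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBlocksBed <- function(blocks, path) {
    df <- data.frame(chrom = as.character(seqnames(blocks)),
                     start = start(blocks) - 1L, end = end(blocks),
                     name = sprintf("block_%d", seq_along(blocks)),
                     score = mcols(blocks)$nDonor, strand = ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
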