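#' Construct a GeneModels object
#'
#' @param genes `GRanges` of gene bodies with `mcols(genes)$gene_id` and
#'   strand set.
#' @param exons,utr5,utr3 `GRangesList` of exon / 5' UTR / 3' UTR intervals
#'   named by gene id. Genes absent from a list simply lack that feature.
#'
#' @return A [GeneModels-class] object.
#' @seealso [readGeneModels()], [writeGeneModels()], [classifyRegion()]
#' @export
GeneModels <- function(genes, exons, utr5 = GRangesList(), utr3 = GRangesList()) {
    new("GeneModels", genes = genes, exons = exons, utr5 = utr5, utr3 = utr3)
}

#' @describeIn GeneModels number of genes
#' @param x,object a `GeneModels` object
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

#' @describeIn GeneModels `GRanges` of gene bodies
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModels
#' @export
setMethod("geneRanges", "GeneModels", function(x) x@genes)

#' @describeIn GeneModels character vector of gene ids
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModels
#' @export
setMethod("geneIds", "GeneModels", function(x) mcols(x@genes)$gene_id)

#' @describeIn GeneModels exon intervals as a `GRangesList` named by gene id
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname GeneModels
#' @export
setMethod("exonRanges", "GeneModels", function(x) x@exons)

#' @describeIn GeneModels UTR intervals as a `GRangesList` named by gene id
#' @param side `"five"` or `"three"`
#' @export
setGeneric("utrRanges", function(x, side = c("five", "three"))
    standardGeneric("utrRanges"))

#' @rdname GeneModels
#' @export
setMethod("utrRanges", "GeneModels", function(x, side = c("five", "three")) {
    if (match.arg(side) == "five") x@utr5 else x@utr3
})

setMethod("show", "GeneModels", function(object) {
    cat("GeneModels with", length(object), "genes on",
        length(unique(as.character(seqnames(object@genes)))),
        "chromosome(s);",
        sum(S4Vectors::elementNROWS(object@exons)), "exons,",
        sum(S4Vectors::elementNROWS(object@utr5)), "5'UTRs,",
        sum(S4Vectors::elementNROWS(object@utr3)), "3'UTRs\n")
})

#' Read gene models from a GFF3 file
#'
#' Expects `gene` features with an `ID` attribute and `exon`,
#' `five_prime_UTR`, `three_prime_UTR` features whose `Parent` points at the
#' gene (directly, as written by [writeGeneModels()]).
#'
#' @param path GFF3 file.
#' @return A [GeneModels-class] object.
#' @export
readGeneModels <- function(path) {
    gff <- rtracklayer::import(path, format = "gff3")
    genes <- gff[gff$type == "gene"]
    mcols(genes) <- DataFrame(gene_id = as.character(genes$ID))
    grab <- function(type) {
        feat <- gff[gff$type == type]
        parent <- as.character(unlist(feat$Parent))
        mcols(feat) <- NULL
        S4Vectors::split(feat, factor(parent, levels = unique(parent)))
    }
    GeneModels(genes = genes, exons = grab("exon"),
               utr5 = grab("five_prime_UTR"), utr3 = grab("three_prime_UTR"))
}

#' Write gene models to a GFF3 file
#'
#' Features are written 1-based closed with `exon`/`five_prime_UTR`/
#' `three_prime_UTR` rows parented directly on their `gene` row
#' (single-transcript models, no mRNA level).
#'
#' @param models a [GeneModels-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
    genes <- geneRanges(models)
    ids <- geneIds(models)
    mcols(genes) <- DataFrame(
        type = "gene", ID = ids,
        Parent = IRanges::CharacterList(vector("list", length(genes))))
    featRows <- function(grl, type) {
        if (!length(grl)) return(genes[0])
        feat <- unlist(grl, use.names = FALSE)
        parent <- rep(names(grl), S4Vectors::elementNROWS(grl))
        mcols(feat) <- DataFrame(type = type, ID = NA_character_,
                                 Parent = IRanges::CharacterList(as.list(parent)))
        feat
    }
    out <- c(genes,
             featRows(models@exons, "exon"),
             featRows(models@utr5, "five_prime_UTR"),
             featRows(models@utr3, "three_prime_UTR"))
    out <- out[order(as.character(seqnames(out)), start(out),
                     match(out$type, c("gene", "five_prime_UTR", "exon",
                                       "three_prime_UTR")))]
    out$source <- "trioCAPS"
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}
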