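#' Construct a TrioVariants object
#'
#' @param chrom character, chromosome of each site.
#' @param pos integer, 1-based VCF position (indel anchor base).
#' @param ref,alt character, reference and alternate alleles.
#' @param qual numeric, phred-like site quality.
#' @param gtDonor,gtRecipient,gtLine character genotype states, each one of
#'   `"hom_ref"`, `"hom_alt"`, `"het"`, `"missing"`, `"other_alt"`.
#' @param samples named character vector (`donor`, `recipient`, `line`)
#'   giving sample names; defaults to those literal names.
#'
#' @return A [TrioVariants-class] object, sorted by (chromosome, position).
#' @examples
#' tv <- TrioVariants("chr1", c(100, 200), ref = c("A", "T"),
#'                    alt = c("G", "TTA"), qual = c(50, 60),
#'                    gtDonor = c("hom_alt", "hom_alt"),
#'                    gtRecipient = c("hom_ref", "hom_ref"),
#'                    gtLine = c("hom_alt", "hom_ref"))
#' tv
#' @export
TrioVariants <- function(chrom, pos, ref, alt, qual,
                         gtDonor, gtRecipient, gtLine,
                         samples = c(donor = "donor", recipient = "recipient",
                                     line = "line")) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L))
    mcols(gr) <- DataFrame(
        ref = as.character(ref), alt = as.character(alt),
        varClass = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "indel"),
        qual = as.numeric(qual),
        gtDonor = as.character(gtDonor),
        gtRecipient = as.character(gtRecipient),
        gtLine = as.character(gtLine))
    gr <- gr[order(as.character(seqnames(gr)), start(gr))]
    new("TrioVariants", ranges = gr, samples = samples)
}

#' @describeIn TrioVariants number of variant sites
#' @param x,object a `TrioVariants` object
#' @export
setMethod("length", "TrioVariants", function(x) length(x@ranges))

#' @describeIn TrioVariants subset sites
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "TrioVariants", function(x, i, j, ..., drop = FALSE) {
    initialize(x, ranges = x@ranges[i])
})

#' @describeIn TrioVariants the underlying `GRanges` of variant anchors with
#'   all metadata columns
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' @rdname TrioVariants
#' @export
setMethod("variantRanges", "TrioVariants", function(x) x@ranges)

#' @describeIn TrioVariants named vector of VCF sample names
#' @export
setGeneric("trioSamples", function(x) standardGeneric("trioSamples"))

#' @rdname TrioVariants
#' @export
setMethod("trioSamples", "TrioVariants", function(x) x@samples)

setMethod("show", "TrioVariants", function(object) {
    m <- mcols(object@ranges)
    cat("TrioVariants with", length(object), "sites (",
        sum(m$varClass == "SNV"), "SNVs,",
        sum(m$varClass == "indel"), "indels ) on",
        length(unique(as.character(seqnames(object@ranges)))),
        "chromosome(s)\n")
    cat("samples: donor =", object@samples[["donor"]],
        ", recipient =", object@samples[["recipient"]],
        ", line =", object@samples[["line"]], "\n")
})
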