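.GT_STRING <- c(hom_ref = "0/0", hom_alt = "1/1", het = "0/1",
                missing = "./.")

#' Write a TrioVariants object as a three-sample VCF v4.2
#'
#' Emits one biallelic record per site with QUAL and a GT-only FORMAT, plus
#' `##contig` header lines when chromosome lengths are supplied. Sites with
#' genotype state `"other_alt"` cannot be represented in a biallelic record
#' and are rejected.
#'
#' @param tv a [TrioVariants-class] object.
#' @param path output file (plain text `.vcf`).
#' @param contigLengths optional named vector of chromosome lengths for the
#'   header.
#' @return `path`, invisibly.
#' @seealso [readTrioVcf()]
#' @export
writeTrioVcf <- function(tv, path, contigLengths = NULL) {
    gr <- variantRanges(tv)
    m <- mcols(gr)
    gts <- cbind(m$gtDonor, m$gtRecipient, m$gtLine)
    if (any(gts == "other_alt"))
        stop("'other_alt' genotypes cannot be written to a biallelic record")
    header <- c(
        "##fileformat=VCFv4.2",
        "##source=trioCAPS",
        if (!is.null(contigLengths))
            sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
                    as.integer(contigLengths)),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", trioSamples(tv)[c("donor", "recipient",
                                                    "line")]),
              collapse = "\t"))
    body <- paste(as.character(seqnames(gr)), start(gr), ".",
                  m$ref, m$alt, format(m$qual, trim = TRUE), ".", ".", "GT",
                  .GT_STRING[m$gtDonor], .GT_STRING[m$gtRecipient],
                  .GT_STRING[m$gtLine], sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read a three-sample VCF into a TrioVariants object
#'
#' Reads with [VariantAnnotation::readVcf()], expands multi-allelic records
#' into biallelic sites, and collapses diploid GT strings to the allelic
#' states the trio analysis uses. After expansion, a genotype homozygous for
#' an allele other than the record's own ALT becomes `"other_alt"`; any
#' heterozygous call (phased or not) becomes `"het"`.
#'
#' @param path VCF file.
#' @param donor,recipient,line VCF sample names of the donor parent, the
#'   recipient parent and the introgression line.
#' @return A [TrioVariants-class] object.
#' @seealso [writeTrioVcf()], [assignParent()]
#' @export
readTrioVcf <- function(path, donor = "donor", recipient = "recipient",
                        line = "line") {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    samp <- colnames(vcf)
    need <- c(donor, recipient, line)
    if (!all(need %in% samp))
        stop("samples not found in VCF: ",
             paste(setdiff(need, samp), collapse = ", "))
    gt <- VariantAnnotation::geno(vcf)$GT
    rr <- SummarizedExperiment::rowRanges(vcf)
    ## split multi-allelic records: one biallelic site per ALT allele, with
    ## GT allele indices reinterpreted relative to that ALT
    altList <- VariantAnnotation::alt(vcf)
    nalt <- S4Vectors::elementNROWS(altList)
    idx <- rep(seq_along(nalt), nalt)
    altIndex <- unlist(lapply(nalt, seq_len), use.names = FALSE)
    alt <- as.character(unlist(altList, use.names = FALSE))
    ref <- as.character(rr$REF)[idx]
    collapse <- function(g, k) {
        out <- character(length(g))
        al <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
        for (i in seq_along(g)) {
            a <- al[[i]]
            if (length(a) != 2L || any(a == ".")) { out[i] <- "missing"; next }
            a <- as.integer(a)
            if (a[1] != a[2]) out[i] <- "het"
            else if (a[1] == 0L) out[i] <- "hom_ref"
            else if (a[1] == k[i]) out[i] <- "hom_alt"
            else out[i] <- "other_alt"
        }
        out
    }
    TrioVariants(chrom = as.character(seqnames(rr))[idx], pos = start(rr)[idx],
                 ref = ref, alt = alt, qual = rr$QUAL[idx],
                 gtDonor = collapse(gt[idx, donor], altIndex),
                 gtRecipient = collapse(gt[idx, recipient], altIndex),
                 gtLine = collapse(gt[idx, line], altIndex),
                 samples = c(donor = donor, recipient = recipient,
                             line = line))
}
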