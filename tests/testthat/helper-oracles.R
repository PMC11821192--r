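## Independent oracles and small fixture builders used across tests.
## These re-derive expected results from first principles and must not call
## the package internals they are checking.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
})

## --- tiny TrioVariants builder -------------------------------------------
makeSites <- function(pos, gtD, gtR, gtL, chrom = "chr1", qual = 50,
                      ref = "A", alt = "G") {
    n <- length(pos)
    TrioVariants(rep(chrom, length.out = n), pos,
                 rep(ref, length.out = n), rep(alt, length.out = n),
                 rep(qual, length.out = n),
                 rep(gtD, length.out = n), rep(gtR, length.out = n),
                 rep(gtL, length.out = n))
}

## one gene: [start,end], utr5/exons/utr3 given as IRanges-style matrices
makeGene <- function(id, chrom, start, end, strand, exons, utr5 = NULL,
                     utr3 = NULL) {
    list(id = id, chrom = chrom, start = start, end = end, strand = strand,
         exons = exons, utr5 = utr5, utr3 = utr3)
}

makeModels <- function(...) {
    gs <- list(...)
    gr <- GRanges(vapply(gs, `[[`, "", "chrom"),
                  IRanges(vapply(gs, function(g) g$start, 1),
                          vapply(gs, function(g) g$end, 1)),
                  strand = vapply(gs, `[[`, "", "strand"))
    mcols(gr)$gene_id <- vapply(gs, `[[`, "", "id")
    grl <- function(field) {
        lst <- lapply(gs, function(g) {
            iv <- g[[field]]
            if (is.null(iv)) return(NULL)
            GRanges(g$chrom, IRanges(iv[, 1], iv[, 2]), strand = g$strand)
        })
        names(lst) <- vapply(gs, `[[`, "", "id")
        GRangesList(lst[!vapply(lst, is.null, TRUE)])
    }
    GeneModels(gr, grl("exons"), grl("utr5"), grl("utr3"))
}

## --- brute-force enumerator of maximal donor runs -------------------------
## donor: logical vector over informative sites; returns data.frame of
## (i, j) index bounds of maximal valid runs with >= minSupport donor sites,
## where valid means: endpoints are donor sites and no stretch of more than
## maxGap consecutive non-donor sites lies strictly inside
bruteForceRuns <- function(donor, maxGap, minSupport) {
    idx <- which(donor)
    D <- length(idx)
    if (!D) return(data.frame(i = integer(), j = integer()))
    ## non-donor informative sites between consecutive donor sites
    g <- if (D > 1) diff(idx) - 1L else integer()
    ## validity of the run from donor ordinal t to u: every inner stretch
    ## of consecutive non-donor sites fits in maxGap
    valid <- matrix(FALSE, D, D)
    for (t in seq_len(D)) for (u in t:D)
        valid[t, u] <- u == t || max(g[t:(u - 1L)]) <= maxGap
    out <- list()
    for (t in seq_len(D)) for (u in t:D) {
        if (!valid[t, u]) next
        extendable <- (t > 1L && valid[t - 1L, u]) ||
                      (u < D && valid[t, u + 1L])
        if (extendable) next
        if (u - t + 1L < minSupport) next
        out[[length(out) + 1L]] <- c(idx[t], idx[u])
    }
    if (!length(out)) return(data.frame(i = integer(), j = integer()))
    m <- do.call(rbind, out)
    data.frame(i = m[, 1], j = m[, 2])
}

## --- position-by-position IUPAC scanner oracle ----------------------------
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracleRevcomp <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
              N = "N")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

oracleMatch <- function(seqChars, pattern) {
    pc <- strsplit(pattern, "")[[1]]
    plen <- length(pc)
    L <- length(seqChars)
    if (plen > L) return(integer())
    starts <- seq_len(L - plen + 1L)
    ok <- rep(TRUE, length(starts))
    for (k in seq_len(plen))  # position-by-position comparison
        ok <- ok & seqChars[starts + k - 1L] %in% IUPAC_SETS[[pc[k]]]
    starts[ok]
}

## same cut-position convention as scanSites: palindromic patterns on the
## given strand only; minus-strand matches at offset (plen - cut) from the
## left end of the plus-strand footprint
oracleScan <- function(seq, pattern, offset) {
    sc <- strsplit(seq, "")[[1]]
    plen <- nchar(pattern)
    cuts <- oracleMatch(sc, pattern) - 1L + offset
    if (!identical(pattern, oracleRevcomp(pattern)))
        cuts <- c(cuts, oracleMatch(sc, oracleRevcomp(pattern)) - 1L +
                        (plen - offset))
    sort(unique(cuts))
}

randomDnaStr <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")
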