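## internal, generator-side IUPAC matcher (independent of scanSites):
## sliding-window regex over every start position, both strands
.iupacRegex <- function(pattern) {
    paste0(vapply(strsplit(pattern, "")[[1]], function(ch) {
        b <- .IUPAC[[ch]]
        if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
    }, character(1)), collapse = "")
}

.matchStarts <- function(seq, pattern) {
    L <- nchar(seq); plen <- nchar(pattern)
    if (plen > L) return(integer())
    starts <- seq_len(L - plen + 1L)
    win <- substring(seq, starts, starts + plen - 1L)
    starts[grepl(paste0("^", .iupacRegex(pattern), "$"), win)]
}

## cut boundaries under the same convention as scanSites()
.cutBoundaries <- function(seq, pattern, offset) {
    plen <- nchar(pattern)
    cuts <- .matchStarts(seq, pattern) - 1L + offset
    if (!identical(pattern, .revcomp(pattern)))
        cuts <- c(cuts,
                  .matchStarts(seq, .revcomp(pattern)) - 1L + (plen - offset))
    sort(unique(cuts))
}

.fragmentsOf <- function(seq, pattern, offset) {
    L <- nchar(seq)
    cuts <- .cutBoundaries(seq, pattern, offset)
    cuts <- cuts[cuts > 0L & cuts < L]
    sort(diff(c(0L, cuts, L)))
}

## which table enzymes give different fragment multisets on a and b
.discriminating <- function(a, b, enzymes) {
    hit <- vapply(seq_len(nrow(enzymes)), function(i) {
        !identical(.fragmentsOf(a, enzymes$pattern[i], enzymes$cut_offset[i]),
                   .fragmentsOf(b, enzymes$pattern[i], enzymes$cut_offset[i]))
    }, logical(1))
    enzymes$name[hit]
}

## a substitution at pos can only create/destroy pattern matches that
## overlap pos; comparing the window around pos is equivalent to comparing
## full-sequence cut sets, and much faster
.windowNeutral <- function(before, after, pos, enzymes, maxPat) {
    lo <- max(1L, pos - maxPat + 1L)
    hi <- min(nchar(before), pos + maxPat - 1L)
    wb <- substring(before, lo, hi)
    wa <- substring(after, lo, hi)
    for (i in seq_len(nrow(enzymes))) {
        pat <- enzymes$pattern[i]
        if (!identical(.matchStarts(wb, pat), .matchStarts(wa, pat)))
            return(FALSE)
        rc <- .revcomp(pat)
        if (!identical(pat, rc) &&
            !identical(.matchStarts(wb, rc), .matchStarts(wa, rc)))
            return(FALSE)
    }
    TRUE
}

.applySub <- function(seq, pos, base) {
    paste0(substring(seq, 1L, pos - 1L), base,
           substring(seq, pos + 1L, nchar(seq)))
}

#' Generate a pair of allele templates carrying a planted CAPS site
#'
#' Builds two templates of equal length that differ at exactly `k`
#' positions. Both carry one forward-primer site and one reverse-primer
#' (reverse-complement) site. When `plantSite = TRUE`, allele A additionally
#' carries a concrete instance of the chosen enzyme's recognition site
#' between the primer footprints, and allele B destroys it with a single
#' substitution (one of the `k` differences). Background sequence and the
#' remaining `k - 1` substitutions are rejection-sampled so that no
#' substitution changes the recognition-site content of any *other* enzyme
#' in the table — the chosen enzyme is therefore the only discriminating
#' one, by construction.
#'
#' @param seed integer seed.
#' @param templateLength total template length (bp), default 1106.
#' @param k number of differences between the alleles (>= 1 when a site is
#'   planted; `k = 0` with `plantSite = TRUE` is a contradiction and is
#'   rejected).
#' @param pair a [PrimerPair-class] (default [nodXPrimers()]).
#' @param enzymeName name of the enzyme to plant (must be in `enzymes`).
#' @param enzymes enzyme table (default [defaultEnzymes()]).
#' @param plantSite logical; plant a discriminating site?
#' @return list with `templates` (`DNAStringSet` of `alleleA`, `alleleB`),
#'   `pair`, and `truth` (list: `enzyme`, `sitePos` — template position of
#'   the planted pattern start — and `diffPositions`).
#' @export
generateMarkerTemplates <- function(seed = 1L, templateLength = 1106L,
                                    k = 24L, pair = nodXPrimers(),
                                    enzymeName = "RsaI",
                                    enzymes = defaultEnzymes(),
                                    plantSite = TRUE) {
    stopifnot(k >= 0L)
    if (plantSite && k == 0L)
        stop("k = 0 contradicts a planted discriminating site")
    set.seed(seed)
    fwd <- pair@forward; rev <- pair@reverse
    lenF <- nchar(fwd); lenR <- nchar(rev)
    pad <- 15L
    enz <- enzymes[enzymes$name == enzymeName, ]
    if (plantSite && nrow(enz) != 1L)
        stop("enzyme not in table: ", enzymeName)
    patLen <- if (plantSite) nchar(enz$pattern) else 0L
    maxPat <- max(nchar(enzymes$pattern))
    if (templateLength < 2 * pad + lenF + lenR + patLen + 20L)
        stop("template too short for primers and planted site")
    fStart <- pad + 1L
    rEnd <- templateLength - pad
    innerLo <- fStart + lenF + maxPat   # keep the site clear of the primers
    innerHi <- rEnd - lenR - maxPat - patLen

    for (try in seq_len(100L)) {
        a <- .randomDna(templateLength)
        a <- paste0(substring(a, 1L, fStart - 1L), fwd,
                    substring(a, fStart + lenF, nchar(a)))
        rcR <- .revcomp(rev)
        a <- paste0(substring(a, 1L, rEnd - lenR), rcR,
                    substring(a, rEnd + 1L, nchar(a)))
        sitePos <- NA_integer_
        if (plantSite) {
            sitePos <- sample(innerLo:innerHi, 1L)
            ## concrete instance of the (possibly degenerate) pattern
            inst <- paste(vapply(strsplit(enz$pattern, "")[[1]],
                                 function(ch) sample(.IUPAC[[ch]], 1L),
                                 character(1)), collapse = "")
            a <- paste0(substring(a, 1L, sitePos - 1L), inst,
                        substring(a, sitePos + patLen, nchar(a)))
        }
        ## exactly one qualifying site per primer, correct orientation
        fs <- findBindingSites(a, fwd, pair@maxMismatch, pair@anchor)
        rs <- findBindingSites(a, rev, pair@maxMismatch, pair@anchor)
        if (!(nrow(fs) == 1L && fs$strand == "+" && fs$start == fStart &&
              nrow(rs) == 1L && rs$strand == "-" &&
              rs$start == rEnd - lenR + 1L)) next

        b <- a
        diffPos <- integer()
        ok <- TRUE
        if (plantSite) {
            ## destroy the planted site with one substitution that leaves
            ## every other enzyme's site content unchanged
            destroyed <- FALSE
            for (attempt in seq_len(50L)) {
                j <- sample.int(patLen, 1L)
                pos <- sitePos + j - 1L
                allowed <- .IUPAC[[substring(enz$pattern, j, j)]]
                cand <- setdiff(c("A", "C", "G", "T"),
                                c(allowed, substring(b, pos, pos)))
                if (!length(cand)) next
                base <- sample(cand, 1L)
                b2 <- .applySub(b, pos, base)
                others <- enzymes[enzymes$name != enzymeName, ]
                if (!.windowNeutral(b, b2, pos, others, maxPat)) next
                b <- b2; diffPos <- pos; destroyed <- TRUE
                break
            }
            if (!destroyed) next
        }
        ## remaining substitutions, each neutral for every enzyme
        nExtra <- k - length(diffPos)
        pool <- setdiff(seq_len(templateLength),
                        c(seq(fStart, fStart + lenF - 1L),
                          seq(rEnd - lenR + 1L, rEnd),
                          if (plantSite)
                              seq(sitePos - maxPat, sitePos + patLen - 1L +
                                                    maxPat)))
        placed <- 0L
        guard <- 0L
        while (placed < nExtra && guard < 2000L) {
            guard <- guard + 1L
            pos <- sample(pool, 1L)
            if (pos %in% diffPos) next
            base <- sample(setdiff(c("A", "C", "G", "T"),
                                   substring(b, pos, pos)), 1L)
            b2 <- .applySub(b, pos, base)
            if (!.windowNeutral(b, b2, pos, enzymes, maxPat)) next
            b <- b2; diffPos <- c(diffPos, pos); placed <- placed + 1L
        }
        if (placed < nExtra) next
        ## construction guarantee: the planted enzyme is the only
        ## discriminating one (or none at all when no site was planted)
        disc <- .discriminating(a, b, enzymes)
        want <- if (plantSite) enzymeName else character(0)
        if (!identical(sort(disc), sort(want))) next
        templates <- Biostrings::DNAStringSet(c(alleleA = a, alleleB = b))
        return(list(templates = templates, pair = pair,
                    truth = list(enzyme = if (plantSite) enzymeName else NA,
                                 sitePos = sitePos,
                                 diffPositions = sort(diffPos))))
    }
    stop("failed to construct templates after 100 attempts; ",
         "relax k or the enzyme table")
}
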