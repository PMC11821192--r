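#' Construct a primer pair
#'
#' @param forward,reverse primer sequences, 5'->3', over A/C/G/T, length
#'   >= 15.
#' @param maxMismatch maximum mismatches tolerated per primer (default 2).
#' @param anchor number of 3'-terminal bases that must match exactly
#'   (default 3).
#' @return A [PrimerPair-class] object.
#' @export
primerPair <- function(forward, reverse, maxMismatch = 2L, anchor = 3L) {
    new("PrimerPair", forward = toupper(forward), reverse = toupper(reverse),
        maxMismatch = as.integer(maxMismatch), anchor = as.integer(anchor))
}

setMethod("show", "PrimerPair", function(object) {
    cat("PrimerPair  F: 5'-", object@forward, "-3' (", nchar(object@forward),
        " nt)\n            R: 5'-", object@reverse, "-3' (",
        nchar(object@reverse), " nt)\n", sep = "")
    cat("  max mismatches:", object@maxMismatch,
        " | exact 3' anchor:", object@anchor, "nt\n")
})

#' The nodX genotyping primer pair
#'
#' The pair used to amplify the rhizobial *nodX* fragment from single-nodule
#' DNA; matches the TOM and A1 alleles but not more distant *nodX*
#' sequences.
#' @param maxMismatch,anchor matching stringency, see [primerPair()].
#' @return A [PrimerPair-class] object.
#' @export
nodXPrimers <- function(maxMismatch = 2L, anchor = 3L) {
    primerPair("GATGAATGCCACTTTCACAGTAAG", "CAGATACTGCAAGATGCCGGTA",
               maxMismatch, anchor)
}

#' The nodE control primer pair
#'
#' Amplifies a fragment of *nodE*, present in all rhizobia; serves as the
#' amplification control in nodule genotyping.
#' @inheritParams nodXPrimers
#' @return A [PrimerPair-class] object.
#' @export
nodEPrimers <- function(maxMismatch = 2L, anchor = 3L) {
    primerPair("CACCGATGCTTCCTCTATCTGGAC", "AACGCAAGGACAGCATTCAT",
               maxMismatch, anchor)
}

#' Locate primer binding sites on a template
#'
#' A position qualifies when the primer aligns with at most `maxMismatch`
#' mismatches *and* its `anchor` 3'-terminal bases match exactly. Both
#' strands are scanned; for a minus-strand site the primer binds the
#' reverse complement, so its 3' end faces leftwards on the template.
#'
#' @param template a `DNAString`/character template sequence.
#' @param primer character primer, 5'->3'.
#' @param maxMismatch maximum mismatches.
#' @param anchor exact-match 3' bases.
#' @return `data.frame` with columns `start` (1-based leftmost template
#'   position of the footprint), `strand` (`"+"`/`"-"`) and `mismatches`.
#'   Empty when the primer is longer than the template.
#' @export
findBindingSites <- function(template, primer, maxMismatch = 2L,
                             anchor = 3L) {
    template <- Biostrings::DNAString(as.character(template))
    primer <- toupper(as.character(primer))
    pl <- nchar(primer)
    stopifnot(anchor <= pl)
    if (pl > length(template))
        return(data.frame(start = integer(), strand = character(),
                          mismatches = integer()))
    scanStrand <- function(pat, strand) {
        hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), template,
                                         max.mismatch = maxMismatch)
        if (!length(hits))
            return(data.frame(start = integer(), strand = character(),
                              mismatches = integer()))
        st <- Biostrings::start(hits)
        patChars <- strsplit(pat, "")[[1]]
        mm <- vapply(seq_along(st), function(i) {
            sub <- as.character(Biostrings::subseq(template, st[i],
                                                   width = pl))
            sum(strsplit(sub, "")[[1]] != patChars)
        }, integer(1))
        ## anchor: 3' end of the primer is the right end on '+', left on '-'
        ok <- vapply(seq_along(st), function(i) {
            sub <- strsplit(as.character(
                Biostrings::subseq(template, st[i], width = pl)), "")[[1]]
            if (anchor == 0L) return(TRUE)
            idx <- if (strand == "+") (pl - anchor + 1L):pl else 1:anchor
            all(sub[idx] == patChars[idx])
        }, logical(1))
        data.frame(start = st, strand = strand, mismatches = mm)[ok, ,
                                                                 drop = FALSE]
    }
    out <- rbind(scanStrand(primer, "+"),
                 scanStrand(.revcomp(primer), "-"))
    out <- out[out$mismatches <= maxMismatch, , drop = FALSE]
    out[order(out$start, out$strand), , drop = FALSE]
}

#' In-silico PCR: enumerate amplicons of a primer pair on a template
#'
#' Every orientation-valid pairing of a plus-strand forward-primer site with
#' a downstream minus-strand reverse-primer site whose product is at most
#' `maxProduct` bp yields one amplicon. Zero or several amplicons are
#' reported as such, never collapsed.
#'
#' @param template a `DNAString`/character template, or a named character /
#'   `DNAStringSet` of templates.
#' @param pair a [PrimerPair-class].
#' @param maxProduct maximum product length in bp (default 5000).
#' @return `data.frame` with columns `template`, `start`, `end` (1-based
#'   closed, including both primer footprints) and `sequence`.
#' @export
inSilicoPcr <- function(template, pair, maxProduct = 5000L) {
    stopifnot(is(pair, "PrimerPair"),
              maxProduct > nchar(pair@forward) + nchar(pair@reverse))
    seqs <- if (is(template, "DNAStringSet")) as.character(template)
            else as.character(template)
    if (is.null(names(seqs)))
        names(seqs) <- if (length(seqs) == 1L) "template" else
            paste0("template", seq_along(seqs))
    res <- lapply(names(seqs), function(nm) {
        tmpl <- seqs[[nm]]
        fwd <- findBindingSites(tmpl, pair@forward, pair@maxMismatch,
                                pair@anchor)
        rev <- findBindingSites(tmpl, pair@reverse, pair@maxMismatch,
                                pair@anchor)
        fwd <- fwd[fwd$strand == "+", , drop = FALSE]
        rev <- rev[rev$strand == "-", , drop = FALSE]
        if (!nrow(fwd) || !nrow(rev)) return(NULL)
        lenR <- nchar(pair@reverse)
        combos <- expand.grid(f = fwd$start, r = rev$start)
        combos <- combos[combos$r >= combos$f + nchar(pair@forward), ,
                         drop = FALSE]
        combos$end <- combos$r + lenR - 1L
        combos <- combos[combos$end - combos$f + 1L <= maxProduct, ,
                         drop = FALSE]
        if (!nrow(combos)) return(NULL)
        data.frame(template = nm, start = combos$f, end = combos$end,
                   sequence = substring(tmpl, combos$f, combos$end))
    })
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(template = character(), start = integer(),
                          end = integer(), sequence = character())
    rownames(out) <- NULL
    out[order(out$template, out$start, out$end), , drop = FALSE]
}

#' Built-in restriction enzyme table
#'
#' A small editable table of common CAPS enzymes: `name`, IUPAC
#' `pattern` and `cut_offset` (bases 5' of the cut within the pattern, on
#' the strand the pattern is written on). RsaI carries its canonical
#' blunt-cutting site GT^AC; GATC is the recognition site of MboI, also in
#' the table. Users can supply their own table via [readEnzymeTable()].
#'
#' @return `data.frame` with columns `name`, `pattern`, `cut_offset`.
#' @export
defaultEnzymes <- function() {
    readEnzymeTable(system.file("extdata", "enzymes.tsv",
                                package = "trioCAPS"))
}

#' Read a restriction enzyme table
#'
#' @param path TSV with columns `name`, `pattern`, `cut_offset`.
#' @return validated `data.frame`.
#' @export
readEnzymeTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "pattern", "cut_offset") %in% colnames(tab)))
    tab$pattern <- toupper(tab$pattern)
    bad <- !vapply(tab$pattern, .validIupac, logical(1))
    if (any(bad))
        stop("invalid IUPAC pattern(s): ",
             paste(tab$pattern[bad], collapse = ", "))
    if (any(tab$cut_offset < 0 | tab$cut_offset > nchar(tab$pattern)))
        stop("cut_offset must lie within the recognition pattern")
    tab
}

.isPalindromic <- function(pattern) {
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pattern)))
    identical(pattern, rc)
}

#' Scan a sequence for restriction cut positions
#'
#' Matches the enzyme's IUPAC-degenerate recognition pattern on both strands
#' and converts each match to a cut position via the enzyme's cut offset. A
#' cut position `c` means the enzyme cuts between bases `c` and `c + 1` of
#' the scanned strand. Palindromic patterns (equal to their reverse
#' complement) are matched on one strand only, so each locus is counted
#' once; positions are deduplicated and sorted.
#'
#' @param seq `DNAString`/character sequence.
#' @param enzyme one row of an enzyme table (list/`data.frame` with `name`,
#'   `pattern`, `cut_offset`).
#' @return sorted integer vector of cut positions (0 .. length).
#' @export
scanSites <- function(seq, enzyme) {
    pattern <- toupper(as.character(enzyme$pattern))
    if (!.validIupac(pattern))
        stop("invalid IUPAC code in pattern: ", pattern)
    offset <- as.integer(enzyme$cut_offset)
    subject <- Biostrings::DNAString(as.character(seq))
    plen <- nchar(pattern)
    hitStarts <- function(pat) {
        Biostrings::start(Biostrings::matchPattern(
            Biostrings::DNAString(pat), subject, fixed = "subject"))
    }
    cuts <- hitStarts(pattern) - 1L + offset
    if (!.isPalindromic(pattern)) {
        ## a match of the pattern on the minus strand appears on the plus
        ## strand as its reverse complement; the cut sits offset bases from
        ## the pattern's 5' end, i.e. (plen - offset) from the left end here
        rcCuts <- hitStarts(.revcomp(pattern)) - 1L + (plen - offset)
        cuts <- c(cuts, rcCuts)
    }
    sort(unique(cuts))
}

#' Predict restriction fragments of a linear amplicon
#'
#' @param amplicon character/`DNAString` amplicon sequence, or one row of
#'   the `data.frame` returned by [inSilicoPcr()].
#' @param enzyme one row of an enzyme table.
#' @return list with `enzyme`, `cuts` (interior cut positions) and
#'   `fragments` (bp, ordered along the amplicon; sums to the amplicon
#'   length; one more fragment than cuts).
#' @examples
#' digestAmplicon("AAAGTACAAA", list(name = "RsaI", pattern = "GTAC",
#'                                   cut_offset = 2))$fragments  # 5 5
#' @export
digestAmplicon <- function(amplicon, enzyme) {
    if (is.list(amplicon) && !is.null(amplicon$sequence))
        amplicon <- amplicon$sequence[[1]]
    seqChar <- as.character(amplicon)
    L <- nchar(seqChar)
    stopifnot(L > 0)
    cuts <- scanSites(seqChar, enzyme)
    cuts <- cuts[cuts > 0L & cuts < L]  # boundary cuts yield no fragment
    list(enzyme = as.character(enzyme$name), cuts = cuts,
         fragments = diff(c(0L, cuts, L)))
}

#' Find enzymes discriminating two allelic amplicons
#'
#' Digests both amplicons with every enzyme in the table and reports those
#' whose predicted fragment-length multisets differ — the CAPS candidates.
#' Fragments below `gelFloor` bp are flagged as potentially invisible on an
#' agarose gel.
#'
#' @param ampA,ampB amplicon sequences (character/`DNAString`).
#' @param enzymes enzyme table (`data.frame`; default [defaultEnzymes()]).
#' @param gelFloor resolution floor in bp (default 20).
#' @return `data.frame` with one row per discriminating enzyme: `enzyme`,
#'   `pattern`, `cutsA`, `cutsB`, `fragmentsA`, `fragmentsB`
#'   (comma-separated bp), `minFragment`, `belowGelFloor`.
#' @export
findDiscriminatingEnzymes <- function(ampA, ampB,
                                      enzymes = defaultEnzymes(),
                                      gelFloor = 20L) {
    ampA <- as.character(ampA); ampB <- as.character(ampB)
    stopifnot(nchar(ampA) > 0, nchar(ampB) > 0)
    rows <- lapply(seq_len(nrow(enzymes)), function(i) {
        enz <- enzymes[i, ]
        da <- digestAmplicon(ampA, enz)
        db <- digestAmplicon(ampB, enz)
        if (identical(sort(da$fragments), sort(db$fragments))) return(NULL)
        frag <- c(da$fragments, db$fragments)
        data.frame(enzyme = enz$name, pattern = enz$pattern,
                   cutsA = length(da$cuts), cutsB = length(db$cuts),
                   fragmentsA = paste(da$fragments, collapse = ","),
                   fragmentsB = paste(db$fragments, collapse = ","),
                   minFragment = min(frag),
                   belowGelFloor = min(frag) < gelFloor)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(enzyme = character(), pattern = character(),
                          cutsA = integer(), cutsB = integer(),
                          fragmentsA = character(), fragmentsB = character(),
                          minFragment = integer(), belowGelFloor = logical())
    rownames(out) <- NULL
    out
}

#' Pairwise identity of an aligned sequence pair
#'
#' Counts differing columns (gap columns count as differences) and reports
#' percent identity `100 * (L - diffs) / L`, rounded half-up to two
#' decimals.
#'
#' @param a,b equal-length aligned sequences (character/`DNAString`).
#' @return list with `length`, `differences`, `identity` (percent, 2 dp).
#' @examples
#' seqA <- paste(rep("A", 1106), collapse = "")
#' seqB <- paste(c(rep("C", 24), rep("A", 1082)), collapse = "")
#' pairwiseIdentity(seqA, seqB)$identity  # 97.83
#' @export
pairwiseIdentity <- function(a, b) {
    a <- toupper(as.character(a)); b <- toupper(as.character(b))
    if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
    if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    diffs <- sum(av != bv)
    L <- nchar(a)
    list(length = L, differences = diffs,
         identity = .roundHalfUp(100 * (L - diffs) / L, 2L))
}

#' Design a CAPS marker for two allele templates
#'
#' Runs [inSilicoPcr()] on both templates and, when each yields exactly one
#' amplicon, reports the discriminating enzymes. Zero or multiple amplicons
#' on either allele are reported as an error condition.
#'
#' @param alleleA,alleleB template sequences.
#' @param pair a [PrimerPair-class].
#' @param enzymes enzyme table.
#' @param maxProduct maximum PCR product size (bp).
#' @param gelFloor gel resolution floor (bp).
#' @return list with `ampliconA`, `ampliconB` (one-row data.frames) and
#'   `markers` (from [findDiscriminatingEnzymes()]).
#' @export
designCapsMarker <- function(alleleA, alleleB, pair = nodXPrimers(),
                             enzymes = defaultEnzymes(), maxProduct = 5000L,
                             gelFloor = 20L) {
    ampA <- inSilicoPcr(alleleA, pair, maxProduct)
    ampB <- inSilicoPcr(alleleB, pair, maxProduct)
    if (nrow(ampA) != 1L || nrow(ampB) != 1L)
        stop("expected exactly one amplicon per allele, got ",
             nrow(ampA), " (A) and ", nrow(ampB), " (B)")
    list(ampliconA = ampA, ampliconB = ampB,
         markers = findDiscriminatingEnzymes(ampA$sequence, ampB$sequence,
                                             enzymes, gelFloor))
}
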