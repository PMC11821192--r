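rsaI <- list(name = "RsaI", pattern = "GTAC", cut_offset = 2L)

test_that("primer binding requires the 3' anchor and tolerates mismatches", {
    primer <- "GATGAATGCCACTTTCACAGTAAG"
    tmpl <- paste0(randomDnaStr(50), primer, randomDnaStr(50))
    set.seed(1)
    hit <- findBindingSites(tmpl, primer, maxMismatch = 2, anchor = 3)
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$start, 51L)
    expect_equal(hit$strand, "+")
    expect_equal(hit$mismatches, 0L)

    ## a mismatch at the 3'-terminal base disqualifies the site
    broken <- sub("AAG$", "AAC", primer)
    tmpl2 <- paste0(randomDnaStr(50), broken, randomDnaStr(50))
    expect_equal(nrow(findBindingSites(tmpl2, primer, 2, 3)), 0L)
    ## ...but is accepted with anchor 0
    expect_equal(nrow(findBindingSites(tmpl2, primer, 2, 0)), 1L)

    ## reverse-complement template -> minus strand site
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(primer)))
    expect_equal(findBindingSites(rc, primer, 0, 3)$strand, "-")

    ## primer longer than template -> empty
    expect_equal(nrow(findBindingSites("ACGT", primer, 2, 3)), 0L)
})

test_that("in-silico PCR enumerates orientation-valid amplicons", {
    pair <- nodXPrimers()
    f <- pair@forward; r <- pair@reverse
    rcR <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(r)))
    set.seed(2)
    spacer <- randomDnaStr(100)
    tmpl <- paste0(f, spacer, rcR)
    amp <- inSilicoPcr(tmpl, pair)
    expect_equal(nrow(amp), 1L)
    expect_equal(nchar(amp$sequence), nchar(f) + 100L + nchar(r))
    expect_equal(amp$sequence, tmpl)

    ## missing reverse site -> no amplicon
    expect_equal(nrow(inSilicoPcr(paste0(f, spacer), pair)), 0L)

    ## two forward sites upstream of one reverse site -> two amplicons
    tmpl2 <- paste0(f, randomDnaStr(60), f, randomDnaStr(60), rcR)
    amp2 <- inSilicoPcr(tmpl2, pair)
    expect_equal(nrow(amp2), 2L)
    expect_equal(sort(amp2$start), c(1L, nchar(f) + 61L))
    expect_true(all(amp2$end == nchar(tmpl2)))

    ## product cap excludes the long amplicon
    amp3 <- inSilicoPcr(tmpl2, pair, maxProduct = nchar(f) + 60 + nchar(r))
    expect_equal(nrow(amp3), 1L)
})

test_that("site scanning handles degenerate patterns and rejects bad codes", {
    expect_equal(scanSites("AAGTACAA", rsaI), 4L)
    ## degenerate R = A/G
    grac <- list(name = "x", pattern = "GRAC", cut_offset = 2L)
    expect_equal(length(scanSites("AAGAACAAGGACAA", grac)), 2L)
    expect_error(scanSites("ACGT", list(name = "x", pattern = "GQAC",
                                        cut_offset = 1L)), "IUPAC")
})

test_that("site scanning matches the position-by-position oracle", {
    enzymes <- defaultEnzymes()
    set.seed(3)
    for (rep in 1:25) {
        seq <- randomDnaStr(1000)
        for (i in seq_len(nrow(enzymes))) {
            got <- scanSites(seq, enzymes[i, ])
            want <- oracleScan(seq, enzymes$pattern[i],
                               enzymes$cut_offset[i])
            expect_equal(got, want, info = enzymes$name[i])
        }
    }
})

test_that("scanning is strand-symmetric (mirror positions on the reverse complement)", {
    set.seed(4)
    cases <- list(rsaI,  # blunt palindrome
                  list(name = "nonpal", pattern = "GGTCTC", cut_offset = 1L),
                  list(name = "deg", pattern = "GRAC", cut_offset = 2L))
    for (enz in cases) {
        seq <- randomDnaStr(600)
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seq)))
        fwd <- scanSites(seq, enz)
        rev <- scanSites(rc, enz)
        expect_equal(sort(600L - fwd), sort(rev), info = enz$name)
    }
})

test_that("digest conserves length and counts fragments as cuts + 1", {
    ## no site -> undigested single fragment
    d0 <- digestAmplicon("AAAATTTT", rsaI)
    expect_equal(d0$fragments, 8L)
    expect_length(d0$cuts, 0L)
    ## one site -> two fragments
    d1 <- digestAmplicon("AAAGTACAAA", rsaI)
    expect_equal(d1$fragments, c(5L, 5L))
    ## conservation on random sequences
    set.seed(5)
    for (rep in 1:20) {
        seq <- randomDnaStr(sample(50:500, 1))
        d <- digestAmplicon(seq, rsaI)
        expect_equal(sum(d$fragments), nchar(seq))
        expect_equal(length(d$fragments), length(d$cuts) + 1L)
    }
})

test_that("digest is a pure function of sequence and enzyme", {
    seq <- paste0("AA", "GTAC", "CCGTACGG")
    viaString <- digestAmplicon(seq, rsaI)
    viaAmplicon <- digestAmplicon(data.frame(template = "t", start = 1,
                                             end = nchar(seq),
                                             sequence = seq), rsaI)
    expect_identical(viaString, viaAmplicon)
})

test_that("discriminating-enzyme search is symmetric and excludes shared cutters", {
    enzymes <- defaultEnzymes()
    set.seed(6)
    base <- randomDnaStr(400)
    ## identical amplicons -> nothing discriminates
    expect_equal(nrow(findDiscriminatingEnzymes(base, base, enzymes)), 0L)

    ## plant a RsaI site in A only, in a region free of other sites
    a <- paste0(base, "AATTAGCAAT", "GTAC", "AATTAGCAAT")
    b <- paste0(base, "AATTAGCAAT", "GAAC", "AATTAGCAAT")
    ab <- findDiscriminatingEnzymes(a, b, enzymes)
    ba <- findDiscriminatingEnzymes(b, a, enzymes)
    expect_true("RsaI" %in% ab$enzyme)
    expect_equal(sort(ab$enzyme), sort(ba$enzyme))
    expect_equal(ab[ab$enzyme == "RsaI", "fragmentsA"],
                 ba[ba$enzyme == "RsaI", "fragmentsB"])
})

test_that("pairwise identity counts differences and reports two decimals", {
    a100 <- paste(rep("A", 100), collapse = "")
    expect_equal(pairwiseIdentity(a100, a100),
                 list(length = 100L, differences = 0L, identity = 100))
    expect_equal(pairwiseIdentity("AC", "AG")$identity, 50)
    ## gap columns count as differences
    expect_equal(pairwiseIdentity("A-CT", "AACT")$differences, 1L)
    expect_error(pairwiseIdentity("", "A"), "empty")
    expect_error(pairwiseIdentity("AAA", "AA"), "equal length")
})

test_that("marker templates carry the planted site and exactly k differences", {
    mk <- generateMarkerTemplates(seed = 10, k = 24)
    a <- as.character(mk$templates[["alleleA"]])
    b <- as.character(mk$templates[["alleleB"]])
    expect_equal(pairwiseIdentity(a, b)$differences, 24L)
    ## planted RsaI instance present in A at the truth position, absent in B
    site <- substring(a, mk$truth$sitePos, mk$truth$sitePos + 3L)
    expect_equal(site, "GTAC")
    expect_false(substring(b, mk$truth$sitePos,
                           mk$truth$sitePos + 3L) == "GTAC")
    ## k = 0 without a planted site -> identical templates
    mk0 <- generateMarkerTemplates(seed = 10, k = 0, plantSite = FALSE)
    expect_equal(as.character(mk0$templates[[1]]),
                 as.character(mk0$templates[[2]]))
    ## contradiction rejected
    expect_error(generateMarkerTemplates(seed = 1, k = 0, plantSite = TRUE),
                 "contradicts")
})

test_that("end-to-end marker design recovers the planted enzyme", {
    for (s in c(21, 22, 23)) {
        mk <- generateMarkerTemplates(seed = s, k = 24)
        design <- designCapsMarker(as.character(mk$templates[[1]]),
                                   as.character(mk$templates[[2]]),
                                   pair = mk$pair)
        expect_equal(design$markers$enzyme, mk$truth$enzyme)
    }
})
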