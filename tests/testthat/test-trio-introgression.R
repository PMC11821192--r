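test_that("quality filter keeps the boundary value and preserves order", {
    tv <- makeSites(pos = c(10, 20, 30), gtD = "hom_alt", gtR = "hom_ref",
                    gtL = "hom_alt", qual = c(20, 19.9, 35))
    kept <- filterQuality(tv, 20)
    expect_equal(start(variantRanges(kept)), c(10, 30))
    expect_equal(length(filterQuality(tv[0], 20)), 0L)
})

test_that("parental assignment follows the trio allelic-state rule", {
    cases <- list(
        list(d = "hom_alt", r = "hom_ref", l = "hom_alt", want = "DONOR"),
        list(d = "hom_ref", r = "hom_alt", l = "hom_ref", want = "DONOR"),
        list(d = "hom_alt", r = "hom_ref", l = "hom_ref", want = "RECIPIENT"),
        list(d = "hom_alt", r = "hom_alt", l = "hom_alt",
             want = "UNINFORMATIVE"),
        list(d = "het",     r = "hom_ref", l = "hom_alt",
             want = "UNINFORMATIVE"),
        list(d = "hom_alt", r = "hom_ref", l = "missing",
             want = "UNINFORMATIVE"),
        list(d = "hom_alt", r = "hom_ref", l = "other_alt",
             want = "CONFLICT"))
    for (cs in cases) {
        tv <- makeSites(1, cs$d, cs$r, cs$l)
        expect_equal(as.character(assignParent(tv)), cs$want,
                     info = paste(cs$d, cs$r, cs$l))
    }
})

test_that("region classification applies UTR > exon > intron and strand-aware flanks", {
    ## gene A (+): [1000, 3000]: 5'UTR 1000-1199, exons 1200-1599 &
    ## 2000-2599, intron 1600-1999, 3'UTR 2600-3000
    ## gene B (-): [20000, 22000], exon only
    models <- makeModels(
        makeGene("gA", "chr1", 1000, 3000, "+",
                 exons = rbind(c(1200, 1599), c(2000, 2599)),
                 utr5 = rbind(c(1000, 1199)), utr3 = rbind(c(2600, 3000))),
        makeGene("gB", "chr1", 20000, 22000, "-",
                 exons = rbind(c(20000, 22000))))
    ## positions in sorted order (TrioVariants sorts on construction)
    pos <- c(900, 1100, 1300, 1700, 2700, 3100, 8001, 12000, 19999, 22100)
    want <- c("UPSTREAM", "FIVE_UTR", "EXON", "INTRON", "THREE_UTR",
              "DOWNSTREAM", "INTERGENIC", "INTERGENIC", "DOWNSTREAM",
              "UPSTREAM")
    tv <- makeSites(pos, "hom_alt", "hom_ref", "hom_alt")
    got <- classifyRegion(tv, models, flankWindow = 5000)
    expect_equal(as.character(got$regionClass), want)
    expect_equal(got$geneId[1:6], rep("gA", 6))
    expect_equal(got$geneId[c(9, 10)], c("gB", "gB"))
    expect_true(all(is.na(got$geneId[7:8])))
})

test_that("overlapping flanks go to the nearer gene, ties to the smaller start", {
    models <- makeModels(
        makeGene("left", "chr1", 100, 200, "+", exons = rbind(c(100, 200))),
        makeGene("right", "chr1", 1200, 1300, "+",
                 exons = rbind(c(1200, 1300))))
    ## 600 is 400 from 'left', 600 from 'right' -> left's downstream
    ## 700 is equidistant (500/500) -> tie broken to 'left' (smaller start)
    ## 900 is 700/300 -> right's upstream
    tv <- makeSites(c(600, 700, 900), "hom_alt", "hom_ref", "hom_alt")
    got <- classifyRegion(tv, models, flankWindow = 5000)
    expect_equal(got$geneId, c("left", "left", "right"))
    expect_equal(as.character(got$regionClass),
                 c("DOWNSTREAM", "DOWNSTREAM", "UPSTREAM"))
})

test_that("sites on unannotated chromosomes are intergenic with a warning", {
    models <- makeModels(makeGene("g", "chr1", 100, 200, "+",
                                  exons = rbind(c(100, 200))))
    tv <- makeSites(50, "hom_alt", "hom_ref", "hom_alt", chrom = "chrZ")
    expect_warning(got <- classifyRegion(tv, models), "absent")
    expect_equal(as.character(got$regionClass), "INTERGENIC")
})

test_that("region filter retains only UTR and exon classes", {
    cls <- factor(c("EXON", "INTRON", "UPSTREAM", "FIVE_UTR", "INTERGENIC",
                    "THREE_UTR", "DOWNSTREAM"),
                  levels = c("FIVE_UTR", "EXON", "THREE_UTR", "INTRON",
                             "UPSTREAM", "DOWNSTREAM", "INTERGENIC"))
    expect_equal(applyRegionFilter(cls), c(1L, 4L, 6L))
    expect_length(applyRegionFilter(cls[cls == "INTERGENIC"]), 0L)
})

test_that("region table counts by class and variant type and conserves totals", {
    tab <- variantRegionTable(c("EXON", "EXON", "FIVE_UTR"),
                              c("SNV", "SNV", "indel"))
    expect_equal(tab["EXON", "SNV"], 2L)
    expect_equal(tab["FIVE_UTR", "indel"], 1L)
    expect_equal(sum(tab), 3L)
    empty <- variantRegionTable(character(), character())
    expect_equal(sum(empty), 0L)
    expect_error(variantRegionTable("INTRON", "SNV"), "region-filtered")
})

test_that("gene origin assignment partitions genes and conserves counts", {
    models <- makeModels(
        makeGene("g1", "chr1", 100, 200, "+", exons = rbind(c(100, 200))),
        makeGene("g2", "chr1", 300, 400, "+", exons = rbind(c(300, 400))),
        makeGene("g3", "chr1", 500, 600, "+", exons = rbind(c(500, 600))),
        makeGene("g4", "chr1", 700, 800, "+", exons = rbind(c(700, 800))))
    geneId <- c("g1", "g1", "g1", "g2", "g3", "g3")
    assignment <- factor(c("DONOR", "DONOR", "DONOR", "RECIPIENT",
                           "DONOR", "RECIPIENT"),
                         levels = c("DONOR", "RECIPIENT", "UNINFORMATIVE",
                                    "CONFLICT"))
    origin <- assignGeneOrigin(models, geneId, assignment)
    expect_equal(as.character(origin[c("g1", "g2", "g3", "g4")]),
                 c("DONOR", "RECIPIENT", "CONFLICT", "NON_POLYMORPHIC"))
    expect_equal(sum(table(origin)), length(models))
})

test_that("inheritance fraction matches its formula and is complementary", {
    expect_equal(inheritanceFraction(0, 1000, digits = 1), 0)
    expect_equal(inheritanceFraction(7, 7, digits = 1), 50)
    for (ab in list(c(3, 97), c(464, 14365), c(1, 2)))
        expect_equal(inheritanceFraction(ab[1], ab[2]) +
                     inheritanceFraction(ab[2], ab[1]), 100)
    expect_error(inheritanceFraction(0, 0), "undefined")
})

test_that("block detection handles runs, gaps and support thresholds", {
    ## 10 consecutive donor sites -> one block first..last
    tv <- makeSites(seq(100, 1000, by = 100), "hom_alt", "hom_ref",
                    "hom_alt")
    b <- detectBlocks(tv, assignParent(tv), maxGapSites = 0,
                      minSupportSites = 5)
    expect_equal(length(b), 1L)
    expect_equal(c(start(b), end(b)), c(100, 1000))
    expect_equal(mcols(b)$span, 901L)

    ## donor run, 1 recipient site, donor run; maxGap 0 -> two blocks,
    ## maxGap 1 -> one
    gtL <- rep("hom_alt", 11); gtL[6] <- "hom_ref"
    tv2 <- makeSites(seq(100, 1100, by = 100), "hom_alt", "hom_ref", gtL)
    asg <- assignParent(tv2)
    expect_equal(length(detectBlocks(tv2, asg, 0, 2)), 2L)
    b1 <- detectBlocks(tv2, asg, 1, 2)
    expect_equal(length(b1), 1L)
    expect_equal(mcols(b1)$nInterior, 1L)
    expect_equal(mcols(b1)$nDonor, 10L)

    ## support threshold drops short runs
    expect_equal(length(detectBlocks(tv2, asg, 0, 6)), 0L)
})

test_that("block detection agrees with the brute-force run enumerator", {
    set.seed(42)
    for (rep in 1:40) {
        n <- sample(5:200, 1)
        donor <- runif(n) < runif(1, 0.2, 0.8)
        maxGap <- sample(0:3, 1)
        minSupport <- sample(1:5, 1)
        pos <- sort(sample.int(10 * n, n))
        tv <- makeSites(pos, "hom_alt", "hom_ref",
                        ifelse(donor, "hom_alt", "hom_ref"))
        got <- detectBlocks(tv, assignParent(tv), maxGap, minSupport)
        want <- bruteForceRuns(donor, maxGap, minSupport)
        expect_equal(length(got), nrow(want))
        if (nrow(want)) {
            expect_equal(start(got), pos[want$i])
            expect_equal(end(got), pos[want$j])
        }
    }
})

test_that("block summaries count genes by >= 1 bp overlap and span correctly", {
    models <- makeModels(
        makeGene("in1", "chr1", 50, 150, "+", exons = rbind(c(50, 150))),
        makeGene("out1", "chr1", 2000, 2500, "+",
                 exons = rbind(c(2000, 2500))))
    blocks <- GRanges("chr1", IRanges(100, 1099))
    mcols(blocks) <- S4Vectors::DataFrame(nDonor = 5L, nInterior = 0L,
                                          span = 1000L)
    s <- summarizeBlocks(blocks, models)
    expect_equal(width(s), 1000L)
    expect_equal(mcols(s)$nGenes, 1L)
    expect_equal(as.character(mcols(s)$genes[[1]]), "in1")
})

test_that("chromosome distribution conserves donor-site totals", {
    tv <- makeSites(c(5, 10, 400, 1500, 2500), "hom_alt", "hom_ref",
                    "hom_alt")
    d <- chromosomeDistribution(tv, assignParent(tv), binSize = 1000,
                                chromLengths = c(chr1 = 3000))
    expect_equal(d$count, c(3L, 1L, 1L))
    expect_equal(sum(d$count), 5L)
    ## all-recipient input gives all-zero bins
    tv0 <- makeSites(c(5, 10), "hom_alt", "hom_ref", "hom_ref")
    d0 <- chromosomeDistribution(tv0, assignParent(tv0), binSize = 1000,
                                 chromLengths = c(chr1 = 3000))
    expect_true(all(d0$count == 0))
})

test_that("every quality-passing site gets exactly one assignment and region class", {
    cfg <- trioSimConfig(seed = 11, chromLengths = c(chr1 = 2e5),
                         donorBlocks = data.frame(chrom = "chr1",
                                                  start = 5e4, end = 1e5),
                         geneCount = 40L)
    ds <- generateTrioDataset(cfg)
    tv <- filterQuality(ds$variants, 20)
    asg <- assignParent(tv)
    reg <- classifyRegion(tv, ds$models)
    expect_false(anyNA(asg))
    expect_false(anyNA(reg$regionClass))
    expect_equal(length(asg), length(tv))
    origin <- assignGeneOrigin(ds$models, reg$geneId[applyRegionFilter(
        reg$regionClass)], asg[applyRegionFilter(reg$regionClass)])
    expect_equal(sum(table(origin)), length(ds$models))
})
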