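## IUPAC nucleotide code -> set of matching bases
.IUPAC <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T"))

.validIupac <- function(pattern) {
    all(strsplit(toupper(pattern), "")[[1]] %in% names(.IUPAC))
}

.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## rounding used for reported percentages: half-up, not banker's
.roundHalfUp <- function(x, digits = 0L) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

.randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## derive a substream seed (< 2^31) from a base seed and a stream index
.subSeed <- function(seed, k) {
    (as.integer(seed) %% 1000000L) * 1009L + as.integer(k)
}
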