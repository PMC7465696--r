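suppressPackageStartupMessages({
    library(GenomicRanges)
    library(GenomeInfoDb)
})

testGenome <- function(len = 2e7, chroms = "chrT")
    Seqinfo(chroms, rep(as.integer(len), length(chroms)))

# A bundle with truth intervals planted jointly with a het mask (one
# plantTruth call keeps them disjoint), tracks simulated on top.
maskedBundle <- function(seed, coloc = 1, noiseCV = 0,
                         counts = c(complex = 8, domain = 2),
                         nMask = 2, len = 2e7,
                         marks = c("HP1a", "H3K9me3"), binWidth = 5000) {
    si <- testGenome(len)
    ranges <- c(defaultSizeRanges(), list(mask = c(1e6, 2e6)))
    planted <- plantTruth(si, c(counts, mask = nMask),
                          sizeRanges = ranges, seed = seed,
                          snap = binWidth)
    mask <- planted[planted$sizeClass == "mask"]
    mcols(mask) <- NULL
    truth <- planted[planted$sizeClass != "mask"]
    simulateTracks(si, binWidth, truth, mask = mask, marks = marks,
                   coloc = coloc, noiseCV = noiseCV, seed = seed + 1000L)
}

plainBundle <- function(seed, coloc = 1, noiseCV = 0,
                        counts = c(complex = 8, domain = 2), len = 2e7,
                        marks = c("HP1a", "H3K9me3"), binWidth = 5000) {
    si <- testGenome(len)
    truth <- plantTruth(si, counts, seed = seed, snap = binWidth)
    simulateTracks(si, binWidth, truth, marks = marks, coloc = coloc,
                   noiseCV = noiseCV, seed = seed + 1000L)
}

# manual single-chromosome track from a bin-value vector
manualTrack <- function(values, binWidth = 5000, mark = "m",
                        genome = NULL) {
    if (is.null(genome))
        genome <- testGenome(length(values) * binWidth)
    BinnedTrack(genome, values, binWidth = binWidth, mark = mark)
}
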