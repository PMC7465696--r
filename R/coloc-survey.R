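# Windowed fold-enrichment correlation between an HP1 track and
# H3K9me3, genome-wide or relative to a constitutive-heterochromatin
# mask. The window is the track bin width (5 kb for mammals/fly, 200 bp
# for fission yeast in the usual presets).

.REGION_MODES <- c("whole_genome", "exclude_mask", "mask_only")

# Logical keep-vector over unlisted bins: a bin is "in the mask" when
# its midpoint lies inside a mask interval.
.binKeep <- function(track, mask, mode) {
    mode <- match.arg(mode, .REGION_MODES)
    bins <- tileGenome(seqinfo(track), tilewidth = binWidth(track),
                       cut.last.tile.in.chrom = TRUE)
    if (mode == "whole_genome" || is.null(mask) || !length(mask))
        inMask <- rep(FALSE, length(bins))
    else {
        mids <- GRanges(seqnames(bins),
                        IRanges((start(bins) + end(bins)) %/% 2L,
                                width = 1L))
        inMask <- overlapsAny(mids, mask)
    }
    switch(mode,
           whole_genome = rep(TRUE, length(bins)),
           exclude_mask = !inMask,
           mask_only = inMask)
}

#' Restrict a track's bins relative to a heterochromatin mask
#'
#' Returns the bin values retained under a region mode:
#' \code{"whole_genome"} keeps every bin, \code{"exclude_mask"} drops
#' every bin whose midpoint lies inside a mask interval (the masked
#' regions are excluded prior to analysis), \code{"mask_only"} keeps
#' only those bins.
#'
#' @param track A \linkS4class{BinnedTrack}.
#' @param mask A \link[GenomicRanges]{GRanges} constitutive
#'   heterochromatin mask (sorted, non-overlapping), or \code{NULL}.
#' @param mode One of \code{"whole_genome"}, \code{"exclude_mask"},
#'   \code{"mask_only"}.
#' @return Numeric vector of the retained bin values (genome order).
#'   Errors if fewer than 3 bins remain.
#' @export
applyRegionMode <- function(track, mask = NULL,
                            mode = c("whole_genome", "exclude_mask",
                                     "mask_only")) {
    stopifnot(is(track, "BinnedTrack"))
    mode <- match.arg(mode)
    keep <- .binKeep(track, mask, mode)
    if (sum(keep) < 3L)
        stop("fewer than 3 bins retained under mode '", mode, "'")
    unlist(trackValues(track), use.names = FALSE)[keep]
}

#' Windowed Pearson correlation between two fold-enrichment tracks
#'
#' Pearson correlation of two marks' binned fold enrichments over the
#' bins retained under a region mode. The correlation window is the
#' shared bin width. Bins where both tracks are exactly zero are
#' retained: co-absence is informative for co-localization.
#'
#' @param trackA,trackB \linkS4class{BinnedTrack}s sharing genome and
#'   bin width.
#' @inheritParams applyRegionMode
#' @return A one-row \link[S4Vectors]{DataFrame} with columns
#'   \code{markA}, \code{markB}, \code{r}, \code{nBins}, \code{window},
#'   \code{regionMode}.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chrT", 5e4)
#' a <- BinnedTrack(si, c(1, 5, 1, 5, 1, 5, 1, 5, 1, 2), 5000, "HP1a")
#' windowedCorrelation(a, a)$r   # 1
#' @export
windowedCorrelation <- function(trackA, trackB, mask = NULL,
                                mode = c("whole_genome", "exclude_mask",
                                         "mask_only")) {
    stopifnot(is(trackA, "BinnedTrack"), is(trackB, "BinnedTrack"))
    mode <- match.arg(mode)
    if (!identical(seqinfo(trackA), seqinfo(trackB)))
        stop("tracks must share a genome")
    if (binWidth(trackA) != binWidth(trackB))
        stop("tracks must share a bin width")
    a <- applyRegionMode(trackA, mask, mode)
    b <- applyRegionMode(trackB, mask, mode)
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("undefined correlation: zero variance under mode '",
             mode, "'")
    DataFrame(markA = markName(trackA), markB = markName(trackB),
              r = stats::cor(a, b), nBins = length(a),
              window = binWidth(trackA), regionMode = mode)
}

#' Survey co-localization of HP1 marks with H3K9me3
#'
#' Correlates each HP1 track with the H3K9me3 track under each
#' requested region mode, one row per (mark, mode) pair --- the tabular
#' core of a genome-wide co-localization figure.
#'
#' @param hp1Tracks List of \linkS4class{BinnedTrack}s (one per HP1
#'   isoform), or a single track.
#' @param k9Track The H3K9me3 \linkS4class{BinnedTrack}.
#' @param mask Constitutive-heterochromatin mask
#'   (\link[GenomicRanges]{GRanges}) or \code{NULL}.
#' @param modes Character vector of region modes to evaluate.
#' @return A \link[S4Vectors]{DataFrame}, rows ordered mark-major.
#' @export
surveyMatrix <- function(hp1Tracks, k9Track, mask = NULL,
                         modes = c("whole_genome", "exclude_mask",
                                   "mask_only")) {
    if (is(hp1Tracks, "BinnedTrack"))
        hp1Tracks <- list(hp1Tracks)
    stopifnot(length(hp1Tracks) >= 1)
    modes <- match.arg(modes, .REGION_MODES, several.ok = TRUE)
    rows <- lapply(hp1Tracks, function(tr)
        do.call(rbind, lapply(modes, function(md)
            windowedCorrelation(tr, k9Track, mask, md))))
    do.call(rbind, rows)
}
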