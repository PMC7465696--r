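# Calling heterochromatin-like domains/complexes: genomic intervals
# co-enriched for at least one HP1 isoform and H3K9me3, classified into
# three size classes (complex 10-100 kb, domain 0.1-1 Mb, large domain
# >= 1 Mb; half-open boundaries).

#' Parameters for the domain caller
#'
#' @param enrichThreshold Fold-enrichment cutoff tau (> 0) above which a
#'   bin counts as enriched. There is no canonical value; 2-fold is the
#'   default and is recorded in the output.
#' @param mergeGap Maximum gap (bp) between enriched runs that is merged
#'   into one interval. \code{NULL} (default) means one bin width --- the
#'   smallest gap distinguishable at track resolution.
#' @param minSize Minimum call length in bp (default 10 kb, the lower
#'   edge of the complex class).
#' @param sizeBounds Two class edges in bp, default \code{c(1e5, 1e6)}:
#'   lengths in \code{[minSize, sizeBounds[1])} are complexes,
#'   \code{[sizeBounds[1], sizeBounds[2])} domains, and
#'   \code{>= sizeBounds[2]} large domains.
#' @return A validated list of class \code{"CallerParams"}.
#' @export
callerParams <- function(enrichThreshold = 2, mergeGap = NULL,
                         minSize = 1e4, sizeBounds = c(1e5, 1e6)) {
    stopifnot(enrichThreshold > 0, is.null(mergeGap) || mergeGap >= 0,
              length(sizeBounds) == 2,
              minSize < sizeBounds[1], sizeBounds[1] < sizeBounds[2])
    structure(list(enrichThreshold = enrichThreshold, mergeGap = mergeGap,
                   minSize = minSize, sizeBounds = sizeBounds),
              class = "CallerParams")
}

.sizeClass <- function(widths, minSize, sizeBounds) {
    cls <- ifelse(widths >= sizeBounds[2], "large_domain",
           ifelse(widths >= sizeBounds[1], "domain", "complex"))
    factor(cls, levels = .SIZE_CLASSES)
}

#' Enriched intervals of a single track
#'
#' Maximal runs of bins with value >= tau, converted to bp intervals
#' (snapped to bin edges, clipped at chromosome ends); runs separated by
#' at most \code{mergeGap} bp are merged, then intervals shorter than
#' \code{minSize} are dropped. Output is sorted and non-overlapping.
#'
#' @param track A \linkS4class{BinnedTrack}.
#' @param tau Fold-enrichment threshold (> 0).
#' @param mergeGap Maximum merged gap in bp; default one bin width.
#' @param minSize Minimum interval length in bp (0 keeps everything).
#' @return A \link[GenomicRanges]{GRanges} (possibly empty).
#' @export
enrichedIntervals <- function(track, tau, mergeGap = binWidth(track),
                              minSize = 0) {
    stopifnot(is(track, "BinnedTrack"), tau > 0, mergeGap >= 0)
    bins <- binRanges(track)
    hot <- bins[bins$score >= tau]
    mcols(hot) <- NULL
    out <- reduce(hot, min.gapwidth = mergeGap + 1)
    out[width(out) >= minSize]
}

#' Call heterochromatin-like domains and complexes
#'
#' Intersects the union (or intersection, see \code{combine}) of the
#' HP1 isoforms' enriched intervals with the enriched intervals of
#' H3K9me3; under \code{mode = "exclude_mask"} drops calls overlapping
#' the constitutive-heterochromatin mask (by default when >= 50\% of the
#' call's length is masked); filters to \code{minSize}; and classifies
#' survivors into complexes, domains and large domains.
#'
#' @param hp1Tracks List of HP1 \linkS4class{BinnedTrack}s (>= 1), or a
#'   single track.
#' @param k9Track The H3K9me3 \linkS4class{BinnedTrack}.
#' @param params A \code{\link{callerParams}} object.
#' @param mask Constitutive-heterochromatin mask
#'   (\link[GenomicRanges]{GRanges}); required for
#'   \code{"exclude_mask"}.
#' @param mode \code{"whole_genome"} or \code{"exclude_mask"}.
#' @param combine How HP1 isoforms are combined before intersection with
#'   H3K9me3: \code{"union"} (a call needs at least one isoform,
#'   default) or \code{"intersection"} (all isoforms).
#' @param maskRule How mask overlap removes a call under
#'   \code{"exclude_mask"}: \code{"half"} (>= 50\% of call length
#'   masked, default), \code{"midpoint"} (call midpoint in mask) or
#'   \code{"any"} (any overlap).
#' @return A sorted \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{sizeClass}, \code{marks} (a
#'   \link[IRanges]{CharacterList} of the marks whose enriched intervals
#'   overlap the call) and one \code{mean_<mark>} column of mean fold
#'   enrichment per input track.
#' @export
callDomains <- function(hp1Tracks, k9Track, params = callerParams(),
                        mask = NULL,
                        mode = c("whole_genome", "exclude_mask"),
                        combine = c("union", "intersection"),
                        maskRule = c("half", "midpoint", "any")) {
    if (is(hp1Tracks, "BinnedTrack"))
        hp1Tracks <- list(hp1Tracks)
    if (!length(hp1Tracks))
        stop("at least one HP1 track is required")
    stopifnot(is(k9Track, "BinnedTrack"), inherits(params, "CallerParams"))
    mode <- match.arg(mode)
    combine <- match.arg(combine)
    maskRule <- match.arg(maskRule)
    tau <- params$enrichThreshold
    gap <- if (is.null(params$mergeGap)) binWidth(k9Track) else
        params$mergeGap
    hp1Sets <- lapply(hp1Tracks, enrichedIntervals, tau = tau,
                      mergeGap = gap)
    hp1Comb <- hp1Sets[[1L]]
    if (length(hp1Sets) > 1L)
        for (s in hp1Sets[-1L])
            hp1Comb <- if (combine == "union")
                reduce(c(hp1Comb, s)) else
                GenomicRanges::intersect(hp1Comb, s)
    k9Set <- enrichedIntervals(k9Track, tau, mergeGap = gap)
    calls <- GenomicRanges::intersect(hp1Comb, k9Set)
    if (mode == "exclude_mask" && !is.null(mask) && length(mask) &&
        length(calls)) {
        drop <- switch(maskRule,
            half = {
                # per-call masked bp via findOverlaps/pintersect
                hits <- findOverlaps(calls, mask)
                maskedBp <- rep(0, length(calls))
                if (length(hits)) {
                    pw <- width(pintersect(calls[queryHits(hits)],
                                           mask[subjectHits(hits)]))
                    agg <- tapply(pw, queryHits(hits), sum)
                    maskedBp[as.integer(names(agg))] <- agg
                }
                maskedBp >= 0.5 * width(calls)
            },
            midpoint = {
                mids <- GRanges(seqnames(calls),
                                IRanges((start(calls) + end(calls)) %/% 2L,
                                        width = 1L))
                overlapsAny(mids, mask)
            },
            any = overlapsAny(calls, mask))
        calls <- calls[!drop]
    }
    calls <- calls[width(calls) >= params$minSize]
    calls <- sort(calls)
    calls$sizeClass <- .sizeClass(width(calls), params$minSize,
                                  params$sizeBounds)
    allSets <- c(hp1Sets, list(k9Set))
    allTracks <- c(hp1Tracks, list(k9Track))
    markNames <- vapply(allTracks, markName, character(1))
    present <- lapply(seq_along(calls), function(i) character(0))
    for (si in seq_along(allSets)) {
        hit <- overlapsAny(calls, allSets[[si]])
        for (i in which(hit))
            present[[i]] <- c(present[[i]], markNames[si])
    }
    calls$marks <- IRanges::CharacterList(present)
    for (ti in seq_along(allTracks)) {
        tr <- allTracks[[ti]]
        bins <- binRanges(tr)
        mids <- GRanges(seqnames(bins),
                        IRanges((start(bins) + end(bins)) %/% 2L,
                                width = 1L))
        hits <- findOverlaps(mids, calls)
        means <- rep(NA_real_, length(calls))
        if (length(hits)) {
            agg <- tapply(bins$score[queryHits(hits)], subjectHits(hits),
                          mean)
            means[as.integer(names(agg))] <- agg
        }
        mcols(calls)[[paste0("mean_", markNames[ti])]] <- means
    }
    metadata(calls) <- list(params = unclass(params), mode = mode,
                            combine = combine, maskRule = maskRule)
    calls
}

#' Summarize domain calls into a census table
#'
#' Counts calls per size class for each region mode and reports the
#' share of complexes in the 10--30 kb range (closed interval), the
#' quantity usually quoted for the complex class.
#'
#' @param callsByMode Named list of call \link[GenomicRanges]{GRanges},
#'   e.g. \code{list(whole_genome = ..., exclude_mask = ...)}.
#' @return A list of class \code{"SurveySummary"}: \code{counts} (size
#'   class x mode integer matrix), \code{fraction_10_30kb} (named
#'   numeric per mode; \code{NA} where a mode has no complexes) and
#'   \code{has_complexes} (named logical flag per mode).
#' @export
summarizeCalls <- function(callsByMode) {
    stopifnot(is.list(callsByMode), length(callsByMode) >= 1,
              !is.null(names(callsByMode)))
    modes <- names(callsByMode)
    counts <- sapply(callsByMode, function(calls)
        table(factor(calls$sizeClass, levels = .SIZE_CLASSES)))
    counts <- matrix(as.integer(counts), nrow = length(.SIZE_CLASSES),
                     dimnames = list(.SIZE_CLASSES, modes))
    frac <- vapply(callsByMode, function(calls) {
        w <- width(calls)[calls$sizeClass == "complex"]
        if (!length(w)) NA_real_ else mean(w >= 1e4 & w <= 3e4)
    }, numeric(1))
    structure(list(counts = counts, fraction_10_30kb = frac,
                   has_complexes = !is.na(frac)),
              class = "SurveySummary")
}

#' @export
print.SurveySummary <- function(x, ...) {
    cat("Heterochromatin-like domain/complex census\n")
    print(x$counts)
    cat("fraction of complexes in 10-30 kb:\n")
    print(round(x$fraction_10_30kb, 3))
    invisible(x)
}
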