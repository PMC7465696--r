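# Synthetic multi-mark fold-enrichment tracks with planted ground truth.
# The generator emulates the statistical structure of an HP1/H3K9me3
# co-localization survey: co-enriched intervals in three size classes, a
# constitutive-heterochromatin mask enriched in every mark, tunable
# interval-level co-localization and multiplicative log-normal noise.

.SIZE_CLASSES <- c("complex", "domain", "large_domain")

#' Default size-class ranges for planted intervals
#'
#' Size classes follow the three-way census convention: complexes
#' 10--100 kb, domains 0.1--1 Mb, large domains more than 1 Mb (capped
#' here at 4 Mb, the scale of the largest known heterochromatin-like
#' domains). Half-open in bp: \code{[1e4, 1e5)}, \code{[1e5, 1e6)},
#' \code{[1e6, 4e6)}.
#'
#' @return Named list of \code{c(min, max)} bp ranges.
#' @export
defaultSizeRanges <- function() {
    list(complex      = c(1e4, 1e5),
         domain       = c(1e5, 1e6),
         large_domain = c(1e6, 4e6))
}

# Run `expr` under seed `seed` without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Plant labelled ground-truth intervals in a genome
#'
#' Draws non-overlapping labelled intervals whose sizes are uniform
#' within each size class's range, separated by at least \code{minGap},
#' and snapped to a coordinate grid so that binned tracks at the same
#' resolution represent them exactly. Placement is deterministic given
#' \code{seed}. Intervals are assigned to chromosomes with probability
#' proportional to chromosome length; if a random assignment cannot be
#' packed, assignment is retried, and an error reporting the achievable
#' counts is raised if packing keeps failing.
#'
#' @param genome A \link[GenomeInfoDb]{Seqinfo}.
#' @param counts Named integer vector of interval counts per class, e.g.
#'   \code{c(complex = 50, domain = 5, large_domain = 1)}. Classes absent
#'   from \code{counts} get zero intervals.
#' @param sizeRanges Named list of \code{c(min, max)} bp ranges per
#'   class; defaults to \code{\link{defaultSizeRanges}}.
#' @param minGap Minimum separation between planted intervals, bp.
#' @param seed Integer RNG seed.
#' @param snap Coordinate grid (bp) that starts and sizes are snapped
#'   to; use the intended track bin width (default 5000).
#' @return A sorted \link[GenomicRanges]{GRanges} with a
#'   \code{sizeClass} metadata column.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chrT", 2e7)
#' plantTruth(si, c(complex = 3, domain = 1), seed = 1)
#' @export
plantTruth <- function(genome, counts, sizeRanges = defaultSizeRanges(),
                       minGap = 50000, seed = 1, snap = 5000) {
    stopifnot(is(genome, "Seqinfo"), minGap >= 0, snap >= 1)
    counts <- counts[counts > 0]
    if (!length(counts))
        return(GRanges(seqinfo = genome,
                       sizeClass = character(0)))
    if (!all(names(counts) %in% names(sizeRanges)))
        stop("no size range given for class: ",
             paste(setdiff(names(counts), names(sizeRanges)),
                   collapse = ", "))
    .withSeed(seed, {
        classes <- rep(names(counts), counts)
        sizes <- vapply(classes, function(cl) {
            rg <- sizeRanges[[cl]]
            # snap down so the size stays inside the half-open class range
            max(snap * floor(rg[1] / snap),
                snap * floor(runif(1, rg[1], rg[2]) / snap))
        }, numeric(1))
        sl <- as.numeric(seqlengths(genome))
        nms <- seqnames(genome)
        # snapping moves starts left by < snap, so keep an extra snap of
        # separation to guarantee minGap after snapping
        gap <- minGap + snap
        for (attempt in seq_len(200L)) {
            chrom <- sample(seq_along(sl), length(sizes), replace = TRUE,
                            prob = sl)
            ok <- TRUE
            starts <- numeric(length(sizes))
            for (ci in unique(chrom)) {
                idx <- which(chrom == ci)
                k <- length(idx)
                need <- sum(sizes[idx]) + (k - 1) * gap
                slack <- sl[ci] - need
                if (slack < 0) { ok <- FALSE; break }
                # uniform non-overlapping placement: spread the slack
                offs <- sort(runif(k, 0, slack))
                ord <- sample(idx)     # random left-to-right order
                st <- offs + cumsum(c(0, sizes[ord][-k] + gap))
                starts[ord] <- snap * floor(st / snap)
            }
            if (ok) {
                gr <- GRanges(nms[chrom],
                              IRanges(start = starts + 1,
                                      width = sizes),
                              seqinfo = genome)
                gr$sizeClass <- classes
                return(sort(gr))
            }
        }
        achieved <- floor(sum(sl) / (mean(sizes) + gap))
        stop("cannot pack ", sum(counts), " intervals (",
             format(sum(sizes), big.mark = ","), " bp) into the genome ",
             "with minGap = ", minGap, "; roughly ", achieved,
             " intervals of this size mix would fit")
    })
}

#' Simulate co-localized fold-enrichment tracks with known truth
#'
#' Builds one \linkS4class{BinnedTrack} per mark. Each track equals
#' \code{backgroundMean} outside the planted intervals and mask,
#' \code{enrichMean} inside the constitutive-heterochromatin mask (all
#' marks) and inside the planted truth intervals assigned to that mark,
#' and is then multiplied bin-wise by log-normal noise with mean 1 and
#' coefficient of variation \code{noiseCV}. With probability
#' \code{coloc} a truth interval carries all marks; otherwise it carries
#' exactly one mark chosen uniformly (co-localization is modelled at
#' interval granularity). A bin belongs to an interval when its midpoint
#' lies inside it. Deterministic given \code{seed}; one RNG stream per
#' bundle.
#'
#' @param genome A \link[GenomeInfoDb]{Seqinfo}.
#' @param binWidth Bin width in bp.
#' @param truth \link[GenomicRanges]{GRanges} of planted co-enriched
#'   intervals (see \code{\link{plantTruth}}).
#' @param mask \link[GenomicRanges]{GRanges} of planted constitutive
#'   heterochromatin (may be empty).
#' @param marks Character vector of mark names, e.g.
#'   \code{c("HP1a", "HP1b", "H3K9me3")}.
#' @param enrichMean Mean fold enrichment inside enriched regions
#'   (> backgroundMean).
#' @param backgroundMean Mean fold enrichment elsewhere (>= 0).
#' @param coloc Probability in [0, 1] that a truth interval is enriched
#'   in all marks rather than a single random one.
#' @param noiseCV Coefficient of variation of the multiplicative
#'   log-normal noise (>= 0; 0 disables noise).
#' @param maskProfileCV Coefficient of variation of a log-normal
#'   bin-level intensity profile inside the mask, shared across all
#'   marks (default 0.5; 0 makes the mask uniformly enriched).
#'   Constitutive heterochromatin is not uniformly enriched: its
#'   locus-to-locus enrichment profile is common to the mark and its
#'   readers, which is what makes within-mask correlations approach 1.
#' @param seed Integer RNG seed.
#' @return A \linkS4class{SimBundle}. The returned truth carries a
#'   \code{marks} \link[IRanges]{CharacterList} column recording which
#'   marks each interval was enriched in.
#' @export
simulateTracks <- function(genome, binWidth, truth, mask = GRanges(),
                           marks = c("HP1a", "H3K9me3"),
                           enrichMean = 8, backgroundMean = 1,
                           coloc = 1, noiseCV = 0.3,
                           maskProfileCV = 0.5, seed = 1) {
    stopifnot(is(genome, "Seqinfo"), is(truth, "GRanges"),
              is(mask, "GRanges"), length(marks) >= 1,
              enrichMean > backgroundMean, backgroundMean >= 0,
              coloc >= 0, coloc <= 1, noiseCV >= 0, maskProfileCV >= 0)
    bins <- tileGenome(genome, tilewidth = binWidth,
                       cut.last.tile.in.chrom = TRUE)
    mids <- GRanges(seqnames(bins),
                    IRanges(start = (start(bins) + end(bins)) %/% 2L,
                            width = 1L))
    nbin <- length(bins)
    chromFac <- factor(as.character(seqnames(bins)),
                       levels = seqnames(genome))
    .withSeed(seed, {
        # interval-level mark assignment
        all_marks <- runif(length(truth)) < coloc
        single <- sample.int(length(marks), length(truth), replace = TRUE)
        assigned <- lapply(seq_along(truth), function(i)
            if (all_marks[i]) marks else marks[single[i]])
        maskHit <- overlapsAny(mids, mask)
        maskLevel <- rep(enrichMean, sum(maskHit))
        if (maskProfileCV > 0 && any(maskHit)) {
            sdp <- sqrt(log(1 + maskProfileCV^2))
            maskLevel <- maskLevel * stats::rlnorm(sum(maskHit),
                                                   meanlog = -sdp^2 / 2,
                                                   sdlog = sdp)
        }
        tracks <- list()
        for (mi in seq_along(marks)) {
            m <- marks[mi]
            base <- rep(backgroundMean, nbin)
            carrying <- truth[vapply(assigned, function(a) m %in% a,
                                     logical(1))]
            base[overlapsAny(mids, carrying)] <- enrichMean
            base[maskHit] <- maskLevel
            if (noiseCV > 0) {
                sdlog <- sqrt(log(1 + noiseCV^2))
                base <- base * stats::rlnorm(nbin, meanlog = -sdlog^2 / 2,
                                             sdlog = sdlog)
            }
            values <- split(base, chromFac)
            tracks[[m]] <- BinnedTrack(genome, as.list(values),
                                       binWidth = binWidth, mark = m)
        }
        truthOut <- truth
        truthOut$marks <- IRanges::CharacterList(assigned)
        new("SimBundle", tracks = tracks, truth = truthOut,
            mask = mask,
            params = list(binWidth = binWidth, marks = marks,
                          enrichMean = enrichMean,
                          backgroundMean = backgroundMean,
                          coloc = coloc, noiseCV = noiseCV,
                          maskProfileCV = maskProfileCV, seed = seed))
    })
}

#' Write a SimBundle to disk as plain-text files
#'
#' Writes \code{chrom.sizes}, one bedGraph per mark
#' (\code{<mark>.bedGraph}), \code{truth.bed}, \code{het_mask.bed} and
#' \code{params.yaml} into \code{dir}.
#'
#' @param x A \linkS4class{SimBundle}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeSimBundle <- function(x, dir) {
    stopifnot(is(x, "SimBundle"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    si <- seqinfo(x)
    writeLines(paste(seqnames(si), seqlengths(si), sep = "\t"),
               file.path(dir, "chrom.sizes"))
    for (m in names(bundleTracks(x)))
        writeBedGraph(bundleTracks(x)[[m]],
                      file.path(dir, paste0(m, ".bedGraph")))
    truth <- bundleTruth(x)
    truth$name <- truth$sizeClass
    writeBed(truth, file.path(dir, "truth.bed"))
    if (length(bundleMask(x)))
        writeBed(bundleMask(x), file.path(dir, "het_mask.bed"))
    yaml::write_yaml(bundleParams(x), file.path(dir, "params.yaml"))
    invisible(dir)
}
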