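#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import GenomeInfoDb
#' @importFrom stats runif
#' @importFrom rtracklayer import export
#' @importFrom yaml write_yaml
NULL

#' BinnedTrack: a fixed-width binned fold-enrichment track
#'
#' A \code{BinnedTrack} holds one mark's fold-enrichment signal averaged
#' into fixed-width bins across a genome. Bin \code{i} (0-based) on a
#' chromosome of length \code{L} covers \code{[i*binWidth,
#' min((i+1)*binWidth, L))} in 0-based half-open coordinates, so the last
#' bin of each chromosome may be partial (bins clip at chromosome ends).
#' Values are non-negative; fold enrichment is a ratio, and uncovered
#' positions are taken to contribute zero signal.
#'
#' @slot genome A \link[GenomeInfoDb]{Seqinfo} giving the ordered
#'   chromosome names and lengths (the coordinate universe).
#' @slot binWidth Integer bin width in base pairs.
#' @slot values Named list, one numeric vector per chromosome in genome
#'   order; element \code{i} is the mean fold enrichment of bin
#'   \code{i - 1}. Per chromosome there are \code{ceiling(length /
#'   binWidth)} bins.
#' @slot mark Character scalar naming the mark (e.g. \code{"HP1a"},
#'   \code{"H3K9me3"}).
#'
#' @seealso \code{\link{readBedGraph}} to build one from a bedGraph file,
#'   \code{\link{binRanges}} for the bin coordinates as a
#'   \link[GenomicRanges]{GRanges}.
#' @export
setClass("BinnedTrack",
    representation(
        genome   = "Seqinfo",
        binWidth = "integer",
        values   = "list",
        mark     = "character"
    )
)

setValidity("BinnedTrack", function(object) {
    msg <- character()
    sl <- seqlengths(object@genome)
    if (length(sl) == 0L)
        msg <- c(msg, "genome has no chromosomes")
    if (anyNA(sl) || any(sl <= 0L))
        msg <- c(msg, "all chromosome lengths must be positive")
    if (length(object@binWidth) != 1L || is.na(object@binWidth) ||
        object@binWidth < 1L)
        msg <- c(msg, "binWidth must be a single positive integer")
    if (length(object@mark) != 1L || is.na(object@mark) ||
        !nzchar(object@mark))
        msg <- c(msg, "mark must be a non-empty string")
    if (!identical(names(object@values), seqnames(object@genome))) {
        msg <- c(msg, "values must be named by chromosome, in genome order")
    } else {
        expected <- as.integer(ceiling(sl / as.numeric(object@binWidth)))
        got <- lengths(object@values)
        if (!all(got == expected))
            msg <- c(msg, sprintf(
                "wrong bin count on %s",
                paste(names(got)[got != expected], collapse = ", ")))
        vals <- unlist(object@values, use.names = FALSE)
        if (anyNA(vals) || any(vals < 0))
            msg <- c(msg, "all bin values must be finite and >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a BinnedTrack
#'
#' @param genome A \link[GenomeInfoDb]{Seqinfo}, e.g. from
#'   \code{\link{readChromSizes}}.
#' @param values Named list of per-chromosome numeric vectors (one value
#'   per bin, chromosomes in genome order), or a single numeric vector if
#'   the genome has one chromosome.
#' @param binWidth Bin width in base pairs.
#' @param mark Mark name.
#' @return A \linkS4class{BinnedTrack}.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chrT", 20000)
#' tr <- BinnedTrack(si, rep(1, 4), binWidth = 5000, mark = "HP1a")
#' binWidth(tr)
#' @export
BinnedTrack <- function(genome, values, binWidth, mark) {
    if (is.numeric(values))
        values <- list(values)
    if (is.null(names(values)))
        names(values) <- seqnames(genome)
    values <- lapply(values, as.numeric)
    new("BinnedTrack", genome = genome,
        binWidth = as.integer(binWidth),
        values = values[seqnames(genome)], mark = mark)
}

#' Genome of a BinnedTrack or SimBundle
#' @param x A \linkS4class{BinnedTrack} or \linkS4class{SimBundle}.
#' @return A \link[GenomeInfoDb]{Seqinfo}.
#' @name seqinfo-methods
#' @aliases seqinfo,BinnedTrack-method seqinfo,SimBundle-method
#' @export
setMethod("seqinfo", "BinnedTrack", function(x) x@genome)

#' Bin width of a binned track
#' @param x A \linkS4class{BinnedTrack} or \linkS4class{SimBundle}.
#' @return Integer bin width in base pairs.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname binWidth
#' @export
setMethod("binWidth", "BinnedTrack", function(x) x@binWidth)

#' Mark name of a binned track
#' @param x A \linkS4class{BinnedTrack}.
#' @return Character scalar.
#' @export
setGeneric("markName", function(x) standardGeneric("markName"))

#' @rdname markName
#' @export
setMethod("markName", "BinnedTrack", function(x) x@mark)

#' Bin values of a binned track
#' @param x A \linkS4class{BinnedTrack}.
#' @param chrom Optional chromosome name; if omitted the full named list
#'   is returned.
#' @return Named list of numeric vectors, or one numeric vector.
#' @export
setGeneric("trackValues", function(x, chrom = NULL)
    standardGeneric("trackValues"))

#' @rdname trackValues
#' @export
setMethod("trackValues", "BinnedTrack", function(x, chrom = NULL) {
    if (is.null(chrom)) x@values else x@values[[chrom]]
})

setMethod("show", "BinnedTrack", function(object) {
    nb <- sum(lengths(object@values))
    cat("BinnedTrack '", object@mark, "': ",
        length(seqnames(object@genome)), " chromosome(s), ",
        nb, " bins of ", object@binWidth, " bp\n", sep = "")
    v <- unlist(object@values, use.names = FALSE)
    cat("  value range: [", format(min(v)), ", ", format(max(v)),
        "], mean ", format(mean(v), digits = 4), "\n", sep = "")
})

#' Bin coordinates of a track as a GRanges
#'
#' Returns the fixed-width bins underlying a \linkS4class{BinnedTrack}
#' (last bin per chromosome clipped at the chromosome end), in the same
#' order as the unlisted track values, with the bin values in the
#' \code{score} column.
#'
#' @param x A \linkS4class{BinnedTrack}.
#' @return A \link[GenomicRanges]{GRanges} with a \code{score} column.
#' @export
binRanges <- function(x) {
    stopifnot(is(x, "BinnedTrack"))
    bins <- tileGenome(seqinfo(x), tilewidth = binWidth(x),
                       cut.last.tile.in.chrom = TRUE)
    bins$score <- unlist(trackValues(x), use.names = FALSE)
    bins
}

#' SimBundle: synthetic multi-mark tracks with known ground truth
#'
#' Output container of \code{\link{simulateTracks}}: one
#' \linkS4class{BinnedTrack} per simulated mark, the planted co-enriched
#' intervals (truth), the planted constitutive-heterochromatin mask and
#' the simulation parameters. All tracks share genome and bin width.
#'
#' @slot tracks Named list of \linkS4class{BinnedTrack}, one per mark.
#' @slot truth \link[GenomicRanges]{GRanges} of planted intervals;
#'   \code{truth$sizeClass} holds the size-class label and
#'   \code{truth$marks} the marks each interval is enriched in.
#' @slot mask \link[GenomicRanges]{GRanges} of planted constitutive
#'   heterochromatin.
#' @slot params Named list of the simulation parameters as supplied.
#' @export
setClass("SimBundle",
    representation(
        tracks = "list",
        truth  = "GRanges",
        mask   = "GRanges",
        params = "list"
    )
)

setValidity("SimBundle", function(object) {
    msg <- character()
    if (!length(object@tracks) ||
        !all(vapply(object@tracks, is, logical(1), "BinnedTrack")))
        msg <- c(msg, "tracks must be a non-empty list of BinnedTrack")
    else {
        bw <- vapply(object@tracks, binWidth, integer(1))
        if (length(unique(bw)) != 1L)
            msg <- c(msg, "all tracks must share one bin width")
        g1 <- seqinfo(object@tracks[[1L]])
        same <- vapply(object@tracks,
                       function(t) identical(seqinfo(t), g1), logical(1))
        if (!all(same))
            msg <- c(msg, "all tracks must share one genome")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname seqinfo-methods
#' @export
setMethod("seqinfo", "SimBundle", function(x) seqinfo(x@tracks[[1L]]))

#' @rdname binWidth
#' @export
setMethod("binWidth", "SimBundle", function(x) binWidth(x@tracks[[1L]]))

#' Accessors for SimBundle components
#'
#' \code{bundleTracks} returns the named list of per-mark
#' \linkS4class{BinnedTrack}s; \code{bundleTruth} the planted intervals;
#' \code{bundleMask} the planted constitutive-heterochromatin mask;
#' \code{bundleParams} the simulation parameters.
#'
#' @param x A \linkS4class{SimBundle}.
#' @return See above.
#' @name bundle-accessors
NULL

#' @rdname bundle-accessors
#' @export
bundleTracks <- function(x) { stopifnot(is(x, "SimBundle")); x@tracks }

#' @rdname bundle-accessors
#' @export
bundleTruth <- function(x) { stopifnot(is(x, "SimBundle")); x@truth }

#' @rdname bundle-accessors
#' @export
bundleMask <- function(x) { stopifnot(is(x, "SimBundle")); x@mask }

#' @rdname bundle-accessors
#' @export
bundleParams <- function(x) { stopifnot(is(x, "SimBundle")); x@params }

setMethod("show", "SimBundle", function(object) {
    cat("SimBundle: ", length(object@tracks), " mark(s) [",
        paste(names(object@tracks), collapse = ", "), "], ",
        length(object@truth), " planted interval(s), ",
        length(object@mask), " mask interval(s)\n", sep = "")
    cat("  genome: ", sum(seqlengths(seqinfo(object))), " bp in ",
        length(seqnames(seqinfo(object))), " chromosome(s); bins of ",
        binWidth(object), " bp\n", sep = "")
})
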