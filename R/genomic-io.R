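# Text-format I/O. Coordinates are 0-based half-open throughout (BED and
# bedGraph native); Seqinfo/GRanges are 1-based internally and conversion
# happens only at the file boundary, via rtracklayer.

#' Read a chrom.sizes file
#'
#' Parses the UCSC two-column chrom.sizes format (chromosome name, then
#' length in bp, whitespace-delimited) into a
#' \link[GenomeInfoDb]{Seqinfo} in file order. Gzipped files are accepted
#' transparently.
#'
#' @param path Path to a chrom.sizes file.
#' @return A \link[GenomeInfoDb]{Seqinfo}.
#' @examples
#' f <- tempfile(); writeLines("chrT\t1000000", f)
#' readChromSizes(f)
#' @export
readChromSizes <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        stop("no chromosomes in '", path, "'")
    fields <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(fields) != 2L)
    if (length(bad))
        stop("malformed chrom.sizes line ", bad[1L], " in '", path,
             "': expected two columns")
    nm <- vapply(fields, `[`, character(1), 1L)
    len <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
    bad <- which(is.na(len) | len <= 0 | len != floor(len))
    if (length(bad))
        stop("chrom.sizes line ", bad[1L],
             ": length must be a positive integer")
    dup <- which(duplicated(nm))
    if (length(dup))
        stop("chrom.sizes line ", dup[1L], ": duplicate chromosome '",
             nm[dup[1L]], "'")
    Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

# Validate that a GRanges read from a file fits inside `genome`.
.checkBounds <- function(gr, genome, what) {
    sl <- seqlengths(genome)
    unknown <- setdiff(as.character(unique(seqnames(gr))), names(sl))
    if (length(unknown))
        stop(what, " on unknown chromosome: ",
             paste(unknown, collapse = ", "))
    ends <- end(gr)
    lim <- sl[as.character(seqnames(gr))]
    if (any(start(gr) < 1L) || any(ends > lim))
        stop(what, " outside chromosome bounds")
    gr
}

#' Read a bedGraph file into a binned fold-enrichment track
#'
#' Reads a 4-column bedGraph (chrom, start, end, value; 0-based
#' half-open) and averages the values into fixed-width bins, weighting
#' each record by the length of its overlap with the bin. Positions not
#' covered by any record contribute value 0 (fold-enrichment tracks are
#' dense; absence means no enrichment). The last bin of each chromosome
#' is clipped at the chromosome end and averaged over its actual width.
#'
#' @param path Path to a bedGraph file (gz accepted).
#' @param genome A \link[GenomeInfoDb]{Seqinfo} (see
#'   \code{\link{readChromSizes}}).
#' @param binWidth Bin width in bp (e.g. 5000 for the mammalian/fly
#'   presets, 200 for fission yeast).
#' @param mark Mark name to attach to the track; defaults to the file
#'   base name.
#' @return A \linkS4class{BinnedTrack}.
#' @export
readBedGraph <- function(path, genome, binWidth,
                         mark = sub("\\.(bedgraph|bg)(\\.gz)?$", "",
                                    basename(path), ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr)) {
        if (any(gr$score < 0))
            stop("negative fold-enrichment value in '", path, "'")
        .checkBounds(gr, genome, "bedGraph record")
    }
    seqlevels(gr) <- seqnames(genome)
    seqinfo(gr) <- genome
    cvg <- coverage(gr, weight = gr$score)
    bins <- tileGenome(genome, tilewidth = binWidth,
                       cut.last.tile.in.chrom = TRUE)
    bins <- GenomicRanges::binnedAverage(bins, cvg, "value")
    values <- split(bins$value, factor(as.character(seqnames(bins)),
                                       levels = seqnames(genome)))
    BinnedTrack(genome, as.list(values), binWidth = binWidth, mark = mark)
}

#' Read and write BED interval files
#'
#' \code{readBed} reads a BED3/BED4 file (0-based half-open) into a
#' \link[GenomicRanges]{GRanges} validated against \code{genome}; labels
#' in column 4, if present, are kept in the \code{name} column.
#' \code{writeBed} writes a GRanges back out (column 4 written when a
#' \code{name} column is present), so that write-then-read is the
#' identity on sorted, non-overlapping interval sets.
#'
#' @param path Path to a BED file (gz accepted on read).
#' @param genome A \link[GenomeInfoDb]{Seqinfo}.
#' @param x A \link[GenomicRanges]{GRanges} to write.
#' @return \code{readBed}: a GRanges; \code{writeBed}: \code{path},
#'   invisibly.
#' @export
readBed <- function(path, genome) {
    gr <- rtracklayer::import(path, format = "bed")
    if (any(width(gr) < 1L))
        stop("BED interval with start >= end in '", path, "'")
    .checkBounds(gr, genome, "BED interval")
    seqlevels(gr) <- seqnames(genome)
    seqinfo(gr) <- genome
    mcols(gr) <- mcols(gr)[, intersect("name", colnames(mcols(gr))),
                           drop = FALSE]
    gr
}

#' @rdname readBed
#' @export
writeBed <- function(x, path) {
    stopifnot(is(x, "GRanges"))
    if (any(width(x) < 1L))
        stop("cannot write zero-width interval")
    rtracklayer::export(x, path, format = "bed")
    invisible(path)
}

#' Write a binned track as bedGraph
#'
#' Emits one record per bin (bin mean as the value), the inverse of
#' \code{\link{readBedGraph}} up to binning.
#'
#' @param x A \linkS4class{BinnedTrack}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(x, path) {
    stopifnot(is(x, "BinnedTrack"))
    bins <- binRanges(x)
    rtracklayer::export(bins, path, format = "bedGraph")
    invisible(path)
}
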