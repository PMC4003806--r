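#' @importFrom utils read.delim write.table
#' @importFrom GenomicRanges GRanges seqnames start end
NULL

#' Read a marker allele-count table
#'
#' Parses the canonical tab-separated marker table with header columns
#' \code{CHROM}, \code{POS}, \code{SUPERIOR_COUNT}, \code{TOTAL_COUNT} and an
#' optional \code{QUAL} column.  Lines starting with \code{#} are ignored.
#' Counts must already be oriented toward the superior parent by the
#' upstream caller.
#'
#' @param path path to a TSV file (or a connection).
#' @return A \linkS4class{MarkerSet} covering all chromosomes in the file,
#'   sorted by chromosome and position.  An empty file (header only) yields
#'   an empty \code{MarkerSet}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("CHROM\tPOS\tSUPERIOR_COUNT\tTOTAL_COUNT",
#'              "chrI\t100\t12\t25", "chrI\t500\t30\t60"), tf)
#' readMarkerTable(tf)
#' @export
readMarkerTable <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                     stringsAsFactors = FALSE, check.names = FALSE)
    req <- c("CHROM", "POS", "SUPERIOR_COUNT", "TOTAL_COUNT")
    missing <- setdiff(req, colnames(df))
    if (length(missing))
        stop("marker table is missing required column(s): ",
             paste(missing, collapse = ", "))
    if (nrow(df) == 0L)
        return(MarkerSet(character(), integer(), integer(), integer()))
    line <- seq_len(nrow(df)) + 1L   # header is line 1
    pos <- suppressWarnings(as.integer(df$POS))
    sc <- suppressWarnings(as.integer(df$SUPERIOR_COUNT))
    tc <- suppressWarnings(as.integer(df$TOTAL_COUNT))
    bad <- which(is.na(pos) | is.na(sc) | is.na(tc))
    if (length(bad))
        stop("malformed marker row at line ", line[bad[1L]])
    bad <- which(pos < 1L)
    if (length(bad))
        stop("non-positive POS at line ", line[bad[1L]])
    bad <- which(sc < 0L | tc < 0L | sc > tc)
    if (length(bad))
        stop("SUPERIOR_COUNT/TOTAL_COUNT invalid at line ", line[bad[1L]])
    dup <- duplicated(paste(df$CHROM, pos))
    if (any(dup))
        stop("duplicate (CHROM, POS) at line ", line[which(dup)[1L]])
    qual <- if ("QUAL" %in% colnames(df)) as.numeric(df$QUAL) else NULL
    MarkerSet(df$CHROM, pos, sc, tc, qual = qual)
}

#' Write a marker allele-count table
#'
#' Inverse of [readMarkerTable()]: writes the canonical TSV so that
#' read-write-read round-trips exactly on the retained columns.
#'
#' @param markers a \linkS4class{MarkerSet}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeMarkerTable <- function(markers, path) {
    stopifnot(is(markers, "MarkerSet"))
    df <- data.frame(CHROM = as.character(seqnames(markers)),
                     POS = start(markers),
                     SUPERIOR_COUNT = superiorCount(markers),
                     TOTAL_COUNT = totalCount(markers),
                     check.names = FALSE)
    q <- markerQual(markers)
    if (!is.null(q)) df$QUAL <- q
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Coverage filter
#'
#' Retains marker sites whose total read count lies inside the inclusive
#' window \code{[minCov, maxCov]}.  The defaults reproduce the usual
#' real-data practice of ignoring sites with coverage below 20 or above 100,
#' where counts are dominated by sampling error or by collapsed repeats.
#'
#' @param markers a \linkS4class{MarkerSet}.
#' @param minCov,maxCov inclusive coverage bounds.
#' @return The filtered \code{MarkerSet} (possibly empty); order preserved.
#' @export
filterByCoverage <- function(markers, minCov = 20, maxCov = 100) {
    stopifnot(is(markers, "MarkerSet"), minCov <= maxCov)
    tc <- totalCount(markers)
    markers[tc >= minCov & tc <= maxCov]
}

#' Marker spacing filter
#'
#' Drops every site lying closer than \code{minSpacing} bp to its nearest
#' neighbor on the same chromosome, removing BOTH members of any too-close
#' pair.  Distances are measured on the input in a single pass, so the
#' filter is order-independent and idempotent.  Densely packed variants are
#' typically local misalignment artifacts.
#'
#' @param markers a \linkS4class{MarkerSet}.
#' @param minSpacing minimum allowed distance to the nearest neighbor (bp).
#' @return The filtered \code{MarkerSet}.
#' @export
filterBySpacing <- function(markers, minSpacing = 30) {
    stopifnot(is(markers, "MarkerSet"))
    if (length(markers) < 2L)
        return(markers)
    chrom <- as.character(seqnames(markers))
    pos <- start(markers)
    keep <- logical(length(markers))
    for (idx in split(seq_along(markers), chrom)) {
        p <- pos[idx]
        gapL <- c(Inf, diff(p))
        gapR <- c(diff(p), Inf)
        keep[idx] <- pmin(gapL, gapR) >= minSpacing
    }
    markers[keep]
}

#' Genotype-quality filter
#'
#' Retains sites whose upstream genotype quality is at least
#' \code{minQual}.
#'
#' @param markers a \linkS4class{MarkerSet} carrying a \code{qual} column.
#' @param minQual minimum quality score (default 40).
#' @return The filtered \code{MarkerSet}.
#' @export
filterByQuality <- function(markers, minQual = 40) {
    stopifnot(is(markers, "MarkerSet"))
    q <- markerQual(markers)
    if (is.null(q))
        stop("quality filter requested but markers carry no 'qual' column")
    markers[q >= minQual]
}

#' Write per-site posteriors as TSV
#'
#' Writes \code{CHROM}, \code{POS}, \code{SUPERIOR_COUNT},
#' \code{TOTAL_COUNT}, \code{POSTERIOR} (6 decimal places).
#'
#' @param posteriors a \linkS4class{PosteriorSet}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writePosteriorTable <- function(posteriors, path) {
    stopifnot(is(posteriors, "PosteriorSet"))
    df <- data.frame(CHROM = as.character(seqnames(posteriors)),
                     POS = start(posteriors),
                     SUPERIOR_COUNT = superiorCount(posteriors),
                     TOTAL_COUNT = totalCount(posteriors),
                     POSTERIOR = sprintf("%.6f", posterior(posteriors)),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write called regions as BED
#'
#' Emits 5-column BED (0-based, half-open): \code{chromStart} is the first
#' marker position minus 1, \code{chromEnd} the last marker position; the
#' score column is \code{round(1000 * maxPosterior)}.
#'
#' @param regions a \link[GenomicRanges]{GRanges} of linked regions as
#'   returned by [callLinkedRegions()].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeRegionsBed <- function(regions, path) {
    stopifnot(is(regions, "GRanges"))
    if (length(regions) == 0L) {
        cat("", file = path)
        return(invisible(path))
    }
    lines <- sprintf("%s\t%d\t%d\tregion_%d\t%d",
                     as.character(seqnames(regions)),
                     start(regions) - 1L, end(regions),
                     seq_along(regions),
                     as.integer(round(1000 * regions$maxPosterior)))
    writeLines(lines, path)
    invisible(path)
}
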