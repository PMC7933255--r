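## Segment-table IO (Sequenza-style TSV, 1-based closed coordinates).

.SEG_SYNONYMS <- list(
    chromosome = c("chromosome", "chrom", "chr"),
    start = c("start", "start.pos", "start_pos", "pos.start"),
    end = c("end", "end.pos", "end_pos", "pos.end"),
    major_cn = c("major_cn", "major", "a", "cn_major"),
    minor_cn = c("minor_cn", "minor", "b", "cn_minor"),
    total_cn = c("total_cn", "total", "cnt", "cn_total"))

.matchColumn <- function(header, field) {
    i <- match(.SEG_SYNONYMS[[field]], tolower(header))
    i <- i[!is.na(i)]
    if (length(i)) i[1L] else NA_integer_
}

## first overlapping pair among 1-based closed intervals of one sample;
## returns NULL or a description of the offending overlap
.findOverlapViolation <- function(chrom, start, end) {
    for (ch in unique(chrom)) {
        i <- which(chrom == ch)
        if (length(i) < 2L) next
        o <- order(start[i])
        s <- start[i][o]; e <- end[i][o]
        bad <- which(s[-1L] <= e[-length(e)])
        if (length(bad)) {
            b <- bad[1L]
            return(sprintf("%s:%d-%d overlaps %s:%d-%d (shared interval %d-%d)",
                           ch, s[b], e[b], ch, s[b + 1L], e[b + 1L],
                           s[b + 1L], min(e[b], e[b + 1L])))
        }
    }
    NULL
}

#' Read a Sequenza-style allele-specific segment table
#'
#' Reads a tab-separated table with 1-based closed coordinates and a
#' header naming at least chromosome/start/end plus either the
#' (major, minor) or the total copy-number column (Sequenza's
#' \code{chromosome/start.pos/end.pos/CNt/A/B} names are recognised).
#' \code{"chr"} prefixes are accepted and stripped. Copy-number fields
#' that fail numeric parsing (or the literal \code{NA} / empty field)
#' become undetermined rows rather than being dropped; row order is
#' preserved.
#'
#' @param file path (or connection) to the TSV.
#' @param sampleId sample identifier to attach.
#' @return A [SegmentTable-class].
#' @seealso [writeSegmentTable()]
#' @export
readSegmentTable <- function(file, sampleId) {
    df <- utils::read.delim(file, header = TRUE, sep = "\t",
                            colClasses = "character",
                            check.names = FALSE,
                            stringsAsFactors = FALSE)
    header <- names(df)
    idx <- vapply(names(.SEG_SYNONYMS), .matchColumn, 0L, header = header)
    for (f in c("chromosome", "start", "end"))
        if (is.na(idx[[f]]))
            .stopf("segment table is missing mandatory column '%s'", f)
    hasAB <- !is.na(idx[["major_cn"]]) && !is.na(idx[["minor_cn"]])
    if (!hasAB && is.na(idx[["total_cn"]]))
        .stopf(paste0("segment table must name either 'major_cn'/'minor_cn'",
                      " (or Sequenza A/B) or 'total_cn' (CNt)"))
    if (nrow(df) == 0L) {
        gr0 <- GRanges()
        mcols(gr0) <- DataFrame(majorCN = integer(0), minorCN = integer(0),
                                totalCN = integer(0))
        return(new("SegmentTable", sampleId = as.character(sampleId),
                   segments = gr0))
    }
    chrom <- .chrNorm(df[[idx[["chromosome"]]]])
    start <- suppressWarnings(as.numeric(df[[idx[["start"]]]]))
    end <- suppressWarnings(as.numeric(df[[idx[["end"]]]]))
    if (anyNA(start) || anyNA(end))
        .stopf("unparseable start/end coordinate at row %d",
               which(is.na(start) | is.na(end))[1L])
    if (any(start >= end))
        .stopf("start >= end at %s:%d-%d", chrom[start >= end][1L],
               start[start >= end][1L], end[start >= end][1L])
    maj <- if (hasAB) .parseIntegerCN(df[[idx[["major_cn"]]]])
           else rep(NA_integer_, nrow(df))
    mnr <- if (hasAB) .parseIntegerCN(df[[idx[["minor_cn"]]]])
           else rep(NA_integer_, nrow(df))
    tot <- if (!is.na(idx[["total_cn"]])) .parseIntegerCN(df[[idx[["total_cn"]]]])
           else maj + mnr
    ## a half-parsed allele pair is undetermined as a pair
    half <- xor(is.na(maj), is.na(mnr))
    maj[half] <- NA_integer_; mnr[half] <- NA_integer_
    both <- !is.na(maj) & !is.na(mnr)
    if (any(mnr[both] > maj[both])) {
        i <- which(both)[which(mnr[both] > maj[both])[1L]]
        .stopf("minor CN %d exceeds major CN %d at %s:%d-%d",
               mnr[i], maj[i], chrom[i], start[i], end[i])
    }
    all3 <- both & !is.na(tot)
    if (any(tot[all3] != maj[all3] + mnr[all3])) {
        i <- which(all3)[which(tot[all3] != maj[all3] + mnr[all3])[1L]]
        .stopf("total CN %d != major %d + minor %d at %s:%d-%d",
               tot[i], maj[i], mnr[i], chrom[i], start[i], end[i])
    }
    tot[both & is.na(tot)] <- maj[both & is.na(tot)] + mnr[both & is.na(tot)]
    viol <- .findOverlapViolation(chrom, start, end)
    if (!is.null(viol)) .stopf("overlapping segments: %s", viol)
    gr <- GRanges(chrom, IRanges(start, end),
                  majorCN = maj, minorCN = mnr, totalCN = tot)
    new("SegmentTable", sampleId = as.character(sampleId), segments = gr)
}

#' Write a segment table
#'
#' Serialises a [SegmentTable-class] back to the tab-separated dialect
#' read by [readSegmentTable()] (1-based closed coordinates, \code{NA}
#' for undetermined copy numbers), reproducing all parsed fields exactly.
#'
#' @param segTable a [SegmentTable-class].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeSegmentTable <- function(segTable, file) {
    stopifnot(is(segTable, "SegmentTable"))
    gr <- segments(segTable)
    df <- data.frame(chromosome = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr),
                     total_cn = mcols(gr)$totalCN,
                     major_cn = mcols(gr)$majorCN,
                     minor_cn = mcols(gr)$minorCN)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(file)
}
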