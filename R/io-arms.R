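## Chromosome-arm definitions from UCSC cytoBand files.

#' Default arm exclusion list
#'
#' Acrocentric short arms whose copy number is not modelled at the arm
#' level; together with the sex chromosomes this leaves 39 modelled
#' autosomal arms.
#' @export
DEFAULT_EXCLUDED_ARMS <- c("13p", "14p", "15p", "21p", "22p")

#' Read chromosome-arm definitions from a cytoBand file
#'
#' Parses UCSC cytoBand lines (\code{chrom, start, end, band, stain};
#' 0-based half-open) and derives one interval per arm by splitting each
#' chromosome at its centromere, i.e. at the boundary between the p- and
#' q-side \code{acen} bands. Coordinates are converted to the package's
#' internal 1-based closed convention. The default exclusion list flags
#' the acrocentric short arms, and sex-chromosome arms are excluded from
#' modelling by default because their copy-number interpretation differs
#' by sex.
#'
#' @param file path to a cytoBand-format file (no header).
#' @param excludeArms arm ids flagged \code{included = FALSE}.
#' @param excludeSex flag X/Y arms \code{included = FALSE} (default TRUE).
#' @return An [ArmDefinitions-class].
#' @seealso [hg19Arms()], [writeArmDefinitions()]
#' @export
readArmDefinitions <- function(file, excludeArms = DEFAULT_EXCLUDED_ARMS,
                               excludeSex = TRUE) {
    df <- utils::read.delim(file, header = FALSE, sep = "\t",
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 5L)
        .stopf("cytoBand input must have 5 columns (chrom, start, end, band, stain)")
    names(df)[1:5] <- c("chrom", "start", "end", "band", "stain")
    df$chrom <- .chrNorm(df$chrom)
    df$start <- as.numeric(df$start)
    df$end <- as.numeric(df$end)
    chroms <- unique(df$chrom)
    recs <- lapply(chroms, function(ch) {
        b <- df[df$chrom == ch, , drop = FALSE]
        acen <- b[b$stain == "acen", , drop = FALSE]
        if (nrow(acen) == 0L)
            .stopf("chromosome %s has no centromere (acen) band", ch)
        qacen <- acen[grepl("^q", acen$band), , drop = FALSE]
        split0 <- if (nrow(qacen)) min(qacen$start) else max(acen$end)
        lo <- min(b$start); hi <- max(b$end)
        out <- list()
        if (split0 > lo)
            out$p <- c(start0 = lo, end0 = split0)
        if (hi > split0)
            out$q <- c(start0 = split0, end0 = hi)
        data.frame(chrom = ch, arm = names(out),
                   start0 = vapply(out, `[[`, 0, "start0"),
                   end0 = vapply(out, `[[`, 0, "end0"),
                   stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    armId <- paste0(recs$chrom, recs$arm)
    included <- !(armId %in% excludeArms)
    if (excludeSex) included <- included & !(recs$chrom %in% c("X", "Y"))
    gr <- GRanges(recs$chrom,
                  IRanges(recs$start0 + 1, recs$end0),  # to 1-based closed
                  armId = armId, included = included)
    new("ArmDefinitions", arms = gr)
}

#' Write arm definitions as cytoBand-format lines
#'
#' Serialises an [ArmDefinitions-class] to a minimal cytoBand dialect
#' (four bands per chromosome with a two-band centromere), such that
#' [readArmDefinitions()] recovers the identical arm intervals.
#'
#' @param armDefs an [ArmDefinitions-class].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeArmDefinitions <- function(armDefs, file) {
    stopifnot(is(armDefs, "ArmDefinitions"))
    gr <- arms(armDefs)
    id <- mcols(gr)$armId
    chrom <- sub("[pq]$", "", id)
    arm <- sub("^.*(p|q)$", "\\1", id)
    lines <- character(0)
    for (ch in unique(chrom)) {
        p <- which(chrom == ch & arm == "p")
        q <- which(chrom == ch & arm == "q")
        if (!length(p) || !length(q))
            .stopf("chromosome %s lacks a %s arm; cannot serialise", ch,
                   if (length(p)) "q" else "p")
        p0 <- as.integer(start(gr)[p] - 1)  # back to 0-based half-open
        s0 <- as.integer(end(gr)[p])        # split point
        e0 <- as.integer(end(gr)[q])
        if (s0 != start(gr)[q] - 1)
            .stopf("arms of chromosome %s are not contiguous", ch)
        lines <- c(lines,
            sprintf("chr%s\t%d\t%d\tp11\tgneg", ch, p0, s0 - 1),
            sprintf("chr%s\t%d\t%d\tp11.1\tacen", ch, s0 - 1, s0),
            sprintf("chr%s\t%d\t%d\tq11\tacen", ch, s0, s0 + 1),
            sprintf("chr%s\t%d\t%d\tq11.2\tgneg", ch, s0 + 1, e0))
    }
    writeLines(lines, file)
    invisible(file)
}

#' Bundled hg19 chromosome-arm definitions
#'
#' Arm boundaries for hg19: exact chromosome lengths with centromere
#' split points at cytogenetic-band resolution, stored as an
#' arm-resolution cytoBand file under \code{inst/extdata}. The default
#' inclusion rules leave the 39 modelled autosomal arms.
#'
#' @inheritParams readArmDefinitions
#' @return An [ArmDefinitions-class].
#' @examples
#' sum(S4Vectors::mcols(arms(hg19Arms()))$included)  # 39
#' @export
hg19Arms <- function(excludeArms = DEFAULT_EXCLUDED_ARMS,
                     excludeSex = TRUE) {
    readArmDefinitions(system.file("extdata", "cytoBand_hg19_minimal.tsv",
                                   package = "WGDinfer", mustWork = TRUE),
                       excludeArms = excludeArms, excludeSex = excludeSex)
}
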