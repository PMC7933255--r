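#' Detect mirrored allelic imbalance between two samples
#'
#' Mirrored allelic imbalance is the same region imbalanced in two
#' samples but with opposite parental alleles favoured, visible as
#' reflected B-allele frequencies (BAFs) of shared heterozygous SNPs.
#' The mirror score is the negated Pearson correlation of the centred
#' BAFs \code{(baf - 0.5)} across shared SNPs; the call requires both
#' samples imbalanced (mean \code{|baf - 0.5|} above
#' \code{imbalanceThreshold}) and a score above \code{scoreThreshold}.
#' Both thresholds are tuning parameters of this package.
#'
#' @param bafA,bafB BAF \code{data.frame}s (see [readBafTable()]).
#' @param region restrict to a region: a chromosome name (e.g.
#'   \code{"10"} or \code{"chr10"}), a \code{GRanges}, or \code{NULL}
#'   for all shared SNPs.
#' @param imbalanceThreshold minimum mean \code{|baf - 0.5|} per sample.
#' @param scoreThreshold minimum mirror score for a mirrored call.
#' @param minSnps minimum number of shared SNPs (default 10).
#' @return list with \code{mirrorScore}, \code{isMirrored},
#'   \code{nSnps}, \code{meanDevA}, \code{meanDevB}.
#' @export
detectMirroredAI <- function(bafA, bafB, region = NULL,
                             imbalanceThreshold = 0.1,
                             scoreThreshold = 0.5, minSnps = 10L) {
    restrict <- function(df) {
        if (is.null(region)) return(df)
        if (is(region, "GRanges")) {
            gr <- GRanges(df$chromosome, IRanges(df$position, width = 1))
            df[overlapsAny(gr, region), , drop = FALSE]
        } else {
            df[df$chromosome %in% .chrNorm(region), , drop = FALSE]
        }
    }
    a <- restrict(bafA); b <- restrict(bafB)
    m <- merge(a[, c("chromosome", "position", "baf")],
               b[, c("chromosome", "position", "baf")],
               by = c("chromosome", "position"), suffixes = c("A", "B"))
    if (nrow(m) < minSnps)
        .stopf("only %d shared heterozygous SNPs in region (need >= %d)",
               nrow(m), minSnps)
    devA <- m$bafA - 0.5; devB <- m$bafB - 0.5
    score <- if (stats::sd(devA) == 0 || stats::sd(devB) == 0) NA_real_
             else -stats::cor(devA, devB)
    meanDevA <- mean(abs(devA)); meanDevB <- mean(abs(devB))
    mirrored <- !is.na(score) && meanDevA > imbalanceThreshold &&
        meanDevB > imbalanceThreshold && score > scoreThreshold
    list(mirrorScore = score, isMirrored = mirrored, nSnps = nrow(m),
         meanDevA = meanDevA, meanDevB = meanDevB)
}
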