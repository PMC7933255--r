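## Readers/writers for codon-usage, mutation, neoantigen and BAF tables.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read a codon-usage table
#'
#' Two-column tab- or whitespace-separated text mapping codons to
#' relative frequencies (any positive scale, e.g. per-1000 counts).
#' RNA alphabets (U) are accepted. Stop codons are permitted in the
#' input but dropped; the remaining sense-codon frequencies are
#' normalised to sum to 1.
#'
#' @param file path to the table; a header line is detected and skipped.
#' @return named numeric vector of normalised sense-codon frequencies.
#' @export
readCodonUsage <- function(file) {
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) .stopf("empty codon usage table")
    parts <- strsplit(trimws(lines), "[\t ]+")
    codon <- toupper(chartr("U", "T", vapply(parts, `[`, "", 1L)))
    valid <- names(Biostrings::GENETIC_CODE)
    ## a header line has a non-codon first field AND a non-numeric second
    if (!codon[1L] %in% valid &&
        is.na(suppressWarnings(as.numeric(parts[[1L]][2L])))) {
        parts <- parts[-1L]; codon <- codon[-1L]
        if (!length(codon)) .stopf("codon usage table has no data rows")
    }
    freq <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    if (anyNA(freq))
        .stopf("unparseable frequency for codon '%s'", codon[which(is.na(freq))[1L]])
    bad <- setdiff(codon, valid)
    if (length(bad))
        .stopf("'%s' is not a codon of the standard genetic code", bad[1L])
    if (any(freq < 0)) .stopf("negative codon frequency")
    keep <- !(codon %in% .STOP_CODONS)
    codon <- codon[keep]; freq <- freq[keep]
    if (anyDuplicated(codon)) .stopf("duplicate codon '%s'",
                                     codon[duplicated(codon)][1L])
    if (!length(freq) || sum(freq) <= 0)
        .stopf("codon usage frequencies are all zero")
    out <- freq / sum(freq)
    names(out) <- codon
    out
}

#' Bundled human codon-usage frequencies
#'
#' Standard human codon usage (GenBank-derived per-1000 frequencies),
#' normalised over the 61 sense codons.
#' @return named numeric vector of length 61.
#' @export
humanCodonUsage <- function() {
    readCodonUsage(system.file("extdata", "codon_usage_human.tsv",
                               package = "WGDinfer", mustWork = TRUE))
}

#' Read a per-mutation table
#'
#' Tab-separated with header columns \code{mutation_id, chromosome,
#' position, gene, consequence, present_in} and optional \code{ccf}.
#' \code{consequence} must be \code{synonymous} or \code{nonsynonymous};
#' \code{present_in} is a comma-separated list of sample ids (non-empty);
#' \code{ccf}, when present, must lie in [0, 1].
#'
#' @param file path to the TSV.
#' @return A \code{GRanges} (width-1 positions) with metadata columns
#'   \code{mutationId}, \code{gene}, \code{consequence},
#'   \code{presentIn} (a \code{CharacterList}) and \code{ccf}.
#' @export
readMutationTable <- function(file) {
    df <- utils::read.delim(file, header = TRUE, sep = "\t",
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    need <- c("mutation_id", "chromosome", "position", "gene",
              "consequence", "present_in")
    miss <- setdiff(need, tolower(names(df)))
    if (length(miss)) .stopf("mutation table missing column '%s'", miss[1L])
    names(df) <- tolower(names(df))
    pos <- suppressWarnings(as.numeric(df$position))
    if (nrow(df) && anyNA(pos)) .stopf("unparseable mutation position")
    cons <- tolower(df$consequence)
    ok <- cons %in% c("synonymous", "nonsynonymous")
    if (!all(ok))
        .stopf("consequence must be synonymous/nonsynonymous, got '%s'",
               df$consequence[!ok][1L])
    pres <- strsplit(df$present_in, ",", fixed = TRUE)
    pres <- lapply(pres, function(x) trimws(x[nzchar(trimws(x))]))
    if (any(lengths(pres) == 0L) && nrow(df))
        .stopf("mutation '%s' has an empty present_in set",
               df$mutation_id[lengths(pres) == 0L][1L])
    ccf <- if ("ccf" %in% names(df))
        suppressWarnings(as.numeric(df$ccf)) else rep(NA_real_, nrow(df))
    if (any(!is.na(ccf) & (ccf < 0 | ccf > 1)))
        .stopf("ccf outside [0, 1]")
    gr <- GRanges(.chrNorm(df$chromosome), IRanges(pos, width = 1),
                  mutationId = df$mutation_id, gene = df$gene,
                  consequence = cons, ccf = ccf)
    mcols(gr)$presentIn <- IRanges::CharacterList(pres)
    gr
}

#' Write a per-mutation table
#'
#' @param mutations a mutation \code{GRanges} as returned by
#'   [readMutationTable()].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeMutationTable <- function(mutations, file) {
    mc <- mcols(mutations)
    df <- data.frame(mutation_id = mc$mutationId,
                     chromosome = as.character(seqnames(mutations)),
                     position = start(mutations), gene = mc$gene,
                     consequence = mc$consequence,
                     present_in = vapply(mc$presentIn, paste, "",
                                         collapse = ","),
                     ccf = mc$ccf)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(file)
}

#' Read a predicted-neoantigen table
#'
#' Tab-separated with header columns \code{mutation_id, hla_allele,
#' binding_rank, expressed}. Binding ranks are NetMHC-style percentile
#' ranks in (0, 100].
#'
#' @param file path to the TSV.
#' @return \code{data.frame} with columns \code{mutationId},
#'   \code{hlaAllele}, \code{bindingRank}, \code{expressed}.
#' @export
readNeoantigenTable <- function(file) {
    df <- utils::read.delim(file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("mutation_id", "hla_allele", "binding_rank", "expressed")
    miss <- setdiff(need, tolower(names(df)))
    if (length(miss)) .stopf("neoantigen table missing column '%s'", miss[1L])
    names(df) <- tolower(names(df))
    rank <- as.numeric(df$binding_rank)
    if (any(is.na(rank) | rank <= 0 | rank > 100))
        .stopf("binding_rank must lie in (0, 100]")
    data.frame(mutationId = as.character(df$mutation_id),
               hlaAllele = as.character(df$hla_allele),
               bindingRank = rank,
               expressed = as.logical(df$expressed),
               stringsAsFactors = FALSE)
}

#' Write a predicted-neoantigen table
#' @param neo data.frame as returned by [readNeoantigenTable()].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeNeoantigenTable <- function(neo, file) {
    df <- data.frame(mutation_id = neo$mutationId,
                     hla_allele = neo$hlaAllele,
                     binding_rank = neo$bindingRank,
                     expressed = neo$expressed)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read a B-allele-frequency table
#'
#' Tab-separated with header columns \code{chromosome, position, baf}
#' for germline-heterozygous SNPs of one sample.
#'
#' @param file path to the TSV.
#' @param sampleId sample identifier to attach.
#' @return \code{data.frame} with columns \code{sampleId},
#'   \code{chromosome}, \code{position}, \code{baf}.
#' @export
readBafTable <- function(file, sampleId) {
    df <- utils::read.delim(file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("chromosome", "position", "baf")
    miss <- setdiff(need, tolower(names(df)))
    if (length(miss)) .stopf("BAF table missing column '%s'", miss[1L])
    names(df) <- tolower(names(df))
    baf <- as.numeric(df$baf)
    if (any(is.na(baf) | baf < 0 | baf > 1))
        .stopf("baf values must lie in [0, 1]")
    data.frame(sampleId = as.character(sampleId),
               chromosome = .chrNorm(df$chromosome),
               position = as.numeric(df$position), baf = baf,
               stringsAsFactors = FALSE)
}

#' Write a B-allele-frequency table
#' @param baf data.frame as returned by [readBafTable()].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeBafTable <- function(baf, file) {
    utils::write.table(baf[, c("chromosome", "position", "baf")], file,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}
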