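# shared internal helpers

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## normalise chromosome labels: accept and strip "chr" prefixes
.chrNorm <- function(x) sub("^chr", "", as.character(x))

.isCount <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
    x >= 0 && x == round(x)

## parse a numeric column leniently: non-numeric tokens and empty fields
## become NA instead of aborting the read
.parseIntegerCN <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "NA", "na", ".")] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(v) & (v < 0 | v != round(v))
    v[bad] <- NA_real_
    as.integer(round(v))
}

## allelic state levels used throughout
.AI_STATES <- c("balanced", "ai_no_loh", "ai_loh", "undetermined")
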