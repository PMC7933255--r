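#' Predicted neoantigens lost per LOH event
#'
#' A neoantigenic mutation counts as lost to an LOH event when its
#' position lies inside the event interval and the mutation is absent
#' from every member late sample of the event. Per-event counts and the
#' patient total (distinct mutations across events) are returned;
#' \code{expressedOnly} restricts to neoantigens flagged as arising in
#' expressed genes.
#'
#' @param events event \code{GRanges} from [mergeLOHEvents()] (with the
#'   \code{memberSamples} column).
#' @param neoantigens neoantigen \code{data.frame} (see
#'   [readNeoantigenTable()]). Every \code{mutationId} must exist in
#'   \code{mutations}.
#' @param mutations mutation \code{GRanges} (see [readMutationTable()]).
#' @param expressedOnly count only expressed neoantigens (default TRUE).
#' @return list with \code{perEvent} (integer vector, one per event),
#'   \code{patientTotal}, and \code{lostIds} (list of mutation ids per
#'   event).
#' @export
neoantigenLosses <- function(events, neoantigens, mutations,
                             expressedOnly = TRUE) {
    stopifnot(is(events, "GRanges"))
    ids <- mcols(mutations)$mutationId
    dangling <- setdiff(neoantigens$mutationId, ids)
    if (length(dangling))
        .stopf("neoantigen table references unknown mutation_id '%s'",
               dangling[1L])
    neo <- neoantigens
    if (expressedOnly) neo <- neo[neo$expressed, , drop = FALSE]
    neoMut <- mutations[ids %in% unique(neo$mutationId)]
    memb <- mcols(events)$memberSamples
    perEvent <- integer(length(events))
    lostIds <- vector("list", length(events))
    for (i in seq_along(events)) {
        cand <- neoMut[overlapsAny(neoMut, events[i])]
        if (!length(cand)) next
        absent <- vapply(mcols(cand)$presentIn, function(p)
            !any(memb[[i]] %in% p), TRUE)
        perEvent[i] <- sum(absent)
        lostIds[[i]] <- mcols(cand)$mutationId[absent]
    }
    list(perEvent = perEvent,
         patientTotal = length(unique(unlist(lostIds))),
         lostIds = lostIds)
}
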