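#' @include AllClasses.R AllGenerics.R
NULL

## ---- DomainHits ----

#' @rdname DomainHits-accessors
setMethod("seqId", "DomainHits", function(x) x@hits$seq_id)
#' @rdname DomainHits-accessors
setMethod("familyAcc", "DomainHits", function(x) x@hits$family_acc)
#' @rdname DomainHits-accessors
setMethod("seqEvalue", "DomainHits", function(x) x@hits$seq_evalue)
#' @rdname DomainHits-accessors
setMethod("domEvalue", "DomainHits", function(x) x@hits$dom_evalue)
#' @rdname DomainHits-accessors
setMethod("bitScore", "DomainHits", function(x) x@hits$bit_score)
#' @rdname DomainHits-accessors
setMethod("biasScore", "DomainHits", function(x) x@hits$bias_score)
#' @rdname DomainHits-accessors
setMethod("aliStart", "DomainHits", function(x) x@hits$ali_start)
#' @rdname DomainHits-accessors
setMethod("aliEnd", "DomainHits", function(x) x@hits$ali_end)
#' @rdname DomainHits-accessors
setMethod("envStart", "DomainHits", function(x) x@hits$env_start)
#' @rdname DomainHits-accessors
setMethod("envEnd", "DomainHits", function(x) x@hits$env_end)

#' @rdname DomainHits-accessors
setMethod("hitKeys", "DomainHits", function(x) {
    if (length(x) == 0L)
        return(character())
    keys <- sprintf("%s|%s|%d-%d", x@hits$seq_id, x@hits$family_acc,
                    x@hits$ali_start, x@hits$ali_end)
    make.unique(keys, sep = "#")
})

#' @describeIn DomainHits number of hits
#' @param x a DomainHits object
#' @export
setMethod("length", "DomainHits", function(x) nrow(x@hits))

#' @describeIn DomainHits subset hits by row index or logical vector
#' @param i row index
#' @param j,drop,... ignored
#' @export
setMethod("[", "DomainHits", function(x, i, j, ..., drop = FALSE) {
    DomainHits(x@hits[i, , drop = FALSE])
})

#' @exportS3Method base::as.data.frame
as.data.frame.DomainHits <- function(x, ...) x@hits

setMethod("show", "DomainHits", function(object) {
    cat(sprintf("DomainHits with %d hit(s), %d sequence(s), %d family(ies)\n",
                length(object),
                length(unique(object@hits$seq_id)),
                length(unique(object@hits$family_acc))))
    if (length(object) > 0L)
        print(utils::head(object@hits, 5L))
    if (length(object) > 5L)
        cat("...\n")
})

## ---- ClanMap ----

#' @rdname effectiveClan
setMethod("effectiveClan", "ClanMap", function(map, families) {
    families <- as.character(families)
    idx <- match(families, map@family)
    clan <- map@clan[idx]
    singleton <- is.na(idx) | is.na(clan)
    clan[singleton] <- paste0("SINGLETON:", families[singleton])
    clan
})

#' @describeIn ClanMap number of families in the map
#' @param x a ClanMap
#' @export
setMethod("length", "ClanMap", function(x) length(x@family))

#' @exportS3Method base::as.data.frame
as.data.frame.ClanMap <- function(x, ...)
    data.frame(family_acc = x@family, clan_acc = x@clan)

setMethod("show", "ClanMap", function(object) {
    cat(sprintf("ClanMap: %d family(ies), %d in named clans, %d clanless\n",
                length(object@family), sum(!is.na(object@clan)),
                sum(is.na(object@clan))))
})

## ---- FeatureTracks ----

#' @exportS3Method base::as.data.frame
as.data.frame.FeatureTracks <- function(x, ...) x@segments

#' @describeIn FeatureTracks number of (normalized) segments
#' @param x a FeatureTracks object
#' @export
setMethod("length", "FeatureTracks", function(x) nrow(x@segments))

setMethod("show", "FeatureTracks", function(object) {
    df <- object@segments
    cat(sprintf("FeatureTracks: %d segment(s) on %d sequence(s)\n",
                nrow(df), length(unique(df$seq_id))))
    if (nrow(df) > 0L)
        print(table(df$kind))
})

#' Extract the segments of one sequence and kind as an IRanges
#'
#' @param tracks a \linkS4class{FeatureTracks}.
#' @param seq_id sequence identifier.
#' @param kind one of \code{"coiled_coil"}, \code{"transmembrane"},
#'   \code{"disorder"}.
#' @return an \code{IRanges} (possibly empty) of predicted segments.
#' @export
trackSegments <- function(tracks, seq_id, kind) {
    stopifnot(is(tracks, "FeatureTracks"))
    if (!kind %in% .TRACK_KINDS)
        stop("unknown track kind '", kind, "'")
    df <- tracks@segments
    sel <- df$seq_id == seq_id & df$kind == kind
    IRanges::IRanges(df$start[sel], df$end[sel])
}

## ---- OverlapPairs ----

#' @exportS3Method base::as.data.frame
as.data.frame.OverlapPairs <- function(x, ...) x@pairs

#' @describeIn OverlapPairs number of qualifying pairs
#' @param x an OverlapPairs object
#' @export
setMethod("length", "OverlapPairs", function(x) nrow(x@pairs))

setMethod("show", "OverlapPairs", function(object) {
    df <- object@pairs
    nd <- length(unique(c(df$key_a, df$key_b)))
    cat(sprintf(
        "OverlapPairs: %d pair(s) among %d domain(s) (min coverage %.2f)\n",
        nrow(df), nd, object@min_frac))
})

## ---- AssignmentResult ----

#' Accessors for AssignmentResult
#'
#' \code{assignments} returns the per-domain attribution table (columns
#' \code{key}, \code{family_acc}, \code{seq_id}); \code{selectionOrder} the
#' per-family selection record (columns \code{family_acc}, \code{n_domains}).
#'
#' @param x an \linkS4class{AssignmentResult}.
#' @return a \code{data.frame}.
#' @name assignmentAccessors
NULL

#' @rdname assignmentAccessors
setMethod("assignments", "AssignmentResult", function(x) x@assignments)
#' @rdname assignmentAccessors
setMethod("selectionOrder", "AssignmentResult", function(x) x@selection_order)

setMethod("show", "AssignmentResult", function(object) {
    cat(sprintf(
        "AssignmentResult (%s): %d domain(s) attributed to %d family(ies)\n",
        object@strategy, nrow(object@assignments),
        length(unique(object@assignments$family_acc))))
})
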