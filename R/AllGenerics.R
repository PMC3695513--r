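#' @include AllClasses.R
NULL

#' Accessors for DomainHits
#'
#' Column accessors returning per-hit vectors, plus \code{hitKeys}, which
#' returns a stable unique key per hit
#' (\code{<seq_id>|<family_acc>|<ali_start>-<ali_end>}, disambiguated for
#' exact duplicates). Keys identify individual domains through overlap
#' detection and assignment.
#'
#' @param x a \linkS4class{DomainHits} object.
#' @return a vector with one element per hit.
#' @name DomainHits-accessors
#' @aliases seqId familyAcc seqEvalue domEvalue bitScore biasScore
#'   aliStart aliEnd envStart envEnd hitKeys
NULL

#' @rdname DomainHits-accessors
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))
#' @rdname DomainHits-accessors
#' @export
setGeneric("familyAcc", function(x) standardGeneric("familyAcc"))
#' @rdname DomainHits-accessors
#' @export
setGeneric("seqEvalue", function(x) standardGeneric("seqEvalue"))
#' @rdname DomainHits-accessors
#' @export
setGeneric("domEvalue", function(x) standardGeneric("domEvalue"))
#' @rdname DomainHits-accessors
#' @export
setGeneric("bitScore", function(x) standardGeneric("bitScore"))
#' @rdname DomainHits-accessors
#' @export
setGeneric("biasScore", function(x) standardGeneric("biasScore"))
#' @rdname DomainHits-accessors
#' @export
setGeneric("aliStart", function(x) standardGeneric("aliStart"))
#' @rdname DomainHits-accessors
#' @export
setGeneric("aliEnd", function(x) standardGeneric("aliEnd"))
#' @rdname DomainHits-accessors
#' @export
setGeneric("envStart", function(x) standardGeneric("envStart"))
#' @rdname DomainHits-accessors
#' @export
setGeneric("envEnd", function(x) standardGeneric("envEnd"))
#' @rdname DomainHits-accessors
#' @export
setGeneric("hitKeys", function(x) standardGeneric("hitKeys"))

#' Resolve the effective clan of families
#'
#' Families mapped to a clan return that clan; clanless families (NA clan or
#' absent from the map) return \code{SINGLETON:<accession>}, implementing the
#' convention that a family outside any clan is treated as a clan whose only
#' member is itself.
#'
#' @param map a \linkS4class{ClanMap}.
#' @param families character vector of family accessions.
#' @return character vector of effective clan identifiers, same length as
#'   \code{families}.
#' @examples
#' cm <- ClanMap(c("PF1", "PF2"), c("CL1", NA))
#' effectiveClan(cm, c("PF1", "PF2", "PF3"))
#' @export
setGeneric("effectiveClan",
           function(map, families) standardGeneric("effectiveClan"))

#' @rdname assignmentAccessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname assignmentAccessors
#' @export
setGeneric("selectionOrder", function(x) standardGeneric("selectionOrder"))
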