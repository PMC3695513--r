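#' @import methods
#' @importFrom S4Vectors isSorted
NULL

.HIT_COLUMNS <- c("seq_id", "family_acc", "seq_evalue", "dom_evalue",
                  "bit_score", "bias_score", "ali_start", "ali_end",
                  "env_start", "env_end")

.TRACK_KINDS <- c("coiled_coil", "transmembrane", "disorder")

#' DomainHits: a table of profile-HMM domain alignments
#'
#' One row per domain hit of a family model against a target sequence, as
#' reported by \code{hmmsearch}: per-sequence and per-domain (independent)
#' E-values, the domain bit score, the null2 bias-composition correction
#' (in bits), and 1-based inclusive alignment and envelope coordinates.
#' The envelope always contains the alignment.
#'
#' @slot hits a \code{data.frame} with columns \code{seq_id},
#'   \code{family_acc}, \code{seq_evalue}, \code{dom_evalue},
#'   \code{bit_score}, \code{bias_score}, \code{ali_start}, \code{ali_end},
#'   \code{env_start}, \code{env_end}.
#'
#' @seealso [DomainHits()] to construct, [readDomainHits()] to parse files.
#' @exportClass DomainHits
setClass("DomainHits", representation(hits = "data.frame"))

.validateHitFrame <- function(df) {
    missing <- setdiff(.HIT_COLUMNS, names(df))
    if (length(missing))
        return(paste("missing hit columns:", paste(missing, collapse = ", ")))
    if (nrow(df) == 0L)
        return(TRUE)
    num <- c("seq_evalue", "dom_evalue", "bit_score", "bias_score",
             "ali_start", "ali_end", "env_start", "env_end")
    for (col in num)
        if (!is.numeric(df[[col]]))
            return(sprintf("column '%s' must be numeric", col))
    bad <- which(df$ali_start < 1L | df$ali_start > df$ali_end)
    if (length(bad))
        return(sprintf("row %d: alignment coordinates violate 1 <= ali_start <= ali_end",
                       bad[1L]))
    bad <- which(df$env_start > df$ali_start | df$ali_end > df$env_end)
    if (length(bad))
        return(sprintf("row %d: envelope must contain the alignment coordinates",
                       bad[1L]))
    bad <- which(df$seq_evalue < 0 | df$dom_evalue < 0 | df$bias_score < 0)
    if (length(bad))
        return(sprintf("row %d: E-values and bias score must be non-negative",
                       bad[1L]))
    TRUE
}

setValidity("DomainHits", function(object) .validateHitFrame(object@hits))

#' Construct a DomainHits object
#'
#' @param hits a \code{data.frame} (or coercible) with the ten hit columns;
#'   see \linkS4class{DomainHits}.
#' @return a \linkS4class{DomainHits} object.
#' @examples
#' h <- DomainHits(data.frame(
#'   seq_id = "s1", family_acc = "PF00001",
#'   seq_evalue = 1e-5, dom_evalue = 1e-5,
#'   bit_score = 50, bias_score = 1,
#'   ali_start = 10L, ali_end = 60L, env_start = 8L, env_end = 63L))
#' length(h)
#' @export
DomainHits <- function(hits = data.frame()) {
    if (nrow(as.data.frame(hits)) == 0L) {
        hits <- data.frame(seq_id = character(), family_acc = character(),
                           seq_evalue = numeric(), dom_evalue = numeric(),
                           bit_score = numeric(), bias_score = numeric(),
                           ali_start = integer(), ali_end = integer(),
                           env_start = integer(), env_end = integer())
    } else {
        hits <- as.data.frame(hits)[, .HIT_COLUMNS]
        for (col in c("ali_start", "ali_end", "env_start", "env_end"))
            hits[[col]] <- as.integer(hits[[col]])
        hits$seq_id <- as.character(hits$seq_id)
        hits$family_acc <- as.character(hits$family_acc)
        rownames(hits) <- NULL
    }
    new("DomainHits", hits = hits)
}

#' ClanMap: family-to-clan membership
#'
#' Maps family accessions to clan accessions. Families without a clan (an
#' \code{NA} clan, or families absent from the map altogether) resolve to a
#' deterministic singleton clan \code{SINGLETON:<accession>}, so that every
#' family has exactly one effective clan and clanless families are treated as
#' clans with a single member.
#'
#' @slot family character vector of family accessions (unique).
#' @slot clan character vector of clan accessions, \code{NA} for clanless
#'   families.
#' @exportClass ClanMap
setClass("ClanMap", representation(family = "character", clan = "character"))

setValidity("ClanMap", function(object) {
    if (length(object@family) != length(object@clan))
        return("family and clan vectors must have the same length")
    if (anyDuplicated(object@family))
        return("duplicate family accession in clan map")
    TRUE
})

#' Construct a ClanMap
#'
#' @param family character vector of family accessions.
#' @param clan character vector of clan accessions; \code{NA} or \code{""}
#'   marks a clanless family.
#' @return a \linkS4class{ClanMap}.
#' @examples
#' cm <- ClanMap(c("PF1", "PF2", "PF3"), c("CL1", "CL1", NA))
#' effectiveClan(cm, c("PF1", "PF3", "PF9"))
#' @export
ClanMap <- function(family = character(), clan = character()) {
    family <- as.character(family)
    clan <- as.character(clan)
    clan[!is.na(clan) & !nzchar(clan)] <- NA_character_
    new("ClanMap", family = family, clan = clan)
}

#' FeatureTracks: per-residue predictor segments
#'
#' Segment lists produced by per-residue predictors (ncoils-style coiled-coil,
#' Phobius-style transmembrane helices, IUPred-style disorder), one row per
#' predicted segment with 1-based inclusive coordinates. On construction,
#' segments of the same sequence and kind are normalized: sorted and merged
#' where overlapping or adjacent. Note that merging adjacency makes the
#' stored transmembrane segments unsuitable for counting individual helices
#' only when two predicted helices abut directly, which predictors do not
#' emit in practice (a loop always separates helices).
#'
#' @slot segments a \code{data.frame} with columns \code{seq_id},
#'   \code{kind} (one of \code{coiled_coil}, \code{transmembrane},
#'   \code{disorder}), \code{start}, \code{end}.
#' @exportClass FeatureTracks
setClass("FeatureTracks", representation(segments = "data.frame"))

setValidity("FeatureTracks", function(object) {
    df <- object@segments
    need <- c("seq_id", "kind", "start", "end")
    if (!all(need %in% names(df)))
        return(paste("missing track columns:",
                     paste(setdiff(need, names(df)), collapse = ", ")))
    if (nrow(df) == 0L)
        return(TRUE)
    bad <- !df$kind %in% .TRACK_KINDS
    if (any(bad))
        return(sprintf("unknown track kind '%s'", df$kind[which(bad)[1L]]))
    if (any(df$start > df$end))
        return("track segment with start > end")
    if (any(df$start < 1L))
        return("track coordinates are 1-based; start < 1")
    TRUE
})

#' Construct (and normalize) FeatureTracks
#'
#' @param segments a \code{data.frame} with columns \code{seq_id},
#'   \code{kind}, \code{start}, \code{end} (1-based inclusive).
#' @return a \linkS4class{FeatureTracks} with sorted, merged segments.
#' @examples
#' ft <- FeatureTracks(data.frame(seq_id = "s1", kind = "coiled_coil",
#'                                start = c(5L, 11L), end = c(10L, 20L)))
#' as.data.frame(ft)  # one merged segment 5..20
#' @export
FeatureTracks <- function(segments = data.frame()) {
    if (nrow(as.data.frame(segments)) == 0L) {
        segments <- data.frame(seq_id = character(), kind = character(),
                               start = integer(), end = integer())
    } else {
        segments <- as.data.frame(segments)[, c("seq_id", "kind", "start", "end")]
        segments$seq_id <- as.character(segments$seq_id)
        segments$kind <- as.character(segments$kind)
        segments$start <- as.integer(segments$start)
        segments$end <- as.integer(segments$end)
        bad <- !segments$kind %in% .TRACK_KINDS
        if (any(bad))
            stop("unknown track kind '", segments$kind[which(bad)[1L]], "'")
        if (any(segments$start > segments$end))
            stop("track segment with start > end")
        segments <- .normalizeSegments(segments)
    }
    new("FeatureTracks", segments = segments)
}

# merge overlapping/adjacent segments per (seq_id, kind); deterministic order
.normalizeSegments <- function(df) {
    pieces <- split(df, list(df$seq_id, df$kind), drop = TRUE)
    out <- lapply(pieces, function(p) {
        ir <- IRanges::reduce(IRanges::IRanges(p$start, p$end))
        data.frame(seq_id = p$seq_id[1L], kind = p$kind[1L],
                   start = IRanges::start(ir), end = IRanges::end(ir))
    })
    out <- do.call(rbind, out)
    out <- out[order(out$seq_id, out$kind, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' OverlapPairs: qualifying cross-clan overlaps
#'
#' Each row is an unordered pair of domain hits on the same sequence whose
#' alignment intervals intersect, whose families belong to different
#' effective clans, and where the intersection covers at least
#' \code{min_frac} (default 50\%) of the alignment coordinates of at least
#' one of the two hits. Produced by [detectOverlaps()].
#'
#' @slot pairs a \code{data.frame}, one row per qualifying pair, carrying the
#'   hit keys, families, effective clans, alignment intervals, domain
#'   E-values, the intersection interval and the two coverage fractions.
#' @slot min_frac the coverage threshold the pairs were built with.
#' @exportClass OverlapPairs
setClass("OverlapPairs",
         representation(pairs = "data.frame", min_frac = "numeric"))

setValidity("OverlapPairs", function(object) {
    df <- object@pairs
    if (nrow(df) == 0L)
        return(TRUE)
    if (any(df$family_a == df$family_b))
        return("pair between two hits of the same family")
    if (any(df$clan_a == df$clan_b))
        return("pair between two families of the same effective clan")
    if (any(pmax(df$frac_a, df$frac_b) < object@min_frac))
        return("pair below the minimum coverage fraction")
    if (any(df$inter_len <= 0L))
        return("pair with empty intersection")
    TRUE
})

.emptyPairFrame <- function() {
    data.frame(seq_id = character(),
               key_a = character(), key_b = character(),
               family_a = character(), family_b = character(),
               clan_a = character(), clan_b = character(),
               ali_start_a = integer(), ali_end_a = integer(),
               ali_start_b = integer(), ali_end_b = integer(),
               dom_evalue_a = numeric(), dom_evalue_b = numeric(),
               inter_start = integer(), inter_end = integer(),
               inter_len = integer(),
               frac_a = numeric(), frac_b = numeric())
}

#' AssignmentResult: attribution of overlapping domains to families
#'
#' Records which overlapping domains ended up counted, and for which family,
#' after resolution by [greedyAssign()] or [assignByEvalue()]. Domains whose
#' every overlap partner was consumed by an earlier greedy selection drop out
#' unassigned, exactly as in the iterative procedure.
#'
#' @slot assignments \code{data.frame} with columns \code{key} (domain hit
#'   key), \code{family_acc} (the family the domain is attributed to — its
#'   own family), \code{seq_id}.
#' @slot selection_order \code{data.frame} with columns \code{family_acc} and
#'   \code{n_domains} (the family's overlapping-domain count at selection
#'   time), in selection order.
#' @slot strategy \code{"greedy"} or \code{"evalue"}.
#' @exportClass AssignmentResult
setClass("AssignmentResult",
         representation(assignments = "data.frame",
                        selection_order = "data.frame",
                        strategy = "character"))

setValidity("AssignmentResult", function(object) {
    if (anyDuplicated(object@assignments$key))
        return("a domain is assigned more than once")
    TRUE
})
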