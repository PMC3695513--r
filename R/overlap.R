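#' @include AllClasses.R methods.R
NULL

#' Filter hits by an E-value significance threshold
#'
#' A hit is retained when both its per-domain (independent) E-value and its
#' full-sequence E-value are less than or equal to the threshold; the
#' sequence and domain thresholds are taken to be equal, as in a study
#' restricted to families whose curated sequence and domain thresholds
#' coincide. The comparison is inclusive and input order is preserved.
#'
#' @param hits a \linkS4class{DomainHits}.
#' @param threshold positive E-value threshold.
#' @return the retained \linkS4class{DomainHits}.
#' @export
filterHitsByEvalue <- function(hits, threshold) {
    stopifnot(is(hits, "DomainHits"))
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
        stop("threshold must be a single positive E-value", call. = FALSE)
    keep <- domEvalue(hits) <= threshold & seqEvalue(hits) <= threshold
    hits[keep]
}

# closed-interval intersection length
.interLen <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)

#' Test two domain hits for a qualifying cross-clan overlap
#'
#' Two hits qualify when they lie on the same sequence, their families belong
#' to different effective clans (see [effectiveClan()]), their alignment
#' intervals intersect, and the intersection covers at least \code{min_frac}
#' of the alignment coordinates of at least one of the two hits. Intersection
#' is computed on alignment (not envelope) coordinates with closed-interval
#' arithmetic. Two hits of the same family never qualify.
#'
#' @param a,b single-hit \linkS4class{DomainHits} objects (or a 1-row subset).
#' @param clans a \linkS4class{ClanMap}.
#' @param min_frac minimum coverage fraction, default 0.5.
#' @return a one-row pair \code{data.frame} (as stored in
#'   \linkS4class{OverlapPairs}) or \code{NULL} when the pair does not
#'   qualify.
#' @examples
#' cm <- ClanMap(c("F1", "F2"), c("CL1", "CL2"))
#' h <- DomainHits(data.frame(
#'   seq_id = "s", family_acc = c("F1", "F2"),
#'   seq_evalue = 1e-6, dom_evalue = 1e-6, bit_score = 30, bias_score = 0,
#'   ali_start = c(100L, 150L), ali_end = c(200L, 250L),
#'   env_start = c(100L, 150L), env_end = c(200L, 250L)))
#' pairwiseOverlap(h[1], h[2], cm)$inter_len  # 51
#' @export
pairwiseOverlap <- function(a, b, clans, min_frac = 0.5) {
    stopifnot(is(a, "DomainHits"), is(b, "DomainHits"), length(a) == 1L,
              length(b) == 1L, is(clans, "ClanMap"))
    .pairRow(as.data.frame(a), hitKeys(a), 1L,
             as.data.frame(b), hitKeys(b), 1L, clans, min_frac)
}

# core pair test on plain rows; ra/rb are 1-row data.frames
.pairRow <- function(ra, key_a, ia, rb, key_b, ib, clans, min_frac) {
    if (ra$seq_id != rb$seq_id || ra$family_acc == rb$family_acc)
        return(NULL)
    clan_a <- effectiveClan(clans, ra$family_acc)
    clan_b <- effectiveClan(clans, rb$family_acc)
    if (clan_a == clan_b)
        return(NULL)
    is_ <- max(ra$ali_start, rb$ali_start)
    ie_ <- min(ra$ali_end, rb$ali_end)
    il <- ie_ - is_ + 1L
    if (il <= 0L)
        return(NULL)
    len_a <- ra$ali_end - ra$ali_start + 1L
    len_b <- rb$ali_end - rb$ali_start + 1L
    frac_a <- il / len_a
    frac_b <- il / len_b
    if (frac_a < min_frac && frac_b < min_frac)
        return(NULL)
    data.frame(seq_id = ra$seq_id,
               key_a = key_a, key_b = key_b,
               family_a = ra$family_acc, family_b = rb$family_acc,
               clan_a = clan_a, clan_b = clan_b,
               ali_start_a = ra$ali_start, ali_end_a = ra$ali_end,
               ali_start_b = rb$ali_start, ali_end_b = rb$ali_end,
               dom_evalue_a = ra$dom_evalue, dom_evalue_b = rb$dom_evalue,
               inter_start = as.integer(is_), inter_end = as.integer(ie_),
               inter_len = as.integer(il),
               frac_a = frac_a, frac_b = frac_b)
}

#' Detect all qualifying cross-clan overlaps at a threshold
#'
#' Filters hits at the E-value threshold (see [filterHitsByEvalue()]), then
#' enumerates, per sequence, every unordered pair of hits and keeps the
#' qualifying ones (see [pairwiseOverlap()]). Each pair is reported once, with
#' \code{family_a < family_b} lexicographically, ordered by sequence id then
#' by the accession pair — so the output is deterministic regardless of
#' input order.
#'
#' Candidate pairs are found with an interval-tree query
#' (\code{IRanges::findOverlaps}) per sequence rather than by all-pairs
#' scanning.
#'
#' @param hits a \linkS4class{DomainHits}.
#' @param clans a \linkS4class{ClanMap}.
#' @param threshold E-value significance threshold (commonly 0.001, 0.01 or
#'   0.1). Use \code{Inf} to skip filtering.
#' @param min_frac minimum coverage fraction, default 0.5.
#' @return an \linkS4class{OverlapPairs}.
#' @export
detectOverlaps <- function(hits, clans, threshold = 0.01, min_frac = 0.5) {
    stopifnot(is(hits, "DomainHits"), is(clans, "ClanMap"))
    # keys are assigned on the input table, before filtering, so the same
    # hit keeps the same key at every threshold
    df <- as.data.frame(hits)
    df$key <- hitKeys(hits)
    if (is.finite(threshold)) {
        if (!is.numeric(threshold) || threshold <= 0)
            stop("threshold must be a single positive E-value", call. = FALSE)
        df <- df[df$dom_evalue <= threshold & df$seq_evalue <= threshold, ,
                 drop = FALSE]
    }
    rows <- list()
    for (sq in unique(df$seq_id)) {
        sub <- df[df$seq_id == sq, , drop = FALSE]
        n <- nrow(sub)
        if (n < 2L)
            next
        ir <- IRanges::IRanges(sub$ali_start, sub$ali_end)
        ov <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
        qh <- S4Vectors::queryHits(ov)
        sh <- S4Vectors::subjectHits(ov)
        for (k in seq_along(qh)) {
            i <- qh[k]; j <- sh[k]
            # canonical orientation: smaller accession first
            if (sub$family_acc[j] < sub$family_acc[i]) {
                tmp <- i; i <- j; j <- tmp
            }
            p <- .pairRow(sub[i, , drop = FALSE], sub$key[i], i,
                          sub[j, , drop = FALSE], sub$key[j], j,
                          clans, min_frac)
            if (!is.null(p))
                rows[[length(rows) + 1L]] <- p
        }
    }
    if (!length(rows)) {
        pairs <- .emptyPairFrame()
    } else {
        pairs <- do.call(rbind, rows)
        # a repeat hit of the same two families can generate duplicate
        # canonical pairs only via distinct hit keys, so keys disambiguate
        pairs <- pairs[!duplicated(pairs[, c("key_a", "key_b")]), ,
                       drop = FALSE]
        pairs <- pairs[order(pairs$seq_id, pairs$family_a, pairs$family_b,
                             pairs$key_a, pairs$key_b), , drop = FALSE]
        rownames(pairs) <- NULL
    }
    new("OverlapPairs", pairs = pairs, min_frac = min_frac)
}

#' Union of overlap regions, per sequence
#'
#' Collapses the pair intersection intervals of an \linkS4class{OverlapPairs}
#' into a per-sequence union of regions (a residue appearing in several pairs
#' counts once). These are the "overlap regions" over which residue-level
#' bias proportions are computed.
#'
#' @param pairs an \linkS4class{OverlapPairs}, or a \code{data.frame} with
#'   columns \code{seq_id}, \code{inter_start}, \code{inter_end} (or
#'   \code{start}, \code{end}).
#' @return a \code{data.frame} with columns \code{seq_id}, \code{start},
#'   \code{end}, disjoint per sequence.
#' @export
overlapRegions <- function(pairs) {
    df <- as.data.frame(pairs)
    if (nrow(df) == 0L)
        return(data.frame(seq_id = character(), start = integer(),
                          end = integer()))
    if ("inter_start" %in% names(df)) {
        df <- data.frame(seq_id = df$seq_id, start = df$inter_start,
                         end = df$inter_end)
    }
    out <- lapply(split(df, df$seq_id), function(p) {
        ir <- IRanges::reduce(IRanges::IRanges(p$start, p$end))
        data.frame(seq_id = p$seq_id[1L], start = IRanges::start(ir),
                   end = IRanges::end(ir))
    })
    out <- do.call(rbind, out)
    out <- out[order(out$seq_id, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}
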