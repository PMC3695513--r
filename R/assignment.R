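#' @include AllClasses.R methods.R
NULL

# key -> family / seq lookup tables from a pair frame
.pairLookup <- function(df) {
    keys <- c(df$key_a, df$key_b)
    fams <- c(df$family_a, df$family_b)
    seqs <- c(df$seq_id, df$seq_id)
    keep <- !duplicated(keys)
    list(key = keys[keep], family = fams[keep], seq_id = seqs[keep])
}

#' Winner-takes-all greedy assignment of overlapping domains
#'
#' Iteratively resolves overlap pairs: (1) for every family, count its member
#' domains involved in at least one remaining pair; (2) select the family
#' with the highest count, breaking ties toward the lexicographically
#' smallest accession; (3) attribute that family's overlapping domains to it;
#' (4) delete every pair involving any of those domains; (5) families left
#' with no overlapping domains drop out; repeat until no pairs remain.
#' Domains whose every partner was consumed by an earlier selection are never
#' attributed to any family.
#'
#' @param pairs an \linkS4class{OverlapPairs} from [detectOverlaps()].
#' @param clans a \linkS4class{ClanMap} (kept for interface symmetry with
#'   [countOverlappingClans()]; the selection itself needs only the pairs).
#' @return an \linkS4class{AssignmentResult} with \code{strategy = "greedy"}.
#' @examples
#' # three domains of F1 each overlapping a different partner family:
#' # F1 is selected once with count 3 and takes all its domains
#' @export
greedyAssign <- function(pairs, clans = NULL) {
    stopifnot(is(pairs, "OverlapPairs"))
    df <- as.data.frame(pairs)
    lk <- .pairLookup(df)
    assigned_key <- character()
    assigned_fam <- character()
    order_fam <- character()
    order_n <- integer()
    act_a <- df$key_a; act_b <- df$key_b   # remaining pairs
    fam_a <- df$family_a; fam_b <- df$family_b
    while (length(act_a) > 0L) {
        keys <- c(act_a, act_b)
        fams <- c(fam_a, fam_b)
        dom <- !duplicated(keys)
        counts <- table(fams[dom])
        best <- max(counts)
        cand <- sort(names(counts)[counts == best])
        sel <- cand[1L]
        sel_keys <- sort(unique(keys[dom][fams[dom] == sel]))
        assigned_key <- c(assigned_key, sel_keys)
        assigned_fam <- c(assigned_fam, rep(sel, length(sel_keys)))
        order_fam <- c(order_fam, sel)
        order_n <- c(order_n, as.integer(best))
        drop <- act_a %in% sel_keys | act_b %in% sel_keys
        act_a <- act_a[!drop]; act_b <- act_b[!drop]
        fam_a <- fam_a[!drop]; fam_b <- fam_b[!drop]
    }
    new("AssignmentResult",
        assignments = data.frame(
            key = assigned_key, family_acc = assigned_fam,
            seq_id = lk$seq_id[match(assigned_key, lk$key)]),
        selection_order = data.frame(family_acc = order_fam,
                                     n_domains = order_n),
        strategy = "greedy")
}

#' E-value-based assignment of overlapping domains
#'
#' The alternative resolution rule: within each pair, the hit with the higher
#' per-domain E-value is marked as the overlapping (suspect) domain of its
#' own family — the lower-E-value hit is awarded the genuine match. A domain
#' appearing in several pairs is marked at most once: losing any one pair
#' suffices. Exact E-value ties are broken by marking the domain of the
#' lexicographically larger family accession.
#'
#' @param pairs an \linkS4class{OverlapPairs}.
#' @return an \linkS4class{AssignmentResult} with \code{strategy = "evalue"};
#'   \code{selectionOrder} lists families by marked-domain count, descending
#'   (ties by accession).
#' @export
assignByEvalue <- function(pairs) {
    stopifnot(is(pairs, "OverlapPairs"))
    df <- as.data.frame(pairs)
    if (nrow(df) == 0L)
        return(new("AssignmentResult",
                   assignments = data.frame(key = character(),
                                            family_acc = character(),
                                            seq_id = character()),
                   selection_order = data.frame(family_acc = character(),
                                                n_domains = integer()),
                   strategy = "evalue"))
    a_loses <- df$dom_evalue_a > df$dom_evalue_b |
        (df$dom_evalue_a == df$dom_evalue_b & df$family_a > df$family_b)
    key <- ifelse(a_loses, df$key_a, df$key_b)
    fam <- ifelse(a_loses, df$family_a, df$family_b)
    sq <- df$seq_id
    keep <- !duplicated(key)
    asn <- data.frame(key = key[keep], family_acc = fam[keep],
                      seq_id = sq[keep])
    asn <- asn[order(asn$family_acc, asn$key), , drop = FALSE]
    rownames(asn) <- NULL
    counts <- table(asn$family_acc)
    ord <- order(-as.integer(counts), names(counts))
    new("AssignmentResult",
        assignments = asn,
        selection_order = data.frame(
            family_acc = names(counts)[ord],
            n_domains = as.integer(counts)[ord]),
        strategy = "evalue")
}

#' Count distinct overlapping clans per family
#'
#' For each family retaining at least one attributed overlapping domain, the
#' number of effective clans its domains overlap with, computed on the
#' original pair list: every partner of every attributed domain contributes
#' its effective clan, clanless partners their singleton clan. Where one
#' domain overlaps several clans, all are counted. The default counts the
#' distinct union over the family's domains; \code{method = "sum"} instead
#' sums each domain's distinct-partner-clan count.
#'
#' @param result an \linkS4class{AssignmentResult}.
#' @param pairs the \linkS4class{OverlapPairs} the result was computed from.
#' @param clans a \linkS4class{ClanMap} (partner clans are re-resolved
#'   through it).
#' @param method \code{"union"} (default) or \code{"sum"}.
#' @return a named integer vector, family accession -> clan count, sorted by
#'   count descending then accession.
#' @export
countOverlappingClans <- function(result, pairs, clans,
                                  method = c("union", "sum")) {
    method <- match.arg(method)
    stopifnot(is(result, "AssignmentResult"), is(pairs, "OverlapPairs"),
              is(clans, "ClanMap"))
    df <- as.data.frame(pairs)
    asn <- assignments(result)
    if (nrow(asn) == 0L)
        return(stats::setNames(integer(), character()))
    # long table: (domain key, partner family) over both pair orientations
    long <- data.frame(key = c(df$key_a, df$key_b),
                       partner = c(df$family_b, df$family_a))
    long$clan <- effectiveClan(clans, long$partner)
    long <- long[long$key %in% asn$key, , drop = FALSE]
    long$family <- asn$family_acc[match(long$key, asn$key)]
    counts <- vapply(split(long, long$family), function(p) {
        if (method == "union")
            length(unique(p$clan))
        else
            sum(vapply(split(p$clan, p$key), function(cl)
                length(unique(cl)), integer(1L)))
    }, integer(1L))
    counts[order(-counts, names(counts))]
}

#' Families overlapping at least k clans
#'
#' Convenience selector on the output of [countOverlappingClans()]: the
#' "promiscuous" families whose attributed domains overlap \code{min_clans}
#' or more distinct clans.
#'
#' @param clan_counts named integer vector from [countOverlappingClans()].
#' @param min_clans minimum number of overlapping clans (default 2).
#' @return character vector of family accessions, sorted.
#' @export
promiscuousFamilies <- function(clan_counts, min_clans = 2L) {
    sort(names(clan_counts)[clan_counts >= min_clans])
}
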