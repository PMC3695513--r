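# Independent re-implementations used as oracles. They share no code with
# the package internals: plain base-R double loops over plain data.frames.

# effective clan, restated from the membership table directly
oracleClan <- function(clan_df, fam) {
    i <- match(fam, clan_df$family_acc)
    if (is.na(i) || is.na(clan_df$clan_acc[i]))
        paste0("SINGLETON:", fam)
    else
        clan_df$clan_acc[i]
}

# all-pairs O(n^2) overlap checker; returns a sorted character vector of
# canonical pair identifiers "key1||key2" (keys sorted within the pair)
bruteForceOverlaps <- function(hit_df, keys, clan_df, threshold,
                               min_frac = 0.5) {
    keep <- hit_df$dom_evalue <= threshold & hit_df$seq_evalue <= threshold
    hit_df <- hit_df[keep, , drop = FALSE]
    keys <- keys[keep]
    found <- character()
    n <- nrow(hit_df)
    if (n < 2L)
        return(found)
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            if (hit_df$seq_id[i] != hit_df$seq_id[j]) next
            if (hit_df$family_acc[i] == hit_df$family_acc[j]) next
            if (oracleClan(clan_df, hit_df$family_acc[i]) ==
                oracleClan(clan_df, hit_df$family_acc[j])) next
            lo <- max(hit_df$ali_start[i], hit_df$ali_start[j])
            hi <- min(hit_df$ali_end[i], hit_df$ali_end[j])
            if (hi < lo) next
            il <- hi - lo + 1
            li <- hit_df$ali_end[i] - hit_df$ali_start[i] + 1
            lj <- hit_df$ali_end[j] - hit_df$ali_start[j] + 1
            if (il / li >= min_frac || il / lj >= min_frac)
                found <- c(found,
                           paste(sort(c(keys[i], keys[j])), collapse = "||"))
        }
    }
    sort(found)
}

canonicalPairIds <- function(pairs) {
    df <- as.data.frame(pairs)
    if (nrow(df) == 0L)
        return(character())
    sort(vapply(seq_len(nrow(df)), function(r)
        paste(sort(c(df$key_a[r], df$key_b[r])), collapse = "||"),
        character(1L)))
}

# step-by-step greedy simulator over a plain pair table; returns the
# per-domain attribution (named vector key -> family) and the selection log
greedyOracle <- function(pair_df) {
    remaining <- pair_df[, c("key_a", "family_a", "key_b", "family_b")]
    attribution <- structure(character(), names = character())
    log_fam <- character(); log_n <- integer()
    repeat {
        if (nrow(remaining) == 0L) break
        # family -> set of its domains still in play
        fam_doms <- list()
        for (r in seq_len(nrow(remaining))) {
            fam_doms[[remaining$family_a[r]]] <-
                union(fam_doms[[remaining$family_a[r]]], remaining$key_a[r])
            fam_doms[[remaining$family_b[r]]] <-
                union(fam_doms[[remaining$family_b[r]]], remaining$key_b[r])
        }
        sizes <- vapply(fam_doms, length, integer(1L))
        winners <- names(sizes)[sizes == max(sizes)]
        sel <- sort(winners)[1L]
        doms <- fam_doms[[sel]]
        attribution[doms] <- sel
        log_fam <- c(log_fam, sel)
        log_n <- c(log_n, length(doms))
        keep <- !(remaining$key_a %in% doms | remaining$key_b %in% doms)
        remaining <- remaining[keep, , drop = FALSE]
    }
    list(attribution = attribution,
         order = data.frame(family_acc = log_fam, n_domains = log_n))
}
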