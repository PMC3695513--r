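#' @include overlap.R assignment.R labeling.R statistics.R
NULL

#' Run the full overlap-analysis pipeline
#'
#' Convenience wrapper chaining the stages: E-value filtering and cross-clan
#' overlap detection, winner-takes-all (or E-value-based) assignment,
#' per-family overlapping-clan counts, family labelling from seed tracks,
#' the cumulative overlap curve and, when labels are available, the
#' overrepresentation curve along the clan-count ranking.
#'
#' @param hits a \linkS4class{DomainHits}.
#' @param clans a \linkS4class{ClanMap}.
#' @param seeds optional seed-region \code{data.frame} (with \code{tracks},
#'   enables labelling).
#' @param tracks optional \linkS4class{FeatureTracks}.
#' @param threshold E-value significance threshold, default 0.01.
#' @param min_frac overlap coverage fraction, default 0.5.
#' @param strategy \code{"greedy"} (default) or \code{"evalue"}.
#' @return a list with \code{pairs}, \code{assignment}, \code{clan_counts},
#'   \code{curve} and, when seeds and tracks are given, \code{labels} and
#'   \code{overrepresentation}.
#' @export
runOverlapPipeline <- function(hits, clans, seeds = NULL, tracks = NULL,
                               threshold = 0.01, min_frac = 0.5,
                               strategy = c("greedy", "evalue")) {
    strategy <- match.arg(strategy)
    pairs <- detectOverlaps(hits, clans, threshold, min_frac)
    assignment <- if (strategy == "greedy") greedyAssign(pairs, clans)
                  else assignByEvalue(pairs)
    clan_counts <- countOverlappingClans(assignment, pairs, clans)
    out <- list(pairs = pairs, assignment = assignment,
                clan_counts = clan_counts,
                curve = cumulativeOverlapCurve(assignment))
    if (!is.null(seeds) && !is.null(tracks)) {
        out$labels <- labelFamilies(seeds, tracks)
        if (length(clan_counts) > 0L)
            out$overrepresentation <- overrepresentationCurve(
                names(clan_counts), out$labels)
    }
    out
}
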