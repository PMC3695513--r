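#' @include AllClasses.R methods.R
NULL

#' Longest contiguous predicted run within a seed region
#'
#' Clips a kind's predicted segments to the seed-member region and returns
#' the length (in residues) of the longest contiguous run; predicted
#' residues outside the region are not taken into consideration.
#'
#' @param tracks a \linkS4class{FeatureTracks}.
#' @param seq_id sequence identifier of the seed member.
#' @param kind track kind (\code{"coiled_coil"}, \code{"disorder"},
#'   \code{"transmembrane"}).
#' @param start,end 1-based inclusive seed region bounds.
#' @return integer run length (0 when nothing is predicted in the region).
#' @examples
#' ft <- FeatureTracks(data.frame(seq_id = "s", kind = "coiled_coil",
#'                                start = c(5L, 12L), end = c(10L, 30L)))
#' longestTrueRun(ft, "s", "coiled_coil", 1, 100)  # 19
#' @export
longestTrueRun <- function(tracks, seq_id, kind, start, end) {
    stopifnot(start <= end)
    segs <- trackSegments(tracks, seq_id, kind)
    clipped <- IRanges::restrict(segs, start = as.integer(start),
                                 end = as.integer(end))
    clipped <- clipped[IRanges::width(clipped) > 0L]
    if (length(clipped) == 0L)
        return(0L)
    max(IRanges::width(IRanges::reduce(clipped)))
}

#' Count predicted transmembrane helices intersecting a seed region
#'
#' Each predictor segment whose intersection with the region is non-empty
#' counts as one helix; a helix clipped by the region boundary still counts
#' if at least one residue intersects.
#'
#' @param tracks a \linkS4class{FeatureTracks}; only \code{transmembrane}
#'   segments are considered.
#' @param seq_id sequence identifier.
#' @param start,end 1-based inclusive region bounds.
#' @return integer helix count.
#' @export
countTmHelices <- function(tracks, seq_id, start, end) {
    stopifnot(start <= end)
    segs <- trackSegments(tracks, seq_id, "transmembrane")
    sum(IRanges::start(segs) <= end & IRanges::end(segs) >= start)
}

.labelOneFamily <- function(seeds, tracks, member_frac, cc_run, cc_long_run,
                            dis_run, tm_min) {
    n <- nrow(seeds)
    cc_runs <- integer(n); dis_runs <- integer(n); tm_counts <- integer(n)
    for (i in seq_len(n)) {
        s <- seeds[i, ]
        cc_runs[i] <- longestTrueRun(tracks, s$seq_id, "coiled_coil",
                                     s$start, s$end)
        dis_runs[i] <- longestTrueRun(tracks, s$seq_id, "disorder",
                                      s$start, s$end)
        tm_counts[i] <- countTmHelices(tracks, s$seq_id, s$start, s$end)
    }
    c(cc20 = mean(cc_runs >= cc_run) >= member_frac,
      cc50 = mean(cc_runs >= cc_long_run) >= member_frac,
      dis20 = mean(dis_runs >= dis_run) >= member_frac,
      tmh2 = mean(tm_counts >= tm_min) >= member_frac)
}

#' Assign compositional-bias labels to families
#'
#' A family is labelled \code{cc20} (coiled-coil) when at least
#' \code{member_frac} (default 50\%) of its seed member regions contain
#' \code{cc_run} (default 20) consecutive residues predicted to be
#' coiled-coil; \code{dis20} (disordered) analogously for disorder;
#' \code{cc50} for the longer \code{cc_long_run} (default 50) coiled-coil
#' run; and \code{tmh2} (transmembrane) when at least \code{member_frac} of
#' members have \code{tm_min} (default 2) or more predicted transmembrane
#' helices intersecting the seed region. Predicted residues outside seed
#' regions are ignored, and a seed member with no track record counts as
#' having no predicted residues. All four labels are computed independently;
#' \code{cc50} implies \code{cc20} because a 50-residue run contains a
#' 20-residue run.
#'
#' @param seeds seed-region \code{data.frame} (columns \code{family_acc},
#'   \code{seq_id}, \code{start}, \code{end}); must be non-empty.
#' @param tracks a \linkS4class{FeatureTracks}.
#' @param member_frac minimum fraction of seed members, default 0.5
#'   (inclusive comparison).
#' @param cc_run,cc_long_run,dis_run run lengths in residues (20, 50, 20).
#' @param tm_min minimum helix count, default 2.
#' @return a \code{data.frame} with columns \code{family_acc}, \code{cc20},
#'   \code{cc50}, \code{dis20}, \code{tmh2}, one row per family, sorted by
#'   accession.
#' @export
labelFamilies <- function(seeds, tracks, member_frac = 0.5, cc_run = 20L,
                          cc_long_run = 50L, dis_run = 20L, tm_min = 2L) {
    if (!is.data.frame(seeds) || nrow(seeds) == 0L)
        stop("seeds must be a non-empty seed-region data.frame",
             call. = FALSE)
    stopifnot(is(tracks, "FeatureTracks"))
    fams <- sort(unique(seeds$family_acc))
    lab <- t(vapply(fams, function(f)
        .labelOneFamily(seeds[seeds$family_acc == f, , drop = FALSE], tracks,
                        member_frac, cc_run, cc_long_run, dis_run, tm_min),
        logical(4L)))
    out <- data.frame(family_acc = fams, cc20 = lab[, "cc20"],
                      cc50 = lab[, "cc50"], dis20 = lab[, "dis20"],
                      tmh2 = lab[, "tmh2"])
    rownames(out) <- NULL
    out
}

#' @rdname labelFamilies
#' @param family_acc label a single family: its rows are selected from
#'   \code{seeds}.
#' @param ... passed on to \code{labelFamilies}.
#' @export
labelFamily <- function(seeds, tracks, family_acc, ...) {
    sub <- seeds[seeds$family_acc == family_acc, , drop = FALSE]
    if (nrow(sub) == 0L)
        stop("no seed regions for family ", family_acc, call. = FALSE)
    labelFamilies(sub, tracks, ...)
}
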