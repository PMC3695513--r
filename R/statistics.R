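#' @include AllClasses.R methods.R overlap.R
NULL

#' Expected number of false-positive domains at an E-value threshold
#'
#' For a library of \code{n_families} profile-HMMs each searched against the
#' same database, with the per-sequence E-value threshold \code{e_seq} and
#' per-domain threshold \code{e_dom}, the expected number of false positives
#' is \deqn{N \cdot E_{seq} + N \cdot E_{seq} \cdot E_{dom}.} The first term
#' counts the expected false sequence matches across the N searches; the
#' second the expected additional false domains within truly matching
#' sequences.
#'
#' @param n_families number of family searches N (>= 0).
#' @param e_seq per-sequence E-value threshold (>= 0).
#' @param e_dom per-domain E-value threshold (>= 0).
#' @return expected false-positive count (not rounded).
#' @examples
#' expectedFalsePositives(13356, 0.01, 0.01)  # 134.8956, i.e. ~135
#' @export
expectedFalsePositives <- function(n_families, e_seq, e_dom) {
    if (n_families < 0 || e_seq < 0 || e_dom < 0)
        stop("n_families and E-value thresholds must be non-negative",
             call. = FALSE)
    n_families * e_seq + n_families * e_seq * e_dom
}

#' Cumulative proportion of overlapping domains across ranked families
#'
#' Families are ranked by their attributed overlapping-domain count,
#' descending (ties broken by accession), and the cumulative proportion of
#' all attributed domains is reported at each rank. The curve is
#' non-decreasing and reaches exactly 1 at the last rank.
#'
#' @param result an \linkS4class{AssignmentResult}.
#' @return a \code{data.frame} with columns \code{rank}, \code{family_acc},
#'   \code{n_domains}, \code{cum_prop}; zero rows when no domain was
#'   attributed.
#' @export
cumulativeOverlapCurve <- function(result) {
    stopifnot(is(result, "AssignmentResult"))
    asn <- assignments(result)
    if (nrow(asn) == 0L)
        return(data.frame(rank = integer(), family_acc = character(),
                          n_domains = integer(), cum_prop = numeric()))
    counts <- table(asn$family_acc)
    ord <- order(-as.integer(counts), names(counts))
    n <- as.integer(counts)[ord]
    data.frame(rank = seq_along(n),
               family_acc = names(counts)[ord],
               n_domains = n,
               cum_prop = cumsum(n) / sum(n))
}

#' Number of top-ranked families holding a fraction of overlapping domains
#'
#' The smallest rank of the cumulative curve whose cumulative proportion
#' reaches \code{target} — e.g. how many families hold 50\% or 75\% of all
#' overlapping domains.
#'
#' @param curve output of [cumulativeOverlapCurve()].
#' @param target fraction in (0, 1].
#' @return integer rank.
#' @export
familiesForFraction <- function(curve, target) {
    if (!is.numeric(target) || target <= 0 || target > 1)
        stop("target must be a fraction in (0, 1]", call. = FALSE)
    if (nrow(curve) == 0L)
        stop("empty cumulative curve: no overlapping domains", call. = FALSE)
    which(curve$cum_prop >= target)[1L]
}

#' Label overrepresentation along a family ranking
#'
#' Given families ranked by overlapping-clan count (descending) and a label
#' table for the whole family universe, computes at every rank x the
#' proportion of labelled families among the first x, divided by the
#' proportion of labelled families in the universe — the fold
#' overrepresentation. At x equal to the universe size the fold is exactly 1
#' by construction. Labels whose universe proportion is 0 are reported as
#' \code{NA}.
#'
#' @param ranked character vector of family accessions, most overlapping
#'   clans first; every element must appear in \code{universe$family_acc}.
#' @param universe label \code{data.frame} as returned by [labelFamilies()]
#'   (column \code{family_acc} plus one logical column per label) covering
#'   all families considered.
#' @param labels which label columns to report; defaults to all logical
#'   columns of \code{universe}.
#' @return a \code{data.frame} with columns \code{rank}, \code{family_acc}
#'   and one \code{fold_<label>} column per label.
#' @export
overrepresentationCurve <- function(ranked, universe, labels = NULL) {
    if (is.null(labels))
        labels <- names(universe)[vapply(universe, is.logical, logical(1L))]
    if (!all(ranked %in% universe$family_acc))
        stop("ranked families missing from the label universe", call. = FALSE)
    if (anyDuplicated(ranked))
        stop("duplicated family in ranking", call. = FALSE)
    x <- seq_along(ranked)
    out <- data.frame(rank = x, family_acc = ranked)
    idx <- match(ranked, universe$family_acc)
    for (lab in labels) {
        base <- mean(universe[[lab]])
        fold <- if (base == 0) rep(NA_real_, length(x))
                else (cumsum(universe[[lab]][idx]) / x) / base
        out[[paste0("fold_", lab)]] <- fold
    }
    out
}

# residues of `regions` covered by `kind` segments, per sequence, via IRanges
.coveredWidth <- function(regions, tracks, kind) {
    total <- 0L
    for (sq in unique(regions$seq_id)) {
        r <- regions[regions$seq_id == sq, , drop = FALSE]
        reg <- IRanges::reduce(IRanges::IRanges(r$start, r$end))
        segs <- trackSegments(tracks, sq, kind)
        total <- total + sum(IRanges::width(IRanges::intersect(reg, segs)))
    }
    total
}

#' Proportion of region residues under each predicted feature
#'
#' For a set of sequence regions (typically overlap regions from
#' [overlapRegions()]), the fraction of their residues covered by predicted
#' coiled-coil, transmembrane and disorder segments. Regions are unioned per
#' sequence first, so a residue never counts twice.
#'
#' @param regions a \code{data.frame} with columns \code{seq_id},
#'   \code{start}, \code{end}; must contain at least one residue.
#' @param tracks a \linkS4class{FeatureTracks}.
#' @param kinds track kinds to report; default all three.
#' @return named numeric vector of fractions in [0, 1].
#' @export
residueBiasProportions <- function(regions, tracks, kinds = .TRACK_KINDS) {
    stopifnot(is(tracks, "FeatureTracks"))
    if (!is.data.frame(regions) || nrow(regions) == 0L)
        stop("regions must be a non-empty data.frame", call. = FALSE)
    regions <- overlapRegions(regions)   # normalize to per-sequence unions
    total <- sum(regions$end - regions$start + 1)
    if (total == 0)
        stop("regions contain zero residues", call. = FALSE)
    vapply(stats::setNames(kinds, kinds),
           function(k) .coveredWidth(regions, tracks, k) / total, numeric(1L))
}

#' Conditional co-prediction of two feature kinds within regions
#'
#' Among the residues of \code{regions} predicted as \code{given_kind}, the
#' fraction also predicted as \code{also_kind} — e.g. the share of predicted
#' disordered residues that are simultaneously predicted coiled-coil.
#'
#' @param regions a \code{data.frame} with columns \code{seq_id},
#'   \code{start}, \code{end}.
#' @param tracks a \linkS4class{FeatureTracks}.
#' @param given_kind,also_kind track kinds.
#' @return a fraction in [0, 1].
#' @export
conditionalTrackOverlap <- function(regions, tracks, given_kind, also_kind) {
    stopifnot(is(tracks, "FeatureTracks"))
    regions <- overlapRegions(regions)
    given_total <- 0L
    both_total <- 0L
    for (sq in unique(regions$seq_id)) {
        r <- regions[regions$seq_id == sq, , drop = FALSE]
        reg <- IRanges::reduce(IRanges::IRanges(r$start, r$end))
        given <- IRanges::intersect(reg, trackSegments(tracks, sq, given_kind))
        given_total <- given_total + sum(IRanges::width(given))
        also <- trackSegments(tracks, sq, also_kind)
        both_total <- both_total + sum(IRanges::width(
            IRanges::intersect(given, also)))
    }
    if (given_total == 0L)
        stop("no residues predicted as '", given_kind, "' in the regions",
             call. = FALSE)
    both_total / given_total
}

#' Flag families whose hits carry high null2 bias corrections
#'
#' Among a family's hits passing the per-domain E-value threshold, a hit is
#' "high-bias" when its bias-correction score exceeds \code{ratio_cut} times
#' its bit score. The family is flagged when the fraction of high-bias hits
#' strictly exceeds \code{domain_frac}. Families with no qualifying hit are
#' excluded from consideration (neither flagged nor counted).
#'
#' @param hits a \linkS4class{DomainHits}; bit scores of qualifying hits
#'   must be positive.
#' @param ratio_cut bias/bit ratio cut-off, default 0.1 (strict \code{>}).
#' @param domain_frac fraction of domains cut-off, default 0.5 (strict
#'   \code{>}).
#' @param threshold per-domain E-value threshold, default 0.01.
#' @return sorted character vector of flagged family accessions.
#' @export
biasFlagFamilies <- function(hits, ratio_cut = 0.1, domain_frac = 0.5,
                             threshold = 0.01) {
    stopifnot(is(hits, "DomainHits"))
    keep <- domEvalue(hits) <= threshold
    fam <- familyAcc(hits)[keep]
    bit <- bitScore(hits)[keep]
    if (any(bit <= 0))
        stop("qualifying hits must have positive bit scores", call. = FALSE)
    ratio <- biasScore(hits)[keep] / bit
    high <- vapply(split(ratio > ratio_cut, fam), mean, numeric(1L))
    sort(names(high)[high > domain_frac])
}

#' Fold enrichment of a flagged set within a subset, from counts
#'
#' \code{enrichmentFold} computes
#' \eqn{(k / n_{subset}) / (K / n_{universe})} from the four counts;
#' \code{flagEnrichment} derives the counts from membership vectors: how
#' much more frequent flagged families are among the promiscuous subset than
#' in the whole universe.
#'
#' @param n_flagged_subset flagged families inside the subset (k).
#' @param n_subset subset size.
#' @param n_flagged flagged families overall (K).
#' @param n_universe universe size.
#' @return the fold enrichment (dimensionless).
#' @examples
#' enrichmentFold(36, 96, 744, 13356)  # ~6.73
#' @export
enrichmentFold <- function(n_flagged_subset, n_subset, n_flagged,
                           n_universe) {
    if (n_subset <= 0 || n_flagged <= 0 || n_universe <= 0)
        stop("subset, flagged and universe counts must be positive",
             call. = FALSE)
    (n_flagged_subset / n_subset) / (n_flagged / n_universe)
}

#' @rdname enrichmentFold
#' @param flagged character vector of flagged family accessions.
#' @param promiscuous character vector of subset accessions (e.g. families
#'   overlapping >= 3 clans).
#' @param universe character vector of all family accessions considered.
#' @export
flagEnrichment <- function(flagged, promiscuous, universe) {
    flagged <- intersect(flagged, universe)
    promiscuous <- intersect(promiscuous, universe)
    enrichmentFold(length(intersect(flagged, promiscuous)),
                   length(promiscuous), length(flagged), length(universe))
}

#' Convert a gathering threshold to an E-value
#'
#' Profile-HMM bit scores follow a Gumbel law in the null model, so a
#' family-specific bit-score inclusion threshold x translates to the
#' database E-value \deqn{E = N \exp[-\lambda (x - \tau)]} with slope
#' \eqn{\lambda} and location \eqn{\tau} taken from the model's calibration
#' and N the database size in sequences. At \eqn{x = \tau} the E-value
#' equals N, and it decreases strictly as the threshold rises.
#'
#' @param ga_bits bit-score gathering threshold x.
#' @param lam calibration slope \eqn{\lambda} (> 0).
#' @param tau calibration location \eqn{\tau} (bits).
#' @param db_size database size N (>= 1 sequences).
#' @return the E-value.
#' @examples
#' gaToEvalue(25, log(2), 15, 1024)  # 1024 * 2^-10 = 1
#' @export
gaToEvalue <- function(ga_bits, lam, tau, db_size) {
    if (any(lam <= 0))
        stop("lam must be positive", call. = FALSE)
    if (any(db_size < 1))
        stop("db_size must be >= 1", call. = FALSE)
    db_size * exp(-lam * (ga_bits - tau))
}
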