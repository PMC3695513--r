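test_that("expected false positives follow N*Eseq + N*Eseq*Edom", {
    expect_equal(expectedFalsePositives(13356, 0.01, 0.01), 134.8956)
    expect_equal(round(expectedFalsePositives(13356, 0.01, 0.01)), 135)
    expect_equal(expectedFalsePositives(5000, 0, 0.5), 0)
    expect_equal(expectedFalsePositives(100, 0.1, 0.1), 11)
    expect_error(expectedFalsePositives(-1, 0.01, 0.01), "non-negative")
    expect_error(expectedFalsePositives(10, -0.01, 0.01), "non-negative")
    # linear in N, monotone in both thresholds
    expect_equal(expectedFalsePositives(2 * 13356, 0.01, 0.01),
                 2 * expectedFalsePositives(13356, 0.01, 0.01))
    expect_lt(expectedFalsePositives(100, 0.001, 0.001),
              expectedFalsePositives(100, 0.01, 0.01))
})

mkResult <- function(counts) {
    keys <- as.character(unlist(lapply(names(counts), function(f)
        sprintf("%s_d%02d", f, seq_len(counts[[f]])))))
    fams <- as.character(rep(names(counts), unlist(counts)))
    new("AssignmentResult",
        assignments = data.frame(key = keys, family_acc = fams,
                                 seq_id = rep("s", length(keys))),
        selection_order = data.frame(family_acc = names(counts),
                                     n_domains = as.integer(unlist(counts))),
        strategy = "greedy")
}

test_that("cumulative overlap curves rank families and end at exactly 1", {
    curve <- cumulativeOverlapCurve(mkResult(c(F1 = 5L, F2 = 3L, F3 = 2L)))
    expect_equal(curve$family_acc, c("F1", "F2", "F3"))
    expect_equal(curve$cum_prop, c(0.5, 0.8, 1.0))
    expect_equal(familiesForFraction(curve, 0.5), 1L)
    expect_equal(familiesForFraction(curve, 0.75), 2L)
    expect_equal(familiesForFraction(curve, 1.0), 3L)

    single <- cumulativeOverlapCurve(mkResult(c(Fx = 4L)))
    expect_equal(single$cum_prop, 1.0)

    # equal counts: accession order, strictly increasing proportions
    tied <- cumulativeOverlapCurve(mkResult(c(B = 2L, A = 2L, C = 2L)))
    expect_equal(tied$family_acc, c("A", "B", "C"))
    expect_true(all(diff(tied$cum_prop) > 0))
    expect_equal(tied$cum_prop[3], 1.0)

    empty <- cumulativeOverlapCurve(mkResult(integer()))
    expect_equal(nrow(empty), 0L)
    expect_error(familiesForFraction(empty, 0.5), "empty")
    expect_error(familiesForFraction(curve, 0), "fraction")
    expect_error(familiesForFraction(curve, 1.5), "fraction")
})

test_that("overrepresentation folds normalize to 1 at full rank", {
    # universe of 100 families, 10 labelled; the first 10 ranked hold 5
    universe <- data.frame(
        family_acc = sprintf("F%03d", 1:100),
        cc = c(rep(c(TRUE, FALSE), 5), rep(TRUE, 5), rep(FALSE, 85)))
    ranked10 <- sprintf("F%03d", 1:10)
    oc <- overrepresentationCurve(ranked10, universe)
    expect_equal(oc$fold_cc[10], (5 / 10) / (10 / 100))  # fold 5

    # uniformly spread label -> fold 1 wherever the running proportion
    # matches the universe proportion
    uni <- data.frame(family_acc = sprintf("U%02d", 1:20),
                      lab = rep(c(TRUE, FALSE), 10))
    ocu <- overrepresentationCurve(uni$family_acc, uni)
    expect_equal(ocu$fold_lab[seq(2, 20, 2)], rep(1, 10))
    # at x = |universe| the fold is exactly 1 for any ranking
    perm <- sample(uni$family_acc)
    expect_equal(overrepresentationCurve(perm, uni)$fold_lab[20], 1)

    # an all-false label has no defined fold
    uni$never <- FALSE
    expect_true(all(is.na(overrepresentationCurve(uni$family_acc,
                                                  uni)$fold_never)))
    expect_error(overrepresentationCurve(c("U01", "NOPE"), uni), "missing")
    expect_error(overrepresentationCurve(c("U01", "U01"), uni), "duplicated")
})

test_that("residue bias proportions count covered residues once", {
    regions <- data.frame(seq_id = "s", start = 1L, end = 100L)
    ft <- FeatureTracks(data.frame(seq_id = "s", kind = "coiled_coil",
                                   start = 40L, end = 61L))
    p <- residueBiasProportions(regions, ft)
    expect_equal(p[["coiled_coil"]], 0.22)
    expect_equal(p[["disorder"]], 0)
    expect_equal(p[["transmembrane"]], 0)

    # full coverage -> 1; duplicated/overlapping regions still count once
    ftfull <- FeatureTracks(data.frame(seq_id = "s", kind = "disorder",
                                       start = 1L, end = 100L))
    dup <- rbind(regions, data.frame(seq_id = "s", start = 50L, end = 100L))
    expect_equal(residueBiasProportions(dup, ftfull)[["disorder"]], 1)
    expect_error(residueBiasProportions(regions[0, ], ft), "non-empty")
    # proportions of disjoint kinds never exceed 1 in total coverage
    both <- FeatureTracks(data.frame(seq_id = "s",
                                     kind = c("coiled_coil", "transmembrane"),
                                     start = c(1L, 51L), end = c(50L, 100L)))
    pb <- residueBiasProportions(regions, both)
    expect_equal(sum(pb[c("coiled_coil", "transmembrane")]), 1)
})

test_that("conditional co-prediction fractions follow the residue counts", {
    regions <- data.frame(seq_id = "s", start = 1L, end = 100L)
    ft <- FeatureTracks(data.frame(
        seq_id = "s", kind = c("disorder", "coiled_coil"),
        start = c(11L, 15L), end = c(20L, 40L)))
    # 10 disordered residues (11..20), 6 of them coiled-coil (15..20)
    expect_equal(conditionalTrackOverlap(regions, ft, "disorder",
                                         "coiled_coil"), 0.6)
    disjoint <- FeatureTracks(data.frame(
        seq_id = "s", kind = c("disorder", "coiled_coil"),
        start = c(1L, 60L), end = c(20L, 80L)))
    expect_equal(conditionalTrackOverlap(regions, disjoint, "disorder",
                                         "coiled_coil"), 0)
    same <- FeatureTracks(data.frame(
        seq_id = "s", kind = c("disorder", "coiled_coil"),
        start = 30L, end = 59L))
    expect_equal(conditionalTrackOverlap(regions, same, "disorder",
                                         "coiled_coil"), 1)
    expect_error(conditionalTrackOverlap(regions, disjoint, "transmembrane",
                                         "disorder"), "no residues")
})

test_that("bias flagging uses strict cuts on ratio and domain fraction", {
    h <- function(fam, ratios, ev = 1e-6)
        mkHits("s", fam, seq(1, by = 200, length.out = length(ratios)),
               seq(100, by = 200, length.out = length(ratios)),
               dom_e = ev, bit = 100, bias = 100 * ratios)
    # 2/3 of domains above ratio 0.1 -> flagged
    flagged <- biasFlagFamilies(h("FA", c(0.2, 0.15, 0.05)))
    expect_equal(flagged, "FA")
    # all ratios zero -> not flagged
    expect_equal(length(biasFlagFamilies(h("FB", c(0, 0, 0)))), 0L)
    # exactly half qualifying is NOT flagged (strict > 50%)
    expect_equal(length(biasFlagFamilies(h("FC", c(0.2, 0.05)))), 0L)
    # ratio exactly 0.1 does not count (strict > 0.1)
    expect_equal(length(biasFlagFamilies(h("FD", c(0.1, 0.1, 0.2)))), 0L)
    # hits above the E-value threshold are excluded from the fraction
    hits <- DomainHits(rbind(as.data.frame(h("FE", c(0.3, 0.3))),
                             as.data.frame(h("FE", c(0, 0, 0), ev = 1))))
    expect_equal(biasFlagFamilies(hits), "FE")
    # a family with no qualifying hits is excluded entirely
    expect_equal(length(biasFlagFamilies(h("FF", c(0.9, 0.9), ev = 1))), 0L)
})

test_that("enrichment folds reproduce hand ratios from counts or sets", {
    expect_equal(enrichmentFold(36, 96, 744, 13356), (36 / 96) / (744 / 13356))
    # all promiscuous flagged while 10% flagged overall -> fold 10
    expect_equal(enrichmentFold(5, 5, 10, 100), 10)
    universe <- sprintf("F%03d", 1:100)
    flagged <- universe[1:10]
    promiscuous <- universe[6:15]        # 5 of 10 flagged
    expect_equal(flagEnrichment(flagged, promiscuous, universe),
                 (5 / 10) / (10 / 100))
    # uniformly distributed flags -> fold 1
    expect_equal(flagEnrichment(universe[seq(1, 100, 10)], universe[1:50],
                                universe), 1)
    expect_error(enrichmentFold(1, 0, 10, 100), "positive")
})

test_that("gathering-threshold E-value conversion follows the Gumbel form", {
    # x = tau -> E = N
    expect_equal(gaToEvalue(25, 0.7, 25, 5e7), 5e7)
    # N = 1024, lambda = ln 2, x - tau = 10 -> E = 1024 * 2^-10 = 1
    expect_equal(gaToEvalue(25, log(2), 15, 1024), 1)
    # strictly decreasing in x, strictly increasing in N
    e <- gaToEvalue(c(20, 25, 30), 0.7, 10, 1e6)
    expect_true(all(diff(e) < 0))
    expect_lt(gaToEvalue(25, 0.7, 10, 1e6), gaToEvalue(25, 0.7, 10, 2e6))
    expect_error(gaToEvalue(25, -1, 10, 1e6), "lam")
    expect_error(gaToEvalue(25, 0.7, 10, 0), "db_size")
})
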