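#' @include AllClasses.R methods.R overlap.R
NULL

#' Build a synthetic-scenario configuration
#'
#' Describes a seeded synthetic dataset: a family universe partitioned into
#' clans (with a clanless fraction resolving to singleton clans), a set of
#' planted "promiscuous" families whose domains overlap partners from a
#' planned number of distinct clans, background hits that never overlap
#' across clans, and per-residue feature tracks planting heptad-length
#' coiled-coil runs (and disorder / transmembrane features) in seed members.
#'
#' Planted overlap hits draw their E-values log-uniformly below the analysis
#' threshold so filtering never removes planted structure, while background
#' hits straddle the threshold to exercise filtering. Promiscuous families'
#' hits carry high null2 bias ratios for a configurable fraction of domains.
#'
#' When \code{cc_fold} is set, coiled-coil labels are planted stochastically
#' so that promiscuous families are labelled at \code{cc_fold} times the
#' universe rate in expectation (promiscuous families labelled with
#' probability \code{cc_prom_prob}; the background probability is derived).
#'
#' @param seed RNG seed (integer).
#' @param n_families,n_clans,n_sequences universe sizes; \code{n_sequences}
#'   is the number of background hit sequences (overlap sequences are
#'   created on top as needed).
#' @param clanless_frac fraction of families left outside any named clan.
#' @param frac_cc_families,frac_cc_long_families,frac_dis_families,frac_tm_families
#'   fractions of families planted with the corresponding feature
#'   (\code{frac_cc_long_families} plants 50-residue-plus coiled-coil runs
#'   and is drawn from within the coiled-coil families).
#' @param promiscuity_plan \code{data.frame} with columns \code{n_clans}
#'   (distinct partner clans per planted family, >= 2) and \code{n_domains}
#'   (overlapping domains per partner clan, >= 1); one row per planted
#'   promiscuous family. May have zero rows (null scenario).
#' @param evalue_log10 log10 bounds for planted-hit E-values (below the
#'   threshold).
#' @param bg_evalue_log10 log10 bounds for background-hit E-values
#'   (straddling the threshold).
#' @param region_length_range alignment-length bounds for planted hits
#'   (residues).
#' @param heptad_period coiled-coil repeat period, 7 residues.
#' @param seed_members seed members per family.
#' @param threshold the analysis E-value threshold the scenario is built for.
#' @param bias_ratio_high,bias_ratio_low,bias_high_frac null2 bias/bit
#'   ratios planted for promiscuous-family and background hits, and the
#'   fraction of promiscuous-family domains receiving the high ratio.
#' @param cc_fold optional planted coiled-coil overrepresentation fold.
#' @param cc_prom_prob labelling probability for promiscuous families when
#'   \code{cc_fold} is set.
#' @return a list of class \code{"ScenarioConfig"}.
#' @export
scenarioConfig <- function(seed = 1L,
                           n_families = 60L,
                           n_clans = 30L,
                           n_sequences = 40L,
                           clanless_frac = 0.1,
                           frac_cc_families = 0.2,
                           frac_cc_long_families = 0,
                           frac_dis_families = 0.1,
                           frac_tm_families = 0.1,
                           promiscuity_plan = data.frame(
                               n_clans = c(3L, 2L, 4L),
                               n_domains = c(2L, 2L, 1L)),
                           evalue_log10 = c(-10, -4),
                           bg_evalue_log10 = c(-6, 1),
                           region_length_range = c(60L, 150L),
                           heptad_period = 7L,
                           seed_members = 4L,
                           threshold = 0.01,
                           bias_ratio_high = 0.15,
                           bias_ratio_low = 0.02,
                           bias_high_frac = 0.75,
                           cc_fold = NULL,
                           cc_prom_prob = 0.8) {
    cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
                n_clans = as.integer(n_clans),
                n_sequences = as.integer(n_sequences),
                clanless_frac = clanless_frac,
                frac_cc_families = frac_cc_families,
                frac_cc_long_families = frac_cc_long_families,
                frac_dis_families = frac_dis_families,
                frac_tm_families = frac_tm_families,
                promiscuity_plan = promiscuity_plan,
                evalue_log10 = evalue_log10,
                bg_evalue_log10 = bg_evalue_log10,
                region_length_range = as.integer(region_length_range),
                heptad_period = as.integer(heptad_period),
                seed_members = as.integer(seed_members),
                threshold = threshold,
                bias_ratio_high = bias_ratio_high,
                bias_ratio_low = bias_ratio_low,
                bias_high_frac = bias_high_frac,
                cc_fold = cc_fold, cc_prom_prob = cc_prom_prob)
    class(cfg) <- "ScenarioConfig"
    .validateScenarioConfig(cfg)
    cfg
}

.validateScenarioConfig <- function(cfg) {
    fracs <- c(cfg$clanless_frac, cfg$frac_cc_families,
               cfg$frac_cc_long_families, cfg$frac_dis_families,
               cfg$frac_tm_families)
    if (any(fracs < 0 | fracs > 1))
        stop("fractions must lie in [0, 1]", call. = FALSE)
    if (cfg$n_clans > cfg$n_families)
        stop("n_clans must not exceed n_families", call. = FALSE)
    if (cfg$n_families < 1L || cfg$n_sequences < 0L || cfg$seed_members < 1L)
        stop("counts must be positive", call. = FALSE)
    plan <- cfg$promiscuity_plan
    if (nrow(plan) > 0L) {
        if (any(plan$n_clans < 2L))
            stop("planted promiscuous families need >= 2 partner clans",
                 call. = FALSE)
        if (any(plan$n_domains < 1L))
            stop("n_domains per partner clan must be >= 1", call. = FALSE)
        if (any(plan$n_clans > cfg$n_clans - 1L))
            stop("infeasible promiscuity plan: more partner clans than ",
                 "n_clans - 1", call. = FALSE)
        if (nrow(plan) + sum(plan$n_clans) > cfg$n_families)
            stop("infeasible promiscuity plan: not enough families for ",
                 "distinct partners", call. = FALSE)
    }
    invisible(cfg)
}

#' Generate a contiguous heptad-repeat coiled-coil track
#'
#' Coiled-coil predictors emit contiguous segments whose lengths are
#' multiples of the 7-residue heptad period; this helper plants one such
#' segment of \code{n_repeats} heptads starting at \code{start}.
#'
#' @param seq_length length of the carrier sequence (residues).
#' @param n_repeats number of heptads (0 gives an empty track).
#' @param start 1-based start position.
#' @param seq_id sequence identifier for the emitted track.
#' @param period repeat period, default 7.
#' @return a \linkS4class{FeatureTracks} with zero or one coiled-coil
#'   segment.
#' @examples
#' as.data.frame(generateHeptadTrack(100, 3, 10))  # segment 10..30
#' @export
generateHeptadTrack <- function(seq_length, n_repeats, start,
                                seq_id = "synthetic", period = 7L) {
    if (n_repeats == 0L)
        return(FeatureTracks())
    end <- start + period * n_repeats - 1L
    if (start < 1L || end > seq_length)
        stop("heptad track out of bounds: ", start, "..", end,
             " on a sequence of length ", seq_length, call. = FALSE)
    FeatureTracks(data.frame(seq_id = seq_id, kind = "coiled_coil",
                             start = as.integer(start), end = as.integer(end)))
}

# log-uniform draw of E-values
.drawEvalues <- function(n, log10_range)
    10^stats::runif(n, log10_range[1L], log10_range[2L])

#' Generate a full synthetic scenario
#'
#' Emits a hit table, clan map, seed regions and feature tracks with planted
#' overlap and label structure, together with the ground truth the pipeline
#' is expected to recover. Deterministic for a fixed configuration seed:
#' generating twice yields byte-identical files.
#'
#' Each planted promiscuous family receives, for every planned partner clan,
#' a distinct partner family and \code{n_domains} dedicated sequences; on
#' each, the promiscuous hit and the partner hit share at least 75\% of
#' their alignment coordinates, comfortably beyond the 50\% qualifying rule.
#' Partner clans are distinct and differ from the promiscuous family's own
#' effective clan, so after greedy assignment the planted family's
#' overlapping-clan count equals the planned number. Background hits are
#' placed on disjoint intervals so they can never form qualifying pairs.
#'
#' @param config a [scenarioConfig()].
#' @param out_dir optional directory; when given, the five files
#'   (\code{hits.tsv}, \code{clans.tsv}, \code{seed_regions.tsv},
#'   \code{tracks.tsv}, \code{truth_labels.tsv} +
#'   \code{truth_promiscuous.tsv}) are written there.
#' @return a list with elements \code{hits} (\linkS4class{DomainHits}),
#'   \code{clans} (\linkS4class{ClanMap}), \code{seeds} (data.frame),
#'   \code{tracks} (\linkS4class{FeatureTracks}), \code{truth} (list with
#'   \code{promiscuous}, \code{clan_counts}, \code{labels}) and, when
#'   \code{out_dir} is given, \code{paths}.
#' @export
generateScenario <- function(config, out_dir = NULL) {
    stopifnot(inherits(config, "ScenarioConfig"))
    .validateScenarioConfig(config)
    if (exists(".Random.seed", envir = globalenv())) {
        saved <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", saved, envir = globalenv()))
    }
    set.seed(config$seed)

    fams <- sprintf("FAM%04d", seq_len(config$n_families))
    clan_ids <- sprintf("CL%04d", seq_len(config$n_clans))
    clan_of <- clan_ids[((seq_along(fams) - 1L) %% config$n_clans) + 1L]
    n_clanless <- floor(config$clanless_frac * config$n_families)
    if (n_clanless > 0L)   # last families become clanless -> singleton clans
        clan_of[seq(config$n_families - n_clanless + 1L, config$n_families)] <-
            NA_character_
    clans <- ClanMap(fams, clan_of)
    eff <- effectiveClan(clans, fams)

    plan <- config$promiscuity_plan
    n_prom <- nrow(plan)
    prom <- if (n_prom > 0L) sort(sample(fams, n_prom)) else character()

    ## ---- planted overlap hits ----
    hit_rows <- list()
    truth_clans <- stats::setNames(integer(n_prom), prom)
    truth_doms <- stats::setNames(integer(n_prom), prom)
    pool <- setdiff(fams, prom)          # partner families, used once each
    for (p in seq_len(n_prom)) {
        P <- prom[p]
        k <- plan$n_clans[p]
        m <- plan$n_domains[p]
        # partners from k distinct effective clans, all != P's clan
        avail <- pool[eff[match(pool, fams)] != eff[match(P, fams)]]
        avail <- sample(avail)
        partners <- character()
        used_clans <- character()
        for (q in avail) {
            qc <- eff[match(q, fams)]
            if (!qc %in% used_clans) {
                partners <- c(partners, q)
                used_clans <- c(used_clans, qc)
                if (length(partners) == k) break
            }
        }
        if (length(partners) < k)
            stop("infeasible promiscuity plan: could not find ", k,
                 " distinct partner clans for ", P, call. = FALSE)
        pool <- setdiff(pool, partners)
        for (qi in seq_along(partners)) {
            Q <- partners[qi]
            for (d in seq_len(m)) {
                sq <- sprintf("OVSEQ_%s_%s_%02d", P, Q, d)
                L <- sample(seq(config$region_length_range[1L],
                                config$region_length_range[2L]), 1L)
                a <- sample(50:250, 1L)
                shift <- sample(0:(L %/% 4L), 1L)
                ev <- .drawEvalues(2L, config$evalue_log10)
                bit <- stats::runif(2L, 30, 200)
                high <- stats::runif(1L) < config$bias_high_frac
                bias_p <- bit[1L] * if (high) config$bias_ratio_high
                          else config$bias_ratio_low
                hit_rows[[length(hit_rows) + 1L]] <- data.frame(
                    seq_id = sq,
                    family_acc = c(P, Q),
                    seq_evalue = ev, dom_evalue = ev,
                    bit_score = bit,
                    bias_score = c(bias_p, bit[2L] * config$bias_ratio_low),
                    ali_start = c(a, a + shift),
                    ali_end = c(a + L - 1L, a + shift + L - 1L),
                    env_start = c(a, a + shift) - 3L,
                    env_end = c(a + L - 1L, a + shift + L - 1L) + 3L)
            }
        }
        truth_clans[P] <- k
        truth_doms[P] <- k * m
    }

    ## ---- background hits: disjoint intervals, never qualifying ----
    if (config$n_sequences > 0L) {
        bg_seqs <- sprintf("BGSEQ%04d", seq_len(config$n_sequences))
        fam_cycle <- rep(fams, length.out = 2L * config$n_sequences)
        slot_start <- c(1L, 301L)   # two disjoint windows per sequence
        for (i in seq_len(config$n_sequences)) {
            for (s in 1:2) {
                f <- fam_cycle[2L * (i - 1L) + s]
                L <- sample(60:120, 1L)
                a <- slot_start[s] + sample(0:50, 1L)
                ev <- .drawEvalues(1L, config$bg_evalue_log10)
                bit <- stats::runif(1L, 20, 150)
                hit_rows[[length(hit_rows) + 1L]] <- data.frame(
                    seq_id = bg_seqs[i], family_acc = f,
                    seq_evalue = ev, dom_evalue = ev,
                    bit_score = bit,
                    bias_score = bit * config$bias_ratio_low,
                    ali_start = a, ali_end = a + L - 1L,
                    env_start = a - 2L, env_end = a + L + 1L)
            }
        }
    }
    hits <- DomainHits(do.call(rbind, hit_rows))

    ## ---- planted labels ----
    if (!is.null(config$cc_fold)) {
        f <- config$cc_fold
        p_p <- config$cc_prom_prob
        n_bg <- config$n_families - n_prom
        p_b <- (config$n_families * p_p / f - n_prom * p_p) / n_bg
        if (p_b < 0 || p_b > 1)
            stop("infeasible cc_fold plan: derived background labelling ",
                 "probability ", signif(p_b, 3), " outside [0, 1]",
                 call. = FALSE)
        is_cc <- stats::setNames(logical(config$n_families), fams)
        is_cc[prom] <- stats::runif(n_prom) < p_p
        bg <- setdiff(fams, prom)
        is_cc[bg] <- stats::runif(n_bg) < p_b
        cc_fams <- fams[is_cc]
    } else {
        cc_fams <- sort(sample(fams, round(config$frac_cc_families *
                                           config$n_families)))
    }
    cc_long_fams <- if (config$frac_cc_long_families > 0)
        sort(sample(cc_fams, min(length(cc_fams),
                                 round(config$frac_cc_long_families *
                                       config$n_families))))
        else character()
    dis_fams <- sort(sample(fams, round(config$frac_dis_families *
                                        config$n_families)))
    tm_fams <- sort(sample(fams, round(config$frac_tm_families *
                                       config$n_families)))

    ## ---- seed regions + tracks ----
    region_len <- 200L
    n_pos <- ceiling(config$seed_members / 2)  # members carrying the feature
    seed_rows <- list(); track_rows <- list()
    for (f in fams) {
        for (k in seq_len(config$seed_members)) {
            sq <- sprintf("SEED_%s_%d", f, k)
            seed_rows[[length(seed_rows) + 1L]] <- data.frame(
                family_acc = f, seq_id = sq, start = 1L, end = region_len)
            if (f %in% cc_fams && k <= n_pos) {
                reps <- if (f %in% cc_long_fams) 8L else 4L  # 56 or 28 res
                st <- sample(seq(5L, region_len - reps * config$heptad_period),
                             1L)
                track_rows[[length(track_rows) + 1L]] <- data.frame(
                    seq_id = sq, kind = "coiled_coil", start = st,
                    end = st + reps * config$heptad_period - 1L)
            } else if (k == 1L) {
                # sub-threshold decoy run (14 residues, 2 heptads)
                track_rows[[length(track_rows) + 1L]] <- data.frame(
                    seq_id = sq, kind = "coiled_coil", start = 20L, end = 33L)
            }
            if (f %in% dis_fams && k <= n_pos)
                track_rows[[length(track_rows) + 1L]] <- data.frame(
                    seq_id = sq, kind = "disorder", start = 100L, end = 129L)
            if (f %in% tm_fams && k <= n_pos)
                track_rows[[length(track_rows) + 1L]] <- data.frame(
                    seq_id = sq, kind = "transmembrane",
                    start = c(10L, 45L), end = c(30L, 65L))
        }
    }
    seeds <- do.call(rbind, seed_rows)
    rownames(seeds) <- NULL
    tracks <- FeatureTracks(do.call(rbind, track_rows))

    truth <- list(
        promiscuous = prom,
        clan_counts = truth_clans,
        overlapping_domains = truth_doms,
        labels = data.frame(
            family_acc = fams,
            cc20 = fams %in% cc_fams,
            cc50 = fams %in% cc_long_fams,
            dis20 = fams %in% dis_fams,
            tmh2 = fams %in% tm_fams))

    out <- list(hits = hits, clans = clans, seeds = seeds, tracks = tracks,
                truth = truth, config = config)
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        paths <- c(hits = file.path(out_dir, "hits.tsv"),
                   clans = file.path(out_dir, "clans.tsv"),
                   seeds = file.path(out_dir, "seed_regions.tsv"),
                   tracks = file.path(out_dir, "tracks.tsv"),
                   truth_labels = file.path(out_dir, "truth_labels.tsv"),
                   truth_promiscuous = file.path(out_dir,
                                                 "truth_promiscuous.tsv"))
        writeDomainHits(hits, paths["hits"])
        writeClanMap(clans, paths["clans"])
        writeSeedRegions(seeds, paths["seeds"])
        writeFeatureTracks(tracks, paths["tracks"])
        utils::write.table(truth$labels, paths["truth_labels"], sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(
            data.frame(family_acc = prom, n_clans = as.integer(truth_clans),
                       n_overlapping_domains = as.integer(truth_doms)),
            paths["truth_promiscuous"], sep = "\t", quote = FALSE,
            row.names = FALSE)
        out$paths <- paths
    }
    out
}

#' Generate a null scenario with no planted overlaps
#'
#' Same as [generateScenario()] with an empty promiscuity plan: every hit
#' lies on its own disjoint interval, so overlap detection must return no
#' pairs, while labels and expected-false-positive computations remain
#' exercised.
#'
#' @param config a [scenarioConfig()]; its promiscuity plan is replaced by
#'   an empty one.
#' @param out_dir optional output directory, as in [generateScenario()].
#' @return as [generateScenario()].
#' @export
generateNullScenario <- function(config, out_dir = NULL) {
    config$promiscuity_plan <- data.frame(n_clans = integer(),
                                          n_domains = integer())
    generateScenario(config, out_dir)
}
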