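test_that("DomainHits enforces coordinate and score invariants", {
    expect_error(mkHits("s1", "PF1", 150, 140), "ali_start")
    expect_error(DomainHits(data.frame(
        seq_id = "s1", family_acc = "PF1", seq_evalue = 1e-5,
        dom_evalue = 1e-5, bit_score = 50, bias_score = 0,
        ali_start = 10L, ali_end = 60L, env_start = 20L, env_end = 70L)),
        "envelope")
    expect_error(DomainHits(data.frame(
        seq_id = "s1", family_acc = "PF1", seq_evalue = -1,
        dom_evalue = 1e-5, bit_score = 50, bias_score = 0,
        ali_start = 10L, ali_end = 60L, env_start = 10L, env_end = 60L)),
        "non-negative")
    h <- mkHits("s1", "PF1", 10, 60)
    expect_s4_class(h, "DomainHits")
    expect_equal(length(h), 1L)
})

test_that("genuine hmmsearch --domtblout output parses with the documented column mapping", {
    f <- system.file("extdata", "toy_domtblout.txt", package = "ClanOverlaps")
    h <- readDomainHits(f)
    expect_equal(length(h), 3L)
    expect_equal(seqId(h), c("t1", "t1", "t2"))
    # query accession column is "-" in this run: family falls back to name
    expect_equal(unique(familyAcc(h)), "seed")
    expect_equal(seqEvalue(h)[1], 1.5e-42)
    expect_equal(domEvalue(h)[1], 3.3e-23)   # independent E-value column
    expect_equal(bitScore(h)[1], 68.3)       # domain, not sequence, score
    expect_equal(biasScore(h)[1], 5.7)
    expect_equal(aliStart(h), c(1L, 27L, 1L))
    expect_equal(aliEnd(h), c(26L, 52L, 26L))
    expect_true(all(envStart(h) <= aliStart(h) & aliEnd(h) <= envEnd(h)))
})

test_that("domtblout parsing handles accessions, comments and malformed rows", {
    row <- paste("sp|Q1|SEQ1 - 500 FamA PF00001.12 120",
                 "1e-30 99.9 1.2 1 2 1e-20 2e-20 55.5 0.8",
                 "5 110 101 190 99 195 0.98 a description with spaces")
    f <- withr::local_tempfile(lines = c("# comment", row, "#"))
    h <- readDomainHits(f, dialect = "domtblout")
    expect_equal(familyAcc(h), "PF00001.12")
    expect_equal(seqId(h), "sp|Q1|SEQ1")
    expect_equal(domEvalue(h), 2e-20)
    expect_equal(c(aliStart(h), aliEnd(h), envStart(h), envEnd(h)),
                 c(101L, 190L, 99L, 195L))

    empty <- withr::local_tempfile(lines = c("# only", "# comments"))
    expect_equal(length(readDomainHits(empty)), 0L)

    short <- withr::local_tempfile(lines = c("# ok", "a b c"))
    expect_error(readDomainHits(short, dialect = "domtblout"), "line 2")

    # ali outside env -> validation error citing the line
    bad <- sub("99 195", "105 195", row)
    fb <- withr::local_tempfile(lines = c("# c", bad))
    expect_error(readDomainHits(fb, dialect = "domtblout"), "line 2")

    missing <- file.path(withr::local_tempdir(), "nope.txt")
    expect_error(readDomainHits(missing), "no such file")
})

test_that("internal TSV round-trips losslessly and is auto-detected", {
    set.seed(42)
    h <- randomHits(25)
    f <- withr::local_tempfile()
    writeDomainHits(h, f)
    h2 <- readDomainHits(f)               # dialect sniffed from header
    expect_equal(as.data.frame(h2), as.data.frame(h), tolerance = 0)
    h3 <- readDomainHits(f, dialect = "tsv")
    expect_equal(as.data.frame(h3), as.data.frame(h))

    f0 <- withr::local_tempfile()
    writeDomainHits(DomainHits(), f0)
    expect_equal(length(readDomainHits(f0)), 0L)
})

test_that("clan map reading implements the singleton convention", {
    f <- withr::local_tempfile(lines = c("PF1\tCL1", "PF2\tCL1", "PF3\t"))
    cm <- readClanMap(f)
    eff <- effectiveClan(cm, c("PF1", "PF2", "PF3"))
    expect_equal(eff[1], eff[2])                    # shared clan
    expect_equal(eff[3], "SINGLETON:PF3")           # clanless -> own clan
    # families absent from the map also resolve to singletons
    expect_equal(effectiveClan(cm, "PF9"), "SINGLETON:PF9")

    empty <- withr::local_tempfile(lines = character())
    cm0 <- readClanMap(empty)
    expect_equal(length(cm0), 0L)
    expect_equal(effectiveClan(cm0, "PFX"), "SINGLETON:PFX")

    conflict <- withr::local_tempfile(lines = c("PF1\tCL1", "PF1\tCL2"))
    expect_error(readClanMap(conflict), "conflicting clans")
    # duplicate but consistent rows are tolerated
    dup <- withr::local_tempfile(lines = c("PF1\tCL1", "PF1\tCL1"))
    expect_equal(length(readClanMap(dup)), 1L)

    f2 <- withr::local_tempfile()
    writeClanMap(cm, f2)
    expect_equal(effectiveClan(readClanMap(f2), c("PF1", "PF3")),
                 c("CL1", "SINGLETON:PF3"))
})

test_that("feature tracks normalize on construction and the operation is idempotent", {
    ft <- FeatureTracks(data.frame(seq_id = "s1", kind = "coiled_coil",
                                   start = c(11L, 5L), end = c(20L, 10L)))
    df <- as.data.frame(ft)
    expect_equal(nrow(df), 1L)           # adjacent segments merged
    expect_equal(c(df$start, df$end), c(5L, 20L))

    # idempotence: re-normalizing a normalized object changes nothing
    expect_equal(as.data.frame(FeatureTracks(df)), df)

    # different kinds and sequences are never merged together
    ft2 <- FeatureTracks(data.frame(
        seq_id = c("s1", "s1", "s2"),
        kind = c("coiled_coil", "disorder", "coiled_coil"),
        start = 5L, end = 10L))
    expect_equal(length(ft2), 3L)

    expect_error(FeatureTracks(data.frame(seq_id = "s1", kind = "disorder",
                                          start = 10L, end = 5L)),
                 "start > end")
    expect_error(FeatureTracks(data.frame(seq_id = "s1", kind = "helix",
                                          start = 1L, end = 5L)),
                 "unknown track kind")
})

test_that("feature-track and seed-region files read and write faithfully", {
    f <- withr::local_tempfile(lines = c(
        "# coordinates: 1-based inclusive", "seq_id\tstart\tend\tkind",
        "s1\t5\t10\tcoiled_coil", "s1\t11\t20\tcoiled_coil",
        "s2\t3\t9\tdisorder"))
    ft <- readFeatureTracks(f)
    expect_equal(length(ft), 2L)        # s1 segments merged on read
    expect_equal(as.data.frame(ft)$end[1], 20L)

    bad <- withr::local_tempfile(lines = c("seq_id\tstart\tend\tkind",
                                           "s1\t10\t5\tdisorder"))
    expect_error(readFeatureTracks(bad), "line 2")
    unk <- withr::local_tempfile(lines = c("s1\t1\t5\thelix"))
    expect_error(readFeatureTracks(unk), "unknown track kind")
    empty <- withr::local_tempfile(lines = character())
    expect_equal(length(readFeatureTracks(empty)), 0L)

    f2 <- withr::local_tempfile()
    writeFeatureTracks(ft, f2)
    expect_equal(as.data.frame(readFeatureTracks(f2)), as.data.frame(ft))

    seeds <- data.frame(family_acc = c("PF1", "PF1"), seq_id = c("a", "b"),
                        start = c(1L, 10L), end = c(90L, 99L))
    f3 <- withr::local_tempfile()
    writeSeedRegions(seeds, f3)
    expect_equal(readSeedRegions(f3), seeds)
    badseed <- withr::local_tempfile(lines = c("family_acc\tseq_id\tstart\tend",
                                               "PF1\ta\t9\t2"))
    expect_error(readSeedRegions(badseed), "start > end")
})
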