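#' @include AllClasses.R
NULL

# split a raw line on runs of whitespace
.splitFields <- function(line) strsplit(trimws(line), "[ \t]+")[[1L]]

.parseNum <- function(x, what, lineno) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v)))
        stop(sprintf("line %d: cannot parse %s ('%s')", lineno, what,
                     x[is.na(v)][1L]), call. = FALSE)
    v
}

#' Read domain hits from a file
#'
#' Parses either the HMMER3 per-domain tabular output (\code{--domtblout}:
#' whitespace-separated columns, comment lines starting with \code{#}) or the
#' package's internal 10-column TSV written by [writeDomainHits()]. In the
#' HMMER3 dialect the per-domain E-value is taken from the independent
#' E-value column (i-Evalue), the score and bias from the domain columns, and
#' coordinates from the \code{ali from/to} and \code{env from/to} columns;
#' the family accession falls back to the query name when the accession
#' column is \code{"-"}.
#'
#' @param path path to the hit table.
#' @param dialect \code{"auto"} (default; sniffs the format), \code{"domtblout"}
#'   or \code{"tsv"}.
#' @return a \linkS4class{DomainHits}.
#' @examples
#' f <- system.file("extdata", "toy_domtblout.txt", package = "ClanOverlaps")
#' readDomainHits(f)
#' @export
readDomainHits <- function(path, dialect = c("auto", "domtblout", "tsv")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("no such file: ", path, call. = FALSE)
    lines <- readLines(path)
    if (dialect == "auto") {
        body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
        dialect <- if (length(body) && startsWith(body[1L], "seq_id\t"))
            "tsv" else "domtblout"
    }
    if (dialect == "tsv")
        .readHitsTsv(lines) else .readHitsDomtblout(lines)
}

.readHitsDomtblout <- function(lines) {
    rows <- list()
    for (i in seq_along(lines)) {
        line <- lines[i]
        if (!nzchar(trimws(line)) || startsWith(trimws(line), "#"))
            next
        f <- .splitFields(line)
        if (length(f) < 21L)
            stop(sprintf("line %d: expected >= 21 whitespace-separated fields, got %d",
                         i, length(f)), call. = FALSE)
        acc <- if (f[5L] == "-") f[4L] else f[5L]
        rows[[length(rows) + 1L]] <- data.frame(
            seq_id = f[1L], family_acc = acc,
            seq_evalue = .parseNum(f[7L], "sequence E-value", i),
            dom_evalue = .parseNum(f[13L], "domain E-value", i),
            bit_score = .parseNum(f[14L], "bit score", i),
            bias_score = .parseNum(f[15L], "bias score", i),
            ali_start = .parseNum(f[18L], "ali from", i),
            ali_end = .parseNum(f[19L], "ali to", i),
            env_start = .parseNum(f[20L], "env from", i),
            env_end = .parseNum(f[21L], "env to", i),
            lineno = i)
    }
    .buildHits(rows)
}

.readHitsTsv <- function(lines) {
    rows <- list()
    header_seen <- FALSE
    for (i in seq_along(lines)) {
        line <- lines[i]
        if (!nzchar(trimws(line)) || startsWith(trimws(line), "#"))
            next
        f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
        if (!header_seen) {
            if (!identical(f, .HIT_COLUMNS))
                stop(sprintf("line %d: bad TSV header", i), call. = FALSE)
            header_seen <- TRUE
            next
        }
        if (length(f) != 10L)
            stop(sprintf("line %d: expected 10 tab-separated fields, got %d",
                         i, length(f)), call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
            seq_id = f[1L], family_acc = f[2L],
            seq_evalue = .parseNum(f[3L], "sequence E-value", i),
            dom_evalue = .parseNum(f[4L], "domain E-value", i),
            bit_score = .parseNum(f[5L], "bit score", i),
            bias_score = .parseNum(f[6L], "bias score", i),
            ali_start = .parseNum(f[7L], "ali_start", i),
            ali_end = .parseNum(f[8L], "ali_end", i),
            env_start = .parseNum(f[9L], "env_start", i),
            env_end = .parseNum(f[10L], "env_end", i),
            lineno = i)
    }
    .buildHits(rows)
}

.buildHits <- function(rows) {
    if (!length(rows))
        return(DomainHits())
    df <- do.call(rbind, rows)
    msg <- .validateHitFrame(df)
    if (!isTRUE(msg)) {
        # re-check row by row to cite the offending input line
        for (r in seq_len(nrow(df))) {
            m <- .validateHitFrame(df[r, , drop = FALSE])
            if (!isTRUE(m))
                stop(sprintf("line %d: %s", df$lineno[r],
                             sub("^row 1: ", "", m)), call. = FALSE)
        }
        stop(msg, call. = FALSE)
    }
    df$lineno <- NULL
    DomainHits(df)
}

#' Write domain hits to the internal TSV dialect
#'
#' Emits a header line followed by one tab-separated row per hit; E-values
#' and scores are printed with full precision so that a write/read round
#' trip is lossless.
#'
#' @param hits a \linkS4class{DomainHits}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDomainHits <- function(hits, path) {
    stopifnot(is(hits, "DomainHits"))
    df <- as.data.frame(hits)
    lines <- paste(.HIT_COLUMNS, collapse = "\t")
    if (nrow(df) > 0L) {
        body <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d",
                        df$seq_id, df$family_acc,
                        format(df$seq_evalue, digits = 17, trim = TRUE,
                               scientific = TRUE),
                        format(df$dom_evalue, digits = 17, trim = TRUE,
                               scientific = TRUE),
                        format(df$bit_score, digits = 17, trim = TRUE),
                        format(df$bias_score, digits = 17, trim = TRUE),
                        df$ali_start, df$ali_end, df$env_start, df$env_end)
        lines <- c(lines, body)
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read a family-to-clan membership table
#'
#' Accepts a two-or-more-column TSV in the Pfam-A.clans style: first column
#' the family accession, second the clan accession (empty for clanless
#' families); extra columns are ignored. A header line starting with
#' \code{family_acc} and comment lines starting with \code{#} are skipped.
#'
#' @param path path to the TSV.
#' @return a \linkS4class{ClanMap}.
#' @export
readClanMap <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path, call. = FALSE)
    lines <- readLines(path)
    fam <- character(); clan <- character()
    for (i in seq_along(lines)) {
        line <- lines[i]
        if (!nzchar(trimws(line)) || startsWith(line, "#"))
            next
        f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
        if (f[1L] == "family_acc")
            next
        fam <- c(fam, f[1L])
        clan <- c(clan, if (length(f) >= 2L && nzchar(f[2L])) f[2L]
                  else NA_character_)
    }
    if (anyDuplicated(fam)) {
        dup <- fam[duplicated(fam)]
        for (d in unique(dup)) {
            cl <- unique(clan[fam == d])
            if (length(cl) > 1L)
                stop("family ", d, " mapped to conflicting clans: ",
                     paste(cl, collapse = ", "), call. = FALSE)
        }
        keep <- !duplicated(fam)
        fam <- fam[keep]; clan <- clan[keep]
    }
    ClanMap(fam, clan)
}

#' @rdname readClanMap
#' @param map a \linkS4class{ClanMap} to write.
#' @export
writeClanMap <- function(map, path) {
    stopifnot(is(map, "ClanMap"))
    cl <- map@clan
    cl[is.na(cl)] <- ""
    writeLines(c("family_acc\tclan_acc",
                 paste(map@family, cl, sep = "\t")), path)
    invisible(path)
}

#' Read per-residue feature tracks
#'
#' BED-like TSV with columns \code{seq_id}, \code{start}, \code{end},
#' \code{kind}; coordinates are 1-based inclusive (declared in the file
#' header comment). Segments are normalized on read: sorted and merged where
#' overlapping or adjacent, per sequence and kind.
#'
#' @param path path to the TSV.
#' @return a \linkS4class{FeatureTracks}.
#' @export
readFeatureTracks <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path, call. = FALSE)
    lines <- readLines(path)
    rows <- list()
    for (i in seq_along(lines)) {
        line <- lines[i]
        if (!nzchar(trimws(line)) || startsWith(line, "#"))
            next
        f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
        if (f[1L] == "seq_id")
            next
        if (length(f) < 4L)
            stop(sprintf("line %d: expected 4 fields", i), call. = FALSE)
        start <- .parseNum(f[2L], "start", i)
        end <- .parseNum(f[3L], "end", i)
        if (!f[4L] %in% .TRACK_KINDS)
            stop(sprintf("line %d: unknown track kind '%s'", i, f[4L]),
                 call. = FALSE)
        if (start > end)
            stop(sprintf("line %d: segment start %d > end %d", i, start, end),
                 call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
            seq_id = f[1L], kind = f[4L],
            start = as.integer(start), end = as.integer(end))
    }
    if (!length(rows))
        return(FeatureTracks())
    FeatureTracks(do.call(rbind, rows))
}

#' @rdname readFeatureTracks
#' @param tracks a \linkS4class{FeatureTracks} to write.
#' @export
writeFeatureTracks <- function(tracks, path) {
    stopifnot(is(tracks, "FeatureTracks"))
    df <- as.data.frame(tracks)
    writeLines(c("# coordinates: 1-based inclusive",
                 "seq_id\tstart\tend\tkind",
                 if (nrow(df)) sprintf("%s\t%d\t%d\t%s", df$seq_id, df$start,
                                       df$end, df$kind)), path)
    invisible(path)
}

#' Read/write seed regions
#'
#' Seed regions are the curated member regions a family's profile-HMM was
#' built from; labels are computed from predictor tracks clipped to these
#' regions. TSV columns: \code{family_acc}, \code{seq_id}, \code{start},
#' \code{end} (1-based inclusive).
#'
#' @param path path to the TSV.
#' @return a \code{data.frame} with those four columns.
#' @export
readSeedRegions <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path, call. = FALSE)
    lines <- readLines(path)
    rows <- list()
    for (i in seq_along(lines)) {
        line <- lines[i]
        if (!nzchar(trimws(line)) || startsWith(line, "#"))
            next
        f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
        if (f[1L] == "family_acc")
            next
        start <- .parseNum(f[3L], "start", i)
        end <- .parseNum(f[4L], "end", i)
        if (start > end)
            stop(sprintf("line %d: seed region start > end", i), call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
            family_acc = f[1L], seq_id = f[2L],
            start = as.integer(start), end = as.integer(end))
    }
    if (!length(rows))
        return(data.frame(family_acc = character(), seq_id = character(),
                          start = integer(), end = integer()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' @rdname readSeedRegions
#' @param seeds a seed-region \code{data.frame} to write.
#' @export
writeSeedRegions <- function(seeds, path) {
    writeLines(c("family_acc\tseq_id\tstart\tend",
                 if (nrow(seeds)) sprintf("%s\t%s\t%d\t%d", seeds$family_acc,
                                          seeds$seq_id, as.integer(seeds$start),
                                          as.integer(seeds$end))), path)
    invisible(path)
}
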