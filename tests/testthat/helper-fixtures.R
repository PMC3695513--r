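# compact builders for hand-constructed instances

mkHits <- function(seq_id, fam, s, e, dom_e = 1e-6, seq_e = dom_e,
                   bit = 50, bias = 0) {
    n <- max(length(seq_id), length(fam), length(s), length(e))
    DomainHits(data.frame(
        seq_id = rep_len(seq_id, n), family_acc = rep_len(fam, n),
        seq_evalue = rep_len(seq_e, n), dom_evalue = rep_len(dom_e, n),
        bit_score = rep_len(bit, n), bias_score = rep_len(bias, n),
        ali_start = as.integer(rep_len(s, n)),
        ali_end = as.integer(rep_len(e, n)),
        env_start = as.integer(rep_len(s, n)),
        env_end = as.integer(rep_len(e, n))))
}

# random instance for property tests: n hits spread over a few sequences
# and families, alignment intervals short enough to collide often
randomHits <- function(n, n_seqs = 3L, n_fams = 8L) {
    s <- sample(1:150, n, replace = TRUE)
    len <- sample(10:80, n, replace = TRUE)
    ev <- 10^stats::runif(n, -8, 1)
    DomainHits(data.frame(
        seq_id = sprintf("s%02d", sample(n_seqs, n, replace = TRUE)),
        family_acc = sprintf("PF%02d", sample(n_fams, n, replace = TRUE)),
        seq_evalue = ev, dom_evalue = ev,
        bit_score = stats::runif(n, 10, 100),
        bias_score = stats::runif(n, 0, 5),
        ali_start = s, ali_end = s + len - 1L,
        env_start = pmax(1L, s - 2L), env_end = s + len + 1L))
}

# random clan map over PF01..PFk with some clanless families
randomClanMap <- function(n_fams = 8L, n_clans = 4L) {
    clan <- sprintf("CL%d", sample(n_clans, n_fams, replace = TRUE))
    clan[stats::runif(n_fams) < 0.2] <- NA
    ClanMap(sprintf("PF%02d", seq_len(n_fams)), clan)
}
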