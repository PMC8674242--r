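# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately brute-force and base-R so it shares no
# code path with the package implementation.

oracle_revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

# Exact occurrences of `query` in `subject` (plain strings), forward strand,
# via fixed-string gregexpr; returns integer start positions.
oracle_find_fwd <- function(query, subject) {
  if (nchar(query) == 0 || nchar(subject) < nchar(query)) return(integer(0))
  hits <- gregexpr(query, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  out <- integer(0)          # gregexpr skips overlapping hits; rescan
  pos <- 1L
  while (pos + nchar(query) - 1L <= nchar(subject)) {
    h <- regexpr(query, substr(subject, pos, nchar(subject)), fixed = TRUE)
    if (h == -1) break
    out <- c(out, pos + h - 1L)
    pos <- pos + h
  }
  out
}

# Does `query` occur on either strand of any subject string?
oracle_occurs <- function(query, subjects) {
  rc <- oracle_revcomp(query)
  any(vapply(subjects, function(s)
    length(oracle_find_fwd(query, s)) > 0 ||
      length(oracle_find_fwd(rc, s)) > 0, logical(1)))
}

# Brute-force adapter trim implementing the stated rule directly on
# character vectors (longest flush-end suffix vs adapter prefix).
oracle_trim <- function(seq, adapter, rate = 0.10) {
  L <- nchar(seq)
  sv <- strsplit(seq, "")[[1]]
  av <- strsplit(adapter, "")[[1]]
  for (k in seq(min(L, length(av)), 1L)) {
    mism <- sum(sv[(L - k + 1):L] != av[1:k])
    if (mism <= floor(k * rate)) return(substr(seq, 1, L - k))
  }
  seq
}

# Brute-force tandem-extension repeat length: longest run immediately
# adjacent to the event over which `context` equals cyclic copies of `unit`.
# `side` = "three" scans forward from index `from`; "five" scans backward
# with the unit in reverse phase.
oracle_repeat_run <- function(context, from, unit, side) {
  uv <- strsplit(unit, "")[[1]]; N <- length(uv)
  cv <- strsplit(context, "")[[1]]
  r <- 0L
  if (side == "three") {
    while (from + r <= length(cv) && cv[from + r] == uv[(r %% N) + 1]) r <- r + 1L
  } else {
    while (from - r >= 1 && cv[from - r] == uv[((N - 1 - r) %% N) + 1]) r <- r + 1L
  }
  r
}

# Exhaustive placement oracle for the theoretical supporting-length range.
# Enumerates every placement of an L-base read over the event and keeps the
# placements that yield a mutation-supporting observation:
#   * substitutions: every placement containing the event (the per-base
#     mismatch cost never favors clipping the event);
#   * indels: the gapped alignment (penalty N+6, matches +1) must score at
#     least as well as clipping either side at the junction (penalty 5), and
#     the read must contain the full flanking repeat runs (len >= R).
# Returns the achievable sets of 5', 3' and shorter supporting lengths.
oracle_bounds <- function(mut_type, N, L, R5 = 0, R3 = 0) {
  if (mut_type %in% c("SNV", "MNV")) {
    len5 <- 0:(L - N)
    len3 <- (L - N) - len5
    keep <- rep(TRUE, length(len5))
  } else if (mut_type == "DEL") {
    len5 <- 0:L
    len3 <- L - len5
    through <- L - (N + 6)               # all read bases match across the gap
    keep <- through >= (len5 - 5) & through >= (len3 - 5) &
      len5 >= R5 & len3 >= R3
  } else {                               # INS
    len5 <- 0:(L - N)
    len3 <- (L - N) - len5
    through <- (L - N) - (N + 6)         # inserted bases earn no match points
    keep <- through >= (len5 - 5) & through >= (len3 - 5) &
      len5 >= R5 & len3 >= R3
  }
  list(len5 = len5[keep], len3 = len3[keep],
       shorter = pmin(len5, len3)[keep])
}

# Build an aligned-read data.frame row compatible with fetch_reads() output.
make_read <- function(qname, pos, cigar, seq, strand = "+", flag = NULL,
                      qual = NULL) {
  if (is.null(flag)) flag <- if (strand == "-") 16L else 0L
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  data.frame(qname = qname, flag = flag, strand = strand, pos = as.integer(pos),
             cigar = cigar, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

make_reads <- function(...) do.call(rbind, list(...))

# In-memory genome from named character sequences.
make_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Write a SAM + BAM for a reads data.frame over a genome; returns bam path.
write_test_bam <- function(reads, genome, dir, extra_lines = character(0)) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      Biostrings::width(genome)))
  ## stable sort by position only: within-position record order is the
  ## caller's, which lets tests vary BAM record order legally
  reads <- reads[order(reads$pos), , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag,
                  if (!is.null(reads$rname)) reads$rname else names(genome)[1],
                  reads$pos, reads$cigar, reads$seq, reads$qual)
  sam <- file.path(dir, "test.sam")
  writeLines(c(header, body, extra_lines), sam)
  Rsamtools::asBam(sam, file.path(dir, "test"), overwrite = TRUE,
                   indexDestination = TRUE)
}
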