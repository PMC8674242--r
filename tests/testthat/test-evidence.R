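# Adapter trimming, event location, supporting lengths, repeat context.

test_that("adapter trimming removes flush-end occurrences within the rate", {
  ad <- "AGATCGGAAGAGC"                        # 13 bases
  r <- trim_adapter(paste0("ACGTACGT", ad), NULL, ad)
  expect_equal(r$seq, "ACGTACGT")
  expect_equal(r$n_trimmed, 13L)
  ad1 <- sub("G", "T", ad)                     # 1 mismatch in 13 (7.7% <= 10%)
  r <- trim_adapter(paste0("ACGTACGT", ad1), NULL, ad)
  expect_equal(r$seq, "ACGTACGT")
  r <- trim_adapter("ACGTACGTACGTCCCC", NULL, ad)
  expect_equal(r$n_trimmed, 0L)                # no adapter-like suffix
  expect_equal(r$seq, "ACGTACGTACGTCCCC")
})

test_that("partial adapter suffixes trim and qualities follow in lockstep", {
  ad <- "AGATCGGAAGAGC"
  seq <- paste0("CCCCCCCC", substr(ad, 1, 6))  # 6-base partial read-through
  qual <- paste0(strrep("I", 8), strrep("#", 6))
  r <- trim_adapter(seq, qual, ad)
  expect_equal(r$seq, "CCCCCCCC")
  expect_equal(r$qual, strrep("I", 8))
})

test_that("trimming never lengthens and is idempotent on adapter-clean inserts", {
  ad <- "AGATCGGAAGAGC"
  set.seed(42)
  for (i in 1:50) {
    ins <- paste0(random_seq(sample(20:60, 1)), "C")  # insert not ending in A
    read <- paste0(ins, substr(ad, 1, sample(0:13, 1)))
    t1 <- trim_adapter(read, NULL, ad)
    expect_lte(nchar(t1$seq), nchar(read))
    expect_equal(t1$seq, oracle_trim(read, ad))        # brute-force oracle
    t2 <- trim_adapter(t1$seq, NULL, ad)
    expect_equal(t2$seq, t1$seq)
  }
})

test_that("mutation location follows the CIGAR and soft-clips exclude reads", {
  genome <- make_genome(chr1 = random_seq(600))
  g <- as.character(genome[[1]])
  rec <- mutation_record("S1", "chr1", 300, substr(g, 300, 300),
                         setdiff(c("A", "C", "G", "T"),
                                 substr(g, 300, 300))[1])
  alt <- rec$alt
  mk <- function(s, cigar, seq) make_read("r", s, cigar, seq)
  seq_sup <- substr(g, 201, 350); substr(seq_sup, 100, 100) <- alt
  r <- locate_mutation_in_read(mk(201, "150M", seq_sup), rec)
  expect_true(r$supports_mutation); expect_equal(r$read_offset, 100L)
  seq_ref <- substr(g, 201, 350)
  r <- locate_mutation_in_read(mk(201, "150M", seq_ref), rec)
  expect_false(r$supports_mutation)
  ## 30S120M with the locus inside the clipped 30 bases: undetermined
  seq_clip <- paste0(random_seq(30), substr(g, 310, 429))
  r <- locate_mutation_in_read(mk(310, "30S120M", seq_clip), rec)
  expect_true(is.na(r$supports_mutation))
  expect_error(locate_mutation_in_read(mk(201, "151M", seq_sup), rec),
               "inconsistent")
})

test_that("supporting lengths count read bases and exclude clips", {
  genome <- make_genome(chr1 = random_seq(600))
  g <- as.character(genome[[1]])
  ref300 <- substr(g, 300, 300)
  alt <- setdiff(c("A", "C", "G", "T"), ref300)[1]
  rec <- mutation_record("S1", "chr1", 300, ref300, alt)
  ## SNV at read offset 11 of a fully mapped read: len5=10, len3=139
  s <- 290L
  seq <- substr(g, s, s + 149L); substr(seq, 11, 11) <- alt
  sl <- compute_supporting_lengths(make_read("r", s, "150M", seq), rec)
  expect_equal(sl, list(len5 = 10L, len3 = 139L, shorter_len = 10L))
  ## 20S130M with the SNV at the first matched base: len5=0, len3=129
  seq <- paste0(random_seq(20), substr(g, 300, 429)); substr(seq, 21, 21) <- alt
  sl <- compute_supporting_lengths(make_read("r", 300, "20S130M", seq), rec)
  expect_equal(sl, list(len5 = 0L, len3 = 129L, shorter_len = 0L))
})

test_that("deletion junctions split the mapped read bases as 60 + 88", {
  genome <- make_genome(chr1 = random_seq(600))
  g <- as.character(genome[[1]])
  p <- 300L
  rec <- mutation_record("S1", "chr1", p, substr(g, p, p + 2L),
                         substr(g, p, p))     # 2-base deletion at 301..302
  s <- p - 59L                                 # 60 mapped bases through p
  seq <- paste0(substr(g, s, p), substr(g, p + 3L, p + 3L + 87L))
  sl <- compute_supporting_lengths(make_read("r", s, "60M2D88M", seq), rec)
  expect_equal(sl, list(len5 = 60L, len3 = 88L, shorter_len = 60L))
  loc <- locate_mutation_in_read(make_read("r", s, "60M2D88M", seq), rec)
  expect_true(loc$supports_mutation)
  ## a reference-conforming read at the same locus is a null observation
  seq_ref <- substr(g, s, s + 147L)
  loc <- locate_mutation_in_read(make_read("r", s, "148M", seq_ref), rec)
  expect_false(loc$supports_mutation)
})

test_that("insertions are located by the I operation and its bases", {
  genome <- make_genome(chr1 = random_seq(600))
  g <- as.character(genome[[1]])
  p <- 300L
  rec <- mutation_record("S1", "chr1", p, substr(g, p, p),
                         paste0(substr(g, p, p), "TT"))
  s <- p - 59L
  seq <- paste0(substr(g, s, p), "TT", substr(g, p + 1L, p + 88L))
  rd <- make_read("r", s, "60M2I88M", seq)
  loc <- locate_mutation_in_read(rd, rec)
  expect_true(loc$supports_mutation)
  sl <- compute_supporting_lengths(rd, rec)
  expect_equal(sl, list(len5 = 60L, len3 = 88L, shorter_len = 60L))
  ## wrong inserted bases: neither supporting nor null
  rd2 <- make_read("r", s, "60M2I88M",
                   paste0(substr(g, s, p), "CA", substr(g, p + 1L, p + 88L)))
  loc2 <- locate_mutation_in_read(rd2, rec)
  expect_true(is.na(loc2$supports_mutation) || !loc2$supports_mutation)
})

test_that("5'/3' supporting lengths swap under genomic reverse complement", {
  set.seed(7)
  for (i in 1:10) {
    g <- random_seq(400)
    p <- 200L
    refb <- substr(g, p, p)
    alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
    rec <- mutation_record("S1", "chr1", p, refb, alt)
    s <- p - sample(20:150, 1)
    L <- 160L
    seq <- substr(g, s, s + L - 1L); substr(seq, p - s + 1L, p - s + 1L) <- alt
    fwd <- compute_supporting_lengths(make_read("r", s, paste0(L, "M"), seq),
                                      rec)
    ## mirror the whole fixture
    grc <- oracle_revcomp(g)
    p2 <- nchar(g) - p + 1L
    rec2 <- mutation_record("S1", "chr1", p2, oracle_revcomp(refb),
                            oracle_revcomp(alt))
    s2 <- nchar(g) - (s + L - 1L) + 1L
    rev <- compute_supporting_lengths(
      make_read("r", s2, paste0(L, "M"), oracle_revcomp(seq)), rec2)
    expect_equal(rev$len5, fwd$len3)
    expect_equal(rev$len3, fwd$len5)
    expect_equal(rev$shorter_len, fwd$shorter_len)
  }
})

test_that("len5 + len3 + N = L holds for fully mapped substitution reads", {
  set.seed(8)
  g <- random_seq(500)
  for (N in 1:3) {
    p <- 250L
    ref <- substr(g, p, p + N - 1L)
    alt <- oracle_revcomp(ref)
    if (alt == ref) next
    rec <- mutation_record("S1", "chr1", p, ref, alt)
    for (i in 1:20) {
      L <- sample(c(100L, 150L), 1)
      s <- p - sample.int(L - N, 1) + 1L
      seq <- substr(g, s, s + L - 1L)
      substr(seq, p - s + 1L, p - s + N) <- alt
      sl <- compute_supporting_lengths(make_read("r", s, paste0(L, "M"), seq),
                                       rec)
      expect_equal(sl$len5 + sl$len3 + N, L)
    }
  }
})

test_that("repeat context counts tandem extensions of the event unit", {
  ## deletion of A in ...C[A]AAAG...: R3 = 3, R5 = 0
  g <- paste0(random_seq(100), "CAAAAG", random_seq(100))
  genome <- make_genome(chr1 = g)
  rec <- mutation_record("S1", "chr1", 101, "CA", "C")
  rc <- compute_repeat_context(genome, rec)
  expect_equal(rc$R3, 3L); expect_equal(rc$R5, 0L)
  ## deletion of AG in ...T[AG]AGAGC...: R3 = 4
  g <- paste0(random_seq(100), "TAGAGAGC", random_seq(100))
  genome <- make_genome(chr1 = g)
  rec <- mutation_record("S1", "chr1", 101, "TAG", "T")
  rc <- compute_repeat_context(genome, rec)
  expect_equal(rc$R3, 4L)
  ## insertion in a non-repetitive context: R5 = R3 = 0 unless flanks repeat
  g <- paste0(strrep("C", 100), "T", strrep("G", 100))
  genome <- make_genome(chr1 = g)
  rec <- mutation_record("S1", "chr1", 101, "T", "TAGA")
  rc <- compute_repeat_context(genome, rec)
  expect_equal(rc$R3, 0L); expect_equal(rc$R5, 0L)
})

test_that("repeat context matches the exhaustive tandem oracle", {
  set.seed(13)
  for (i in 1:200) {
    N <- sample(1:3, 1)
    unit <- random_seq(N)
    ## build a context with a planted partial tandem run after the event
    left <- random_seq(25)
    run3 <- paste0(strrep(unit, sample(0:4, 1)),
                   substr(unit, 1, sample(0:N, 1)))
    ctx <- paste0(left, "T", unit, run3, random_seq(25))
    p <- 26L                                  # anchor base "T"
    del_rec <- mutation_record("S1", "chr1", p, paste0("T", unit), "T")
    genome <- make_genome(chr1 = ctx)
    got <- compute_repeat_context(genome, del_rec)
    exp3 <- oracle_repeat_run(ctx, p + N + 1L, unit, "three")
    exp5 <- oracle_repeat_run(ctx, p, unit, "five")
    expect_equal(got$R3, exp3)
    expect_equal(got$R5, exp5)
  }
})

test_that("adapter trimming inside evidence shortens clipped tails only", {
  ad <- "AGATCGGAAGAGC"
  genome <- make_genome(chr1 = random_seq(400))
  g <- as.character(genome[[1]])
  p <- 200L
  refb <- substr(g, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  rec <- mutation_record("S1", "chr1", p, refb, alt)
  ## forward read: 100 mapped bases then 37 clipped garbage + 13 adapter
  s <- p - 50L
  mapped <- substr(g, s, s + 99L); substr(mapped, 51, 51) <- alt
  seq <- paste0(mapped, random_seq(36), "C", ad)
  reads <- make_read("r1", s, "100M50S", seq)
  cfg <- micr_config(adapters = ad)
  ev <- build_read_evidence(reads, rec, genome, cfg)
  expect_equal(ev$read_len, 137L)              # 13 adapter bases removed
  expect_true(ev$supports)
  expect_equal(ev$len5, 50L)                   # mapped region untouched
  expect_equal(ev$len3, 49L)
})
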