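# The synthetic fixture generator: determinism, planted structure, and the
# read-level signatures the filters rely on.

test_that("identical seeds give byte-identical fixtures", {
  spec <- fixture_spec(genome_length = 50000, n_true = 3, n_hairpin = 3,
                       n_homology = 3, depth = 60, seed = 77)
  d1 <- tempfile(); d2 <- tempfile()
  fx1 <- simulate_fixture(spec, d1)
  fx2 <- simulate_fixture(spec, d2)
  expect_identical(readLines(fx1$fasta), readLines(fx2$fasta))
  expect_identical(readLines(fx1$mutations), readLines(fx2$mutations))
  expect_identical(readLines(fx1$truth), readLines(fx2$truth))
  r1 <- make_reference(spec); r2 <- make_reference(spec)
  s1 <- simulate_reads(spec, r1); s2 <- simulate_reads(spec, r2)
  expect_identical(s1$sam_lines, s2$sam_lines)
})

test_that("hairpin sites carry two reverse-complementary arms, one mismatch", {
  spec <- fixture_spec(genome_length = 45000, n_true = 0, n_hairpin = 1,
                       n_homology = 0, depth = 50, seed = 5)
  ref <- make_reference(spec)
  reg <- ref$registry
  expect_equal(nrow(reg), 1L)
  g1 <- ref$seqs[["sim1"]]
  m <- reg$pos; arm <- spec$palindrome_arm
  h3 <- arm %/% 2; h5 <- arm - 1 - h3
  arm1_ref <- substr(g1, m - h5, m + h3)       # reference arm (ref base at m)
  arm2 <- substr(g1, reg$arm2_start, reg$arm2_start + arm - 1)
  ## planted arm2 is the reverse complement of arm1 with the alt base
  arm1_mut <- arm1_ref
  substr(arm1_mut, h5 + 1, h5 + 1) <- reg$alt
  expect_identical(arm2, oracle_revcomp(arm1_mut))
  ## exactly one internal difference from the perfect palindrome
  diffs <- sum(strsplit(arm2, "")[[1]] != strsplit(oracle_revcomp(arm1_ref),
                                                   "")[[1]])
  expect_equal(diffs, 1L)
  ## within the 200-base hairpin search window
  expect_lte(reg$arm2_start + arm - 1 - m, 200L)
})

test_that("homology sites have a distant one-mismatch copy covering the query", {
  spec <- fixture_spec(genome_length = 45000, n_true = 0, n_hairpin = 0,
                       n_homology = 2, depth = 50, seed = 6)
  ref <- make_reference(spec)
  reg <- ref$registry
  g1 <- ref$seqs[["sim1"]]; g2 <- ref$seqs[["sim2"]]
  for (i in 1:2) {
    m <- reg$pos[i]; b <- reg$block_start[i]; blk <- spec$homology_block
    block <- substr(g2, b, b + blk - 1)
    local <- substr(g1, m - 35, m - 35 + blk - 1)
    d <- sum(strsplit(block, "")[[1]] != strsplit(local, "")[[1]])
    expect_equal(d, 1L)                        # exactly one base differs
    expect_equal(substr(block, 36, 36), reg$alt[i])
    expect_equal(reg$block_chrom[i], "sim2")   # different contig (distant)
  }
})

test_that("true-mutation context k-mers are unique in the genome (self-scan)", {
  spec <- fixture_spec(genome_length = 45000, n_true = 3, n_hairpin = 1,
                       n_homology = 1, depth = 50, seed = 8)
  ref <- make_reference(spec)
  reg <- ref$registry[ref$registry$label == "true_mutation", ]
  for (i in seq_len(nrow(reg))) {
    m <- reg$pos[i]
    q <- substr(ref$seqs[["sim1"]], m - 35, m + 4)
    substr(q, 36, 36) <- reg$alt[i]
    expect_false(oracle_occurs(q, unname(ref$seqs)))
  }
})

test_that("supporting-read counts and offsets behave statistically", {
  spec <- fixture_spec(genome_length = 45000, n_true = 5, n_hairpin = 0,
                       n_homology = 0, depth = 100, vaf = 0.3, seed = 9)
  ref <- make_reference(spec)
  sim <- simulate_reads(spec, ref)
  body <- sim$sam_lines[!startsWith(sim$sam_lines, "@")]
  fields <- strsplit(body, "\t")
  qn <- vapply(fields, `[[`, "", 1)
  is_mut <- grepl("_m", qn)
  ## supporting counts approximately Binomial(100, 0.3) per locus
  per_site <- table(sub("_.*", "", qn[is_mut]))
  expect_true(all(per_site > 10 & per_site < 55))
  expect_gt(mean(per_site), 20); expect_lt(mean(per_site), 40)
  ## mutated-base offsets are spread over most of the read
  pos <- as.integer(vapply(fields, `[[`, "", 4))
  site1 <- sub("_.*", "", qn) == "s001"
  m1 <- sim$truth$pos[1]
  offs <- m1 - pos[site1 & is_mut] + 1
  expect_gt(max(offs) - min(offs), 100)        # wide placement band
})

test_that("hairpin artifact reads pin the 3' supporting length to the arm", {
  spec <- fixture_spec(genome_length = 45000, n_true = 0, n_hairpin = 2,
                       n_homology = 0, depth = 80, seed = 10)
  d <- tempfile()
  fx <- simulate_fixture(spec, d)
  genome <- load_reference(fx$fasta)
  muts <- read_mutation_list(fx$mutations)
  h3 <- spec$palindrome_arm %/% 2
  for (i in seq_len(nrow(muts))) {
    rec <- muts[i, ]
    ev <- build_read_evidence(fetch_reads(fx$bam, rec), rec, genome)
    sup <- ev[which(ev$supports), ]
    expect_gt(nrow(sup), 5)
    expect_true(all(sup$len3 == h3))           # pinned at the arm overhang
    expect_true(all(sup$shorter <= spec$palindrome_arm))
    ## soft-clipped chimeric tails are present
    expect_true(all(sup$read_len - (sup$len5 + 1 + sup$len3) > 0))
  }
})

test_that("homology artifact reads carry the distant block's 40-mer verbatim", {
  spec <- fixture_spec(genome_length = 45000, n_true = 0, n_hairpin = 0,
                       n_homology = 2, depth = 80, seed = 12)
  ref <- make_reference(spec)
  sim <- simulate_reads(spec, ref)
  g2 <- ref$seqs[["sim2"]]
  body <- sim$sam_lines[!startsWith(sim$sam_lines, "@")]
  fields <- strsplit(body, "\t")
  qn <- vapply(fields, `[[`, "", 1)
  seqs <- vapply(fields, `[[`, "", 10)
  pos <- as.integer(vapply(fields, `[[`, "", 4))
  for (i in 1:2) {
    m <- ref$registry$pos[i]
    keep <- sub("_.*", "", qn) == sprintf("s%03d", i) & grepl("_m", qn)
    ## reads long enough on the 5' side yield the 3'-anchored 40-mer
    n_checked <- 0L
    for (j in which(keep)) {
      o <- m - pos[j] + 1L
      if (o >= 36 && o + 4 <= 150) {
        q3 <- substr(seqs[j], o - 35, o + 4)
        expect_equal(length(oracle_find_fwd(q3, g2)), 1L)
        n_checked <- n_checked + 1L
      }
    }
    expect_gt(n_checked, 5)
  }
})

test_that("a genome too small for the requested sites errors with the minimum", {
  spec <- fixture_spec(genome_length = 30000, n_true = 50, n_hairpin = 50,
                       n_homology = 50, seed = 1)
  expect_error(make_reference(spec), "at least")
})
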