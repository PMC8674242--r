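## Synthetic fixtures: toy genomes and aligned reads with planted true
## mutations, hairpin artifacts and homology artifacts, plus truth labels.
##
## Artifacts are planted at the read-evidence signature level, not by
## simulating FFPE chemistry: hairpin-artifact supporting reads are chimeric
## (mapped up to the 3' end of the planted palindromic arm, remainder
## soft-clipped, so their 3' supporting length is pinned at the arm
## overhang) and carry a 15-base mutation context that occurs reverse-
## complemented within 200 bases; homology-artifact supporting reads carry a
## mutation-containing 40-mer that occurs verbatim at a planted distant
## block.  True mutations sit on verified-unique sequence with uniformly
## placed supporting reads.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fixture specification
#'
#' Parameters of the synthetic data generator.  Defaults define the standard
#' validation fixture: 50 true mutations, 50 hairpin artifacts and 50
#' homology artifacts at depth 200, variant allele fraction 0.25 and 150-base
#' reads (mirroring deep targeted panel sequencing of FFPE material, where
#' called mutations are backed by tens of supporting reads).
#'
#' @param genome_length Total genome size in bases over all contigs.
#' @param n_contigs Number of contigs (2: sites on the first, distant
#'   homology blocks on the second).
#' @param n_true,n_hairpin,n_homology Planted site counts per class.
#' @param read_length Read length in bases.
#' @param depth Reads per locus (mutant + background).
#' @param vaf Variant allele fraction of planted mutations.
#' @param palindrome_arm Palindromic arm length for hairpin sites (>= 17 so
#'   both arms carry 7-base flanks around the mismatch).
#' @param homology_block Length of the distant duplicated block (>= 40).
#' @param seed Integer seed; `(spec, seed)` fully determines all outputs.
#' @param mut_depth Optional exact number of mutation-supporting reads per
#'   locus, overriding the binomial draw at `vaf` (used for depth sweeps).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(genome_length = 220000L, n_contigs = 2L,
                         n_true = 50L, n_hairpin = 50L, n_homology = 50L,
                         read_length = 150L, depth = 200L, vaf = 0.25,
                         palindrome_arm = 20L, homology_block = 60L,
                         seed = 1234L, mut_depth = NULL) {
  stopifnot(depth >= 1, vaf > 0, vaf <= 1,
            palindrome_arm >= 17, homology_block >= 40,
            read_length >= 60, n_contigs == 2L)
  structure(list(genome_length = as.integer(genome_length),
                 n_contigs = 2L,
                 n_true = as.integer(n_true),
                 n_hairpin = as.integer(n_hairpin),
                 n_homology = as.integer(n_homology),
                 read_length = as.integer(read_length),
                 depth = as.integer(depth), vaf = vaf,
                 palindrome_arm = as.integer(palindrome_arm),
                 homology_block = as.integer(homology_block),
                 seed = as.integer(seed),
                 mut_depth = if (is.null(mut_depth)) NULL
                             else as.integer(mut_depth)),
            class = "fixture_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate the toy reference genome with planted sites
#'
#' Builds a random genome and plants, per site class: two reverse-
#' complementary arms within 200 bases differing at exactly one internal
#' base (hairpin sites); a distant duplicated block differing at exactly one
#' base, on the second contig (homology sites); or nothing (true-mutation
#' sites, whose mutation-context k-mers are verified unique by a self-scan).
#'
#' @param spec A [fixture_spec()].
#' @return list with `genome` (`DNAStringSet`), `seqs` (plain character
#'   version) and `registry` (data.frame: `site`, `label`, `chrom`, `pos`,
#'   `ref`, `alt`, `arm2_start`, `block_chrom`, `block_start`).
#' @export
make_reference <- function(spec) {
  set.seed(spec$seed)
  n_sites <- spec$n_true + spec$n_hairpin + spec$n_homology
  spacing <- 1000L
  len2 <- max(20000L, spec$n_homology * spacing + 2000L)
  len1 <- spec$genome_length - len2
  need1 <- n_sites * spacing + 1600L
  if (len1 < need1)
    stop(sprintf("genome too small: need at least %d bases (%d sites)",
                 need1 + len2, n_sites))
  g1 <- random_dna(len1)
  g2 <- random_dna(len2)
  labels <- sample(rep(c("true_mutation", "hairpin_artifact",
                         "homology_artifact"),
                       times = c(spec$n_true, spec$n_hairpin,
                                 spec$n_homology)))
  bases <- c("A", "C", "G", "T")
  arm <- spec$palindrome_arm
  h3 <- arm %/% 2L; h5 <- arm - 1L - h3
  blk <- spec$homology_block
  reg <- data.frame(site = seq_len(n_sites), label = labels,
                    chrom = "sim1", pos = NA_integer_,
                    ref = NA_character_, alt = NA_character_,
                    arm2_start = NA_integer_,
                    block_chrom = NA_character_,
                    block_start = NA_integer_, stringsAsFactors = FALSE)
  k_hom <- 0L
  for (i in seq_len(n_sites)) {
    m <- 800L + (i - 1L) * spacing + sample.int(200L, 1L) - 1L
    refb <- substr(g1, m, m)
    altb <- sample(setdiff(bases, refb), 1L)
    reg$pos[i] <- m; reg$ref[i] <- refb; reg$alt[i] <- altb
    if (labels[i] == "hairpin_artifact") {
      arm1 <- substr(g1, m - h5, m + h3)
      substr(arm1, h5 + 1L, h5 + 1L) <- altb      # arm as read through the fold
      arm2 <- revcomp_chr(arm1)
      g <- m + 60L
      substr(g1, g, g + arm - 1L) <- arm2
      reg$arm2_start[i] <- g
    } else if (labels[i] == "homology_artifact") {
      k_hom <- k_hom + 1L
      b_lo <- m - 35L
      block <- substr(g1, b_lo, b_lo + blk - 1L)
      substr(block, 36L, 36L) <- altb
      b_pos <- 500L + (k_hom - 1L) * spacing
      substr(g2, b_pos, b_pos + blk - 1L) <- block
      reg$block_chrom[i] <- "sim2"
      reg$block_start[i] <- b_pos
    }
  }
  genome <- Biostrings::DNAStringSet(c(sim1 = g1, sim2 = g2))
  ## self-scan: mutation-context k-mers of true sites must be unique
  for (i in which(labels == "true_mutation")) {
    m <- reg$pos[i]
    q3 <- substr(g1, m - 35L, m + 4L); substr(q3, 36L, 36L) <- reg$alt[i]
    q5 <- substr(g1, m - 4L, m + 35L); substr(q5, 5L, 5L) <- reg$alt[i]
    hp <- substr(g1, m - 7L, m + 7L); substr(hp, 8L, 8L) <- reg$alt[i]
    n_hits <- sum(vapply(names(genome), function(ctg)
      sum(Biostrings::countPattern(q3, genome[[ctg]]),
          Biostrings::countPattern(revcomp_chr(q3), genome[[ctg]]),
          Biostrings::countPattern(q5, genome[[ctg]]),
          Biostrings::countPattern(revcomp_chr(q5), genome[[ctg]])),
      numeric(1)))
    win <- substr(g1, m - 200L, m + 200L)
    hp_hits <- Biostrings::countPattern(revcomp_chr(hp),
                                        Biostrings::DNAString(win))
    if (n_hits > 0 || hp_hits > 0)
      stop(sprintf("true-mutation site %d at sim1:%d is not unique; %s",
                   i, m, "use a different seed"))
  }
  list(genome = genome, seqs = c(sim1 = g1, sim2 = g2), registry = reg)
}

#' Simulate aligned reads over the planted sites
#'
#' True-mutation and homology-artifact supporting reads are fully mapped
#' (`<L>M`) with uniform start positions; hairpin-artifact supporting reads
#' are chimeric, mapped up to the 3' end of the palindromic arm with the
#' remainder soft-clipped (fold-back continuation on the opposite strand).
#' Every locus also receives reference-conforming background reads so the
#' supporting-length null distribution is well populated.
#'
#' @param spec A [fixture_spec()].
#' @param ref Output of [make_reference()].
#' @return list with `sam_lines` (complete coordinate-sorted SAM text),
#'   `mutations` (normalized mutation data.frame), `truth` (mutations plus
#'   `label`).
#' @export
simulate_reads <- function(spec, ref) {
  set.seed(spec$seed + 1L)
  reg <- ref$registry
  g1 <- ref$seqs[["sim1"]]
  L <- spec$read_length
  arm <- spec$palindrome_arm
  h3 <- arm %/% 2L
  qual <- strrep("I", L)
  recs <- vector("list", nrow(reg))
  n_alloc <- nrow(reg) * spec$depth
  qn <- character(n_alloc); fl <- integer(n_alloc); po <- integer(n_alloc)
  cg <- character(n_alloc); sq <- character(n_alloc)
  k <- 0L
  for (i in seq_len(nrow(reg))) {
    m <- reg$pos[i]
    E <- spec$mut_depth %||% rbinom(1L, spec$depth, spec$vaf)
    E <- min(E, spec$depth)
    n_null <- spec$depth - E
    ## background reads: uniform placement over all starts covering m
    if (n_null > 0) {
      s <- (m - L + 1L) + sample.int(L, n_null, replace = TRUE) - 1L
      for (j in seq_len(n_null)) {
        k <- k + 1L
        qn[k] <- sprintf("s%03d_n%04d", i, j)
        fl[k] <- sample(c(0L, 16L), 1L)
        po[k] <- s[j]
        cg[k] <- paste0(L, "M")
        sq[k] <- substr(g1, s[j], s[j] + L - 1L)
      }
    }
    if (E > 0) {
      if (reg$label[i] == "hairpin_artifact") {
        s_lo <- m + h3 + 20L - L; s_hi <- m - 20L
        s <- s_lo + sample.int(s_hi - s_lo + 1L, E, replace = TRUE) - 1L
        g <- reg$arm2_start[i]
        for (j in seq_len(E)) {
          k <- k + 1L
          mapped <- m + h3 - s[j] + 1L
          clip <- L - mapped
          pre <- substr(g1, s[j], m + h3)
          substr(pre, m - s[j] + 1L, m - s[j] + 1L) <- reg$alt[i]
          fold <- revcomp_chr(substr(g1, g - clip, g - 1L))
          qn[k] <- sprintf("s%03d_m%04d", i, j)
          fl[k] <- sample(c(0L, 16L), 1L)
          po[k] <- s[j]
          cg[k] <- paste0(mapped, "M", clip, "S")
          sq[k] <- paste0(pre, fold)
        }
      } else {
        s <- (m - L + 1L) + sample.int(L, E, replace = TRUE) - 1L
        for (j in seq_len(E)) {
          k <- k + 1L
          rd <- substr(g1, s[j], s[j] + L - 1L)
          substr(rd, m - s[j] + 1L, m - s[j] + 1L) <- reg$alt[i]
          qn[k] <- sprintf("s%03d_m%04d", i, j)
          fl[k] <- sample(c(0L, 16L), 1L)
          po[k] <- s[j]
          cg[k] <- paste0(L, "M")
          sq[k] <- rd
        }
      }
    }
    recs[[i]] <- mutation_record("fixture01", "sim1", m, reg$ref[i],
                                 reg$alt[i])
  }
  keep <- seq_len(k)
  ord <- order(po[keep], qn[keep])
  body <- sprintf("%s\t%d\tsim1\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                  qn[keep][ord], fl[keep][ord], po[keep][ord],
                  cg[keep][ord], sq[keep][ord], qual)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref$seqs),
                      nchar(ref$seqs)))
  mutations <- do.call(rbind, recs)
  truth <- cbind(mutations, label = reg$label, stringsAsFactors = FALSE)
  list(sam_lines = c(header, body), mutations = mutations, truth = truth)
}

#' Write a complete synthetic fixture to disk
#'
#' Runs [make_reference()] and [simulate_reads()] and writes
#' `reference.fa` (+ `.fai`), `reads.bam` (+ `.bai`), `mutations.tsv` and
#' `truth.tsv` into `out_dir`.  Identical spec and seed give identical
#' files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return list with the file paths (`fasta`, `bam`, `mutations`, `truth`)
#'   plus `registry` and `truth` data.frames.
#' @export
simulate_fixture <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(spec)
  sim <- simulate_reads(spec, ref)
  fasta <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(ref$genome, fasta)
  Rsamtools::indexFa(fasta)
  sam <- file.path(out_dir, "reads.sam")
  writeLines(sim$sam_lines, sam)
  bam <- Rsamtools::asBam(sam, file.path(out_dir, "reads"),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  mut_path <- file.path(out_dir, "mutations.tsv")
  write_mutation_list(sim$mutations, mut_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  tt <- data.frame(Sample = sim$truth$sample, Chr = sim$truth$chrom,
                   Pos = sim$truth$pos, Ref = sim$truth$ref,
                   Alt = sim$truth$alt, Label = sim$truth$label,
                   stringsAsFactors = FALSE)
  write.table(tt, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, bam = bam, mutations = mut_path, truth = truth_path,
       registry = ref$registry, truth_df = tt)
}
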