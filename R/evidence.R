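## Per-read evidence at a mutation locus.
##
## Each aligned read overlapping a locus is reduced to: does it carry the
## mutation, and how many non-clipped read bases lie 5' and 3' of the event
## (the supporting lengths).  Supporting lengths count read bases -- bases
## consumed by I operations count, D consumes none, soft/hard clips never
## count -- and are expressed in reference orientation.

#' Trim a 3' adapter from a read
#'
#' Removes the longest suffix of `seq` that matches a prefix of `adapter`
#' with a mismatch fraction of at most `max_mismatch_rate` (partial-suffix
#' overlaps allowed; the adapter must be flush with the read end).  Qualities
#' are trimmed in lockstep.  The read is assumed to be in sequencing
#' orientation (adapter read-through appears at its 3' end).
#'
#' @param seq Read sequence (character scalar).
#' @param qual Base-quality string of the same length (or `NULL`).
#' @param adapter Adapter sequence (ACGT).
#' @param max_mismatch_rate Maximum fraction of mismatching bases in the
#'   overlap (default 0.10); the allowance is `floor(k * rate)` for an
#'   overlap of `k` bases.
#' @return list with `seq`, `qual`, and `n_trimmed` (bases removed).
#' @examples
#' trim_adapter("ACGTACGTAGATCGGAAGAGC", NULL, "AGATCGGAAGAGC")$seq
#' @export
trim_adapter <- function(seq, qual = NULL, adapter,
                         max_mismatch_rate = 0.10) {
  stopifnot(length(seq) == 1, nchar(adapter) >= 1,
            max_mismatch_rate >= 0, max_mismatch_rate < 1)
  L <- nchar(seq)
  ar <- charToRaw(adapter)
  sr <- charToRaw(seq)
  kmax <- min(L, nchar(adapter))
  trim <- 0L
  for (k in seq(kmax, 1L)) {
    mism <- sum(sr[(L - k + 1L):L] != ar[1:k])
    if (mism <= floor(k * max_mismatch_rate)) { trim <- k; break }
  }
  if (trim == 0L) return(list(seq = seq, qual = qual, n_trimmed = 0L))
  list(seq = substr(seq, 1L, L - trim),
       qual = if (is.null(qual)) NULL else substr(qual, 1L, L - trim),
       n_trimmed = trim)
}

## ---- CIGAR machinery ------------------------------------------------------

## Parse one CIGAR into parallel segment vectors with 1-based read and
## reference coordinates.  H and P consume nothing; S and I consume read
## only; D and N consume reference only; M/=/X consume both.
cigar_segments <- function(cigar, pos, ops = NULL, lens = NULL) {
  if (is.null(ops)) {
    ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  }
  consumes_read <- ops %in% c("M", "=", "X", "I", "S")
  consumes_ref <- ops %in% c("M", "=", "X", "D", "N")
  rc <- cumsum(c(1L, lens * consumes_read))[seq_along(ops)]
  fc <- cumsum(c(as.integer(pos), lens * consumes_ref))[seq_along(ops)]
  list(op = ops, len = lens,
       read_start = ifelse(consumes_read, rc, NA_integer_),
       read_end = ifelse(consumes_read, rc + lens - 1L, NA_integer_),
       ref_start = ifelse(consumes_ref, fc, NA_integer_),
       ref_end = ifelse(consumes_ref, fc + lens - 1L, NA_integer_))
}

seg_subset <- function(segs, keep) {
  list(op = segs$op[keep], len = segs$len[keep],
       read_start = segs$read_start[keep], read_end = segs$read_end[keep],
       ref_start = segs$ref_start[keep], ref_end = segs$ref_end[keep])
}

## Read offset aligned to a reference position: integer offset, "del" if the
## position falls in a D/N operation, or "outside" the mapped span.
offset_of_ref <- function(segs, refpos) {
  al <- segs$op %in% c("M", "=", "X")
  if (!any(al)) return("outside")
  hit <- which(al & segs$ref_start <= refpos & refpos <= segs$ref_end)
  if (length(hit) == 1)
    return(segs$read_start[hit] + (refpos - segs$ref_start[hit]))
  dl <- which(segs$op %in% c("D", "N") &
                segs$ref_start <= refpos & refpos <= segs$ref_end)
  if (length(dl) > 0) return("del")
  "outside"
}

## Full per-read geometry of the event.  Returns a list with
##   status: "support" | "null" | "excluded"
##   es, ee: 1-based read span of the event (ee < es for a zero-width
##           junction: deletions, and the insertion point on null reads)
##   len5, len3: supporting lengths (read bases, clips excluded)
read_event_geometry <- function(segs, seq, record) {
  p <- record$pos; N <- record$mut_len; type <- record$mut_type
  al <- which(segs$op %in% c("M", "=", "X"))
  if (length(al) == 0) return(list(status = "excluded"))
  first_off <- min(segs$read_start[al]); last_off <- max(segs$read_end[al])
  excluded <- list(status = "excluded")

  if (type %in% c("SNV", "MNV")) {
    offs <- vapply(p:(p + N - 1L), function(rp) {
      o <- offset_of_ref(segs, rp)
      if (is.character(o)) NA_integer_ else o
    }, integer(1))
    if (anyNA(offs)) return(excluded)
    es <- offs[1]; ee <- offs[N]
    if (ee - es + 1L != N) return(excluded)   # indel inside the event
    bases <- substr(seq, es, ee)
    list(status = if (identical(bases, record$alt)) "support" else "null",
         es = es, ee = ee,
         len5 = es - first_off, len3 = last_off - ee)
  } else if (type == "DEL") {
    ## deleted reference bases occupy p+1 .. p+N
    hit <- which(segs$op == "D" & segs$ref_start == p + 1L & segs$len == N)
    if (length(hit) >= 1) {
      jr <- offset_of_ref(segs, p)
      if (is.character(jr)) return(excluded)
      return(list(status = "support", es = jr + 1L, ee = jr,
                  len5 = jr - first_off + 1L, len3 = last_off - jr))
    }
    o5 <- offset_of_ref(segs, p); o3 <- offset_of_ref(segs, p + N + 1L)
    if (is.character(o5) || is.character(o3)) return(excluded)
    ## reference-conforming only if the event span is plain M with no indels
    if (o3 - o5 != N + 1L) return(excluded)
    list(status = "null", es = o5 + 1L, ee = o3 - 1L,
         len5 = o5 - first_off + 1L, len3 = last_off - o3 + 1L)
  } else {                                    # INS: inserted after p
    ## the insertion sits between the read offsets aligned to p and p+1
    o5 <- offset_of_ref(segs, p); o3 <- offset_of_ref(segs, p + 1L)
    if (is.character(o5) || is.character(o3)) return(excluded)
    gap <- o3 - o5 - 1L                       # read bases between the anchors
    if (gap == 0L)
      return(list(status = "null", es = o5 + 1L, ee = o5,
                  len5 = o5 - first_off + 1L, len3 = last_off - o3 + 1L))
    if (gap != N) return(excluded)            # insertion of the wrong length
    ins <- substr(seq, o5 + 1L, o5 + N)
    if (!identical(ins, substr(record$alt, 2L, N + 1L))) return(excluded)
    list(status = "support", es = o5 + 1L, ee = o5 + N,
         len5 = o5 - first_off + 1L, len3 = last_off - o3 + 1L)
  }
}

#' Locate a mutation within one aligned read
#'
#' Walks the CIGAR string to map the genomic event onto read coordinates and
#' decides whether the read supports the mutation (alt bases present; for a
#' deletion, a D operation of the right length at the locus; for an
#' insertion, an I operation with the inserted bases).  Reads whose alignment
#' places the locus in a soft-clip, or that carry a different event at the
#' locus, are reported as undetermined and take part in neither the mutant
#' nor the null set.
#'
#' @param read One-row data.frame with `pos`, `cigar`, `seq` (as returned by
#'   [fetch_reads()]).
#' @param record One-row mutation data.frame.
#' @return list with `supports_mutation` (TRUE/FALSE/NA for undetermined) and
#'   `read_offset` (1-based offset of the first event base in the read, NA
#'   when undetermined; for deletions, the offset just 5' of the junction).
#' @export
locate_mutation_in_read <- function(read, record) {
  check_cigar_consistency(read)
  segs <- cigar_segments(read$cigar, read$pos)
  g <- read_event_geometry(segs, read$seq, record)
  if (g$status == "excluded")
    return(list(supports_mutation = NA, read_offset = NA_integer_))
  off <- if (record$mut_type == "DEL") g$ee else g$es
  list(supports_mutation = g$status == "support", read_offset = off)
}

#' Supporting lengths of one read
#'
#' Counts the non-clipped read bases 5' and 3' of the event (mutated bases
#' excluded) in reference orientation.  Read bases consumed by insertions
#' elsewhere in the alignment count; deletions consume none; soft- and
#' hard-clipped bases contribute to neither side.
#'
#' @inheritParams locate_mutation_in_read
#' @return list with `len5`, `len3`, `shorter_len` (all NA when the read is
#'   undetermined at the locus).
#' @export
compute_supporting_lengths <- function(read, record) {
  check_cigar_consistency(read)
  segs <- cigar_segments(read$cigar, read$pos)
  g <- read_event_geometry(segs, read$seq, record)
  if (g$status == "excluded")
    return(list(len5 = NA_integer_, len3 = NA_integer_,
                shorter_len = NA_integer_))
  list(len5 = g$len5, len3 = g$len3, shorter_len = min(g$len5, g$len3))
}

check_cigar_consistency <- function(read) {
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(read$cigar)
  if (qw != nchar(read$seq))
    stop(sprintf("CIGAR %s inconsistent with sequence length %d for read %s",
                 read$cigar, nchar(read$seq),
                 if (!is.null(read$qname)) read$qname else "?"))
  invisible(TRUE)
}

#' Repeat context around an indel
#'
#' For an insertion/deletion with unit sequence `U` (the inserted or deleted
#' bases), `R3` is the length of the maximal stretch immediately 3' of the
#' event over which the reference equals tandem copies of `U` (a trailing
#' partial copy counts base-by-base until the first mismatch); `R5` is the
#' symmetric count with `U` read in reverse phase.  Substitutions have
#' `R5 = R3 = 0`.  Mutation-supporting reads must span these runs, which is
#' why they enter the theoretical supporting-length bounds.
#'
#' @param genome `DNAStringSet` reference.
#' @param record One-row mutation data.frame.
#' @param max_run Cap on the scan (default 200 bases).
#' @return list with `R5`, `R3` and `neighborhood` (reference sequence within
#'   200 bases of the locus; truncated at contig ends, with attribute
#'   `"start"`).
#' @export
compute_repeat_context <- function(genome, record, max_run = 200L) {
  p <- record$pos; N <- record$mut_len
  nbh <- ref_window(genome, record$chrom, p - 200L,
                    p + nchar(record$ref) - 1L + 200L)
  if (record$mut_type %in% c("SNV", "MNV"))
    return(list(R5 = 0L, R3 = 0L, neighborhood = nbh))
  U <- if (record$mut_type == "DEL") substr(record$ref, 2L, N + 1L)
       else substr(record$alt, 2L, N + 1L)
  uchr <- strsplit(U, "")[[1]]
  start3 <- if (record$mut_type == "DEL") p + N + 1L else p + 1L
  clen <- Biostrings::width(genome[record$chrom])
  r3 <- 0L
  while (r3 < max_run && start3 + r3 <= clen) {
    b <- as.character(Biostrings::subseq(genome[[record$chrom]],
                                         start3 + r3, start3 + r3))
    if (b != uchr[(r3 %% N) + 1L]) break
    r3 <- r3 + 1L
  }
  r5 <- 0L
  while (r5 < max_run && p - r5 >= 1L) {
    b <- as.character(Biostrings::subseq(genome[[record$chrom]],
                                         p - r5, p - r5))
    if (b != uchr[((N - 1L - r5) %% N) + 1L]) break
    r5 <- r5 + 1L
  }
  list(R5 = r5, R3 = r3, neighborhood = nbh)
}

## ---- evidence assembly ----------------------------------------------------

## Mismatches against the reference within the 10 bases surrounding the
## event in this read (5 on each side, mutated bases excluded), counted over
## the positions actually aligned.
local_mismatches <- function(segs, seq, record, accessor) {
  p <- record$pos; N <- record$mut_len
  flanks <- switch(record$mut_type,
    SNV = , MNV = c((p - 5L):(p - 1L), (p + N):(p + N + 4L)),
    DEL = c((p - 4L):p, (p + N + 1L):(p + N + 5L)),
    INS = c((p - 4L):p, (p + 1L):(p + 5L)))
  mm <- 0L
  for (rp in flanks) {
    o <- offset_of_ref(segs, rp)
    if (is.character(o)) next
    rb <- substr(seq, o, o)
    gb <- accessor$get(rp)
    if (!is.na(gb) && nzchar(gb) && rb != gb) mm <- mm + 1L
  }
  mm
}

#' Assemble per-read evidence for a mutation
#'
#' Applies adapter trimming, locates the event in every read, computes
#' supporting lengths and local mismatch counts, and classifies each read as
#' mutation-supporting, reference-conforming (null) or undetermined.
#'
#' @param reads data.frame of raw reads (see [fetch_reads()]).
#' @param record One-row mutation data.frame.
#' @param genome `DNAStringSet` reference.
#' @param config A [micr_config()].
#' @return data.frame with one row per read: `qname`, `strand`, `seq`,
#'   `read_len` (post-trim), `supports` (logical, NA = undetermined), `len5`,
#'   `len3`, `shorter`, `es`, `ee` (read-coordinate event span), `mm_local`
#'   (local mismatch count; computed for supporting reads, NA otherwise).
#' @export
build_read_evidence <- function(reads, record, genome, config = micr_config()) {
  n <- nrow(reads)
  if (n == 0)
    return(data.frame(qname = character(0), strand = character(0),
                      seq = character(0), read_len = integer(0),
                      supports = logical(0), len5 = integer(0),
                      len3 = integer(0), shorter = integer(0),
                      es = integer(0), ee = integer(0),
                      mm_local = integer(0), stringsAsFactors = FALSE))
  ## cheap positional accessor for mismatch counting
  p <- record$pos
  ctx <- ref_window(genome, record$chrom, max(1L, p - 220L),
                    p + nchar(record$ref) + 220L)
  ctx_start <- attr(ctx, "start")
  acc <- list(get = function(rp) {
    i <- rp - ctx_start + 1L
    if (i < 1L || i > nchar(ctx)) NA_character_ else substr(ctx, i, i)
  })
  all_ops <- GenomicAlignments::explodeCigarOps(reads$cigar)
  all_lens <- GenomicAlignments::explodeCigarOpLengths(reads$cigar)
  qwidths <- GenomicAlignments::cigarWidthAlongQuerySpace(reads$cigar)
  seqs <- reads$seq; strands <- reads$strand
  o_seq <- character(n); o_len <- integer(n)
  o_sup <- rep(NA, n)
  o_l5 <- rep(NA_integer_, n); o_l3 <- rep(NA_integer_, n)
  o_es <- rep(NA_integer_, n); o_ee <- rep(NA_integer_, n)
  o_mm <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    seq <- seqs[i]
    if (qwidths[i] != nchar(seq))
      stop(sprintf("CIGAR %s inconsistent with sequence length %d for read %s",
                   reads$cigar[i], nchar(seq), reads$qname[i]))
    segs <- cigar_segments(NULL, reads$pos[i],
                           ops = all_ops[[i]], lens = all_lens[[i]])
    ## adapter trimming on the sequencing 3' end, confined to the soft clip
    ## on that end (mapped bases are never adapter)
    if (length(config$adapters) > 0) {
      rev_strand <- identical(strands[i], "-")
      for (ad in config$adapters) {
        nseg <- length(segs$op)
        if (rev_strand) {
          tr <- trim_adapter(revcomp_chr(seq), NULL, ad,
                             config$adapter_mismatch_rate)
          lead <- if (segs$op[1] == "S") segs$len[1] else 0L
          k <- min(tr$n_trimmed, lead)
          if (k > 0L) {
            seq <- substr(seq, k + 1L, nchar(seq))
            segs$len[1] <- segs$len[1] - k
            segs <- seg_subset(segs, segs$len > 0L)
            segs$read_start <- segs$read_start - k
            segs$read_end <- segs$read_end - k
            if (length(segs$op) > 0 && segs$op[1] == "S")
              segs$read_start[1] <- 1L
          }
        } else {
          tr <- trim_adapter(seq, NULL, ad, config$adapter_mismatch_rate)
          trail <- if (segs$op[nseg] == "S") segs$len[nseg] else 0L
          k <- min(tr$n_trimmed, trail)
          if (k > 0L) {
            seq <- substr(seq, 1L, nchar(seq) - k)
            segs$len[nseg] <- segs$len[nseg] - k
            segs$read_end[nseg] <- segs$read_end[nseg] - k
            segs <- seg_subset(segs, segs$len > 0L)
          }
        }
      }
    }
    g <- read_event_geometry(segs, seq, record)
    o_seq[i] <- seq
    o_len[i] <- nchar(seq)
    if (g$status == "excluded") next
    o_sup[i] <- g$status == "support"
    o_l5[i] <- g$len5; o_l3[i] <- g$len3
    o_es[i] <- g$es; o_ee[i] <- g$ee
    if (o_sup[i]) o_mm[i] <- local_mismatches(segs, seq, record, acc)
  }
  data.frame(qname = reads$qname, strand = strands, seq = o_seq,
             read_len = o_len, supports = o_sup, len5 = o_l5, len3 = o_l3,
             shorter = pmin(o_l5, o_l3), es = o_es, ee = o_ee,
             mm_local = o_mm, stringsAsFactors = FALSE)
}
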