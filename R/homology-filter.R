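## Distant homologous region detection: Filter 4.
##
## Mis-annealing of two single-stranded molecules from distant regions with
## identical local sequence yields reads whose mutation-containing window is
## verbatim the *other* region's sequence.  Two 40-base queries are taken
## from each supporting read -- anchored 4 bases 5' and 4 bases 3' of the
## mutated core -- and searched exactly, on both strands, against the whole
## genome outside the locus neighborhood.

#' Build the 40-base homology query pair for a supporting read
#'
#' The core is the mutated bases plus the read bases covering the flanking
#' repeat runs (`R5` bases 5', `R3` bases 3').  The 5'-anchored query is 4
#' read bases 5' of the core, the core, then 3' read bases up to a total of
#' `query_len`; the 3'-anchored query is the mirror image.  A member is
#' absent when the read is too short on the required side; a huge repeat run
#' (core + 4 > `query_len`) makes both members absent.
#'
#' @param evidence_row One row of [build_read_evidence()] output for a
#'   supporting read.
#' @param record One-row mutation data.frame.
#' @param repeats [compute_repeat_context()] output.
#' @param query_len Total query length (default 40).
#' @param anchor Anchor width (default 4).
#' @return list with `q_5anchor` and `q_3anchor` (character or `NA`).
#' @export
build_homology_queries <- function(evidence_row, record, repeats,
                                   query_len = 40L, anchor = 4L) {
  es <- evidence_row$es; ee <- evidence_row$ee
  if (is.na(es) || is.na(ee))
    return(list(q_5anchor = NA_character_, q_3anchor = NA_character_))
  L <- evidence_row$read_len
  cs <- es - repeats$R5
  ce <- ee + repeats$R3
  core_len <- ce - cs + 1L            # 0 for a bare deletion junction
  if (core_len + anchor > query_len)
    return(list(q_5anchor = NA_character_, q_3anchor = NA_character_))
  q5_lo <- cs - anchor; q5_hi <- q5_lo + query_len - 1L
  q3_hi <- ce + anchor; q3_lo <- q3_hi - query_len + 1L
  q5 <- if (q5_lo >= 1L && q5_hi <= L)
    substr(evidence_row$seq, q5_lo, q5_hi) else NA_character_
  q3 <- if (q3_lo >= 1L && q3_hi <= L)
    substr(evidence_row$seq, q3_lo, q3_hi) else NA_character_
  list(q_5anchor = q5, q_3anchor = q3)
}

#' Exact genome-wide search for a query outside the locus neighborhood
#'
#' TRUE iff `query` occurs exactly, on either strand, at one or more genomic
#' positions outside the exclusion zone around the locus (default: locus
#' footprint +/- 200 bases), so a read's own origin never self-matches.
#' Queries containing ambiguity codes never match.
#'
#' @param query Query string (typically 40 bases).
#' @param genome `DNAStringSet` reference.
#' @param chrom,pos Locus of the mutation under test.
#' @param ref_len Reference-footprint length of the event
#'   (`nchar(record$ref)`).
#' @param exclusion Half-width of the exclusion zone (default 200).
#' @return logical.
#' @export
genome_exact_match <- function(query, genome, chrom, pos, ref_len = 1L,
                               exclusion = 200L) {
  hits <- genome_match_queries(query, genome)[[1]]
  any_hit_outside(hits, chrom, pos, ref_len, nchar(query), exclusion)
}

## All exact occurrences (both strands) of each query in the genome.
## Returns, per query, a data.frame(chrom, start) of forward-coordinate
## match starts (a reverse-strand occurrence is reported at the position of
## the reverse-complemented query on the forward strand).  NA / non-ACGT
## queries yield zero hits.
genome_match_queries <- function(queries, genome) {
  out <- rep(list(data.frame(chrom = character(0), start = integer(0),
                             stringsAsFactors = FALSE)), length(queries))
  ok <- !is.na(queries) & is_acgt(queries)
  if (!any(ok)) return(out)
  uq <- unique(queries[ok])
  pats <- Biostrings::DNAStringSet(c(uq, revcomp_chr(uq)))
  acc <- setNames(rep(list(list(chrom = character(0), start = integer(0))),
                      length(uq)), uq)
  ## PDict preprocessing has a large fixed cost; worth it only for many
  ## patterns (pooled batches), not for the handful of distinct queries a
  ## single locus yields
  use_pdict <- length(unique(nchar(uq))) == 1 && length(uq) >= 16
  pd <- if (use_pdict) Biostrings::PDict(pats) else NULL
  for (ctg in names(genome)) {
    subject <- genome[[ctg]]
    if (use_pdict) {
      ml <- Biostrings::matchPDict(pd, subject)
      starts <- IRanges::start(ml)
    } else {
      starts <- lapply(seq_along(pats), function(i)
        IRanges::start(Biostrings::matchPattern(pats[[i]], subject,
                                                fixed = TRUE)))
    }
    for (i in seq_along(uq)) {
      st <- c(starts[[i]], starts[[i + length(uq)]])
      if (length(st)) {
        acc[[i]]$chrom <- c(acc[[i]]$chrom, rep(ctg, length(st)))
        acc[[i]]$start <- c(acc[[i]]$start, st)
      }
    }
  }
  for (j in seq_along(queries)) {
    if (!ok[j]) next
    a <- acc[[queries[j]]]
    out[[j]] <- data.frame(chrom = a$chrom, start = a$start,
                           stringsAsFactors = FALSE)
  }
  out
}

any_hit_outside <- function(hits, chrom, pos, ref_len, qlen, exclusion) {
  if (nrow(hits) == 0) return(FALSE)
  zone_lo <- pos - exclusion
  zone_hi <- pos + ref_len - 1L + exclusion
  inside <- hits$chrom == chrom &
    hits$start <= zone_hi & (hits$start + qlen - 1L) >= zone_lo
  any(!inside)
}

#' Apply the homology filter to one mutation
#'
#' Computes the fraction of mutation-supporting reads with at least one
#' query matching exactly elsewhere in the genome (denominator: all
#' supporting reads, including those yielding no valid query) and flags the
#' mutation when the fraction exceeds `rate_threshold` (strict: exactly 15%
#' is not flagged).
#'
#' @param evidence [build_read_evidence()] output.
#' @param record One-row mutation data.frame.
#' @param repeats [compute_repeat_context()] output.
#' @param genome `DNAStringSet` reference.
#' @param rate_threshold Strict flagging threshold (default 0.15).
#' @param exclusion Exclusion-zone half-width (default 200).
#' @return list with `flagged` and `homology_read_rate`.
#' @export
apply_homology_filter <- function(evidence, record, repeats, genome,
                                  rate_threshold = 0.15, exclusion = 200L) {
  sup <- evidence[which(evidence$supports), , drop = FALSE]
  if (nrow(sup) == 0)
    return(list(flagged = FALSE, homology_read_rate = NA_real_))
  qp <- lapply(seq_len(nrow(sup)), function(i)
    build_homology_queries(list(seq = sup$seq[i], es = sup$es[i],
                                ee = sup$ee[i], read_len = sup$read_len[i]),
                           record, repeats))
  all_q <- unlist(lapply(qp, function(x) c(x$q_5anchor, x$q_3anchor)))
  hits <- genome_match_queries(all_q, genome)
  ref_len <- nchar(record$ref)
  matched <- vapply(hits, function(h) {
    if (nrow(h) == 0) return(FALSE)
    any_hit_outside(h, record$chrom, record$pos, ref_len, 40L, exclusion)
  }, logical(1))
  per_read <- matched[seq(1, length(matched), by = 2)] |
    matched[seq(2, length(matched), by = 2)]
  rate <- sum(per_read) / nrow(sup)
  list(flagged = rate > rate_threshold, homology_read_rate = rate)
}
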