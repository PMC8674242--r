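## Hairpin (palindrome) detection: Filter 2.
##
## A fold-back chimeric read copies the opposite strand across the mismatch
## of two proximal palindromic arms, so the sequence around the artifact
## base -- taken from the read, which captures the artifact -- occurs
## *exactly* on the opposite strand near the locus.

#' Extract the hairpin query from a supporting read
#'
#' Returns the window of the read sequence centered on the mutated bases:
#' 7 bases on each flank plus the event itself (length `max(15, N + 14)`;
#' for deletions the event occupies no read bases and the window is the 15
#' bases around the junction).  Soft-clipped bases are included -- fold-back
#' reads carry the opposite-strand sequence precisely in the clipped tail.
#'
#' @param evidence_row One row of [build_read_evidence()] output for a
#'   mutation-supporting read (fields `seq`, `es`, `ee`, `read_len`).
#' @param record One-row mutation data.frame.
#' @param flank Flank width (default 7, giving the 15-base minimum query).
#' @return Query string, or `NA` when the read has fewer than `flank` bases
#'   on either side of the event (such reads count as non-hairpin-derived).
#' @export
extract_hairpin_query <- function(evidence_row, record, flank = 7L) {
  es <- evidence_row$es; ee <- evidence_row$ee
  if (is.na(es) || is.na(ee)) return(NA_character_)
  L <- evidence_row$read_len
  if (record$mut_type == "DEL") {
    ## zero-width junction at ee (= es - 1): 7 bases 5', 8 bases 3'
    lo <- ee - flank + 1L; hi <- ee + flank + 1L
  } else {
    lo <- es - flank; hi <- ee + flank
  }
  if (lo < 1L || hi > L) return(NA_character_)
  substr(evidence_row$seq, lo, hi)
}

#' Is a read hairpin-derived?
#'
#' TRUE iff the query occurs on the opposite strand of the reference within
#' the neighborhood window, i.e. the reverse complement of the query occurs
#' exactly (zero mismatches) in the forward reference sequence.  Queries or
#' windows containing ambiguity codes never match.
#'
#' @param query Read-derived query (see [extract_hairpin_query()]).
#' @param neighborhood Reference sequence of the window around the locus
#'   (character scalar, e.g. from [ref_window()]).
#' @return logical.
#' @export
is_hairpin_read <- function(query, neighborhood) {
  if (is.na(query) || !is_acgt(query)) return(FALSE)
  if (nchar(neighborhood) < nchar(query)) return(FALSE)
  rc <- revcomp_chr(query)
  Biostrings::countPattern(rc, Biostrings::DNAString(neighborhood),
                           fixed = TRUE) > 0
}

#' Apply the hairpin filter to one mutation
#'
#' Computes the fraction of mutation-supporting reads whose centered query
#' occurs on the opposite strand within `window` bases of the locus, and
#' flags the mutation when that fraction exceeds `rate_threshold` (strict:
#' exactly half is not flagged).
#'
#' @param evidence [build_read_evidence()] output.
#' @param record One-row mutation data.frame.
#' @param genome `DNAStringSet` reference.
#' @param window Window half-width in bases around the locus (default 200).
#' @param rate_threshold Strict flagging threshold on the rate (default 0.5).
#' @return list with `flagged` and `hairpin_read_rate`.
#' @export
apply_hairpin_filter <- function(evidence, record, genome,
                                 window = 200L, rate_threshold = 0.5) {
  sup <- evidence[which(evidence$supports), , drop = FALSE]
  if (nrow(sup) == 0)
    return(list(flagged = FALSE, hairpin_read_rate = NA_real_))
  nbh <- ref_window(genome, record$chrom, record$pos - window,
                    record$pos + nchar(record$ref) - 1L + window)
  queries <- vapply(seq_len(nrow(sup)), function(i)
    extract_hairpin_query(list(seq = sup$seq[i], es = sup$es[i],
                               ee = sup$ee[i], read_len = sup$read_len[i]),
                          record), character(1))
  ## identical queries are common at deep coverage; test each string once
  uq <- unique(queries[!is.na(queries)])
  hit_map <- setNames(vapply(uq, is_hairpin_read, logical(1),
                             neighborhood = nbh), uq)
  hits <- !is.na(queries) & unname(hit_map[queries])
  hits[is.na(hits)] <- FALSE
  rate <- sum(hits) / nrow(sup)
  list(flagged = rate > rate_threshold, hairpin_read_rate = rate)
}
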