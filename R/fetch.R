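#' Fetch reads overlapping a mutation locus
#'
#' Extracts all primary, non-duplicate alignments whose mapped span overlaps
#' the reference footprint of the mutation (`[pos, pos + nchar(ref) - 1]`).
#' Secondary, supplementary, unmapped and duplicate-flagged alignments are
#' excluded.  Reads with mapping quality 0 are retained: the filters make no
#' mapping-quality assumption.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file (or a
#'   [Rsamtools::BamFile]).
#' @param record One-row mutation data.frame (see [mutation_record()]).
#' @param pad Bases of padding around the locus used for the random-access
#'   query window (default 200; results are identical for any pad >= 0
#'   because the overlap condition is re-checked).
#' @return data.frame with one row per alignment: `qname`, `flag`, `strand`
#'   (`"+"`/`"-"`), `pos` (leftmost mapped position), `cigar`, `seq`, `qual`
#'   (character strings).
#' @export
fetch_reads <- function(bam, record, pad = 200L) {
  stopifnot(nrow(record) == 1)
  bf <- if (inherits(bam, "BamFile")) bam else Rsamtools::BamFile(bam)
  hdr <- Rsamtools::scanBamHeader(bf)
  targets <- hdr$targets
  if (!record$chrom %in% names(targets))
    stop("contig absent from BAM header: ", record$chrom)
  lo <- record$pos
  hi <- record$pos + nchar(record$ref) - 1L
  which <- GenomicRanges::GRanges(record$chrom,
                                  IRanges::IRanges(max(1L, lo - pad), hi + pad))
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "flag", "pos", "cigar", "seq", "qual", "strand"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE))
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0) return(empty_reads_df())
  reads <- data.frame(
    qname = res$qname,
    flag = res$flag,
    strand = as.character(res$strand),
    pos = res$pos,
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    stringsAsFactors = FALSE)
  ## re-check overlap of the mapped span with the locus footprint
  span_end <- reads$pos +
    GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar) - 1L
  keep <- reads$pos <= hi & span_end >= lo
  reads <- reads[keep, , drop = FALSE]
  ## stable order independent of BAM internals
  reads <- reads[order(reads$pos, reads$qname, reads$flag), , drop = FALSE]
  rownames(reads) <- NULL
  reads
}

empty_reads_df <- function() {
  data.frame(qname = character(0), flag = integer(0), strand = character(0),
             pos = integer(0), cigar = character(0), seq = character(0),
             qual = character(0), stringsAsFactors = FALSE)
}
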