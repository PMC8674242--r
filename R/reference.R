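#' Load a reference genome
#'
#' Reads a FASTA file into memory as a [Biostrings::DNAStringSet] and trims
#' sequence names to their first whitespace-separated token (the convention
#' used by BAM headers).  Intended for panel-sized or toy references; windows
#' are then extracted in memory.
#'
#' @param fasta Path to a FASTA file.
#' @return A named `DNAStringSet`.
#' @export
load_reference <- function(fasta) {
  if (!file.exists(fasta)) stop("reference FASTA not found: ", fasta)
  genome <- Biostrings::readDNAStringSet(fasta)
  if (length(genome) == 0) stop("reference FASTA is empty: ", fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Extract a reference window
#'
#' Returns the reference sequence on `chrom` over the 1-based inclusive
#' interval `[start, end]`, truncated at contig ends.
#'
#' @param genome A `DNAStringSet` as returned by [load_reference()].
#' @param chrom Contig name.
#' @param start,end 1-based inclusive coordinates (clipped to the contig).
#' @return A character scalar (possibly shorter than requested near contig
#'   ends).  The actual start used is available as attribute `"start"`.
#' @export
ref_window <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("contig not present in reference: ", chrom)
  len <- Biostrings::width(genome[chrom])
  s <- max(1L, as.integer(start))
  e <- min(len, as.integer(end))
  if (s > e) return(structure("", start = s))
  out <- as.character(Biostrings::subseq(genome[[chrom]], s, e))
  structure(out, start = s)
}

## Reverse complement for plain character vectors (ACGTN alphabet).
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_acgt <- function(x) grepl("^[ACGT]+$", x)
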