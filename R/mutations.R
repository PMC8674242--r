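## Mutation list IO and allele normalization.
##
## Internal representation: a data.frame with one row per mutation and columns
##   sample, chrom, pos, ref, alt, mut_type, mut_len
## Alleles are anchored (VCF-style): for indels, ref and alt share their first
## base and pos is the position of that anchor base.  pos is 1-based.

#' Construct a normalized mutation record
#'
#' Builds a single-row mutation data.frame in the package's internal
#' representation and derives the mutation type and event length.  Alleles
#' must already be anchored (use [read_mutation_list()] for files in the
#' `"-"` indel dialect).
#'
#' @param sample Sample name.
#' @param chrom Contig name.
#' @param pos 1-based position of the first reference base of the event
#'   (anchor base for indels).
#' @param ref,alt Reference and alternate allele strings (ACGT).
#' @return One-row data.frame with columns `sample`, `chrom`, `pos`, `ref`,
#'   `alt`, `mut_type` (`SNV`, `MNV`, `INS` or `DEL`) and `mut_len` (number
#'   of substituted bases, or inserted/deleted bases).
#' @examples
#' mutation_record("S1", "chr1", 100, "TAG", "T")  # 2-base deletion
#' @export
mutation_record <- function(sample, chrom, pos, ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  pos <- suppressWarnings(as.integer(pos))
  if (is.na(pos) || pos < 1) stop("pos must be a coordinate >= 1")
  if (!is_acgt(ref) || !is_acgt(alt)) stop("alleles must be nonempty ACGT strings")
  if (ref == alt) stop("ref and alt alleles are identical")
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) {
    mut_type <- if (nr == 1L) "SNV" else "MNV"
    mut_len <- nr
  } else {
    if (substr(ref, 1, 1) != substr(alt, 1, 1))
      stop("indel alleles must share their leading (anchor) base")
    mut_type <- if (nr > na) "DEL" else "INS"
    mut_len <- abs(nr - na)
    if (min(nr, na) != 1L)
      stop("indel alleles must be fully anchored (shorter allele of length 1)")
  }
  data.frame(sample = as.character(sample), chrom = as.character(chrom),
             pos = pos, ref = ref, alt = alt,
             mut_type = mut_type, mut_len = as.integer(mut_len),
             stringsAsFactors = FALSE)
}

#' Read a mutation list
#'
#' Reads a tab-separated mutation list with header columns `Sample`, `Chr`,
#' `Pos`, `Ref`, `Alt`.  Two indel dialects are accepted: anchored (VCF-style)
#' alleles, and the `"-"` dialect in which an insertion has `Ref = "-"`
#' (bases inserted after `Pos`) and a deletion has `Alt = "-"` (bases
#' `Pos..Pos+n-1` deleted).  `"-"` records are re-anchored using the
#' reference genome.  Malformed records are dropped with a diagnostic;
#' duplicate records are collapsed.
#'
#' @param path Path to the TSV file.
#' @param genome Optional `DNAStringSet` (see [load_reference()]); required
#'   only when the file uses the `"-"` dialect.
#' @return Normalized mutation data.frame (see [mutation_record()]).
#' @export
read_mutation_list <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("mutation list not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE)
  need <- c("Sample", "Chr", "Pos", "Ref", "Alt")
  if (!all(need %in% names(tab)))
    stop("mutation list must have header columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0) stop("mutation list is empty: ", path)
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    rows[[i]] <- tryCatch(
      normalize_mutation_row(tab$Sample[i], tab$Chr[i], tab$Pos[i],
                             tab$Ref[i], tab$Alt[i], genome),
      error = function(e) {
        message(sprintf("skipping mutation list row %d (%s %s:%s %s>%s): %s",
                        i, tab$Sample[i], tab$Chr[i], tab$Pos[i],
                        tab$Ref[i], tab$Alt[i], conditionMessage(e)))
        NULL
      })
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no valid mutation records in ", path)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("sample", "chrom", "pos", "ref", "alt")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

## One raw row -> normalized record, resolving the "-" dialect if needed.
normalize_mutation_row <- function(sample, chrom, pos, ref, alt, genome) {
  ref <- toupper(trimws(ref)); alt <- toupper(trimws(alt))
  pos <- suppressWarnings(as.integer(trimws(pos)))
  if (is.na(pos) || pos < 1) stop("malformed coordinate")
  if (ref == "-" || alt == "-") {
    if (is.null(genome))
      stop("'-' indel dialect requires the reference genome for re-anchoring")
    if (ref == "-" && alt == "-") stop("both alleles are '-'")
    if (ref == "-") {                      # insertion after pos
      if (!is_acgt(alt)) stop("non-DNA inserted allele")
      anchor <- ref_window(genome, chrom, pos, pos)
      if (nchar(anchor) != 1) stop("anchor position outside contig")
      return(mutation_record(sample, chrom, pos, anchor, paste0(anchor, alt)))
    } else {                               # deletion of ref at pos..pos+n-1
      if (!is_acgt(ref)) stop("non-DNA deleted allele")
      if (pos < 2) stop("deletion at contig start cannot be anchored")
      anchor <- ref_window(genome, chrom, pos - 1L, pos - 1L)
      if (nchar(anchor) != 1) stop("anchor position outside contig")
      seen <- ref_window(genome, chrom, pos, pos + nchar(ref) - 1L)
      if (!identical(as.character(seen), ref))
        stop("deleted allele does not match the reference")
      return(mutation_record(sample, chrom, pos - 1L, paste0(anchor, ref), anchor))
    }
  }
  mutation_record(sample, chrom, pos, ref, alt)
}

#' Write a mutation list
#'
#' Writes normalized mutation records back to the tab-separated `Sample`,
#' `Chr`, `Pos`, `Ref`, `Alt` format (anchored alleles).  Reading the result
#' with [read_mutation_list()] reproduces the records.
#'
#' @param mutations Mutation data.frame (see [mutation_record()]).
#' @param path Output path.
#' @export
write_mutation_list <- function(mutations, path) {
  out <- data.frame(Sample = mutations$sample, Chr = mutations$chrom,
                    Pos = mutations$pos, Ref = mutations$ref,
                    Alt = mutations$alt, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## Fixed column order of the results table.
result_columns <- function() {
  c("Sample", "Chr", "Pos", "Ref", "Alt", "Type", "ReadDepth",
    "MutSupportingReads", "P_shorter", "P_directional", "HairpinRate",
    "HomologyRate", "Filter1", "Filter2", "Filter3", "Filter4",
    "Exemptions", "Verdict")
}

#' Write per-mutation filter results
#'
#' Serializes classification results (one row per input mutation; the filters
#' annotate, they never drop rows) as a tab-separated table with a stable
#' column order.  Probabilities are written in scientific notation, booleans
#' as TRUE/FALSE, absent values as NA.
#'
#' @param rows Results data.frame as produced by [classify_mutation()] /
#'   [run_pipeline()].
#' @param path Output path.
#' @export
write_results <- function(rows, path) {
  cols <- result_columns()
  if (nrow(rows) == 0) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(NULL))
  }
  stopifnot(all(cols %in% names(rows)))
  out <- rows[cols]
  fmt_p <- function(p) ifelse(is.na(p), "NA", sprintf("%.6e", p))
  fmt_r <- function(r) ifelse(is.na(r), "NA", sprintf("%.6f", r))
  out$P_shorter <- fmt_p(out$P_shorter)
  out$P_directional <- fmt_p(out$P_directional)
  out$HairpinRate <- fmt_r(out$HairpinRate)
  out$HomologyRate <- fmt_r(out$HomologyRate)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a results table written by [write_results()]
#'
#' @param path Path to the results TSV.
#' @return data.frame with the columns of [write_results()], with numeric and
#'   logical columns restored.
#' @export
read_results <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  for (cc in c("Pos", "ReadDepth", "MutSupportingReads"))
    tab[[cc]] <- as.integer(tab[[cc]])
  for (cc in c("P_shorter", "P_directional", "HairpinRate", "HomologyRate"))
    tab[[cc]] <- suppressWarnings(as.numeric(tab[[cc]]))
  for (cc in paste0("Filter", 1:4))
    tab[[cc]] <- as.logical(tab[[cc]])
  tab
}
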