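#' Pipeline configuration
#'
#' Bundles the tunable parameters of the artifact filters.  Defaults are the
#' published operating point of the method; see the methods vignette for the
#' rationale behind each value.
#'
#' @param read_length Nominal read length in bases.  Used only for sanity
#'   warnings: all supporting-length arithmetic uses each read's actual
#'   post-trim length.
#' @param adapters Character vector of 0--2 adapter sequences trimmed from the
#'   sequencing 3' end of each read before analysis (no-op on pre-trimmed
#'   libraries).
#' @param p_threshold Probability threshold of the supporting-length test;
#'   mutations with p strictly below it are flagged (default `1e-6`).
#' @param hairpin_window Distance in bases around the locus searched for the
#'   opposite-strand occurrence of the read-derived query (default 200).
#' @param hairpin_min_len Minimum hairpin query length in bases (default 15).
#' @param hairpin_rate Fraction of supporting reads that must look
#'   hairpin-derived before Filter 2 fires; strict inequality (default 0.5).
#' @param homology_len Length in bases of the homology queries (default 40).
#' @param homology_rate Fraction of supporting reads whose queries must match
#'   elsewhere in the genome before Filter 4 fires; strict (default 0.15).
#' @param exemption_fraction Observed-range / observed-mass fraction of the
#'   theoretical range above which the length test is deliberately not
#'   applied, guarding against over-filtering at deep coverage (default 0.75).
#' @param adapter_mismatch_rate Maximum mismatch fraction tolerated when
#'   matching the adapter (default 0.10).
#' @param null_from Source of the empirical null distribution `f`: reads
#'   without the mutation at the same locus (`"nonmutant"`, default) or the
#'   mutation-supporting reads themselves (`"mutant"`; provided for
#'   comparison).
#' @param min_depth_warn Locus depth below which a coverage warning is
#'   emitted (default 100).
#'
#' @return A list of class `micr_config`.
#' @examples
#' cfg <- micr_config(p_threshold = 1e-5)
#' cfg$p_threshold
#' @export
micr_config <- function(read_length = 150L,
                        adapters = character(0),
                        p_threshold = 1e-6,
                        hairpin_window = 200L,
                        hairpin_min_len = 15L,
                        hairpin_rate = 0.5,
                        homology_len = 40L,
                        homology_rate = 0.15,
                        exemption_fraction = 0.75,
                        adapter_mismatch_rate = 0.10,
                        null_from = c("nonmutant", "mutant"),
                        min_depth_warn = 100L) {
  null_from <- match.arg(null_from)
  stopifnot(
    read_length > 0,
    length(adapters) <= 2,
    p_threshold > 0, p_threshold < 1,
    hairpin_window > 0,
    hairpin_min_len >= 1,
    hairpin_rate >= 0, hairpin_rate <= 1,
    homology_len >= 1,
    homology_rate >= 0, homology_rate <= 1,
    exemption_fraction > 0, exemption_fraction < 1,
    adapter_mismatch_rate >= 0, adapter_mismatch_rate < 1
  )
  if (length(adapters) > 0) {
    adapters <- toupper(adapters)
    if (!all(grepl("^[ACGT]+$", adapters)))
      stop("adapters must be ACGT-only sequences")
  }
  structure(list(
    read_length = as.integer(read_length),
    adapters = adapters,
    p_threshold = p_threshold,
    hairpin_window = as.integer(hairpin_window),
    hairpin_min_len = as.integer(hairpin_min_len),
    hairpin_rate = hairpin_rate,
    homology_len = as.integer(homology_len),
    homology_rate = homology_rate,
    exemption_fraction = exemption_fraction,
    adapter_mismatch_rate = adapter_mismatch_rate,
    null_from = null_from,
    min_depth_warn = as.integer(min_depth_warn)
  ), class = "micr_config")
}

#' @export
print.micr_config <- function(x, ...) {
  cat("micrfilter configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (length(v) == 0) "(none)" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
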