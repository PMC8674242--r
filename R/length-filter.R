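## Positional-bias (supporting-length) test: Filters 1 and 3.
##
## For a true mutation the supporting lengths of mutation-carrying reads
## spread over the whole theoretically achievable range; chimeric-read
## artifacts pin them into a narrow band.  The test compares the observed
## range [A, B] with the theoretical range [C, D] using the empirical
## distribution f of supporting lengths in reads without the mutation:
##     p = ( sum_{m=A..B} f(m) / sum_{n=C..D} f(n) )^E
## with E the number of mutation-supporting reads.

#' Theoretical supporting-length range
#'
#' Bounds of the supporting lengths an aligner can generate for reads
#' carrying the mutation, given the read length `L`, event size `N` and the
#' flanking repeat runs `R5`/`R3` (see [compute_repeat_context()]).  For an
#' `N`-base substitution the directional lengths range over `0 .. L - N` and
#' the shorter length over `0 .. floor((L - N) / 2)`.  Indels additionally
#' require at least `N + 1` matching bases outside the gap (an `N`-base gap
#' costs `N + 6` while soft-clipping costs 5) and full coverage of the
#' flanking repeat runs, giving per-side minima of `max(R, N + 1)`.
#'
#' @param mut_type `"SNV"`, `"MNV"`, `"DEL"` or `"INS"`.
#' @param N Event length in bases (`mut_len` of the record).
#' @param L Read length in bases (post-trim).
#' @param R5,R3 Flanking repeat-run lengths (0 for substitutions).
#' @param which `"five_prime"`, `"three_prime"` or `"shorter"`.
#' @return list with integer bounds `C`, `D` and `valid` (FALSE when the
#'   bounds invert, which marks the mutation unfilterable by length).
#' @examples
#' theoretical_bounds("SNV", 1, 150, which = "shorter")   # C=0, D=74
#' theoretical_bounds("DEL", 2, 150, R5 = 0, R3 = 4, which = "three_prime")
#' @export
theoretical_bounds <- function(mut_type, N, L, R5 = 0L, R3 = 0L,
                               which = c("five_prime", "three_prime",
                                         "shorter")) {
  which <- match.arg(which)
  stopifnot(L > N, N >= 1, R5 >= 0, R3 >= 0)
  N <- as.integer(N); L <- as.integer(L)
  R5 <- as.integer(R5); R3 <- as.integer(R3)
  m5 <- max(R5, N + 1L); m3 <- max(R3, N + 1L)
  b <- switch(mut_type,
    SNV = , MNV = switch(which,
      five_prime = , three_prime = c(0L, L - N),
      shorter = c(0L, (L - N) %/% 2L)),
    DEL = switch(which,
      five_prime = c(m5, L - m3),
      three_prime = c(m3, L - m5),
      shorter = c(min(m3, m5), L %/% 2L)),
    INS = switch(which,
      five_prime = c(m5, L - N - m3),
      three_prime = c(m3, L - N - m5),
      shorter = c(min(m3, m5), (L - N) %/% 2L)),
    stop("unknown mutation type: ", mut_type))
  list(C = b[1], D = b[2], valid = b[1] <= b[2])
}

#' Empirical null distribution of supporting lengths
#'
#' Tabulates the supporting lengths of reads without the mutation at the
#' locus, computed by the same positional rules as for mutant reads.
#'
#' @param lengths Integer vector of supporting lengths of the non-mutant
#'   reads (one per read; NAs dropped).
#' @return Named integer vector: `f[x]` = number of reads with supporting
#'   length `x`.  Zero-length input returns an empty vector (the caller
#'   applies the insufficient-reads exemption).
#' @export
null_distribution <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  if (length(lengths) == 0) return(setNames(integer(0), character(0)))
  tab <- table(lengths)
  setNames(as.integer(tab), names(tab))
}

#' Multinomial probability of the observed supporting-length range
#'
#' Computes `p = (sum_{m=A..B} f(m) / sum_{n=C..D} f(n))^E` in log space so
#' that deep coverage (large `E`) does not underflow.
#'
#' @param f Named integer vector of null counts (see [null_distribution()]).
#' @param A,B Observed supporting-length range (after clamping into `[C, D]`).
#' @param C,D Theoretical supporting-length range.
#' @param E Number of mutation-supporting reads.
#' @return Probability in `[0, 1]`, or NA when the denominator is zero
#'   (insufficient null mass; callers fall back to the uniform null).
#' @examples
#' f <- setNames(rep(1L, 10), 0:9)
#' multinomial_p(f, A = 3, B = 3, C = 0, D = 9, E = 5)  # (1/10)^5
#' @export
multinomial_p <- function(f, A, B, C, D, E) {
  stopifnot(E >= 1, C <= D, A >= C, B <= D, A <= B)
  v <- as.integer(names(f))
  num <- sum(f[v >= A & v <= B])
  den <- sum(f[v >= C & v <= D])
  if (den == 0) return(NA_real_)
  if (num == 0) return(0)
  log_p <- E * (log(num) - log(den))
  if (log_p >= log(1e-300)) (num / den)^E else exp(log_p)
}

#' Apply the supporting-length filter for one statistic
#'
#' Runs the positional-bias test on one supporting-length statistic (shorter,
#' 5' or 3') of one mutation.  The mutation is flagged when `p` falls
#' strictly below `p_threshold`, unless an exemption holds: observed range
#' covering more than `exemption_fraction` of the theoretical range; observed
#' null mass exceeding `exemption_fraction` of the total null mass; or no
#' usable reads.  If any supporting read has more than three mismatches in
#' the ten bases surrounding the mutation (`dense_mismatch`), the theoretical
#' minimum is set to zero before testing, which avoids over-filtering of
#' clustered mutations whose cumulative mismatch penalties shift the
#' achievable range.
#'
#' @param mut_lens Supporting lengths of the mutation-supporting reads.
#' @param null_lens Supporting lengths of the non-mutant reads (empty
#'   triggers the insufficient-reads exemption).
#' @param bounds Output of [theoretical_bounds()].
#' @param p_threshold Flagging threshold (default `1e-6`, strict `<`).
#' @param exemption_fraction Exemption fraction (default 0.75, strict `>`).
#' @param dense_mismatch TRUE when the 3-mismatches-in-10-bases rule applies.
#' @return list: `flagged`, `p`, `A`, `B`, `C`, `D`, `E`, `exemptions`
#'   (character vector among `range_75pct`, `mass_75pct`, `dense_mismatch`,
#'   `insufficient_reads`), `n_clamped` (observations clamped into `[C, D]`),
#'   `uniform_fallback` (TRUE when the null had no mass on `[C, D]` and the
#'   uniform null was used).
#' @export
apply_length_filter <- function(mut_lens, null_lens, bounds,
                                p_threshold = 1e-6,
                                exemption_fraction = 0.75,
                                dense_mismatch = FALSE) {
  res <- list(flagged = FALSE, p = NA_real_, A = NA_integer_, B = NA_integer_,
              C = NA_integer_, D = NA_integer_, E = length(mut_lens),
              exemptions = character(0), n_clamped = 0L,
              uniform_fallback = FALSE)
  mut_lens <- mut_lens[!is.na(mut_lens)]
  null_lens <- null_lens[!is.na(null_lens)]
  res$E <- length(mut_lens)
  if (res$E == 0 || !isTRUE(bounds$valid)) {
    res$exemptions <- "insufficient_reads"
    return(res)
  }
  C <- if (dense_mismatch) 0L else bounds$C
  D <- bounds$D
  if (dense_mismatch) res$exemptions <- "dense_mismatch"
  res$C <- C; res$D <- D
  clamped <- pmin(pmax(mut_lens, C), D)
  res$n_clamped <- sum(clamped != mut_lens)
  A <- min(clamped); B <- max(clamped)
  res$A <- A; res$B <- B
  if (length(null_lens) == 0) {
    res$exemptions <- union(res$exemptions, "insufficient_reads")
    return(res)
  }
  f <- null_distribution(null_lens)
  p <- multinomial_p(f, A, B, C, D, res$E)
  if (is.na(p)) {            # no null mass on [C, D]: uniform fallback
    res$uniform_fallback <- TRUE
    ratio <- (B - A + 1) / (D - C + 1)
    p <- if (ratio >= 1) 1 else {
      lp <- res$E * log(ratio)
      if (lp >= log(1e-300)) ratio^res$E else exp(lp)
    }
    num_frac_exempt <- (B - A + 1) > exemption_fraction * (D - C + 1)
    if (num_frac_exempt)
      res$exemptions <- union(res$exemptions, "mass_75pct")
  } else {
    v <- as.integer(names(f))
    num <- sum(f[v >= A & v <= B])
    den <- sum(f[v >= C & v <= D])
    if (num > exemption_fraction * den)
      res$exemptions <- union(res$exemptions, "mass_75pct")
  }
  res$p <- p
  if ((B - A + 1) > exemption_fraction * (D - C + 1))
    res$exemptions <- union(res$exemptions, "range_75pct")
  blocking <- setdiff(res$exemptions, "dense_mismatch")
  res$flagged <- length(blocking) == 0 && !is.na(p) && p < p_threshold
  res
}

## Locus-level wrapper: runs the three statistics and combines them into
## Filter 1 (shorter) and Filter 3 (either directional).
length_filter_verdicts <- function(evidence, record, repeats, config) {
  sup <- evidence[which(evidence$supports), , drop = FALSE]
  nul <- evidence[which(!evidence$supports), , drop = FALSE]
  L <- if (nrow(evidence) > 0) max(evidence$read_len) else config$read_length
  if (L > config$read_length)
    message(sprintf("locus %s:%d: observed read length %d exceeds configured %d",
                    record$chrom, record$pos, L, config$read_length))
  dense <- nrow(sup) > 0 && any(sup$mm_local > 3L, na.rm = TRUE)
  one <- function(which, mcol) {
    b <- theoretical_bounds(record$mut_type, record$mut_len, L,
                            repeats$R5, repeats$R3, which)
    if (!b$valid)
      message(sprintf("locus %s:%d: inverted theoretical bounds for %s; %s",
                      record$chrom, record$pos, which,
                      "mutation unfilterable by length"))
    apply_length_filter(sup[[mcol]], nul[[mcol]], b,
                        p_threshold = config$p_threshold,
                        exemption_fraction = config$exemption_fraction,
                        dense_mismatch = dense)
  }
  if (config$null_from == "mutant") {
    ## comparison mode: Eq. 1's f taken from the mutant reads themselves
    nul <- sup
  }
  shorter <- one("shorter", "shorter")
  five <- one("five_prime", "len5")
  three <- one("three_prime", "len3")
  list(
    shorter = shorter, five = five, three = three,
    filter1 = shorter$flagged,
    filter3 = five$flagged || three$flagged,
    p_shorter = shorter$p,
    p_directional = {
      vals <- c(five$p, three$p); vals <- vals[!is.na(vals)]
      if (length(vals)) min(vals) else NA_real_
    },
    exemptions = Reduce(union, list(shorter$exemptions, five$exemptions,
                                    three$exemptions))
  )
}
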