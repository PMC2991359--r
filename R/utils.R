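# Shared helpers: rounding, interval arithmetic, sequence utilities.

#' Round half away from zero
#'
#' Percentages in reports are printed to a fixed number of decimals with
#' ties rounded up (half-up), unlike base `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentage numerator/denominator -> one-decimal half-up value (NA if n = 0)
pct1 <- function(num, den) {
  ifelse(den == 0, NA_real_, round_half_up(100 * num / den, 1))
}

# total width of the union of 1-based inclusive intervals
interval_union_width <- function(start, end) {
  if (length(start) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = start, end = end))))
}

# reverse complement of a plain character DNA string (keeps N)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# base counts of a plain character string
base_counts <- function(seq) {
  lf <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                    c("A", "C", "G", "T", "N"))
  stats::setNames(as.numeric(lf), c("A", "C", "G", "T", "N"))
}

# G+C fraction ignoring N; NA if no unambiguous base
gc_fraction <- function(seq) {
  bc <- base_counts(seq)
  den <- sum(bc[c("A", "C", "G", "T")])
  if (den == 0) return(NA_real_)
  unname((bc["G"] + bc["C"]) / den)
}

# extract subsequence of a replicon, wrapping the origin when circular and
# end > length (callers pass coordinates already normalised to >= 1)
replicon_subseq <- function(rep, start, end) {
  n <- rep$length_bp
  if (end <= n) return(substr(rep$sequence, start, end))
  if (rep$topology != "circular") {
    stop("subsequence beyond the end of a linear replicon", call. = FALSE)
  }
  paste0(substr(rep$sequence, start, n), substr(rep$sequence, 1, end - n))
}

stop_validation <- function(...) {
  stop(structure(
    class = c("cladecompare_validation_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

stop_usage <- function(...) {
  stop(structure(
    class = c("cladecompare_usage_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}
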