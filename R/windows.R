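# Windowed genome signatures: G+C content and GC skew.

# window boundaries tiling a replicon; on circular replicons the final
# window wraps the origin so every window has exactly window_bp bases,
# on linear replicons the final window may be shorter
window_bounds <- function(rep, window_bp) {
  stopifnot(window_bp >= 1)
  n <- rep$length_bp
  if (window_bp >= n) {
    return(data.frame(start = 1L, end = n))
  }
  starts <- seq.int(1L, n, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, n)
  if (rep$topology == "circular" && ends[length(ends)] < starts[length(ends)] + window_bp - 1L) {
    ends[length(ends)] <- starts[length(ends)] + window_bp - 1L  # wraps origin
  }
  data.frame(start = starts, end = ends)
}

new_window_track <- function(replicon_id, window_bp, start, end, value) {
  structure(list(replicon_id = replicon_id, window_bp = as.integer(window_bp),
                 records = data.frame(start = start, end = end, value = value)),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat(sprintf("<window_track> %s: %d windows of %s bp\n", x$replicon_id,
              nrow(x$records), format(x$window_bp, big.mark = ",")))
  invisible(x)
}

# shared engine: map each window's base counts to a value
window_stat <- function(rep, window_bp, fun) {
  b <- window_bounds(rep, window_bp)
  vals <- vapply(seq_len(nrow(b)), function(i) {
    bc <- base_counts(replicon_subseq(rep, b$start[i], b$end[i]))
    fun(bc)
  }, numeric(1))
  new_window_track(rep$id, window_bp, b$start, b$end, vals)
}

#' Windowed G+C content
#'
#' Fraction (G+C)/(A+C+G+T) in non-overlapping windows tiling the
#' replicon. Ns are excluded from both numerator and denominator; a window
#' consisting only of Ns yields `NA`. On circular replicons the final
#' window wraps around the origin (coordinates beyond the replicon length
#' denote the wrapped part); on linear replicons it is simply shorter.
#'
#' @param rep A [replicon()].
#' @param window_bp Window size in bp (default 10000, the conventional
#'   atlas resolution).
#' @return A `window_track` whose `records` hold `(start, end, value)`.
#' @export
windowed_gc <- function(rep, window_bp = 10000) {
  window_stat(rep, window_bp, function(bc) {
    den <- sum(bc[c("A", "C", "G", "T")])
    if (den == 0) NA_real_ else (bc[["G"]] + bc[["C"]]) / den
  })
}

#' Windowed GC skew
#'
#' (G - C)/(G + C) per window; the sign change of cumulative skew marks
#' the replication origin/terminus boundary in most bacterial chromosomes.
#' Windows with G + C = 0 return 0 by convention so AT-only sequence does
#' not produce undefined values.
#'
#' @inheritParams windowed_gc
#' @return A `window_track`; values lie in [-1, 1].
#' @export
gc_skew <- function(rep, window_bp = 10000) {
  window_stat(rep, window_bp, function(bc) {
    gpc <- bc[["G"]] + bc[["C"]]
    if (gpc == 0) 0 else (bc[["G"]] - bc[["C"]]) / gpc
  })
}
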