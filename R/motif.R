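# Upstream regulator-motif scanning (IUPAC patterns, e.g. IdeR boxes).

IUPAC_EXPAND <- c(A = "A", C = "C", G = "G", T = "T",
                  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Scan CDS upstream regions for an IUPAC motif
#'
#' Extracts the coding-strand upstream region of every (non-pseudo) CDS and
#' searches it for a motif given in IUPAC nucleotide code, allowing up to
#' `max_mismatches` substitutions. Both the motif and its reverse
#' complement are matched; the reported strand says which. Positions are
#' relative to the translation start: the base immediately 5' of the start
#' codon is -1, and the reported position is that of the motif's first
#' (5'-most) base in the upstream region. On circular replicons the
#' upstream region may wrap the origin.
#'
#' @param annotation A `genome_annotation`.
#' @param motif Motif string over IUPAC codes.
#' @param max_upstream_bp How far upstream to look (default 200).
#' @param max_mismatches Allowed substitutions (default 0).
#' @param include_pseudo Scan pseudogene CDSs too? Default FALSE.
#' @return A data.frame with columns `locus_tag`, `position` (negative
#'   integer), `matched_seq`, `strand` (`+` motif as given, `-` its
#'   reverse complement).
#' @examples
#' # an IdeR-type box planted 32 bp upstream of a toy gene
#' up <- "TTTGGTCAGGCTCACCTAA"
#' seq <- paste0(strrep("A", 10), up, strrep("A", 13), "ATGAAATAA")
#' ann <- genome_annotation("toy", replicon("chr", seq),
#'   gene_features("g1", "chr", nchar(seq) - 8, nchar(seq)))
#' upstream_motif_scan(ann, up)  # hit at position -32
#' @export
upstream_motif_scan <- function(annotation, motif, max_upstream_bp = 200,
                                max_mismatches = 0, include_pseudo = FALSE) {
  motif <- toupper(motif)
  chars <- strsplit(motif, "")[[1]]
  if (!all(chars %in% names(IUPAC_EXPAND))) {
    stop_validation("non-IUPAC character(s) in motif: ",
                    paste(unique(setdiff(chars, names(IUPAC_EXPAND))),
                          collapse = ", "))
  }
  if (max_upstream_bp < nchar(motif)) {
    stop_validation("max_upstream_bp must be >= motif length")
  }
  f <- annotation$features
  idx <- which(f$ftype == "CDS" & (include_pseudo | !f$is_pseudo))
  out <- list()
  rc <- revcomp(motif)
  for (i in idx) {
    up <- upstream_region(annotation$replicons[[f$replicon_id[i]]],
                          f$start[i], f$end[i], f$strand[i], max_upstream_bp)
    L <- nchar(up)
    if (L < nchar(motif)) next
    for (m in list(list(pat = motif, strand = "+"),
                   list(pat = rc, strand = "-"))) {
      pos <- iupac_match_positions(up, m$pat, max_mismatches)
      for (p in pos) {
        out[[length(out) + 1L]] <- data.frame(
          locus_tag = f$locus_tag[i],
          position = p - L - 1L,  # last upstream base is position -1
          matched_seq = substr(up, p, p + nchar(motif) - 1L),
          strand = m$strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(locus_tag = character(0), position = integer(0),
                      matched_seq = character(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$locus_tag, res$position, res$strand), , drop = FALSE]
}

# coding-strand upstream region of a CDS, 5'->3', ending at the base
# adjacent to the start codon; clipped at the replicon edge when linear,
# wrapped around the origin when circular (never far enough to reach
# into the gene itself)
upstream_region <- function(rep, start, end, strand, max_upstream_bp) {
  n <- rep$length_bp
  gene_len <- end - start + 1L
  eff <- min(max_upstream_bp, n - gene_len)
  if (eff <= 0L) return("")
  if (rep$topology == "circular") {
    dbl <- paste0(rep$sequence, rep$sequence)
    if (strand == "+") {
      to <- start - 1L + n  # doubled coordinates
      substr(dbl, to - eff + 1L, to)
    } else {
      revcomp(substr(dbl, end + 1L, end + eff))
    }
  } else {
    if (strand == "+") {
      if (start == 1L) return("")
      substr(rep$sequence, max(1L, start - eff), start - 1L)
    } else {
      if (end == n) return("")
      revcomp(substr(rep$sequence, end + 1L, min(n, end + eff)))
    }
  }
}

# positions (1-based) where an IUPAC pattern matches a plain subject with
# at most k mismatches; Biostrings does the degenerate-base matching
iupac_match_positions <- function(subject, pattern, k) {
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    max.mismatch = k, with.indels = FALSE,
    fixed = c(pattern = FALSE, subject = TRUE))
  BiocGenerics::start(hits)
}
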