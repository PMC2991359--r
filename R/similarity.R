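# Directed protein similarity hits: desk-scale local alignment, tabular
# hit import/export, best-hit filtering, taxonomic best-hit profiling.

hit_columns <- c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore", "query_len", "subject_len")

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_length = integer(0),
             mismatch = integer(0), gapopen = integer(0),
             qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             query_len = integer(0), subject_len = integer(0),
             stringsAsFactors = FALSE)
}

#' Read a 12-column tabular hit file
#'
#' Parses the standard tab-separated hit format (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore), with
#' optional columns 13-14 giving query and subject lengths. Lines starting
#' with `#` are skipped. When lengths are not embedded, supply them via
#' `query_lengths`/`subject_lengths` (named integer vectors), e.g. read
#' from sidecar 2-column TSV length tables.
#'
#' @param path Hit table path.
#' @param query_lengths,subject_lengths Optional named vectors
#'   (id -> sequence length) used when columns 13-14 are absent.
#' @return A hit data.frame (one row per hit).
#' @export
read_hit_table <- function(path, query_lengths = NULL, subject_lengths = NULL) {
  if (!file.exists(path)) stop_validation("hit table not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (!all(ncols %in% c(12L, 14L))) {
    bad <- which(!ncols %in% c(12L, 14L))[1]
    stop_validation("hit table ", path, ": expected 12 or 14 columns, got ",
                    ncols[bad], " at data line ", bad)
  }
  if (length(unique(ncols)) != 1L) {
    stop_validation("hit table ", path, ": mixed column counts")
  }
  m <- do.call(rbind, parts)
  df <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (ncols[1] == 14L) {
    df$query_len <- as.integer(m[, 13])
    df$subject_len <- as.integer(m[, 14])
  } else {
    if (is.null(query_lengths) || is.null(subject_lengths)) {
      stop_validation("hit table ", path, " has no length columns; supply ",
                      "query_lengths and subject_lengths")
    }
    df$query_len <- as.integer(query_lengths[df$query_id])
    df$subject_len <- as.integer(subject_lengths[df$subject_id])
    if (anyNA(df$query_len) || anyNA(df$subject_len)) {
      stop_validation("hit table ", path, ": sequence ids missing from ",
                      "length tables")
    }
  }
  if (any(!is.finite(df$evalue))) {
    stop_validation("hit table ", path, ": non-finite e-value")
  }
  df
}

#' @rdname read_hit_table
#' @param hits A hit data.frame.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, hit_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ungapped BLOSUM62 Karlin-Altschul constants used for the e-value layer
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Local protein alignment at desk scale
#'
#' All-vs-all Smith-Waterman local alignment (BLOSUM62, affine gaps: open
#' 11, extend 1) of a query set against a subject set, reported in the
#' tabular hit convention. E-values use the Karlin-Altschul formula
#' E = K m n exp(-lambda S) with ungapped BLOSUM62 constants (K = 0.041,
#' lambda = 0.267) and search space m n = query length x total subject
#' length — an approximation adequate for the small protein sets this
#' function targets; externally computed hit tables remain authoritative
#' for real genomes.
#'
#' @param query_set,subject_set Named character vectors of amino-acid
#'   sequences (or `AAStringSet`).
#' @param min_score Alignments scoring below this raw score are not
#'   reported (default 0 reports everything with positive score).
#' @return A hit data.frame; self-comparisons of identical ids are kept
#'   (downstream best-hit filtering removes them).
#' @export
align_proteins <- function(query_set, subject_set, min_score = 1) {
  q <- as_aa_set(query_set, "query_set")
  s <- as_aa_set(subject_set, "subject_set")
  if (!length(q) || !length(s)) return(empty_hits())
  total_s <- sum(Biostrings::width(s))
  blosum <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  # one vectorized alignment over the full query x subject grid
  qi <- rep(seq_along(q), each = length(s))
  sj <- rep(seq_along(s), times = length(q))
  aln <- Biostrings::pairwiseAlignment(
    pattern = q[qi], subject = s[sj], type = "local",
    substitutionMatrix = blosum, gapOpening = 11, gapExtension = 1)
  score <- Biostrings::score(aln)
  keep <- which(score >= min_score)
  if (!length(keep)) return(empty_hits())
  kept <- aln[keep]
  nmatch <- Biostrings::nmatch(kept)
  nmis <- Biostrings::nmismatch(kept)
  indel <- Biostrings::nindel(kept)
  ins <- Biostrings::insertion(indel)
  del <- Biostrings::deletion(indel)
  alen <- nmatch + nmis + ins[, "WidthSum"] + del[, "WidthSum"]
  data.frame(
    query_id = names(q)[qi[keep]], subject_id = names(s)[sj[keep]],
    pct_identity = round(100 * nmatch / alen, 2),
    aln_length = alen,
    mismatch = nmis,
    gapopen = ins[, "Length"] + del[, "Length"],
    qstart = BiocGenerics::start(Biostrings::pattern(kept)),
    qend = BiocGenerics::end(Biostrings::pattern(kept)),
    sstart = BiocGenerics::start(Biostrings::subject(kept)),
    send = BiocGenerics::end(Biostrings::subject(kept)),
    evalue = KA_K * Biostrings::width(q)[qi[keep]] * total_s *
      exp(-KA_LAMBDA * score[keep]),
    bitscore = round((KA_LAMBDA * score[keep] - log(KA_K)) / log(2), 1),
    query_len = Biostrings::width(q)[qi[keep]],
    subject_len = Biostrings::width(s)[sj[keep]],
    stringsAsFactors = FALSE
  )
}

as_aa_set <- function(x, what) {
  if (inherits(x, "AAStringSet")) {
    if (is.null(names(x))) stop_validation(what, " must be named")
    return(x)
  }
  if (!is.character(x) || is.null(names(x))) {
    stop_validation(what, " must be a named character vector or AAStringSet")
  }
  bad <- gsub("[ACDEFGHIKLMNPQRSTVWYX*]", "", toupper(x))
  if (any(nzchar(bad))) {
    stop_validation(what, ": non-amino-acid characters in ",
                    paste(names(x)[nzchar(bad)][1], collapse = ", "))
  }
  Biostrings::AAStringSet(toupper(x))
}

#' Filter hits to the best hit per query
#'
#' Applies the standard comparative-genomics retention rule — e-value
#' strictly below `evalue_max` and alignment overlap strictly above
#' `min_overlap` — then keeps a single best hit per query: lowest e-value,
#' ties broken by highest bitscore, then lexicographically smallest
#' subject id (so the result is deterministic under input permutation).
#' Self-hits (query id equal to subject id) and hits touching an excluded
#' gene (e.g. transposases) are dropped.
#'
#' @param hits A hit data.frame.
#' @param evalue_max E-value threshold, exclusive (default 1e-3).
#' @param min_overlap Overlap threshold, exclusive (default 0.8).
#' @param overlap_basis `"query"` (alignment length / query length, the
#'   default) or `"shorter"` (alignment length / shorter sequence length).
#' @param exclude Character vector of gene ids to drop on either side.
#' @return An object of class `best_hit_map`: a data.frame with one row
#'   per retained query, ordered by query id.
#' @export
filter_best_hits <- function(hits, evalue_max = 1e-3, min_overlap = 0.8,
                             overlap_basis = c("query", "shorter"),
                             exclude = character(0)) {
  overlap_basis <- match.arg(overlap_basis)
  h <- hits
  if (nrow(h)) {
    den <- if (overlap_basis == "query") h$query_len
           else pmin(h$query_len, h$subject_len)
    keep <- h$evalue < evalue_max & h$aln_length / den > min_overlap &
      h$query_id != h$subject_id &
      !(h$query_id %in% exclude) & !(h$subject_id %in% exclude)
    h <- h[keep, , drop = FALSE]
  }
  if (nrow(h)) {
    ord <- order(h$query_id, h$evalue, -h$bitscore, h$subject_id)
    h <- h[ord, , drop = FALSE]
    h <- h[!duplicated(h$query_id), , drop = FALSE]
  }
  rownames(h) <- NULL
  structure(h, class = c("best_hit_map", "data.frame"))
}

#' Taxonomic profile of best hits
#'
#' Tallies best hits by the taxon of their subject; subjects without a
#' taxon assignment count as `"unknown"`. The display cutoff mirrors the
#' usual practice of plotting only taxa with more than `min_count` best
#' matches; all taxa are always returned, with an `above_cutoff` flag.
#'
#' @param best_hits A `best_hit_map`.
#' @param taxon_of Named character vector mapping subject id -> taxon.
#' @param min_count Display cutoff (default 20).
#' @return A data.frame `(taxon, count, above_cutoff)` sorted by
#'   decreasing count.
#' @export
taxonomy_profile <- function(best_hits, taxon_of, min_count = 20) {
  if (nrow(best_hits) == 0L) {
    return(data.frame(taxon = character(0), count = integer(0),
                      above_cutoff = logical(0), stringsAsFactors = FALSE))
  }
  taxa <- unname(taxon_of[best_hits$subject_id])
  taxa[is.na(taxa)] <- "unknown"
  tab <- sort(table(taxa), decreasing = TRUE)
  data.frame(taxon = names(tab), count = as.integer(tab),
             above_cutoff = as.integer(tab) > min_count,
             stringsAsFactors = FALSE)
}

#' Percentage of best hits falling in a clade
#'
#' @param profile Output of [taxonomy_profile()].
#' @param taxa Taxon names making up the clade.
#' @param digits Decimals (0 = nearest integer, the usual reporting style).
#' @return Percentage of all profiled best hits whose taxon is in `taxa`.
#' @export
taxon_pct <- function(profile, taxa, digits = 0) {
  total <- sum(profile$count)
  if (total == 0) return(NA_real_)
  round_half_up(100 * sum(profile$count[profile$taxon %in% taxa]) / total,
                digits)
}
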