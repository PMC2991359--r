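#' Construct a replicon
#'
#' A replicon is one DNA molecule of a genome (chromosome or plasmid) with a
#' declared topology. Topology is never inferred from sequence content: a
#' circular chromosome and a linear contig of the same sequence behave
#' differently in windowed statistics, so the caller must say which it is.
#'
#' @param id Replicon identifier (unique within a genome).
#' @param sequence DNA sequence as a single string over A, C, G, T, N
#'   (lower case accepted and normalised).
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `replicon` with fields `id`, `topology`,
#'   `sequence` and `length_bp`.
#' @examples
#' rep <- replicon("chr", "ACGTACGT", topology = "circular")
#' rep$length_bp
#' @export
replicon <- function(id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("replicon 'id' must be a non-empty string", call. = FALSE)
  }
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence)) {
    stop("replicon 'sequence' must be a single string", call. = FALSE)
  }
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop(sprintf("replicon '%s': sequence contains non-ACGTN characters: %s",
                 id, substr(bad, 1, 10)), call. = FALSE)
  }
  if (nchar(sequence) < 1L) {
    stop(sprintf("replicon '%s': empty sequence", id), call. = FALSE)
  }
  structure(
    list(id = id, topology = topology, sequence = sequence,
         length_bp = nchar(sequence)),
    class = "replicon"
  )
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s  %s  %s bp\n", x$id, x$topology,
              format(x$length_bp, big.mark = ",")))
  invisible(x)
}

feature_columns <- c("locus_tag", "replicon_id", "start", "end", "strand",
                     "ftype", "is_pseudo", "is_transposase", "product",
                     "cog", "families", "protein")

#' Construct a gene feature table
#'
#' Returns a validated data frame of gene features in the internal
#' convention: coordinates 1-based inclusive with `start <= end` on the
#' forward projection, strand `+`/`-`, and feature type one of CDS, tRNA,
#' rRNA, other. `cog` and `families` hold semicolon-separated COG category
#' letters and domain-family identifiers (empty string = unannotated).
#'
#' @param locus_tag,replicon_id Character vectors.
#' @param start,end Integer coordinates, 1-based inclusive.
#' @param strand `"+"` or `"-"`.
#' @param ftype Feature type: CDS, tRNA, rRNA or other.
#' @param is_pseudo,is_transposase Logical flags.
#' @param product Free-text product description.
#' @param cog Semicolon-separated single-letter COG categories.
#' @param families Semicolon-separated domain-family IDs (e.g. PF00356).
#' @param protein Amino-acid sequence, `""` if unavailable.
#' @return A data.frame with one row per feature.
#' @export
gene_features <- function(locus_tag, replicon_id, start, end,
                          strand = "+", ftype = "CDS",
                          is_pseudo = FALSE, is_transposase = FALSE,
                          product = "", cog = "", families = "",
                          protein = "") {
  n <- length(locus_tag)
  df <- data.frame(
    locus_tag = as.character(locus_tag),
    replicon_id = rep_len(as.character(replicon_id), n),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    strand = rep_len(as.character(strand), n),
    ftype = rep_len(as.character(ftype), n),
    is_pseudo = rep_len(as.logical(is_pseudo), n),
    is_transposase = rep_len(as.logical(is_transposase), n),
    product = rep_len(as.character(product), n),
    cog = rep_len(as.character(cog), n),
    families = rep_len(as.character(families), n),
    protein = rep_len(as.character(protein), n),
    stringsAsFactors = FALSE
  )
  df
}

empty_features <- function() {
  gene_features(character(0), character(0), integer(0), integer(0))[0, ]
}

#' Assemble a genome annotation
#'
#' Binds an ordered set of replicons and a gene-feature table into one
#' validated genome object, the unit on which all downstream analyses
#' operate.
#'
#' @param genome_id Genome identifier.
#' @param replicons A list of [replicon()] objects (order is kept).
#' @param features A feature data frame as built by [gene_features()] or
#'   read by [read_feature_table()]; may have zero rows.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, replicons, features = empty_features()) {
  if (inherits(replicons, "replicon")) replicons <- list(replicons)
  stopifnot(is.list(replicons), length(replicons) >= 1L)
  names(replicons) <- vapply(replicons, function(r) r$id, character(1))
  if (anyDuplicated(names(replicons))) {
    stop("duplicate replicon ids", call. = FALSE)
  }
  if (is.null(features) || nrow(features) == 0L) {
    features <- empty_features()
  }
  missing_cols <- setdiff(feature_columns, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  features <- features[, feature_columns]
  obj <- structure(
    list(genome_id = genome_id, replicons = replicons, features = features),
    class = "genome_annotation"
  )
  validate_annotation(obj)
  obj
}

#' Validate a genome annotation
#'
#' Checks the structural invariants: unique locus tags, every feature on an
#' existing replicon, coordinates within the replicon and `start <= end`,
#' strand in `+`/`-`, known feature types.
#'
#' @param x A `genome_annotation`.
#' @return `x`, invisibly, if valid; otherwise an error of class
#'   `cladecompare_validation_error` listing offending locus tags.
#' @export
validate_annotation <- function(x) {
  f <- x$features
  fail <- function(msg) {
    stop(structure(
      class = c("cladecompare_validation_error", "error", "condition"),
      list(message = msg, call = NULL)
    ))
  }
  if (nrow(f) == 0L) return(invisible(x))
  if (anyDuplicated(f$locus_tag)) {
    fail(paste0("duplicate locus_tags: ",
                paste(unique(f$locus_tag[duplicated(f$locus_tag)]),
                      collapse = ", ")))
  }
  unknown <- setdiff(unique(f$replicon_id), names(x$replicons))
  if (length(unknown)) {
    bad <- f$locus_tag[f$replicon_id %in% unknown]
    fail(paste0("features on unknown replicons: ",
                paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(f$start < 1L) || any(f$start > f$end)) {
    bad <- f$locus_tag[f$start < 1L | f$start > f$end]
    fail(paste0("bad coordinates (start < 1 or start > end): ",
                paste(utils::head(bad, 5), collapse = ", ")))
  }
  rlen <- vapply(x$replicons, function(r) r$length_bp, numeric(1))
  over <- f$end > rlen[f$replicon_id]
  if (any(over)) {
    fail(paste0("features outside replicon bounds: ",
                paste(utils::head(f$locus_tag[over], 5), collapse = ", ")))
  }
  if (!all(f$strand %in% c("+", "-"))) {
    fail("strand must be '+' or '-'")
  }
  if (!all(f$ftype %in% c("CDS", "tRNA", "rRNA", "other"))) {
    fail(paste0("unknown feature type(s): ",
                paste(setdiff(unique(f$ftype),
                              c("CDS", "tRNA", "rRNA", "other")),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d replicon(s), %s bp, %d feature(s)\n",
              x$genome_id, length(x$replicons),
              format(sum(vapply(x$replicons, function(r) r$length_bp,
                                numeric(1))), big.mark = ","),
              nrow(x$features)))
  invisible(x)
}

# split a semicolon-separated annotation cell into a character set
split_multi <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
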