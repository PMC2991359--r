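# Insertion-sequence census, cluster-region scanning and nested-insertion
# ("russian doll") detection.

is_columns <- c("element_id", "name", "family", "replicon_id", "start",
                "end", "strand", "completeness", "parent_name")

#' Build / read / write an IS element table
#'
#' Elements are annotated copies of insertion sequences: `name` identifies
#' the IS (e.g. ISAar15), `family` its IS family (e.g. IS3),
#' `completeness` is `complete`, `partial` or `unset` (to be classified
#' against a catalog), and fragments of one interrupted copy share a
#' `parent_name`.
#'
#' @param element_id,name,family,replicon_id Character vectors.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"`/`"-"`.
#' @param completeness `complete`, `partial` or `unset`.
#' @param parent_name Shared label of fragments of one interrupted copy
#'   (`""` = none).
#' @return data.frame of IS elements.
#' @export
is_elements <- function(element_id, name, family, replicon_id, start, end,
                        strand = "+", completeness = "unset",
                        parent_name = "") {
  n <- length(element_id)
  data.frame(
    element_id = as.character(element_id),
    name = rep_len(as.character(name), n),
    family = rep_len(as.character(family), n),
    replicon_id = rep_len(as.character(replicon_id), n),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    strand = rep_len(as.character(strand), n),
    completeness = rep_len(as.character(completeness), n),
    parent_name = rep_len(as.character(parent_name), n),
    stringsAsFactors = FALSE)
}

#' @rdname is_elements
#' @param path TSV path (columns element_id, name, family, replicon,
#'   start, end, strand, completeness, parent).
#' @export
read_is_table <- function(path) {
  if (!file.exists(path)) stop_validation("IS table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  is_elements(df$element_id, df$name, df$family, df$replicon,
              as.integer(df$start), as.integer(df$end), df$strand,
              df$completeness, df$parent)
}

#' @rdname is_elements
#' @param elements An IS element data.frame.
#' @export
write_is_table <- function(elements, path) {
  out <- data.frame(element_id = elements$element_id, name = elements$name,
                    family = elements$family,
                    replicon = elements$replicon_id,
                    start = elements$start, end = elements$end,
                    strand = elements$strand,
                    completeness = elements$completeness,
                    parent = elements$parent_name, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' IS catalog of reference lengths
#'
#' @param name IS names.
#' @param family IS family per name.
#' @param reference_length_bp Full-length reference size per name.
#' @return data.frame catalog keyed by `name`.
#' @export
is_catalog <- function(name, family, reference_length_bp) {
  stopifnot(all(reference_length_bp > 0))
  data.frame(name = as.character(name), family = as.character(family),
             reference_length_bp = as.integer(reference_length_bp),
             stringsAsFactors = FALSE)
}

#' Classify IS copies as complete or partial
#'
#' A copy is complete when its length reaches `min_fraction` of the
#' catalog reference length for its IS (boundary inclusive). Copies whose
#' completeness is already set (`complete`/`partial`, e.g. curated labels
#' ingested with the table) are kept as-is; only `unset` copies are
#' classified.
#'
#' @param elements IS element data.frame.
#' @param catalog An [is_catalog()].
#' @param min_fraction Completeness threshold (default 0.9).
#' @return `elements` with `completeness` filled in.
#' @export
classify_completeness <- function(elements, catalog, min_fraction = 0.9) {
  unk <- setdiff(unique(elements$name), catalog$name)
  if (length(unk)) {
    stop_validation("IS name(s) missing from catalog: ",
                    paste(unk, collapse = ", "))
  }
  ref <- stats::setNames(catalog$reference_length_bp, catalog$name)
  unset <- elements$completeness == "unset"
  len <- elements$end - elements$start + 1L
  elements$completeness[unset] <-
    ifelse(len[unset] >= min_fraction * ref[elements$name[unset]],
           "complete", "partial")
  elements
}

#' IS census of a genome
#'
#' Per-family complete/partial copy counts, totals, and the fraction of
#' each replicon covered by the union of IS intervals (overlapping copies
#' are not double-counted; the denominator is the single replicon's
#' length).
#'
#' @param annotation A `genome_annotation` (provides replicon lengths).
#' @param elements IS element data.frame with completeness set.
#' @return Object of class `is_census`: list with `by_family` (family,
#'   n_complete, n_partial), `n_complete`, `n_partial`, `n_families`, and
#'   `covered_fraction` (named per replicon).
#' @export
is_census <- function(annotation, elements) {
  if (nrow(elements) &&
      any(!elements$completeness %in% c("complete", "partial"))) {
    stop_validation("census needs completeness classified for all ",
                    "elements; run classify_completeness()")
  }
  fams <- sort(unique(elements$family))
  by_family <- data.frame(
    family = fams,
    n_complete = vapply(fams, function(f)
      sum(elements$family == f & elements$completeness == "complete"),
      integer(1)),
    n_partial = vapply(fams, function(f)
      sum(elements$family == f & elements$completeness == "partial"),
      integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  covered <- vapply(names(annotation$replicons), function(rid) {
    sel <- elements$replicon_id == rid
    interval_union_width(elements$start[sel], elements$end[sel]) /
      annotation$replicons[[rid]]$length_bp
  }, numeric(1))
  structure(list(
    by_family = by_family,
    n_complete = sum(elements$completeness == "complete"),
    n_partial = sum(elements$completeness == "partial"),
    n_families = length(fams),
    covered_fraction = covered), class = "is_census")
}

#' @export
print.is_census <- function(x, ...) {
  cat(sprintf("<is_census> %d complete + %d partial copies, %d families\n",
              x$n_complete, x$n_partial, x$n_families))
  for (r in names(x$covered_fraction)) {
    cat(sprintf("  %s: %.2f%% covered\n", r, 100 * x$covered_fraction[r]))
  }
  invisible(x)
}

#' Scan a replicon for IS-dense regions
#'
#' Slides a window along the replicon and reports maximal regions where
#' windows contain at least `min_copies` IS starts; overlapping qualifying
#' windows are merged and copy counts recomputed on the merged spans.
#'
#' @param elements IS element data.frame (one replicon's worth is used).
#' @param rep A [replicon()].
#' @param window_bp,step_bp Window geometry (defaults 200 kb / 10 kb).
#' @param min_copies Density threshold (default 10).
#' @return data.frame `(start, end, n_complete, n_partial)` of disjoint
#'   dense regions.
#' @export
is_cluster_scan <- function(elements, rep, window_bp = 200000,
                            step_bp = 10000, min_copies = 10) {
  if (window_bp < step_bp) stop_validation("window_bp must be >= step_bp")
  el <- elements[elements$replicon_id == rep$id, , drop = FALSE]
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_complete = integer(0), n_partial = integer(0))
  if (nrow(el) < min_copies) return(empty)
  starts <- seq.int(1L, max(1L, rep$length_bp - 1L), by = step_bp)
  ends <- pmin(starts + window_bp - 1L, rep$length_bp)
  n_in <- vapply(seq_along(starts), function(i)
    sum(el$start >= starts[i] & el$start <= ends[i]), integer(1))
  ok <- n_in >= min_copies
  if (!any(ok)) return(empty)
  merged <- IRanges::reduce(IRanges::IRanges(starts[ok], ends[ok]))
  data.frame(
    start = BiocGenerics::start(merged), end = BiocGenerics::end(merged),
    n_complete = vapply(seq_along(merged), function(i)
      sum(el$start >= BiocGenerics::start(merged)[i] &
            el$start <= BiocGenerics::end(merged)[i] &
            el$completeness == "complete"), integer(1)),
    n_partial = vapply(seq_along(merged), function(i)
      sum(el$start >= BiocGenerics::start(merged)[i] &
            el$start <= BiocGenerics::end(merged)[i] &
            el$completeness == "partial"), integer(1)))
}

#' Detect nested ("russian doll") IS insertions
#'
#' Reports a complete element as nested inside an interrupted copy when it
#' lies strictly between two fragments sharing a `parent_name` and the
#' fragments' facing ends are within `adjacency_bp` of the inner element's
#' ends — the signature left when a later insertion splits an earlier
#' copy.
#'
#' @param elements IS element data.frame with completeness set.
#' @param adjacency_bp Maximum distance between a fragment's facing end
#'   and the inner element's end (default 10).
#' @return data.frame `(inner_element, outer_parent_name)`.
#' @export
nested_is_detect <- function(elements, adjacency_bp = 10) {
  out <- data.frame(inner_element = character(0),
                    outer_parent_name = character(0),
                    stringsAsFactors = FALSE)
  parents <- unique(elements$parent_name[nzchar(elements$parent_name)])
  complete <- elements[elements$completeness == "complete", , drop = FALSE]
  for (p in parents) {
    fr <- elements[elements$parent_name == p, , drop = FALSE]
    if (nrow(fr) < 2L) next
    fr <- fr[order(fr$start), , drop = FALSE]
    for (k in seq_len(nrow(fr) - 1L)) {
      lo <- fr$end[k]; hi <- fr$start[k + 1L]
      cand <- complete$replicon_id == fr$replicon_id[k] &
        complete$start > lo & complete$end < hi &
        (complete$start - (lo + 1L)) <= adjacency_bp &
        ((hi - 1L) - complete$end) <= adjacency_bp
      if (any(cand)) {
        out <- rbind(out, data.frame(
          inner_element = complete$element_id[cand],
          outer_parent_name = p, stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}
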