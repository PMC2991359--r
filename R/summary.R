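# Genome-level summary statistics.

#' Summarise a genome
#'
#' Computes the standard genome-table fields: per-replicon and total sizes,
#' G+C mol% (over all replicons, Ns excluded from numerator and
#' denominator), gene counts by type, pseudogene count, genes with/without
#' a function prediction, average gene length and coding density. Coding
#' density uses the union of gene intervals per replicon, so overlapping
#' genes are not double-counted.
#'
#' @param annotation A `genome_annotation`.
#' @param has_function Optional logical vector parallel to the feature
#'   table flagging protein-coding genes with a predicted function; by
#'   default a CDS "has function" when its product is non-empty and is not
#'   a hypothetical/unknown label.
#' @return An object of class `genome_summary`: a list with fields
#'   `replicon_sizes_bp`, `total_size_bp`, `gc_molpct`, `n_genes`, `n_cds`,
#'   `n_rrna`, `n_trna`, `n_pseudo`, `n_with_function`,
#'   `n_without_function`, `average_gene_length_bp`, `coding_density_pct`.
#' @examples
#' ann <- genome_annotation("toy", replicon("chr", strrep("ACGT", 250)),
#'   gene_features(c("g1", "g2"), "chr", c(1, 51), c(100, 200)))
#' genome_summary(ann)$coding_density_pct  # 20.0: union of 1-100, 51-200
#' @export
genome_summary <- function(annotation, has_function = NULL) {
  f <- annotation$features
  sizes <- vapply(annotation$replicons, function(r) r$length_bp, numeric(1))
  bc <- Reduce(`+`, lapply(annotation$replicons,
                           function(r) base_counts(r$sequence)))
  acgt <- sum(bc[c("A", "C", "G", "T")])
  gc <- if (acgt == 0) NA_real_
        else round_half_up(100 * (bc[["G"]] + bc[["C"]]) / acgt, 1)

  is_cds <- f$ftype == "CDS"
  if (is.null(has_function)) {
    has_function <- is_cds & nzchar(f$product) &
      !grepl("hypothetical|unknown|uncharacteri[sz]ed", f$product,
             ignore.case = TRUE)
  } else {
    stopifnot(length(has_function) == nrow(f))
    has_function <- has_function & is_cds
  }

  widths <- f$end - f$start + 1L
  cov <- 0L
  for (rid in names(annotation$replicons)) {
    sel <- f$replicon_id == rid
    cov <- cov + interval_union_width(f$start[sel], f$end[sel])
  }
  structure(list(
    genome_id = annotation$genome_id,
    replicon_sizes_bp = sizes,
    total_size_bp = sum(sizes),
    gc_molpct = gc,
    n_genes = nrow(f),
    n_cds = sum(is_cds),
    n_rrna = sum(f$ftype == "rRNA"),
    n_trna = sum(f$ftype == "tRNA"),
    n_pseudo = sum(f$is_pseudo),
    n_with_function = sum(has_function),
    n_without_function = sum(is_cds) - sum(has_function),
    average_gene_length_bp = if (nrow(f)) mean(widths) else NA_real_,
    coding_density_pct = round_half_up(100 * cov / sum(sizes), 1)
  ), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("Genome %s\n", x$genome_id))
  cat(sprintf("  total size      %s bp (%d replicons)\n",
              format(x$total_size_bp, big.mark = ","),
              length(x$replicon_sizes_bp)))
  cat(sprintf("  G+C             %.1f mol%%\n", x$gc_molpct))
  cat(sprintf("  genes           %d (CDS %d, rRNA %d, tRNA %d, pseudo %d)\n",
              x$n_genes, x$n_cds, x$n_rrna, x$n_trna, x$n_pseudo))
  cat(sprintf("  with function   %d / %d CDS\n", x$n_with_function, x$n_cds))
  cat(sprintf("  coding density  %.1f%%\n", x$coding_density_pct))
  invisible(x)
}

#' G+C mol% of the region spanned by two genes
#'
#' Computes the G+C content of the span from the smaller start to the
#' larger end of two loci on the same replicon — the usual check for
#' horizontally acquired islands whose base composition is offset from the
#' genome background.
#'
#' @param annotation A `genome_annotation`.
#' @param from_locus,to_locus Locus tags delimiting the region.
#' @return G+C mol% (0-100) of the spanned sequence, Ns ignored.
#' @export
region_gc <- function(annotation, from_locus, to_locus) {
  f <- annotation$features
  i <- match(from_locus, f$locus_tag)
  j <- match(to_locus, f$locus_tag)
  if (is.na(i) || is.na(j)) {
    stop_validation("locus tag not found: ",
                    paste(c(from_locus, to_locus)[c(is.na(i), is.na(j))],
                          collapse = ", "))
  }
  if (f$replicon_id[i] != f$replicon_id[j]) {
    stop_validation("loci ", from_locus, " and ", to_locus,
                    " are on different replicons")
  }
  rep <- annotation$replicons[[f$replicon_id[i]]]
  span <- substr(rep$sequence, min(f$start[i], f$start[j]),
                 max(f$end[i], f$end[j]))
  100 * gc_fraction(span)
}

#' Codon usage over all intact protein-coding genes
#'
#' Counts the 64 codons over every non-pseudo CDS, read on the coding
#' strand. CDSs whose length is not divisible by 3 are skipped with a
#' warning.
#'
#' @param annotation A `genome_annotation`.
#' @return A named integer vector of length 64 (codon -> count).
#' @export
codon_usage <- function(annotation) {
  codons <- as.character(Biostrings::DNA_BASES)
  all64 <- as.vector(outer(outer(codons, codons, paste0), codons, paste0))
  all64 <- sort(all64)
  counts <- stats::setNames(integer(64), all64)
  f <- annotation$features
  idx <- which(f$ftype == "CDS" & !f$is_pseudo)
  for (i in idx) {
    rep <- annotation$replicons[[f$replicon_id[i]]]
    nt <- substr(rep$sequence, f$start[i], f$end[i])
    if (f$strand[i] == "-") nt <- revcomp(nt)
    if (nchar(nt) %% 3 != 0) {
      warning(sprintf("CDS %s length not divisible by 3; skipped in codon usage",
                      f$locus_tag[i]), call. = FALSE)
      next
    }
    cod <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
    cod <- cod[cod %in% all64]  # codons containing N are not counted
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}
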