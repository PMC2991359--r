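# Reciprocal-best-hit orthology, pan-genome partitioning, COG profiling
# and domain-family count queries.

#' Reciprocal best hits between two genomes
#'
#' The operational ortholog definition: genes a (genome A) and b (genome B)
#' are orthologs iff a's best hit is b and b's best hit is a, both maps
#' having been built under the same thresholds. The result is a partial
#' matching: injective in both directions.
#'
#' @param best_ab Best-hit map with A genes as queries.
#' @param best_ba Best-hit map with B genes as queries.
#' @param genome_a,genome_b Optional genome ids recorded on the result.
#' @return An object of class `ortholog_map`: a data.frame `(gene_a,
#'   gene_b)` sorted by `gene_a`, with `genome_a`/`genome_b` attributes.
#' @export
reciprocal_best_hits <- function(best_ab, best_ba,
                                 genome_a = "A", genome_b = "B") {
  ab <- stats::setNames(best_ab$subject_id, best_ab$query_id)
  ba <- stats::setNames(best_ba$subject_id, best_ba$query_id)
  a <- names(ab)
  b <- unname(ab)
  recip <- !is.na(ba[b]) & ba[b] == a
  pairs <- data.frame(gene_a = a[recip], gene_b = b[recip],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, class = c("ortholog_map", "data.frame"),
            genome_a = genome_a, genome_b = genome_b)
}

# lookup helper: ortholog partner(s) of `genes` of genome `from` in a map
ortho_partner <- function(map, genes, from = c("a", "b")) {
  from <- match.arg(from)
  if (from == "a") stats::setNames(map$gene_b, map$gene_a)[genes]
  else stats::setNames(map$gene_a, map$gene_b)[genes]
}

#' Pan-genome partition of a focal genome
#'
#' Assigns every non-transposase gene of the focal genome a presence
#' pattern over the other genomes (present in genome X iff the gene occurs
#' in the focal-X ortholog map) and derives the Venn-cell label: `core`
#' (present in all others), `specific` (present in none), or the sorted
#' `+`-joined subset of genomes sharing it. Membership is per-pair — no
#' transitivity across genomes is required — which reproduces a Venn
#' diagram directly. `mode = "clique"` additionally requires, for every
#' pair of genomes in the pattern, that the two partner genes are
#' themselves orthologs in that pair's map (supply `cross_maps`).
#'
#' @param focal A `genome_annotation`.
#' @param maps Named list of `ortholog_map`s, one per other genome, with
#'   focal genes on the `gene_a` side.
#' @param mode `"pattern"` (default) or `"clique"`.
#' @param cross_maps For clique mode: named list of maps between non-focal
#'   genome pairs, names like `"X|Y"`, X genes on the `gene_a` side.
#' @param include_pseudo Include pseudogene CDSs (default FALSE).
#' @return Object of class `pan_partition`: list with `table` (locus_tag,
#'   one logical column per genome, `cell`), `cells` (named cell counts)
#'   and `focal_id`.
#' @export
pan_partition <- function(focal, maps, mode = c("pattern", "clique"),
                          cross_maps = NULL, include_pseudo = FALSE) {
  mode <- match.arg(mode)
  if (is.null(names(maps)) || any(!nzchar(names(maps)))) {
    stop_validation("'maps' must be a named list (one ortholog map per ",
                    "non-focal genome)")
  }
  f <- focal$features
  genes <- f$locus_tag[f$ftype == "CDS" & !f$is_transposase &
                         (include_pseudo | !f$is_pseudo)]
  others <- names(maps)
  pres <- matrix(FALSE, nrow = length(genes), ncol = length(others),
                 dimnames = list(genes, others))
  for (g in others) {
    pres[, g] <- genes %in% maps[[g]]$gene_a
  }
  if (mode == "clique" && length(others) >= 2L) {
    if (is.null(cross_maps)) {
      stop_validation("clique mode needs 'cross_maps' between non-focal ",
                      "genome pairs")
    }
    pair_map <- function(x, y) {
      if (!is.null(cross_maps[[paste(x, y, sep = "|")]])) {
        list(map = cross_maps[[paste(x, y, sep = "|")]], from = "a")
      } else if (!is.null(cross_maps[[paste(y, x, sep = "|")]])) {
        list(map = cross_maps[[paste(y, x, sep = "|")]], from = "b")
      } else {
        stop_validation("clique mode: no cross map for genomes ", x,
                        " and ", y)
      }
    }
    for (i in seq_along(genes)) {
      on <- others[pres[i, ]]
      if (length(on) < 2L) next
      partners <- vapply(on, function(g)
        unname(ortho_partner(maps[[g]], genes[i], "a")), character(1))
      ok <- TRUE
      for (x in seq_len(length(on) - 1L)) {
        for (y in seq.int(x + 1L, length(on))) {
          pm <- pair_map(on[x], on[y])
          hit <- ortho_partner(pm$map, partners[x], pm$from)
          if (is.na(hit) || hit != partners[y]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) pres[i, ] <- FALSE  # not a clique: gene counts as specific
    }
  }
  cell <- apply(pres, 1L, function(p) {
    if (all(p)) "core"
    else if (!any(p)) "specific"
    else paste(sort(others[p]), collapse = "+")
  })
  tab <- data.frame(locus_tag = genes, pres, cell = unname(cell),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(tab) <- NULL
  structure(list(focal_id = focal$genome_id, table = tab,
                 cells = table(tab$cell)),
            class = "pan_partition")
}

#' @export
print.pan_partition <- function(x, ...) {
  cat(sprintf("<pan_partition> focal %s, %d genes\n", x$focal_id,
              nrow(x$table)))
  print(x$cells)
  invisible(x)
}

#' COG category profile of a gene set
#'
#' Counts genes per COG category with fractional weighting: a gene carrying
#' k categories contributes 1/k to each, so weights sum to one per
#' annotated gene and proportions over annotated genes sum to one. Genes
#' without any category are reported separately in the `n_unannotated`
#' attribute.
#'
#' @param features Feature data frame rows for the gene set.
#' @param exclude_transposases Drop transposase-flagged genes
#'   (default TRUE, the usual convention for functional profiles).
#' @return data.frame `(category, count, proportion)` sorted by category,
#'   with attribute `n_unannotated`.
#' @export
cog_profile <- function(features, exclude_transposases = TRUE) {
  f <- features
  if (exclude_transposases) f <- f[!f$is_transposase, , drop = FALSE]
  cats <- split_multi(f$cog)
  k <- lengths(cats)
  ann <- k > 0L
  w <- unlist(lapply(which(ann), function(i) {
    stats::setNames(rep(1 / k[i], k[i]), cats[[i]])
  }))
  if (is.null(w)) {
    out <- data.frame(category = character(0), count = numeric(0),
                      proportion = numeric(0), stringsAsFactors = FALSE)
  } else {
    agg <- tapply(w, names(w), sum)
    out <- data.frame(category = names(agg), count = as.numeric(agg),
                      proportion = as.numeric(agg) / sum(ann),
                      stringsAsFactors = FALSE)
    out <- out[order(out$category), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_unannotated") <- sum(!ann)
  out
}

#' Compare two COG profiles
#'
#' @param profile_a,profile_b Outputs of [cog_profile()].
#' @return data.frame `(category, prop_a, prop_b, difference)` over the
#'   union of categories (absent category = proportion 0); difference is
#'   `prop_a - prop_b`.
#' @export
compare_profiles <- function(profile_a, profile_b) {
  cats <- sort(union(profile_a$category, profile_b$category))
  pa <- stats::setNames(profile_a$proportion, profile_a$category)[cats]
  pb <- stats::setNames(profile_b$proportion, profile_b$category)[cats]
  pa[is.na(pa)] <- 0
  pb[is.na(pb)] <- 0
  data.frame(category = cats, prop_a = unname(pa), prop_b = unname(pb),
             difference = unname(pa - pb), stringsAsFactors = FALSE)
}

#' Count genes carrying a domain family
#'
#' @param annotation A `genome_annotation`.
#' @param family_id Family identifier (e.g. `"PF00356"` for LacI-family
#'   regulators).
#' @param include_pseudo Count pseudogenes too (default FALSE).
#' @return Integer count of genes whose `families` set contains
#'   `family_id`.
#' @export
family_count <- function(annotation, family_id, include_pseudo = FALSE) {
  f <- annotation$features
  keep <- include_pseudo | !f$is_pseudo
  sum(vapply(split_multi(f$families[keep]),
             function(v) family_id %in% v, logical(1)))
}

#' Serialize / read an ortholog map as 2-column TSV
#'
#' @param map An `ortholog_map`.
#' @param path File path.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(
    data.frame(gene_a = map$gene_a, gene_b = map$gene_b),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_map
#' @param genome_a,genome_b Genome ids recorded on the result.
#' @export
read_ortholog_map <- function(path, genome_a = "A", genome_b = "B") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  structure(data.frame(gene_a = df$gene_a, gene_b = df$gene_b,
                       stringsAsFactors = FALSE),
            class = c("ortholog_map", "data.frame"),
            genome_a = genome_a, genome_b = genome_b)
}
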