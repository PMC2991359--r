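# Circular-atlas track export (karyotype + per-track data files in the
# common 0-based half-open track dialect) and tabular reports.

#' Describe one atlas track
#'
#' @param name Track (and file) name.
#' @param source One of `cds_strand`, `functional_category`, `is_elements`,
#'   `rna_genes`, `pseudogenes`, `ortholog_presence`, `custom_gene_set`,
#'   `gc_content`, `gc_skew`.
#' @param genome For `ortholog_presence`: which ortholog map (name in
#'   `analyses$ortholog_maps`) to draw.
#' @param genes For `custom_gene_set`: locus tags to draw.
#' @param color Fill colour hint written in the options column of tile
#'   tracks.
#' @return A `track_spec` list.
#' @export
track_spec <- function(name, source, genome = NULL, genes = NULL,
                       color = NULL) {
  sources <- c("cds_strand", "functional_category", "is_elements",
               "rna_genes", "pseudogenes", "ortholog_presence",
               "custom_gene_set", "gc_content", "gc_skew")
  if (!source %in% sources) {
    stop_validation("unknown track source '", source, "'")
  }
  structure(list(name = name, source = source, genome = genome,
                 genes = genes, color = color), class = "track_spec")
}

# 1-based inclusive -> 0-based half-open happens in exactly this writer
tile_line <- function(replicon, start, end, options = NULL) {
  base <- sprintf("%s %d %d", replicon, start - 1L, end)
  if (is.null(options)) base else paste(base, options)
}

#' Export circular-atlas track files
#'
#' Writes one karyotype file (`karyotype.txt`: replicon name, 0, length)
#' and one data file per track into `out_dir`. Gene-derived tracks are
#' tile lines `chr start end [options]`; `gc_content` and `gc_skew` are
#' value lines `chr start end value` taken from precomputed window tracks
#' in `analyses$gc_content` / `analyses$gc_skew` (lists keyed by replicon
#' id). This writer is the only place coordinates leave the internal
#' 1-based inclusive convention (output is 0-based half-open).
#'
#' @param annotation A `genome_annotation`.
#' @param specs List of [track_spec()]s.
#' @param out_dir Output directory (created if needed).
#' @param analyses Named list of precomputed inputs: `gc_content`,
#'   `gc_skew` (lists of `window_track` keyed by replicon),
#'   `is_elements` (IS table), `ortholog_maps` (named list of
#'   `ortholog_map`, focal genes in `gene_a`).
#' @return Invisibly, the written file paths.
#' @export
export_tracks <- function(annotation, specs = list(), out_dir,
                          analyses = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  kar <- file.path(out_dir, "karyotype.txt")
  writeLines(vapply(annotation$replicons, function(r)
    sprintf("chr - %s %s 0 %d grey", r$id, r$id, r$length_bp),
    character(1)), kar)
  paths <- c(paths, kar)
  f <- annotation$features
  has_fun <- nzchar(f$product) &
    !grepl("hypothetical|unknown|uncharacteri[sz]ed", f$product,
           ignore.case = TRUE)
  for (sp in specs) {
    path <- file.path(out_dir, paste0(sp$name, ".txt"))
    lines <- switch(sp$source,
      cds_strand = {
        sel <- f$ftype == "CDS" & !f$is_transposase
        tile_line(f$replicon_id[sel], f$start[sel], f$end[sel],
                  sprintf("fill_color=%s",
                          ifelse(f$strand[sel] == "+", "red", "blue")))
      },
      functional_category = {
        sel <- f$ftype == "CDS"
        tile_line(f$replicon_id[sel], f$start[sel], f$end[sel],
                  sprintf("fill_color=%s",
                          ifelse(has_fun[sel], "blue", "purple")))
      },
      rna_genes = {
        sel <- f$ftype %in% c("rRNA", "tRNA")
        tile_line(f$replicon_id[sel], f$start[sel], f$end[sel],
                  sprintf("fill_color=%s",
                          ifelse(f$ftype[sel] == "rRNA", "grey", "red")))
      },
      pseudogenes = {
        sel <- f$is_pseudo & !f$is_transposase
        tile_line(f$replicon_id[sel], f$start[sel], f$end[sel])
      },
      is_elements = {
        el <- analyses$is_elements
        if (is.null(el)) {
          stop_validation("track '", sp$name,
                          "': analyses$is_elements missing")
        }
        tile_line(el$replicon_id, el$start, el$end, "fill_color=green")
      },
      ortholog_presence = {
        maps <- analyses$ortholog_maps
        if (is.null(maps) || is.null(maps[[sp$genome]])) {
          stop_validation("track '", sp$name, "': no ortholog map for ",
                          "genome '", sp$genome, "'")
        }
        sel <- f$locus_tag %in% maps[[sp$genome]]$gene_a
        tile_line(f$replicon_id[sel], f$start[sel], f$end[sel],
                  "fill_color=blue")
      },
      custom_gene_set = {
        sel <- f$locus_tag %in% sp$genes
        tile_line(f$replicon_id[sel], f$start[sel], f$end[sel],
                  if (is.null(sp$color)) NULL
                  else sprintf("fill_color=%s", sp$color))
      },
      gc_content = value_track_lines(annotation, analyses$gc_content,
                                     sp$name),
      gc_skew = value_track_lines(annotation, analyses$gc_skew, sp$name)
    )
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

value_track_lines <- function(annotation, tracks, name) {
  if (is.null(tracks)) {
    stop_validation("track '", name, "': window tracks not supplied")
  }
  unlist(lapply(tracks, function(tr) {
    n <- annotation$replicons[[tr$replicon_id]]$length_bp
    sprintf("%s %d %d %s", tr$replicon_id, tr$records$start - 1L,
            pmin(tr$records$end, n),
            ifelse(is.na(tr$records$value), "NA",
                   format(tr$records$value, digits = 6)))
  }), use.names = FALSE)
}

#' Count genes matching functional categories across genomes
#'
#' Tabulates, for each genome, the genes whose product matches each
#' category pattern (regular expression, case-insensitive) — the classic
#' per-genome transporter/component comparison table, with a totals row.
#'
#' @param annotations Named list of `genome_annotation`s (column order).
#' @param categories Named character vector: category label -> regex
#'   matched against gene products.
#' @param include_pseudo Count pseudogenes (default FALSE).
#' @return Object of class `category_table`: integer matrix (categories x
#'   genomes) with a `Total` row, plus a `loci` attribute (list of
#'   matched locus tags per cell).
#' @export
category_table <- function(annotations, categories, include_pseudo = FALSE) {
  m <- matrix(0L, nrow = length(categories), ncol = length(annotations),
              dimnames = list(names(categories), names(annotations)))
  loci <- list()
  for (g in names(annotations)) {
    f <- annotations[[g]]$features
    f <- f[f$ftype == "CDS" & (include_pseudo | !f$is_pseudo), ,
           drop = FALSE]
    for (cat in names(categories)) {
      hit <- grepl(categories[[cat]], f$product, ignore.case = TRUE)
      m[cat, g] <- sum(hit)
      loci[[paste(cat, g, sep = "|")]] <- f$locus_tag[hit]
    }
  }
  out <- rbind(m, Total = colSums(m))
  structure(out, class = c("category_table", class(out)), loci = loci)
}

#' Structured genome report
#'
#' Assembles the pipeline's headline numbers into one structure: the
#' genome-table fields of [genome_summary()], derived percentages (printed
#' to one decimal, computed before rounding; `NA` when the denominator is
#' zero), optional pan-genome Venn cell counts, optional COG profile and
#' optional category table.
#'
#' @param annotation A `genome_annotation`.
#' @param partition Optional `pan_partition`.
#' @param profile Optional [cog_profile()] output.
#' @param categories Optional `category_table`.
#' @param has_function Passed to [genome_summary()].
#' @return Object of class `genome_report` (list); see
#'   [write_report()] for serialization.
#' @export
summary_report <- function(annotation, partition = NULL, profile = NULL,
                           categories = NULL, has_function = NULL) {
  s <- genome_summary(annotation, has_function = has_function)
  pct <- list(
    genes_with_function = pct1(s$n_with_function, s$n_cds),
    genes_without_function = pct1(s$n_without_function, s$n_cds),
    pseudogenes_of_total = pct1(s$n_pseudo, s$n_genes)
  )
  venn <- if (!is.null(partition)) {
    v <- as.integer(partition$cells)
    names(v) <- names(partition$cells)
    v
  }
  structure(list(summary = s, percentages = pct, venn_cells = venn,
                 cog_profile = profile, category_table = categories),
            class = "genome_report")
}

#' Write a report as JSON and Markdown
#'
#' @param report A `genome_report`.
#' @param json_path,md_path Output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, json_path = NULL, md_path = NULL) {
  paths <- character(0)
  s <- report$summary
  if (!is.null(json_path)) {
    obj <- list(
      genome_id = s$genome_id,
      replicon_sizes_bp = as.list(s$replicon_sizes_bp),
      total_size_bp = s$total_size_bp,
      gc_molpct = s$gc_molpct,
      n_genes = s$n_genes, n_cds = s$n_cds, n_rrna = s$n_rrna,
      n_trna = s$n_trna, n_pseudo = s$n_pseudo,
      n_with_function = s$n_with_function,
      n_without_function = s$n_without_function,
      average_gene_length_bp = s$average_gene_length_bp,
      coding_density_pct = s$coding_density_pct,
      percentages = report$percentages,
      venn_cells = if (!is.null(report$venn_cells))
        as.list(report$venn_cells)
    )
    if (!is.null(report$category_table)) {
      obj$category_table <- apply(report$category_table, 2, as.list)
    }
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    paths <- c(paths, json_path)
  }
  if (!is.null(md_path)) {
    fmt <- function(x) if (is.na(x)) "NA" else format(x, big.mark = ",")
    lines <- c(
      sprintf("# Genome report: %s", s$genome_id), "",
      "| Feature | Value |", "| --- | --- |",
      sprintf("| Total size (bp) | %s |", fmt(s$total_size_bp)),
      sprintf("| G+C (mol%%) | %s |", fmt(s$gc_molpct)),
      sprintf("| Genes | %s |", fmt(s$n_genes)),
      sprintf("| Protein-encoding | %s |", fmt(s$n_cds)),
      sprintf("| rRNA / tRNA | %s / %s |", fmt(s$n_rrna), fmt(s$n_trna)),
      sprintf("| Pseudogenes | %s |", fmt(s$n_pseudo)),
      sprintf("| With function (%%) | %s (%s%%) |",
              fmt(s$n_with_function),
              fmt(report$percentages$genes_with_function)),
      sprintf("| Coding density (%%) | %s |", fmt(s$coding_density_pct)))
    if (!is.null(report$venn_cells)) {
      lines <- c(lines, "", "## Pan-genome cells", "",
                 sprintf("- %s: %d", names(report$venn_cells),
                         report$venn_cells))
    }
    writeLines(lines, md_path)
    paths <- c(paths, md_path)
  }
  invisible(paths)
}

#' Check replicon length and G+C against expected values
#'
#' Given locally available sequence files (e.g. downloaded database
#' records), verifies that each replicon's length and G+C mol% match
#' expectations. Intended for spot-checking a pipeline installation
#' against published replicon statistics when the user has the sequences
#' on disk; nothing is downloaded.
#'
#' @param path FASTA or GenBank file.
#' @param expected data.frame with columns `replicon_id` (or `NA` to take
#'   the first), `length_bp`, `gc_molpct` (1 decimal; `NA` = skip).
#' @return data.frame with observed and expected values and a logical
#'   `ok` per row.
#' @export
verify_replicon_expectations <- function(path, expected) {
  ann <- read_genome(path, translate_missing = FALSE)
  rows <- lapply(seq_len(nrow(expected)), function(i) {
    rid <- expected$replicon_id[i]
    rep <- if (is.na(rid)) ann$replicons[[1]] else ann$replicons[[rid]]
    if (is.null(rep)) {
      stop_validation("replicon '", rid, "' not found in ", path)
    }
    gc_obs <- round_half_up(100 * gc_fraction(rep$sequence), 1)
    ok_len <- rep$length_bp == expected$length_bp[i]
    ok_gc <- is.na(expected$gc_molpct[i]) ||
      isTRUE(all.equal(gc_obs, expected$gc_molpct[i]))
    data.frame(replicon_id = rep$id,
               length_bp = rep$length_bp,
               expected_length_bp = expected$length_bp[i],
               gc_molpct = gc_obs,
               expected_gc_molpct = expected$gc_molpct[i],
               ok = ok_len && ok_gc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
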