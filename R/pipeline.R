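# End-to-end orchestration: a config-driven runner behind the thin CLI at
# inst/cli/cladecompare.R. Each subcommand writes its stage outputs as
# TSV/JSON into the configured output directory; reruns with the same
# config and seed are byte-identical.

#' Default pipeline configuration
#'
#' @return A named list with all threshold defaults: `evalue_max` 1e-3,
#'   `min_overlap` 0.8, `window_bp` 10000, synteny scores (+2/+1/-1, min
#'   3 matches, min score 4), IS completeness fraction 0.9, cluster-scan
#'   geometry (200 kb window, 10 kb step, 10 copies), seed 1.
#' @export
pipeline_defaults <- function() {
  list(
    evalue_max = 1e-3,
    min_overlap = 0.8,
    window_bp = 10000,
    synteny = list(match = 2, mismatch = 1, gap = -1,
                   min_block_matches = 3, min_score = 4,
                   strand_aware = TRUE),
    is_min_fraction = 0.9,
    cluster = list(window_bp = 200000, step_bp = 10000, min_copies = 10),
    motif_max_upstream_bp = 200,
    motif_max_mismatches = 0,
    seed = 1,
    out_dir = "cladecompare_out"
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_validation("config file not found: ", config)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_usage("config must be a list or a YAML path")
  cfg <- utils::modifyList(pipeline_defaults(), config)
  cfg
}

load_config_genomes <- function(cfg) {
  if (is.null(cfg$genomes) || !length(cfg$genomes)) {
    stop_validation("config lists no genomes")
  }
  anns <- list()
  for (g in cfg$genomes) {
    if (is.null(g$id) || is.null(g$fasta)) {
      stop_validation("each genome entry needs 'id' and 'fasta'")
    }
    if (!file.exists(g$fasta)) {
      stop_validation("sequence file not found: ", g$fasta)
    }
    if (!is.null(g$features) && !file.exists(g$features)) {
      stop_validation("feature file not found: ", g$features)
    }
    anns[[g$id]] <- read_genome(g$fasta, feature_table = g$features,
                                genome_id = g$id)
  }
  anns
}

# all-vs-all best-hit maps between two annotations' proteomes
proteome <- function(ann, include_pseudo = FALSE) {
  f <- ann$features
  keep <- f$ftype == "CDS" & nzchar(f$protein) &
    (include_pseudo | !f$is_pseudo)
  stats::setNames(f$protein[keep], f$locus_tag[keep])
}

transposase_ids <- function(ann) {
  ann$features$locus_tag[ann$features$is_transposase]
}

#' Orthologs between two genomes from sequence alone
#'
#' Convenience wrapper tying the similarity and orthology modules
#' together: aligns the two proteomes both ways, filters best hits under
#' the configured thresholds (transposases excluded) and returns the
#' reciprocal-best-hit map, with the two best-hit maps attached as
#' attributes (`best_ab`, `best_ba`) for downstream homology relations.
#'
#' @param ann_a,ann_b `genome_annotation`s.
#' @param evalue_max,min_overlap Filter thresholds.
#' @return An `ortholog_map`.
#' @export
orthologs_between <- function(ann_a, ann_b, evalue_max = 1e-3,
                              min_overlap = 0.8) {
  pa <- proteome(ann_a); pb <- proteome(ann_b)
  excl <- c(transposase_ids(ann_a), transposase_ids(ann_b))
  hits_ab <- align_proteins(pa, pb)
  hits_ba <- align_proteins(pb, pa)
  best_ab <- filter_best_hits(hits_ab, evalue_max, min_overlap,
                              exclude = excl)
  best_ba <- filter_best_hits(hits_ba, evalue_max, min_overlap,
                              exclude = excl)
  map <- reciprocal_best_hits(best_ab, best_ba,
                              genome_a = ann_a$genome_id,
                              genome_b = ann_b$genome_id)
  attr(map, "best_ab") <- best_ab
  attr(map, "best_ba") <- best_ba
  map
}

#' Run a pipeline stage
#'
#' Subcommands: `simulate` (write a synthetic clade into the output
#' directory), `summarize`, `orthologs`, `pangenome`, `synteny`,
#' `mobilome`, `scan-motif`, `atlas`, `score`. Configuration is a named
#' list or a YAML file; unknown subcommands raise a
#' `cladecompare_usage_error`, bad inputs a
#' `cladecompare_validation_error` (the CLI maps these to exit codes 2
#' and 1).
#'
#' @param subcommand Stage name.
#' @param config Named list or YAML path; see [pipeline_defaults()] for
#'   thresholds and the vignette for the genome-entry layout.
#' @return Invisibly, a named list of written paths (and stage results).
#' @export
run_pipeline <- function(subcommand, config = list()) {
  known <- c("simulate", "summarize", "orthologs", "pangenome", "synteny",
             "mobilome", "scan-motif", "atlas", "score")
  if (length(subcommand) != 1L || !subcommand %in% known) {
    stop_usage("unknown subcommand '", paste(subcommand, collapse = " "),
               "'; expected one of: ", paste(known, collapse = ", "))
  }
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("[cladecompare] %s: seed %s, e-value < %g, overlap > %g",
                  subcommand, cfg$seed, cfg$evalue_max, cfg$min_overlap))
  switch(subcommand,
    simulate = {
      gen_args <- cfg$clade
      if (is.null(gen_args)) gen_args <- list()
      gen_args$seed <- cfg$seed
      clade <- generate_clade(do.call(clade_config, gen_args))
      write_clade(clade, cfg$out_dir)
      invisible(list(dir = cfg$out_dir, clade = clade))
    },
    summarize = {
      anns <- load_config_genomes(cfg)
      paths <- character(0)
      for (id in names(anns)) {
        rep <- summary_report(anns[[id]])
        jp <- file.path(cfg$out_dir, paste0(id, "_summary.json"))
        mp <- file.path(cfg$out_dir, paste0(id, "_summary.md"))
        write_report(rep, jp, mp)
        for (r in anns[[id]]$replicons) {
          write_window_track(windowed_gc(r, cfg$window_bp),
                             file.path(cfg$out_dir,
                                       paste0(id, "_", r$id, "_gc.tsv")))
          write_window_track(gc_skew(r, cfg$window_bp),
                             file.path(cfg$out_dir,
                                       paste0(id, "_", r$id, "_skew.tsv")))
        }
        paths <- c(paths, jp, mp)
      }
      invisible(list(paths = paths))
    },
    orthologs = {
      anns <- load_config_genomes(cfg)
      ids <- names(anns)
      maps <- list()
      for (i in seq_len(length(ids) - 1L)) {
        for (j in seq.int(i + 1L, length(ids))) {
          key <- paste(ids[i], ids[j], sep = "|")
          maps[[key]] <- orthologs_between(anns[[ids[i]]], anns[[ids[j]]],
                                           cfg$evalue_max, cfg$min_overlap)
          write_ortholog_map(maps[[key]],
                             file.path(cfg$out_dir,
                                       paste0("orthologs_", ids[i], "_",
                                              ids[j], ".tsv")))
        }
      }
      invisible(list(maps = maps))
    },
    pangenome = {
      anns <- load_config_genomes(cfg)
      ids <- names(anns)
      focal <- if (!is.null(cfg$focal)) cfg$focal else ids[1]
      maps <- list()
      for (other in setdiff(ids, focal)) {
        maps[[other]] <- orthologs_between(anns[[focal]], anns[[other]],
                                           cfg$evalue_max, cfg$min_overlap)
      }
      part <- pan_partition(anns[[focal]], maps)
      tab_path <- file.path(cfg$out_dir, "pangenome_partition.tsv")
      utils::write.table(part$table, tab_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(as.list(part$cells),
                           file.path(cfg$out_dir, "pangenome_cells.json"),
                           auto_unbox = TRUE, digits = NA)
      invisible(list(partition = part, paths = tab_path))
    },
    synteny = {
      anns <- load_config_genomes(cfg)
      ids <- names(anns)
      if (length(ids) < 2L) stop_validation("synteny needs two genomes")
      a <- anns[[ids[1]]]; b <- anns[[ids[2]]]
      map <- orthologs_between(a, b, cfg$evalue_max, cfg$min_overlap)
      rel <- gene_relations(map, attr(map, "best_ab"),
                            attr(map, "best_ba"))
      oa <- build_gene_order(a, names(a$replicons)[1])
      ob <- build_gene_order(b, names(b$replicons)[1])
      blocks <- align_gene_trains(
        oa, ob, rel, match = cfg$synteny$match,
        mismatch = cfg$synteny$mismatch, gap = cfg$synteny$gap,
        min_block_matches = cfg$synteny$min_block_matches,
        min_score = cfg$synteny$min_score,
        strand_aware = cfg$synteny$strand_aware)
      bp <- file.path(cfg$out_dir,
                      paste0("synteny_", ids[1], "_", ids[2], ".tsv"))
      write_synteny_blocks(blocks, bp)
      dots <- dotplot_export(map, a, b)
      dp <- file.path(cfg$out_dir,
                      paste0("dotplot_", ids[1], "_", ids[2], ".tsv"))
      utils::write.table(dots, dp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      invisible(list(blocks = blocks, paths = c(bp, dp)))
    },
    mobilome = {
      anns <- load_config_genomes(cfg)
      out <- list()
      for (g in cfg$genomes) {
        if (is.null(g$is_table)) next
        if (!file.exists(g$is_table)) {
          stop_validation("IS table not found: ", g$is_table)
        }
        el <- read_is_table(g$is_table)
        if (!is.null(cfg$is_catalog)) {
          catal <- utils::read.delim(cfg$is_catalog, sep = "\t",
                                     stringsAsFactors = FALSE)
          el <- classify_completeness(el, catal, cfg$is_min_fraction)
        }
        cen <- is_census(anns[[g$id]], el)
        jsonlite::write_json(list(
          n_complete = cen$n_complete, n_partial = cen$n_partial,
          n_families = cen$n_families,
          covered_fraction = as.list(cen$covered_fraction)),
          file.path(cfg$out_dir, paste0(g$id, "_is_census.json")),
          auto_unbox = TRUE, digits = NA)
        utils::write.table(cen$by_family,
                           file.path(cfg$out_dir,
                                     paste0(g$id, "_is_census.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out[[g$id]] <- cen
      }
      invisible(list(census = out))
    },
    `scan-motif` = {
      anns <- load_config_genomes(cfg)
      if (is.null(cfg$motif)) stop_usage("scan-motif needs config$motif")
      paths <- character(0)
      for (id in names(anns)) {
        hits <- upstream_motif_scan(anns[[id]], cfg$motif,
                                    cfg$motif_max_upstream_bp,
                                    cfg$motif_max_mismatches)
        p <- file.path(cfg$out_dir, paste0(id, "_motif_hits.tsv"))
        utils::write.table(hits, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, p)
      }
      invisible(list(paths = paths))
    },
    atlas = {
      anns <- load_config_genomes(cfg)
      ann <- anns[[1]]
      analyses <- list(
        gc_content = lapply(ann$replicons, windowed_gc, cfg$window_bp),
        gc_skew = lapply(ann$replicons, gc_skew, cfg$window_bp))
      specs <- list(
        track_spec("cds_plusminus", "cds_strand"),
        track_spec("rna_genes", "rna_genes"),
        track_spec("pseudogenes", "pseudogenes"),
        track_spec("gc_content", "gc_content"),
        track_spec("gc_skew", "gc_skew"))
      paths <- export_tracks(ann, specs,
                             file.path(cfg$out_dir, "atlas"), analyses)
      invisible(list(paths = paths))
    },
    score = {
      # compare stage outputs in out_dir with the generator's truth.json
      tr_path <- file.path(cfg$out_dir, "truth.json")
      if (!file.exists(tr_path)) {
        stop_validation("no truth.json in ", cfg$out_dir,
                        " (run 'simulate' first)")
      }
      truth <- jsonlite::read_json(tr_path, simplifyVector = TRUE)
      truth$ortholog_pairs <- lapply(truth$ortholog_pairs, as.data.frame)
      scores <- list()
      ofiles <- list.files(cfg$out_dir, "^orthologs_.*\\.tsv$",
                           full.names = TRUE)
      for (p in ofiles) {
        ids <- strsplit(sub("^orthologs_(.*)\\.tsv$", "\\1", basename(p)),
                        "_")[[1]]
        map <- read_ortholog_map(p, genome_a = ids[1], genome_b = ids[2])
        scores[[paste0("orthologs_", ids[1], "_", ids[2])]] <-
          score_recovery(map, truth)
      }
      pp <- file.path(cfg$out_dir, "pangenome_partition.tsv")
      if (file.exists(pp)) {
        tab <- utils::read.delim(pp, stringsAsFactors = FALSE)
        part <- structure(list(focal_id = "focal", table = tab,
                               cells = table(tab$cell)),
                          class = "pan_partition")
        scores$pangenome <- score_recovery(part, truth)
      }
      sp <- file.path(cfg$out_dir, "score.json")
      jsonlite::write_json(scores, sp, auto_unbox = TRUE, digits = NA)
      invisible(list(scores = scores, paths = sp))
    })
}
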