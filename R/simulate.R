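# Synthetic genome-clade generator with ground truth. Emulates the
# comparative structure the pipeline is built for: a core gene set shared
# across a star phylogeny of genomes, strain-specific genes, planted
# inversions, IS expansions (complete, truncated, and nested copies that
# fragment earlier copies), and a horizontally acquired island with offset
# G+C. Every emitted genome round-trips through the package's own readers.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

#' Configuration for a synthetic clade
#'
#' Defaults describe a small four-genome clade: 50 core families, 10
#' strain-specific genes per genome, one 5-gene family subset shared by
#' genomes 1-3, 150-residue proteins, a low per-site substitution
#' probability per branch, one planted inversion in genome 2, an IS
#' expansion in genome 1 (12 insertion events vs 3 elsewhere) and one
#' 10-kb island at +10 G+C points in genome 1.
#'
#' @param n_genomes Number of genomes (genome 1 is the focal genome).
#' @param n_core Core families present in all genomes.
#' @param n_specific Strain-specific genes per genome (recycled).
#' @param shared_subsets List of `list(genomes =, n_genes =)` family sets
#'   present only in the given genome indices.
#' @param protein_length_mean,protein_length_sd Ancestral protein length
#'   distribution (gamma, residues; minimum 30).
#' @param p_substitution Per-site amino-acid substitution probability on
#'   each branch of the star phylogeny.
#' @param n_inversions Planted inversions (contiguous core-gene runs).
#' @param inversion_genes Inversion length range in genes, `c(min, max)`.
#' @param inversion_genomes Genome indices receiving inversions (recycled;
#'   never the focal genome).
#' @param is_families Number of synthetic IS families.
#' @param is_copies IS insertion events per genome (recycled).
#' @param is_fragment_prob Probability an insertion is a truncated
#'   (partial) copy.
#' @param is_nest_prob Probability an insertion nests inside an earlier
#'   complete copy, splitting it into fragments.
#' @param n_islands Islands inserted into the focal genome.
#' @param island_length_bp Approximate island length.
#' @param island_gc_offset Island G+C offset in percentage points.
#' @param gc_target Genome G+C target in mol% (recycled per genome).
#' @param intergenic_mean_bp Mean intergenic spacer (geometric).
#' @param seed Random seed; the same seed reproduces the clade
#'   byte-for-byte.
#' @return A `clade_config` list.
#' @export
clade_config <- function(n_genomes = 4,
                         n_core = 50,
                         n_specific = 10,
                         shared_subsets = list(list(genomes = c(1, 2, 3),
                                                    n_genes = 5)),
                         protein_length_mean = 150,
                         protein_length_sd = 30,
                         p_substitution = 0.02,
                         n_inversions = 1,
                         inversion_genes = c(4, 8),
                         inversion_genomes = 2,
                         is_families = 3,
                         is_copies = c(12, 3, 3, 3),
                         is_fragment_prob = 0.2,
                         is_nest_prob = 0.2,
                         n_islands = 1,
                         island_length_bp = 10000,
                         island_gc_offset = 10,
                         gc_target = 60,
                         intergenic_mean_bp = 100,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genomes >= 1, cfg$n_core >= 0,
            cfg$p_substitution >= 0, cfg$p_substitution < 1,
            cfg$is_fragment_prob >= 0, cfg$is_nest_prob >= 0)
  if (any(unlist(lapply(cfg$shared_subsets, `[[`, "genomes")) >
          cfg$n_genomes)) {
    stop_validation("shared_subsets reference genomes beyond n_genomes")
  }
  cfg$n_specific <- rep_len(cfg$n_specific, cfg$n_genomes)
  cfg$is_copies <- rep_len(cfg$is_copies, cfg$n_genomes)
  cfg$gc_target <- rep_len(cfg$gc_target, cfg$n_genomes)
  structure(cfg, class = "clade_config")
}

# codon list per amino acid under the bacterial code (standard AA mapping)
codons_by_aa <- function() {
  gc <- Biostrings::getGeneticCode("11")
  split(names(gc), unname(gc))
}

# solve a single bias weight so the expected CDS G+C hits the target.
# Codon c gets weight w^gc(c) within its synonymous family. With
# `bias_aa = TRUE` the amino-acid composition itself is biased the same
# way (weight w^E[gc|aa]) — the GARP-shift real high-G+C genes show, and
# the only way to reach targets beyond what synonymous choice alone
# allows (~28-66%).
codon_bias_tables <- function(gc_target_pct, bias_aa = FALSE) {
  by_aa <- codons_by_aa()
  gcount <- function(c3) vapply(strsplit(c3, ""), function(v)
    sum(v %in% c("G", "C")), numeric(1))
  gc_given_aa <- function(w) {
    vapply(AA20, function(aa) {
      g <- gcount(by_aa[[aa]])
      wt <- w^g
      sum(wt * g) / sum(wt)
    }, numeric(1))
  }
  expected_gc <- function(w) {
    gaa <- gc_given_aa(w)
    if (bias_aa) {
      q <- w^gaa
      sum(q * gaa) / sum(q) / 3
    } else {
      mean(gaa) / 3
    }
  }
  target <- gc_target_pct / 100
  lo <- expected_gc(0.02); hi <- expected_gc(50)
  if (target <= lo || target >= hi) {
    stop_validation("gc_target ", gc_target_pct, "% not reachable (",
                    round(100 * lo), "-", round(100 * hi),
                    "% with this bias model)")
  }
  w <- stats::uniroot(function(x) expected_gc(x) - target,
                      c(0.02, 50), tol = 1e-9)$root
  gaa <- gc_given_aa(w)
  aa_probs <- if (bias_aa) {
    q <- w^gaa
    q / sum(q)
  } else {
    stats::setNames(rep(1 / 20, 20), AA20)
  }
  list(
    by_aa = lapply(by_aa, function(cs) {
      g <- gcount(cs)
      p <- w^g
      list(codons = cs, prob = p / sum(p))
    }),
    aa_probs = aa_probs
  )
}

sample_protein <- function(length_aa, aa_probs = NULL) {
  rest <- if (is.null(aa_probs)) {
    sample(AA20, length_aa - 1, replace = TRUE)
  } else {
    sample(AA20, length_aa - 1, replace = TRUE, prob = aa_probs[AA20])
  }
  paste0("M", paste(rest, collapse = ""))
}

back_translate <- function(protein, bias) {
  by_aa <- bias$by_aa
  aas <- strsplit(protein, "")[[1]]
  cods <- vapply(aas, function(aa) {
    tb <- by_aa[[aa]]
    if (is.null(tb)) stop_validation("cannot back-translate residue ", aa)
    if (length(tb$codons) == 1L) tb$codons else
      sample(tb$codons, 1L, prob = tb$prob)
  }, character(1))
  stop_tb <- by_aa[["*"]]
  stop_c <- if (!is.null(stop_tb)) {
    if (length(stop_tb$codons) == 1L) stop_tb$codons else
      sample(stop_tb$codons, 1L, prob = stop_tb$prob)
  } else "TAA"
  paste0(paste(cods, collapse = ""), stop_c)
}

random_dna <- function(n, gc_pct) {
  p <- gc_pct / 200
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(p, p, 0.5 - p, 0.5 - p)), collapse = "")
}

mutate_protein <- function(protein, p) {
  if (p <= 0) return(protein)
  aas <- strsplit(protein, "")[[1]]
  hit <- which(stats::runif(length(aas)) < p)
  for (i in hit) {
    aas[i] <- sample(setdiff(AA20, aas[i]), 1L)
  }
  paste(aas, collapse = "")
}

#' Generate a synthetic clade with ground truth
#'
#' See [clade_config()] for the model. Ancestral proteins are sampled
#' i.i.d. over the 20 amino acids (leading methionine fixed), descendants
#' are mutated independently along a star phylogeny, CDSs are
#' back-translated with a genome-specific codon bias calibrated to the
#' G+C target, and each genome is laid out as one circular replicon with
#' geometric intergenic spacers. Inversions reverse a contiguous run of
#' core genes and flip their strands. IS insertions land in intergenic
#' space (or inside an earlier complete IS copy when nesting, splitting it
#' into fragments that share a parent label). Islands are contiguous
#' gene+spacer stretches generated at an offset G+C and inserted into the
#' focal genome.
#'
#' @param config A [clade_config()].
#' @return A list of class `synthetic_clade` with elements `genomes`
#'   (named list of `genome_annotation`), `is_tables` (named list of IS
#'   element data.frames, completeness unset), `catalog` (IS reference
#'   catalog), `truth` (see details) and `config`. `truth` carries
#'   `families` (genome, locus_tag, family), `venn` (focal locus_tag,
#'   cell), `ortholog_pairs` (per genome pair), `inversions`, `is_counts`
#'   (per genome complete/partial tallies as emitted) and `islands`
#'   (coordinates and target G+C).
#' @export
generate_clade <- function(config = clade_config()) {
  stopifnot(inherits(config, "clade_config"))
  set.seed(config$seed)
  ng <- config$n_genomes
  gids <- paste0("G", seq_len(ng))

  # --- ancestral families ------------------------------------------------
  n_subset <- vapply(config$shared_subsets, function(s) s$n_genes,
                     numeric(1))
  fam_core <- if (config$n_core) sprintf("FAM%04d", seq_len(config$n_core))
              else character(0)
  fam_subset <- list()
  nxt <- config$n_core
  for (k in seq_along(config$shared_subsets)) {
    fam_subset[[k]] <- sprintf("FAM%04d", nxt + seq_len(n_subset[k]))
    nxt <- nxt + n_subset[k]
  }
  fam_shared <- c(fam_core, unlist(fam_subset))
  member <- lapply(seq_len(ng), function(g) {
    c(fam_core, unlist(fam_subset[vapply(config$shared_subsets,
                                         function(s) g %in% s$genomes,
                                         logical(1))]))
  })
  # ancestral order of shared families (one draw, common to all genomes)
  anc_order <- sample(fam_shared)

  plen <- function(n) pmax(30L, round(stats::rgamma(
    n, shape = (config$protein_length_mean / config$protein_length_sd)^2,
    scale = config$protein_length_sd^2 / config$protein_length_mean)))
  anc_protein <- stats::setNames(
    vapply(plen(length(fam_shared)), sample_protein, character(1)),
    fam_shared)
  anc_strand <- stats::setNames(sample(c("+", "-"), length(fam_shared),
                                       replace = TRUE), fam_shared)
  cog_letters <- strsplit("JAKLBDYVTMNZWUOCGEFHIPQRS", "")[[1]][1:20]
  anc_cog <- stats::setNames(sample(cog_letters, length(fam_shared),
                                    replace = TRUE), fam_shared)

  focal_fam_order <- NULL
  truth_families <- list(); truth_pairs <- list()
  truth_inversions <- list(); truth_islands <- list()
  truth_is <- list()
  genomes <- list(); is_tables <- list()

  # IS catalog shared by the clade
  ref_len <- sample(c(800L, 1000L, 1200L, 1500L), config$is_families,
                    replace = TRUE)
  cat_names <- sprintf("ISSyn%d", seq_len(config$is_families))
  cat_fams <- sprintf("IS%d", sample(3:30, config$is_families))
  catalog <- is_catalog(cat_names, cat_fams, ref_len)
  is_refseq <- stats::setNames(vapply(ref_len, random_dna,
                                      character(1),
                                      gc_pct = config$gc_target[1]),
                               cat_names)

  inv_genomes <- rep_len(config$inversion_genomes,
                         max(1L, config$n_inversions))
  if (config$n_inversions > 0 && any(inv_genomes == 1L)) {
    stop_validation("inversions are planted in non-focal genomes")
  }

  for (g in seq_len(ng)) {
    gid <- gids[g]
    bias <- codon_bias_tables(config$gc_target[g])
    # layout: shared families in ancestral order, specifics interleaved
    fams <- intersect(anc_order, member[[g]])
    n_spec <- config$n_specific[g]
    spec_ids <- if (n_spec) sprintf("SPEC_%s_%03d", gid, seq_len(n_spec))
                else character(0)
    layout <- data.frame(
      family = c(fams, spec_ids),
      shared = c(rep(TRUE, length(fams)), rep(FALSE, n_spec)),
      stringsAsFactors = FALSE)
    pos <- c(seq_along(fams),
             if (n_spec) stats::runif(n_spec, 0.5, length(fams) + 0.5))
    layout <- layout[order(pos), , drop = FALSE]
    layout$strand <- ifelse(layout$shared, anc_strand[layout$family],
                            sample(c("+", "-"), nrow(layout),
                                   replace = TRUE))
    spec_proteins <- vapply(plen(nrow(layout)), sample_protein,
                            character(1))
    layout$protein <- ifelse(
      layout$shared,
      vapply(anc_protein[layout$family], mutate_protein, character(1),
             p = config$p_substitution),
      spec_proteins)
    layout$cog <- ifelse(layout$shared, anc_cog[layout$family],
                         sample(cog_letters, nrow(layout), replace = TRUE))
    layout$island <- FALSE

    # planted inversions: contiguous runs of shared (core) genes that are
    # also near-contiguous on the focal side (a clean, recoverable
    # inversion; a run interrupted focal-side by an island or many
    # strain-specific genes is a compound rearrangement, not an
    # inversion)
    for (k in which(inv_genomes == g & seq_along(inv_genomes) <=
                    config$n_inversions)) {
      L <- sample(seq(config$inversion_genes[1], config$inversion_genes[2]),
                  1L)
      shared_idx <- which(layout$shared)
      runs <- shared_idx[vapply(seq_along(shared_idx), function(i) {
        i + L - 1L <= length(shared_idx) &&
          shared_idx[i + L - 1L] - shared_idx[i] == L - 1L
      }, logical(1))]
      if (length(runs) && !is.null(focal_fam_order)) {
        span_ok <- vapply(runs, function(from) {
          fams_run <- layout$family[from:(from + L - 1L)]
          pos <- match(fams_run, focal_fam_order)
          all(!is.na(pos)) && (max(pos) - min(pos)) <= L + 1L
        }, logical(1))
        if (any(span_ok)) runs <- runs[span_ok]
      }
      if (!length(runs)) {
        stop_validation("no contiguous core run of length ", L,
                        " available for inversion in genome ", gid)
      }
      from <- sample(runs, 1L)
      idx <- from:(from + L - 1L)
      layout[idx, ] <- layout[rev(idx), ]
      layout$strand[idx] <- ifelse(layout$strand[idx] == "+", "-", "+")
      truth_inversions[[length(truth_inversions) + 1L]] <- list(
        genome = gid, families = rev(layout$family[idx]))
    }

    # island genes (focal genome): contiguous, offset G+C
    island_rows <- NULL
    if (g == 1L && config$n_islands > 0) {
      ibias <- codon_bias_tables(config$gc_target[g] +
                                   config$island_gc_offset,
                                 bias_aa = TRUE)
      island_cds <- list(); island_spacer <- list()
      for (isl in seq_len(config$n_islands)) {
        n_igenes <- max(1L, round(config$island_length_bp /
          (3 * (config$protein_length_mean + 1) +
             config$intergenic_mean_bp)))
        irows <- data.frame(
          family = sprintf("ISL%d_%s_%03d", isl, gid, seq_len(n_igenes)),
          shared = FALSE,
          strand = sample(c("+", "-"), n_igenes, replace = TRUE),
          protein = vapply(plen(n_igenes), sample_protein, character(1),
                           aa_probs = ibias$aa_probs),
          cog = sample(cog_letters, n_igenes, replace = TRUE),
          island = TRUE, stringsAsFactors = FALSE)
        # Pre-build the island's sequence so the spanned region (first to
        # last island gene) hits the offset target by construction: the
        # internal spacers receive an exactly compensating composition,
        # cancelling the sampling noise of ~3000 codon draws.
        cds <- vapply(seq_len(n_igenes), function(i) {
          x <- back_translate(irows$protein[i], ibias)
          if (irows$strand[i] == "-") revcomp(x) else x
        }, character(1))
        sp_len <- if (n_igenes > 1)
          1L + stats::rgeom(n_igenes - 1L, 1 / config$intergenic_mean_bp)
        else integer(0)
        target_frac <- (config$gc_target[g] + config$island_gc_offset) / 100
        cds_gc <- sum(vapply(cds, function(x)
          sum(strsplit(x, "")[[1]] %in% c("G", "C")), numeric(1)))
        total_len <- sum(nchar(cds)) + sum(sp_len)
        need <- round(target_frac * total_len) - cds_gc
        need <- min(max(need, 0L), sum(sp_len))
        sp_bases <- sample(c(rep(c("G", "C"), length.out = need),
                             rep(c("A", "T"), length.out = sum(sp_len) - need)))
        sp_seq <- character(0)
        if (n_igenes > 1) {
          ends <- cumsum(sp_len)
          sp_seq <- vapply(seq_along(sp_len), function(i)
            paste(sp_bases[(ends[i] - sp_len[i] + 1):ends[i]],
                  collapse = ""), character(1))
        }
        island_cds[irows$family] <- as.list(unname(cds))
        island_spacer[irows$family[-1]] <- as.list(unname(sp_seq))
        at <- sample(nrow(layout), 1L)
        layout <- rbind(layout[seq_len(at), ], irows,
                        layout[-seq_len(at), ])
        island_rows <- c(island_rows, list(list(isl = isl,
                                                fams = irows$family)))
      }
    }
    rownames(layout) <- NULL
    if (g == 1L) focal_fam_order <- layout$family

    # --- assemble the replicon -------------------------------------------
    rid <- paste0(gid, "_chr")
    spacer_len <- function(n, mean_bp) 1L + stats::rgeom(n, 1 / mean_bp)
    segs <- character(0); feat <- list(); cursor <- 0L
    island_span <- list()
    for (i in seq_len(nrow(layout))) {
      fam <- layout$family[i]
      if (layout$island[i]) {
        spacer <- island_spacer[[fam]]
        if (is.null(spacer)) {  # first gene of its island
          spacer <- random_dna(spacer_len(1L, config$intergenic_mean_bp),
                               config$gc_target[g] +
                                 config$island_gc_offset)
        }
        cds <- island_cds[[fam]]
      } else {
        spacer <- random_dna(spacer_len(1L, config$intergenic_mean_bp),
                             config$gc_target[g])
        cds <- back_translate(layout$protein[i], bias)
        if (layout$strand[i] == "-") cds <- revcomp(cds)
      }
      segs <- c(segs, spacer)
      cursor <- cursor + nchar(spacer)
      feat[[i]] <- data.frame(start = cursor + 1L,
                              end = cursor + nchar(cds),
                              stringsAsFactors = FALSE)
      segs <- c(segs, cds)
      cursor <- cursor + nchar(cds)
    }
    segs <- c(segs, random_dna(spacer_len(1L, config$intergenic_mean_bp),
                               config$gc_target[g]))
    seq <- paste(segs, collapse = "")
    feat <- do.call(rbind, feat)
    feat$locus_tag <- sprintf("%s_%05d", gid, 10L * seq_len(nrow(layout)))
    feat$strand <- layout$strand
    if (any(layout$island)) {
      for (ir in island_rows) {
        sel <- layout$family %in% ir$fams
        island_span[[length(island_span) + 1L]] <-
          c(start = min(feat$start[sel]), end = max(feat$end[sel]))
      }
    }

    features <- gene_features(
      locus_tag = feat$locus_tag, replicon_id = rid,
      start = feat$start, end = feat$end, strand = feat$strand,
      ftype = "CDS", product = paste("synthetic protein", layout$family),
      cog = layout$cog, protein = layout$protein)

    # --- IS insertions ----------------------------------------------------
    elements <- is_elements(character(0), character(0), character(0),
                            character(0), integer(0), integer(0))
    shift_after <- function(df, at, by) {
      sel <- df$start > at
      df$start[sel] <- df$start[sel] + by
      df$end[df$end > at] <- df$end[df$end > at] + by
      df
    }
    eid <- 0L
    for (ev in seq_len(config$is_copies[g])) {
      nm <- sample(cat_names, 1L)
      full <- is_refseq[[nm]]
      u <- stats::runif(1)
      nest_ok <- any(elements$completeness == "complete" &
                       !nzchar(elements$parent_name))
      if (u < config$is_nest_prob && nest_ok) {
        # nest inside an earlier intact copy, splitting it into fragments
        host_i <- sample(which(elements$completeness == "complete" &
                                 !nzchar(elements$parent_name)), 1L)
        host <- elements[host_i, ]
        cut <- host$start +
          floor(stats::runif(1, 0.2, 0.8) * (host$end - host$start))
        ins <- full
        at <- cut
        seq <- paste0(substr(seq, 1, at), ins,
                      substr(seq, at + 1, nchar(seq)))
        features <- shift_after(features, at, nchar(ins))
        elements <- shift_after(elements, at, nchar(ins))
        for (isp in seq_along(island_span)) {
          if (island_span[[isp]]["start"] > at)
            island_span[[isp]] <- island_span[[isp]] + nchar(ins)
        }
        parent <- sprintf("%s_parent%03d", gid, host_i)
        # host becomes two fragments sharing the parent label
        eid <- eid + 1L
        frag2 <- is_elements(sprintf("%s_IS%03d", gid, eid), host$name,
                             host$family, rid, at + nchar(ins) + 1L,
                             host$end + nchar(ins), host$strand,
                             "partial", parent)
        elements$end[host_i] <- at
        elements$completeness[host_i] <- "partial"
        elements$parent_name[host_i] <- parent
        eid <- eid + 1L
        inner <- is_elements(sprintf("%s_IS%03d", gid, eid), nm,
                             catalog$family[catalog$name == nm], rid,
                             at + 1L, at + nchar(ins),
                             sample(c("+", "-"), 1L), "complete", "")
        elements <- rbind(elements, frag2, inner)
      } else {
        partial <- u >= config$is_nest_prob &&
          u < config$is_nest_prob + config$is_fragment_prob
        ins <- if (partial) {
          keep <- floor(stats::runif(1, 0.3, 0.7) * nchar(full))
          substr(full, 1, max(keep, 50L))
        } else full
        # land in intergenic space, outside islands and existing elements
        at <- intergenic_point(nchar(seq), features, elements, island_span)
        seq <- paste0(substr(seq, 1, at), ins,
                      substr(seq, at + 1, nchar(seq)))
        features <- shift_after(features, at, nchar(ins))
        elements <- shift_after(elements, at, nchar(ins))
        for (isp in seq_along(island_span)) {
          if (island_span[[isp]]["start"] > at)
            island_span[[isp]] <- island_span[[isp]] + nchar(ins)
        }
        eid <- eid + 1L
        elements <- rbind(elements, is_elements(
          sprintf("%s_IS%03d", gid, eid), nm,
          catalog$family[catalog$name == nm], rid, at + 1L,
          at + nchar(ins), sample(c("+", "-"), 1L),
          if (partial) "partial" else "complete", ""))
      }
    }
    n_complete_truth <- sum(elements$completeness == "complete")
    n_partial_truth <- sum(elements$completeness == "partial")

    rep <- replicon(rid, seq, topology = "circular")
    ann <- genome_annotation(gid, list(rep), features)
    genomes[[gid]] <- ann
    truth_is[[gid]] <- list(
      n_complete = n_complete_truth, n_partial = n_partial_truth,
      by_family = if (nrow(elements)) stats::aggregate(
        list(n = rep_len(1L, nrow(elements))),
        by = list(family = elements$family,
                  completeness = elements$completeness), FUN = sum)
      else data.frame(family = character(0), completeness = character(0),
                      n = integer(0)))
    # emitted tables carry completeness unset: classification is the
    # pipeline's job
    emitted <- elements
    if (nrow(emitted)) emitted$completeness <- "unset"
    is_tables[[gid]] <- emitted

    truth_families[[gid]] <- data.frame(
      genome = gid, locus_tag = feat$locus_tag, family = layout$family,
      shared = layout$shared, stringsAsFactors = FALSE)
    if (length(island_span)) {
      truth_islands[[gid]] <- do.call(rbind, lapply(
        seq_along(island_span), function(i) data.frame(
          genome = gid, replicon_id = rid,
          start = unname(island_span[[i]]["start"]),
          end = unname(island_span[[i]]["end"]),
          gc_target = config$gc_target[g] + config$island_gc_offset,
          stringsAsFactors = FALSE)))
    }
  }

  # pairwise ortholog truth: shared families present in both genomes
  fam_tab <- do.call(rbind, truth_families)
  for (i in seq_len(ng - 1L)) {
    for (j in seq.int(i + 1L, ng)) {
      fi <- fam_tab[fam_tab$genome == gids[i] & fam_tab$shared, ]
      fj <- fam_tab[fam_tab$genome == gids[j] & fam_tab$shared, ]
      common <- intersect(fi$family, fj$family)
      truth_pairs[[paste(gids[i], gids[j], sep = "|")]] <- data.frame(
        gene_a = fi$locus_tag[match(common, fi$family)],
        gene_b = fj$locus_tag[match(common, fj$family)],
        stringsAsFactors = FALSE)
    }
  }

  # focal Venn cells
  focal <- fam_tab[fam_tab$genome == gids[1], ]
  others <- gids[-1]
  cell <- vapply(seq_len(nrow(focal)), function(i) {
    if (!focal$shared[i]) return("specific")
    pres <- others[vapply(others, function(og)
      focal$family[i] %in% fam_tab$family[fam_tab$genome == og],
      logical(1))]
    if (length(pres) == length(others)) "core"
    else if (!length(pres)) "specific"
    else paste(sort(pres), collapse = "+")
  }, character(1))
  venn <- data.frame(locus_tag = focal$locus_tag, cell = cell,
                     stringsAsFactors = FALSE)

  # map inversion families to locus tags in both genomes
  inversions <- lapply(truth_inversions, function(iv) {
    gtab <- fam_tab[fam_tab$genome == iv$genome, ]
    ftab <- fam_tab[fam_tab$genome == gids[1], ]
    list(genome = iv$genome,
         locus_tags = gtab$locus_tag[match(iv$families, gtab$family)],
         focal_partners = ftab$locus_tag[match(iv$families, ftab$family)])
  })

  structure(list(
    genomes = genomes, is_tables = is_tables, catalog = catalog,
    truth = list(families = fam_tab, venn = venn,
                 ortholog_pairs = truth_pairs, inversions = inversions,
                 is_counts = truth_is,
                 islands = if (length(truth_islands))
                   do.call(rbind, truth_islands)),
    config = config), class = "synthetic_clade")
}

# uniform point in intergenic space: not inside a gene, an IS element or
# an island span
intergenic_point <- function(n, features, elements, island_span) {
  for (try in 1:200) {
    at <- sample.int(n - 1L, 1L)
    in_gene <- any(features$start <= at + 1L & features$end >= at)
    in_el <- nrow(elements) > 0 &&
      any(elements$start <= at + 1L & elements$end >= at)
    in_isl <- length(island_span) > 0 &&
      any(vapply(island_span, function(s) s["start"] <= at + 1L &&
                   s["end"] >= at, logical(1)))
    if (!in_gene && !in_el && !in_isl) return(at)
  }
  stop_validation("could not place an IS insertion in intergenic space")
}

#' @export
print.synthetic_clade <- function(x, ...) {
  cat(sprintf("<synthetic_clade> %d genomes, seed %d\n",
              length(x$genomes), x$config$seed))
  invisible(x)
}

#' Write a synthetic clade to disk
#'
#' Writes, per genome, `<id>.fasta` + `<id>_features.tsv` + `<id>_is.tsv`,
#' plus `is_catalog.tsv` and `truth.json` — the same formats the package's
#' readers consume.
#'
#' @param clade A `synthetic_clade`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_clade <- function(clade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gid in names(clade$genomes)) {
    write_genome(clade$genomes[[gid]],
                 file.path(dir, paste0(gid, ".fasta")),
                 file.path(dir, paste0(gid, "_features.tsv")))
    write_is_table(clade$is_tables[[gid]],
                   file.path(dir, paste0(gid, "_is.tsv")))
  }
  utils::write.table(clade$catalog, file.path(dir, "is_catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- clade$truth
  jsonlite::write_json(list(
    families = tr$families, venn = tr$venn,
    ortholog_pairs = tr$ortholog_pairs,
    inversions = tr$inversions, is_counts = tr$is_counts,
    islands = tr$islands), file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Score inferred results against clade ground truth
#'
#' Precision/recall of an `ortholog_map` against the planted ortholog
#' pairs; exact-cell comparison of a `pan_partition` against the planted
#' Venn cells; exact-recovery flags of synteny blocks against planted
#' inversions; count comparison of an `is_census`. By convention an empty
#' inference has precision 1 and recall 0.
#'
#' @param inferred An `ortholog_map`, `pan_partition`, list of
#'   `synteny_block`s, or `is_census`.
#' @param truth The `truth` element of a `synthetic_clade`.
#' @param ... Method-specific: `genome_a`/`genome_b` (ortholog map),
#'   `genome` (inversions, census).
#' @return A list of scores; see the individual methods.
#' @export
score_recovery <- function(inferred, truth, ...) {
  UseMethod("score_recovery")
}

#' @rdname score_recovery
#' @param genome_a,genome_b Genome ids of the map's two sides.
#' @export
score_recovery.ortholog_map <- function(inferred, truth,
                                        genome_a = attr(inferred, "genome_a"),
                                        genome_b = attr(inferred, "genome_b"),
                                        ...) {
  key <- paste(genome_a, genome_b, sep = "|")
  rkey <- paste(genome_b, genome_a, sep = "|")
  tp <- truth$ortholog_pairs[[key]]
  flip <- FALSE
  if (is.null(tp)) { tp <- truth$ortholog_pairs[[rkey]]; flip <- TRUE }
  if (is.null(tp)) stop_validation("no truth pairs for genomes ",
                                   genome_a, "/", genome_b)
  want <- if (flip) paste(tp$gene_b, tp$gene_a) else paste(tp$gene_a,
                                                           tp$gene_b)
  got <- paste(inferred$gene_a, inferred$gene_b)
  list(precision = if (!length(got)) 1 else mean(got %in% want),
       recall = if (!length(want)) 1 else mean(want %in% got),
       n_inferred = length(got), n_truth = length(want))
}

#' @rdname score_recovery
#' @export
score_recovery.pan_partition <- function(inferred, truth, ...) {
  want <- stats::setNames(truth$venn$cell, truth$venn$locus_tag)
  got <- stats::setNames(inferred$table$cell, inferred$table$locus_tag)
  common <- intersect(names(want), names(got))
  cells_want <- table(want)
  cells_got <- table(factor(got, levels = names(cells_want)))
  list(exact = setequal(names(want), names(got)) &&
         all(want[common] == got[common]),
       accuracy = if (!length(common)) NA_real_
                  else mean(want[common] == got[common]),
       cell_counts_equal = all(as.integer(cells_want) ==
                                 as.integer(cells_got)))
}

#' @rdname score_recovery
#' @param genome Genome id whose planted inversions are scored (blocks'
#'   B side).
#' @export
score_recovery.list <- function(inferred, truth, genome, ...) {
  invs <- Filter(function(iv) iv$genome == genome, truth$inversions)
  found <- vapply(invs, function(iv) {
    any(vapply(inferred, function(b) {
      if (b$orientation != "inverted") return(FALSE)
      bg <- b$columns$gene_b[b$columns$type %in% c("match", "mismatch")]
      setequal(bg[!is.na(bg)], iv$locus_tags)
    }, logical(1)))
  }, logical(1))
  list(n_planted = length(invs), n_recovered = sum(found),
       all_recovered = all(found))
}

#' @rdname score_recovery
#' @export
score_recovery.is_census <- function(inferred, truth, genome, ...) {
  want <- truth$is_counts[[genome]]
  list(complete_equal = inferred$n_complete == want$n_complete,
       partial_equal = inferred$n_partial == want$n_partial,
       n_complete = inferred$n_complete,
       n_partial = inferred$n_partial,
       want_complete = want$n_complete, want_partial = want$n_partial)
}
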