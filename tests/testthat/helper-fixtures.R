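# Shared fixtures. The default zero-mutation clade and its derived maps
# are expensive (~half a minute of all-vs-all alignment), so they are
# computed once per test run and memoised.

toy_annotation <- function(seq = strrep("ACGT", 250),
                           genes = NULL, genome_id = "toy",
                           topology = "linear") {
  rep <- replicon("chr", seq, topology = topology)
  feats <- if (is.null(genes)) empty_features_df() else genes
  genome_annotation(genome_id, list(rep), feats)
}

empty_features_df <- function() {
  gene_features(character(0), character(0), integer(0), integer(0))
}

# a best_hit_map-shaped data.frame from bare pairs (for RBH logic tests)
fake_best_map <- function(query, subject) {
  structure(data.frame(query_id = query, subject_id = subject,
                       stringsAsFactors = FALSE),
            class = c("best_hit_map", "data.frame"))
}

# gene_relations from explicit pair lists
fake_relations <- function(ortho_a = character(0), ortho_b = character(0),
                           homol_a = character(0), homol_b = character(0)) {
  gene_relations(
    data.frame(gene_a = ortho_a, gene_b = ortho_b,
               stringsAsFactors = FALSE),
    best_ab = if (length(homol_a))
      data.frame(query_id = homol_a, subject_id = homol_b,
                 stringsAsFactors = FALSE))
}

gene_order_df <- function(tags, strands = "+") {
  structure(data.frame(locus_tag = tags,
                       strand = rep_len(strands, length(tags)),
                       stringsAsFactors = FALSE),
            class = c("gene_order", "data.frame"))
}

# memoised default clade (zero mutation) plus its focal ortholog maps,
# pan-genome partition and G1-G2 synteny blocks
clade_fixture <- local({
  cache <- new.env()
  function() {
    if (!is.null(cache$fix)) return(cache$fix)
    clade <- generate_clade(clade_config(seed = 1, p_substitution = 0))
    maps <- list(
      G2 = orthologs_between(clade$genomes$G1, clade$genomes$G2),
      G3 = orthologs_between(clade$genomes$G1, clade$genomes$G3),
      G4 = orthologs_between(clade$genomes$G1, clade$genomes$G4))
    partition <- pan_partition(clade$genomes$G1, maps)
    rel <- gene_relations(maps$G2, attr(maps$G2, "best_ab"),
                          attr(maps$G2, "best_ba"))
    blocks <- align_gene_trains(
      build_gene_order(clade$genomes$G1, "G1_chr"),
      build_gene_order(clade$genomes$G2, "G2_chr"), rel)
    cache$fix <- list(clade = clade, maps = maps, partition = partition,
                      blocks = blocks)
    cache$fix
  }
})

# plain-R G+C fraction used in expectations
gc_fraction_of <- function(s) {
  v <- strsplit(s, "")[[1]]
  sum(v %in% c("G", "C")) / sum(v %in% c("A", "C", "G", "T"))
}
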