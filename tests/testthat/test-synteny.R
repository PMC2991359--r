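# Gene-order synteny: ordering, the train-alignment DP, block
# extraction, dot-plot export.

test_that("gene orders sort by start with locus-tag tie-breaks", {
  genes <- gene_features(c("g200", "g10", "g50"), "chr",
                         c(200, 10, 50), c(290, 40, 90))
  ord <- build_gene_order(toy_annotation(genes = genes), "chr")
  expect_equal(ord$locus_tag, c("g10", "g50", "g200"))

  tie <- gene_features(c("zz", "aa"), "chr", c(10, 10), c(40, 40))
  ordt <- build_gene_order(toy_annotation(genes = tie), "chr")
  expect_equal(ordt$locus_tag, c("aa", "zz"))

  shuffled <- build_gene_order(
    toy_annotation(genes = genes[c(2, 3, 1), ]), "chr")
  expect_equal(shuffled$locus_tag, ord$locus_tag)

  empty <- build_gene_order(toy_annotation(), "chr")
  expect_equal(nrow(empty), 0)
  expect_error(build_gene_order(toy_annotation(), "nope"),
               class = "cladecompare_validation_error")
})

test_that("identical gene trains give one full-length collinear block", {
  oa <- gene_order_df(paste0("a", 1:5))
  ob <- gene_order_df(paste0("b", 1:5))
  rel <- fake_relations(paste0("a", 1:5), paste0("b", 1:5))
  blocks <- align_gene_trains(oa, ob, rel)
  expect_length(blocks, 1)
  b <- blocks[[1]]
  expect_equal(b$orientation, "same")
  expect_equal(b$n_matches, 5)
  expect_equal(b$score, 10)
  expect_equal(b$n_gaps, 0)
})

test_that("a fully reversed train is reported as one inverted block", {
  oa <- gene_order_df(paste0("a", 1:5), "+")
  ob <- gene_order_df(paste0("b", 5:1), "-")  # reversed, strands flipped
  rel <- fake_relations(paste0("a", 1:5), paste0("b", 1:5))
  blocks <- align_gene_trains(oa, ob, rel)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$orientation, "inverted")
  expect_equal(blocks[[1]]$n_matches, 5)
  got_b <- blocks[[1]]$columns$gene_b
  expect_equal(sort(got_b), paste0("b", 1:5))
})

test_that("homolog-only genes align as mismatch columns", {
  oa <- gene_order_df(paste0("a", 1:5))
  ob <- gene_order_df(c("b1", "b2", "x", "b4", "b5"))
  rel <- fake_relations(paste0("a", c(1, 2, 4, 5)),
                        paste0("b", c(1, 2, 4, 5)),
                        homol_a = "a3", homol_b = "x")
  blocks <- align_gene_trains(oa, ob, rel)
  expect_length(blocks, 1)
  b <- blocks[[1]]
  expect_equal(b$n_matches, 4)
  expect_equal(b$n_mismatches, 1)
  expect_equal(b$score, 9)  # 4 matches x2 + 1 mismatch x1
  expect_equal(b$columns$type[3], "mismatch")
})

test_that("unrelated genes can only be gapped, never aligned", {
  oa <- gene_order_df(paste0("a", 1:5))
  ob <- gene_order_df(c("b1", "b2", "u", "b4", "b5"))
  rel <- fake_relations(paste0("a", c(1, 2, 4, 5)),
                        paste0("b", c(1, 2, 4, 5)))
  blocks <- align_gene_trains(oa, ob, rel, min_block_matches = 3,
                              min_score = 4)
  b <- blocks[[1]]
  expect_equal(b$n_matches, 4)
  expect_equal(b$n_mismatches, 0)
  expect_equal(b$n_gaps, 2)  # a3 and u both skipped
  expect_equal(b$score, 4 * 2 - 2)
})

test_that("train alignment is symmetric in its two genomes", {
  fix <- clade_fixture()
  cl <- fix$clade
  m <- fix$maps$G2
  rel_ab <- gene_relations(m, attr(m, "best_ab"), attr(m, "best_ba"))
  flipped <- structure(data.frame(gene_a = m$gene_b, gene_b = m$gene_a),
                       class = c("ortholog_map", "data.frame"))
  rel_ba <- gene_relations(flipped, attr(m, "best_ba"),
                           attr(m, "best_ab"))
  oa <- build_gene_order(cl$genomes$G1, "G1_chr")
  ob <- build_gene_order(cl$genomes$G2, "G2_chr")
  fwd <- align_gene_trains(oa, ob, rel_ab)
  bwd <- align_gene_trains(ob, oa, rel_ba)
  expect_equal(length(fwd), length(bwd))
  expect_equal(sort(vapply(fwd, `[[`, numeric(1), "score")),
               sort(vapply(bwd, `[[`, numeric(1), "score")))
  key <- function(bl) paste(sort(c(bl$columns$gene_a, bl$columns$gene_b)),
                            collapse = ",")
  expect_setequal(vapply(fwd, key, character(1)),
                  vapply(bwd, key, character(1)))
})

test_that("no gene is matched in two blocks (masking)", {
  fix <- clade_fixture()
  aligned_a <- unlist(lapply(fix$blocks, function(b)
    b$columns$gene_a[b$columns$type %in% c("match", "mismatch")]))
  aligned_b <- unlist(lapply(fix$blocks, function(b)
    b$columns$gene_b[b$columns$type %in% c("match", "mismatch")]))
  expect_equal(anyDuplicated(aligned_a), 0)
  expect_equal(anyDuplicated(aligned_b), 0)
})

test_that("the DP equals exhaustive collinear-chain scoring on small orders", {
  set.seed(29)
  n_cases <- 120
  for (k in seq_len(n_cases)) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    rel <- matrix(sample(0:2, na * nb, replace = TRUE,
                         prob = c(0.55, 0.15, 0.3)), na, nb)
    strand_a <- sample(c("+", "-"), na, replace = TRUE)
    strand_b <- sample(c("+", "-"), nb, replace = TRUE)
    aware <- sample(c(TRUE, FALSE), 1)
    oa <- gene_order_df(paste0("A", seq_len(na)), strand_a)
    ob <- gene_order_df(paste0("B", seq_len(nb)), strand_b)
    pairs <- which(rel > 0, arr.ind = TRUE)
    relations <- fake_relations(
      ortho_a = paste0("A", pairs[rel[pairs] == 2, 1]),
      ortho_b = paste0("B", pairs[rel[pairs] == 2, 2]),
      homol_a = paste0("A", pairs[rel[pairs] == 1, 1]),
      homol_b = paste0("B", pairs[rel[pairs] == 1, 2]))
    blocks <- align_gene_trains(oa, ob, relations,
                                min_block_matches = 0, min_score = 1,
                                strand_aware = aware)
    s <- oracle_score_matrices(rel, strand_a, strand_b,
                               strand_aware = aware)
    want <- max(oracle_best_chain(s$fwd), oracle_best_chain(s$rev))
    got <- if (length(blocks)) blocks[[1]]$score else 0
    expect_equal(got, want)
  }
})

test_that("the planted inversion is recovered exactly at zero mutation", {
  fix <- clade_fixture()
  sc <- score_recovery(fix$blocks, fix$clade$truth, genome = "G2")
  expect_gte(sc$n_planted, 1)
  expect_true(sc$all_recovered)
})

test_that("dot-plot export places one coloured point per ortholog pair", {
  ga <- toy_annotation(genes = gene_features(c("a1", "a2"), "chr",
                                             c(1, 101), c(60, 160),
                                             strand = c("+", "-")),
                       genome_id = "A")
  gb <- toy_annotation(genes = gene_features(c("b1", "b2"), "chr",
                                             c(11, 111), c(70, 170),
                                             strand = c("+", "+")),
                       genome_id = "B")
  map <- structure(data.frame(gene_a = c("a1", "a2"),
                              gene_b = c("b1", "b2")),
                   class = c("ortholog_map", "data.frame"))
  d <- dotplot_export(map, ga, gb)
  expect_equal(nrow(d), 2)
  expect_equal(d$color, c("red", "blue"))
  expect_equal(d$pos_a, c(30.5, 130.5))
  bad <- structure(data.frame(gene_a = "a9", gene_b = "b1"),
                   class = c("ortholog_map", "data.frame"))
  expect_error(dotplot_export(bad, ga, gb),
               class = "cladecompare_validation_error")
})

test_that("blocks serialize to TSV with per-column detail", {
  fix <- clade_fixture()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_synteny_blocks(fix$blocks, p)
  tab <- utils::read.delim(p)
  expect_equal(nrow(tab), length(fix$blocks))
  expect_true(all(c("orientation", "score", "n_match", "columns") %in%
                    names(tab)))
})
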