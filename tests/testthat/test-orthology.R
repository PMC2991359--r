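# Reciprocal-best-hit orthology, pan-genome partition, COG profiles,
# family counts.

test_that("reciprocal best hits require agreement in both directions", {
  expect_equal(nrow(reciprocal_best_hits(fake_best_map("a1", "b1"),
                                         fake_best_map("b1", "a1"))), 1)
  expect_equal(nrow(reciprocal_best_hits(fake_best_map("a1", "b1"),
                                         fake_best_map("b1", "a2"))), 0)

  # 6-gene toy vs brute force over all pairs
  ab <- fake_best_map(c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  ba <- fake_best_map(c("b1", "b2", "b3"), c("a1", "a9", "a3"))
  got <- reciprocal_best_hits(ab, ba)
  brute <- list()
  for (i in seq_len(nrow(ab))) {
    for (j in seq_len(nrow(ba))) {
      if (ab$subject_id[i] == ba$query_id[j] &&
          ba$subject_id[j] == ab$query_id[i]) {
        brute[[length(brute) + 1]] <- c(ab$query_id[i], ab$subject_id[i])
      }
    }
  }
  brute <- do.call(rbind, brute)
  expect_equal(got$gene_a, sort(brute[, 1]))
  expect_equal(nrow(got), 2)

  # injective in both directions
  expect_false(anyDuplicated(got$gene_a) > 0)
  expect_false(anyDuplicated(got$gene_b) > 0)
})

test_that("pan-genome partition labels core, specific and subset cells", {
  genes <- gene_features(paste0("f", 1:4), "chr", c(1, 101, 201, 301),
                         c(90, 190, 290, 390))
  focal <- toy_annotation(genes = genes)
  maps <- list(
    X = structure(data.frame(gene_a = c("f1", "f2", "f3"),
                             gene_b = c("x1", "x2", "x3")),
                  class = c("ortholog_map", "data.frame")),
    Y = structure(data.frame(gene_a = c("f1", "f2"),
                             gene_b = c("y1", "y2")),
                  class = c("ortholog_map", "data.frame")))
  part <- pan_partition(focal, maps)
  cells <- stats::setNames(part$table$cell, part$table$locus_tag)
  expect_equal(unname(cells[c("f1", "f2", "f3", "f4")]),
               c("core", "core", "X", "specific"))
  expect_equal(sum(part$cells), 4)  # partition covers every gene
  expect_error(pan_partition(focal, unname(maps)),
               class = "cladecompare_validation_error")

  # transposases never enter the partition
  genes2 <- genes
  genes2$is_transposase[4] <- TRUE
  part2 <- pan_partition(toy_annotation(genes = genes2), maps)
  expect_false("f4" %in% part2$table$locus_tag)
  expect_equal(sum(part2$cells), 3)
})

test_that("identical genomes are all-core; empty maps are all-specific", {
  genes <- gene_features(paste0("g", 1:5), "chr",
                         seq(1, 401, 100), seq(60, 460, 100))
  focal <- toy_annotation(genes = genes)
  self_map <- structure(
    data.frame(gene_a = genes$locus_tag, gene_b = genes$locus_tag),
    class = c("ortholog_map", "data.frame"))
  allcore <- pan_partition(focal, list(twin = self_map))
  expect_true(all(allcore$table$cell == "core"))
  none <- pan_partition(focal, list(
    twin = structure(data.frame(gene_a = character(0),
                                gene_b = character(0)),
                     class = c("ortholog_map", "data.frame"))))
  expect_true(all(none$table$cell == "specific"))
})

test_that("clique mode demotes non-transitive presence patterns", {
  genes <- gene_features(c("f1", "f2"), "chr", c(1, 101), c(90, 190))
  focal <- toy_annotation(genes = genes)
  maps <- list(
    X = structure(data.frame(gene_a = c("f1", "f2"),
                             gene_b = c("x1", "x2")),
                  class = c("ortholog_map", "data.frame")),
    Y = structure(data.frame(gene_a = c("f1", "f2"),
                             gene_b = c("y1", "y2")),
                  class = c("ortholog_map", "data.frame")))
  # X-Y map agrees for f1's partners but not f2's
  cross <- list("X|Y" = structure(
    data.frame(gene_a = c("x1", "x2"), gene_b = c("y1", "y9")),
    class = c("ortholog_map", "data.frame")))
  patt <- pan_partition(focal, maps, mode = "pattern")
  cliq <- pan_partition(focal, maps, mode = "clique", cross_maps = cross)
  expect_equal(unname(stats::setNames(patt$table$cell,
                                      patt$table$locus_tag)[c("f1", "f2")]),
               c("core", "core"))
  expect_equal(unname(stats::setNames(cliq$table$cell,
                                      cliq$table$locus_tag)[c("f1", "f2")]),
               c("core", "specific"))
})

test_that("zero-mutation clade: RBH and Venn cells match planted truth", {
  fix <- clade_fixture()
  for (g in c("G2", "G3", "G4")) {
    sc <- score_recovery(fix$maps[[g]], fix$clade$truth)
    expect_equal(sc$precision, 1.0)
    expect_equal(sc$recall, 1.0)
  }
  sc <- score_recovery(fix$partition, fix$clade$truth)
  expect_true(sc$exact)
  cfg <- fix$clade$config
  cells <- fix$partition$cells
  expect_equal(unname(cells["core"]), cfg$n_core,
               ignore_attr = TRUE)
  expect_equal(unname(cells["G2+G3"]),
               cfg$shared_subsets[[1]]$n_genes, ignore_attr = TRUE)
  n_island_genes <- sum(grepl("^ISL", fix$clade$truth$families$family))
  expect_equal(unname(cells["specific"]),
               cfg$n_specific[1] + n_island_genes, ignore_attr = TRUE)
})

test_that("COG profiles weight multi-category genes fractionally", {
  f <- gene_features(c("g1", "g2", "g3", "g4"), "chr",
                     c(1, 101, 201, 301), c(90, 190, 290, 390),
                     cog = c("G", "E;G", "", "K"))
  prof <- cog_profile(f)
  expect_equal(attr(prof, "n_unannotated"), 1)
  expect_equal(prof$count[prof$category == "G"], 1.5)
  expect_equal(prof$count[prof$category == "E"], 0.5)
  expect_equal(sum(prof$proportion), 1)

  solo <- cog_profile(gene_features("g", "chr", 1, 60, cog = "G"))
  expect_equal(solo$proportion, 1)

  # a set enriched in G by construction shows a positive difference
  bg <- gene_features(paste0("b", 1:20), "chr", seq(1, 96, 5),
                      seq(4, 99, 5),
                      cog = rep(c("G", "E", "K", "C"), 5))
  enriched <- gene_features(paste0("e", 1:10), "chr", seq(1, 46, 5),
                            seq(4, 49, 5),
                            cog = rep(c("G", "G", "G", "G", "E"), 2))
  d <- compare_profiles(cog_profile(enriched), cog_profile(bg))
  expect_gt(d$difference[d$category == "G"], 0)
})

test_that("family counts see only non-pseudo carriers and ignore order", {
  f <- gene_features(paste0("g", 1:12), "chr", seq(1, 111, 10),
                     seq(6, 116, 10),
                     families = c(rep("PF00356", 9), "PF00356;PF01234",
                                  "", "PF09999"),
                     is_pseudo = c(rep(FALSE, 10), FALSE, FALSE))
  f$is_pseudo[10] <- TRUE  # the double-annotated one is a pseudogene
  ann <- toy_annotation(genes = f)
  expect_equal(family_count(ann, "PF00356"), 9)
  expect_equal(family_count(ann, "PF00356", include_pseudo = TRUE), 10)
  expect_equal(family_count(ann, "PF00000"), 0)
  shuffled <- toy_annotation(genes = f[sample(nrow(f)), ])
  expect_equal(family_count(shuffled, "PF00356"), 9)
})

test_that("ortholog maps round-trip through TSV", {
  fix <- clade_fixture()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_ortholog_map(fix$maps$G2, p)
  back <- read_ortholog_map(p, "G1", "G2")
  expect_equal(back$gene_a, fix$maps$G2$gene_a)
  expect_equal(back$gene_b, fix$maps$G2$gene_b)
})
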