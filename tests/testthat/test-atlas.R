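# Atlas track export and tabular reports.

test_that("an annotation without features exports only the karyotype", {
  ann <- genome_annotation("g", replicon("chr", strrep("ACGT", 100)))
  d <- withr::local_tempdir()
  paths <- export_tracks(ann, list(), d)
  expect_equal(basename(paths), "karyotype.txt")
  kar <- readLines(file.path(d, "karyotype.txt"))
  expect_equal(kar, "chr - chr chr 0 400 grey")
})

test_that("cds_strand tracks colour tiles by strand in 0-based half-open", {
  genes <- gene_features(c("g1", "g2", "tn"), "chr", c(11, 101, 201),
                         c(70, 160, 260), strand = c("+", "-", "+"),
                         is_transposase = c(FALSE, FALSE, TRUE))
  ann <- toy_annotation(genes = genes)
  d <- withr::local_tempdir()
  export_tracks(ann, list(track_spec("cds", "cds_strand")), d)
  lines <- readLines(file.path(d, "cds.txt"))
  expect_length(lines, 2)  # transposases are excluded from this track
  expect_equal(lines[1], "chr 10 70 fill_color=red")
  expect_equal(lines[2], "chr 100 160 fill_color=blue")
})

test_that("value tracks carry one line per window", {
  ann <- genome_annotation("g", replicon("chr", strrep("ACGT", 1000)))
  tracks <- list(gc_skew = lapply(ann$replicons, gc_skew, 500))
  d <- withr::local_tempdir()
  export_tracks(ann, list(track_spec("skew", "gc_skew")), d,
                analyses = list(gc_skew = tracks$gc_skew))
  lines <- readLines(file.path(d, "skew.txt"))
  expect_length(lines, nrow(tracks$gc_skew$chr$records))
  expect_error(
    export_tracks(ann, list(track_spec("skew", "gc_skew")), d),
    class = "cladecompare_validation_error")
  expect_error(track_spec("x", "not_a_source"),
               class = "cladecompare_validation_error")
})

test_that("ortholog-presence and custom tracks resolve against analyses", {
  genes <- gene_features(c("g1", "g2"), "chr", c(1, 101), c(60, 160))
  ann <- toy_annotation(genes = genes)
  maps <- list(other = structure(
    data.frame(gene_a = "g1", gene_b = "o1"),
    class = c("ortholog_map", "data.frame")))
  d <- withr::local_tempdir()
  export_tracks(ann,
                list(track_spec("ortho", "ortholog_presence",
                                genome = "other"),
                     track_spec("picked", "custom_gene_set",
                                genes = "g2", color = "orange")),
                d, analyses = list(ortholog_maps = maps))
  expect_equal(readLines(file.path(d, "ortho.txt")),
               "chr 0 60 fill_color=blue")
  expect_equal(readLines(file.path(d, "picked.txt")),
               "chr 100 160 fill_color=orange")
  expect_error(
    export_tracks(ann, list(track_spec("o", "ortholog_presence",
                                       genome = "missing")), d,
                  analyses = list(ortholog_maps = maps)),
    class = "cladecompare_validation_error")
})

test_that("report percentages recompute from counts, one decimal half-up", {
  expect_equal(round_half_up(100 * 2155 / 3436, 1), 62.7)
  expect_equal(round_half_up(100 * 356 / 3436, 1), 10.4)
  expect_equal(round_half_up(100 * 253 / 3436, 1), 7.4)
  expect_equal(round_half_up(0.25, 1), 0.3)  # half rounds up

  n_cds <- 200; n_fun <- 127
  genes <- gene_features(paste0("g", 1:n_cds), "chr", 1:n_cds, 1:n_cds)
  ann <- toy_annotation(genes = genes)
  rep <- summary_report(ann, has_function = c(rep(TRUE, n_fun),
                                              rep(FALSE, n_cds - n_fun)))
  expect_equal(rep$percentages$genes_with_function,
               round_half_up(100 * n_fun / n_cds, 1))
  expect_equal(rep$summary$n_with_function +
                 rep$summary$n_without_function, n_cds)
})

test_that("an empty genome reports zero counts and NA percentages", {
  ann <- genome_annotation("empty", replicon("chr", strrep("ACGT", 50)))
  rep <- summary_report(ann)
  expect_equal(rep$summary$n_genes, 0)
  expect_true(is.na(rep$percentages$genes_with_function))
  d <- withr::local_tempdir()
  write_report(rep, file.path(d, "r.json"), file.path(d, "r.md"))
  js <- jsonlite::read_json(file.path(d, "r.json"))
  expect_equal(js$n_genes, 0)
  expect_null(js$percentages$genes_with_function)
  expect_true(any(grepl("NA", readLines(file.path(d, "r.md")))))
})

test_that("category tables count per genome with a totals row", {
  cats <- c(atpase = "system, ATPase component",
            permease = "system, permease component",
            binding = "substrate binding",
            fused = "fused permease and ATPase")
  counts <- list(Re117 = c(5, 14, 9, 2), TC1 = c(5, 9, 4, 0),
                 FB24 = c(1, 2, 1, 0), A6 = c(3, 5, 3, 0))
  anns <- lapply(names(counts), function(g) {
    k <- counts[[g]]
    prods <- c(
      rep("ABC-type Fe3+/siderophore transport system, ATPase component",
          k[1]),
      rep("ABC-type Fe3+/siderophore transport system, permease component",
          k[2]),
      rep("ABC-type Fe3+/siderophore transport system, substrate binding component",
          k[3]),
      rep("ABC-type transport system, fused permease and ATPase component",
          k[4]))
    n <- length(prods)
    toy_annotation(strrep("ACGT", 2 * n + 10),
                   gene_features(sprintf("%s_%03d", g, seq_len(n)), "chr",
                                 seq_len(n), seq_len(n) + 3,
                                 product = prods),
                   genome_id = g)
  })
  names(anns) <- names(counts)
  tab <- category_table(anns, cats)
  expect_equal(unname(tab["Total", ]), c(30, 18, 4, 11))
  expect_equal(unname(tab[, "Re117"]), c(5, 14, 9, 2, 30))
  expect_equal(colSums(tab[names(cats), ]), tab["Total", ])
})

test_that("track files round-trip coordinates through a reader", {
  genes <- gene_features(c("g1", "g2"), "chr", c(11, 101), c(70, 160))
  ann <- toy_annotation(genes = genes)
  d <- withr::local_tempdir()
  export_tracks(ann, list(track_spec("cds", "cds_strand")), d)
  lines <- read.table(file.path(d, "cds.txt"))
  # 0-based half-open back to 1-based inclusive
  expect_equal(lines$V2 + 1, genes$start)
  expect_equal(lines$V3, genes$end)
})

test_that("replicon expectation checks pass on matching synthetic input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  set.seed(37)
  n <- 5000
  seq <- paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
                      prob = c(0.296, 0.296, 0.204, 0.204)), collapse = "")
  writeLines(c(">synth_chr topology=circular",
               substring(seq, seq(1, n, 70), pmin(seq(70, n + 69, 70), n))),
             fa)
  gc_obs <- round_half_up(100 * gc_fraction_of(seq), 1)
  chk <- verify_replicon_expectations(
    fa, data.frame(replicon_id = "synth_chr", length_bp = n,
                   gc_molpct = gc_obs))
  expect_true(all(chk$ok))
  chk2 <- verify_replicon_expectations(
    fa, data.frame(replicon_id = "synth_chr", length_bp = n + 1,
                   gc_molpct = gc_obs))
  expect_false(any(chk2$ok))
})
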