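# Readers and writers. Internal coordinates are 1-based inclusive
# (GenBank/EMBL feature convention); the only place a different convention
# appears is the atlas track writer, which emits 0-based half-open lines.

#' Read a genome from FASTA (+ feature TSV) or a GenBank flat file
#'
#' For FASTA input the replicon topology is taken from a `topology=circular`
#' token in the description line (default linear) and features come from the
#' TSV table; for GenBank input both sequence and features come from the flat
#' file (LOCUS line topology; CDS/tRNA/rRNA features with simple or
#' `complement()` locations). CDS features without an annotated protein are
#' translated in place from their coordinates with the bacterial genetic
#' code (table 11).
#'
#' @param path FASTA or GenBank file.
#' @param feature_table Optional TSV feature table (required with FASTA if
#'   the genome has features); see [read_feature_table()] for the dialect.
#' @param genome_id Genome identifier; defaults to the file base name.
#' @param translate_missing Translate CDS proteins absent from the input?
#' @return A validated [genome_annotation()].
#' @export
read_genome <- function(path, feature_table = NULL, genome_id = NULL,
                        translate_missing = TRUE) {
  if (!file.exists(path)) {
    stop_validation("genome file not found: ", path)
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fasta|fna|gb|gbk|gbff|dat|embl)$", "",
                     basename(path))
  }
  first <- readLines(path, n = 1L)
  if (startsWith(first, "LOCUS")) {
    parsed <- parse_genbank(path)
    reps <- parsed$replicons
    feats <- parsed$features
  } else if (startsWith(first, ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    reps <- lapply(seq_along(seqs), function(i) {
      header <- names(seqs)[i]
      id <- strsplit(header, "[ \t]+")[[1]][1]
      topo <- if (grepl("topology=circular", header, fixed = TRUE))
        "circular" else "linear"
      replicon(id, as.character(seqs[[i]]), topology = topo)
    })
    feats <- if (is.null(feature_table)) empty_features()
             else read_feature_table(feature_table)
  } else {
    stop_validation("unrecognized genome file format (line 1): ",
                    substr(first, 1, 40))
  }
  ann <- genome_annotation(genome_id, reps, feats)
  if (translate_missing) ann <- fill_proteins(ann)
  ann
}

#' Read the gene-feature TSV dialect
#'
#' Tab-separated with header columns `locus_tag, replicon, start, end,
#' strand, type, pseudo, transposase, product, cog, families, protein`;
#' `cog` and `families` are semicolon-separated sets.
#'
#' @param path TSV path.
#' @return A feature data frame (internal column names).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    stop_validation("feature table not found: ", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE)
  need <- c("locus_tag", "replicon", "start", "end", "strand", "type",
            "pseudo", "transposase", "product", "cog", "families", "protein")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_validation("feature table ", path, " lacks columns: ",
                    paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) return(empty_features())
  st <- suppressWarnings(as.integer(df$start))
  en <- suppressWarnings(as.integer(df$end))
  if (anyNA(st) || anyNA(en)) {
    bad <- which(is.na(st) | is.na(en))[1]
    stop_validation("feature table ", path, ": non-integer coordinates at ",
                    "data line ", bad)
  }
  gene_features(
    locus_tag = df$locus_tag, replicon_id = df$replicon,
    start = st, end = en, strand = df$strand, ftype = df$type,
    is_pseudo = tolower(df$pseudo) %in% c("1", "true", "yes"),
    is_transposase = tolower(df$transposase) %in% c("1", "true", "yes"),
    product = df$product, cog = df$cog, families = df$families,
    protein = df$protein
  )
}

#' Write a genome as FASTA plus feature TSV
#'
#' Inverse of [read_genome()] for the FASTA+TSV route: the description line
#' carries a `topology=` token so topology round-trips.
#'
#' @param annotation A `genome_annotation`.
#' @param fasta_path,feature_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(annotation, fasta_path, feature_path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(annotation$replicons, function(r) r$sequence, character(1)))
  names(seqs) <- vapply(annotation$replicons, function(r)
    paste0(r$id, " topology=", r$topology), character(1))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  write_feature_table(annotation$features, feature_path)
  invisible(c(fasta_path, feature_path))
}

#' @rdname read_feature_table
#' @param features A feature data frame.
#' @export
write_feature_table <- function(features, path) {
  out <- data.frame(
    locus_tag = features$locus_tag, replicon = features$replicon_id,
    start = features$start, end = features$end, strand = features$strand,
    type = features$ftype,
    pseudo = ifelse(features$is_pseudo, "1", "0"),
    transposase = ifelse(features$is_transposase, "1", "0"),
    product = features$product, cog = features$cog,
    families = features$families, protein = features$protein,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# translate CDS proteins missing from the feature table, bacterial code 11;
# internal stops in a non-pseudo CDS warn (annotation files contain them)
fill_proteins <- function(annotation) {
  f <- annotation$features
  idx <- which(f$ftype == "CDS" & !nzchar(f$protein) & !f$is_pseudo)
  for (i in idx) {
    rep <- annotation$replicons[[f$replicon_id[i]]]
    nt <- substr(rep$sequence, f$start[i], f$end[i])
    if (f$strand[i] == "-") nt <- revcomp(nt)
    if (nchar(nt) %% 3 != 0) {
      warning(sprintf("CDS %s length not divisible by 3; not translated",
                      f$locus_tag[i]), call. = FALSE)
      next
    }
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt),
      genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "X"))
    aa <- sub("\\*$", "", aa)
    if (grepl("*", aa, fixed = TRUE)) {
      warning(sprintf("internal stop codon in non-pseudo CDS %s",
                      f$locus_tag[i]), call. = FALSE)
      aa <- gsub("*", "X", aa, fixed = TRUE)
    }
    f$protein[i] <- aa
  }
  annotation$features <- f
  annotation
}

# --- minimal GenBank flat-file reader -------------------------------------
# Supports the subset needed for bacterial annotation exchange: LOCUS
# topology, CDS/tRNA/rRNA/gene features with `start..end` or
# `complement(start..end)` locations, /locus_tag /product /pseudo
# /translation qualifiers, ORIGIN sequence. Joined locations are not
# supported (bacterial CDSs are contiguous).
parse_genbank <- function(path) {
  lines <- readLines(path)
  rec_starts <- which(startsWith(lines, "LOCUS"))
  if (!length(rec_starts)) stop_validation("no LOCUS line in ", path)
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  replicons <- list()
  feats <- list()
  for (r in seq_along(rec_starts)) {
    block <- lines[rec_starts[r]:rec_ends[r]]
    locus <- strsplit(block[1], "[ \t]+")[[1]]
    rep_id <- locus[2]
    topo <- if (any(tolower(locus) == "circular")) "circular" else "linear"
    ori <- which(startsWith(block, "ORIGIN"))
    if (!length(ori)) {
      stop_validation("GenBank record ", rep_id, ": no ORIGIN section ",
                      "(line ", rec_starts[r], ")")
    }
    seq_lines <- block[(ori[1] + 1L):length(block)]
    seq_lines <- seq_lines[!startsWith(seq_lines, "//")]
    seq <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
    replicons[[rep_id]] <- replicon(rep_id, seq, topology = topo)

    fstart <- which(startsWith(block, "FEATURES"))
    if (length(fstart)) {
      fblock <- block[(fstart[1] + 1L):(ori[1] - 1L)]
      feats[[rep_id]] <- parse_genbank_features(fblock, rep_id, path)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else empty_features()
  rownames(features) <- NULL
  list(replicons = replicons, features = features)
}

parse_genbank_features <- function(fblock, rep_id, path) {
  key_line <- grepl("^     \\S", fblock)
  idx <- which(key_line)
  rows <- list()
  auto <- 0L
  for (k in seq_along(idx)) {
    from <- idx[k]
    to <- if (k < length(idx)) idx[k + 1] - 1L else length(fblock)
    chunk <- fblock[from:to]
    parts <- strsplit(sub("^\\s+", "", chunk[1]), "[ \t]+")[[1]]
    key <- parts[1]
    if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature")) next
    loc <- paste(parts[-1], collapse = "")
    strand <- if (grepl("complement", loc, fixed = TRUE)) "-" else "+"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
    if (length(nums) < 2L) {
      stop_validation("unparseable location '", loc, "' in ", path)
    }
    quals <- paste(sub("^\\s+", "", chunk[-1]), collapse = "\n")
    get_qual <- function(name) {
      m <- regmatches(quals,
        regexpr(sprintf('/%s="[^"]*"', name), quals))
      if (!length(m)) return("")
      gsub("\n", " ", sub(sprintf('/%s="([^"]*)"', name), "\\1", m))
    }
    tag <- get_qual("locus_tag")
    if (!nzchar(tag)) {
      auto <- auto + 1L
      tag <- sprintf("%s_f%04d", rep_id, auto)
    }
    product <- get_qual("product")
    rows[[length(rows) + 1L]] <- gene_features(
      locus_tag = tag, replicon_id = rep_id,
      start = as.integer(nums[1]), end = as.integer(nums[length(nums)]),
      strand = strand,
      ftype = if (key == "misc_feature") "other" else key,
      is_pseudo = grepl("/pseudo", quals, fixed = TRUE),
      is_transposase = grepl("transposase", product, ignore.case = TRUE),
      product = product, protein = get_qual("translation")
    )
  }
  if (!length(rows)) return(empty_features())
  do.call(rbind, rows)
}

#' Read/write a window track as 4-column TSV
#'
#' Columns `replicon, start, end, value`; missing values (e.g. all-N
#' windows) serialize as `NA`.
#'
#' @param track A `window_track` (see [windowed_gc()]).
#' @param path Output/input path.
#' @return `write_window_track()` the path, invisibly;
#'   `read_window_track()` a `window_track`.
#' @export
write_window_track <- function(track, path) {
  out <- data.frame(replicon = track$replicon_id,
                    start = track$records$start,
                    end = track$records$end,
                    value = track$records$value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_track
#' @export
read_window_track <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  structure(list(replicon_id = as.character(df$replicon[1]),
                 window_bp = NA_integer_,
                 records = data.frame(start = as.integer(df$start),
                                      end = as.integer(df$end),
                                      value = as.numeric(df$value))),
            class = "window_track")
}
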