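# Gene-order synteny: conserved gene trains between two chromosomes found
# by local dynamic programming over gene indices, allowing gaps and
# homolog-level "mismatches". Unrelated gene pairs can never occupy one
# alignment column; they must be gapped.

#' Ordered gene list of a replicon
#'
#' @param annotation A `genome_annotation`.
#' @param replicon_id Which replicon.
#' @param exclude_transposases Drop transposase genes (default TRUE; IS
#'   elements recombine and would fake collinearity breaks).
#' @param types Feature types included (default CDS).
#' @param include_pseudo Include pseudogenes (default FALSE).
#' @return Object of class `gene_order`: data.frame `(locus_tag, start,
#'   end, strand)` sorted by start (ties by locus_tag).
#' @export
build_gene_order <- function(annotation, replicon_id,
                             exclude_transposases = TRUE,
                             types = "CDS", include_pseudo = FALSE) {
  if (!replicon_id %in% names(annotation$replicons)) {
    stop_validation("no replicon '", replicon_id, "' in genome ",
                    annotation$genome_id)
  }
  f <- annotation$features
  keep <- f$replicon_id == replicon_id & f$ftype %in% types &
    (!exclude_transposases | !f$is_transposase) &
    (include_pseudo | !f$is_pseudo)
  g <- f[keep, c("locus_tag", "start", "end", "strand"), drop = FALSE]
  g <- g[order(g$start, g$locus_tag), , drop = FALSE]
  rownames(g) <- NULL
  structure(g, class = c("gene_order", "data.frame"),
            replicon_id = replicon_id, genome_id = annotation$genome_id)
}

#' Gene-pair relations for synteny alignment
#'
#' Builds the ortholog/homolog relation used to score alignment columns.
#' Orthologs come from a reciprocal-best-hit map; homologs are pairs
#' related by a best hit in either direction under the same thresholds but
#' without the reciprocity requirement. Every ortholog pair is also a
#' homolog pair.
#'
#' @param orthologs An `ortholog_map` (A genes in `gene_a`).
#' @param best_ab,best_ba Optional best-hit maps used to add homolog-only
#'   pairs.
#' @return Object of class `gene_relations` with `ortho` and `homol` pair
#'   key sets.
#' @export
gene_relations <- function(orthologs, best_ab = NULL, best_ba = NULL) {
  key <- function(a, b) paste(a, b, sep = "\r")
  ortho <- key(orthologs$gene_a, orthologs$gene_b)
  homol <- ortho
  if (!is.null(best_ab) && nrow(best_ab)) {
    homol <- c(homol, key(best_ab$query_id, best_ab$subject_id))
  }
  if (!is.null(best_ba) && nrow(best_ba)) {
    homol <- c(homol, key(best_ba$subject_id, best_ba$query_id))
  }
  structure(list(ortho = unique(ortho), homol = unique(homol)),
            class = "gene_relations")
}

# relation of each (a, b) pair: 2 = ortholog, 1 = homolog only, 0 = none
relation_code <- function(relations, a, b) {
  k <- paste(a, b, sep = "\r")
  out <- integer(length(k))
  out[k %in% relations$homol] <- 1L
  out[k %in% relations$ortho] <- 2L
  out
}

#' Conserved gene trains between two gene orders
#'
#' Local dynamic programming over the two gene orders. A column aligning
#' genes (a, b) scores `match` if the pair is orthologous, `mismatch` if
#' it is homologous but not orthologous, and is forbidden otherwise; genes
#' skipped on either side score `gap`. The alignment is run against the
#' second order as given (orientation `same`) and reversed (orientation
#' `inverted`). Blocks are extracted greedily by descending score — ties
#' broken by smaller start index in the first order, then by orientation
#' `same` — with genes of accepted blocks masked so no gene appears twice.
#' Blocks with fewer than `min_block_matches` ortholog columns or score
#' below `min_score` are discarded.
#'
#' @param order_a,order_b `gene_order` objects (or data.frames with
#'   `locus_tag` and `strand`).
#' @param relations A `gene_relations` object.
#' @param match,mismatch,gap Column scores (defaults +2, +1, -1).
#' @param min_block_matches Minimum ortholog columns per block (default 3).
#' @param min_score Minimum block score (default 4).
#' @param strand_aware When both orders carry strand information (default
#'   TRUE), a same-orientation column also requires the two genes to lie
#'   on the same strand and an inverted column requires opposite strands —
#'   the gene-level signature of a true inversion, and what keeps a large
#'   collinear block from swallowing single genes out of a locally
#'   inverted segment.
#' @param wrap_b Double the second order so blocks spanning a circular
#'   origin are caught (default FALSE).
#' @return List of `synteny_block` objects, each a list with `orientation`,
#'   `score`, `n_matches`, `n_mismatches`, `n_gaps`, `columns` (data.frame
#'   `type, gene_a, gene_b`), index anchors `a_start`, `a_end`, `b_start`,
#'   `b_end` (positions in the input orders), and coordinate anchors when
#'   the orders carry coordinates.
#' @export
align_gene_trains <- function(order_a, order_b, relations,
                              match = 2, mismatch = 1, gap = -1,
                              min_block_matches = 3, min_score = 4,
                              strand_aware = TRUE, wrap_b = FALSE) {
  a <- order_a$locus_tag
  b <- order_b$locus_tag
  strand_a <- order_a$strand
  strand_b <- order_b$strand
  strand_aware <- strand_aware && !is.null(strand_a) && !is.null(strand_b)
  nb0 <- length(b)
  b_index <- seq_along(b)
  if (wrap_b) {
    b <- c(b, b)
    b_index <- c(b_index, seq_len(nb0))
    if (strand_aware) strand_b <- c(strand_b, strand_b)
  }
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(list())
  # column-score matrices for both orientations (NA = forbidden column)
  rel <- matrix(relation_code(relations, rep(a, times = nb),
                              rep(b, each = na)), nrow = na)
  smat_fwd <- matrix(NA_real_, na, nb)
  smat_fwd[rel == 2L] <- match
  smat_fwd[rel == 1L] <- mismatch
  smat_rev <- smat_fwd[, nb:1, drop = FALSE]
  rel_rev <- rel[, nb:1, drop = FALSE]
  if (strand_aware) {
    same_strand <- outer(strand_a, strand_b, `==`)
    smat_fwd[!same_strand] <- NA_real_
    smat_rev[same_strand[, nb:1, drop = FALSE]] <- NA_real_
  }

  used_a <- rep(FALSE, na)
  used_b <- rep(FALSE, nb0)
  blocks <- list()
  repeat {
    mask_b_fwd <- used_b[b_index]
    cand_f <- best_local_block(smat_fwd, rel, used_a, mask_b_fwd, gap)
    cand_r <- best_local_block(smat_rev, rel_rev, used_a, rev(mask_b_fwd), gap)
    cand <- pick_candidate(cand_f, cand_r)
    if (is.null(cand) || cand$score < min_score) break
    # translate column indices of the reversed matrix back to input order
    jmap <- if (cand$orientation == "inverted") nb + 1L - cand$cols_j
            else cand$cols_j
    gene_b_idx <- b_index[jmap]
    # mask aligned genes (match/mismatch columns) whether or not the
    # block is reported; gap-skipped genes stay available — being jumped
    # over by a chain does not place a gene in that block
    aligned_col <- cand$col_type %in% c("match", "mismatch")
    used_a[cand$cols_i[aligned_col]] <- TRUE
    used_b[gene_b_idx[aligned_col]] <- TRUE
    if (cand$n_matches < min_block_matches) next
    cols <- data.frame(
      type = cand$col_type,
      gene_a = ifelse(is.na(cand$cols_i), NA_character_, a[cand$cols_i]),
      gene_b = ifelse(is.na(jmap), NA_character_, b[jmap]),
      stringsAsFactors = FALSE)
    ai <- cand$cols_i[!is.na(cand$cols_i)]
    bi <- gene_b_idx[!is.na(jmap)]
    blk <- list(orientation = cand$orientation, score = cand$score,
                n_matches = cand$n_matches, n_mismatches = cand$n_mismatches,
                n_gaps = cand$n_gaps, columns = cols,
                a_start = min(ai), a_end = max(ai),
                b_start = min(bi), b_end = max(bi))
    if (!is.null(order_a$start)) {
      blk$a_coord_start <- min(order_a$start[ai])
      blk$a_coord_end <- max(order_a$end[ai])
    }
    if (!is.null(order_b$start)) {
      blk$b_coord_start <- min(order_b$start[bi])
      blk$b_coord_end <- max(order_b$end[bi])
    }
    blocks[[length(blocks) + 1L]] <- structure(blk, class = "synteny_block")
  }
  blocks
}

# pick the higher-scoring candidate; ties -> smaller A start, then 'same'
pick_candidate <- function(f, r) {
  if (is.null(f) && is.null(r)) return(NULL)
  if (is.null(r)) { f$orientation <- "same"; return(f) }
  if (is.null(f)) { r$orientation <- "inverted"; return(r) }
  fa <- min(f$cols_i, na.rm = TRUE); ra <- min(r$cols_i, na.rm = TRUE)
  take_f <- f$score > r$score || (f$score == r$score && fa <= ra)
  if (take_f) { f$orientation <- "same"; f } else { r$orientation <- "inverted"; r }
}

# best-scoring local alignment over gene indices; smat holds column scores
# (NA = forbidden), rel the relation codes, gap the per-skipped-gene score.
# Returns NULL when no positive-score block exists among unmasked genes.
best_local_block <- function(smat, rel, mask_i, mask_j, gap) {
  na <- nrow(smat); nb <- ncol(smat)
  H <- matrix(0, na + 1L, nb + 1L)
  P <- matrix(0L, na + 1L, nb + 1L)  # 1 diag, 2 up (gap in B), 3 left
  s <- smat
  if (any(mask_i)) s[mask_i, ] <- NA_real_
  if (any(mask_j)) s[, mask_j] <- NA_real_
  for (i in seq_len(na)) {
    Hi1 <- H[i, ]; Hi <- H[i + 1L, ]
    for (j in seq_len(nb)) {
      diag <- if (is.na(s[i, j])) -Inf else Hi1[j] + s[i, j]
      up <- Hi1[j + 1L] + gap
      left <- Hi[j] + gap
      best <- max(0, diag, up, left)
      Hi[j + 1L] <- best
      P[i + 1L, j + 1L] <-
        if (best == 0) 0L
        else if (best == diag) 1L
        else if (best == up) 2L
        else 3L
    }
    H[i + 1L, ] <- Hi
  }
  top <- max(H)
  if (top <= 0) return(NULL)
  # end cell: highest score; ties -> smallest i then smallest j
  ends <- which(H == top, arr.ind = TRUE)
  ends <- ends[order(ends[, 1], ends[, 2]), , drop = FALSE]
  i <- ends[1, 1]; j <- ends[1, 2]
  cols_i <- integer(0); cols_j <- integer(0); col_type <- character(0)
  while (i > 1L && j > 1L && H[i, j] > 0) {
    move <- P[i, j]
    if (move == 0L) break
    if (move == 1L) {
      cols_i <- c(i - 1L, cols_i); cols_j <- c(j - 1L, cols_j)
      col_type <- c(if (rel[i - 1L, j - 1L] == 2L) "match" else "mismatch",
                    col_type)
      i <- i - 1L; j <- j - 1L
    } else if (move == 2L) {
      cols_i <- c(i - 1L, cols_i); cols_j <- c(NA_integer_, cols_j)
      col_type <- c("gap_b", col_type)
      i <- i - 1L
    } else {
      cols_i <- c(NA_integer_, cols_i); cols_j <- c(j - 1L, cols_j)
      col_type <- c("gap_a", col_type)
      j <- j - 1L
    }
  }
  list(score = top, cols_i = cols_i, cols_j = cols_j, col_type = col_type,
       n_matches = sum(col_type == "match"),
       n_mismatches = sum(col_type == "mismatch"),
       n_gaps = sum(col_type %in% c("gap_a", "gap_b")))
}

#' @export
print.synteny_block <- function(x, ...) {
  cat(sprintf("<synteny_block> %s, score %.0f: %d match / %d mismatch / %d gap; A[%d-%d] B[%d-%d]\n",
              x$orientation, x$score, x$n_matches, x$n_mismatches, x$n_gaps,
              x$a_start, x$a_end, x$b_start, x$b_end))
  invisible(x)
}

#' Export synteny blocks as TSV
#'
#' One row per block: id, orientation, score, column tallies, index and
#' coordinate anchors, and the column list as compact text
#' (`a1=b1,a2=b2,a3-,-b4,...`; `-` marks the gapped side).
#'
#' @param blocks List of `synteny_block`s.
#' @param path Output path.
#' @export
write_synteny_blocks <- function(blocks, path) {
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    colstr <- paste(ifelse(is.na(b$columns$gene_a), "-", b$columns$gene_a),
                    ifelse(is.na(b$columns$gene_b), "-", b$columns$gene_b),
                    sep = "=", collapse = ",")
    data.frame(block_id = i, orientation = b$orientation, score = b$score,
               n_match = b$n_matches, n_mismatch = b$n_mismatches,
               n_gap = b$n_gaps,
               a_start = b$a_start, a_end = b$a_end,
               b_start = b$b_start, b_end = b$b_end,
               columns = colstr, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block_id = integer(0), orientation = character(0),
               score = numeric(0), n_match = integer(0),
               n_mismatch = integer(0), n_gap = integer(0),
               a_start = integer(0), a_end = integer(0),
               b_start = integer(0), b_end = integer(0),
               columns = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dot-plot records for an ortholog map
#'
#' One record per ortholog pair at the two gene midpoints, coloured by
#' strand agreement (red = same orientation, blue = reverse), the data
#' behind the classic synteny dot plot.
#'
#' @param map An `ortholog_map`.
#' @param annot_a,annot_b The two `genome_annotation`s.
#' @return data.frame `(gene_a, gene_b, pos_a, pos_b, color)`.
#' @export
dotplot_export <- function(map, annot_a, annot_b) {
  fa <- annot_a$features; fb <- annot_b$features
  ia <- match(map$gene_a, fa$locus_tag)
  ib <- match(map$gene_b, fb$locus_tag)
  if (anyNA(ia) || anyNA(ib)) {
    stop_validation("ortholog pair gene(s) missing coordinates: ",
                    paste(utils::head(c(map$gene_a[is.na(ia)],
                                        map$gene_b[is.na(ib)]), 5),
                          collapse = ", "))
  }
  data.frame(
    gene_a = map$gene_a, gene_b = map$gene_b,
    pos_a = (fa$start[ia] + fa$end[ia]) / 2,
    pos_b = (fb$start[ib] + fb$end[ib]) / 2,
    color = ifelse(fa$strand[ia] == fb$strand[ib], "red", "blue"),
    stringsAsFactors = FALSE)
}
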