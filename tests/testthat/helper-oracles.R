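# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package code paths they check.

# --- Smith-Waterman (Gotoh affine) on two amino-acid strings ------------
# Returns the best local alignment score under BLOSUM62 with gap open 11 /
# extend 1 (first gapped residue costs 12, like the package aligner).
oracle_sw_score <- function(a, b) {
  mat <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in A (move along B)
  F <- matrix(NEG, n + 1, m + 1)  # gap in B (move along A)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - 12, E[i, j - 1] - 1)
      F[i, j] <- max(H[i - 1, j] - 12, F[i - 1, j] - 1)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# --- brute-force IUPAC motif scan ---------------------------------------
IUPAC_TAB <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

oracle_motif_positions <- function(subject, pattern, max_mismatch = 0) {
  sv <- strsplit(subject, "")[[1]]
  pv <- strsplit(pattern, "")[[1]]
  L <- length(pv); n <- length(sv)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (p in seq_len(n - L + 1)) {
    mm <- 0L
    for (k in seq_len(L)) {
      allowed <- strsplit(IUPAC_TAB[[pv[k]]], "")[[1]]
      if (!(sv[p + k - 1] %in% allowed)) mm <- mm + 1L
      if (mm > max_mismatch) break
    }
    if (mm <= max_mismatch) hits <- c(hits, p)
  }
  hits
}

# --- collinear-chain enumeration for synteny ----------------------------
# Best chain of columns over a score matrix s (NA = forbidden column),
# columns strictly increasing in both indices, internal skips costing
# `gap` per skipped gene. This is the pair-chaining formulation, a
# different recurrence from the package's alignment-matrix DP.
oracle_best_chain <- function(s, gap = -1) {
  idx <- which(!is.na(s), arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  best_end <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    prev <- 0
    for (l in seq_len(k - 1)) {
      pi <- idx[l, 1]; pj <- idx[l, 2]
      if (pi < i && pj < j) {
        cand <- best_end[l] + gap * ((i - pi - 1) + (j - pj - 1))
        if (cand > prev) prev <- cand
      }
    }
    best_end[k] <- s[idx[k, 1], idx[k, 2]] + max(0, prev)
  }
  max(0, max(best_end))
}

# effective column-score matrices for a random synteny case, mirroring
# the documented column-validity rule (ortholog/homolog scores, optional
# strand agreement per orientation)
oracle_score_matrices <- function(rel, strand_a, strand_b,
                                  match = 2, mismatch = 1,
                                  strand_aware = TRUE) {
  na <- nrow(rel); nb <- ncol(rel)
  fwd <- matrix(NA_real_, na, nb)
  fwd[rel == 2L] <- match
  fwd[rel == 1L] <- mismatch
  rev_ <- fwd[, rev(seq_len(nb)), drop = FALSE]
  if (strand_aware) {
    same <- outer(strand_a, strand_b, `==`)
    fwd[!same] <- NA_real_
    rev_[same[, rev(seq_len(nb)), drop = FALSE]] <- NA_real_
  }
  list(fwd = fwd, rev = rev_)
}

# --- brute-force best-hit selection -------------------------------------
oracle_best_hits <- function(hits, evalue_max = 1e-3, min_overlap = 0.8,
                             exclude = character(0)) {
  out <- list()
  for (q in sort(unique(hits$query_id))) {
    if (q %in% exclude) next
    cand <- hits[hits$query_id == q, , drop = FALSE]
    cand <- cand[cand$evalue < evalue_max &
                   cand$aln_length / cand$query_len > min_overlap &
                   cand$subject_id != q &
                   !(cand$subject_id %in% exclude), , drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[order(cand$evalue, -cand$bitscore, cand$subject_id), ,
                 drop = FALSE]
    out[[q]] <- cand[1, , drop = FALSE]
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
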