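# Progressive multiple alignment: pairwise NW distances -> UPGMA guide tree
# -> profile-profile merges. Used for both DNA (barcode MSA) and protein
# (codon-aware alignment) sequences; deterministic throughout.

#' Progressive multiple sequence alignment
#'
#' Pairwise global alignments give percent-identity distances, a UPGMA guide
#' tree fixes the merge order, and profiles are merged with an affine-gap
#' profile aligner. Deterministic: ties in the guide tree and traceback are
#' broken by fixed preference.
#'
#' @param seqs named character vector (or list) of sequences (>= 2,
#'   non-empty).
#' @param alphabet residue alphabet; defaults to DNA. Residues outside the
#'   alphabet are treated as mismatching everything.
#' @param match,mismatch,gap_open,gap_ext scoring parameters.
#' @return an object of class `msa`: a character matrix (rows = sequences,
#'   named) of single characters with `"-"` gaps.
#' @export
build_msa <- function(seqs, alphabet = c("A", "C", "G", "T"),
                      match = 2, mismatch = -1, gap_open = 10, gap_ext = 2) {
  seqs <- unlist(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (any(!nchar(seqs))) stop("empty sequence")
  seqs <- toupper(seqs)
  n <- length(seqs)
  if (n == 1L) {
    m <- matrix(seq_chars(seqs[[1]]), nrow = 1,
                dimnames = list(names(seqs), NULL))
    return(structure(m, class = "msa"))
  }
  # guide distances from pairwise alignments
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- .nw_affine_cpp(seqs[[i]], seqs[[j]], match, mismatch, gap_open, gap_ext)
    ca <- seq_chars(al$a); cb <- seq_chars(al$b)
    ident <- mean(ca == cb)
    d[i, j] <- d[j, i] <- 1 - ident
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")

  profiles <- lapply(seq_len(n), function(i) {
    matrix(seq_chars(seqs[[i]]), nrow = 1, dimnames = list(names(seqs)[i], NULL))
  })
  merged <- vector("list", nrow(hc$merge))
  get_aln <- function(k) if (k < 0) profiles[[-k]] else merged[[k]]
  for (s in seq_len(nrow(hc$merge))) {
    a <- get_aln(hc$merge[s, 1]); b <- get_aln(hc$merge[s, 2])
    merged[[s]] <- merge_profiles(a, b, alphabet, match, mismatch,
                                  gap_open, gap_ext)
  }
  out <- merged[[length(merged)]]
  out <- out[names(seqs), , drop = FALSE]  # stable row order = input order
  # leave-one-out refinement corrects locally suboptimal gap placements the
  # greedy progressive merge can leave behind
  if (n > 2L) {
    for (pass in 1:2) {
      for (i in seq_len(n)) {
        row <- out[i, , drop = FALSE]
        row <- row[, row[1, ] != "-", drop = FALSE]
        rest <- out[-i, , drop = FALSE]
        rest <- rest[, colSums(rest != "-") > 0L, drop = FALSE]
        out <- merge_profiles(rest, row, alphabet, match, mismatch,
                              gap_open, gap_ext)[names(seqs), , drop = FALSE]
      }
    }
  }
  structure(normalize_msa_gaps(out), class = "msa")
}

# Canonicalize gap placement: within each row, slide a gap run left whenever
# the residue before the run equals the residue after it (content-preserving
# moves inside homopolymer stretches), then drop all-gap columns. Removes
# spurious "private" gap columns created by equivalent-score tracebacks in
# independent profile merges.
normalize_msa_gaps <- function(m) {
  repeat {
    any_change <- FALSE
    # merge adjacent complementary columns (no row occupies both): two
    # half-gap columns become one substitution column, the representation an
    # optimal aligner prefers whenever a gap costs more than a mismatch
    j <- 1L
    while (j < ncol(m)) {
      both <- m[, j] != "-" & m[, j + 1L] != "-"
      if (!any(both)) {
        m[, j] <- ifelse(m[, j] != "-", m[, j], m[, j + 1L])
        m <- m[, -(j + 1L), drop = FALSE]
        any_change <- TRUE
      } else j <- j + 1L
    }
    # reposition split gaps: columns j and k both carry gaps for disjoint row
    # sets with gap-free columns between them; moving the minority gaps onto
    # the majority column is accepted when it does not add mismatches
    gapped_cols <- which(colSums(m == "-") > 0L)
    for (j in gapped_cols) {
      if (j > ncol(m)) break
      for (k in (j + 1L):min(j + 8L, ncol(m))) {
        if (k > ncol(m)) break
        gj <- m[, j] == "-"; gk <- m[, k] == "-"
        if (!any(gj) || !any(gk) || any(gj & gk)) next
        if (k > j + 1L &&
            any(m[, (j + 1L):(k - 1L), drop = FALSE] == "-")) break
        blk <- m[, j:k, drop = FALSE]
        t_is_k <- sum(gk) >= sum(gj)
        new_blk <- blk
        movers <- if (t_is_k) which(gj) else which(gk)
        for (r in movers) {
          bases <- blk[r, ][blk[r, ] != "-"]
          new_blk[r, ] <- if (t_is_k) c(bases, "-") else c("-", bases)
        }
        mism <- function(x) {
          sum(apply(x, 2, function(col) {
            col <- col[col != "-"]
            if (!length(col)) 0L else sum(col != names(which.max(table(col))))
          }))
        }
        if (mism(new_blk) <= mism(blk)) {
          m[, j:k] <- new_blk
          any_change <- TRUE
        }
        break  # handle one partner per j; outer loop re-runs to fixpoint
      }
    }
    keep <- colSums(m != "-") > 0L
    if (!all(keep)) { m <- m[, keep, drop = FALSE]; any_change <- TRUE }
    if (!any_change) break
  }
  m
}

merge_profiles <- function(a, b, alphabet, match, mismatch, gap_open, gap_ext) {
  pa <- profile_matrix(a, alphabet)
  pb <- profile_matrix(b, alphabet)
  path <- .profile_align_cpp(pa, pb, match, mismatch, gap_open, gap_ext)
  L <- length(path)
  out <- matrix("-", nrow(a) + nrow(b), L,
                dimnames = list(c(rownames(a), rownames(b)), NULL))
  ia <- 0L; ib <- 0L
  for (k in seq_len(L)) {
    if (path[k] != 2L) { ia <- ia + 1L; out[seq_len(nrow(a)), k] <- a[, ia] }
    if (path[k] != 1L) { ib <- ib + 1L; out[nrow(a) + seq_len(nrow(b)), k] <- b[, ib] }
  }
  out
}

profile_matrix <- function(aln, alphabet) {
  R <- length(alphabet)
  pm <- matrix(0, R + 1L, ncol(aln))
  for (r in seq_len(R)) pm[r, ] <- colMeans(aln == alphabet[r])
  pm[R + 1L, ] <- colMeans(aln == "-")
  pm
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", nrow(x), ncol(x)))
  invisible(x)
}

# collapse an msa matrix to gapped strings
msa_strings <- function(m) apply(m, 1, paste, collapse = "")
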