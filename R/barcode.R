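#' Species-diagnostic sites in a multiple alignment
#'
#' A diagnostic SNP is an alignment column where every sequence has an
#' unambiguous base, exactly one species differs, and the remaining species
#' are unanimous. A diagnostic indel is a maximal run of columns in which the
#' same single species is gapped while all others hold bases (or vice versa:
#' a private insertion); each such run counts as ONE indel site. Columns
#' containing an ambiguous base are skipped.
#'
#' @param msa an [build_msa()] result (or character matrix, rows = species).
#' @return a tibble: `column` (1-based MSA start column), `kind`
#'   (`"SNP"`/`"indel"`), `species`, `state`, `background_state`, `width`.
#' @export
diagnostic_sites <- function(msa) {
  m <- unclass(msa)
  stopifnot(is.matrix(m))
  if (nrow(m) < 3L) stop("diagnostic sites need >= 3 species (a background of >= 2)")
  species <- rownames(m)
  L <- ncol(m)
  bases <- c("A", "C", "G", "T")
  snps <- list()
  for (j in seq_len(L)) {
    col <- m[, j]
    if (!all(col %in% bases)) next  # gaps and ambiguity codes handled elsewhere
    tab <- table(col)
    if (length(tab) == 2L && min(tab) == 1L) {
      minor <- names(tab)[which.min(tab)]
      sp <- species[col == minor]
      snps[[length(snps) + 1L]] <- tibble::tibble(
        column = j, kind = "SNP", species = sp, state = minor,
        background_state = names(tab)[which.max(tab)], width = 1L)
    }
  }
  # private gap runs: per column, is exactly one species gapped (others all
  # bases), or exactly one species based (others all gapped)?
  gap <- m == "-"
  base_ok <- matrix(m %in% bases, nrow(m))
  owner <- rep(NA_character_, L)
  mode <- rep(NA_character_, L)
  for (j in seq_len(L)) {
    g <- gap[, j]; bk <- base_ok[, j]
    if (sum(g) == 1L && all(bk[!g])) {
      owner[j] <- species[g]; mode[j] <- "deletion"
    } else if (sum(g) == nrow(m) - 1L && bk[!g]) {
      owner[j] <- species[!g]; mode[j] <- "insertion"
    }
  }
  key <- ifelse(is.na(owner), "", paste(owner, mode))
  r <- rle(key)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  indels <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] == "") next
    j0 <- starts[k]; j1 <- ends[k]
    sp <- owner[j0]
    del <- mode[j0] == "deletion"
    state <- if (del) strrep("-", j1 - j0 + 1L) else
      paste(m[sp, j0:j1], collapse = "")
    others <- setdiff(species, sp)
    bgs <- unique(apply(m[others, j0:j1, drop = FALSE], 1, paste, collapse = ""))
    indels[[length(indels) + 1L]] <- tibble::tibble(
      column = j0, kind = "indel", species = sp, state = state,
      background_state = if (length(bgs) == 1L) bgs else NA_character_,
      width = j1 - j0 + 1L)
  }
  out <- dplyr::bind_rows(c(snps, indels))
  if (nrow(out) == 0L) {
    return(tibble::tibble(column = integer(), kind = character(),
                          species = character(), state = character(),
                          background_state = character(), width = integer()))
  }
  dplyr::arrange(out, .data$column)
}

#' Search for conserved primer pairs bounding diagnostic products
#'
#' Emulates strict zero-mismatch primer discovery: enumerate alignment
#' windows of primer length that are fully conserved across all species (no
#' substitutions, no gaps) and pass a GC-fraction filter, then pair windows
#' whose enclosed product length lies within `[min_len, max_len]` in every
#' species. Candidates are scored by the number of enclosed diagnostic
#' sites, and a greedy pass keeps non-overlapping top candidates.
#'
#' @param msa a [build_msa()] result over one locus.
#' @param min_len,max_len allowed product length (including primers), nt.
#' @param primer_len primer length, nt (18-27 typical).
#' @param gc_range allowed primer GC fraction.
#' @param max_candidates cap on reported non-overlapping candidates.
#' @param region label for the source locus.
#' @return an object of class `marker_candidates`: tibble `name`, `region`,
#'   `forward_primer`, `reverse_primer`, `fwd_column`, `rev_column`,
#'   `n_sites`, `product_min`, `product_max`; attributes `sites` (the
#'   diagnostic site table) and `products` (per-species product lengths).
#' @export
primer_search <- function(msa, min_len = 100L, max_len = 1000L,
                          primer_len = 20L, gc_range = c(0.3, 0.7),
                          max_candidates = 10L, region = "locus") {
  m <- unclass(msa)
  stopifnot(is.matrix(m), min_len > 0L, max_len > min_len)
  L <- ncol(m)
  bases <- c("A", "C", "G", "T")
  conserved <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    all(col %in% bases) && length(unique(col)) == 1L
  }, logical(1))
  # window fully conserved = all primer_len columns conserved
  if (L < primer_len || !any(conserved)) {
    warning("no conserved primer window", call. = FALSE)
    return(empty_markers(region))
  }
  run_ok <- stats::filter(as.numeric(conserved), rep(1, primer_len),
                          sides = 1)
  win_starts <- which(!is.na(run_ok) & run_ok == primer_len) - primer_len + 1L
  if (!length(win_starts)) {
    warning("no conserved primer window", call. = FALSE)
    return(empty_markers(region))
  }
  consensus <- m[1, ]
  win_seq <- vapply(win_starts, function(s)
    paste(consensus[s:(s + primer_len - 1L)], collapse = ""), character(1))
  gc <- vapply(win_seq, gc_content, numeric(1))
  keep <- gc >= gc_range[1] & gc <= gc_range[2]
  win_starts <- win_starts[keep]; win_seq <- win_seq[keep]
  if (!length(win_starts)) {
    warning("no conserved primer window", call. = FALSE)
    return(empty_markers(region))
  }
  sites <- if (nrow(m) >= 3L) diagnostic_sites(m) else
    tibble::tibble(column = integer(), kind = character(),
                   species = character(), state = character(),
                   background_state = character(), width = integer())

  # per-species cumulative ungapped length up to each column
  unglen <- apply(m != "-", 1, cumsum)  # L x n_species
  sc <- sort(sites$column)
  nw <- length(win_starts)
  acc <- vector("list", nw)
  for (i in seq_len(nw)) {
    fs <- win_starts[i]
    js <- which(win_starts > fs + primer_len - 1L)  # reverse window beyond
    if (!length(js)) next
    rs <- win_starts[js]
    re <- rs + primer_len - 1L
    # product spans columns fs..re; per-species ungapped length
    off <- if (fs > 1L) unglen[fs - 1L, ] else rep(0L, ncol(unglen))
    plens <- unglen[re, , drop = FALSE] - rep(off, each = length(js))
    pmin_ <- apply(plens, 1, min); pmax_ <- apply(plens, 1, max)
    ok <- pmin_ >= min_len & pmax_ <= max_len
    if (!any(ok)) next
    ns <- findInterval(rs[ok] - 1L, sc) -
      findInterval(fs + primer_len - 1L, sc)
    acc[[i]] <- list(fs = rep(fs, sum(ok)), rs = rs[ok], i = rep(i, sum(ok)),
                     j = js[ok], ns = ns,
                     pmin = pmin_[ok], pmax = pmax_[ok],
                     plens = plens[ok, , drop = FALSE])
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (!length(acc)) {
    warning("no primer pair with admissible product length", call. = FALSE)
    return(empty_markers(region))
  }
  plens_all <- do.call(rbind, lapply(acc, `[[`, "plens"))
  colnames(plens_all) <- rownames(m)
  tab <- tibble::tibble(
    fwd_column = unlist(lapply(acc, `[[`, "fs")),
    rev_column = unlist(lapply(acc, `[[`, "rs")),
    n_sites = unlist(lapply(acc, `[[`, "ns")),
    forward_primer = win_seq[unlist(lapply(acc, `[[`, "i"))],
    reverse_primer = vapply(win_seq[unlist(lapply(acc, `[[`, "j"))],
                            revcomp, character(1), USE.NAMES = FALSE),
    product_min = as.integer(unlist(lapply(acc, `[[`, "pmin"))),
    product_max = as.integer(unlist(lapply(acc, `[[`, "pmax"))),
    products = lapply(seq_len(nrow(plens_all)), function(r) plens_all[r, ])) |>
    dplyr::arrange(dplyr::desc(.data$n_sites), .data$fwd_column, .data$rev_column)
  # greedy non-overlapping selection
  chosen <- list()
  occ_lo <- integer(0); occ_hi <- integer(0)
  for (r in seq_len(nrow(tab))) {
    lo <- tab$fwd_column[r]; hi <- tab$rev_column[r] + primer_len - 1L
    if (any(lo <= occ_hi & hi >= occ_lo)) next
    chosen[[length(chosen) + 1L]] <- tab[r, ]
    occ_lo <- c(occ_lo, lo); occ_hi <- c(occ_hi, hi)
    if (length(chosen) >= max_candidates) break
  }
  out <- dplyr::bind_rows(chosen)
  products <- out$products
  out$products <- NULL
  out$name <- sprintf("%s-mk%02d", region, seq_len(nrow(out)))
  out$region <- region
  out <- out[c("name", "region", "forward_primer", "reverse_primer",
               "fwd_column", "rev_column", "n_sites", "product_min",
               "product_max")]
  # attach the diagnostic sites enclosed by each candidate
  site_idx <- lapply(seq_len(nrow(out)), function(r) {
    which(sites$column > out$fwd_column[r] + primer_len - 1L &
          sites$column < out$rev_column[r])
  })
  structure(out, class = c("marker_candidates", class(out)),
            sites = sites, site_index = site_idx, products = products,
            primer_len = primer_len)
}

empty_markers <- function(region) {
  structure(tibble::tibble(name = character(), region = character(),
                           forward_primer = character(),
                           reverse_primer = character(),
                           fwd_column = integer(), rev_column = integer(),
                           n_sites = integer(), product_min = integer(),
                           product_max = integer()),
            class = c("marker_candidates", "tbl_df", "tbl", "data.frame"),
            sites = NULL, site_index = list(), products = list(),
            primer_len = NA_integer_)
}

#' Species discrimination matrix for a marker set
#'
#' A species pair `(i, j)` is discriminated when some retained candidate
#' encloses a diagnostic site private to `i` or to `j`. The matrix is
#' symmetric with a `TRUE` diagonal by convention; the success flag is `TRUE`
#' iff all off-diagonal pairs are discriminated.
#'
#' @param candidates a [primer_search()] result.
#' @param species character vector of species in the comparison.
#' @return a list of class `discrimination`: `matrix` (species x species
#'   logical), `success`, `per_pair` tibble.
#' @export
discrimination_matrix <- function(candidates, species) {
  stopifnot(inherits(candidates, "marker_candidates"))
  sites <- attr(candidates, "sites")
  site_idx <- attr(candidates, "site_index")
  if (nrow(candidates) == 0L) stop("no candidate markers")
  M <- matrix(FALSE, length(species), length(species),
              dimnames = list(species, species))
  diag(M) <- TRUE
  enclosed <- unique(unlist(site_idx))
  if (length(enclosed) && !is.null(sites)) {
    for (sp in unique(sites$species[enclosed])) {
      if (!sp %in% species) next
      others <- setdiff(species, sp)
      M[sp, others] <- TRUE
      M[others, sp] <- TRUE
    }
  }
  pairs <- utils::combn(species, 2L)
  per_pair <- tibble::tibble(species_a = pairs[1, ], species_b = pairs[2, ],
                             discriminated = M[cbind(pairs[1, ], pairs[2, ])])
  structure(list(matrix = M, success = all(per_pair$discriminated),
                 per_pair = per_pair),
            class = "discrimination")
}

#' @export
print.discrimination <- function(x, ...) {
  cat(sprintf("<discrimination> %s (%d/%d pairs)\n",
              if (x$success) "all species pairs discriminated" else "incomplete",
              sum(x$per_pair$discriminated), nrow(x$per_pair)))
  print(x$matrix)
  invisible(x)
}

#' Verify primers against raw (unaligned) region sequences
#'
#' Re-scans every reported primer for an exact, gap-free occurrence in every
#' species' region sequence (the reverse primer as its reverse complement),
#' independently of the alignment that produced it.
#'
#' @param candidates a [primer_search()] result.
#' @param seqs named character vector of the raw region sequences.
#' @return logical: do all primers occur exactly in all species?
#' @export
verify_primers <- function(candidates, seqs) {
  if (nrow(candidates) == 0L) return(FALSE)
  all(vapply(seq_len(nrow(candidates)), function(r) {
    fwd <- candidates$forward_primer[r]
    rev <- revcomp(candidates$reverse_primer[r])
    all(vapply(seqs, function(s) {
      grepl(fwd, s, fixed = TRUE) && grepl(rev, s, fixed = TRUE)
    }, logical(1)))
  }, logical(1)))
}
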