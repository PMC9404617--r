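# Independent oracles used across the suite. Each is a from-scratch
# implementation kept deliberately naive (enumeration / plain DP / O(n^3)
# agglomeration) and never shares code with the package internals.

# small simulation config used where full-size toys would be wasteful
small_cfg <- function(seed = 1L, species = NULL) {
  sim_config(seed = seed, n_pcg = 10L, n_trna = 4L,
             lsc_len = 5000L, ssc_len = 1900L, ir_len = 1300L,
             species = species)
}

quiet_species <- function(n = 3L) {
  # explicit, deterministic degradation settings with no random noise
  cfgs <- list(
    list(deletions = character(0), ir_delta = 0L, igs_sub_rate = 0),
    list(n_deletions = 1L,
         pseudo = c(frameshift = 1L), ir_delta = 80L, igs_sub_rate = 0),
    list(n_deletions = 2L,
         pseudo = c(premature_stop = 1L, truncation = 1L),
         ir_delta = -60L, igs_sub_rate = 0)
  )
  stats::setNames(cfgs[seq_len(n)], paste0("sp", seq_len(n)))
}

# ---- exhaustive global alignment score (tiny inputs only) -------------------
# scores every possible alignment; gap run of length L costs open+(L-1)*ext
brute_force_align_score <- function(a, b, match = 2, mismatch = -1,
                                    gap_open = 10, gap_ext = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  gap_cost <- function(L) if (L == 0) 0 else gap_open + (L - 1) * gap_ext
  rec <- function(i, j, prev) {
    # prev: "m" (match state), "a" (gap in b), "b" (gap in a), "s" start
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(a)) {
      pen <- if (prev == "a") gap_ext else gap_open
      best <- max(best, -pen + rec(i + 1, j, "a"))
    }
    if (j <= length(b)) {
      pen <- if (prev == "b") gap_ext else gap_open
      best <- max(best, -pen + rec(i, j + 1, "b"))
    }
    best
  }
  rec(1, 1, "s")
}

# ---- plain iterative Gotoh score (independent DP reimplementation) ----------
plain_gotoh_score <- function(a, b, match = 2, mismatch = -1,
                              gap_open = 10, gap_ext = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(-Inf, n + 1, m + 1); Ia <- M; Ib <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ia[i, 1] <- -(gap_open + (i - 2) * gap_ext)
  for (j in 2:(m + 1)) Ib[1, j] <- -(gap_open + (j - 2) * gap_ext)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    M[i, j] <- s + max(M[i - 1, j - 1], Ia[i - 1, j - 1], Ib[i - 1, j - 1])
    Ia[i, j] <- max(M[i - 1, j] - gap_open, Ia[i - 1, j] - gap_ext,
                    Ib[i - 1, j] - gap_open)
    Ib[i, j] <- max(M[i, j - 1] - gap_open, Ib[i, j - 1] - gap_ext,
                    Ia[i, j - 1] - gap_open)
  }
  max(M[n + 1, m + 1], Ia[n + 1, m + 1], Ib[n + 1, m + 1])
}

# ---- naive O(n^3) UPGMA returning a cophenetic matrix -----------------------
naive_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- lapply(seq_len(n), function(i) labels[i])
  sizes <- rep(1L, n)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  active <- seq_len(n)
  dm <- d
  while (length(active) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (dm[i, j] < bestd) { bestd <- dm[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    for (x in clusters[[i]]) for (y in clusters[[j]]) {
      coph[x, y] <- coph[y, x] <- bestd
    }
    # UPGMA update: size-weighted average distance to the new cluster
    for (k in active) {
      if (k == i || k == j) next
      dm[i, k] <- dm[k, i] <-
        (sizes[i] * dm[i, k] + sizes[j] * dm[j, k]) / (sizes[i] + sizes[j])
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  coph
}

# ---- brute-force Nei-Gojobori counting --------------------------------------
.gc_tab <- Biostrings::GENETIC_CODE
.stops <- names(.gc_tab)[.gc_tab == "*"]

brute_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa <- .gc_tab[[codon]]
  tot <- 0
  for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), ch[pos])) {
    alt <- ch; alt[pos] <- nt; alt <- paste(alt, collapse = "")
    if (!(alt %in% .stops) && .gc_tab[[alt]] == aa) tot <- tot + 1
  }
  tot / 3
}

# enumerate every permutation of the differing positions; drop pathways with
# stop intermediates (fall back to all pathways if none survive)
brute_path_counts <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  perms <- if (length(pos) == 1) list(pos) else {
    do.call(rbind, lapply(combinat_perms(length(pos)), function(ix) pos[ix]))
    }
  if (is.matrix(perms)) perms <- lapply(seq_len(nrow(perms)), function(r) perms[r, ])
  score_path <- function(ord, forbid_stops) {
    cur <- strsplit(ca, "")[[1]]; tgt <- strsplit(cb, "")[[1]]
    sd <- 0; nd <- 0
    for (p in ord) {
      before <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      after <- paste(cur, collapse = "")
      if (forbid_stops && after %in% .stops && after != cb) return(NULL)
      if (before %in% .stops || after %in% .stops) nd <- nd + 1
      else if (.gc_tab[[before]] == .gc_tab[[after]]) sd <- sd + 1
      else nd <- nd + 1
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, score_path, forbid_stops = TRUE))
  if (!length(res)) res <- lapply(perms, score_path, forbid_stops = FALSE)
  colMeans(do.call(rbind, res))
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (tail in combinat_perms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[tail])
    }
  }
  out
}

brute_ng86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    !(ca %in% .stops) & !(cb %in% .stops)
  ca <- ca[ok]; cb <- cb[ok]
  S <- (sum(vapply(ca, brute_syn_sites, numeric(1))) +
          sum(vapply(cb, brute_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  cnt <- vapply(seq_along(ca), function(i) brute_path_counts(ca[i], cb[i]),
                numeric(2))
  list(S_sites = S, N_sites = N, Sd = sum(cnt[1, ]), Nd = sum(cnt[2, ]))
}

# random sense codon sequence
random_codons <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(.gc_tab), .stops)
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
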