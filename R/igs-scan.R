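#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch with Gotoh affine gaps. Defaults emulate the classic
#' ClustalW-style DNA settings: match +2, mismatch -1, gap open 10, gap
#' extend 2 (penalties positive; a gap run of length L costs
#' `gap_open + (L-1) * gap_ext`). Traceback is deterministic, preferring
#' diagonal, then up, then left on ties.
#'
#' @param a,b DNA strings (non-empty).
#' @param match,mismatch,gap_open,gap_ext scoring parameters.
#' @return a list of class `pairwise_alignment` with elements `a`, `b`
#'   (gapped strings of equal length) and `score`.
#' @export
global_align <- function(a, b, match = 2, mismatch = -1,
                         gap_open = 10, gap_ext = 2) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (!nchar(a) || !nchar(b)) stop("empty input sequence")
  res <- .nw_affine_cpp(toupper(a), toupper(b), match, mismatch, gap_open, gap_ext)
  structure(res, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %d columns, score %.1f\n", nchar(x$a), x$score))
  invisible(x)
}

#' Kimura 2-parameter distance from a pairwise alignment
#'
#' Counts transitions (P) and transversions (Q) over alignment columns with
#' two unambiguous bases (gap or ambiguous columns excluded from the site
#' count) and applies `d = -1/2 ln((1 - 2P - Q) * sqrt(1 - 2Q))`.
#'
#' @param aln a [global_align()] result, or a list with gapped strings `a`
#'   and `b`.
#' @return a tibble row: `P`, `Q`, `d`, `sites`, `transitions`,
#'   `transversions`.
#' @export
k2p_distance <- function(aln) {
  ca <- toupper(seq_chars(aln$a))
  cb <- toupper(seq_chars(aln$b))
  stopifnot(length(ca) == length(cb))
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[ok]; cb <- cb[ok]
  sites <- length(ca)
  if (sites == 0L) stop("zero usable sites")
  diff <- ca != cb
  purine <- function(x) x %in% c("A", "G")
  ts <- sum(diff & (purine(ca) == purine(cb)))  # A<->G or C<->T
  tv <- sum(diff) - ts
  P <- ts / sites; Q <- tv / sites
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("distance undefined (saturation)")
  d <- -0.5 * log(w1 * sqrt(w2))
  tibble::tibble(P = P, Q = Q, d = d, sites = sites,
                 transitions = ts, transversions = tv)
}

#' Extract intergenic spacers shared by all plastomes
#'
#' Enumerates spacers between consecutive gene features on the canonical
#' rotation of each plastome (wrapping spacer included) and keeps those whose
#' unordered flanking-gene pair bounds a spacer in every input. Spacer
#' sequences are orientation-normalized so the flank order matches the first
#' plastome; reversed occurrences are reverse-complemented before comparison.
#'
#' @param plastomes a named list of annotated [plastome] objects (names are
#'   species/accession labels; unnamed lists use the plastome ids).
#' @param canonicalize rotate each genome to its quadripartite canonical form
#'   first (requires a detectable IR; set `FALSE` to use genomes as given).
#' @param min_ir passed to [detect_inverted_repeat()] when canonicalizing.
#' @return a tibble with columns `region` (\"geneA-geneB\"), `species`,
#'   `start`, `end`, `length`, `flipped`, `sequence`.
#' @export
extract_shared_igs <- function(plastomes, canonicalize = TRUE, min_ir = 1000L) {
  if (inherits(plastomes, "plastome")) plastomes <- list(plastomes)
  nms <- names(plastomes)
  if (is.null(nms)) nms <- vapply(plastomes, `[[`, character(1), "id")
  per <- purrr::map2(plastomes, nms, function(p, nm) {
    if (nrow(p$features) < 2L) stop("plastome ", nm, " has fewer than 2 genes")
    if (canonicalize && p$circular) {
      q <- tryCatch(detect_inverted_repeat(p, min_ir), error = function(e) NULL)
      if (!is.null(q) && isTRUE(q$has_quadripartite)) p <- q$plastome
    }
    igs_of_plastome(p, nm)
  })
  first <- per[[1]]
  shared <- first
  for (tab in per[-1]) {
    shared <- shared[shared$key %in% tab$key, , drop = FALSE]
  }
  if (nrow(shared) == 0L) {
    return(tibble::tibble(region = character(), species = character(),
                          start = integer(), end = integer(),
                          length = integer(), flipped = logical(),
                          sequence = character()))
  }
  out <- purrr::map_dfr(per, function(tab) {
    tab <- tab[match(shared$key, tab$key), , drop = FALSE]  # first occurrence
    # orientation-normalize to the first plastome's flank order
    flip <- tab$up != shared$up[match(tab$key, shared$key)]
    tab$sequence[flip] <- vapply(tab$sequence[flip], revcomp, character(1))
    tab$flipped <- flip
    tab$region <- shared$region[match(tab$key, shared$key)]
    tab
  })
  out <- out[nchar(out$sequence) >= 1L, , drop = FALSE]
  # a shared region must be non-empty in every species
  full <- names(which(table(out$region) == length(per)))
  out <- out[out$region %in% full, , drop = FALSE]
  tibble::as_tibble(out[order(out$region, match(out$species, nms)),
                        c("region", "species", "start", "end", "length",
                          "flipped", "sequence")])
}

# all spacers of one plastome, on its current rotation
igs_of_plastome <- function(p, species) {
  f <- p$features
  n <- nchar(p$sequence)
  spans <- feature_spans(f, n)
  ord <- order(spans$start)
  start <- spans$start[ord]; len <- spans$len[ord]
  end <- (start + len)
  gene <- normalize_gene_name(f$gene[ord])
  m <- length(ord)
  rows <- vector("list", m)
  seen <- character(0)
  for (i in seq_len(m)) {
    jn <- if (i < m) i + 1L else 1L
    s <- end[i] %% n
    e <- start[jn]
    glen <- (e - s) %% n
    if (i == m && glen == 0L && m > 1L) glen <- (e - s) %% n
    if (glen <= 0L) next
    # skip spacer if the next feature actually overlaps this one
    if (i < m && end[i] > start[jn]) next
    up <- gene[i]; dn <- gene[jn]
    key <- paste(sort(c(up, dn)), collapse = "|")
    if (key %in% seen) next  # IR-duplicated adjacency: keep first occurrence
    seen <- c(seen, key)
    rows[[i]] <- tibble::tibble(
      species = species, key = key, up = up,
      region = paste0(up, "-", dn),
      start = as.integer(s), end = as.integer((s + glen) %% n),
      length = as.integer(glen),
      sequence = circ_substr(p$sequence, s, (s + glen) %% n))
  }
  dplyr::bind_rows(rows)
}

#' Rank shared intergenic spacers by K2p divergence
#'
#' For every shared region and every species pair, globally aligns the two
#' spacer copies and computes the K2p distance; regions are summarized by
#' min, mean and max pairwise distance (also reported x100, the way distmat
#' prints percentages) and sorted by mean descending (ties by name).
#'
#' @param igs a tibble from [extract_shared_igs()].
#' @param ... alignment parameters passed to [global_align()].
#' @return an object of class `igs_divergence`: a tibble with `region`,
#'   `n_pairs`, `d_min`, `d_mean`, `d_max`, `d_mean_pct`, plus a `pairs`
#'   attribute holding the per-pair table.
#' @export
rank_igs <- function(igs, ...) {
  stopifnot(all(c("region", "species", "sequence") %in% names(igs)))
  species <- unique(igs$species)
  if (length(species) < 2L) stop("need >= 2 plastomes to rank divergence")
  pairs <- utils::combn(species, 2L, simplify = FALSE)
  per_pair <- purrr::map_dfr(unique(igs$region), function(rg) {
    sub <- igs[igs$region == rg, ]
    purrr::map_dfr(pairs, function(pr) {
      sa <- sub$sequence[sub$species == pr[1]]
      sb <- sub$sequence[sub$species == pr[2]]
      if (!length(sa) || !length(sb)) return(NULL)
      res <- tryCatch(k2p_distance(global_align(sa, sb, ...)),
                      error = function(e) {
                        warning("region ", rg, " pair ", pr[1], "/", pr[2],
                                ": ", conditionMessage(e), call. = FALSE)
                        NULL
                      })
      if (is.null(res)) return(NULL)
      dplyr::bind_cols(tibble::tibble(region = rg, species_a = pr[1],
                                      species_b = pr[2]), res)
    })
  })
  if (nrow(per_pair) == 0L) stop("no region pair computable")
  summ <- per_pair |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_pairs = dplyr::n(), d_min = min(.data$d),
                     d_mean = mean(.data$d), d_max = max(.data$d),
                     .groups = "drop") |>
    dplyr::mutate(d_mean_pct = 100 * .data$d_mean) |>
    dplyr::arrange(dplyr::desc(.data$d_mean), .data$region)
  structure(summ, class = c("igs_divergence", class(summ)), pairs = per_pair)
}

#' @export
autoplot.igs_divergence <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$region <- factor(df$region, levels = df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = 100 * .data$d_min,
                                         ymax = 100 * .data$d_max)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$d_mean_pct), shape = 18, size = 3) +
    ggplot2::labs(x = "intergenic spacer", y = "K2p distance (x100)",
                  title = "Divergence of shared intergenic spacers") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
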