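#' Codon-aware multiple alignment of CDS sequences
#'
#' Translates each CDS, progressively aligns the proteins (UPGMA guide tree
#' from pairwise identities), then threads the nucleotides back through the
#' protein alignment so every gap is a multiple of 3 on a codon boundary.
#'
#' @param gene_seqs named character vector/list of CDS sequences; incomplete
#'   terminal codons are trimmed; internal stops are an error (pseudogenes
#'   must be excluded upstream).
#' @return a list of class `codon_msa`: `dna` (character matrix of codon
#'   columns as single nt characters), `protein` (the protein `msa`),
#'   `codons` (species x codon-column matrix of 3-nt strings, `"---"` for
#'   gaps).
#' @export
codon_align <- function(gene_seqs) {
  seqs <- toupper(unlist(gene_seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- vapply(seqs, function(s) substr(s, 1L, nchar(s) - nchar(s) %% 3L),
                 character(1))
  if (any(!nchar(seqs))) stop("empty CDS after trimming")
  prot <- character(length(seqs))
  for (i in seq_along(seqs)) {
    cods <- split_codons(seqs[[i]])
    # a terminal stop is allowed and aligned as '*'
    internal <- is_stop(cods[-length(cods)])
    if (any(internal)) {
      stop("internal stop codon in ", names(seqs)[i], " at codon ",
           which(internal)[1])
    }
    prot[i] <- translate_dna(seqs[[i]])
  }
  names(prot) <- names(seqs)
  aa_alpha <- sort(unique(unlist(strsplit(c(prot, "ACDEFGHIKLMNPQRSTVWY*X"), ""))))
  aa_alpha <- setdiff(aa_alpha, "-")
  pm <- if (length(prot) >= 2L) {
    build_msa(prot, alphabet = aa_alpha, match = 2, mismatch = -1,
              gap_open = 11, gap_ext = 1)
  } else {
    structure(matrix(seq_chars(prot[[1]]), nrow = 1,
                     dimnames = list(names(prot), NULL)), class = "msa")
  }
  ncolumns <- ncol(pm)
  codons <- matrix("---", length(seqs), ncolumns,
                   dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    cods <- split_codons(seqs[[i]])
    k <- 0L
    for (j in seq_len(ncolumns)) {
      if (pm[names(seqs)[i], j] != "-") {
        k <- k + 1L
        codons[i, j] <- cods[k]
      }
    }
    stopifnot(k == length(cods))  # back-threading consumed every codon
  }
  dna <- matrix("-", length(seqs), 3L * ncolumns,
                dimnames = list(names(seqs), NULL))
  for (j in seq_len(ncolumns)) {
    cols <- (3L * j - 2L):(3L * j)
    dna[, cols] <- t(vapply(codons[, j], function(cd) strsplit(cd, "")[[1]],
                            character(3)))
  }
  structure(list(dna = dna, protein = pm, codons = codons),
            class = "codon_msa")
}

#' @export
print.codon_msa <- function(x, ...) {
  cat(sprintf("<codon_msa> %d sequences x %d codon columns\n",
              nrow(x$codons), ncol(x$codons)))
  invisible(x)
}

## ---- Nei-Gojobori (1986) counting ------------------------------------------

# fraction of the 3 possible changes at each codon position that are
# synonymous; changes creating a stop codon count as nonsynonymous so that
# S + N == 3 exactly per codon
codon_syn_sites <- function(codon) {
  codon <- toupper(codon)
  aa <- GENETIC_CODE_MAP[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  ch <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (b in setdiff(bases, ch[pos])) {
      alt <- ch; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      if (!is_stop(alt) && GENETIC_CODE_MAP[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# average synonymous/nonsynonymous difference counts between two codons over
# all minimal substitution pathways, excluding pathways through stop codons
codon_path_counts <- function(ca, cb) {
  ca <- toupper(ca); cb <- toupper(cb)
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(nd, list(pos),
                  list(pos, pos[2:1]),
                  { p <- pos
                    list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                         p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)]) })
  eval_path <- function(ord) {
    cur <- strsplit(ca, "")[[1]]
    tb <- strsplit(cb, "")[[1]]
    sd <- 0; ndn <- 0
    for (p in ord) {
      prev <- paste(cur, collapse = "")
      cur[p] <- tb[p]
      nxt <- paste(cur, collapse = "")
      if (is_stop(nxt) && nxt != cb) return(NULL)  # pathway through a stop
      if (is_stop(prev) || is_stop(nxt)) { ndn <- ndn + 1 }
      else if (GENETIC_CODE_MAP[[prev]] == GENETIC_CODE_MAP[[nxt]]) sd <- sd + 1
      else ndn <- ndn + 1
    }
    c(sd = sd, nd = ndn)
  }
  res <- purrr::compact(lapply(perms, eval_path))
  if (!length(res)) {
    # all pathways blocked by stops (possible only when an endpoint is near
    # the stop neighbourhood): fall back to the unrestricted average
    res <- lapply(perms, function(ord) {
      cur <- strsplit(ca, "")[[1]]; tb <- strsplit(cb, "")[[1]]
      sd <- 0; ndn <- 0
      for (p in ord) {
        prev <- paste(cur, collapse = ""); cur[p] <- tb[p]
        nxt <- paste(cur, collapse = "")
        if (is_stop(prev) || is_stop(nxt)) ndn <- ndn + 1
        else if (GENETIC_CODE_MAP[[prev]] == GENETIC_CODE_MAP[[nxt]]) sd <- sd + 1
        else ndn <- ndn + 1
      }
      c(sd = sd, nd = ndn)
    })
  }
  colMeans(do.call(rbind, res))
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Synonymous site counts come from the fraction of the three possible
#' changes at each codon position that preserve the amino acid (averaged over
#' the two sequences); differences in multi-hit codons are averaged over all
#' minimal substitution pathways, excluding pathways through stop codons.
#' Proportions are corrected with the Jukes-Cantor formula
#' `d = -3/4 ln(1 - 4p/3)`.
#'
#' @param a,b aligned codon sequences of equal length (gapped with `-`;
#'   codon columns containing a gap or ambiguous base are excluded).
#' @param gene,pair optional labels carried into the result.
#' @return a one-row tibble: `gene`, `species_a`, `species_b`, `codons`,
#'   `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`
#'   (`NA` when `dS == 0`). A proportion at or beyond the Jukes-Cantor limit
#'   (0.75) is saturated: the corrected rate becomes `NA` with a warning.
#' @export
ng86_dn_ds <- function(a, b, gene = NA_character_, pair = c(NA, NA)) {
  if (is.matrix(a)) a <- paste(a, collapse = "")
  if (is.matrix(b)) b <- paste(b, collapse = "")
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences of unequal length")
  ca <- split_codons(a); cb <- split_codons(b)
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
        !is_stop(ca) & !is_stop(cb)
  ca <- ca[ok]; cb <- cb[ok]
  ncod <- length(ca)
  if (ncod == 0L) stop("zero comparable codons")
  Sa <- sum(vapply(ca, codon_syn_sites, numeric(1)))
  Sb <- sum(vapply(cb, codon_syn_sites, numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * ncod - S
  counts <- vapply(seq_len(ncod),
                   function(i) codon_path_counts(ca[i], cb[i]), numeric(2))
  Sd <- sum(counts["sd", ]); Nd <- sum(counts["nd", ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p, what) {
    if (p >= 0.75) {
      warning("saturation: ", what, " proportion ", signif(p, 3),
              " exceeds the correctable range", call. = FALSE)
      return(NA_real_)
    }
    -0.75 * log(1 - 4 * p / 3) + 0  # + 0 normalizes IEEE negative zero
  }
  dS <- jc(pS, "synonymous"); dN <- jc(pN, "nonsynonymous")
  omega <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  tibble::tibble(gene = gene, species_a = pair[1], species_b = pair[2],
                 codons = ncod, S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, dS = dS, dN = dN, omega = omega)
}

#' Pairwise dN/dS screen across shared genes
#'
#' For every gene present in at least two species (census status, when a
#' census is supplied; otherwise every annotated CDS) computes all pairwise
#' NG86 estimates from pairwise codon-aware alignments and summarizes the
#' per-gene omega distribution; genes with median omega above 1 are flagged
#' as positive-selection candidates.
#'
#' @param plastomes named list of annotated [plastome]s.
#' @param census optional `gene_census`; only genes with status `present`
#'   enter the comparison for a species.
#' @return an object of class `omega_table`: a tibble `gene`, `n_pairs`,
#'   `omega_median`, `omega_min`, `omega_max`, `dn_median`, `ds_median`,
#'   `positive_selection_candidate`, with attribute `pairs` holding all
#'   pairwise estimates.
#' @export
omega_table <- function(plastomes, census = NULL) {
  nms <- names(plastomes)
  if (is.null(nms)) nms <- vapply(plastomes, `[[`, character(1), "id")
  names(plastomes) <- nms
  # gene -> species with a usable CDS
  per_gene <- list()
  for (sp in nms) {
    f <- plastomes[[sp]]$features
    idx <- which(f$kind == "CDS")
    for (i in idx) {
      g <- normalize_gene_name(f$gene[i])
      if (!is.null(census)) {
        st <- census$cells$status[census$cells$species == sp &
                                  normalize_gene_name(census$cells$gene) == g]
        if (!length(st) || st[1] != "present") next
      }
      if (!is.null(per_gene[[g]]) && sp %in% names(per_gene[[g]])) next
      seqv <- extract_feature_sequence(plastomes[[sp]], i)
      per_gene[[g]] <- c(per_gene[[g]], stats::setNames(seqv, sp))
    }
  }
  rows <- list()
  for (g in sort(names(per_gene))) {
    seqs <- per_gene[[g]]
    if (length(seqs) < 2L) {
      warning("gene ", g, " present in < 2 species; skipped", call. = FALSE)
      next
    }
    prs <- utils::combn(names(seqs), 2L, simplify = FALSE)
    for (pr in prs) {
      est <- tryCatch({
        cal <- codon_align(seqs[pr])
        ng86_dn_ds(paste(cal$dna[1, ], collapse = ""),
                   paste(cal$dna[2, ], collapse = ""),
                   gene = g, pair = pr)
      }, error = function(e) {
        warning("gene ", g, " pair ", paste(pr, collapse = "/"), ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (!is.null(est)) rows[[length(rows) + 1L]] <- est
    }
  }
  pairs <- dplyr::bind_rows(rows)
  if (nrow(pairs) == 0L) stop("no gene pair computable")
  summ <- pairs |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      omega_median = stats::median(.data$omega, na.rm = TRUE),
      omega_min = if (all(is.na(.data$omega))) NA_real_ else
        min(.data$omega, na.rm = TRUE),
      omega_max = if (all(is.na(.data$omega))) NA_real_ else
        max(.data$omega, na.rm = TRUE),
      dn_median = stats::median(.data$dN), ds_median = stats::median(.data$dS),
      .groups = "drop") |>
    dplyr::mutate(positive_selection_candidate =
                    !is.na(.data$omega_median) & .data$omega_median > 1) |>
    dplyr::arrange(dplyr::desc(.data$omega_median))
  structure(summ, class = c("omega_table", class(summ)), pairs = pairs)
}

#' @export
autoplot.omega_table <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$gene, y = .data$omega)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(omega == dN / dS),
                  title = "Pairwise dN/dS per shared gene") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
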