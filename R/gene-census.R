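#' Default thresholds for the gene census
#'
#' The degradation rule is qualitative in origin (a gene is a pseudogene when
#' truncated or carrying a frameshift relative to a non-degraded reference),
#' so the quantitative cutoffs are package parameters: a similarity hit is
#' accepted at identity >= 0.6 over >= 30% of the reference CDS; aligned
#' coverage below 0.9 counts as truncation; an in-frame stop is "premature"
#' only before the final 5% of codons.
#'
#' @param min_identity minimum identity of the best local hit.
#' @param min_hit_coverage minimum fraction of the reference CDS covered by
#'   the hit for the gene to count as found at all.
#' @param truncation_coverage aligned-coverage cutoff below which a found
#'   gene is called truncated.
#' @param stop_grace final fraction of codons within which an in-frame stop
#'   is tolerated.
#' @return a named list of thresholds.
#' @export
census_thresholds <- function(min_identity = 0.6, min_hit_coverage = 0.3,
                              truncation_coverage = 0.9, stop_grace = 0.05) {
  list(min_identity = min_identity, min_hit_coverage = min_hit_coverage,
       truncation_coverage = truncation_coverage, stop_grace = stop_grace)
}

#' Classify one reference gene in a target plastome
#'
#' Searches both strands of the target for the reference CDS (local
#' alignment); with no acceptable hit the gene is `lost`. The best hit region
#' is then re-aligned globally to the reference CDS and inspected for
#' frameshifts (an aligned indel run whose length is not a multiple of 3),
#' premature in-frame stops, and truncation (aligned coverage below the
#' cutoff); any of these makes the gene a `pseudogene`, otherwise it is
#' `present`.
#'
#' @param target a [plastome].
#' @param ref_cds reference CDS string (length a multiple of 3, starting with
#'   a start codon, no internal stop).
#' @param gene gene symbol used in the report.
#' @param thresholds see [census_thresholds()].
#' @return a one-row tibble: `gene`, `status` (`present`/`pseudogene`/
#'   `lost`), `evidence` (`intact`/`frameshift`/`premature_stop`/`truncated`/
#'   `no_hit`), `identity`, `coverage`.
#' @export
classify_gene <- function(target, ref_cds, gene = "gene",
                          thresholds = census_thresholds()) {
  stopifnot(inherits(target, "plastome"))
  ref_cds <- toupper(ref_cds)
  if (nchar(ref_cds) %% 3L != 0L) stop("invalid reference CDS: length not a multiple of 3")
  codons <- split_codons(ref_cds)
  if (!(codons[1] %in% c("ATG", "GTG", "TTG"))) stop("invalid reference CDS: no start codon")
  if (any(is_stop(codons[-length(codons)]))) stop("invalid reference CDS: internal stop")

  # extend the subject across the origin so hits wrapping a circular genome
  # are found; extension is capped so no hit can be double-counted
  subj <- target$sequence
  if (target$circular && nchar(subj) > nchar(ref_cds)) {
    ext <- min(nchar(ref_cds), nchar(subj))
    subj <- paste0(subj, substr(subj, 1L, ext))
  }
  # fast path: an exact full-length copy on either strand is intact
  if (grepl(ref_cds, subj, fixed = TRUE) ||
      grepl(revcomp(ref_cds), subj, fixed = TRUE)) {
    return(tibble::tibble(gene = gene, status = "present",
                          evidence = "intact", identity = 1, coverage = 1))
  }
  hit_f <- best_local_hit(ref_cds, subj)
  hit_r <- best_local_hit(ref_cds, revcomp(subj))
  hit <- if (hit_f$score >= hit_r$score) hit_f else hit_r

  no_hit <- tibble::tibble(gene = gene, status = "lost", evidence = "no_hit",
                           identity = NA_real_, coverage = 0)
  if (hit$score <= 0) return(no_hit)
  if (hit$identity < thresholds$min_identity ||
      hit$ref_cov < thresholds$min_hit_coverage) return(no_hit)

  # the local alignment itself is the refit: non-homologous reference ends
  # are clipped (missing coverage), internal indels stay internal
  diag <- inspect_cds_alignment(hit$pa, hit$sa, thresholds,
                                ref_total = nchar(ref_cds),
                                ref_offset = hit$ref_start)
  status <- if (diag$evidence == "intact") "present" else "pseudogene"
  tibble::tibble(gene = gene, status = status, evidence = diag$evidence,
                 identity = diag$identity, coverage = diag$coverage)
}

# best local alignment of ref against one strand; returns score, identity
# over aligned columns, coverage of ref, subject window coordinates (1-based)
best_local_hit <- function(ref, subject) {
  la <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(subject),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 8, gapExtension = 2)
  sc <- Biostrings::score(la)
  if (sc <= 0) return(list(score = -Inf, identity = 0, ref_cov = 0))
  pr <- Biostrings::pattern(la)
  list(score = sc,
       identity = Biostrings::pid(la) / 100,
       ref_cov = (Biostrings::end(pr) - Biostrings::start(pr) + 1L) / nchar(ref),
       ref_start = Biostrings::start(pr),
       pa = as.character(Biostrings::alignedPattern(la)),
       sa = as.character(Biostrings::alignedSubject(la)))
}

# walk an ends-free refit alignment: frameshift, premature stop and
# truncation diagnostics in the reference reading frame. `ref_offset` is the
# 1-based position of the first aligned reference base (clipped ends count
# as uncovered, never as frameshifts).
inspect_cds_alignment <- function(pa, sa, thresholds, ref_total = NULL,
                                  ref_offset = 1L) {
  ca <- seq_chars(pa); cb <- seq_chars(sa)
  stopifnot(length(ca) == length(cb))
  if (is.null(ref_total)) ref_total <- sum(ca != "-")
  # indel runs strictly inside the aligned CDS
  gap_a <- ca == "-"; gap_b <- cb == "-"
  inner <- which(!gap_a & !gap_b)
  frameshift <- FALSE
  if (length(inner) >= 2L) {
    core <- seq(min(inner), max(inner))
    runs <- rle(ifelse(gap_a[core], "ins", ifelse(gap_b[core], "del", "m")))
    bad <- runs$values %in% c("ins", "del") & (runs$lengths %% 3L != 0L)
    frameshift <- any(bad)
  }
  # project target bases onto the full reference coordinate range
  proj <- rep("-", ref_total)
  r <- ref_offset - 1L
  for (i in seq_along(ca)) {
    if (ca[i] != "-") {
      r <- r + 1L
      proj[r] <- cb[i]
    }
  }
  covered <- proj %in% c("A", "C", "G", "T")
  coverage <- mean(covered)
  ref_chars <- rep(NA_character_, ref_total)
  ref_chars[seq.int(ref_offset, r)] <- seq_chars(gsub("-", "", pa))
  matches <- sum(covered & !is.na(ref_chars) & proj == ref_chars)
  identity <- if (any(covered)) matches / sum(covered) else 0

  n_codons <- ref_total %/% 3L
  grace_from <- ceiling((1 - thresholds$stop_grace) * n_codons)
  premature <- FALSE
  for (cidx in seq_len(max(0L, grace_from - 1L))) {
    cd <- paste(proj[(3L * cidx - 2L):(3L * cidx)], collapse = "")
    if (is_stop(cd)) { premature <- TRUE; break }
  }
  evidence <- if (frameshift) "frameshift"
    else if (premature) "premature_stop"
    else if (coverage < thresholds$truncation_coverage) "truncated"
    else "intact"
  list(evidence = evidence, identity = identity, coverage = coverage)
}

#' Census every reference protein-coding gene across target plastomes
#'
#' Applies [classify_gene()] to each CDS annotated in the reference, for each
#' target. Reference genes are deduplicated by normalized symbol (inverted-
#' repeat copies collapse to one gene); when a target carries several copies
#' the best status wins (present > pseudogene > lost). tRNA/rRNA features are
#' not part of the protein-coding census.
#'
#' @param targets named list of target [plastome]s.
#' @param reference the non-degraded reference [plastome] (>= 1 CDS feature).
#' @param thresholds see [census_thresholds()].
#' @return an object of class `gene_census`: list with `cells` (tibble
#'   species x gene status), `species`, `genes`, `n_ref_pcg`.
#' @export
census_matrix <- function(targets, reference, thresholds = census_thresholds()) {
  if (inherits(targets, "plastome")) targets <- list(targets)
  if (length(targets) == 0L) stop("empty target list")
  nms <- names(targets)
  if (is.null(nms)) nms <- vapply(targets, `[[`, character(1), "id")
  f <- reference$features
  cds_idx <- which(f$kind == "CDS")
  if (!length(cds_idx)) stop("reference has no CDS feature")
  sym <- normalize_gene_name(f$gene[cds_idx])
  keep <- cds_idx[!duplicated(sym)]
  genes <- f$gene[keep]
  refseqs <- lapply(keep, function(i) extract_feature_sequence(reference, i))
  names(refseqs) <- genes

  cells <- purrr::map_dfr(seq_along(targets), function(ti) {
    purrr::map_dfr(seq_along(genes), function(gi) {
      res <- classify_gene(targets[[ti]], refseqs[[gi]], gene = genes[gi],
                           thresholds = thresholds)
      res$species <- nms[ti]
      res
    })
  })
  cells <- cells[c("species", "gene", "status", "evidence", "identity", "coverage")]
  structure(list(cells = tibble::as_tibble(cells), species = nms,
                 genes = genes, n_ref_pcg = length(genes)),
            class = "gene_census")
}

#' @export
print.gene_census <- function(x, ...) {
  cat(sprintf("<gene_census> %d species x %d reference PCGs\n",
              length(x$species), x$n_ref_pcg))
  tab <- x$cells |>
    dplyr::count(.data$species, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n", values_fill = 0L)
  print(tab)
  invisible(x)
}

#' Tidy the census cells
#' @param x a `gene_census`.
#' @param ... unused.
#' @return the per-species, per-gene status tibble.
#' @export
tidy.gene_census <- function(x, ...) x$cells

#' Per-species census summary
#' @param x a `gene_census`.
#' @param ... unused.
#' @return the [degradation_ratios()] tibble.
#' @export
glance.gene_census <- function(x, ...) degradation_ratios(x)

#' Census matrix in display form
#'
#' Wide species-by-gene matrix using the conventional legend: `•`
#' present, `Ψ` pseudogene, `○` lost.
#'
#' @param x a `gene_census`.
#' @return a tibble, one row per gene, one column per species.
#' @export
census_legend_matrix <- function(x) {
  stopifnot(inherits(x, "gene_census"))
  lg <- c(present = "•", pseudogene = "Ψ", lost = "○")
  x$cells |>
    dplyr::mutate(symbol = lg[.data$status]) |>
    dplyr::select("gene", "species", "symbol") |>
    tidyr::pivot_wider(names_from = "species", values_from = "symbol")
}

#' @export
autoplot.gene_census <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$species, y = .data$gene,
                               fill = .data$status)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(present = "#2b8cbe",
                                          pseudogene = "#fdae61",
                                          lost = "#d7191c")) +
    ggplot2::labs(x = NULL, y = NULL, title = "Gene status census") +
    ggplot2::theme_minimal()
}

#' Degradation ratios per species
#'
#' The ratio of lost genes (pseudogenes) is the number of lost genes
#' (pseudogenes) divided by the number of protein-coding genes in the
#' reference; the denominator is reported, never hard-coded.
#'
#' @param m a `gene_census` from [census_matrix()].
#' @return a tibble: `species`, `n_present`, `n_pseudo`, `n_lost`,
#'   `ratio_pseudo`, `ratio_lost`, `n_ref_pcg`.
#' @export
degradation_ratios <- function(m) {
  stopifnot(inherits(m, "gene_census"))
  m$cells |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_present = sum(.data$status == "present"),
      n_pseudo = sum(.data$status == "pseudogene"),
      n_lost = sum(.data$status == "lost"), .groups = "drop") |>
    dplyr::mutate(ratio_pseudo = .data$n_pseudo / m$n_ref_pcg,
                  ratio_lost = .data$n_lost / m$n_ref_pcg,
                  n_ref_pcg = m$n_ref_pcg) |>
    dplyr::arrange(match(.data$species, m$species))
}

#' Cluster species on degradation-ratio profiles
#'
#' Agglomerative clustering with average linkage (UPGMA) on the Euclidean
#' distance between per-species ratio vectors; deterministic.
#'
#' @param profiles a data frame with a `species` column and numeric ratio
#'   columns (e.g. the output of [degradation_ratios()]), or a numeric matrix
#'   with species rownames.
#' @param columns ratio columns used (default `ratio_lost`, `ratio_pseudo`).
#' @return a list of class `species_clustering`: `hclust`, `newick`,
#'   `heights`.
#' @export
cluster_species <- function(profiles, columns = c("ratio_lost", "ratio_pseudo")) {
  if (is.data.frame(profiles)) {
    stopifnot("species" %in% names(profiles))
    miss <- setdiff(columns, names(profiles))
    if (length(miss)) stop("missing ratio columns: ", paste(miss, collapse = ", "))
    mat <- as.matrix(profiles[columns])
    rownames(mat) <- profiles$species
  } else {
    mat <- as.matrix(profiles)
  }
  if (nrow(mat) < 2L) stop("need >= 2 species")
  if (anyNA(mat)) stop("profiles contain NA")
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"), method = "average")
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, newick = ape::write.tree(phy),
                 heights = hc$height),
            class = "species_clustering")
}

#' @export
print.species_clustering <- function(x, ...) {
  cat("<species_clustering> UPGMA on degradation ratios\n  ", x$newick, "\n")
  invisible(x)
}
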