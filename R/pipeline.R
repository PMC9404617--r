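#' Run the full comparative pipeline and write tabular outputs
#'
#' Orchestrates all stages on a set of annotated plastomes plus a reference:
#' quadripartite partition and junction report, gene census and degradation
#' ratios with UPGMA clustering, shared-spacer K2p ranking, pairwise dN/dS
#' screen, and barcode marker design with a discrimination matrix. Writes
#' `partition.bed`, `junctions.tsv`, `census.tsv`, `ratios.tsv`,
#' `cluster.nwk`, `igs_divergence.tsv`, `omega.tsv`, `markers.tsv`,
#' `discrimination.tsv` and `run_log.txt` into `outdir`.
#'
#' @param targets named list of target [plastome]s (or paths to GenBank
#'   files).
#' @param reference the reference [plastome] (or a GenBank path).
#' @param outdir output directory (created if missing).
#' @param min_ir minimum IR length for [detect_inverted_repeat()].
#' @param thresholds census thresholds, see [census_thresholds()].
#' @param marker_region spacer used for marker design (default: the most
#'   divergent shared spacer).
#' @param min_len,max_len,primer_len marker product bounds and primer
#'   length, see [primer_search()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list of all stage results.
#' @export
run_pipeline <- function(targets, reference, outdir = "plastdrift_out",
                         min_ir = 1000L, thresholds = census_thresholds(),
                         marker_region = NULL, min_len = 100L,
                         max_len = 1000L, primer_len = 20L, quiet = FALSE) {
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   paste0(...))
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  if (is.character(reference)) {
    if (!file.exists(reference)) stop("reference file not found: ", reference)
    reference <- read_genbank(reference)
  }
  if (is.character(targets)) targets <- as.list(targets)
  targets <- lapply(targets, function(t) if (is.character(t)) read_genbank(t) else t)
  nms <- names(targets)
  if (is.null(nms)) {
    nms <- vapply(targets, `[[`, character(1), "id")
    names(targets) <- nms
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  say("partitioning ", length(targets), " plastomes")
  res$partitions <- lapply(targets, function(p) {
    tryCatch(detect_inverted_repeat(p, min_ir), error = function(e) NULL)
  })
  part_rows <- purrr::imap_dfr(res$partitions, function(q, sp) {
    if (is.null(q) || !q$has_quadripartite) return(NULL)
    tibble::tibble(chrom = sp,
                   name = c("LSC", "IRb", "SSC", "IRa"),
                   start = c(q$lsc[1], q$irb[1], q$ssc[1], q$ira[1]),
                   end = c(q$lsc[2], q$irb[2], q$ssc[2], q$ira[2]))
  })
  write_region_table(part_rows, file.path(outdir, "partition.bed"))

  jn <- purrr::imap_dfr(res$partitions, function(q, sp) {
    if (is.null(q) || !q$has_quadripartite) return(NULL)
    dplyr::mutate(junction_report(q = q), species = sp, .before = 1)
  })
  res$junctions <- jn
  write_tsv_file(jn, file.path(outdir, "junctions.tsv"))

  say("gene census against ", reference$id)
  res$census <- census_matrix(targets, reference, thresholds)
  cens_wide <- census_legend_matrix(res$census)
  cells <- res$census$cells |>
    tidyr::pivot_wider(id_cols = "gene", names_from = "species",
                       values_from = "status", names_prefix = "status_")
  write_tsv_file(dplyr::left_join(cens_wide, cells, by = "gene"),
                 file.path(outdir, "census.tsv"))
  res$ratios <- degradation_ratios(res$census)
  write_tsv_file(res$ratios, file.path(outdir, "ratios.tsv"))
  if (nrow(res$ratios) >= 2L) {
    res$cluster <- cluster_species(res$ratios)
    writeLines(res$cluster$newick, file.path(outdir, "cluster.nwk"))
  }

  say("shared intergenic spacers")
  res$igs <- extract_shared_igs(targets, min_ir = min_ir)
  if (nrow(res$igs) && length(unique(res$igs$species)) >= 2L) {
    res$igs_rank <- rank_igs(res$igs)
    write_tsv_file(tibble::as_tibble(res$igs_rank),
                   file.path(outdir, "igs_divergence.tsv"))
  }

  say("pairwise dN/dS screen")
  res$omega <- tryCatch(omega_table(targets, res$census),
                        error = function(e) { say("dnds skipped: ",
                                                  conditionMessage(e)); NULL })
  if (!is.null(res$omega)) {
    write_tsv_file(tibble::as_tibble(res$omega), file.path(outdir, "omega.tsv"))
  }

  say("barcode marker design")
  if (!is.null(res$igs_rank) && nrow(res$igs_rank)) {
    region <- marker_region %||% res$igs_rank$region[1]
    seqs <- res$igs$sequence[res$igs$region == region]
    names(seqs) <- res$igs$species[res$igs$region == region]
    msa <- build_msa(seqs)
    res$markers <- primer_search(msa, min_len = min_len, max_len = max_len,
                                 primer_len = primer_len, region = region)
    write_tsv_file(tibble::as_tibble(res$markers),
                   file.path(outdir, "markers.tsv"))
    if (nrow(res$markers) && length(seqs) >= 3L) {
      res$discrimination <- discrimination_matrix(res$markers, names(seqs))
      write_tsv_file(res$discrimination$per_pair,
                     file.path(outdir, "discrimination.tsv"))
    }
  }
  say("done")
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(res)
}

write_tsv_file <- function(x, path) {
  utils::write.table(flatten_for_tsv(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

flatten_for_tsv <- function(x) {
  x <- as.data.frame(x)
  is_list <- vapply(x, is.list, logical(1))
  x[is_list] <- lapply(x[is_list], function(col)
    vapply(col, function(v) paste(v, collapse = ","), character(1)))
  x
}
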