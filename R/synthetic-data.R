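# Synthetic circular quadripartite plastomes with a truth manifest.
#
# Genomes are assembled from an internal "builder": region sequences for
# LSC, IRb and SSC (IRa is always derived as revcomp(IRb)) plus a
# region-relative feature table. All randomness flows through seeds derived
# from the config seed; per-species substreams are derived by hashing the
# species id, so adding a species never perturbs the others.

PLASTID_GENE_POOL <- c(
  "matK", "rbcL", "atpA", "atpB", "atpE", "atpF", "atpH", "atpI",
  "rpoA", "rpoB", "rpoC1", "rpoC2", "psaA", "psaB", "psaC", "psaI", "psaJ",
  "psbA", "psbB", "psbC", "psbD", "psbE", "psbF", "psbH", "psbI", "psbJ",
  "psbK", "psbL", "psbM", "psbN", "psbT", "psbZ", "petA", "petB", "petD",
  "petG", "petL", "petN", "ndhA", "ndhB", "ndhC", "ndhD", "ndhE", "ndhF",
  "ndhG", "ndhH", "ndhI", "ndhJ", "ndhK", "rps2", "rps3", "rps4", "rps7",
  "rps8", "rps11", "rps12", "rps14", "rps15", "rps16", "rps18", "rps19",
  "rpl2", "rpl14", "rpl16", "rpl20", "rpl22", "rpl23", "rpl32", "rpl33",
  "rpl36", "clpP", "accD", "ccsA", "cemA", "infA", "ycf1", "ycf2", "ycf3",
  "ycf4", "ycf15")

TRNA_POOL <- c("trnH-GUG", "trnK-UUU", "trnQ-UUG", "trnS-GCU", "trnC-GCA",
               "trnD-GUC", "trnY-GUA", "trnE-UUC", "trnR-ACG", "trnN-GUU",
               "trnL-UAA", "trnF-GAA")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable 31-bit hash of a string, mixed with the master seed
derive_seed <- function(seed, id) {
  h <- 0
  for (v in utf8ToInt(id)) h <- (h * 131 + v) %% 1048573
  as.integer((as.numeric(seed) * 2654435 + h * 977 + 12345) %% 2147483587)
}

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random valid ORF: start codon, sense codons, stop codon
rand_orf <- function(n_codons) {
  sense <- setdiff(names(GENETIC_CODE_MAP), STOP_CODONS)
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), sample(STOP_CODONS, 1L))
}

#' Configuration for the synthetic plastome generator
#'
#' Defaults produce an ~18 kb toy with 30 protein-coding genes and four
#' degraded species emulating a holoparasite series: a handful of gene
#' deletions and pseudogenizations per species (mixed frameshift / premature
#' stop / truncation mechanisms), modest IR boundary shifts, and intergenic
#' point mutations with transition/transversion ratio kappa = 2. One long
#' (400 nt) spacer is always created so barcode markers can be planted.
#'
#' @param seed master seed; every stage derives its stream from it.
#' @param n_pcg number of protein-coding genes in the reference.
#' @param n_trna number of tRNA placeholders in single-copy regions.
#' @param lsc_len,ssc_len,ir_len target region lengths (nt); packing errors
#'   if the gene content does not fit.
#' @param igs_len min/max intergenic spacer length (nt).
#' @param cds_codons min/max CDS length in codons (including start/stop).
#' @param marker_igs_len length of the designated long spacer.
#' @param species named list of per-species settings; each entry may set
#'   `deletions` (gene symbols) or `n_deletions`, `pseudo` (named counts for
#'   `frameshift`, `premature_stop`, `truncation`) or explicit
#'   `pseudo_genes`, `ir_delta` (signed nt), `invert_ssc`, `igs_sub_rate`,
#'   `kappa`, `hypervariable_igs` (`list(region =, multiplier =)`).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_pcg = 30L, n_trna = 6L,
                       lsc_len = 10000L, ssc_len = 3000L, ir_len = 2500L,
                       igs_len = c(80L, 200L), cds_codons = c(40L, 80L),
                       marker_igs_len = 400L,
                       species = NULL) {
  if (is.null(species)) {
    species <- list(
      spA = list(n_deletions = 3L,
                 pseudo = c(frameshift = 2L, premature_stop = 1L, truncation = 1L),
                 ir_delta = 120L, igs_sub_rate = 0.02, kappa = 2),
      spB = list(n_deletions = 4L,
                 pseudo = c(frameshift = 1L, premature_stop = 2L, truncation = 1L),
                 ir_delta = -80L, igs_sub_rate = 0.02, kappa = 2),
      spC = list(n_deletions = 5L,
                 pseudo = c(frameshift = 2L, premature_stop = 2L, truncation = 1L),
                 ir_delta = 0L, igs_sub_rate = 0.02, kappa = 2),
      spD = list(n_deletions = 6L,
                 pseudo = c(frameshift = 2L, premature_stop = 2L, truncation = 2L),
                 ir_delta = 60L, igs_sub_rate = 0.02, kappa = 2)
    )
  }
  stopifnot(n_pcg >= 2L, ir_len >= 1000L, lsc_len > ssc_len)
  structure(list(seed = as.integer(seed), n_pcg = as.integer(n_pcg),
                 n_trna = as.integer(n_trna), lsc_len = as.integer(lsc_len),
                 ssc_len = as.integer(ssc_len), ir_len = as.integer(ir_len),
                 igs_len = as.integer(igs_len),
                 cds_codons = as.integer(cds_codons),
                 marker_igs_len = as.integer(marker_igs_len),
                 species = species),
            class = "sim_config")
}

## ---- builder ---------------------------------------------------------------

builder_new <- function() {
  list(regions = list(lsc = "", irb = "", ssc = ""),
       features = tibble::tibble(gene = character(), kind = character(),
                                 region = character(), start = integer(),
                                 end = integer(), strand = character()))
}

builder_add <- function(b, region, gene, kind, seqs, strand = "+") {
  pos <- nchar(b$regions[[region]])
  b$regions[[region]] <- paste0(b$regions[[region]], seqs)
  b$features <- dplyr::bind_rows(b$features, tibble::tibble(
    gene = gene, kind = kind, region = region,
    start = pos, end = pos + nchar(seqs), strand = strand))
  b
}

builder_pad <- function(b, region, seqs) {
  b$regions[[region]] <- paste0(b$regions[[region]], seqs)
  b
}

# ensure the detected IR cannot extend by one base beyond the planted
# boundaries: first LSC base vs last LSC base, first vs last SSC base
fix_ir_boundaries <- function(b) {
  fix <- function(s, at, avoid) {
    cur <- substr(s, at, at)
    if (cur != avoid) return(s)
    repl <- setdiff(c("A", "C", "G", "T"), avoid)[1]
    paste0(substr(s, 1L, at - 1L), repl, substr(s, at + 1L, nchar(s)))
  }
  comp1 <- function(x) chartr("ACGT", "TGCA", x)
  lsc <- b$regions$lsc; ssc <- b$regions$ssc
  # outward: first LSC base must not complement last LSC base
  b$regions$lsc <- fix(lsc, 1L, comp1(substr(lsc, nchar(lsc), nchar(lsc))))
  # inward: first SSC base must not complement last SSC base
  b$regions$ssc <- fix(ssc, 1L, comp1(substr(ssc, nchar(ssc), nchar(ssc))))
  b
}

# assemble a plastome object from a builder (IRa derived from IRb)
emit_plastome <- function(b, id) {
  b <- fix_ir_boundaries(b)
  lsc <- b$regions$lsc; irb <- b$regions$irb; ssc <- b$regions$ssc
  L <- nchar(lsc); I <- nchar(irb); S <- nchar(ssc)
  sequence <- paste0(lsc, irb, ssc, revcomp(irb))
  offs <- c(lsc = 0L, irb = L, ssc = L + I)
  f <- b$features
  main <- tibble::tibble(gene = f$gene, kind = f$kind,
                         start = f$start + unname(offs[f$region]),
                         end = f$end + unname(offs[f$region]),
                         strand = f$strand)
  ir <- f[f$region == "irb", ]
  mirror <- tibble::tibble(gene = ir$gene, kind = ir$kind,
                           start = L + I + S + (I - ir$end),
                           end = L + I + S + (I - ir$start),
                           strand = ifelse(ir$strand == "+", "-", "+"))
  plastome(id = id, sequence = sequence,
           features = dplyr::bind_rows(main, mirror), circular = TRUE,
           source = NA_character_)
}

builder_boundaries <- function(b) {
  L <- nchar(b$regions$lsc); I <- nchar(b$regions$irb)
  S <- nchar(b$regions$ssc)
  list(lsc = c(0L, L), irb = c(L, L + I), ssc = c(L + I, L + I + S),
       ira = c(L + I + S, L + 2L * I + S),
       junctions = c(JLB = L, JSB = L + I, JSA = L + I + S, JLA = 0L),
       ir_length = I, genome_length = L + 2L * I + S)
}

# spacers between consecutive features inside one single-copy region
builder_spacers <- function(b, region) {
  f <- b$features[b$features$region == region, ]
  f <- f[order(f$start), ]
  if (nrow(f) < 2L) return(tibble::tibble())
  i <- seq_len(nrow(f) - 1L)
  s <- f$end[i]; e <- f$start[i + 1L]
  keep <- e > s
  tibble::tibble(
    region = region, start = s[keep], end = e[keep],
    length = (e - s)[keep],
    up = f$gene[i][keep], dn = f$gene[i + 1L][keep],
    name = paste0(normalize_gene_name(f$gene[i][keep]), "-",
                  normalize_gene_name(f$gene[i + 1L][keep])))
}

## ---- reference -------------------------------------------------------------

#' Build the synthetic reference plastome
#'
#' Circular LSC-IRb-SSC-IRa genome with non-overlapping valid ORFs (start
#' codon, no internal stop, terminal stop) and tRNA placeholders in the
#' single-copy regions, and an rRNA-like block duplicated in the inverted
#' repeats. Same seed, same genome, byte for byte.
#'
#' @param cfg a [sim_config()].
#' @return a list: `plastome`, `builder` (internal), `gene_table` (gene,
#'   kind, region), `boundaries`.
#' @export
make_reference <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "reference"), {
    pool <- PLASTID_GENE_POOL
    if (cfg$n_pcg > length(pool)) {
      pool <- c(pool, sprintf("orf%03d", seq_len(cfg$n_pcg - length(pool))))
    }
    genes <- pool[seq_len(cfg$n_pcg)]
    n_ssc <- max(1L, round(cfg$n_pcg * 0.2))
    ssc_genes <- genes[(cfg$n_pcg - n_ssc + 1L):cfg$n_pcg]
    lsc_genes <- setdiff(genes, ssc_genes)
    trnas <- TRNA_POOL[seq_len(min(cfg$n_trna, length(TRNA_POOL)))]

    igs <- function() rand_dna(sample(cfg$igs_len[1]:cfg$igs_len[2], 1L))
    orf <- function() rand_orf(sample(cfg$cds_codons[1]:cfg$cds_codons[2], 1L))

    b <- builder_new()
    # LSC: leading spacer, genes with spacers, one designated long spacer
    b <- builder_pad(b, "lsc", igs())
    add_cds <- function(b, region, gene) {
      strand <- sample(c("+", "-"), 1L)
      cds <- orf()  # stored on the forward strand; extraction undoes this
      builder_add(b, region, gene, "CDS",
                  if (strand == "-") revcomp(cds) else cds, strand = strand)
    }
    marker_after <- ceiling(length(lsc_genes) / 2)
    for (i in seq_along(lsc_genes)) {
      b <- add_cds(b, "lsc", lsc_genes[i])
      b <- builder_pad(b, "lsc",
                       if (i == marker_after) rand_dna(cfg$marker_igs_len) else igs())
    }
    for (tn in trnas[seq_len(ceiling(length(trnas) / 2))]) {
      b <- builder_add(b, "lsc", tn, "tRNA", rand_dna(75L),
                       strand = sample(c("+", "-"), 1L))
      b <- builder_pad(b, "lsc", igs())
    }
    used <- nchar(b$regions$lsc)
    if (used > cfg$lsc_len) stop("infeasible packing: LSC content ", used,
                                 " nt exceeds lsc_len ", cfg$lsc_len)
    b <- builder_pad(b, "lsc", rand_dna(cfg$lsc_len - used))

    # IRb: leading pad (boundary-shift buffer), rRNA block, tRNA, pad
    b <- builder_pad(b, "irb", rand_dna(300L))
    b <- builder_add(b, "irb", "rrn16", "rRNA", rand_dna(700L))
    b <- builder_pad(b, "irb", rand_dna(120L))
    b <- builder_add(b, "irb", "trnI-GAU", "tRNA", rand_dna(75L))
    used <- nchar(b$regions$irb)
    if (used > cfg$ir_len) stop("infeasible packing: IR content ", used,
                                " nt exceeds ir_len ", cfg$ir_len)
    b <- builder_pad(b, "irb", rand_dna(cfg$ir_len - used))

    # SSC
    b <- builder_pad(b, "ssc", igs())
    for (g in ssc_genes) {
      b <- add_cds(b, "ssc", g)
      b <- builder_pad(b, "ssc", igs())
    }
    for (tn in trnas[-seq_len(ceiling(length(trnas) / 2))]) {
      b <- builder_add(b, "ssc", tn, "tRNA", rand_dna(75L))
      b <- builder_pad(b, "ssc", igs())
    }
    used <- nchar(b$regions$ssc)
    if (used > cfg$ssc_len) stop("infeasible packing: SSC content ", used,
                                 " nt exceeds ssc_len ", cfg$ssc_len)
    b <- builder_pad(b, "ssc", rand_dna(cfg$ssc_len - used))
    b <- fix_ir_boundaries(b)

    p <- emit_plastome(b, "reference")
    gene_table <- b$features[c("gene", "kind", "region")]
    # genes flanking the designated long spacer are kept intact in every
    # species (marker design presumes conserved flanking anchors)
    marker_flanks <- c(lsc_genes[marker_after],
                       if (marker_after < length(lsc_genes))
                         lsc_genes[marker_after + 1L] else trnas[1])
    list(plastome = p, builder = b, gene_table = gene_table,
         boundaries = builder_boundaries(b), marker_flanks = marker_flanks)
  })
}

## ---- degradation -----------------------------------------------------------

#' Degrade the reference into one synthetic species
#'
#' Applies, in order: gene deletions (feature and sequence removed),
#' pseudogenization (frameshift = 1-2 nt indel at a uniform position in the
#' first 70% of the CDS; premature stop = point mutation creating a stop in
#' the first 70% of codons; truncation = removal of >10% of the terminal
#' CDS), an IR boundary
#' shift of `ir_delta` nt (migrating sequence between LSC and the repeats
#' while keeping IRa == revcomp(IRb)), an optional SSC inversion, and
#' intergenic point mutations with transition probability
#' `kappa / (kappa + 2)`.
#'
#' @param ref a [make_reference()] result.
#' @param species_cfg one entry of `sim_config()$species`.
#' @param species_id species label (also seeds the per-species RNG stream).
#' @param seed master seed (defaults to the one the reference builder can no
#'   longer see; pass `cfg$seed`).
#' @return a list: `plastome`, `builder`, `truth` (list with `lost`,
#'   `pseudo` tibble, `ir_delta`, `boundaries`, `igs_mutations` tibble).
#' @export
degrade <- function(ref, species_cfg = list(), species_id, seed = 1L) {
  b <- ref$builder
  sc <- species_cfg
  with_seed(derive_seed(seed, species_id), {
    pcg <- b$features$gene[b$features$kind == "CDS"]
    protected <- ref$marker_flanks %||% character(0)

    lost <- sc$deletions
    if (is.null(lost) && !is.null(sc$n_deletions) && sc$n_deletions > 0L) {
      lost <- sample(setdiff(pcg, protected), sc$n_deletions)
    }
    lost <- intersect(lost %||% character(0), pcg)
    for (g in lost) b <- builder_delete_gene(b, g)

    remaining <- setdiff(pcg, lost)
    pseudo <- tibble::tibble(gene = character(), mechanism = character())
    if (!is.null(sc$pseudo_genes)) {
      pseudo <- tibble::as_tibble(sc$pseudo_genes)
    } else if (!is.null(sc$pseudo)) {
      cnt <- sc$pseudo
      total <- sum(cnt)
      if (total > length(remaining)) stop("more pseudogenes requested than genes left")
      pick <- sample(setdiff(remaining, protected), total)
      pseudo <- tibble::tibble(
        gene = pick,
        mechanism = rep(names(cnt), times = cnt))
    }
    for (i in seq_len(nrow(pseudo))) {
      b <- builder_pseudogenize(b, pseudo$gene[i], pseudo$mechanism[i])
    }

    ir_delta <- sc$ir_delta %||% 0L
    if (ir_delta != 0L) b <- builder_shift_ir(b, as.integer(ir_delta))
    if (isTRUE(sc$invert_ssc)) b <- builder_invert_ssc(b)

    igs_tab <- tibble::tibble()
    rate <- sc$igs_sub_rate %||% 0
    if (rate > 0) {
      res <- builder_mutate_igs(b, rate, kappa = sc$kappa %||% 2,
                                hyper = sc$hypervariable_igs)
      b <- res$builder
      igs_tab <- res$counts
    }
    b <- fix_ir_boundaries(b)
    p <- emit_plastome(b, species_id)
    list(plastome = p, builder = b,
         truth = list(lost = lost, pseudo = pseudo, ir_delta = ir_delta,
                      invert_ssc = isTRUE(sc$invert_ssc),
                      boundaries = builder_boundaries(b),
                      igs_mutations = igs_tab))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

builder_feature_row <- function(b, gene) {
  i <- which(b$features$gene == gene)
  if (!length(i)) stop("gene not in builder: ", gene)
  i[1]
}

# remove a span [s, e) from a region string, shifting downstream features
builder_cut <- function(b, region, s, e) {
  seqs <- b$regions[[region]]
  b$regions[[region]] <- paste0(substr(seqs, 1L, s), substr(seqs, e + 1L, nchar(seqs)))
  w <- b$features$region == region
  len <- e - s
  overlaps <- w & b$features$start < e & b$features$end > s
  if (any(overlaps)) stop("cut overlaps a feature")
  shift <- w & b$features$start >= e
  b$features$start[shift] <- b$features$start[shift] - len
  b$features$end[shift] <- b$features$end[shift] - len
  b
}

builder_delete_gene <- function(b, gene) {
  i <- builder_feature_row(b, gene)
  region <- b$features$region[i]
  s <- b$features$start[i]; e <- b$features$end[i]
  b$features <- b$features[-i, ]
  builder_cut(b, region, s, e)
}

# splice new sequence in place of [s, e) within a feature, updating lengths
builder_splice <- function(b, region, s, e, replacement) {
  seqs <- b$regions[[region]]
  b$regions[[region]] <- paste0(substr(seqs, 1L, s), replacement,
                                substr(seqs, e + 1L, nchar(seqs)))
  delta <- nchar(replacement) - (e - s)
  w <- which(b$features$region == region)
  for (i in w) {
    if (b$features$start[i] >= e) {
      b$features$start[i] <- b$features$start[i] + delta
      b$features$end[i] <- b$features$end[i] + delta
    } else if (b$features$end[i] > s) {
      b$features$end[i] <- b$features$end[i] + delta  # edited inside feature
    }
  }
  b
}

builder_pseudogenize <- function(b, gene, mechanism) {
  i <- builder_feature_row(b, gene)
  region <- b$features$region[i]
  s <- b$features$start[i]; e <- b$features$end[i]
  cds <- substr(b$regions[[region]], s + 1L, e)
  if (b$features$strand[i] == "-") cds <- revcomp(cds)
  n <- nchar(cds); ncod <- n %/% 3L

  edit_cds <- function(cds) {
    if (mechanism == "frameshift") {
      k <- sample(1:2, 1L)
      # within the first 70% so the shifted tail is long enough to diagnose
      at <- sample(seq(4L, min(floor(0.7 * n), n - 4L - k)), 1L)
      if (stats::runif(1) < 0.5) {
        paste0(substr(cds, 1L, at), substr(cds, at + k + 1L, n))      # deletion
      } else {
        paste0(substr(cds, 1L, at), rand_dna(k), substr(cds, at + 1L, n))
      }
    } else if (mechanism == "premature_stop") {
      lim <- max(2L, floor(0.7 * ncod))
      cand_start <- sample(2:lim, 1L)
      for (ci in c(cand_start:lim, 2:cand_start)) {
        cod <- substr(cds, 3L * ci - 2L, 3L * ci)
        for (stp in STOP_CODONS) {
          dif <- which(strsplit(cod, "")[[1]] != strsplit(stp, "")[[1]])
          if (length(dif) == 1L) {
            return(paste0(substr(cds, 1L, 3L * (ci - 1L) + dif - 1L),
                          substr(stp, dif, dif),
                          substr(cds, 3L * (ci - 1L) + dif + 1L, n)))
          }
        }
      }
      stop("no codon mutable to a stop in ", gene)
    } else if (mechanism == "truncation") {
      frac <- stats::runif(1, 0.15, 0.4)
      keep <- n - ceiling(frac * n)
      substr(cds, 1L, keep)
    } else stop("unknown pseudogenization mechanism: ", mechanism)
  }
  new_cds <- edit_cds(cds)
  if (b$features$strand[i] == "-") new_cds <- revcomp(new_cds)
  b <- builder_splice(b, region, s, e, new_cds)
  b$features$kind[b$features$gene == gene] <- "pseudo"
  b
}

# signed IR boundary shift at the LSC|IRb boundary (and, by mirror symmetry,
# the IRa|LSC boundary). Positive delta: the IR expands, duplicating the
# last delta nt of LSC. Negative: the first |delta| nt of IRb become
# single-copy LSC sequence (the mirrored copy in IRa is lost).
builder_shift_ir <- function(b, delta) {
  lsc <- b$regions$lsc; irb <- b$regions$irb
  L <- nchar(lsc); I <- nchar(irb)
  if (delta > 0L) {
    if (delta >= L) stop("ir_delta exceeds adjacent single-copy length")
    if (any(b$features$region == "lsc" & b$features$end > L - delta))
      stop("IR shift would cut a feature")
    b$regions$lsc <- substr(lsc, 1L, L - delta)
    b$regions$irb <- paste0(substr(lsc, L - delta + 1L, L), irb)
    w <- b$features$region == "irb"
    b$features$start[w] <- b$features$start[w] + delta
    b$features$end[w] <- b$features$end[w] + delta
  } else {
    d <- -delta
    if (d >= I) stop("ir_delta exceeds IR length")
    if (any(b$features$region == "irb" & b$features$start < d))
      stop("IR shift would cut a feature")
    b$regions$lsc <- paste0(lsc, substr(irb, 1L, d))
    b$regions$irb <- substr(irb, d + 1L, I)
    w <- b$features$region == "irb"
    b$features$start[w] <- b$features$start[w] - d
    b$features$end[w] <- b$features$end[w] - d
  }
  b
}

builder_invert_ssc <- function(b) {
  S <- nchar(b$regions$ssc)
  b$regions$ssc <- revcomp(b$regions$ssc)
  w <- which(b$features$region == "ssc")
  for (i in w) {
    s <- b$features$start[i]; e <- b$features$end[i]
    b$features$start[i] <- S - e
    b$features$end[i] <- S - s
    b$features$strand[i] <- if (b$features$strand[i] == "+") "-" else "+"
  }
  b$features <- b$features[order(b$features$region, b$features$start), ]
  b
}

# point mutations in single-copy intergenic positions
builder_mutate_igs <- function(b, rate, kappa = 2, hyper = NULL) {
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  counts <- list()
  for (region in c("lsc", "ssc")) {
    sp <- builder_spacers(b, region)
    if (!nrow(sp)) next
    ch <- seq_chars(b$regions[[region]])
    for (r in seq_len(nrow(sp))) {
      mult <- 1
      if (!is.null(hyper) && identical(hyper$region, sp$name[r])) {
        mult <- hyper$multiplier %||% 10
      }
      idx <- (sp$start[r] + 1L):sp$end[r]
      hitp <- stats::runif(length(idx)) < rate * mult
      nts <- 0L; ntv <- 0L
      for (pos in idx[hitp]) {
        base <- ch[pos]
        if (!base %in% names(transitions)) next
        if (stats::runif(1) < kappa / (kappa + 2)) {
          ch[pos] <- transitions[[base]]; nts <- nts + 1L
        } else {
          ch[pos] <- sample(transversions[[base]], 1L); ntv <- ntv + 1L
        }
      }
      counts[[length(counts) + 1L]] <- tibble::tibble(
        region_name = sp$name[r], region = region, length = sp$length[r],
        transitions = nts, transversions = ntv)
    }
    b$regions[[region]] <- paste(ch, collapse = "")
  }
  list(builder = b, counts = dplyr::bind_rows(counts))
}

## ---- one-call simulation + marker planting ---------------------------------

#' Simulate a reference and a set of degraded plastomes
#'
#' @param cfg a [sim_config()].
#' @return a list of class `plastome_sim`: `reference` (plastome), `species`
#'   (named list of plastomes), `manifest` (per-species truth), `builders`
#'   (internal, used by [plant_marker()]), `cfg`.
#' @export
simulate_plastomes <- function(cfg = sim_config()) {
  ref <- make_reference(cfg)
  species <- list(); manifest <- list(); builders <- list()
  for (sp in names(cfg$species)) {
    d <- degrade(ref, cfg$species[[sp]], sp, seed = cfg$seed)
    species[[sp]] <- d$plastome
    manifest[[sp]] <- d$truth
    builders[[sp]] <- d$builder
  }
  structure(list(reference = ref$plastome, species = species,
                 manifest = manifest,
                 builders = c(list(reference = ref$builder), builders),
                 gene_table = ref$gene_table,
                 ref_boundaries = ref$boundaries,
                 marker_flanks = ref$marker_flanks, cfg = cfg),
            class = "plastome_sim")
}

#' @export
print.plastome_sim <- function(x, ...) {
  cat(sprintf("<plastome_sim> reference %d nt + %d species (seed %d)\n",
              nchar(x$reference$sequence), length(x$species), x$cfg$seed))
  invisible(x)
}

#' Plant species-diagnostic marker sites into a simulated set
#'
#' Overwrites one long spacer with a common base sequence carrying conserved
#' flanks, then plants `k_snps` private SNPs and `m_indels` private 3-nt
#' deletions, assigned round-robin to the species. The planted truth is the
#' oracle for the barcode stage.
#'
#' @param sim a [simulate_plastomes()] result.
#' @param k_snps,m_indels numbers of private SNP / indel sites.
#' @param flank_len conserved flank length (nt) on each side.
#' @param region spacer name ("geneA-geneB"); default: the longest LSC
#'   spacer of the reference.
#' @param species species receiving sites (default: all).
#' @return `sim`, with modified species plastomes/builders and a new
#'   `marker_truth` element (tibble: `site`, `kind`, `species`, `pos`,
#'   `state`, plus attributes `region` and `flank_len`).
#' @export
plant_marker <- function(sim, k_snps = 9L, m_indels = 3L, flank_len = 60L,
                         region = NULL, species = NULL) {
  stopifnot(inherits(sim, "plastome_sim"))
  species <- species %||% names(sim$species)
  ref_b <- sim$builders$reference
  sp_tab <- builder_spacers(ref_b, "lsc")
  if (is.null(region)) {
    # longest reference spacer whose flank pair survives in every species
    in_all <- vapply(sp_tab$name, function(nm) {
      all(vapply(names(sim$species), function(sp)
        nm %in% builder_spacers(sim$builders[[sp]], "lsc")$name, logical(1)))
    }, logical(1))
    if (!any(in_all)) stop("no spacer shared by all species")
    cand <- sp_tab[in_all, ]
    region <- cand$name[which.max(cand$length)]
  }
  row <- sp_tab[sp_tab$name == region, ]
  if (!nrow(row)) stop("no such spacer in reference: ", region)
  n_sites <- k_snps + m_indels
  step <- 7L
  need <- 2L * flank_len + 5L + step * n_sites + 5L
  if (row$length[1] < need) {
    stop("insufficient spacer length: ", region, " has ", row$length[1],
         " nt, need ", need)
  }
  base_seq <- substr(ref_b$regions$lsc, row$start[1] + 1L, row$end[1])

  # per-site layout on the base spacer (1-based positions)
  site_pos <- flank_len + 5L + step * (seq_len(n_sites) - 1L)
  kinds <- c(rep("SNP", k_snps), rep("indel", m_indels))

  # make every planted 3-nt deletion positionally unambiguous: block shifts
  # of the deletion window by one (base[p-1] != base[p+2], base[p] != base[p+3])
  bch <- seq_chars(base_seq)
  pick_base <- function(avoid) setdiff(c("A", "C", "G", "T"), avoid)[1]
  for (si in which(kinds == "indel")) {
    p <- site_pos[si]
    if (bch[p - 1L] == bch[p + 2L]) {
      bch[p + 2L] <- pick_base(c(bch[p - 1L], bch[p + 1L], bch[p + 3L]))
    }
    if (bch[p] == bch[p + 3L]) {
      bch[p + 3L] <- pick_base(c(bch[p], bch[p + 2L], bch[p + 4L]))
    }
  }
  base_seq <- paste(bch, collapse = "")
  owner_snp <- species[((seq_len(k_snps) - 1L) %% length(species)) + 1L]
  owner_ind <- species[((seq_len(m_indels) - 1L) %% length(species)) + 1L]
  owners <- c(owner_snp, owner_ind)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")

  truth <- tibble::tibble(site = seq_len(n_sites), kind = kinds,
                          species = owners, pos = site_pos,
                          state = NA_character_)
  for (sp in names(sim$species)) {
    b <- sim$builders[[sp]]
    tab <- builder_spacers(b, "lsc")
    hit <- tab[tab$name == region, ]
    if (!nrow(hit)) {
      stop("spacer ", region, " missing in ", sp,
           " (a flanking gene was deleted)")
    }
    s <- hit$start[1]; e <- hit$end[1]
    newseq <- base_seq
    mine <- which(owners == sp)
    for (si in rev(mine)) {  # descending positions: edits do not shift others
      p <- site_pos[si]
      if (kinds[si] == "SNP") {
        old <- substr(newseq, p, p)
        newb <- transitions[[old]]
        newseq <- paste0(substr(newseq, 1L, p - 1L), newb,
                         substr(newseq, p + 1L, nchar(newseq)))
        truth$state[si] <- newb
      } else {
        newseq <- paste0(substr(newseq, 1L, p - 1L),
                         substr(newseq, p + 3L, nchar(newseq)))
        truth$state[si] <- "---"
      }
    }
    b <- builder_splice(b, "lsc", s, e, newseq)
    sim$builders[[sp]] <- b
    sim$species[[sp]] <- emit_plastome(b, sp)
  }
  # SNP states are identical edits across species of the same site position,
  # fill from the base sequence for sites owned by absent species
  for (si in seq_len(n_sites)) {
    if (is.na(truth$state[si])) {
      truth$state[si] <- if (kinds[si] == "SNP")
        transitions[[substr(base_seq, site_pos[si], site_pos[si])]] else "---"
    }
  }
  attr(truth, "region") <- region
  attr(truth, "flank_len") <- flank_len
  attr(truth, "base_seq") <- base_seq
  sim$marker_truth <- truth
  sim
}

#' Plant synonymous and nonsynonymous substitutions into a CDS
#'
#' Introduces exactly `n_syn` synonymous and `n_nonsyn` nonsynonymous
#' single-base substitutions at distinct codons (never the start or stop
#' codon, never creating a stop), for simulating selection regimes with a
#' known substitution mix.
#'
#' @param cds a valid CDS string.
#' @param n_syn,n_nonsyn substitution counts.
#' @param seed RNG seed.
#' @return the mutated CDS string.
#' @export
mutate_cds_sites <- function(cds, n_syn, n_nonsyn, seed = 1L) {
  with_seed(as.integer(seed), {
    cods <- split_codons(toupper(cds))
    ncod <- length(cods)
    editable <- 2:(ncod - 1L)
    bases <- c("A", "C", "G", "T")
    options_for <- function(cod, syn) {
      aa <- GENETIC_CODE_MAP[[cod]]
      out <- list()
      ch <- strsplit(cod, "")[[1]]
      for (pos in 1:3) for (b in setdiff(bases, ch[pos])) {
        alt <- ch; alt[pos] <- b; alt <- paste(alt, collapse = "")
        if (is_stop(alt)) next
        if ((GENETIC_CODE_MAP[[alt]] == aa) == syn) out[[length(out) + 1L]] <- alt
      }
      out
    }
    picks <- sample(editable, n_syn + n_nonsyn)
    types <- c(rep(TRUE, n_syn), rep(FALSE, n_nonsyn))
    for (k in seq_along(picks)) {
      i <- picks[k]
      opts <- options_for(cods[i], types[k])
      tries <- 0L
      while (!length(opts) && tries < 50L) {  # codon without a move of this type
        i <- sample(setdiff(editable, picks), 1L)
        opts <- options_for(cods[i], types[k])
        tries <- tries + 1L
      }
      if (!length(opts)) stop("could not place substitution")
      cods[i] <- opts[[sample.int(length(opts), 1L)]]
    }
    paste(cods, collapse = "")
  })
}

#' Extract one named spacer's sequence from every simulated species
#'
#' @param sim a `plastome_sim` (after [plant_marker()] or not).
#' @param region spacer name.
#' @return named character vector of spacer sequences.
#' @export
sim_spacer_seqs <- function(sim, region) {
  out <- character(0)
  for (sp in names(sim$species)) {
    b <- sim$builders[[sp]]
    tab <- builder_spacers(b, "lsc")
    hit <- tab[tab$name == region, ]
    if (!nrow(hit)) next
    out[sp] <- substr(b$regions$lsc, hit$start[1] + 1L, hit$end[1])
  }
  out
}
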