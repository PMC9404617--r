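#' Construct an annotated plastome object
#'
#' The central container of the package: a (by default circular) DNA sequence
#' plus an ordered table of gene features. All coordinates are 0-based
#' half-open; GenBank I/O converts at the boundary.
#'
#' @param id accession or sample identifier.
#' @param sequence a single DNA string over `{A,C,G,T,N}` (IUPAC codes are
#'   preserved but excluded from distance computations downstream).
#' @param features a data frame with columns `gene` (symbol), `kind`
#'   (`"CDS"`, `"tRNA"`, `"rRNA"` or `"pseudo"`), `strand` (`"+"`/`"-"`), and
#'   either integer columns `start`,`end` (single-interval features) or list
#'   columns `starts`,`ends` (multi-interval features, e.g. spliced genes or
#'   features wrapping the circular origin).
#' @param circular is the molecule circular? Default `TRUE`.
#' @param source optional source file path.
#' @return an object of class `plastome`.
#' @export
plastome <- function(id, sequence, features = NULL, circular = TRUE,
                     source = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  features <- normalize_features(features, n)
  structure(
    list(id = id, sequence = sequence, circular = isTRUE(circular),
         features = features, source = source),
    class = "plastome"
  )
}

# Canonical feature tibble: gene, kind, strand, starts (list), ends (list),
# start (first interval start, used for ordering), pseudo flag kept in kind.
normalize_features <- function(features, n) {
  if (is.null(features) || nrow(as.data.frame(features)) == 0L) {
    return(tibble::tibble(gene = character(), kind = character(),
                          strand = character(),
                          starts = list(), ends = list(), start = integer()))
  }
  f <- tibble::as_tibble(features)
  if (!"starts" %in% names(f)) {
    f$starts <- as.list(as.integer(f$start))
    f$ends <- as.list(as.integer(f$end))
  }
  f$starts <- lapply(f$starts, as.integer)
  f$ends <- lapply(f$ends, as.integer)
  bad_kind <- setdiff(unique(f$kind), c("CDS", "tRNA", "rRNA", "pseudo"))
  if (length(bad_kind)) stop("unknown feature kind: ", paste(bad_kind, collapse = ", "))
  stopifnot(all(f$strand %in% c("+", "-")))
  for (i in seq_len(nrow(f))) {
    s <- f$starts[[i]]; e <- f$ends[[i]]
    if (length(s) == 0L || length(s) != length(e)) stop("feature ", f$gene[i], ": bad intervals")
    wraps <- e < s  # a wrapping interval is allowed on circular molecules
    if (any(!wraps & (e <= s))) stop("feature ", f$gene[i], ": empty interval")
    if (any(s < 0L | s >= n) || any(e < 0L | e > n))
      stop("feature ", f$gene[i], ": interval outside [0, length)")
  }
  f$start <- vapply(f$starts, `[[`, integer(1), 1L)
  f <- f[order(f$start, vapply(f$ends, `[[`, integer(1), 1L), f$gene), , drop = FALSE]
  f[c("gene", "kind", "strand", "starts", "ends", "start")]
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %s nt (%s), %d features, GC %.2f%%\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features), 100 * gc_content(x$sequence)))
  invisible(x)
}

#' @export
length.plastome <- function(x) nchar(x$sequence)

#' Normalize a gene symbol for cross-genome matching
#'
#' Case-insensitive, with trailing copy suffixes (`"_1"`, `"-2"`, `"_copy1"`,
#' `"-fragment"`) stripped so that duplicated inverted-repeat copies collapse
#' to one symbol in the census.
#'
#' @param x character vector of gene symbols.
#' @return normalized symbols.
#' @export
normalize_gene_name <- function(x) {
  x <- sub("(?i)([_-](copy)?\\d+|[_-]fragment\\d*)$", "", x, perl = TRUE)
  tolower(x)
}

## ---- GenBank flat file ------------------------------------------------------

#' Read an annotated plastome from a GenBank flat file
#'
#' Captures `gene`, `CDS`, `tRNA` and `rRNA` features; converts 1-based
#' inclusive GenBank coordinates to 0-based half-open; honours
#' `complement()` and `join()` locations; features carrying a `/pseudo`
#' qualifier get `kind = "pseudo"`. Standalone `gene` features are kept only
#' when no `CDS`/`tRNA`/`rRNA` feature shares their symbol (annotation styles
#' differ on whether pseudogenes get a CDS entry, so the reader accepts both).
#'
#' @param path path to a GenBank flat file.
#' @return a [plastome] object.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("malformed GenBank record: no LOCUS line in ", path)
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- if (length(locus) >= 2) locus[2] else basename(path)
  circular <- any(grepl("circular", lines[locus_i[1]], ignore.case = TRUE))

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) stop("GenBank record without sequence (no ORIGIN): ", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > orig_i[1]][1] else length(lines) + 1L

  seq_lines <- lines[(orig_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("GenBank record without sequence: ", path)

  feats <- list()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur)) return(NULL)
      cur$qualifiers <- paste(cur$qual_lines, collapse = " ")
      cur
    }
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) {  # new feature: key at column 6
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- flush(cur)
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        cur <- list(key = parts[1],
                    loc = paste(parts[-1], collapse = ""),
                    qual_lines = character(), in_loc = TRUE)
      } else if (!is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) {
          cur$in_loc <- FALSE
          cur$qual_lines <- c(cur$qual_lines, txt)
        } else if (isTRUE(cur$in_loc)) {
          cur$loc <- paste0(cur$loc, txt)  # continued location line
        } else if (length(cur$qual_lines)) {
          cur$qual_lines[length(cur$qual_lines)] <-
            paste(cur$qual_lines[length(cur$qual_lines)], txt)
        }
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- flush(cur)
  }

  keep <- c("gene", "CDS", "tRNA", "rRNA")
  rows <- list()
  for (ft in feats) {
    if (!(ft$key %in% keep)) next
    loc <- tryCatch(parse_genbank_location(ft$loc),
                    error = function(e) stop("cannot parse location '", ft$loc,
                                             "' in ", path, ": ", conditionMessage(e)))
    gene <- qualifier_value(ft$qualifiers, "gene")
    if (is.na(gene)) gene <- qualifier_value(ft$qualifiers, "locus_tag")
    if (is.na(gene)) gene <- qualifier_value(ft$qualifiers, "product")
    if (is.na(gene)) gene <- paste0(ft$key, "_", loc$starts[1] + 1L)
    pseudo <- grepl("/pseudo(gene)?\\b", ft$qualifiers)
    kind <- if (pseudo) "pseudo" else ft$key
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = gene, kind = kind, key = ft$key, strand = loc$strand,
      starts = list(loc$starts), ends = list(loc$ends))
  }
  f <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(gene = character(), kind = character(), key = character(),
                   strand = character(), starts = list(), ends = list())

  # drop standalone `gene` umbrella features duplicated by a concrete feature
  if (nrow(f)) {
    sym <- normalize_gene_name(f$gene)
    concrete <- sym[f$key != "gene"]
    drop <- f$key == "gene" & f$kind != "pseudo" & sym %in% concrete
    f <- f[!drop, , drop = FALSE]
    f$kind[f$key == "gene" & f$kind != "pseudo"] <- "CDS"
    f$key <- NULL
  } else f$key <- NULL

  plastome(id = id, sequence = sequence, features = f,
           circular = circular, source = path)
}

qualifier_value <- function(quals, name) {
  m <- regmatches(quals, regexpr(paste0("/", name, '="[^"]*"'), quals))
  if (!length(m)) {
    m <- regmatches(quals, regexpr(paste0("/", name, "=[^ /]+"), quals))
    if (!length(m)) return(NA_character_)
    return(sub(paste0("/", name, "="), "", m))
  }
  sub('"$', "", sub(paste0("/", name, '="'), "", m))
}

# GenBank location -> list(starts, ends (0-based half-open), strand)
parse_genbank_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  } else parts <- loc
  if (any(grepl("complement", parts))) {
    # complement inside join: rare; normalize to whole-feature complement
    parts <- sub("^complement\\((.*)\\)$", "\\1", parts)
    strand <- "-"
  }
  starts <- integer(0); ends <- integer(0)
  for (p in parts) {
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
      starts <- c(starts, ab[1] - 1L); ends <- c(ends, ab[2])
    } else if (grepl("^\\d+$", p)) {
      starts <- c(starts, as.integer(p) - 1L); ends <- c(ends, as.integer(p))
    } else stop("unsupported location element: ", p)
  }
  list(starts = starts, ends = ends, strand = strand)
}

#' Write a plastome as a GenBank flat file
#'
#' Emits a minimal, re-readable flavour of the format: a LOCUS line, a
#' feature table with `/gene` qualifiers (and `/pseudo` for pseudogene
#' features), and the ORIGIN sequence block. Round-trips through
#' [read_genbank()] with identical sequence and features.
#'
#' @param p a [plastome].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(p, path) {
  stopifnot(inherits(p, "plastome"))
  n <- nchar(p$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                     p$id, n, if (p$circular) "circular" else "linear",
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s plastome.", p$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  f <- p$features
  for (i in seq_len(nrow(f))) {
    segs <- sprintf("%d..%d", f$starts[[i]] + 1L, f$ends[[i]])
    loc <- if (length(segs) > 1L) sprintf("join(%s)", paste(segs, collapse = ",")) else segs
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    key <- if (f$kind[i] == "pseudo") "gene" else f$kind[i]
    writeLines(sprintf("     %-15s %s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$gene[i]), con)
    if (f$kind[i] == "pseudo") writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, n, by = 60L)
  for (s in pos) {
    chunk <- substr(p$sequence, s, min(s + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

## ---- FASTA / BED ------------------------------------------------------------

#' Read plastomes from a FASTA file
#'
#' @param path FASTA file; each record becomes an unannotated [plastome].
#' @param circular treat sequences as circular? Default `TRUE`.
#' @return a list of [plastome] objects.
#' @export
read_fasta_plastome <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i) {
    plastome(id = sub("\\s.*$", "", names(ss)[i]),
             sequence = as.character(ss[[i]]),
             circular = circular, source = path)
  })
}

#' Write plastome sequences to FASTA
#'
#' @param plastomes a [plastome] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_plastome <- function(plastomes, path) {
  if (inherits(plastomes, "plastome")) plastomes <- list(plastomes)
  ss <- Biostrings::DNAStringSet(vapply(plastomes, `[[`, character(1), "sequence"))
  names(ss) <- vapply(plastomes, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write named regions as a BED file
#'
#' BED uses the package's native 0-based half-open convention, so coordinates
#' pass through unchanged.
#'
#' @param regions a data frame with columns `name`, `start`, `end` (and
#'   optionally `chrom`).
#' @param path output path.
#' @param chrom chromosome/sequence name used when `regions` has no `chrom`
#'   column.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path, chrom = "plastome") {
  regions <- tibble::as_tibble(regions)
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(c("name", "start", "end") %in% names(regions)),
            all(regions$end > regions$start), all(regions$start >= 0))
  if (!"chrom" %in% names(regions)) regions$chrom <- chrom
  utils::write.table(regions[c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

## ---- feature sequence extraction -------------------------------------------

#' Extract the DNA sequence of a feature
#'
#' Concatenates the feature's interval sequences in order and
#' reverse-complements the result for minus-strand features. Intervals with
#' `end < start` wrap the circular origin.
#'
#' @param p a [plastome].
#' @param f a one-row feature tibble (a row of `p$features`), a row index, or
#'   a gene symbol (first match after [normalize_gene_name()]).
#' @return the feature's DNA string.
#' @export
extract_feature_sequence <- function(p, f) {
  stopifnot(inherits(p, "plastome"))
  if (is.character(f)) {
    idx <- which(normalize_gene_name(p$features$gene) == normalize_gene_name(f))
    if (!length(idx)) stop("no feature named ", f)
    f <- p$features[idx[1], ]
  } else if (is.numeric(f)) {
    f <- p$features[f, ]
  }
  n <- nchar(p$sequence)
  starts <- f$starts[[1]]; ends <- f$ends[[1]]
  segs <- character(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    if (e < s || e > n) {
      if (!p$circular) stop("interval exceeds sequence length on linear molecule")
    }
    segs[i] <- circ_substr(p$sequence, s, if (e < s) e else e)
  }
  out <- paste(segs, collapse = "")
  if (f$strand[[1]] == "-") out <- revcomp(out)
  out
}

# rotate a circular plastome so that original coordinate `offset` becomes 0
rotate_plastome <- function(p, offset) {
  stopifnot(inherits(p, "plastome"), p$circular)
  n <- nchar(p$sequence)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0L) return(p)
  seq2 <- paste0(substr(p$sequence, offset + 1L, n), substr(p$sequence, 1L, offset))
  f <- p$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      s <- (f$starts[[i]] - offset) %% n
      e <- f$ends[[i]] - offset
      e <- ifelse(e <= 0L, e + n, e)
      e <- ifelse(e > n, e - n, e)
      # an interval may now wrap: keep as (start > end) wrap representation
      f$starts[[i]] <- as.integer(s)
      f$ends[[i]] <- as.integer(ifelse(e == 0L, n, e))
    }
  }
  plastome(id = p$id, sequence = seq2, features = f, circular = TRUE,
           source = p$source)
}
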