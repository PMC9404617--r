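#' Reverse complement of a DNA string
#'
#' Complements A/C/G/T (and lower case) and reverses; `N` and IUPAC ambiguity
#' codes are complemented where defined and otherwise preserved.
#'
#' @param x a single DNA string.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' @keywords internal
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' GC content of a DNA string
#'
#' Fraction of unambiguous bases that are G or C; N and other ambiguity codes
#' are excluded from the denominator.
#'
#' @param x a single DNA string.
#' @return a fraction in \[0, 1\].
#' @export
gc_content <- function(x) {
  ch <- toupper(seq_chars(x))
  n_gc <- sum(ch %in% c("G", "C"))
  n_at <- sum(ch %in% c("A", "T"))
  if (n_gc + n_at == 0L) return(NA_real_)
  n_gc / (n_gc + n_at)
}

# Circular substring: 0-based half-open [start, end) with end possibly > n
# or start > end meaning "wraps the origin".
circ_substr <- function(seq, start, end) {
  n <- nchar(seq)
  if (end > n || start > end) {
    if (start > end) end <- end + n
    stopifnot(end - start <= n)
    first <- substr(seq, start + 1L, n)
    rest <- substr(seq, 1L, end - n)
    paste0(first, rest)
  } else {
    substr(seq, start + 1L, end)
  }
}

# Standard-code translation of a CDS string; returns AA string, stops as '*'.
translate_dna <- function(x) {
  x <- toupper(x)
  n <- nchar(x) - nchar(x) %% 3L
  if (n == 0L) return("")
  codons <- substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  paste(unname(GENETIC_CODE_MAP[codons]), collapse = "")
}

GENETIC_CODE_MAP <- Biostrings::GENETIC_CODE

STOP_CODONS <- c("TAA", "TAG", "TGA")

is_stop <- function(codon) toupper(codon) %in% STOP_CODONS

# Split a CDS string into codons (drops incomplete terminal codon).
split_codons <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}
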