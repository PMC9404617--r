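#' Detect the inverted-repeat pair and partition a plastome
#'
#' Finds the longest pair of exact maximal inverted repeats on the circular
#' sequence (seed-and-extend against the reverse complement), labels the
#' longer intervening single-copy region LSC and the shorter SSC, and rotates
#' the genome so that LSC starts at 0 with region order LSC-IRb-SSC-IRa.
#'
#' Exact matching is used deliberately: assembled plastomes carry two
#' identical IR copies. When two repeat pairs tie in length the pair
#' minimizing SSC length wins, remaining ties by smallest start coordinate.
#'
#' @param p a [plastome].
#' @param min_len minimum inverted-repeat length to accept (nt, >= 50).
#'   Default 1000.
#' @return an object of class `quadripartite`: fields `has_quadripartite`,
#'   `lsc`, `irb`, `ssc`, `ira` (0-based half-open intervals in the canonical
#'   rotation), `junctions` (named positions `JLB`, `JSB`, `JSA`, `JLA`),
#'   `ir_length`, `offset` (rotation applied, original coordinate of the
#'   canonical origin) and `plastome` (the canonically rotated input).
#' @export
detect_inverted_repeat <- function(p, min_len = 1000L) {
  stopifnot(inherits(p, "plastome"))
  min_len <- as.integer(min_len)
  if (min_len < 50L) stop("min_len must be >= 50")
  n <- nchar(p$sequence)
  if (n < 2L * min_len) stop("sequence shorter than 2*min_len")

  # an IR arm never wraps the origin in at least one of two rotations half a
  # genome apart (arms are < n/2); take the better of the two
  cand0 <- find_best_ir(p$sequence, min_len)
  p_half <- rotate_plastome(p, n %/% 2L)
  cand1 <- find_best_ir(p_half$sequence, min_len)
  use_half <- FALSE
  if (is.null(cand0) && is.null(cand1)) {
    return(structure(list(has_quadripartite = FALSE, lsc = NULL, irb = NULL,
                          ssc = NULL, ira = NULL, junctions = NULL,
                          ir_length = 0L, offset = 0L, plastome = p),
                     class = "quadripartite"))
  }
  if (is.null(cand0) || (!is.null(cand1) && cand1$len > cand0$len)) {
    use_half <- TRUE
  } else if (!is.null(cand1) && cand1$len == cand0$len && cand1$ssc_len < cand0$ssc_len) {
    use_half <- TRUE
  }
  cand <- if (use_half) cand1 else cand0
  base <- if (use_half) p_half else p

  # cand: arm1 start a1, arm2 start a2 (a1 < a2 in this rotation), length len
  a1 <- cand$a1; a2 <- cand$a2; len <- cand$len
  if (a1 + len > a2) stop("IR arms overlap")
  gap_mid <- a2 - (a1 + len)               # between arm1 end and arm2 start
  gap_out <- n - (a2 + len) + a1           # wraps around the origin
  if (gap_mid >= gap_out) {
    # the gap between the arms is the longer one: it becomes LSC, and the
    # arm following it (arm2) is IRb
    lsc_len <- gap_mid; ssc_len <- gap_out
    lsc_start <- a1 + len
  } else {
    # the wrap-around gap is LSC; arm1 is IRb
    lsc_len <- gap_out; ssc_len <- gap_mid
    lsc_start <- (a2 + len) %% n
  }
  q_p <- rotate_plastome(base, lsc_start)
  off_total <- ((if (use_half) n %/% 2L else 0L) + lsc_start) %% n

  lsc <- c(0L, lsc_len)
  irb <- c(lsc_len, lsc_len + len)
  ssc <- c(lsc_len + len, lsc_len + len + ssc_len)
  ira <- c(lsc_len + len + ssc_len, n)
  junctions <- c(JLB = lsc_len, JSB = lsc_len + len,
                 JSA = lsc_len + len + ssc_len, JLA = 0L)
  # sanity: mirror property must hold on the rotated sequence
  sb <- substr(q_p$sequence, irb[1] + 1L, irb[2])
  sa <- substr(q_p$sequence, ira[1] + 1L, ira[2])
  stopifnot(identical(sa, revcomp(sb)))

  structure(list(has_quadripartite = TRUE, lsc = lsc, irb = irb, ssc = ssc,
                 ira = ira, junctions = junctions, ir_length = len,
                 offset = off_total, plastome = q_p),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  if (!x$has_quadripartite) {
    cat("<quadripartite> no inverted repeat detected\n")
    return(invisible(x))
  }
  cat(sprintf("<quadripartite> LSC %d nt | IRb %d nt | SSC %d nt | IRa %d nt\n",
              diff(x$lsc), diff(x$irb), diff(x$ssc), diff(x$ira)))
  cat(sprintf("  junctions: JLB=%d JSB=%d JSA=%d JLA=%d (canonical rotation, offset %d)\n",
              x$junctions["JLB"], x$junctions["JSB"], x$junctions["JSA"],
              x$junctions["JLA"], x$offset))
  invisible(x)
}

# seed-and-extend search for the longest exact inverted repeat pair on the
# (linearized) sequence; returns NULL or list(a1, a2, len, ssc_len)
find_best_ir <- function(s, min_len) {
  n <- nchar(s)
  k <- min(31L, min_len)
  t <- revcomp(s)
  seeds_s <- substring(s, 1:(n - k + 1L), k:n)
  seeds_t <- substring(t, 1:(n - k + 1L), k:n)
  # positions in t of each distinct seed
  tpos <- split(seq_along(seeds_t), seeds_t)
  hits_per_seed <- tpos[seeds_s]
  best <- NULL
  covered_s <- rep(FALSE, n)  # skip seeds inside an arm already found
  schars <- seq_chars(s); tchars <- seq_chars(t)
  for (i in seq_along(hits_per_seed)) {
    hp <- hits_per_seed[[i]]
    if (is.null(hp)) next
    if (covered_s[i]) next
    for (j in hp) {
      # extend the exact match s[i..] == t[j..] maximally (1-based here)
      li <- i; lj <- j
      while (li > 1L && lj > 1L && schars[li - 1L] == tchars[lj - 1L]) {
        li <- li - 1L; lj <- lj - 1L
      }
      # rightward extension
      ri <- i + k - 1L; rj <- j + k - 1L
      while (ri < n && rj < n && schars[ri + 1L] == tchars[rj + 1L]) {
        ri <- ri + 1L; rj <- rj + 1L
      }
      len <- ri - li + 1L
      if (len < min_len) next
      # map t-interval back to s: t position q (1-based) = s position n - q + 1
      m1 <- c(li - 1L, ri)                    # 0-based half-open in s
      m2 <- c(n - rj, n - lj + 1L)            # 0-based half-open in s
      if (m1[1] > m2[1]) { tmp <- m1; m1 <- m2; m2 <- tmp }
      if (identical(m1, m2)) next             # self-palindrome, not a pair
      if (m1[2] > m2[1]) next                 # overlapping arms: reject pair
      ssc_len <- min(m2[1] - m1[2], n - m2[2] + m1[1])
      cand <- list(a1 = m1[1], a2 = m2[1], len = len, ssc_len = ssc_len)
      if (is.null(best) || len > best$len ||
          (len == best$len && (ssc_len < best$ssc_len ||
                               (ssc_len == best$ssc_len && m1[1] < best$a1)))) {
        best <- cand
      }
      covered_s[seq.int(li, max(li, ri - k + 1L))] <- TRUE
    }
  }
  best
}

#' Report the gene context at the four quadripartite junctions
#'
#' For each junction (JLB, JSB, JSA, JLA) finds the nearest annotated gene on
#' each side with exact nucleotide distances (circular), plus any gene whose
#' interval spans the junction. A junction is the coordinate of the first
#' base of the downstream region (half-open convention), so a gene ending
#' exactly at the junction has `left_distance` 0.
#'
#' @param p a [plastome] in the canonical rotation of `q` (pass `q$plastome`
#'   or leave `NULL` to use it).
#' @param q a [detect_inverted_repeat()] result with `has_quadripartite`.
#' @return a tibble with one row per junction: `junction`, `position`,
#'   `left_gene`, `left_strand`, `left_distance`, `right_gene`,
#'   `right_strand`, `right_distance`, `spanning_gene`.
#' @export
junction_report <- function(p = NULL, q) {
  stopifnot(inherits(q, "quadripartite"))
  if (!q$has_quadripartite) stop("no quadripartite structure detected")
  if (is.null(p)) p <- q$plastome
  f <- p$features
  if (nrow(f) == 0L) stop("no annotation")
  n <- nchar(p$sequence)
  spans <- feature_spans(f, n)

  purrr::map_dfr(names(q$junctions), function(jn) {
    j <- unname(q$junctions[jn])
    # circular distance from each gene end to junction (gene left of junction)
    dl <- (j - spans$end) %% n
    dr <- (spans$start - j) %% n
    il <- which.min(dl); ir <- which.min(dr)
    spanning <- which(((j - spans$start) %% n) < spans$len &
                      ((j - spans$start) %% n) > 0L)
    tibble::tibble(
      junction = jn, position = j,
      left_gene = f$gene[il], left_strand = f$strand[il],
      left_distance = as.integer(dl[il]),
      right_gene = f$gene[ir], right_strand = f$strand[ir],
      right_distance = as.integer(dr[ir]),
      spanning_gene = if (length(spanning)) f$gene[spanning[1]] else NA_character_
    )
  })
}

# per-feature overall span on the circle: start of first interval, end of
# last (unwrapped), and length along the circle
feature_spans <- function(f, n) {
  start <- vapply(f$starts, `[[`, integer(1), 1L)
  last_end <- vapply(f$ends, function(e) e[[length(e)]], integer(1))
  len <- ((last_end - start) %% n)
  len[len == 0L] <- n
  list(start = start, end = (start + len) %% n, len = len)
}

#' Assign each gene to a quadripartite region
#'
#' Assignment is by midpoint containment; a feature whose interval crosses a
#' junction is labeled `"spanning"`.
#'
#' @inheritParams junction_report
#' @return a tibble with columns `gene`, `kind`, `strand`, `region`.
#' @export
assign_genes_to_regions <- function(p = NULL, q) {
  stopifnot(inherits(q, "quadripartite"))
  if (!q$has_quadripartite) stop("no quadripartite structure detected")
  if (is.null(p)) p <- q$plastome
  f <- p$features
  n <- nchar(p$sequence)
  spans <- feature_spans(f, n)
  mid <- (spans$start + spans$len %/% 2L) %% n
  regions <- list(LSC = q$lsc, IRb = q$irb, SSC = q$ssc, IRa = q$ira)
  jpos <- unname(q$junctions)

  region_of <- function(pos) {
    for (nm in names(regions)) {
      r <- regions[[nm]]
      if (pos >= r[1] && pos < r[2]) return(nm)
    }
    "LSC"  # unreachable: regions tile [0, n)
  }
  crosses <- vapply(seq_len(nrow(f)), function(i) {
    any(((jpos - spans$start[i]) %% n) < spans$len[i] &
        ((jpos - spans$start[i]) %% n) > 0L)
  }, logical(1))
  tibble::tibble(
    gene = f$gene, kind = f$kind, strand = f$strand,
    region = ifelse(crosses, "spanning",
                    vapply(mid, region_of, character(1)))
  )
}
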