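# Codon-aware alignment and NG86 dN/dS

test_that("codon alignment is gap-free for identical CDSs and round-trips", {
  cds <- paste0("ATG", random_codons(30, seed = 51), "TAA")
  ca <- codon_align(c(a = cds, b = cds, c = cds))
  expect_false(any(ca$dna == "-"))
  expect_identical(ncol(ca$codons) * 3L, nchar(cds))
  for (sp in rownames(ca$dna)) {
    expect_identical(paste(ca$dna[sp, ca$dna[sp, ] != "-"], collapse = ""), cds)
  }
})

test_that("a single codon deletion aligns as one 3-nt gap on a codon boundary", {
  cds <- paste0("ATG", random_codons(30, seed = 52), "TAA")
  del <- paste0(substr(cds, 1, 30), substr(cds, 34, nchar(cds)))
  ca <- codon_align(c(full = cds, short = del))
  gaps <- which(ca$dna["short", ] == "-")
  expect_identical(length(gaps), 3L)
  expect_identical(diff(gaps), c(1L, 1L))
  expect_identical((gaps[1] - 1L) %% 3L, 0L)  # codon boundary
  # round trip
  expect_identical(paste(ca$dna["short", ca$dna["short", ] != "-"],
                         collapse = ""), del)
})

test_that("internal stops are rejected with species and codon index", {
  cds <- paste0("ATG", random_codons(10, seed = 53), "TAA")
  ch <- strsplit(cds, "")[[1]]
  ch[13:15] <- c("T", "G", "A")
  bad <- paste(ch, collapse = "")
  expect_error(codon_align(c(ok = cds, broken = bad)), "broken.*codon 5")
})

test_that("NG86 handles the trivial and single-change cases", {
  cds <- paste0("ATGGGAGGG")
  r0 <- ng86_dn_ds(cds, cds)
  expect_identical(r0$Sd + r0$Nd, 0)
  expect_identical(r0$dN, 0)
  expect_identical(r0$dS, 0)
  expect_true(is.na(r0$omega))

  # GGA -> GGG is synonymous (Gly); a single synonymous site saturates the
  # JC correction for dS but dN stays exactly 0
  expect_warning(r <- ng86_dn_ds("GGA", "GGG"), "saturation")
  expect_identical(r$Sd, 1)
  expect_identical(r$Nd, 0)
  expect_identical(r$dN, 0)
  expect_true(is.na(r$dS))

  expect_error(ng86_dn_ds("", ""), "zero comparable")
  expect_error(ng86_dn_ds("AAA", "AAATTT"), "unequal")
})

test_that("site counts always partition 3 x codons and estimates are symmetric", {
  set.seed(61)
  for (i in 1:8) {
    a <- random_codons(12); b <- random_codons(12)
    ab <- suppressWarnings(ng86_dn_ds(a, b))
    expect_equal(ab$S_sites + ab$N_sites, 3 * ab$codons, tolerance = 1e-12)
    ba <- suppressWarnings(ng86_dn_ds(b, a))
    expect_equal(ab$S_sites, ba$S_sites, tolerance = 1e-12)
    expect_equal(ab$Sd, ba$Sd, tolerance = 1e-12)
    expect_equal(ab$Nd, ba$Nd, tolerance = 1e-12)
  }
})

test_that("NG86 counts equal brute-force pathway enumeration up to 10 codons", {
  set.seed(62)
  for (len in 1:10) {
    for (rep in 1:4) {
      a <- random_codons(len)
      # derive b by mutating a few positions so multi-hit codons occur often
      ch <- strsplit(a, "")[[1]]
      k <- sample.int(max(1, len), 1) + (len > 3)
      idx <- sample(length(ch), min(length(ch), k + 2))
      ch[idx] <- vapply(ch[idx], function(x)
        sample(c("A", "C", "G", "T"), 1), character(1))
      b <- paste(ch, collapse = "")
      # skip if mutation created stop codons (invalid CDS input)
      cods_b <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
      if (any(cods_b %in% c("TAA", "TAG", "TGA"))) next
      got <- suppressWarnings(ng86_dn_ds(a, b))
      want <- brute_ng86(a, b)
      expect_equal(got$S_sites, want$S_sites, tolerance = 1e-12)
      expect_equal(got$N_sites, want$N_sites, tolerance = 1e-12)
      expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
      expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    }
  }
})

test_that("saturated comparisons degrade to NA with a warning", {
  # maximally different codons drive the proportions over the JC limit
  a <- paste(rep("AAA", 30), collapse = "")
  b <- paste(rep("CCC", 30), collapse = "")
  w <- capture_warnings(r <- ng86_dn_ds(a, b))
  expect_true(any(grepl("saturation", w)))  # both rates saturate here
  expect_true(is.na(r$omega))
})

test_that("planted substitution regimes produce the expected omega calls", {
  cds <- paste0("ATG", random_codons(200, seed = 63), "TAA")
  syn_only <- mutate_cds_sites(cds, n_syn = 10, n_nonsyn = 0, seed = 71)
  ca <- codon_align(c(a = cds, b = syn_only))
  est <- ng86_dn_ds(paste(ca$dna[1, ], collapse = ""),
                    paste(ca$dna[2, ], collapse = ""))
  expect_identical(est$Nd, 0)
  expect_identical(est$dN, 0)
  expect_identical(est$omega, 0)

  # nonsynonymous excess beyond the site-count ratio drives omega above 1
  pos <- mutate_cds_sites(cds, n_syn = 2, n_nonsyn = 24, seed = 72)
  cb <- codon_align(c(a = cds, b = pos))
  est2 <- ng86_dn_ds(paste(cb$dna[1, ], collapse = ""),
                     paste(cb$dna[2, ], collapse = ""))
  expect_gt(est2$omega, 1)
})

test_that("omega_table summarizes pairwise estimates and flags candidates", {
  cds1 <- paste0("ATG", random_codons(150, seed = 64), "TAA")
  cds2 <- paste0("ATG", random_codons(120, seed = 65), "TAA")
  mk_plastome <- function(id, g1, g2) {
    set.seed(100 + nchar(id))
    plastome(id, paste0(random_dna(200), g1, random_dna(150), g2, random_dna(200)),
             features = data.frame(gene = c("selGene", "neutGene"),
                                   kind = "CDS", strand = "+",
                                   start = c(200L, 200L + nchar(g1) + 150L),
                                   end = c(200L + nchar(g1),
                                           200L + nchar(g1) + 150L + nchar(g2))),
             circular = FALSE)
  }
  pa <- mk_plastome("x", cds1, cds2)
  pb <- mk_plastome("yy", mutate_cds_sites(cds1, 2, 24, seed = 81),
                    mutate_cds_sites(cds2, 10, 0, seed = 82))
  om <- omega_table(list(x = pa, yy = pb))
  expect_s3_class(om, "omega_table")
  sel <- om[om$gene == "selgene", ]
  neut <- om[om$gene == "neutgene", ]
  expect_true(sel$positive_selection_candidate)
  expect_gt(sel$omega_median, 1)
  expect_false(neut$positive_selection_candidate)
  expect_identical(neut$omega_median, 0)
  expect_error(suppressWarnings(omega_table(list(x = pa, solo = plastome(
    "solo", pa$sequence,
    features = data.frame(gene = "other", kind = "CDS", strand = "+",
                          start = 200L, end = 200L + nchar(cds1)),
    circular = FALSE)))), "no gene pair")
})
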