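# Gene classification, census matrix, ratios, clustering

# tiny target: one gene embedded in random flanks
embed_gene <- function(cds, id = "t", flank = 400L, seed = 1) {
  set.seed(seed)
  plastome(id, paste0(random_dna(flank), cds, random_dna(flank)),
           circular = FALSE)
}

test_that("classify_gene separates intact, frameshift, premature-stop, truncated and lost", {
  ref <- random_codons(80, seed = 21)
  ref <- paste0("ATG", ref, "TAA")
  n <- nchar(ref)

  expect_identical(classify_gene(embed_gene(ref), ref)$evidence, "intact")
  expect_identical(classify_gene(embed_gene(ref), ref)$status, "present")

  # single mid-CDS deletion forces a frame disruption
  fs <- paste0(substr(ref, 1, 100), substr(ref, 102, n))
  res <- classify_gene(embed_gene(fs), ref)
  expect_identical(res$status, "pseudogene")
  expect_identical(res$evidence, "frameshift")

  # point mutation creating an in-frame stop at codon 20
  ch <- strsplit(ref, "")[[1]]
  ch[(20 - 1) * 3 + (1:3)] <- c("T", "A", "A")
  ps <- paste(ch, collapse = "")
  res <- classify_gene(embed_gene(ps), ref)
  expect_identical(res$status, "pseudogene")
  expect_identical(res$evidence, "premature_stop")

  # 30% of the CDS removed from the 3' end
  tr <- substr(ref, 1, floor(0.7 * n))
  res <- classify_gene(embed_gene(tr), ref)
  expect_identical(res$status, "pseudogene")
  expect_identical(res$evidence, "truncated")
  expect_lt(res$coverage, 0.9)

  # gene absent altogether
  set.seed(3)
  res <- classify_gene(plastome("empty", random_dna(2000)), ref)
  expect_identical(res$status, "lost")
  expect_identical(res$evidence, "no_hit")

  # reference CDS validation
  bad <- paste0("ATG", "TAA", random_codons(10, seed = 4), "TAA")
  expect_error(classify_gene(embed_gene(ref), bad), "invalid reference CDS")
  expect_error(classify_gene(embed_gene(ref), substr(ref, 1, n - 1)),
               "multiple of 3")
})

test_that("a minus-strand copy is found and classified identically", {
  ref <- paste0("ATG", random_codons(60, seed = 31), "TGA")
  p <- embed_gene(revcomp(ref), seed = 8)
  expect_identical(classify_gene(p, ref)$status, "present")
})

test_that("self-census reports every reference gene present", {
  sim <- simulate_plastomes(small_cfg(seed = 10, species = quiet_species(1)))
  cen <- census_matrix(list(self = sim$reference), sim$reference)
  expect_true(all(cen$cells$status == "present"))
  expect_identical(nrow(cen$cells), cen$n_ref_pcg)
  expect_error(census_matrix(list(), sim$reference), "empty")
})

test_that("census recovers planted deletions and pseudogenes exactly", {
  sim <- simulate_plastomes(small_cfg(seed = 12, species = quiet_species(3)))
  cen <- census_matrix(sim$species, sim$reference)
  for (sp in names(sim$species)) {
    tr <- sim$manifest[[sp]]
    cells <- cen$cells[cen$cells$species == sp, ]
    expect_setequal(cells$gene[cells$status == "lost"], tr$lost)
    expect_setequal(cells$gene[cells$status == "pseudogene"], tr$pseudo$gene)
    # census conservation: statuses sum to the reference PCG count
    expect_identical(nrow(cells), cen$n_ref_pcg)
  }
})

test_that("adding one planted deletion changes exactly one cell", {
  cfgA <- list(deletions = c("matK"), igs_sub_rate = 0)
  cfgB <- list(deletions = c("matK", "atpE"), igs_sub_rate = 0)
  base <- small_cfg(seed = 14, species = list(x = cfgA))
  ref <- make_reference(base)
  dA <- degrade(ref, cfgA, "x", seed = base$seed)
  dB <- degrade(ref, cfgB, "x", seed = base$seed)
  cA <- census_matrix(list(x = dA$plastome), ref$plastome)$cells
  cB <- census_matrix(list(x = dB$plastome), ref$plastome)$cells
  changed <- cA$gene[cA$status != cB$status[match(cA$gene, cB$gene)]]
  expect_identical(changed, "atpE")
  expect_identical(sum(cB$status == "lost") - sum(cA$status == "lost"), 1L)
})

test_that("degradation ratios are the counts over the reference PCG number", {
  sim <- simulate_plastomes(small_cfg(seed = 12, species = quiet_species(3)))
  cen <- census_matrix(sim$species, sim$reference)
  r <- degradation_ratios(cen)
  expect_identical(r$ratio_lost, r$n_lost / cen$n_ref_pcg)
  expect_identical(r$ratio_pseudo, r$n_pseudo / cen$n_ref_pcg)
  expect_true(all(r$ratio_lost >= 0 & r$ratio_lost <= 1))
  expect_identical(r$n_present + r$n_pseudo + r$n_lost,
                   rep(cen$n_ref_pcg, nrow(r)))
  # the published-style ratio arithmetic: 33 pseudogenes over 80 PCGs
  expect_equal(33 / 80, 0.4125)
  zero <- r[r$n_lost == 0 & r$n_pseudo == 0, ]
  if (nrow(zero)) expect_true(all(zero$ratio_lost == 0 & zero$ratio_pseudo == 0))
})

test_that("UPGMA clustering matches a naive O(n^3) agglomeration", {
  set.seed(99)
  for (rep in 1:3) {
    profiles <- tibble::tibble(
      species = paste0("s", 1:6),
      ratio_lost = round(runif(6), 3),
      ratio_pseudo = round(runif(6), 3))
    cl <- cluster_species(profiles)
    mat <- as.matrix(profiles[, c("ratio_lost", "ratio_pseudo")])
    rownames(mat) <- profiles$species
    coph_naive <- naive_upgma_cophenetic(dist(mat))
    coph_hc <- as.matrix(stats::cophenetic(cl$hclust))
    expect_equal(coph_hc[rownames(coph_naive), colnames(coph_naive)],
                 coph_naive, tolerance = 1e-12)
  }
})

test_that("clustering boundary cases behave deterministically", {
  two <- tibble::tibble(species = c("a", "b"),
                        ratio_lost = c(0.2, 0.2), ratio_pseudo = c(0.1, 0.1))
  cl <- cluster_species(two)
  expect_equal(cl$heights, 0)   # identical profiles merge at height 0

  three <- tibble::tibble(species = c("a", "b", "c"),
                          ratio_lost = c(0, 0, 1), ratio_pseudo = c(0, 0.1, 1))
  cl3 <- cluster_species(three)
  # brute force over the three pairwise distances: a-b merge first
  expect_identical(sort(cl3$hclust$merge[1, ]), c(-2L, -1L))
  expect_error(cluster_species(two[0, ]), "2 species")
  expect_error(cluster_species(two, columns = c("nope")), "missing ratio")
})

test_that("tidy and glance expose the census as tibbles", {
  sim <- simulate_plastomes(small_cfg(seed = 10, species = quiet_species(1)))
  cen <- census_matrix(sim$species, sim$reference)
  expect_identical(tidy(cen), cen$cells)
  expect_identical(glance(cen), degradation_ratios(cen))
  wide <- census_legend_matrix(cen)
  expect_true(all(unlist(wide[-1]) %in% c("•", "Ψ", "○")))
})
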