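# Progressive MSA, diagnostic sites, primer search, discrimination

test_that("identical sequences give a gap-free MSA with stable row order", {
  s <- random_dna(120)
  msa <- build_msa(c(x = s, y = s, z = s))
  expect_false(any(unclass(msa) == "-"))
  expect_identical(rownames(msa), c("x", "y", "z"))
  expect_identical(ncol(msa), 120L)
  expect_error(build_msa(c(a = "", b = "ACGT")), "empty")
})

test_that("a private 4-nt insertion produces a single 4-column gap block", {
  set.seed(81)
  s <- random_dna(150)
  ins <- paste0(substr(s, 1, 70), "CATG", substr(s, 71, 150))
  msa <- build_msa(c(a = s, b = ins, c = s))
  m <- unclass(msa)
  expect_gte(ncol(m), 150L)  # column count at least the longest input
  ga <- which(m["a", ] == "-")
  expect_identical(length(ga), 4L)
  expect_identical(diff(ga), rep(1L, 3))
  expect_identical(which(m["c", ] == "-"), ga)
  expect_false(any(m["b", ] == "-"))
})

test_that("diagnostic sites are strict one-vs-rest calls", {
  m <- rbind(A = c("A", "C", "G", "T", "A", "C"),
             B = c("A", "C", "G", "T", "A", "C"),
             C = c("A", "C", "G", "T", "A", "C"),
             D = c("A", "T", "G", "T", "A", "C"))
  ds <- diagnostic_sites(structure(m, class = "msa"))
  expect_identical(nrow(ds), 1L)
  expect_identical(ds$species, "D")
  expect_identical(ds$column, 2L)
  expect_identical(ds$state, "T")
  expect_identical(ds$background_state, "C")

  # two species sharing the variant is not diagnostic
  m2 <- m; m2["C", 2] <- "T"
  expect_identical(nrow(diagnostic_sites(structure(m2, class = "msa"))), 0L)

  # ambiguous base in the column: skipped
  m3 <- m; m3["A", 2] <- "N"
  expect_identical(nrow(diagnostic_sites(structure(m3, class = "msa"))), 0L)

  # all-identical alignment: empty
  m4 <- m; m4["D", 2] <- "C"
  expect_identical(nrow(diagnostic_sites(structure(m4, class = "msa"))), 0L)
  expect_error(diagnostic_sites(structure(m[1:2, ], class = "msa")), ">= 3")
})

test_that("planted private SNPs and a private deletion are each found once", {
  set.seed(83)
  base <- random_dna(200)
  a <- base; substr(a, 50, 50) <- if (substr(base, 50, 50) == "A") "G" else "A"
  a2 <- a; substr(a2, 90, 90) <- if (substr(base, 90, 90) == "C") "T" else "C"
  b <- paste0(substr(base, 1, 139), substr(base, 143, 200))  # 3-nt deletion
  msa <- build_msa(c(spA = a2, spB = b, spC = base, spD = base))
  ds <- diagnostic_sites(msa)
  expect_identical(sum(ds$kind == "SNP" & ds$species == "spA"), 2L)
  expect_identical(sum(ds$kind == "indel" & ds$species == "spB"), 1L)
  expect_identical(nrow(ds), 3L)
})

test_that("primer pairs are conserved windows bounding admissible products", {
  sim <- plant_marker(simulate_plastomes(small_cfg(seed = 30,
                                                   species = quiet_species(3))),
                      k_snps = 4, m_indels = 2, flank_len = 60)
  region <- attr(sim$marker_truth, "region")
  seqs <- sim_spacer_seqs(sim, region)
  msa <- build_msa(seqs)
  mk <- primer_search(msa, min_len = 100, max_len = 1000, primer_len = 20,
                      region = "toy")
  expect_gt(nrow(mk), 0)
  top <- mk[1, ]
  expect_identical(top$n_sites, 6L)
  expect_true(verify_primers(mk, seqs))
  expect_true(all(mk$product_min >= 100 & mk$product_max <= 1000))
  # the primers bound every product within the allowed range per species
  products <- attr(mk, "products")[[1]]
  expect_true(all(products >= 100 & products <= 1000))

  # a max_len below the smallest admissible product rejects all pairs
  expect_warning(none <- primer_search(msa, min_len = 10, max_len = 30,
                                       primer_len = 20, region = "toy"),
                 "no primer pair|no conserved")
  expect_identical(nrow(none), 0L)
})

test_that("a fully variable alignment yields no conserved window", {
  set.seed(85)
  m <- matrix(sample(c("A", "C", "G", "T"), 3 * 60, TRUE), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  expect_warning(res <- primer_search(structure(m, class = "msa"),
                                      primer_len = 20), "no conserved")
  expect_identical(nrow(res), 0L)
})

test_that("discrimination matrix is symmetric, true-diagonal and site-driven", {
  sim <- plant_marker(simulate_plastomes(small_cfg(seed = 31,
                                                   species = quiet_species(3))),
                      k_snps = 3, m_indels = 0, flank_len = 60)
  region <- attr(sim$marker_truth, "region")
  seqs <- sim_spacer_seqs(sim, region)
  mk <- primer_search(build_msa(seqs), region = "m")
  dm <- discrimination_matrix(mk, names(seqs))
  expect_true(isSymmetric(dm$matrix))
  expect_true(all(diag(dm$matrix)))
  # 3 SNPs round-robin over 3 species: every species has a private site
  expect_true(dm$success)
  expect_true(all(dm$per_pair$discriminated))

  # with sites for only one species, pairs among the others are undiscriminated
  sim1 <- plant_marker(simulate_plastomes(small_cfg(seed = 31,
                                                    species = quiet_species(3))),
                       k_snps = 1, m_indels = 0, flank_len = 60,
                       species = "sp1")
  seqs1 <- sim_spacer_seqs(sim1, attr(sim1$marker_truth, "region"))
  mk1 <- primer_search(build_msa(seqs1), region = "m")
  dm1 <- discrimination_matrix(mk1, names(seqs1))
  expect_false(dm1$success)
  expect_false(dm1$matrix["sp2", "sp3"])
  expect_true(dm1$matrix["sp1", "sp2"])  # sp1's private site separates it
})

test_that("the planted nine-SNP three-indel marker is recovered exactly", {
  for (sd in c(1, 7)) {
    sim <- plant_marker(simulate_plastomes(sim_config(seed = sd)),
                        k_snps = 9, m_indels = 3, flank_len = 60)
    tr <- sim$marker_truth
    seqs <- sim_spacer_seqs(sim, attr(tr, "region"))
    msa <- build_msa(seqs)
    ds <- diagnostic_sites(msa)
    expect_identical(sum(ds$kind == "SNP"), 9L)
    expect_identical(sum(ds$kind == "indel"), 3L)
    expect_identical(as.character(ds$species[ds$kind == "SNP"]),
                     tr$species[tr$kind == "SNP"])
    mk <- primer_search(msa, region = "mk")
    expect_identical(mk$n_sites[1], 12L)
    expect_true(verify_primers(mk, seqs))
    dm <- discrimination_matrix(mk, names(seqs))
    expect_true(dm$success)
  }
})

test_that("planting no sites yields no diagnostics", {
  sim <- plant_marker(simulate_plastomes(small_cfg(seed = 33,
                                                   species = quiet_species(3))),
                      k_snps = 0, m_indels = 0, flank_len = 60)
  seqs <- sim_spacer_seqs(sim, attr(sim$marker_truth, "region"))
  expect_identical(nrow(diagnostic_sites(build_msa(seqs))), 0L)
})
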