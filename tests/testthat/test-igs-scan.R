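# Shared spacer extraction, global alignment, K2p, divergence ranking

test_that("identical strings align gap-free with the expected score", {
  al <- global_align("ACGTACGTAC", "ACGTACGTAC")
  expect_identical(al$a, al$b)
  expect_false(grepl("-", al$a, fixed = TRUE))
  expect_identical(al$score, 20)
  expect_error(global_align("", "ACGT"), "empty")
})

test_that("small alignments match exhaustive enumeration over all alignments", {
  al <- global_align("ACGT", "ACT")
  expect_identical(sum(strsplit(al$a, "")[[1]] == "-") +
                     sum(strsplit(al$b, "")[[1]] == "-"), 1L)
  expect_identical(al$score, brute_force_align_score("ACGT", "ACT"))
  set.seed(17)
  for (i in 1:15) {
    a <- random_dna(sample(2:6, 1)); b <- random_dna(sample(2:6, 1))
    expect_identical(global_align(a, b)$score, brute_force_align_score(a, b))
  }
})

test_that("alignment scores equal an independent plain DP on random 50-nt pairs", {
  set.seed(23)
  for (i in 1:10) {
    a <- random_dna(50); b <- random_dna(50)
    expect_identical(global_align(a, b)$score, plain_gotoh_score(a, b))
  }
})

test_that("K2p follows its closed form exactly", {
  # identical pair
  r0 <- k2p_distance(list(a = "ACGTACGT", b = "ACGTACGT"))
  expect_identical(r0$d, 0)
  expect_identical(r0$P + r0$Q, 0)

  # 100 sites, exactly 10 transitions, 5 transversions
  a <- strsplit(paste(rep("ACGT", 25), collapse = ""), "")[[1]]
  b <- a
  b[seq(1, 19, 2)] <- chartr("ACGT", "GTAC", a[seq(1, 19, 2)])    # transitions
  b[c(30, 34, 38, 42, 46)] <- chartr("ACGT", "CAGA", a[c(30, 34, 38, 42, 46)])
  r <- k2p_distance(list(a = paste(a, collapse = ""), b = paste(b, collapse = "")))
  expect_identical(r$sites, 100L)
  expect_identical(r$transitions, 10L)
  expect_identical(r$transversions, 5L)
  expect_equal(r$d, -0.5 * log((1 - 2 * 0.1 - 0.05) * sqrt(1 - 2 * 0.05)),
               tolerance = 1e-12)

  # 100 sites, 10 transitions only: d = -0.5 ln(0.8)
  b2 <- a
  b2[seq(1, 19, 2)] <- chartr("ACGT", "GTAC", a[seq(1, 19, 2)])
  r2 <- k2p_distance(list(a = paste(a, collapse = ""),
                          b = paste(b2, collapse = "")))
  expect_equal(r2$d, -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(r2$d, 0.111572, tolerance = 1e-5)
})

test_that("K2p excludes gapped/ambiguous columns, errors at saturation", {
  r <- k2p_distance(list(a = "AC-GTN", b = "ACCG-A"))
  expect_identical(r$sites, 3L)   # columns 1,2,4 usable
  expect_error(k2p_distance(list(a = "----", b = "AAAA")), "zero usable")
  # saturated: all transversions
  expect_error(k2p_distance(list(a = "AAAA", b = "CCCC")), "saturation")
})

test_that("K2p agrees with ape::dist.dna on gap-free random pairs", {
  set.seed(41)
  for (i in 1:5) {
    a <- random_dna(600)
    ch <- strsplit(a, "")[[1]]
    mut <- runif(600) < 0.08
    ch[mut] <- vapply(ch[mut], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    b <- paste(ch, collapse = "")
    ours <- k2p_distance(list(a = a, b = b))$d
    bin <- ape::as.DNAbin(rbind(x = strsplit(tolower(a), "")[[1]],
                                y = strsplit(tolower(b), "")[[1]]))
    theirs <- as.numeric(ape::dist.dna(bin, model = "K80"))
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("K2p estimator is consistent under simulated K2p evolution", {
  # per-site transition prob pt, transversion prob pq with pt = 2 pq;
  # the plug-in closed form at (pt, pq) is the target distance
  for (target in c(0.01, 0.05, 0.1)) {
    f <- function(x) -0.5 * log((1 - 2 * (2 * x) - x) * sqrt(1 - 2 * x)) - target
    pq <- uniroot(f, c(1e-9, 0.18))$root
    pt <- 2 * pq
    set.seed(round(1e4 * target))
    est <- replicate(20, {
      a <- strsplit(random_dna(10000), "")[[1]]
      b <- a
      u <- runif(10000)
      ts <- u < pt; tv1 <- u >= pt & u < pt + pq / 2
      tv2 <- u >= pt + pq / 2 & u < pt + pq
      b[ts] <- chartr("ACGT", "GTAC", a[ts])
      b[tv1] <- chartr("ACGT", "CATG", a[tv1])  # A>C C>A G>T T>G
      b[tv2] <- chartr("ACGT", "TGCA", a[tv2])  # A>T C>G G>C T>A
      k2p_distance(list(a = paste(a, collapse = ""),
                        b = paste(b, collapse = "")))$d
    })
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - target), 3 * se + 1e-4)
  }
})

test_that("spacers shared by all plastomes are extracted and oriented", {
  sim <- simulate_plastomes(small_cfg(seed = 7, species = quiet_species(3)))
  # single plastome: every spacer trivially shared
  solo <- extract_shared_igs(list(only = sim$reference))
  expect_gt(nrow(solo), 5)
  expect_true(all(solo$length >= 1))

  igs <- extract_shared_igs(sim$species)
  expect_identical(sort(unique(igs$species)), sort(names(sim$species)))
  counts <- table(igs$region)
  expect_true(all(counts == length(sim$species)))
  # a deleted flanking gene breaks the adjacency in that species
  lost <- unlist(lapply(sim$manifest, function(m) m$lost))
  lost_norm <- normalize_gene_name(lost)
  for (rg in unique(igs$region)) {
    expect_false(any(vapply(lost_norm, function(g)
      grepl(g, rg, fixed = TRUE), logical(1))),
      info = paste("region", rg, "should not involve a deleted gene"))
  }
  expect_error(extract_shared_igs(list(plastome("x", "ACGTACGT"))), "fewer than 2")
})

test_that("symmetry: spacer distance is direction independent", {
  set.seed(70)
  a <- random_dna(300)
  ch <- strsplit(a, "")[[1]]
  idx <- sample(300, 12)
  ch[idx] <- vapply(ch[idx], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  b <- paste(ch, collapse = "")
  d1 <- k2p_distance(global_align(a, b))$d
  d2 <- k2p_distance(global_align(b, a))$d
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("a planted hypervariable spacer ranks first", {
  base <- small_cfg(seed = 20)
  ref <- make_reference(base)
  sp_tab <- plastdrift:::builder_spacers(ref$builder, "lsc")
  hyper <- sp_tab$name[which.max(sp_tab$length)]
  species <- lapply(stats::setNames(1:4, paste0("sp", 1:4)), function(i) {
    list(igs_sub_rate = 0.01, kappa = 2,
         hypervariable_igs = list(region = hyper, multiplier = 10))
  })
  cfg <- small_cfg(seed = 20, species = species)
  sim <- simulate_plastomes(cfg)
  igs <- extract_shared_igs(sim$species)
  rk <- suppressWarnings(rank_igs(igs))
  expect_identical(rk$region[1], hyper)
  expect_true(all(diff(rk$d_mean) <= 1e-12))  # sorted descending
  expect_equal(rk$d_mean_pct, 100 * rk$d_mean)
})

test_that("identical genomes give zero divergence with name-stable order", {
  sim <- simulate_plastomes(small_cfg(seed = 25, species = list(
    a = list(igs_sub_rate = 0), b = list(igs_sub_rate = 0))))
  igs <- extract_shared_igs(sim$species)
  rk <- rank_igs(igs)
  expect_true(all(rk$d_mean == 0))
  expect_identical(rk$region, sort(rk$region))
})
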