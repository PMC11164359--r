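code5 <- genetic_code("invertebrate_mito")

test_that("count_sites hand examples under the invertebrate mito code", {
  # TTT (Phe): third position neighbors TTC (syn), TTA, TTG (Leu) -> 1/3;
  # positions 1-2 fully nonsynonymous -> (1/3, 8/3)
  expect_equal(count_sites("TTT", code5), c(s_sites = 1 / 3, n_sites = 8 / 3))
  # GTT (Val, 4-fold): third position fully synonymous
  expect_gte(count_sites("GTT", code5)[["s_sites"]], 1)
  expect_error(count_sites("TAA", code5), "not a sense codon")
})

test_that("s + n = 3 for every sense codon, any kappa", {
  for (kap in c(1, 2)) {
    for (cd in code5$sense_codons) {
      s <- count_sites(cd, code5, kappa = kap)
      expect_equal(unname(sum(s)), 3)
    }
  }
})

test_that("count_sites matches the brute-force neighbor oracle", {
  for (cd in code5$sense_codons) {
    expect_equal(unname(count_sites(cd, code5)),
                 unname(oracle_count_sites(cd)), label = cd)
    expect_equal(unname(count_sites(cd, code5, kappa = 2)),
                 unname(oracle_count_sites(cd, kappa = 2)), label = cd)
  }
})

test_that("count_differences hand examples", {
  d <- count_differences("TTT", "TTC", code5)
  expect_equal(d[["sd"]], 1)
  expect_equal(d[["nd"]], 0)
  d0 <- count_differences("TTT", "TTT", code5)
  expect_equal(d0[["sd"]] + d0[["nd"]], 0)
  # two differences: both orderings averaged; sd + nd = Hamming distance
  d2 <- count_differences("TTT", "GTA", code5)
  expect_equal(d2[["sd"]] + d2[["nd"]], 2)
})

test_that("pathway counting matches exhaustive enumeration on random pairs", {
  set.seed(13)
  pairs <- cbind(sample(code5$sense_codons, 150, replace = TRUE),
                 sample(code5$sense_codons, 150, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    d <- count_differences(pairs[i, 1], pairs[i, 2], code5)
    o <- oracle_count_differences(pairs[i, 1], pairs[i, 2])
    expect_equal(d[["sd"]], o[["sd"]],
                 label = paste(pairs[i, ], collapse = "-"))
    expect_equal(d[["nd"]], o[["nd"]],
                 label = paste(pairs[i, ], collapse = "-"))
  }
})

test_that("sd + nd equals the Hamming distance for all sense pairs", {
  # spot-check the full pathway table against nucleotide Hamming distance
  set.seed(21)
  a <- sample(code5$sense_codons, 300, replace = TRUE)
  b <- sample(code5$sense_codons, 300, replace = TRUE)
  for (i in seq_along(a)) {
    d <- count_differences(a[i], b[i], code5)
    hd <- sum(strsplit(a[i], "")[[1]] != strsplit(b[i], "")[[1]])
    expect_equal(d[["sd"]] + d[["nd"]], hd)
  }
})

test_that("kaks_pair: identity and single synonymous change", {
  s <- paste(rep("ATGAAATTTGGG", 25), collapse = "")
  r0 <- kaks_pair(s, s, code5)
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$ratio))       # Ks = 0: ratio undefined
  # one synonymous third-position transition (TTT -> TTC)
  s2 <- sub("TTT", "TTC", s)
  r1 <- kaks_pair(s, s2, code5)
  expect_gt(r1$Ks, 0)
  expect_equal(r1$Ka, 0)
  expect_equal(r1$ratio, 0)
  # site counts: S + N = 3 * codons
  expect_equal(r1$S + r1$N, 3 * r1$n_codons)
})

test_that("kaks_pair equals the independent NG86+JC oracle on toy pairs", {
  set.seed(31)
  for (rep in 1:5) {
    a <- paste(sample(code5$sense_codons, 20, replace = TRUE), collapse = "")
    # mutate a few positions, rejecting stops
    av <- strsplit(a, "")[[1]]
    bv <- av
    repeat {
      bv <- av
      pos <- sample(60, 5)
      bv[pos] <- sample(c("A", "C", "G", "T"), 5, replace = TRUE)
      cods <- substring(paste(bv, collapse = ""), seq(1, 58, 3), seq(3, 60, 3))
      if (!any(cods %in% code5$stops)) break
    }
    b <- paste(bv, collapse = "")
    r <- kaks_pair(a, b, code5)
    o <- oracle_kaks_jc(a, b)
    expect_equal(r$S, o$S)
    expect_equal(r$N, o$N)
    expect_equal(r$Sd, o$Sd)
    expect_equal(r$Nd, o$Nd)
    expect_equal(r$Ks, o$Ks)
    expect_equal(r$Ka, o$Ka)
  }
})

test_that("gapped and stop-containing columns are removed pairwise", {
  a <- "ATGAAATTTGGG"
  b <- "ATG---TTTGGG"
  r <- kaks_pair(a, b, code5)
  expect_identical(r$n_codons, 3L)
  # stop codon column dropped
  r2 <- kaks_pair("ATGAAATTT", "ATGTAATTT", code5)
  expect_identical(r2$n_codons, 2L)
})

test_that("kumar_k2p equals ng86_jc site counts at kappa 1 and reacts to kappa", {
  a <- paste(rep("ATGAAATTTGGGCCC", 20), collapse = "")
  b <- gsub("AAA", "AAG", a, fixed = TRUE)  # synonymous Lys transitions
  r1 <- kaks_pair(a, b, code5, method = "kumar_k2p", kappa = 1)
  r2 <- kaks_pair(a, b, code5, method = "ng86_jc")
  expect_equal(r1$S, r2$S)
  expect_equal(r1$N, r2$N)
  r3 <- kaks_pair(a, b, code5, method = "kumar_k2p", kappa = 3)
  expect_false(isTRUE(all.equal(r3$S, r1$S)))
})

test_that("gene_kaks_summary: degenerate identical alignment", {
  aln <- c(x = strrep("ATGAAATTTGGG", 10), y = strrep("ATGAAATTTGGG", 10))
  s <- gene_kaks_summary(aln, code5, bootstrap_reps = 50, seed = 1)
  expect_equal(s$mean_ka, 0)
  expect_equal(s$mean_ks, 0)
  expect_true(is.nan(s$mean_ratio) || is.na(s$mean_ratio))
  expect_equal(s$se_ka, 0)
  expect_equal(s$se_ks, 0)
})

test_that("gene_kaks_summary means equal the mean of pairwise rates", {
  g <- generate_genome(synthetic_config(seed = 4))
  root <- extract_gene(g, "atp8")
  root <- substr(root, 1, nchar(root) - 3L)  # drop stop codon
  tips <- evolve_coding(root, "(a:0.03,b:0.03,c:0.03);",
                        omega = 0.3, kappa = 2, seed = 9, code = code5)
  s <- gene_kaks_summary(tips, code5, bootstrap_reps = 100, seed = 2)
  expect_identical(s$n_pairs, 3L)
  expect_equal(s$mean_ka, mean(s$pairs$Ka))
  expect_equal(s$mean_ks, mean(s$pairs$Ks))
  expect_true(s$se_ka >= 0 && s$se_ks >= 0)
})

test_that("bootstrap SEs are deterministic given the seed", {
  aln <- c(x = strrep("ATGAAATTTGGGCAT", 20), y = strrep("ATGAAATTCGGGCAC", 20))
  s1 <- gene_kaks_summary(aln, code5, bootstrap_reps = 100, seed = 7)
  s2 <- gene_kaks_summary(aln, code5, bootstrap_reps = 100, seed = 7)
  expect_identical(s1$se_ks, s2$se_ks)
  s3 <- gene_kaks_summary(aln, code5, bootstrap_reps = 100, seed = 8)
  expect_false(identical(s1$se_ks, s3$se_ks))
})
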