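code5 <- genetic_code("invertebrate_mito")

counts_from <- function(named) {
  # build a CodonCounts from a named integer vector
  cc <- count_codons(list("ATGTAA"), code5)  # template
  cc$counts[] <- 0L
  cc$counts[names(named)] <- as.integer(named)
  cc$total <- sum(cc$counts)
  cc
}

test_that("count_codons drops stops, partial and ambiguous codons", {
  cc <- count_codons(list("ATGAAATAA"), code5)
  expect_identical(cc$counts[["ATG"]], 1L)
  expect_identical(cc$counts[["AAA"]], 1L)
  expect_identical(cc$total, 2L)
  cc2 <- count_codons(list("ATGNAAAAA"), code5)
  expect_identical(cc2$total, 2L)               # NAA excluded
  cc3 <- count_codons(list("ATGAAAT"), code5)   # trailing partial dropped
  expect_identical(cc3$total, 2L)
  expect_warning(count_codons(list("AT"), code5), "shorter than 3")
})

test_that("RSCU: uniform family is 1, extreme is k and 0", {
  r <- rscu(counts_from(c(TTT = 5, TTC = 5)))
  expect_equal(r$rscu[r$codon %in% c("TTT", "TTC")], c(1, 1))
  r2 <- rscu(counts_from(c(TTT = 10, TTC = 0)))
  expect_equal(r2$rscu[r2$codon == "TTT"], 2)
  expect_equal(r2$rscu[r2$codon == "TTC"], 0)
  # 4-fold family: GTA 4, GTT 2, GTG 1, GTC 1 -> GTA RSCU = 4*4/8 = 2
  r3 <- rscu(counts_from(c(GTA = 4, GTT = 2, GTG = 1, GTC = 1)))
  expect_equal(r3$rscu[r3$codon == "GTA"], 2)
  # unobserved families stay NA
  expect_true(is.na(r3$rscu[r3$codon == "TTT"]))
})

test_that("RSCU values in every observed family sum to the family size", {
  set.seed(1)
  for (i in 1:10) {
    cds <- paste(sample(code5$sense_codons, 600, replace = TRUE), collapse = "")
    r <- rscu(count_codons(list(cds), code5))
    for (fam in code5$families) {
      vals <- r$rscu[match(fam, r$codon)]
      if (all(is.na(vals))) next
      expect_equal(sum(vals), length(fam))
    }
  }
})

test_that("ENC equals 20 at maximal bias", {
  # one codon per amino acid, each seen many times
  one_per_aa <- vapply(code5$families, `[`, character(1), 1)
  cc <- counts_from(setNames(rep(50L, length(one_per_aa)), one_per_aa))
  expect_equal(enc(cc), 20)
})

test_that("ENC tends to 62 under uniform usage", {
  cc <- counts_from(setNames(rep(1e5L, 62L), code5$sense_codons))
  expect_lt(abs(enc(cc) - 62), 0.5)
})

test_that("ENC closed-form class arithmetic", {
  # per-class biased counts with hand-computed homozygosities:
  # 2-fold {3,1}: F = (4*(10/16)-1)/3 = 0.5
  # 4-fold {13,1,1,1}: F = (16*(172/256)-1)/15 = 0.65
  # 6-fold {10,1,1,1,1,1}: F = (15*(105/225)-1)/14 = 3/7
  # 8-fold {9,1,1,1,1,1,1,1}: F = (16*(88/256)-1)/15 = 0.3
  named <- integer(0)
  for (aa in names(code5$families)) {
    fam <- code5$families[[aa]]
    k <- length(fam)
    named[fam] <- switch(as.character(k),
                         "2" = c(3L, 1L),
                         "4" = c(13L, rep(1L, 3)),
                         "6" = c(10L, rep(1L, 5)),
                         "8" = c(9L, rep(1L, 7)))
  }
  cc <- counts_from(named)
  expect_equal(enc(cc), 12 / 0.5 + 6 / 0.65 + 1 / (3 / 7) + 1 / 0.3)
})

test_that("ENC decreases monotonically along a bias sweep", {
  set.seed(5)
  freqs <- mitocomp:::.base_freqs(0.8, 0, -0.3)
  encs <- vapply(c(0.5, 1, 1.5, 2.5, 4), function(b) {
    cds <- paste(mitocomp:::.sample_codons(30000, freqs, code5, b),
                 collapse = "")
    enc(count_codons(list(cds), code5))
  }, numeric(1))
  expect_true(all(diff(encs) < 0))
})

test_that("ENC errors on insufficient data and warns on empty classes", {
  expect_error(enc(counts_from(c(ATG = 1))), "insufficient")
  # only a 2-fold family observed: 4/6/8-fold classes each imputed, with
  # one warning per empty class
  w <- capture_warnings(enc(counts_from(c(TTT = 30, TTC = 10))))
  expect_identical(sum(grepl("imputing", w)), 3L)
})

test_that("CBI hand example and extremes", {
  # two 2-fold families with counts {3,1} and {4,0}, modal preferred:
  # CBI = ((3+4) - (2+2)) / ((4+4) - (2+2)) = 0.75
  cc <- counts_from(c(TTT = 3, TTC = 1, TAT = 4, TAC = 0))
  expect_equal(cbi(cc), 0.75)
  # all preferred -> 1
  expect_equal(cbi(counts_from(c(TTT = 10, TAT = 7))), 1)
  # uniform usage with preferred fixed a priori -> 0
  cc2 <- counts_from(c(TTT = 5, TTC = 5, TAT = 7, TAC = 7))
  expect_equal(cbi(cc2, preferred = c(F = "TTT", Y = "TAT")), 0)
})

test_that("positional GC hand examples", {
  pg <- positional_gc(list("ATG"), code5)
  expect_equal(pg$gc3, 100)
  expect_equal(pg$gc1, 0)
  expect_equal(pg$at3, 0)
  pg2 <- positional_gc(list("GCGGCG"), code5)
  expect_equal(pg2$gc1, 100)
  expect_equal(pg2$gc2, 100)
  expect_equal(pg2$gc3, 100)
  expect_equal(pg2$gc12, 100)
})

test_that("ENC null curve closed form and shifted symmetry", {
  expect_equal(enc_null_curve(0.5), 60.5)
  expect_equal(enc_null_curve(0.3) - 0.3, enc_null_curve(0.7) - 0.7)
  expect_error(enc_null_curve(0), "in \\(0, 1\\)")
  expect_error(enc_null_curve(1), "in \\(0, 1\\)")
})

test_that("correlation wrapper: exact, null and hand-computed cases", {
  expect_equal(codon_correlation(1:10, 2 * (1:10))$r_squared, 1)
  x <- c(-1, 0, 1, 0)
  y <- c(0, 1, 0, -1)  # orthogonal to x and to the constant
  expect_equal(codon_correlation(x, y)$r_squared, 0)
  # hand computation: cov = 4.5, var_x = 5, var_y = 4.75 (times n-1),
  # r^2 = 4.5^2 / (5 * 4.75) = 20.25 / 23.75
  r <- codon_correlation(c(1, 2, 3, 4), c(1, 2, 2, 4))
  expect_equal(r$r_squared, 20.25 / 23.75)
  expect_error(codon_correlation(1:2, 1:2), ">= 3")
  expect_error(codon_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("neutrality regression recovers slope 1 and slope 0 regimes", {
  set.seed(11)
  gc3 <- seq(5, 40, length.out = 12)
  # mutation-pressure regime: GC12 tracks GC3 one-for-one
  fit1 <- neutrality_plot(gc3 + rnorm(12, 0, 0.01), gc3)
  expect_equal(fit1$slope, 1, tolerance = 0.01)
  # constraint regime: GC12 flat regardless of GC3
  fit0 <- neutrality_plot(rep(30, 12) + rnorm(12, 0, 0.01), gc3)
  expect_equal(fit0$slope, 0, tolerance = 0.01)
  expect_error(neutrality_plot(1:2, 1:2), ">= 3")
})

test_that("codon_usage_stats bundles consistently in both modes", {
  g <- generate_genome(synthetic_config(seed = 2))
  nm <- g$features$name[g$features$kind == "PCG"]
  seqs <- setNames(lapply(nm, extract_gene, genome = g), nm)
  st <- codon_usage_stats(seqs, code5)
  expect_equal(st$enc, enc(count_codons(seqs, code5)))
  expect_equal(st$s, st$gc3 / 100)
  st2 <- codon_usage_stats(seqs, code5, mode = "per_gene_mean")
  per <- vapply(seqs, function(s) enc(count_codons(list(s), code5)),
                numeric(1))
  expect_equal(st2$enc, mean(per))
})
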