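make_toy_genome <- function() {
  # 60 bp circular toy genome with one gene of each kind
  seq <- paste0("ATGAAATTTTAA",             # [0,12)  PCG fwd
                "ACGTACGTAC",               # [12,22) tRNA fwd
                revcomp("ATGCCCTAA"),       # [22,31) PCG on N strand
                "TTTTTTTTT",                # [31,40) CR
                "GATTACAGATTACAGATTA")      # [40,59) rRNA fwd; 1 nt spare
  feats <- data.frame(
    name = c("nad3", "trnA", "atp8", "CR", "rrnS"),
    kind = c("PCG", "tRNA", "PCG", "CR", "rRNA"),
    strand = c("J", "J", "N", "J", "J"),
    start = c(0, 12, 22, 31, 40),
    end = c(12, 22, 31, 40, 59))
  annotated_genome("TOY1", "Toyus exemplaris", seq, feats)
}

test_that("extract_gene returns coding-orientation sequences", {
  g <- make_toy_genome()
  expect_identical(extract_gene(g, "nad3"), "ATGAAATTTTAA")
  expect_identical(extract_gene(g, "atp8"), "ATGCCCTAA")
  expect_error(extract_gene(g, "nope"), "unknown gene")
})

test_that("J and N strand slices behave per the coordinate contract", {
  feats <- data.frame(name = c("a", "b"), kind = c("other", "other"),
                      strand = c("J", "N"), start = c(2, 2), end = c(5, 5))
  g <- annotated_genome("X", "x", "AACGTT",
                        feats[1, , drop = FALSE], is_circular = FALSE)
  expect_identical(extract_gene(g, "a"), "CGT")
  g2 <- annotated_genome("X", "x", "AACGTT",
                         feats[2, , drop = FALSE], is_circular = FALSE)
  expect_identical(extract_gene(g2, "b"), "ACG")
})

test_that("origin-wrapping features are resolved by rotation", {
  feats <- data.frame(name = "w", kind = "other", strand = "J",
                      start = 5, end = 8)
  g <- annotated_genome("X", "x", "AACGTT", feats, is_circular = TRUE)
  # oracle: rotate the sequence so the feature is contiguous, then slice
  expect_identical(extract_gene(g, "w"), "TAA")
  expect_error(
    annotated_genome("X", "x", "AACGTT", feats, is_circular = FALSE),
    "wrapping")
})

test_that("extraction is invariant under genome reverse complement", {
  g <- make_toy_genome()
  rc <- revcomp_genome(g)
  for (nm in g$features$name) {
    expect_identical(extract_gene(rc, nm), extract_gene(g, nm), label = nm)
  }
})

test_that("validator rejects malformed feature tables", {
  seqs <- "ACGTACGTAC"
  f <- function(...) data.frame(...)
  expect_error(annotated_genome("X", "x", "ACGU", f(
    name = "a", kind = "other", strand = "J", start = 0, end = 2)), "A,C,G,T,N")
  expect_error(annotated_genome("X", "x", seqs, f(
    name = "a", kind = "other", strand = "J", start = 3, end = 3)),
    "end must exceed")
  expect_error(annotated_genome("X", "x", seqs, f(
    name = c("a", "a"), kind = "other", strand = "J",
    start = c(0, 4), end = c(2, 6))), "unique")
  expect_error(annotated_genome("X", "x", seqs, f(
    name = "a", kind = "gene", strand = "J", start = 0, end = 2)),
    "unknown feature kind")
  expect_error(annotated_genome("X", "x", seqs, f(
    name = "a", kind = "other", strand = "+", start = 0, end = 2)), "strand")
})

test_that("compute_spacers partitions the circle with features", {
  feats <- data.frame(name = c("a", "b"), kind = "other", strand = "J",
                      start = c(0, 5), end = c(3, 8))
  g <- annotated_genome("X", "x", "ACGTACGTAC", feats)
  sp <- compute_spacers(g)
  expect_identical(sp$length, c(2L, 2L))         # a-b gap and wraparound
  expect_identical(sp$sequence[1], "TA")          # positions [3,5)
  expect_identical(sp$sequence[2], "AC")          # positions [8,10)
  # feature lengths + spacer lengths = genome length
  expect_equal(sum(feats$end - feats$start) + sum(sp$length), 10)
})

test_that("compute_spacers reports overlaps as negative lengths", {
  feats <- data.frame(name = c("a", "b"), kind = "other", strand = "J",
                      start = c(0, 3), end = c(5, 8))
  g <- annotated_genome("X", "x", "ACGTACGTAC", feats)
  sp <- compute_spacers(g)
  expect_identical(sp$length[sp$upstream_gene == "a"], -2L)
  expect_identical(sp$sequence[sp$upstream_gene == "a"], "")
})

test_that("gene order labels: ancestral, trnM translocation, other", {
  build <- function(ord) {
    n <- nrow(ord)
    feats <- data.frame(name = ord$name,
                        kind = "other", strand = ord$strand,
                        start = seq(0, by = 10, length.out = n),
                        end = seq(5, by = 10, length.out = n))
    annotated_genome("X", "x", strrep("ACGTT", 2L * n), feats)
  }
  anc <- mitocomp:::.ancestral_order()
  expect_identical(gene_order_signature(build(anc))$label, "ancestral")
  frm <- mitocomp:::.formica_order()
  expect_identical(gene_order_signature(build(frm))$label,
                   "trnM_translocation")
  nom <- anc[anc$name != "trnM", ]
  sig <- gene_order_signature(build(nom))
  expect_identical(sig$label, "other")
  expect_identical(sig$missing, "trnM")
})

test_that("survey_start_stop classifies stops", {
  mk <- function(cds) {
    feats <- data.frame(name = "nad3", kind = "PCG", strand = "J",
                        start = 0, end = nchar(cds))
    annotated_genome("X", "x", paste0(cds, "AC"), feats, is_circular = FALSE)
  }
  s1 <- survey_start_stop(mk("ATGAAATAA"))
  expect_identical(s1$start_codon, "ATG")
  expect_identical(s1$stop_class, "TAA")
  expect_identical(s1$internal_stops, 0L)
  # 3k+1 ending in T -> incomplete T stop
  s2 <- survey_start_stop(mk("ATGAAAT"))
  expect_identical(s2$stop_class, "incomplete_T")
  s3 <- survey_start_stop(mk("ATGAAATA"))
  expect_identical(s3$stop_class, "incomplete_TA")
  # TGA is Trp under the invertebrate mito code: no internal stop
  s4 <- survey_start_stop(mk("ATGTGATAA"))
  expect_identical(s4$internal_stops, 0L)
  s5 <- survey_start_stop(mk("ATGTAAAAATAA"))
  expect_identical(s5$internal_stops, 1L)
  s6 <- survey_start_stop(mk("ATGAAAAAC"))
  expect_identical(s6$stop_class, "none")
})

test_that("GenBank round trip preserves everything", {
  g <- make_toy_genome()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- parse_genbank(path)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$features, g$features)
  expect_identical(g2$genome_id, g$genome_id)
  expect_identical(g2$is_circular, g$is_circular)
  # write-parse-write is byte-stable
  path2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("minimal hand-written GenBank record parses", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       MINI1 6 bp    DNA     linear MIT",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..6",
    '                     /gene="nad3"',
    "ORIGIN",
    "        1 atgtaa",
    "//"), path)
  g <- parse_genbank(path)
  expect_identical(g$features$name, "nad3")
  expect_identical(g$features$kind, "PCG")
  expect_identical(g$features$start, 0L)
  expect_identical(g$features$end, 6L)
  expect_identical(extract_gene(g, "nad3"), "ATGTAA")
})

test_that("complement locations give strand N and reverse complement", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       MINI2 6 bp    DNA     linear MIT",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(1..6)",
    '                     /gene="ND3"',
    "ORIGIN",
    "        1 atgtaa",
    "//"), path)
  g <- parse_genbank(path)
  expect_identical(g$features$strand, "N")
  expect_identical(g$features$name, "nad3")  # synonym normalized
  expect_identical(extract_gene(g, "nad3"), revcomp("ATGTAA"))
})

test_that("gene name normalization maps common synonyms", {
  expect_identical(normalize_gene_name("COI")$name, "cox1")
  expect_identical(normalize_gene_name("COX1")$name, "cox1")
  expect_identical(normalize_gene_name("12S ribosomal RNA")$name, "rrnS")
  expect_identical(normalize_gene_name("tRNA-Met")$name, "trnM")
  expect_identical(normalize_gene_name("D-loop")$name, "CR")
  expect_identical(normalize_gene_name("ATPase subunit 8")$name, "atp8")
})

test_that("malformed records error with a line-aware message", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("FEATURES", "ORIGIN", "//"), path)
  expect_error(parse_genbank(path), "no LOCUS")
  writeLines(c("LOCUS       X 10 bp DNA linear", "FEATURES"), path)
  expect_error(parse_genbank(path), "no ORIGIN")
  writeLines(c("LOCUS       X 10 bp DNA linear",
               "ORIGIN", "        1 acgt", "//"), path)
  expect_error(parse_genbank(path), "LOCUS length")
})
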