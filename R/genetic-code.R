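#' @importFrom seqinr s2c c2s translate comp
NULL

# package-level cache for code tables and derived lookups
.mc_cache <- new.env(parent = emptyenv())

.NUC <- c("A", "C", "G", "T")

#' All 64 codons in a fixed lexicographic order
#' @keywords internal
all_codons <- function() {
  as.vector(outer(outer(.NUC, .NUC, paste0), .NUC, paste0))
}

#' Build a genetic code table
#'
#' Constructs a `GeneticCode` object: the codon to amino-acid map for an NCBI
#' translation table, its stop-codon set, and the synonymous-family
#' (degeneracy) classes derived from the map. The default is the invertebrate
#' mitochondrial code (NCBI table 5), which has 62 sense codons, stops
#' TAA/TAG, and family sizes 12 x 2-fold, 6 x 4-fold, 1 x 6-fold (Leu) and
#' 1 x 8-fold (Ser).
#'
#' @param code_id one of `"invertebrate_mito"` (table 5) or `"standard"`
#'   (table 1), or an NCBI numcode integer understood by seqinr.
#' @return a `GeneticCode` list with elements `code_id`, `codon_aa` (named
#'   character of length 64), `stops`, `sense_codons`, `families` (list of
#'   codon vectors per amino acid), `family_size` (named integer per codon).
#' @examples
#' gc5 <- genetic_code()
#' length(gc5$sense_codons)  # 62
#' @export
genetic_code <- function(code_id = "invertebrate_mito") {
  key <- as.character(code_id)
  if (!is.null(.mc_cache[[paste0("code_", key)]])) {
    return(.mc_cache[[paste0("code_", key)]])
  }
  numcode <- switch(key,
    invertebrate_mito = 5L,
    standard = 1L,
    {
      n <- suppressWarnings(as.integer(key))
      if (is.na(n)) stop("unknown genetic code id: ", key)
      n
    }
  )
  codons <- all_codons()
  aa <- vapply(codons, function(cd) {
    seqinr::translate(seqinr::s2c(tolower(cd)), numcode = numcode)
  }, character(1))
  names(aa) <- codons
  stops <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  fams <- split(sense, aa[sense])
  fsize <- integer(0)
  for (f in fams) fsize[f] <- length(f)
  obj <- structure(list(
    code_id = key,
    numcode = numcode,
    codon_aa = aa,
    stops = stops,
    sense_codons = sense,
    families = fams,
    family_size = fsize
  ), class = "GeneticCode")
  .mc_cache[[paste0("code_", key)]] <- obj
  obj
}

#' Degeneracy classes of a genetic code
#'
#' Groups amino acids by synonymous-family size. Used by the code-aware
#' effective-number-of-codons estimator, which needs the class multiplicities
#' (for the invertebrate mitochondrial code: 12 two-fold, 6 four-fold,
#' 1 six-fold, 1 eight-fold amino acids).
#'
#' @param code a `GeneticCode`
#' @return named integer vector: number of amino acids per family size
#'   (names are the sizes)
#' @export
degeneracy_classes <- function(code) {
  sizes <- vapply(code$families, length, integer(1))
  tab <- table(sizes)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Translate a coding sequence
#'
#' @param cds DNA string, length a multiple of 3 (trailing partial codon
#'   dropped with a warning)
#' @param code a `GeneticCode`
#' @return amino-acid string; stops as `*`
#' @export
translate_cds <- function(cds, code = genetic_code()) {
  cods <- split_codons(cds)
  paste(unname(code$codon_aa[cods]), collapse = "")
}

#' Split a DNA string into codons
#' @keywords internal
split_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) return(character(0))
  starts <- seq(1L, n - 2L, by = 3L)
  substring(cds, starts, starts + 2L)
}

#' Reverse complement of a DNA string (IUPAC-aware via seqinr)
#' @param seq DNA string
#' @return reverse-complemented string, uppercase
#' @export
revcomp <- function(seq) {
  toupper(seqinr::c2s(rev(seqinr::comp(seqinr::s2c(tolower(seq)), ambiguous = TRUE))))
}

# TRUE if the single-nucleotide change a -> b is a transition
.is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# the 9 single-nucleotide neighbors of a codon
.codon_neighbors <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  out <- character(0)
  pos <- integer(0)
  ts <- logical(0)
  for (p in 1:3) {
    for (b in setdiff(.NUC, bases[p])) {
      nb <- bases
      nb[p] <- b
      out <- c(out, paste(nb, collapse = ""))
      pos <- c(pos, p)
      ts <- c(ts, .is_transition(bases[p], b))
    }
  }
  data.frame(codon = out, pos = pos, transition = ts, stringsAsFactors = FALSE)
}
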