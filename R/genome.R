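#' Construct an annotated mitochondrial genome
#'
#' The central container of the package: a circular (or linear) J-strand
#' sequence plus an ordered table of typed, stranded gene features on a
#' 0-based half-open coordinate system. Features may run past the sequence
#' end (`end > length`) to represent origin-wrapping genes on a circular
#' molecule.
#'
#' @param genome_id identifier (e.g. accession)
#' @param taxon organism name
#' @param sequence DNA string over A/C/G/T/N, J-strand as deposited
#' @param features data.frame with columns `name` (canonical gene symbol),
#'   `kind` (one of PCG/tRNA/rRNA/CR), `strand` ("J" or "N"), `start`, `end`
#'   (0-based half-open on the J-strand)
#' @param is_circular logical
#' @param genetic_code code id passed to [genetic_code()]
#' @return an `AnnotatedGenome` object
#' @export
annotated_genome <- function(genome_id, taxon, sequence, features,
                             is_circular = TRUE,
                             genetic_code = "invertebrate_mito") {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  stopifnot(len > 0L)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  req <- c("name", "kind", "strand", "start", "end")
  if (!all(req %in% names(features))) {
    stop("features must have columns: ", paste(req, collapse = ", "))
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$end <= features$start)) stop("feature end must exceed start")
  if (any(features$start < 0L) || any(features$start >= len)) {
    stop("feature start must lie in [0, length)")
  }
  if (!is_circular && any(features$end > len)) {
    stop("origin-wrapping feature on a linear genome")
  }
  if (anyDuplicated(features$name)) {
    stop("feature names must be unique per genome: ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "))
  }
  bad <- !features$kind %in% c("PCG", "tRNA", "rRNA", "CR", "other")
  if (any(bad)) stop("unknown feature kind: ", paste(features$kind[bad], collapse = ", "))
  if (!all(features$strand %in% c("J", "N"))) stop("strand must be 'J' or 'N'")
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(
    genome_id = genome_id,
    taxon = taxon,
    sequence = sequence,
    length = len,
    is_circular = is_circular,
    genetic_code = genetic_code,
    features = features
  ), class = "AnnotatedGenome")
}

#' @export
print.AnnotatedGenome <- function(x, ...) {
  cat(sprintf("AnnotatedGenome %s (%s): %d bp, %s, %d features\n",
              x$genome_id, x$taxon, x$length,
              if (x$is_circular) "circular" else "linear",
              nrow(x$features)))
  tab <- table(x$features$kind)
  cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# substring on a circular sequence; [start, end) with end possibly > length
.circ_substr <- function(sequence, start, end, circular = TRUE) {
  len <- nchar(sequence)
  if (end <= len) return(substr(sequence, start + 1L, end))
  if (!circular) stop("coordinates exceed linear sequence length")
  paste0(substr(sequence, start + 1L, len), substr(sequence, 1L, end - len))
}

#' Extract the coding-strand sequence of a gene
#'
#' Returns the feature's sequence in its own reading orientation:
#' minority-strand (N) features are reverse-complemented; origin-wrapping
#' features are resolved by modular indexing on the circular molecule.
#'
#' @param genome an `AnnotatedGenome`
#' @param name canonical gene symbol
#' @return DNA string
#' @export
extract_gene <- function(genome, name) {
  i <- match(name, genome$features$name)
  if (is.na(i)) stop("unknown gene: ", name)
  f <- genome$features[i, ]
  s <- .circ_substr(genome$sequence, f$start, f$end, genome$is_circular)
  if (f$strand == "N") s <- revcomp(s)
  s
}

#' Intergenic spacers and overlaps around the circle
#'
#' Walks consecutive features in circular J-strand order and emits one record
#' per adjacent pair: a spacer (positive length, with sequence) or an overlap
#' (negative length, empty sequence). The pair spanning the origin is
#' included, so records partition the genome together with the features.
#'
#' @param genome an `AnnotatedGenome` with at least 2 features
#' @return data.frame with columns `upstream_gene`, `downstream_gene`,
#'   `length`, `sequence`
#' @export
compute_spacers <- function(genome) {
  fs <- genome$features
  if (nrow(fs) < 2L) stop("need at least 2 features")
  n <- nrow(fs)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    gap_start <- fs$end[i]
    gap_end <- if (i == n) fs$start[j] + genome$length else fs$start[j]
    len <- gap_end - gap_start
    seqstr <- if (len > 0L) {
      .circ_substr(genome$sequence, gap_start %% genome$length,
                   gap_start %% genome$length + len, genome$is_circular)
    } else ""
    out[[i]] <- data.frame(
      upstream_gene = fs$name[i], downstream_gene = fs$name[j],
      length = len, sequence = seqstr, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ancestral insect (Drosophila-like) mitochondrial gene order, anchored at
# cox1, with majority/minority strand of each gene
.ancestral_order <- function() {
  data.frame(
    name = c("cox1", "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6", "cox3",
             "trnG", "nad3", "trnA", "trnR", "trnN", "trnS1", "trnE", "trnF",
             "nad5", "trnH", "nad4", "nad4L", "trnT", "trnP", "nad6", "cob",
             "trnS2", "nad1", "trnL1", "rrnL", "trnV", "rrnS", "CR", "trnI",
             "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY"),
    strand = c("J", "J", "J", "J", "J", "J", "J", "J",
               "J", "J", "J", "J", "J", "J", "J", "N",
               "N", "N", "N", "N", "J", "N", "J", "J",
               "J", "N", "N", "N", "N", "N", "J", "J",
               "N", "J", "J", "J", "N", "N"),
    stringsAsFactors = FALSE)
}

# the Formica order: trnI-trnQ-trnM rewritten as trnM-trnI-trnQ, i.e. the CR
# is followed by trnM (tandem duplication / random loss of the ancestral
# trnI-trnQ-trnM block)
.formica_order <- function() {
  anc <- .ancestral_order()
  idx <- match(c("trnI", "trnQ", "trnM"), anc$name)
  anc$name[idx] <- c("trnM", "trnI", "trnQ")
  anc$strand[idx] <- c("J", "J", "N")
  anc
}

#' Gene order signature and rearrangement label
#'
#' Normalizes the circular gene order by anchoring at `cox1` and compares it
#' with the ancestral insect arrangement. The derived ant arrangement, in
#' which trnM is translocated in front of trnI-trnQ, is recognized as
#' `"trnM_translocation"`; anything else (including genomes with missing
#' genes) is labelled `"other"`.
#'
#' @param genome an `AnnotatedGenome`
#' @return list with `order` (data.frame of name/strand in circular order
#'   from cox1), `label` one of `"ancestral"`, `"trnM_translocation"`,
#'   `"other"`, and `missing` (genes absent relative to the ancestral set)
#' @export
gene_order_signature <- function(genome) {
  fs <- genome$features
  ord <- fs[order(fs$start), c("name", "strand")]
  anc <- .ancestral_order()
  missing <- setdiff(anc$name, ord$name)
  a <- match("cox1", ord$name)
  if (!is.na(a)) {
    idx <- c(a:nrow(ord), seq_len(a - 1L))
    ord <- ord[idx, , drop = FALSE]
  }
  rownames(ord) <- NULL
  label <- "other"
  if (length(missing) == 0L && !is.na(a)) {
    same <- function(ref) {
      ref <- ref[ref$name %in% ord$name, , drop = FALSE]
      nrow(ord) == nrow(ref) &&
        all(ord$name == ref$name) && all(ord$strand == ref$strand)
    }
    if (same(anc)) label <- "ancestral"
    else if (same(.formica_order())) label <- "trnM_translocation"
  }
  list(order = ord, label = label, missing = missing)
}

#' Start and stop codons of all protein-coding genes
#'
#' Classifies each PCG's stop as complete (TAA/TAG) or incomplete: a CDS
#' length of 1 mod 3 implies a truncated T stop, 2 mod 3 a truncated TA stop
#' (both completed to TAA by polyadenylation in vivo). Internal stop codons
#' under the genome's genetic code are flagged but do not abort.
#'
#' @param genome an `AnnotatedGenome`
#' @return data.frame with columns `gene`, `start_codon`, `stop_class`,
#'   `internal_stops`
#' @export
survey_start_stop <- function(genome) {
  code <- genetic_code(genome$genetic_code)
  pcgs <- genome$features$name[genome$features$kind == "PCG"]
  if (length(pcgs) == 0L) stop("no protein-coding genes annotated")
  rows <- lapply(pcgs, function(g) {
    s <- extract_gene(genome, g)
    n <- nchar(s)
    rem <- n %% 3L
    stop_class <- if (rem == 1L) "incomplete_T"
      else if (rem == 2L) "incomplete_TA"
      else {
        last <- substr(s, n - 2L, n)
        if (last %in% code$stops) last else "none"
      }
    ncod <- n %/% 3L
    internal <- 0L
    if (ncod > 1L) {
      body <- split_codons(substr(s, 1L, (ncod - 1L) * 3L))
      internal <- sum(body %in% code$stops)
    }
    data.frame(gene = g, start_codon = substr(s, 1, 3),
               stop_class = stop_class, internal_stops = internal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reverse-complement a genome, flipping feature strands
#'
#' Utility mainly used to test strand symmetry of extraction and skews.
#' @param genome an `AnnotatedGenome`
#' @return an `AnnotatedGenome` on the opposite strand
#' @export
revcomp_genome <- function(genome) {
  len <- genome$length
  fs <- genome$features
  new <- fs
  # interval [s,e) maps to [len-e, len-s) on the complement (mod len)
  new$start <- (len - fs$end) %% len
  new$end <- new$start + (fs$end - fs$start)
  new$strand <- ifelse(fs$strand == "J", "N", "J")
  annotated_genome(genome$genome_id, genome$taxon, revcomp(genome$sequence),
                   new, genome$is_circular, genome$genetic_code)
}
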