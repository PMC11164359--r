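#' Gene-name synonym table
#'
#' Loads the bundled table mapping GenBank/MITOS gene-name dialects
#' (COI, ND4L, tRNA-Ser(UCN), D-loop, ...) to the canonical symbols used
#' throughout the package (cox1, nad4L, trnS2, CR, ...).
#'
#' @return data.frame with columns `synonym`, `canonical`, `kind`
#' @export
gene_synonyms <- function() {
  if (is.null(.mc_cache$synonyms)) {
    path <- system.file("extdata", "gene_synonyms.csv", package = "mitocomp")
    .mc_cache$synonyms <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .mc_cache$synonyms
}

#' Normalize a raw gene name to its canonical symbol
#'
#' @param raw name as found in a `/gene` or `/product` qualifier
#' @return list with `name` (canonical symbol, or the raw name when no
#'   synonym matches), `kind` (or NA), `mapped` (logical)
#' @export
normalize_gene_name <- function(raw) {
  syn <- gene_synonyms()
  key <- toupper(trimws(raw))
  i <- match(key, syn$synonym)
  if (is.na(i)) {
    list(name = raw, kind = NA_character_, mapped = FALSE)
  } else {
    list(name = syn$canonical[i], kind = syn$kind[i], mapped = TRUE)
  }
}

# parse a GenBank location string into (start0, end0, strand) on 0-based
# half-open J-strand coordinates; a join() wrapping the origin becomes an
# interval with end > length
.parse_location <- function(loc, seqlen, lineno) {
  strand <- "J"
  loc <- gsub("[<>]", "", trimws(loc))
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    ivs <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^\\s*(\\d+)\\.\\.(\\d+)\\s*$", p))[[1]]
      if (length(m) != 3L) stop("malformed location at line ", lineno, ": ", loc)
      as.integer(m[2:3])
    })
    if (length(ivs) == 2L && ivs[[1]][2] == seqlen && ivs[[2]][1] == 1L) {
      return(list(start = ivs[[1]][1] - 1L,
                  end = seqlen + ivs[[2]][2], strand = strand))
    }
    stop("unsupported join location at line ", lineno, ": ", loc)
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) != 3L) stop("malformed location at line ", lineno, ": ", loc)
  list(start = as.integer(m[2]) - 1L, end = as.integer(m[3]), strand = strand)
}

#' Read an annotated mitogenome from a GenBank flat file
#'
#' A self-contained reader for the subset of the GenBank format produced by
#' mitogenome annotation pipelines: LOCUS/DEFINITION/ORGANISM headers, a
#' FEATURES table with CDS, tRNA, rRNA, D-loop and misc_feature keys
#' (simple, complement and origin-wrapping two-part join locations), and the
#' ORIGIN sequence block. 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention, and gene names are normalized via
#' [gene_synonyms()]; unmappable names are kept verbatim with a warning and a
#' kind inferred from the feature key.
#'
#' @param path file path
#' @param genetic_code code id for the resulting genome
#' @return an [annotated_genome()] object
#' @export
parse_genbank <- function(path, genetic_code = "invertebrate_mito") {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("malformed record: no LOCUS line in ", path)
  locus <- lines[locus_i[1]]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  genome_id <- toks[2]
  seqlen <- suppressWarnings(as.integer(toks[3]))
  if (is.na(seqlen)) stop("malformed record at line ", locus_i[1], ": ", locus)
  is_circular <- grepl("circular", locus, ignore.case = TRUE)

  taxon <- NA_character_
  org_i <- grep("^\\s{2}ORGANISM", lines)
  if (length(org_i) > 0L) taxon <- trimws(sub("^\\s*ORGANISM\\s*", "", lines[org_i[1]]))
  acc_i <- grep("^VERSION", lines)
  if (length(acc_i) > 0L) {
    v <- strsplit(trimws(lines[acc_i[1]]), "\\s+")[[1]]
    if (length(v) >= 2L) genome_id <- v[2]
  }

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0L) stop("malformed record: no ORIGIN block in ", path)

  # sequence
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > orig_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[(orig_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) != seqlen) {
    stop("malformed record: LOCUS length ", seqlen, " but ORIGIN has ",
         nchar(sequence), " bases")
  }

  feats <- list()
  if (length(feat_i) > 0L) {
    i <- feat_i[1] + 1L
    keys_wanted <- c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")
    while (i < orig_i[1]) {
      line <- lines[i]
      m <- regmatches(line, regexec("^\\s{5}(\\S+)\\s+(\\S.*)$", line))[[1]]
      if (length(m) == 3L && !grepl("^\\s{6}", line)) {
        key <- m[2]
        loc <- m[3]
        lineno <- i
        # collect qualifier lines
        quals <- character(0)
        j <- i + 1L
        while (j < orig_i[1] && grepl("^\\s{10,}", lines[j]) &&
               !grepl("^\\s{5}\\S", lines[j])) {
          quals <- c(quals, trimws(lines[j]))
          j <- j + 1L
        }
        i <- j
        if (key %in% keys_wanted) {
          getq <- function(q) {
            hit <- grep(paste0("^/", q, "="), quals, value = TRUE)
            if (length(hit) == 0L) return(NA_character_)
            gsub('^/[a-z_]+="?|"$', "", hit[1])
          }
          raw <- getq("gene")
          if (is.na(raw)) raw <- getq("product")
          if (is.na(raw)) raw <- getq("note")
          if (is.na(raw)) raw <- if (key == "D-loop") "control region" else key
          nm <- normalize_gene_name(raw)
          kind <- nm$kind
          if (is.na(kind)) {
            kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                           "D-loop" = "CR", "other")
            warning("unmappable gene name '", raw, "' at line ", lineno,
                    "; kept with kind inferred from feature key (", kind, ")")
          }
          if (key == "misc_feature" && kind != "CR") next
          pos <- .parse_location(loc, seqlen, lineno)
          feats[[length(feats) + 1L]] <- data.frame(
            name = nm$name, kind = kind, strand = pos$strand,
            start = pos$start, end = pos$end, stringsAsFactors = FALSE)
        }
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(feats) == 0L) stop("no features parsed from ", path)
  annotated_genome(genome_id, taxon, sequence, do.call(rbind, feats),
                   is_circular, genetic_code)
}

# canonical symbol -> GenBank feature key and qualifier value
.gb_key <- function(kind) {
  switch(kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop",
         "misc_feature")
}

#' Write an annotated mitogenome as a GenBank flat file
#'
#' Inverse of [parse_genbank()]: emits LOCUS, ORGANISM, a FEATURES table and
#' the ORIGIN block, converting back to 1-based inclusive coordinates
#' (origin-wrapping features become two-part joins). A parse-write-parse
#' round trip preserves all coordinates and strands.
#'
#' @param genome an `AnnotatedGenome`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  out <- function(...) writeLines(sprintf(...), con)
  out("LOCUS       %s %d bp    DNA     %s MIT",
      genome$genome_id, genome$length,
      if (genome$is_circular) "circular" else "linear")
  out("DEFINITION  %s mitochondrion, complete genome.", genome$taxon)
  out("VERSION     %s", genome$genome_id)
  out("  ORGANISM  %s", genome$taxon)
  out("FEATURES             Location/Qualifiers")
  out("     source          1..%d", genome$length)
  out("                     /organism=\"%s\"", genome$taxon)
  for (i in seq_len(nrow(genome$features))) {
    f <- genome$features[i, ]
    loc <- if (f$end <= genome$length) {
      sprintf("%d..%d", f$start + 1L, f$end)
    } else {
      sprintf("join(%d..%d,1..%d)", f$start + 1L, genome$length,
              f$end - genome$length)
    }
    if (f$strand == "N") loc <- sprintf("complement(%s)", loc)
    out("     %-15s %s", .gb_key(f$kind), loc)
    out("                     /gene=\"%s\"", f$name)
  }
  out("ORIGIN")
  seq <- tolower(genome$sequence)
  pos <- seq(1L, genome$length, by = 60L)
  for (p in pos) {
    chunk <- substr(seq, p, min(p + 59L, genome$length))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out("%9d %s", p, paste(tens, collapse = " "))
  }
  out("//")
  invisible(path)
}
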