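#' Configuration for the synthetic mitogenome generator
#'
#' Defaults emulate an ant (Formica-like) mitogenome: ~16.5 kb circular
#' molecule, A+T content 0.835, slightly negative AT-skew (-0.02) and
#' strongly negative GC-skew (-0.31) on the J-strand, the derived ant gene
#' order with trnM translocated in front of trnI-trnQ, and a control region
#' carrying a tandem-repeat array, poly-A/poly-T runs and TATA motifs.
#'
#' @param seed integer seed; identical seeds give byte-identical genomes
#' @param genome_length approximate target length (the control region
#'   absorbs the remainder; a minimum CR of 400 bp is enforced)
#' @param at_content target A+T fraction of the J-strand
#' @param at_skew,gc_skew target J-strand skews
#' @param gene_order `"formica"` (trnM translocation) or `"ancestral"`
#' @param codon_bias exponent sharpening codon usage within each synonymous
#'   family (1 = bias purely from positional base composition; 0 = uniform
#'   within families). The default 1.15 reproduces the effective number of
#'   codons (~34) and third-position A+T (~92%) observed in ant
#'   mitochondrial protein-coding genes, i.e. codon bias beyond composition
#'   alone, which places synthetic genomes below the ENC null curve
#' @param omega,kappa defaults used by [evolve_coding()] when simulating
#'   from this genome's coding sequences
#' @param tree newick string or `ape::phylo` used by simulation helpers
#' @param cr_spec list: `repeat_period`, `repeat_copies`, `polyA`, `polyT`,
#'   `tata_n` (number of concatenated TATA motifs)
#' @return a `SyntheticConfig` list
#' @export
synthetic_config <- function(seed = 1, genome_length = 16500,
                             at_content = 0.835, at_skew = -0.02,
                             gc_skew = -0.31,
                             gene_order = c("formica", "ancestral"),
                             codon_bias = 1.15, omega = 0.3, kappa = 2,
                             tree = NULL,
                             cr_spec = list(repeat_period = 36,
                                            repeat_copies = 3,
                                            polyA = 10, polyT = 12,
                                            tata_n = 8)) {
  gene_order <- match.arg(gene_order)
  stopifnot(at_content > 0, at_content < 1,
            at_skew >= -1, at_skew <= 1, gc_skew >= -1, gc_skew <= 1,
            omega > 0, kappa > 0, codon_bias >= 0)
  f <- .base_freqs(at_content, at_skew, gc_skew)
  if (any(f <= 0.005)) {
    stop("infeasible composition targets: a base frequency would be ~0")
  }
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 at_content = at_content, at_skew = at_skew,
                 gc_skew = gc_skew, gene_order = gene_order,
                 codon_bias = codon_bias, omega = omega, kappa = kappa,
                 tree = tree, cr_spec = cr_spec),
            class = "SyntheticConfig")
}

# target base frequencies (A, C, G, T) from content + skews
.base_freqs <- function(at, at_skew, gc_skew) {
  c(A = at * (1 + at_skew) / 2,
    C = (1 - at) * (1 - gc_skew) / 2,
    G = (1 - at) * (1 + gc_skew) / 2,
    T = at * (1 - at_skew) / 2)
}

# typical ant mitochondrial gene lengths (PCGs include start + stop)
.gene_lengths <- function() {
  pcg <- c(cox1 = 1536, cox2 = 678, cox3 = 786, cob = 1140, nad1 = 936,
           nad2 = 999, nad3 = 351, nad4 = 1338, nad4L = 288, nad5 = 1716,
           nad6 = 498, atp6 = 678, atp8 = 159)
  trna <- rep(65L, 22)
  names(trna) <- c("trnA", "trnR", "trnN", "trnD", "trnC", "trnE", "trnQ",
                   "trnG", "trnH", "trnI", "trnK", "trnM", "trnF", "trnP",
                   "trnT", "trnW", "trnY", "trnV", "trnL1", "trnL2",
                   "trnS1", "trnS2")
  c(pcg, trna, rrnL = 1300L, rrnS = 780L)
}

# per-codon-position base frequencies for protein-coding genes: first and
# second positions are constrained below the genome-wide A+T level while
# third positions are A+T-enriched, mirroring the positional composition
# observed in ant mitochondrial PCGs
.codon_pos_freqs <- function(freqs) {
  at <- freqs[["A"]] + freqs[["T"]]
  ats <- if (at > 0) (freqs[["A"]] - freqs[["T"]]) / at else 0
  gc <- 1 - at
  gcs <- if (gc > 0) (freqs[["G"]] - freqs[["C"]]) / gc else 0
  pos_at <- pmin(at * c(0.92, 0.88, 1.08), 0.97)
  lapply(seq_len(3), function(p) .base_freqs(pos_at[p], ats, gcs))
}

# codon sampling distribution: amino-acid usage follows the positional
# composition, while the bias exponent sharpens usage WITHIN each
# synonymous family (codon usage bias proper): bias = 1 is compositional
# sampling, 0 flattens families to uniform, larger values concentrate each
# family on its modal (A/T-rich) codon and so depress the effective number
# of codons without changing amino-acid usage
.codon_dist <- function(freqs, code, bias = 1) {
  pf <- .codon_pos_freqs(freqs)
  sense <- code$sense_codons
  q0 <- vapply(sense, function(cd) {
    b <- strsplit(cd, "")[[1]]
    pf[[1]][b[1]] * pf[[2]][b[2]] * pf[[3]][b[3]]
  }, numeric(1))
  q0 <- q0 / sum(q0)
  q <- q0
  for (fam in code$families) {
    mass <- sum(q0[fam])
    if (mass == 0) next
    cond <- q0[fam] / mass
    cond <- if (bias == 0) rep(1 / length(fam), length(fam)) else cond^bias
    q[fam] <- mass * cond / sum(cond)
  }
  q
}

# sample m codons from the biased positional-composition distribution
.sample_codons <- function(m, freqs, code, bias = 1) {
  q <- .codon_dist(freqs, code, bias)
  code$sense_codons[sample.int(length(q), m, replace = TRUE, prob = q)]
}

# a protein-coding sequence: ATN start, clean body, TAA stop
.sample_cds <- function(len, freqs, code, bias = 1) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  starts <- c("ATT", "ATC", "ATA", "ATG")
  sp <- vapply(starts, function(cd) prod(freqs[strsplit(cd, "")[[1]]]), numeric(1))
  start <- starts[sample.int(4L, 1L, prob = sp)]
  body <- .sample_codons(len / 3L - 2L, freqs, code, bias)
  paste0(start, paste(body, collapse = ""), "TAA")
}

#' Generate a synthetic annotated mitogenome
#'
#' Emits a circular genome with 13 protein-coding genes (ATN starts, TAA
#' stops, no internal stops under the invertebrate mitochondrial code), 22
#' tRNAs, 2 rRNAs and a control region containing the configured tandem
#' repeats, homopolymer runs and TATA motifs, in the configured gene order
#' with the ant J/N strand split. An atp8/atp6 overlap of 7 nt is built in
#' (the largest overlap, as in real ant mitogenomes) and the trnF-nad5
#' spacer is the largest intergenic spacer. Whole-genome base composition is
#' steered to the configured A+T content and skews by sampling and then
#' filling the unconstrained (spacer/filler) positions with the exact
#' residual base multiset.
#'
#' @param config a [synthetic_config()]
#' @return an [annotated_genome()]
#' @export
generate_genome <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  code <- genetic_code("invertebrate_mito")
  f <- .base_freqs(config$at_content, config$at_skew, config$gc_skew)
  fc <- f[c("T", "G", "C", "A")]  # complemented frequencies
  names(fc) <- names(f)
  ord <- if (config$gene_order == "formica") .formica_order() else .ancestral_order()
  lens <- .gene_lengths()

  # protein-coding sequences; N-strand genes are sampled from complemented
  # frequencies so their J-strand projection matches the genome targets.
  # tRNA/rRNA bodies are unconstrained and are drawn from the adjustable
  # pool below, which concentrates the residual A+T outside the PCGs just
  # as in real mitogenomes.
  gene_seq <- list()
  for (i in seq_len(nrow(ord))) {
    g <- ord$name[i]
    if (!grepl("^(cox|cob|nad|atp)", g)) next
    use_f <- if (ord$strand[i] == "J") f else fc
    gene_seq[[g]] <- .sample_cds(lens[[g]], use_f, code, config$codon_bias)
  }
  # atp8/atp6 overlap: atp6 begins ATGATAAAT...; atp8's tail is rewritten so
  # its last codons read ...ATA TGA TAA across the shared 7 bases
  atp6 <- gene_seq[["atp6"]]
  atp6 <- paste0("ATGATAAAT", substr(atp6, 10L, nchar(atp6)))
  gene_seq[["atp6"]] <- atp6
  atp8 <- gene_seq[["atp8"]]
  atp8 <- paste0(substr(atp8, 1L, nchar(atp8) - 9L), "AT", substr(atp6, 1L, 7L))
  gene_seq[["atp8"]] <- atp8

  # control region parts around free filler
  cr <- config$cr_spec
  unit <- paste(sample(names(f), cr$repeat_period, replace = TRUE,
                       prob = f / sum(f)), collapse = "")
  full <- floor(cr$repeat_copies)
  fracn <- round((cr$repeat_copies - full) * cr$repeat_period)
  rep_arr <- paste0(strrep(unit, full), substr(unit, 1L, fracn))
  tata <- strrep("TATA", cr$tata_n)
  cr_fixed <- list(polyT = strrep("T", cr$polyT), rep = rep_arr,
                   tata = tata, polyA = strrep("A", cr$polyA))

  # lay the genome out: features separated by small spacers (free filler),
  # trnF-nad5 getting the largest spacer, atp8-atp6 overlapping by 7
  gaps <- rep(2L, nrow(ord))
  names(gaps) <- ord$name  # gap AFTER each feature
  gaps[["trnF"]] <- 24L
  gaps[["atp8"]] <- -7L
  gaps[["rrnS"]] <- 0L
  gaps[["CR"]] <- 0L

  rna_len <- sum(lens[!grepl("^(cox|cob|nad|atp)", names(lens))])
  fixed_len <- sum(vapply(gene_seq, nchar, integer(1)))
  cr_fixed_len <- sum(vapply(cr_fixed, nchar, integer(1)))
  gap_total <- sum(pmax(gaps[names(gaps) != "CR"], 0L))
  # the atp8/atp6 overlap shortens the laid-out genome by 7 bp
  cr_free <- config$genome_length - (fixed_len - 7L) - rna_len -
    cr_fixed_len - gap_total
  if (cr_free < max(60L, 400L - cr_fixed_len)) {
    cr_free <- max(60L, 400L - cr_fixed_len)
  }
  cr_free_a <- cr_free %/% 3L
  cr_free_b <- cr_free %/% 3L
  cr_free_c <- cr_free - cr_free_a - cr_free_b

  # assemble; free segments are recorded for the composition fill-in pass
  pieces <- character(0)
  free_marks <- list()  # (offset, length) of free segments, 0-based
  pos <- 0L
  feat_rows <- list()
  push <- function(s) { pieces[[length(pieces) + 1L]] <<- s; pos <<- pos + nchar(s) }
  push_free <- function(nn) {
    if (nn <= 0L) return(invisible())
    free_marks[[length(free_marks) + 1L]] <<- c(pos, nn)
    push(paste(sample(names(f), nn, replace = TRUE, prob = f), collapse = ""))
  }
  # rotate order so the genome starts right after the CR
  cr_i <- which(ord$name == "CR")
  rot <- c(seq_len(nrow(ord))[-seq_len(cr_i)], seq_len(cr_i))
  ordr <- ord[rot, , drop = FALSE]
  overlap_carry <- 0L
  for (i in seq_len(nrow(ordr))) {
    g <- ordr$name[i]
    if (g == "CR") {
      start <- pos
      push_free(cr_free_a)
      push(cr_fixed$polyT)
      push_free(cr_free_b)
      push(cr_fixed$rep)
      push(cr_fixed$tata)
      push(cr_fixed$polyA)
      push_free(cr_free_c)
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        name = "CR", kind = "CR", strand = "J", start = start, end = pos,
        stringsAsFactors = FALSE)
      next
    }
    kind <- if (grepl("^(cox|cob|nad|atp)", g)) "PCG"
            else if (grepl("^trn", g)) "tRNA"
            else "rRNA"
    if (kind == "PCG") {
      s <- gene_seq[[g]]
      jseq <- if (ordr$strand[i] == "J") s else revcomp(s)
      start <- pos - overlap_carry
      if (overlap_carry > 0L) {
        # shared bases already emitted by the upstream gene
        jseq <- substr(jseq, overlap_carry + 1L, nchar(jseq))
        overlap_carry <- 0L
      }
      push(jseq)
      glen <- nchar(s)
    } else {
      start <- pos
      push_free(lens[[g]])
      glen <- lens[[g]]
    }
    feat_rows[[length(feat_rows) + 1L]] <- data.frame(
      name = g, kind = kind, strand = ordr$strand[i],
      start = start, end = start + glen, stringsAsFactors = FALSE)
    gap <- gaps[[g]]
    if (gap >= 0L) push_free(gap) else overlap_carry <- -gap
  }
  sequence <- paste(pieces, collapse = "")
  L <- nchar(sequence)

  # composition fill-in: replace free positions with the exact residual
  # multiset needed to hit the target counts
  v <- strsplit(sequence, "")[[1]]
  free_idx <- unlist(lapply(free_marks, function(m) (m[1] + 1L):(m[1] + m[2])))
  target <- round(f / sum(f) * L)
  target[1] <- target[1] + (L - sum(target))
  fixed_counts <- table(factor(v[-free_idx], levels = names(f)))
  need <- pmax(target - as.integer(fixed_counts), 0L)
  # rescale to the pool size (largest remainders) in case clipping or
  # rounding left a mismatch
  if (sum(need) != length(free_idx)) {
    raw <- need / max(sum(need), 1L) * length(free_idx)
    need <- floor(raw)
    rem <- length(free_idx) - sum(need)
    if (rem > 0L) {
      up <- order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]
      need[up] <- need[up] + 1L
    }
  }
  v[free_idx] <- sample(rep(names(f), times = need))
  sequence <- paste(v, collapse = "")

  annotated_genome(paste0("SYN", config$seed), "Formica synthetica", sequence,
                   do.call(rbind, feat_rows), is_circular = TRUE,
                   genetic_code = "invertebrate_mito")
}

# per-codon mutation tables: for each sense codon the 9 neighbor targets
# with transition and synonymy flags (stop targets dropped)
.mutation_tables <- function(code) {
  key <- paste0("mut_", code$code_id)
  if (!is.null(.mc_cache[[key]])) return(.mc_cache[[key]])
  tabs <- lapply(code$sense_codons, function(cd) {
    nb <- .codon_neighbors(cd)
    nb <- nb[!(nb$codon %in% code$stops), , drop = FALSE]
    nb$syn <- code$codon_aa[nb$codon] == code$codon_aa[[cd]]
    nb$target <- match(nb$codon, code$sense_codons)
    nb
  })
  names(tabs) <- code$sense_codons
  .mc_cache[[key]] <- tabs
  tabs
}

#' Evolve coding sequences along a tree
#'
#' Codon-level continuous-time simulation: each possible single-nucleotide
#' codon change has relative rate `kappa` (transitions) or 1
#' (transversions), multiplied by `omega` when the change is
#' nonsynonymous; changes creating stop codons are forbidden. Rates are
#' normalized once so that one unit of branch length corresponds to one
#' expected substitution per nucleotide site for the root sequence, and
#' events are drawn by Gillespie sampling along each branch. No indels, no
#' rate heterogeneity: the output is a gap-free alignment.
#'
#' @param root_cds root coding sequence (length a multiple of 3, sense
#'   codons only)
#' @param tree `ape::phylo` or newick string with branch lengths
#' @param omega dN/dS of the simulation
#' @param kappa transition/transversion rate ratio
#' @param seed integer seed
#' @param code a [genetic_code()]
#' @return named character vector of aligned tip sequences
#' @export
evolve_coding <- function(root_cds, tree, omega, kappa, seed = 1,
                          code = genetic_code()) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  root_cds <- toupper(root_cds)
  if (nchar(root_cds) %% 3L != 0L) stop("root length must be a multiple of 3")
  cods <- split_codons(root_cds)
  idx0 <- match(cods, code$sense_codons)
  if (anyNA(idx0)) stop("root contains stop or ambiguous codons")
  tabs <- .mutation_tables(code)
  # per-codon-state total rate and per-neighbor weights for this (omega,kappa)
  wts <- lapply(tabs, function(nb) {
    ifelse(nb$transition, kappa, 1) * ifelse(nb$syn, 1, omega)
  })
  tot <- vapply(wts, sum, numeric(1))
  n_nt <- 3L * length(idx0)
  C <- sum(tot[idx0]) / n_nt  # root normalization: 1 unit = 1 sub/site

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  evolve_branch <- function(idx, t) {
    if (t <= 0) return(idx)
    r <- tot[idx]
    R <- sum(r)
    elapsed <- 0
    repeat {
      elapsed <- elapsed + stats::rexp(1, rate = R / C)
      if (elapsed > t) break
      site <- sample.int(length(idx), 1L, prob = r)
      nb <- tabs[[idx[site]]]
      w <- wts[[idx[site]]]
      ch <- sample.int(nrow(nb), 1L, prob = w)
      idx[site] <- nb$target[ch]
      R <- R - r[site] + tot[idx[site]]
      r[site] <- tot[idx[site]]
    }
    idx
  }

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- idx0
  # preorder: ape edges are already root-to-tip ordered after reorder()
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    states[[ch]] <- evolve_branch(states[[par]], tr$edge.length[e])
  }
  out <- vapply(seq_len(ntip), function(i) {
    paste(code$sense_codons[states[[i]]], collapse = "")
  }, character(1))
  names(out) <- tree$tip.label
  out
}

#' Read an aligned FASTA file as a named character vector
#' @param path FASTA file
#' @return named uppercase character vector
#' @export
read_fasta_aln <- function(path) {
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  out <- toupper(vapply(x, as.character, character(1)))
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(seqs), names = names(seqs), file.out = path,
                      nbchar = 70)
  invisible(path)
}
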