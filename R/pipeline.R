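#' Run configuration for the comparative pipeline
#'
#' @param genomes list of `AnnotatedGenome` objects and/or GenBank file paths
#' @param alignments optional named list of per-gene codon alignments (named
#'   character vectors); when absent, genes whose extracted CDSs happen to
#'   have equal lengths across genomes (e.g. simulator output) are compared
#'   directly
#' @param out_dir output directory for TSV/newick exports (NULL = no files)
#' @param genetic_code code id
#' @param kaks_method,kappa passed to [gene_kaks_summary()]
#' @param bootstrap_reps bootstrap replicates for Ka/Ks SEs and tree support
#' @param seed integer seed controlling all resampling
#' @return a `RunConfig` list
#' @export
run_config <- function(genomes, alignments = NULL, out_dir = NULL,
                       genetic_code = "invertebrate_mito",
                       kaks_method = "ng86_jc", kappa = 1,
                       bootstrap_reps = 200, seed = 1) {
  structure(list(genomes = genomes, alignments = alignments,
                 out_dir = out_dir, genetic_code = genetic_code,
                 kaks_method = kaks_method, kappa = kappa,
                 bootstrap_reps = bootstrap_reps, seed = as.integer(seed)),
            class = "RunConfig")
}

# tiny FNV-1a hash of a deparsed object, for provenance headers
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 987654323
  sprintf("%08x", h)
}

.write_tsv <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(format(df, digits = 10, trim = TRUE, nsmall = 0,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Run the full comparative mitogenomic analysis
#'
#' Orchestrates every module over a set of annotated genomes: feature/size
#' accounting, per-region composition and skews, codon usage (counts, RSCU,
#' ENC, CBI, positional GC), ENC-plot and neutrality-plot data, per-gene
#' Ka/Ks with bootstrap SEs, spacer/control-region characterization, and a
#' K2P + NJ phylogeny with bootstrap supports. Stage failures are isolated:
#' the run continues and failed stages are listed in the returned manifest.
#' With a single genome the pairwise and phylogenetic stages are skipped
#' with a notice. Outputs are deterministic given the config (provenance
#' headers carry the seed and a config hash, no timestamps).
#'
#' @param config a [run_config()]
#' @return a result bundle (list of tables/trees) with elements `status`
#'   (0 success, 1 partial failures) and `failures`
#' @export
run_comparative <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  genomes <- lapply(config$genomes, function(g) {
    if (inherits(g, "AnnotatedGenome")) g else parse_genbank(g, config$genetic_code)
  })
  if (length(genomes) == 0L) stop("no parseable genome")
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  names(genomes) <- ids
  code <- genetic_code(config$genetic_code)
  hash <- .config_hash(list(ids, config$kaks_method, config$kappa,
                            config$bootstrap_reps, config$seed))
  hdr <- c(sprintf("# mitocomp run: %d genome(s)", length(genomes)),
           sprintf("# seed=%d config_hash=%s", config$seed, hash))
  res <- list(status = 0L, failures = character(0))
  fail <- function(stage, e) {
    res$failures <<- c(res$failures, paste0(stage, ": ", conditionMessage(e)))
    res$status <<- 1L
    NULL
  }
  stage <- function(name, expr) tryCatch(expr, error = function(e) fail(name, e))

  res$features <- stage("features", {
    rows <- lapply(genomes, function(g) {
      fs <- g$features
      flen <- ifelse(fs$end > g$length, fs$end - fs$start, fs$end - fs$start)
      data.frame(genome = g$genome_id, taxon = g$taxon, length = g$length,
                 pcg_total = sum(flen[fs$kind == "PCG"]),
                 trna_total = sum(flen[fs$kind == "tRNA"]),
                 rrnL = if ("rrnL" %in% fs$name) nchar(extract_gene(g, "rrnL")) else NA,
                 rrnS = if ("rrnS" %in% fs$name) nchar(extract_gene(g, "rrnS")) else NA,
                 cr = sum(flen[fs$kind == "CR"]),
                 gene_order = gene_order_signature(g)$label,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  res$start_stop <- stage("start_stop", {
    do.call(rbind, lapply(genomes, function(g) {
      cbind(genome = g$genome_id, survey_start_stop(g))
    }))
  })

  res$composition <- stage("composition", {
    do.call(rbind, lapply(genomes, function(g) {
      cbind(genome = g$genome_id, regional_composition(g))
    }))
  })

  pcg_seqs <- lapply(genomes, function(g) {
    nm <- g$features$name[g$features$kind == "PCG"]
    stats::setNames(lapply(nm, extract_gene, genome = g), nm)
  })

  res$codon_usage <- stage("codon_usage", {
    rows <- lapply(names(genomes), function(id) {
      st <- codon_usage_stats(pcg_seqs[[id]], code)
      data.frame(genome = id, n_codons = st$counts$total, enc = st$enc,
                 cbi = st$cbi, gc_all = st$gc_all, gc12 = st$gc12,
                 gc3 = st$gc3, at3 = st$at3,
                 enc_expected = enc_null_curve(st$s),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  res$rscu <- stage("rscu", {
    do.call(rbind, lapply(names(genomes), function(id) {
      cbind(genome = id, rscu(count_codons(pcg_seqs[[id]], code)))
    }))
  })

  res$neutrality <- stage("neutrality", {
    cu <- res$codon_usage
    if (is.null(cu) || nrow(cu) < 3L) {
      message("neutrality regression skipped: needs >= 3 genomes")
      NULL
    } else neutrality_plot(cu$gc12, cu$gc3)
  })

  res$spacers <- stage("spacers", {
    do.call(rbind, lapply(genomes, function(g) {
      sp <- compute_spacers(g)
      cbind(genome = g$genome_id, sp[, c("upstream_gene", "downstream_gene",
                                         "length")])
    }))
  })

  res$noncoding <- stage("noncoding", {
    rows <- lapply(genomes, function(g) {
      if (!"CR" %in% g$features$name) return(NULL)
      crs <- extract_gene(g, "CR")
      reps <- find_tandem_repeats(crs)
      data.frame(genome = g$genome_id, cr_length = nchar(crs),
                 n_repeat_arrays = nrow(reps),
                 max_repeat_period = if (nrow(reps)) max(reps$period) else NA,
                 n_polyA = nrow(find_runs(crs, "A")),
                 n_polyT = nrow(find_runs(crs, "T")),
                 tata_motifs = count_motif(crs, "TATA"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, Filter(Negate(is.null), rows))
  })

  # per-gene comparable CDS sets for pairwise stages
  get_alignments <- function() {
    if (!is.null(config$alignments)) return(config$alignments)
    genes <- Reduce(intersect, lapply(pcg_seqs, names))
    out <- list()
    for (g in genes) {
      seqs <- vapply(names(genomes), function(id) pcg_seqs[[id]][[g]],
                     character(1))
      if (length(unique(nchar(seqs))) == 1L) out[[g]] <- seqs
    }
    out
  }

  if (length(genomes) >= 2L) {
    res$kaks <- stage("kaks", {
      alns <- get_alignments()
      if (length(alns) == 0L) stop("no comparable per-gene alignments")
      rows <- lapply(names(alns), function(g) {
        s <- gene_kaks_summary(alns[[g]], code, method = config$kaks_method,
                               kappa = config$kappa,
                               bootstrap_reps = config$bootstrap_reps,
                               seed = config$seed)
        gc <- mean(vapply(alns[[g]], function(x) composition(x)$gc_content,
                          numeric(1)))
        data.frame(gene = g, mean_ka = s$mean_ka, mean_ks = s$mean_ks,
                   mean_ratio = s$mean_ratio,
                   ratio_of_means = s$ratio_of_means,
                   se_ka = s$se_ka, se_ks = s$se_ks, se_ratio = s$se_ratio,
                   gc_content = gc, n_pairs = s$n_pairs,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
  } else message("pairwise Ka/Ks skipped: single genome")

  if (length(genomes) >= 3L) {
    res$phylogeny <- stage("phylogeny", {
      alns <- get_alignments()
      if (length(alns) == 0L) stop("no comparable alignments for phylogeny")
      concat <- vapply(names(genomes), function(id) {
        paste(vapply(alns, `[[`, character(1), id), collapse = "")
      }, character(1))
      bs <- bootstrap_support(concat, reps = config$bootstrap_reps,
                              seed = config$seed)
      list(tree = bs$tree, distances = k2p_matrix(concat),
           reps_used = bs$reps_used, reps_dropped = bs$reps_dropped)
    })
  } else message("phylogeny skipped: fewer than 3 genomes")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(nm) {
      if (!is.null(res[[nm]]) && is.data.frame(res[[nm]])) {
        .write_tsv(res[[nm]], file.path(config$out_dir, paste0(nm, ".tsv")), hdr)
      }
    }
    for (nm in c("features", "start_stop", "composition", "codon_usage",
                 "rscu", "spacers", "noncoding", "kaks")) wr(nm)
    if (!is.null(res$phylogeny)) {
      ape::write.tree(res$phylogeny$tree,
                      file.path(config$out_dir, "nj_tree.nwk"))
      dm <- as.data.frame(res$phylogeny$distances)
      dm <- cbind(taxon = rownames(dm), dm)
      .write_tsv(dm, file.path(config$out_dir, "k2p_distances.tsv"), hdr)
    }
    if (length(res$failures) > 0L) {
      writeLines(res$failures, file.path(config$out_dir, "failures.txt"))
    }
  }
  res
}
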