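#' Nucleotide composition and strand-asymmetry skews
#'
#' Counts A/C/G/T (ambiguity codes and N are excluded from both numerator
#' and denominator) and computes A+T and G+C content together with the
#' strand-asymmetry skews
#' \deqn{AT\,skew = (A - T)/(A + T), \qquad GC\,skew = (G - C)/(G + C).}
#' Skews are reported as `NA` when their denominator is zero. Percentages
#' are kept at full precision; round only at the reporting layer.
#'
#' @param seq DNA string
#' @return a `CompositionStats` list: `counts` (named A/C/G/T), `n_used`,
#'   `at_content`, `gc_content` (percent), `at_skew`, `gc_skew`
#' @examples
#' composition("AAAT")$at_skew  # 0.5
#' @export
composition <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  counts <- c(A = sum(v == "A"), C = sum(v == "C"),
              G = sum(v == "G"), T = sum(v == "T"))
  n <- sum(counts)
  if (n == 0L) stop("no unambiguous bases")
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(list(
    counts = counts,
    n_used = n,
    at_content = 100 * at / n,
    gc_content = 100 * gc / n,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_
  ), class = "CompositionStats")
}

#' @export
print.CompositionStats <- function(x, ...) {
  cat(sprintf("A+T %.2f%%  G+C %.2f%%  AT-skew %+.4f  GC-skew %+.4f (n=%d)\n",
              x$at_content, x$gc_content, x$at_skew, x$gc_skew, x$n_used))
  invisible(x)
}

#' Composition by genomic region
#'
#' One row per region: the whole J-strand, the concatenated PCGs, tRNAs and
#' rRNAs (J-strand-oriented, i.e. feature intervals taken as deposited
#' without re-orientation, so regional counts are consistent with the
#' whole-genome strand accounting), the control region, the concatenated
#' intergenic spacers, and every individual gene (these in coding
#' orientation).
#'
#' @param genome an `AnnotatedGenome`
#' @return data.frame keyed by `region` with count/content/skew columns
#' @export
regional_composition <- function(genome) {
  row_of <- function(region, seq) {
    cs <- composition(seq)
    data.frame(region = region, n = cs$n_used,
               A = cs$counts[["A"]], C = cs$counts[["C"]],
               G = cs$counts[["G"]], T = cs$counts[["T"]],
               at_content = cs$at_content, gc_content = cs$gc_content,
               at_skew = cs$at_skew, gc_skew = cs$gc_skew,
               stringsAsFactors = FALSE)
  }
  fs <- genome$features
  jseq <- function(i) .circ_substr(genome$sequence, fs$start[i], fs$end[i],
                                   genome$is_circular)
  rows <- list(row_of("whole", genome$sequence))
  for (kd in c("PCG", "tRNA", "rRNA")) {
    idx <- which(fs$kind == kd)
    if (length(idx) == 0L) {
      message("region absent: ", kd)
      next
    }
    cc <- paste(vapply(idx, jseq, character(1)), collapse = "")
    rows[[length(rows) + 1L]] <- row_of(paste0(kd, "s"), cc)
  }
  cr <- which(fs$kind == "CR")
  if (length(cr) > 0L) {
    rows[[length(rows) + 1L]] <- row_of("CR", jseq(cr[1]))
  } else message("region absent: CR")
  if (nrow(fs) >= 2L) {
    sp <- compute_spacers(genome)
    igs <- paste(sp$sequence[sp$length > 0L], collapse = "")
    if (nzchar(igs)) rows[[length(rows) + 1L]] <- row_of("IGS_concatenated", igs)
  }
  for (i in seq_len(nrow(fs))) {
    if (fs$kind[i] == "CR") next  # already reported as the CR region row
    rows[[length(rows) + 1L]] <- row_of(fs$name[i], extract_gene(genome, fs$name[i]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
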