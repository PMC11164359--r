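#' Count codons across a set of coding sequences
#'
#' Aggregates in-frame codon counts over one or more CDSs. Trailing partial
#' codons (truncated stop codons) are dropped, codons containing non-ACGT
#' characters are excluded, and stop codons are excluded by default so that
#' statistics live in the 62-sense-codon universe of the invertebrate
#' mitochondrial code.
#'
#' @param cds_list character vector (or list) of CDS strings
#' @param code a [genetic_code()]
#' @param exclude_stops drop stop codons from the counts (default TRUE)
#' @return a `CodonCounts` list: `counts` (named integer over codons),
#'   `total`, `code_id`
#' @export
count_codons <- function(cds_list, code = genetic_code(), exclude_stops = TRUE) {
  cods <- character(0)
  for (cds in cds_list) {
    if (nchar(cds) < 3L) {
      warning("CDS shorter than 3 nt skipped")
      next
    }
    cods <- c(cods, split_codons(cds))
  }
  cods <- cods[!grepl("[^ACGT]", cods)]
  if (exclude_stops) cods <- cods[!cods %in% code$stops]
  universe <- if (exclude_stops) code$sense_codons else all_codons()
  counts <- integer(length(universe))
  names(counts) <- universe
  tab <- table(cods)
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, total = sum(counts), code_id = code$code_id),
            class = "CodonCounts")
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c in a synonymous family of size k with counts n:
#' `k * n_c / sum(n_family)`. Families with zero total get `NA`. Within each
#' observed family the RSCU values average to 1 and sum to k.
#'
#' @param counts a [count_codons()] result
#' @return data.frame with columns `codon`, `aa`, `count`, `rscu`
#' @export
rscu <- function(counts) {
  code <- genetic_code(counts$code_id)
  out <- data.frame(codon = names(counts$counts),
                    aa = unname(code$codon_aa[names(counts$counts)]),
                    count = as.integer(counts$counts),
                    rscu = NA_real_, stringsAsFactors = FALSE)
  for (fam in code$families) {
    idx <- match(fam, out$codon)
    tot <- sum(out$count[idx])
    if (tot > 0L) out$rscu[idx] <- length(fam) * out$count[idx] / tot
  }
  out
}

#' Effective number of codons (code-aware Wright estimator)
#'
#' Wright's ENC generalized to arbitrary degeneracy classes. For each amino
#' acid with n >= 2 counted codons, the codon homozygosity is estimated as
#' \deqn{\hat F = (n \sum_i p_i^2 - 1)/(n - 1)}
#' and averaged within each synonymous-family-size class; then
#' `ENC = sum_k m_k / Fbar_k`, with m_k the number of amino acids whose
#' family has size k. For the invertebrate mitochondrial code this is
#' `12/Fbar_2 + 6/Fbar_4 + 1/Fbar_6 + 1/Fbar_8`, ranging from 20 (maximal
#' bias) to 62 (uniform usage). A class with no defined F-hat is imputed as
#' uniform (Fbar = 1/k) with a warning; amino acids with a single codon
#' contribute their count m_1 directly. The result is clamped to
#' [total amino acids, total sense codons].
#'
#' @param counts a [count_codons()] result
#' @param standard_classes if TRUE, pool amino acids into Wright's
#'   standard-code classes by family size anyway (compatibility mode; with a
#'   code-derived family table the two are identical). Default FALSE.
#' @return ENC value
#' @export
enc <- function(counts, standard_classes = FALSE) {
  code <- genetic_code(counts$code_id)
  fsize <- vapply(code$families, length, integer(1))
  fhat <- rep(NA_real_, length(code$families))
  for (i in seq_along(code$families)) {
    n_c <- counts$counts[code$families[[i]]]
    n <- sum(n_c)
    if (n >= 2L) {
      p <- n_c / n
      fhat[i] <- (n * sum(p^2) - 1) / (n - 1)
    }
  }
  if (all(is.na(fhat[fsize > 1L]))) stop("insufficient codons")
  enc_val <- 0
  for (k in sort(unique(fsize))) {
    m_k <- sum(fsize == k)
    if (k == 1L) {
      enc_val <- enc_val + m_k
      next
    }
    fk <- fhat[fsize == k]
    fk <- fk[!is.na(fk) & fk > 0]
    fbar <- if (length(fk) > 0L) mean(fk) else {
      warning("no amino acid with >= 2 codons in the ", k,
              "-fold class; imputing uniform homozygosity 1/", k)
      1 / k
    }
    enc_val <- enc_val + m_k / fbar
  }
  max(length(code$families), min(enc_val, length(code$sense_codons)))
}

#' Codon bias index
#'
#' CBI measures excess usage of preferred codons:
#' `(N_pref - N_rand) / (N_tot - N_rand)` where N_tot counts codons of amino
#' acids with >= 2 synonyms, N_pref those that are the preferred codon, and
#' N_rand = sum over amino acids of n_aa / k_aa (the expectation under
#' uniform synonymous usage). The preferred codon defaults to the modal
#' codon of each family in the data (ties broken alphabetically); a fixed
#' preferred set can be supplied to mirror other software's conventions.
#'
#' @param counts a [count_codons()] result
#' @param preferred optional named character vector, amino acid -> codon
#' @return CBI value (1 = only preferred codons used; 0 = uniform usage)
#' @export
cbi <- function(counts, preferred = NULL) {
  code <- genetic_code(counts$code_id)
  n_tot <- 0; n_pref <- 0; n_rand <- 0
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    k <- length(fam)
    if (k < 2L) next
    n_c <- counts$counts[fam]
    n <- sum(n_c)
    if (n == 0L) next
    pref <- if (!is.null(preferred) && aa %in% names(preferred)) {
      preferred[[aa]]
    } else {
      fam[which.max(n_c)]  # modal; which.max ties -> first (alphabetical)
    }
    n_tot <- n_tot + n
    n_pref <- n_pref + n_c[[pref]]
    n_rand <- n_rand + n / k
  }
  if (n_tot == n_rand) stop("degenerate counts: N_tot equals N_rand")
  (n_pref - n_rand) / (n_tot - n_rand)
}

#' GC and AT content by codon position
#'
#' Percent G+C (and A+T) at codon positions 1, 2 and 3 over all counted
#' codons, plus GC12 (mean of GC1 and GC2) and overall GC. Codon filtering
#' follows [count_codons()].
#'
#' @inheritParams count_codons
#' @return named list: `gc1`, `gc2`, `gc3`, `gc12`, `gc_all`,
#'   `at1`, `at2`, `at3` (percent)
#' @export
positional_gc <- function(cds_list, code = genetic_code()) {
  cc <- count_codons(cds_list, code)
  cods <- names(cc$counts)
  n <- cc$counts
  tot <- sum(n)
  if (tot == 0L) stop("no codons counted")
  pos_gc <- vapply(1:3, function(p) {
    b <- substr(cods, p, p)
    100 * sum(n[b %in% c("G", "C")]) / tot
  }, numeric(1))
  list(gc1 = pos_gc[1], gc2 = pos_gc[2], gc3 = pos_gc[3],
       gc12 = mean(pos_gc[1:2]), gc_all = mean(pos_gc),
       at1 = 100 - pos_gc[1], at2 = 100 - pos_gc[2], at3 = 100 - pos_gc[3])
}

#' Expected ENC under pure compositional (mutation) bias
#'
#' Wright's null curve for the ENC-vs-GC3 plot:
#' \deqn{ENC_{exp}(s) = 2 + s + 29/(s^2 + (1-s)^2)}
#' with s the G+C fraction at third codon positions. Genes falling well
#' below the curve show codon bias beyond what composition alone explains
#' (selection); genes on the curve are consistent with mutation pressure.
#' The standard-code formula is used regardless of genetic code, as is
#' conventional for ENC plots.
#'
#' @param s GC3 as a fraction in (0, 1)
#' @return expected ENC
#' @examples
#' enc_null_curve(0.5)  # 60.5
#' @export
enc_null_curve <- function(s) {
  if (any(s <= 0) || any(s >= 1)) stop("s must lie in (0, 1)")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Pearson correlation with t test
#'
#' Convenience wrapper reporting r, R-squared and the two-sided p value, as
#' used for the ENC/CBI/GC correlation panels.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return list: `r`, `r_squared`, `p_value`
#' @export
codon_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stop("need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value)
}

#' Full codon-usage summary for a gene set
#'
#' Bundles counts, RSCU, ENC, CBI and positional GC for a set of CDSs
#' (typically the 13 PCGs of one mitogenome, either concatenated or kept
#' separate — see `mode`).
#'
#' @inheritParams count_codons
#' @param mode `"concatenate"` (ENC/CBI on pooled counts, the default) or
#'   `"per_gene_mean"` (mean of per-CDS ENC/CBI values, skipping CDSs with
#'   insufficient codons)
#' @return a `CodonUsageStats` list
#' @export
codon_usage_stats <- function(cds_list, code = genetic_code(),
                              mode = c("concatenate", "per_gene_mean")) {
  mode <- match.arg(mode)
  cc <- count_codons(cds_list, code)
  pg <- positional_gc(cds_list, code)
  if (mode == "concatenate") {
    enc_v <- enc(cc)
    cbi_v <- cbi(cc)
  } else {
    per <- lapply(cds_list, function(s) {
      tryCatch({
        one <- count_codons(list(s), code)
        c(enc(one), cbi(one))
      }, error = function(e) c(NA_real_, NA_real_))
    })
    m <- do.call(rbind, per)
    enc_v <- mean(m[, 1], na.rm = TRUE)
    cbi_v <- mean(m[, 2], na.rm = TRUE)
  }
  structure(list(
    counts = cc, rscu = rscu(cc), enc = enc_v, cbi = cbi_v,
    gc1 = pg$gc1, gc2 = pg$gc2, gc3 = pg$gc3, gc12 = pg$gc12,
    gc_all = pg$gc_all, at3 = pg$at3,
    s = pg$gc3 / 100, mode = mode
  ), class = "CodonUsageStats")
}

#' @export
print.CodonUsageStats <- function(x, ...) {
  cat(sprintf("%d codons; ENC %.2f, CBI %.3f, GC %.2f%%, GC3 %.2f%% (%s)\n",
              x$counts$total, x$enc, x$cbi, x$gc_all, x$gc3, x$mode))
  invisible(x)
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Regresses GC12 on GC3 across gene sets or genomes. A slope near 1 means
#' third-position composition predicts the constrained positions, i.e.
#' mutation pressure dominates; a slope near 0 means positions 1+2 are
#' decoupled from position 3, i.e. selection/constraint dominates.
#'
#' @param gc12,gc3 numeric vectors (percent), equal length >= 3
#' @return list: `slope`, `intercept`, `r_squared`, `p_value`
#' @export
neutrality_plot <- function(gc12, gc3) {
  if (length(gc12) != length(gc3) || length(gc3) < 3L) {
    stop("need equal lengths >= 3")
  }
  fit <- stats::lm(gc12 ~ gc3)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4])
}
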