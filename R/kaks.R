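#' Synonymous and nonsynonymous site counts of a codon
#'
#' Nei-Gojobori site counting: at each codon position the synonymous
#' fraction is the number of synonymous single-nucleotide neighbors divided
#' by the number of non-stop neighbors at that position; synonymous sites
#' are the sum of the three fractions and nonsynonymous sites the
#' complement, so `s + n = 3` for every sense codon. With `kappa != 1` the
#' neighbors are transition/transversion weighted (the modified
#' Nei-Gojobori counting used by the Kumar method), which matters when the
#' substitution process is transition-biased.
#'
#' @param codon sense codon string
#' @param code a [genetic_code()]
#' @param kappa transition/transversion rate ratio used to weight neighbor
#'   counts (1 = classic unweighted NG86)
#' @return numeric c(s_sites, n_sites)
#' @export
count_sites <- function(codon, code = genetic_code(), kappa = 1) {
  codon <- toupper(codon)
  if (codon %in% code$stops || grepl("[^ACGT]", codon)) {
    stop("not a sense codon: ", codon)
  }
  aa <- code$codon_aa[[codon]]
  nb <- .codon_neighbors(codon)
  w <- ifelse(nb$transition, kappa, 1)
  s <- 0
  for (p in 1:3) {
    sel <- nb$pos == p & !(nb$codon %in% code$stops)
    wt <- sum(w[sel])
    if (wt == 0) next
    syn <- sum(w[sel & code$codon_aa[nb$codon] == aa])
    s <- s + syn / wt
  }
  c(s_sites = s, n_sites = 3 - s)
}

# site counts for every sense codon, cached per (code, kappa)
.site_table <- function(code, kappa = 1) {
  key <- paste0("sites_", code$code_id, "_", format(kappa, digits = 12))
  if (is.null(.mc_cache[[key]])) {
    m <- t(vapply(code$sense_codons, count_sites, numeric(2),
                  code = code, kappa = kappa))
    .mc_cache[[key]] <- m
  }
  .mc_cache[[key]]
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Enumerates all minimal mutational pathways between two aligned sense
#' codons (the permutations of the differing positions), discards pathways
#' passing through a stop codon, classifies each step as synonymous or
#' nonsynonymous (and transition or transversion), and averages the step
#' counts over the valid pathways, so `sd + nd` equals the Hamming distance
#' of the pair. If no stop-free pathway exists the pair is scored with the
#' convention sd = 0, nd = Hamming distance.
#'
#' @param codon_a,codon_b aligned sense codons
#' @param code a [genetic_code()]
#' @return named numeric: `sd`, `nd`, `sd_ts`, `sd_tv`, `nd_ts`, `nd_tv`,
#'   `n_paths` (number of valid pathways)
#' @export
count_differences <- function(codon_a, codon_b, code = genetic_code()) {
  a <- strsplit(toupper(codon_a), "")[[1]]
  b <- strsplit(toupper(codon_b), "")[[1]]
  diffpos <- which(a != b)
  zero <- c(sd = 0, nd = 0, sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0,
            n_paths = 1)
  if (length(diffpos) == 0L) return(zero)
  perms <- .permutations(diffpos)
  acc <- NULL
  nvalid <- 0L
  for (ord in perms) {
    cur <- a
    steps <- c(sd = 0, nd = 0, sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      cod_from <- paste(cur, collapse = "")
      cod_to <- paste(nxt, collapse = "")
      if (code$codon_aa[[cod_to]] == "*") { ok <- FALSE; break }
      syn <- code$codon_aa[[cod_from]] == code$codon_aa[[cod_to]]
      ts <- .is_transition(cur[p], b[p])
      key <- paste0(if (syn) "sd" else "nd", if (ts) "_ts" else "_tv")
      steps[[key]] <- steps[[key]] + 1
      steps[[if (syn) "sd" else "nd"]] <- steps[[if (syn) "sd" else "nd"]] + 1
      cur <- nxt
    }
    if (ok) {
      acc <- if (is.null(acc)) steps else acc + steps
      nvalid <- nvalid + 1L
    }
  }
  if (nvalid == 0L) {
    # no stop-free pathway: score all differences nonsynonymous
    ts_n <- sum(vapply(diffpos, function(p) .is_transition(a[p], b[p]), logical(1)))
    return(c(sd = 0, nd = length(diffpos), sd_ts = 0, sd_tv = 0,
             nd_ts = ts_n, nd_tv = length(diffpos) - ts_n, n_paths = 0))
  }
  out <- acc / nvalid
  c(out, n_paths = nvalid)
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# 62 x 62 pathway-difference tables, cached per code
.pair_tables <- function(code) {
  key <- paste0("pairs_", code$code_id)
  if (!is.null(.mc_cache[[key]])) return(.mc_cache[[key]])
  sense <- code$sense_codons
  n <- length(sense)
  stats <- c("sd", "nd", "sd_ts", "sd_tv", "nd_ts", "nd_tv")
  tabs <- lapply(stats, function(s) {
    m <- matrix(0, n, n, dimnames = list(sense, sense))
    m
  })
  names(tabs) <- stats
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- count_differences(sense[i], sense[j], code)
      for (s in stats) tabs[[s]][i, j] <- d[[s]]
    }
  }
  .mc_cache[[key]] <- tabs
  tabs
}

# split two aligned CDSs into comparable codon columns: drop columns with
# gaps, ambiguity or stop codons in either sequence
.comparable_codons <- function(cds_a, cds_b, code) {
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  L <- min(length(ca), length(cb))
  ca <- ca[seq_len(L)]; cb <- cb[seq_len(L)]
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    !(ca %in% code$stops) & !(cb %in% code$stops)
  list(a = ca[ok], b = cb[ok])
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)  # saturated
  -0.75 * log(1 - 4 * p / 3)
}

.k2p_correct <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (is.na(a1) || is.na(a2) || a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Pairwise Ka and Ks for two aligned coding sequences
#'
#' Nei-Gojobori pathway counting with a choice of distance correction:
#' `"ng86_jc"` applies the Jukes-Cantor correction
#' `K = -(3/4) log(1 - 4p/3)` to the synonymous and nonsynonymous
#' proportions, while `"kumar_k2p"` splits differences into transitions and
#' transversions within each site class and applies the Kimura 2-parameter
#' correction `d = -1/2 log(1-2P-Q) - 1/4 log(1-2Q)` separately to the
#' synonymous and nonsynonymous classes (with `kappa`-weighted site counts
#' when `kappa != 1`). Columns with gaps, ambiguity codes or stop codons in
#' either sequence are removed pairwise before counting.
#'
#' @param cds_a,cds_b aligned codon sequences (equal frame)
#' @param code a [genetic_code()]
#' @param method `"ng86_jc"` (default) or `"kumar_k2p"`
#' @param kappa transition/transversion ratio for site counting (kumar_k2p)
#' @return a `PairwiseRates` list: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`,
#'   `Ka`, `ratio` (NA when Ks is 0 or a correction saturates), `n_codons`
#' @export
kaks_pair <- function(cds_a, cds_b, code = genetic_code(),
                      method = c("ng86_jc", "kumar_k2p"), kappa = 1) {
  method <- match.arg(method)
  cmp <- .comparable_codons(cds_a, cds_b, code)
  if (length(cmp$a) == 0L) stop("no comparable codons")
  st <- .site_table(code, if (method == "kumar_k2p") kappa else 1)
  tabs <- .pair_tables(code)
  ia <- cmp$a; ib <- cmp$b
  S <- (sum(st[ia, 1]) + sum(st[ib, 1])) / 2
  N <- (sum(st[ia, 2]) + sum(st[ib, 2])) / 2
  idx <- cbind(match(ia, rownames(tabs$sd)), match(ib, colnames(tabs$sd)))
  Sd <- sum(tabs$sd[idx]); Nd <- sum(tabs$nd[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  if (method == "ng86_jc") {
    Ks <- if (Sd == 0) 0 else .jc_correct(pS)
    Ka <- if (Nd == 0) 0 else .jc_correct(pN)
  } else {
    Ps <- sum(tabs$sd_ts[idx]) / S; Qs <- sum(tabs$sd_tv[idx]) / S
    Pn <- sum(tabs$nd_ts[idx]) / N; Qn <- sum(tabs$nd_tv[idx]) / N
    Ks <- if (Sd == 0) 0 else .k2p_correct(Ps, Qs)
    Ka <- if (Nd == 0) 0 else .k2p_correct(Pn, Qn)
  }
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, ratio = ratio, n_codons = length(ia),
                 method = method),
            class = "PairwiseRates")
}

#' @export
print.PairwiseRates <- function(x, ...) {
  cat(sprintf("Ka %.4f  Ks %.4f  Ka/Ks %s  (S %.1f, N %.1f, %d codons, %s)\n",
              x$Ka, x$Ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio),
              x$S, x$N, x$n_codons, x$method))
  invisible(x)
}

#' Per-gene Ka/Ks summary with bootstrap standard errors
#'
#' For one gene's codon alignment (>= 2 sequences), computes Ka, Ks and
#' Ka/Ks for every unordered sequence pair, reports their means (both the
#' mean of pairwise ratios and the ratio of mean Ka to mean Ks), and
#' attaches standard errors obtained by resampling codon columns with
#' replacement, preserving codon structure.
#'
#' @param alignment named character vector of aligned CDSs (equal length)
#' @param code a [genetic_code()]
#' @param method,kappa passed to [kaks_pair()]
#' @param bootstrap_reps number of bootstrap replicates (0 disables)
#' @param seed integer seed for the resampling
#' @return list: `mean_ka`, `mean_ks`, `mean_ratio` (mean over pairs),
#'   `ratio_of_means`, `se_ka`, `se_ks`, `se_ratio`, `n_pairs`, `pairs`
#'   (data.frame of the pairwise rates)
#' @export
gene_kaks_summary <- function(alignment, code = genetic_code(),
                              method = c("ng86_jc", "kumar_k2p"), kappa = 1,
                              bootstrap_reps = 1000, seed = 1) {
  method <- match.arg(method)
  if (length(alignment) < 2L) stop("need at least 2 sequences")
  taxa <- names(alignment)
  if (is.null(taxa)) taxa <- paste0("seq", seq_along(alignment))
  prs <- utils::combn(length(alignment), 2)
  rows <- apply(prs, 2, function(ij) {
    r <- kaks_pair(alignment[[ij[1]]], alignment[[ij[2]]], code, method, kappa)
    data.frame(a = taxa[ij[1]], b = taxa[ij[2]], Ka = r$Ka, Ks = r$Ks,
               ratio = r$ratio, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  out <- list(
    mean_ka = mean(pairs$Ka, na.rm = TRUE),
    mean_ks = mean(pairs$Ks, na.rm = TRUE),
    mean_ratio = mean(pairs$ratio, na.rm = TRUE),
    ratio_of_means = mean(pairs$Ka, na.rm = TRUE) / mean(pairs$Ks, na.rm = TRUE),
    se_ka = NA_real_, se_ks = NA_real_, se_ratio = NA_real_,
    n_pairs = nrow(pairs), pairs = pairs)
  if (bootstrap_reps > 0) {
    bs <- .kaks_bootstrap(alignment, code, method, kappa, bootstrap_reps, seed)
    out$se_ka <- bs$se_ka; out$se_ks <- bs$se_ks; out$se_ratio <- bs$se_ratio
  }
  out
}

# column-resampling bootstrap; per-pair, per-column statistics are
# precomputed once so each replicate is a matrix product
.kaks_bootstrap <- function(alignment, code, method, kappa, reps, seed) {
  st <- .site_table(code, if (method == "kumar_k2p") kappa else 1)
  tabs <- .pair_tables(code)
  prs <- utils::combn(length(alignment), 2)
  npair <- ncol(prs)
  cods <- lapply(alignment, split_codons)
  L <- min(vapply(cods, length, integer(1)))
  cods <- lapply(cods, function(x) x[seq_len(L)])
  # per pair x column stats; non-comparable columns contribute zeros
  stat_names <- c("S", "N", "sd", "nd", "sd_ts", "sd_tv", "nd_ts", "nd_tv")
  M <- matrix(0, npair * length(stat_names), L)
  for (k in seq_len(npair)) {
    ca <- cods[[prs[1, k]]]; cb <- cods[[prs[2, k]]]
    ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
      !(ca %in% code$stops) & !(cb %in% code$stops)
    ii <- which(ok)
    ridx <- (k - 1L) * length(stat_names)
    ai <- match(ca[ii], rownames(tabs$sd)); bi <- match(cb[ii], rownames(tabs$sd))
    M[ridx + 1L, ii] <- (st[ai, 1] + st[bi, 1]) / 2
    M[ridx + 2L, ii] <- (st[ai, 2] + st[bi, 2]) / 2
    M[ridx + 3L, ii] <- tabs$sd[cbind(ai, bi)]
    M[ridx + 4L, ii] <- tabs$nd[cbind(ai, bi)]
    M[ridx + 5L, ii] <- tabs$sd_ts[cbind(ai, bi)]
    M[ridx + 6L, ii] <- tabs$sd_tv[cbind(ai, bi)]
    M[ridx + 7L, ii] <- tabs$nd_ts[cbind(ai, bi)]
    M[ridx + 8L, ii] <- tabs$nd_tv[cbind(ai, bi)]
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- matrix(0, L, reps)
  for (r in seq_len(reps)) W[, r] <- tabulate(sample.int(L, L, replace = TRUE), L)
  SS <- M %*% W  # (npair*8) x reps
  ka_reps <- matrix(NA_real_, npair, reps)
  ks_reps <- matrix(NA_real_, npair, reps)
  for (k in seq_len(npair)) {
    ridx <- (k - 1L) * 8L
    S <- SS[ridx + 1L, ]; N <- SS[ridx + 2L, ]
    Sd <- SS[ridx + 3L, ]; Nd <- SS[ridx + 4L, ]
    if (method == "ng86_jc") {
      ks_reps[k, ] <- ifelse(Sd == 0, 0,
        ifelse(Sd / S >= 0.75, NA, -0.75 * log(pmax(1 - 4 * (Sd / S) / 3, 1e-12))))
      ka_reps[k, ] <- ifelse(Nd == 0, 0,
        ifelse(Nd / N >= 0.75, NA, -0.75 * log(pmax(1 - 4 * (Nd / N) / 3, 1e-12))))
    } else {
      Ps <- SS[ridx + 5L, ] / S; Qs <- SS[ridx + 6L, ] / S
      Pn <- SS[ridx + 7L, ] / N; Qn <- SS[ridx + 8L, ] / N
      k2p <- function(P, Q) {
        a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
        ifelse(a1 <= 0 | a2 <= 0, NA, -0.5 * log(a1) - 0.25 * log(a2))
      }
      ks_reps[k, ] <- ifelse(Sd == 0, 0, k2p(Ps, Qs))
      ka_reps[k, ] <- ifelse(Nd == 0, 0, k2p(Pn, Qn))
    }
  }
  ratio_reps <- ifelse(!is.na(ks_reps) & ks_reps > 0, ka_reps / ks_reps, NA)
  list(se_ka = stats::sd(colMeans(ka_reps, na.rm = TRUE), na.rm = TRUE),
       se_ks = stats::sd(colMeans(ks_reps, na.rm = TRUE), na.rm = TRUE),
       se_ratio = stats::sd(colMeans(ratio_reps, na.rm = TRUE), na.rm = TRUE))
}

# save/restore the global RNG state so seeded internals do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
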