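# Independent brute-force oracles used throughout the suite. These are
# written from the definitions, not by calling package internals, so that a
# bug in the package and a bug in the oracle are unlikely to coincide.

NUC4 <- c("A", "C", "G", "T")

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(NUC4, n, replace = TRUE, prob = prob), collapse = "")
}

# -- composition ------------------------------------------------------------

oracle_composition <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  a <- sum(v == "A"); c_ <- sum(v == "C"); g <- sum(v == "G"); t <- sum(v == "T")
  list(at_content = 100 * (a + t) / (a + c_ + g + t),
       at_skew = (a - t) / (a + t),
       gc_skew = (g - c_) / (g + c_))
}

# -- simple translation table for the invertebrate mito code ---------------
# built here by translating each codon independently via seqinr, then used
# by the Ka/Ks oracles below

oracle_code5 <- local({
  codons <- apply(expand.grid(NUC4, NUC4, NUC4)[, 3:1], 1, paste, collapse = "")
  aa <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(tolower(cd), "")[[1]], numcode = 5)
  }, character(1))
  names(aa) <- codons
  aa
})

oracle_is_ts <- function(x, y) {
  (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
}

# NG86 site fractions of one codon, by direct neighbor enumeration
oracle_count_sites <- function(codon, kappa = 1) {
  b <- strsplit(codon, "")[[1]]
  aa <- oracle_code5[[codon]]
  s <- 0
  for (p in 1:3) {
    wsum <- 0; wsyn <- 0
    for (nb in setdiff(NUC4, b[p])) {
      b2 <- b; b2[p] <- nb
      cod2 <- paste(b2, collapse = "")
      if (oracle_code5[[cod2]] == "*") next
      w <- if (oracle_is_ts(b[p], nb)) kappa else 1
      wsum <- wsum + w
      if (oracle_code5[[cod2]] == aa) wsyn <- wsyn + w
    }
    if (wsum > 0) s <- s + wsyn / wsum
  }
  c(s, 3 - s)
}

# pathway-averaged differences by depth-first enumeration of orderings
oracle_count_differences <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  dp <- which(a != b)
  if (length(dp) == 0L) return(c(sd = 0, nd = 0))
  paths <- list()
  walk <- function(cur, remaining, sd, nd) {
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- c(sd, nd)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- b[p]
      to <- paste(nxt, collapse = "")
      if (oracle_code5[[to]] == "*") next
      syn <- oracle_code5[[paste(cur, collapse = "")]] == oracle_code5[[to]]
      walk(nxt, setdiff(remaining, p), sd + syn, nd + !syn)
    }
  }
  walk(a, dp, 0, 0)
  if (length(paths) == 0L) return(c(sd = 0, nd = length(dp)))
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# full NG86 + Jukes-Cantor Ka/Ks of an aligned pair, recounted from scratch
oracle_kaks_jc <- function(cds_a, cds_b) {
  split3 <- function(s) {
    n <- nchar(s)
    substring(s, seq(1, n - 2, 3), seq(3, n, 3))
  }
  ca <- split3(cds_a); cb <- split3(cds_b)
  keep <- oracle_code5[ca] != "*" & oracle_code5[cb] != "*" &
    !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[keep]; cb <- cb[keep]
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    sa <- oracle_count_sites(ca[i]); sb <- oracle_count_sites(cb[i])
    S <- S + (sa[1] + sb[1]) / 2
    N <- N + (sa[2] + sb[2]) / 2
    d <- oracle_count_differences(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- if (Sd == 0) 0 else jc(Sd / S)
  Ka <- if (Nd == 0) 0 else jc(Nd / N)
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ks = Ks, Ka = Ka)
}

# -- noncoding scans --------------------------------------------------------

oracle_runs <- function(seq, base, min_len = 6) {
  v <- strsplit(toupper(seq), "")[[1]] == base
  out <- list()
  i <- 1L
  while (i <= length(v)) {
    if (v[i]) {
      j <- i
      while (j < length(v) && v[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) out[[length(out) + 1L]] <- c(i - 1L, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), length = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], length = m[, 2])
}

oracle_motif_count <- function(seq, motif) {
  n <- nchar(seq); k <- nchar(motif)
  if (n < k) return(0L)
  sum(vapply(1:(n - k + 1L), function(i) substr(seq, i, i + k - 1L) == motif,
             logical(1)))
}

# TRUE iff a perfect tandem array (identity 1) with period >= min_p and
# >= copies full copies exists anywhere, by exhaustive scan
oracle_has_perfect_tandem <- function(seq, min_p, copies) {
  n <- nchar(seq)
  for (p in min_p:(n %/% copies)) {
    for (i in 1:(n - copies * p + 1L)) {
      unit <- substr(seq, i, i + p - 1L)
      if (substr(seq, i, i + copies * p - 1L) == strrep(unit, copies)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# exhaustive maximal exact-WC hairpin candidates (0-based coords), mirroring
# the documented output contract but via an O(n^2 * stem) full scan
oracle_hairpins <- function(seq, min_stem = 6, loop_range = c(3, 20)) {
  v <- strsplit(toupper(seq), "")[[1]]
  n <- length(v)
  compl <- c(A = "T", C = "G", G = "C", T = "A")
  cands <- list()
  for (inner5 in seq_len(n)) {        # 1-based inner end of the 5' arm
    for (loop in loop_range[1]:loop_range[2]) {
      inner3 <- inner5 + loop + 1L    # 1-based inner start of the 3' arm
      if (inner3 > n) break
      s <- 0L
      while (inner5 - s >= 1L && inner3 + s <= n &&
             compl[[v[inner5 - s]]] == v[inner3 + s]) s <- s + 1L
      if (s >= min_stem) {
        cands[[length(cands) + 1L]] <- data.frame(
          stem_start_5p = inner5 - s, stem_start_3p = inner3 - 1L,
          stem_len = s, loop_len = loop)
      }
    }
  }
  empty <- data.frame(stem_start_5p = integer(0), stem_start_3p = integer(0),
                      stem_len = integer(0), loop_len = integer(0))
  if (length(cands) == 0L) return(empty)
  cand <- unique(do.call(rbind, cands))
  # same documented selection contract: longest stem first, no overlap
  cand <- cand[order(-cand$stem_len, cand$stem_start_5p, cand$loop_len), ]
  chosen <- empty
  for (i in seq_len(nrow(cand))) {
    s1 <- cand$stem_start_5p[i]
    e1 <- cand$stem_start_3p[i] + cand$stem_len[i]
    ok <- TRUE
    for (j in seq_len(nrow(chosen))) {
      s2 <- chosen$stem_start_5p[j]
      e2 <- chosen$stem_start_3p[j] + chosen$stem_len[j]
      if (s1 < e2 && s2 < e1) { ok <- FALSE; break }
    }
    if (ok) chosen <- rbind(chosen, cand[i, ])
  }
  chosen <- chosen[order(chosen$stem_start_5p), ]
  rownames(chosen) <- NULL
  chosen
}

# -- trees ------------------------------------------------------------------

# random binary tree on n taxa by sequential random attachment, returned as
# an ape::phylo with exponential branch lengths
random_additive_tree <- function(n, mean_bl = 0.1) {
  tip <- paste0("t", seq_len(n))
  tr <- ape::rtree(n, tip.label = tip, br = NULL)
  tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / mean_bl) + 0.01
  ape::unroot(tr)
}

# patristic (path-length) distance matrix of a phylo
tree_distances <- function(tr) {
  d <- ape::cophenetic.phylo(tr)
  d[tr$tip.label, tr$tip.label]
}

# least-squares best of the three unrooted 4-taxon topologies for a distance
# matrix; returns the taxon paired with taxa[1]
oracle_ls_quartet <- function(dm) {
  taxa <- rownames(dm)
  pairings <- list(c(2, 3, 4), c(3, 2, 4), c(4, 2, 3))
  best <- NULL; best_ss <- Inf
  for (p in pairings) {
    # topology ((1,p1),(p2,p3)); fit 5 branch lengths by least squares
    # against the 6 pairwise distances using the path-length design matrix
    A <- matrix(0, 6, 5)
    y <- numeric(6)
    prs <- utils::combn(4, 2)
    on_path <- function(i, j, p1) {
      # columns 1..4 = pendant branches of taxa 1..4, column 5 = internal
      grp <- c(1, p1)
      row <- numeric(5)
      row[i] <- 1; row[j] <- 1
      if (xor(i %in% grp, j %in% grp)) row[5] <- 1
      row
    }
    for (k in 1:6) {
      i <- prs[1, k]; j <- prs[2, k]
      A[k, ] <- on_path(i, j, p[1])
      y[k] <- dm[taxa[i], taxa[j]]
    }
    fit <- stats::lm.fit(A, y)
    ss <- sum(fit$residuals^2)
    if (ss < best_ss) { best_ss <- ss; best <- taxa[p[1]] }
  }
  best
}

# independent UPGMA (average linkage) returning a merge order signature:
# the set of clades (as sorted taxon strings)
oracle_upgma_clades <- function(dm) {
  clusters <- as.list(rownames(dm))
  sizes <- rep(1L, nrow(dm))
  D <- dm
  clades <- character(0)
  while (length(clusters) > 1L) {
    diag(D) <- Inf
    ij <- which(D == min(D), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    newc <- sort(c(clusters[[i]], clusters[[j]]))
    clades <- c(clades, paste(newc, collapse = ","))
    dn <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_along(clusters), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    clusters <- c(clusters[keep], list(newc))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  clades
}

# unrooted bipartitions of a phylo, as canonical strings (side containing
# the first taxon alphabetically), internal edges only
tree_bipartitions <- function(tr) {
  tips <- sort(tr$tip.label)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (p in pp) {
    side <- sort(labs[p])
    other <- setdiff(tips, side)
    if (length(side) <= 1L || length(other) <= 1L) next
    canon <- if (tips[1] %in% side) side else other
    out <- c(out, paste(canon, collapse = ","))
  }
  sort(unique(out))
}
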