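#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites with gaps or ambiguity codes in either sequence are excluded
#' pairwise; P and Q are the transition and transversion proportions over
#' the remaining sites and
#' \deqn{d = -\tfrac12 \log(1 - 2P - Q) - \tfrac14 \log(1 - 2Q).}
#'
#' @param seq_a,seq_b aligned DNA strings of equal length
#' @return distance (substitutions/site)
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ok <- a %in% .NUC & b %in% .NUC
  a <- a[ok]; b <- b[ok]
  if (length(a) == 0L) stop("no comparable sites")
  diff <- a != b
  ts <- diff & ((a %in% c("A", "G") & b %in% c("A", "G")) |
                (a %in% c("C", "T") & b %in% c("C", "T")))
  P <- sum(ts) / length(a)
  Q <- sum(diff & !ts) / length(a)
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) stop("saturated: K2P log argument <= 0")
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' K2P distance matrix for a set of aligned sequences
#'
#' @param alignment named character vector of equal-length sequences
#' @return symmetric matrix with zero diagonal, taxa as dimnames
#' @export
k2p_matrix <- function(alignment) {
  n <- length(alignment)
  taxa <- names(alignment)
  if (is.null(taxa)) taxa <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- k2p_distance(alignment[[i]], alignment[[j]])
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler criterion
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j`; ties are broken deterministically by
#' the lexicographically smallest taxon pair. Branch lengths follow the
#' standard NJ formulas; negative estimates are clamped to zero with the
#' deficit moved to the sister branch (noted via `message`). Exact on
#' additive distance matrices.
#'
#' @param dm symmetric distance matrix with taxa as dimnames (or a `dist`)
#' @return an unrooted `ape::phylo` tree with branch lengths
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")
  taxa <- rownames(dm)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  # active nodes: newick fragment + representative (min) leaf label
  nwk <- taxa
  rep_lab <- taxa
  D <- dm
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (length(nwk) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Qm <- (r - 2) * D - outer(R, R, `+`)
    diag(Qm) <- Inf
    qmin <- min(Qm)
    hits <- which(Qm <= qmin + 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest (label_i, label_j)
    keys <- apply(hits, 1, function(ij) {
      labs <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(labs, collapse = "\r")
    })
    pick <- hits[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0; message("negative NJ branch clamped") }
    if (lj < 0) { li <- li + lj; lj <- 0; message("negative NJ branch clamped") }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    new_lab <- min(rep_lab[i], rep_lab[j])
    dk <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_lab)
  }
  if (length(nwk) == 3L) {
    d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
    l1 <- (d12 + d13 - d23) / 2
    l2 <- (d12 + d23 - d13) / 2
    l3 <- (d13 + d23 - d12) / 2
    text <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(l1),
                    nwk[2], fmt(l2), nwk[3], fmt(l3))
  } else {
    stop("internal error: fewer than 3 active nodes")
  }
  ape::read.tree(text = text)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' per replicate, and reports for each internal edge of the full-data tree
#' the percentage of replicates containing the same bipartition. Replicates
#' in which any pairwise distance saturates are dropped and counted.
#'
#' @param alignment named character vector of equal-length sequences
#' @param reps number of replicates
#' @param seed integer seed
#' @return list: `tree` (phylo with node labels = integer percent support;
#'   the root node label is empty), `reps_used`, `reps_dropped`
#' @export
bootstrap_support <- function(alignment, reps = 1000, seed = 1) {
  full <- nj_tree(k2p_matrix(alignment))
  mat <- do.call(rbind, strsplit(toupper(unlist(alignment)), ""))
  rownames(mat) <- names(alignment)
  L <- ncol(mat)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boots <- list()
  dropped <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    sub <- apply(mat[, idx, drop = FALSE], 1, paste, collapse = "")
    tr <- tryCatch(nj_tree(k2p_matrix(sub)), error = function(e) NULL)
    if (is.null(tr)) dropped <- dropped + 1L else boots[[length(boots) + 1L]] <- tr
  }
  if (length(boots) == 0L) stop("all bootstrap replicates failed")
  cl <- ape::prop.clades(full, boots, rooted = FALSE)
  cl[is.na(cl)] <- 0L
  support <- round(100 * cl / length(boots))
  full$node.label <- as.character(support)
  if (length(full$node.label) > 0L) full$node.label[1] <- ""
  list(tree = full, reps_used = length(boots), reps_dropped = dropped)
}
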