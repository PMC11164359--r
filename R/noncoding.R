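#' Find tandem repeat arrays
#'
#' Self-contained detector for approximate tandem repeats, intended for
#' AT-rich mitochondrial control regions. For every candidate period, arrays
#' are seeded where one period matches the next at or above the identity
#' threshold, extended copy by copy (a fractional final copy is allowed),
#' scored against the per-column majority consensus of the full copies,
#' reduced to their primitive period (the smallest divisor of the detected
#' period that still explains the array at the identity threshold), and
#' overlapping candidates are resolved greedily by longer array, then higher
#' identity, then smaller period.
#'
#' @param seq DNA string
#' @param min_period,max_period period bounds in nucleotides
#' @param min_copies minimum (possibly fractional) copy number
#' @param identity_threshold minimum fraction of positions matching the
#'   consensus
#' @return data.frame with columns `start` (0-based), `period`, `copies`,
#'   `length`, `consensus`, `identity`; zero rows when nothing is found
#' @export
find_tandem_repeats <- function(seq, min_period = 5, max_period = 200,
                                min_copies = 2.0, identity_threshold = 0.85) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  v <- strsplit(seq, "")[[1]]
  max_period <- min(max_period, n %/% 2L)
  cands <- list()
  for (p in seq(min_period, max(min_period, max_period))) {
    if (2L * p > n) break
    i <- 1L
    while (i + 2L * p - 1L <= n) {
      m1 <- v[i:(i + p - 1L)]
      m2 <- v[(i + p):(i + 2L * p - 1L)]
      if (mean(m1 == m2) >= identity_threshold) {
        # extend full copies to the right
        k <- 2L
        while (i + (k + 1L) * p - 1L <= n) {
          nxt <- v[(i + k * p):(i + (k + 1L) * p - 1L)]
          if (mean(m1 == nxt) < identity_threshold) break
          k <- k + 1L
        }
        # fractional final copy
        frac <- 0L
        if (i + k * p <= n) {
          tail_len <- min(p - 1L, n - (i + k * p) + 1L)
          if (tail_len > 0L) {
            tl <- v[(i + k * p):(i + k * p + tail_len - 1L)]
            matches <- tl == m1[seq_len(tail_len)]
            run <- which(!matches)
            frac <- if (length(run) == 0L) tail_len else run[1] - 1L
          }
        }
        total_len <- k * p + frac
        copies <- total_len / p
        if (copies >= min_copies) {
          block <- matrix(v[i:(i + k * p - 1L)], nrow = p)
          cons <- apply(block, 1, function(col) names(which.max(table(col))))
          idn <- mean(block == matrix(cons, nrow = p, ncol = k))
          if (idn >= identity_threshold) {
            # reduce to the primitive period: the smallest divisor of p that
            # still explains the array at the identity threshold
            pp <- p; kk <- k; cc <- cons; ii <- idn
            for (q in seq_len(p - 1L)) {
              if (q < min_period || p %% q != 0L) next
              kq <- total_len %/% q
              bq <- matrix(v[i:(i + kq * q - 1L)], nrow = q)
              cq <- apply(bq, 1, function(col) names(which.max(table(col))))
              iq <- mean(bq == matrix(cq, nrow = q, ncol = kq))
              if (iq >= identity_threshold) {
                pp <- q; kk <- kq; cc <- cq; ii <- iq
                break
              }
            }
            cands[[length(cands) + 1L]] <- data.frame(
              start = i - 1L, period = pp, copies = total_len / pp,
              length = total_len, consensus = paste(cc, collapse = ""),
              identity = ii, stringsAsFactors = FALSE)
          }
        }
        i <- i + max(1L, total_len - 2L * p + 1L)
      } else {
        i <- i + 1L
      }
    }
  }
  empty <- data.frame(start = integer(0), period = integer(0),
                      copies = numeric(0), length = integer(0),
                      consensus = character(0), identity = numeric(0))
  if (length(cands) == 0L) return(empty)
  cand <- do.call(rbind, cands)
  cand <- cand[order(-cand$length, -cand$identity, cand$period), ]
  chosen <- empty
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- s + cand$length[i]
    if (nrow(chosen) == 0L ||
        all(e <= chosen$start | s >= chosen$start + chosen$length)) {
      chosen <- rbind(chosen, cand[i, ])
    }
  }
  chosen <- chosen[order(chosen$start), ]
  rownames(chosen) <- NULL
  chosen
}

#' Find homopolymer runs
#'
#' Maximal runs of a single base of at least `min_len` nucleotides
#' (the poly-A / poly-T stretches characteristic of control regions).
#'
#' @param seq DNA string
#' @param base single base, usually "A" or "T"
#' @param min_len minimum run length
#' @return data.frame with columns `start` (0-based) and `length`
#' @export
find_runs <- function(seq, base, min_len = 6) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence")
  r <- rle(strsplit(seq, "")[[1]] == toupper(base))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_len
  data.frame(start = starts[sel] - 1L, length = r$lengths[sel])
}

#' Count (overlapping) occurrences of a motif
#'
#' @param seq DNA string
#' @param motif exact motif over ACGT (default the TATA box-like motif
#'   abundant in ant control regions)
#' @return integer count, overlapping matches included
#' @examples
#' count_motif("TATATA")  # 2
#' @export
count_motif <- function(seq, motif = "TATA") {
  seq <- toupper(seq); motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop("motif must be over ACGT")
  m <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# base set -> minimal IUPAC code
.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
            CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")

#' IUPAC consensus of an aligned block
#'
#' Per alignment column, the minimal IUPAC degeneracy code covering every
#' base observed at frequency above `min_freq`; columns containing a gap in
#' any row are excluded from the consensus string. With the default
#' `min_freq = 0` any observed base enters the code, which is how degenerate
#' spacer motifs such as TAAATTAYA arise across species.
#'
#' @param aligned_block character vector of >= 2 equal-length rows
#' @param min_freq minimum base frequency for inclusion in a column's code
#' @return a `ConsensusMotif` list: `consensus` (IUPAC string),
#'   `conservation` (per kept column, frequency of the modal base),
#'   `kept_columns` (0-based indices of gap-free columns)
#' @examples
#' consensus_motif(c("ACA", "ATA"))$consensus  # "AYA"
#' @export
consensus_motif <- function(aligned_block, min_freq = 0) {
  if (length(aligned_block) < 2L) stop("need at least 2 rows")
  aligned_block <- toupper(aligned_block)
  lens <- nchar(aligned_block)
  if (length(unique(lens)) != 1L) stop("rows must have equal lengths")
  m <- do.call(rbind, strsplit(aligned_block, ""))
  keep <- which(colSums(m == "-") == 0L)
  cons <- character(0)
  conservation <- numeric(0)
  for (j in keep) {
    tab <- table(m[, j])
    freqs <- tab / sum(tab)
    bases <- sort(intersect(names(freqs)[freqs > min_freq], c("A", "C", "G", "T")))
    key <- paste(bases, collapse = "")
    cons <- c(cons, if (key %in% names(.IUPAC)) .IUPAC[[key]] else "N")
    conservation <- c(conservation, max(freqs))
  }
  structure(list(consensus = paste(cons, collapse = ""),
                 conservation = conservation,
                 kept_columns = keep - 1L),
            class = "ConsensusMotif")
}

#' Find hairpin (stem-loop) candidates
#'
#' Exact Watson-Crick inverted repeats: a 5' arm whose reverse complement
#' reappears after a loop of `loop_range` nucleotides. All maximal stems are
#' enumerated, then selected greedily longest-stem-first without overlap.
#' No wobble pairing and no thermodynamics - this flags candidate stem-loop
#' structures, it does not fold them.
#'
#' @param seq DNA string
#' @param min_stem minimum stem arm length
#' @param loop_range c(min, max) loop length
#' @return data.frame with columns `stem_start_5p`, `stem_start_3p`
#'   (0-based), `stem_len`, `loop_len`
#' @export
find_hairpins <- function(seq, min_stem = 6, loop_range = c(3, 20)) {
  min_stem <- as.integer(min_stem)
  loop_range <- as.integer(loop_range)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  v <- strsplit(seq, "")[[1]]
  compl <- c(A = "T", C = "G", G = "C", T = "A")
  cands <- list()
  # i = 0-based 5' arm start, j = 0-based 3' arm start
  for (i in 0:(n - 2L * min_stem - loop_range[1])) {
    for (loop in loop_range[1]:loop_range[2]) {
      j <- i + min_stem + loop
      if (j + min_stem > n) break
      # check stem of min_stem, then extend inward? arms pair outward:
      # 5' arm v[i+1 .. i+s], 3' arm v[j+1 .. j+s]; pairing requires
      # v[i+k] complementary to v[j + s - k + 1] -- i.e. arm2 is the
      # reverse complement of arm1.
      s <- 0L
      while (TRUE) {
        k <- s + 1L
        a <- v[i + k]
        b <- v[j + min_stem - k + 1L]
        if (is.na(a) || is.na(b) || compl[[a]] != b) break
        s <- k
        if (s == min_stem) break
      }
      if (s == min_stem) {
        # extend the stem outward (grow both arms, loop fixed between
        # inner ends); inner ends are fixed at i+min_stem and j+1; extend
        # by checking positions past min_stem while keeping the loop
        ext <- 0L
        while (i - ext - 1L >= 0L && j + min_stem + ext < n) {
          a <- v[i - ext]
          b <- v[j + min_stem + ext + 1L]
          if (compl[[a]] != b) break
          ext <- ext + 1L
        }
        cands[[length(cands) + 1L]] <- data.frame(
          stem_start_5p = i - ext, stem_start_3p = j,
          stem_len = min_stem + ext, loop_len = loop)
      }
    }
  }
  empty <- data.frame(stem_start_5p = integer(0), stem_start_3p = integer(0),
                      stem_len = integer(0), loop_len = integer(0))
  if (length(cands) == 0L) return(empty)
  cand <- unique(do.call(rbind, cands))
  cand <- cand[order(-cand$stem_len, cand$stem_start_5p, cand$loop_len), ]
  chosen <- empty
  span <- function(r) c(r$stem_start_5p, r$stem_start_3p + r$stem_len)
  for (i in seq_len(nrow(cand))) {
    sp <- span(cand[i, ])
    ok <- TRUE
    if (nrow(chosen) > 0L) {
      for (j in seq_len(nrow(chosen))) {
        sc <- span(chosen[j, ])
        if (sp[1] < sc[2] && sc[1] < sp[2]) { ok <- FALSE; break }
      }
    }
    if (ok) chosen <- rbind(chosen, cand[i, ])
  }
  chosen <- chosen[order(chosen$stem_start_5p), ]
  rownames(chosen) <- NULL
  chosen
}
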