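# Microsatellite (cpSSR) and approximate long-repeat detection.
#
# SSRs follow the MISA convention: a maximal perfect tandem run of a 1-6 bp
# unit is reported at its primitive unit length when the copy number reaches
# the per-unit-length threshold. Long repeats follow the REPuter convention:
# maximal pairs of >= min_len bp arms within a Hamming distance budget, for
# forward, reverse, complement and palindromic (reverse-complement) kinds.

#' Find microsatellites (SSRs)
#'
#' Scans for maximal perfect tandem repeats of 1-6 bp units. A run is
#' reported exactly once, at its primitive unit length (a poly-A run is a
#' mononucleotide SSR, never an `AA` dinucleotide), when its whole-copy count
#' reaches the unit-length threshold. Runs are truncated to whole copies so
#' that `end - start + 1 == unit_len * copies`. `N` never matches anything.
#'
#' @param seq Uppercase DNA string.
#' @param min_copies Integer vector of length 6: minimum copy number for
#'   mono- through hexanucleotide units. Default `c(7, 4, 4, 3, 3, 3)`.
#' @param features Optional `gene_features` table used to annotate each SSR
#'   with the overlapping feature name (else `"intergenic"`).
#' @return A data frame with columns `motif`, `unit_len`, `copies`, `start`,
#'   `end`, `context`, sorted by `start`.
#' @export
find_ssrs <- function(seq, min_copies = c(7L, 4L, 4L, 3L, 3L, 3L),
                      features = NULL) {
  validate_dna(seq, "seq")
  stopifnot(length(min_copies) == 6L, all(min_copies >= 1L))
  s <- strsplit(seq, "")[[1L]]
  n <- length(s)
  recs <- list()
  for (u in 1:6) {
    if (n < u * min_copies[u]) next
    m <- s[seq_len(n - u)] == s[(u + 1L):n] & s[seq_len(n - u)] != "N"
    r <- rle(m)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    keep <- which(r$values & r$lengths + u >= u * min_copies[u])
    for (k in keep) {
      i <- starts_idx[k]
      total <- r$lengths[k] + u
      copies <- total %/% u
      motif <- substr(seq, i, i + u - 1L)
      if (!is_primitive(motif)) next
      recs[[length(recs) + 1L]] <- data.frame(
        motif = motif, unit_len = u, copies = copies,
        start = i, end = i + u * copies - 1L, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(motif = character(), unit_len = integer(), copies = integer(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out$context <- if (is.null(features) || nrow(out) == 0L)
    rep("intergenic", nrow(out)) else feature_context(out, features)
  out
}

# a motif is primitive when it is not a whole-number repetition of any
# shorter unit
is_primitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (identical(strrep(substr(motif, 1L, d), u %/% d), motif)) return(FALSE)
  }
  TRUE
}

feature_context <- function(recs, features) {
  spans <- t(vapply(features$parts, feature_span, integer(2L)))
  vapply(seq_len(nrow(recs)), function(i) {
    hit <- which(spans[, 1L] <= recs$end[i] & spans[, 2L] >= recs$start[i])
    if (length(hit)) features$name[hit[1L]] else "intergenic"
  }, "")
}

#' Canonical SSR motif
#'
#' Groups a motif with its rotations and their reverse complements and
#' returns the lexicographically smallest representative (`AG`, `GA`, `CT`,
#' `TC` all canonicalize to `AG`). Used for reporting; per-locus counts are
#' unaffected.
#'
#' @param motif Character vector of repeat units.
#' @return Character vector of canonical units.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    u <- nchar(m)
    rots <- vapply(seq_len(u), function(i)
      paste0(substr(m, i, u), substr(m, 1L, i - 1L)), "")
    min(c(rots, vapply(rots, revcomp, "")))
  }, "", USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# Long repeats

REPEAT_KINDS <- c("forward", "reverse", "complement", "palindromic")

#' Find long approximate repeats
#'
#' Reports maximal pairs of equal-length arms of at least `min_len` bp whose
#' Hamming distance is at most `max_hamming`, for each requested kind:
#' `forward` (direct copy), `reverse` (reversed copy, no complement),
#' `complement` (complemented copy, same orientation) and `palindromic`
#' (reverse complement). A pair is maximal when its arms are flanked by
#' mismatches or sequence ends, i.e. extending by one base would increase
#' the distance; maximal pairs are enumerated for every distance
#' `0..max_hamming`. Overlapping discoveries of the same locus (same
#' diagonal) are collapsed to one record, preferring fewer mismatches, then
#' greater length, then the leftmost start, and pairs whose arms are both
#' strictly contained in a no-worse reported pair of the same kind are
#' dropped. Arms may overlap; the trivial self-match is excluded. `N` never
#' matches anything.
#'
#' Detection is seed-and-extend: by pigeonhole, any qualifying arm pair
#' shares an exact seed of `floor(min_len / (max_hamming + 1))` bp, so all
#' candidate diagonals are found from exact k-mer matches and scanned with a
#' mismatch budget.
#'
#' @param seq Uppercase DNA string.
#' @param min_len Minimum arm length (default 30; values below 8 are refused
#'   because the seed scheme degenerates).
#' @param max_hamming Maximum Hamming distance between arms (default 3).
#' @param kinds Subset of `c("forward", "reverse", "complement",
#'   "palindromic")`.
#' @return A data frame with columns `kind`, `start1`, `end1`, `start2`,
#'   `end2`, `length`, `mismatches`, sorted by kind then coordinates.
#' @export
find_long_repeats <- function(seq, min_len = 30L, max_hamming = 3L,
                              kinds = REPEAT_KINDS) {
  validate_dna(seq, "seq")
  if (min_len < 8L) stop("min_len < 8 refused (seed scheme degenerates)",
                         call. = FALSE)
  kinds <- match.arg(kinds, REPEAT_KINDS, several.ok = TRUE)
  n <- nchar(seq)
  if (n < min_len) stop("sequence shorter than min_len", call. = FALSE)
  s <- strsplit(seq, "")[[1L]]
  out <- list()
  for (kind in kinds) {
    t_str <- switch(kind,
      forward = seq,
      reverse = paste(rev(s), collapse = ""),
      complement = comp_chr(seq),
      palindromic = revcomp(seq))
    hits <- scan_pairs(s, strsplit(t_str, "")[[1L]], min_len, max_hamming,
                       self_forward = kind == "forward")
    if (nrow(hits) == 0L) next
    arm2 <- map_arm2(hits, kind, n)
    rec <- data.frame(kind = kind,
                      start1 = hits$a, end1 = hits$b,
                      start2 = arm2[, 1L], end2 = arm2[, 2L],
                      length = hits$b - hits$a + 1L,
                      mismatches = hits$mm, stringsAsFactors = FALSE)
    # canonical arm order + dedupe of symmetric discoveries
    swap <- rec$start2 < rec$start1 |
      (rec$start2 == rec$start1 & rec$end2 < rec$end1)
    rec[swap, c("start1", "end1", "start2", "end2")] <-
      rec[swap, c("start2", "end2", "start1", "end1")]
    rec <- unique(rec)
    rec <- drop_contained(rec)
    out[[length(out) + 1L]] <- rec
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(), start1 = integer(), end1 = integer(),
               start2 = integer(), end2 = integer(), length = integer(),
               mismatches = integer(), stringsAsFactors = FALSE)
  res <- res[order(match(res$kind, REPEAT_KINDS), res$start1, res$start2), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# seed-and-extend scan of s against a transformed copy t (both character
# vectors); returns windows (a..b in s paired with a+d..b+d in t) that are
# maximal under the mismatch budget. Every qualifying window contains an
# exact k-mer seed (pigeonhole), so only seed neighbourhoods need scanning:
# the scan range around the seeds of a diagonal is grown until at least
# max_hamming + 1 mismatches separate its edges from the outermost seeds
# (or the diagonal ends), after which no window can cross the edge.
scan_pairs <- function(s, t, min_len, max_hamming, self_forward = FALSE) {
  n <- length(s)
  k <- max(2L, min_len %/% (max_hamming + 1L))
  km_s <- substring(paste(s, collapse = ""), 1:(n - k + 1L), k:n)
  km_t <- substring(paste(t, collapse = ""), 1:(n - k + 1L), k:n)
  grp <- split(seq_len(n - k + 1L), km_t)
  grp <- grp[!grepl("N", names(grp), fixed = TRUE)]
  mat <- grp[km_s]
  mat[grepl("N", km_s, fixed = TRUE)] <- list(NULL)
  seed_i <- rep.int(seq_along(mat), lengths(mat))
  seed_j <- unlist(mat, use.names = FALSE)
  if (!length(seed_i)) return(data.frame(a = integer(0), b = integer(0),
                                         mm = integer(0), d = integer(0)))
  dd <- seed_j - seed_i
  if (self_forward) {
    keep <- dd > 0L
    seed_i <- seed_i[keep]; dd <- dd[keep]
  }
  if (!length(seed_i)) return(data.frame(a = integer(0), b = integer(0),
                                         mm = integer(0), d = integer(0)))
  # collapse runs of consecutive seeds (one representative per maximal
  # exact run on a diagonal), then keep only runs whose best achievable
  # window (budget split across the flanking mismatches) reaches min_len
  o <- order(dd, seed_i)
  dd <- dd[o]; seed_i <- seed_i[o]
  m <- length(seed_i)
  first <- c(TRUE, dd[-1L] != dd[-m] | seed_i[-1L] != seed_i[-m] + 1L)
  run_d <- dd[first]
  run_start <- seed_i[first]
  run_end <- seed_i[c(first[-1L], TRUE)] + k - 1L
  surv <- survives_filter(s, t, run_start, run_end, run_d, max_hamming,
                          min_len, n)
  if (!any(surv)) return(data.frame(a = integer(0), b = integer(0),
                                    mm = integer(0), d = integer(0)))
  by_diag <- split(data.frame(lo = run_start[surv], hi = run_end[surv]),
                   run_d[surv])
  pad <- min_len + 20L * (max_hamming + 1L)
  res_a <- integer(0); res_b <- integer(0); res_mm <- integer(0)
  res_d <- integer(0)
  for (ds in names(by_diag)) {
    d <- as.integer(ds)
    dlo <- max(1L, 1L - d); dhi <- min(n, n - d)   # s index range on diagonal
    if (dhi - dlo + 1L < min_len) next
    p_lo <- min(by_diag[[ds]]$lo); p_hi <- max(by_diag[[ds]]$hi)
    lo <- max(dlo, p_lo - pad); hi <- min(dhi, p_hi + pad)
    repeat {
      idx <- lo:hi
      mm <- s[idx] != t[idx + d] | s[idx] == "N" | t[idx + d] == "N"
      short_lo <- lo > dlo && sum(mm[idx < p_lo]) <= max_hamming
      short_hi <- hi < dhi && sum(mm[idx > p_hi]) <= max_hamming
      if (!short_lo && !short_hi) break
      if (short_lo) lo <- max(dlo, lo - 4L * pad)
      if (short_hi) hi <- min(dhi, hi + 4L * pad)
    }
    win <- diagonal_repeats(mm, max_hamming, min_len)
    if (nrow(win)) {
      res_a <- c(res_a, idx[win[, 1L]])
      res_b <- c(res_b, idx[win[, 2L]])
      res_mm <- c(res_mm, win[, 3L])
      res_d <- c(res_d, rep(d, nrow(win)))
    }
  }
  data.frame(a = res_a, b = res_b, mm = res_mm, d = res_d)
}

# vectorized necessity filter for exact-run representatives: from each run's
# edges, hop outward over up to h+1 flanking mismatches on the diagonal
# (vectorized across runs) and test whether any budget split l + r = h
# yields a window of length >= min_len. Windows that the full scan would
# report always contain an exact run, so dropping failing runs is safe.
survives_filter <- function(s, t, run_start, run_end, run_d, h, min_len, n) {
  nr <- length(run_start)
  dlo <- pmax(1L, 1L - run_d)
  dhi <- pmin(n, n - run_d)
  hop <- function(cur, dir) {
    # dir = -1: positions of the 1st..(h+1)th mismatch left of cur;
    # dir = +1: right of cur; boundary sentinels just outside the diagonal
    out <- matrix(0L, nr, h + 1L)
    for (m in seq_len(h + 1L)) {
      p <- cur + dir
      act <- seq_len(nr)
      repeat {
        inb <- if (dir < 0L) p[act] >= dlo[act] else p[act] <= dhi[act]
        act <- act[inb]
        if (!length(act)) break
        tp <- p[act] + run_d[act]
        ok <- s[p[act]] == t[tp] & s[p[act]] != "N" & t[tp] != "N"
        act <- act[ok]
        if (!length(act)) break
        p[act] <- p[act] + dir
      }
      out[, m] <- ifelse(if (dir < 0L) p >= dlo else p <= dhi,
                         p, if (dir < 0L) dlo - 1L else dhi + 1L)
      cur <- out[, m]
    }
    out
  }
  L <- hop(run_start, -1L)
  R <- hop(run_end, +1L)
  best <- rep(0L, nr)
  for (l in 0:h) {
    len <- (R[, h - l + 1L] - 1L) - (L[, l + 1L] + 1L) + 1L
    best <- pmax(best, len)
  }
  best >= min_len
}

# repeats reported from one diagonal: enumerate, for every k in 0..h, the
# windows with exactly k internal mismatches flanked by mismatches or the
# diagonal ends (maximal exact-k repeats), keep those >= min_len, then
# collapse overlapping windows to one record preferring (fewer mismatches,
# longer, leftmost). Returns matrix (start, end, mismatches) in local indices.
diagonal_repeats <- function(mm, h, min_len) {
  len <- length(mm)
  bnd <- c(0L, which(mm), len + 1L)
  m <- length(bnd)
  cand <- list()
  for (k in 0:min(h, m - 2L)) {
    i <- seq_len(m - k - 1L)
    a <- bnd[i] + 1L
    b <- bnd[i + k + 1L] - 1L
    keep <- (b - a + 1L) >= min_len
    if (any(keep)) cand[[length(cand) + 1L]] <-
      cbind(a[keep], b[keep], k)
  }
  if (!length(cand)) return(matrix(integer(0), ncol = 3L))
  w <- do.call(rbind, cand)
  w <- w[order(w[, 3L], -(w[, 2L] - w[, 1L]), w[, 1L]), , drop = FALSE]
  acc <- matrix(integer(0), ncol = 3L)
  for (i in seq_len(nrow(w))) {
    if (nrow(acc) == 0L ||
        !any(w[i, 1L] <= acc[, 2L] & w[i, 2L] >= acc[, 1L]))
      acc <- rbind(acc, w[i, , drop = FALSE])
  }
  acc
}

# map the second arm (t coordinates a+d..b+d) back into s coordinates;
# reverse and palindromic copies read right-to-left in s
map_arm2 <- function(hits, kind, n) {
  j1 <- hits$a + hits$d
  j2 <- hits$b + hits$d
  if (kind %in% c("forward", "complement")) cbind(j1, j2)
  else cbind(n - j2 + 1L, n - j1 + 1L)
}

# drop pairs whose arms are both strictly contained in the arms of another
# no-worse (mismatch-wise) pair of the same kind
drop_contained <- function(rec) {
  if (nrow(rec) <= 1L) return(rec)
  keep <- rep(TRUE, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    inside1 <- rec$start1 <= rec$start1[i] & rec$end1 >= rec$end1[i]
    inside2 <- rec$start2 <= rec$start2[i] & rec$end2 >= rec$end2[i]
    strict <- rec$length > rec$length[i] & rec$mismatches <= rec$mismatches[i]
    if (any(inside1 & inside2 & strict)) keep[i] <- FALSE
  }
  rec[keep, , drop = FALSE]
}
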