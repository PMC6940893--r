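# Brute-force oracles and fixture builders, implemented independently of
# the package internals (plain loops, no seeding, no shared helpers).

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# --- SSR oracle -------------------------------------------------------
# direct per-position enumeration of maximal perfect tandem runs
oracle_ssrs <- function(seq, thr = c(7L, 4L, 4L, 3L, 3L, 3L)) {
  s <- strsplit(seq, "")[[1L]]
  n <- length(s)
  recs <- list()
  for (u in 1:6) {
    if (n < u * thr[u]) next
    for (i in seq_len(n - u * thr[u] + 1L)) {
      motif <- s[i:(i + u - 1L)]
      if (any(motif == "N")) next
      # left-maximality: the periodic run must not continue to the left
      if (i > 1L && i - 1L + u <= n && s[i - 1L] == s[i - 1L + u] &&
            s[i - 1L] != "N") next
      p <- i
      while (p + u <= n && s[p + u] == s[p] && s[p] != "N") p <- p + 1L
      total <- (p - i) + u
      copies <- total %/% u
      if (copies < thr[u]) next
      prim <- TRUE
      for (d in seq_len(u - 1L)) {
        if (u %% d != 0L) next
        if (all(motif == rep(motif[1:d], u / d))) { prim <- FALSE; break }
      }
      if (!prim) next
      recs[[length(recs) + 1L]] <-
        data.frame(motif = paste(motif, collapse = ""), unit_len = u,
                   copies = copies, start = i, end = i + u * copies - 1L,
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(motif = character(), unit_len = integer(),
               copies = integer(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- long-repeat oracle -----------------------------------------------
# exhaustive scan of every diagonal (no seeding): enumerate maximal
# exact-k windows for k in 0..h, collapse per diagonal preferring fewer
# mismatches / longer / leftmost, then cross-diagonal containment drop.
oracle_long_repeats <- function(seq, min_len = 30L, max_hamming = 3L,
                                kinds = c("forward", "reverse",
                                          "complement", "palindromic")) {
  s <- strsplit(seq, "")[[1L]]
  n <- length(s)
  all_rec <- list()
  for (kind in kinds) {
    tr <- switch(kind,
      forward = s,
      reverse = rev(s),
      complement = strsplit(chartr("ACGT", "TGCA", seq), "")[[1L]],
      palindromic = strsplit(rc(seq), "")[[1L]])
    drange <- if (kind == "forward") seq_len(n - 1L) else
      seq.int(-(n - 1L), n - 1L)
    recs <- list()
    for (d in drange) {
      lo <- max(1L, 1L - d); hi <- min(n, n - d)
      if (hi - lo + 1L < min_len) next
      idx <- lo:hi
      mis <- s[idx] != tr[idx + d] | s[idx] == "N" | tr[idx + d] == "N"
      bnd <- c(lo - 1L, idx[mis], hi + 1L)
      cand <- list()
      for (k in 0:max_hamming) {
        if (length(bnd) - 1L <= k) {
          if (k == length(bnd) - 1L && hi - lo + 1L >= min_len)
            cand[[length(cand) + 1L]] <- c(lo, hi, sum(mis))
          break
        }
        for (ii in seq_len(length(bnd) - k - 1L)) {
          a <- bnd[ii] + 1L; b <- bnd[ii + k + 1L] - 1L
          if (b - a + 1L >= min_len)
            cand[[length(cand) + 1L]] <- c(a, b, k)
        }
      }
      if (!length(cand)) next
      cm <- do.call(rbind, cand)
      cm <- cm[order(cm[, 3L], -(cm[, 2L] - cm[, 1L]), cm[, 1L]), ,
               drop = FALSE]
      acc <- NULL
      for (r in seq_len(nrow(cm))) {
        if (is.null(acc) ||
            !any(cm[r, 1L] <= acc[, 2L] & cm[r, 2L] >= acc[, 1L]))
          acc <- rbind(acc, cm[r, , drop = FALSE])
      }
      for (r in seq_len(nrow(acc))) {
        a <- acc[r, 1L]; b <- acc[r, 2L]
        j1 <- a + d; j2 <- b + d
        arm2 <- if (kind %in% c("forward", "complement")) c(j1, j2) else
          c(n - j2 + 1L, n - j1 + 1L)
        p <- c(a, b, arm2)
        if (p[3L] < p[1L] || (p[3L] == p[1L] && p[4L] < p[2L]))
          p <- p[c(3L, 4L, 1L, 2L)]
        recs[[length(recs) + 1L]] <-
          data.frame(kind = kind, start1 = p[1L], end1 = p[2L],
                     start2 = p[3L], end2 = p[4L], length = b - a + 1L,
                     mismatches = acc[r, 3L], stringsAsFactors = FALSE)
      }
    }
    if (!length(recs)) next
    rr <- unique(do.call(rbind, recs))
    keep <- rep(TRUE, nrow(rr))
    for (i in seq_len(nrow(rr))) {
      cont <- rr$start1 <= rr$start1[i] & rr$end1 >= rr$end1[i] &
        rr$start2 <= rr$start2[i] & rr$end2 >= rr$end2[i] &
        rr$length > rr$length[i] & rr$mismatches <= rr$mismatches[i]
      if (any(cont)) keep[i] <- FALSE
    }
    all_rec[[kind]] <- rr[keep, , drop = FALSE]
  }
  out <- if (length(all_rec)) do.call(rbind, all_rec) else
    data.frame(kind = character(), start1 = integer(), end1 = integer(),
               start2 = integer(), end2 = integer(), length = integer(),
               mismatches = integer(), stringsAsFactors = FALSE)
  out <- out[order(match(out$kind, c("forward", "reverse", "complement",
                                     "palindromic")),
                   out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- per-site nucleotide diversity oracle -----------------------------
# plain loops; per-site pi averaged over sites (valid on gap-free input)
oracle_persite_pi <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  nr <- nrow(mat)
  vapply(seq_len(ncol(mat)), function(j) {
    diffs <- 0L; pairs <- 0L
    for (i1 in 1:(nr - 1L)) for (i2 in (i1 + 1L):nr) {
      b1 <- mat[i1, j]; b2 <- mat[i2, j]
      if (b1 %in% c("A", "C", "G", "T") && b2 %in% c("A", "C", "G", "T")) {
        pairs <- pairs + 1L
        if (b1 != b2) diffs <- diffs + 1L
      }
    }
    if (pairs == 0L) NA_real_ else diffs / pairs
  }, 1)
}

# --- editing recount oracle -------------------------------------------
# independent per-site recount over the pileup table
oracle_editing_recount <- function(pileups, plastome, min_cov = 10L,
                                   min_reps = 2L) {
  reps <- sort(unique(as.character(pileups$replicate)))
  called <- list()
  for (pos in sort(unique(pileups$position))) {
    f <- plastome$features
    gene <- NA_character_; strand <- NA_character_
    for (i in seq_len(nrow(f))) {
      if (f$category[i] != "protein_coding" || f$partial[i]) next
      p <- f$parts[[i]]
      if (any(p[, 1L] <= pos & p[, 2L] >= pos)) {
        gene <- f$name[i]; strand <- f$strand[i]; break
      }
    }
    if (is.na(gene)) next
    refb <- substr(plastome$seq, pos, pos)
    if (strand == "+" && refb != "C") next
    if (strand == "-" && refb != "G") next
    levels <- numeric(0)
    n_support <- 0L
    for (r in reps) {
      sub <- pileups[pileups$replicate == r & pileups$position == pos, ]
      ed <- sum(sub[[if (strand == "+") "T" else "A"]])
      rf <- sum(sub[[if (strand == "+") "C" else "G"]])
      cov <- sum(sub$A, sub$C, sub$G, sub$T)
      lv <- if (ed + rf > 0) 100 * ed / (ed + rf) else 0
      levels <- c(levels, lv)
      if (lv > 0 && cov >= min_cov) n_support <- n_support + 1L
    }
    if (n_support >= min_reps)
      called[[length(called) + 1L]] <-
        data.frame(position = pos, gene = gene, strand = strand,
                   t(setNames(levels, paste0("level_", reps))))
  }
  if (!length(called))
    return(data.frame(position = integer(), gene = character(),
                      strand = character()))
  out <- do.call(rbind, called)
  rownames(out) <- NULL
  out
}

# --- toy quadripartite genome -----------------------------------------
# junction bases of the single-copy regions are pinned to A so the planted
# IR arms can never extend by a chance complementary flank
make_quadripartite <- function(lsc, ir, ssc) {
  pin <- function(s) {
    substr(s, 1, 1) <- "A"
    substr(s, nchar(s), nchar(s)) <- "A"
    s
  }
  x <- pin(random_dna(lsc)); r <- random_dna(ir); y <- pin(random_dna(ssc))
  list(seq = paste0(x, r, y, rc(r)), lsc = lsc, ir = ir, ssc = ssc)
}
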