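# Alignment-based intraspecific polymorphism: sliding-window nucleotide
# diversity (pi), per-feature pi, hotspot calling and pairwise windowed
# identity.
#
# pi is the raw average pairwise difference proportion (no Jukes-Cantor
# correction). Gaps are handled by pairwise deletion: a site contributes to
# a row pair only when both rows carry an unambiguous base there.

#' Construct a multiple alignment
#'
#' @param rows Character vector of equal-length aligned sequences over
#'   `A/C/G/T/N/-` (case-insensitive).
#' @param names Sequence identifiers (defaults to names of `rows`).
#' @param reference Identifier of the reference row used for coordinate
#'   projection (default: the first row).
#' @return A `multiple_alignment` object.
#' @export
multiple_alignment <- function(rows, names = base::names(rows),
                               reference = NULL) {
  if (is.null(names)) names <- paste0("seq", seq_along(rows))
  rows <- toupper(unname(rows))
  if (length(rows) < 2L) stop("alignment needs >= 2 rows", call. = FALSE)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  bad <- gsub("[ACGTN-]", "", paste(rows, collapse = ""))
  if (nchar(bad) > 0L)
    stop("alignment contains characters outside A/C/G/T/N/-", call. = FALSE)
  if (is.null(reference)) reference <- names[1L]
  if (!reference %in% names) stop("reference row not found", call. = FALSE)
  structure(list(names = names, rows = rows, reference = reference),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("<multiple_alignment> ", length(x$rows), " rows x ", nchar(x$rows[1L]),
      " columns (reference: ", x$reference, ")\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path Aligned FASTA (equal-length records).
#' @param reference Optional reference row name.
#' @return A [multiple_alignment()].
#' @export
read_alignment <- function(path, reference = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  multiple_alignment(as.character(ss), names = sub("\\s.*$", "", names(ss)),
                     reference = reference)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, ""))
}

# map alignment column -> reference position (number of reference bases up
# to and including the column; gap columns inherit the preceding base)
reference_positions <- function(aln) {
  ref <- strsplit(aln$rows[match(aln$reference, aln$names)], "")[[1L]]
  cumsum(ref != "-")
}

window_starts <- function(ncol, window, step) {
  if (window < 1L || step < 1L) stop("window and step must be >= 1",
                                     call. = FALSE)
  seq.int(1L, ncol, by = step)
}

#' Sliding-window nucleotide diversity
#'
#' For each window, pi is the mean over all unordered row pairs of
#' (pairwise differences / pairwise comparable sites), where a site is
#' comparable for a pair only when both rows have an `A/C/G/T` base there.
#' Pairs with no comparable site in a window are excluded from the mean; a
#' window in which no pair has comparable sites reports `NA`.
#'
#' @param aln A [multiple_alignment()].
#' @param window,step Window length and step in alignment columns (defaults
#'   500/500, i.e. non-overlapping tiling windows; the trailing partial
#'   window is included).
#' @return A data frame with `window_start`, `window_end`, `ref_start`,
#'   `ref_end` (reference-coordinate projection), `pi`, `n_sites_used` (the
#'   number of columns where at least one pair is comparable).
#' @export
sliding_window_pi <- function(aln, window = 500L, step = 500L) {
  mat <- aln_matrix(aln)
  nc <- ncol(mat)
  starts <- window_starts(nc, window, step)
  ends <- pmin(starts + window - 1L, nc)
  pairs <- utils::combn(nrow(mat), 2L)
  ok <- mat %in% DNA_BASES
  dim(ok) <- dim(mat)
  # per-pair cumulative comparable/different counts for O(1) window sums
  cmp_cs <- diff_cs <- matrix(0, ncol(pairs), nc + 1L)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    comparable <- ok[i, ] & ok[j, ]
    differs <- comparable & mat[i, ] != mat[j, ]
    cmp_cs[p, ] <- c(0, cumsum(comparable))
    diff_cs[p, ] <- c(0, cumsum(differs))
  }
  refpos <- reference_positions(aln)
  res <- data.frame(window_start = starts, window_end = ends,
                    ref_start = refpos[starts], ref_end = refpos[ends],
                    pi = NA_real_, n_sites_used = 0L)
  any_cmp_cs <- c(0, cumsum(colSums(matrix(ok[pairs[1L, ], ] &
                                           ok[pairs[2L, ], ],
                                           ncol(pairs), nc) > 0) > 0))
  for (w in seq_along(starts)) {
    a <- starts[w]; b <- ends[w]
    cmp <- cmp_cs[, b + 1L] - cmp_cs[, a]
    dif <- diff_cs[, b + 1L] - diff_cs[, a]
    use <- cmp > 0
    res$pi[w] <- if (any(use)) mean(dif[use] / cmp[use]) else NA_real_
    res$n_sites_used[w] <- as.integer(any_cmp_cs[b + 1L] - any_cmp_cs[a])
  }
  res
}

#' Per-feature nucleotide diversity
#'
#' Computes pi over the union of the alignment columns of each feature,
#' where features are given in reference coordinates and projected through
#' the reference row.
#'
#' @param aln A [multiple_alignment()].
#' @param features Data frame with columns `feature`, `class` (one of
#'   `"gene"`, `"intron"`, `"intergenic"`), `start`, `end` (1-based
#'   inclusive, reference coordinates).
#' @return The input table with `pi` and `n_sites_used` columns appended.
#' @export
per_feature_pi <- function(aln, features) {
  stopifnot(all(c("feature", "class", "start", "end") %in% names(features)))
  mat <- aln_matrix(aln)
  refpos <- reference_positions(aln)
  reflen <- max(refpos)
  if (any(features$start < 1L) || any(features$end > reflen))
    stop("feature outside the reference coordinate range", call. = FALSE)
  pairs <- utils::combn(nrow(mat), 2L)
  ok <- mat %in% DNA_BASES
  dim(ok) <- dim(mat)
  out <- features
  out$pi <- NA_real_
  out$n_sites_used <- 0L
  for (k in seq_len(nrow(features))) {
    cols <- which(refpos >= features$start[k] & refpos <= features$end[k])
    ratios <- numeric(0)
    nuse <- 0L
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      comparable <- ok[i, cols] & ok[j, cols]
      nc <- sum(comparable)
      if (nc > 0L)
        ratios <- c(ratios, sum(comparable & mat[i, cols] != mat[j, cols]) / nc)
    }
    if (length(cols))
      nuse <- as.integer(sum(colSums(matrix(ok[pairs[1L, ], cols] &
                                              ok[pairs[2L, ], cols],
                                            ncol(pairs), length(cols))) > 0))
    out$pi[k] <- if (length(ratios)) mean(ratios) else NA_real_
    out$n_sites_used[k] <- nuse
  }
  out
}

#' Call diversity hotspots
#'
#' Returns the windows (or features) whose pi strictly exceeds the
#' threshold, sorted by pi descending.
#'
#' @param track A data frame with a `pi` column, from
#'   [sliding_window_pi()] or [per_feature_pi()].
#' @param threshold Hotspot threshold (default 0.02; strict `>`).
#' @return The qualifying rows of `track`, sorted by `pi` descending.
#' @export
call_hotspots <- function(track, threshold = 0.02) {
  stopifnot(is.data.frame(track), "pi" %in% names(track), nrow(track) > 0L)
  hit <- !is.na(track$pi) & track$pi > threshold
  out <- track[hit, , drop = FALSE]
  out <- out[order(-out$pi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Windowed percent identity between two alignment rows
#'
#' mVISTA-style track: identity = matches / comparable sites x 100 per
#' window; a site is comparable when both rows have an `A/C/G/T` base.
#'
#' @param aln A [multiple_alignment()].
#' @param reference,other Row names to compare (default: the alignment's
#'   reference against `other`).
#' @param window,step Window and step in alignment columns.
#' @return A data frame with `window_start`, `window_end`, `identity`
#'   (percent, `NA` when no comparable site) and `n_sites_used`.
#' @export
identity_track <- function(aln, other, reference = aln$reference,
                           window = 500L, step = 500L) {
  i <- match(reference, aln$names)
  j <- match(other, aln$names)
  if (is.na(i) || is.na(j)) stop("row name not in alignment", call. = FALSE)
  mat <- aln_matrix(aln)
  nc <- ncol(mat)
  comparable <- mat[i, ] %in% DNA_BASES & mat[j, ] %in% DNA_BASES
  matches <- comparable & mat[i, ] == mat[j, ]
  cmp_cs <- c(0, cumsum(comparable))
  mat_cs <- c(0, cumsum(matches))
  starts <- window_starts(nc, window, step)
  ends <- pmin(starts + window - 1L, nc)
  cmp <- cmp_cs[ends + 1L] - cmp_cs[starts]
  mt <- mat_cs[ends + 1L] - mat_cs[starts]
  data.frame(window_start = starts, window_end = ends,
             identity = ifelse(cmp > 0, 100 * mt / cmp, NA_real_),
             n_sites_used = cmp)
}
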