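# Inter-genome architecture comparison: signed gene-order inversions,
# gene presence/absence (the ndh repertoire), and SSC/IR junction reports.

#' The eleven plastid NAD(P)H-dehydrogenase complex genes
#' @export
NDH_GENES <- paste0("ndh", c("A", "B", "C", "D", "E", "F", "G", "H", "I",
                             "J", "K"))

#' Signed gene order of a plastome
#'
#' One entry per feature copy, ordered by ascending start coordinate, with
#' the strand as the sign. Trans-spliced parts appear once per locus.
#'
#' @param plastome An [annotated_plastome()].
#' @return A data frame with `symbol`, `strand`, `copy_index`, `start`,
#'   `end`.
#' @export
gene_order <- function(plastome) {
  f <- plastome$features
  if (nrow(f) == 0L) stop("plastome has no features", call. = FALSE)
  spans <- t(vapply(f$parts, feature_span, integer(2L)))
  out <- data.frame(symbol = f$name, strand = f$strand,
                    copy_index = f$copy_index,
                    start = spans[, 1L], end = spans[, 2L],
                    stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect gene-order inversions between two genomes
#'
#' Matches gene copies by symbol and copy index, then reports every maximal
#' contiguous block that appears in genome B reversed in order with flipped
#' strands relative to genome A as one `inversion`. Order differences not
#' explainable as a single block reversal are reported as
#' `translocation_or_other`. Symbols present in only one genome are reported
#' as `presence_absence`.
#'
#' @param order_a,order_b Signed gene orders from [gene_order()].
#' @return A data frame with `kind`, `genes` (comma-separated symbols),
#'   `a_start`, `a_end`, `b_start`, `b_end` (genomic coordinates of the
#'   block in each genome; `NA` for presence/absence).
#' @export
detect_inversions <- function(order_a, order_b) {
  if (nrow(order_a) == 0L || nrow(order_b) == 0L)
    stop("empty gene order", call. = FALSE)
  # occurrence index makes keys unique when a symbol+copy appears several
  # times (trans-spliced loci stored as separate features)
  occ_key <- function(o) {
    k <- paste(o$symbol, o$copy_index)
    paste(k, stats::ave(seq_along(k), k, FUN = seq_along))
  }
  key_a <- occ_key(order_a)
  key_b <- occ_key(order_b)
  shared <- intersect(key_a, key_b)
  rec <- list()
  add <- function(kind, genes, a_iv, b_iv) {
    rec[[length(rec) + 1L]] <<- data.frame(
      kind = kind, genes = paste(genes, collapse = ","),
      a_start = a_iv[1L], a_end = a_iv[2L],
      b_start = b_iv[1L], b_end = b_iv[2L], stringsAsFactors = FALSE)
  }
  for (k in setdiff(key_a, key_b)) {
    w <- which(key_a == k)
    add("presence_absence", order_a$symbol[w],
        c(order_a$start[w], order_a$end[w]), c(NA, NA))
  }
  for (k in setdiff(key_b, key_a)) {
    w <- which(key_b == k)
    add("presence_absence", order_b$symbol[w], c(NA, NA),
        c(order_b$start[w], order_b$end[w]))
  }
  a <- order_a[key_a %in% shared, , drop = FALSE]
  b <- order_b[key_b %in% shared, , drop = FALSE]
  ka <- key_a[key_a %in% shared]
  kb <- key_b[key_b %in% shared]
  pos <- match(kb, ka)              # position in A of each B entry
  same <- a$strand[pos] == b$strand # strand agreement per B entry
  n <- length(pos)
  i <- 1L
  while (i <= n) {
    if (pos[i] == i && same[i]) { i <- i + 1L; next }
    j <- pos[i]                     # candidate block end (reversal target)
    is_inv <- j >= i && j <= n &&
      identical(pos[i:j], j:i) && !any(same[i:j])
    if (is_inv) {
      idx_a <- i:j
      add("inversion", a$symbol[i:j],
          c(min(a$start[idx_a]), max(a$end[idx_a])),
          c(min(b$start[i:j]), max(b$end[i:j])))
      i <- j + 1L
    } else {
      m <- i
      while (m <= n && !(pos[m] == m && same[m])) m <- m + 1L
      idx <- i:(m - 1L)
      add("translocation_or_other", unique(b$symbol[idx]),
          c(min(a$start[pos[idx]]), max(a$end[pos[idx]])),
          c(min(b$start[idx]), max(b$end[idx])))
      i <- m
    }
  }
  if (!length(rec))
    return(data.frame(kind = character(), genes = character(),
                      a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rec)
  out <- out[order(match(out$kind, c("inversion", "translocation_or_other",
                                     "presence_absence")), out$genes), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene presence/absence matrix
#'
#' A genomes-by-genes binary matrix: 1 iff a non-partial feature with that
#' symbol is annotated. Defaults to the eleven ndh genes, whose variable
#' loss across Utricularia is the comparison of interest. Symbols absent
#' from every genome trigger a warning and an all-zero column.
#'
#' @param plastomes A list of [annotated_plastome()] objects.
#' @param gene_set Character vector of gene symbols (default [NDH_GENES]).
#' @return An integer matrix with a `total` attribute column appended as the
#'   last column (`n_present` per genome).
#' @export
presence_absence_matrix <- function(plastomes, gene_set = NDH_GENES) {
  stopifnot(length(plastomes) >= 1L)
  ids <- vapply(plastomes, function(p) p$id, "")
  m <- matrix(0L, length(plastomes), length(gene_set),
              dimnames = list(ids, gene_set))
  if (length(gene_set) == 0L)
    return(cbind(m, n_present = integer(length(plastomes))))
  for (i in seq_along(plastomes)) {
    f <- plastomes[[i]]$features
    present <- unique(f$name[!f$partial])
    m[i, ] <- as.integer(gene_set %in% present)
  }
  missing_everywhere <- colSums(m) == 0L
  if (any(missing_everywhere))
    warning("symbol(s) not annotated in any genome: ",
            paste(gene_set[missing_everywhere], collapse = ", "),
            call. = FALSE)
  cbind(m, n_present = as.integer(rowSums(m)))
}

#' Genes at the single-copy/IR junctions
#'
#' For each of the four junctions (LSC/IRa, IRa/SSC, SSC/IRb, IRb/LSC),
#' reports the nearest feature on each side with its signed distance in bp
#' (negative when the feature lies before the junction in circular
#' coordinate order, positive after, 0 when it straddles). Features
#' straddling a junction additionally report the overlap length on each
#' side, which sums to the gene length for a gene spanning the junction
#' completely.
#'
#' @param plastome An [annotated_plastome()].
#' @param partition A partition from [detect_quadripartite()].
#' @return A data frame with `junction`, `side`, `gene`, `distance`,
#'   `overlap_before`, `overlap_after`.
#' @export
ssc_boundary_report <- function(plastome, partition) {
  f <- plastome$features
  n <- partition$genome_length
  # junction between region r1 and r2: boundary after last base of r1
  junctions <- list(
    c("LSC/IRa", partition$lsc[2L]),
    c("IRa/SSC", partition$ira[2L]),
    c("SSC/IRb", partition$ssc[2L]),
    c("IRb/LSC", partition$irb[2L]))
  if (nrow(f) == 0L)
    return(data.frame(junction = character(), side = character(),
                      gene = character(), distance = integer(),
                      overlap_before = integer(), overlap_after = integer(),
                      stringsAsFactors = FALSE))
  spans <- t(vapply(f$parts, feature_span, integer(2L)))
  rows <- list()
  for (jn in junctions) {
    bpos <- as.integer(jn[2L])             # junction sits after base bpos
    # circular signed distance from feature to the junction boundary
    gene_len <- spans[, 2L] - spans[, 1L] + 1L
    # distance from feature end to boundary, going forward on the circle
    d_before <- (bpos - spans[, 2L]) %% n  # 0 when feature ends at boundary
    d_after <- (spans[, 1L] - bpos - 1L) %% n
    # feature straddles when the boundary falls strictly inside it
    straddle <- (bpos - spans[, 1L]) %% n < gene_len - 1L
    ov_before <- ifelse(straddle, ((bpos - spans[, 1L]) %% n) + 1L, NA_integer_)
    ov_after <- ifelse(straddle, gene_len - ov_before, NA_integer_)
    if (any(straddle)) {
      for (w in which(straddle))
        rows[[length(rows) + 1L]] <- data.frame(
          junction = jn[1L], side = "spanning", gene = f$name[w],
          distance = 0L, overlap_before = ov_before[w],
          overlap_after = ov_after[w], stringsAsFactors = FALSE)
    }
    clean <- !straddle
    if (any(clean)) {
      wb <- which(clean)[which.min(d_before[clean])]
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jn[1L], side = "before", gene = f$name[wb],
        distance = -as.integer(d_before[wb]), overlap_before = NA_integer_,
        overlap_after = NA_integer_, stringsAsFactors = FALSE)
      wa <- which(clean)[which.min(d_after[clean])]
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jn[1L], side = "after", gene = f$name[wa],
        distance = as.integer(d_after[wa]), overlap_before = NA_integer_,
        overlap_after = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
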