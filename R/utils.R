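# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#' `N` is preserved as `N`.
#'
#' @param x A single DNA string over `A/C/G/T/N`.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# complement without reversal (character scalar)
comp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

# validate an uppercase DNA string restricted to {A,C,G,T,N}
validate_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  bad <- gsub("[ACGTN]", "", x)
  if (nchar(bad) > 0L)
    stop(what, " contains non-DNA characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","), call. = FALSE)
  invisible(x)
}

# round-half-up to `digits` decimals (report parity; base round() is
# round-half-even)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Run `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# substring a circular sequence; `start`/`end` are 1-based on the circle and
# `end < start` means the interval wraps through the origin
substr_circular <- function(seq, start, end) {
  n <- nchar(seq)
  stopifnot(start >= 1L, start <= n, end >= 1L, end <= n)
  if (end >= start) substr(seq, start, end)
  else paste0(substr(seq, start, n), substr(seq, 1L, end))
}

interval_len_circular <- function(start, end, n) {
  if (end >= start) end - start + 1L else n - start + 1L + end
}

# fraction of G+C among unambiguous bases, in percent
gc_percent <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  acgt <- s %in% DNA_BASES
  if (!any(acgt)) return(NA_real_)
  100 * sum(s %in% c("G", "C")) / sum(acgt)
}
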