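# Plastome containers and I/O: GenBank flat files, FASTA + GFF3, the
# quadripartite LSC/IRa/SSC/IRb partition, region statistics and gene census.

#' Construct an annotated plastome
#'
#' The central container of the package: a circular chloroplast genome
#' sequence together with its gene features. Coordinates are 1-based
#' inclusive everywhere in the public interface.
#'
#' @param id Accession or label for the genome.
#' @param seq DNA sequence as a single uppercase string over `A/C/G/T/N`.
#' @param features A data frame of gene features, as built by
#'   [gene_feature()] / [gene_features()]; may have zero rows.
#' @param circular Logical; plastomes are circular molecules (default `TRUE`).
#' @return An object of class `annotated_plastome` with elements `id`, `seq`,
#'   `circular` and `features`.
#' @export
annotated_plastome <- function(id, seq, features = gene_features(), circular = TRUE) {
  seq <- toupper(seq)
  validate_dna(seq, "plastome sequence")
  features <- as_gene_features(features)
  n <- nchar(seq)
  if (nrow(features) > 0L) {
    for (i in seq_len(nrow(features))) {
      p <- features$parts[[i]]
      if (any(p < 1L) || any(p > n))
        stop("feature '", features$name[i],
             "' has an interval outside [1, ", n, "]", call. = FALSE)
    }
  }
  structure(list(id = as.character(id), seq = seq, circular = isTRUE(circular),
                 features = features),
            class = "annotated_plastome")
}

#' @export
print.annotated_plastome <- function(x, ...) {
  cat("<annotated_plastome> ", x$id, ": ", nchar(x$seq), " bp",
      if (x$circular) " (circular)", ", ", nrow(x$features),
      " features\n", sep = "")
  invisible(x)
}

#' @export
length.annotated_plastome <- function(x) nchar(x$seq)

#' Build a single gene feature row
#'
#' @param name Gene symbol (e.g. `"psbA"`, `"rps12"`).
#' @param category One of `"protein_coding"`, `"tRNA"`, `"rRNA"`,
#'   `"pseudogene"`.
#' @param strand `"+"` or `"-"`.
#' @param parts A two-column matrix (`start`, `end`) of 1-based inclusive
#'   exon intervals, in transcription order on the plus strand of the genome.
#' @param copy_index Integer distinguishing IR-duplicated copies of the same
#'   symbol (1 for the first copy in coordinate order).
#' @param partial Logical; `TRUE` for partial genes / putative pseudogene
#'   fragments.
#' @param trans_spliced Logical; `TRUE` for loci whose mRNA is assembled from
#'   exons at separate genomic locations (rps12).
#' @return A one-row `gene_features` data frame.
#' @export
gene_feature <- function(name, category = "protein_coding", strand = "+",
                         parts, copy_index = 1L, partial = FALSE,
                         trans_spliced = FALSE) {
  stopifnot(category %in% c("protein_coding", "tRNA", "rRNA", "pseudogene"),
            strand %in% c("+", "-"))
  if (is.vector(parts) && length(parts) == 2L) parts <- matrix(parts, nrow = 1L)
  parts <- matrix(as.integer(parts), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(parts) == 0L) stop("parts must be non-empty", call. = FALSE)
  if (any(parts[, 2L] < parts[, 1L]))
    stop("feature part with end < start", call. = FALSE)
  o <- order(parts[, 1L])
  if (nrow(parts) > 1L && any(parts[o, 1L][-1L] <= parts[o, 2L][-nrow(parts)]))
    stop("overlapping parts within one feature", call. = FALSE)
  df <- data.frame(name = as.character(name), category = category,
                   strand = strand, copy_index = as.integer(copy_index),
                   partial = isTRUE(partial),
                   trans_spliced = isTRUE(trans_spliced),
                   stringsAsFactors = FALSE)
  df$parts <- list(parts)
  class(df) <- c("gene_features", "data.frame")
  df
}

#' Combine gene features into a feature table
#'
#' @param ... `gene_features` rows from [gene_feature()].
#' @return A `gene_features` data frame sorted by start coordinate.
#' @export
gene_features <- function(...) {
  rows <- list(...)
  if (length(rows) == 0L) {
    df <- data.frame(name = character(), category = character(),
                     strand = character(), copy_index = integer(),
                     partial = logical(), trans_spliced = logical(),
                     stringsAsFactors = FALSE)
    df$parts <- list()
    class(df) <- c("gene_features", "data.frame")
    return(df)
  }
  df <- do.call(rbind, rows)
  df[order(vapply(df$parts, function(p) min(p[, 1L]), 1L)), , drop = FALSE]
}

as_gene_features <- function(x) {
  if (inherits(x, "gene_features")) return(x)
  stopifnot(is.data.frame(x), all(c("name", "category", "strand", "parts") %in% names(x)))
  if (is.null(x$copy_index)) x$copy_index <- 1L
  if (is.null(x$partial)) x$partial <- FALSE
  if (is.null(x$trans_spliced)) x$trans_spliced <- FALSE
  class(x) <- c("gene_features", "data.frame")
  x
}

# overall genomic span of a feature (ignores circular wrapping)
feature_span <- function(parts) c(min(parts[, 1L]), max(parts[, 2L]))

#' Read a plastome from GenBank or FASTA(+GFF3)
#'
#' The GenBank reader is a minimal flat-file parser covering the feature
#' types used in plastome records (`CDS`, `tRNA`, `rRNA`), including
#' `join(...)` multi-exon and `complement(...)` locations, `/gene` and
#' `/pseudo` qualifiers, and partial-end markers (`<`, `>`). FASTA input goes
#' through Biostrings; annotations come from a GFF3 file via rtracklayer.
#'
#' @param path Path to the sequence file.
#' @param format `"genbank"` or `"fasta"`.
#' @param gff Optional path to a GFF3 annotation file (FASTA input only).
#' @return An [annotated_plastome()].
#' @export
read_plastome <- function(path, format = c("genbank", "fasta"), gff = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "genbank") return(read_genbank(path))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected exactly one FASTA record", call. = FALSE)
  id <- sub("\\s.*$", "", names(ss)[1L])
  seq <- toupper(as.character(ss[[1L]]))
  feats <- if (is.null(gff)) gene_features() else read_gff3_features(gff, nchar(seq))
  annotated_plastome(id, seq, feats)
}

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1L]), "\\s+")[[1L]][2L] else basename(path)
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(acc[1L]), "\\s+")[[1L]]
    if (length(a) >= 2L) id <- a[2L]
  }
  # sequence block
  oi <- grep("^ORIGIN", lines)
  if (length(oi) != 1L) stop("no ORIGIN block in GenBank file", call. = FALSE)
  seq_lines <- lines[(oi + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  seq <- gsub("[^ACGTN]", "N", seq)  # ambiguity codes collapse to N
  # feature block
  fi <- grep("^FEATURES", lines)
  feats <- gene_features()
  if (length(fi) == 1L) {
    block <- lines[(fi + 1L):(oi - 1L)]
    feats <- parse_genbank_features(block, nchar(seq))
  }
  annotated_plastome(id, seq, feats)
}

parse_genbank_features <- function(block, seqlen) {
  # a new feature starts at column 6; continuation/qualifier lines at column 22
  starts <- grep("^ {5}\\S", block)
  if (!length(starts)) return(gene_features())
  ends <- c(starts[-1L] - 1L, length(block))
  keep_types <- c(CDS = "protein_coding", tRNA = "tRNA", rRNA = "rRNA")
  out <- list()
  for (k in seq_along(starts)) {
    first <- block[starts[k]]
    type <- sub("^ {5}(\\S+).*$", "\\1", first)
    if (!type %in% names(keep_types)) next
    body <- block[starts[k]:ends[k]]
    # location may continue over lines until the first qualifier
    qual_at <- grep("^ +/", body)
    loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(body)
    loc <- paste(trimws(sub("^ {5}\\S+", "", body[1L])),
                 paste(trimws(body[seq_len(loc_end)[-1L]]), collapse = ""),
                 sep = "")
    loc <- gsub("\\s", "", loc)
    quals <- paste(body[seq_along(body) >= loc_end + 1L], collapse = " ")
    gene <- sub('.*?/gene="([^"]+)".*', "\\1", quals)
    if (identical(gene, quals)) {
      gene <- sub('.*?/product="([^"]+)".*', "\\1", quals)
      if (identical(gene, quals)) gene <- paste0(tolower(type), "_", k)
    }
    pseudo <- grepl("/pseudo(\\s|$|/)", quals)
    partial <- grepl("[<>]", loc)
    strand <- if (grepl("^complement\\(", loc)) "-" else "+"
    inner <- gsub("^complement\\(|^join\\(|^order\\(|\\)+$", "", loc)
    inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", inner)
    pieces <- strsplit(inner, ",")[[1L]]
    iv <- t(vapply(pieces, function(p) {
      p <- gsub("[<>]", "", p)
      xs <- as.integer(strsplit(p, "\\.\\.")[[1L]])
      if (length(xs) == 1L) xs <- c(xs, xs)
      xs
    }, integer(2L)))
    if (any(iv > seqlen))
      stop("GenBank feature interval outside sequence length", call. = FALSE)
    category <- if (pseudo) "pseudogene" else keep_types[[type]]
    out[[length(out) + 1L]] <-
      gene_feature(gene, category, strand, iv, partial = partial)
  }
  if (!length(out)) return(gene_features())
  assign_copy_index(do.call(gene_features, out))
}

# copy_index: per symbol, 1..k in ascending start order
assign_copy_index <- function(feats) {
  if (nrow(feats) == 0L) return(feats)
  starts <- vapply(feats$parts, function(p) min(p[, 1L]), 1L)
  feats <- feats[order(starts), , drop = FALSE]
  feats$copy_index <- stats::ave(seq_len(nrow(feats)), feats$name,
                                 FUN = seq_along)
  rownames(feats) <- NULL
  feats
}

#' Write a plastome as FASTA + GFF3
#'
#' @param plastome An [annotated_plastome()].
#' @param fasta,gff Output paths. The GFF3 carries one row per feature part
#'   with type `CDS`/`tRNA`/`rRNA`, grouped by `ID`, plus `gene`,
#'   `copy_index`, `partial` and `trans_spliced` attributes.
#' @return Invisibly, the plastome.
#' @export
write_plastome <- function(plastome, fasta, gff = NULL) {
  ss <- Biostrings::DNAStringSet(plastome$seq)
  names(ss) <- plastome$id
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(gff)) {
    f <- plastome$features
    con <- file(gff, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    writeLines(sprintf("##sequence-region %s 1 %d", plastome$id,
                       nchar(plastome$seq)), con)
    if (nrow(f) > 0L) {
      type_of <- c(protein_coding = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                   pseudogene = "CDS")
      for (i in seq_len(nrow(f))) {
        p <- f$parts[[i]]
        attrs <- sprintf(
          "ID=%s;gene=%s;copy_index=%d;partial=%s;trans_spliced=%s;pseudo=%s",
          paste0(f$name[i], ".", f$copy_index[i],
                 if (f$trans_spliced[i]) paste0(".ts", i) else ""),
          f$name[i], f$copy_index[i],
          tolower(f$partial[i]), tolower(f$trans_spliced[i]),
          tolower(f$category[i] == "pseudogene"))
        writeLines(sprintf("%s\tplastomics\t%s\t%d\t%d\t.\t%s\t.\t%s",
                           plastome$id, type_of[[f$category[i]]],
                           p[, 1L], p[, 2L], f$strand[i], attrs), con)
      }
    }
  }
  invisible(plastome)
}

read_gff3_features <- function(gff, seqlen) {
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("CDS", "tRNA", "rRNA")]
  if (length(gr) == 0L) return(gene_features())
  md <- S4Vectors::mcols(gr)
  get_chr <- function(col, default) {
    if (col %in% names(md)) {
      v <- as.character(md[[col]])
      ifelse(is.na(v), default, v)
    } else rep(default, length(gr))
  }
  ids <- get_chr("ID", NA_character_)
  if (anyNA(ids)) ids[is.na(ids)] <- paste0("feat", which(is.na(ids)))
  genes <- get_chr("gene", NA_character_)
  genes[is.na(genes)] <- ids[is.na(genes)]
  partial <- get_chr("partial", "false") == "true"
  ts <- get_chr("trans_spliced", "false") == "true"
  pseudo <- get_chr("pseudo", "false") == "true"
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  if (any(en > seqlen))
    stop("GFF3 feature interval beyond sequence length", call. = FALSE)
  type <- as.character(gr$type)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  copy_attr <- get_chr("copy_index", NA_character_)
  out <- list()
  for (id in unique(ids)) {
    w <- which(ids == id)
    category <- if (pseudo[w[1L]]) "pseudogene"
                else c(CDS = "protein_coding", tRNA = "tRNA",
                       rRNA = "rRNA")[[type[w[1L]]]]
    out[[length(out) + 1L]] <- gene_feature(
      genes[w[1L]], category, strand[w[1L]],
      cbind(st[w], en[w]),
      copy_index = if (is.na(copy_attr[w[1L]])) 1L
                   else as.integer(copy_attr[w[1L]]),
      partial = partial[w[1L]], trans_spliced = ts[w[1L]])
  }
  feats <- do.call(gene_features, out)
  # assign copy indices only when the annotation does not carry them
  if (all(is.na(copy_attr))) assign_copy_index(feats) else {
    rownames(feats) <- NULL
    feats
  }
}

# ---------------------------------------------------------------------------
# Quadripartite structure

#' Detect the quadripartite LSC/IRa/SSC/IRb partition
#'
#' Finds the longest pair of exact reverse-complement repeats consistent with
#' a circular quadripartite tiling of the genome. The search runs on the
#' doubled sequence so that arms crossing the sequence origin are found. The
#' shorter single-copy region between the arms is labelled SSC. Ties on arm
#' length are broken by the candidate minimizing `|len(SSC) - len(LSC)|`,
#' then by lowest start coordinate.
#'
#' @param plastome An [annotated_plastome()].
#' @param min_ir_len Minimum inverted-repeat arm length in bp (default 1000).
#' @return A `quadripartite_partition`: list of `lsc`, `ira`, `ssc`, `irb`
#'   intervals (`c(start, end)`, 1-based inclusive; `end < start` means the
#'   interval wraps through the origin) plus `genome_length`.
#' @export
detect_quadripartite <- function(plastome, min_ir_len = 1000L) {
  seq <- plastome$seq
  n <- nchar(seq)
  if (min_ir_len < 1L) stop("min_ir_len must be positive", call. = FALSE)
  doubled <- Biostrings::DNAString(paste0(seq, seq))
  hits <- Biostrings::findPalindromes(doubled, min.armlength = min_ir_len,
                                      max.looplength = n, max.mismatch = 0)
  cand <- list()
  seen <- character()
  for (i in seq_along(hits)) {
    la <- Biostrings::palindromeLeftArm(hits[i])
    ra <- Biostrings::palindromeRightArm(hits[i])
    w <- Biostrings::palindromeArmLength(hits[i])
    s1 <- GenomicRanges::start(la@ranges); s2 <- GenomicRanges::start(ra@ranges)
    # map to circle
    a1 <- ((s1 - 1L) %% n) + 1L
    a2 <- ((s2 - 1L) %% n) + 1L
    gap1 <- s2 - (s1 + w)              # loop between the arms
    gap2 <- n - 2L * w - gap1          # remaining single-copy region
    if (gap2 < 0L) next                # arms overlap on the circle
    key <- paste(sort(c(a1, a2)), w, collapse = "_")
    if (key %in% seen) next
    seen <- c(seen, key)
    cand[[length(cand) + 1L]] <- list(a1 = a1, a2 = a2, w = w,
                                      gap1 = gap1, gap2 = gap2)
  }
  if (!length(cand))
    stop(structure(class = c("no_ir_detected", "error", "condition"),
                   list(message = paste0("no IR detected (no reverse-complement ",
                                         "repeat pair >= ", min_ir_len, " bp)"),
                        call = sys.call())))
  ws <- vapply(cand, `[[`, 1L, "w")
  asym <- vapply(cand, function(cc) abs(cc$gap1 - cc$gap2), 1L)
  a1s <- vapply(cand, `[[`, 1L, "a1")
  best <- cand[[order(-ws, asym, a1s)[1L]]]
  circ <- function(p) ((p - 1L) %% n) + 1L
  ira_start <- best$a1
  ira_end <- circ(best$a1 + best$w - 1L)
  ssc_start <- circ(best$a1 + best$w)
  ssc_end <- circ(best$a1 + best$w + best$gap1 - 1L)
  irb_start <- best$a2
  irb_end <- circ(best$a2 + best$w - 1L)
  lsc_start <- circ(best$a2 + best$w)
  lsc_end <- circ(best$a1 - 1L)
  ssc <- c(ssc_start, ssc_end)
  lsc <- c(lsc_start, lsc_end)
  # the longer single-copy region is the LSC
  if (best$gap1 > best$gap2) {
    tmp <- ssc; ssc <- lsc; lsc <- tmp
    part <- list(lsc = lsc, ira = c(irb_start, irb_end), ssc = ssc,
                 irb = c(ira_start, ira_end))
  } else {
    part <- list(lsc = lsc, ira = c(ira_start, ira_end), ssc = ssc,
                 irb = c(irb_start, irb_end))
  }
  part$genome_length <- n
  class(part) <- "quadripartite_partition"
  stopifnot(identical(substr_circular(seq, part$ira[1L], part$ira[2L]),
                      revcomp(substr_circular(seq, part$irb[1L], part$irb[2L]))))
  part
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  n <- x$genome_length
  cat("<quadripartite_partition> genome", n, "bp\n")
  for (r in c("lsc", "ira", "ssc", "irb")) {
    iv <- x[[r]]
    cat(sprintf("  %-4s %7d..%-7d (%d bp)\n", toupper(r), iv[1L], iv[2L],
                interval_len_circular(iv[1L], iv[2L], n)))
  }
  invisible(x)
}

partition_lengths <- function(partition) {
  n <- partition$genome_length
  vapply(partition[c("lsc", "ira", "ssc", "irb")],
         function(iv) interval_len_circular(iv[1L], iv[2L], n), 1L)
}

#' Region length, fraction and GC report
#'
#' One row per region (LSC, IRa, SSC, IRb) plus a `total` row. Fractions are
#' of the genome length; `%GC = (G+C)/(A+C+G+T) * 100`, rounded half-up to
#' one decimal. Note that published tables sometimes print IR percentages on
#' a different denominator; this report always uses fraction-of-genome.
#'
#' @param plastome An [annotated_plastome()].
#' @param partition A partition from [detect_quadripartite()].
#' @return A data frame with columns `region`, `length_bp`, `fraction`,
#'   `pct_gc`.
#' @export
region_report <- function(plastome, partition) {
  n <- nchar(plastome$seq)
  stopifnot(partition$genome_length == n)
  lens <- partition_lengths(partition)
  if (sum(lens) != n)
    stop("partition does not tile the genome", call. = FALSE)
  regions <- c("lsc", "ira", "ssc", "irb")
  seqs <- vapply(regions, function(r)
    substr_circular(plastome$seq, partition[[r]][1L], partition[[r]][2L]), "")
  df <- data.frame(
    region = c(toupper(regions), "total"),
    length_bp = c(unname(lens), n),
    fraction = round_half_up(100 * c(unname(lens), n) / n, 1L),
    pct_gc = round_half_up(c(vapply(seqs, gc_percent, 1), gc_percent(plastome$seq)), 1L),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Gene census
#'
#' Counts annotated genes the way comparative plastome tables do: the total
#' counts every feature copy (IR duplicates included); `unique_protein_coding`
#' collapses IR duplicates by symbol and excludes partial genes; tRNA/rRNA
#' counts are unique symbols; `intron_containing` counts features with more
#' than one exon; `duplicated_in_ir` counts symbols with more than one
#' non-partial copy.
#'
#' @param plastome An [annotated_plastome()].
#' @return A one-row data frame of counts.
#' @export
gene_census <- function(plastome) {
  f <- plastome$features
  if (nrow(f) == 0L)
    return(data.frame(total_genes = 0L, unique_protein_coding = 0L,
                      trna = 0L, rrna = 0L, intron_containing = 0L,
                      duplicated_in_ir = 0L, partial = 0L))
  full <- !f$partial
  # trans-spliced loci are stored as separate features but are one gene
  n_ts_extra <- max(0L, sum(f$trans_spliced) - length(unique(f$name[f$trans_spliced])))
  pc <- f$name[f$category == "protein_coding" & full]
  data.frame(
    total_genes = nrow(f) - n_ts_extra,
    unique_protein_coding = length(unique(pc)),
    trna = length(unique(f$name[f$category == "tRNA" & full])),
    rrna = length(unique(f$name[f$category == "rRNA" & full])),
    intron_containing = sum(vapply(f$parts, nrow, 1L) > 1L & !f$trans_spliced),
    duplicated_in_ir = length(unique(f$name[full][duplicated(f$name[full])])),
    partial = sum(f$partial))
}

#' IR-reduced sequence
#'
#' Returns the genome with one inverted-repeat copy (IRb) removed, i.e.
#' `LSC + IRa + SSC` concatenated in circular order. Repeat and SSR censuses
#' are conventionally run on this reduced sequence to avoid double-counting
#' the IR.
#'
#' @param plastome An [annotated_plastome()].
#' @param partition A partition from [detect_quadripartite()].
#' @return A single DNA string.
#' @export
ir_reduced_seq <- function(plastome, partition) {
  paste0(substr_circular(plastome$seq, partition$lsc[1L], partition$lsc[2L]),
         substr_circular(plastome$seq, partition$ira[1L], partition$ira[2L]),
         substr_circular(plastome$seq, partition$ssc[1L], partition$ssc[2L]))
}
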