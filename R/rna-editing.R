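# C-to-U RNA-editing site calling from per-replicate pileups, with
# codon-change annotation under the plastid (bacterial) genetic code and
# physicochemical classification of amino-acid transitions.
#
# A C-to-U edit shows up in plus-strand RNA reads as T where the genome has
# C (plus-strand genes) or as A where the genome has G (minus-strand
# genes). The editing level in a replicate is
# edited / (edited + reference) * 100; reads supporting neither base
# (sequencing error) are excluded from the denominator.

#' Editing-site filter configuration
#'
#' @param min_coverage Minimum total read coverage in a replicate for that
#'   replicate to count as supporting (default 10).
#' @param min_replicates Minimum number of supporting replicates for a site
#'   to be called (default 2).
#' @param min_level Editing-level presence threshold in percent; a
#'   replicate supports a site when its level strictly exceeds this
#'   (default 0).
#' @return An `editing_filter_config` list.
#' @export
editing_filter_config <- function(min_coverage = 10L, min_replicates = 2L,
                                  min_level = 0) {
  stopifnot(min_coverage >= 1L, min_replicates >= 1L, min_level >= 0)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_replicates = as.integer(min_replicates),
                 min_level = min_level),
            class = "editing_filter_config")
}

#' Read per-replicate pileup tables
#'
#' @param paths Character vector of TSV files, each with columns
#'   `replicate`, `position`, `A`, `C`, `G`, `T` (plus-strand base counts
#'   from uniquely mapped reads). A single file may carry several
#'   replicates.
#' @return One combined data frame.
#' @export
read_pileups <- function(paths) {
  out <- do.call(rbind, lapply(paths, function(p) {
    df <- utils::read.delim(p, stringsAsFactors = FALSE)
    need <- c("replicate", "position", "A", "C", "G", "T")
    if (!all(need %in% names(df)))
      stop("pileup ", p, " lacks columns: ",
           paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
    df[need]
  }))
  if (any(out[c("A", "C", "G", "T")] < 0))
    stop("negative base count in pileup", call. = FALSE)
  out
}

# genomic position -> containing CDS feature index (first match), or NA
cds_feature_at <- function(plastome, position) {
  f <- plastome$features
  for (i in seq_len(nrow(f))) {
    if (f$category[i] != "protein_coding" || f$partial[i]) next
    p <- f$parts[[i]]
    if (any(p[, 1L] <= position & p[, 2L] >= position)) return(i)
  }
  NA_integer_
}

#' Call C-to-U RNA-editing sites
#'
#' A site is called when (a) the reference base is C on the strand of an
#' overlapping CDS, (b) the edited base (T on plus-strand genes, A on
#' minus-strand genes, in plus-strand pileup counts) is observed with level
#' above `cfg$min_level` in at least `cfg$min_replicates` replicates, each
#' with coverage of at least `cfg$min_coverage` at the site, and (c) the
#' editing level per replicate is `edited / (edited + reference) * 100`,
#' reported for all replicates including zeros. Positions outside annotated
#' CDS, or whose reference base is not C on the gene strand, are skipped and
#' listed in the `skipped` attribute.
#'
#' @param pileups A data frame from [read_pileups()] (columns `replicate`,
#'   `position`, `A`, `C`, `G`, `T`), covering at least two replicates.
#' @param plastome An [annotated_plastome()] with CDS annotations.
#' @param cfg An [editing_filter_config()].
#' @return A data frame with one row per called site: `gene`, `position`,
#'   `strand`, `codon_from`, `codon_to`, `codon_position`, `aa_from`,
#'   `aa_to`, `effect`, `physicochemical_change`, and one `level_<rep>`
#'   column per replicate; attribute `skipped` records skipped positions
#'   with reasons.
#' @export
call_editing_sites <- function(pileups, plastome,
                               cfg = editing_filter_config()) {
  stopifnot(is.data.frame(pileups),
            all(c("replicate", "position", "A", "C", "G", "T") %in%
                  names(pileups)))
  reps <- sort(unique(as.character(pileups$replicate)))
  if (length(reps) < 2L)
    stop("need pileups from >= 2 replicates", call. = FALSE)
  skipped <- list()
  rows <- list()
  for (pos in sort(unique(pileups$position))) {
    fi <- cds_feature_at(plastome, pos)
    if (is.na(fi)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(position = pos, reason = "not in CDS")
      next
    }
    strand <- plastome$features$strand[fi]
    refbase <- substr(plastome$seq, pos, pos)
    if ((strand == "+" && refbase != "C") ||
        (strand == "-" && refbase != "G")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(position = pos, reason = "reference not C on gene strand")
      next
    }
    ref_col <- if (strand == "+") "C" else "G"
    edit_col <- if (strand == "+") "T" else "A"
    sub <- pileups[pileups$position == pos, , drop = FALSE]
    lev <- cov <- setNames(numeric(length(reps)), reps)
    for (r in reps) {
      sr <- sub[as.character(sub$replicate) == r, , drop = FALSE]
      if (nrow(sr) == 0L) next
      edited <- sum(sr[[edit_col]])
      refn <- sum(sr[[ref_col]])
      cov[r] <- sum(sr$A, sr$C, sr$G, sr$T)
      lev[r] <- if (edited + refn > 0) 100 * edited / (edited + refn) else 0
    }
    supporting <- sum(lev > cfg$min_level & cov >= cfg$min_coverage)
    if (supporting < cfg$min_replicates) next
    ann <- annotate_codon_change(pos, plastome)
    phys <- classify_physicochemical(ann$aa_from, ann$aa_to)
    row <- data.frame(gene = ann$gene, position = pos, strand = strand,
                      codon_from = ann$codon_from, codon_to = ann$codon_to,
                      codon_position = ann$codon_position,
                      aa_from = ann$aa_from, aa_to = ann$aa_to,
                      effect = ann$effect,
                      physicochemical_change = phys$changed,
                      stringsAsFactors = FALSE)
    for (r in reps) row[[paste0("level_", r)]] <- unname(lev[r])
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    df <- data.frame(gene = character(), position = integer(),
                     strand = character(), codon_from = character(),
                     codon_to = character(), codon_position = integer(),
                     aa_from = character(), aa_to = character(),
                     effect = character(), physicochemical_change = logical(),
                     stringsAsFactors = FALSE)
    for (r in reps) df[[paste0("level_", r)]] <- numeric()
    df
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(position = integer(), reason = character())
  out
}

# spliced, strand-oriented CDS string and the CDS-coordinate of a genomic
# position; trans-spliced loci concatenate all their parts
spliced_cds <- function(plastome, fi) {
  f <- plastome$features
  if (f$trans_spliced[fi]) {
    idx <- which(f$name == f$name[fi] & f$trans_spliced &
                   f$copy_index == f$copy_index[fi])
  } else idx <- fi
  parts <- do.call(rbind, f$parts[idx])
  parts <- parts[order(parts[, 1L]), , drop = FALSE]
  strand <- f$strand[fi]
  segs <- vapply(seq_len(nrow(parts)), function(i)
    substr(plastome$seq, parts[i, 1L], parts[i, 2L]), "")
  cds <- paste(segs, collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  list(cds = cds, parts = parts, strand = strand, n_parts = nrow(parts))
}

cds_position_of <- function(sp, position) {
  # offset of the genomic position within the spliced plus-strand sequence
  off <- 0L
  hit <- NA_integer_
  for (i in seq_len(nrow(sp$parts))) {
    a <- sp$parts[i, 1L]; b <- sp$parts[i, 2L]
    if (position >= a && position <= b) { hit <- off + (position - a + 1L); break }
    off <- off + (b - a + 1L)
  }
  if (is.na(hit)) return(NA_integer_)
  hit <- as.integer(unname(hit))
  if (sp$strand == "+") hit else nchar(sp$cds) - hit + 1L
}

#' Annotate the codon change of a C-to-U edit
#'
#' Extracts the codon containing the position from the spliced,
#' strand-oriented CDS, replaces the edited position by U, and translates
#' both codons under the bacterial/plant-plastid genetic code.
#'
#' @param position 1-based genomic position of the edited C (C on the gene
#'   strand).
#' @param plastome An [annotated_plastome()].
#' @return A list with `gene`, `codon_from`, `codon_to` (RNA triplets),
#'   `codon_position` (1-3), `aa_from`, `aa_to` (one-letter, `*` for Stop),
#'   `effect` (`synonymous`, `nonsynonymous`, `stop_gained`, or
#'   `unresolved` for incomplete trans-spliced loci), and `start_codon`
#'   (flag for edits inside the annotated start codon).
#' @export
annotate_codon_change <- function(position, plastome) {
  fi <- cds_feature_at(plastome, position)
  if (is.na(fi)) stop("position ", position, " is not inside a CDS",
                      call. = FALSE)
  f <- plastome$features
  sp <- spliced_cds(plastome, fi)
  gene <- f$name[fi]
  if (f$trans_spliced[fi] && sp$n_parts < 3L)
    return(list(gene = gene, codon_from = NA_character_,
                codon_to = NA_character_, codon_position = NA_integer_,
                aa_from = NA_character_, aa_to = NA_character_,
                effect = "unresolved", start_codon = FALSE))
  if (nchar(sp$cds) %% 3L != 0L)
    stop("partial CDS: length of ", gene, " not divisible by 3",
         call. = FALSE)
  cpos <- cds_position_of(sp, position)
  base <- substr(sp$cds, cpos, cpos)
  if (base != "C")
    stop("position ", position, " is not a C on the ", gene, " strand",
         call. = FALSE)
  codon_idx <- (cpos - 1L) %/% 3L + 1L
  codon_position <- (cpos - 1L) %% 3L + 1L
  codon_dna <- substr(sp$cds, 3L * codon_idx - 2L, 3L * codon_idx)
  codon_to_dna <- codon_dna
  substr(codon_to_dna, codon_position, codon_position) <- "T"
  aa_from <- translate_codon(codon_dna)
  aa_to <- translate_codon(codon_to_dna)
  effect <- if (aa_to == "*" && aa_from != "*") "stop_gained"
            else if (aa_from == aa_to) "synonymous" else "nonsynonymous"
  list(gene = gene,
       codon_from = chartr("T", "U", codon_dna),
       codon_to = chartr("T", "U", codon_to_dna),
       codon_position = codon_position,
       aa_from = aa_from, aa_to = aa_to, effect = effect,
       start_codon = codon_idx == 1L)
}

PLASTID_CODE <- NULL  # populated on first use

translate_codon <- function(codon) {
  code <- getOption("plastomics.genetic_code")
  if (is.null(code)) {
    code <- as.list(Biostrings::getGeneticCode("11"))
    options(plastomics.genetic_code = code)
  }
  aa <- code[[codon]]
  if (is.null(aa)) stop("cannot translate codon ", codon, call. = FALSE)
  aa
}

#' Classify the physicochemical effect of an amino-acid transition
#'
#' Follows the study convention for C-to-U editing verbatim: transitions
#' crossing the hydrophilic/hydrophobic divide (`S->L`, `S->F`, `R->C`) are
#' `changed`; `A->V`, `H->Y`, `L->F`, `P->F`, `P->L`, `P->S`, `R->W`,
#' `T->I`, `T->M` are `unchanged`; identity transitions are unchanged;
#' transitions involving Stop are flagged separately as category `"stop"`.
#' The convention is followed as enumerated, without extrapolation
#' (transitions outside the table return `NA` with category `"unlisted"`);
#' note that it internally classifies `R->W` as no-change although
#' tryptophan is canonically hydrophobic.
#'
#' @param aa_from,aa_to One-letter amino-acid codes (or `"*"` for Stop).
#' @return A list with `changed` (logical, `NA` when unlisted or stop),
#'   `category` (`"hydrophilic_to_hydrophobic"`, `"no_change"`,
#'   `"identity"`, `"stop"`, `"unlisted"`).
#' @export
classify_physicochemical <- function(aa_from, aa_to) {
  valid <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "*")
  if (is.na(aa_from) || is.na(aa_to) ||
      !aa_from %in% valid || !aa_to %in% valid)
    stop("unknown residue: ", aa_from, " or ", aa_to, call. = FALSE)
  if (aa_from == "*" || aa_to == "*")
    return(list(changed = NA, category = "stop"))
  if (aa_from == aa_to)
    return(list(changed = FALSE, category = "identity"))
  key <- paste0(aa_from, aa_to)
  changed_set <- c("SL", "SF", "RC")
  unchanged_set <- c("AV", "HY", "LF", "PF", "PL", "PS", "RW", "TI", "TM")
  if (key %in% changed_set)
    list(changed = TRUE, category = "hydrophilic_to_hydrophobic")
  else if (key %in% unchanged_set)
    list(changed = FALSE, category = "no_change")
  else list(changed = NA, category = "unlisted")
}

#' Amino-acid transition spectrum of editing sites
#'
#' @param sites A data frame of editing sites (from [call_editing_sites()]
#'   or an annotated table with `aa_from`, `aa_to`, `effect`).
#' @return A list with `transitions` (data frame `aa_from`, `aa_to`, `n`,
#'   nonsynonymous changes only, sorted by count), and `totals` (counts of
#'   synonymous, nonsynonymous, stop_gained sites).
#' @export
transition_spectrum <- function(sites) {
  if (nrow(sites) == 0L)
    return(list(transitions = data.frame(aa_from = character(),
                                         aa_to = character(), n = integer()),
                totals = c(synonymous = 0L, nonsynonymous = 0L,
                           stop_gained = 0L)))
  totals <- c(synonymous = sum(sites$effect == "synonymous"),
              nonsynonymous = sum(sites$effect == "nonsynonymous"),
              stop_gained = sum(sites$effect == "stop_gained"))
  ns <- sites[sites$effect == "nonsynonymous", , drop = FALSE]
  if (nrow(ns)) {
    tab <- stats::aggregate(list(n = seq_len(nrow(ns))),
                            by = list(aa_from = ns$aa_from, aa_to = ns$aa_to),
                            FUN = length)
    tab <- tab[order(-tab$n, tab$aa_from, tab$aa_to), , drop = FALSE]
    rownames(tab) <- NULL
  } else tab <- data.frame(aa_from = character(), aa_to = character(),
                           n = integer())
  list(transitions = tab, totals = totals)
}

#' Reclassify a printed editing-site table from its codons
#'
#' Recomputes `codon_to`, the amino-acid pair and the synonymous /
#' nonsynonymous call of each row of an editing-site table from its printed
#' `codon_from` and `codon_position` (C-to-U on the codon), and compares
#' them with the printed values where present. Rows whose printed amino
#' acids disagree with what their codons encode are reported in
#' `inconsistencies`, not silently reproduced.
#'
#' @param tab Data frame with columns `codon_from`, `codon_to`,
#'   `codon_position`, and optionally `aa_from`, `aa_to` (printed values;
#'   `"Synonym"` convention supported: both NA with `effect` synonymous).
#' @return A list: `table` (input with recomputed `aa_from_calc`,
#'   `aa_to_calc`, `codon_to_calc`, `effect_calc` columns),
#'   `inconsistencies` (rows where printed and computed annotations
#'   disagree), `totals` (computed synonymous/nonsynonymous counts).
#' @export
reclassify_codon_table <- function(tab) {
  stopifnot(all(c("codon_from", "codon_position") %in% names(tab)))
  n <- nrow(tab)
  res <- tab
  res$codon_to_calc <- res$aa_from_calc <- res$aa_to_calc <-
    res$effect_calc <- NA_character_
  for (i in seq_len(n)) {
    codon <- chartr("U", "T", tab$codon_from[i])
    cp <- tab$codon_position[i]
    if (substr(codon, cp, cp) != "C")
      stop("row ", i, ": codon ", tab$codon_from[i], " has no C at position ",
           cp, call. = FALSE)
    to <- codon
    substr(to, cp, cp) <- "T"
    af <- translate_codon(codon)
    at <- translate_codon(to)
    res$codon_to_calc[i] <- chartr("T", "U", to)
    res$aa_from_calc[i] <- af
    res$aa_to_calc[i] <- at
    res$effect_calc[i] <- if (at == "*" && af != "*") "stop_gained"
                          else if (af == at) "synonymous" else "nonsynonymous"
  }
  bad <- rep(FALSE, n)
  if (all(c("aa_from", "aa_to") %in% names(tab))) {
    printed <- !is.na(tab$aa_from) & !is.na(tab$aa_to)
    bad <- printed & (tab$aa_from != res$aa_from_calc |
                        tab$aa_to != res$aa_to_calc)
  }
  if ("codon_to" %in% names(tab))
    bad <- bad | chartr("U", "T", tab$codon_to) !=
      chartr("U", "T", res$codon_to_calc)
  list(table = res,
       inconsistencies = res[bad, , drop = FALSE],
       totals = c(synonymous = sum(res$effect_calc == "synonymous"),
                  nonsynonymous = sum(res$effect_calc == "nonsynonymous"),
                  stop_gained = sum(res$effect_calc == "stop_gained")))
}
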