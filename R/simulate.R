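# Seeded generator of synthetic plastome trios, alignments, RNA-Seq pileups
# and count matrices with planted ground truth, so that every pipeline stage
# is testable without downloads.
#
# The default configuration mirrors the study design it emulates: three
# haplotypes ("purple", "white", "yellow") with RNA-Seq replicates 3/3/2, a
# circular quadripartite genome with IR-duplicated genes, a petN/psbM-style
# invertible gene pair carried by the third haplotype, SNP divergence with
# localized hotspots, planted SSR/long-repeat motifs, C-to-U editing sites
# at Table-2-like levels, and negative-binomial counts. Genome region
# lengths default to a scaled-down plastome (20/6/6 kb LSC/IR/SSC) so the
# full pipeline runs in seconds; paper-scale lengths are a config change.

#' Simulation configuration
#'
#' @param seed Integer seed; all generator functions are deterministic given
#'   the seed.
#' @param lsc_len,ir_len,ssc_len Region lengths in bp.
#' @param haplotypes Haplotype names; the first is the reference.
#' @param background_rate Per-site substitution probability between the
#'   reference and each derived haplotype outside hotspots.
#' @param hotspot_rate Elevated per-site substitution probability inside
#'   hotspot intervals.
#' @param hotspots List of `c(start, end)` absolute intervals (defaults to
#'   three 500-bp windows, two in the LSC and one in the SSC).
#' @param inversion Plant the two-gene (psbM/petN) inversion in the last
#'   haplotype?
#' @param ssr_plantings Data frame `motif`, `copies`, `offset` (offset into
#'   the LSC planting zone).
#' @param repeat_plantings Data frame `kind`, `length`, `mismatches`.
#' @param editing_plantings Data frame `gene`, `level` (percent),
#'   `coverage` (reads per replicate); optional `present_in`
#'   (comma-separated replicate indices carrying the edit, default all).
#' @param error_rate Per-read sequencing error probability at background
#'   pileup positions (errors fall uniformly on the three other bases).
#' @param n_background Number of non-edited C-context CDS positions emitted
#'   in pileups (candidate false-positive sites when `error_rate > 0`).
#' @param replicates Named integer vector of RNA-Seq replicates per
#'   haplotype (default `c(3, 3, 2)`).
#' @param dispersion Negative-binomial dispersion for counts (0 = Poisson).
#' @param lib_multipliers Optional per-sample library-size multipliers.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       lsc_len = 20000L, ir_len = 6000L, ssc_len = 6000L,
                       haplotypes = c("purple", "white", "yellow"),
                       background_rate = 0.001, hotspot_rate = 0.05,
                       hotspots = NULL,
                       inversion = TRUE,
                       ssr_plantings = default_ssr_plantings(),
                       repeat_plantings = default_repeat_plantings(),
                       editing_plantings = default_editing_plantings(),
                       error_rate = 0, n_background = 0L,
                       replicates = c(purple = 3L, white = 3L, yellow = 2L),
                       dispersion = 0.05, lib_multipliers = NULL) {
  stopifnot(lsc_len >= 16000L, ir_len >= 6000L, ssc_len >= 6000L,
            length(haplotypes) >= 2L,
            background_rate >= 0, background_rate <= 1,
            hotspot_rate >= 0, hotspot_rate <= 1,
            error_rate >= 0, error_rate < 1)
  if (is.null(hotspots)) {
    # aligned to the default 500-bp window grid: one window each
    ssc_start <- lsc_len + ir_len
    hotspots <- list(c(4501L, 5000L), c(9501L, 10000L),
                     ssc_start + c(501L, 1000L))
  }
  structure(list(seed = as.integer(seed), lsc_len = as.integer(lsc_len),
                 ir_len = as.integer(ir_len), ssc_len = as.integer(ssc_len),
                 haplotypes = haplotypes,
                 background_rate = background_rate,
                 hotspot_rate = hotspot_rate, hotspots = hotspots,
                 inversion = isTRUE(inversion),
                 ssr_plantings = ssr_plantings,
                 repeat_plantings = repeat_plantings,
                 editing_plantings = editing_plantings,
                 error_rate = error_rate,
                 n_background = as.integer(n_background),
                 replicates = replicates, dispersion = dispersion,
                 lib_multipliers = lib_multipliers),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_ssr_plantings <- function() {
  data.frame(motif = c("A", "AT", "AAG", "ACCT", "AATAG", "AATGCC"),
             copies = c(12L, 6L, 5L, 4L, 3L, 3L),
             offset = c(0L, 400L, 800L, 1200L, 1600L, 2000L),
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_repeat_plantings <- function() {
  data.frame(kind = c("forward", "palindromic", "reverse", "complement"),
             length = c(40L, 40L, 34L, 34L),
             mismatches = c(0L, 1L, 0L, 0L),
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_editing_plantings <- function() {
  data.frame(gene = c("psbA", "rbcL", "petB", "rps14", "ndhD", "ndhB"),
             level = c(95, 100, 97, 70, 50, 85),
             coverage = c(30L, 25L, 40L, 20L, 30L, 15L),
             stringsAsFactors = FALSE)
}

# fixed synthetic gene complement: (name, category, strand, region,
# offset within region, exon lengths, flags). All 11 ndh genes present;
# ndhB and rRNA/tRNA genes duplicated through the IR; atpF intron; rps12
# trans-spliced with exon 1 in the LSC and exons 2+3 in the IR.
synthetic_gene_models <- function() {
  g <- function(name, cat, strand, region, offset, exons, gaps = integer(0),
                partial = FALSE, ts = FALSE)
    list(name = name, cat = cat, strand = strand, region = region,
         offset = offset, exons = exons, gaps = gaps, partial = partial,
         ts = ts)
  list(
    g("trnH",  "tRNA",           "+", "lsc", 100L, 74L),
    g("psbA",  "protein_coding", "+", "lsc", 250L, 1062L),
    g("rps16", "protein_coding", "-", "lsc", 1500L, c(240L, 300L), 800L),
    g("atpF",  "protein_coding", "-", "lsc", 3600L, c(555L, 411L), 700L),
    g("rps14", "protein_coding", "-", "lsc", 5600L, 303L),
    g("psbM",  "protein_coding", "+", "lsc", 6100L, 105L),
    g("petN",  "protein_coding", "+", "lsc", 6500L, 90L),
    g("petB",  "protein_coding", "+", "lsc", 6900L, 648L),
    g("rbcL",  "protein_coding", "+", "lsc", 7800L, 1428L),
    g("ndhC",  "protein_coding", "-", "lsc", 10000L, 363L),
    g("ndhK",  "protein_coding", "-", "lsc", 10500L, 678L),
    g("ndhJ",  "protein_coding", "-", "lsc", 11300L, 477L),
    g("rps12", "protein_coding", "-", "lsc", 11900L, 114L, ts = TRUE),
    g("psbB",  "protein_coding", "+", "lsc", 12100L, 1527L),
    # IRa
    g("rps12", "protein_coding", "-", "ira", 300L, 232L, ts = TRUE),
    g("rps12", "protein_coding", "-", "ira", 700L, 26L, ts = TRUE),
    g("ndhB",  "protein_coding", "-", "ira", 1000L, c(777L, 756L), 700L),
    g("rps7",  "protein_coding", "+", "ira", 3500L, 468L),
    g("trnV",  "tRNA",           "-", "ira", 4150L, 72L),
    g("rrn16", "rRNA",           "+", "ira", 4350L, 1490L),
    g("ycf15", "pseudogene",     "+", "ira", 5870L, 120L, partial = TRUE),
    # SSC
    g("ndhF",  "protein_coding", "-", "ssc", 100L, 930L),
    g("rpl32", "protein_coding", "+", "ssc", 1100L, 171L),
    g("ccsA",  "protein_coding", "+", "ssc", 1320L, 966L),
    g("ndhD",  "protein_coding", "-", "ssc", 2350L, 501L),
    g("psaC",  "protein_coding", "-", "ssc", 2900L, 246L),
    g("ndhE",  "protein_coding", "-", "ssc", 3180L, 306L),
    g("ndhG",  "protein_coding", "-", "ssc", 3520L, 300L),
    g("ndhI",  "protein_coding", "-", "ssc", 3860L, 330L),
    g("ndhA",  "protein_coding", "-", "ssc", 4230L, c(540L, 552L), 330L),
    g("ndhH",  "protein_coding", "-", "ssc", 5680L, 300L))
}

rand_bases <- function(n) sample(DNA_BASES, n, replace = TRUE)

# mutate accidental SSRs (outside protected intervals) until the sequence
# is SSR-free except for the plantings; IR symmetry is restored after each
# pass. `protected` is a 2-col matrix of intervals to leave untouched.
repair_ssrs <- function(chars, protected, lsc_len, ir_len, ssc_len,
                        min_copies = c(7L, 4L, 4L, 3L, 3L, 3L)) {
  n <- length(chars)
  ira_start <- lsc_len + 1L
  irb_start <- lsc_len + ir_len + ssc_len + 1L
  is_protected <- function(a, b) {
    nrow(protected) > 0L && any(protected[, 1L] <= b & protected[, 2L] >= a)
  }
  for (iter in 1:25) {
    ss <- find_ssrs(paste(chars, collapse = ""), min_copies)
    dirty <- FALSE
    for (i in seq_len(nrow(ss))) {
      if (is_protected(ss$start[i], ss$end[i])) next
      dirty <- TRUE
      mid <- ss$start[i] + (ss$end[i] - ss$start[i]) %/% 2L
      # map a hit inside IRb back to its IRa mirror so symmetry survives
      if (mid >= irb_start) {
        off <- mid - irb_start           # 0-based offset in IRb
        mid <- ira_start + (ir_len - 1L - off)
        repl <- setdiff(DNA_BASES, chars[mid])
      } else repl <- setdiff(DNA_BASES, chars[mid])
      chars[mid] <- repl[(iter + mid) %% length(repl) + 1L]
    }
    # restore IR mirror
    ira <- chars[ira_start:(ira_start + ir_len - 1L)]
    chars[irb_start:(irb_start + ir_len - 1L)] <-
      rev(chartr("ACGT", "TGCA", paste(ira, collapse = "")) |>
            strsplit("") |> unlist())
    if (!dirty) break
  }
  chars
}

#' Simulate a set of related plastomes with planted ground truth
#'
#' Builds a circular quadripartite reference (background i.i.d. uniform
#' bases, repaired to be free of accidental SSRs above the census
#' thresholds), annotates the synthetic gene complement, plants SSR and
#' long-repeat motifs in a reserved LSC zone, then derives the remaining
#' haplotypes by random substitutions (elevated rate inside hotspot
#' intervals; planted motifs and the IRb mirror are kept intact) and, if
#' configured, reverse-complements the psbM-petN block of the last
#' haplotype. Identical seeds give identical output.
#'
#' @param cfg A [sim_config()].
#' @return A list with `plastomes` (named list of [annotated_plastome()]),
#'   `alignment` (gap-free [multiple_alignment()] of the haplotypes) and
#'   `truth` (planted SSRs, repeats, inversion block, hotspot intervals,
#'   substitution positions per haplotype, region lengths).
#' @export
simulate_plastome_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_plastome_set_impl(cfg))
}

simulate_plastome_set_impl <- function(cfg) {
  l1 <- cfg$lsc_len; li <- cfg$ir_len; l2 <- cfg$ssc_len
  n <- l1 + 2L * li + l2
  ira_start <- l1 + 1L
  ssc_start <- l1 + li + 1L
  irb_start <- l1 + li + l2 + 1L
  chars <- rand_bases(l1 + li + l2)
  # pin the single-copy junction bases: an A next to the IR can never
  # extend the exact reverse-complement arm (its mirror would need a T),
  # so the detected partition equals the planted one exactly
  junctions <- c(1L, l1, l1 + li + 1L, l1 + li + l2)
  chars[junctions] <- "A"

  # --- features -------------------------------------------------------
  region_base <- c(lsc = 0L, ira = l1, ssc = l1 + li)
  feats <- list()
  gene_iv <- matrix(integer(0), 0, 2)
  for (gm in synthetic_gene_models()) {
    starts <- region_base[[gm$region]] + gm$offset +
      cumsum(c(0L, head(gm$exons, -1L) + gm$gaps))
    parts <- cbind(starts, starts + gm$exons - 1L)
    feats[[length(feats) + 1L]] <- gene_feature(
      gm$name, gm$cat, gm$strand, parts, copy_index = 1L,
      partial = gm$partial, trans_spliced = gm$ts)
    gene_iv <- rbind(gene_iv, parts)
  }
  # mirror IRa features into IRb (flipped strand, copy_index 2)
  mirror <- function(iv) cbind(irb_start + (li - 1L) - (iv[, 2L] - ira_start),
                               irb_start + (li - 1L) - (iv[, 1L] - ira_start))
  for (gm in synthetic_gene_models()) {
    if (gm$region != "ira") next
    starts <- region_base[["ira"]] + gm$offset +
      cumsum(c(0L, head(gm$exons, -1L) + gm$gaps))
    parts <- cbind(starts, starts + gm$exons - 1L)
    mp <- mirror(parts)
    mp <- mp[order(mp[, 1L]), , drop = FALSE]
    feats[[length(feats) + 1L]] <- gene_feature(
      gm$name, gm$cat, if (gm$strand == "+") "-" else "+", mp,
      copy_index = 2L, partial = gm$partial, trans_spliced = gm$ts)
    gene_iv <- rbind(gene_iv, mp)
  }
  features <- do.call(gene_features, feats)

  # --- plantings (reserved LSC zone after the last LSC gene) ----------
  zone_start <- 14000L
  planted <- cbind(junctions, junctions)   # protected from repair/mutation
  truth_ssr <- list()
  sp <- cfg$ssr_plantings
  for (i in seq_len(nrow(sp))) {
    u <- nchar(sp$motif[i])
    start <- zone_start + sp$offset[i]
    len <- u * sp$copies[i]
    iv <- c(start, start + len - 1L)
    if (iv[2L] > l1 - 100L) stop("SSR planting outside the LSC zone",
                                 call. = FALSE)
    if (nrow(planted) && any(planted[, 1L] <= iv[2L] + 1L &
                             planted[, 2L] >= iv[1L] - 1L))
      stop("plantings overlap", call. = FALSE)
    chars[iv[1L]:iv[2L]] <- strsplit(strrep(sp$motif[i], sp$copies[i]),
                                     "")[[1L]]
    # pin the flanks so the planted run is maximal exactly as configured
    last <- substr(sp$motif[i], u, u); first <- substr(sp$motif[i], 1L, 1L)
    chars[iv[1L] - 1L] <- setdiff(DNA_BASES, last)[1L]
    chars[iv[2L] + 1L] <- setdiff(DNA_BASES, first)[1L]
    planted <- rbind(planted, iv + c(-1L, 1L))
    truth_ssr[[i]] <- data.frame(motif = sp$motif[i], unit_len = u,
                                 copies = sp$copies[i], start = iv[1L],
                                 end = iv[2L], stringsAsFactors = FALSE)
  }
  rp <- cfg$repeat_plantings
  truth_rep <- list()
  rep_zone <- zone_start + 2600L
  for (i in seq_len(nrow(rp))) {
    len <- rp$length[i]
    a1 <- rep_zone; a2 <- rep_zone + len + 260L
    rep_zone <- a2 + len + 260L
    if (a2 + len > l1 - 100L) stop("repeat planting outside the LSC zone",
                                   call. = FALSE)
    arm <- rand_bases(len)
    arm2 <- switch(rp$kind[i],
      forward = arm,
      reverse = rev(arm),
      complement = chartr("ACGT", "TGCA", arm),
      palindromic = rev(chartr("ACGT", "TGCA", arm)))
    if (rp$mismatches[i] > 0L) {
      # centred so that no exact segment reaches the 30-bp minimum and the
      # finder reports the full planted window at the planted distance
      at <- round(len * seq_len(rp$mismatches[i]) / (rp$mismatches[i] + 1L))
      for (p in at) arm2[p] <- setdiff(DNA_BASES, arm2[p])[1L]
    }
    chars[a1:(a1 + len - 1L)] <- arm
    chars[a2:(a2 + len - 1L)] <- arm2
    # pin the four flanking bases so no kind's pairing extends by chance
    chars[a1 - 1L] <- "A"; chars[a1 + len] <- "A"
    chars[a2 - 1L] <- "C"; chars[a2 + len] <- "C"
    planted <- rbind(planted, c(a1 - 1L, a1 + len), c(a2 - 1L, a2 + len))
    truth_rep[[i]] <- data.frame(kind = rp$kind[i], start1 = a1,
                                 end1 = a1 + len - 1L, start2 = a2,
                                 end2 = a2 + len - 1L, length = len,
                                 mismatches = rp$mismatches[i],
                                 stringsAsFactors = FALSE)
  }

  # --- assemble circular genome, repair accidental SSRs ---------------
  ira <- chars[ira_start:(ira_start + li - 1L)]
  chars <- c(chars, rev(strsplit(chartr("ACGT", "TGCA",
                                        paste(ira, collapse = "")),
                                 "")[[1L]]))
  chars <- repair_ssrs(chars, planted, l1, li, l2)
  ref_seq <- paste(chars, collapse = "")

  # --- derived haplotypes ---------------------------------------------
  hot <- rep(FALSE, n)
  for (iv in cfg$hotspots) hot[iv[1L]:iv[2L]] <- TRUE
  eligible <- rep(TRUE, l1 + li + l2)   # mutate LSC+IRa+SSC, mirror IRb
  for (i in seq_len(nrow(planted)))
    eligible[planted[i, 1L]:planted[i, 2L]] <- FALSE
  rate <- ifelse(hot[seq_len(l1 + li + l2)], cfg$hotspot_rate,
                 cfg$background_rate)
  haps <- list()
  haps[[cfg$haplotypes[1L]]] <- ref_seq
  subs <- list()
  for (h in cfg$haplotypes[-1L]) {
    hc <- strsplit(ref_seq, "")[[1L]]
    mut <- which(eligible & runif(l1 + li + l2) < rate)
    for (p in mut) hc[p] <- sample(setdiff(DNA_BASES, hc[p]), 1L)
    ira_h <- hc[ira_start:(ira_start + li - 1L)]
    hc[irb_start:(irb_start + li - 1L)] <-
      rev(strsplit(chartr("ACGT", "TGCA", paste(ira_h, collapse = "")),
                   "")[[1L]])
    subs[[h]] <- mut
    haps[[h]] <- paste(hc, collapse = "")
  }

  # --- inversion in the last haplotype --------------------------------
  inv_truth <- NULL
  feat_by_hap <- stats::setNames(rep(list(features), length(cfg$haplotypes)),
                                 cfg$haplotypes)
  if (cfg$inversion && length(cfg$haplotypes) >= 2L) {
    target <- cfg$haplotypes[length(cfg$haplotypes)]
    fb <- features
    spans <- t(vapply(fb$parts, feature_span, integer(2L)))
    bi <- which(fb$name %in% c("psbM", "petN"))
    bs <- min(spans[bi, 1L]) - 20L
    be <- max(spans[bi, 2L]) + 20L
    hs <- haps[[target]]
    haps[[target]] <- paste0(substr(hs, 1L, bs - 1L),
                             revcomp(substr(hs, bs, be)),
                             substr(hs, be + 1L, n))
    for (i in bi) {
      p <- fb$parts[[i]]
      np <- cbind(bs + (be - p[, 2L]), bs + (be - p[, 1L]))
      np <- np[order(np[, 1L]), , drop = FALSE]
      dimnames(np) <- list(NULL, c("start", "end"))
      fb$parts[[i]] <- np
      fb$strand[i] <- if (fb$strand[i] == "+") "-" else "+"
    }
    fb <- fb[order(vapply(fb$parts, function(p) min(p[, 1L]), 1L)), ,
             drop = FALSE]
    rownames(fb) <- NULL
    feat_by_hap[[target]] <- fb
    inv_truth <- list(haplotype = target, block = c(bs, be),
                      genes = sort(unique(fb$name[bi])))
  }

  plastomes <- lapply(cfg$haplotypes, function(h)
    annotated_plastome(h, haps[[h]], feat_by_hap[[h]]))
  names(plastomes) <- cfg$haplotypes
  aln <- multiple_alignment(unlist(haps[cfg$haplotypes]),
                            names = cfg$haplotypes)
  truth <- list(
    region_lengths = c(lsc = l1, ira = li, ssc = l2, irb = li),
    ssrs = do.call(rbind, truth_ssr),
    repeats = do.call(rbind, truth_rep),
    hotspots = cfg$hotspots,
    substitutions = subs,
    inversion = inv_truth)
  list(plastomes = plastomes, alignment = aln, truth = truth)
}

# genomic position of a spliced-CDS coordinate (inverse of
# cds_position_of)
genomic_position_of <- function(sp, cds_pos) {
  if (sp$strand == "-") cds_pos <- nchar(sp$cds) - cds_pos + 1L
  off <- 0L
  for (i in seq_len(nrow(sp$parts))) {
    w <- sp$parts[i, 2L] - sp$parts[i, 1L] + 1L
    if (cds_pos <= off + w) return(unname(sp$parts[i, 1L] + (cds_pos - off - 1L)))
    off <- off + w
  }
  NA_integer_
}

# first editable C (codon position 2, beyond the start codon) of a gene
find_editable_site <- function(plastome, gene) {
  f <- plastome$features
  fi <- which(f$name == gene & f$category == "protein_coding" &
                f$copy_index == 1L)[1L]
  if (is.na(fi)) stop("no CDS named ", gene, call. = FALSE)
  sp <- spliced_cds(plastome, fi)
  bases <- strsplit(sp$cds, "")[[1L]]
  cand <- which(bases == "C" & (seq_along(bases) - 1L) %% 3L == 1L)
  cand <- cand[cand > 3L]
  if (!length(cand)) stop("no editable C in ", gene, call. = FALSE)
  pos <- genomic_position_of(sp, cand[1L])
  list(position = pos, strand = sp$strand)
}

#' Simulate per-replicate RNA-Seq pileups with planted C-to-U edits
#'
#' For each planted site, edited-read counts are drawn
#' `Binomial(coverage, level/100)` per carrying replicate; the remainder are
#' reference reads. Optionally, `cfg$n_background` non-edited C-context CDS
#' positions are emitted with sequencing errors at `cfg$error_rate` (errors
#' uniform over the three non-reference bases), providing candidate false
#' positives for filter calibration. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param plastome An [annotated_plastome()] from
#'   [simulate_plastome_set()].
#' @param n_replicates Number of biological replicates (default from
#'   `cfg$replicates` for the plastome's haplotype, else 3).
#' @return A list with `pileups` (data frame `replicate`, `position`, `A`,
#'   `C`, `G`, `T`) and `truth` (planted sites with gene, position, strand,
#'   level, coverage, carrying replicates).
#' @export
simulate_pileups <- function(cfg, plastome, n_replicates = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(n_replicates)) {
    n_replicates <- cfg$replicates[plastome$id]
    if (is.na(n_replicates)) n_replicates <- 3L
  }
  with_seed(cfg$seed + 1000L,
            simulate_pileups_impl(cfg, plastome, as.integer(n_replicates)))
}

simulate_pileups_impl <- function(cfg, plastome, n_replicates) {
  ep <- cfg$editing_plantings
  reps <- paste0("R", seq_len(n_replicates))
  rows <- list()
  truth <- list()
  used <- integer(0)
  for (i in seq_len(nrow(ep))) {
    site <- find_editable_site(plastome, ep$gene[i])
    refbase <- substr(plastome$seq, site$position, site$position)
    if ((site$strand == "+" && refbase != "C") ||
        (site$strand == "-" && refbase != "G"))
      stop("planting at non-C reference in ", ep$gene[i], call. = FALSE)
    carrying <- if (!is.null(ep$present_in) && !is.na(ep$present_in[i]) &&
                    nzchar(ep$present_in[i]))
      as.integer(strsplit(ep$present_in[i], ",")[[1L]])
    else seq_len(n_replicates)
    used <- c(used, site$position)
    lv <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      cov <- ep$coverage[i]
      edited <- if (r %in% carrying) rbinom(1L, cov, ep$level[i] / 100) else 0L
      cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      if (site$strand == "+") {
        cnt["T"] <- edited; cnt["C"] <- cov - edited
      } else {
        cnt["A"] <- edited; cnt["G"] <- cov - edited
      }
      lv[r] <- 100 * edited / cov
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = reps[r], position = site$position,
        A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
        stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(gene = ep$gene[i], position = site$position,
                             strand = site$strand, level = ep$level[i],
                             coverage = ep$coverage[i],
                             present_in = paste(carrying, collapse = ","),
                             stringsAsFactors = FALSE)
    truth[[i]][paste0("drawn_level_", reps)] <- as.list(lv)
  }
  if (cfg$n_background > 0L) {
    cand <- background_c_positions(plastome, exclude = used)
    take <- cand[seq_len(min(cfg$n_background, nrow(cand))), , drop = FALSE]
    for (j in seq_len(nrow(take))) {
      ref_col <- if (take$strand[j] == "+") "C" else "G"
      others <- setdiff(c("A", "C", "G", "T"), ref_col)
      for (r in seq_len(n_replicates)) {
        cov <- 20L
        err <- rbinom(1L, cov, cfg$error_rate)
        cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L)
        cnt[ref_col] <- cov - err
        if (err > 0L) {
          alloc <- table(sample(others, err, replace = TRUE))
          cnt[names(alloc)] <- cnt[names(alloc)] + as.integer(alloc)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = reps[r], position = take$position[j],
          A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  pel <- do.call(rbind, rows)
  pel <- pel[order(pel$position, pel$replicate), , drop = FALSE]
  rownames(pel) <- NULL
  list(pileups = pel, truth = do.call(rbind, truth))
}

# sample of non-edited C-context CDS positions (C on the gene strand)
background_c_positions <- function(plastome, exclude = integer(0)) {
  f <- plastome$features
  out <- list()
  for (i in which(f$category == "protein_coding" & !f$partial &
                    f$copy_index == 1L & !f$trans_spliced)) {
    p <- f$parts[[i]]
    want <- if (f$strand[i] == "+") "C" else "G"
    for (r in seq_len(nrow(p))) {
      seg <- strsplit(substr(plastome$seq, p[r, 1L], p[r, 2L]), "")[[1L]]
      hits <- p[r, 1L] + which(seg == want) - 1L
      hits <- setdiff(hits, exclude)
      if (length(hits))
        out[[length(out) + 1L]] <- data.frame(position = hits,
                                              strand = f$strand[i])
    }
  }
  res <- do.call(rbind, out)
  res[sample.int(nrow(res)), , drop = FALSE]
}

#' Simulate a per-gene count matrix with replicate structure
#'
#' Per-gene baseline means are log-normal with strongly expressed
#' photosystem/rubisco genes; a third of the genes carry group-specific
#' fold-changes so the haplotype groups have distinct expression profiles.
#' Counts are negative binomial (`cfg$dispersion > 0`) or Poisson, with
#' optional per-sample library-size multipliers. IR-duplicated genes are
#' separate `_1`/`_2` rows and the trans-spliced rps12 contributes three
#' rows. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` (a [count_matrix()]) and `truth` (expected
#'   means per gene and group, multipliers, dispersion).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 2000L, simulate_counts_impl(cfg))
}

simulate_counts_impl <- function(cfg) {
  gm <- synthetic_gene_models()
  pc <- Filter(function(g) g$cat == "protein_coding", gm)
  nm <- vapply(pc, `[[`, "", "name")
  genes <- character(0)
  for (g in pc) {
    if (g$ts) next
    genes <- c(genes,
               if (g$region == "ira") paste0(g$name, c("_1", "_2")) else g$name)
  }
  genes <- c(genes, "rps12", "rps12_2", "rps12_3")
  genes <- unique(genes)
  ng <- length(genes)
  groups <- rep(names(cfg$replicates), cfg$replicates)
  samples <- unlist(lapply(names(cfg$replicates), function(h)
    paste0(h, "_", seq_len(cfg$replicates[[h]]))))
  base_mean <- stats::rlnorm(ng, meanlog = log(500), sdlog = 1)
  hi <- grepl("^(psbA|rbcL|psaA|psbB|psbC|psbD)", genes)
  base_mean[hi] <- base_mean[hi] * 20
  mu <- matrix(rep(base_mean, length(unique(groups))), ng,
               dimnames = list(genes, unique(groups)))
  de <- seq_len(ng) %% 3L == 0L    # group-specific profile genes
  for (g in unique(groups))
    mu[de, g] <- mu[de, g] * stats::rlnorm(sum(de), 0, 0.6)
  mult <- cfg$lib_multipliers
  if (is.null(mult)) mult <- rep(1, length(samples))
  stopifnot(length(mult) == length(samples))
  counts <- matrix(0L, ng, length(samples),
                   dimnames = list(genes, samples))
  for (s in seq_along(samples)) {
    m <- mu[, groups[s]] * mult[s]
    counts[, s] <- if (cfg$dispersion > 0)
      rnbinom(ng, mu = m, size = 1 / cfg$dispersion)
    else rpois(ng, m)
  }
  list(counts = count_matrix(counts, groups),
       truth = list(group_means = mu, multipliers = setNames(mult, samples),
                    dispersion = cfg$dispersion, de_genes = genes[de]))
}
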