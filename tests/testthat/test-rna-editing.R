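# C-to-U editing-site calling, codon annotation and physicochemical
# classification.

# toy genome: a plus-strand gene (ATG CCA GCC CAA TAA at 11..25) and a
# minus-strand gene whose mRNA reads ATG TCA CGG TAA (at 41..52 on the
# minus strand), plus intergenic padding
toy_editing_genome <- function() {
  plus_cds <- "ATGCCAGCCCAATAA"
  minus_mrna <- "ATGTCACGGTAA"
  seq <- paste0(strrep("G", 10), plus_cds, strrep("A", 15),
                rc(minus_mrna), strrep("G", 10))
  annotated_plastome("toy", seq, gene_features(
    gene_feature("petB", "protein_coding", "+", c(11, 25)),
    gene_feature("rps14", "protein_coding", "-", c(41, 52))))
}

pileup_row <- function(rep, pos, A = 0, C = 0, G = 0, T = 0)
  data.frame(replicate = rep, position = pos, A = A, C = C, G = G, T = T)

test_that("editing levels and replicate/coverage filters follow the contract", {
  g <- toy_editing_genome()
  # plus-strand C at 15 (CCA codon position 2): T=24/cov25, T=30/30, T=0/20
  pil <- rbind(pileup_row("R1", 15, C = 1, T = 24),
               pileup_row("R2", 15, T = 30),
               pileup_row("R3", 15, C = 20))
  sites <- call_editing_sites(pil, g)
  expect_identical(nrow(sites), 1L)
  expect_equal(c(sites$level_R1, sites$level_R2, sites$level_R3),
               c(96, 100, 0))
  expect_identical(sites$codon_from, "CCA")
  expect_identical(sites$codon_to, "CUA")
  expect_identical(sites$effect, "nonsynonymous")
  # coverage 9 in one of only two positive replicates: not called
  pil2 <- rbind(pileup_row("R1", 15, C = 1, T = 8),
                pileup_row("R2", 15, T = 30),
                pileup_row("R3", 15, C = 20))
  expect_identical(nrow(call_editing_sites(pil2, g)), 0L)
  # edited base present in exactly one replicate: not called
  pil3 <- rbind(pileup_row("R1", 15, C = 25),
                pileup_row("R2", 15, T = 30),
                pileup_row("R3", 15, C = 20))
  expect_identical(nrow(call_editing_sites(pil3, g)), 0L)
  # a zero-level replicate is retained in the report when two others pass
  expect_true("level_R3" %in% names(sites))
  expect_error(call_editing_sites(pileup_row("R1", 15, T = 30), g),
               ">= 2 replicates")
})

test_that("minus-strand genes are called from plus-strand G/A counts", {
  g <- toy_editing_genome()
  # mRNA codon 2 is TCA; its C sits at mRNA position 5 -> genomic 41 + (12-5) = 48
  pos <- 48
  expect_identical(substr(g$seq, pos, pos), "G")
  pil <- rbind(pileup_row("R1", pos, G = 5, A = 15),
               pileup_row("R2", pos, A = 20))
  sites <- call_editing_sites(pil, g)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$gene, "rps14")
  expect_identical(sites$strand, "-")
  expect_identical(sites$codon_from, "UCA")
  expect_identical(sites$codon_to, "UUA")
  expect_identical(c(sites$aa_from, sites$aa_to), c("S", "L"))
  expect_true(sites$physicochemical_change)
  expect_equal(c(sites$level_R1, sites$level_R2), c(75, 100))
})

test_that("non-CDS and non-C positions are skipped with a log entry", {
  g <- toy_editing_genome()
  pil <- rbind(pileup_row("R1", 30, T = 20), pileup_row("R2", 30, T = 20),
               pileup_row("R1", 12, T = 20), pileup_row("R2", 12, T = 20))
  sites <- call_editing_sites(pil, g)
  expect_identical(nrow(sites), 0L)
  skipped <- attr(sites, "skipped")
  expect_identical(skipped$reason[skipped$position == 30], "not in CDS")
  expect_match(skipped$reason[skipped$position == 12], "not C")
})

test_that("codon annotation covers the documented edit types", {
  g <- toy_editing_genome()
  # CCA -> CUA at codon position 2: P to L
  a <- annotate_codon_change(15, g)
  expect_identical(a[c("codon_from", "codon_to", "codon_position",
                       "aa_from", "aa_to", "effect")],
                   list(codon_from = "CCA", codon_to = "CUA",
                        codon_position = 2L, aa_from = "P", aa_to = "L",
                        effect = "nonsynonymous"))
  # GCC -> GCU at position 3: synonymous
  a <- annotate_codon_change(19, g)
  expect_identical(a$codon_to, "GCU")
  expect_identical(a$effect, "synonymous")
  # CAA -> UAA at position 1: Q to Stop
  a <- annotate_codon_change(20, g)
  expect_identical(a$codon_to, "UAA")
  expect_identical(c(a$aa_from, a$aa_to), c("Q", "*"))
  expect_identical(a$effect, "stop_gained")
  expect_error(annotate_codon_change(30, g), "not inside a CDS")
  expect_error(annotate_codon_change(11, g), "not a C")
})

test_that("multi-exon and trans-spliced CDS use spliced coordinates", {
  set.seed(600)
  # exon1 ATG CCA | intron | exon2 GCA TAA, minus strand overall handled
  # separately below
  seq <- paste0(strrep("T", 5), "ATGCCA", strrep("G", 20), "GCATAA",
                strrep("T", 5))
  g <- annotated_plastome("t", seq, gene_features(
    gene_feature("rps16", "protein_coding", "+",
                 rbind(c(6, 11), c(32, 37)))))
  a <- annotate_codon_change(10, g)   # CCA position 2
  expect_identical(a$codon_from, "CCA")
  expect_identical(a$effect, "nonsynonymous")
  # trans-spliced: only 2 of 3 parts present -> unresolved
  g2 <- annotated_plastome("t", seq, gene_features(
    gene_feature("rps12", "protein_coding", "+", c(6, 11),
                 trans_spliced = TRUE),
    gene_feature("rps12", "protein_coding", "+", c(32, 37),
                 trans_spliced = TRUE)))
  expect_identical(annotate_codon_change(10, g2)$effect, "unresolved")
  # CDS length not divisible by 3
  g3 <- annotated_plastome("t", seq, gene_features(
    gene_feature("bad", "protein_coding", "+", c(6, 12))))
  expect_error(annotate_codon_change(10, g3), "partial CDS")
})

test_that("physicochemical classification follows the editing convention", {
  changed <- list(c("S", "L"), c("S", "F"), c("R", "C"))
  unchanged <- list(c("A", "V"), c("H", "Y"), c("L", "F"), c("P", "F"),
                    c("P", "L"), c("P", "S"), c("R", "W"), c("T", "I"),
                    c("T", "M"))
  for (p in changed)
    expect_true(classify_physicochemical(p[1], p[2])$changed)
  for (p in unchanged)
    expect_false(classify_physicochemical(p[1], p[2])$changed)
  # identity is never a change; Stop transitions are flagged separately
  for (aa in c("A", "S", "W"))
    expect_false(classify_physicochemical(aa, aa)$changed)
  expect_identical(classify_physicochemical("Q", "*")$category, "stop")
  expect_identical(classify_physicochemical("E", "K")$category, "unlisted")
  expect_error(classify_physicochemical("S", "B"), "unknown residue")
})

test_that("transition spectrum counts types and effect totals", {
  sites <- data.frame(
    aa_from = c("S", "P", "P", "A", "A", "Q"),
    aa_to = c("L", "L", "L", "A", "A", "*"),
    effect = c("nonsynonymous", "nonsynonymous", "nonsynonymous",
               "synonymous", "synonymous", "stop_gained"))
  sp <- transition_spectrum(sites)
  expect_identical(unname(sp$totals),
                   c(2L, 3L, 1L))
  expect_identical(sp$transitions$n, c(2L, 1L))
  expect_identical(sp$transitions$aa_from[1], "P")
  empty <- transition_spectrum(sites[0, ])
  expect_identical(sum(empty$totals), 0L)
})

test_that("editing level is monotone in the edited count at fixed coverage", {
  g <- toy_editing_genome()
  lv <- vapply(c(5, 10, 15, 20), function(t) {
    pil <- rbind(pileup_row("R1", 15, C = 25 - t, T = t),
                 pileup_row("R2", 15, T = 30))
    call_editing_sites(pil, g)$level_R1
  }, 1)
  expect_true(all(diff(lv) > 0))
  expect_true(all(lv >= 0 & lv <= 100))
})

test_that("calling is strand-consistent under genome reverse complement", {
  cfg <- sim_config(seed = 31)
  sim <- simulate_plastome_set(cfg)
  pl <- sim$plastomes$purple
  pil <- simulate_pileups(cfg, pl)
  sites <- call_editing_sites(pil$pileups, pl)
  n <- nchar(pl$seq)
  # mirror genome, features and pileup counts
  flipped_feats <- pl$features
  for (i in seq_len(nrow(flipped_feats))) {
    p <- flipped_feats$parts[[i]]
    np <- cbind(n - p[, 2] + 1L, n - p[, 1] + 1L)
    flipped_feats$parts[[i]] <- np[order(np[, 1]), , drop = FALSE]
    flipped_feats$strand[i] <- if (flipped_feats$strand[i] == "+") "-" else "+"
  }
  gflip <- annotated_plastome("flip", rc(pl$seq), flipped_feats)
  pflip <- pil$pileups
  pflip$position <- n - pflip$position + 1L
  pflip[c("A", "C", "G", "T")] <- pflip[c("T", "G", "C", "A")]
  sflip <- call_editing_sites(pflip, gflip)
  expect_identical(nrow(sflip), nrow(sites))
  expect_setequal(n - sflip$position + 1L, sites$position)
  m <- match(n - sflip$position + 1L, sites$position)
  expect_identical(sflip$codon_from, sites$codon_from[m])
  expect_identical(sflip$aa_to, sites$aa_to[m])
  expect_equal(sflip$level_R1, sites$level_R1[m])
})

test_that("caller agrees with the per-site recount oracle on simulated data", {
  cfg <- sim_config(seed = 32, error_rate = 0.01, n_background = 60)
  sim <- simulate_plastome_set(cfg)
  pl <- sim$plastomes$white
  pil <- simulate_pileups(cfg, pl)
  got <- call_editing_sites(pil$pileups, pl)
  want <- oracle_editing_recount(pil$pileups, pl)
  expect_identical(got$position, want$position)
  expect_identical(got$gene, want$gene)
  for (r in c("level_R1", "level_R2", "level_R3"))
    expect_equal(got[[r]], want[[r]])
})

test_that("sequencing-error false positives are controlled by the replicate filter", {
  # at 1% read error (errors uniform over the three non-reference bases)
  # and 20x coverage, a non-edited C-context site shows the edited base in
  # >= 2 of 3 replicates only rarely; estimated over seeds, each candidate
  # site must fail the filter in >= 95% of trials
  cfg0 <- sim_config(seed = 60)
  sim <- simulate_plastome_set(cfg0)
  pl <- sim$plastomes$purple
  n_called <- 0L
  n_candidates <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(seed = 6000 + seed, error_rate = 0.01,
                      n_background = 60,
                      editing_plantings = default_editing_plantings()[1, ])
    pil <- simulate_pileups(cfg, pl)
    sites <- call_editing_sites(pil$pileups, pl)
    fp <- setdiff(sites$position, pil$truth$position)
    n_called <- n_called + length(fp)
    n_candidates <- n_candidates + 60L
    # the planted site itself is always recovered
    expect_true(all(pil$truth$position %in% sites$position))
  }
  expect_lt(n_called / n_candidates, 0.05)
})
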