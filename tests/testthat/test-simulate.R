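# The synthetic-data generator: reproducibility, planted ground truth, and
# validity of every emitted artifact under the package's own readers.

test_that("the generator is byte-reproducible and honours zero divergence", {
  cfg <- sim_config(seed = 21)
  s1 <- simulate_plastome_set(cfg)
  s2 <- simulate_plastome_set(cfg)
  expect_identical(lapply(s1$plastomes, `[[`, "seq"),
                   lapply(s2$plastomes, `[[`, "seq"))
  expect_identical(s1$truth, s2$truth)
  # zero divergence, no inversion: identical haplotypes, pi all zero
  cfg0 <- sim_config(seed = 21, background_rate = 0, hotspot_rate = 0,
                     inversion = FALSE)
  s0 <- simulate_plastome_set(cfg0)
  expect_identical(s0$plastomes$purple$seq, s0$plastomes$yellow$seq)
  expect_true(all(sliding_window_pi(s0$alignment)$pi == 0))
})

test_that("planted quadripartite, SSR and repeat truth is recovered exactly", {
  for (seed in c(5, 23)) {
    cfg <- sim_config(seed = seed)
    sim <- simulate_plastome_set(cfg)
    pl <- sim$plastomes$purple
    part <- detect_quadripartite(pl, 1000)
    expect_identical(unname(partition_lengths(part)),
                     unname(sim$truth$region_lengths))
    red <- ir_reduced_seq(pl, part)
    ss <- find_ssrs(red)
    expect_identical(ss[c("motif", "unit_len", "copies", "start", "end")],
                     sim$truth$ssrs[c("motif", "unit_len", "copies",
                                      "start", "end")])
    rr <- find_long_repeats(red)
    tt <- sim$truth$repeats
    tt <- tt[order(match(tt$kind, c("forward", "reverse", "complement",
                                    "palindromic")), tt$start1), ]
    rownames(tt) <- NULL
    expect_identical(rr, tt)
  }
})

test_that("the planted two-gene inversion is recovered from gene orders", {
  cfg <- sim_config(seed = 24)
  sim <- simulate_plastome_set(cfg)
  inv <- detect_inversions(gene_order(sim$plastomes$purple),
                           gene_order(sim$plastomes$yellow))
  expect_identical(nrow(inv), 1L)
  expect_identical(inv$kind, "inversion")
  expect_setequal(strsplit(inv$genes, ",")[[1]], sim$truth$inversion$genes)
  # no difference between the first two haplotypes
  expect_identical(nrow(detect_inversions(gene_order(sim$plastomes$purple),
                                          gene_order(sim$plastomes$white))),
                   0L)
})

test_that("hotspot windows dominate background windows across seeds", {
  hits <- 0L
  n_seeds <- 8L
  for (seed in seq_len(n_seeds)) {
    cfg <- sim_config(seed = 900 + seed, inversion = FALSE)
    sim <- simulate_plastome_set(cfg)
    tr <- sliding_window_pi(sim$alignment)
    hot_lo <- vapply(cfg$hotspots, `[[`, 1L, 1L)
    is_hot <- tr$window_start %in% hot_lo
    if (min(tr$pi[is_hot]) > max(tr$pi[!is_hot])) hits <- hits + 1L
    # the three hotspot windows are exactly the >0.02 calls
    hs <- call_hotspots(tr)
    expect_identical(sort(hs$window_start), sort(tr$window_start[is_hot]))
  }
  expect_gte(hits, n_seeds - 1L)
})

test_that("emitted files validate under the package readers", {
  cfg <- sim_config(seed = 25)
  sim <- simulate_plastome_set(cfg)
  td <- withr::local_tempdir()
  for (h in names(sim$plastomes))
    write_plastome(sim$plastomes[[h]], file.path(td, paste0(h, ".fasta")),
                   file.path(td, paste0(h, ".gff3")))
  back <- read_plastome(file.path(td, "yellow.fasta"), "fasta",
                        gff = file.path(td, "yellow.gff3"))
  expect_identical(back$seq, sim$plastomes$yellow$seq)
  expect_identical(back$features$parts, sim$plastomes$yellow$features$parts)
  aln_file <- file.path(td, "aln.fasta")
  ss <- Biostrings::DNAStringSet(sim$alignment$rows)
  names(ss) <- sim$alignment$names
  Biostrings::writeXStringSet(ss, aln_file)
  aln <- read_alignment(aln_file)
  expect_identical(aln$rows, sim$alignment$rows)
  # pileup TSV round trip
  pil <- simulate_pileups(cfg, sim$plastomes$purple)
  pf <- file.path(td, "pileup.tsv")
  write.table(pil$pileups, pf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_pileups(pf), pil$pileups)
})

test_that("pileup simulation respects plantings, levels and replicates", {
  cfg <- sim_config(seed = 26)
  sim <- simulate_plastome_set(cfg)
  pl <- sim$plastomes$purple
  pil <- simulate_pileups(cfg, pl)
  expect_identical(simulate_pileups(cfg, pl)$pileups, pil$pileups)
  # level 100, coverage 20: called with level 100 in both replicates
  cfg2 <- sim_config(seed = 26, editing_plantings = data.frame(
    gene = "rbcL", level = 100, coverage = 20))
  pil2 <- simulate_pileups(cfg2, pl, n_replicates = 2)
  sites2 <- call_editing_sites(pil2$pileups, pl)
  expect_identical(nrow(sites2), 1L)
  expect_equal(c(sites2$level_R1, sites2$level_R2), c(100, 100))
  # binomial concentration: level 50 at coverage 10000 lands within 1 point
  cfg3 <- sim_config(seed = 27, editing_plantings = data.frame(
    gene = "psbA", level = 50, coverage = 10000))
  for (seed in 1:5) {
    cfg3$seed <- 27 + seed
    p3 <- simulate_pileups(cfg3, pl, n_replicates = 2)
    s3 <- call_editing_sites(p3$pileups, pl)
    expect_lt(abs(s3$level_R1 - 50), 1)
  }
  # planting carried by a single replicate is rejected downstream
  cfg4 <- sim_config(seed = 28, editing_plantings = data.frame(
    gene = "psbA", level = 90, coverage = 30, present_in = "1"))
  p4 <- simulate_pileups(cfg4, pl, n_replicates = 3)
  expect_identical(nrow(call_editing_sites(p4$pileups, pl)), 0L)
})

test_that("count simulation recovers library multipliers and is seeded", {
  cfg <- sim_config(seed = 29, dispersion = 0,
                    lib_multipliers = c(2, 1, 1, 1, 1, 1, 1, 1))
  sc <- simulate_counts(cfg)
  expect_identical(simulate_counts(cfg)$counts$counts, sc$counts$counts)
  nf <- rle_normalize(sc$counts)
  others <- exp(mean(log(nf$size_factors[-1])))
  expect_equal(unname(nf$size_factors[1] / others), 2, tolerance = 0.05)
  # negative-binomial mode keeps the replicate/group structure
  scnb <- simulate_counts(sim_config(seed = 30))
  expect_identical(dim(scnb$counts$counts),
                   c(nrow(scnb$truth$group_means), 8L))
  expect_identical(as.integer(table(scnb$counts$groups)[c("purple", "white",
                                                          "yellow")]),
                   c(3L, 3L, 2L))
})
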