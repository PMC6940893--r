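# Plastome containers, readers/writers, quadripartite detection and region
# statistics.

test_that("quadripartite partition recovers a planted IR structure", {
  set.seed(11)
  g <- make_quadripartite(1000, 1500, 400)
  pl <- annotated_plastome("toy", g$seq)
  p <- detect_quadripartite(pl, min_ir_len = 1000)
  expect_identical(unname(partition_lengths(p)), c(1000L, 1500L, 400L, 1500L))
  # SSC is the shorter single-copy region, by construction the Y segment
  expect_identical(substr_circ <- substr(g$seq, p$ssc[1], p$ssc[2]),
                   substr(g$seq, 2501, 2900))
  # tiling and IR symmetry
  rep <- region_report(pl, p)
  expect_identical(sum(rep$length_bp[1:4]), nchar(g$seq))
  expect_identical(substr(g$seq, p$ira[1], p$ira[2]),
                   rc(substr(g$seq, p$irb[1], p$irb[2])))
  # fractions of a 4400-bp genome: 1000/1500/400/1500
  expect_equal(rep$fraction[1:4], c(22.7, 34.1, 9.1, 34.1))
})

test_that("partition detection works across the sequence origin", {
  set.seed(12)
  g <- make_quadripartite(1200, 1100, 500)
  # rotate so that the LSC spans the origin
  rot <- 600L
  seq2 <- paste0(substr(g$seq, rot + 1, nchar(g$seq)), substr(g$seq, 1, rot))
  p <- detect_quadripartite(annotated_plastome("rot", seq2), 1000)
  expect_identical(unname(partition_lengths(p)), c(1200L, 1100L, 500L, 1100L))
})

test_that("a genome without inverted repeats raises 'no IR detected'", {
  set.seed(13)
  # brute-force confirms the random background has no revcomp repeat pair
  # >= 300 bp (the oracle scans every diagonal)
  seq <- random_dna(3000)
  orc <- oracle_long_repeats(seq, min_len = 300, max_hamming = 0,
                             kinds = "palindromic")
  expect_identical(nrow(orc), 0L)
  expect_error(detect_quadripartite(annotated_plastome("r", seq),
                                    min_ir_len = 300),
               class = "no_ir_detected")
})

test_that("partition detection recovers planted lengths over 100 seeds", {
  for (seed in 1:100) {
    set.seed(seed)
    lsc <- sample(2000:4000, 1); ir <- sample(1000:2000, 1)
    ssc <- sample(400:1500, 1)
    g <- make_quadripartite(lsc, ir, ssc)
    p <- detect_quadripartite(annotated_plastome("s", g$seq), 1000)
    expect_identical(unname(partition_lengths(p)),
                     as.integer(c(lsc, ir, ssc, ir)))
  }
})

test_that("region GC report follows the (G+C)/(A+C+G+T) convention", {
  # all-GC toy sequence reports 100.0
  expect_equal(gc_percent(strrep("GC", 50)), 100)
  set.seed(14)
  g <- make_quadripartite(1000, 1200, 500)
  pl <- annotated_plastome("toy", g$seq)
  rep <- region_report(pl, detect_quadripartite(pl, 1000))
  s <- strsplit(g$seq, "")[[1]]
  expect_equal(rep$pct_gc[rep$region == "total"],
               round(100 * sum(s %in% c("G", "C")) / length(s), 1),
               tolerance = 0.051)
})

test_that("gene census collapses IR duplicates and counts introns", {
  f <- gene_features(
    gene_feature("psbA", "protein_coding", "+", c(10, 309)),
    gene_feature("ndhB", "protein_coding", "-", rbind(c(400, 600), c(700, 899)),
                 copy_index = 1L),
    gene_feature("ndhB", "protein_coding", "-", rbind(c(1200, 1400), c(1500, 1699)),
                 copy_index = 2L),
    gene_feature("trnH", "tRNA", "+", c(2000, 2070)),
    gene_feature("ycf1", "pseudogene", "+", c(2100, 2200), partial = TRUE))
  set.seed(15)
  pl <- annotated_plastome("toy", random_dna(2500), f)
  cs <- gene_census(pl)
  # 5 feature copies, 2 unique protein-coding symbols, 1 tRNA, 2 features
  # with introns, 1 symbol duplicated, 1 partial
  expect_identical(cs$total_genes, 5L)
  expect_identical(cs$unique_protein_coding, 2L)
  expect_identical(cs$trna, 1L)
  expect_identical(cs$rrna, 0L)
  expect_identical(cs$intron_containing, 2L)
  expect_identical(cs$duplicated_in_ir, 1L)
  expect_identical(cs$partial, 1L)
  # empty annotation: all zeros
  empty <- gene_census(annotated_plastome("e", "ACGTACGT"))
  expect_true(all(unlist(empty) == 0L))
})

test_that("FASTA+GFF3 round trip preserves the plastome exactly", {
  set.seed(16)
  f <- gene_features(
    gene_feature("psbA", "protein_coding", "+", c(10, 309)),
    gene_feature("rps16", "protein_coding", "-", rbind(c(400, 600), c(700, 899))),
    gene_feature("rps12", "protein_coding", "-", c(1000, 1113),
                 trans_spliced = TRUE),
    gene_feature("rps12", "protein_coding", "-", c(1300, 1531),
                 trans_spliced = TRUE),
    gene_feature("trnH", "tRNA", "+", c(2000, 2070)),
    gene_feature("rrn16", "rRNA", "+", c(2100, 2300)),
    gene_feature("ycf1", "pseudogene", "+", c(2350, 2449), partial = TRUE))
  pl <- annotated_plastome("toy", random_dna(2500), f)
  fa <- withr::local_tempfile(fileext = ".fasta")
  gf <- withr::local_tempfile(fileext = ".gff3")
  write_plastome(pl, fa, gf)
  back <- read_plastome(fa, "fasta", gff = gf)
  expect_identical(back$seq, pl$seq)
  for (col in c("name", "category", "strand", "copy_index", "partial",
                "trans_spliced", "parts"))
    expect_identical(back$features[[col]], pl$features[[col]])
  # FASTA with no annotation file: zero features
  bare <- read_plastome(fa, "fasta")
  expect_identical(nrow(bare$features), 0L)
})

test_that("the GenBank reader parses joins, complements and qualifiers", {
  set.seed(17)
  seq <- tolower(random_dna(120))
  gb <- withr::local_tempfile(fileext = ".gb")
  origin <- paste(vapply(seq(1, 120, 60), function(i) {
    blocks <- vapply(seq(i, min(i + 59, 120), 10), function(j)
      substr(seq, j, min(j + 9, 120)), "")
    sprintf("%9d %s", i, paste(blocks, collapse = " "))
  }, ""), collapse = "\n")
  writeLines(c(
    "LOCUS       SYNPLAST     120 bp    DNA     circular PLN 01-JAN-2020",
    "ACCESSION   SYN0001",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             11..40",
    '                     /gene="psbA"',
    "     CDS             complement(join(51..70,81..100))",
    '                     /gene="ndhB"',
    "     tRNA            105..115",
    '                     /gene="trnH"',
    "     CDS             <101..103",
    '                     /gene="ycf1"',
    "ORIGIN",
    origin,
    "//"), gb)
  pl <- read_plastome(gb, "genbank")
  expect_identical(pl$id, "SYN0001")
  expect_identical(pl$seq, toupper(seq))
  expect_identical(nrow(pl$features), 4L)
  ndhb <- pl$features[pl$features$name == "ndhB", ]
  expect_identical(ndhb$strand, "-")
  expect_identical(ndhb$parts[[1]],
                   matrix(c(51L, 81L, 70L, 100L), 2,
                          dimnames = list(NULL, c("start", "end"))))
  expect_true(pl$features$partial[pl$features$name == "ycf1"])
  expect_identical(pl$features$category[pl$features$name == "trnH"], "tRNA")
})

test_that("invalid inputs are rejected with clear errors", {
  expect_error(annotated_plastome("x", "ACGTX"), "non-DNA")
  expect_error(annotated_plastome("x", "ACGT",
                                  gene_features(gene_feature("g", parts = c(2, 10)))),
               "outside")
  set.seed(18)
  fa <- withr::local_tempfile(fileext = ".fasta")
  gf <- withr::local_tempfile(fileext = ".gff3")
  pl <- annotated_plastome("t", random_dna(100))
  write_plastome(pl, fa)
  writeLines(c("##gff-version 3",
               "t\tx\tCDS\t50\t200\t.\t+\t.\tID=g1;gene=g1"), gf)
  expect_error(read_plastome(fa, "fasta", gff = gf), "beyond|outside")
})
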