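test_that("NG86 sites are conserved and the statistic is symmetric", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    a <- random_sense_codons(n)
    b <- random_sense_codons(n)
    f <- ka_ks_ng86(list(codons_a = a, codons_b = b))
    expect_equal(f$S + f$N, 3 * f$n_codons)
    r <- ka_ks_ng86(list(codons_a = b, codons_b = a))
    expect_equal(f$Sd, r$Sd)
    expect_equal(f$Nd, r$Nd)
    expect_equal(f$ks, r$ks)
  }
})

test_that("NG86 handles the degenerate difference structures", {
  same <- list(codons_a = c("ATG", "GCT", "AAA"),
               codons_b = c("ATG", "GCT", "AAA"))
  f <- ka_ks_ng86(same)
  expect_equal(f$ka, 0)
  expect_equal(f$ks, 0)
  # purely nonsynonymous change: AAA (K) -> GAA (E)
  ns <- ka_ks_ng86(list(codons_a = c("AAA", "TTT"),
                        codons_b = c("GAA", "TTT")))
  expect_equal(ns$ks, 0)
  expect_gt(ns$ka, 0)
  # purely synonymous change at a fourfold site: GGA -> GGC
  sy <- ka_ks_ng86(list(codons_a = c("GGA", "TTT", "GGG"),
                        codons_b = c("GGC", "TTT", "GGG")))
  expect_equal(sy$ka, 0)
  expect_gt(sy$ks, 0)
  # gap and stop codons are skipped
  sk <- ka_ks_ng86(list(codons_a = c("---", "TAA", "GGA"),
                        codons_b = c("ATG", "GGG", "GGC")))
  expect_equal(sk$n_codons, 1)
  expect_error(ka_ks_ng86(list(codons_a = "---", codons_b = "ATG")),
               "no analyzable")
})

test_that("codon back-translation expands the protein alignment faithfully", {
  # gapless pair concatenates the original codons
  ca <- backtranslate_alignment("MK", "MK", "ATGAAA", "ATGAAG")
  expect_equal(ca$codons_a, c("ATG", "AAA"))
  expect_equal(ca$codons_b, c("ATG", "AAG"))
  # trailing stop is trimmed
  ca2 <- backtranslate_alignment("MK", "MK", "ATGAAATAA", "ATGAAG")
  expect_equal(ca2$codons_a, c("ATG", "AAA"))
  # a protein gap becomes a gap triplet at the matching position
  ca3 <- backtranslate_alignment("M-K", "MEK", "ATGAAA", "ATGGAGAAA")
  expect_equal(ca3$codons_a, c("ATG", "---", "AAA"))
  expect_equal(ca3$codons_b, c("ATG", "GAG", "AAA"))
  # mismatched translation errors with the offending id
  expect_error(backtranslate_alignment("MK", "MK", "ATGCCC", "ATGAAA",
                                       ids = c("gx", "gy")), "gx")
  # random pairs: translating each non-gap triplet reproduces the protein row
  set.seed(72)
  for (i in 1:10) {
    cds <- paste(random_sense_codons(30), collapse = "")
    prot <- translate_cds(cds)
    ca <- backtranslate_alignment(prot, prot, cds, cds)
    trans <- vapply(ca$codons_a, function(x)
      Biostrings::GENETIC_CODE[[x]], "")
    expect_equal(paste(trans, collapse = ""), prot)
  }
})

test_that("duplicate pair detection keeps planted pairs and drops decoys", {
  sim <- generate_duplications(n_pairs = 4, ks_levels = 0.1, seed = 73,
                               n_codons = 120, ancestors = "all")
  pairs <- find_duplicate_pairs(sim$proteins)
  key <- function(df) paste(df$gene_a, df$gene_b)
  expect_setequal(key(pairs), key(sim$pairs))
  expect_true(all(pairs$identity > 0.9))

  ident <- data.frame(id = c("d1", "d2"),
                      sequence = rep(random_protein(80), 2))
  p2 <- find_duplicate_pairs(ident)
  expect_equal(p2$identity, 1)

  set.seed(74)
  rand <- data.frame(id = c("r1", "r2"),
                     sequence = c(random_protein(150), random_protein(150)))
  expect_equal(nrow(find_duplicate_pairs(rand)), 0)
})

test_that("pair modes follow the base-pair gap rules", {
  loci <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    seqname = c("chr01", "chr01", "chr01", "chr06"),
    start = c(100L, 50000L, 900000L, 100L),
    end = c(400L, 51000L, 901000L, 400L),
    strand = "+", chromosome_flag = TRUE, stringsAsFactors = FALSE)
  expect_equal(classify_pair_mode("a", "b", loci), "tandem")
  expect_equal(classify_pair_mode("a", "c", loci), "proximal")
  expect_equal(classify_pair_mode("a", "d", loci), "dispersed")
  expect_equal(classify_pair_mode("a", "zz", loci), "unplaced")
})

test_that("tandem arrays are the connected components ordered by position", {
  loci <- data.frame(
    gene_id = c("a", "b", "c", "x", "y"),
    seqname = c(rep("chr01", 3), rep("chr05", 2)),
    start = c(300L, 100L, 200L, 10L, 20L), end = c(310L, 110L, 210L, 11L, 21L),
    strand = "+", chromosome_flag = TRUE, stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = c("a", "b", "x"), gene_b = c("b", "c", "y"),
                      mode = "tandem", stringsAsFactors = FALSE)
  arrays <- merge_tandem_arrays(pairs, loci)
  expect_length(arrays, 2)
  expect_equal(arrays[[1]], c("b", "c", "a"))
  expect_equal(arrays[[2]], c("x", "y"))
  expect_length(merge_tandem_arrays(pairs[0, ], loci), 0)
})

test_that("a planted 12-gene tandem array is recovered as one array", {
  sim <- generate_duplications(n_pairs = 2, ks_levels = 0.3, seed = 75,
                               n_codons = 150, tandem_array_size = 12)
  pairs <- find_duplicate_pairs(sim$proteins)
  pairs$mode <- vapply(seq_len(nrow(pairs)), function(r)
    classify_pair_mode(pairs$gene_a[r], pairs$gene_b[r], sim$loci), "")
  arrays <- merge_tandem_arrays(pairs, sim$loci)
  expect_length(arrays, 1)
  expect_length(arrays[[1]], 12)
  expect_setequal(arrays[[1]], sim$truth$array)
  # members come back in chromosomal order
  ix <- match(arrays[[1]], sim$loci$gene_id)
  expect_true(all(diff(sim$loci$start[ix]) > 0))
})

test_that("ks histogram applies the saturation cut-off", {
  pairs <- data.frame(ks = c(0.1, 0.1, 1.9, 2.5, NA))
  h <- ks_distribution(pairs)
  expect_equal(sum(h$count[h$group == "all"]), 3)
  h0 <- ks_distribution(data.frame(ks = c(NA_real_, NA_real_)))
  expect_equal(sum(h0$count), 0)
})
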