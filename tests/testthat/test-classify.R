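test_that("signature classification maps published quadruplets correctly", {
  tab <- load_signature_table()
  call_of <- function(q) classify_by_signature(
    setNames(q, c("h2", "h5", "le1", "le2")), tab)
  expect_equal(call_of(c("F", "H", "T", "R"))$subfamily, "PIP")
  expect_equal(call_of(c("W", "V", "A", "R"))$subfamily, "NIP")
  expect_equal(call_of(c("I", "T", "A", "R"))$subfamily, "XIP")
  expect_equal(call_of(c("H", "T", "A", "M"))$subgroup, "TIP4")
  expect_equal(call_of(c("-", "-", "-", "-"))$reason, "insufficient")
  # three present residues are enough
  expect_equal(call_of(c("-", "H", "T", "R"))$subfamily, "PIP")
  # a quadruplet matching two subfamilies is ambiguous, never guessed
  expect_equal(call_of(c("-", "V", "A", "R"))$reason, "ambiguous")
})

test_that("classification by signature agrees with the published table", {
  tab <- load_family_table()
  sig <- load_signature_table()
  classified <- 0
  for (r in seq_len(nrow(tab))) {
    filt <- setNames(unlist(tab[r, c("h2", "h5", "le1", "le2")]),
                     c("h2", "h5", "le1", "le2"))
    call <- classify_by_signature(filt, sig)
    if (identical(call$reason, "ok")) {
      classified <- classified + 1
      expect_equal(call$subfamily, tab$subfamily[r],
                   label = paste("signature call for", tab$gene_name[r]))
    }
  }
  # most of the family is signature-resolvable; the rest goes to fallback
  expect_gte(classified, 45)
  expect_lte(classified, 72)
})

test_that("filter extraction reads residues and gaps at the located columns", {
  rows <- c(g1 = "FAHATARA", g2 = "FA-ATARA", g3 = "--------")
  aln <- aqp_alignment(names(rows), unname(rows))
  trimmed <- trim_gappy_columns(aln, 0.9)
  fc <- list(h2_col = 1L, h5_col = 3L, le1_col = 5L, le2_col = 7L)
  expect_equal(unname(extract_arr_filter(trimmed, "g1", fc)),
               c("F", "H", "T", "R"))
  expect_equal(unname(extract_arr_filter(trimmed, "g2", fc)),
               c("F", "-", "T", "R"))
  expect_equal(unname(extract_arr_filter(trimmed, "g3", fc)),
               c("-", "-", "-", "-"))
})

test_that("filter columns anchored on NPA recover all planted residues", {
  fam <- generate_family(n_per_subgroup = 3, seed = 41, noise_rate = 0.05)
  cl <- classify_family(fam$proteins)
  truth <- fam$truth$genes
  for (i in seq_len(nrow(cl$calls))) {
    t_row <- truth[truth$id == cl$calls$id[i], ]
    expect_equal(unname(unlist(cl$calls[i, c("h2", "h5", "le1", "le2")])),
                 unname(unlist(t_row[c("h2", "h5", "le1", "le2")])))
  }
  # degenerate configuration: zero offsets return the anchors themselves
  fc0 <- locate_filter_columns(cl$trimmed, cl$anchors$npa_b_col,
                               cl$anchors$npa_e_col,
                               c(h2 = 0, h5 = 0, le1 = 0, le2 = 0))
  expect_equal(fc0$h2_col, cl$anchors$npa_b_col)
  expect_equal(fc0$le2_col, cl$anchors$npa_e_col)
  # out-of-range offsets error
  expect_error(locate_filter_columns(cl$trimmed, cl$anchors$npa_b_col,
                                     cl$anchors$npa_e_col,
                                     c(h2 = -1e4, h5 = 0, le1 = 0, le2 = 0)),
               "range")
})

test_that("nearest-neighbour fallback inherits from the best-scoring reference", {
  fam <- generate_family(n_per_subgroup = 2, seed = 43, noise_rate = 0)
  refs <- fam$proteins
  truth <- fam$truth$genes
  ref_calls <- data.frame(id = truth$id, subfamily = truth$subfamily,
                          subgroup = truth$subgroup, stringsAsFactors = FALSE)
  # self-match dominates
  q <- refs$sequence[refs$id == "SYN_TIP3_01"]
  nn <- classify_by_nearest(q, refs, ref_calls)
  expect_equal(nn$best_match_id, "SYN_TIP3_01")
  expect_equal(nn$subgroup, "TIP3")
  expect_equal(nn$method, "fallback")
  # tie between two identical references breaks to the smaller id,
  # verified against exhaustive scoring
  two <- refs[refs$id %in% c("SYN_TIP1_01", "SYN_TIP1_02"), ]
  two$sequence <- two$sequence[1]
  nn2 <- classify_by_nearest(two$sequence[1], two,
                             ref_calls[ref_calls$id %in% two$id, ])
  scores <- vapply(two$sequence, function(s)
    pairwise_align(two$sequence[1], s)$score, numeric(1))
  expect_equal(unname(diff(scores)), 0)
  expect_equal(nn2$best_match_id, "SYN_TIP1_01")
  expect_error(classify_by_nearest(q, refs[0, ], ref_calls[0, ]))
})

test_that("gene naming is positional within subgroups and idempotent", {
  loci <- data.frame(
    gene_id = c("x1", "x2", "x3", "x4"),
    seqname = c("chr01", "chr01", "scaffold9", "chr02"),
    start = c(200L, 100L, 50L, 500L), end = c(300L, 180L, 90L, 600L),
    strand = "+", chromosome_flag = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  calls <- data.frame(id = c("x1", "x2", "x3", "x4"),
                      subfamily = c("TIP", "TIP", "TIP", "PIP"),
                      subgroup = c("TIP4", "TIP4", "TIP4", "PIP1"),
                      stringsAsFactors = FALSE)
  named <- assign_names(calls, loci, "Ca")
  # chr01 genes by start first, scaffold gene last
  expect_equal(named$assigned_name[named$id == "x2"], "CaTIP4;1")
  expect_equal(named$assigned_name[named$id == "x1"], "CaTIP4;2")
  expect_equal(named$assigned_name[named$id == "x3"], "CaTIP4;3")
  expect_equal(named$assigned_name[named$id == "x4"], "CaPIP1;1")
  again <- assign_names(named, loci, "Ca")
  expect_equal(again$assigned_name, named$assigned_name)
  calls$subgroup[1] <- NA
  expect_error(assign_names(calls, loci, "Ca"), "unresolved")
})
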