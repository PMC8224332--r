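test_that("NPA motifs are found at planted positions and prefer exact NPA", {
  seq1 <- paste0(strrep("G", 30), "NPA", strrep("G", 70), "NPA",
                 strrep("G", 30))
  hit <- find_npa_motifs(seq1)
  expect_equal(hit$loop_b_pos, 30)
  expect_equal(hit$loop_e_pos, 103)
  expect_equal(hit$variants, c("NPA", "NPA"))

  # NPA ... NPV ... NPA: the exact pair must win over the variant
  seq2 <- paste0(strrep("G", 10), "NPA", strrep("G", 60), "NPV",
                 strrep("G", 60), "NPA", strrep("G", 10))
  hit2 <- find_npa_motifs(seq2)
  expect_equal(hit2$variants, c("NPA", "NPA"))
  expect_equal(hit2$loop_b_pos, 10)
  expect_equal(hit2$loop_e_pos, 10 + 3 + 60 + 3 + 60)
})

test_that("NPA search exhaustively matches a brute-force candidate scan", {
  # brute force: enumerate all candidate pairs, rank by (canonical count,
  # earliest positions); repeated over random sequences with planted motifs
  cfg <- aqp_config()
  set.seed(11)
  for (rep in 1:20) {
    n <- 250
    chars <- sample(setdiff(LETTERS[LETTERS %in% strsplit(
      "ARNDCQEGHILKMFPSTWYV", "")[[1]]], c("N", "P")), n, replace = TRUE)
    pos <- sort(sample(seq(1, n - 3), 4))
    for (p in pos) {
      chars[p:(p + 2)] <- c("N", "P", sample(c("A", "V", "S"), 1))
    }
    s <- paste(chars, collapse = "")
    mine <- find_npa_motifs(s, cfg)
    starts <- integer(); trips <- character()
    for (i in 1:(n - 2)) {
      tri <- substr(s, i, i + 2)
      if (substr(tri, 1, 1) == "N" && substr(tri, 2, 2) == "P" &&
          substr(tri, 3, 3) %in% cfg$npa_third) {
        starts <- c(starts, i); trips <- c(trips, tri)
      }
    }
    best <- NULL
    for (i in seq_along(starts)) for (j in seq_along(starts)) {
      if (j <= i) next
      sep <- starts[j] - starts[i]
      if (sep < cfg$npa_min_sep || sep > cfg$npa_max_sep) next
      key <- c(sum(trips[c(i, j)] == "NPA"), -starts[i], -starts[j])
      if (is.null(best) ||
          isTRUE(key[1] > best$key[1] ||
                 (key[1] == best$key[1] &&
                  (key[2] > best$key[2] ||
                   (key[2] == best$key[2] && key[3] > best$key[3]))))) {
        best <- list(key = key, b = starts[i] - 1L, e = starts[j] - 1L)
      }
    }
    if (is.null(best)) {
      expect_null(mine)
    } else {
      expect_equal(mine$loop_b_pos, best$b)
      expect_equal(mine$loop_e_pos, best$e)
    }
  }
})

test_that("NPA search is position-equivariant under prefixing", {
  fam <- generate_family(n_per_subgroup = 1, seed = 3)
  s <- fam$proteins$sequence[1]
  base <- find_npa_motifs(s)
  for (k in c(1, 7, 23)) {
    shifted <- find_npa_motifs(paste0(strrep("G", k), s))
    expect_equal(shifted$loop_b_pos, base$loop_b_pos + k)
    expect_equal(shifted$loop_e_pos, base$loop_e_pos + k)
  }
})

test_that("hydropathy TM prediction finds extreme segments and planted helices", {
  one <- paste0(strrep("R", 30), strrep("I", 30), strrep("R", 30))
  tm <- predict_tm_helices(one)
  expect_equal(nrow(tm$spans), 1)
  expect_true(tm$spans[1, 1] >= 30 - 9 && tm$spans[1, 2] <= 59 + 9)

  expect_equal(nrow(predict_tm_helices(strrep("R", 80))$spans), 0)
  expect_error(predict_tm_helices("IIII"), "window")

  fam <- generate_family(n_per_subgroup = 2, seed = 5)
  planted <- fam$truth$tm_spans
  for (s in fam$proteins$sequence) {
    spans <- predict_tm_helices(s)$spans
    expect_equal(nrow(spans), 6)
    overlaps <- vapply(seq_len(6), function(h)
      spans[h, 1] <= planted[h, "end"] && spans[h, 2] >= planted[h, "start"],
      logical(1))
    expect_true(all(overlaps))
  }
})

test_that("candidate verdict separates planted AQPs from decoys", {
  fam <- generate_family(n_per_subgroup = 3, seed = 9, noise_rate = 0)
  verdicts <- scan_candidates(fam$proteins)
  expect_true(all(verdicts$candidate))

  set.seed(10)
  decoys <- vapply(1:20, function(i)
    random_protein(260, alphabet = c("S", "T", "G", "D", "E", "K", "R", "Q",
                                     "H", "Y")), "")
  dec <- vapply(decoys, function(s) is_candidate_aqp(s)$candidate, logical(1))
  expect_false(any(dec))

  short <- is_candidate_aqp(random_protein(50))
  expect_false(short$candidate)
  expect_true("length" %in% short$reasons)

  # deleting the loop-E NPA must fail the npa criterion
  s <- fam$proteins$sequence[1]
  npa <- find_npa_motifs(s)
  mutated <- paste0(substr(s, 1, npa$loop_e_pos), "G",
                    substr(s, npa$loop_e_pos + 2, nchar(s)))
  broken <- is_candidate_aqp(mutated)
  expect_false(broken$candidate)
  expect_true("npa" %in% broken$reasons)
})
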