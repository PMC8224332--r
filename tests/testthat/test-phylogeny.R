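test_that("protein distances match a per-pair recount with Poisson correction", {
  rows <- c(a = paste(rep("ACDEFGHIKL", 3), collapse = ""),
            b = paste(rep("ACDEFGHIKL", 3), collapse = ""),
            c = paste(rep("ACDEFGHIKM", 3), collapse = ""))
  aln <- aqp_alignment(names(rows), unname(rows))
  trimmed <- trim_gappy_columns(aln)
  D <- protein_distance(trimmed)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], -log(1 - 0.1))  # 3 mismatches over 30 columns
  expect_equal(protein_distance(trimmed, "raw")["a", "c"], 0.1)

  set.seed(51)
  fam <- generate_family(n_per_subgroup = 2, seed = 52, noise_rate = 0.05)
  trimmed <- trim_gappy_columns(progressive_align(fam$proteins))
  D <- protein_distance(trimmed)
  m <- aln_matrix(trimmed$alignment)
  for (pick in 1:10) {
    ij <- sample(nrow(m), 2)
    both <- m[ij[1], ] != "-" & m[ij[2], ] != "-"
    p <- mean(m[ij[1], both] != m[ij[2], both])
    expect_equal(D[ij[1], ij[2]], -log(1 - min(p, 0.95)))
  }
  expect_true(isSymmetric(unname(D[seq_len(nrow(D)), ])))
})

test_that("too few shared columns is an error naming the pair", {
  rows <- c(p = paste0(strrep("A", 10), strrep("-", 30)),
            q = paste0(strrep("-", 30), strrep("A", 10)))
  aln <- aqp_alignment(names(rows), unname(rows))
  trimmed <- trim_gappy_columns(aln, 0.9)
  expect_error(protein_distance(trimmed), "p / q")
})

test_that("neighbor joining solves the three-taxon case in closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  pd <- ape::cophenetic.phylo(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(pd), unname(D))
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["A"]], (3 + 4 - 5) / 2)
  expect_equal(el[["B"]], (3 + 5 - 4) / 2)
  expect_equal(el[["C"]], (4 + 5 - 3) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining exactly recovers additive trees", {
  set.seed(53)
  n_ok <- 0
  for (i in 1:60) {
    ntaxa <- sample(4:10, 1)
    tr <- ape::rtree(ntaxa, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
    D <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), est), 0, ignore_attr = TRUE)
    pd <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_equal(pd, D, tolerance = 1e-10)
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 60)
})

test_that("neighbor joining matches UPGMA topology on ultrametric input", {
  set.seed(54)
  tr <- ape::rcoal(8)
  D <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(D)
  hc <- hclust(as.dist(D), method = "average")
  upgma <- ape::as.phylo(hc)
  expect_equal(ape::dist.topo(ape::unroot(upgma), nj), 0, ignore_attr = TRUE)
})

test_that("subgroup assignment follows nearest labelled leaf with flags", {
  # caterpillar tree: u sits right next to the TIP4 reference
  tr <- ape::read.tree(text = "((ref_TIP4:0.1,u:0.1):1,(ref_PIP1:0.1,v:2):1);")
  got <- assign_subgroups(tr, c(ref_TIP4 = "TIP4", ref_PIP1 = "PIP1"))
  expect_equal(got$subgroup[got$id == "u"], "TIP4")
  expect_equal(got$subgroup[got$id == "v"], "PIP1")
  expect_error(assign_subgroups(tr, setNames(character(), character())))

  # equidistant leaf: deterministic choice verified against brute-force paths
  tr2 <- ape::read.tree(text = "((a_lab:1,q:1):0.0,(b_lab:1,x:5):0.0);")
  pd <- ape::cophenetic.phylo(tr2)
  expect_equal(pd["q", "a_lab"], pd["q", "b_lab"])
  got2 <- assign_subgroups(tr2, c(a_lab = "G1", b_lab = "G2"))
  expect_equal(got2$subgroup[got2$id == "q"], "G1")  # lexicographic tie-break
})

test_that("synthetic 12-subgroup family is fully recovered from references", {
  fam <- generate_family(n_per_subgroup = 3, seed = 55, noise_rate = 0.05)
  truth <- fam$truth$genes
  aln <- progressive_align(fam$proteins)
  trimmed <- trim_gappy_columns(aln)
  tree <- neighbor_joining(protein_distance(trimmed))
  refs <- truth$id[grepl("_01$", truth$id)]
  labels <- setNames(truth$subgroup[match(refs, truth$id)], refs)
  got <- assign_subgroups(tree, labels)
  expect_equal(got$subgroup, truth$subgroup[match(got$id, truth$id)])

  # invariance to leaf input order
  ord <- sample(nrow(fam$proteins))
  aln2 <- progressive_align(fam$proteins[ord, ])
  tree2 <- neighbor_joining(protein_distance(trim_gappy_columns(aln2)))
  got2 <- assign_subgroups(tree2, labels)
  expect_equal(setNames(got2$subgroup, got2$id)[got$id],
               setNames(got$subgroup, got$id))
})
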