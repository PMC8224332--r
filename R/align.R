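#' Construct an alignment object
#'
#' @param ids Row identifiers.
#' @param rows Equal-length gapped strings.
#' @return Object of class `aqp_alignment`.
#' @export
aqp_alignment <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), !anyDuplicated(ids))
  widths <- nchar(rows)
  stopifnot(length(unique(widths)) <= 1)
  structure(list(ids = as.character(ids), rows = unname(rows),
                 ncols = if (length(rows)) unname(widths[1]) else 0L),
            class = "aqp_alignment")
}

#' @export
print.aqp_alignment <- function(x, ...) {
  cat("aqp_alignment:", length(x$ids), "rows x", x$ncols, "columns\n")
  invisible(x)
}

#' Alignment as a character matrix (rows x columns)
#' @param alignment An `aqp_alignment`.
#' @return Character matrix with row names set to the ids.
#' @export
aln_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$rows, ""))
  if (is.null(m)) m <- matrix(character(), 0, 0)
  rownames(m) <- alignment$ids
  m
}

#' Remove gaps from one alignment row
#' @param alignment An `aqp_alignment`.
#' @param id Row identifier.
#' @return Ungapped sequence string.
#' @export
aln_ungap <- function(alignment, id) {
  gsub("-", "", alignment$rows[match(id, alignment$ids)], fixed = TRUE)
}

#' Columns occupied by each residue of a row
#' @param alignment An `aqp_alignment`.
#' @param id Row identifier.
#' @return Integer vector: for residue i of the ungapped sequence, its
#'   1-based alignment column.
#' @export
aln_residue_columns <- function(alignment, id) {
  chars <- strsplit(alignment$rows[match(id, alignment$ids)], "")[[1]]
  which(chars != "-")
}

#' k-mer distance between two sequences
#'
#' One minus the shared k-mer multiset size divided by the smaller total
#' k-mer count; 0 for identical sequences, 1 for sequences sharing no k-mer.
#'
#' @param a,b Sequence strings of length at least `k`.
#' @param k k-mer length.
#' @return Number in `[0, 1]`.
#' @export
kmer_distance <- function(a, b, k = 3) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) stop("sequences must be at least k residues long")
  km <- function(s, n) {
    table(substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1))
  }
  ta <- km(a, na); tb <- km(b, nb)
  common <- intersect(names(ta), names(tb))
  shared <- sum(pmin(ta[common], tb[common]))
  1 - shared / min(sum(ta), sum(tb))
}

# profile of an alignment block: 21 x ncol frequency matrix (gap mass omitted)
.profile_of <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  ab <- c(AA_ALPHABET20, "X")
  p <- matrix(0, length(ab), ncol(m), dimnames = list(ab, NULL))
  for (a in ab) p[a, ] <- colSums(m == a)
  p / nrow(m)
}

.align_two_blocks <- function(rows1, rows2, config) {
  p1 <- .profile_of(rows1)
  p2 <- .profile_of(rows2)
  S <- crossprod(p1, blosum62 %*% p2)
  path <- nw_affine_path(S, config$gap_open, config$gap_extend)
  expand <- function(rows, idx) {
    m <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow(m), length(idx))
    out[, idx > 0] <- m[, idx[idx > 0], drop = FALSE]
    apply(out, 1, paste, collapse = "")
  }
  list(rows1 = expand(rows1, path$path1),
       rows2 = expand(rows2, path$path2),
       score = path$score)
}

#' Progressive multiple sequence alignment
#'
#' UPGMA guide tree on k-mer distances, then profile-profile global alignment
#' with BLOSUM62 and affine gaps, merging from the leaves to the root.
#' Deterministic for a fixed input order.
#'
#' @param records data.frame from [read_fasta()] or a named character vector
#'   of sequences.
#' @param config Configuration list from [aqp_config()].
#' @return An `aqp_alignment` with rows in the input order.
#' @export
progressive_align <- function(records, config = aqp_config()) {
  if (is.data.frame(records)) {
    seqs <- setNames(records$sequence, records$id)
  } else {
    seqs <- records
  }
  n <- length(seqs)
  stopifnot(n >= 1)
  if (n == 1) return(aqp_alignment(names(seqs), unname(seqs)))
  if (n == 2) {
    ali <- .align_two_blocks(seqs[1], seqs[2], config)
    return(aqp_alignment(names(seqs), c(ali$rows1, ali$rows2)))
  }
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- kmer_distance(seqs[i], seqs[j], config$kmer_k)
    }
  }
  hc <- hclust(as.dist(D), method = "average")
  # follow the UPGMA merge order; each node carries row ids and gapped rows
  nodes <- vector("list", n - 1)
  get_node <- function(x) {
    if (x < 0) list(ids = names(seqs)[-x], rows = unname(seqs[-x]))
    else nodes[[x]]
  }
  for (step in seq_len(n - 1)) {
    a <- get_node(hc$merge[step, 1])
    b <- get_node(hc$merge[step, 2])
    ali <- .align_two_blocks(a$rows, b$rows, config)
    nodes[[step]] <- list(ids = c(a$ids, b$ids),
                          rows = c(ali$rows1, ali$rows2))
  }
  final <- nodes[[n - 1]]
  ord <- match(names(seqs), final$ids)
  aqp_alignment(names(seqs), final$rows[ord])
}

#' Pairwise global alignment of two sequences
#'
#' Same scoring as the progressive aligner (BLOSUM62, affine gaps, end gaps
#' penalised).
#'
#' @param a,b Sequence strings.
#' @param config Configuration list from [aqp_config()].
#' @return list with gapped strings `a`, `b`, the alignment `score`,
#'   `identity` (matches / aligned columns with both residues present) and
#'   `coverage` (aligned residue pairs / length of the shorter sequence).
#' @export
pairwise_align <- function(a, b, config = aqp_config()) {
  ali <- .align_two_blocks(a, b, config)
  x <- strsplit(ali$rows1, "")[[1]]
  y <- strsplit(ali$rows2, "")[[1]]
  both <- x != "-" & y != "-"
  matches <- sum(both & x == y)
  list(a = ali$rows1, b = ali$rows2, score = ali$score,
       identity = if (any(both)) matches / sum(both) else 0,
       coverage = sum(both) / min(nchar(a), nchar(b)))
}

#' Drop gap-rich alignment columns
#'
#' @param alignment An `aqp_alignment`.
#' @param max_gap_fraction Columns with a gap fraction strictly above this
#'   value are removed.
#' @return list of class `aqp_trimmed` with fields `alignment` (trimmed),
#'   `kept_columns` (1-based original column indices) and
#'   `column_gap_fraction` (per original column).
#' @export
trim_gappy_columns <- function(alignment, max_gap_fraction = 0.8) {
  stopifnot(length(alignment$ids) > 0)
  m <- aln_matrix(alignment)
  gap_frac <- colMeans(m == "-")
  kept <- which(gap_frac <= max_gap_fraction)
  if (!length(kept)) stop("all columns exceed the gap-fraction threshold")
  rows <- apply(m[, kept, drop = FALSE], 1, paste, collapse = "")
  structure(list(alignment = aqp_alignment(alignment$ids, rows),
                 kept_columns = kept,
                 column_gap_fraction = unname(gap_frac)),
            class = "aqp_trimmed")
}
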