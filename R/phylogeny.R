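#' Pairwise protein distances from a trimmed alignment
#'
#' Distances are computed over the columns where both rows carry a residue;
#' each pair needs at least 20 such columns. `p` is the mismatch fraction;
#' the Poisson correction `d = -ln(1 - p)` is the default, `"raw"` returns
#' `p`. Pairs at `p >= 0.95` are capped at the `p = 0.95` distance and
#' recorded in the `capped` attribute.
#'
#' @param trimmed `aqp_trimmed` from [trim_gappy_columns()].
#' @param correction `"poisson"` or `"raw"`.
#' @return Symmetric numeric matrix with zero diagonal, ids as dimnames and
#'   a `capped` attribute (two-column matrix of id pairs).
#' @export
protein_distance <- function(trimmed, correction = c("poisson", "raw")) {
  correction <- match.arg(correction)
  m <- aln_matrix(trimmed$alignment)
  n <- nrow(m)
  stopifnot(n >= 2)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  capped <- NULL
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      if (sum(both) < 20) {
        stop("fewer than 20 shared columns for pair ",
             rownames(m)[i], " / ", rownames(m)[j])
      }
      p <- mean(m[i, both] != m[j, both])
      if (p >= 0.95) {
        capped <- rbind(capped, c(rownames(m)[i], rownames(m)[j]))
        p <- 0.95
      }
      D[i, j] <- D[j, i] <- if (correction == "poisson") -log(1 - p) else p
    }
  }
  attr(D, "capped") <- capped
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the standard Q criterion and
#' branch-length formulas. Ties on Q break toward the lexicographically
#' smallest id pair, making the result deterministic. Negative branch-length
#' estimates are clamped to zero with a warning.
#'
#' @param D Symmetric distance matrix with ids as dimnames (n >= 3).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  ids <- rownames(D)
  n <- length(ids)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  stopifnot(isTRUE(all.equal(D, t(D))), all(diag(D) == 0))
  labels <- ids                 # newick fragment per active cluster
  d <- D
  clamped <- FALSE
  fmt <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.17g", x)
  }
  while (length(labels) > 3) {
    k <- length(labels)
    r <- rowSums(d)
    Q <- (k - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij)
      paste(sort(c(rownames(d)[ij[1]], rownames(d)[ij[2]])), collapse = "\r"))
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    bj <- d[i, j] - bi
    new_lab <- paste0("(", labels[i], ":", fmt(bi), ",",
                      labels[j], ":", fmt(bj), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nm <- c(rownames(d)[keep], paste0("node", k))
    dimnames(d2) <- list(nm, nm)
    d <- d2
    labels <- c(labels[keep], new_lab)
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- paste0("(", labels[1], ":", fmt(b1), ",", labels[2], ":", fmt(b2),
                   ",", labels[3], ":", fmt(b3), ");")
  if (clamped) warning("negative branch-length estimate(s) clamped to 0")
  ape::read.tree(text = newick)
}

#' Assign subgroups from labelled tree leaves
#'
#' Every unlabelled leaf inherits the subgroup of its nearest labelled leaf
#' by patristic (path) distance; ties break toward the lexicographically
#' smallest labelled id. A leaf is flagged ambiguous when the smallest
#' unrooted split containing it together with its nearest labelled leaf also
#' contains labels of two or more subgroups.
#'
#' @param tree `ape::phylo` with leaf labels.
#' @param labeled Named character vector mapping leaf id to subgroup.
#' @return data.frame with columns `id`, `subgroup`, `nearest_label`,
#'   `ambiguous`; labelled leaves keep their labels.
#' @export
assign_subgroups <- function(tree, labeled) {
  if (!length(labeled)) stop("no labelled leaves supplied")
  stopifnot(all(names(labeled) %in% tree$tip.label))
  pd <- ape::cophenetic.phylo(tree)
  tips <- tree$tip.label
  lab_ids <- sort(names(labeled))
  out <- data.frame(id = tips, subgroup = NA_character_,
                    nearest_label = NA_character_, ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  splits <- .leaf_splits(tree)
  for (i in seq_along(tips)) {
    tip <- tips[i]
    if (tip %in% lab_ids) {
      out$subgroup[i] <- labeled[[tip]]
      out$nearest_label[i] <- tip
      next
    }
    dists <- pd[tip, lab_ids]
    nearest <- lab_ids[order(dists, lab_ids)[1]]
    out$subgroup[i] <- labeled[[nearest]]
    out$nearest_label[i] <- nearest
    # smallest split side holding both the query and its nearest label
    sizes <- vapply(splits, length, integer(1))
    holds <- vapply(splits, function(s) tip %in% s && nearest %in% s,
                    logical(1))
    if (any(holds)) {
      side <- splits[[which(holds)[which.min(sizes[holds])]]]
      sg <- unique(unlist(labeled[intersect(side, names(labeled))]))
      if (length(sg) > 1) out$ambiguous[i] <- TRUE
    }
  }
  out
}

# all leaf bipartition sides (both sides of every edge) of an unrooted tree
.leaf_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  adj <- split(c(tree$edge[, 2], tree$edge[, 1]),
               c(tree$edge[, 1], tree$edge[, 2]))
  side_leaves <- function(from, to) {
    seen <- c(from, to)
    collected <- to
    stack <- to
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      nb <- setdiff(adj[[as.character(v)]], seen)
      seen <- c(seen, nb)
      collected <- c(collected, nb)
      stack <- c(stack, nb)
    }
    tree$tip.label[collected[collected <= ntip]]
  }
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    out[[2 * e - 1]] <- side_leaves(a, b)
    out[[2 * e]] <- setdiff(tree$tip.label, out[[2 * e - 1]])
  }
  unique(out)
}
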