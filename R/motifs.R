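#' Consensus transmembrane column spans of a trimmed alignment
#'
#' Each row's ungapped sequence is run through the hydropathy TM predictor
#' and its spans are mapped into trimmed-column space; columns covered in at
#' least `min_support` of the rows form the consensus, whose maximal runs
#' are the consensus helix intervals.
#'
#' @param trimmed `aqp_trimmed`.
#' @param min_support Column support fraction (default 0.5).
#' @param config Configuration list from [aqp_config()].
#' @return Integer matrix with columns `start`, `end` (1-based trimmed
#'   columns), one row per consensus interval, ordered by start.
#' @export
consensus_tm_spans <- function(trimmed, min_support = 0.5,
                               config = aqp_config()) {
  aln <- trimmed$alignment
  cover <- numeric(aln$ncols)
  for (id in aln$ids) {
    seq_i <- aln_ungap(aln, id)
    if (nchar(seq_i) < config$tm_window) next
    tm <- predict_tm_helices(seq_i, config)
    cols <- aln_residue_columns(aln, id)
    for (r in seq_len(nrow(tm$spans))) {
      idx <- (tm$spans[r, 1]:tm$spans[r, 2]) + 1L
      cover[cols[idx]] <- cover[cols[idx]] + 1
    }
  }
  runs <- .runs_from_positions(which(cover / length(aln$ids) >= min_support))
  colnames(runs) <- c("start", "end")
  runs
}

#' Segment the trimmed alignment into the 14-position domain architecture
#'
#' The six consensus helix intervals anchor the tiling: N-terminus, the six
#' helix blocks, the inter-helix loops and the C-terminus give up to 13
#' blocks; the widest non-helix blocks are then split in half (leftmost
#' first on ties) until exactly 14 contiguous blocks tile all columns.
#'
#' @param trimmed `aqp_trimmed`.
#' @param tm_spans Matrix from [consensus_tm_spans()]; when more than six
#'   intervals are found the six longest are kept, fewer than six is an
#'   error.
#' @param filter_columns list from [locate_filter_columns()] (optional) used
#'   to report which blocks carry the ar/R filter residues.
#' @return list with `blocks` (data.frame `block`, `start`, `end`, `role`)
#'   and `filter_block_ids`.
#' @export
segment_domain <- function(trimmed, tm_spans, filter_columns = NULL) {
  nc <- trimmed$alignment$ncols
  if (nrow(tm_spans) < 6) {
    stop("need at least 6 consensus helix intervals, found ", nrow(tm_spans))
  }
  if (nrow(tm_spans) > 6) {
    len <- tm_spans[, 2] - tm_spans[, 1] + 1
    keep <- order(-len, tm_spans[, 1])[1:6]
    tm_spans <- tm_spans[sort(keep), , drop = FALSE]
  }
  helix_roles <- paste0("H", 1:6)
  blocks <- data.frame(start = integer(), end = integer(), role = character(),
                       stringsAsFactors = FALSE)
  add <- function(blocks, s, e, role) {
    if (s <= e) rbind(blocks, data.frame(start = s, end = e, role = role,
                                         stringsAsFactors = FALSE))
    else blocks
  }
  blocks <- add(blocks, 1L, tm_spans[1, 1] - 1L, "N-term")
  for (h in 1:6) {
    blocks <- add(blocks, tm_spans[h, 1], tm_spans[h, 2], helix_roles[h])
    if (h < 6) {
      loop_role <- switch(as.character(h), "2" = "LB", "5" = "LE",
                          "inter-helix")
      blocks <- add(blocks, tm_spans[h, 2] + 1L, tm_spans[h + 1, 1] - 1L,
                    loop_role)
    }
  }
  blocks <- add(blocks, tm_spans[6, 2] + 1L, nc, "C-term")
  while (nrow(blocks) < 14) {
    widths <- blocks$end - blocks$start + 1
    splittable <- !(blocks$role %in% helix_roles) & widths >= 2
    if (!any(splittable)) stop("cannot reach 14 blocks: no splittable block")
    pick <- which(splittable)[which.max(widths[splittable])]
    s <- blocks$start[pick]; e <- blocks$end[pick]
    mid <- s + (e - s) %/% 2
    left <- data.frame(start = s, end = mid, role = blocks$role[pick],
                       stringsAsFactors = FALSE)
    right <- data.frame(start = mid + 1L, end = e, role = blocks$role[pick],
                        stringsAsFactors = FALSE)
    blocks <- rbind(blocks[seq_len(pick - 1), ], left, right,
                    blocks[-seq_len(pick), ])
  }
  blocks <- blocks[order(blocks$start), ]
  blocks$block <- seq_len(nrow(blocks))
  rownames(blocks) <- NULL
  filter_block_ids <- integer()
  if (!is.null(filter_columns)) {
    for (col in unlist(filter_columns)) {
      filter_block_ids <- c(filter_block_ids,
                            blocks$block[blocks$start <= col & col <= blocks$end])
    }
    filter_block_ids <- sort(unique(filter_block_ids))
  }
  list(blocks = blocks[, c("block", "start", "end", "role")],
       filter_block_ids = filter_block_ids)
}

# identity of two gapped block strings: matching residue columns over
# columns where either string has a residue
.block_identity <- function(x, y) {
  either <- x != "-" | y != "-"
  if (!any(either)) return(0)
  sum(x == y & x != "-" & either) / sum(either)
}

#' Label block occurrences as motifs
#'
#' Within each architecture block, the rows' block subsequences are
#' single-linkage clustered at the identity threshold; each cluster becomes
#' one motif label, numbered by descending frequency (ties by consensus
#' string), so labels are invariant to row order. Rows that are all-gap in a
#' block carry no label there.
#'
#' @param trimmed `aqp_trimmed`.
#' @param architecture list from [segment_domain()].
#' @param identity_threshold Single-linkage threshold (default 0.7).
#' @return list of class `aqp_motif_catalog`: per block, `labels` (named
#'   integer vector per row id, `NA` = absent) and `consensus` (per label).
#' @export
label_block_motifs <- function(trimmed, architecture,
                               identity_threshold = 0.7) {
  m <- aln_matrix(trimmed$alignment)
  ids <- rownames(m)
  out <- list()
  for (b in seq_len(nrow(architecture$blocks))) {
    cols <- architecture$blocks$start[b]:architecture$blocks$end[b]
    sub <- m[, cols, drop = FALSE]
    occupied <- rowSums(sub != "-") > 0
    idx <- which(occupied)
    labels <- setNames(rep(NA_integer_, length(ids)), ids)
    consensus <- character()
    if (length(idx)) {
      parent <- seq_along(idx)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      if (length(idx) > 1) {
        for (i in 1:(length(idx) - 1)) {
          for (j in (i + 1):length(idx)) {
            if (.block_identity(sub[idx[i], ], sub[idx[j], ]) >=
                identity_threshold) {
              ri <- find(i); rj <- find(j)
              if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
            }
          }
        }
      }
      roots <- vapply(seq_along(idx), find, integer(1))
      clusters <- split(idx, roots)
      cons <- vapply(clusters, function(rows) {
        apply(sub[rows, , drop = FALSE], 2, function(col) {
          col <- col[col != "-"]
          if (!length(col)) "-" else names(sort(table(col),
                                                decreasing = TRUE))[1]
        }) |> paste(collapse = "")
      }, "")
      sizes <- vapply(clusters, length, integer(1))
      ord <- order(-sizes, cons)
      for (rank in seq_along(ord)) {
        labels[clusters[[ord[rank]]]] <- rank
      }
      consensus <- cons[ord]
    }
    out[[b]] <- list(labels = labels, consensus = unname(consensus))
  }
  structure(list(blocks = out, ids = ids,
                 architecture = architecture), class = "aqp_motif_catalog")
}

#' Per-group motif occupancy counts
#'
#' @param catalog `aqp_motif_catalog`.
#' @param group_map Named character vector mapping row id to group.
#' @return data.frame with columns `block`, `motif`, `group`, `count`.
#' @export
motif_counts <- function(catalog, group_map) {
  res <- list()
  for (b in seq_along(catalog$blocks)) {
    labels <- catalog$blocks[[b]]$labels
    ok <- !is.na(labels)
    if (!any(ok)) next
    tab <- table(motif = labels[ok], group = group_map[names(labels)[ok]])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, , drop = FALSE]
    if (nrow(df)) {
      res[[length(res) + 1]] <- data.frame(
        block = b, motif = as.integer(df$motif), group = df$group,
        count = df$Freq, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Detect group-specific motifs
#'
#' A motif is specific to group G when its frequency is at least `min_in`
#' within G and at most `max_out` outside G.
#'
#' @param catalog `aqp_motif_catalog`.
#' @param group_map Named character vector mapping row id to group.
#' @param min_in,max_out Frequency thresholds.
#' @return data.frame with columns `block`, `motif`, `group`, `freq_in`,
#'   `freq_out`.
#' @export
find_group_specific_motifs <- function(catalog, group_map, min_in = 0.6,
                                       max_out = 0.1) {
  groups <- unique(group_map)
  res <- list()
  for (b in seq_along(catalog$blocks)) {
    labels <- catalog$blocks[[b]]$labels
    for (mo in sort(unique(labels[!is.na(labels)]))) {
      has <- !is.na(labels) & labels == mo
      for (g in groups) {
        ing <- group_map[names(labels)] == g
        fin <- sum(has & ing) / sum(ing)
        fout <- if (any(!ing)) sum(has & !ing) / sum(!ing) else 0
        if (fin >= min_in && fout <= max_out) {
          res[[length(res) + 1]] <- data.frame(
            block = b, motif = mo, group = g, freq_in = fin,
            freq_out = fout, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(block = integer(), motif = integer(),
                      group = character(), freq_in = numeric(),
                      freq_out = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}
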