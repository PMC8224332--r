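#' Find candidate duplicate gene pairs
#'
#' All-vs-all global protein alignment with the package scorer; pairs
#' meeting both the identity and coverage thresholds are kept, each reported
#' once with `gene_a < gene_b`.
#'
#' @param records data.frame from [read_fasta()] (proteins).
#' @param min_identity,min_coverage Retention thresholds.
#' @param config Configuration list from [aqp_config()].
#' @return data.frame with columns `gene_a`, `gene_b`, `identity`,
#'   `coverage`.
#' @export
find_duplicate_pairs <- function(records,
                                 min_identity = aqp_config()$min_pair_identity,
                                 min_coverage = aqp_config()$min_pair_coverage,
                                 config = aqp_config()) {
  n <- nrow(records)
  stopifnot(n >= 2)
  res <- list()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ali <- pairwise_align(records$sequence[i], records$sequence[j], config)
      if (ali$identity >= min_identity && ali$coverage >= min_coverage) {
        ids <- sort(c(records$id[i], records$id[j]))
        res[[length(res) + 1]] <- data.frame(
          gene_a = ids[1], gene_b = ids[2],
          identity = ali$identity, coverage = ali$coverage,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Classify the duplication mode of a gene pair
#'
#' Same sequence and an inter-gene gap at most `tandem_max_gap_bp` is
#' tandem; same sequence within `proximal_max_gap_bp` is proximal; otherwise
#' dispersed. Pairs with an unlocated gene are unplaced. The gap is the
#' distance between the facing gene ends (0 when the loci overlap).
#'
#' @param gene_a,gene_b Gene ids.
#' @param loci data.frame from [read_gff3()].
#' @param config Configuration list from [aqp_config()].
#' @return One of `"tandem"`, `"proximal"`, `"dispersed"`, `"unplaced"`.
#' @export
classify_pair_mode <- function(gene_a, gene_b, loci, config = aqp_config()) {
  ia <- match(gene_a, loci$gene_id)
  ib <- match(gene_b, loci$gene_id)
  if (is.na(ia) || is.na(ib)) return("unplaced")
  if (loci$seqname[ia] != loci$seqname[ib]) return("dispersed")
  gap <- max(0, max(loci$start[ia], loci$start[ib]) -
               min(loci$end[ia], loci$end[ib]))
  if (gap <= config$tandem_max_gap_bp) return("tandem")
  if (gap <= config$proximal_max_gap_bp) return("proximal")
  "dispersed"
}

#' Merge tandem pairs into tandem arrays
#'
#' Arrays are the connected components of the tandem-pair graph; members are
#' ordered by start coordinate.
#'
#' @param pairs data.frame with `gene_a`, `gene_b` and a `mode` column
#'   (only `mode == "tandem"` rows are used) or tandem pairs only.
#' @param loci data.frame from [read_gff3()].
#' @return list of character vectors (one per array, ordered by position).
#' @export
merge_tandem_arrays <- function(pairs, loci) {
  if (!is.null(pairs$mode)) pairs <- pairs[pairs$mode == "tandem", ,
                                           drop = FALSE]
  if (!nrow(pairs)) return(list())
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  parent <- seq_along(genes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(match(pairs$gene_a[r], genes))
    rb <- find(match(pairs$gene_b[r], genes))
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(genes), find, integer(1))
  arrays <- split(genes, roots)
  arrays <- lapply(arrays, function(g) {
    ix <- match(g, loci$gene_id)
    g[order(loci$seqname[ix], loci$start[ix])]
  })
  names(arrays) <- NULL
  arrays[order(vapply(arrays, `[`, "", 1))]
}

#' Ka/Ks for duplicate pairs
#'
#' Aligns each protein pair, back-translates to codons and applies NG86
#' counting; the duplication mode is attached from the loci.
#'
#' @param pairs data.frame from [find_duplicate_pairs()].
#' @param records Protein records (data.frame with `id`, `sequence`).
#' @param cds CDS records (data.frame with `id`, `sequence`).
#' @param loci data.frame from [read_gff3()] or `NULL`.
#' @param config Configuration list from [aqp_config()].
#' @return `pairs` with added `mode`, `ka`, `ks`, `ka_ks`, `flags` columns.
#' @export
pair_ka_ks <- function(pairs, records, cds, loci = NULL,
                       config = aqp_config()) {
  pairs$mode <- NA_character_
  pairs$ka <- pairs$ks <- pairs$ka_ks <- NA_real_
  pairs$flags <- ""
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[r]; b <- pairs$gene_b[r]
    pairs$mode[r] <- if (is.null(loci)) "unplaced" else
      classify_pair_mode(a, b, loci, config)
    pa <- records$sequence[match(a, records$id)]
    pb <- records$sequence[match(b, records$id)]
    ali <- pairwise_align(pa, pb, config)
    ca <- backtranslate_alignment(ali$a, ali$b,
                                  cds$sequence[match(a, cds$id)],
                                  cds$sequence[match(b, cds$id)],
                                  ids = c(a, b))
    kk <- ka_ks_ng86(ca)
    pairs$ka[r] <- kk$ka
    pairs$ks[r] <- kk$ks
    pairs$ka_ks[r] <- kk$ka_ks
    pairs$flags[r] <- paste(kk$flags, collapse = ";")
  }
  pairs
}

#' Histogram of Ks values
#'
#' Pairs with a defined Ks below `ks_max` are binned with the given width;
#' counts are reported pooled and per group when a grouping is supplied.
#'
#' @param pairs data.frame with a `ks` column (e.g. from [pair_ka_ks()]).
#' @param ks_max Upper bound (exclusive); the conventional cut-off of 2
#'   removes saturated estimates.
#' @param bin_width Bin width.
#' @param groups Optional character vector (one per pair) for per-group
#'   counts.
#' @return data.frame with `bin_start`, `bin_end`, `group` (`"all"` pooled)
#'   and `count`.
#' @export
ks_distribution <- function(pairs, ks_max = 2, bin_width = 0.05,
                            groups = NULL) {
  ks <- pairs$ks
  keep <- !is.na(ks) & ks < ks_max
  breaks <- seq(0, ks_max, by = bin_width)
  tally <- function(v) {
    if (!length(v)) return(integer(length(breaks) - 1))
    as.integer(table(cut(v, breaks = breaks, right = FALSE,
                         include.lowest = FALSE)))
  }
  out <- data.frame(bin_start = breaks[-length(breaks)],
                    bin_end = breaks[-1],
                    group = "all",
                    count = tally(ks[keep]),
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    for (g in sort(unique(groups))) {
      sel <- keep & groups == g
      out <- rbind(out, data.frame(bin_start = breaks[-length(breaks)],
                                   bin_end = breaks[-1], group = g,
                                   count = tally(ks[sel]),
                                   stringsAsFactors = FALSE))
    }
  }
  out[out$count > 0 | out$group == "all", ]
}
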