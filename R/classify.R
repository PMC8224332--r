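#' Find the NPA anchor columns of a trimmed alignment
#'
#' For every row, the loop-B and loop-E NPA motifs are located on the
#' ungapped sequence and their asparagine positions are mapped through the
#' alignment into trimmed-column space. The consensus anchor column is the
#' trimmed column supported by the largest fraction of rows; it must reach
#' the configured support (default 70%).
#'
#' @param trimmed `aqp_trimmed` from [trim_gappy_columns()].
#' @param config Configuration list from [aqp_config()].
#' @return list with `npa_b_col`, `npa_e_col` (1-based trimmed columns) and
#'   the per-row anchor columns (`NA` where a row has no motif or its anchor
#'   was trimmed away).
#' @export
find_npa_columns <- function(trimmed, config = aqp_config()) {
  aln <- trimmed$alignment
  n <- length(aln$ids)
  row_b <- row_e <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    id <- aln$ids[i]
    seq_i <- aln_ungap(aln, id)
    npa <- find_npa_motifs(seq_i, config)
    if (is.null(npa)) next
    cols <- aln_residue_columns(aln, id)  # already trimmed-column space
    row_b[i] <- cols[npa$loop_b_pos + 1L]
    row_e[i] <- cols[npa$loop_e_pos + 1L]
  }
  consensus <- function(cols, which) {
    tab <- table(cols)
    if (!length(tab)) stop("no row carries a detectable ", which, " NPA motif")
    best <- as.integer(names(tab)[which.max(tab)])
    if (max(tab) / n < config$npa_column_support) {
      stop(which, " NPA anchor column support ",
           round(max(tab) / n, 2), " below required ",
           config$npa_column_support)
    }
    best
  }
  list(npa_b_col = consensus(row_b, "loop-B"),
       npa_e_col = consensus(row_e, "loop-E"),
       row_b = row_b, row_e = row_e)
}

#' Locate the four ar/R selectivity-filter columns
#'
#' The H2 column is offset from the loop-B NPA anchor; H5, LE1 and LE2 are
#' offset from the loop-E anchor. Offsets are frozen in the configuration
#' (defaults follow the canonical AQP fold geometry).
#'
#' @param trimmed `aqp_trimmed` from [trim_gappy_columns()].
#' @param npa_b_col,npa_e_col 1-based trimmed anchor columns.
#' @param offsets Named numeric vector `h2`, `h5`, `le1`, `le2`.
#' @return list with 1-based trimmed columns `h2_col`, `h5_col`, `le1_col`,
#'   `le2_col`.
#' @export
locate_filter_columns <- function(trimmed, npa_b_col, npa_e_col,
                                  offsets = aqp_config()$filter_offsets) {
  cols <- c(h2_col = npa_b_col + offsets[["h2"]],
            h5_col = npa_e_col + offsets[["h5"]],
            le1_col = npa_e_col + offsets[["le1"]],
            le2_col = npa_e_col + offsets[["le2"]])
  nc <- trimmed$alignment$ncols
  if (any(cols < 1 | cols > nc)) {
    stop("filter column out of alignment range [1, ", nc, "]: ",
         paste(names(cols)[cols < 1 | cols > nc], collapse = ", "))
  }
  as.list(setNames(as.integer(cols), names(cols)))
}

#' Extract the ar/R filter residues of one aligned row
#'
#' @param trimmed `aqp_trimmed`.
#' @param id Row identifier.
#' @param filter_columns list from [locate_filter_columns()].
#' @return Named character vector `h2`, `h5`, `le1`, `le2`; gaps become `-`.
#' @export
extract_arr_filter <- function(trimmed, id, filter_columns) {
  row <- strsplit(trimmed$alignment$rows[match(id, trimmed$alignment$ids)],
                  "")[[1]]
  c(h2 = row[filter_columns$h2_col], h5 = row[filter_columns$h5_col],
    le1 = row[filter_columns$le1_col], le2 = row[filter_columns$le2_col])
}

.pattern_matches <- function(filter, pattern) {
  pos <- c("h2", "h5", "le1", "le2")
  present <- which(filter[pos] != "-")
  all(vapply(present, function(i) {
    allowed <- pattern[[pos[i]]]
    allowed == "." || grepl(filter[[pos[i]]], allowed, fixed = TRUE)
  }, logical(1)))
}

#' Classify a filter quadruplet against the signature table
#'
#' Requires at least three non-missing positions, all of which must fall in
#' the allowed residue set of a pattern. When matching patterns span more
#' than one subfamily the call is ambiguous and the gene is left
#' unclassified (to be routed to the nearest-neighbour fallback); within one
#' subfamily the highest-priority (earliest) pattern supplies the
#' provisional subgroup.
#'
#' @param filter Named character vector `h2`, `h5`, `le1`, `le2`.
#' @param table Signature table from [load_signature_table()].
#' @return list with `subfamily`, `subgroup`, `method = "signature"` and
#'   `reason = "ok"`; or a list with `subfamily = NA` and `reason` one of
#'   `"insufficient"` (fewer than three residues present), `"nomatch"` or
#'   `"ambiguous"` (matching patterns span several subfamilies).
#' @export
classify_by_signature <- function(filter, table = load_signature_table()) {
  unclassified <- function(reason) {
    list(subfamily = NA_character_, subgroup = NA_character_,
         method = NA_character_, reason = reason)
  }
  if (sum(filter[c("h2", "h5", "le1", "le2")] != "-") < 3) {
    return(unclassified("insufficient"))
  }
  hits <- which(vapply(seq_len(nrow(table)), function(r)
    .pattern_matches(filter, table[r, ]), logical(1)))
  if (!length(hits)) return(unclassified("nomatch"))
  fams <- unique(table$subfamily[hits])
  if (length(fams) > 1) return(unclassified("ambiguous"))
  list(subfamily = fams, subgroup = table$subgroup[hits[1]],
       method = "signature", reason = "ok")
}

#' Classify by best global-alignment match against labelled references
#'
#' @param query Sequence string.
#' @param ref_records data.frame with columns `id`, `sequence`.
#' @param ref_calls data.frame with columns `id`, `subfamily`, `subgroup`.
#' @param config Configuration list from [aqp_config()].
#' @return list with `subfamily`, `subgroup`, `method = "fallback"` and
#'   `best_match_id`. Ties on score break by higher percent identity, then
#'   lexicographically smaller reference id.
#' @export
classify_by_nearest <- function(query, ref_records, ref_calls,
                                config = aqp_config()) {
  stopifnot(nrow(ref_records) >= 1)
  scores <- identities <- numeric(nrow(ref_records))
  for (i in seq_len(nrow(ref_records))) {
    ali <- pairwise_align(query, ref_records$sequence[i], config)
    scores[i] <- ali$score
    identities[i] <- ali$identity
  }
  ord <- order(-scores, -identities, ref_records$id)
  best <- ord[1]
  call <- ref_calls[match(ref_records$id[best], ref_calls$id), ]
  list(subfamily = call$subfamily, subgroup = call$subgroup,
       method = "fallback", best_match_id = ref_records$id[best])
}

#' Assign family gene names
#'
#' Names follow the `<prefix><subgroup>;<index>` convention; indices run
#' within each subgroup over chromosome-anchored genes first (ordered by
#' chromosome name then start), followed by scaffold-placed genes (ordered
#' by scaffold name then start). Re-running on an already-named set
#' reproduces the same names.
#'
#' @param calls data.frame with columns `id`, `subfamily`, `subgroup`.
#' @param loci data.frame from [read_gff3()].
#' @param species_prefix e.g. `"Ca"`.
#' @return `calls` with an added `assigned_name` column.
#' @export
assign_names <- function(calls, loci, species_prefix) {
  if (any(is.na(calls$subgroup) | calls$subgroup == "")) {
    stop("cannot assign names with unresolved subgroups")
  }
  ix <- match(calls$id, loci$gene_id)
  if (anyNA(ix)) stop("missing loci for: ",
                      paste(calls$id[is.na(ix)], collapse = ", "))
  key <- order(calls$subgroup,
               !loci$chromosome_flag[ix],
               loci$seqname[ix],
               loci$start[ix])
  calls$assigned_name <- NA_character_
  counters <- list()
  for (r in key) {
    sg <- calls$subgroup[r]
    counters[[sg]] <- (counters[[sg]] %||% 0L) + 1L
    calls$assigned_name[r] <- paste0(species_prefix, sg, ";", counters[[sg]])
  }
  calls
}

#' Extract the ar/R filter of one sequence from its own NPA anchors
#'
#' Residue-space counterpart of [extract_arr_filter()]: positions are the
#' configured offsets applied to the sequence's own loop-B and loop-E NPA
#' anchors, so a row misregistered in the alignment (an insertion between
#' the anchors) is still read correctly. Out-of-range positions give `-`.
#'
#' @param sequence Amino-acid string.
#' @param npa list from [find_npa_motifs()].
#' @param offsets Named numeric vector `h2`, `h5`, `le1`, `le2`.
#' @return Named character vector `h2`, `h5`, `le1`, `le2`.
#' @export
extract_arr_filter_by_anchor <- function(sequence, npa,
                                         offsets =
                                           aqp_config()$filter_offsets) {
  pos <- c(h2 = npa$loop_b_pos + offsets[["h2"]],
           h5 = npa$loop_e_pos + offsets[["h5"]],
           le1 = npa$loop_e_pos + offsets[["le1"]],
           le2 = npa$loop_e_pos + offsets[["le2"]]) + 1
  chars <- strsplit(sequence, "")[[1]]
  out <- rep("-", 4)
  ok <- pos >= 1 & pos <= length(chars)
  out[ok] <- chars[pos[ok]]
  setNames(out, c("h2", "h5", "le1", "le2"))
}

#' Classify a protein family end to end
#'
#' Aligns the records, trims gappy columns, anchors the filter columns on
#' the NPA consensus columns and extracts the ar/R residues — per row from
#' the row's own NPA anchors where they are detectable, from the consensus
#' filter columns otherwise — then classifies by signature and routes the
#' remainder through the nearest-neighbour fallback against the
#' signature-classified genes.
#'
#' @param records data.frame from [read_fasta()].
#' @param signature_table Signature table from [load_signature_table()].
#' @param config Configuration list from [aqp_config()].
#' @return list with the trimmed alignment, filter columns and a data.frame
#'   `calls` (id, residues, subfamily, subgroup, method, best_match_id).
#' @export
classify_family <- function(records, signature_table = load_signature_table(),
                            config = aqp_config()) {
  aln <- progressive_align(records, config)
  trimmed <- trim_gappy_columns(aln, config$max_gap_fraction)
  anchors <- find_npa_columns(trimmed, config)
  fc <- locate_filter_columns(trimmed, anchors$npa_b_col, anchors$npa_e_col,
                              config$filter_offsets)
  n <- nrow(records)
  calls <- data.frame(id = records$id,
                      h2 = NA_character_, h5 = NA_character_,
                      le1 = NA_character_, le2 = NA_character_,
                      subfamily = NA_character_, subgroup = NA_character_,
                      method = NA_character_, best_match_id = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    npa_i <- find_npa_motifs(records$sequence[i], config)
    filt <- if (!is.null(npa_i)) {
      extract_arr_filter_by_anchor(records$sequence[i], npa_i,
                                   config$filter_offsets)
    } else {
      extract_arr_filter(trimmed, records$id[i], fc)
    }
    calls[i, c("h2", "h5", "le1", "le2")] <- as.list(filt)
    sig <- classify_by_signature(filt, signature_table)
    if (identical(sig$reason, "ok")) {
      calls$subfamily[i] <- sig$subfamily
      calls$subgroup[i] <- sig$subgroup
      calls$method[i] <- "signature"
    }
  }
  labelled <- !is.na(calls$method)
  if (any(!labelled) && any(labelled)) {
    refs <- records[labelled, , drop = FALSE]
    ref_calls <- calls[labelled, c("id", "subfamily", "subgroup")]
    for (i in which(!labelled)) {
      nn <- classify_by_nearest(records$sequence[i], refs, ref_calls, config)
      calls$subfamily[i] <- nn$subfamily
      calls$subgroup[i] <- nn$subgroup
      calls$method[i] <- "fallback"
      calls$best_match_id[i] <- nn$best_match_id
    }
  }
  list(trimmed = trimmed, anchors = anchors, filter_columns = fc,
       calls = calls)
}
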