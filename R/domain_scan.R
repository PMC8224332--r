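#' Locate the two NPA motifs of an AQP-like sequence
#'
#' Scans for N-P-x triplets where x is one of the tolerated third residues
#' (exact NPA plus the relaxed variants seen in plant SIP/NIP loop-B motifs)
#' and selects the candidate pair whose separation falls inside the
#' configured window, preferring pairs with more exact `NPA` matches; among
#' equally canonical pairs the leftmost (smallest loop-B position, then
#' smallest loop-E position) wins.
#'
#' @param sequence Amino-acid string.
#' @param config Configuration list from [aqp_config()].
#' @return list with 0-based `loop_b_pos`, `loop_e_pos` and the matched
#'   `variants` (length-2 character), or `NULL` when no valid pair exists.
#' @export
find_npa_motifs <- function(sequence, config = aqp_config()) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 3) return(NULL)
  starts <- which(chars[-c(n - 1, n)] == "N" & chars[2:(n - 1)] == "P" &
                    chars[3:n] %in% config$npa_third)
  if (length(starts) < 2) return(NULL)
  triplets <- vapply(starts, function(i) paste(chars[i:(i + 2)], collapse = ""),
                     "")
  best <- NULL
  for (i in seq_along(starts)) {
    for (j in seq_along(starts)) {
      if (j <= i) next
      sep <- starts[j] - starts[i]
      if (sep < config$npa_min_sep || sep > config$npa_max_sep) next
      key <- c(sum(triplets[c(i, j)] == "NPA"), -starts[i], -starts[j])
      if (is.null(best) || .lex_gt(key, best$key)) {
        best <- list(i = i, j = j, key = key)
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(loop_b_pos = starts[best$i] - 1L,
       loop_e_pos = starts[best$j] - 1L,
       variants = unname(triplets[c(best$i, best$j)]))
}

# lexicographic strictly-greater on numeric vectors
.lex_gt <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] > 0
}

#' Predict transmembrane helices by Kyte-Doolittle hydropathy
#'
#' Computes the sliding-window mean hydropathy, takes maximal runs of window
#' centres at or above the threshold, merges runs separated by fewer than
#' `tm_merge_gap` residues, and keeps runs of at least `tm_min_len` residues.
#'
#' @param sequence Amino-acid string, at least as long as the window.
#' @param config Configuration list from [aqp_config()]; fields `tm_window`,
#'   `tm_threshold`, `tm_merge_gap`, `tm_min_len`.
#' @return list with `spans` (matrix of 0-based inclusive `start`,`end`
#'   residue intervals) and `score_profile` (per window-centre score).
#' @export
predict_tm_helices <- function(sequence, config = aqp_config()) {
  chars <- strsplit(sequence, "")[[1]]
  w <- config$tm_window
  if (length(chars) < w) {
    stop("sequence shorter than the hydropathy window (", w, ")")
  }
  h <- unname(KD_HYDROPATHY[chars])
  h[is.na(h)] <- 0
  prof <- as.numeric(stats::filter(h, rep(1 / w, w), sides = 2))
  centers <- which(!is.na(prof) & prof >= config$tm_threshold)
  spans <- .runs_from_positions(centers)
  if (nrow(spans)) {
    # merge spans separated by small gaps
    merged <- spans[1, , drop = FALSE]
    if (nrow(spans) > 1) {
      for (r in 2:nrow(spans)) {
        if (spans[r, 1] - merged[nrow(merged), 2] - 1 < config$tm_merge_gap) {
          merged[nrow(merged), 2] <- spans[r, 2]
        } else {
          merged <- rbind(merged, spans[r, , drop = FALSE])
        }
      }
    }
    spans <- merged[merged[, 2] - merged[, 1] + 1 >= config$tm_min_len, ,
                    drop = FALSE]
  }
  spans <- spans - 1L  # 0-based
  colnames(spans) <- c("start", "end")
  list(spans = spans, score_profile = prof)
}

.runs_from_positions <- function(pos) {
  if (!length(pos)) return(matrix(integer(), 0, 2))
  breaks <- which(diff(pos) > 1)
  starts <- pos[c(1, breaks + 1)]
  ends <- pos[c(breaks, length(pos))]
  cbind(starts, ends)
}

#' Decide whether a sequence is an AQP candidate
#'
#' A candidate must carry two NPA motifs at a valid separation, have a
#' predicted transmembrane-helix count inside the accepted window (default
#' 5-7, tolerant of truncated gene models) and a length inside the accepted
#' range (default 200-400 residues, the small-protein range typical of the
#' family).
#'
#' @param sequence Amino-acid string.
#' @param config Configuration list from [aqp_config()].
#' @return list with `candidate` (logical), `reasons` (character vector of
#'   failed criteria among `"npa"`, `"tm"`, `"length"`), `npa` and `tm`.
#' @export
is_candidate_aqp <- function(sequence, config = aqp_config()) {
  reasons <- character()
  len <- nchar(sequence)
  if (len < config$length_range[1] || len > config$length_range[2]) {
    reasons <- c(reasons, "length")
  }
  npa <- find_npa_motifs(sequence, config)
  if (is.null(npa)) reasons <- c(reasons, "npa")
  tm <- if (len >= config$tm_window) predict_tm_helices(sequence, config) else
    list(spans = matrix(integer(), 0, 2))
  ntm <- nrow(tm$spans)
  if (ntm < config$tm_count_range[1] || ntm > config$tm_count_range[2]) {
    reasons <- c(reasons, "tm")
  }
  list(candidate = length(reasons) == 0, reasons = reasons, npa = npa, tm = tm)
}

#' Scan a protein set for AQP candidates
#'
#' @param records data.frame from [read_fasta()].
#' @param config Configuration list from [aqp_config()].
#' @return data.frame with per-record NPA positions, TM count, verdict and
#'   reasons.
#' @export
scan_candidates <- function(records, config = aqp_config()) {
  res <- lapply(records$sequence, is_candidate_aqp, config = config)
  data.frame(
    id = records$id,
    npa_b = vapply(res, function(r) if (is.null(r$npa)) NA_integer_ else
      r$npa$loop_b_pos, integer(1)),
    npa_e = vapply(res, function(r) if (is.null(r$npa)) NA_integer_ else
      r$npa$loop_e_pos, integer(1)),
    tm_count = vapply(res, function(r) nrow(r$tm$spans), integer(1)),
    candidate = vapply(res, `[[`, logical(1), "candidate"),
    reasons = vapply(res, function(r) paste(r$reasons, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
}
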