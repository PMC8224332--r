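# Nei-Gojobori (1986) codon counting with Jukes-Cantor correction.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
NUCS <- c("A", "C", "G", "T")

#' Translate a coding sequence
#' @param cds Nucleotide string with length a multiple of 3.
#' @return Amino-acid string; codons containing ambiguity become `X`, stop
#'   codons become `*`.
#' @export
translate_cds <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- GENETIC_CODE_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# fraction of synonymous sites per codon position (NG86 site counting;
# changes to stop codons count as nonsynonymous)
.ng86_syn_sites <- function(codon) {
  aa <- GENETIC_CODE_TABLE[[codon]]
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    for (nt in setdiff(NUCS, chars[p])) {
      mut <- chars
      mut[p] <- nt
      if (identical(GENETIC_CODE_TABLE[[paste(mut, collapse = "")]], aa)) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

.ng86_env <- new.env(parent = emptyenv())

.ng86_sites_table <- function() {
  if (is.null(.ng86_env$sites)) {
    .ng86_env$sites <- vapply(SENSE_CODONS, .ng86_syn_sites, numeric(1))
  }
  .ng86_env$sites
}

# average synonymous/nonsynonymous differences between two sense codons over
# all minimal mutational pathways, excluding pathways that pass through a
# stop codon. Returns c(sd, nd), or c(NA, NA) when every pathway is blocked.
.ng86_pair_diff <- function(a, b) {
  if (is.null(.ng86_env$pairs)) .ng86_env$pairs <- new.env(parent = emptyenv())
  key <- paste(a, b)
  if (exists(key, envir = .ng86_env$pairs, inherits = FALSE)) {
    return(get(key, envir = .ng86_env$pairs))
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  diff_pos <- which(ca != cb)
  k <- length(diff_pos)
  res <- c(sd = 0, nd = 0)
  if (k > 0) {
    perms <- if (k == 1) list(diff_pos) else
      apply(.permutations(diff_pos), 1, identity, simplify = FALSE)
    tot_sd <- tot_nd <- 0
    n_valid <- 0
    for (ord in perms) {
      cur <- ca
      sd <- nd <- 0
      ok <- TRUE
      for (p in ord) {
        nxt <- cur
        nxt[p] <- cb[p]
        cod1 <- paste(cur, collapse = "")
        cod2 <- paste(nxt, collapse = "")
        if (GENETIC_CODE_TABLE[[cod2]] == "*") { ok <- FALSE; break }
        if (GENETIC_CODE_TABLE[[cod1]] == GENETIC_CODE_TABLE[[cod2]]) {
          sd <- sd + 1
        } else {
          nd <- nd + 1
        }
        cur <- nxt
      }
      if (ok) {
        tot_sd <- tot_sd + sd
        tot_nd <- tot_nd + nd
        n_valid <- n_valid + 1
      }
    }
    res <- if (n_valid == 0) c(sd = NA_real_, nd = NA_real_) else
      c(sd = tot_sd / n_valid, nd = tot_nd / n_valid)
  }
  assign(key, res, envir = .ng86_env$pairs)
  res
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Split a codon string into triplets
#' @param x Nucleotide string (possibly gapped), length a multiple of 3.
#' @return Character vector of triplets.
#' @export
split_codons <- function(x) {
  stopifnot(nchar(x) %% 3 == 0)
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' NG86 Ka/Ks from a pairwise codon alignment
#'
#' Nei-Gojobori (1986) counting: per-codon synonymous site fractions from
#' the standard genetic code averaged over the two sequences; differences at
#' multi-substitution codons averaged over all minimal mutational pathways,
#' excluding pathways through stop codons; proportions corrected with
#' Jukes-Cantor, `d = -(3/4) ln(1 - (4/3) p)`. Codon columns with a gap,
#' ambiguity, stop codon, or with all pathways blocked are skipped.
#'
#' @param codon_alignment list with `codons_a`, `codons_b` (equal-length
#'   triplet vectors) as produced by [backtranslate_alignment()].
#' @return list with `ka`, `ks`, `ka_ks` (NA when undefined), the raw counts
#'   `S`, `N`, `Sd`, `Nd`, `n_codons` (analyzable columns) and `flags`.
#' @export
ka_ks_ng86 <- function(codon_alignment) {
  a <- toupper(codon_alignment$codons_a)
  b <- toupper(codon_alignment$codons_b)
  stopifnot(length(a) == length(b))
  sites <- .ng86_sites_table()
  flags <- character()
  S <- N <- Sd <- Nd <- 0
  n_used <- 0L
  for (i in seq_along(a)) {
    if (!(a[i] %in% SENSE_CODONS) || !(b[i] %in% SENSE_CODONS)) next
    d <- .ng86_pair_diff(a[i], b[i])
    if (anyNA(d)) {
      flags <- union(flags, "blocked_pathway_codon_skipped")
      next
    }
    S <- S + (sites[[a[i]]] + sites[[b[i]]]) / 2
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no analyzable codon columns")
  N <- 3 * n_used - S
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  ps <- Sd / S
  pn <- Nd / N
  ks <- jc(ps)
  ka <- jc(pn)
  if (is.na(ks)) flags <- union(flags, "ks_saturated")
  if (is.na(ka)) flags <- union(flags, "ka_saturated")
  ka_ks <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  list(ka = ka, ks = ks, ka_ks = ka_ks, S = S, N = N, Sd = Sd, Nd = Nd,
       ps = ps, pn = pn, n_codons = n_used, flags = flags)
}

#' Back-translate a protein pair alignment to a codon alignment
#'
#' Each aligned amino-acid column is expanded to its source codon; protein
#' gaps become gap triplets. One trailing stop codon on each CDS is removed
#' when present, and the CDS must translate to its aligned protein.
#'
#' @param aligned_a,aligned_b Gapped protein strings of equal length.
#' @param cds_a,cds_b Coding sequences for the two proteins.
#' @param ids Optional length-2 ids used in error messages.
#' @param max_mismatch Number of tolerated translation mismatches (default 0).
#' @return list of class `aqp_codon_alignment` with `codons_a`, `codons_b`.
#' @export
backtranslate_alignment <- function(aligned_a, aligned_b, cds_a, cds_b,
                                    ids = c("seq_a", "seq_b"),
                                    max_mismatch = 0) {
  expand <- function(aligned, cds, id) {
    if (nchar(cds) %% 3 != 0) {
      stop("CDS length of ", id, " is not a multiple of 3")
    }
    codons <- split_codons(toupper(cds))
    if (length(codons) &&
        identical(GENETIC_CODE_TABLE[[codons[length(codons)]]], "*")) {
      codons <- codons[-length(codons)]
    }
    prot <- gsub("-", "", aligned, fixed = TRUE)
    if (length(codons) != nchar(prot)) {
      stop("CDS of ", id, " (", length(codons), " codons) does not match ",
           "its protein (", nchar(prot), " residues)")
    }
    trans <- strsplit(translate_cds(paste(codons, collapse = "")), "")[[1]]
    mism <- sum(trans != strsplit(prot, "")[[1]] & trans != "X")
    if (mism > max_mismatch) {
      stop("CDS of ", id, " disagrees with its protein at ", mism,
           " position(s)")
    }
    cols <- strsplit(aligned, "")[[1]]
    out <- rep("---", length(cols))
    out[cols != "-"] <- codons
    out
  }
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  structure(list(codons_a = expand(aligned_a, cds_a, ids[1]),
                 codons_b = expand(aligned_b, cds_b, ids[2])),
            class = "aqp_codon_alignment")
}
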