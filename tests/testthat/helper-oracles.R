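# Independent oracles used by the tests. These deliberately reimplement the
# quantities under test by direct enumeration / closed forms, without
# touching the package internals they check.

# --- NG86 by exhaustive recursion -------------------------------------------

.gc <- Biostrings::GENETIC_CODE

oracle_syn_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  aa <- .gc[[codon]]
  syn <- 0
  for (p in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), chars[p])) {
      alt <- chars
      alt[p] <- nt
      if (.gc[[paste(alt, collapse = "")]] == aa) syn <- syn + 1 / 3
    }
  }
  syn
}

# all stop-free mutational pathways between two sense codons, by recursion;
# returns average (sd, nd) or NULL when every pathway is blocked
oracle_pathways <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  walk <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(0, 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- cb[p]
      if (.gc[[paste(nxt, collapse = "")]] == "*") next
      step <- if (.gc[[paste(cur, collapse = "")]] ==
                  .gc[[paste(nxt, collapse = "")]]) c(1, 0) else c(0, 1)
      for (rest in walk(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1]] <- step + rest
      }
    }
    out
  }
  paths <- walk(ca, which(ca != cb))
  if (!length(paths)) return(NULL)
  Reduce(`+`, paths) / length(paths)
}

oracle_ng86 <- function(codons_a, codons_b) {
  sense <- names(.gc)[.gc != "*"]
  S <- Sd <- Nd <- 0
  used <- 0
  for (i in seq_along(codons_a)) {
    if (!(codons_a[i] %in% sense) || !(codons_b[i] %in% sense)) next
    pw <- oracle_pathways(codons_a[i], codons_b[i])
    if (is.null(pw)) next
    S <- S + (oracle_syn_sites(codons_a[i]) + oracle_syn_sites(codons_b[i])) / 2
    Sd <- Sd + pw[1]
    Nd <- Nd + pw[2]
    used <- used + 1
  }
  N <- 3 * used - S
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       ks = jc(Sd / S), ka = jc(Nd / N), n_codons = used)
}

# --- hypergeometric upper tail by direct summation --------------------------

oracle_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(exp(lchoose(n, i) + lchoose(N - n, K - i) - lchoose(N, K)))
}

# --- pairwise global alignment score via Biostrings -------------------------

oracle_nw_score <- function(a, b) {
  # gap of length L costs 10 + (L - 1): gapOpening 9 + gapExtension 1 per
  # residue in the Biostrings cost model
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 9, gapExtension = 1,
    type = "global", scoreOnly = TRUE)
}

# --- k-mer multiset distance by direct enumeration --------------------------

oracle_kmer_distance <- function(a, b, k = 3) {
  kmers <- function(s) {
    vapply(seq_len(nchar(s) - k + 1), function(i) substr(s, i, i + k - 1), "")
  }
  ka <- kmers(a)
  kb <- kmers(b)
  shared <- 0
  kb_pool <- kb
  for (x in ka) {
    hit <- match(x, kb_pool)
    if (!is.na(hit)) {
      shared <- shared + 1
      kb_pool <- kb_pool[-hit]
    }
  }
  1 - shared / min(length(ka), length(kb))
}

# --- misc -------------------------------------------------------------------

random_protein <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                           "G", "H", "I", "L", "K", "M", "F",
                                           "P", "S", "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_sense_codons <- function(n) {
  sense <- names(.gc)[.gc != "*"]
  sense[sample.int(length(sense), n, replace = TRUE)]
}
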