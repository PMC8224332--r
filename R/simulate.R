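# Seeded generators emulating the statistical structure the pipeline
# assumes: multi-subgroup AQP-like proteins with planted NPA motifs, filter
# residues and TM segments; duplicate CDS pairs with planted synonymous
# divergence; loci with planted tandem arrays; FPKM matrices with planted
# fuzzy clusters; GO maps with planted enriched terms. Every generator is a
# pure function of (parameters, seed) and returns a ground-truth record.

HYDROPHOBIC_SET <- c("I", "L", "V", "F", "A", "M")
HYDROPHOBIC_W <- c(3, 3, 3, 2, 1, 1)
HYDROPHILIC_SET <- c("S", "T", "G", "D", "E", "K", "R", "Q", "H", "Y")

# fixed 0-based segment layout of the synthetic AQP fold (212 residues):
# termini and loops are hydrophilic, the six 22-residue helices hydrophobic;
# NPA triplets sit in loops B and E; the ar/R residues sit at the offsets
# frozen in aqp_config()$filter_offsets relative to the NPA anchors.
.aqp_layout <- function() {
  segs <- list(
    c("N-term", 10), c("H1", 22), c("LA", 8), c("H2", 22), c("LB", 14),
    c("H3", 22), c("LC", 10), c("H4", 22), c("LD", 8), c("H5", 22),
    c("LE", 16), c("H6", 22), c("C-term", 14))
  start <- 0L
  out <- data.frame(role = character(), start = integer(), end = integer())
  for (s in segs) {
    len <- as.integer(s[2])
    out <- rbind(out, data.frame(role = s[1], start = start,
                                 end = start + len - 1L))
    start <- start + len
  }
  npa_b <- out$start[out$role == "LB"] + 8L   # 70
  npa_e <- out$start[out$role == "LE"] + 6L   # 166
  list(segments = out, length = start, npa_b = npa_b, npa_e = npa_e,
       filter_pos = c(h2 = npa_b - 20L, h5 = npa_e - 12L,
                      le1 = npa_e - 3L, le2 = npa_e + 3L))
}

# canonical planted filter quadruplet per subgroup
.subgroup_signatures <- function() {
  list(PIP1 = c("F", "H", "T", "R"), PIP2 = c("F", "H", "T", "R"),
       PIP3 = c("F", "H", "T", "R"), TIP1 = c("H", "I", "A", "R"),
       TIP2 = c("H", "I", "G", "R"), TIP3 = c("H", "V", "A", "R"),
       TIP4 = c("H", "T", "A", "M"), NIP1 = c("A", "I", "G", "R"),
       NIP2 = c("G", "S", "G", "R"), NIP3 = c("W", "V", "A", "R"),
       SIP1 = c("I", "A", "G", "S"), XIP1 = c("I", "T", "A", "R"))
}

.random_aqp_consensus <- function(layout) {
  chars <- character(layout$length)
  for (r in seq_len(nrow(layout$segments))) {
    idx <- (layout$segments$start[r]:layout$segments$end[r]) + 1L
    if (grepl("^H[1-6]$", layout$segments$role[r])) {
      chars[idx] <- sample(HYDROPHOBIC_SET, length(idx), replace = TRUE,
                           prob = HYDROPHOBIC_W)
    } else {
      chars[idx] <- sample(HYDROPHILIC_SET, length(idx), replace = TRUE)
    }
  }
  chars[layout$npa_b + 1:3] <- c("N", "P", "A")
  chars[layout$npa_e + 1:3] <- c("N", "P", "A")
  chars
}

# diverge a sequence at `rate` per position, replacing residues within their
# hydropathy class so the TM architecture survives (homologs, not random
# sequences); protected positions are never touched
.diverge_within_class <- function(chars, rate, layout, protected) {
  hit <- setdiff(which(runif(length(chars)) < rate), protected)
  for (p in hit) {
    helix <- any(vapply(seq_len(nrow(layout$segments)), function(r)
      grepl("^H[1-6]$", layout$segments$role[r]) &&
        p >= layout$segments$start[r] + 1L &&
        p <= layout$segments$end[r] + 1L, logical(1)))
    pool <- if (helix) HYDROPHOBIC_SET else HYDROPHILIC_SET
    pool <- setdiff(pool, chars[p])
    chars[p] <- pool[sample.int(length(pool), 1)]
  }
  chars
}

#' Generate a synthetic AQP family with ground truth
#'
#' One family ancestor is drawn on the synthetic AQP fold (six hydrophobic
#' helices, NPA motifs in loops B and E); each of the 12 subgroups diverges
#' from it by class-preserving substitutions at `subgroup_divergence` and
#' carries its ar/R residues at the frozen anchor offsets; members are
#' subgroup-consensus copies with point substitutions at `noise_rate`
#' outside the NPA and filter positions (noise never introduces N or P, so
#' no spurious NPA motifs arise). CDS are random back-translations; loci are
#' laid out over 12 chromosomes.
#'
#' @param n_per_subgroup Genes per subgroup (>= 1).
#' @param seed Integer seed.
#' @param noise_rate Per-residue substitution probability outside protected
#'   positions.
#' @param subgroups Subgroup names (default all 12).
#' @param cds_ks Expected synonymous divergence planted between each member
#'   CDS and its subgroup consensus CDS (default 0.05, mimicking recent
#'   within-subgroup duplication).
#' @param subgroup_divergence Per-position substitution rate separating each
#'   subgroup consensus from the family ancestor (default 0.3, giving the
#'   40-60 percent inter-subgroup protein identity typical of the family).
#' @param tip4_motifs When `TRUE`, the TIP4 consensus is rewritten in three
#'   downstream regions (post-NPA loop E, helix 6, C-terminus) so the
#'   subgroup carries three private motif variants; the regions are recorded
#'   in the truth as `tip4_regions` (0-based).
#' @return list with `proteins`, `cds`, `loci` (data.frames) and `truth`.
#' @export
generate_family <- function(n_per_subgroup = 5, seed = 1, noise_rate = 0,
                            subgroups = names(.subgroup_signatures()),
                            cds_ks = 0.05, subgroup_divergence = 0.3,
                            tip4_motifs = FALSE) {
  sigs <- .subgroup_signatures()
  bad <- setdiff(subgroups, names(sigs))
  if (length(bad)) stop("unknown subgroup(s): ", paste(bad, collapse = ", "))
  stopifnot(n_per_subgroup >= 1)
  set.seed(seed)
  layout <- .aqp_layout()
  noise_pool <- setdiff(c(AA_ALPHABET20), c("N", "P"))
  protected <- c(layout$npa_b + 1:3, layout$npa_e + 1:3,
                 layout$filter_pos + 1L)
  proteins <- cds <- loci <- list()
  truth_rows <- list()
  tip4_regions <- NULL
  ancestor <- .random_aqp_consensus(layout)
  for (gi in seq_along(subgroups)) {
    sg <- subgroups[gi]
    consensus <- .diverge_within_class(ancestor, subgroup_divergence, layout,
                                       protected)
    consensus[layout$filter_pos + 1L] <- sigs[[sg]]
    if (tip4_motifs && sg == "TIP4") {
      seg <- layout$segments
      le_end <- seg$end[seg$role == "LE"]
      h6 <- seg[seg$role == "H6", ]
      ct <- seg[seg$role == "C-term", ]
      tip4_regions <- list(le_post = (layout$npa_e + 3L):le_end,
                           h6 = h6$start:h6$end, cterm = ct$start:ct$end)
      free <- setdiff(tip4_regions$le_post, layout$filter_pos)
      consensus[free + 1L] <- sample(HYDROPHILIC_SET, length(free),
                                     replace = TRUE)
      consensus[tip4_regions$h6 + 1L] <-
        sample(HYDROPHOBIC_SET, length(tip4_regions$h6), replace = TRUE,
               prob = HYDROPHOBIC_W)
      consensus[tip4_regions$cterm + 1L] <-
        sample(HYDROPHILIC_SET, length(tip4_regions$cterm), replace = TRUE)
    }
    consensus_codons <- split_codons(
      .random_backtranslate(paste(consensus, collapse = "")))
    for (m in seq_len(n_per_subgroup)) {
      id <- sprintf("SYN_%s_%02d", sg, m)
      chars <- consensus
      if (noise_rate > 0) {
        hit <- which(runif(layout$length) < noise_rate)
        hit <- setdiff(hit, protected)
        for (p in hit) {
          chars[p] <- sample(setdiff(noise_pool, chars[p]), 1)
        }
      }
      prot <- paste(chars, collapse = "")
      proteins[[id]] <- prot
      codons <- consensus_codons
      changed <- which(chars != consensus)
      if (length(changed)) {
        tab <- .codons_by_aa()
        for (p in changed) {
          opts <- tab[[chars[p]]]
          codons[p] <- opts[sample.int(length(opts), 1)]
        }
      }
      cds[[id]] <- if (cds_ks > 0) {
        .evolve_cds(paste(codons, collapse = ""), cds_ks, 0)
      } else {
        paste(codons, collapse = "")
      }
      chrom <- sprintf("chr%02d", ((gi - 1) %% 12) + 1)
      start <- 2e6 * m + 1e4 * gi
      loci[[id]] <- data.frame(gene_id = id, seqname = chrom,
                               start = as.integer(start),
                               end = as.integer(start + 1500),
                               strand = "+", chromosome_flag = TRUE,
                               stringsAsFactors = FALSE)
      truth_rows[[id]] <- data.frame(
        id = id, subfamily = substr(sg, 1, 3), subgroup = sg,
        h2 = sigs[[sg]][1], h5 = sigs[[sg]][2], le1 = sigs[[sg]][3],
        le2 = sigs[[sg]][4], npa_b = layout$npa_b, npa_e = layout$npa_e,
        stringsAsFactors = FALSE)
    }
  }
  ids <- names(proteins)
  helix <- layout$segments[grepl("^H[1-6]$", layout$segments$role), ]
  list(
    proteins = data.frame(id = ids, species = "synthetic",
                          sequence = unlist(proteins, use.names = FALSE),
                          stringsAsFactors = FALSE),
    cds = data.frame(id = ids, species = "synthetic",
                     sequence = unlist(cds, use.names = FALSE),
                     stringsAsFactors = FALSE),
    loci = do.call(rbind, c(loci, list(make.row.names = FALSE))),
    truth = list(genes = do.call(rbind, c(truth_rows,
                                          list(make.row.names = FALSE))),
                 tm_spans = cbind(start = helix$start, end = helix$end),
                 layout = layout, seed = seed, noise_rate = noise_rate,
                 n_per_subgroup = n_per_subgroup,
                 tip4_regions = if (tip4_motifs) tip4_regions else NULL)
  )
}

.codons_by_aa <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- split(names(Biostrings::GENETIC_CODE),
                    unname(Biostrings::GENETIC_CODE))
    }
    tab
  }
})

.random_backtranslate <- function(protein) {
  tab <- .codons_by_aa()
  chars <- strsplit(protein, "")[[1]]
  paste(vapply(chars, function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1)]
  }, ""), collapse = "")
}

# random CDS of n_codons sense codons (no stops)
.random_cds <- function(n_codons) {
  paste(SENSE_CODONS[sample.int(length(SENSE_CODONS), n_codons,
                                replace = TRUE)], collapse = "")
}

# random CDS drawn from fourfold-degenerate codon families (Ala, Gly, Pro,
# Thr, Val, TCN-Ser). Every synonymous site of such a codon is a third
# position free to take all four nucleotides, i.e. exactly the
# equal-rates four-state site the Jukes-Cantor correction models, so a
# planted divergence is recovered without degeneracy-mixture bias.
FOURFOLD_CODONS <- c(t(outer(c("GC", "GG", "CC", "AC", "GT", "TC"),
                             c("A", "C", "G", "T"), paste0)))

.random_fourfold_cds <- function(n_codons) {
  paste(FOURFOLD_CODONS[sample.int(length(FOURFOLD_CODONS), n_codons,
                                   replace = TRUE)], collapse = "")
}

# evolve a CDS by a synonymous (and optionally nonsynonymous) jump process:
# expected ks = synonymous events per NG86 synonymous site, expected ka
# likewise per nonsynonymous site. Events pick uniformly among the currently
# available single-nucleotide changes of the requested kind (stop-creating
# changes excluded), so multiple hits accumulate naturally.
.codon_changes_table <- function() {
  if (is.null(.ng86_env$changes)) {
    syn <- nonsyn <- setNames(vector("list", length(SENSE_CODONS)),
                              SENSE_CODONS)
    for (cod in SENSE_CODONS) {
      chars <- strsplit(cod, "")[[1]]
      aa <- GENETIC_CODE_TABLE[[cod]]
      s_opts <- n_opts <- character()
      for (p in 1:3) for (nt in setdiff(NUCS, chars[p])) {
        mut <- chars; mut[p] <- nt
        cod2 <- paste(mut, collapse = "")
        aa2 <- GENETIC_CODE_TABLE[[cod2]]
        if (aa2 == "*") next
        if (aa2 == aa) s_opts <- c(s_opts, cod2) else n_opts <- c(n_opts, cod2)
      }
      syn[[cod]] <- s_opts
      nonsyn[[cod]] <- n_opts
    }
    .ng86_env$changes <- list(syn = syn, nonsyn = nonsyn)
  }
  .ng86_env$changes
}

.evolve_cds <- function(cds, ks_true, ka_true = 0) {
  codons <- split_codons(cds)
  sites <- .ng86_sites_table()
  S <- sum(sites[codons])
  N <- 3 * length(codons) - S
  chg <- .codon_changes_table()
  apply_events <- function(codons, n_events, kind) {
    opts <- chg[[kind]]
    for (e in seq_len(n_events)) {
      counts <- lengths(opts[codons])
      if (sum(counts) == 0) break
      ci <- sample.int(length(codons), 1, prob = counts)
      alts <- opts[[codons[ci]]]
      codons[ci] <- alts[sample.int(length(alts), 1)]
    }
    codons
  }
  codons <- apply_events(codons, rpois(1, ks_true * S), "syn")
  if (ka_true > 0) {
    codons <- apply_events(codons, rpois(1, ka_true * N), "nonsyn")
  }
  paste(codons, collapse = "")
}

#' Generate duplicate CDS pairs with planted synonymous divergence
#'
#' Each pair is an ancestor CDS plus a copy evolved by a per-site Poisson
#' substitution process targeting the requested expected synonymous
#' divergence (nonsynonymous rate separately configurable). Random ancestors
#' are drawn from fourfold-degenerate codon families so that every
#' synonymous site follows the four-state model the distance correction
#' assumes and the planted divergence is an unbiased target. Optionally one
#' tandem array is planted: adjacent loci on one chromosome with inter-gene
#' gaps well under the tandem cut-off.
#'
#' @param n_pairs Pairs per Ks level.
#' @param ks_levels Numeric vector of true synonymous divergences in (0, 1.5].
#' @param seed Integer seed.
#' @param n_codons Ancestor length in codons.
#' @param ka_true Expected nonsynonymous divergence per pair (default 0.02).
#' @param tandem_array_size When > 0, additionally plants a tandem array of
#'   this many near-identical genes on chromosome 1.
#' @param base_cds Optional data.frame (`id`, `sequence`) of ancestor CDS to
#'   sample from instead of random ancestors.
#' @param ancestors `"fourfold"` (default) draws ancestors from
#'   fourfold-degenerate codon families, the unbiased benchmark for
#'   divergence recovery; `"all"` draws uniform sense codons, giving
#'   full-alphabet proteins suited to pair-detection studies.
#' @return list with `proteins`, `cds`, `loci`, `pairs` (gene_a, gene_b,
#'   true Ks level), `truth`.
#' @export
generate_duplications <- function(n_pairs = 100, ks_levels = 0.15, seed = 1,
                                  n_codons = 200, ka_true = 0.02,
                                  tandem_array_size = 0, base_cds = NULL,
                                  ancestors = c("fourfold", "all")) {
  stopifnot(all(ks_levels > 0 | ks_levels == 0), all(ks_levels <= 1.5))
  ancestors <- match.arg(ancestors)
  draw_cds <- if (ancestors == "fourfold") .random_fourfold_cds else
    .random_cds
  set.seed(seed)
  cds <- list(); pair_rows <- list(); loci <- list()
  chrom_i <- 2L
  for (lev in ks_levels) {
    for (p in seq_len(n_pairs)) {
      anc <- if (is.null(base_cds)) draw_cds(n_codons) else
        base_cds$sequence[sample.int(nrow(base_cds), 1)]
      ida <- sprintf("DUP_ks%s_%03d_a", format(lev), p)
      idb <- sprintf("DUP_ks%s_%03d_b", format(lev), p)
      cds[[ida]] <- anc
      cds[[idb]] <- .evolve_cds(anc, lev, ka_true)
      chrom <- sprintf("chr%02d", (chrom_i %% 12) + 1)
      chrom_i <- chrom_i + 1L
      base_pos <- 1e6 + 3e6 * p
      loci[[ida]] <- data.frame(gene_id = ida, seqname = chrom,
                                start = base_pos, end = base_pos + 600,
                                strand = "+", chromosome_flag = TRUE)
      loci[[idb]] <- data.frame(gene_id = idb, seqname = sprintf("chr%02d",
                                                                 (chrom_i %% 12) + 1),
                                start = base_pos, end = base_pos + 600,
                                strand = "+", chromosome_flag = TRUE)
      chrom_i <- chrom_i + 1L
      pair_rows[[length(pair_rows) + 1]] <- data.frame(
        gene_a = ida, gene_b = idb, ks_true = lev, ka_true = ka_true,
        stringsAsFactors = FALSE)
    }
  }
  array_ids <- character()
  if (tandem_array_size > 0) {
    anc <- draw_cds(n_codons)
    pos <- 1e5
    for (m in seq_len(tandem_array_size)) {
      id <- sprintf("TANDEM_%02d", m)
      array_ids <- c(array_ids, id)
      cds[[id]] <- .evolve_cds(anc, 0.05, ka_true)
      loci[[id]] <- data.frame(gene_id = id, seqname = "chr01",
                               start = pos, end = pos + 600, strand = "+",
                               chromosome_flag = TRUE)
      pos <- pos + 50000  # well inside the 100 kb tandem cut-off
    }
  }
  ids <- names(cds)
  proteins <- vapply(unlist(cds, use.names = FALSE), translate_cds, "")
  list(
    proteins = data.frame(id = ids, species = "synthetic",
                          sequence = unname(proteins),
                          stringsAsFactors = FALSE),
    cds = data.frame(id = ids, species = "synthetic",
                     sequence = unlist(cds, use.names = FALSE),
                     stringsAsFactors = FALSE),
    loci = do.call(rbind, c(loci, list(make.row.names = FALSE))),
    pairs = do.call(rbind, c(pair_rows, list(make.row.names = FALSE))),
    truth = list(array = array_ids, seed = seed, ks_levels = ks_levels,
                 ka_true = ka_true, n_codons = n_codons)
  )
}

#' Generate a synthetic stress-response FPKM matrix
#'
#' Gene baselines are log-normal; responders add a cluster-specific
#' Gaussian-bump temporal profile (on the log2 scale) in every stress
#' condition; non-responders share the stress and control distributions.
#' Gaussian noise of `noise_sd` is added on the log2 scale.
#'
#' @param n_genes Number of genes.
#' @param k_clusters Number of planted response clusters.
#' @param n_responders Number of responder genes (<= n_genes).
#' @param conditions Stress condition names.
#' @param timepoints Number of timepoints.
#' @param replicates Replicates per condition x timepoint.
#' @param amplitude Peak log2 induction of responders (default 2 = 4-fold).
#' @param noise_sd Log2-scale noise standard deviation.
#' @param seed Integer seed.
#' @return list with `fpkm`, `samples` and `truth` (`cluster`, `responder`).
#' @export
generate_expression <- function(n_genes = 1000, k_clusters = 3,
                                n_responders = 100,
                                conditions = c("cold", "heat", "salt",
                                               "mannitol"),
                                timepoints = 4, replicates = 2,
                                amplitude = 2, noise_sd = 0.25, seed = 1) {
  stopifnot(n_responders <= n_genes, k_clusters >= 1)
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  responder <- c(rep(TRUE, n_responders), rep(FALSE, n_genes - n_responders))
  cluster <- rep(NA_integer_, n_genes)
  if (n_responders > 0) {
    cluster[seq_len(n_responders)] <-
      rep_len(seq_len(k_clusters), n_responders)
  }
  baseline <- rnorm(n_genes, mean = 3, sd = 1.5)
  peaks <- round(seq(1, timepoints, length.out = k_clusters))
  # sustained induction plus a cluster-specific temporal bump: responders
  # stay induced at every timepoint (so they are testable as DEGs) while the
  # bump position separates the clusters
  profile <- function(cl, tp) {
    amplitude * (0.4 + 0.6 * exp(-(tp - peaks[cl])^2 / 2))
  }
  all_conds <- c(conditions, "control")
  sample_rows <- expand.grid(replicate = seq_len(replicates),
                             timepoint = seq_len(timepoints),
                             condition = all_conds,
                             stringsAsFactors = FALSE)
  sample_rows$sample <- sprintf("%s_t%d_r%d", sample_rows$condition,
                                sample_rows$timepoint, sample_rows$replicate)
  fpkm <- matrix(0, n_genes, nrow(sample_rows),
                 dimnames = list(genes, sample_rows$sample))
  for (s in seq_len(nrow(sample_rows))) {
    delta <- numeric(n_genes)
    if (sample_rows$condition[s] != "control") {
      hit <- which(responder)
      if (length(hit)) {
        delta[hit] <- profile(cluster[hit], sample_rows$timepoint[s])
      }
    }
    logval <- baseline + delta +
      if (noise_sd > 0) rnorm(n_genes, 0, noise_sd) else 0
    fpkm[, s] <- 2^logval
  }
  list(fpkm = fpkm,
       samples = sample_rows[, c("sample", "condition", "timepoint",
                                 "replicate")],
       truth = list(cluster = setNames(cluster, genes),
                    responder = setNames(responder, genes),
                    k_clusters = k_clusters, amplitude = amplitude,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate a gene-to-GO annotation map with planted enrichment
#'
#' Background terms annotate genes uniformly at `base_rate`; each entry of
#' `enriched_spec` names a target gene set that an extra term annotates at
#' `rate_in` (and non-targets at `base_rate`).
#'
#' @param background_genes Character vector of gene ids.
#' @param n_terms Number of background terms.
#' @param enriched_spec list of lists with fields `genes` (character) and
#'   optionally `rate_in` (default 0.8).
#' @param base_rate Background annotation probability per gene per term.
#' @param seed Integer seed.
#' @return list with `go_map` (named list) and `truth` (`enriched_terms`).
#' @export
generate_go <- function(background_genes, n_terms = 50,
                        enriched_spec = list(), base_rate = 0.05, seed = 1) {
  set.seed(seed)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  ann <- setNames(vector("list", length(background_genes)), background_genes)
  for (tm in terms) {
    hit <- background_genes[runif(length(background_genes)) < base_rate]
    for (g in hit) ann[[g]] <- c(ann[[g]], tm)
  }
  enriched_terms <- character()
  for (i in seq_along(enriched_spec)) {
    spec <- enriched_spec[[i]]
    tm <- sprintf("GO:%07d", n_terms + i)
    enriched_terms <- c(enriched_terms, tm)
    rate_in <- spec$rate_in %||% 0.8
    for (g in background_genes) {
      r <- if (g %in% spec$genes) rate_in else base_rate
      if (runif(1) < r) ann[[g]] <- c(ann[[g]], tm)
    }
  }
  list(go_map = ann, truth = list(enriched_terms = enriched_terms,
                                  base_rate = base_rate, seed = seed))
}
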