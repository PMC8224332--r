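#' Round half up
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded values (ties away from zero for positives).
#' @export
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarise a classified family table
#'
#' Computes the per-subfamily and per-subgroup counts, newly-annotated
#' counts, chromosome-anchored counts and percentages from a
#' characterisation table shaped like the packaged pepper fixture
#' ([load_family_table()]) or like [classify_family()] output joined with
#' loci.
#'
#' @param rows data.frame with columns `subfamily`, `subgroup`, `location`
#'   and optionally `newly_annotated`, `chromosome_flag`.
#' @param config Configuration list from [aqp_config()].
#' @return list with `total`, `subfamily_counts`, `subfamily_pct` (one
#'   decimal), `newly_annotated`, `subgroup_counts`, `chromosome_anchored`,
#'   `chromosome_counts` and `chromosome_pct_int` (integer percentages of
#'   chromosome-anchored genes, rounded half up).
#' @export
summarize_family <- function(rows, config = aqp_config()) {
  total <- nrow(rows)
  sub_counts <- setNames(integer(length(SUBFAMILIES)), SUBFAMILIES)
  if (total) {
    tab <- table(factor(rows$subfamily, levels = SUBFAMILIES))
    sub_counts[names(tab)] <- as.integer(tab)
  }
  sub_pct <- if (total) round_half_up(100 * sub_counts / total, 1) else
    sub_counts * 0
  newly <- if (!is.null(rows$newly_annotated)) sum(rows$newly_annotated) else
    NA_integer_
  sg_counts <- if (total) table(rows$subgroup) else integer()
  chrom_flag <- rows$chromosome_flag %||%
    grepl(config$chromosome_pattern, rows$location)
  anchored <- sum(chrom_flag)
  chrom_counts <- if (anchored) table(rows$location[chrom_flag]) else integer()
  chrom_pct <- if (anchored) {
    setNames(as.integer(round_half_up(100 * as.integer(chrom_counts) /
                                        anchored)),
             names(chrom_counts))
  } else integer()
  list(total = total,
       subfamily_counts = sub_counts,
       subfamily_pct = sub_pct,
       newly_annotated = newly,
       subgroup_counts = sg_counts,
       chromosome_anchored = anchored,
       chromosome_counts = chrom_counts,
       chromosome_pct_int = chrom_pct)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a full set of pipeline inputs
#'
#' Writes a protein FASTA, CDS FASTA, GFF3 loci, FPKM matrix with sample
#' sheet, GO map and the ground-truth JSON into a directory, all derived
#' deterministically from one seed.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if absent).
#' @param n_per_subgroup Family genes per subgroup.
#' @param n_genes,k_clusters,n_responders Expression generator sizes.
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_full <- function(seed, dir, n_per_subgroup = 3, n_genes = 400,
                          k_clusters = 3, n_responders = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- generate_family(n_per_subgroup = n_per_subgroup, seed = seed,
                         noise_rate = 0.05)
  expr <- generate_expression(n_genes = n_genes, k_clusters = k_clusters,
                              n_responders = n_responders, seed = seed + 1)
  resp <- names(expr$truth$responder)[expr$truth$responder]
  go <- generate_go(rownames(expr$fpkm), n_terms = 30,
                    enriched_spec = list(list(genes = resp, rate_in = 0.8)),
                    seed = seed + 2)
  paths <- list(
    proteins = file.path(dir, "proteins.faa"),
    cds = file.path(dir, "cds.fna"),
    loci = file.path(dir, "loci.gff3"),
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    go_map = file.path(dir, "go_map.tsv"),
    truth = file.path(dir, "truth.json"))
  write_fasta(fam$proteins, paths$proteins)
  write_fasta(fam$cds, paths$cds)
  write_gff3(fam$loci, paths$loci)
  .write_tsv(cbind(data.frame(gene = rownames(expr$fpkm)),
                   as.data.frame(expr$fpkm)), paths$expression)
  .write_tsv(expr$samples, paths$samples)
  write_go_map(go$go_map, paths$go_map)
  truth <- list(family = fam$truth$genes,
                expression_cluster = expr$truth$cluster,
                responder = expr$truth$responder,
                enriched_terms = go$truth$enriched_terms,
                seed = seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(paths)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on file inputs and
#' writes per-stage TSV/Newick reports plus a JSON run log of parameters and
#' seed. Reruns with the same config and seed produce byte-identical
#' outputs.
#'
#' @param config list with `out_dir`, `seed`, `stages` (subset of `scan`,
#'   `classify`, `tree`, `motifs`, `dups`, `cluster`, `enrich`, `report`),
#'   input paths (`proteins`, `cds`, `loci`, `expression`, `samples`,
#'   `go_map`) as required by the stages, and optionally `species_prefix`.
#' @return Invisibly, a named list of written report paths.
#' @export
run_pipeline <- function(config) {
  stages <- config$stages %||% c("scan", "classify", "tree", "motifs",
                                 "dups", "cluster", "enrich", "report")
  out_dir <- config$out_dir
  stopifnot(!is.null(out_dir))
  seed <- config$seed %||% 1
  needs <- list(
    scan = "proteins", classify = "proteins", tree = "proteins",
    motifs = "proteins", dups = c("proteins", "cds", "loci"),
    cluster = c("expression", "samples"),
    enrich = c("expression", "samples", "go_map"), report = "proteins")
  for (st in stages) {
    missing <- setdiff(needs[[st]], names(config))
    if (length(missing)) {
      stop("stage '", st, "' requires input(s): ",
           paste(missing, collapse = ", "))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- aqp_config()
  outputs <- list()
  seq_stages <- intersect(c("scan", "classify", "tree", "motifs", "dups",
                            "cluster", "enrich", "report"), stages)

  proteins <- NULL; classification <- NULL; trimmed <- NULL; fc <- NULL
  tree <- NULL; subgroup_map <- NULL
  need_seq <- any(seq_stages %in% c("scan", "classify", "tree", "motifs",
                                    "dups", "report"))
  if (need_seq) proteins <- read_fasta(config$proteins, "protein", cfg)

  if ("scan" %in% stages) {
    scan <- scan_candidates(proteins, cfg)
    outputs$candidates <- .write_tsv(scan, file.path(out_dir,
                                                     "candidates.tsv"))
  }
  if (any(stages %in% c("classify", "tree", "motifs", "report"))) {
    cl <- classify_family(proteins, config = cfg)
    classification <- cl$calls
    trimmed <- cl$trimmed
    fc <- cl$filter_columns
  }
  if (any(stages %in% c("tree", "report"))) {
    D <- protein_distance(trimmed)
    tree <- neighbor_joining(D)
    # leaves with a subgroup-resolving signature call label the tree
    resolved <- classification$method == "signature" &
      grepl("[0-9]$", classification$subgroup)
    if (any(resolved)) {
      labels <- setNames(classification$subgroup[resolved],
                         classification$id[resolved])
      sg <- assign_subgroups(tree, labels)
      subgroup_map <- setNames(sg$subgroup, sg$id)
      classification$subgroup <- unname(subgroup_map[classification$id])
    }
    if ("tree" %in% stages) {
      tree_path <- file.path(out_dir, "tree.nwk")
      ape::write.tree(tree, file = tree_path)
      outputs$tree <- tree_path
    }
  }
  if ("classify" %in% stages) {
    out <- classification
    if (!is.null(config$loci)) {
      loci <- read_gff3(config$loci, cfg)
      if (all(!is.na(out$subgroup)) && all(grepl("[0-9]$", out$subgroup))) {
        out <- assign_names(out, loci, config$species_prefix %||% "Syn")
      }
      out$location <- loci$seqname[match(out$id, loci$gene_id)]
    }
    outputs$classification <- .write_tsv(out, file.path(out_dir,
                                                        "classification.tsv"))
    classification <- out
  }
  if ("motifs" %in% stages) {
    spans <- consensus_tm_spans(trimmed, config = cfg)
    arch <- segment_domain(trimmed, spans, fc)
    catalog <- label_block_motifs(trimmed, arch)
    groups <- setNames(classification$subgroup, classification$id)
    counts <- motif_counts(catalog, groups)
    outputs$motifs <- .write_tsv(counts, file.path(out_dir, "motifs.tsv"))
    specific <- find_group_specific_motifs(catalog, groups)
    outputs$specific_motifs <- .write_tsv(
      specific, file.path(out_dir, "specific_motifs.tsv"))
  }
  if ("dups" %in% stages) {
    cds <- read_fasta(config$cds, "dna", cfg)
    loci <- read_gff3(config$loci, cfg)
    pairs <- find_duplicate_pairs(proteins, config = cfg)
    if (nrow(pairs)) {
      pairs <- pair_ka_ks(pairs, proteins, cds, loci, cfg)
      arrays <- merge_tandem_arrays(pairs, loci)
      outputs$arrays <- .write_tsv(
        data.frame(array = rep(seq_along(arrays),
                               vapply(arrays, length, integer(1))),
                   gene = unlist(arrays) %||% character()),
        file.path(out_dir, "tandem_arrays.tsv"))
      hist <- ks_distribution(pairs)
      outputs$ks_hist <- .write_tsv(hist, file.path(out_dir, "ks_hist.tsv"))
    }
    outputs$pairs <- .write_tsv(pairs, file.path(out_dir, "pairs.tsv"))
  }
  clustering <- NULL; expr <- NULL
  if (any(stages %in% c("cluster", "enrich"))) {
    expr <- read_expression(config$expression, config$samples)
    degs <- select_degs(expr$fpkm, expr$samples)
    deg_union <- sort(unique(unlist(lapply(degs, function(d)
      d$table$gene[d$table$deg]))))
    deg_tab <- do.call(rbind, lapply(names(degs), function(cn)
      cbind(condition = cn, degs[[cn]]$table)))
    outputs$degs <- .write_tsv(deg_tab, file.path(out_dir, "degs.tsv"))
    if (length(deg_union) >= 12) {
      prof <- do.call(cbind, lapply(degs, function(d)
        d$log2fc[deg_union, , drop = FALSE]))
      prof <- standardize_rows(prof)
      k <- choose_k(prof, seed = seed)
      clustering <- fuzzy_cmeans(prof, k, seed = seed)
      memb <- data.frame(gene = rownames(clustering$membership),
                         cluster = clustering$cluster,
                         round(clustering$membership, 6))
      outputs$membership <- .write_tsv(memb, file.path(out_dir,
                                                       "membership.tsv"))
    }
  }
  if ("enrich" %in% stages && !is.null(clustering)) {
    go_map <- read_go_map(config$go_map)
    background <- rownames(expr$fpkm)
    enr <- list()
    for (k_i in sort(unique(clustering$cluster))) {
      genes <- names(clustering$cluster)[clustering$cluster == k_i]
      res <- fisher_enrichment(genes, background, go_map)
      if (nrow(res)) enr[[length(enr) + 1]] <- cbind(cluster = k_i, res)
    }
    outputs$enrichment <- .write_tsv(
      do.call(rbind, enr), file.path(out_dir, "enrichment.tsv"))
  }
  if ("report" %in% stages) {
    rows <- data.frame(subfamily = classification$subfamily,
                       subgroup = classification$subgroup,
                       location = classification$location %||% NA_character_,
                       stringsAsFactors = FALSE)
    summ <- summarize_family(rows, cfg)
    summary_df <- data.frame(
      metric = c("total", paste0("n_", names(summ$subfamily_counts)),
                 paste0("pct_", names(summ$subfamily_pct)),
                 "chromosome_anchored"),
      value = c(summ$total, as.numeric(summ$subfamily_counts),
                as.numeric(summ$subfamily_pct), summ$chromosome_anchored),
      stringsAsFactors = FALSE)
    outputs$summary <- .write_tsv(summary_df, file.path(out_dir,
                                                        "summary.tsv"))
  }
  log <- list(package = "aqpscan",
              version = as.character(utils::packageVersion("aqpscan")),
              seed = seed, stages = seq_stages,
              parameters = cfg[order(names(cfg))],
              inputs = lapply(config[intersect(names(config),
                                               unique(unlist(needs)))],
                              function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs$run_log <- file.path(out_dir, "run_log.json")
  invisible(outputs)
}
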