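#' Read a protein or CDS FASTA file
#'
#' Headers are parsed as `id [species=...]`; when the species tag is absent
#' the configured default species is used. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"` or `"dna"`; controls alphabet validation.
#' @param config Configuration list from [aqp_config()].
#' @return A data.frame with columns `id`, `species`, `sequence`.
#' @export
read_fasta <- function(path, type = c("protein", "dna"), config = aqp_config()) {
  type <- match.arg(type)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  species <- ifelse(grepl("\\[species=", headers),
                    sub(".*\\[species=([^]]+)\\].*", "\\1", headers),
                    config$default_species)
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  alphabet <- if (type == "protein") c(AA_ALPHABET20, "X") else
    c("A", "C", "G", "T", "N")
  bad <- !vapply(strsplit(seqs, ""), function(x) all(x %in% alphabet), logical(1))
  if (any(bad)) {
    stop("invalid ", type, " alphabet in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  data.frame(id = ids, species = species, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `species` (emitted as a `[species=...]` header tag).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  headers <- records$id
  if (!is.null(records$species)) {
    headers <- paste0(headers, " [species=", records$species, "]")
  }
  set <- Biostrings::BStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene loci from a GFF3 file
#'
#' Keeps `gene` features (all features when none is typed `gene`) and flags
#' each locus as chromosome-anchored when its seqname matches the configured
#' chromosome pattern (default `"^chr"`).
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @param config Configuration list from [aqp_config()].
#' @return data.frame with columns `gene_id`, `seqname`, `start`, `end`,
#'   `strand`, `chromosome_flag`.
#' @export
read_gff3 <- function(path, config = aqp_config()) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if ("type" %in% names(df) && any(df$type == "gene")) {
    df <- df[df$type == "gene", , drop = FALSE]
  }
  if (is.null(df$ID) || anyNA(df$ID)) {
    stop("GFF3 gene feature without an ID attribute in ", path)
  }
  if (any(df$start > df$end)) {
    stop("GFF3 feature with start > end: ",
         paste(df$ID[df$start > df$end], collapse = ", "))
  }
  data.frame(
    gene_id = as.character(df$ID),
    seqname = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = ifelse(as.character(df$strand) %in% c("+", "-"),
                    as.character(df$strand), "+"),
    chromosome_flag = grepl(config$chromosome_pattern, as.character(df$seqnames)),
    stringsAsFactors = FALSE
  )
}

#' Write gene loci to a GFF3 file
#'
#' @param loci data.frame as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(loci, path) {
  stopifnot(all(loci$start <= loci$end))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\taqpscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     loci$seqname, loci$start, loci$end, loci$strand,
                     loci$gene_id), con)
  invisible(path)
}

SUBFAMILIES <- c("PIP", "TIP", "NIP", "SIP", "XIP")

#' Load a family characterisation table
#'
#' Reads a TSV shaped like the packaged pepper table (`table2.tsv`): gene
#' name, locus id, subfamily, subgroup, the four ar/R filter residues
#' (H2, H5, LE1, LE2; `-` for missing) and chromosome/scaffold location.
#'
#' @param path Path to the TSV; defaults to the packaged pepper fixture.
#' @param config Configuration list from [aqp_config()].
#' @return data.frame, one row per gene, with an added logical column
#'   `newly_annotated` (locus id prefixed `CANN_MIP.`) and
#'   `chromosome_flag`.
#' @export
load_family_table <- function(path = system.file("extdata", "table2.tsv",
                                                 package = "aqpscan"),
                              config = aqp_config()) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    return(data.frame(gene_name = character(), locus_id = character(),
                      subfamily = character(), subgroup = character(),
                      h2 = character(), h5 = character(), le1 = character(),
                      le2 = character(), location = character(),
                      newly_annotated = logical(),
                      chromosome_flag = logical(), stringsAsFactors = FALSE))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_name", "locus_id", "subfamily", "subgroup",
            "h2", "h5", "le1", "le2", "location")
  stopifnot(all(need %in% names(tab)))
  bad <- setdiff(unique(tab$subfamily), SUBFAMILIES)
  if (length(bad)) stop("unknown subfamily token(s): ", paste(bad, collapse = ", "))
  if (any(substr(tab$subgroup, 1, 3) != tab$subfamily)) {
    stop("subgroup prefix must equal subfamily")
  }
  tab$newly_annotated <- startsWith(tab$locus_id, "CANN_MIP.")
  tab$chromosome_flag <- grepl(config$chromosome_pattern, tab$location)
  tab
}

#' Load the per-species family summary fixture
#'
#' @param path Path to the TSV; defaults to the packaged fixture.
#' @return data.frame with per-species totals, per-subfamily counts and
#'   newly-annotated counts.
#' @export
load_species_summary <- function(path = system.file("extdata", "table1.tsv",
                                                    package = "aqpscan")) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Load an ar/R signature table
#'
#' Each row is a priority-ordered pattern: per position a set of allowed
#' residues (several letters) or `.` for "any residue".
#'
#' @param path Path to the TSV; defaults to the packaged table compiled from
#'   published plant AQP selectivity-filter signatures.
#' @return data.frame with columns `subfamily`, `subgroup`, `h2`, `h5`,
#'   `le1`, `le2`.
#' @export
load_signature_table <- function(path = system.file("extdata", "signatures.tsv",
                                                    package = "aqpscan")) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("subfamily", "subgroup", "h2", "h5", "le1", "le2") %in%
                  names(tab)))
  stopifnot(all(tab$subfamily %in% SUBFAMILIES))
  tab
}

#' Read an expression matrix and its sample sheet
#'
#' @param matrix_path TSV of FPKM values, first column gene ids, remaining
#'   columns samples.
#' @param samples_path TSV with columns `sample`, `condition`, `timepoint`,
#'   `replicate`.
#' @return list with `fpkm` (numeric matrix, genes x samples) and `samples`
#'   (data.frame).
#' @export
read_expression <- function(matrix_path, samples_path) {
  tab <- read.delim(matrix_path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("FPKM values must be nonnegative")
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "condition", "timepoint", "replicate") %in%
                  names(samples)))
  stopifnot(all(colnames(m) %in% samples$sample))
  samples <- samples[match(colnames(m), samples$sample), , drop = FALSE]
  list(fpkm = m, samples = samples)
}

#' Read a gene-to-GO annotation map
#'
#' @param path TSV with two columns: gene id and a comma-separated GO id list.
#' @return Named list mapping gene id to a character vector of GO ids.
#' @export
read_go_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, header = TRUE,
                    colClasses = "character")
  terms <- strsplit(tab[[2]], ",", fixed = TRUE)
  terms <- lapply(terms, function(x) x[nzchar(x)])
  setNames(terms, tab[[1]])
}

#' Write a gene-to-GO annotation map
#' @param go_map Named list as returned by [read_go_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_go_map <- function(go_map, path) {
  df <- data.frame(gene = names(go_map),
                   terms = vapply(go_map, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
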