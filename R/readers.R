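#' Readers for the plain-text input formats
#'
#' All inputs are tab-separated text in their field-standard layouts:
#' BLAST outfmt-6-style hit tables, BED6 gene loci, bedGraph signal
#' tracks, GMT gene sets, and simple per-gene TSVs.  Every reader returns
#' a tibble with the column names the analysis functions expect.
#'
#' @name readers
NULL

read_tsv_quiet <- function(path, col_names, col_types) {
  readr::read_tsv(path, col_names = col_names, col_types = col_types,
                  comment = "#", progress = FALSE)
}

#' Read a BLAST-style homology hit table
#'
#' Tab-separated with columns `qseqid`, `sseqid`, `evalue`, `length`
#' (aligned query residues), `qlen` (query protein length), `staxid`.
#' A header row is optional and `#` comment lines are skipped.
#'
#' @param path File path.
#' @return Tibble with columns `query_gene`, `subject_id`, `e_value`,
#'   `align_length`, `query_length`, `subject_taxon`.
#' @export
read_homology_hits <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) > 0 && grepl("qseqid", lines[1], fixed = TRUE)) {
    lines <- lines[-1]
  }
  x <- readr::read_tsv(I(lines),
                       col_names = c("qseqid", "sseqid", "evalue", "length",
                                     "qlen", "staxid"),
                       col_types = "ccdiic", progress = FALSE)
  tibble::tibble(query_gene = x$qseqid, subject_id = x$sseqid,
                 e_value = x$evalue, align_length = x$length,
                 query_length = x$qlen, subject_taxon = x$staxid)
}

#' Read a lineage table
#'
#' TSV with columns `taxon_id`, `in_lineage` (0/1), `genome_label`,
#' `phylo_rank` (integer distance from the focal species).
#'
#' @param path File path.
#' @return Tibble with columns `taxon`, `in_lineage` (logical),
#'   `genome_label`, `phylo_rank`.
#' @export
read_lineage <- function(path) {
  x <- read_tsv_quiet(path, c("taxon_id", "in_lineage", "genome_label",
                              "phylo_rank"), "cicc")
  tibble::tibble(taxon = x$taxon_id, in_lineage = x$in_lineage == 1,
                 genome_label = x$genome_label,
                 phylo_rank = as.integer(x$phylo_rank))
}

#' Read a per-gene domain annotation table
#'
#' TSV `gene`, comma-joined domain accessions (empty field = no domains).
#'
#' @param path File path.
#' @return Tibble with columns `gene`, `domains`.
#' @export
read_domains <- function(path) {
  x <- read_tsv_quiet(path, c("gene", "domains"), "cc")
  x$domains[is.na(x$domains)] <- ""
  x
}

#' Read an essential-gene list (one identifier per line)
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_essential_genes <- function(path) {
  lines <- readr::read_lines(path)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read gene loci from a BED6 file
#'
#' Standard BED: 0-based half-open `chrom`, `start`, `end`, `name`,
#' `score` (ignored), `strand`.
#'
#' @param path File path.
#' @return Tibble with columns `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed6 <- function(path) {
  x <- read_tsv_quiet(path, c("chrom", "start", "end", "name", "score",
                              "strand"), "ciiccc")
  tibble::tibble(gene = x$name, chrom = x$chrom, start = x$start,
                 end = x$end, strand = x$strand)
}

#' Read a bedGraph signal track
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open intervals).
#' @export
read_bedgraph <- function(path) {
  read_tsv_quiet(path, c("chrom", "start", "end", "value"), "ciid")
}

#' Read a per-gene scalar table (e.g. expression level or dN/dS)
#'
#' @param path File path.
#' @param value_name Name for the value column.
#' @return Tibble with columns `gene` and `value_name`.
#' @export
read_gene_values <- function(path, value_name = "value") {
  x <- read_tsv_quiet(path, c("gene", value_name), "cd")
  x
}

#' Read an expression dataset matrix
#'
#' TSV whose first column is the gene identifier and remaining columns are
#' samples.  Rows must already be collapsed to one per gene (multi-probe
#' genes averaged per dataset before export).
#'
#' @param path File path.
#' @param dataset_id Identifier attached to the result.
#' @return A list with elements `dataset_id`, `genes` (character) and
#'   `values` (numeric matrix, genes x samples, rownames = genes).
#' @export
read_expression_dataset <- function(path, dataset_id = basename(path)) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (anyDuplicated(x$gene)) {
    stop("duplicate gene identifiers in expression dataset ", dataset_id,
         "; collapse probes to one row per gene first")
  }
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene
  if (ncol(m) < 3) stop("expression dataset ", dataset_id, " has < 3 samples")
  list(dataset_id = dataset_id, genes = x$gene, values = m)
}

#' Read an expression manifest and all datasets it lists
#'
#' The manifest is a TSV with columns `dataset_id`, `path` (relative paths
#' resolved against the manifest's directory).
#'
#' @param path Manifest file path.
#' @return List of datasets as returned by [read_expression_dataset()].
#' @export
read_expression_manifest <- function(path) {
  man <- read_tsv_quiet(path, c("dataset_id", "path"), "cc")
  purrr::map2(man$dataset_id, man$path, function(id, p) {
    if (!file.exists(p)) p <- file.path(dirname(path), p)
    read_expression_dataset(p, id)
  })
}

#' Read a GMT gene-set collection
#'
#' Uses the standard GMT layout (set id, description, member genes).
#'
#' @param path File path.
#' @return Named list of character vectors (set id -> member genes).
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0 || any(lengths(sets) == 0)) {
    stop("empty gene-set collection in ", path)
  }
  sets
}

#' Read an undirected edge list
#'
#' TSV `gene_a`, `gene_b` with optional `weight` and `evidence_type`
#' columns.  Duplicate and reversed pairs are merged (first weight kept),
#' and self-loops are dropped with a message.
#'
#' @param path File path.
#' @param evidence Optional evidence-type filter (e.g. `"AP-MS"`); rows
#'   with other evidence values are dropped before de-duplication.
#' @return Tibble with columns `gene_a`, `gene_b`, `weight`.
#' @export
read_edge_list <- function(path, evidence = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), comment = "#",
                         progress = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(raw))) {
    names(raw)[1:2] <- c("gene_a", "gene_b")
  }
  if (!is.null(evidence)) {
    if (!"evidence_type" %in% names(raw)) {
      stop("evidence filter requested but no evidence_type column present")
    }
    raw <- dplyr::filter(raw, .data$evidence_type %in% evidence)
  }
  if (!"weight" %in% names(raw)) raw$weight <- 1
  tidy_edges(raw[c("gene_a", "gene_b", "weight")])
}

# canonicalize an edge tibble: drop self-loops, merge duplicates/reverses
tidy_edges <- function(edges) {
  n_self <- sum(edges$gene_a == edges$gene_b)
  if (n_self > 0) {
    message("dropped ", n_self, " self-loop(s) from edge list")
    edges <- dplyr::filter(edges, .data$gene_a != .data$gene_b)
  }
  edges |>
    dplyr::mutate(a = pmin(.data$gene_a, .data$gene_b),
                  b = pmax(.data$gene_a, .data$gene_b)) |>
    dplyr::distinct(.data$a, .data$b, .keep_all = TRUE) |>
    dplyr::transmute(gene_a = .data$a, gene_b = .data$b,
                     weight = .data$weight)
}

#' Read a per-protein feature table (disorder + coiled coil)
#'
#' TSV `gene`, `ordered_fraction` (fraction of residues predicted ordered,
#' in `[0, 1]`), `has_coiled_coil` (0/1).
#'
#' @param path File path.
#' @return Tibble with columns `gene`, `ordered_fraction`,
#'   `has_coiled_coil` (logical).
#' @export
read_protein_features <- function(path) {
  x <- read_tsv_quiet(path, c("gene", "ordered_fraction", "has_coiled_coil"),
                      "cdi")
  if (any(x$ordered_fraction < 0 | x$ordered_fraction > 1)) {
    stop("ordered_fraction outside [0, 1] in ", path)
  }
  x$has_coiled_coil <- x$has_coiled_coil == 1
  x
}

#' Read a per-gene dN/dS + functional-class table
#'
#' TSV `gene`, `dnds`, `functional_class`; genes annotated to several
#' classes appear as duplicated rows.
#'
#' @param path File path.
#' @return Tibble with columns `gene`, `dnds`, `functional_class`.
#' @export
read_rates <- function(path) {
  x <- read_tsv_quiet(path, c("gene", "dnds", "functional_class"), "cdc")
  if (any(x$dnds < 0)) stop("negative dN/dS in ", path)
  x
}

#' Read a gene-class table written by the pipeline
#'
#' @param path File path.
#' @return Tibble with the [assign_four_classes()] columns.
#' @export
read_gene_classes <- function(path) {
  readr::read_tsv(path, col_types = "cclcl", progress = FALSE)
}
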