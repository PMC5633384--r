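#' Configuration for a synthetic TRG world
#'
#' Defines the study conditions for the synthetic-data generator: a
#' genome's worth of genes split into taxonomically restricted vs shared
#' and essential vs nonessential, plus every planted effect the analysis
#' pipeline is designed to detect.  Defaults describe a genome in which
#' 15% of genes are TRGs (typical eukaryotic genomes carry ~10-20%
#' lineage-restricted genes), 17% are essential, and 3% are essential
#' TRGs, with planted coexpression, genomic-context, network, protein-
#' feature and rate effects in the directions the comparisons test.
#'
#' @param n_genes Number of genes (default 2000).
#' @param frac_trg Fraction of genes that are TRGs (default 0.15).
#' @param frac_essential Fraction of genes essential (default 0.17).
#' @param frac_trg_essential Fraction of genes that are essential TRGs
#'   (default 0.03); must not exceed `frac_trg` or `frac_essential`.
#' @param frac_trg_weak_hits Fraction of TRGs given a weak out-of-lineage
#'   hit (E = 1e-4 over 15% of the protein) visible only to relaxed
#'   cutoffs (default 0.25).
#' @param frac_domain_excluded Fraction of genes with no out-of-lineage
#'   homology but an annotated domain, so the domain rule re-labels them
#'   shared (default 0.02).
#' @param n_datasets,n_samples_per_dataset Expression compendium shape
#'   (default 6 datasets x 30 samples).
#' @param n_pathways,n_essential_pathways,pathway_size Gene-set
#'   collection: `n_pathways` disjoint pathways of `pathway_size` shared
#'   genes, the first `n_essential_pathways` drawn from shared essentials
#'   (defaults 20 / 5 / 15).
#' @param coexpr_loading Loading of essential genes on the
#'   essential-pathway latent factors (default 0.8; 0 removes the
#'   coexpression signal).  Per-gene strength is jittered uniformly on
#'   (0.2, 1) times this value.
#' @param neighbor_shift Log-expression bump for essential TRGs and their
#'   three flanking genes on each side (default 1).
#' @param chromatin_shift Added activation-mark signal in bins within
#'   5 kb of an essential TRG (default 1).
#' @param ppi_block_sizes Community sizes of the interaction network
#'   (default 15 blocks of 40).
#' @param p_in,p_out Within/between-block edge probabilities (defaults
#'   0.3 / 0.01).
#' @param ppi_trg_block_fraction TRG fraction packed into the first block
#'   (default 0.6); `NA` disables the planted cluster (nodes assigned to
#'   blocks at random).
#' @param degree_bias_essential Edge-probability multiplier for essential
#'   nodes (default 3 for essential TRGs, its square root for shared
#'   essentials; 1 disables the degree effect).
#' @param disorder_params Named list of Beta shape pairs for the
#'   ordered fraction per four-class.
#' @param coiled_coil_probs Named vector of coiled-coil probabilities per
#'   four-class.
#' @param dnds_gamma_params Named list of Gamma (shape, rate) pairs per
#'   functional class.
#' @param trg_class_bias Named multiplier on the class-assignment weights
#'   for TRGs (plants the TRG-rich/TRG-poor functional classes).
#' @param n_chromosomes Number of chromosomes (default 5).
#' @param seed Integer seed; the whole world is a deterministic function
#'   of the configuration.
#' @return Object of class `trg_world_config` (a validated list).
#' @seealso [null_world_config()] for the all-effects-zero configuration.
#' @export
world_config <- function(n_genes = 2000,
                         frac_trg = 0.15,
                         frac_essential = 0.17,
                         frac_trg_essential = 0.03,
                         frac_trg_weak_hits = 0.25,
                         frac_domain_excluded = 0.02,
                         n_datasets = 6,
                         n_samples_per_dataset = 30,
                         n_pathways = 20,
                         n_essential_pathways = 5,
                         pathway_size = 15,
                         coexpr_loading = 0.8,
                         neighbor_shift = 1,
                         chromatin_shift = 1,
                         ppi_block_sizes = rep(40, 15),
                         p_in = 0.3,
                         p_out = 0.01,
                         ppi_trg_block_fraction = 0.6,
                         degree_bias_essential = 3,
                         disorder_params = list(
                           "TRG-E" = c(5.5, 4.5), "TRG-NE" = c(7, 3),
                           "Shared-E" = c(8.5, 1.5), "Shared-NE" = c(8, 2)),
                         coiled_coil_probs = c(
                           "TRG-E" = 0.5, "TRG-NE" = 0.2,
                           "Shared-E" = 0.3, "Shared-NE" = 0.2),
                         dnds_gamma_params = list(
                           "amino acid biosynthesis" = c(3, 55),
                           "translation" = c(3, 45),
                           "transcription" = c(3, 40),
                           "secretion" = c(3, 35),
                           "mitochondrial" = c(3, 33),
                           "cell cycle" = c(3, 30),
                           "signaling" = c(3, 28),
                           "chromosome segregation" = c(3, 24)),
                         trg_class_bias = c(
                           "amino acid biosynthesis" = 0.25,
                           "translation" = 0.5,
                           "transcription" = 0.6,
                           "secretion" = 0.8,
                           "mitochondrial" = 0.8,
                           "cell cycle" = 1,
                           "signaling" = 1.2,
                           "chromosome segregation" = 2.5),
                         n_chromosomes = 5,
                         seed = 1) {
  cfg <- as.list(environment())
  fr <- c(frac_trg, frac_essential, frac_trg_essential, frac_trg_weak_hits,
          frac_domain_excluded)
  if (any(fr < 0 | fr > 1)) stop("world_config(): fractions must lie in [0, 1]")
  if (frac_trg_essential > frac_essential) {
    stop("infeasible configuration: frac_trg_essential (", frac_trg_essential,
         ") exceeds frac_essential (", frac_essential, ")")
  }
  if (frac_trg_essential > frac_trg) {
    stop("infeasible configuration: frac_trg_essential (", frac_trg_essential,
         ") exceeds frac_trg (", frac_trg, ")")
  }
  if (sum(ppi_block_sizes) > n_genes) {
    stop("infeasible configuration: network larger than the genome")
  }
  if (n_essential_pathways > n_pathways) {
    stop("infeasible configuration: n_essential_pathways > n_pathways")
  }
  n_she <- round(n_genes * (frac_essential - frac_trg_essential))
  n_shne <- n_genes - round(n_genes * frac_trg) - n_she
  if (n_essential_pathways * pathway_size > n_she ||
      (n_pathways - n_essential_pathways) * pathway_size > n_shne) {
    stop("infeasible configuration: pathways need more shared genes ",
         "than the class fractions provide")
  }
  structure(cfg, class = "trg_world_config")
}

#' All-effects-zero configuration
#'
#' The same world shape as [world_config()] but with every planted effect
#' removed: no coexpression loading, no neighborhood or chromatin shift,
#' no degree bias, no TRG-rich network block, identical protein-feature
#' and rate distributions across classes.  Used to calibrate the
#' pipeline's false-positive behavior.
#'
#' @param ... Overrides passed to [world_config()].
#' @return A `trg_world_config`.
#' @export
null_world_config <- function(...) {
  flat_beta <- list("TRG-E" = c(8, 2), "TRG-NE" = c(8, 2),
                    "Shared-E" = c(8, 2), "Shared-NE" = c(8, 2))
  flat_cc <- c("TRG-E" = 0.2, "TRG-NE" = 0.2,
               "Shared-E" = 0.2, "Shared-NE" = 0.2)
  flat_gamma <- list(
    "amino acid biosynthesis" = c(3, 35), "translation" = c(3, 35),
    "transcription" = c(3, 35), "secretion" = c(3, 35),
    "mitochondrial" = c(3, 35), "cell cycle" = c(3, 35),
    "signaling" = c(3, 35), "chromosome segregation" = c(3, 35))
  flat_bias <- stats::setNames(rep(1, 8), names(flat_gamma))
  world_config(coexpr_loading = 0, neighbor_shift = 0, chromatin_shift = 0,
               ppi_trg_block_fraction = NA, degree_bias_essential = 1,
               disorder_params = flat_beta, coiled_coil_probs = flat_cc,
               dnds_gamma_params = flat_gamma, trg_class_bias = flat_bias,
               ...)
}

#' Generate a synthetic TRG world
#'
#' Produces an internally consistent set of inputs for every pipeline
#' stage — homology hits, lineage and domain tables, gene loci,
#' expression datasets, pathway gene sets, chromatin tracks, an
#' interaction network, protein features and evolutionary rates — with
#' full ground-truth bookkeeping.  The world is a deterministic function
#' of the configuration (same config, byte-identical world).
#'
#' @param config A [world_config()].
#' @param dir Optional directory: when given, the world is also written
#'   to disk via [write_world()].
#' @return Object of class `trg_world`: list with `config`, `genes`
#'   (truth table), `hits`, `lineage`, `domains`, `essential_genes`,
#'   `loci`, `expr_levels`, `datasets`, `pathways`,
#'   `essential_pathways`, `tracks`, `ppi_edges`, `network_truth`,
#'   `protein_features`, `rates`, `truth`.
#' @export
generate_world <- function(config = world_config(), dir = NULL) {
  stopifnot(inherits(config, "trg_world_config"))
  world <- withr::with_seed(config$seed, build_world(config))
  if (!is.null(dir)) write_world(world, dir)
  world
}

build_world <- function(cfg) {
  n <- cfg$n_genes
  genes <- sprintf("gene%05d", seq_len(n))

  # --- classes -------------------------------------------------------
  n_trg <- round(n * cfg$frac_trg)
  n_te <- round(n * cfg$frac_trg_essential)
  n_ess <- round(n * cfg$frac_essential)
  idx <- sample(n)
  trg_idx <- idx[seq_len(n_trg)]
  te_idx <- trg_idx[seq_len(n_te)]
  she_idx <- idx[(n_trg + 1):(n_trg + (n_ess - n_te))]
  conservation <- ifelse(seq_len(n) %in% trg_idx, "TRG", "shared")
  essential <- seq_len(n) %in% c(te_idx, she_idx)
  four_class <- paste0(ifelse(conservation == "TRG", "TRG", "Shared"),
                       ifelse(essential, "-E", "-NE"))

  # domain-excluded genes: shared, no out-lineage homology, but a domain
  shared_pool <- which(conservation == "shared")
  n_dom_excl <- round(n * cfg$frac_domain_excluded)
  dom_excl_idx <- sample(shared_pool, n_dom_excl)

  # --- loci: genes laid down chromosome by chromosome ----------------
  chrom <- rep(paste0("chr", utils::as.roman(seq_len(cfg$n_chromosomes))),
               length.out = n)
  chrom <- sort(chrom)
  loci <- tibble::tibble(gene = genes, chrom = chrom) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      .len = round(stats::runif(dplyr::n(), 1000, 3000)),
      .gap = round(stats::runif(dplyr::n(), 1000, 10000)),
      start = cumsum(.data$.gap) + dplyr::lag(cumsum(.data$.len), default = 0),
      end = .data$start + .data$.len,
      strand = sample(c("+", "-"), dplyr::n(), replace = TRUE)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "chrom", "start", "end", "strand")

  # --- lineage table -------------------------------------------------
  lineage <- tibble::tibble(
    taxon = paste0("taxon", 1:12),
    in_lineage = c(rep(TRUE, 4), rep(FALSE, 8)),
    genome_label = c("Focal", "Sister1", "Sister2", "Sister3",
                     "Out1", "Out2", "Out3", "Out4", "Out5", "Out6",
                     "Out7", "Out8"),
    phylo_rank = 1:12)
  out_taxa <- lineage$taxon[!lineage$in_lineage]

  # --- homology hits -------------------------------------------------
  qlen <- sample(150:800, n, replace = TRUE)
  in_hits <- tibble::tibble(
    query_gene = rep(genes, 2),
    subject_taxon = rep(c("taxon1", "taxon2"), each = n),
    e_value = 10^stats::runif(2 * n, -150, -40),
    align_length = round(rep(qlen, 2) * stats::runif(2 * n, 0.6, 1)))
  # shared genes (except domain-excluded) get qualifying out-lineage hits
  out_qualify_idx <- setdiff(shared_pool, dom_excl_idx)
  n_extra <- stats::rpois(length(out_qualify_idx), 2)
  out_hits <- tibble::tibble(
    query_gene = rep(genes[out_qualify_idx], 1 + n_extra),
    subject_taxon = sample(out_taxa, sum(1 + n_extra), replace = TRUE),
    e_value = 10^stats::runif(sum(1 + n_extra), -120, -8),
    align_length = round(rep(qlen[out_qualify_idx], 1 + n_extra) *
                           stats::runif(sum(1 + n_extra), 0.35, 0.95)))
  # a fixed-strength weak out-lineage hit for some TRGs (relaxed scan)
  n_weak <- round(n_trg * cfg$frac_trg_weak_hits)
  weak_idx <- sample(trg_idx, n_weak)
  weak_hits <- tibble::tibble(
    query_gene = genes[weak_idx],
    subject_taxon = sample(out_taxa, n_weak, replace = TRUE),
    e_value = 1e-4,
    align_length = round(qlen[weak_idx] * 0.15))
  hits <- dplyr::bind_rows(in_hits, out_hits, weak_hits) |>
    dplyr::mutate(
      query_length = qlen[match(.data$query_gene, genes)],
      align_length = pmax(pmin(.data$align_length, .data$query_length), 10L),
      subject_id = paste0(.data$subject_taxon, "_prot",
                          seq_len(dplyr::n()))) |>
    dplyr::select("query_gene", "subject_id", "e_value", "align_length",
                  "query_length", "subject_taxon")

  # --- domains: shared genes carry domains; TRGs never do ------------
  has_domain <- logical(n)
  has_domain[dom_excl_idx] <- TRUE
  other_shared <- setdiff(shared_pool, dom_excl_idx)
  has_domain[sample(other_shared, round(0.6 * length(other_shared)))] <- TRUE
  domains <- tibble::tibble(
    gene = genes,
    domains = ifelse(has_domain,
                     paste0("IPR", sprintf("%06d", sample(1e5, n, TRUE))), ""))

  # --- pathways over shared genes ------------------------------------
  she_genes <- genes[she_idx]
  shne_genes <- genes[setdiff(shared_pool, she_idx)]
  n_ep <- cfg$n_essential_pathways
  ep_members <- matrix(sample(she_genes, n_ep * cfg$pathway_size),
                       nrow = cfg$pathway_size)
  np_members <- matrix(sample(shne_genes,
                              (cfg$n_pathways - n_ep) * cfg$pathway_size),
                       nrow = cfg$pathway_size)
  pathways <- c(
    stats::setNames(asplit(ep_members, 2), paste0("pw_ess", seq_len(n_ep))),
    stats::setNames(asplit(np_members, 2),
                    paste0("pw", seq_len(cfg$n_pathways - n_ep))))
  pathways <- lapply(pathways, as.character)
  essential_pathways <- paste0("pw_ess", seq_len(n_ep))

  # --- expression: latent pathway factors ----------------------------
  # loading matrix is biological (fixed across datasets)
  loading <- matrix(0, n, cfg$n_pathways,
                    dimnames = list(genes, names(pathways)))
  for (p in names(pathways)) loading[pathways[[p]], p] <- 1
  ess_strength <- stats::runif(n, 0.2, 1) * cfg$coexpr_loading
  ess_rows <- essential  # both shared and TRG essentials co-express
  for (p in essential_pathways) {
    loading[ess_rows, p] <- loading[ess_rows, p] + ess_strength[ess_rows]
  }
  datasets <- lapply(seq_len(cfg$n_datasets), function(d) {
    f <- matrix(stats::rnorm(cfg$n_pathways * cfg$n_samples_per_dataset),
                cfg$n_pathways)
    x <- loading %*% f +
      matrix(stats::rnorm(n * cfg$n_samples_per_dataset), n)
    colnames(x) <- paste0("s", seq_len(ncol(x)))
    list(dataset_id = paste0("ds", d), genes = genes, values = x)
  })

  # --- scalar expression levels with a neighborhood effect -----------
  pos <- loci |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.pos = dplyr::row_number()) |>
    dplyr::ungroup()
  te_genes <- genes[te_idx]
  near_te <- pos |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(near = {
      te_pos <- .data$.pos[.data$gene %in% te_genes]
      vapply(.data$.pos, function(p) any(abs(p - te_pos) <= 3), logical(1))
    }) |>
    dplyr::ungroup()
  neighborhood <- near_te$near[match(genes, near_te$gene)]
  expr_levels <- tibble::tibble(
    gene = genes,
    value = 5 + stats::rnorm(n) + cfg$neighbor_shift * neighborhood)

  # --- chromatin tracks ----------------------------------------------
  tracks <- make_tracks(loci, te_genes, cfg$chromatin_shift)

  # --- interaction network -------------------------------------------
  net <- make_ppi(genes, four_class, te_idx, trg_idx, cfg)

  # --- protein features ----------------------------------------------
  dp <- cfg$disorder_params
  of <- numeric(n); cc <- logical(n)
  for (cl in names(dp)) {
    i <- four_class == cl
    of[i] <- stats::rbeta(sum(i), dp[[cl]][1], dp[[cl]][2])
    cc[i] <- stats::rbinom(sum(i), 1, cfg$coiled_coil_probs[[cl]]) == 1
  }
  protein_features <- tibble::tibble(gene = genes, ordered_fraction = of,
                                     has_coiled_coil = cc)

  # --- evolutionary rates by functional class ------------------------
  fc <- names(cfg$dnds_gamma_params)
  base_w <- rep(1, length(fc))
  w_trg <- base_w * cfg$trg_class_bias[fc]
  fclass <- ifelse(conservation == "TRG",
                   sample(fc, n, TRUE, prob = w_trg),
                   sample(fc, n, TRUE, prob = base_w))
  dnds <- vapply(seq_len(n), function(i) {
    pr <- cfg$dnds_gamma_params[[fclass[i]]]
    stats::rgamma(1, pr[1], pr[2])
  }, numeric(1))
  rates <- tibble::tibble(gene = genes, dnds = dnds, functional_class = fclass)

  gene_table <- tibble::tibble(
    gene = genes, conservation = conservation, essential = essential,
    four_class = four_class,
    domain_excluded = seq_len(n) %in% dom_excl_idx,
    weak_hit = seq_len(n) %in% weak_idx,
    near_essential_trg = neighborhood)

  truth <- list(
    counts = dplyr::count(gene_table, .data$four_class, name = "n"),
    trg_genes = genes[trg_idx],
    essential_genes = genes[sort(c(te_idx, she_idx))],
    weak_hit_genes = genes[weak_idx],
    weak_hit_e = 1e-4, weak_hit_coverage = 0.15,
    domain_excluded_genes = genes[dom_excl_idx],
    essential_pathways = essential_pathways,
    planted_block_genes = net$planted_block_genes,
    network_trg_fraction = mean(net$node_table$conservation == "TRG"),
    effects = cfg[c("coexpr_loading", "neighbor_shift", "chromatin_shift",
                    "degree_bias_essential", "ppi_trg_block_fraction")])

  structure(list(
    config = cfg, genes = gene_table, hits = hits, lineage = lineage,
    domains = domains, essential_genes = truth$essential_genes,
    loci = loci, expr_levels = expr_levels, datasets = datasets,
    pathways = pathways, essential_pathways = essential_pathways,
    tracks = tracks, ppi_edges = net$edges, network_truth = net$node_table,
    protein_features = protein_features, rates = rates, truth = truth
  ), class = "trg_world")
}

make_tracks <- function(loci, te_genes, chromatin_shift, bin = 500) {
  purrr::map(c(h3k79 = "h3k79", h3k27 = "h3k27"), function(mark) {
    out <- purrr::map_dfr(unique(loci$chrom), function(chr) {
      here <- loci[loci$chrom == chr, ]
      chrom_end <- max(here$end) + 6000
      starts <- seq(0, chrom_end, by = bin)
      val <- stats::rnorm(length(starts))
      if (mark == "h3k79" && chromatin_shift != 0) {
        te <- here[here$gene %in% te_genes, ]
        if (nrow(te) > 0) {
          active <- rep(FALSE, length(starts))
          for (i in seq_len(nrow(te))) {
            active <- active | (starts + bin > te$start[i] - 5000 &
                                  starts < te$end[i] + 5000)
          }
          val <- val + chromatin_shift * active
        }
      }
      tibble::tibble(chrom = chr, start = starts, end = starts + bin,
                     value = round(val, 4))
    })
    out
  })
}

make_ppi <- function(genes, four_class, te_idx, trg_idx, cfg) {
  n_nodes <- sum(cfg$ppi_block_sizes)
  te_genes <- genes[te_idx]
  tne_genes <- genes[setdiff(trg_idx, te_idx)]
  she_genes <- genes[four_class == "Shared-E"]
  shne_genes <- genes[four_class == "Shared-NE"]
  b1 <- cfg$ppi_block_sizes[1]
  if (!is.na(cfg$ppi_trg_block_fraction)) {
    # planted TRG-rich first block
    n_b1_trg <- round(b1 * cfg$ppi_trg_block_fraction)
    b1_te <- utils::head(te_genes, ceiling(n_b1_trg / 2))
    b1_tne <- utils::head(tne_genes, n_b1_trg - length(b1_te))
    n_b1_sh <- b1 - n_b1_trg
    b1_nodes <- c(b1_te, b1_tne,
                  utils::head(she_genes, ceiling(n_b1_sh / 2)),
                  utils::head(shne_genes, floor(n_b1_sh / 2)))
    rest_te <- setdiff(te_genes, b1_nodes)
    n_rest <- n_nodes - b1
    rest_tne <- utils::head(setdiff(tne_genes, b1_nodes),
                            max(0, round(0.05 * n_rest)))
    rest_she <- utils::head(setdiff(she_genes, b1_nodes),
                            round(0.36 * n_rest))
    n_fill <- n_rest - length(rest_te) - length(rest_tne) - length(rest_she)
    rest_sh <- utils::head(setdiff(shne_genes, b1_nodes), n_fill)
    nodes <- c(b1_nodes, sample(c(rest_te, rest_tne, rest_she, rest_sh)))
    block <- rep(seq_along(cfg$ppi_block_sizes), cfg$ppi_block_sizes)
  } else {
    # no planted cluster: same node pool, random block assignment
    pool <- c(te_genes,
              utils::head(tne_genes, max(0, round(0.05 * n_nodes))),
              utils::head(she_genes, round(0.36 * n_nodes)))
    pool <- c(pool, utils::head(shne_genes, n_nodes - length(pool)))
    nodes <- sample(pool)
    block <- rep(seq_along(cfg$ppi_block_sizes), cfg$ppi_block_sizes)
  }
  fc <- four_class[match(nodes, genes)]
  bias <- ifelse(fc == "TRG-E", cfg$degree_bias_essential,
                 ifelse(fc == "Shared-E", sqrt(cfg$degree_bias_essential), 1))
  pairs <- utils::combn(n_nodes, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  p_base <- ifelse(block[i] == block[j], cfg$p_in, cfg$p_out)
  p_edge <- pmin(0.9, p_base * bias[i] * bias[j])
  keep <- stats::rbinom(length(p_edge), 1, p_edge) == 1
  edges <- tibble::tibble(gene_a = nodes[i[keep]], gene_b = nodes[j[keep]],
                          weight = 1)
  list(edges = edges,
       node_table = tibble::tibble(gene = nodes, block = block,
                                   four_class = fc,
                                   conservation = ifelse(startsWith(fc, "TRG"),
                                                         "TRG", "shared")),
       planted_block_genes = if (!is.na(cfg$ppi_trg_block_fraction))
         nodes[block == 1] else character())
}

#' @export
print.trg_world <- function(x, ...) {
  cat("Synthetic TRG world:", nrow(x$genes), "genes on",
      x$config$n_chromosomes, "chromosomes (seed", x$config$seed, ")\n")
  print(x$truth$counts)
  invisible(x)
}

#' Write a synthetic world to disk in the pipeline's input formats
#'
#' Emits `hits.tsv`, `lineage.tsv`, `domains.tsv`, `essential.txt`,
#' `genes.bed`, `expr/` (manifest + per-dataset TSVs), `pathways.gmt`,
#' `h3k79.bedgraph`, `h3k27.bedgraph`, `expr_levels.tsv`, `ppi.tsv`,
#' `protein_features.tsv`, `rates.tsv` and `truth.json`.
#'
#' @param world A `trg_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(...) file.path(dir, ...)
  h <- world$hits
  readr::write_tsv(
    tibble::tibble(qseqid = h$query_gene, sseqid = h$subject_id,
                   evalue = h$e_value, length = h$align_length,
                   qlen = h$query_length, staxid = h$subject_taxon),
    w("hits.tsv"))
  l <- world$lineage
  readr::write_tsv(
    tibble::tibble(taxon_id = l$taxon, in_lineage = as.integer(l$in_lineage),
                   genome_label = l$genome_label, phylo_rank = l$phylo_rank),
    w("lineage.tsv"), col_names = FALSE)
  readr::write_tsv(world$domains, w("domains.tsv"), col_names = FALSE)
  writeLines(world$essential_genes, w("essential.txt"))
  readr::write_tsv(
    dplyr::transmute(world$loci, .data$chrom, .data$start, .data$end,
                     name = .data$gene, score = 0, .data$strand),
    w("genes.bed"), col_names = FALSE)
  dir.create(w("expr"), showWarnings = FALSE)
  man <- purrr::map_dfr(world$datasets, function(d) {
    fname <- paste0(d$dataset_id, ".tsv")
    readr::write_tsv(
      dplyr::bind_cols(tibble::tibble(gene = d$genes),
                       tibble::as_tibble(d$values)),
      w("expr", fname))
    # paths relative to the manifest's own directory
    tibble::tibble(dataset_id = d$dataset_id, path = fname)
  })
  readr::write_tsv(man, w("expr", "manifest.tsv"), col_names = FALSE)
  writeLines(vapply(names(world$pathways), function(p) {
    paste(c(p, "synthetic pathway", world$pathways[[p]]), collapse = "\t")
  }, character(1)), w("pathways.gmt"))
  readr::write_tsv(world$tracks$h3k79, w("h3k79.bedgraph"), col_names = FALSE)
  readr::write_tsv(world$tracks$h3k27, w("h3k27.bedgraph"), col_names = FALSE)
  readr::write_tsv(world$expr_levels, w("expr_levels.tsv"), col_names = FALSE)
  readr::write_tsv(world$ppi_edges, w("ppi.tsv"))
  readr::write_tsv(
    dplyr::mutate(world$protein_features,
                  has_coiled_coil = as.integer(.data$has_coiled_coil)),
    w("protein_features.tsv"), col_names = FALSE)
  readr::write_tsv(world$rates, w("rates.tsv"), col_names = FALSE)
  jsonlite::write_json(
    list(counts = world$truth$counts,
         trg_genes = world$truth$trg_genes,
         essential_genes = world$truth$essential_genes,
         weak_hit_genes = world$truth$weak_hit_genes,
         weak_hit_e = world$truth$weak_hit_e,
         weak_hit_coverage = world$truth$weak_hit_coverage,
         domain_excluded_genes = world$truth$domain_excluded_genes,
         essential_pathways = world$truth$essential_pathways,
         planted_block_genes = world$truth$planted_block_genes,
         network_trg_fraction = world$truth$network_trg_fraction,
         effects = world$truth$effects),
    w("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Summarize the ground truth of a synthetic world
#'
#' @param world A `trg_world` object, or a directory written by
#'   [write_world()] (its `truth.json` is read).
#' @return List with `counts` (per four-class tibble), `n_genes`,
#'   `planted_block_trg_fraction`, `network_trg_fraction`,
#'   `n_weak_hit_trgs`, `n_domain_excluded`, `effects`.
#' @export
truth_report <- function(world) {
  if (is.character(world)) {
    tf <- file.path(world, "truth.json")
    if (!file.exists(tf)) stop("no truth.json under ", world)
    tr <- jsonlite::read_json(tf, simplifyVector = TRUE)
    tr$counts <- tibble::as_tibble(tr$counts)
    planted_frac <- if (length(tr$planted_block_genes) > 0)
      mean(tr$planted_block_genes %in% tr$trg_genes) else NA_real_
    return(list(counts = tr$counts, n_genes = sum(tr$counts$n),
                planted_block_trg_fraction = planted_frac,
                network_trg_fraction = tr$network_trg_fraction,
                n_weak_hit_trgs = length(tr$weak_hit_genes),
                n_domain_excluded = length(tr$domain_excluded_genes),
                effects = tr$effects))
  }
  stopifnot(inherits(world, "trg_world"))
  tr <- world$truth
  planted_frac <- if (length(tr$planted_block_genes) > 0)
    mean(tr$planted_block_genes %in% tr$trg_genes) else NA_real_
  list(counts = tr$counts, n_genes = nrow(world$genes),
       planted_block_trg_fraction = planted_frac,
       network_trg_fraction = tr$network_trg_fraction,
       n_weak_hit_trgs = length(tr$weak_hit_genes),
       n_domain_excluded = length(tr$domain_excluded_genes),
       effects = tr$effects)
}
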