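#' Specification of a planted gene cluster
#'
#' @param contig contig index (1-based) the cluster sits on.
#' @param start 0-based gene ordinal within that contig of the cluster's
#'   first gene.
#' @param length number of consecutive genes.
#' @param fc_range linear fold-change range; each cluster protein's true
#'   fold change is drawn log-uniformly from it.
#' @param frac_unique fraction of the cluster's proteins made
#'   case-unique by forcing control-side dropout.
#' @return list describing the cluster.
#' @export
planted_cluster <- function(contig = 1, start = 50, length = 9,
                            fc_range = c(20, 40), frac_unique = 0.2) {
  stopifnot(length >= 1, fc_range[1] > 0, fc_range[2] >= fc_range[1],
            frac_unique >= 0, frac_unique <= 1, start >= 0)
  list(contig = as.integer(contig), start = as.integer(start),
       length = as.integer(length), fc_range = fc_range,
       frac_unique = frac_unique)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a label-free bacterial
#' screen: 2 conditions x 2 biological x 2 technical replicates, about
#' 65% of genes with a quantified protein (the identified-proteome vs
#' coding-sequence ratio typical of such datasets), log-normal abundance
#' with nested biological/technical noise on the log2 scale, logistic
#' abundance-dependent detection dropout, a small background rate of
#' differential proteins, and one planted 9-gene high-fold-change cluster
#' embedded in genome order.
#'
#' @param n_genes genes in the genome (split evenly across contigs).
#' @param n_contigs contigs.
#' @param frac_quantified fraction of genes with a quantified protein
#'   (planted-cluster genes always have one; the fraction is met by
#'   sampling background genes).
#' @param conditions the two condition labels, case first.
#' @param n_bio,n_tech biological / technical replicates per condition.
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution.
#' @param sigma_bio,sigma_tech biological / technical noise sd (log2).
#' @param dropout_midpoint,dropout_scale logistic dropout: a value with
#'   log2 abundance `x` is missing with probability
#'   `plogis((dropout_midpoint - x) / dropout_scale)`.
#' @param planted_clusters list of [planted_cluster()] specs.
#' @param background_dap_rate probability a background protein carries a
#'   true effect.
#' @param background_lfc_range absolute log2 fold-change range of
#'   background effects (sign random).
#' @param ct_intercept,ct_slope,ct_noise_sd,n_ct_genes,n_ct_reps CT-table
#'   generation: CT = intercept - slope * log2(expression) + noise, for
#'   up to `n_ct_genes` planted genes, `n_ct_reps` technical replicates.
#' @param seed integer seed; the same seed yields identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 400, n_contigs = 2, frac_quantified = 0.65,
                       conditions = c("IAA", "IAACon"), n_bio = 2,
                       n_tech = 2, baseline_mean = 20, baseline_sd = 2,
                       sigma_bio = 0.25, sigma_tech = 0.1,
                       dropout_midpoint = 16, dropout_scale = 1.5,
                       planted_clusters = list(planted_cluster()),
                       background_dap_rate = 0.02,
                       background_lfc_range = c(1, 3),
                       ct_intercept = 40, ct_slope = 1, ct_noise_sd = 0.15,
                       n_ct_genes = 5, n_ct_reps = 3, seed = 1) {
  stopifnot(n_genes >= n_contigs, n_contigs >= 1,
            frac_quantified > 0, frac_quantified <= 1,
            length(conditions) == 2, n_bio >= 1, n_tech >= 1,
            sigma_bio >= 0, sigma_tech >= 0, dropout_scale > 0,
            background_dap_rate >= 0, background_dap_rate <= 1)
  per_contig <- contig_sizes(n_genes, n_contigs)
  occupied <- lapply(seq_len(n_contigs), function(i) integer(0))
  for (pc in planted_clusters) {
    if (pc$contig < 1 || pc$contig > n_contigs)
      stop("planted cluster on nonexistent contig ", pc$contig)
    if (pc$start + pc$length > per_contig[pc$contig])
      stop("planted cluster exceeds contig ", pc$contig, " bounds")
    span <- pc$start:(pc$start + pc$length - 1L)
    if (length(intersect(span, occupied[[pc$contig]])))
      stop("planted clusters overlap on contig ", pc$contig)
    occupied[[pc$contig]] <- c(occupied[[pc$contig]], span)
  }
  structure(as.list(environment())[names(formals(sim_config))],
            class = "sim_config")
}

contig_sizes <- function(n_genes, n_contigs) {
  sz <- rep(n_genes %/% n_contigs, n_contigs)
  extra <- n_genes %% n_contigs
  if (extra) sz[seq_len(extra)] <- sz[seq_len(extra)] + 1L
  sz
}

#' Expected dropout (missingness) rate implied by a configuration
#'
#' Integrates the logistic dropout probability over the marginal log2
#' abundance distribution of a null protein's run value,
#' N(baseline_mean, sqrt(baseline_sd^2 + sigma_bio^2 + sigma_tech^2)).
#'
#' @param config a [sim_config()].
#' @return expected fraction of missing cells (ignoring planted effects
#'   and forced-unique proteins, which perturb it only marginally).
#' @export
expected_missing_rate <- function(config) {
  s <- sqrt(config$baseline_sd^2 + config$sigma_bio^2 + config$sigma_tech^2)
  f <- function(x) stats::plogis((config$dropout_midpoint - x) /
                                   config$dropout_scale) *
    stats::dnorm(x, config$baseline_mean, s)
  stats::integrate(f, -Inf, Inf)$value
}

#' Simulate a proteogenomic dataset with planted ground truth
#'
#' Generates a genome annotation (contigs tiled with 1 kb genes and 100
#' bp gaps), a replicated label-free quantification matrix, a qPCR CT
#' table for planted-cluster genes, and the ground truth needed for
#' recovery experiments. Abundance of protein i in run r is
#' `2^(baseline_i + lfc_i * [r is case] + bio_{i,sample(r)} + tech_{i,r})`
#' with logistic abundance-dependent dropout; a configured fraction of
#' each planted cluster's proteins is made case-unique by forcing
#' control-side dropout.
#'
#' @param config a [sim_config()].
#' @return list with elements `quant` ([quant_matrix()]), `genes`
#'   (ordered gene models), `design` (run design data.frame), `ct`
#'   (CT table), `truth` (list: `proteins` data.frame with `protein_id`,
#'   `gene_id`, `true_lfc`, `true_status`; `clusters` data.frame with
#'   global ordinal spans), and `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 80, planted_clusters = list(planted_cluster(start = 5)), seed = 42))
#' sim$quant
#' sim$truth$clusters
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_contigs <- config$n_contigs
  sizes <- contig_sizes(config$n_genes, n_contigs)
  contig_names <- sprintf("contig_%02d", seq_len(n_contigs))

  # genome: 1 kb genes, 100 bp gaps, tiled per contig
  genes <- do.call(rbind, lapply(seq_len(n_contigs), function(ci) {
    i <- seq_len(sizes[ci])
    data.frame(gene_id = NA_character_, contig = contig_names[ci],
               start = (i - 1L) * 1100L + 1L, end = (i - 1L) * 1100L + 1000L,
               strand = sample(c("+", "-"), sizes[ci], replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  genes$gene_id <- sprintf("LOC%04d", seq_len(nrow(genes)))
  genes$protein_id <- genes$gene_id
  genes <- order_genes(genes)
  offsets <- c(0L, cumsum(sizes))[seq_len(n_contigs)]

  # planted spans in global ordinals
  planted <- lapply(config$planted_clusters, function(pc) {
    first <- offsets[pc$contig] + pc$start
    list(spec = pc, first = first, last = first + pc$length - 1L,
         gene_ids = genes$gene_id[genes$ordinal %in% first:(first + pc$length - 1L)])
  })
  planted_ids <- unlist(lapply(planted, `[[`, "gene_ids"))

  # quantified proteins: all planted genes + sampled background genes
  n_quant <- max(round(config$frac_quantified * config$n_genes),
                 length(planted_ids))
  background_pool <- setdiff(genes$gene_id, planted_ids)
  n_bg <- min(n_quant - length(planted_ids), length(background_pool))
  quant_ids <- genes$gene_id[genes$gene_id %in%
                               c(planted_ids, sample(background_pool, n_bg))]
  n_prot <- length(quant_ids)

  # true effects
  true_lfc <- stats::setNames(numeric(n_prot), quant_ids)
  true_status <- stats::setNames(rep("unchanged", n_prot), quant_ids)
  unique_ids <- character(0)
  for (pl in planted) {
    fc <- exp(stats::runif(length(pl$gene_ids),
                           log(pl$spec$fc_range[1]), log(pl$spec$fc_range[2])))
    true_lfc[pl$gene_ids] <- log2(fc)
    true_status[pl$gene_ids] <- "up"
    n_uni <- round(pl$spec$frac_unique * length(pl$gene_ids))
    if (n_uni > 0) {
      ids <- sample(pl$gene_ids, n_uni)
      true_status[ids] <- "unique_case"
      unique_ids <- c(unique_ids, ids)
    }
  }
  bg_ids <- setdiff(quant_ids, planted_ids)
  hit <- bg_ids[stats::runif(length(bg_ids)) < config$background_dap_rate]
  if (length(hit)) {
    sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
    mag <- stats::runif(length(hit), config$background_lfc_range[1],
                        config$background_lfc_range[2])
    true_lfc[hit] <- sgn * mag
    true_status[hit] <- ifelse(sgn > 0, "up", "down")
  }

  # run design
  design <- expand.grid(tech_rep = seq_len(config$n_tech),
                        bio_rep = seq_len(config$n_bio),
                        condition = config$conditions,
                        stringsAsFactors = FALSE)
  design <- design[, c("condition", "bio_rep", "tech_rep")]
  design$run_id <- sprintf("%s_b%d_t%d", design$condition, design$bio_rep,
                           design$tech_rep)
  design <- design[, c("run_id", "condition", "bio_rep", "tech_rep")]

  case <- config$conditions[1]
  n_runs <- nrow(design)
  baseline <- stats::rnorm(n_prot, config$baseline_mean, config$baseline_sd)
  # biological effects: one per protein x (condition, bio_rep)
  bio_key <- paste(design$condition, design$bio_rep, sep = "//")
  bio_levels <- unique(bio_key)
  bio_eff <- matrix(stats::rnorm(n_prot * length(bio_levels), 0,
                                 config$sigma_bio),
                    n_prot, length(bio_levels),
                    dimnames = list(NULL, bio_levels))
  log2ab <- matrix(0, n_prot, n_runs,
                   dimnames = list(quant_ids, design$run_id))
  for (r in seq_len(n_runs)) {
    log2ab[, r] <- baseline +
      true_lfc * (design$condition[r] == case) +
      bio_eff[, bio_key[r]] +
      stats::rnorm(n_prot, 0, config$sigma_tech)
  }
  p_miss <- stats::plogis((config$dropout_midpoint - log2ab) /
                            config$dropout_scale)
  drop <- matrix(stats::runif(length(p_miss)) < p_miss, n_prot, n_runs)
  ab <- 2^log2ab
  ab[drop] <- NA
  # forced case-unique proteins: complete control-side dropout
  if (length(unique_ids))
    ab[unique_ids, design$condition != case] <- NA

  quant <- quant_matrix(ab, design)

  # CT table for the first planted cluster's first genes
  ct <- NULL
  if (length(planted) && config$n_ct_genes > 0) {
    ct_genes <- utils::head(planted[[1]]$gene_ids, config$n_ct_genes)
    samples <- expand.grid(bio_rep = seq_len(config$n_bio),
                           condition = config$conditions,
                           stringsAsFactors = FALSE)
    samples$sample <- sprintf("%s_b%d", samples$condition, samples$bio_rep)
    rows <- list()
    for (si in seq_len(nrow(samples))) {
      is_case <- samples$condition[si] == case
      for (gid in ct_genes) {
        expr <- baseline[match(gid, quant_ids)] +
          true_lfc[gid] * is_case + stats::rnorm(1, 0, config$sigma_bio)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples$sample[si], gene = gid,
          ct = config$ct_intercept - config$ct_slope * expr +
            stats::rnorm(config$n_ct_reps, 0, config$ct_noise_sd),
          stringsAsFactors = FALSE)
      }
      # reference gene: constant high expression in every sample
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples$sample[si], gene = "rrn16S",
        ct = config$ct_intercept - config$ct_slope * 26 +
          stats::rnorm(config$n_ct_reps, 0, config$ct_noise_sd),
        stringsAsFactors = FALSE)
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
  }

  truth <- list(
    proteins = data.frame(protein_id = quant_ids, gene_id = quant_ids,
                          true_lfc = unname(true_lfc),
                          true_status = unname(true_status),
                          stringsAsFactors = FALSE),
    clusters = do.call(rbind, lapply(seq_along(planted), function(i)
      data.frame(cluster = i,
                 contig = contig_names[planted[[i]]$spec$contig],
                 first_ordinal = planted[[i]]$first,
                 last_ordinal = planted[[i]]$last,
                 gene_ids = paste(planted[[i]]$gene_ids, collapse = ","),
                 stringsAsFactors = FALSE))))

  list(quant = quant, genes = genes, design = design, ct = ct,
       truth = truth, config = config)
}

#' Write a simulated dataset to a directory
#'
#' Writes `quant.tsv`, `design.yaml`, `genome.gff3`, `ct.tsv` and
#' `truth_proteins.tsv` / `truth_clusters.tsv` so the full pipeline can
#' be exercised through its file-based readers.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_quant_table(sim$quant, file.path(dir, "quant.tsv"))
  write_design(sim$design, file.path(dir, "design.yaml"))
  write_gff3(sim$genes, file.path(dir, "genome.gff3"))
  if (!is.null(sim$ct)) write_results(sim$ct, file.path(dir, "ct.tsv"))
  write_results(sim$truth$proteins, file.path(dir, "truth_proteins.tsv"))
  write_results(sim$truth$clusters, file.path(dir, "truth_clusters.tsv"))
  invisible(dir)
}
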