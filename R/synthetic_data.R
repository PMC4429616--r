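#' Configuration for the tumor/normal methylation-expression simulator
#'
#' Bundles every knob of [simulate_dataset()] and validates it. Defaults
#' emulate a 450K-style breast-cancer-like cohort: 8 normal vs 57 tumor
#' samples, several CpGs per gene with signed TSS distances, methylation-
#' expression correlation negative near the TSS and mildly positive beyond
#' ~5 kb, and 10% of genes planted as differentially correlated.
#'
#' @param n_genes Number of genes.
#' @param n_tumor,n_normal Samples per group (each >= 4).
#' @param platform_mode `"k450"` (several CpGs per gene) or `"k27"` (1-2
#'   CpGs per gene, intended for gene-averaged analysis).
#' @param cpgs_per_gene_range Integer pair; CpG count per gene is drawn
#'   uniformly from this range. Defaults depend on `platform_mode`.
#' @param dcg_fraction Fraction of genes planted as DCGs, in \[0, 1\].
#' @param rho_normal_fn,rho_tumor_fn Functions of absolute TSS distance (bp)
#'   returning the target methylation-expression correlation in (-1, 1) for
#'   each group. The default is -0.4 within 2 kb of the TSS, rising linearly
#'   to +0.15 at 5 kb and flat beyond.
#' @param dcg_delta Target correlation difference planted in DCGs.
#' @param dcg_split `"symmetric"` (default) moves the two groups apart by
#'   `+/- dcg_delta / 2` each around the baseline correlation; `"tumor"`
#'   shifts only the tumor correlation by `+/- dcg_delta` (infeasible when
#'   the baseline plus the full delta leaves (-1, 1)).
#' @param noise_sd Standard deviation of the latent expression signal (> 0).
#' @param tss_distance_range Integer pair of absolute TSS distances (bp)
#'   CpGs are placed in.
#' @param seed Integer seed; identical configs with identical seeds produce
#'   bit-identical datasets.
#' @return A validated list of class `"sim_config"`.
#' @export
simulation_config <- function(n_genes = 1000,
                              n_tumor = 57,
                              n_normal = 8,
                              platform_mode = c("k450", "k27"),
                              cpgs_per_gene_range = NULL,
                              dcg_fraction = 0.1,
                              rho_normal_fn = default_rho_fn,
                              rho_tumor_fn = default_rho_fn,
                              dcg_delta = 0.8,
                              dcg_split = c("symmetric", "tumor"),
                              noise_sd = 1,
                              tss_distance_range = c(0L, 200000L),
                              seed = 1L) {
  platform_mode <- match.arg(platform_mode)
  dcg_split <- match.arg(dcg_split)
  if (is.null(cpgs_per_gene_range)) {
    cpgs_per_gene_range <- if (platform_mode == "k450") c(3L, 12L) else c(1L, 2L)
  }
  cfg <- list(n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
              n_normal = as.integer(n_normal), platform_mode = platform_mode,
              cpgs_per_gene_range = as.integer(cpgs_per_gene_range),
              dcg_fraction = dcg_fraction, rho_normal_fn = rho_normal_fn,
              rho_tumor_fn = rho_tumor_fn, dcg_delta = dcg_delta,
              dcg_split = dcg_split, noise_sd = noise_sd,
              tss_distance_range = as.integer(tss_distance_range),
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1, cfg$n_tumor >= 4, cfg$n_normal >= 4,
            length(cfg$cpgs_per_gene_range) == 2,
            cfg$cpgs_per_gene_range[1] >= 1,
            cfg$cpgs_per_gene_range[1] <= cfg$cpgs_per_gene_range[2],
            cfg$dcg_fraction >= 0, cfg$dcg_fraction <= 1,
            cfg$dcg_delta >= 0, cfg$noise_sd > 0,
            length(cfg$tss_distance_range) == 2,
            cfg$tss_distance_range[1] >= 0,
            cfg$tss_distance_range[1] <= cfg$tss_distance_range[2],
            is.function(cfg$rho_normal_fn), is.function(cfg$rho_tumor_fn))
  class(cfg) <- "sim_config"
  cfg
}

#' Default correlation-vs-TSS-distance profile
#'
#' Negative (-0.4) within 2 kb of the TSS, linearly rising to +0.15 at 5 kb
#' and constant beyond: the qualitative promoter-repressive / distally
#' permissive shape seen on high-density methylation arrays.
#'
#' @param d Absolute TSS distance(s) in bp.
#' @return Target correlation(s) in (-1, 1).
#' @export
default_rho_fn <- function(d) {
  ifelse(d <= 2000, -0.4,
         ifelse(d >= 5000, 0.15, -0.4 + 0.55 * (d - 2000) / 3000))
}

#' Simulate a tumor/normal expression + methylation dataset
#'
#' Generates, per gene, a latent log-expression vector per group and, per
#' CpG, a methylation M value drawn as the bivariate-Gaussian partner of
#' expression with the configured target correlation `rho(group, distance)`.
#' Planted DCG genes have their correlations shifted by the configured
#' delta. M values are mapped to betas via `2^M / (2^M + 1)`, so betas are
#' strictly inside (0, 1) and round-trip through [beta_to_m()]. Correlation
#' is induced on the M scale; correlation measured on the beta scale is
#' attenuated by the logistic transform.
#'
#' @param config A [simulation_config()].
#' @return List with elements `expression` (genes x samples matrix),
#'   `methylation_beta` (CpGs x samples matrix of betas), `annotation`
#'   (cpg_id, chrom, pos, gene_id, tss_pos, strand, signed_tss_dist,
#'   abs_tss_dist), `groups` (sample_id, group) and `truth` (gene_id,
#'   is_dcg, rho_normal_true, rho_tumor_true, direction_true).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  nt <- config$n_tumor
  nn <- config$n_normal
  gene_ids <- sprintf("gene%05d", seq_len(ng))
  tumor_ids <- sprintf("tumor%03d", seq_len(nt))
  normal_ids <- sprintf("normal%03d", seq_len(nn))
  groups <- data.frame(sample_id = c(normal_ids, tumor_ids),
                       group = rep(c("normal", "tumor"), c(nn, nt)),
                       stringsAsFactors = FALSE)

  # CpG layout: count per gene, gene TSS positions spread along one
  # chromosome, absolute distances roughly exponential (median ~10 kb) so
  # promoters are well represented, clipped into the configured range.
  cpg_counts <- seq(config$cpgs_per_gene_range[1],
                    config$cpgs_per_gene_range[2])
  n_cpg_gene <- cpg_counts[sample.int(length(cpg_counts), ng, replace = TRUE)]
  n_cpgs <- sum(n_cpg_gene)
  cpg_gene <- rep(seq_len(ng), n_cpg_gene)
  # 250 genes per chromosome, 1 Mb apart: keeps positions in integer range
  gene_chrom <- paste0("chr", (seq_len(ng) - 1L) %/% 250L + 1L)
  tss_pos <- (((seq_len(ng) - 1L) %% 250L) + 1L) * 1000000L
  lo <- config$tss_distance_range[1]
  hi <- config$tss_distance_range[2]
  abs_d <- pmin(pmax(floor(stats::rexp(n_cpgs, rate = 1 / 15000)), lo), hi)
  sign_d <- sample(c(-1L, 1L), n_cpgs, replace = TRUE)
  signed_d <- as.integer(sign_d * abs_d)
  strand <- sample(c("+", "-"), ng, replace = TRUE)

  # planted differential correlation
  is_dcg <- stats::runif(ng) < config$dcg_fraction
  dcg_sign <- ifelse(stats::runif(ng) < 0.5, 1, -1) # +1: higher rho in tumor

  rho_n_cpg <- config$rho_normal_fn(abs_d)
  rho_t_cpg <- config$rho_tumor_fn(abs_d)
  shift <- (dcg_sign * is_dcg)[cpg_gene]
  if (config$dcg_split == "tumor") {
    rho_t_cpg <- rho_t_cpg + shift * config$dcg_delta
  } else {
    rho_n_cpg <- rho_n_cpg - shift * config$dcg_delta / 2
    rho_t_cpg <- rho_t_cpg + shift * config$dcg_delta / 2
  }
  if (any(abs(rho_n_cpg) >= 1) || any(abs(rho_t_cpg) >= 1)) {
    stop("infeasible correlation target: |rho| >= 1 after planting; ",
         "reduce dcg_delta or use dcg_split = \"symmetric\"")
  }

  # latent expression: per-gene baseline, unit-variance signal scaled by
  # noise_sd; methylation M = rho * z_expr + sqrt(1-rho^2) * noise, shifted
  # by a per-CpG baseline so betas span realistic levels
  mu_g <- stats::runif(ng, 6, 12)
  z_norm <- matrix(stats::rnorm(ng * nn), ng, nn)
  z_tum <- matrix(stats::rnorm(ng * nt), ng, nt)
  expr <- cbind(mu_g + config$noise_sd * z_norm,
                mu_g + config$noise_sd * z_tum)
  dimnames(expr) <- list(gene_ids, c(normal_ids, tumor_ids))

  mu_cpg <- stats::runif(n_cpgs, -3, 3)
  eps_n <- matrix(stats::rnorm(n_cpgs * nn), n_cpgs, nn)
  eps_t <- matrix(stats::rnorm(n_cpgs * nt), n_cpgs, nt)
  m_norm <- rho_n_cpg * z_norm[cpg_gene, , drop = FALSE] +
    sqrt(1 - rho_n_cpg^2) * eps_n
  m_tum <- rho_t_cpg * z_tum[cpg_gene, , drop = FALSE] +
    sqrt(1 - rho_t_cpg^2) * eps_t
  mvals <- cbind(m_norm, m_tum) + mu_cpg
  beta <- m_to_beta(mvals)
  cpg_ids <- sprintf("cg%07d", seq_len(n_cpgs))
  dimnames(beta) <- list(cpg_ids, c(normal_ids, tumor_ids))

  annotation <- data.frame(
    cpg_id = cpg_ids,
    chrom = gene_chrom[cpg_gene],
    pos = as.integer(tss_pos[cpg_gene] + signed_d),
    gene_id = gene_ids[cpg_gene],
    tss_pos = as.integer(tss_pos[cpg_gene]),
    strand = strand[cpg_gene],
    signed_tss_dist = signed_d,
    abs_tss_dist = as.integer(abs_d),
    stringsAsFactors = FALSE)

  rho_n_gene <- as.vector(tapply(rho_n_cpg, cpg_gene, mean))
  rho_t_gene <- as.vector(tapply(rho_t_cpg, cpg_gene, mean))
  truth <- data.frame(
    gene_id = gene_ids,
    is_dcg = is_dcg,
    rho_normal_true = rho_n_gene,
    rho_tumor_true = rho_t_gene,
    direction_true = ifelse(!is_dcg, "none",
                            ifelse(dcg_sign > 0, "pos_in_cancer",
                                   "neg_in_cancer")),
    stringsAsFactors = FALSE)

  list(expression = expr, methylation_beta = beta, annotation = annotation,
       groups = groups, truth = truth, config = config)
}

#' Write a simulated dataset to a directory of plain-text tables
#'
#' Emits expression and methylation TSV matrices, the CpG annotation,
#' sample-group and truth tables, matching the formats the read functions
#' in this package consume.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_tsv(dataset$expression, file.path(dir, "expression.tsv"),
                   id_col = "gene_id")
  write_matrix_tsv(dataset$methylation_beta, file.path(dir, "methylation.tsv"),
                   id_col = "cpg_id")
  write_table_tsv(dataset$annotation, file.path(dir, "annotation.tsv"))
  write_table_tsv(dataset$groups, file.path(dir, "groups.tsv"))
  write_table_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Simulate labeled gene segments and a matching "ChIP-seq" track
#'
#' Places `n_case + n_control` disjoint 1-kb gene segments along one
#' chromosome and builds a synthetic peak track that overlaps each case
#' segment with probability `track_hit_rate_case` and each control segment
#' with probability `track_hit_rate_control` (a 500-bp peak inside the
#' segment). Used to exercise the Monte-Carlo preferential-overlap test
#' with a known effect size.
#'
#' @param n_case,n_control Segment counts per label.
#' @param track_hit_rate_case,track_hit_rate_control Hit probabilities in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @return List with `segments` (chrom, start, end, label with values
#'   case/control; BED-style 0-based half-open) and `track` (chrom, start,
#'   end).
#' @export
simulate_segment_tracks <- function(n_case, n_control,
                                    track_hit_rate_case,
                                    track_hit_rate_control,
                                    seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1,
            track_hit_rate_case >= 0, track_hit_rate_case <= 1,
            track_hit_rate_control >= 0, track_hit_rate_control <= 1)
  set.seed(seed)
  n <- n_case + n_control
  label <- sample(rep(c("case", "control"), c(n_case, n_control)))
  start <- (seq_len(n) - 1L) * 10000L
  segments <- data.frame(chrom = "chr1", start = start, end = start + 1000L,
                         label = label, stringsAsFactors = FALSE)
  rate <- ifelse(label == "case", track_hit_rate_case, track_hit_rate_control)
  hit <- stats::runif(n) < rate
  track <- data.frame(chrom = "chr1",
                      start = start[hit] + 250L,
                      end = start[hit] + 750L,
                      stringsAsFactors = FALSE)
  list(segments = segments, track = track)
}
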