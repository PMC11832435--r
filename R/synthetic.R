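#' Configuration for the synthetic multi-omics cohort generator
#'
#' Describes a cohort of pup samples at the high-fat-diet timepoint with three
#' measurement layers (genus-level taxa, lipid species, genes). Ground truth
#' is planted in two ways: cross-layer monotone associations
#' (`planted_links`), realised through a Gaussian copula, and group-specific
#' fold changes on designated lipids or genes (`planted_de_lipids`,
#' `planted_de_genes`).
#'
#' @param n_samples_per_group samples per exposure group.
#' @param groups group labels; default the four exposure arms CC, AC, CA, AA.
#' @param n_taxa,n_lipids,n_genes feature counts per layer.
#' @param planted_links list of `list(taxon=, lipid=, gene=, rho=)` entries:
#'   1-based feature indices and the target rank (Spearman) correlation in
#'   (-1, 1) shared along the taxon-lipid-gene chain.
#' @param planted_de_lipids,planted_de_genes lists of
#'   `list(feature=, group=, fold=)`: the group's mean is multiplied by
#'   `fold` (> 0) on the linear scale.
#' @param noise_sd log-scale standard deviation of the log-normal marginals.
#' @param seed integer seed; the generator uses one local RNG per call and
#'   never touches the global RNG state.
#' @return a validated config list of class `multiomics_config`.
#' @export
multiomics_config <- function(n_samples_per_group = 5,
                              groups = c("CC", "AC", "CA", "AA"),
                              n_taxa = 10, n_lipids = 20, n_genes = 50,
                              planted_links = list(),
                              planted_de_lipids = list(),
                              planted_de_genes = list(),
                              noise_sd = 0.5,
                              seed = 1L) {
  cfg <- list(n_samples_per_group = as.integer(n_samples_per_group),
              groups = as.character(groups),
              n_taxa = as.integer(n_taxa), n_lipids = as.integer(n_lipids),
              n_genes = as.integer(n_genes),
              planted_links = planted_links,
              planted_de_lipids = planted_de_lipids,
              planted_de_genes = planted_de_genes,
              noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  for (fld in c("n_samples_per_group", "n_taxa", "n_lipids", "n_genes")) {
    if (is.na(cfg[[fld]]) || cfg[[fld]] < 1) {
      stop("invalid config: `", fld, "` must be a count >= 1", call. = FALSE)
    }
  }
  if (length(cfg$groups) < 1) stop("invalid config: `groups` empty", call. = FALSE)
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stop("invalid config: `noise_sd` must be positive", call. = FALSE)
  }
  for (lk in cfg$planted_links) {
    if (!all(c("taxon", "lipid", "gene", "rho") %in% names(lk))) {
      stop("invalid config: `planted_links` entries need taxon, lipid, gene, rho",
           call. = FALSE)
    }
    if (abs(lk$rho) >= 1) {
      stop("invalid config: `planted_links` rho must satisfy |rho| < 1", call. = FALSE)
    }
    if (lk$taxon < 1 || lk$taxon > cfg$n_taxa) {
      stop("invalid config: `planted_links` taxon index out of bounds", call. = FALSE)
    }
    if (lk$lipid < 1 || lk$lipid > cfg$n_lipids) {
      stop("invalid config: `planted_links` lipid index out of bounds", call. = FALSE)
    }
    if (lk$gene < 1 || lk$gene > cfg$n_genes) {
      stop("invalid config: `planted_links` gene index out of bounds", call. = FALSE)
    }
  }
  check_de_list <- function(lst, n, fld) {
    for (de in lst) {
      if (!all(c("feature", "group", "fold") %in% names(de))) {
        stop("invalid config: `", fld, "` entries need feature, group, fold",
             call. = FALSE)
      }
      if (de$fold <= 0) stop("invalid config: `", fld, "` fold must be > 0",
                             call. = FALSE)
      if (de$feature < 1 || de$feature > n) {
        stop("invalid config: `", fld, "` feature index out of bounds", call. = FALSE)
      }
      if (!(de$group %in% cfg$groups)) {
        stop("invalid config: `", fld, "` group '", de$group, "' not in groups",
             call. = FALSE)
      }
    }
  }
  check_de_list(cfg$planted_de_lipids, cfg$n_lipids, "planted_de_lipids")
  check_de_list(cfg$planted_de_genes, cfg$n_genes, "planted_de_genes")
  class(cfg) <- "multiomics_config"
  cfg
}

#' Configuration for the synthetic dam-pup dyad generator
#'
#' Each dyad has one dam profile drawn from a Dirichlet distribution and one
#' pup profile obtained from the dam by group-specific taxon dropout,
#' multiplicative jitter on surviving taxa, and renormalisation. Dropout that
#' rises with antibiotic exposure emulates the loss of maternally transmitted
#' genera in exposed litters.
#'
#' @param n_dyads_per_group dyads per group.
#' @param n_taxa number of genera.
#' @param dropout_by_group named vector/list of per-group taxon dropout
#'   probabilities in \[0, 1\].
#' @param abundance_concentration Dirichlet concentration parameter for the
#'   dam profile (smaller = more uneven communities).
#' @param jitter_sd log-scale sd of the multiplicative noise applied to
#'   surviving pup taxa.
#' @param seed integer seed (local RNG per call).
#' @return a validated config list of class `dyad_config`.
#' @export
dyad_config <- function(n_dyads_per_group = 6, n_taxa = 40,
                        dropout_by_group = c(CC = 0.05, AC = 0.1,
                                             CA = 0.4, AA = 0.5),
                        abundance_concentration = 0.5,
                        jitter_sd = 0.2,
                        seed = 1L) {
  cfg <- list(n_dyads_per_group = as.integer(n_dyads_per_group),
              n_taxa = as.integer(n_taxa),
              dropout_by_group = unlist(dropout_by_group),
              abundance_concentration = as.numeric(abundance_concentration),
              jitter_sd = as.numeric(jitter_sd),
              seed = as.integer(seed))
  if (cfg$n_dyads_per_group < 1 || cfg$n_taxa < 1) {
    stop("invalid config: counts must be >= 1", call. = FALSE)
  }
  if (is.null(names(cfg$dropout_by_group)) || any(!nzchar(names(cfg$dropout_by_group)))) {
    stop("invalid config: `dropout_by_group` must be named by group", call. = FALSE)
  }
  check_levels(names(cfg$dropout_by_group), GROUP_LEVELS, "group")
  if (any(cfg$dropout_by_group < 0 | cfg$dropout_by_group > 1)) {
    stop("invalid config: `dropout_by_group` probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$abundance_concentration <= 0) {
    stop("invalid config: `abundance_concentration` must be positive", call. = FALSE)
  }
  if (cfg$jitter_sd < 0) stop("invalid config: `jitter_sd` must be >= 0", call. = FALSE)
  class(cfg) <- "dyad_config"
  cfg
}

# Gaussian-copula parameter giving a target Spearman rho for bivariate
# normal margins: r = 2 sin(pi * rho_s / 6).
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Project a symmetric matrix to the nearest positive-definite correlation
# matrix by eigenvalue clipping, then restore the unit diagonal. Arbitrary
# planted blocks may be mutually inconsistent; clipping makes them samplable.
nearest_pd_corr <- function(R, eps = 1e-8) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < eps) {
    vals <- pmax(e$values, eps)
    R <- e$vectors %*% (vals * t(e$vectors))
    R <- stats::cov2cor(R)
  }
  R
}

# Draw n rows from MVN(0, R) given the correlation matrix R.
rmvnorm_chol <- function(n, R) {
  L <- chol(R)
  Z <- matrix(stats::rnorm(n * ncol(R)), nrow = n)
  Z %*% L
}

#' Generate a synthetic multi-omics cohort with planted truth
#'
#' Samples a latent Gaussian copula whose correlation matrix carries the
#' planted taxon-lipid-gene blocks (converted so that the *Spearman*
#' correlation of the output matches the planted value), transforms each
#' feature through a log-normal marginal with a feature-specific location
#' drawn once per cohort, then applies the planted group fold multipliers on
#' the linear scale. All samples are pups at the HFD timepoint.
#'
#' @param config a [multiomics_config()].
#' @return list with elements `taxa`, `lipids`, `genes` (each a
#'   [feature_table()] sharing sample IDs), `metadata`
#'   ([sample_metadata()]), and `truth` (the planted links, DE features and
#'   generator settings).
#' @export
generate_multiomics_cohort <- function(config) {
  if (!inherits(config, "multiomics_config")) config <- do.call(multiomics_config, config)
  withr::with_seed(config$seed, {
    n_groups <- length(config$groups)
    n <- config$n_samples_per_group * n_groups
    p <- config$n_taxa + config$n_lipids + config$n_genes
    taxa_ids <- sprintf("Genus_%02d", seq_len(config$n_taxa))
    lipid_ids <- sprintf("Lipid_%02d", seq_len(config$n_lipids))
    gene_ids <- sprintf("Gene_%03d", seq_len(config$n_genes))
    off_l <- config$n_taxa
    off_g <- config$n_taxa + config$n_lipids

    R <- diag(p)
    for (lk in config$planted_links) {
      r <- spearman_to_pearson(lk$rho)
      it <- lk$taxon; il <- off_l + lk$lipid; ig <- off_g + lk$gene
      R[it, il] <- R[il, it] <- r
      R[il, ig] <- R[ig, il] <- r
      R[it, ig] <- R[ig, it] <- r * r  # consistent chain correlation
    }
    R <- nearest_pd_corr(R)

    Z <- rmvnorm_chol(n, R)
    meanlog <- stats::rnorm(p, mean = 3, sd = 1)   # feature-specific location
    X <- exp(sweep(Z * config$noise_sd, 2, meanlog, "+"))

    group <- rep(config$groups, each = config$n_samples_per_group)
    sample_ids <- sprintf("P%s_%02d", group,
                          sequence(rep(config$n_samples_per_group, n_groups)))
    rownames(X) <- sample_ids
    for (de in config$planted_de_lipids) {
      j <- off_l + de$feature
      X[group == de$group, j] <- X[group == de$group, j] * de$fold
    }
    for (de in config$planted_de_genes) {
      j <- off_g + de$feature
      X[group == de$group, j] <- X[group == de$group, j] * de$fold
    }

    taxa <- feature_table(X[, seq_len(config$n_taxa), drop = FALSE] |>
                            `colnames<-`(taxa_ids), "taxon")
    lipids <- feature_table(X[, off_l + seq_len(config$n_lipids), drop = FALSE] |>
                              `colnames<-`(lipid_ids), "lipid")
    genes <- feature_table(X[, off_g + seq_len(config$n_genes), drop = FALSE] |>
                             `colnames<-`(gene_ids), "gene")
    metadata <- sample_metadata(tibble::tibble(
      sample_id = sample_ids, group = group, timepoint = "HFD",
      generation = "pup", dyad_id = NA_character_))
    truth <- list(
      links = lapply(config$planted_links, function(lk) {
        list(taxon = taxa_ids[lk$taxon], lipid = lipid_ids[lk$lipid],
             gene = gene_ids[lk$gene], rho = lk$rho)
      }),
      de_lipids = lapply(config$planted_de_lipids, function(de) {
        list(feature = lipid_ids[de$feature], group = de$group, fold = de$fold)
      }),
      de_genes = lapply(config$planted_de_genes, function(de) {
        list(feature = gene_ids[de$feature], group = de$group, fold = de$fold)
      }),
      config = unclass(config))
    list(taxa = taxa, lipids = lipids, genes = genes,
         metadata = metadata, truth = truth)
  })
}

#' Generate a synthetic dam-pup dyad cohort
#'
#' Dam relative-abundance profiles are Dirichlet draws; each pup profile is
#' its dam's profile with every taxon independently zeroed at the group's
#' dropout probability, surviving abundances jittered multiplicatively
#' (log-normal), and the profile renormalised to sum 1 (an all-zero pup, which
#' can only arise at dropout 1, is left as zeros).
#'
#' @param config a [dyad_config()].
#' @return list with elements `table` (a taxon [feature_table()], dams and
#'   pups as rows), `metadata`, and `truth` (per-dyad retained taxon sets).
#' @export
generate_dyad_cohort <- function(config) {
  if (!inherits(config, "dyad_config")) config <- do.call(dyad_config, config)
  withr::with_seed(config$seed, {
    groups <- names(config$dropout_by_group)
    taxa_ids <- sprintf("Genus_%02d", seq_len(config$n_taxa))
    rows <- list(); meta <- list(); retained <- list()
    for (g in groups) {
      for (d in seq_len(config$n_dyads_per_group)) {
        dyad_id <- sprintf("%s_D%02d", g, d)
        dam <- stats::rgamma(config$n_taxa, shape = config$abundance_concentration)
        dam <- dam / sum(dam)
        keep <- stats::runif(config$n_taxa) >= config$dropout_by_group[[g]]
        pup <- dam * keep
        if (config$jitter_sd > 0) {
          pup <- pup * exp(stats::rnorm(config$n_taxa, 0, config$jitter_sd))
          pup[!keep] <- 0
        }
        if (sum(pup) > 0) pup <- pup / sum(pup)
        dam_id <- paste0(dyad_id, "_dam"); pup_id <- paste0(dyad_id, "_pup")
        rows[[dam_id]] <- dam; rows[[pup_id]] <- pup
        meta[[dam_id]] <- list(sample_id = dam_id, group = g, timepoint = "BF",
                               generation = "dam", dyad_id = dyad_id)
        meta[[pup_id]] <- list(sample_id = pup_id, group = g, timepoint = "BF",
                               generation = "pup", dyad_id = dyad_id)
        retained[[dyad_id]] <- taxa_ids[keep & dam > 0]
      }
    }
    mat <- do.call(rbind, rows)
    colnames(mat) <- taxa_ids
    table <- feature_table(mat, "taxon")
    metadata <- sample_metadata(tibble::as_tibble(
      do.call(rbind, lapply(meta, as.data.frame))))
    list(table = table, metadata = metadata,
         truth = list(retained = retained, config = unclass(config)))
  })
}

#' Read a generator config from YAML or JSON
#'
#' The file must contain a top-level `type` field, `"multiomics"` or `"dyad"`,
#' plus the fields of the corresponding config constructor.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `multiomics_config` or `dyad_config`.
#' @export
read_generator_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  type <- lst$type
  if (is.null(type)) stop("config file needs a `type` field (multiomics|dyad)",
                          call. = FALSE)
  lst$type <- NULL
  switch(type,
         multiomics = do.call(multiomics_config, lst),
         dyad = do.call(dyad_config, lst),
         stop("unknown config type '", type, "'", call. = FALSE))
}

#' Write a cohort's planted-truth manifest as JSON
#' @param truth the `truth` element of a generated cohort.
#' @param path output path.
#' @export
write_truth_manifest <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
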