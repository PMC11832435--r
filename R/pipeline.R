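#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: either file paths to taxa /
#' lipid / gene tables plus metadata, or a [multiomics_config()] to simulate
#' them; optionally a [dyad_config()] for the transfer-fidelity stage; the
#' decision thresholds, pinned by default to the published values (abundance
#' ratio outside \[0.66, 1.2\], VIP > 1, taxon-lipid rho > 0.3, lipid-gene
#' |rho| > 0.4, LDA score > 2, alpha 0.05); and the master seed from which
#' every stochastic stage derives its own sub-seed.
#'
#' @param multiomics a [multiomics_config()], or `NULL` when reading files.
#' @param dyad optional [dyad_config()] for the transfer stage.
#' @param taxa_path,lipids_path,genes_path,metadata_path input TSVs (used
#'   when `multiomics` is `NULL`).
#' @param gene_edges optional literature gene-gene edge tibble.
#' @param pathway_map optional named list gene -> pathways.
#' @param pathway_set pathways retained by the gene screen; `NULL` skips the
#'   screen.
#' @param contrasts exposed groups contrasted against `reference_group`.
#' @param reference_group reference arm (default CC).
#' @param thresholds named list: `ratio_low`, `ratio_high`, `vip`,
#'   `rho_taxon_lipid`, `rho_lipid_gene`, `lda`, `alpha`,
#'   `presence` (dam-pup presence threshold).
#' @param lipid_names optional character vector renaming lipid features to
#'   shorthand species names (enables cognate matching on synthetic data).
#' @param fa_table optional fatty-acid metabolite [feature_table()]
#'   (serum metabolomics layer) screened for co-elevation.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(multiomics = NULL, dyad = NULL,
                            taxa_path = NULL, lipids_path = NULL,
                            genes_path = NULL, metadata_path = NULL,
                            gene_edges = NULL, pathway_map = NULL,
                            pathway_set = NULL,
                            contrasts = c("AC", "CA", "AA"),
                            reference_group = "CC",
                            thresholds = list(),
                            lipid_names = NULL, fa_table = NULL,
                            seed = 1L) {
  def <- list(ratio_low = 0.66, ratio_high = 1.2, vip = 1,
              rho_taxon_lipid = 0.3, rho_lipid_gene = 0.4,
              lda = 2, alpha = 0.05, presence = 1e-4)
  thresholds <- utils::modifyList(def, thresholds)
  if (any(unlist(thresholds) <= 0)) {
    stop("thresholds must be positive", call. = FALSE)
  }
  if (is.null(multiomics) &&
      (is.null(taxa_path) || is.null(lipids_path) || is.null(genes_path) ||
       is.null(metadata_path))) {
    stop("either `multiomics` or all four input paths must be given", call. = FALSE)
  }
  structure(list(multiomics = multiomics, dyad = dyad,
                 taxa_path = taxa_path, lipids_path = lipids_path,
                 genes_path = genes_path, metadata_path = metadata_path,
                 gene_edges = gene_edges, pathway_map = pathway_map,
                 pathway_set = pathway_set,
                 contrasts = contrasts, reference_group = reference_group,
                 thresholds = thresholds, lipid_names = lipid_names,
                 fa_table = fa_table, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Stable stage sub-seed: hashing (master seed, stage name) means inserting a
# stage never reshuffles the randomness of the others.
stage_seed <- function(seed, stage) {
  h <- rlang::hash(paste(seed, stage, sep = "/"))
  as.integer(strtoi(substr(h, 1, 7), 16L) %% 2147483647L)
}

#' Run the end-to-end analysis pipeline
#'
#' Stage order: simulate or ingest the cohort; relative abundance and
#' diversity (alpha, Bray-Curtis, PCoA, PERMANOVA on group labels);
#' optionally the dam-pup transfer-fidelity stage on a dyad cohort; the
#' LEfSe-style taxon screen; per-contrast lipid screening (ratio + VIP);
#' cognate LPC/fatty-acid matching and co-elevation filtering (when lipid
#' features carry shorthand species names); per-contrast network assembly
#' and summaries. Every artifact is written under `out_dir` along with a run
#' manifest (config hash, seed, stage shapes) that reproduces the run.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print one line per stage.
#' @return list of class `pipeline_result`: `artifacts` (named file paths),
#'   `summaries` (per-contrast network summary tibble), `de` (per-contrast
#'   DE screens), `networks`, `lefse`, `transfer`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("pupomics_run_"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- list()
  log_stage <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
  }

  # --- ingest / simulate -----------------------------------------------
  if (!is.null(config$multiomics)) {
    mo <- config$multiomics
    mo$seed <- stage_seed(config$seed, "simulate")
    cohort <- generate_multiomics_cohort(do.call(
      multiomics_config, mo[setdiff(names(mo), NULL)]))
    taxa <- cohort$taxa; lipids <- cohort$lipids; genes <- cohort$genes
    metadata <- cohort$metadata
    art$truth <- file.path(out_dir, "truth.json")
    write_truth_manifest(cohort$truth, art$truth)
  } else {
    taxa <- read_feature_table(config$taxa_path, "taxon")
    lipids <- read_feature_table(config$lipids_path, "lipid")
    genes <- read_feature_table(config$genes_path, "gene")
    metadata <- read_metadata(config$metadata_path)
    cohort <- NULL
  }
  if (!is.null(config$lipid_names)) {
    colnames(lipids) <- config$lipid_names
  }
  log_stage("ingest", nrow(taxa), " samples; ", ncol(taxa), " taxa, ",
            ncol(lipids), " lipids, ", ncol(genes), " genes")

  md <- align_metadata(taxa, metadata)
  th <- config$thresholds

  # --- diversity --------------------------------------------------------
  rel_taxa <- relative_abundance(taxa)
  bc <- bray_curtis_matrix(taxa)
  ord <- pcoa(bc, n_axes = 2)
  perm <- permanova(bc, md$group, n_perm = 999,
                    seed = stage_seed(config$seed, "permanova"))
  art$distance <- file.path(out_dir, "bray_curtis.tsv")
  write_distance_matrix(bc, art$distance)
  log_stage("diversity", "PERMANOVA F = ", signif(perm$statistic, 4),
            ", p = ", signif(perm$p_value, 4))

  # --- transfer fidelity (optional dyad cohort) ------------------------
  transfer <- NULL
  if (!is.null(config$dyad)) {
    dy <- config$dyad
    dy$seed <- stage_seed(config$seed, "dyads")
    dyad_cohort <- generate_dyad_cohort(do.call(dyad_config, dy))
    transfer <- transfer_report(dyad_cohort$table, dyad_cohort$metadata,
                                presence_threshold = th$presence,
                                reference_group = config$reference_group)
    art$transfer_json <- file.path(out_dir, "transfer_report.json")
    art$transfer_tsv <- file.path(out_dir, "transfer_events.tsv")
    write_transfer_report(transfer, art$transfer_json, art$transfer_tsv)
    log_stage("transfer", nrow(transfer$dyads), " dyads")
  }

  # --- LEfSe-style taxon screen ----------------------------------------
  lefse <- lefse_screen(rel_taxa, md$group, alpha = th$alpha,
                        lda_threshold = th$lda,
                        seed = stage_seed(config$seed, "lefse"))
  art$lefse <- file.path(out_dir, "lefse.tsv")
  write_lefse_result(lefse, art$lefse)
  log_stage("lefse", nrow(lefse), " discriminating taxa")

  # --- per-contrast lipid screen, cognates, network --------------------
  parsed_lipids <- tryCatch(parse_lipid_name(colnames(lipids)),
                            error = function(e) NULL)
  fa_species <- if (!is.null(config$fa_table))
    tryCatch(parse_lipid_name(colnames(config$fa_table)),
             error = function(e) NULL) else NULL
  gene_ids <- if (!is.null(config$pathway_map) && !is.null(config$pathway_set)) {
    pathway_screen(genes, config$pathway_map, config$pathway_set)
  } else colnames(genes)
  genes_used <- feature_table(ft_matrix(genes)[, gene_ids, drop = FALSE], "gene")

  de_list <- list(); networks <- list(); summaries <- list()
  for (ct in config$contrasts) {
    de <- screen_de_lipids(lipids, metadata, ct, config$reference_group,
                           ratio_low = th$ratio_low, ratio_high = th$ratio_high,
                           vip_threshold = th$vip)
    if (!is.null(parsed_lipids)) de$feature <- parsed_lipids$canonical
    de_list[[ct]] <- de
    art[[paste0("de_", ct)]] <- file.path(out_dir, paste0("de_lipids_", ct, ".tsv"))
    write_de_screen(de, art[[paste0("de_", ct)]])

    # correlation layers over the contrast + reference samples at HFD
    sel <- metadata$sample_id[metadata$timepoint == "HFD" &
                              metadata$group %in% c(ct, config$reference_group)]
    sub <- function(tb) feature_table(ft_matrix(tb)[intersect(rownames(tb), sel),
                                                    , drop = FALSE],
                                      table_kind(tb))
    lip_sub <- sub(lipids)
    if (!is.null(parsed_lipids)) colnames(lip_sub) <- parsed_lipids$canonical
    tl <- threshold_edges(spearman_matrix(sub(taxa), lip_sub), "taxon-lipid")
    lg <- threshold_edges(spearman_matrix(lip_sub, sub(genes_used)), "lipid-gene")

    cognates <- NULL; coelev <- NULL
    if (!is.null(parsed_lipids) && !is.null(fa_species)) {
      cognates <- match_cognates(parsed_lipids, fa_species)
      if (nrow(cognates) > 0) {
        fa_de <- screen_de_lipids(config$fa_table, metadata, ct,
                                  config$reference_group,
                                  ratio_low = th$ratio_low,
                                  ratio_high = th$ratio_high,
                                  vip_threshold = th$vip)
        fa_de$feature <- fa_species$canonical
        coelev <- co_elevation_filter(cognates, rbind(de, fa_de))
      }
    }
    fc <- c(fold_change_map(lip_sub, metadata, ct, config$reference_group),
            fold_change_map(genes_used, metadata, ct, config$reference_group))
    net <- assemble_network(tl, lg, gene_edges = config$gene_edges,
                            cognate_pairs = cognates,
                            coelevated_pairs = coelev,
                            fold_changes = fc,
                            pathway_map = config$pathway_map, group = ct)
    networks[[ct]] <- net
    art[[paste0("network_", ct)]] <- file.path(out_dir,
                                               paste0("network_", ct, ".graphml"))
    write_network(net, art[[paste0("network_", ct)]], "graphml")
    summaries[[ct]] <- network_summary(net)
    log_stage("network", ct, ": ", nrow(net$nodes), " nodes, ",
              nrow(net$edges), " edges")
  }
  summaries <- do.call(rbind, summaries)
  art$summaries <- file.path(out_dir, "network_summaries.tsv")
  utils::write.table(as.data.frame(summaries), art$summaries, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("pupomics")),
    stages = list(
      samples = nrow(taxa), taxa = ncol(taxa), lipids = ncol(lipids),
      genes = ncol(genes_used),
      permanova_f = perm$statistic, permanova_p = perm$p_value,
      n_lefse = nrow(lefse),
      n_de = vapply(de_list, function(d) sum(d$flagged), numeric(1))))
  art$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, art$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  structure(list(artifacts = art, summaries = summaries, de = de_list,
                 networks = networks, lefse = lefse, transfer = transfer,
                 permanova = perm, ordination = ord, manifest = manifest,
                 out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summaries)
  invisible(x)
}
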