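#' Spearman correlation matrix between two feature tables
#'
#' Rank correlation (average ranks for ties; Pearson on ranks) between every
#' feature of `table_a` and every feature of `table_b`, computed over their
#' shared samples. Constant features are excluded with a warning. p-values
#' use the t approximation `t = rho sqrt((n-2)/(1-rho^2))`; they are reported
#' for transparency but never used for edge selection (the network thresholds
#' act on rho alone).
#'
#' @param table_a,table_b [feature_table()]s.
#' @return list of class `spearman_matrix`: `rho` (features_a x features_b),
#'   `p_value`, `n` (shared samples), `kind_a`, `kind_b`.
#' @export
spearman_matrix <- function(table_a, table_b) {
  shared <- intersect(rownames(table_a), rownames(table_b))
  if (length(shared) < 4) {
    stop("need >= 4 shared samples; got ", length(shared), call. = FALSE)
  }
  A <- ft_matrix(table_a)[shared, , drop = FALSE]
  B <- ft_matrix(table_b)[shared, , drop = FALSE]
  drop_constant <- function(m, label) {
    cst <- apply(m, 2, function(v) stats::var(v) == 0)
    if (any(cst)) {
      warning("excluding ", sum(cst), " constant ", label, " feature(s): ",
              paste(utils::head(colnames(m)[cst], 5), collapse = ", "),
              call. = FALSE)
    }
    m[, !cst, drop = FALSE]
  }
  A <- drop_constant(A, table_kind(table_a))
  B <- drop_constant(B, table_kind(table_b))
  n <- length(shared)
  rho <- stats::cor(apply(A, 2, rank), apply(B, 2, rank), method = "pearson")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  structure(list(rho = rho, p_value = p, n = n,
                 kind_a = table_kind(table_a), kind_b = table_kind(table_b)),
            class = "spearman_matrix")
}

LAYER_RULES <- list(
  "taxon-lipid" = list(threshold = 0.3, positive_only = TRUE),
  "lipid-gene"  = list(threshold = 0.4, positive_only = FALSE))

#' Threshold a correlation matrix into network edges
#'
#' Applies the layer's selection rule with strict inequalities: taxon-lipid
#' edges keep only positive correlations with rho > 0.3; lipid-gene edges
#' keep |rho| > 0.4 of either sign.
#'
#' @param sm a [spearman_matrix()] (or a bare rho matrix).
#' @param layer `"taxon-lipid"` or `"lipid-gene"`.
#' @return tibble of edges: `source`, `target`, `source_type`, `target_type`,
#'   `rho`, `layer`, `n`.
#' @export
threshold_edges <- function(sm, layer) {
  if (!(layer %in% names(LAYER_RULES))) {
    stop("unknown layer '", layer, "'; expected one of: ",
         paste(names(LAYER_RULES), collapse = ", "), call. = FALSE)
  }
  rule <- LAYER_RULES[[layer]]
  types <- strsplit(layer, "-", fixed = TRUE)[[1]]
  if (inherits(sm, "spearman_matrix")) {
    rho <- sm$rho; n <- sm$n
  } else {
    rho <- as.matrix(sm); n <- NA_integer_
  }
  pass <- if (rule$positive_only) rho > rule$threshold else abs(rho) > rule$threshold
  idx <- which(pass, arr.ind = TRUE)
  out <- tibble::tibble(
    source = rownames(rho)[idx[, 1]], target = colnames(rho)[idx[, 2]],
    source_type = types[1], target_type = types[2],
    rho = rho[idx], layer = layer, n = n)
  out[order(out$source, out$target), , drop = FALSE]
}

#' Screen genes by pathway annotation
#'
#' Keeps genes annotated to at least one pathway of interest — by default the
#' processes tied to MASLD pathogenesis (ER stress, apoptosis, inflammatory
#' response, PI3K-AKT, TNF-MAPK, PPAR signalling) — before they enter the
#' correlation network.
#'
#' @param genes character vector of gene IDs (or a gene [feature_table()],
#'   whose feature IDs are used).
#' @param pathway_map named list gene -> character vector of pathway labels
#'   (see [read_pathway_map()]).
#' @param pathway_set pathways of interest; must be non-empty.
#' @return character vector of retained gene IDs.
#' @export
pathway_screen <- function(genes, pathway_map,
                           pathway_set = c("ER stress", "apoptosis",
                                           "inflammatory response", "PI3K-AKT",
                                           "TNF-MAPK", "PPAR signaling")) {
  if (length(pathway_set) == 0) stop("pathway_set must be non-empty", call. = FALSE)
  if (inherits(genes, "feature_table")) genes <- colnames(genes)
  keep <- vapply(genes, function(g) {
    anns <- pathway_map[[g]]
    !is.null(anns) && any(anns %in% pathway_set)
  }, logical(1))
  genes[keep]
}

#' Per-feature fold change of a group against a reference
#'
#' Linear mean ratio at a timepoint, with the same zero-mean pseudocount
#' policy as [abundance_ratio()]; this is the fold-change annotation carried
#' by network nodes.
#'
#' @inheritParams abundance_ratio
#' @param group contrast group.
#' @return named numeric vector of fold changes.
#' @export
fold_change_map <- function(table, metadata, group, reference_group = "CC",
                            timepoint = "HFD") {
  abundance_ratio(table, metadata, group, reference_group, timepoint)
}

#' Assemble an integrated taxa-lipid-gene network
#'
#' Builds the typed multi-layer network for one exposure contrast: nodes are
#' instantiated from the endpoints of the thresholded taxon-lipid and
#' lipid-gene correlation edges; fatty-acid nodes are attached to their LPCs
#' through cognate pairs; literature gene-gene edges are added only between
#' genes already present (dangling endpoints are skipped with a warning,
#' since curated interaction lists routinely exceed the expression table);
#' fold-change and pathway annotations are attached; node degrees computed.
#'
#' When `coelevated_pairs` is supplied, a pruning pass applies the
#' "hidden unless co-expressed" rule: LPC nodes whose cognate fatty acid is
#' not co-elevated are removed together with their incident edges, and nodes
#' left isolated are dropped.
#'
#' @param taxon_lipid_edges,lipid_gene_edges edge tibbles from
#'   [threshold_edges()].
#' @param gene_edges literature gene-gene edge tibble
#'   (see [gene_edge_list()]); optional.
#' @param cognate_pairs tibble from [match_cognates()]; optional. LPC node
#'   IDs must appear in the lipid layer for attachment.
#' @param coelevated_pairs tibble from [co_elevation_filter()]; enables the
#'   pruning pass. `NULL` disables pruning.
#' @param fold_changes named numeric vector of fold changes vs the reference
#'   (any subset of nodes); optional.
#' @param pathway_map named list gene -> pathways; optional.
#' @param group group label recorded on the network.
#' @return list of class `integrated_network`: `nodes` (tibble: `id`, `type`,
#'   `fold_change`, `pathways`, `degree`), `edges` (tibble: `source`,
#'   `target`, `layer`, `rho`), `group`.
#' @export
assemble_network <- function(taxon_lipid_edges, lipid_gene_edges,
                             gene_edges = NULL, cognate_pairs = NULL,
                             coelevated_pairs = NULL, fold_changes = NULL,
                             pathway_map = NULL, group = NA_character_) {
  edges <- tibble::tibble(
    source = character(0), target = character(0), source_type = character(0),
    target_type = character(0), rho = numeric(0), layer = character(0))
  add <- function(edges, new) if (nrow(new) > 0) rbind(edges, new) else edges
  if (!is.null(taxon_lipid_edges) && nrow(taxon_lipid_edges) > 0) {
    stopifnot(all(taxon_lipid_edges$layer == "taxon-lipid"))
    check_layer_invariant(taxon_lipid_edges)
    edges <- add(edges, taxon_lipid_edges[names(edges)])
  }
  if (!is.null(lipid_gene_edges) && nrow(lipid_gene_edges) > 0) {
    stopifnot(all(lipid_gene_edges$layer == "lipid-gene"))
    check_layer_invariant(lipid_gene_edges)
    edges <- add(edges, lipid_gene_edges[names(edges)])
  }
  # cognate fatty acids hang off their LPC nodes
  if (!is.null(cognate_pairs) && nrow(cognate_pairs) > 0) {
    present <- cognate_pairs$lpc %in% c(edges$source, edges$target)
    cp <- cognate_pairs[present, , drop = FALSE]
    if (nrow(cp) > 0) {
      edges <- add(edges, tibble::tibble(
        source = cp$lpc, target = cp$fa, source_type = "lipid",
        target_type = "fatty_acid", rho = NA_real_, layer = "cognate"))
    }
  }
  # literature gene-gene edges only between genes already in the network
  if (!is.null(gene_edges) && nrow(gene_edges) > 0) {
    gene_edges <- gene_edge_list(gene_edges)
    genes_here <- unique(c(edges$target[edges$target_type == "gene"],
                           edges$source[edges$source_type == "gene"]))
    ok <- gene_edges$gene_a %in% genes_here & gene_edges$gene_b %in% genes_here
    if (any(!ok)) {
      warning("skipping ", sum(!ok),
              " literature gene-gene edge(s) with endpoints outside the network",
              call. = FALSE)
    }
    ge <- gene_edges[ok, , drop = FALSE]
    if (nrow(ge) > 0) {
      edges <- add(edges, tibble::tibble(
        source = ge$gene_a, target = ge$gene_b, source_type = "gene",
        target_type = "gene", rho = NA_real_, layer = "gene-gene"))
    }
  }
  net <- build_network_object(edges, fold_changes, pathway_map, group)
  if (!is.null(coelevated_pairs)) {
    net <- prune_non_coelevated(net, coelevated_pairs)
  }
  net
}

check_layer_invariant <- function(edges) {
  for (i in seq_len(nrow(edges))) {
    rule <- LAYER_RULES[[edges$layer[i]]]
    ok <- if (rule$positive_only) edges$rho[i] > rule$threshold
          else abs(edges$rho[i]) > rule$threshold
    if (!ok) {
      stop("edge ", edges$source[i], " -> ", edges$target[i],
           " violates the ", edges$layer[i], " threshold", call. = FALSE)
    }
  }
  invisible(edges)
}

build_network_object <- function(edges, fold_changes, pathway_map, group) {
  node_ids <- unique(c(edges$source, edges$target))
  node_type <- character(length(node_ids))
  names(node_type) <- node_ids
  node_type[edges$source] <- edges$source_type
  node_type[edges$target] <- edges$target_type
  fc <- rep(NA_real_, length(node_ids))
  if (!is.null(fold_changes)) {
    hit <- match(node_ids, names(fold_changes))
    fc[!is.na(hit)] <- fold_changes[hit[!is.na(hit)]]
  }
  pw <- rep(NA_character_, length(node_ids))
  if (!is.null(pathway_map)) {
    pw <- vapply(node_ids, function(id) {
      anns <- pathway_map[[id]]
      if (is.null(anns)) NA_character_ else paste(anns, collapse = ";")
    }, character(1))
  }
  deg <- vapply(node_ids, function(id) {
    sum(edges$source == id) + sum(edges$target == id)
  }, numeric(1))
  nodes <- tibble::tibble(id = node_ids, type = unname(node_type[node_ids]),
                          fold_change = fc, pathways = unname(pw),
                          degree = unname(deg))
  structure(list(nodes = nodes,
                 edges = edges[c("source", "target", "layer", "rho")],
                 group = group),
            class = "integrated_network")
}

# Fig-style pruning: LPC subnetworks without a co-elevated cognate fatty
# acid are hidden. Removes the non-co-elevated LPC nodes, their incident
# edges, then any node left with degree 0.
prune_non_coelevated <- function(net, coelevated_pairs) {
  lpc_nodes <- net$nodes$id[net$nodes$type == "lipid" &
                            grepl("^LPC\\(", net$nodes$id)]
  keep_lpc <- lpc_nodes[lpc_nodes %in% coelevated_pairs$lpc]
  drop_lpc <- setdiff(lpc_nodes, keep_lpc)
  # fatty acids whose pair is gone disappear with their LPC
  drop_fa <- setdiff(net$nodes$id[net$nodes$type == "fatty_acid"],
                     coelevated_pairs$fa)
  drop <- c(drop_lpc, drop_fa)
  edges <- net$edges[!(net$edges$source %in% drop | net$edges$target %in% drop),
                     , drop = FALSE]
  # recompute, dropping isolated nodes
  alive <- unique(c(edges$source, edges$target))
  nodes <- net$nodes[net$nodes$id %in% alive, , drop = FALSE]
  nodes$degree <- vapply(nodes$id, function(id) {
    sum(edges$source == id) + sum(edges$target == id)
  }, numeric(1))
  structure(list(nodes = nodes, edges = edges, group = net$group),
            class = "integrated_network")
}

#' Summarise an integrated network
#'
#' Counts the display quantities of a per-group network: LPC-class lipid
#' nodes, fatty-acid nodes, and correlation-layer edges (taxon-lipid plus
#' lipid-gene; cognate and literature gene-gene edges are not correlations).
#'
#' @param network an [assemble_network()] result.
#' @param group optional label override.
#' @return tibble with `group`, `n_lpc`, `n_fatty_acid`, `n_correlations`,
#'   `n_nodes`, `n_edges`.
#' @export
network_summary <- function(network, group = network$group) {
  stopifnot(inherits(network, "integrated_network"))
  n_lpc <- sum(network$nodes$type == "lipid" & grepl("^LPC\\(", network$nodes$id))
  n_fa <- sum(network$nodes$type == "fatty_acid")
  n_corr <- sum(network$edges$layer %in% c("taxon-lipid", "lipid-gene"))
  tibble::tibble(group = group, n_lpc = n_lpc, n_fatty_acid = n_fa,
                 n_correlations = n_corr, n_nodes = nrow(network$nodes),
                 n_edges = nrow(network$edges))
}

#' @export
print.integrated_network <- function(x, ...) {
  cat(sprintf("<integrated_network> group %s: %d nodes, %d edges\n",
              x$group, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export an integrated network
#'
#' Writes GraphML (via igraph), SIF (`source<TAB>layer<TAB>target`) or JSON.
#' GraphML and JSON exports round-trip through [read_network()].
#'
#' @param network an [assemble_network()] result.
#' @param path output file.
#' @param format `"graphml"`, `"sif"` or `"json"`.
#' @export
write_network <- function(network, path, format = c("graphml", "sif", "json")) {
  stopifnot(inherits(network, "integrated_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown network format '",
                                              format[1], "'", call. = FALSE))
  dangling <- setdiff(c(network$edges$source, network$edges$target),
                      network$nodes$id)
  if (length(dangling) > 0) {
    stop("refusing to write: edge endpoint(s) missing from node set: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", network$edges$source, network$edges$layer,
                     network$edges$target)
    writeLines(lines, path)
    return(invisible(path))
  }
  if (format == "json") {
    jsonlite::write_json(list(group = network$group, nodes = network$nodes,
                              edges = network$edges),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$source, to = network$edges$target,
                   layer = network$edges$layer,
                   rho = ifelse(is.na(network$edges$rho), NaN, network$edges$rho)),
    directed = FALSE,
    vertices = data.frame(name = network$nodes$id, type = network$nodes$type,
                          fold_change = ifelse(is.na(network$nodes$fold_change),
                                               NaN, network$nodes$fold_change),
                          pathways = ifelse(is.na(network$nodes$pathways), "",
                                            network$nodes$pathways),
                          degree = network$nodes$degree))
  if (!is.na(network$group)) g <- igraph::set_graph_attr(g, "group", network$group)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Re-import an exported network
#' @param path file written by [write_network()].
#' @param format `"graphml"` or `"json"` (SIF drops attributes and is not
#'   round-trippable).
#' @return an `integrated_network`.
#' @export
read_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    lst <- jsonlite::fromJSON(path)
    nodes <- tibble::as_tibble(lst$nodes)
    edges <- tibble::as_tibble(lst$edges)
    if (nrow(edges) == 0) {
      edges <- tibble::tibble(source = character(0), target = character(0),
                              layer = character(0), rho = numeric(0))
    }
    if (nrow(nodes) == 0) {
      nodes <- tibble::tibble(id = character(0), type = character(0),
                              fold_change = numeric(0), pathways = character(0),
                              degree = numeric(0))
    }
    nodes$fold_change <- as.numeric(nodes$fold_change)
    edges$rho <- as.numeric(edges$rho)
    grp <- if (is.null(lst$group)) NA_character_ else lst$group
    return(structure(list(nodes = nodes, edges = edges, group = grp),
                     class = "integrated_network"))
  }
  g <- igraph::read_graph(path, format = "graphml")
  vat <- igraph::vertex_attr(g)
  nodes <- tibble::tibble(id = vat$name, type = vat$type,
                          fold_change = ifelse(is.nan(vat$fold_change),
                                               NA_real_, vat$fold_change),
                          pathways = ifelse(vat$pathways == "", NA_character_,
                                            vat$pathways),
                          degree = vat$degree)
  el <- igraph::as_edgelist(g)
  eat <- igraph::edge_attr(g)
  edges <- tibble::tibble(
    source = if (nrow(el)) el[, 1] else character(0),
    target = if (nrow(el)) el[, 2] else character(0),
    layer = if (length(eat$layer)) eat$layer else character(0),
    rho = if (length(eat$rho)) ifelse(is.nan(eat$rho), NA_real_, eat$rho)
          else numeric(0))
  grp <- if ("group" %in% igraph::graph_attr_names(g))
    igraph::graph_attr(g, "group") else NA_character_
  structure(list(nodes = nodes, edges = edges, group = grp),
            class = "integrated_network")
}
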