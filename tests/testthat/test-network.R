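test_that("Spearman matrix equals the rank-then-Pearson brute-force oracle", {
  withr::with_seed(1, {
    for (i in 1:200) {
      x <- sample(1:4, 6, replace = TRUE)  # heavy ties
      y <- stats::rexp(6)
      A <- ft(matrix(x, ncol = 1), "taxon")
      B <- ft(matrix(y, ncol = 1), "lipid")
      expect_equal(unname(spearman_matrix(A, B)$rho[1, 1]),
                   spearman_oracle(x, y), tolerance = 1e-12)
    }
  })
  # monotone endpoints
  up <- ft(matrix(1:6, ncol = 1)); dn <- ft(matrix(6:1, ncol = 1), "lipid")
  expect_equal(unname(spearman_matrix(up, up)$rho[1, 1]), 1)
  expect_equal(unname(spearman_matrix(up, dn)$rho[1, 1]), -1)
  expect_error(spearman_matrix(ft(matrix(1:3, ncol = 1)),
                               ft(matrix(1:3, ncol = 1), "lipid")),
               ">= 4 shared samples")
  cst <- ft(cbind(flat = rep(1, 6), ok = rexp(6)), "lipid")
  expect_warning(sm <- spearman_matrix(up, cst), "constant")
  expect_equal(colnames(sm$rho), "ok")
})

test_that("Spearman is invariant to strictly monotone transforms", {
  withr::with_seed(2, {
    A <- ft(matrix(rlnorm(24), 6), "taxon")
    B <- ft(matrix(rlnorm(24), 6), "lipid")
    r1 <- spearman_matrix(A, B)$rho
    A2 <- ft(exp(unclass(A)), "taxon")          # strictly increasing
    B2 <- ft(sqrt(unclass(B)), "lipid")
    expect_equal(spearman_matrix(A2, B2)$rho, r1, tolerance = 1e-12)
  })
})

test_that("edge thresholds are strict and layer-specific", {
  rho <- matrix(c(0.31, 0.29, -0.9, 0.45), 2, 2,
                dimnames = list(c("T1", "T2"), c("L1", "L2")))
  sm <- structure(list(rho = rho, n = 10), class = "spearman_matrix")
  tl <- threshold_edges(sm, "taxon-lipid")
  expect_equal(nrow(tl), 2)  # 0.31 and 0.45 pass; 0.29 and -0.9 do not
  expect_true(all(tl$rho > 0.3))
  expect_false(any(tl$rho < 0))  # positive-only rule

  rho2 <- matrix(c(-0.45, 0.41, 0.4, -0.4), 2, 2,
                 dimnames = list(c("L1", "L2"), c("G1", "G2")))
  lg <- threshold_edges(structure(list(rho = rho2, n = 10),
                                  class = "spearman_matrix"), "lipid-gene")
  expect_equal(nrow(lg), 2)  # |-0.45| and 0.41 pass; the two 0.4s are strict
  expect_true(all(abs(lg$rho) > 0.4))
  expect_true(any(lg$rho < 0))  # negative lipid-gene edges allowed
  expect_error(threshold_edges(sm, "taxon-gene"), "unknown layer")
})

test_that("null taxon-lipid edge rate matches the Monte-Carlo Spearman null", {
  n <- 20
  withr::with_seed(3, {
    # package route: unplanted feature pairs through the generator, averaged
    # over independent cohorts (pairs within one cohort share samples)
    rates <- vapply(1:5, function(s) {
      cfg <- multiomics_config(n_samples_per_group = 5, n_taxa = 100,
                               n_lipids = 10, n_genes = 1, seed = 70 + s)
      co <- generate_multiomics_cohort(cfg)
      sm <- spearman_matrix(co$taxa, co$lipids)
      nrow(threshold_edges(sm, "taxon-lipid")) / length(sm$rho)
    }, numeric(1))
    # Monte-Carlo null at the same n
    mc <- mean(replicate(2000, cor(rnorm(n), rnorm(n),
                                   method = "spearman") > 0.3))
    expect_lt(abs(mean(rates) - mc), 0.02)
  })
})

test_that("pathway screen keeps exactly the annotated genes", {
  pm <- list(G1 = c("ER stress"), G2 = c("cell cycle"), G3 = c("apoptosis"))
  genes <- c("G1", "G2", "G3", "G4")
  expect_setequal(pathway_screen(genes, pm, c("ER stress", "apoptosis")),
                  c("G1", "G3"))
  # saturation: all map labels retained = all annotated genes
  expect_setequal(pathway_screen(genes, pm, unique(unlist(pm))),
                  c("G1", "G2", "G3"))
  expect_error(pathway_screen(genes, pm, character(0)), "non-empty")
})

test_that("network assembly instantiates nodes, degrees and literature edges", {
  tl <- tibble::tibble(source = "T1", target = "L1", source_type = "taxon",
                       target_type = "lipid", rho = 0.5,
                       layer = "taxon-lipid", n = 10)
  lg <- tibble::tibble(source = "L1", target = "G1", source_type = "lipid",
                       target_type = "gene", rho = 0.6, layer = "lipid-gene",
                       n = 10)
  expect_warning(
    net <- assemble_network(tl, lg,
                            gene_edges = tibble::tibble(gene_a = "G1",
                                                        gene_b = "G9")),
    "outside the network")
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$nodes$degree[net$nodes$id == "L1"], 2)
  # empty network
  empty <- assemble_network(NULL, NULL)
  expect_equal(nrow(empty$nodes), 0)
  s <- network_summary(empty, "CC")
  expect_equal(unlist(s[c("n_lpc", "n_fatty_acid", "n_correlations")],
                      use.names = FALSE), c(0, 0, 0))
  # an out-of-threshold edge is refused at construction
  bad <- tl; bad$rho <- 0.2
  expect_error(assemble_network(bad, NULL), "violates")
})

test_that("summaries count LPCs, fatty acids and correlation edges", {
  tl <- tibble::tibble(source = c("T1", "T1"), target = c("LPC(22:0)", "LPC(18:1)"),
                       source_type = "taxon", target_type = "lipid",
                       rho = c(0.5, 0.6), layer = "taxon-lipid", n = 10)
  lg <- tibble::tibble(source = c("LPC(22:0)", "LPC(18:1)", "LPC(22:0)"),
                       target = c("G1", "G2", "G2"), source_type = "lipid",
                       target_type = "gene", rho = c(0.6, -0.5, 0.45),
                       layer = "lipid-gene", n = 10)
  cg <- tibble::tibble(lpc = "LPC(22:0)", fa = "FA(22:0)",
                       lpc_name = "LPC(22:0)", fa_name = "behenic acid",
                       carbons = 22L, double_bonds = 0L)
  net <- assemble_network(tl, lg, cognate_pairs = cg)
  s <- network_summary(net, "AA")
  expect_equal(s$n_lpc, 2)
  expect_equal(s$n_fatty_acid, 1)
  expect_equal(s$n_correlations, 5)
  # counts survive a GraphML round trip
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, "graphml")
  back <- read_network(path, "graphml")
  s2 <- network_summary(back, "AA")
  expect_equal(s2[c("n_lpc", "n_fatty_acid", "n_correlations")],
               s[c("n_lpc", "n_fatty_acid", "n_correlations")])
})

test_that("pruning hides LPC subnetworks without co-elevated cognates and never adds", {
  tl <- tibble::tibble(source = c("T1", "T1"), target = c("LPC(22:0)", "LPC(18:1)"),
                       source_type = "taxon", target_type = "lipid",
                       rho = c(0.5, 0.6), layer = "taxon-lipid", n = 10)
  lg <- tibble::tibble(source = c("LPC(22:0)", "LPC(18:1)"),
                       target = c("G1", "G2"), source_type = "lipid",
                       target_type = "gene", rho = c(0.6, -0.5),
                       layer = "lipid-gene", n = 10)
  cg <- tibble::tibble(lpc = c("LPC(22:0)", "LPC(18:1)"),
                       fa = c("FA(22:0)", "FA(18:1)"),
                       lpc_name = c("LPC(22:0)", "LPC(18:1)"),
                       fa_name = c("behenic acid", "oleic acid"),
                       carbons = c(22L, 18L), double_bonds = c(0L, 1L))
  coelev <- cg[1, ]
  full <- assemble_network(tl, lg, cognate_pairs = cg)
  pruned <- assemble_network(tl, lg, cognate_pairs = cg,
                             coelevated_pairs = coelev)
  expect_true(all(pruned$nodes$id %in% full$nodes$id))
  expect_false("LPC(18:1)" %in% pruned$nodes$id)
  expect_false("G2" %in% pruned$nodes$id)      # isolated after pruning
  expect_false("FA(18:1)" %in% pruned$nodes$id)
  expect_true(all(c("LPC(22:0)", "FA(22:0)", "T1", "G1") %in% pruned$nodes$id))
  sf <- network_summary(full); sp <- network_summary(pruned)
  expect_lte(sp$n_lpc, sf$n_lpc)
  expect_lte(sp$n_correlations, sf$n_correlations)
})
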