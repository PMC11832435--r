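test_that("multiomics generator is deterministic and shapes are right", {
  cfg <- multiomics_config(n_samples_per_group = 5, n_taxa = 10,
                           n_lipids = 20, n_genes = 50, seed = 7)
  a <- generate_multiomics_cohort(cfg)
  b <- generate_multiomics_cohort(cfg)
  expect_identical(serialize(a$taxa, NULL), serialize(b$taxa, NULL))
  expect_identical(serialize(a$lipids, NULL), serialize(b$lipids, NULL))
  expect_identical(serialize(a$genes, NULL), serialize(b$genes, NULL))
  expect_equal(dim(a$taxa), c(20, 10))
  expect_equal(dim(a$lipids), c(20, 20))
  expect_equal(dim(a$genes), c(20, 50))
  expect_identical(rownames(a$taxa), rownames(a$genes))
  expect_true(all(a$metadata$timepoint == "HFD"))
  expect_true(all(a$metadata$generation == "pup"))
  expect_true(all(unclass(a$taxa) >= 0))
  # global RNG untouched
  invisible(stats::runif(1))  # ensure .Random.seed exists
  seed_before <- .Random.seed
  generate_multiomics_cohort(cfg)
  expect_identical(seed_before, .Random.seed)
})

test_that("planted latent correlation is recovered as Spearman rho", {
  cfg <- multiomics_config(n_samples_per_group = 50,
                           planted_links = list(list(taxon = 1, lipid = 1,
                                                     gene = 1, rho = 0.7)),
                           seed = 42)
  co <- generate_multiomics_cohort(cfg)
  rho_hat <- cor(unclass(co$taxa)[, 1], unclass(co$lipids)[, 1],
                 method = "spearman")
  expect_lt(abs(rho_hat - 0.7), 0.1)
  # the lipid-gene leg of the chain too
  rho_lg <- cor(unclass(co$lipids)[, 1], unclass(co$genes)[, 1],
                method = "spearman")
  expect_lt(abs(rho_lg - 0.7), 0.1)
})

test_that("fold multipliers shift group means on the linear scale", {
  cfg <- multiomics_config(
    n_samples_per_group = 200, n_lipids = 5,
    planted_de_lipids = list(list(feature = 2, group = "AA", fold = 3)),
    seed = 9)
  co <- generate_multiomics_cohort(cfg)
  md <- co$metadata
  r <- mean(unclass(co$lipids)[md$group == "AA", 2]) /
    mean(unclass(co$lipids)[md$group == "CC", 2])
  expect_lt(abs(r - 3), 0.8)  # lognormal sampling noise at n=200
})

test_that("config validation names the offending field", {
  expect_error(multiomics_config(n_taxa = 0), "n_taxa")
  expect_error(multiomics_config(noise_sd = -1), "noise_sd")
  expect_error(multiomics_config(
    planted_links = list(list(taxon = 99, lipid = 1, gene = 1, rho = 0.5))),
    "taxon index out of bounds")
  expect_error(multiomics_config(
    planted_links = list(list(taxon = 1, lipid = 1, gene = 1, rho = 1))),
    "rho")
  expect_error(multiomics_config(
    planted_de_lipids = list(list(feature = 1, group = "CC", fold = 0))),
    "fold")
  expect_error(dyad_config(dropout_by_group = c(CC = -0.1)), "\\[0, 1\\]")
})

test_that("dyad generator honours dropout limits and renormalisation", {
  # dropout 0: pup support equals dam support
  co0 <- generate_dyad_cohort(dyad_config(
    n_dyads_per_group = 4, n_taxa = 30,
    dropout_by_group = c(CC = 0, AA = 0), seed = 3))
  m <- unclass(co0$table)
  dyads <- pair_dyads(co0$metadata)
  for (i in seq_len(nrow(dyads))) {
    expect_identical(m[dyads$pup_sample[i], ] > 0, m[dyads$dam_sample[i], ] > 0)
  }
  pups <- co0$metadata$sample_id[co0$metadata$generation == "pup"]
  expect_equal(unname(rowSums(m[pups, ])), rep(1, length(pups)),
               tolerance = 1e-9)

  # dropout 1: no shared taxa in any dyad
  co1 <- generate_dyad_cohort(dyad_config(
    n_dyads_per_group = 4, n_taxa = 30,
    dropout_by_group = c(CC = 1), seed = 3))
  m1 <- unclass(co1$table)
  dy1 <- pair_dyads(co1$metadata)
  for (i in seq_len(nrow(dy1))) {
    expect_equal(
      shared_taxa(m1[dy1$dam_sample[i], ], m1[dy1$pup_sample[i], ],
                  presence_threshold = 1e-12)$count, 0)
  }
})

test_that("mean shared count matches the binomial expectation", {
  # 40 taxa at dropout 0.5: shared ~ Binomial(40, 0.5) per dyad
  co <- generate_dyad_cohort(dyad_config(
    n_dyads_per_group = 200, n_taxa = 40,
    dropout_by_group = c(CC = 0.5), abundance_concentration = 5,
    jitter_sd = 0, seed = 21))
  m <- unclass(co$table)
  dyads <- pair_dyads(co$metadata)
  shared <- vapply(seq_len(nrow(dyads)), function(i) {
    shared_taxa(m[dyads$dam_sample[i], ], m[dyads$pup_sample[i], ],
                presence_threshold = 1e-12)$count
  }, numeric(1))
  se <- sqrt(40 * 0.25 / length(shared))
  expect_lt(abs(mean(shared) - 20), 3 * se)
})

test_that("generator config files load from YAML and JSON", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("type: multiomics", "n_samples_per_group: 3", "n_taxa: 4",
               "n_lipids: 4", "n_genes: 4", "seed: 5"), yml)
  cfg <- read_generator_config(yml)
  expect_s3_class(cfg, "multiomics_config")
  expect_equal(cfg$n_taxa, 4L)

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"type": "dyad", "n_dyads_per_group": 2, "n_taxa": 10,
    "dropout_by_group": {"CC": 0.1}, "seed": 2}', js)
  cfg2 <- read_generator_config(js)
  expect_s3_class(cfg2, "dyad_config")
  expect_equal(unname(cfg2$dropout_by_group["CC"]), 0.1)
})
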