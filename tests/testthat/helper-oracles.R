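# Independent oracles and small fixture builders shared across test files.

# Quick feature table from a matrix, inventing IDs when absent.
ft <- function(m, kind = "taxon") {
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("F", seq_len(ncol(m)))
  feature_table(m, kind)
}

# Average ranks computed from first principles (sort + tie runs), kept
# independent of base::rank.
avg_rank_oracle <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Rank-then-Pearson Spearman oracle.
spearman_oracle <- function(x, y) {
  rx <- avg_rank_oracle(x); ry <- avg_rank_oracle(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Independent PLS1 solver: each weight is the dominant left singular vector
# of the current cross-covariance X_a' y (obtained from an eigendecomposition
# of its outer product rather than the NIPALS recursion), with the same
# autoscaling and deflation contract as the fitted model.
svd_pls1_oracle <- function(X, y_labels, n_components = 2) {
  classes <- sort(unique(y_labels))
  yv <- ifelse(y_labels == classes[2], 1, -1)
  yv <- yv - mean(yv)
  Xs <- scale(X)
  W <- matrix(0, ncol(Xs), n_components)
  Tt <- matrix(0, nrow(Xs), n_components)
  Xa <- Xs
  for (a in seq_len(n_components)) {
    s <- crossprod(Xa, yv)                 # p x 1 cross-covariance
    M <- tcrossprod(s)                     # rank-1, symmetric
    w <- eigen(M, symmetric = TRUE)$vectors[, 1]
    if (sum(w * s) < 0) w <- -w            # orient along the covariance
    tt <- Xa %*% w
    p_a <- crossprod(Xa, tt) / sum(tt^2)
    Xa <- Xa - tcrossprod(tt, p_a)
    W[, a] <- w; Tt[, a] <- tt
  }
  list(weights = W, scores = Tt)
}

# Random multiomics config with one planted chain, used by several files.
planted_chain_config <- function(seed, n_per_group = 25, rho = 0.8,
                                 fold = 2) {
  multiomics_config(
    n_samples_per_group = n_per_group,
    n_taxa = 10, n_lipids = 20, n_genes = 15,
    planted_links = list(list(taxon = 1, lipid = 1, gene = 1, rho = rho)),
    planted_de_lipids = list(list(feature = 1, group = "AA", fold = fold)),
    planted_de_genes = list(list(feature = 1, group = "AA", fold = fold)),
    seed = seed)
}

# Shorthand lipid names for a 20-lipid table whose first feature is the
# planted LPC.
chain_lipid_names <- function() {
  c("LPC(22:0)", paste0("PC(", 30:47, ":2)"), "DG(36:2)")
}

# Serum fatty-acid layer sharing the cohort's samples; feature 1 is the
# cognate of LPC(22:0) and can be elevated in a chosen group.
chain_fa_table <- function(metadata, seed, elevated_group = "AA",
                           fold = 2) {
  withr::with_seed(seed, {
    m <- matrix(rlnorm(nrow(metadata) * 3, 2, 0.4), nrow(metadata), 3,
                dimnames = list(metadata$sample_id,
                                c("behenic acid (22:0)", "oleic acid",
                                  "palmitic acid")))
    m[metadata$group == elevated_group, 1] <-
      m[metadata$group == elevated_group, 1] * fold
    feature_table(m, "metabolite")
  })
}
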