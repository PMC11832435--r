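#' LEfSe-style differential-abundance screen
#'
#' Two-stage screen for group-discriminating taxa. Stage 1 keeps taxa whose
#' Kruskal-Wallis p-value across groups falls below `alpha` (no multiplicity
#' correction, following the published LEfSe algorithm). Stage 2 rescales
#' abundances to a per-sample sum of 1e6, then estimates a linear-discriminant
#' effect size by bootstrapping: in each of `n_boot` rounds a fraction
#' `boot_fraction` of samples is drawn per group, an LDA is fitted on the
#' surviving taxa for each group pair, and the per-taxon effect combines the
#' scaled discriminant coefficient with the raw class-mean difference. The
#' reported score is `log10(1 + mean |effect|)`; taxa with score above
#' `lda_threshold` are reported, labelled with the group of highest mean
#' abundance. With more than two groups the maximum pairwise effect is used.
#'
#' Exact numeric parity with the reference LEfSe tool is not promised;
#' parity of decisions on well-separated cases is the contract.
#'
#' @param table relative-abundance taxon [feature_table()].
#' @param groups group label per sample (character, matrix row order).
#' @param alpha stage-1 significance level (default 0.05).
#' @param lda_threshold log10 effect-size cutoff (default 2).
#' @param n_boot bootstrap rounds (default 30).
#' @param boot_fraction per-group subsample fraction (default 2/3).
#' @param seed integer seed.
#' @return tibble with columns `taxon`, `p_value`, `lda_score`, `enriched_in`,
#'   one row per reported taxon (p < alpha and score > threshold).
#' @export
lefse_screen <- function(table, groups, alpha = 0.05, lda_threshold = 2,
                         n_boot = 30, boot_fraction = 2 / 3, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  m <- ft_matrix(table)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stop("`groups` length must match samples",
                                      call. = FALSE)
  tab <- base::table(groups)
  if (length(tab) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 3)) {
    stop("group '", names(tab)[which(tab < 3)[1]],
         "' has fewer than 3 samples (LDA degeneracy)", call. = FALSE)
  }
  # canonical sample order (group, then ID) so that jointly permuting the
  # table and labels cannot reshuffle the bootstrap draws
  ord <- order(groups, rownames(m))
  m <- m[ord, , drop = FALSE]
  groups <- groups[ord]

  # stage 1: Kruskal-Wallis per taxon; constant taxa can never discriminate
  p_values <- apply(m, 2, function(v) {
    if (stats::var(v) == 0) return(1)
    stats::kruskal.test(v, factor(groups))$p.value
  })
  survivors <- which(p_values < alpha)
  if (length(survivors) == 0) {
    return(tibble::tibble(taxon = character(0), p_value = numeric(0),
                          lda_score = numeric(0), enriched_in = character(0)))
  }

  # stage 2: 1e6 rescaling then bootstrapped LDA effect size
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  m6 <- m / tot * 1e6
  glab <- sort(unique(groups))
  pairs <- utils::combn(glab, 2, simplify = FALSE)
  scores <- withr::with_seed(seed, {
    eff_by_pair <- vapply(pairs, function(pr) {
      idx <- which(groups %in% pr)
      mean_boot_effects(m6[idx, survivors, drop = FALSE], groups[idx],
                        n_boot, boot_fraction)
    }, numeric(length(survivors)))
    eff_by_pair <- matrix(eff_by_pair, nrow = length(survivors))
    apply(eff_by_pair, 1, max)  # one-vs-all as maximum pairwise effect
  })
  lda_score <- log10(1 + scores)
  keep <- lda_score > lda_threshold
  enriched <- vapply(survivors, function(j) {
    means <- tapply(m6[, j], groups, mean)
    names(means)[which.max(means)]
  }, character(1))
  out <- tibble::tibble(taxon = colnames(m)[survivors],
                        p_value = unname(p_values[survivors]),
                        lda_score = unname(lda_score),
                        enriched_in = unname(enriched))[keep, ]
  out[order(-out$lda_score), ]
}

# Bootstrap-averaged absolute LDA effect per feature for a two-class
# problem. Each round subsamples `frac` of each class, fits one MASS::lda on
# all features, scales LD1 to unit norm and weights each coefficient by the
# projected class separation; the per-feature effect is the mean of that
# term and the raw class-mean difference. LDA failures (singular
# within-class covariance on a subsample) fall back to the mean difference
# alone for that round.
mean_boot_effects <- function(X, g, n_boot, frac) {
  cls <- sort(unique(g))
  p <- ncol(X)
  acc <- matrix(0, n_boot, p)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(cls, function(cl) {
      pool <- which(g == cl)
      sample(pool, max(2, floor(length(pool) * frac)))
    }))
    Xb <- X[idx, , drop = FALSE]
    gb <- g[idx]
    md <- abs(colMeans(Xb[gb == cls[1], , drop = FALSE]) -
              colMeans(Xb[gb == cls[2], , drop = FALSE]))
    w_term <- tryCatch({
      keep_cols <- which(apply(Xb, 2, stats::var) > 0)
      if (length(keep_cols) == 0) md
      else {
        fit <- suppressWarnings(MASS::lda(Xb[, keep_cols, drop = FALSE],
                                          grouping = factor(gb)))
        w <- fit$scaling[, 1]
        w <- w / sqrt(sum(w^2))
        proj <- Xb[, keep_cols, drop = FALSE] %*% w
        sep <- abs(mean(proj[gb == cls[1]]) - mean(proj[gb == cls[2]]))
        out <- numeric(p)
        out[keep_cols] <- abs(w) * sep
        out
      }
    }, error = function(e) md)
    acc[b, ] <- (w_term + md) / 2
  }
  colMeans(acc)
}

#' Write a differential-abundance result as TSV
#' @param result tibble from [lefse_screen()].
#' @param path output path.
#' @export
write_lefse_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
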