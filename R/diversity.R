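#' Convert a table to relative abundance
#'
#' Divides each sample row by its total so profiles sum to one, the scale on
#' which Bray-Curtis dissimilarities and presence thresholds are interpreted.
#'
#' @param table a [feature_table()].
#' @return a [feature_table()] of the same shape with unit row sums.
#' @examples
#' m <- matrix(c(2, 2), nrow = 1, dimnames = list("S1", c("A", "B")))
#' relative_abundance(feature_table(m, "taxon"))
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  m <- ft_matrix(table)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("sample '", rownames(m)[which(tot == 0)[1]],
         "' has zero total abundance; cannot normalise", call. = FALSE)
  }
  feature_table(m / tot, table_kind(table))
}

#' Alpha diversity: observed richness and bias-corrected Chao1
#'
#' Observed richness is the number of features with a nonzero count. The
#' Chao1 estimator uses the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1` and `F2` are the numbers
#' of singletons and doubletons; this form is defined even when no doubletons
#' exist. An all-zero sample returns observed 0 and Chao1 0 by convention.
#'
#' @param counts non-negative integer count vector, or a count
#'   [feature_table()] (per-sample results are then returned).
#' @return tibble with columns `sample_id` (when a table is given),
#'   `observed`, `chao1`.
#' @examples
#' alpha_diversity(c(5, 2, 1, 1, 1))  # observed 5, Chao1 6.5
#' @export
alpha_diversity <- function(counts) {
  if (inherits(counts, "feature_table")) {
    m <- ft_matrix(counts)
    res <- t(apply(m, 1, chao1_one))
    return(tibble::tibble(sample_id = rownames(m),
                          observed = unname(res[, 1]),
                          chao1 = unname(res[, 2])))
  }
  res <- chao1_one(counts)
  tibble::tibble(observed = unname(res[1]), chao1 = unname(res[2]))
}

chao1_one <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  c(observed = s_obs, chao1 = s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
}

#' Distance matrix container
#'
#' Wraps a symmetric dissimilarity matrix with a zero diagonal; used for
#' Bray-Curtis matrices and any distance passed to [pcoa()] or [permanova()].
#'
#' @param m square symmetric numeric matrix with sample IDs as dimnames.
#' @return object of class `dist_matrix`.
#' @export
dist_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("distance matrix must be square",
                                                call. = FALSE)
  if (is.null(rownames(m))) stop("distance matrix needs sample IDs as dimnames",
                                 call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix is not symmetric",
                                       call. = FALSE)
  if (max(abs(diag(m))) > 1e-12) stop("distance matrix diagonal must be zero",
                                      call. = FALSE)
  colnames(m) <- rownames(m)
  structure(m, class = c("dist_matrix", "matrix", "array"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over all sample pairs.
#' Computed on relative abundances by default, matching how microbiota
#' profiles are compared after normalisation; set `relative = FALSE` to use
#' the raw values.
#'
#' @param table a [feature_table()] with non-negative values.
#' @param relative normalise rows to unit sum first (default `TRUE`).
#' @return a [dist_matrix()] with entries in \[0, 1\].
#' @export
bray_curtis_matrix <- function(table, relative = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  m <- ft_matrix(table)
  tot <- rowSums(m)
  if (sum(tot == 0) >= 2) {
    stop("Bray-Curtis is undefined between two all-zero samples (",
         paste(utils::head(rownames(m)[tot == 0], 2), collapse = ", "), ")",
         call. = FALSE)
  }
  if (relative) {
    if (any(tot == 0)) {
      stop("sample '", rownames(m)[which(tot == 0)[1]],
           "' has zero total abundance; cannot normalise", call. = FALSE)
    }
    m <- m / tot
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  diag(d) <- 0
  dist_matrix(d)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower double-centering of `-D^2/2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Negative eigenvalues, which arise for semimetric inputs such
#' as Bray-Curtis, are reported unchanged rather than corrected. Proportion
#' explained is relative to the sum of positive eigenvalues.
#'
#' @param dm a [dist_matrix()].
#' @param n_axes number of axes to return (capped at the number of positive
#'   eigenvalues).
#' @return list of class `ordination`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, in non-increasing order), `proportion_explained`.
#' @export
pcoa <- function(dm, n_axes = 2) {
  dm <- dist_matrix(as.matrix(dm))
  n <- nrow(dm)
  # cmdscale warns when fewer than k eigenvalues are positive; the trailing
  # axes are reported as zeros here, so that warning is redundant
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = max(1, min(n_axes, n - 1)),
                    eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- eig[eig > 1e-12]
  k_pos <- min(n_axes, max(0L, length(pos)))
  k <- min(n_axes, n - 1)  # axes beyond the positive spectrum are zero
  coords <- matrix(0, n, k, dimnames = list(rownames(dm),
                                            if (k > 0) paste0("PCo", seq_len(k))))
  if (k_pos > 0) coords[, seq_len(k_pos)] <- fit$points[, seq_len(k_pos)]
  prop <- if (length(pos) > 0) pmax(eig, 0) / sum(pos) else rep(0, length(eig))
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = prop), class = "ordination")
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way pseudo-F in the distance-based (Anderson) formulation:
#' `SS_total = sum(d_ij^2)/n` over all pairs, `SS_within` summed within
#' groups, `F = (SS_between/(a-1)) / (SS_within/(n-a))`. The p-value is
#' `(1 + #permuted F >= observed F) / (1 + n_perm)` from free label
#' permutations; with `n_perm = "exact"` all distinct label arrangements are
#' enumerated instead.
#'
#' @param dm a [dist_matrix()].
#' @param groups group label per sample (length = number of samples, in the
#'   order of the matrix rows).
#' @param n_perm number of permutations, or `"exact"` for full enumeration
#'   (feasible only for small n).
#' @param seed integer seed for the permutation draw.
#' @return list of class `perm_test`: `statistic` (pseudo-F), `p_value`,
#'   `method`, `n_perm`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1L) {
  dm <- dist_matrix(as.matrix(dm))
  groups <- as.character(groups)
  if (length(groups) != nrow(dm)) stop("`groups` length must match samples",
                                       call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2) stop("PERMANOVA needs >= 2 groups", call. = FALSE)
  if (any(tab < 2)) {
    stop("group '", names(tab)[which(tab < 2)[1]],
         "' has fewer than 2 samples", call. = FALSE)
  }
  d2 <- unclass(dm)^2
  f_obs <- permanova_f(d2, groups)
  if (identical(n_perm, "exact")) {
    perms <- unique_label_permutations(groups)
    f_perm <- vapply(perms, function(g) permanova_f(d2, g), numeric(1))
    # observed labelling is one of the enumerated arrangements
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
    method <- "PERMANOVA (exact enumeration)"
  } else {
    n_used <- as.integer(n_perm)
    f_perm <- withr::with_seed(seed, {
      vapply(seq_len(n_used),
             function(i) permanova_f(d2, sample(groups)), numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_used)
    method <- "PERMANOVA (free permutations)"
  }
  structure(list(statistic = f_obs, p_value = p, method = method,
                 n_perm = n_used), class = "perm_test")
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  a <- length(unique(groups))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# All distinct assignments of the multiset of labels to positions.
unique_label_permutations <- function(groups) {
  n <- length(groups)
  labs <- sort(unique(groups))
  out <- list()
  rec <- function(remaining_counts, assigned) {
    if (length(assigned) == n) {
      out[[length(out) + 1L]] <<- assigned
      return(invisible())
    }
    for (l in labs) {
      if (remaining_counts[[l]] > 0) {
        rc <- remaining_counts; rc[[l]] <- rc[[l]] - 1L
        rec(rc, c(assigned, l))
      }
    }
  }
  counts <- as.list(table(groups))
  rec(counts, character(0))
  out
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided test on the rank sum. The exact null distribution is enumerated
#' when the combined sample size is at most 12 and no ties are present;
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction is used (the standard large-sample path of
#' [stats::wilcox.test()]).
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list of class `perm_test`: `statistic` (W), `p_value`, `method`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("rank-sum test needs two non-empty samples", call. = FALSE)
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12) && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 method = if (exact) "Wilcoxon rank-sum (exact)"
                          else "Wilcoxon rank-sum (normal approximation)"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}
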