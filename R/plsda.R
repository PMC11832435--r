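#' Fit a two-component PLS-DA model (NIPALS)
#'
#' Partial least squares discriminant analysis for a two-class response:
#' the class labels are coded +1/-1 and centered, predictors are autoscaled
#' (zero mean, unit variance), and components are extracted by NIPALS with
#' deflation of X after each component. Zero-variance features are dropped
#' with a warning before fitting and later receive a VIP of 0.
#'
#' For each component `a`: weight `w_a` (unit norm), scores `t_a = X_a w_a`,
#' X-loading `p_a = X_a' t_a / (t_a' t_a)`, response loading
#' `q_a = y' t_a / (t_a' t_a)`, and explained response variation
#' `SSY_a = q_a^2 (t_a' t_a)`.
#'
#' @param X numeric matrix, samples x features (colnames = feature IDs).
#' @param y class label per sample; exactly two distinct values, each with at
#'   least 3 samples.
#' @param n_components number of latent variables (default 2).
#' @param tol,max_iter NIPALS convergence controls.
#' @return list of class `plsda_model`: `weights` (features x A, unit-norm
#'   columns), `scores` (samples x A), `loadings`, `q` (response loadings),
#'   `ssy` (per-component explained response variation), `center`, `scale`,
#'   `features` (IDs used), `dropped` (zero-variance IDs), `classes`.
#' @export
fit_plsda <- function(X, y, n_components = 2, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) {
    stop("PLS-DA needs exactly two classes; got ", length(classes), call. = FALSE)
  }
  if (any(base::table(y) < 3)) {
    stop("each class needs >= 3 samples", call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("X rows must match y length", call. = FALSE)

  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped), " zero-variance feature(s) before PLS-DA",
            call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(X) == 0) stop("no features with nonzero variance", call. = FALSE)
  ctr <- colMeans(X)
  Xs <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  yv <- ifelse(y == classes[2], 1, -1)
  yv <- yv - mean(yv)
  if (all(yv == 0)) stop("response is constant after centering", call. = FALSE)
  rk <- qr(Xs)$rank
  if (n_components > rk) {
    stop("n_components (", n_components, ") exceeds the rank of X (", rk, ")",
         call. = FALSE)
  }

  p <- ncol(Xs); n <- nrow(Xs); A <- n_components
  W <- matrix(0, p, A); Tt <- matrix(0, n, A); P <- matrix(0, p, A)
  q <- numeric(A); ssy <- numeric(A)
  Xa <- Xs
  for (a in seq_len(A)) {
    w <- crossprod(Xa, yv)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {   # PLS1 converges immediately; loop kept
      tt <- Xa %*% w                  # for the general contract
      q_a <- sum(yv * tt) / sum(tt^2)
      w_new <- crossprod(Xa, yv) * q_a
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
      w <- w_new
    }
    tt <- Xa %*% w
    tt2 <- sum(tt^2)
    p_a <- crossprod(Xa, tt) / tt2
    q_a <- sum(yv * tt) / tt2
    W[, a] <- w; Tt[, a] <- tt; P[, a] <- p_a
    q[a] <- q_a; ssy[a] <- q_a^2 * tt2
    Xa <- Xa - tcrossprod(tt, p_a)
  }
  rownames(W) <- rownames(P) <- colnames(Xs)
  structure(list(weights = W, scores = Tt, loadings = P, q = q, ssy = ssy,
                 center = ctr, scale = sds, features = colnames(Xs),
                 dropped = dropped, classes = classes,
                 n_components = A),
            class = "plsda_model")
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` over the model's
#' components, where `p` is the number of fitted features. Because each
#' weight vector has unit norm, the scores satisfy `sum_j VIP_j^2 = p`
#' exactly. Features dropped before fitting (zero variance) are reported
#' with VIP 0.
#'
#' @param model a [fit_plsda()] model.
#' @return named numeric vector of VIP scores (fitted features first, then
#'   any dropped features with value 0).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  if (sum(model$ssy) <= 0) {
    stop("total explained response variation is zero (constant response)",
         call. = FALSE)
  }
  p <- length(model$features)
  num <- (model$weights^2) %*% model$ssy
  vip <- sqrt(p * num / sum(model$ssy))[, 1]
  names(vip) <- model$features
  if (length(model$dropped) > 0) {
    vip <- c(vip, stats::setNames(rep(0, length(model$dropped)), model$dropped))
  }
  vip
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d components, %d features, classes %s vs %s\n",
              x$n_components, length(x$features), x$classes[1], x$classes[2]))
  invisible(x)
}
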