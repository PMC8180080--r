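# PCA and OPLS-DA separation diagnostics on metabolic profiles.
#
# OPLS-DA is implemented directly (orthogonal-projections NIPALS for a
# single response): predictive variation is extracted after deflating the
# class-uncorrelated ("orthogonal") variation, giving one predictive score
# per sample plus n_orthogonal orthogonal scores. Q2 is estimated by
# stratified k-fold cross-validation with refitting per fold.

# Autoscale or Pareto-scale a samples x compounds matrix using the given
# (or its own) centers/scales. Zero-variance columns get scale 1 so they
# contribute nothing after centering.
.scale_matrix <- function(X, scaling = c("autoscale", "pareto"),
                          center = NULL, scale = NULL) {
  scaling <- match.arg(scaling)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    s <- apply(X, 2, stats::sd)
    if (scaling == "pareto") s <- sqrt(s)
    s[s == 0 | !is.finite(s)] <- 1
    scale <- s
  }
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Principal component analysis of a profile matrix
#'
#' Mean-centers and unit-variance scales the samples x compounds matrix
#' (autoscaling, the convention for metabolomics peak tables where compound
#' abundances span orders of magnitude), then computes a truncated PCA.
#' R2X is the fraction of total (scaled) variance captured by the retained
#' components. Compounds with zero variance carry no information after
#' scaling and are excluded with a warning.
#'
#' @param pm a \code{profile_matrix}.
#' @param n_components number of components to retain.
#' @param scaling \code{"autoscale"} (default) or \code{"pareto"}.
#' @return An object of class \code{pca_model}: list with \code{scores}
#'   (samples x components), \code{loadings} (compounds x components),
#'   \code{r2x}, \code{explained} (per-component variance fractions),
#'   \code{n_components}, \code{scaling}, \code{groups}.
#' @export
fit_pca <- function(pm, n_components = 2, scaling = c("autoscale", "pareto")) {
  stopifnot(inherits(pm, "profile_matrix"))
  scaling <- match.arg(scaling)
  X <- t(pm$abundance)
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance compound(s) excluded from PCA")
    X <- X[, keep, drop = FALSE]
  }
  max_k <- min(nrow(X) - 1, ncol(X))
  if (n_components < 1 || n_components > max_k)
    stop("'n_components' must be in [1, ", max_k, "]")
  pc <- stats::prcomp(X, center = TRUE, scale. = scaling == "autoscale")
  if (scaling == "pareto") {
    sc <- .scale_matrix(X, "pareto")
    pc <- stats::prcomp(sc$X, center = FALSE, scale. = FALSE)
  }
  total_var <- sum(pc$sdev^2)
  explained <- pc$sdev[seq_len(n_components)]^2 / total_var
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 r2x = sum(explained), explained = explained,
                 n_components = n_components, scaling = scaling,
                 groups = pm$groups, sample_ids = pm$sample_ids),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA (", x$scaling, "): ", x$n_components, " components, R2X = ",
      sprintf("%.3f", x$r2x), "\n", sep = "")
  invisible(x)
}

#' @export
plot.pca_model <- function(x, components = c(1, 2), ...) {
  s <- x$scores[, components, drop = FALSE]
  plot(s[, 1], s[, 2], col = as.integer(x$groups), pch = 19,
       xlab = sprintf("PC%d", components[1]),
       ylab = sprintf("PC%d", components[2]),
       main = sprintf("PCA score plot (R2X = %.3f)", x$r2x), ...)
  graphics::legend("topright", legend = levels(x$groups), col = 1:2, pch = 19)
  invisible(x)
}

# One OPLS fit on a pre-scaled X (n x p) and centered y. Returns weights,
# loadings and scores for n_orthogonal orthogonal components plus one
# predictive component.
.opls_core <- function(X, y, n_orthogonal) {
  normalize <- function(v) v / sqrt(sum(v^2))
  W_o <- P_o <- NULL
  T_o <- NULL
  for (k in seq_len(n_orthogonal)) {
    w <- normalize(drop(crossprod(X, y)))
    t <- drop(X %*% w)
    p <- drop(crossprod(X, t)) / sum(t^2)
    w_o <- p - sum(w * p) * w          # loading part orthogonal to w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break             # no orthogonal variation left
    w_o <- w_o / nrm
    t_o <- drop(X %*% w_o)
    p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  w <- normalize(drop(crossprod(X, y)))
  t_pred <- drop(X %*% w)
  p_pred <- drop(crossprod(X, t_pred)) / sum(t_pred^2)
  q <- sum(y * t_pred) / sum(t_pred^2)
  list(w = w, p_pred = p_pred, q = q, t_pred = t_pred,
       W_o = W_o, P_o = P_o, T_o = T_o, X_res = X - tcrossprod(t_pred, p_pred))
}

# Project new (already scaled) rows through a fitted .opls_core.
.opls_project <- function(fit, X_new) {
  T_o <- NULL
  if (!is.null(fit$W_o)) {
    for (k in seq_len(ncol(fit$W_o))) {
      t_o <- drop(X_new %*% fit$W_o[, k])
      X_new <- X_new - tcrossprod(t_o, fit$P_o[, k])
      T_o <- cbind(T_o, t_o)
    }
  }
  t_pred <- drop(X_new %*% fit$w)
  list(t_pred = t_pred, T_o = T_o, y_hat = t_pred * fit$q)
}

# Stratified fold assignment: shuffles within class, then deals folds
# round-robin so every fold keeps both classes.
.stratified_folds <- function(groups, k, seed) {
  fold <- integer(length(groups))
  with_seed(seed, {
    for (g in levels(groups)) {
      idx <- sample(which(groups == g))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  if (min(table(groups)) < k)
    stop("cannot stratify ", k, " folds: smallest class has fewer samples")
  fold
}

#' Orthogonal partial least squares discriminant analysis (OPLS-DA)
#'
#' Fits an OPLS-DA model with one predictive component and
#' \code{n_orthogonal} orthogonal components to a two-group profile matrix.
#' The response is the centered -1/+1 class coding; X is autoscaled by
#' default. R2Y is the fraction of response variance explained on the
#' training fit; Q2 = 1 - PRESS/TSS is estimated by seeded, stratified
#' k-fold cross-validation with the model (including scaling) refit on each
#' training fold. Q2 near or below zero indicates no predictive power; Q2
#' is not guaranteed to be below R2Y only in pathological fits.
#'
#' @param pm a \code{profile_matrix} with both groups.
#' @param n_orthogonal number of orthogonal components (default 1).
#' @param cv_folds folds for the Q2 cross-validation (default 7).
#' @param seed integer seed for the fold assignment.
#' @param scaling \code{"autoscale"} (default) or \code{"pareto"}.
#' @return An object of class \code{oplsda_model}: scores (predictive and
#'   orthogonal), loadings, \code{r2x}, \code{r2y}, \code{q2}, the applied
#'   scaling, and everything needed by \code{predict}.
#' @export
fit_oplsda <- function(pm, n_orthogonal = 1, cv_folds = 7, seed = 1,
                       scaling = c("autoscale", "pareto")) {
  stopifnot(inherits(pm, "profile_matrix"))
  scaling <- match.arg(scaling)
  if (cv_folds < 2) stop("'cv_folds' must be >= 2")
  X_raw <- t(pm$abundance)
  y_code <- ifelse(pm$groups == "case", 1, -1)
  y_mean <- mean(y_code)
  y <- y_code - y_mean

  sc <- .scale_matrix(X_raw, scaling)
  fit <- .opls_core(sc$X, y, n_orthogonal)

  r2y <- 1 - sum((y - fit$t_pred * fit$q)^2) / sum(y^2)
  tss_x <- sum(sc$X^2)
  r2x <- 1 - sum(fit$X_res^2) / tss_x

  # cross-validated predictive power
  fold <- .stratified_folds(pm$groups, cv_folds, seed)
  press <- 0
  for (k in seq_len(cv_folds)) {
    tr <- fold != k
    sc_k <- .scale_matrix(X_raw[tr, , drop = FALSE], scaling)
    y_tr_mean <- mean(y_code[tr])
    fit_k <- .opls_core(sc_k$X, y_code[tr] - y_tr_mean, n_orthogonal)
    X_te <- sweep(sweep(X_raw[!tr, , drop = FALSE], 2, sc_k$center), 2,
                  sc_k$scale, "/")
    y_hat <- .opls_project(fit_k, X_te)$y_hat + y_tr_mean
    press <- press + sum((y_code[!tr] - y_hat)^2)
  }
  q2 <- 1 - press / sum((y_code - y_mean)^2)

  scores <- cbind(t_pred = fit$t_pred, fit$T_o)
  if (!is.null(fit$T_o))
    colnames(scores) <- c("t_pred", paste0("t_ortho", seq_len(ncol(fit$T_o))))
  rownames(scores) <- pm$sample_ids
  loadings <- cbind(p_pred = fit$p_pred, fit$P_o)
  rownames(loadings) <- colnames(X_raw)

  structure(list(scores = scores, loadings = loadings,
                 r2x = r2x, r2y = r2y, q2 = q2,
                 n_predictive = 1L, n_orthogonal = n_orthogonal,
                 cv_folds = cv_folds, seed = seed, scaling = scaling,
                 groups = pm$groups, sample_ids = pm$sample_ids,
                 fit = fit, center = sc$center, scale = sc$scale,
                 y_mean = y_mean),
            class = "oplsda_model")
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat("OPLS-DA (", x$scaling, "): 1 predictive + ", x$n_orthogonal,
      " orthogonal component(s)\n", sep = "")
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2 = %.3f (%d-fold CV)\n",
              x$r2x, x$r2y, x$q2, x$cv_folds))
  invisible(x)
}

#' Predict group membership from an OPLS-DA model
#'
#' @param object an \code{oplsda_model}.
#' @param pm a \code{profile_matrix} with the same compounds.
#' @param ... unused.
#' @return List with predictive scores \code{t_pred}, fitted response
#'   \code{y_hat} on the -1/+1 scale, and hard \code{class} labels.
#' @export
predict.oplsda_model <- function(object, pm, ...) {
  stopifnot(inherits(pm, "profile_matrix"))
  X <- sweep(sweep(t(pm$abundance), 2, object$center), 2, object$scale, "/")
  pr <- .opls_project(object$fit, X)
  y_hat <- pr$y_hat + object$y_mean
  list(t_pred = pr$t_pred, y_hat = y_hat,
       class = factor(ifelse(y_hat > 0, "case", "control"),
                      levels = c("case", "control")))
}

#' @export
plot.oplsda_model <- function(x, ...) {
  t_o <- if (ncol(x$scores) > 1) x$scores[, 2] else seq_along(x$groups)
  plot(x$scores[, 1], t_o, col = as.integer(x$groups), pch = 19,
       xlab = "predictive score", ylab = "orthogonal score",
       main = sprintf("OPLS-DA (R2Y = %.3f, Q2 = %.3f)", x$r2y, x$q2), ...)
  graphics::legend("topright", legend = levels(x$groups), col = 1:2, pch = 19)
  invisible(x)
}

#' Export plot-ready score tables
#'
#' Writes a TSV with one row per sample: score columns plus the group
#' label, suitable for external plotting.
#'
#' @param model a \code{pca_model} or \code{oplsda_model}.
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
write_scores <- function(model, path) {
  df <- data.frame(sample_id = model$sample_ids, model$scores,
                   group = as.character(model$groups), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
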