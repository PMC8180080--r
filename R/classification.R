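# ROC machinery, Youden-J classifying thresholds, single-marker threshold
# classifiers, and the ridge-stabilised logistic marker panel.

#' Receiver operating characteristic curve
#'
#' Computes one operating point per distinct score plus the "predict
#' nothing" endpoint, under the rule "predict case iff score >= threshold".
#' The AUC is the trapezoidal area, which equals the Mann-Whitney
#' concordance probability with ties counted one half.
#'
#' @param values numeric per-sample scores (e.g. abundances or predicted
#'   probabilities).
#' @param labels per-sample group labels, \code{"case"}/\code{"control"}.
#' @return An object of class \code{roc_result}: list with
#'   \code{thresholds} (descending, starting at \code{Inf}),
#'   \code{sensitivity}, \code{specificity}, \code{auc}, and the sorted
#'   distinct scores.
#' @examples
#' roc_curve(c(3, 5, 1, 4), c("case", "case", "control", "control"))$auc  # 0.75
#' @export
roc_curve <- function(values, labels) {
  labels <- as.character(labels)
  if (length(values) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  is_case <- labels == "case"
  if (!any(is_case) || all(is_case)) stop("both classes must be present")
  cutpoints <- sort(unique(values), decreasing = TRUE)
  thresholds <- c(Inf, cutpoints)
  sens <- vapply(thresholds, function(t) mean(values[is_case] >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(values[!is_case] < t), numeric(1))
  # trapezoid over (1 - specificity, sensitivity)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc, cutpoints = cutpoints),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: ", length(x$thresholds), " operating points, AUC = ",
      sprintf("%.3f", x$auc), "\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(1 - x$specificity, x$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Select a classifying threshold by Youden's J
#'
#' Scans the ROC operating points for the maximum of
#' J = sensitivity + specificity - 1 (the best combination of sensitivity
#' and specificity). Ties are broken by higher specificity, then by higher
#' threshold. The returned threshold is placed at the midpoint between the
#' adjacent distinct scores the chosen operating point separates, so any
#' score strictly between them classifies identically.
#'
#' @param roc a \code{roc_result}.
#' @return List with \code{threshold}, \code{sensitivity},
#'   \code{specificity}, \code{j}, and logical \code{degenerate} (TRUE when
#'   all scores are identical, in which case J = 0).
#' @export
select_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  s <- roc$cutpoints  # descending distinct scores
  # midpoint threshold realising each operating point
  mids <- c(s[1] + 1,                              # predict nothing
            if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
            s[length(s)] - 1)                      # predict everything
  j <- roc$sensitivity + roc$specificity - 1
  best <- order(-j, -roc$specificity, -mids)[1]
  list(threshold = mids[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       j = j[best],
       degenerate = length(s) == 1)
}

#' Confusion-matrix metrics of a single-marker threshold classifier
#'
#' Predicts case iff the compound's abundance is at least \code{threshold}
#' and scores the predictions against the true groups.
#'
#' @param pm a \code{profile_matrix} (typically the independent test
#'   cohort).
#' @param compound_id marker compound.
#' @param threshold classifying threshold (finite).
#' @return List with \code{accuracy}, \code{sensitivity},
#'   \code{specificity}.
#' @export
apply_threshold_classifier <- function(pm, compound_id, threshold) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (!compound_id %in% pm$compounds$compound_id)
    stop("unknown compound_id: ", compound_id)
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  pred_case <- pm$abundance[compound_id, ] >= threshold
  is_case <- pm$groups == "case"
  list(accuracy = mean(pred_case == is_case),
       sensitivity = mean(pred_case[is_case]),
       specificity = mean(!pred_case[!is_case]))
}

# Penalised logistic log-likelihood pieces in standardised feature space.
.logistic_irls <- function(Z, y, lambda, max_iter = 200, tol = 1e-10) {
  p_dim <- ncol(Z)
  beta <- numeric(p_dim + 1)          # intercept first, unpenalised
  Zi <- cbind(1, Z)
  pen <- c(0, rep(lambda, p_dim))
  obj <- function(b) {
    eta <- drop(Zi %*% b)
    -sum(y * eta - log1p(exp(eta))) + sum(pen * b^2) / 2
  }
  f_old <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(Zi %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Zi, mu - y)) + pen * beta
    if (sqrt(sum(grad^2)) < tol * max(1, sqrt(sum(beta^2))))
      return(list(beta = beta, iter = it, grad = grad, converged = TRUE))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Zi, Zi * w) + diag(pen, p_dim + 1)
    step <- solve(H, grad)
    # step-halving on the penalised objective
    alpha_step <- 1
    repeat {
      beta_new <- beta - alpha_step * step
      f_new <- obj(beta_new)
      if (is.finite(f_new) && f_new <= f_old + 1e-12) break
      alpha_step <- alpha_step / 2
      if (alpha_step < 1e-12) break
    }
    if (abs(f_old - f_new) < 1e-14 * max(1, abs(f_old))) {
      beta <- beta_new
      grad <- drop(crossprod(Zi, stats::plogis(drop(Zi %*% beta)) - y)) +
        pen * beta
      return(list(beta = beta, iter = it, grad = grad, converged = TRUE))
    }
    beta <- beta_new
    f_old <- f_new
  }
  grad <- drop(crossprod(Zi, stats::plogis(drop(Zi %*% beta)) - y)) + pen * beta
  list(beta = beta, iter = max_iter, grad = grad,
       converged = sqrt(sum(grad^2)) < 1e-6)
}

#' Fit a logistic-regression marker panel
#'
#' Fits a binomial GLM with logit link on the raw abundances of the given
#' markers, with an intercept and a small ridge penalty that keeps the fit
#' finite when the markers separate the cohorts (near-)perfectly. The
#' penalty is applied to the standardised coefficients, so its meaning does
#' not depend on the instrument's abundance units; reported coefficients
#' are on the raw abundance scale (log-odds per abundance unit).
#'
#' @param pm a discovery-cohort \code{profile_matrix}.
#' @param marker_ids character vector of compound ids to use as features.
#' @param ridge ridge strength; default \code{1e-6 * n} samples.
#' @param log1p_transform if TRUE, features enter as \code{log1p(abundance)}.
#' @return An object of class \code{marker_panel}: list with
#'   \code{marker_ids}, \code{intercept}, \code{coefficients} (named, raw
#'   scale), \code{ridge}, \code{log1p_transform}, \code{roc_train} (a
#'   \code{roc_result} on the discovery cohort), and fit diagnostics.
#' @export
fit_logistic_panel <- function(pm, marker_ids, ridge = NULL,
                               log1p_transform = FALSE) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (!length(marker_ids)) stop("need at least one marker")
  missing <- setdiff(marker_ids, pm$compounds$compound_id)
  if (length(missing))
    stop("marker(s) absent from matrix: ", paste(missing, collapse = ", "))
  X <- t(pm$abundance[marker_ids, , drop = FALSE])
  if (log1p_transform) X <- log1p(X)
  y <- as.numeric(pm$groups == "case")
  if (all(y == 1) || all(y == 0)) stop("both groups must be present")
  n <- nrow(X)
  if (is.null(ridge)) ridge <- 1e-6 * n

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  fit <- .logistic_irls(Z, y, lambda = ridge)
  if (!fit$converged)
    stop("logistic panel fit did not converge after bounded iterations ",
         "(penalised gradient norm ", format(sqrt(sum(fit$grad^2))), ")")
  beta_std <- fit$beta[-1]
  coefficients <- beta_std / scl
  intercept <- fit$beta[1] - sum(beta_std * ctr / scl)
  names(coefficients) <- marker_ids

  prob <- stats::plogis(intercept + drop(X %*% coefficients))
  structure(list(marker_ids = marker_ids, intercept = intercept,
                 coefficients = coefficients, ridge = ridge,
                 log1p_transform = log1p_transform,
                 roc_train = roc_curve(prob, as.character(pm$groups)),
                 iterations = fit$iter,
                 gradient_norm = sqrt(sum(fit$grad^2))),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("logistic marker panel: ", length(x$marker_ids), " marker(s), ridge = ",
      format(x$ridge), "\n", sep = "")
  cat(sprintf("  training AUC = %.3f\n", x$roc_train$auc))
  invisible(x)
}

#' @export
coef.marker_panel <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predicted case probabilities from a marker panel
#'
#' @param object a \code{marker_panel}.
#' @param pm a \code{profile_matrix} containing every panel marker.
#' @param ... unused.
#' @return Numeric vector of predicted case probabilities, one per sample.
#' @export
predict.marker_panel <- function(object, pm, ...) {
  stopifnot(inherits(pm, "profile_matrix"))
  missing <- setdiff(object$marker_ids, pm$compounds$compound_id)
  if (length(missing))
    stop("panel marker(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  X <- t(pm$abundance[object$marker_ids, , drop = FALSE])
  if (object$log1p_transform) X <- log1p(X)
  stats::plogis(object$intercept + drop(X %*% object$coefficients))
}

#' Evaluate a marker panel on an independent cohort
#'
#' @param model a \code{marker_panel}.
#' @param pm_test the independent-test \code{profile_matrix}.
#' @return A \code{roc_result} of the predicted probabilities against the
#'   test-cohort groups.
#' @export
evaluate_panel <- function(model, pm_test) {
  roc_curve(predict(model, pm_test), as.character(pm_test$groups))
}
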