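#' Shannon entropy of a repertoire
#'
#' Diversity of the clone-abundance distribution:
#' \eqn{-\sum_j q_j \log q_j} with \eqn{q_j = w_j / \sum_j w_j}.
#' Natural log by default; terms with q = 0 contribute 0. The entropy is
#' bounded by log(m) for m clones, with equality at equal abundances.
#'
#' @param rep A [repertoire()].
#' @param base Logarithm base (default `exp(1)`).
#' @return A single non-negative number.
#' @examples
#' shannon_entropy(repertoire("P1", c("CAF", "CVF", "CLF"), c(1, 1, 2)))
#' @export
shannon_entropy <- function(rep, base = exp(1)) {
  if (!length(rep$abundances)) stop("repertoire is empty")
  q <- rep$abundances / sum(rep$abundances)
  q <- q[q > 0]
  -sum(q * log(q, base = base))
}

#' Unpenalized GLM comparator
#'
#' The covariates-only baseline: an ordinary linear (continuous outcome)
#' or logistic (binary outcome) regression with an intercept. In real
#' data the design typically holds age, gender and Shannon entropy; in
#' simulations it holds the adjusting covariates only.
#'
#' @param y Outcome vector; binary 0/1 outcomes select the logistic
#'   model automatically unless `outcome_type` is given.
#' @param X Covariate matrix, or `NULL` for intercept-only.
#' @param outcome_type `"continuous"` or `"binary"` (default: inferred).
#' @return A `tcr_glm` object with a [predict.tcr_glm()] method.
#' @export
fit_basic_glm <- function(y, X = NULL, outcome_type = NULL) {
  outcome_type <- outcome_type %||%
    if (all(y %in% c(0, 1))) "binary" else "continuous"
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  }
  design <- cbind(`(Intercept)` = rep(1, length(y)), X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("collinear column(s) in design: ", paste(bad, collapse = ", "))
  }
  fit <- if (outcome_type == "binary")
    stats::glm.fit(design, y, family = stats::binomial())
  else stats::lm.fit(design, y)
  structure(list(coefficients = fit$coefficients,
                 outcome_type = outcome_type,
                 covariate_names = colnames(X)),
            class = "tcr_glm")
}

#' @param object A `tcr_glm`.
#' @param X_new Covariate matrix for new individuals.
#' @param type As in [predict.tcr_model()].
#' @param ... Unused.
#' @rdname fit_basic_glm
#' @export
predict.tcr_glm <- function(object, X_new = NULL,
                            type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  co <- object$coefficients
  lin <- if (length(co) > 1) {
    X_new <- as.matrix(X_new)
    drop(cbind(1, X_new) %*% co)
  } else {
    rep(co[1], if (is.null(X_new)) 1L else nrow(as.matrix(X_new)))
  }
  if (object$outcome_type == "continuous") return(unname(lin))
  switch(type,
         link = unname(lin),
         response = unname(logistic(lin)),
         class = unname(as.integer(logistic(lin) >= 0.5)))
}

#' Penalized k-mer regression comparators
#'
#' The lasso and ridge baselines: a penalized linear or logistic
#' regression of the outcome on the screened k-mer features, with the
#' intercept and any adjusting covariates left unpenalized. The penalty
#' weight is chosen by 10-fold cross-validation unless given.
#'
#' @param y Outcome vector (binary 0/1 selects logistic automatically).
#' @param X Optional covariate matrix (unpenalized).
#' @param Z A `tcr_features` object produced by [sis_screen()].
#' @param penalty `"lasso"` (L1) or `"ridge"` (L2).
#' @param lambda `"cv"` or a non-negative number (glmnet scale).
#' @param nfolds CV folds.
#' @param outcome_type `"continuous"`/`"binary"` (default inferred).
#' @return A `tcr_penalized` object with a predict method taking
#'   `X_new` and `Z_new`.
#' @export
fit_tcr_penalized <- function(y, X = NULL, Z, penalty = c("lasso", "ridge"),
                              lambda = "cv", nfolds = 10,
                              outcome_type = NULL) {
  penalty <- match.arg(penalty)
  outcome_type <- outcome_type %||%
    if (all(y %in% c(0, 1))) "binary" else "continuous"
  family <- if (outcome_type == "binary") "binomial" else "gaussian"
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  }
  r <- if (is.null(X)) 0L else ncol(X)
  design <- cbind(X, Z$values)
  pf <- c(rep(0, r), rep(1, ncol(Z$values)))
  a <- if (penalty == "lasso") 1 else 0
  if (identical(lambda, "cv")) {
    foldid <- sample(rep(seq_len(nfolds), length.out = length(y)))
    cv <- suppressWarnings(  # benign small-fold warnings at modest n
      glmnet::cv.glmnet(design, y, family = family, alpha = a,
                        penalty.factor = pf, standardize = FALSE,
                        foldid = foldid))
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(design, y, family = family, alpha = a,
                        lambda = lambda, penalty.factor = pf,
                        standardize = FALSE, thresh = 1e-12)
  co <- as.numeric(stats::coef(fit))
  names(co) <- c("(Intercept)", colnames(design))
  structure(list(beta0 = co[1],
                 beta = co[seq_len(r) + 1],
                 gamma = co[-seq_len(r + 1)],
                 penalty = penalty, lambda = lambda,
                 outcome_type = outcome_type,
                 feature_names = colnames(Z$values),
                 feature_scaling = Z$scaling),
            class = "tcr_penalized")
}

#' @param object A `tcr_penalized`.
#' @param X_new,Z_new Covariates and feature matrix (columns matching the
#'   training feature names) for new individuals.
#' @param type As in [predict.tcr_model()].
#' @param ... Unused.
#' @rdname fit_tcr_penalized
#' @export
predict.tcr_penalized <- function(object, X_new = NULL, Z_new,
                                  type = c("response", "link", "class"),
                                  ...) {
  type <- match.arg(type)
  if (inherits(Z_new, "tcr_features")) Z_new <- Z_new$values
  Z_new <- Z_new[, object$feature_names, drop = FALSE]
  lin <- object$beta0 + drop(Z_new %*% object$gamma)
  if (length(object$beta)) lin <- lin + drop(as.matrix(X_new) %*% object$beta)
  if (object$outcome_type == "continuous") return(unname(lin))
  switch(type,
         link = unname(lin),
         response = unname(logistic(lin)),
         class = unname(as.integer(logistic(lin) >= 0.5)))
}

#' Evaluate predictions against the truth
#'
#' Binary outcomes are scored by the classification error at threshold
#' 0.5 and the AUC computed from the Mann-Whitney rank statistic with
#' midranks for ties; continuous outcomes by the mean squared error.
#'
#' @param predictions Predicted probabilities (binary) or values
#'   (continuous).
#' @param truth Observed outcomes, aligned with `predictions`.
#' @param outcome_type `"binary"` or `"continuous"` (default inferred
#'   from `truth`).
#' @return An `eval_report` list with `outcome_type`, `n_test`, and
#'   either `classification_error` + `auc` or `mse`. A single-class
#'   truth makes the AUC undefined: it is reported as `NA` with a
#'   warning.
#' @examples
#' evaluate_predictions(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc  # 0.75
#' @export
evaluate_predictions <- function(predictions, truth, outcome_type = NULL) {
  stopifnot(length(predictions) == length(truth))
  outcome_type <- outcome_type %||%
    if (all(truth %in% c(0, 1))) "binary" else "continuous"
  if (outcome_type == "continuous") {
    rep <- list(outcome_type = "continuous",
                mse = mean((predictions - truth)^2),
                n_test = length(truth))
  } else {
    err <- mean(as.integer(predictions >= 0.5) != truth)
    n1 <- sum(truth == 1); n0 <- sum(truth == 0)
    if (n1 == 0L || n0 == 0L) {
      warning("AUC undefined: truth contains a single class")
      auc <- NA_real_
    } else {
      r <- rank(predictions)  # midranks
      auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    rep <- list(outcome_type = "binary", classification_error = err,
                auc = auc, n_test = length(truth))
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  if (x$outcome_type == "binary")
    cat(sprintf("<eval_report> binary, n = %d: error %.3f, AUC %.3f\n",
                x$n_test, x$classification_error, x$auc))
  else
    cat(sprintf("<eval_report> continuous, n = %d: MSE %.3f\n",
                x$n_test, x$mse))
  invisible(x)
}
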