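logistic <- function(x) 1 / (1 + exp(-x))

clip_prob <- function(p, eps = 1e-8) pmin(pmax(p, eps), 1 - eps)

# Ridge-type penalty for the kernel coefficient update, tied to the
# current model dimension: (p + r + 1) / n.
lambda_kernel <- function(p, r, n) (p + r + 1) / n

# Linearized pseudo-outcome for the logistic working response. The
# probabilities are trimmed at prob_clip so that both the IRLS weights
# (>= prob_clip*(1-prob_clip)) and the working residual (|y - p|/(p(1-p))
# <= 1/prob_clip) stay bounded: without trimming, one saturated
# misclassified point injects an arbitrarily large pseudo-observation,
# the kernel step absorbs it, and the alternating loop diverges.
working_response <- function(delta, y, prob_clip = 0.01) {
  p <- clip_prob(logistic(delta), prob_clip)
  delta + (y - p) / (p * (1 - p))
}

# L1-penalized (weighted) least squares / logistic step with the
# intercept and the first n_unpen columns unpenalized. `lambda` is the
# effective per-coefficient penalty on the remaining columns in the
# glmnet (1/2n) scale; glmnet's internal rescaling of penalty factors
# (to sum to nvars) and of weights (to mean 1) is neutralized so that
# the same `lambda` means the same amount of shrinkage regardless of
# how many features remain.
penalized_step <- function(design, resp, n_unpen, lambda, weights = NULL,
                           family = "gaussian") {
  p_pen <- ncol(design) - n_unpen
  if (p_pen == 0L) {
    X1 <- cbind(`(Intercept)` = 1, design)
    fit <- if (is.null(weights)) stats::lm.fit(X1, resp)
           else stats::lm.wfit(X1, resp, weights)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    return(list(beta0 = co[1], coefs = co[-1]))
  }
  pf <- c(rep(0, n_unpen), rep(1, p_pen))
  lam <- lambda * sum(pf) / length(pf)       # undo penalty.factor rescaling
  if (!is.null(weights)) lam <- lam / mean(weights)  # undo weight rescaling
  pad <- ncol(design) < 2L
  if (pad) {
    design <- cbind(design, ".pad." = rep(0, nrow(design)))
    pf <- c(pf, 0)
  }
  fit <- glmnet::glmnet(design, resp, family = family, lambda = lam,
                        weights = weights, penalty.factor = pf,
                        standardize = FALSE, thresh = 1e-12, maxit = 500000)
  co <- as.numeric(stats::coef(fit))
  names(co) <- c("(Intercept)", colnames(design))
  if (pad) co <- co[-length(co)]
  list(beta0 = co[1], coefs = co[-1])
}

# 10-fold CV for the first-iteration penalized regression; returns the
# effective per-coefficient penalty (see penalized_step).
cv_lambda <- function(design, resp, n_unpen, weights = NULL,
                      family = "gaussian", nfolds = 10) {
  p_pen <- ncol(design) - n_unpen
  if (p_pen == 0L) return(0)
  pf <- c(rep(0, n_unpen), rep(1, p_pen))
  n <- nrow(design)
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  cv <- suppressWarnings(  # benign small-fold warnings at modest n
    glmnet::cv.glmnet(design, resp, family = family, weights = weights,
                      penalty.factor = pf, standardize = FALSE,
                      foldid = foldid))
  lam <- cv$lambda.min
  lam <- lam * length(pf) / sum(pf)                   # to effective scale
  if (!is.null(weights)) lam <- lam * mean(weights)
  lam
}

check_design <- function(y, X, Z, K, n) {
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
    if (nrow(X) != n) stop("X must have one row per individual")
    if (!all(is.finite(X))) stop("non-finite values in X")
  }
  if (!all(is.finite(y))) stop("non-finite values in y")
  if (!inherits(Z, "tcr_features")) stop("Z must be a tcr_features object")
  if (nrow(Z$values) != n) stop("Z must be row-aligned with y")
  if (!all(is.finite(Z$values))) stop("non-finite values in Z")
  Km <- if (inherits(K, "tcr_kernel")) K$values else as.matrix(K)
  if (!all(dim(Km) == n)) stop("K must be n x n")
  list(X = X, Km = Km)
}

new_tcr_model <- function(...) structure(list(...), class = "tcr_model")

#' @export
print.tcr_model <- function(x, ...) {
  cat(sprintf(paste0("<tcr_model> %s outcome, n = %d\n",
                     "  %d selected k-mer(s), %d covariate(s), %d iteration(s)%s\n"),
              x$outcome_type, length(x$alpha), length(x$gamma),
              length(x$beta), x$n_iterations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Fit the semi-parametric repertoire model, continuous outcome
#'
#' Fits \eqn{E(Y_i) = \beta_0 + X_i^T\beta + Z_i^T\gamma + h(R_i)} where
#' the hidden-feature effect lives in the RKHS of the repertoire-homology
#' kernel, by minimizing the penalized least squares
#' \eqn{\sum_i (Y_i - \beta_0 - X_i^T\beta - Z_i^T\gamma - K_i^T\alpha)^2
#'  + \lambda_0 |\gamma|_1 + \lambda_1 \alpha^T K \alpha} with an
#' alternating scheme: (1) a lasso of the kernel-adjusted response on
#' \[X, Z\] with the intercept and covariates unpenalized, after which
#' only features with non-zero coefficients are retained; (2) the closed
#' form \eqn{\hat\alpha = (\lambda_1 I + K)^{-1}(Y - \hat\beta_0 -
#' X\hat\beta - Z\hat\gamma)} with \eqn{\lambda_1 = (p + r + 1)/n}
#' recomputed from the current support size; (3) the training MSE, whose
#' change drives convergence.
#'
#' @param y Numeric outcome vector.
#' @param X Optional n x r matrix of adjusting covariates (never
#'   penalized).
#' @param Z A `tcr_features` matrix, already prevalence-filtered,
#'   screened, and scaled.
#' @param K A PSD-projected `tcr_kernel` (or plain matrix), row-aligned
#'   with `y`.
#' @param lambda `"cv"` (10-fold cross-validation at the first iteration,
#'   then held fixed) or a non-negative number: the per-coefficient L1
#'   penalty on `gamma` in the glmnet `(1/2n)` objective scale.
#' @param eps Convergence tolerance on the change in training loss
#'   (default 1e-4).
#' @param max_iter Maximum number of outer iterations (default 20).
#' @param nfolds CV folds when `lambda = "cv"`.
#' @param repertoires Optional training repertoires to embed in the model
#'   so [predict.tcr_model()] can build cross-kernels itself.
#' @param seed Optional seed for the CV fold assignment.
#' @return A `tcr_model` with coefficients `beta0`, `beta`, `gamma`
#'   (named, selected support only), `alpha`, the per-iteration kernel
#'   penalties `lambda_kernel_history`, the `loss_trace`, and the
#'   metadata needed for prediction.
#' @export
fit_continuous <- function(y, X = NULL, Z, K, lambda = "cv", eps = 1e-4,
                           max_iter = 20, nfolds = 10, repertoires = NULL,
                           seed = NULL) {
  n <- length(y)
  ck <- check_design(y, X, Z, K, n)
  X <- ck$X; Km <- ck$Km
  r <- if (is.null(X)) 0L else ncol(X)
  if (!is.null(seed)) set.seed(seed)

  Zt <- Z$values
  alpha <- rep(0, n)
  mse_prev <- Inf
  lam_hist <- numeric(0); loss <- numeric(0); supp_hist <- integer(0)
  beta0 <- 0; beta <- stats::setNames(numeric(r), colnames(X))
  gamma <- stats::setNames(numeric(0), character(0))
  converged <- FALSE

  for (t in seq_len(max_iter)) {
    resp <- as.numeric(y - Km %*% alpha)
    design <- cbind(X, Zt)
    if (identical(lambda, "cv")) {
      lambda <- cv_lambda(design, resp, r, family = "gaussian",
                          nfolds = nfolds)
    }
    st <- penalized_step(design, resp, r, lambda)
    beta0 <- unname(st$beta0)
    beta <- st$coefs[seq_len(r)]
    gam_full <- st$coefs[seq_len(ncol(Zt)) + r]
    keep <- which(gam_full != 0)
    Zt <- Zt[, keep, drop = FALSE]
    gamma <- gam_full[keep]
    p_t <- length(keep)

    lam1 <- lambda_kernel(p_t, r, n)
    lin <- beta0 + (if (r) drop(X %*% beta) else 0) +
      (if (p_t) drop(Zt %*% gamma) else 0)
    alpha <- solve(lam1 * diag(n) + Km, y - lin)

    mse <- mean((y - lin - drop(Km %*% alpha))^2)
    lam_hist <- c(lam_hist, lam1)
    loss <- c(loss, mse)
    supp_hist <- c(supp_hist, p_t)
    if (abs(mse - mse_prev) <= eps) { converged <- TRUE; break }
    mse_prev <- mse
  }

  sel <- colnames(Zt)
  new_tcr_model(
    outcome_type = "continuous", beta0 = beta0, beta = beta,
    gamma = stats::setNames(as.numeric(gamma), sel),
    alpha = as.numeric(alpha), lambda_penalty = lambda,
    lambda_kernel_history = lam_hist, support_history = supp_hist,
    training_ids = rownames(Z$values),
    feature_scaling = if (!is.null(Z$scaling)) Z$scaling[sel] else
      stats::setNames(rep(1, length(sel)), sel),
    k = Z$k, weighted = Z$weighted,
    substitution = if (inherits(K, "tcr_kernel")) K$substitution else NA,
    gap_open = if (inherits(K, "tcr_kernel")) K$gap_open else 10,
    gap_extend = if (inherits(K, "tcr_kernel")) K$gap_extend else 1,
    normalized = if (inherits(K, "tcr_kernel")) K$normalized else TRUE,
    n_iterations = length(loss), converged = converged, loss_trace = loss,
    linear_predictor = drop(beta0 + (if (r) X %*% beta else 0) +
                              (if (length(sel)) Zt %*% gamma else 0) +
                              Km %*% alpha),
    training_repertoires = repertoires)
}

#' Fit the semi-parametric repertoire model, binary outcome
#'
#' Binary analogue of [fit_continuous()], minimizing the penalized
#' logistic deviance with \eqn{\lambda_2 |\gamma|_1} and an RKHS penalty
#' on the hidden effect. The optimization linearizes the likelihood with
#' the working response \eqn{Y_w = \Delta + (Y - \pi(\Delta)) /
#' (\pi(\Delta)(1 - \pi(\Delta)))} and iterates: (1) the working response
#' and IRLS weights \eqn{\nu_i = \pi(1-\pi)} at the current linear
#' predictor; (2) a weighted lasso of the kernel-adjusted working
#' response on \[X, Z\], shrinking the feature support; (3) the ridge-type
#' update \eqn{\hat\alpha = (\lambda I + \Omega^{1/2} K)^{-1}
#' \Omega^{1/2}(Y_w - \hat\beta_0 - X\hat\beta - Z\hat\gamma)} with
#' \eqn{\lambda = (p + r + 1)/n}; (4) the training cross-entropy, whose
#' change drives convergence. Initialization is an L1-penalized logistic
#' regression of Y on \[X, Z\] (covariates unpenalized).
#'
#' @inheritParams fit_continuous
#' @param y 0/1 outcome vector.
#' @param alpha_solver `"plain"` solves the update exactly as written
#'   (a generally nonsymmetric system); `"symmetric"` uses the
#'   symmetrized matrix \eqn{\lambda I + \Omega^{1/2} K \Omega^{1/2}},
#'   which is guaranteed well-posed.
#' @param prob_clip Trimming bound for the IRLS probabilities (default
#'   0.01): bounds the working response and weights, preventing a
#'   saturated misclassified observation from blowing up the kernel
#'   step. The cross-entropy is computed from untrimmed probabilities.
#' @return A `tcr_model`; `loss_trace` holds the per-iteration training
#'   cross-entropy.
#' @export
fit_binary <- function(y, X = NULL, Z, K, lambda = "cv", eps = 1e-4,
                       max_iter = 20, nfolds = 10,
                       alpha_solver = c("plain", "symmetric"),
                       prob_clip = 0.01, repertoires = NULL, seed = NULL) {
  alpha_solver <- match.arg(alpha_solver)
  n <- length(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  ck <- check_design(y, X, Z, K, n)
  X <- ck$X; Km <- ck$Km
  r <- if (is.null(X)) 0L else ncol(X)
  if (!is.null(seed)) set.seed(seed)

  Zt <- Z$values
  design <- cbind(X, Zt)
  if (identical(lambda, "cv"))
    lambda <- cv_lambda(design, y, r, family = "binomial", nfolds = nfolds)
  init <- penalized_step(design, y, r, lambda, family = "binomial")
  beta0 <- unname(init$beta0)
  beta <- init$coefs[seq_len(r)]
  gamma <- init$coefs[seq_len(ncol(Zt)) + r]

  alpha <- rep(0, n)
  h <- rep(0, n)
  e_prev <- Inf
  lam_hist <- numeric(0); loss <- numeric(0); supp_hist <- integer(0)
  converged <- FALSE

  for (t in seq_len(max_iter)) {
    lin_fixed <- beta0 + (if (r) drop(X %*% beta) else 0) +
      (if (ncol(Zt)) drop(Zt %*% gamma) else 0)
    delta <- lin_fixed + h
    pi_w <- clip_prob(logistic(delta), prob_clip)   # trimmed for IRLS
    yw <- delta + (y - pi_w) / (pi_w * (1 - pi_w))
    nu <- pi_w * (1 - pi_w)
    pi_d <- clip_prob(logistic(delta))              # untrimmed for the loss

    resp <- as.numeric(yw - Km %*% alpha)
    st <- penalized_step(cbind(X, Zt), resp, r, lambda, weights = nu)
    beta0 <- unname(st$beta0)
    beta <- st$coefs[seq_len(r)]
    gam_full <- st$coefs[seq_len(ncol(Zt)) + r]
    keep <- which(gam_full != 0)
    Zt <- Zt[, keep, drop = FALSE]
    gamma <- gam_full[keep]
    p_t <- length(keep)

    lam_t <- lambda_kernel(p_t, r, n)
    lin <- beta0 + (if (r) drop(X %*% beta) else 0) +
      (if (p_t) drop(Zt %*% gamma) else 0)
    sw <- sqrt(nu)
    resid <- yw - lin
    if (alpha_solver == "plain") {
      A <- lam_t * diag(n) + sw * Km      # row-scaled Omega^{1/2} K
      alpha <- solve(A, sw * resid)
    } else {
      A <- lam_t * diag(n) + sw * sweep(Km, 2, sw, "*")
      alpha <- solve(A, sw * resid)
    }
    h <- drop(Km %*% alpha)

    ce <- -mean(y * log(pi_d) + (1 - y) * log(1 - pi_d))
    lam_hist <- c(lam_hist, lam_t)
    loss <- c(loss, ce)
    supp_hist <- c(supp_hist, p_t)
    if (abs(ce - e_prev) <= eps) { converged <- TRUE; break }
    e_prev <- ce
  }

  sel <- colnames(Zt)
  new_tcr_model(
    outcome_type = "binary", beta0 = beta0, beta = beta,
    gamma = stats::setNames(as.numeric(gamma), sel),
    alpha = as.numeric(alpha), lambda_penalty = lambda,
    lambda_kernel_history = lam_hist, support_history = supp_hist,
    training_ids = rownames(Z$values),
    feature_scaling = if (!is.null(Z$scaling)) Z$scaling[sel] else
      stats::setNames(rep(1, length(sel)), sel),
    k = Z$k, weighted = Z$weighted,
    substitution = if (inherits(K, "tcr_kernel")) K$substitution else NA,
    gap_open = if (inherits(K, "tcr_kernel")) K$gap_open else 10,
    gap_extend = if (inherits(K, "tcr_kernel")) K$gap_extend else 1,
    normalized = if (inherits(K, "tcr_kernel")) K$normalized else TRUE,
    n_iterations = length(loss), converged = converged, loss_trace = loss,
    linear_predictor = drop(beta0 + (if (r) X %*% beta else 0) +
                              (if (length(sel)) Zt %*% gamma else 0) + h),
    training_repertoires = repertoires)
}

# Feature vectors for new repertoires, restricted to the model's selected
# k-mers and put on the training scale. A selected k-mer absent from a
# new repertoire contributes 0.
model_features <- function(model, repertoires) {
  sel <- names(model$gamma)
  Z <- matrix(0, length(repertoires), length(sel),
              dimnames = list(vapply(repertoires, function(r) r$individual_id,
                                     character(1)), sel))
  if (!length(sel)) return(Z)
  for (i in seq_along(repertoires)) {
    km <- extract_kmers(repertoires[[i]], model$k,
                        weight_by_abundance = model$weighted)
    hit <- intersect(names(km), sel)
    Z[i, hit] <- km[hit]
  }
  sweep(Z, 2, model$feature_scaling[sel], "/")
}

#' Predict outcomes for new individuals
#'
#' Computes \eqn{\hat\beta_0 + X^T\hat\beta + Z^T\hat\gamma +
#' K^T\hat\alpha} for each new individual, where Z holds the model's
#' selected k-mers extracted from the new repertoire (on the training
#' scale, 0 when absent) and K is the unprojected cross-kernel against
#' the training repertoires.
#'
#' @param object A fitted `tcr_model`.
#' @param X_new Covariate matrix for the new individuals (or `NULL` when
#'   the model has no covariates).
#' @param repertoires New repertoires; may be omitted when `Z_new` and
#'   `K_new` are supplied precomputed.
#' @param reps_train Training repertoires for the cross-kernel; defaults
#'   to the ones embedded at fit time.
#' @param Z_new,K_new Optional precomputed feature and cross-kernel
#'   matrices (rows = new individuals; `K_new` columns in training
#'   order).
#' @param type `"response"` (default: linear predictor for continuous
#'   models, probability for binary), `"link"` (linear predictor), or
#'   `"class"` (binary only; probability thresholded at 0.5).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.tcr_model <- function(object, X_new = NULL, repertoires = NULL,
                              reps_train = NULL, Z_new = NULL, K_new = NULL,
                              type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  if (is.null(Z_new)) {
    if (is.null(repertoires))
      stop("supply either repertoires or a precomputed Z_new")
    Z_new <- model_features(object, repertoires)
  }
  n_new <- nrow(Z_new)
  if (is.null(K_new)) {
    if (any(object$alpha != 0)) {
      reps_train <- reps_train %||% object$training_repertoires
      if (is.null(reps_train))
        stop("training repertoires are needed to build the cross-kernel")
      if (is.null(repertoires))
        stop("supply repertoires or a precomputed K_new")
      K_new <- kernel_cross(repertoires, reps_train, sub = object$substitution,
                            gap_open = object$gap_open,
                            gap_extend = object$gap_extend,
                            normalize = object$normalized)
    } else {
      K_new <- matrix(0, n_new, length(object$alpha))
    }
  }
  r <- length(object$beta)
  if (r) {
    X_new <- as.matrix(X_new)
    if (is.null(X_new) || ncol(X_new) != r)
      stop("X_new must have the model's ", r, " covariate column(s)")
  }
  lin <- object$beta0 +
    (if (r) drop(X_new %*% object$beta) else 0) +
    (if (length(object$gamma)) drop(Z_new %*% object$gamma) else 0) +
    drop(K_new %*% object$alpha)
  if (object$outcome_type == "continuous") return(unname(lin))
  switch(type,
         link = unname(lin),
         response = unname(logistic(lin)),
         class = unname(as.integer(logistic(lin) >= 0.5)))
}

#' Save / load a fitted model as a self-describing text file
#'
#' Serializes every coefficient, the selected k-mer names and their scale
#' factors, the penalty history and training ids to a versioned JSON
#' file. Training repertoires are referenced by path plus MD5 checksum,
#' never copied, so prediction can rebuild cross-kernels and detect a
#' swapped file.
#'
#' @param model A `tcr_model`.
#' @param path Output path.
#' @param repertoires_file Optional CSV of the training repertoires (as
#'   written by [write_repertoires()]) to reference.
#' @return `write_model()` returns `path` invisibly; `read_model()`
#'   returns a `tcr_model` (without in-memory training repertoires;
#'   use [load_training_repertoires()]).
#' @export
write_model <- function(model, path, repertoires_file = NULL) {
  obj <- model[setdiff(names(model), "training_repertoires")]
  for (f in c("beta", "gamma", "feature_scaling"))
    obj[[f]] <- as.list(obj[[f]])   # keep names in JSON
  obj$schema <- "tcrkern-model-1"
  if (!is.null(repertoires_file)) {
    obj$repertoires_file <- repertoires_file
    obj$repertoires_md5 <- unname(tools::md5sum(repertoires_file))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "tcrkern-model-1"))
    stop("unrecognized model schema")
  for (f in c("beta", "gamma", "feature_scaling"))
    obj[[f]] <- unlist(obj[[f]]) %||% stats::setNames(numeric(0), character(0))
  obj$schema <- NULL
  do.call(new_tcr_model, obj)
}

#' @param model A `tcr_model` read back by `read_model()`.
#' @rdname write_model
#' @export
load_training_repertoires <- function(model) {
  if (is.null(model$repertoires_file))
    stop("model carries no training-repertoire reference")
  if (!file.exists(model$repertoires_file))
    stop("training repertoire file not found: ", model$repertoires_file)
  md5 <- unname(tools::md5sum(model$repertoires_file))
  if (!identical(md5, model$repertoires_md5))
    stop("training repertoire checksum mismatch: file has changed since fitting")
  read_repertoires(model$repertoires_file, format = "csv")
}
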