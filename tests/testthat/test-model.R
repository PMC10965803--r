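test_that("kernel-ridge penalty rule and working response evaluate exactly", {
  expect_equal(tcrkern:::lambda_kernel(6, 1, 500), 0.016)
  expect_equal(tcrkern:::working_response(0, 1), 2)
  expect_equal(tcrkern:::working_response(0, 0), -2)
  expect_equal(tcrkern:::logistic(0), 0.5)
})

test_that("closed-form kernel coefficients equal a numerical minimizer", {
  for (s in 1:3) {
    K <- random_psd(5, seed = 40 + s)
    set.seed(50 + s)
    res <- rnorm(5)
    lam <- 0.3
    a_closed <- solve(lam * diag(5) + K, res)
    obj <- function(a) sum((res - K %*% a)^2) + lam * drop(t(a) %*% K %*% a)
    grad <- function(a) drop(-2 * t(K) %*% (res - K %*% a) + 2 * lam * K %*% a)
    opt <- optim(rep(0, 5), obj, grad, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-16))
    expect_equal(unname(a_closed), opt$par, tolerance = 1e-6)
    # stationarity of the closed form: K(res - K a) = lam K a
    expect_equal(K %*% (res - K %*% a_closed), lam * K %*% a_closed,
                 tolerance = 1e-8)
  }
})

test_that("continuous fit recovers a pure linear signal with an inert kernel", {
  set.seed(61)
  n <- 200
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "X1"))
  y <- 2 - X[, 1] + rnorm(n, sd = 0.5)
  Z <- as_features(matrix(rnorm(n * 15), n,
                          dimnames = list(NULL, sprintf("z%02d", 1:15))))
  K0 <- matrix(0, n, n)
  fit <- fit_continuous(y, X, Z, K0, lambda = "cv", seed = 62)
  expect_equal(fit$beta0, 2, tolerance = 0.25)
  expect_equal(unname(fit$beta["X1"]), -1, tolerance = 0.25)
  expect_lt(sum(abs(fit$gamma)), 0.2)          # noise features stay near zero
  expect_equal(unname(drop(K0 %*% fit$alpha)), rep(0, n))  # no hidden effect
})

test_that("support only shrinks across iterations and the lasso satisfies KKT", {
  set.seed(63)
  n <- 120
  Zm <- matrix(rnorm(n * 12), n, dimnames = list(NULL, sprintf("z%02d", 1:12)))
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "X1"))
  y <- 1 + 0.5 * X[, 1] + 1.5 * Zm[, 1] - 2 * Zm[, 2] + rnorm(n)
  K <- psd_project(random_psd(n, seed = 64) / 5)
  lam <- 0.05
  fit <- fit_continuous(y, X, as_features(Zm), K, lambda = lam, max_iter = 10)
  expect_true(all(diff(fit$support_history) <= 0))
  expect_true(all(c("z01", "z02") %in% names(fit$gamma)))
  expect_identical(length(fit$loss_trace), fit$n_iterations)

  # KKT for one lasso step at the returned lambda:
  # |(1/n) Z_j'(resp - eta)| <= lam, equality (sign-matched) on the support
  resp <- drop(y - K$values %*% fit$alpha)
  st <- tcrkern:::penalized_step(cbind(X, Zm), resp, 1, lam)
  gam <- st$coefs[-1]
  eta <- st$beta0 + X %*% st$coefs[1] + Zm %*% gam
  g <- drop(crossprod(Zm, resp - eta)) / n
  act <- which(gam != 0)
  expect_equal(unname(g[act]), lam * sign(unname(gam[act])), tolerance = 1e-6)
  expect_true(all(abs(g[-act]) <= lam + 1e-6))
})

test_that("with zero penalty and a scaled-identity kernel one iteration is OLS plus ridge", {
  set.seed(65)
  n <- 80
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("X1", "X2")))
  Zm <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(n)
  K <- 2 * diag(n)
  fit <- fit_continuous(y, X, as_features(Zm), K, lambda = 0, max_iter = 1)
  ols <- lm(y ~ X + Zm)
  expect_equal(fit$beta0, unname(coef(ols)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(coef(ols)[2:3]), tolerance = 1e-6)
  expect_equal(unname(fit$gamma), unname(coef(ols)[4:6]), tolerance = 1e-6)
  lam1 <- tcrkern:::lambda_kernel(3, 2, n)
  expect_equal(fit$alpha, unname(resid(ols)) / (lam1 + 2), tolerance = 1e-8)
})

test_that("binary fit with an inert kernel matches a direct penalized logistic fit", {
  set.seed(66)
  n <- 200
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("X1", "X2")))
  Zm <- matrix(rnorm(n * 10), n, dimnames = list(NULL, sprintf("z%02d", 1:10)))
  eta <- 0.5 + X[, 1] - 0.8 * X[, 2] + 1.2 * Zm[, 1] - 1.5 * Zm[, 3]
  y <- rbinom(n, 1, tcrkern:::logistic(eta))
  lam <- 0.02
  # untrimmed IRLS so the fixed point is exactly the penalized optimum
  fit <- fit_binary(y, X, as_features(Zm), matrix(0, n, n), lambda = lam,
                    eps = 1e-10, max_iter = 200, prob_clip = 1e-8)
  design <- cbind(X, Zm)
  pf <- c(0, 0, rep(1, 10))
  direct <- glmnet::glmnet(design, y, family = "binomial",
                           lambda = lam * sum(pf) / length(pf),
                           penalty.factor = pf, standardize = FALSE,
                           thresh = 1e-14)
  co <- as.numeric(coef(direct))
  expect_equal(fit$beta0, co[1], tolerance = 1e-4)
  expect_equal(unname(fit$beta), co[2:3], tolerance = 1e-4)
  gam_full <- setNames(rep(0, 10), colnames(Zm))
  gam_full[names(fit$gamma)] <- fit$gamma
  expect_equal(unname(gam_full), co[4:13], tolerance = 1e-4)
})

test_that("predictions recompute the linear predictor and ignore individual order", {
  pool <- small_pool(30, seed = 71)
  train <- pool[1:20]; test <- pool[21:30]
  Z <- quantile_scale(build_feature_matrix(train, k = 3))
  Z <- prevalence_filter(Z, 0.05)
  set.seed(72)
  y <- rnorm(20)
  Zs <- sis_screen(Z, y, d = 5)
  K <- psd_project(kernel_matrix(train))
  X <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "X1"))
  fit <- fit_continuous(y, X, Zs, K, lambda = 0.01, repertoires = train)

  Xn <- matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "X1"))
  pred <- predict(fit, X_new = Xn, repertoires = test)

  # independent recomputation of beta0 + X beta + Z gamma + K alpha
  Kc <- kernel_cross(test, train)
  Zn <- matrix(0, 10, length(fit$gamma),
               dimnames = list(NULL, names(fit$gamma)))
  for (i in 1:10) {
    km <- extract_kmers(test[[i]], 3)
    hit <- intersect(names(km), names(fit$gamma))
    Zn[i, hit] <- km[hit] / fit$feature_scaling[hit]
  }
  manual <- fit$beta0 + drop(Xn %*% fit$beta) + drop(Zn %*% fit$gamma) +
    drop(Kc %*% fit$alpha)
  expect_equal(pred, unname(manual), tolerance = 1e-10)

  # order invariance
  perm <- sample(10)
  pred_perm <- predict(fit, X_new = Xn[perm, , drop = FALSE],
                       repertoires = test[perm])
  expect_equal(pred_perm, pred[perm], tolerance = 1e-12)

  # a training individual predicts its own fitted value when K is PSD
  K_unproj <- kernel_matrix(train)
  if (min(eigen(K_unproj$values, symmetric = TRUE)$values) > 1e-10) {
    pred_tr <- predict(fit, X_new = X[3, , drop = FALSE],
                       repertoires = train[3])
    expect_equal(pred_tr, unname(fit$linear_predictor[3]), tolerance = 1e-8)
  }
})

test_that("models survive JSON serialization and verify repertoire checksums", {
  pool <- small_pool(12, seed = 75)
  Z <- quantile_scale(build_feature_matrix(pool, k = 3))
  set.seed(76)
  y <- rbinom(12, 1, 0.5)
  Zs <- sis_screen(Z, y, d = 4)
  K <- psd_project(kernel_matrix(pool))
  fit <- fit_binary(y, NULL, Zs, K, lambda = 0.05)

  reps_file <- tempfile(fileext = ".csv")
  write_repertoires(pool, reps_file)
  mf <- tempfile(fileext = ".json")
  write_model(fit, mf, repertoires_file = reps_file)
  back <- read_model(mf)
  expect_equal(back$beta0, fit$beta0)
  expect_equal(back$gamma, fit$gamma)
  expect_equal(back$alpha, fit$alpha, tolerance = 1e-12)

  tr <- load_training_repertoires(back)
  p1 <- predict(fit, repertoires = pool[1:2], reps_train = pool)
  p2 <- predict(back, repertoires = pool[1:2], reps_train = tr)
  expect_equal(p2, p1, tolerance = 1e-8)

  # tampering with the referenced file trips the checksum
  cat("X,Y,1\n", file = reps_file, append = TRUE)
  expect_error(load_training_repertoires(back), "checksum")
})
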