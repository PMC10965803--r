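# Interior-residue frequencies used by the pool generator: a fixed,
# skewed distribution reflecting the glycine/serine-rich composition of
# beta-chain CDR3 loops.
.CDR3_FREQ <- c(A = 0.07, C = 0.02, D = 0.04, E = 0.06, F = 0.04,
                G = 0.12, H = 0.02, I = 0.03, K = 0.03, L = 0.07,
                M = 0.02, N = 0.04, P = 0.04, Q = 0.06, R = 0.06,
                S = 0.11, T = 0.06, V = 0.04, W = 0.02, Y = 0.05)

#' Specification of a synthetic repertoire pool
#'
#' Describes CDR3-like repertoires: per-individual clone counts uniform
#' in a range, sequence lengths uniform in a range, sequences starting
#' with C and ending with F (configurable), interior residues drawn from
#' a skewed amino-acid distribution, and clone abundances following a
#' power law floored at 2 so the pool survives [filter_repertoires()]
#' by construction.
#'
#' Real repertoires are not mutually random: individuals share public
#' clonotypes and convergent motifs, which is what gives the
#' repertoire-homology kernel its between-individual structure. The
#' generator reproduces this with a global set of template sequences
#' preferentially used by latent individual clusters: a fraction of each
#' repertoire consists of lightly mutated template copies (0-2 interior
#' substitutions), the rest is private random sequence.
#'
#' @param n_individuals Pool size (default 1000).
#' @param clones_range Integer range of unique clones per individual
#'   (default `c(10, 60)`).
#' @param length_range Integer range of CDR3 lengths (default
#'   `c(8, 20)`).
#' @param zipf_exponent Power-law exponent of the abundance distribution
#'   (default 1.5).
#' @param max_abundance Upper end of the abundance support (default 50,
#'   the shallow range typical of RNA-seq-derived repertoires; raise for
#'   deeply sequenced repertoires). The lower end is fixed at 2.
#' @param prefix,suffix Character vectors of conserved flanking motifs
#'   emulating the V- and J-segment-encoded ends of the CDR3; one of each
#'   is drawn per clone with geometrically decreasing usage weights, so
#'   the flank-derived k-mers are frequent in every individual without
#'   being perfectly collinear. Use `""` to disable.
#' @param n_templates Number of global public-template sequences
#'   (default 150).
#' @param n_clusters Number of latent individual clusters with distinct
#'   template preferences (default 5).
#' @param public_fraction Fraction of each repertoire derived from
#'   templates (default 0.5); 0 gives fully private repertoires and a
#'   near-diagonal kernel.
#' @return A `pool_spec` list.
#' @export
synthetic_pool_spec <- function(n_individuals = 1000,
                                clones_range = c(10, 60),
                                length_range = c(8, 20),
                                zipf_exponent = 1.5,
                                prefix = c("CASS", "CASR", "CAST", "CAIS"),
                                suffix = c("QYF", "QFF", "EAFF", "YTF"),
                                n_templates = 150, n_clusters = 5,
                                public_fraction = 0.5, max_abundance = 50) {
  stopifnot(n_individuals >= 1, clones_range[1] >= 1,
            clones_range[2] >= clones_range[1],
            length_range[1] >= max(nchar(prefix)) + max(nchar(suffix)),
            length_range[2] >= length_range[1], zipf_exponent > 1,
            n_templates >= 1, n_clusters >= 1,
            public_fraction >= 0, public_fraction <= 1, max_abundance >= 2)
  structure(list(n_individuals = n_individuals, clones_range = clones_range,
                 length_range = length_range, zipf_exponent = zipf_exponent,
                 prefix = prefix, suffix = suffix,
                 n_templates = n_templates, n_clusters = n_clusters,
                 public_fraction = public_fraction,
                 max_abundance = max_abundance),
            class = "pool_spec")
}

#' Generate a synthetic repertoire pool
#'
#' Reproducible given the seed. Sequences within an individual are
#' unique; abundances are at least 2.
#'
#' @param spec A [synthetic_pool_spec()].
#' @param seed Integer seed.
#' @return List of `tcr_repertoire`.
#' @export
generate_pool <- function(spec, seed) {
  set.seed(seed)
  # sample() treats a length-1 vector as 1:x; draw from ranges safely
  rint <- function(lo, hi, n) if (lo == hi) rep(lo, n)
          else sample(lo:hi, n, replace = TRUE)
  ab_support <- 2:spec$max_abundance
  ab_prob <- ab_support^(-spec$zipf_exponent)
  aa <- names(.CDR3_FREQ)
  # geometrically decreasing usage weights over the flank motif pools
  gw <- function(k) 2^-(seq_len(k) - 1)
  draw_parts <- function(n) {
    pre <- sample(spec$prefix, n, replace = TRUE, prob = gw(length(spec$prefix)))
    suf <- sample(spec$suffix, n, replace = TRUE, prob = gw(length(spec$suffix)))
    L <- rint(spec$length_range[1], spec$length_range[2], n)
    blen <- pmax(0L, L - nchar(pre) - nchar(suf))
    body <- vapply(blen, function(l)
      paste(sample(aa, l, replace = TRUE, prob = .CDR3_FREQ), collapse = ""),
      character(1))
    data.frame(pre = pre, body = body, suf = suf, stringsAsFactors = FALSE)
  }
  # public templates and per-cluster template preferences
  templates <- draw_parts(spec$n_templates)
  cluster_w <- matrix(stats::rgamma(spec$n_clusters * spec$n_templates, 0.3),
                      spec$n_clusters, spec$n_templates)
  instantiate <- function(rows) {
    # copy a template with 0-2 interior substitutions
    vapply(rows, function(t) {
      body <- strsplit(templates$body[t], "")[[1]]
      n_mut <- sample(0:2, 1)
      if (n_mut > 0 && length(body)) {
        pos <- sample(length(body), min(n_mut, length(body)))
        body[pos] <- sample(aa, length(pos), replace = TRUE,
                            prob = .CDR3_FREQ)
      }
      paste0(templates$pre[t], paste(body, collapse = ""), templates$suf[t])
    }, character(1))
  }
  random_seq <- function(n) {
    p <- draw_parts(n)
    paste0(p$pre, p$body, p$suf)
  }
  out <- vector("list", spec$n_individuals)
  for (i in seq_len(spec$n_individuals)) {
    m <- rint(spec$clones_range[1], spec$clones_range[2], 1)
    cl <- sample.int(spec$n_clusters, 1)
    n_pub <- round(spec$public_fraction * m)
    seqs <- character(0)
    tries <- 0L
    while (length(seqs) < m) {
      n_pub_left <- max(0L, n_pub - length(seqs))   # fill public first
      n_priv_left <- (m - length(seqs)) - n_pub_left
      new <- c(
        if (n_pub_left > 0)
          instantiate(sample.int(spec$n_templates, n_pub_left,
                                 replace = TRUE, prob = cluster_w[cl, ])),
        if (n_priv_left > 0) random_seq(n_priv_left))
      seqs <- unique(c(seqs, new))
      tries <- tries + 1L
      if (tries > 100L)
        stop("cannot generate ", m, " unique sequences under this spec")
    }
    ab <- sample(ab_support, m, replace = TRUE, prob = ab_prob)
    out[[i]] <- repertoire(sprintf("S%05d", i), seqs, ab)
  }
  out
}

#' Configuration of one simulated prediction experiment
#'
#' Collects every generative parameter: cohort sizes, the k-mer length
#' used both to generate and to analyze, the causal-effect scale c0
#' (coefficients of the `n_causal` most frequent k-mers drawn from
#' c0 * Uniform(-1, 1)), the hidden-effect scale tau (hidden effects
#' drawn from N(0, tau * K)), the substitution matrix behind the
#' generating kernel, the fixed covariate effects, and the binary
#' case-proportion acceptance bounds.
#'
#' @param n_train,n_test Cohort sizes (defaults 500/500).
#' @param k k-mer length (default 3).
#' @param c0 Causal-coefficient scale (default 1).
#' @param tau Hidden-effect scale (default 5).
#' @param substitution `"BLOSUM62"` or `"PAM250"`.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param n_causal Number of causal k-mers (default 6).
#' @param beta0,beta1 Intercept and covariate coefficient (defaults 2
#'   and -1).
#' @param n_replicates Replicates for [run_benchmark()] (default 500).
#' @param seed Integer master seed.
#' @param pool_size Pool size when the benchmark generates its own pool.
#' @param case_prop_bounds Accepted case-proportion interval for binary
#'   replicates (default `c(0.3, 0.7)`).
#' @param continuous_noise_sd Residual SD for continuous outcomes
#'   (default 1).
#' @param max_redraws Binary-outcome redraw limit (default 100).
#' @param rank_causal_after_scaling Rank candidate causal k-mers by
#'   post-scaling column sums instead of raw counts (default `FALSE`:
#'   "most frequent" means largest raw count; quantile scaling can
#'   inflate sparse columns and would turn the ranking into "most
#'   heterogeneous").
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_train = 500, n_test = 500, k = 3, c0 = 1,
                              tau = 5, substitution = "BLOSUM62",
                              outcome_type = c("binary", "continuous"),
                              n_causal = 6, beta0 = 2, beta1 = -1,
                              n_replicates = 500, seed = 1,
                              pool_size = 1000,
                              case_prop_bounds = c(0.3, 0.7),
                              continuous_noise_sd = 1, max_redraws = 100,
                              rank_causal_after_scaling = FALSE) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(n_train >= 1, n_test >= 0, k >= 1, c0 >= 0, tau >= 0,
            n_causal >= 1, n_replicates >= 1, pool_size >= n_train + n_test,
            case_prop_bounds[1] > 0, case_prop_bounds[2] < 1,
            case_prop_bounds[1] < case_prop_bounds[2],
            continuous_noise_sd >= 0)
  structure(list(n_train = n_train, n_test = n_test, k = k, c0 = c0,
                 tau = tau, substitution = substitution,
                 outcome_type = outcome_type, n_causal = n_causal,
                 beta0 = beta0, beta1 = beta1, n_replicates = n_replicates,
                 seed = seed, pool_size = pool_size,
                 case_prop_bounds = case_prop_bounds,
                 continuous_noise_sd = continuous_noise_sd,
                 max_redraws = max_redraws,
                 rank_causal_after_scaling = rank_causal_after_scaling),
            class = "sim_config")
}

# Draw h ~ N(0, tau * K) through the truncated eigen factorization of the
# PSD-projected kernel.
draw_hidden_effects <- function(Kp, tau) {
  if (tau == 0) return(rep(0, nrow(Kp$values)))
  ev <- Kp$eigen$values
  U <- Kp$eigen$vectors
  drop(U %*% (sqrt(tau * ev) * stats::rnorm(length(ev))))
}

#' Simulate one train/test dataset from a repertoire pool
#'
#' Samples `n_train + n_test` repertoires from the pool without
#' replacement, draws one standard-normal adjusting covariate, builds
#' the quantile-scaled k-mer matrix, assigns causal coefficients
#' c0 * U(-1, 1) to the `n_causal` most frequent k-mers (largest
#' post-scaling column sums, ties lexicographic), computes and projects
#' the homology kernel, draws hidden effects from N(0, tau K), and
#' generates the outcome. Binary replicates are redrawn from scratch
#' until the case proportion falls inside the configured bounds.
#'
#' @param cfg A [simulation_config()].
#' @param pool List of `tcr_repertoire` (at least `n_train + n_test`).
#' @param seed Replicate seed.
#' @param kernel_cache Optional [pool_kernel_cache()] over `pool`
#'   matching `cfg$substitution`, to avoid re-aligning repeated pairs
#'   across replicates.
#' @return A list with elements `y`, `X`, `repertoires`, `ids`, `Z`
#'   (joint `tcr_features`), `K` (joint PSD-projected `tcr_kernel`,
#'   `NULL` when `tau = 0`), `train_idx`, `test_idx`, `pool_idx`, and
#'   `truth` (causal names, gamma, hidden effects, beta0, beta1).
#' @export
simulate_dataset <- function(cfg, pool, seed, kernel_cache = NULL) {
  set.seed(seed)
  n <- cfg$n_train + cfg$n_test
  if (length(pool) < n) stop("pool smaller than n_train + n_test")
  for (attempt in seq_len(cfg$max_redraws)) {
    idx <- sample(length(pool), n)
    reps <- pool[idx]
    X1 <- stats::rnorm(n)
    Zraw <- build_feature_matrix(reps, cfg$k)
    Z <- quantile_scale(Zraw, q = 0.75)
    rank_on <- if (cfg$rank_causal_after_scaling) Z$values else Zraw$values
    ord <- order(-colSums(rank_on), colnames(Z$values))
    causal <- colnames(Z$values)[ord[seq_len(cfg$n_causal)]]
    gamma <- cfg$c0 * stats::runif(cfg$n_causal, -1, 1)
    if (cfg$tau > 0) {
      K <- if (!is.null(kernel_cache)) cached_kernel(kernel_cache, idx)
           else kernel_matrix(reps, sub = cfg$substitution)
      Kp <- psd_project(K)
    } else Kp <- NULL
    h <- if (is.null(Kp)) rep(0, n) else draw_hidden_effects(Kp, cfg$tau)
    lin <- cfg$beta0 + cfg$beta1 * X1 +
      drop(Z$values[, causal, drop = FALSE] %*% gamma) + h
    if (cfg$outcome_type == "continuous") {
      y <- lin + stats::rnorm(n, sd = cfg$continuous_noise_sd)
      ok <- TRUE
    } else {
      y <- stats::rbinom(n, 1, logistic(lin))
      prop <- mean(y)
      ok <- prop >= cfg$case_prop_bounds[1] && prop <= cfg$case_prop_bounds[2]
    }
    if (ok) {
      return(list(
        y = y, X = matrix(X1, ncol = 1, dimnames = list(NULL, "X1")),
        repertoires = reps,
        ids = vapply(reps, function(r) r$individual_id, character(1)),
        Z = Z, K = Kp,
        train_idx = seq_len(cfg$n_train),
        test_idx = if (cfg$n_test) cfg$n_train + seq_len(cfg$n_test)
                   else integer(0),
        pool_idx = idx,
        truth = list(causal = causal, gamma = gamma, h = h,
                     beta0 = cfg$beta0, beta1 = cfg$beta1)))
    }
  }
  stop("case proportion outside bounds after ", cfg$max_redraws,
       " redraws; adjust c0/beta0 or the bounds")
}

screen_features <- function(Z, y_train, train_idx, min_prevalence = 0.05,
                            d = NULL) {
  Zp <- prevalence_filter(Z, min_prevalence)
  Ztr <- subset_features(Zp, colnames(Zp$values))
  Ztr$values <- Ztr$values[train_idx, , drop = FALSE]
  d <- d %||% sis_dimension(length(train_idx))
  sel <- colnames(sis_screen(Ztr, y_train, d = d)$values)
  subset_features(Zp, sel)
}

fit_one_method <- function(method, sim, Zs, caches, cfg) {
  tr <- sim$train_idx; te <- sim$test_idx
  y_tr <- sim$y[tr]
  X_tr <- sim$X[tr, , drop = FALSE]
  X_te <- sim$X[te, , drop = FALSE]
  Z_tr <- subset_features(Zs, colnames(Zs$values)); Z_tr$values <- Zs$values[tr, , drop = FALSE]
  Z_te <- Zs$values[te, , drop = FALSE]
  if (method == "basic_glm") {
    fit <- fit_basic_glm(y_tr, X_tr, outcome_type = cfg$outcome_type)
    return(predict(fit, X_te))
  }
  if (method %in% c("tcr_lasso", "tcr_ridge")) {
    fit <- fit_tcr_penalized(y_tr, X_tr, Z_tr,
                             penalty = sub("tcr_", "", method),
                             outcome_type = cfg$outcome_type)
    return(predict(fit, X_te, Z_te))
  }
  sub_name <- switch(method, tcrpred_B = "BLOSUM62", tcrpred_P = "PAM250",
                     stop("unknown method: ", method))
  Kjoint <- cached_kernel(caches[[sub_name]], sim$pool_idx)
  Ktr <- psd_project(new_kernel(Kjoint$values[tr, tr, drop = FALSE],
                                Kjoint$individual_ids[tr], sub_name,
                                Kjoint$gap_open, Kjoint$gap_extend,
                                Kjoint$normalized))
  Kcross <- Kjoint$values[te, tr, drop = FALSE]
  fit <- if (cfg$outcome_type == "binary")
    fit_binary(y_tr, X_tr, Z_tr, Ktr)
  else fit_continuous(y_tr, X_tr, Z_tr, Ktr)
  Zsel <- Z_te[, names(fit$gamma), drop = FALSE]
  predict(fit, X_new = X_te, Z_new = Zsel, K_new = Kcross)
}

#' Benchmark prediction methods on simulated cohorts
#'
#' For each replicate: simulate a train/test dataset with
#' [simulate_dataset()], screen the k-mer features (5% prevalence, then
#' sure-independence screening to floor(n/(2 log n)) using training rows
#' only), fit each requested method on the training half, and score the
#' held-out half. Kernels are cached at the pool level so each pair of
#' pool individuals is aligned at most once per substitution matrix.
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()] with `n_test >= 1`.
#' @param methods Subset of `c("basic_glm", "tcr_lasso", "tcr_ridge",
#'   "tcrpred_B", "tcrpred_P")` (the last two are the semi-parametric
#'   kernel models under BLOSUM62 and PAM250).
#' @param pool Optional pool; generated from
#'   [synthetic_pool_spec()]`(cfg$pool_size)` when `NULL`.
#' @param caches Optional named list of [pool_kernel_cache()] objects
#'   (names `"BLOSUM62"`/`"PAM250"`); built on demand when `NULL`.
#' @param verbose Print per-replicate progress.
#' @return A `benchmark_report`: list with `per_replicate` and
#'   `aggregate` data frames (mean metrics per method).
#' @export
run_benchmark <- function(cfg,
                          methods = c("basic_glm", "tcr_lasso", "tcr_ridge",
                                      "tcrpred_B", "tcrpred_P"),
                          pool = NULL, caches = NULL, verbose = FALSE) {
  stopifnot(cfg$n_test >= 1)
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max, cfg$n_replicates)
  if (is.null(pool))
    pool <- generate_pool(synthetic_pool_spec(cfg$pool_size),
                          seed = rep_seeds[1] %% 100000L + 1L)
  need_subs <- unique(c(
    if (cfg$tau > 0) cfg$substitution,
    if ("tcrpred_B" %in% methods) "BLOSUM62",
    if ("tcrpred_P" %in% methods) "PAM250"))
  if (is.null(caches)) caches <- list()
  for (s in setdiff(need_subs, names(caches)))
    caches[[s]] <- pool_kernel_cache(pool, sub = s)

  rows <- list()
  for (rep_i in seq_len(cfg$n_replicates)) {
    sim <- simulate_dataset(cfg, pool, seed = rep_seeds[rep_i],
                            kernel_cache = caches[[cfg$substitution]])
    Zs <- screen_features(sim$Z, sim$y[sim$train_idx], sim$train_idx)
    y_te <- sim$y[sim$test_idx]
    for (m in methods) {
      pred <- tryCatch(fit_one_method(m, sim, Zs, caches, cfg),
                       error = function(e)
                         stop("replicate ", rep_i, ", method ", m, ": ",
                              conditionMessage(e)))
      ev <- evaluate_predictions(pred, y_te, cfg$outcome_type)
      rows[[length(rows) + 1L]] <- if (cfg$outcome_type == "binary")
        data.frame(replicate = rep_i, method = m,
                   classification_error = ev$classification_error,
                   auc = ev$auc)
      else data.frame(replicate = rep_i, method = m, mse = ev$mse)
    }
    if (verbose) message("replicate ", rep_i, "/", cfg$n_replicates)
  }
  per_rep <- do.call(rbind, rows)
  metrics <- setdiff(names(per_rep), c("replicate", "method"))
  agg <- stats::aggregate(per_rep[metrics], by = list(method = per_rep$method),
                          FUN = mean, na.rm = TRUE)
  agg <- agg[match(methods, agg$method), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(per_replicate = per_rep, aggregate = agg,
                 outcome_type = cfg$outcome_type),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %s outcome, %d replicate(s)\n",
              x$outcome_type, max(x$per_replicate$replicate)))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report to CSV
#'
#' One row per method per replicate plus one aggregate row per method
#' (replicate = NA).
#'
#' @param report A `benchmark_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(report, path) {
  agg <- cbind(replicate = NA, report$aggregate)
  utils::write.csv(rbind(report$per_replicate, agg), path, row.names = FALSE)
  invisible(path)
}
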