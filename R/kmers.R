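#' Extract k-mer counts from one repertoire
#'
#' Slides a window of length `k` along every CDR3 sequence (a sequence of
#' length L contributes its L - k + 1 contiguous k-mers, none if L < k)
#' and aggregates counts across the repertoire. With abundance weighting
#' (the default) each occurrence contributes the clone's abundance, so a
#' k-mer's count reflects how many cells carry it, not merely how many
#' distinct clones.
#'
#' @param rep A [repertoire()].
#' @param k k-mer length, between 1 and 10.
#' @param weight_by_abundance Multiply each occurrence by the clone
#'   abundance (default `TRUE`).
#' @return Named numeric vector of k-mer counts (possibly empty).
#' @examples
#' r <- repertoire("P1", c("CASSF", "CAWSF"), c(5, 1))
#' extract_kmers(r, 3, weight_by_abundance = FALSE)
#' @export
extract_kmers <- function(rep, k, weight_by_abundance = TRUE) {
  stopifnot(k >= 1, k <= 10)
  counts <- new.env(parent = emptyenv())
  tot <- numeric(0)
  kmers <- character(0); wts <- numeric(0)
  for (j in seq_along(rep$sequences)) {
    s <- rep$sequences[j]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    kmers <- c(kmers, km)
    w <- if (weight_by_abundance) rep$abundances[j] else 1
    wts <- c(wts, rep(w, length(km)))
  }
  if (!length(kmers)) return(stats::setNames(numeric(0), character(0)))
  out <- vapply(split(wts, kmers), sum, numeric(1))
  out[order(names(out))]
}

new_feature_matrix <- function(values, k, weighted, scaling = NULL) {
  structure(list(values = values, k = k, weighted = weighted,
                 scaling = scaling),
            class = "tcr_features")
}

#' @export
print.tcr_features <- function(x, ...) {
  cat(sprintf("<tcr_features> %d individuals x %d %d-mers (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$k,
              if (x$weighted) "abundance-weighted" else "unweighted",
              if (is.null(x$scaling)) "unscaled" else "scaled"))
  invisible(x)
}

#' Build the k-mer feature matrix for a cohort
#'
#' Columns are the union of all k-mers observed in any repertoire, sorted
#' lexicographically; row i holds the counts of repertoire i (zero where
#' a k-mer is absent). Row order follows the input repertoire order,
#' which is expected to be the canonical order from [align_cohort()].
#'
#' @inheritParams extract_kmers
#' @param reps List of `tcr_repertoire`.
#' @return A `tcr_features` object with fields `values` (matrix with
#'   individual ids as rownames, k-mers as colnames), `k`, `weighted`,
#'   and `scaling` (NULL until [quantile_scale()] is applied).
#' @export
build_feature_matrix <- function(reps, k, weight_by_abundance = TRUE) {
  if (!length(reps)) stop("at least one repertoire is required")
  per <- lapply(reps, extract_kmers, k = k,
                weight_by_abundance = weight_by_abundance)
  all_kmers <- sort(unique(unlist(lapply(per, names))))
  if (!length(all_kmers))
    stop("no k-mers observed: all sequences shorter than k = ", k)
  ids <- vapply(reps, function(r) r$individual_id, character(1))
  Z <- matrix(0, nrow = length(reps), ncol = length(all_kmers),
              dimnames = list(ids, all_kmers))
  for (i in seq_along(per)) {
    if (length(per[[i]])) Z[i, names(per[[i]])] <- per[[i]]
  }
  new_feature_matrix(Z, k = k, weighted = weight_by_abundance)
}

#' Scale feature columns by an upper quantile
#'
#' Divides each column by its q-th quantile (type-7, the linear
#' interpolation between order statistics used by [stats::quantile()]),
#' computed over all entries or over the non-zero entries only. Columns
#' whose quantile is zero fall back to division by the column maximum,
#' and to a factor of 1 when the column is all zero. The per-column
#' factors are recorded (and composed across repeated calls) so that
#' prediction-time features can be put on the training scale.
#'
#' @param fm A `tcr_features` object.
#' @param q Quantile level, default 0.75.
#' @param nonzero_only Use only non-zero entries when computing the
#'   quantile (the convention for sparse real-data matrices).
#' @return The rescaled `tcr_features`, with updated `scaling`.
#' @export
quantile_scale <- function(fm, q = 0.75, nonzero_only = FALSE) {
  Z <- fm$values
  if (!length(Z)) stop("empty feature matrix")
  factors <- apply(Z, 2, function(col) {
    v <- if (nonzero_only) col[col > 0] else col
    s <- if (length(v)) stats::quantile(v, q, names = FALSE, type = 7) else 0
    if (s == 0) s <- max(col)
    if (s == 0) s <- 1
    s
  })
  Zs <- sweep(Z, 2, factors, "/")
  prev <- fm$scaling %||% stats::setNames(rep(1, ncol(Z)), colnames(Z))
  new_feature_matrix(Zs, fm$k, fm$weighted,
                     scaling = stats::setNames(prev * factors, colnames(Z)))
}

#' Drop k-mers seen in too few individuals
#'
#' Keeps columns whose fraction of individuals with a non-zero entry is
#' at least `min_prevalence` (boundary included).
#'
#' @param fm A `tcr_features` object.
#' @param min_prevalence Minimum prevalence, default 0.05.
#' @return The filtered `tcr_features`.
#' @export
prevalence_filter <- function(fm, min_prevalence = 0.05) {
  prev <- colMeans(fm$values > 0)
  keep <- prev >= min_prevalence
  if (!any(keep))
    stop("prevalence filter removed every k-mer; lower min_prevalence")
  subset_features(fm, colnames(fm$values)[keep])
}

subset_features <- function(fm, feature_names) {
  new_feature_matrix(fm$values[, feature_names, drop = FALSE], fm$k,
                     fm$weighted,
                     scaling = if (!is.null(fm$scaling)) fm$scaling[feature_names])
}

#' Sure-independence screening of k-mer features
#'
#' Ranks columns by the absolute Pearson correlation of the column with
#' the outcome (binary outcomes treated as 0/1 numeric) and keeps the top
#' `d`. Zero-variance columns get correlation 0 and rank last; ties are
#' broken lexicographically by k-mer name. The default dimension is the
#' customary floor(n / (2 log n)) with the natural log.
#'
#' @param fm A `tcr_features` object.
#' @param y Outcome vector aligned with the rows of `fm`.
#' @param d Number of features to keep; default `floor(n / (2 * log(n)))`.
#' @return The screened `tcr_features`, columns ordered by decreasing
#'   marginal association.
#' @export
sis_screen <- function(fm, y, d = NULL) {
  n <- nrow(fm$values)
  if (length(y) != n) stop("y must align with the rows of the feature matrix")
  if (is.null(d)) d <- floor(n / (2 * log(n)))
  if (d < 1) stop("d must be >= 1")
  cors <- suppressWarnings(abs(as.numeric(stats::cor(fm$values, as.numeric(y)))))
  cors[is.na(cors)] <- 0
  ord <- order(-cors, colnames(fm$values))
  keep <- ord[seq_len(min(d, length(ord)))]
  subset_features(fm, colnames(fm$values)[keep])
}

#' Default screening dimension
#'
#' The moderate dimension floor(n / (2 log n)) customarily used by
#' sure-independence screening (natural log).
#'
#' @param n Sample size.
#' @return Integer screening dimension.
#' @examples
#' sis_dimension(500)  # 40
#' @export
sis_dimension <- function(n) floor(n / (2 * log(n)))

#' Export / import a feature matrix as CSV
#'
#' The header row holds the k-mer names; the first column is the
#' individual id.
#'
#' @param fm A `tcr_features` object.
#' @param path File path.
#' @param k,weighted Metadata to attach on import.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns a `tcr_features`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(individual_id = rownames(fm$values), fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, k = NA_integer_, weighted = NA) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  Z <- as.matrix(df[, -1, drop = FALSE])
  rownames(Z) <- df[[1]]
  new_feature_matrix(Z, k = k, weighted = weighted)
}
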