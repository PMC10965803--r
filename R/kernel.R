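encode_sequences <- function(seqs) {
  lapply(strsplit(seqs, ""), function(ch) {
    idx <- match(ch, AA_ALPHABET)
    if (anyNA(idx))
      stop("invalid amino-acid character in sequence: ",
           paste(unique(ch[is.na(idx)]), collapse = ""))
    as.integer(idx - 1L)
  })
}

encode_repertoires <- function(reps, sub) {
  diag_scores <- diag(sub)
  lapply(reps, function(r) {
    enc <- encode_sequences(r$sequences)
    self <- vapply(enc, function(e) sum(diag_scores[e + 1L]), numeric(1))
    list(seqs = enc, w = as.numeric(r$abundances), self = self)
  })
}

#' Normalized alignment similarity between two CDR3 sequences
#'
#' Computes the global (Needleman-Wunsch) alignment score S(a, b) under a
#' substitution matrix with affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`), and by default returns the normalized
#' similarity S(a, b) / sqrt(S(a, a) S(b, b)), clamped to \[-1, 1\]. The
#' positive substitution-matrix diagonal guarantees S(a, a) > 0, so the
#' self-similarity is exactly 1.
#'
#' @param a,b Amino-acid strings over the 20-letter alphabet.
#' @param sub Substitution matrix name or matrix (see
#'   [substitution_matrix()]).
#' @param gap_open,gap_extend Affine gap penalties (defaults 10 and 1).
#' @param normalize Return the self-normalized score (default `TRUE`);
#'   `FALSE` returns the raw integer alignment score.
#' @return A single numeric similarity.
#' @examples
#' sequence_similarity("CASSF", "CASSF")  # 1
#' @export
sequence_similarity <- function(a, b, sub = "BLOSUM62", gap_open = 10,
                                gap_extend = 1, normalize = TRUE) {
  S <- substitution_matrix(sub)
  ea <- encode_sequences(a)[[1]]
  eb <- encode_sequences(b)[[1]]
  if (!length(ea) || !length(eb)) stop("sequences must be non-empty")
  raw <- cpp_nw_score(ea, eb, S, as.integer(gap_open), as.integer(gap_extend))
  if (!normalize) return(raw)
  selfa <- sum(diag(S)[ea + 1L]); selfb <- sum(diag(S)[eb + 1L])
  max(-1, min(1, raw / sqrt(selfa * selfb)))
}

#' Repertoire homology between two individuals
#'
#' The abundance-weighted best-match homology: every clone of one
#' repertoire is matched to its most similar clone in the other
#' repertoire, and the two directions are pooled with abundance weights,
#'
#' \deqn{k(R_i, R_{i'}) = \frac{\sum_j w_{ij} \max_{j'} s(a_{ij}, a_{i'j'})
#'   + \sum_{j'} w_{i'j'} \max_j s(a_{ij}, a_{i'j'})}
#'   {\sum_j w_{ij} + \sum_{j'} w_{i'j'}}.}
#'
#' The ratio form makes the value invariant to rescaling all abundances
#' of one repertoire, and with normalized similarities k(R, R) = 1.
#'
#' @param ri,rj [repertoire()] objects.
#' @inheritParams sequence_similarity
#' @return A single numeric homology value.
#' @export
repertoire_homology <- function(ri, rj, sub = "BLOSUM62", gap_open = 10,
                                gap_extend = 1, normalize = TRUE) {
  S <- substitution_matrix(sub)
  enc <- encode_repertoires(list(ri, rj), S)
  cpp_cross_kernel(enc[1], enc[2], S, as.integer(gap_open),
                   as.integer(gap_extend), normalize)[1, 1]
}

new_kernel <- function(values, ids, sub_name, gap_open, gap_extend,
                       normalized, psd_projected = FALSE, eigen = NULL,
                       n_truncated = NA_integer_,
                       min_eigenvalue = NA_real_) {
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, individual_ids = ids,
                 substitution = sub_name, gap_open = gap_open,
                 gap_extend = gap_extend, normalized = normalized,
                 psd_projected = psd_projected, eigen = eigen,
                 eigen_floor = 0, n_truncated = n_truncated,
                 min_eigenvalue = min_eigenvalue),
            class = "tcr_kernel")
}

#' @export
print.tcr_kernel <- function(x, ...) {
  cat(sprintf("<tcr_kernel> %d x %d (%s%s)\n", nrow(x$values), ncol(x$values),
              x$substitution,
              if (x$psd_projected) ", PSD-projected" else ""))
  invisible(x)
}

#' Repertoire-homology kernel matrix for a cohort
#'
#' Computes the symmetric n x n matrix of pairwise repertoire homologies
#' in the order the repertoires are given (the canonical cohort order).
#' Entries are computed once for i <= j and mirrored.
#'
#' @param reps List of `tcr_repertoire` (n >= 2).
#' @inheritParams sequence_similarity
#' @return A `tcr_kernel` object (not yet PSD-projected).
#' @seealso [psd_project()], [kernel_cross()]
#' @export
kernel_matrix <- function(reps, sub = "BLOSUM62", gap_open = 10,
                          gap_extend = 1, normalize = TRUE) {
  if (length(reps) < 2L) stop("need at least two repertoires")
  S <- substitution_matrix(sub)
  enc <- encode_repertoires(reps, S)
  K <- cpp_kernel(enc, S, as.integer(gap_open), as.integer(gap_extend),
                  normalize)
  ids <- vapply(reps, function(r) r$individual_id, character(1))
  new_kernel(K, ids, attr(S, "name"), gap_open, gap_extend, normalize)
}

#' Project a homology matrix to positive semi-definiteness
#'
#' Eigendecomposes the symmetric matrix, truncates negative eigenvalues
#' at zero, and reconstructs. The eigen factorization is kept on the
#' returned object (it is reused to draw Gaussian effects with covariance
#' proportional to K). The number of truncated eigenvalues and the most
#' negative eigenvalue are recorded.
#'
#' @param K A `tcr_kernel` or a plain symmetric matrix.
#' @return A `tcr_kernel` with `psd_projected = TRUE`.
#' @export
psd_project <- function(K) {
  if (is.matrix(K)) {
    K <- new_kernel(K, rownames(K) %||% as.character(seq_len(nrow(K))),
                    "custom", NA_real_, NA_real_, NA)
  }
  e <- eigen(K$values, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  V <- e$vectors %*% (vals * t(e$vectors))
  V <- (V + t(V)) / 2
  new_kernel(V, K$individual_ids, K$substitution, K$gap_open, K$gap_extend,
             K$normalized, psd_projected = TRUE,
             eigen = list(values = vals, vectors = e$vectors),
             n_truncated = sum(e$values < 0),
             min_eigenvalue = min(e$values))
}

#' Cross-kernel between new and training individuals
#'
#' Computes the matrix of repertoire homologies between each new
#' individual (rows) and each training individual (columns), in the
#' training order stored by the fitted model. No PSD projection is
#' applied to cross terms.
#'
#' @param reps_new,reps_train Lists of `tcr_repertoire`.
#' @inheritParams sequence_similarity
#' @return A plain numeric matrix (n_new x n_train) with id dimnames.
#' @export
kernel_cross <- function(reps_new, reps_train, sub = "BLOSUM62",
                         gap_open = 10, gap_extend = 1, normalize = TRUE) {
  S <- substitution_matrix(sub)
  enc_new <- encode_repertoires(reps_new, S)
  enc_tr <- encode_repertoires(reps_train, S)
  K <- cpp_cross_kernel(enc_new, enc_tr, S, as.integer(gap_open),
                        as.integer(gap_extend), normalize)
  rownames(K) <- vapply(reps_new, function(r) r$individual_id, character(1))
  colnames(K) <- vapply(reps_train, function(r) r$individual_id, character(1))
  K
}

#' Lazily cached kernel over a fixed repertoire pool
#'
#' For simulation studies that repeatedly sample individuals from one
#' pool, pairwise homologies are cached at the individual-pair level:
#' each pool pair is aligned at most once across all replicates.
#' `pool_kernel_cache()` builds the cache; `cached_kernel()` returns the
#' (unprojected) kernel submatrix for an index subset, computing only the
#' entries not seen before. Results are identical with or without the
#' cache.
#'
#' @param pool List of `tcr_repertoire`.
#' @inheritParams sequence_similarity
#' @return `pool_kernel_cache()` returns an environment; `cached_kernel()`
#'   returns a `tcr_kernel` for the subset.
#' @export
pool_kernel_cache <- function(pool, sub = "BLOSUM62", gap_open = 10,
                              gap_extend = 1, normalize = TRUE) {
  S <- substitution_matrix(sub)
  cache <- new.env(parent = emptyenv())
  cache$S <- S
  cache$enc <- encode_repertoires(pool, S)
  cache$ids <- vapply(pool, function(r) r$individual_id, character(1))
  n <- length(pool)
  cache$K <- matrix(NA_real_, n, n)
  if (normalize) diag(cache$K) <- 1
  cache$gap_open <- gap_open
  cache$gap_extend <- gap_extend
  cache$normalize <- normalize
  cache
}

#' @param cache A cache from `pool_kernel_cache()`.
#' @param idx Integer indices into the pool.
#' @rdname pool_kernel_cache
#' @export
cached_kernel <- function(cache, idx) {
  sub <- cache$K[idx, idx, drop = FALSE]
  miss <- which(is.na(sub) & upper.tri(sub, diag = TRUE), arr.ind = TRUE)
  if (nrow(miss)) {
    ii <- idx[miss[, 1]]; jj <- idx[miss[, 2]]
    vals <- cpp_kernel_pairs(cache$enc, ii, jj, cache$S,
                             as.integer(cache$gap_open),
                             as.integer(cache$gap_extend), cache$normalize)
    cache$K[cbind(ii, jj)] <- vals
    cache$K[cbind(jj, ii)] <- vals
    sub <- cache$K[idx, idx, drop = FALSE]
  }
  new_kernel(sub, cache$ids[idx], attr(cache$S, "name"), cache$gap_open,
             cache$gap_extend, cache$normalize)
}

#' Export / import a kernel matrix as CSV
#'
#' Individual ids are stored in the header and first column.
#'
#' @param K A `tcr_kernel`.
#' @param path File path.
#' @return `write_kernel()` returns `path` invisibly; `read_kernel()`
#'   returns a `tcr_kernel` (metadata fields set to `NA`).
#' @export
write_kernel <- function(K, path) {
  df <- data.frame(individual_id = K$individual_ids, K$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  new_kernel(M, df[[1]], "unknown", NA_real_, NA_real_, NA)
}
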