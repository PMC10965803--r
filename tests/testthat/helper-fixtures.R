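# Shared fixtures and independent oracles, all built in code.

# A small pool with modest clone counts so unit tests stay fast.
small_pool <- function(n = 20, seed = 42) {
  generate_pool(synthetic_pool_spec(n, clones_range = c(4, 8),
                                    length_range = c(8, 14)),
                seed = seed)
}

rep_ids <- function(reps) vapply(reps, function(r) r$individual_id, character(1))

# Independent sliding-window k-mer recount (character-by-character).
brute_kmer_count <- function(reps, k, weighted = TRUE) {
  tab <- list()
  ids <- rep_ids(reps)
  for (i in seq_along(reps)) {
    r <- reps[[i]]
    counts <- new.env(parent = emptyenv())
    for (j in seq_along(r$sequences)) {
      s <- r$sequences[j]
      w <- if (weighted) r$abundances[j] else 1
      if (nchar(s) < k) next
      for (st in 1:(nchar(s) - k + 1)) {
        km <- substr(s, st, st + k - 1)
        counts[[km]] <- (if (is.null(counts[[km]])) 0 else counts[[km]]) + w
      }
    }
    tab[[ids[i]]] <- unlist(as.list(counts))
  }
  all_km <- sort(unique(unlist(lapply(tab, names))))
  Z <- matrix(0, length(reps), length(all_km), dimnames = list(ids, all_km))
  for (id in ids) if (length(tab[[id]])) Z[id, names(tab[[id]])] <- tab[[id]]
  Z
}

# Alignment-level oracle through Biostrings (independent of the package's
# compiled scorer).
bios_similarity <- function(a, b, sub = "BLOSUM62", gap_open = 10,
                            gap_extend = 1, normalize = TRUE) {
  requireNamespace("Biostrings", quietly = TRUE)
  mat <- get(data(list = sub, package = "Biostrings", envir = environment()))
  sc <- function(x, y) Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(x), Biostrings::AAString(y),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"))
  raw <- sc(a, b)
  if (!normalize) return(raw)
  max(-1, min(1, raw / sqrt(sc(a, a) * sc(b, b))))
}

# Repertoire-homology oracle: plain R double loop over all clone pairs,
# built on the Biostrings scorer.
brute_homology <- function(ri, rj, sub = "BLOSUM62") {
  S <- outer(seq_along(ri$sequences), seq_along(rj$sequences),
             Vectorize(function(a, b)
               bios_similarity(ri$sequences[a], rj$sequences[b], sub)))
  num <- sum(ri$abundances * apply(S, 1, max)) +
    sum(rj$abundances * apply(S, 2, max))
  num / (sum(ri$abundances) + sum(rj$abundances))
}

# tcr_features wrapper around an arbitrary named matrix.
as_features <- function(Z, k = 3, weighted = TRUE, scaling = NULL) {
  tcrkern:::new_feature_matrix(Z, k = k, weighted = weighted,
                               scaling = scaling)
}

# Random PSD matrix.
random_psd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(n) * 0.1
}

write_repertoire_csv <- function(rows, path) {
  writeLines(c("individual_id,sequence,abundance", rows), path)
  path
}
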