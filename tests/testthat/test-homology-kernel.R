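test_that("normalized similarity is 1 on self, symmetric, and validates input", {
  expect_equal(sequence_similarity("CASSF", "CASSF"), 1)
  expect_equal(sequence_similarity("CDWWF", "CDWWF", sub = "PAM250"), 1)
  set.seed(2)
  for (i in 1:5) {
    a <- paste(sample(AA_ALPHABET, sample(5:12, 1), TRUE), collapse = "")
    b <- paste(sample(AA_ALPHABET, sample(5:12, 1), TRUE), collapse = "")
    expect_equal(sequence_similarity(a, b), sequence_similarity(b, a))
  }
  expect_error(sequence_similarity("CAXSF", "CASSF"), "invalid")
})

test_that("alignment scores reproduce an independent dynamic-programming oracle", {
  skip_if_not_installed("Biostrings")
  # 3x3 grid case, frozen from the hand-checkable DP table
  expect_equal(sequence_similarity("CAS", "CAT", normalize = FALSE), 14)
  expect_equal(sequence_similarity("CAS", "CAT"), 14 / sqrt(17 * 18))
  set.seed(4)
  for (sub in c("BLOSUM62", "PAM250")) {
    for (i in 1:10) {
      a <- paste(sample(AA_ALPHABET, sample(3:20, 1), TRUE), collapse = "")
      b <- paste(sample(AA_ALPHABET, sample(3:20, 1), TRUE), collapse = "")
      expect_equal(sequence_similarity(a, b, sub = sub, normalize = FALSE),
                   bios_similarity(a, b, sub = sub, normalize = FALSE),
                   info = paste(sub, a, b))
    }
  }
})

test_that("repertoire homology has unit self-value and cancels shared weights", {
  pool <- small_pool(4, seed = 31)
  expect_equal(repertoire_homology(pool[[1]], pool[[1]]), 1)

  a <- repertoire("A", "CASSLGF", 3)
  b <- repertoire("B", "CAWRMGF", 11)
  s <- sequence_similarity("CASSLGF", "CAWRMGF")
  expect_equal(repertoire_homology(a, b), s)  # weights cancel for single clones

  # the ratio form cancels a joint rescaling of all abundances
  r1 <- pool[[2]]; r2 <- pool[[3]]
  r1s <- repertoire(r1$individual_id, r1$sequences, r1$abundances * 7)
  r2s <- repertoire(r2$individual_id, r2$sequences, r2$abundances * 7)
  expect_equal(repertoire_homology(r1s, r2s), repertoire_homology(r1, r2),
               tolerance = 1e-12)
  # values stay within the similarity range
  expect_lte(abs(repertoire_homology(r1, r2)), 1)
})

test_that("repertoire homology matches a brute-force double loop", {
  skip_if_not_installed("Biostrings")
  set.seed(6)
  pool <- generate_pool(synthetic_pool_spec(4, clones_range = c(3, 3),
                                            length_range = c(8, 12)), seed = 6)
  for (pair in list(c(1, 2), c(3, 4))) {
    expect_equal(repertoire_homology(pool[[pair[1]]], pool[[pair[2]]]),
                 brute_homology(pool[[pair[1]]], pool[[pair[2]]]),
                 tolerance = 1e-10)
  }
})

test_that("kernel matrix is symmetric with unit diagonal and permutes conformably", {
  pool <- small_pool(6, seed = 33)
  K <- kernel_matrix(pool)
  expect_equal(unname(diag(K$values)), rep(1, 6))
  expect_equal(K$values, t(K$values))
  expect_true(all(abs(K$values) <= 1))

  perm <- c(4, 2, 6, 1, 3, 5)
  K2 <- kernel_matrix(pool[perm])
  expect_equal(K2$values, K$values[perm, perm])

  # entrywise equality with a naive double loop over repertoire_homology
  naive <- outer(1:6, 1:6, Vectorize(function(i, j)
    repertoire_homology(pool[[i]], pool[[j]])))
  expect_equal(unname(K$values), naive, tolerance = 1e-10)
})

test_that("cross-kernel agrees with the symmetric kernel and a brute-force loop", {
  pool <- small_pool(6, seed = 35)
  train <- pool[1:4]; new <- pool[5:6]
  Kc <- kernel_cross(new, train)
  expect_equal(dim(Kc), c(2, 4))
  naive <- outer(5:6, 1:4, Vectorize(function(i, j)
    repertoire_homology(pool[[i]], pool[[j]])))
  expect_equal(unname(Kc), naive, tolerance = 1e-12)

  # cross of the training set with itself equals the unprojected kernel
  expect_equal(kernel_cross(train, train), kernel_matrix(train)$values,
               tolerance = 1e-12)

  # a new individual identical to training individual i has 1 at position i
  Kid <- kernel_cross(pool[2], train)
  expect_equal(unname(Kid[1, 2]), 1)
  expect_true(all(Kid[1, -2] < 1))
})

test_that("PSD projection truncates negative eigenvalues and is a projection", {
  K <- matrix(c(1, 2, 2, 1), 2)
  P <- psd_project(K)
  expect_equal(unname(P$values), matrix(1.5, 2, 2), tolerance = 1e-12)
  expect_identical(P$n_truncated, 1L)
  expect_equal(P$min_eigenvalue, -1)

  # already-PSD input is returned unchanged
  A <- random_psd(6, seed = 9)
  expect_equal(unname(psd_project(A)$values), A, tolerance = 1e-10)

  set.seed(10)
  for (i in 1:5) {
    B <- matrix(rnorm(25), 5); B <- (B + t(B)) / 2
    P1 <- psd_project(B)
    expect_gte(min(eigen(P1$values, symmetric = TRUE)$values), -1e-8)
    # idempotent
    expect_equal(psd_project(P1$values)$values, P1$values, tolerance = 1e-10)
    # projection: no PSD matrix is closer to the input than the projection
    for (j in 1:3) {
      Q <- random_psd(5, seed = 100 * i + j)
      expect_lte(norm(P1$values - unname(B), "F"),
                 norm(Q - unname(B), "F") + 1e-10)
    }
  }
})

test_that("pool-level kernel cache reproduces direct computation", {
  pool <- small_pool(8, seed = 37)
  cache <- pool_kernel_cache(pool, sub = "PAM250")
  idx <- c(2, 5, 7)
  K1 <- cached_kernel(cache, idx)
  K2 <- kernel_matrix(pool[idx], sub = "PAM250")
  expect_equal(K1$values, K2$values)
  # second call hits the cache and must agree
  expect_equal(cached_kernel(cache, idx)$values, K2$values)
  # overlapping subset reuses cached pairs
  idx2 <- c(5, 7, 1)
  expect_equal(cached_kernel(cache, idx2)$values,
               kernel_matrix(pool[idx2], sub = "PAM250")$values)
})

test_that("kernels survive a CSV round trip", {
  pool <- small_pool(4, seed = 39)
  K <- kernel_matrix(pool)
  f <- tempfile(fileext = ".csv")
  write_kernel(K, f)
  expect_equal(read_kernel(f)$values, K$values, tolerance = 1e-12)
})
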