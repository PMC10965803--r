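test_that("k-mer extraction slides L-k+1 windows and respects weighting", {
  r <- repertoire("P1", "CASSHGRAEAFF", 1)
  km <- extract_kmers(r, 3, weight_by_abundance = FALSE)
  expect_length(km, 10)
  expect_true(all(km == 1))
  expect_setequal(names(km), c("CAS", "ASS", "SSH", "SHG", "HGR", "GRA",
                               "RAE", "AEA", "EAF", "AFF"))

  expect_length(extract_kmers(repertoire("P2", "CA", 1), 3), 0)

  r2 <- repertoire("P3", c("CASF", "ASFA"), c(2, 3))
  km2 <- extract_kmers(r2, 2, weight_by_abundance = TRUE)
  expect_equal(km2[["AS"]], 5)
  expect_equal(km2[["SF"]], 5)
  expect_equal(km2[["CA"]], 2)
  expect_equal(km2[["FA"]], 3)
})

test_that("unweighted k-mer mass equals the window count", {
  pool <- small_pool(6, seed = 11)
  for (k in c(2, 4)) {
    for (r in pool) {
      expected <- sum(pmax(0, nchar(r$sequences) - k + 1))
      expect_equal(sum(extract_kmers(r, k, weight_by_abundance = FALSE)),
                   expected)
    }
  }
})

test_that("feature matrix matches a brute-force recount and is row-equivariant", {
  pool <- small_pool(5, seed = 13)
  fm <- build_feature_matrix(pool, k = 3)
  expect_equal(fm$values, brute_kmer_count(pool, 3, weighted = TRUE))
  expect_lte(ncol(fm$values), 20^3)

  perm <- c(3, 1, 5, 2, 4)
  fm_perm <- build_feature_matrix(pool[perm], k = 3)
  expect_identical(fm_perm$values, fm$values[perm, ])

  # disjoint k-mer sets give complementary zero blocks
  a <- repertoire("A", "CAAAF", 2); b <- repertoire("B", "CWWWF", 2)
  blocks <- build_feature_matrix(list(a, b), k = 3)$values
  expect_true(all((blocks["A", ] == 0) | (blocks["B", ] == 0)))

  single <- build_feature_matrix(list(a), k = 3)
  expect_equal(drop(single$values), extract_kmers(a, 3))

  short <- repertoire("S", c("CA", "CF"), c(2, 2))
  expect_error(build_feature_matrix(list(short), k = 3), "shorter than k")
})

test_that("quantile scaling uses type-7 interpolation with degenerate fallbacks", {
  Z <- cbind(a = c(0, 0, 4, 8), b = c(0, 0, 0, 0), c = c(3, 3, 3, 3))
  rownames(Z) <- paste0("i", 1:4)
  fm <- quantile_scale(as_features(Z))
  # sorted a = (0,0,4,8): h = 1 + 3*0.75 = 3.25 -> 4 + 0.25*(8-4) = 5
  expect_equal(fm$scaling[["a"]], 5)
  expect_equal(fm$values[, "a"], c(i1 = 0, i2 = 0, i3 = 0.8, i4 = 1.6))
  expect_equal(fm$scaling[["b"]], 1)          # all-zero column untouched
  expect_equal(unname(fm$values[, "b"]), rep(0, 4))
  expect_equal(unname(fm$values[, "c"]), rep(1, 4))  # constant column -> 1

  # non-zero-entries mode
  fm_nz <- quantile_scale(as_features(Z), nonzero_only = TRUE)
  expect_equal(fm_nz$scaling[["a"]], stats::quantile(c(4, 8), 0.75,
                                                     names = FALSE))

  # undoing the recorded factors reproduces the original to 1e-12
  back <- sweep(fm$values, 2, fm$scaling, "*")
  expect_equal(back, Z, tolerance = 1e-12)
})

test_that("prevalence filter keeps the >= boundary and matches a column scan", {
  Z <- matrix(0, 100, 3, dimnames = list(NULL, c("keep", "drop", "zero")))
  Z[1:5, "keep"] <- 1
  Z[1:4, "drop"] <- 1
  fm <- prevalence_filter(as_features(Z), 0.05)
  expect_identical(colnames(fm$values), "keep")
  expect_identical(colnames(prevalence_filter(as_features(Z), 0)$values),
                   colnames(Z))

  set.seed(5)
  Zr <- matrix(rbinom(50 * 200, 1, 0.08) * runif(50 * 200), 50, 200,
               dimnames = list(NULL, sprintf("f%03d", 1:200)))
  keep_oracle <- colnames(Zr)[apply(Zr, 2, function(col) mean(col > 0) >= 0.05)]
  expect_identical(colnames(prevalence_filter(as_features(Zr), 0.05)$values),
                   keep_oracle)
  expect_error(prevalence_filter(as_features(Zr), 1.1), "lower")
})

test_that("SIS screening ranks by |cor|, breaks ties by name, ignores column order", {
  expect_identical(sis_dimension(500), 40)

  set.seed(8)
  n <- 60
  Z <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, sprintf("k%02d", 1:30)))
  Z[, "k07"] <- Z[, "k07"] - min(Z[, "k07"]) + 0.1
  y <- Z[, "k07"]
  scr <- sis_screen(as_features(Z), y, d = 5)
  expect_identical(colnames(scr$values)[1], "k07")

  # full-enumeration oracle
  cors <- abs(apply(Z, 2, function(col) cor(col, y)))
  oracle <- names(sort(cors, decreasing = TRUE))[1:5]
  expect_setequal(colnames(scr$values), oracle)

  # invariant to input column order
  perm <- sample(ncol(Z))
  scr2 <- sis_screen(as_features(Z[, perm]), y, d = 5)
  expect_identical(scr2$values, scr$values)

  # zero-variance column ranks last instead of erroring
  Z2 <- cbind(Z[, 1:3], const = 1)
  expect_false("const" %in% colnames(sis_screen(as_features(Z2), y, d = 3)$values))

  # default d follows the sample size
  expect_equal(ncol(sis_screen(as_features(Z), y)$values), sis_dimension(n))
})

test_that("feature matrices survive a CSV round trip", {
  pool <- small_pool(4, seed = 21)
  fm <- build_feature_matrix(pool, k = 3)
  f <- tempfile(fileext = ".csv")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f, k = 3, weighted = TRUE)
  expect_equal(back$values, fm$values)
})
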