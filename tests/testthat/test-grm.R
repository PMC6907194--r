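test_that("GRM of duplicated genotypes has off-diagonal equal to diagonal", {
  g1 <- c(0L, 1L, 2L, 1L, 0L)
  geno <- rbind(a = g1, b = g1, c = c(2L, 1L, 0L, 1L, 2L))
  G <- build_grm(geno)$G
  expect_equal(G["a", "a"], G["b", "b"])
  expect_equal(G["a", "b"], G["a", "a"])
})

test_that("GRM matches the double-loop VanRaden oracle element by element", {
  geno <- toy_genotypes(n = 4, m = 3)
  G <- build_grm(geno)$G
  expect_equal(unname(G), grm_double_loop(geno), tolerance = 1e-12)
  expect_identical(G, t(G))
})

test_that("monomorphic markers are rejected with an explicit message", {
  geno <- toy_genotypes(n = 5, m = 3)
  geno[, 2] <- 2L
  expect_error(build_grm(geno), "monomorphic")
  expect_error(build_grm(geno[1, , drop = FALSE]), "2 animals")
})

test_that("eigendecomposition matches characteristic-polynomial roots", {
  b <- build_grm(toy_genotypes(n = 4, m = 6, seed = 9))
  b <- grm_eigen(b)
  expect_equal(b$D, charpoly_eigenvalues(b$G), tolerance = 1e-8)
  # eigenvectors: orthonormal, aligned, reconstruct G
  expect_equal(crossprod(b$U), diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(b$U %*% (b$D * t(b$U))), unname(b$G),
               tolerance = 1e-6)
  expect_false(is.unsorted(rev(b$D)))
  # identity matrix: flat unit spectrum
  id_bundle <- structure(list(G = diag(3), ids = as.character(1:3)),
                         class = "grm_bundle")
  expect_equal(grm_eigen(id_bundle)$D, rep(1, 3))
})

test_that("rank of ZZ' is bounded by the marker count", {
  geno <- toy_genotypes(n = 8, m = 3, seed = 2)
  b <- grm_eigen(build_grm(geno))
  expect_lte(sum(b$D > 1e-8), 3)
})

test_that("variance-explained counts follow the cumulative trace", {
  prof <- variance_explained_profile(c(4, 3, 2, 1), c(0.5, 0.7))
  expect_equal(prof$n_eigenvalues, c(2L, 2L)) # 7/10 >= 0.7 at r = 2
  flat <- variance_explained_profile(rep(1, 100), 0.5)
  expect_equal(flat$n_eigenvalues, 50L)
  expect_error(variance_explained_profile(c(2, 1), 1.5), "thresholds")
  expect_error(variance_explained_profile(c(1, 2), 0.5), "sorted")
  # counts nondecreasing in the threshold; curve monotone ending at 1
  d <- sort(rexp(50), decreasing = TRUE)
  prof <- variance_explained_profile(d, c(0.1, 0.3, 0.5, 0.9, 1))
  expect_false(is.unsorted(prof$n_eigenvalues))
  cv <- cumulative_variance(d)
  expect_false(is.unsorted(cv$cumulative_fraction))
  expect_equal(cv$cumulative_fraction[50], 1)
})

test_that("rank truncation keeps the leading spectrum exactly", {
  b <- grm_eigen(build_grm(toy_genotypes(n = 6, m = 8, seed = 4)))
  n <- length(b$D)
  expect_equal(truncate_grm(b, n), b$G, tolerance = 1e-6, ignore_attr = TRUE)
  G1 <- truncate_grm(b, 1)
  expect_equal(unname(G1), b$D[1] * tcrossprod(b$U[, 1]), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (r in c(2, 4)) {
    Gr <- truncate_grm(b, r)
    expect_equal(sum(diag(Gr)), sum(b$D[1:r]), tolerance = 1e-8)
    expect_gte(min(eigen(Gr, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  expect_error(truncate_grm(b, 0), "r must")
  expect_error(truncate_grm(b, n + 1), "r must")
})

test_that("truncation is Frobenius-optimal among random rank-r candidates", {
  set.seed(31)
  b <- grm_eigen(build_grm(toy_genotypes(n = 10, m = 20, seed = 13)))
  r <- 3
  best <- norm(b$G - truncate_grm(b, r), "F")
  for (i in 1:20) {
    Q <- qr.Q(qr(matrix(rnorm(10 * r), 10, r)))
    lam <- rexp(r)
    cand <- Q %*% (lam * t(Q))
    expect_gte(norm(b$G - cand, "F"), best - 1e-10)
  }
})

test_that("blending shifts the spectrum by epsilon", {
  Z <- matrix(0, 3, 3)
  expect_equal(blend_grm(Z, 0.01), diag(0.01, 3))
  b <- grm_eigen(build_grm(toy_genotypes(n = 6, m = 3, seed = 7)))
  for (r in c(1, 3, 5)) {
    Gb <- blend_grm(truncate_grm(b, r), 0.01)
    expect_silent(chol(Gb)) # positive definite for every r
    ev <- eigen(Gb, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 0.01 - 1e-8)
  }
  # unblended rank-deficient matrix is refused downstream
  expect_error(grm_inverse(b, "standard", epsilon = 0), "singular")
})

test_that("random core selection is a uniform, seed-stable subset", {
  ids <- sprintf("id%03d", 1:60)
  set.seed(10)
  c1 <- select_core_random(ids, 20)
  set.seed(10)
  c2 <- select_core_random(ids, 20)
  expect_identical(c1, c2)
  expect_equal(length(c1), 20)
  expect_false(anyDuplicated(c1) > 0)
  expect_true(all(c1 %in% ids))
  expect_setequal(select_core_random(ids, 60), ids)
  expect_error(select_core_random(ids, 0), "n_core")
  expect_error(select_core_random(ids, 61), "n_core")
})

test_that("APY with every animal in the core reproduces the dense inverse", {
  b <- build_grm(toy_genotypes(n = 7, m = 12, seed = 3))
  Gb <- blend_grm(b, 0.01)
  K <- apy_matrix(apy_inverse(Gb, rownames(Gb)))
  expect_equal(K, solve(Gb), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("APY inverse matches the textbook block formula on a 5-animal fixture", {
  b <- build_grm(toy_genotypes(n = 5, m = 9, seed = 12))
  Gb <- blend_grm(b, 0.01)
  core_idx <- c(1L, 3L, 4L)
  apy <- apy_inverse(Gb, rownames(Gb)[core_idx])
  K <- apy_matrix(apy)
  expect_equal(unname(K), apy_textbook(Gb, core_idx), tolerance = 1e-8)
  expect_identical(K, t(K))
  expect_true(all(apy$mnn > 0))
  # noncore x noncore block is diagonal (the defining sparsity of APY)
  non <- setdiff(seq_len(5), core_idx)
  off <- K[non, non]; diag(off) <- 0
  expect_equal(unname(off), matrix(0, 2, 2))
})

test_that("APY is near-exact when the core spans the GRM row space", {
  # 9 animals, 4 markers: pre-blend rank <= 4
  geno <- toy_genotypes(n = 9, m = 4, seed = 21)
  b <- build_grm(geno)
  Gb <- blend_grm(b, 0.01)
  rank_pre <- sum(grm_eigen(b)$D > 1e-8)
  core <- rownames(Gb)[seq_len(rank_pre + 1)]
  K <- apy_matrix(apy_inverse(Gb, core))
  prod_core <- (K %*% Gb)[core, core]
  expect_equal(unname(prod_core), diag(length(core)), tolerance = 1e-4)
})
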