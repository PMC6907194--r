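fixture_problem <- function(n = 5, m = 9, seed = 17, n_obs = n) {
  geno <- toy_genotypes(n = n, m = m, seed = seed)
  b <- grm_eigen(build_grm(geno))
  set.seed(seed + 1)
  obs <- sort(sample(seq_len(n), n_obs))
  y <- 10 + rnorm(n_obs, sd = 2)
  list(bundle = b, data = tibble::tibble(id = b$ids[obs], y = y),
       obs = obs, sigma_u2 = 1.5, sigma_e2 = 2.5)
}

test_that("records with zero variance yield the mean and zero GEBV", {
  p <- fixture_problem()
  p$data$y <- rep(3.7, nrow(p$data))
  fit <- gblup(p$data, grm_inverse(p$bundle), p$sigma_u2, p$sigma_e2)
  expect_equal(fit$mu_hat, 3.7, tolerance = 1e-10)
  expect_equal(fit$gebv$gebv, rep(0, 5), tolerance = 1e-10)
})

test_that("MME solution equals the joint-covariance GLS BLUP", {
  for (cfg in list(c(5, 9, 17, 5), c(8, 20, 23, 6), c(12, 7, 31, 12))) {
    p <- fixture_problem(cfg[1], cfg[2], cfg[3], cfg[4])
    Gb <- blend_grm(p$bundle, 0.01)
    fit <- gblup(p$data, grm_inverse(p$bundle), p$sigma_u2, p$sigma_e2,
                 keep_lhs_inverse = TRUE)
    oracle <- blup_gls(p$data$y, p$obs, Gb, p$sigma_u2, p$sigma_e2)
    expect_equal(fit$mu_hat, oracle$mu, tolerance = 1e-8)
    expect_equal(fit$gebv$gebv, oracle$u, tolerance = 1e-8)
    # PEV identity: LHS-inverse diagonal equals the covariance form
    expect_equal(fit$gebv$pev, oracle$pev, tolerance = 1e-8)
  }
})

test_that("the analytic eig-option inverse equals the dense inverse of blended G_eig", {
  b <- grm_eigen(build_grm(toy_genotypes(n = 15, m = 30, seed = 77)))
  for (r in c(2, 7, 15)) {
    K <- grm_inverse(b, "eig", r = r)$K
    K_dense <- solve(blend_grm(truncate_grm(b, r), 0.01))
    expect_equal(unname(K), unname(K_dense), tolerance = 1e-9)
  }
})

test_that("full-rank eigen-truncation reproduces the standard fit", {
  p <- fixture_problem(6, 10, 41)
  fit_std <- gblup(p$data, grm_inverse(p$bundle), p$sigma_u2, p$sigma_e2)
  fit_eig <- gblup(p$data, grm_inverse(p$bundle, "eig", r = 6),
                   p$sigma_u2, p$sigma_e2)
  expect_equal(fit_eig$gebv$gebv, fit_std$gebv$gebv, tolerance = 1e-6)
  expect_equal(fit_eig$mu_hat, fit_std$mu_hat, tolerance = 1e-6)
})

test_that("APY with an all-animal core reproduces the standard fit", {
  p <- fixture_problem(7, 11, 51)
  fit_std <- gblup(p$data, grm_inverse(p$bundle), p$sigma_u2, p$sigma_e2)
  fit_apy <- gblup(p$data,
                   grm_inverse(p$bundle, "apy", core_ids = p$bundle$ids),
                   p$sigma_u2, p$sigma_e2)
  expect_equal(fit_apy$gebv$gebv, fit_std$gebv$gebv, tolerance = 1e-6)
})

test_that("GBLUP is translation invariant and scale equivariant", {
  p <- fixture_problem(6, 12, 61)
  ginv <- grm_inverse(p$bundle)
  fit <- gblup(p$data, ginv, p$sigma_u2, p$sigma_e2)
  shifted <- p$data; shifted$y <- shifted$y + 7
  fit_shift <- gblup(shifted, ginv, p$sigma_u2, p$sigma_e2)
  expect_equal(fit_shift$mu_hat, fit$mu_hat + 7, tolerance = 1e-9)
  expect_equal(fit_shift$gebv$gebv, fit$gebv$gebv, tolerance = 1e-9)
  k <- 3.2
  scaled <- p$data; scaled$y <- scaled$y * k
  fit_scale <- gblup(scaled, ginv, p$sigma_u2 * k^2, p$sigma_e2 * k^2)
  expect_equal(fit_scale$gebv$gebv, k * fit$gebv$gebv, tolerance = 1e-9)
})

test_that("dimension and id mismatches are rejected", {
  p <- fixture_problem()
  bad <- p$data; bad$id[1] <- "stranger"
  expect_error(gblup(bad, grm_inverse(p$bundle), p$sigma_u2, p$sigma_e2),
               "absent")
  expect_error(gblup(p$data[, "id", drop = FALSE], grm_inverse(p$bundle),
                     p$sigma_u2, p$sigma_e2), "columns")
})

test_that("one animal, one record: PEV matches the scalar closed form", {
  # model without fixed mean: PEV = sigma_u2 * g * alpha/(alpha + g)
  g11 <- 1.23
  sigma_u2 <- 2; sigma_e2 <- 5
  alpha <- sigma_e2 / sigma_u2
  b <- structure(list(G = matrix(g11, 1, 1, dimnames = list("a", "a")),
                      ids = "a"), class = "grm_bundle")
  ginv <- structure(list(K = matrix(1 / g11, 1, 1), ids = "a",
                         method = "standard", epsilon = 0),
                    class = "grm_inverse")
  pev <- pev_direct(tibble::tibble(id = "a", y = 1), ginv, sigma_u2,
                    sigma_e2, include_mean = FALSE)$pev
  expect_equal(pev, sigma_u2 * g11 * alpha / (alpha + g11),
               tolerance = 1e-12)
  # no-information limit (h2 -> 0): PEV -> prior variance sigma_u2 * g11
  pev0 <- pev_direct(tibble::tibble(id = "a", y = 1), ginv, sigma_u2,
                     sigma_e2 = 1e9, include_mean = FALSE)$pev
  expect_equal(pev0, sigma_u2 * g11, tolerance = 1e-6)
})

test_that("reduced-rank PEV at full rank equals the direct inversion", {
  for (seed in c(71, 83)) {
    geno <- toy_genotypes(n = 12, m = 25, seed = seed)
    b <- grm_eigen(build_grm(geno))
    data <- tibble::tibble(id = b$ids, y = rnorm(12))
    sigma_u2 <- 1.7; sigma_e2 <- 3.1
    direct <- pev_direct(data, grm_inverse(b), sigma_u2, sigma_e2)
    rr <- pev_reduced_rank(b, sigma_u2, sigma_e2)
    expect_equal(rr$pev, direct$pev, tolerance = 1e-6)
    expect_false(attr(rr, "truncated"))
    expect_gt(cor(rr$pev, direct$pev), 0.999999)
  }
})

test_that("reduced-rank PEV on independent animals matches the scalar form", {
  n <- 6
  b <- structure(list(G = diag(n), ids = paste0("a", 1:n)),
                 class = "grm_bundle")
  b <- grm_eigen(b)
  sigma_u2 <- 2; sigma_e2 <- 4
  rr <- pev_reduced_rank(b, sigma_u2, sigma_e2, include_mean = FALSE,
                         epsilon = 0.01)
  g <- 1.01 # blended diagonal
  alpha <- sigma_e2 / sigma_u2
  expect_equal(rr$pev, rep(sigma_e2 * g / (g + alpha), n) , tolerance = 1e-10)
  expect_equal(length(unique(round(rr$pev, 12))), 1L)
})

test_that("truncated PEV is flagged as an approximation", {
  b <- grm_eigen(build_grm(toy_genotypes(n = 8, m = 15, seed = 91)))
  expect_message(rr <- pev_reduced_rank(b, 1, 2, r = 3), "approximation")
  expect_true(attr(rr, "truncated"))
})

test_that("tidy and glance expose the fit as tibbles", {
  p <- fixture_problem()
  fit <- gblup(p$data, grm_inverse(p$bundle), p$sigma_u2, p$sigma_e2,
               keep_lhs_inverse = TRUE)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("id", "gebv", "pev"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_records, nrow(p$data))
})
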