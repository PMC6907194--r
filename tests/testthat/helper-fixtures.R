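# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; nothing is read from disk.

# --- tiny simulation scenarios -------------------------------------------

tiny_scenario <- function(seed = 11, ...) {
  args <- list(
    n_hist_generations = 30, hist_size_start = 100,
    hist_size_bottleneck = 30, hist_size_end = 200,
    n_dams_per_gen = 60, n_sires_per_gen = 10,
    n_snp = 600, n_qtl = 60, n_genotyped = 300, seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(desk_scenario, args)
}

# memoised tiny population shared across test files
.fixture_env <- new.env(parent = emptyenv())

tiny_pop <- function() {
  if (is.null(.fixture_env$pop)) .fixture_env$pop <-
      simulate_population(tiny_scenario())
  .fixture_env$pop
}

tiny_grm <- function() {
  if (is.null(.fixture_env$grm)) .fixture_env$grm <-
      grm_eigen(build_grm(tiny_pop()$genotypes))
  .fixture_env$grm
}

# --- small deterministic genotype tables ---------------------------------

toy_genotypes <- function(n = 6, m = 4, seed = 5) {
  set.seed(seed)
  repeat {
    g <- matrix(sample(0:2, n * m, replace = TRUE,
                       prob = c(0.3, 0.4, 0.3)), n, m)
    p <- colMeans(g) / 2
    if (all(p > 0 & p < 1)) break
  }
  rownames(g) <- paste0("a", seq_len(n))
  colnames(g) <- paste0("m", seq_len(m))
  g
}

# --- independent oracles --------------------------------------------------

# VanRaden GRM by explicit double loops
grm_double_loop <- function(geno) {
  n <- nrow(geno); m <- ncol(geno)
  p <- colMeans(geno) / 2
  denom <- 2 * sum(p * (1 - p))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(m))
      s <- s + (geno[i, k] - 2 * p[k]) * (geno[j, k] - 2 * p[k])
    G[i, j] <- s / denom
  }
  G
}

# characteristic polynomial coefficients by Faddeev-LeVerrier, roots by
# polyroot: an eigen()-free spectrum
charpoly_eigenvalues <- function(A) {
  n <- nrow(A)
  M <- diag(n)
  coefs <- numeric(n + 1)
  coefs[n + 1] <- 1 # lambda^n
  c_prev <- 1
  Mk <- diag(n)
  for (k in seq_len(n)) {
    AM <- A %*% Mk
    ck <- -sum(diag(AM)) / k
    coefs[n + 1 - k] <- ck
    Mk <- AM + ck * diag(n)
  }
  r <- polyroot(coefs)
  sort(Re(r), decreasing = TRUE)
}

# textbook APY block formula, literally assembled with solve()
apy_textbook <- function(Gb, core_idx) {
  n <- nrow(Gb)
  non_idx <- setdiff(seq_len(n), core_idx)
  Gcc <- Gb[core_idx, core_idx, drop = FALSE]
  Gcn <- Gb[core_idx, non_idx, drop = FALSE]
  Gnc <- Gb[non_idx, core_idx, drop = FALSE]
  Gcci <- solve(Gcc)
  mnn <- numeric(length(non_idx))
  for (i in seq_along(non_idx)) {
    gi <- Gb[non_idx[i], core_idx]
    mnn[i] <- Gb[non_idx[i], non_idx[i]] - gi %*% Gcci %*% gi
  }
  top <- rbind(cbind(Gcci, matrix(0, length(core_idx), length(non_idx))),
               matrix(0, length(non_idx), n))
  Lft <- rbind(-Gcci %*% Gcn, diag(length(non_idx)))
  Rgt <- cbind(-Gnc %*% Gcci, diag(length(non_idx)))
  Kperm <- top + Lft %*% diag(1 / mnn, length(non_idx)) %*% Rgt
  # back to original order
  perm <- c(core_idx, non_idx)
  K <- matrix(0, n, n)
  K[perm, perm] <- Kperm
  K
}

# joint-covariance (GLS) BLUP with estimated mean: the closed-form oracle
# for the mixed-model equations. Returns mu, gebv for all animals, and the
# PEV of each animal from the covariance identity.
blup_gls <- function(y, obs_idx, G, sigma_u2, sigma_e2) {
  n <- nrow(G)
  V <- sigma_u2 * G[obs_idx, obs_idx] + diag(sigma_e2, length(obs_idx))
  Vi <- solve(V)
  ones <- rep(1, length(obs_idx))
  mu <- drop((t(ones) %*% Vi %*% y) / (t(ones) %*% Vi %*% ones))
  Cuy <- sigma_u2 * G[, obs_idx, drop = FALSE] # Cov(u, y)
  u <- unname(drop(Cuy %*% Vi %*% (y - mu)))
  vinv1 <- drop(Vi %*% ones)
  s11 <- sum(vinv1)
  pev <- numeric(n)
  for (i in seq_len(n)) {
    ci <- Cuy[i, ]
    pev[i] <- sigma_u2 * G[i, i] - drop(ci %*% Vi %*% ci) +
      (sum(ci * vinv1))^2 / s11
  }
  list(mu = mu, u = u, pev = pev)
}

# single-locus Wright-Fisher Monte Carlo for heterozygosity decay under a
# census-size schedule with recurrent mutation
wf_heterozygosity <- function(sizes, mu, n_loci = 3000, p0 = 0.5,
                              seed = 1) {
  set.seed(seed)
  p <- rep(p0, n_loci)
  for (N in sizes) {
    p <- rbinom(n_loci, 2 * N, p) / (2 * N)
    p <- p * (1 - mu) + (1 - p) * mu
  }
  mean(2 * p * (1 - p))
}
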