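#' Build the VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_j (1 - p_j)))`, where `Z` is the allele-content
#' matrix centered by twice the observed allele frequency `p_j` of each
#' marker. Frequencies are always computed from the supplied genotype set.
#'
#' @param genotypes Animals x markers matrix of 0/1/2 allele counts with
#'   animal ids as row names (as produced by [simulate_population()] or
#'   [read_genotypes()]).
#' @return An object of class `grm_bundle` holding `G`, the frequencies `p`,
#'   the animal ids, and (after [grm_eigen()]) the eigenpairs `U`, `D`.
#' @examples
#' geno <- rbind(a = c(0L, 1L, 2L), b = c(2L, 1L, 0L),
#'               c = c(1L, 2L, 0L), d = c(0L, 1L, 1L))
#' build_grm(geno)
#' @export
build_grm <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 2)
    stop("need at least 2 animals to build a GRM", call. = FALSE)
  if (ncol(genotypes) < 1)
    stop("need at least 1 marker to build a GRM", call. = FALSE)
  if (anyNA(genotypes) || !all(genotypes %in% 0:2))
    stop("genotypes must be complete 0/1/2 allele counts", call. = FALSE)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(genotypes)))
  p <- colMeans(genotypes) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono))
    stop(sprintf(paste0("%d monomorphic marker(s) (e.g. %s): VanRaden ",
                        "centering is undefined for p = 0 or 1; drop them ",
                        "before building the GRM"),
                 sum(mono), colnames(genotypes)[which(mono)[1]] %||%
                   which(mono)[1]),
         call. = FALSE)
  Z <- sweep(genotypes, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(ids, ids)
  structure(list(G = G, p = p, ids = ids, n_markers = ncol(genotypes),
                 denominator = denom, U = NULL, D = NULL,
                 blend_epsilon = NULL),
            class = "grm_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.grm_bundle <- function(x, ...) {
  cat(sprintf("<grm_bundle> %d animals, %d markers; mean diagonal %.3f\n",
              length(x$ids), x$n_markers, mean(diag(x$G))))
  if (!is.null(x$D))
    cat(sprintf("  eigendecomposed: %d eigenvalues, largest %.2f\n",
                length(x$D), x$D[1]))
  invisible(x)
}

#' Eigendecompose a GRM
#'
#' Full symmetric eigendecomposition of the (pre-blend) GRM, eigenvalues
#' sorted in decreasing order with aligned eigenvectors. Tiny negative
#' eigenvalues (numerical noise, above `-1e-8` relative to the largest) are
#' clipped to zero; larger negative values abort, since they signal an input
#' that is not a cross-product matrix.
#'
#' @param bundle A `grm_bundle` from [build_grm()].
#' @return The bundle with `U` (orthonormal eigenvectors) and `D`
#'   (eigenvalues) filled in.
#' @export
grm_eigen <- function(bundle) {
  stopifnot(inherits(bundle, "grm_bundle"))
  if (!all(is.finite(bundle$G)))
    stop("GRM contains non-finite entries", call. = FALSE)
  e <- eigen(bundle$G, symmetric = TRUE)
  tol <- 1e-8 * max(1, abs(e$values[1]))
  if (any(e$values < -tol))
    stop("GRM has substantially negative eigenvalues; not a valid ",
         "relationship matrix", call. = FALSE)
  bundle$D <- pmax(e$values, 0)
  bundle$U <- e$vectors
  rownames(bundle$U) <- bundle$ids
  bundle
}

as_eigenvalues <- function(x) {
  if (inherits(x, "grm_bundle")) {
    if (is.null(x$D)) stop("run grm_eigen() first", call. = FALSE)
    x$D
  } else {
    as.numeric(x)
  }
}

#' Eigenvalue counts needed to explain variance fractions
#'
#' For each threshold `t`, the smallest number of leading eigenvalues `r`
#' such that `tr(D_r)/tr(D) >= t` — the number of eigenvalues explaining a
#' fraction `t` of the genomic variation.
#'
#' @param x A `grm_bundle` with eigenvalues, or a numeric vector of
#'   eigenvalues sorted in decreasing order.
#' @param thresholds Variance fractions in (0, 1].
#' @return A tibble with columns `threshold`, `n_eigenvalues`, and
#'   `fraction_explained` (the cumulative fraction actually attained at that
#'   count).
#' @examples
#' variance_explained_profile(c(4, 3, 2, 1), c(0.5, 0.7))
#' @export
variance_explained_profile <- function(x, thresholds = c(0.10, 0.30, 0.50,
                                                         0.70, 0.90, 0.95,
                                                         0.98)) {
  d <- as_eigenvalues(x)
  if (is.unsorted(rev(d))) stop("eigenvalues must be sorted decreasing",
                                call. = FALSE)
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  total <- sum(d)
  if (total <= 0) stop("tr(D) must be positive", call. = FALSE)
  cf <- cumsum(d) / total
  r <- vapply(thresholds, function(t) which(cf >= t - 1e-12)[1], integer(1))
  tibble::tibble(threshold = thresholds, n_eigenvalues = r,
                 fraction_explained = cf[r])
}

#' Cumulative variance curve of a GRM spectrum
#'
#' @inheritParams variance_explained_profile
#' @return A tibble with `index`, `eigenvalue`, `cumulative_fraction`.
#' @export
cumulative_variance <- function(x) {
  d <- as_eigenvalues(x)
  tibble::tibble(index = seq_along(d), eigenvalue = d,
                 cumulative_fraction = cumsum(d) / sum(d))
}

#' Rank-truncated GRM
#'
#' `G_eig = U D_r U'` keeping only the `r` largest eigenvalues — the best
#' rank-`r` symmetric approximation of `G` in Frobenius norm.
#'
#' @param bundle A `grm_bundle`; the eigendecomposition is computed if absent.
#' @param r Number of leading eigenvalues to keep (1 to `n`).
#' @return A symmetric positive semidefinite matrix of rank at most `r`,
#'   with animal ids as dimnames and an `"r"` attribute.
#' @export
truncate_grm <- function(bundle, r) {
  stopifnot(inherits(bundle, "grm_bundle"))
  if (is.null(bundle$D)) bundle <- grm_eigen(bundle)
  n <- length(bundle$D)
  if (length(r) != 1 || r < 1 || r > n)
    stop("r must lie in 1..", n, call. = FALSE)
  r <- as.integer(r)
  Ur <- bundle$U[, seq_len(r), drop = FALSE]
  Geig <- Ur %*% (bundle$D[seq_len(r)] * t(Ur))
  Geig <- (Geig + t(Geig)) / 2
  dimnames(Geig) <- dimnames(bundle$G)
  attr(Geig, "r") <- r
  Geig
}

#' Blend a relationship matrix to full rank
#'
#' Adds `epsilon * I` so rank-deficient relationship matrices (the GRM of
#' `n` animals with fewer markers than animals, or a rank-truncated GRM)
#' become invertible. The study convention is `epsilon = 0.01`.
#'
#' @param x A square symmetric matrix, or a `grm_bundle` (its `G` is used).
#' @param epsilon Ridge added to the diagonal.
#' @return The blended matrix.
#' @export
blend_grm <- function(x, epsilon = 0.01) {
  M <- if (inherits(x, "grm_bundle")) x$G else as.matrix(x)
  stopifnot(nrow(M) == ncol(M), epsilon >= 0)
  M + diag(epsilon, nrow(M))
}

#' Randomly select APY core animals
#'
#' Uniform sample without replacement, deterministic under a fixed seed.
#'
#' @param ids Character vector of animal ids (or a `grm_bundle`).
#' @param n_core Number of core animals.
#' @return Character vector of core ids.
#' @export
select_core_random <- function(ids, n_core) {
  if (inherits(ids, "grm_bundle")) ids <- ids$ids
  n <- length(ids)
  if (length(n_core) != 1 || n_core < 1 || n_core > n)
    stop("n_core must lie in 1..", n, call. = FALSE)
  sample(ids, n_core)
}

#' APY sparse inverse of a blended GRM
#'
#' The algorithm for proven and young expresses noncore animal effects as
#' linear combinations of core effects plus an individual residual, which
#' yields the sparse generalized inverse
#' `G_APY^-1 = [[Gcc^-1, 0], [0, 0]] +
#'   [-Gcc^-1 Gcn; I] Mnn^-1 [-Gnc Gcc^-1, I]`,
#' with `Mnn = diag{g_ii - g_ic Gcc^-1 g_ci}`. Only the core block is
#' inverted densely.
#'
#' @param G A blended (full-rank) GRM with animal ids as dimnames, or a
#'   `grm_bundle` (then blended with `epsilon` first).
#' @param core_ids Ids of the core animals (see [select_core_random()]).
#' @param epsilon Blend applied when `G` is a `grm_bundle`.
#' @return An object of class `apy_inverse` with the core/noncore partition,
#'   the dense core-block inverse, and the `m_nn` residual variances. Use
#'   [apy_matrix()] to assemble the full inverse in the original animal
#'   order.
#' @export
apy_inverse <- function(G, core_ids, epsilon = 0.01) {
  if (inherits(G, "grm_bundle")) G <- blend_grm(G, epsilon)
  ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  core_ids <- as.character(core_ids)
  if (!all(core_ids %in% ids)) stop("unknown core animal id", call. = FALSE)
  if (anyDuplicated(core_ids)) stop("duplicated core animal id", call. = FALSE)
  core_idx <- match(core_ids, ids)
  non_idx <- setdiff(seq_along(ids), core_idx)
  Gcc <- G[core_idx, core_idx, drop = FALSE]
  ch <- tryCatch(chol(Gcc), error = function(e)
    stop("core block of G is not positive definite; blend G first",
         call. = FALSE))
  Gcc_inv <- chol2inv(ch)
  if (length(non_idx) > 0) {
    Gcn <- G[core_idx, non_idx, drop = FALSE]
    P <- Gcc_inv %*% Gcn # Gcc^-1 Gcn
    mnn <- diag(G)[non_idx] - colSums(Gcn * P)
    if (any(mnn <= 0))
      stop("non-positive APY residual variance m_nn for animal(s) ",
           paste(ids[non_idx][mnn <= 0][1:min(3, sum(mnn <= 0))],
                 collapse = ", "),
           "; core too small or G not blended", call. = FALSE)
  } else {
    Gcn <- matrix(0, length(core_idx), 0)
    P <- Gcn
    mnn <- numeric(0)
  }
  structure(list(ids = ids, core_ids = ids[core_idx],
                 noncore_ids = ids[non_idx], core_idx = core_idx,
                 noncore_idx = non_idx, Gcc_inv = Gcc_inv, P = P, mnn = mnn),
            class = "apy_inverse")
}

#' @export
print.apy_inverse <- function(x, ...) {
  cat(sprintf("<apy_inverse> %d core + %d noncore animals\n",
              length(x$core_ids), length(x$noncore_ids)))
  invisible(x)
}

#' Assemble the APY inverse as a dense matrix
#'
#' @param apy An `apy_inverse`.
#' @return The assembled symmetric inverse, rows/columns in the original
#'   animal order.
#' @export
apy_matrix <- function(apy) {
  stopifnot(inherits(apy, "apy_inverse"))
  n <- length(apy$ids)
  K <- matrix(0, n, n, dimnames = list(apy$ids, apy$ids))
  ci <- apy$core_idx
  ni <- apy$noncore_idx
  if (length(ni) > 0) {
    Pm <- sweep(apy$P, 2, apy$mnn, "/") # Gcc^-1 Gcn Mnn^-1
    K[ci, ci] <- apy$Gcc_inv + Pm %*% t(apy$P)
    K[ci, ni] <- -Pm
    K[ni, ci] <- -t(Pm)
    K[ni, ni] <- diag(1 / apy$mnn, length(ni))
  } else {
    K[ci, ci] <- apy$Gcc_inv
  }
  (K + t(K)) / 2
}
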