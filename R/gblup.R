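#' Relationship-matrix inverse for GBLUP
#'
#' Builds the `G`-inverse used in the mixed-model equations under one of the
#' three study options: `"standard"` (dense inverse of the blended GRM),
#' `"eig"` (inverse of the blended rank-`r` truncation `U D_r U' + eps I`,
#' computed from the eigenpairs without forming a dense inverse), or
#' `"apy"` (the assembled APY sparse inverse with a random or supplied core).
#'
#' @param bundle A `grm_bundle`; for `"eig"` it must carry the
#'   eigendecomposition (see [grm_eigen()]).
#' @param method One of `"standard"`, `"eig"`, `"apy"`.
#' @param r Number of leading eigenvalues kept (`"eig"` only).
#' @param core_ids Core animal ids (`"apy"` only).
#' @param epsilon Blending constant added to the relationship matrix before
#'   inversion (study convention 0.01).
#' @return An object of class `grm_inverse`: the inverse matrix `K`, ids, and
#'   provenance fields.
#' @export
grm_inverse <- function(bundle, method = c("standard", "eig", "apy"),
                        r = NULL, core_ids = NULL, epsilon = 0.01) {
  stopifnot(inherits(bundle, "grm_bundle"))
  method <- match.arg(method)
  n <- length(bundle$ids)
  K <- switch(method,
    standard = {
      Gb <- blend_grm(bundle, epsilon)
      ch <- tryCatch(chol(Gb), error = function(e)
        stop("blended GRM is singular (standard option); increase epsilon",
             call. = FALSE))
      if (any(diag(ch) < 1e-7 * max(diag(ch))))
        stop("blended GRM is numerically singular (standard option); ",
             "increase epsilon", call. = FALSE)
      chol2inv(ch)
    },
    eig = {
      if (is.null(bundle$D)) bundle <- grm_eigen(bundle)
      if (is.null(r)) stop("method 'eig' needs r", call. = FALSE)
      if (r < 1 || r > n) stop("r must lie in 1..", n, call. = FALSE)
      if (epsilon <= 0)
        stop("blended G_eig is singular for epsilon = 0 (eig option)",
             call. = FALSE)
      r <- as.integer(r)
      d <- bundle$D[seq_len(r)]
      Ur <- bundle$U[, seq_len(r), drop = FALSE]
      # (U_r D_r U_r' + eps I)^-1 = (1/eps) (I - U_r diag(d/(d+eps)) U_r')
      K <- -(Ur %*% ((d / (d + epsilon) / epsilon) * t(Ur)))
      diag(K) <- diag(K) + 1 / epsilon
      K
    },
    apy = {
      if (is.null(core_ids)) stop("method 'apy' needs core_ids", call. = FALSE)
      apy_matrix(apy_inverse(bundle, core_ids, epsilon))
    }
  )
  K <- (K + t(K)) / 2
  dimnames(K) <- list(bundle$ids, bundle$ids)
  structure(list(K = K, ids = bundle$ids, method = method,
                 r = if (identical(method, "eig")) as.integer(r) else NULL,
                 n_core = if (identical(method, "apy")) length(core_ids) else NULL,
                 epsilon = epsilon),
            class = "grm_inverse")
}

#' @export
print.grm_inverse <- function(x, ...) {
  extra <- switch(x$method,
                  eig = sprintf(" (r = %d)", x$r),
                  apy = sprintf(" (%d core)", x$n_core), "")
  cat(sprintf("<grm_inverse> %s%s, %d animals, epsilon = %g\n",
              x$method, extra, length(x$ids), x$epsilon))
  invisible(x)
}

resolve_variances <- function(sigma_u2, sigma_e2, h2) {
  if (is.null(sigma_e2)) {
    if (is.null(h2)) stop("supply sigma_e2 or h2", call. = FALSE)
    stopifnot(h2 > 0, h2 <= 1)
    sigma_e2 <- sigma_u2 * (1 - h2) / h2
  }
  stopifnot(sigma_u2 > 0, sigma_e2 >= 0)
  list(sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
       alpha = sigma_e2 / sigma_u2)
}

#' Solve the GBLUP mixed-model equations
#'
#' Fits `y = 1 mu + u + e` with `var(u) = G sigma_u2` and
#' `var(e) = I sigma_e2` by a direct dense factorization of Henderson's
#' mixed-model equations. Every animal in the relationship matrix receives a
#' genomic breeding value; animals without records are predicted through the
#' relationship structure.
#'
#' @param data A data frame with columns `id` (animal id present in the
#'   relationship matrix) and `y` (record). See [training_phenotypes()].
#' @param ginv A `grm_inverse` (any of the three GRM options).
#' @param sigma_u2 Additive genetic variance.
#' @param sigma_e2 Residual variance; alternatively give `h2` and it is
#'   derived as `sigma_u2 (1 - h2)/h2`.
#' @param h2 Heritability used to derive `sigma_e2` when that is missing.
#' @param include_mean Include the overall mean as fixed effect (default).
#'   With `FALSE` the model has no fixed effect (useful for closed-form
#'   checks).
#' @param keep_lhs_inverse Also invert the full coefficient matrix and store
#'   the animal-block diagonal, from which prediction error variances are
#'   read (`PEV_i = sigma_e2 * LHS^ii`).
#' @return An object of class `gblup_fit`; see [tidy.gblup_fit()].
#' @examples
#' geno <- rbind(a = c(0L, 1L, 2L, 1L), b = c(2L, 1L, 0L, 1L),
#'               c = c(1L, 2L, 0L, 0L), d = c(0L, 1L, 1L, 2L))
#' g <- build_grm(geno)
#' fit <- gblup(data.frame(id = c("a", "b", "c"), y = c(1.2, 0.7, 1.9)),
#'              grm_inverse(g), sigma_u2 = 1, sigma_e2 = 2)
#' tidy(fit)
#' @export
gblup <- function(data, ginv, sigma_u2, sigma_e2 = NULL, h2 = NULL,
                  include_mean = TRUE, keep_lhs_inverse = FALSE) {
  stopifnot(inherits(ginv, "grm_inverse"))
  if (!all(c("id", "y") %in% names(data)))
    stop("`data` needs columns `id` and `y`", call. = FALSE)
  vc <- resolve_variances(sigma_u2, sigma_e2, h2)
  ids <- ginv$ids
  n <- length(ids)
  w <- match(as.character(data$id), ids)
  if (anyNA(w))
    stop("phenotyped animal(s) absent from the relationship matrix: ",
         paste(utils::head(data$id[is.na(w)], 3), collapse = ", "),
         call. = FALSE)
  y <- as.numeric(data$y)
  counts <- tabulate(w, nbins = n) # W'W diagonal
  wty <- numeric(n)
  agg <- tapply(y, w, sum)
  wty[as.integer(names(agg))] <- agg

  A <- vc$alpha * ginv$K
  diag(A) <- diag(A) + counts
  if (include_mean) {
    C <- rbind(c(length(y), counts), cbind(counts, A))
    rhs <- c(sum(y), wty)
  } else {
    C <- A
    rhs <- wty
  }
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular mixed-model coefficient matrix (GRM option '",
         ginv$method, "')", call. = FALSE))
  sol <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  mu_hat <- if (include_mean) sol[1] else 0
  u <- if (include_mean) sol[-1] else sol

  pev <- NULL
  if (keep_lhs_inverse) {
    Cinv <- chol2inv(ch)
    di <- diag(Cinv)
    pev <- vc$sigma_e2 * (if (include_mean) di[-1] else di)
  }
  gebv <- tibble::tibble(id = ids, gebv = as.numeric(u))
  if (!is.null(pev)) gebv$pev <- pev
  structure(list(mu_hat = mu_hat, gebv = gebv, alpha = vc$alpha,
                 sigma_u2 = vc$sigma_u2, sigma_e2 = vc$sigma_e2,
                 method = ginv$method, r = ginv$r, n_core = ginv$n_core,
                 n_records = length(y), n_animals = n,
                 include_mean = include_mean),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit> %s GRM, %d records on %d animals\n",
              x$method, x$n_records, x$n_animals))
  cat(sprintf("  mu_hat = %.4g, alpha = %.4g (h2 = %.3g)\n",
              x$mu_hat, x$alpha, 1 / (1 + x$alpha)))
  invisible(x)
}

#' Tidy a GBLUP fit
#'
#' `tidy()` returns one row per animal (`id`, `gebv`, and `pev` when the
#' left-hand-side inverse was kept); `glance()` returns a one-row model
#' summary.
#'
#' @param x A `gblup_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.gblup_fit <- function(x, ...) x$gebv

#' @rdname tidy.gblup_fit
#' @exportS3Method generics::glance
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble::tibble(mu_hat = x$mu_hat, sigma_u2 = x$sigma_u2,
                 sigma_e2 = x$sigma_e2, alpha = x$alpha, method = x$method,
                 n_records = x$n_records, n_animals = x$n_animals)
}

#' Prediction error variance by direct inversion
#'
#' Assembles the mixed-model equations for the supplied (training) animals
#' and reads `PEV_i = sigma_e2 * LHS^ii` off the animal-block diagonal of the
#' dense inverse of the coefficient matrix. In the study's validation
#' protocol the relationship matrix passed here contains training animals
#' only — validation animals are excluded from the equations entirely.
#'
#' @inheritParams gblup
#' @return A tibble with columns `id` and `pev` for every animal in `ginv`.
#' @export
pev_direct <- function(data, ginv, sigma_u2, sigma_e2 = NULL, h2 = NULL,
                       include_mean = TRUE) {
  fit <- gblup(data, ginv, sigma_u2, sigma_e2, h2,
               include_mean = include_mean, keep_lhs_inverse = TRUE)
  fit$gebv[, c("id", "pev")]
}

#' Prediction error variance through the GRM eigenbasis
#'
#' Computes the same per-animal PEV as [pev_direct()] for the common case in
#' which every animal in the equations carries exactly one record, by
#' rotating the mixed-model equations into the eigenbasis of the training
#' GRM. With the blended GRM written as `U diag(d + eps) U'`, the animal
#' block of the coefficient matrix is `c I - U diag(b) U'` with
#' `c = 1 + alpha/eps` and `b_k = (alpha/eps) d_k/(d_k + eps)`, whose inverse
#' diagonal is available in `O(n r)`; the fixed mean enters as a Woodbury
#' rank-one update. With the full eigenbasis (`r = n`) the result is
#' algebraically identical to the direct dense inversion; with `r < n` it is
#' a reduced-rank approximation and the result carries attribute
#' `truncated = TRUE`.
#'
#' @param bundle A `grm_bundle` of the training animals with its
#'   eigendecomposition (pre-blend); see [grm_eigen()].
#' @param sigma_u2,sigma_e2,h2 Variance components as in [gblup()].
#' @param r Number of leading eigenpairs used; default all (exact).
#' @param epsilon Blending constant.
#' @param include_mean Account for the estimated overall mean.
#' @return A tibble with `id` and `pev`; attribute `truncated` marks the
#'   reduced-rank approximation.
#' @export
pev_reduced_rank <- function(bundle, sigma_u2, sigma_e2 = NULL, h2 = NULL,
                             r = NULL, epsilon = 0.01, include_mean = TRUE) {
  stopifnot(inherits(bundle, "grm_bundle"))
  if (is.null(bundle$D)) bundle <- grm_eigen(bundle)
  vc <- resolve_variances(sigma_u2, sigma_e2, h2)
  n <- length(bundle$D)
  if (is.null(r)) r <- n
  if (r < 1 || r > n) stop("r must lie in 1..", n, call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  r <- as.integer(r)
  truncated <- r < n
  if (truncated)
    message("reduced-rank PEV with r = ", r, " < n = ", n,
            ": approximation, not the exact LHS inverse")
  alpha <- vc$alpha
  d <- bundle$D[seq_len(r)]
  U <- bundle$U[, seq_len(r), drop = FALSE]
  cc <- 1 + alpha / epsilon
  b <- (alpha / epsilon) * d / (d + epsilon)
  # diag of A^-1 with A = c I - U diag(b) U'
  w_diag <- b / (cc * (cc - b))
  diagAinv <- 1 / cc + rowSums(sweep(U * U, 2, w_diag, "*"))
  if (include_mean) {
    # (A - 11'/n_rec)^-1 via rank-one Woodbury; one record per animal
    Ut1 <- colSums(U)
    Ainv1 <- 1 / cc + U %*% (w_diag * Ut1)
    s <- sum(Ainv1)
    denom <- n - s
    if (denom <= 0) stop("degenerate mean absorption in reduced-rank PEV",
                         call. = FALSE)
    diagAinv <- diagAinv + as.numeric(Ainv1)^2 / denom
  }
  out <- tibble::tibble(id = bundle$ids,
                        pev = unname(vc$sigma_e2 * diagAinv))
  attr(out, "truncated") <- truncated
  out
}
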