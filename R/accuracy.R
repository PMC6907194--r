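#' Realized accuracy of genomic prediction
#'
#' Pearson correlation between genomic estimated breeding values and
#' simulated true breeding values, computed over the validation animals
#' (unphenotyped last-generation animals).
#'
#' @param fit A `gblup_fit`, or a numeric vector of GEBV.
#' @param truth A `sim_population` (its `animals` tibble supplies TBV), a
#'   data frame with columns `id` and `tbv`, or a numeric vector aligned
#'   with `fit`.
#' @param ids Validation animal ids. Defaults to the population's validation
#'   set when `truth` is a `sim_population`; ignored for bare vectors.
#' @return A single correlation, or `NA` (with a warning) if either vector
#'   has zero variance.
#' @export
realized_accuracy <- function(fit, truth, ids = NULL) {
  if (is.numeric(fit) && is.numeric(truth)) {
    gebv <- fit
    tbv <- truth
  } else {
    stopifnot(inherits(fit, "gblup_fit"))
    tab <- if (inherits(truth, "sim_population")) truth$animals else truth
    if (is.null(ids) && inherits(truth, "sim_population"))
      ids <- validation_ids(truth)
    if (is.null(ids)) stop("supply validation `ids`", call. = FALSE)
    gebv <- fit$gebv$gebv[match(ids, fit$gebv$id)]
    tbv <- tab$tbv[match(ids, tab$id)]
    if (anyNA(gebv) || anyNA(tbv))
      stop("validation ids missing from fit or truth", call. = FALSE)
  }
  if (var(gebv) == 0 || var(tbv) == 0) {
    warning("zero variance in GEBV or TBV; accuracy undefined")
    return(NA_real_)
  }
  cor(gebv, tbv)
}

#' PEV-based individual accuracy
#'
#' `acc_i = sqrt(1 - PEV_i / (sigma_u2 * g_ii))`. Values of PEV marginally
#' above the prior variance (numerical noise) are clipped to accuracy 0;
#' clearly inconsistent inputs abort.
#'
#' @param pev Per-animal prediction error variance.
#' @param sigma_u2 Additive genetic variance.
#' @param g_ii Per-animal diagonal of the relationship matrix used in the
#'   fit (recycled if scalar).
#' @return Vector of accuracies in `[0, 1]`.
#' @export
pev_accuracy <- function(pev, sigma_u2, g_ii) {
  stopifnot(sigma_u2 > 0, all(g_ii > 0))
  prior <- sigma_u2 * g_ii
  tol <- 1e-8 * max(prior)
  if (any(pev < -tol) || any(pev > prior + tol))
    stop("PEV outside [0, sigma_u2 * g_ii]; inconsistent inputs",
         call. = FALSE)
  sqrt(pmax(0, 1 - pev / prior))
}

#' Effective number of genomic records
#'
#' Inverts `acc_i ~ sqrt(1 - alpha / (alpha + d_p + d_g))`:
#' `d_g = alpha * acc^2 / (1 - acc^2) - d_p`, floored at zero. With one
#' phenotype per animal `d_p ~ 1`.
#'
#' @param acc Individual accuracy in `[0, 1)`; accuracy of exactly 1 maps to
#'   `NA` (infinitely many records).
#' @param alpha Variance ratio `sigma_e2 / sigma_u2`.
#' @param d_p Effective phenotypic records per animal (default 1).
#' @return Vector of effective genomic record counts.
#' @export
effective_genomic_records <- function(acc, alpha, d_p = 1) {
  stopifnot(alpha > 0, all(acc >= 0), all(acc <= 1))
  out <- ifelse(acc >= 1, NA_real_,
                pmax(0, alpha * acc^2 / (1 - acc^2) - d_p))
  out
}

#' Population-level accuracy from average genomic information
#'
#' `sqrt(1 - alpha / (alpha + mean_d_g))`: the approximate accuracy of
#' unphenotyped validation animals predicted from the average effective
#' genomic records of the training population.
#'
#' @param mean_d_g Average effective genomic records (non-negative).
#' @param alpha Variance ratio `sigma_e2 / sigma_u2`.
#' @return Accuracy in `[0, 1)`.
#' @export
population_accuracy <- function(mean_d_g, alpha) {
  stopifnot(all(mean_d_g >= 0), alpha > 0)
  sqrt(1 - alpha / (alpha + mean_d_g))
}

#' Eigenvalues exceeding the variance ratio
#'
#' Diagnostic for which part of the spectrum can influence prediction: the
#' number of eigenvalues strictly greater than `alpha = sigma_e2/sigma_u2`,
#' together with the fraction of genomic variance those eigenvalues explain.
#' Smaller eigenvalues are effectively ignored by the mixed model at that
#' information level.
#'
#' @param x Eigenvalues sorted decreasing (or a `grm_bundle`).
#' @param alpha Variance ratio.
#' @return A one-row tibble: `alpha`, `count`, `variance_fraction`.
#' @examples
#' alpha_threshold_count(c(4, 3, 2, 1), 2.5)
#' @export
alpha_threshold_count <- function(x, alpha) {
  d <- as_eigenvalues(x)
  stopifnot(alpha >= 0)
  count <- sum(d > alpha)
  frac <- if (count == 0) 0 else sum(d[seq_len(count)]) / sum(d)
  tibble::tibble(alpha = alpha, count = count, variance_fraction = frac)
}

#' Independent chromosome segment formulas
#'
#' The three classical approximations to the number of independent
#' chromosome segments `M_e` for effective population size `Ne` and genome
#' length `L` in Morgan: `4 Ne L` (junction count under random mating),
#' `2 Ne L` (accounting for selection), and `2 Ne L / ln(4 Ne L)` (natural
#' logarithm).
#'
#' @param Ne Effective population size.
#' @param L Genome length in Morgan.
#' @return A tibble with columns `formula` and `m_e`.
#' @examples
#' me_formulas(100, 30)
#' @export
me_formulas <- function(Ne, L) {
  stopifnot(Ne > 0, L > 0)
  tibble::tibble(
    formula = c("4NeL", "2NeL", "2NeL/log(4NeL)"),
    m_e = c(4 * Ne * L, 2 * Ne * L, 2 * Ne * L / log(4 * Ne * L))
  )
}
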