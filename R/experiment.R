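#' Subset a GRM to a set of animals
#'
#' Extracts the relationship block of the given animals (dropping any stored
#' eigendecomposition, which no longer applies). Used by the PEV validation
#' protocol, where validation animals are excluded from the equations
#' entirely while allele frequencies remain those of the full genotyped set.
#'
#' @param bundle A `grm_bundle`.
#' @param ids Animal ids to keep.
#' @return A `grm_bundle` for the subset.
#' @export
subset_grm <- function(bundle, ids) {
  stopifnot(inherits(bundle, "grm_bundle"))
  idx <- match(as.character(ids), bundle$ids)
  if (anyNA(idx)) stop("unknown animal id in subset", call. = FALSE)
  out <- bundle
  out$G <- bundle$G[idx, idx, drop = FALSE]
  out$ids <- bundle$ids[idx]
  out$U <- NULL
  out$D <- NULL
  out
}

#' Population accuracy from training-set PEV
#'
#' The study's second validation protocol: exclude the validation animals
#' from the equations, compute per-animal PEV for the training set, convert
#' to individual accuracies `sqrt(1 - PEV/(sigma_u2 g_ii))`, invert the
#' effective-record formula to get per-animal genomic information `d_g`, and
#' predict the accuracy of unphenotyped animals from the average
#' `sqrt(1 - alpha/(alpha + mean(d_g)))`.
#'
#' @param pop A `sim_population` (phenotypes at the heritability of
#'   interest; see [assign_phenotypes()]).
#' @param bundle GRM of all genotyped animals ([build_grm()]); the training
#'   block is extracted internally.
#' @param method `"eigen"` (reduced-rank route at full rank, exact) or
#'   `"direct"` (dense inversion of the left-hand side).
#' @param epsilon Blending constant.
#' @return A list: `accuracy` (population-level accuracy of validation
#'   animals), `mean_d_g`, and `training` (per-animal tibble with `pev`,
#'   `acc`, `d_g`).
#' @export
pev_population_accuracy <- function(pop, bundle,
                                    method = c("eigen", "direct"),
                                    epsilon = 0.01) {
  method <- match.arg(method)
  stopifnot(inherits(pop, "sim_population"))
  arch <- pop$architecture
  train <- training_phenotypes(pop)
  gt <- subset_grm(bundle, train$id)
  if (method == "eigen") {
    gt <- grm_eigen(gt)
    pevs <- pev_reduced_rank(gt, sigma_u2 = arch$sigma_u2,
                             sigma_e2 = arch$sigma_e2, epsilon = epsilon)
  } else {
    ginv <- grm_inverse(gt, "standard", epsilon = epsilon)
    pevs <- pev_direct(train, ginv, sigma_u2 = arch$sigma_u2,
                       sigma_e2 = arch$sigma_e2)
  }
  g_ii <- diag(gt$G)[match(pevs$id, gt$ids)] + epsilon
  acc <- pev_accuracy(pevs$pev, arch$sigma_u2, g_ii)
  d_g <- effective_genomic_records(acc, arch$alpha, d_p = 1)
  mean_d_g <- mean(d_g, na.rm = TRUE)
  list(accuracy = population_accuracy(mean_d_g, arch$alpha),
       mean_d_g = mean_d_g,
       training = tibble::tibble(id = pevs$id, pev = pevs$pev, acc = acc,
                                 d_g = d_g))
}

#' Define a replicated simulation study
#'
#' Describes the full experiment: which population sizes and heritabilities
#' to simulate, which variance-fraction thresholds to sweep, which GRM
#' options to fit, and how many replicates. Within a replicate, every GRM
#' option and threshold runs on the same simulated genotypes and phenotypes
#' (paired comparison); all randomness derives from the master seed.
#'
#' @param h2 Heritabilities to run.
#' @param n_genotyped Genotyped-population sizes to run.
#' @param cells Optional tibble with columns `n_genotyped`, `h2` giving the
#'   exact scenario grid; defaults to the full crossing of the two vectors.
#' @param thresholds Explained-variance fractions for the eigen-truncation
#'   sweep; APY uses the same eigenvalue counts as core sizes.
#' @param grm_options Subset of `"standard"`, `"eig"`, `"apy"`.
#' @param n_replicates Number of simulation replicates.
#' @param seed Master seed.
#' @param scenario_fn Function `(n_genotyped, heritability, seed, ...)`
#'   returning a [sim_scenario()]; defaults to [desk_scenario()].
#' @param pev Also compute the PEV-based population accuracy (standard GRM,
#'   training animals only)?
#' @return An object of class `study_design`.
#' @seealso [run_study()]
#' @export
study_design <- function(h2 = c(0.1, 0.3, 0.6, 0.9), n_genotyped = 3000,
                         cells = NULL,
                         thresholds = c(0.10, 0.30, 0.50, 0.70, 0.90, 0.95,
                                        0.98),
                         grm_options = c("standard", "eig", "apy"),
                         n_replicates = 5, seed = 1,
                         scenario_fn = desk_scenario, pev = FALSE) {
  grm_options <- match.arg(grm_options, several.ok = TRUE)
  if (is.null(cells))
    cells <- tidyr::crossing(n_genotyped = n_genotyped, h2 = h2)
  stopifnot(all(c("n_genotyped", "h2") %in% names(cells)),
            n_replicates >= 1)
  structure(list(cells = cells, thresholds = sort(thresholds),
                 grm_options = grm_options, n_replicates = n_replicates,
                 seed = as.integer(seed), scenario_fn = scenario_fn,
                 pev = pev),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d cells x %d replicates, options: %s\n",
              nrow(x$cells), x$n_replicates,
              paste(x$grm_options, collapse = ", ")))
  invisible(x)
}

#' Run a replicated GRM-dimensionality study
#'
#' For each replicate and population size: simulate the population, build
#' and eigendecompose the GRM, record the eigenvalue profile at all
#' thresholds, then for each heritability fit GBLUP with the standard GRM,
#' with the rank-truncated GRM at each threshold's eigenvalue count, and
#' with the APY inverse using that same count as the number of randomly
#' chosen core animals. Realized accuracy is the correlation between GEBV
#' and TBV in the unphenotyped last generation; optionally the PEV-based
#' population accuracy is computed on the training set.
#'
#' A replicate that fails is recorded and skipped; the run aborts if more
#' than one replicate fails.
#'
#' @param design A [study_design()].
#' @return An object of class `grm_study`: tibbles `accuracy` (one row per
#'   replicate x cell x option x threshold) and `profile` (eigenvalue counts
#'   per threshold), plus the design. Summarise with [summarise_study()].
#' @export
run_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  sizes <- sort(unique(design$cells$n_genotyped))
  R <- design$n_replicates
  sim_seeds <- matrix(sample.int(2^31 - 2, R * length(sizes)),
                      nrow = R, dimnames = list(NULL, as.character(sizes)))
  pheno_seeds <- array(sample.int(2^31 - 2, R * nrow(design$cells)),
                       dim = c(R, nrow(design$cells)))
  acc_rows <- list()
  prof_rows <- list()
  failures <- character(0)

  for (rep in seq_len(R)) {
    res <- tryCatch(
      run_study_replicate(design, rep, sim_seeds[rep, ],
                          pheno_seeds[rep, ]),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("replicate ", rep, " failed: ", conditionMessage(res),
              call. = FALSE)
      failures <- c(failures, sprintf("replicate %d: %s", rep,
                                      conditionMessage(res)))
      next
    }
    acc_rows[[rep]] <- res$accuracy
    prof_rows[[rep]] <- res$profile
  }
  if (length(failures) > 1)
    stop("more than one replicate failed:\n",
         paste(failures, collapse = "\n"), call. = FALSE)
  structure(list(accuracy = dplyr::bind_rows(acc_rows),
                 profile = dplyr::bind_rows(prof_rows),
                 design = design, failures = failures),
            class = "grm_study")
}

run_study_replicate <- function(design, rep, sim_seed_by_size, pheno_seeds) {
  acc_rows <- list()
  prof_rows <- list()
  cells <- design$cells
  for (n in sort(unique(cells$n_genotyped))) {
    sc <- design$scenario_fn(n_genotyped = n,
                             seed = sim_seed_by_size[[as.character(n)]])
    pop <- simulate_population(sc)
    grm <- build_grm(pop$genotypes)
    need_eig <- any(design$grm_options %in% c("eig", "apy")) || TRUE
    if (need_eig) grm <- grm_eigen(grm)
    prof <- variance_explained_profile(grm, design$thresholds)
    prof_rows[[length(prof_rows) + 1L]] <-
      dplyr::mutate(prof, replicate = rep, n_genotyped = n,
                    n_animals = length(grm$ids), .before = 1)
    ginv_std <- if ("standard" %in% design$grm_options || design$pev)
      grm_inverse(grm, "standard") else NULL

    cell_idx <- which(cells$n_genotyped == n)
    for (ci in cell_idx) {
      h2 <- cells$h2[ci]
      pop <- assign_phenotypes(pop, h2, seed = pheno_seeds[ci])
      arch <- pop$architecture
      train <- training_phenotypes(pop)
      vids <- validation_ids(pop)
      add_row <- function(option, threshold, rank, fit, pop_acc = NA_real_,
                          mean_d_g = NA_real_) {
        acc <- realized_accuracy(fit, pop, vids)
        acc_rows[[length(acc_rows) + 1L]] <<- tibble::tibble(
          replicate = rep, n_genotyped = n, h2 = h2, option = option,
          threshold = threshold, rank = rank, accuracy = acc,
          pev_accuracy = pop_acc, mean_d_g = mean_d_g,
          sigma_u2 = arch$sigma_u2, sigma_e2 = arch$sigma_e2)
      }
      if ("standard" %in% design$grm_options) {
        fit <- gblup(train, ginv_std, sigma_u2 = arch$sigma_u2,
                     sigma_e2 = arch$sigma_e2)
        if (design$pev) {
          pa <- pev_population_accuracy(pop, grm)
          add_row("standard", NA_real_, NA_integer_, fit, pa$accuracy,
                  pa$mean_d_g)
        } else {
          add_row("standard", NA_real_, NA_integer_, fit)
        }
      }
      for (ti in seq_along(design$thresholds)) {
        r <- prof$n_eigenvalues[ti]
        if ("eig" %in% design$grm_options) {
          fit <- gblup(train, grm_inverse(grm, "eig", r = r),
                       sigma_u2 = arch$sigma_u2, sigma_e2 = arch$sigma_e2)
          add_row("eig", design$thresholds[ti], r, fit)
        }
        if ("apy" %in% design$grm_options) {
          core <- select_core_random(grm, r)
          fit <- gblup(train, grm_inverse(grm, "apy", core_ids = core),
                       sigma_u2 = arch$sigma_u2, sigma_e2 = arch$sigma_e2)
          add_row("apy", design$thresholds[ti], r, fit)
        }
      }
    }
  }
  list(accuracy = dplyr::bind_rows(acc_rows),
       profile = dplyr::bind_rows(prof_rows))
}

#' @export
print.grm_study <- function(x, ...) {
  cat(sprintf("<grm_study> %d accuracy rows, %d profile rows, %d replicates\n",
              nrow(x$accuracy), nrow(x$profile),
              x$design$n_replicates - length(x$failures)))
  invisible(x)
}

#' Summarise a study across replicates
#'
#' Replicate means with standard errors (standard deviation of replicate
#' values divided by the square root of the replicate count).
#'
#' @param study A `grm_study` from [run_study()].
#' @return A tibble with one row per cell x option x threshold: `accuracy`
#'   (mean), `se`, `n_replicates`, and the PEV-based population accuracy
#'   where computed.
#' @export
summarise_study <- function(study) {
  stopifnot(inherits(study, "grm_study"))
  study$accuracy |>
    dplyr::group_by(.data$n_genotyped, .data$h2, .data$option,
                    .data$threshold, .data$rank) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      se = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
      mean_pev_accuracy = mean(.data$pev_accuracy),
      n_replicates = dplyr::n(), .groups = "drop")
}

#' Eigenvalue-profile study across population sizes
#'
#' Simulates populations of the given sizes (sharing genome parameters) and
#' tabulates how many eigenvalues explain each variance fraction.
#'
#' @param n_genotyped Population sizes to profile.
#' @param thresholds Variance fractions.
#' @param n_replicates Replicates per size.
#' @param seed Master seed.
#' @param scenario_fn Scenario generator, as in [study_design()].
#' @return A tibble: `n_genotyped`, `replicate`, `n_animals`, `threshold`,
#'   `n_eigenvalues`, `fraction_explained`.
#' @export
eigen_profile_study <- function(n_genotyped = c(1500, 3000, 6000),
                                thresholds = c(0.10, 0.30, 0.50, 0.70, 0.90,
                                               0.95, 0.98),
                                n_replicates = 1, seed = 1,
                                scenario_fn = desk_scenario) {
  set.seed(seed)
  seeds <- matrix(sample.int(2^31 - 2, n_replicates * length(n_genotyped)),
                  nrow = n_replicates)
  rows <- list()
  for (rep in seq_len(n_replicates)) {
    for (si in seq_along(n_genotyped)) {
      sc <- scenario_fn(n_genotyped = n_genotyped[si], seed = seeds[rep, si])
      pop <- simulate_population(sc)
      grm <- grm_eigen(build_grm(pop$genotypes))
      prof <- variance_explained_profile(grm, thresholds)
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        prof, n_genotyped = n_genotyped[si], replicate = rep,
        n_animals = length(grm$ids), .before = 1)
    }
  }
  dplyr::bind_rows(rows)
}
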