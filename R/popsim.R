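#' Build the locus map for a scenario
#'
#' SNPs are evenly spaced along each chromosome; QTL are placed uniformly at
#' random (so this function consumes random numbers). QTL are distinct loci
#' and are excluded from the marker panel when genotypes are emitted.
#'
#' @param scenario A [sim_scenario()].
#' @return A tibble with one row per locus, ordered by (chromosome, position):
#'   columns `locus` (index), `id`, `chrom`, `pos_cM`, `type` ("snp"/"qtl").
#' @keywords internal
build_genome_map <- function(scenario) {
  nc <- scenario$n_chromosomes
  len <- scenario$chrom_length_cM
  per_chr <- function(total) {
    base <- total %/% nc
    extra <- total %% nc
    base + (seq_len(nc) <= extra)
  }
  n_snp_c <- per_chr(scenario$n_snp)
  n_qtl_c <- per_chr(scenario$n_qtl)
  pieces <- lapply(seq_len(nc), function(c) {
    snp_pos <- if (n_snp_c[c] > 0) (seq_len(n_snp_c[c]) - 0.5) / n_snp_c[c] * len else numeric(0)
    qtl_pos <- sort(runif(n_qtl_c[c], 0, len))
    tibble::tibble(
      chrom = c,
      pos_cM = c(snp_pos, qtl_pos),
      type = rep(c("snp", "qtl"), c(n_snp_c[c], n_qtl_c[c])),
      within = c(seq_len(n_snp_c[c]), seq_len(n_qtl_c[c]))
    )
  })
  map <- dplyr::arrange(dplyr::bind_rows(pieces), .data$chrom, .data$pos_cM)
  map$locus <- seq_len(nrow(map))
  map$id <- sprintf("%s%d_%d", ifelse(map$type == "snp", "snp", "qtl"),
                    map$chrom, map$within)
  map$within <- NULL
  map[, c("locus", "id", "chrom", "pos_cM", "type")]
}

# chromosome geometry in the form the C++ kernel expects
map_geometry <- function(map) {
  stopifnot(!is.unsorted(map$chrom))
  pos_m <- map$pos_cM / 100
  offsets <- c(0L, cumsum(tabulate(map$chrom, nbins = max(map$chrom))))
  list(pos_morgan = pos_m, chrom_offset = as.integer(offsets))
}

# one generation of random union of gametes; haps is loci x (2N) raw
mate_generation <- function(haps, sire_col, dam_col, geom, mutation_rate) {
  n <- length(sire_col)
  g1 <- cpp_drop_gametes(haps, as.integer(sire_col - 1L), geom$pos_morgan,
                         geom$chrom_offset, mutation_rate)
  g2 <- cpp_drop_gametes(haps, as.integer(dam_col - 1L), geom$pos_morgan,
                         geom$chrom_offset, mutation_rate)
  out <- matrix(as.raw(0), nrow(haps), 2L * n)
  out[, seq(1L, 2L * n, by = 2L)] <- g1
  out[, seq(2L, 2L * n, by = 2L)] <- g2
  out
}

#' Simulate one meiosis
#'
#' Produces a single gamete from a parent: crossover counts per chromosome
#' are Poisson with mean equal to the chromosome length in Morgan, crossover
#' positions are uniform (no interference), chromosomes assort independently,
#' and each transmitted allele flips with probability `mutation_rate`.
#'
#' @param parent A loci x 2 matrix of 0/1 allele states (the two haplotypes),
#'   rows ordered as in `map`.
#' @param map Locus map as returned by the simulator (columns `chrom`,
#'   `pos_cM`, sorted by chromosome and position).
#' @param mutation_rate Per-locus flip probability.
#' @return Integer vector of 0/1 allele states, one per locus.
#' @examples
#' map <- tibble::tibble(chrom = 1, pos_cM = c(10, 50, 90))
#' parent <- cbind(c(0L, 0L, 0L), c(1L, 1L, 1L))
#' set.seed(1)
#' meiosis(parent, map)
#' @export
meiosis <- function(parent, map, mutation_rate = 0) {
  parent <- as.matrix(parent)
  stopifnot(ncol(parent) == 2, nrow(parent) == nrow(map),
            all(parent %in% c(0L, 1L)))
  geom <- map_geometry(map)
  haps <- matrix(as.raw(parent), nrow(parent), 2)
  g <- cpp_drop_gametes(haps, 0L, geom$pos_morgan, geom$chrom_offset,
                        mutation_rate)
  as.integer(g)
}

# linear census ramp: start -> bottleneck over the first half of the
# historical generations, bottleneck -> end over the second half
hist_sizes <- function(scenario) {
  n <- scenario$n_hist_generations
  h1 <- n %/% 2L
  first <- if (h1 > 0)
    seq(scenario$hist_size_start, scenario$hist_size_bottleneck,
        length.out = h1 + 1)[-1] else numeric(0)
  second <- seq(scenario$hist_size_bottleneck, scenario$hist_size_end,
                length.out = n - h1 + 1)[-1]
  as.integer(round(c(first, second)))
}

#' Simulate the historical population
#'
#' Runs the long historical phase that establishes linkage disequilibrium and
#' mutation-drift balance: founders carry biallelic loci with equal allele
#' frequencies (each allele Bernoulli(1/2)); each generation is produced by
#' random union of gametes from two distinct parents; the census size follows
#' a linear ramp from the starting size to the bottleneck at the midpoint and
#' back up to the final size; recurrent mutation acts at every meiosis.
#'
#' Calling this function seeds the R random number generator from
#' `scenario$seed`, so a scenario reproduces bit-identically.
#'
#' @param scenario A [sim_scenario()].
#' @param keep_founders Also return the founder haplotypes (for lineage
#'   checks; off by default to save memory).
#' @return An object of class `hist_population`: the final historical
#'   generation (haplotypes), the locus map, the census-size trajectory and
#'   the scenario.
#' @seealso [simulate_recent()], [simulate_population()]
#' @export
simulate_historical <- function(scenario, keep_founders = FALSE) {
  validate_scenario(scenario)
  set.seed(scenario$seed)
  map <- build_genome_map(scenario)
  geom <- map_geometry(map)
  sizes <- hist_sizes(scenario)
  n_loci <- nrow(map)

  n0 <- scenario$hist_size_start
  haps <- matrix(as.raw(rbinom(n_loci * 2L * n0, 1L, 0.5)), n_loci, 2L * n0)
  founders <- if (keep_founders) haps else NULL
  for (g in seq_along(sizes)) {
    n_prev <- ncol(haps) %/% 2L
    n_new <- sizes[g]
    p1 <- sample.int(n_prev, n_new, replace = TRUE)
    # second parent distinct from the first
    p2 <- 1L + (p1 - 1L + sample.int(n_prev - 1L, n_new, replace = TRUE)) %% n_prev
    haps <- mate_generation(haps, p1, p2, geom, scenario$mutation_rate)
  }
  structure(list(haps = haps, map = map, sizes = sizes, scenario = scenario,
                 founders = founders),
            class = "hist_population")
}

#' @export
print.hist_population <- function(x, ...) {
  cat(sprintf("<hist_population> %d individuals, %d loci (%d SNP, %d QTL)\n",
              ncol(x$haps) %/% 2L, nrow(x$map), sum(x$map$type == "snp"),
              sum(x$map$type == "qtl")))
  invisible(x)
}

#' Simulate the recent breeding generations
#'
#' Starting from the final historical generation, simulates discrete recent
#' generations: each generation samples the scenario's number of sires and
#' dams at random from the previous generation and mates them at random (dams
#' and sires drawn with replacement per offspring) until the generation quota
#' is met. The last three generations are genotyped (equal share of
#' `n_genotyped` each); the first two genotyped generations receive
#' phenotypes; the final generation is the unphenotyped validation set.
#'
#' True breeding values are sums of QTL allele counts times gamma-magnitude,
#' random-sign allelic effects. The genetic variance is taken as the realized
#' variance of TBV among genotyped animals, the residual variance is set so
#' that the realized heritability equals the scenario value, and phenotypes
#' are `trait_mean + TBV + N(0, sigma_e2)`. Markers that are monomorphic
#' among genotyped animals are dropped from the genotype matrix; QTL are
#' never part of the marker panel.
#'
#' @param hist A `hist_population` from [simulate_historical()].
#' @param scenario The same scenario (defaults to the one stored in `hist`).
#' @return An object of class `sim_population`; see [simulate_population()].
#' @export
simulate_recent <- function(hist, scenario = hist$scenario) {
  stopifnot(inherits(hist, "hist_population"))
  map <- hist$map
  geom <- map_geometry(map)
  qtl_rows <- which(map$type == "qtl")
  snp_rows <- which(map$type == "snp")
  n_qtl <- length(qtl_rows)
  G <- scenario$n_recent_generations
  geno_gens <- seq.int(max(1L, G - 2L), G)
  pheno_gens <- utils::head(geno_gens, -1)
  per_gen <- ceiling(scenario$n_genotyped / length(geno_gens))
  n_off <- max(per_gen, scenario$n_dams_per_gen + scenario$n_sires_per_gen)

  n0 <- ncol(hist$haps) %/% 2L
  if (n0 < scenario$n_dams_per_gen + scenario$n_sires_per_gen)
    stop("historical population smaller than the required dams + sires",
         call. = FALSE)

  effects <- rgamma(n_qtl, shape = scenario$qtl_gamma_shape, scale = 1) *
    sample(c(-1, 1), n_qtl, replace = TRUE)

  id_of <- function(g, n) sprintf("G%d_%05d", g, seq_len(n))
  haps <- hist$haps
  prev_ids <- id_of(0L, n0)
  ped <- vector("list", G + 1L)
  tbv0 <- drop(cpp_allele_counts(haps, as.integer(qtl_rows - 1L)) %*% effects)
  ped[[1]] <- tibble::tibble(id = prev_ids, sire = NA_character_,
                             dam = NA_character_, generation = 0L,
                             sex = NA_character_, tbv = tbv0)
  geno_parts <- list()
  geno_ids <- character(0)
  geno_gen_of <- integer(0)

  for (g in seq_len(G)) {
    n_prev <- ncol(haps) %/% 2L
    sires <- sample.int(n_prev, scenario$n_sires_per_gen)
    dams <- sample(setdiff(seq_len(n_prev), sires), scenario$n_dams_per_gen)
    # record parental roles as sexes in the previous generation
    sex_prev <- rep(NA_character_, n_prev)
    sex_prev[sires] <- "M"
    sex_prev[dams] <- "F"
    ped[[g]]$sex <- sex_prev

    sire_col <- sample(sires, n_off, replace = TRUE)
    dam_col <- sample(dams, n_off, replace = TRUE)
    haps <- mate_generation(haps, sire_col, dam_col, geom,
                            scenario$mutation_rate)
    ids <- id_of(g, n_off)
    tbv_g <- drop(cpp_allele_counts(haps, as.integer(qtl_rows - 1L)) %*% effects)
    ped[[g + 1L]] <- tibble::tibble(id = ids, sire = prev_ids[sire_col],
                                    dam = prev_ids[dam_col], generation = g,
                                    sex = NA_character_, tbv = tbv_g)
    if (g %in% geno_gens) {
      sel <- if (n_off > per_gen) sort(sample.int(n_off, per_gen)) else seq_len(n_off)
      counts <- cpp_allele_counts(haps, as.integer(snp_rows - 1L))[sel, , drop = FALSE]
      geno_parts[[length(geno_parts) + 1L]] <- counts
      geno_ids <- c(geno_ids, ids[sel])
      geno_gen_of <- c(geno_gen_of, rep(g, length(sel)))
    }
    prev_ids <- ids
  }
  animals <- dplyr::bind_rows(ped)
  animals$sex[is.na(animals$sex) & animals$generation > 0L] <-
    sample(c("M", "F"), sum(is.na(animals$sex) & animals$generation > 0L),
           replace = TRUE)

  geno <- do.call(rbind, geno_parts)
  rownames(geno) <- geno_ids
  colnames(geno) <- map$id[snp_rows]
  p <- colMeans(geno) / 2
  keep <- p > 0 & p < 1
  if (mean(!keep) > 0.5)
    stop(sprintf(paste0("%.0f%% of markers are monomorphic among genotyped ",
                        "animals; drift parameters look degenerate"),
                 100 * mean(!keep)), call. = FALSE)
  geno <- geno[, keep, drop = FALSE]
  marker_map <- map[snp_rows[keep], c("id", "chrom", "pos_cM")]

  animals$genotyped <- animals$id %in% geno_ids
  animals$role <- dplyr::case_when(
    animals$genotyped & animals$generation == G ~ "validation",
    animals$genotyped ~ "training",
    animals$generation == 0L ~ "founder",
    TRUE ~ "ungenotyped"
  )
  pop <- structure(list(
    animals = animals, genotypes = geno, map = marker_map,
    architecture = list(
      qtl_map = map[qtl_rows, c("id", "chrom", "pos_cM")],
      qtl_effects = effects,
      sigma_u2 = NA_real_, sigma_e2 = NA_real_, alpha = NA_real_,
      heritability = NA_real_
    ),
    scenario = scenario,
    n_markers_dropped = sum(!keep),
    phenotyped_generations = pheno_gens
  ), class = "sim_population")
  assign_phenotypes(pop, scenario$heritability)
}

#' Draw (or redraw) phenotypes at a given heritability
#'
#' Phenotypes are assigned to genotyped animals of the phenotyped generations
#' as `trait_mean + TBV + N(0, sigma_e2)`, where the genetic variance is the
#' realized TBV variance among genotyped animals and `sigma_e2` is set so the
#' realized heritability equals `heritability`. Redrawing at a different
#' heritability keeps genotypes and TBV fixed, which is how paired
#' heritability scenarios share one simulated population.
#'
#' @param pop A `sim_population`.
#' @param heritability Heritability in (0, 1].
#' @param seed Optional seed for the residual draw (otherwise the current RNG
#'   stream is used).
#' @return The updated `sim_population`.
#' @export
assign_phenotypes <- function(pop, heritability, seed = NULL) {
  stopifnot(inherits(pop, "sim_population"),
            heritability > 0, heritability <= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- pop$animals
  genotyped_tbv <- a$tbv[a$genotyped]
  sigma_u2 <- var(genotyped_tbv)
  sigma_e2 <- sigma_u2 * (1 - heritability) / heritability
  is_pheno <- a$genotyped & a$generation %in% pop$phenotyped_generations
  a$phenotype <- NA_real_
  a$phenotype[is_pheno] <- pop$scenario$trait_mean + a$tbv[is_pheno] +
    rnorm(sum(is_pheno), 0, sqrt(sigma_e2))
  pop$animals <- a
  pop$architecture$sigma_u2 <- sigma_u2
  pop$architecture$sigma_e2 <- sigma_e2
  pop$architecture$alpha <- sigma_e2 / sigma_u2
  pop$architecture$heritability <- heritability
  pop
}

#' Simulate a full breeding population
#'
#' Convenience wrapper running [simulate_historical()] followed by
#' [simulate_recent()]. All randomness derives from `scenario$seed`.
#'
#' @param scenario A [sim_scenario()].
#' @return An object of class `sim_population` with elements:
#' \describe{
#'   \item{animals}{tibble of all animals: `id`, `sire`, `dam`, `generation`,
#'     `sex`, `tbv`, `phenotype` (NA unless phenotyped), `genotyped`, `role`
#'     (founder / ungenotyped / training / validation).}
#'   \item{genotypes}{integer matrix of 0/1/2 allele counts, genotyped
#'     animals x polymorphic SNP markers, with animal ids as row names.}
#'   \item{map}{tibble of retained markers (`id`, `chrom`, `pos_cM`).}
#'   \item{architecture}{QTL map and effects, realized `sigma_u2`,
#'     `sigma_e2`, `alpha` and heritability.}
#' }
#' @examples
#' sc <- desk_scenario(n_genotyped = 150, n_snp = 400, n_qtl = 40,
#'                     n_dams_per_gen = 40, hist_size_start = 60,
#'                     hist_size_bottleneck = 20, hist_size_end = 100,
#'                     n_hist_generations = 15, seed = 7)
#' pop <- simulate_population(sc)
#' pop
#' @export
simulate_population <- function(scenario) {
  simulate_recent(simulate_historical(scenario), scenario)
}

#' @export
print.sim_population <- function(x, ...) {
  a <- x$animals
  cat(sprintf("<sim_population> %d animals over %d recent generations\n",
              sum(a$generation > 0), x$scenario$n_recent_generations))
  cat(sprintf("  genotyped: %d (%d training, %d validation), markers: %d (%d dropped)\n",
              sum(a$genotyped), sum(a$role == "training"),
              sum(a$role == "validation"), ncol(x$genotypes),
              x$n_markers_dropped))
  cat(sprintf("  h2 = %g, sigma_u2 = %.4g, sigma_e2 = %.4g, alpha = %.4g\n",
              x$architecture$heritability, x$architecture$sigma_u2,
              x$architecture$sigma_e2, x$architecture$alpha))
  invisible(x)
}

#' Training phenotypes and validation ids
#'
#' Helpers extracting the GBLUP inputs from a simulated population:
#' `training_phenotypes()` returns the records of phenotyped (training)
#' animals, `validation_ids()` the ids of the unphenotyped last-generation
#' animals.
#'
#' @param pop A `sim_population`.
#' @return A tibble with columns `id`, `y` (records), or a character vector
#'   of ids.
#' @export
training_phenotypes <- function(pop) {
  a <- dplyr::filter(pop$animals, .data$role == "training")
  tibble::tibble(id = a$id, y = a$phenotype)
}

#' @rdname training_phenotypes
#' @export
validation_ids <- function(pop) {
  pop$animals$id[pop$animals$role == "validation"]
}

#' Mean expected heterozygosity
#'
#' Average over loci of `2 p (1 - p)` with `p` the observed allele frequency.
#' Founders of the historical phase start at 0.5; drift through the
#' bottleneck pushes the value down.
#'
#' @param x A `hist_population`, a `sim_population`, or a 0/1/2 genotype
#'   matrix (animals x loci).
#' @return A single numeric value.
#' @export
mean_heterozygosity <- function(x) {
  counts <- if (inherits(x, "hist_population")) {
    cpp_allele_counts(x$haps, seq_len(nrow(x$map)) - 1L)
  } else if (inherits(x, "sim_population")) {
    x$genotypes
  } else {
    as.matrix(x)
  }
  p <- colMeans(counts) / 2
  mean(2 * p * (1 - p))
}
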