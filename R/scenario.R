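#' Define a breeding-population simulation scenario
#'
#' A scenario bundles every parameter of the forward-in-time simulator: the
#' historical demography that builds up linkage disequilibrium (a long phase
#' with a bottleneck followed by expansion), the recent breeding structure
#' (discrete generations of few sires and many dams, giving a small effective
#' population size), the genome (chromosome number and map length, SNP and QTL
#' counts), the trait architecture (gamma-distributed QTL effects,
#' heritability) and the random seed.
#'
#' The default values reproduce the full-scale study design: a historical
#' population of 1250 generations shrinking linearly from 5000 to 1000
#' individuals over the first half and expanding to 25,015 over the second
#' half; 10 recent generations of 10 sires x 1000 dams (Ne of about 40); a
#' genome of 10 chromosomes of 100 cM; 50,000 SNPs and 3000 QTL with a
#' recurrent mutation rate of 2.5e-5; 6000 genotyped animals in the last three
#' generations, phenotyped in the first two of those. Use [desk_scenario()]
#' for a reduced profile that preserves Ne and genome length and runs on a
#' desktop.
#'
#' @param n_hist_generations Number of historical generations.
#' @param hist_size_start,hist_size_bottleneck,hist_size_end Census sizes of
#'   the historical population at the start, the midpoint bottleneck, and the
#'   end. The size follows a linear ramp between these points.
#' @param n_recent_generations Number of discrete recent generations.
#' @param n_sires_per_gen,n_dams_per_gen Breeding males and females sampled
#'   each recent generation. Effective size is `4*Ns*Nd/(Ns+Nd)`.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_cM Map length of each chromosome in centimorgan.
#' @param n_snp,n_qtl Genome-wide counts of SNP markers (evenly spaced) and
#'   QTL (uniformly placed). QTL are distinct loci, excluded from the marker
#'   panel.
#' @param mutation_rate Per-locus, per-meiosis recurrent mutation probability.
#' @param qtl_gamma_shape Shape of the gamma distribution of QTL effect
#'   magnitudes (scale 1, random sign); the trait is rescaled afterwards so
#'   the absolute scale is irrelevant.
#' @param heritability Narrow-sense heritability of the simulated trait,
#'   in (0, 1].
#' @param trait_mean Overall phenotypic mean (the only fixed effect).
#' @param n_genotyped Total number of genotyped animals, split equally over
#'   the last three recent generations. The last genotyped generation carries
#'   no phenotypes and serves as validation set.
#' @param seed Integer random seed; identical scenarios give bit-identical
#'   simulations.
#' @param scale_factor Optional fraction in (0, 1] applied to the historical
#'   census sizes, the historical generation count, the dam count, the marker
#'   and QTL counts, and `n_genotyped`. The sire count, chromosome number and
#'   chromosome length are never scaled, so Ne and genome length (the drivers
#'   of GRM dimensionality) are preserved.
#'
#' @return An object of class `sim_scenario` (a named list).
#' @seealso [desk_scenario()], [simulate_population()]
#' @examples
#' sc <- desk_scenario(n_genotyped = 300, n_snp = 500, n_qtl = 50,
#'                     n_dams_per_gen = 50, hist_size_start = 80,
#'                     hist_size_bottleneck = 20, hist_size_end = 120,
#'                     n_hist_generations = 20, seed = 42)
#' sc$n_snp
#' @export
sim_scenario <- function(n_hist_generations = 1250,
                         hist_size_start = 5000,
                         hist_size_bottleneck = 1000,
                         hist_size_end = 25015,
                         n_recent_generations = 10,
                         n_sires_per_gen = 10,
                         n_dams_per_gen = 1000,
                         n_chromosomes = 10,
                         chrom_length_cM = 100,
                         n_snp = 50000,
                         n_qtl = 3000,
                         mutation_rate = 2.5e-5,
                         qtl_gamma_shape = 0.4,
                         heritability = 0.6,
                         trait_mean = 100,
                         n_genotyped = 6000,
                         seed = 1,
                         scale_factor = 1) {
  stopifnot(scale_factor > 0, scale_factor <= 1)
  if (scale_factor < 1) {
    sc <- function(x) max(1L, as.integer(round(x * scale_factor)))
    n_hist_generations <- sc(n_hist_generations)
    hist_size_start <- sc(hist_size_start)
    hist_size_bottleneck <- sc(hist_size_bottleneck)
    hist_size_end <- sc(hist_size_end)
    n_dams_per_gen <- sc(n_dams_per_gen)
    n_snp <- sc(n_snp)
    n_qtl <- sc(n_qtl)
    n_genotyped <- sc(n_genotyped)
  }
  out <- list(
    n_hist_generations = as.integer(n_hist_generations),
    hist_size_start = as.integer(hist_size_start),
    hist_size_bottleneck = as.integer(hist_size_bottleneck),
    hist_size_end = as.integer(hist_size_end),
    n_recent_generations = as.integer(n_recent_generations),
    n_sires_per_gen = as.integer(n_sires_per_gen),
    n_dams_per_gen = as.integer(n_dams_per_gen),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_cM = as.numeric(chrom_length_cM),
    n_snp = as.integer(n_snp),
    n_qtl = as.integer(n_qtl),
    mutation_rate = as.numeric(mutation_rate),
    qtl_gamma_shape = as.numeric(qtl_gamma_shape),
    heritability = as.numeric(heritability),
    trait_mean = as.numeric(trait_mean),
    n_genotyped = as.integer(n_genotyped),
    seed = as.integer(seed)
  )
  class(out) <- "sim_scenario"
  validate_scenario(out)
  out
}

validate_scenario <- function(x) {
  counts <- c("n_hist_generations", "hist_size_start", "hist_size_bottleneck",
              "hist_size_end", "n_recent_generations", "n_sires_per_gen",
              "n_dams_per_gen", "n_chromosomes", "n_snp", "n_qtl",
              "n_genotyped")
  for (f in counts) {
    if (!is.finite(x[[f]]) || x[[f]] < 1L)
      stop("scenario field `", f, "` must be a positive count", call. = FALSE)
  }
  if (x$hist_size_bottleneck > x$hist_size_start)
    stop("bottleneck size must not exceed the starting size", call. = FALSE)
  if (min(x$hist_size_start, x$hist_size_bottleneck, x$hist_size_end) < 4L)
    stop("scaled historical population too small (< 2 per sex)", call. = FALSE)
  if (x$heritability <= 0 || x$heritability > 1)
    stop("heritability must lie in (0, 1]", call. = FALSE)
  if (x$mutation_rate < 0 || x$mutation_rate >= 1)
    stop("mutation_rate must lie in [0, 1)", call. = FALSE)
  if (x$chrom_length_cM < 0)
    stop("chrom_length_cM must be non-negative", call. = FALSE)
  invisible(x)
}

#' Desk-scale study scenario
#'
#' A reduced profile of the full study design that runs on a single desktop
#' core while preserving the two quantities that govern the eigenvalue profile
#' of the GRM: the recent effective population size (10 sires are kept, so
#' Ne is about 40) and the genome length (10 chromosomes x 100 cM, i.e. 10
#' Morgan). Historical census sizes and the marker panel are reduced tenfold
#' (500 -> 100 -> 2500 over 125 generations, 5000 SNPs, 300 QTL) and the
#' recent generations use 500 dams. `n_genotyped` of 1500/3000/6000 stands in
#' for the full-scale 3000/6000/12,000 scenarios.
#'
#' @param n_genotyped Total genotyped animals over the last three generations.
#' @param heritability Trait heritability.
#' @param seed Random seed.
#' @param ... Further arguments overriding [sim_scenario()] defaults.
#' @return A `sim_scenario`.
#' @export
desk_scenario <- function(n_genotyped = 3000, heritability = 0.6, seed = 1,
                          ...) {
  args <- list(
    n_hist_generations = 125,
    hist_size_start = 500,
    hist_size_bottleneck = 100,
    hist_size_end = 2500,
    n_dams_per_gen = 500,
    n_snp = 5000,
    n_qtl = 300,
    n_genotyped = n_genotyped,
    heritability = heritability,
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_scenario, args)
}

#' @export
print.sim_scenario <- function(x, ...) {
  ne <- effective_size(x$n_sires_per_gen, x$n_dams_per_gen)
  cat("<sim_scenario>\n")
  cat(sprintf("  historical: %d generations, %d -> %d -> %d\n",
              x$n_hist_generations, x$hist_size_start,
              x$hist_size_bottleneck, x$hist_size_end))
  cat(sprintf("  recent: %d generations, %d sires x %d dams (Ne ~ %.1f)\n",
              x$n_recent_generations, x$n_sires_per_gen, x$n_dams_per_gen, ne))
  cat(sprintf("  genome: %d chromosomes x %g cM; %d SNPs, %d QTL, mu = %g\n",
              x$n_chromosomes, x$chrom_length_cM, x$n_snp, x$n_qtl,
              x$mutation_rate))
  cat(sprintf("  trait: h2 = %g, mean = %g; %d genotyped; seed = %d\n",
              x$heritability, x$trait_mean, x$n_genotyped, x$seed))
  invisible(x)
}

#' Effective population size for unequal sex numbers
#'
#' `4 Nm Nf / (Nm + Nf)` for `Nm` breeding males and `Nf` breeding females.
#'
#' @param n_sires,n_dams Breeding males and females per generation.
#' @return Effective population size (numeric).
#' @examples
#' effective_size(10, 1000) # ~ 39.6
#' @export
effective_size <- function(n_sires, n_dams) {
  4 * n_sires * n_dams / (n_sires + n_dams)
}

#' Read or write a scenario as YAML
#'
#' @param path File path.
#' @return `read_scenario()` returns a `sim_scenario`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_scenario, vals)
}

#' @param scenario A `sim_scenario`.
#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "sim_scenario"))
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}
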