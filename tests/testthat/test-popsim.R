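# A parent with haplotypes all-0 / all-1 makes crossovers directly
# observable as switches in the gamete.
switch_count <- function(g) sum(diff(g) != 0)

test_that("meiosis transmits an intact haplotype when no recombination is possible", {
  map <- tibble::tibble(chrom = 1, pos_cM = rep(0, 50))
  set.seed(1)
  parent <- cbind(rbinom(50, 1, 0.5), rbinom(50, 1, 0.5))
  for (i in 1:10) {
    g <- meiosis(parent, map, mutation_rate = 0)
    expect_true(identical(g, parent[, 1]) || identical(g, parent[, 2]))
  }
})

test_that("every transmitted allele is carried by the parent when mutation is off", {
  set.seed(2)
  map <- tibble::tibble(chrom = rep(1:2, each = 40),
                        pos_cM = rep(seq(1, 99, length.out = 40), 2))
  parent <- cbind(rbinom(80, 1, 0.5), rbinom(80, 1, 0.5))
  for (i in 1:25) {
    g <- meiosis(parent, map, mutation_rate = 0)
    expect_true(all(g == parent[, 1] | g == parent[, 2]))
  }
})

test_that("crossover process matches the Poisson/uniform closed form", {
  n_loci <- 400
  map <- tibble::tibble(chrom = 1, pos_cM = seq(0, 100, length.out = n_loci))
  parent <- cbind(rep(0L, n_loci), rep(1L, n_loci))
  set.seed(3)
  switches <- replicate(3000, switch_count(meiosis(parent, map, 0)))
  # expected switches: sum over intervals of P(odd crossover count),
  # (1 - exp(-2d))/2 per interval of length d Morgan
  d <- diff(map$pos_cM) / 100
  expected <- sum((1 - exp(-2 * d)) / 2)
  se <- sd(switches) / sqrt(length(switches))
  expect_lt(abs(mean(switches) - expected), 3 * se)
})

test_that("mutation count per gamete matches n * mu", {
  n_loci <- 2000
  map <- tibble::tibble(chrom = 1, pos_cM = rep(0, n_loci))
  parent <- cbind(rep(0L, n_loci), rep(0L, n_loci))
  mu <- 5e-4
  set.seed(4)
  muts <- replicate(2000, sum(meiosis(parent, map, mu)))
  se <- sd(muts) / sqrt(length(muts))
  expect_lt(abs(mean(muts) - n_loci * mu), 3 * se)
})

test_that("one no-mutation generation only reshuffles founder alleles", {
  sc <- tiny_scenario(n_hist_generations = 1, hist_size_start = 100,
                      hist_size_bottleneck = 100, hist_size_end = 100,
                      mutation_rate = 0, n_snp = 400, n_qtl = 40)
  hist <- simulate_historical(sc, keep_founders = TRUE)
  child <- matrix(as.integer(hist$haps), nrow(hist$haps))
  founder <- matrix(as.integer(hist$founders), nrow(hist$founders))
  for (l in seq_len(nrow(child)))
    expect_true(all(child[l, ] %in% founder[l, ]))
})

test_that("heterozygosity decays through the bottleneck as Wright-Fisher predicts", {
  sc <- tiny_scenario(n_hist_generations = 40, hist_size_start = 100,
                      hist_size_bottleneck = 20, hist_size_end = 300,
                      n_snp = 1200, n_qtl = 50, seed = 8)
  hist <- simulate_historical(sc)
  h_sim <- mean_heterozygosity(hist)
  h_wf <- wf_heterozygosity(grmdim:::hist_sizes(sc), sc$mutation_rate,
                            n_loci = 5000, seed = 99)
  expect_lt(h_sim, 0.48) # clearly below the founder value of 0.5
  expect_lt(abs(h_sim - h_wf), 0.05)
})

test_that("identical scenario and seed give bit-identical populations", {
  p1 <- simulate_population(tiny_scenario(seed = 21))
  p2 <- simulate_population(tiny_scenario(seed = 21))
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$animals, p2$animals)
  expect_identical(p1$architecture$qtl_effects, p2$architecture$qtl_effects)
})

test_that("genotyping and phenotyping follow the generation layout", {
  pop <- tiny_pop()
  a <- pop$animals
  G <- pop$scenario$n_recent_generations
  per_gen <- pop$scenario$n_genotyped / 3
  # equal genotyped share per generation, phenotypes only in the first two
  # genotyped generations, last generation is unphenotyped validation
  counts <- table(a$generation[a$genotyped])
  expect_equal(unname(counts), rep(per_gen, 3), ignore_attr = TRUE)
  expect_setequal(names(counts), as.character((G - 2):G))
  expect_true(all(is.na(a$phenotype[a$generation == G])))
  expect_true(all(!is.na(a$phenotype[a$genotyped & a$generation %in%
                                       c(G - 2, G - 1)])))
  expect_equal(sum(a$role == "validation"), per_gen)
  # pedigree: parents belong to the previous generation
  ped <- a[a$generation > 0, ]
  parent_gen <- a$generation[match(ped$sire, a$id)]
  expect_true(all(parent_gen == ped$generation - 1))
})

test_that("realized heritability and phenotype regression are calibrated", {
  pop <- tiny_pop()
  pop <- assign_phenotypes(pop, 0.9, seed = 5)
  a <- pop$animals[!is.na(pop$animals$phenotype), ]
  # slope of phenotype on TBV is 1 (additive model, independent noise)
  sl <- coef(lm(phenotype ~ tbv, data = a))[2]
  se <- summary(lm(phenotype ~ tbv, data = a))$coefficients[2, 2]
  expect_lt(abs(sl - 1), 3 * se)
  # var(tbv)/var(phenotype) ~ h2 (loose band at this small n)
  expect_lt(abs(var(a$tbv) / var(a$phenotype) - 0.9), 0.1)
  arch <- pop$architecture
  expect_equal(arch$alpha, arch$sigma_e2 / arch$sigma_u2)
})

test_that("degenerate drift triggers the monomorphic-marker guard", {
  sc <- tiny_scenario(n_hist_generations = 60, hist_size_start = 8,
                      hist_size_bottleneck = 4, hist_size_end = 80,
                      n_dams_per_gen = 20, n_sires_per_gen = 4,
                      n_genotyped = 60, n_snp = 300, n_qtl = 30,
                      mutation_rate = 0, seed = 1)
  expect_error(simulate_population(sc), "monomorphic")
})
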