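n_hist_generations: 125
hist_size_start: 500
hist_size_bottleneck: 100
hist_size_end: 2500
n_recent_generations: 10
n_sires_per_gen: 10
n_dams_per_gen: 500
n_chromosomes: 10
chrom_length_cM: 100.0
n_snp: 5000
n_qtl: 300
mutation_rate: 2.5e-05
qtl_gamma_shape: 0.4
heritability: 0.6
trait_mean: 100.0
n_genotyped: 3000
seed: 1
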