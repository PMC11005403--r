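# Shared fixtures: a small genome for fast simulations and the
# T. barophilus-scale genome used where bin-level coordinates matter.

tiny_genome <- function(L = 200000, ori = 50000, name = "tiny") {
  genome_def(L, ori_position = ori, name = name)
}

tbar_genome <- function() {
  genome_def(2010000, ori_position = 1671000, name = "Tbar")
}

# full chain: simulate -> bin (already binned) -> normalize -> smooth
sim_mfa <- function(genome, n = 2000, r = 0.6, f = 0.5, lambda = 10,
                    bin_size = 1000, sigma = 10, seed = 1) {
  p <- sim_params(genome, n_chromosomes = n, replicating_fraction = r,
                  ori_fraction = f, mean_depth_per_copy = lambda,
                  bin_size = bin_size, seed = seed)
  sim <- simulate_population(p)
  gaussian_smooth(normalize_profile(sim$coverage), sigma = sigma)
}

# an mfa_profile built directly from values (bypasses normalization checks)
make_profile <- function(genome, values, bin_size = 1000, sigma = 1) {
  mfakit:::new_mfa_profile(genome, bin_size, values, sigma = sigma)
}

# triangular profile: baseline + height * (1 - 2 d(x, apex)/L) -- the
# genome-spanning tent of the expected-copy-number model
triangle_profile <- function(genome, apex_at, height, baseline = 1,
                             bin_size = 1000) {
  pos <- (seq_len(ceiling(genome$length / bin_size)) - 1) * bin_size
  d <- circular_distance(pos, apex_at, genome$length)
  make_profile(genome, baseline + height * (1 - 2 * d / genome$length),
               bin_size = bin_size)
}
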