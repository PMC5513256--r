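# shared generators for randomized property checks

# random abundance sample with a mix of singletons/doubletons/abundant species
random_counts <- function(s_max = 40, lambda = 3) {
  s <- sample(2:s_max, 1)
  counts <- rpois(s, lambda) + 1L
  names(counts) <- paste0("sp", seq_len(s))
  abundance_sample(counts)
}

# random incidence set over m sub-samples
random_incidence <- function(m = 2, s_max = 40) {
  s <- sample(2:s_max, 1)
  mat <- matrix(rbinom(s * m, 1, runif(1, 0.2, 0.9)), nrow = s)
  mat[rowSums(mat) == 0, sample.int(m, 1)] <- 1L  # every species observed
  rownames(mat) <- paste0("sp", seq_len(s))
  incidence_set(mat)
}

# small lognormal test assemblage
toy_assemblage <- function(S = 20, cv = 0.8, mean_abundance = 100) {
  catch_probabilities(sad_params("lognormal", S, mean_abundance, cv))
}
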