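# programmatic fixtures shared across test files

make_counts <- function(n_taxa = 50, n_samples = 12, seed = 1, sparsity = 0.3,
                        lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples)
  m[matrix(runif(n_taxa * n_samples) < sparsity, n_taxa, n_samples)] <- 0
  # keep every sample non-empty
  for (j in which(colSums(m) == 0)) m[1, j] <- 1
  dimnames(m) <- list(sprintf("OTU%03d", seq_len(n_taxa)),
                      sprintf("S%02d", seq_len(n_samples)))
  otu_table(m, kind = "counts")
}

make_fx <- function(n_samples = 12, n_fn = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_samples * n_fn, mean = 10, sd = 2), n_samples, n_fn)
  dimnames(m) <- list(sprintf("S%02d", seq_len(n_samples)),
                      paste0("F", seq_len(n_fn)))
  function_table(m)
}

make_meta <- function(n_samples = 12, zones = c("AL", "RZ", "TZ")) {
  per <- n_samples / length(zones)
  data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
             zone = rep(zones, each = per),
             replicate = rep(seq_len(per), length(zones)),
             stringsAsFactors = FALSE)
}
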