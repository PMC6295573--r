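# Fixture builders shared across test files. Everything is generated in
# code; no binary data.

# small random raw tensor over the full atlas
tiny_tensor <- function(n_sub = 3, k = 5, seed = 1) {
  set.seed(seed)
  atlas <- dk_atlas()
  feats <- if (k == 5) morph_features() else paste0("f", seq_len(k))
  vals <- array(stats::rnorm(n_sub * 68 * k), dim = c(n_sub, 68, k))
  feature_tensor(vals, sprintf("sub%02d", seq_len(n_sub)), atlas$region,
                 feats)
}

# one network sampled from a template through the real pipeline
sampled_network <- function(template, k = 5, sqrt_t = NULL, id = "s") {
  x <- sample_subject(template, k, sqrt_t)
  tens <- feature_tensor(array(x, c(1, nrow(template), k)), id,
                         rownames(template), paste0("f", seq_len(k)))
  build_network(zscore_features(tens), 1)
}

# lists of NC/AD networks drawn from two templates
sampled_groups <- function(tpl_nc, tpl_ad, n_nc, n_ad, k = 5) {
  sq_nc <- morphnet:::sym_sqrt(tpl_nc)
  sq_ad <- morphnet:::sym_sqrt(tpl_ad)
  list(
    nc = lapply(seq_len(n_nc), function(i)
      sampled_network(tpl_nc, k, sq_nc, paste0("nc", i))),
    ad = lapply(seq_len(n_ad), function(i)
      sampled_network(tpl_ad, k, sq_ad, paste0("ad", i)))
  )
}
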