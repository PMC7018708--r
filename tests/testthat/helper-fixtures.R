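# shared fixtures: parameters and cached basal states (computed once per run)

test_params <- function(...) default_params(...)

.basal_cache <- new.env(parent = emptyenv())
cached_basal <- function(p = test_params()) {
  key <- digest_params(p)
  if (is.null(.basal_cache[[key]])) .basal_cache[[key]] <- basal_state(p)
  .basal_cache[[key]]
}
digest_params <- function(p) paste(signif(unclass(p), 8), collapse = ",")

# a small bimodal log-fluorescence sample with known composition
bimodal_sample <- function(n, w_high = 0.7, mu = c(0, 2.5), sd = c(0.5, 0.6),
                           seed = 1) {
  set.seed(seed)
  hi <- runif(n) < w_high
  ifelse(hi, rnorm(n, mu[2], sd[2]), rnorm(n, mu[1], sd[1]))
}
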