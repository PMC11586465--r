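# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so single tests stay fast.

tiny_atlas <- function(nc = 20, ns = 2, seed = 1) {
  make_atlas(n_cortical_per_hemi = nc, n_subcortical_per_hemi = ns, seed = seed)
}

tiny_cohort <- function(atlas = tiny_atlas(), seed = 1, ...) {
  simulate_cohort(atlas,
                  n_per_group = c("HC" = 25, "FBTCS-" = 15, "FBTCS+" = 20),
                  seed = seed, ...)
}

# A deterministic weighted-gene universe for enrichment tests.
toy_universe <- function(n = 50, seed = 7) {
  withr::with_seed(seed, {
    w <- stats::rnorm(n)
    names(w) <- sprintf("G%06d", seq_len(n))
    w
  })
}

# 95% binomial acceptance band for `n` Bernoulli(p) trials, as counts.
binomial_band <- function(n, p) {
  c(stats::qbinom(0.025, n, p), stats::qbinom(0.975, n, p))
}
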