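# Small fixture builders shared across test files. Everything is generated
# in code; no data files.

# A tiny deterministic panel with known loadings and optional noise scale.
make_panel <- function(n_time = 20, p = 4, K = 2, noise = 1, seed = 123) {
  withr::with_seed(seed, {
    B <- matrix(rnorm(p * K), p, K)
    Fm <- matrix(rnorm(n_time * K), n_time, K)
    U <- noise * matrix(rnorm(n_time * p), n_time, p)
    list(panel = factor_panel(Fm %*% t(B) + U, Fm), B = B, U = U)
  })
}

# A noiseless panel: Y = F B' exactly.
make_noiseless <- function(n_time = 12, p = 3, K = 2, seed = 7) {
  withr::with_seed(seed, {
    B <- matrix(rnorm(p * K), p, K)
    Fm <- matrix(rnorm(n_time * K), n_time, K)
    list(panel = factor_panel(Fm %*% t(B), Fm), B = B)
  })
}
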